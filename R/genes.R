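# Annotated gene collections: data model, TSV/FASTA/GFF3 ingestion and the
# gene-fragment reliability filter.

GENE_TABLE_COLS <- c("gene_id", "genome_id", "taxon", "nt_length", "complete",
                     "product", "go_terms", "prosite_ids")

split_ids <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character())
    unique(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
  })
}

#' Construct a gene collection
#'
#' The in-memory container for annotated genes: a data frame (one row per
#' gene) with character columns `gene_id`, `genome_id`, `taxon`,
#' `product`, `protein_seq`, integer `nt_length` and `aa_length`, logical
#' `complete`, and list columns `go_terms` and `prosite_ids`. When
#' `nt_length` is missing it is derived as `3 * aa_length + 3` (codons
#' plus stop); an absent `complete` value defaults to `FALSE`
#' (conservative). Gene IDs must be unique.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param genome_id,taxon,product Optional per-gene metadata.
#' @param nt_length Nucleotide lengths (may be `NA` where a protein length
#'   or sequence is available).
#' @param complete Logical completeness flags (`NA` treated as `FALSE`).
#' @param go_terms,prosite_ids Lists of character vectors (or
#'   `";"`-separated strings).
#' @param protein_seq Optional protein sequences (`NA` allowed).
#' @return Object of class `gene_collection` (a data frame).
#' @export
gene_collection <- function(gene_id, genome_id = NA, taxon = NA,
                            nt_length = NA, complete = NA, product = NA,
                            go_terms = NULL, prosite_ids = NULL,
                            protein_seq = NA) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1])
  norm_ids <- function(x) {
    if (is.null(x)) return(rep(list(character()), n))
    if (is.character(x)) return(split_ids(x))
    stopifnot(is.list(x), length(x) == n)
    lapply(x, function(v) unique(as.character(v)))
  }
  gc <- data.frame(gene_id = as.character(gene_id),
                   genome_id = rep_len(as.character(genome_id), n),
                   taxon = rep_len(as.character(taxon), n),
                   nt_length = rep_len(as.integer(nt_length), n),
                   complete = rep_len(as.logical(complete), n),
                   product = rep_len(as.character(product), n),
                   protein_seq = rep_len(as.character(protein_seq), n),
                   stringsAsFactors = FALSE)
  gc$go_terms <- norm_ids(go_terms)
  gc$prosite_ids <- norm_ids(prosite_ids)
  gc$aa_length <- ifelse(is.na(gc$protein_seq), NA_integer_,
                         nchar(gc$protein_seq))
  no_len <- is.na(gc$nt_length) & is.na(gc$aa_length)
  if (any(no_len))
    stop("gene(s) without any length information: ",
         paste(utils::head(gc$gene_id[no_len], 5), collapse = ", "))
  gc$nt_length <- ifelse(is.na(gc$nt_length), 3L * gc$aa_length + 3L,
                         gc$nt_length)
  gc$complete[is.na(gc$complete)] <- FALSE
  class(gc) <- c("gene_collection", "data.frame")
  gc
}

#' Load an annotated gene collection from TSV (and optional FASTA)
#'
#' The annotation table must carry the documented header (`gene_id`,
#' `genome_id`, `taxon`, `nt_length`, `complete`, `product`, `go_terms`,
#' `prosite_ids`); multi-valued descriptor cells are `";"`-separated and
#' are deduplicated on load. Protein sequences are joined on `gene_id`
#' from the FASTA (first whitespace-delimited word of each header); genes
#' present only in the FASTA are appended with empty descriptor sets.
#'
#' @param path Annotation TSV file.
#' @param fasta Optional protein FASTA file.
#' @return A [gene_collection()].
#' @export
read_gene_collection <- function(path, fasta = NULL) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(GENE_TABLE_COLS, names(tab))
  if (length(missing))
    stop("annotation table ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         tab$gene_id[duplicated(tab$gene_id)][1])
  seqs <- NULL
  if (!is.null(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
    seqs <- as.character(aa)
    names(seqs) <- sub("[[:space:]].*$", "", names(aa))
    extra <- setdiff(names(seqs), tab$gene_id)
    if (length(extra)) {
      pad <- data.frame(gene_id = extra, genome_id = NA, taxon = NA,
                        nt_length = NA, complete = NA, product = NA,
                        go_terms = "", prosite_ids = "",
                        stringsAsFactors = FALSE)
      tab <- rbind(tab[GENE_TABLE_COLS], pad[GENE_TABLE_COLS])
    }
  }
  nt <- suppressWarnings(as.integer(tab$nt_length))
  comp <- toupper(trimws(tab$complete)) %in% c("TRUE", "T", "1", "YES", "Y")
  comp[!nzchar(trimws(tab$complete)) | is.na(tab$complete)] <- NA
  gc <- gene_collection(
    gene_id = tab$gene_id, genome_id = tab$genome_id, taxon = tab$taxon,
    nt_length = nt, complete = comp, product = tab$product,
    go_terms = tab$go_terms, prosite_ids = tab$prosite_ids,
    protein_seq = if (is.null(seqs)) NA else unname(seqs[tab$gene_id]))
  attr(gc, "provenance") <- list(table = path, fasta = fasta, n = nrow(gc))
  gc
}

#' Write a gene collection back to the annotation TSV dialect
#'
#' @param gc A [gene_collection()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_collection <- function(gc, path) {
  stopifnot(inherits(gc, "gene_collection"))
  out <- data.frame(
    gene_id = gc$gene_id, genome_id = gc$genome_id, taxon = gc$taxon,
    nt_length = gc$nt_length, complete = gc$complete, product = gc$product,
    go_terms = vapply(gc$go_terms, paste, "", collapse = ";"),
    prosite_ids = vapply(gc$prosite_ids, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a minimal gene table from GFF3
#'
#' Limited ingestion: CDS/gene features contribute `ID`, their span length
#' and a `partial` attribute, which is negated into the `complete` flag.
#' Requires the rtracklayer package.
#'
#' @param path GFF3 file.
#' @return A [gene_collection()] with empty descriptor sets.
#' @export
read_genes_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_genes_gff() requires the rtracklayer package")
  g <- rtracklayer::import(path)
  g <- g[as.character(g$type) %in% c("gene", "CDS")]
  partial <- if ("partial" %in% names(S4Vectors::mcols(g)))
    as.character(g$partial) else rep(NA_character_, length(g))
  gene_collection(
    gene_id = as.character(g$ID),
    nt_length = BiocGenerics::width(g),
    complete = ifelse(is.na(partial), NA,
                      !(tolower(partial) %in% c("true", "1", "yes"))))
}

#' @export
print.gene_collection <- function(x, ...) {
  cat("Gene collection: ", nrow(x), " gene(s), ",
      length(unique(x$genome_id[!is.na(x$genome_id)])), " genome(s); ",
      sum(vapply(x$go_terms, length, 1L) > 0), " with GO terms, ",
      sum(vapply(x$prosite_ids, length, 1L) > 0), " with PROSITE IDs, ",
      sum(!is.na(x$protein_seq)), " with protein sequences\n", sep = "")
  invisible(x)
}

#' Gene-fragment reliability filter
#'
#' Removes genes likely to be non-functional fragments: those shorter than
#' `min_nt` nucleotides (default 300, the minimal length required for
#' functionality) and those not annotated as complete. Order is
#' preserved; the filter is idempotent and monotone. Removal counts per
#' reason are attached as attribute `removed` (a gene failing both tests
#' is counted under both reasons; `total` counts it once).
#'
#' @param gc A [gene_collection()].
#' @param min_nt Minimal nucleotide length kept (genes with
#'   `nt_length >= min_nt` survive).
#' @return The filtered `gene_collection`.
#' @export
gene_fragment_filter <- function(gc, min_nt = 300L) {
  stopifnot(inherits(gc, "gene_collection"))
  short <- gc$nt_length < min_nt
  incomplete <- !gc$complete
  keep <- !short & !incomplete
  out <- gc[keep, , drop = FALSE]
  class(out) <- class(gc)
  attr(out, "removed") <- c(short = sum(short), incomplete = sum(incomplete),
                            total = sum(!keep))
  attr(out, "min_nt") <- min_nt
  out
}
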