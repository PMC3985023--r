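# The PPM processor: profile/pattern filtering, hit deduplication,
# descriptor-combination set building, ranking, meta-set condensation and
# the orchestrating ppm() pipeline.

#' Profile filter: match gene GO annotations against a GO-term list
#'
#' One hit per (gene, matching GO term) pair; a gene annotated with k
#' matching terms yields k hits. This pre-dedup redundancy is intentional
#' and mirrors warehouse-style query output.
#'
#' @param gc A [gene_collection()].
#' @param go_profile Character vector of GO IDs (the profile filter list).
#' @return Data frame of hits: `gene_id`, `descriptor_id`, `kind`
#'   (`"profile"`).
#' @export
profile_filter <- function(gc, go_profile) {
  stopifnot(inherits(gc, "gene_collection"))
  descriptor_hits(gc$gene_id, gc$go_terms, go_profile, "profile")
}

#' Pattern filter: match gene PROSITE annotations or scan sequences
#'
#' In `"annotation"` mode the `prosite_ids` fields of the collection are
#' intersected with the pattern list. In `"scan"` mode the annotations are
#' recomputed by running [scan_genes()] over the protein sequences with
#' the supplied parsed patterns; every gene must then carry a sequence.
#'
#' @param gc A [gene_collection()].
#' @param prosite_list Character vector of PROSITE IDs (the pattern filter
#'   list).
#' @param mode `"annotation"` (default) or `"scan"`.
#' @param patterns For scan mode: list of `prosite_pattern` objects whose
#'   `id`s cover `prosite_list`.
#' @return Data frame of hits: `gene_id`, `descriptor_id`, `kind`
#'   (`"pattern"`).
#' @export
pattern_filter <- function(gc, prosite_list,
                           mode = c("annotation", "scan"), patterns = NULL) {
  stopifnot(inherits(gc, "gene_collection"))
  mode <- match.arg(mode)
  if (mode == "annotation")
    return(descriptor_hits(gc$gene_id, gc$prosite_ids, prosite_list, "pattern"))
  missing_seq <- gc$gene_id[is.na(gc$protein_seq)]
  if (length(missing_seq))
    stop("scan mode requires protein sequences; missing for: ",
         paste(utils::head(missing_seq, 10), collapse = ", "),
         if (length(missing_seq) > 10) ", ...")
  if (is.null(patterns)) stop("scan mode requires parsed patterns")
  ids <- vapply(patterns, `[[`, "", "id")
  use <- patterns[ids %in% prosite_list]
  if (length(use) < length(prosite_list))
    warning("no parsed pattern supplied for ",
            length(prosite_list) - length(use), " PROSITE ID(s)")
  sc <- scan_genes(use, gc)
  combos <- sc$by_gene[gc$gene_id[gc$gene_id %in% names(sc$by_gene)]]
  descriptor_hits(names(combos), combos, prosite_list, "pattern")
}

descriptor_hits <- function(gene_ids, anno, filter_ids, kind) {
  n <- vapply(anno, function(x) sum(x %in% filter_ids), 1L)
  hit_desc <- lapply(anno, function(x) sort(x[x %in% filter_ids]))
  data.frame(gene_id = rep(gene_ids, n),
             descriptor_id = unlist(hit_desc, use.names = FALSE),
             kind = if (sum(n)) kind else character(),
             stringsAsFactors = FALSE)
}

#' Deduplicate hits into per-gene descriptor combinations
#'
#' Genes associated with multiple matched descriptors occur multiple times
#' in the hit list; this collapses them to one entry per gene carrying the
#' full sorted combination of matched descriptors of both kinds.
#'
#' @param hits Data frame of hits (rbind of [profile_filter()] /
#'   [pattern_filter()] output).
#' @return Data frame (first-hit order) with `gene_id` and list columns
#'   `go_combo`, `prosite_combo` (sorted unique descriptor IDs).
#' @export
dedupe_hits <- function(hits) {
  genes <- unique(hits$gene_id)
  go <- lapply(genes, function(g)
    sort(unique(hits$descriptor_id[hits$gene_id == g & hits$kind == "profile"])))
  ps <- lapply(genes, function(g)
    sort(unique(hits$descriptor_id[hits$gene_id == g & hits$kind == "pattern"])))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  out$go_combo <- go
  out$prosite_combo <- ps
  out
}

combo_key <- function(go, ps) paste(c(go, ps), collapse = ";")

#' Group deduplicated genes into ranked PPM sets
#'
#' Genes sharing one exact (GO combination, PROSITE combination) pair form
#' a set. Classes partition the sets: *profile* (GO terms only), *pattern*
#' (PROSITE IDs only) and *profile_and_pattern* (both kinds; such genes
#' belong only here, never to the pure classes). Sets are ranked by number
#' of descriptors (descending), then member count (descending), then
#' lexicographic combination, and receive IDs `"Pro i"` / `"Pat i"` /
#' `"PP i"` per class in rank order. A set is flagged *reliable* when it
#' carries at least two descriptors.
#'
#' @param deduped Output of [dedupe_hits()].
#' @return Object of classes `ppm_sets`/`data.frame`: `set_id`,
#'   `ppm_class`, `go_combo`, `prosite_combo` (`";"`-joined), `n_descriptors`,
#'   `n_members`, `reliable` and list column `members`.
#' @export
build_ppm_sets <- function(deduped) {
  if (nrow(deduped) == 0L) {
    out <- data.frame(set_id = character(), ppm_class = character(),
                      go_combo = character(), prosite_combo = character(),
                      n_descriptors = integer(), n_members = integer(),
                      reliable = logical(), stringsAsFactors = FALSE)
    out$members <- list()
    class(out) <- c("ppm_sets", "data.frame")
    return(out)
  }
  keys <- mapply(combo_key, deduped$go_combo, deduped$prosite_combo)
  idx <- split(seq_len(nrow(deduped)), keys)
  rows <- lapply(idx, function(i) {
    go <- deduped$go_combo[[i[1]]]
    ps <- deduped$prosite_combo[[i[1]]]
    cls <- if (length(go) && length(ps)) "profile_and_pattern"
      else if (length(go)) "profile" else "pattern"
    nd <- length(go) + length(ps)
    list(go = go, ps = ps, cls = cls, nd = nd,
         members = deduped$gene_id[i])
  })
  nd <- vapply(rows, `[[`, 1L, "nd")
  nm <- vapply(rows, function(r) length(r$members), 1L)
  key <- names(idx)
  ord <- order(-nd, -nm, key)
  rows <- rows[ord]
  cls <- vapply(rows, `[[`, "", "cls")
  prefix <- c(profile = "Pro", pattern = "Pat", profile_and_pattern = "PP")[cls]
  num <- stats::ave(seq_along(cls), cls, FUN = seq_along)
  out <- data.frame(
    set_id = paste(prefix, num),
    ppm_class = cls,
    go_combo = vapply(rows, function(r) paste(r$go, collapse = ";"), ""),
    prosite_combo = vapply(rows, function(r) paste(r$ps, collapse = ";"), ""),
    n_descriptors = nd[ord],
    n_members = nm[ord],
    reliable = nd[ord] >= 2L,
    stringsAsFactors = FALSE)
  out$members <- lapply(rows, `[[`, "members")
  rownames(out) <- NULL
  class(out) <- c("ppm_sets", "data.frame")
  out
}

set_combo_key <- function(sets) {
  mapply(function(go, ps) combo_key(
    if (nzchar(go)) strsplit(go, ";")[[1]] else character(),
    if (nzchar(ps)) strsplit(ps, ";")[[1]] else character()),
    sets$go_combo, sets$prosite_combo, USE.NAMES = FALSE)
}

#' Condense PPM sets into enzyme-family meta-sets
#'
#' Sets whose descriptor combinations indicate the same enzyme family
#' (e.g. the three pairwise combinations of the subtilase active-site
#' signatures) are merged under the supplied family label. Condensation
#' was a manual curation step in the original workflow, so the mapping is
#' an explicit input and is never guessed: sets without a mapped label
#' pass through as singleton meta-sets labelled by their own combination.
#'
#' @param sets A `ppm_sets` object.
#' @param family_map Data frame with columns `combo` (the `";"`-joined
#'   sorted descriptor combination, GO terms before PROSITE IDs) and
#'   `family` (the enzyme-family label). `NULL` for the identity map.
#' @return Object of classes `ppm_meta_sets`/`data.frame`: `family`,
#'   `n_sets`, `n_members` plus list columns `set_ids` and `members`
#'   (deduplicated union), ordered by total members descending.
#' @export
condense_meta_sets <- function(sets, family_map = NULL) {
  stopifnot(inherits(sets, "ppm_sets"))
  if (nrow(sets) == 0L) {
    out <- data.frame(family = character(), n_sets = integer(),
                      n_members = integer(), stringsAsFactors = FALSE)
    out$set_ids <- list()
    out$members <- list()
    class(out) <- c("ppm_meta_sets", "data.frame")
    return(out)
  }
  keys <- set_combo_key(sets)
  fam <- keys
  if (!is.null(family_map) && nrow(family_map)) {
    stopifnot(all(c("combo", "family") %in% names(family_map)))
    hit <- match(keys, family_map$combo)
    fam[!is.na(hit)] <- family_map$family[hit[!is.na(hit)]]
  }
  idx <- split(seq_len(nrow(sets)), fam)
  rows <- lapply(names(idx), function(f) {
    i <- idx[[f]]
    members <- unique(unlist(sets$members[i], use.names = FALSE))
    list(family = f, set_ids = sets$set_id[i], members = members)
  })
  nm <- vapply(rows, function(r) length(r$members), 1L)
  ord <- order(-nm, vapply(rows, `[[`, "", "family"))
  rows <- rows[ord]
  out <- data.frame(
    family = vapply(rows, `[[`, "", "family"),
    n_sets = vapply(rows, function(r) length(r$set_ids), 1L),
    n_members = vapply(rows, function(r) length(r$members), 1L),
    stringsAsFactors = FALSE)
  out$set_ids <- lapply(rows, `[[`, "set_ids")
  out$members <- lapply(rows, `[[`, "members")
  class(out) <- c("ppm_meta_sets", "data.frame")
  out
}

#' Run the full PPM pipeline
#'
#' Orchestrates the workflow over an annotated gene collection: the
#' independent profile (GO-term) and pattern (PROSITE-ID) filters, the
#' gene-fragment reliability filter, hit deduplication, descriptor-
#' combination set building and ranking, and optional enzyme-family
#' condensation. By default the descriptor filters run before the
#' fragment filter; the two commute on the final gene set, and
#' `fragment_first = TRUE` swaps the order.
#'
#' @param genes A [gene_collection()].
#' @param go_profile Character vector of GO IDs (profile filter list).
#' @param prosite_list Character vector of PROSITE IDs (pattern filter
#'   list).
#' @param mode Pattern filter mode, `"annotation"` or `"scan"`.
#' @param patterns Parsed patterns for scan mode (see [pattern_filter()]).
#' @param min_nt Gene-fragment filter threshold in nucleotides.
#' @param fragment_first Run the fragment filter before the descriptor
#'   filters.
#' @param family_map Optional enzyme-family map for
#'   [condense_meta_sets()].
#' @return Object of class `ppm_result`: list with `sets`, `meta_sets`,
#'   `deduped`, `hits` (post-fragment-filter) and `stages`, a named vector
#'   of stage counts (raw and filtered hits per branch, non-redundant
#'   genes per branch, deduplicated genes, reliable genes).
#' @examples
#' sim <- simulate_annotated_genes(seed = 1)
#' fit <- ppm(sim$collection, sim$go_profile, sim$prosite_list,
#'            family_map = sim$family_map)
#' fit
#' @export
ppm <- function(genes, go_profile, prosite_list,
                mode = c("annotation", "scan"), patterns = NULL,
                min_nt = 300L, fragment_first = FALSE, family_map = NULL) {
  stopifnot(inherits(genes, "gene_collection"))
  mode <- match.arg(mode)
  run_filters <- function(gc) {
    list(profile = profile_filter(gc, go_profile),
         pattern = pattern_filter(gc, prosite_list, mode, patterns))
  }
  if (fragment_first) {
    filtered <- gene_fragment_filter(genes, min_nt)
    raw <- run_filters(filtered)
    kept <- raw
    n_raw_profile <- NA_integer_; n_raw_pattern <- NA_integer_
  } else {
    raw <- run_filters(genes)
    filtered <- gene_fragment_filter(genes, min_nt)
    kept <- lapply(raw, function(h)
      h[h$gene_id %in% filtered$gene_id, , drop = FALSE])
    n_raw_profile <- nrow(raw$profile); n_raw_pattern <- nrow(raw$pattern)
  }
  hits <- rbind(kept$profile, kept$pattern)
  deduped <- dedupe_hits(hits)
  sets <- build_ppm_sets(deduped)
  meta <- condense_meta_sets(sets, family_map)
  stages <- c(
    genes_total = nrow(genes),
    genes_after_fragment_filter = nrow(filtered),
    profile_hits_raw = n_raw_profile,
    profile_hits_filtered = nrow(kept$profile),
    pattern_hits_raw = n_raw_pattern,
    pattern_hits_filtered = nrow(kept$pattern),
    profile_genes_nonredundant = length(unique(kept$profile$gene_id)),
    pattern_genes_nonredundant = length(unique(kept$pattern$gene_id)),
    deduped_genes = nrow(deduped),
    reliable_genes = sum(sets$n_members[sets$reliable]))
  structure(list(sets = sets, meta_sets = meta, deduped = deduped,
                 hits = hits, stages = stages,
                 call = match.call(),
                 params = list(mode = mode, min_nt = min_nt,
                               fragment_first = fragment_first)),
            class = "ppm_result")
}

#' @export
print.ppm_result <- function(x, ...) {
  s <- x$stages
  cat("PPM result\n")
  cat("  genes: ", s["genes_total"], " (", s["genes_after_fragment_filter"],
      " after gene-fragment filter)\n", sep = "")
  cat("  profile branch: ",
      if (!is.na(s["profile_hits_raw"])) paste0(s["profile_hits_raw"], " -> "),
      s["profile_hits_filtered"], " hits -> ",
      s["profile_genes_nonredundant"], " non-redundant genes\n", sep = "")
  cat("  pattern branch: ",
      if (!is.na(s["pattern_hits_raw"])) paste0(s["pattern_hits_raw"], " -> "),
      s["pattern_hits_filtered"], " hits -> ",
      s["pattern_genes_nonredundant"], " non-redundant genes\n", sep = "")
  tab <- table(factor(x$sets$ppm_class,
                      c("profile", "pattern", "profile_and_pattern")))
  cat("  sets: ", tab["profile"], " profile, ", tab["pattern"], " pattern, ",
      tab["profile_and_pattern"], " profile-and-pattern\n", sep = "")
  cat("  reliable genes (>= 2 descriptors): ", s["reliable_genes"], "\n", sep = "")
  if (nrow(x$meta_sets))
    cat("  meta-sets: ", nrow(x$meta_sets), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ppm_result <- function(object, ...) {
  structure(list(stages = object$stages,
                 sets = object$sets[, setdiff(names(object$sets), "members")],
                 meta = object$meta_sets[, c("family", "n_sets", "n_members")]),
            class = "summary.ppm_result")
}

#' @export
print.summary.ppm_result <- function(x, ...) {
  cat("Stage counts:\n")
  print(x$stages)
  cat("\nRanked sets:\n")
  print(x$sets, row.names = FALSE)
  if (nrow(x$meta)) {
    cat("\nMeta-sets:\n")
    print(x$meta, row.names = FALSE)
  }
  invisible(x)
}

#' Write the ranked PPM report
#'
#' Emits `sets.tsv` (one row per set), `members.tsv` (one row per member
#' gene), `stages.tsv` (the stage-count ledger) and `report.json` (a JSON
#' mirror of all three) into `dir`.
#'
#' @param x A `ppm_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_ppm_report <- function(x, dir) {
  stopifnot(inherits(x, "ppm_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets_flat <- x$sets[, setdiff(names(x$sets), "members")]
  members <- if (nrow(x$sets)) data.frame(
    set_id = rep(x$sets$set_id, x$sets$n_members),
    gene_id = unlist(x$sets$members, use.names = FALSE),
    stringsAsFactors = FALSE)
  else data.frame(set_id = character(), gene_id = character())
  stages <- data.frame(stage = names(x$stages), count = unname(x$stages))
  paths <- file.path(dir, c("sets.tsv", "members.tsv", "stages.tsv",
                            "report.json"))
  utils::write.table(sets_flat, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(members, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(stages, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- x$meta_sets
  jsonlite::write_json(
    list(stages = as.list(x$stages),
         sets = sets_flat,
         members = members,
         meta_sets = data.frame(family = meta$family, n_sets = meta$n_sets,
                                n_members = meta$n_members)),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
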