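# PROSITE consensus-pattern engine: parser, renderer, scanner and
# reliability bookkeeping. Coordinates are 1-based inclusive throughout
# (PROSITE convention).

#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter codes, alphabetically ordered. Ambiguity codes
#' (B, Z, X) are not members; see [prosite_match()] for how they are
#' treated during matching.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

new_pattern_element <- function(kind, residues, min_rep, max_rep) {
  structure(list(kind = kind, residues = residues,
                 min_rep = as.integer(min_rep), max_rep = as.integer(max_rep)),
            class = "pattern_element")
}

#' Parse a PROSITE consensus pattern
#'
#' Parses pattern strings in PROSITE syntax: elements separated by `-`,
#' where `x` matches any residue, `[...]` any listed residue, `{...}` any
#' residue *not* listed, and a single letter a fixed residue. A trailing
#' `(n)` or `(n,m)` repeats the preceding element. A leading `<` anchors
#' the match to the N terminus, a trailing `>` to the C terminus; an
#' optional terminal `.` is ignored.
#'
#' @param text Pattern string, e.g. `"H-x(3)-H"` or
#'   `"R-x-D-x(10,11)-[NC]-x-[QK]-x(5)-H-x(2)-[ED]"`.
#' @param id Optional identifier (PROSITE accession or local name) stored
#'   on the result.
#' @return An object of class `prosite_pattern`: a list with `id`,
#'   `elements` (list of element descriptors), `n_anchored`, `c_anchored`
#'   and `source_text`.
#' @seealso [format.prosite_pattern()], [prosite_match()]
#' @examples
#' p <- parse_prosite_pattern("H-x(3)-H", id = "HIS_PAIR")
#' pattern_span(p)
#' @export
parse_prosite_pattern <- function(text, id = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  src <- text
  s <- gsub("[[:space:]]", "", text)
  s <- sub("\\.$", "", s)
  n_anchored <- startsWith(s, "<")
  if (n_anchored) s <- substring(s, 2L)
  # the PROSITE "[...>]" C-terminal-or-residue idiom is not supported
  if (grepl("\\[[^]]*>", s))
    stop("unsupported PROSITE syntax: '>' inside a bracket class in ", sQuote(src))
  c_anchored <- endsWith(s, ">")
  if (c_anchored) s <- substring(s, 1L, nchar(s) - 1L)
  if (!nzchar(s)) stop("empty pattern: ", sQuote(src))
  toks <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(toks)))
    stop("empty element (stray '-') at position ", which(!nzchar(toks))[1],
         " in ", sQuote(src))
  elements <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tok <- toks[i]
    m <- regmatches(tok, regexec(
      "^(x|[A-Za-z]|\\[[A-Za-z]+\\]|\\{[A-Za-z]+\\})(\\(([0-9]+)(,([0-9]+))?\\))?$",
      tok))[[1]]
    if (length(m) == 0L)
      stop("cannot parse pattern element ", sQuote(tok), " at position ", i,
           " in ", sQuote(src))
    body <- m[2]
    min_rep <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    max_rep <- if (nzchar(m[6])) as.integer(m[6]) else min_rep
    if (min_rep < 1L || max_rep < min_rep)
      stop("invalid repeat range in element ", sQuote(tok), " at position ", i,
           " in ", sQuote(src))
    if (body == "x") {
      elements[[i]] <- new_pattern_element("any", character(), min_rep, max_rep)
    } else if (startsWith(body, "[")) {
      res <- strsplit(toupper(gsub("\\[|\\]", "", body)), "")[[1]]
      check_residues(res, tok, i, src)
      elements[[i]] <- new_pattern_element("any_of", unique(res), min_rep, max_rep)
    } else if (startsWith(body, "{")) {
      res <- strsplit(toupper(gsub("\\{|\\}", "", body)), "")[[1]]
      check_residues(res, tok, i, src)
      elements[[i]] <- new_pattern_element("none_of", unique(res), min_rep, max_rep)
    } else {
      res <- toupper(body)
      check_residues(res, tok, i, src)
      elements[[i]] <- new_pattern_element("fixed", res, min_rep, max_rep)
    }
  }
  structure(list(id = if (is.null(id)) NA_character_ else id,
                 elements = elements,
                 n_anchored = n_anchored, c_anchored = c_anchored,
                 source_text = src),
            class = "prosite_pattern")
}

check_residues <- function(res, tok, i, src) {
  bad <- setdiff(res, AA_ALPHABET)
  if (length(bad))
    stop("non-amino-acid letter ", paste(sQuote(bad), collapse = ", "),
         " in element ", sQuote(tok), " at position ", i, " in ", sQuote(src))
  invisible(TRUE)
}

#' Minimal and maximal span of a pattern
#'
#' @param pattern A `prosite_pattern`.
#' @return Integer vector `c(min, max)`: the shortest and longest
#'   subsequence length the pattern can match (sums of element repeat
#'   bounds).
#' @export
pattern_span <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  c(min = sum(vapply(pattern$elements, `[[`, 1L, "min_rep")),
    max = sum(vapply(pattern$elements, `[[`, 1L, "max_rep")))
}

#' Render a pattern back to canonical PROSITE text
#'
#' Parsing the returned string yields an element list equal to the input's.
#'
#' @param x A `prosite_pattern`.
#' @param ... Ignored.
#' @return Canonical pattern string (no terminal `.`).
#' @export
format.prosite_pattern <- function(x, ...) {
  fmt1 <- function(e) {
    body <- switch(e$kind,
      any = "x",
      fixed = e$residues,
      any_of = paste0("[", paste(e$residues, collapse = ""), "]"),
      none_of = paste0("{", paste(e$residues, collapse = ""), "}"))
    if (e$min_rep == 1L && e$max_rep == 1L) body
    else if (e$min_rep == e$max_rep) paste0(body, "(", e$min_rep, ")")
    else paste0(body, "(", e$min_rep, ",", e$max_rep, ")")
  }
  out <- paste(vapply(x$elements, fmt1, character(1)), collapse = "-")
  if (x$n_anchored) out <- paste0("<", out)
  if (x$c_anchored) out <- paste0(out, ">")
  out
}

#' @export
print.prosite_pattern <- function(x, ...) {
  sp <- pattern_span(x)
  cat("PROSITE pattern", if (!is.na(x$id)) x$id else "",
      "\n  ", format(x), "\n  elements: ", length(x$elements),
      ", span: ", sp[1], if (sp[1] != sp[2]) paste0("-", sp[2]) else "",
      " aa\n", sep = "")
  invisible(x)
}

# Per-position eligibility of each sequence character for one element.
# Ambiguity codes (X, B, Z) and any non-standard letter satisfy only "x";
# they never satisfy fixed, any-of or none-of elements (conservative,
# anti-false-positive).
element_eligible <- function(e, chars) {
  switch(e$kind,
    any = chars %in% c(AA_ALPHABET, "X", "B", "Z"),
    fixed = chars == e$residues,
    any_of = chars %in% e$residues,
    none_of = chars %in% AA_ALPHABET & !(chars %in% e$residues))
}

#' Match a consensus pattern against a protein sequence
#'
#' Reports every distinct span `(start, end)` for which some assignment of
#' per-element repeat lengths matches the sequence contiguously; nested and
#' overlapping spans are all reported. Anchors restrict `start = 1` /
#' `end = nchar(sequence)`.
#'
#' @param pattern A `prosite_pattern` (or a pattern string, parsed on the
#'   fly).
#' @param sequence Protein sequence string. Ambiguity codes X/B/Z are
#'   matched only by `x` elements.
#' @param gene_id Optional identifier recorded in the result.
#' @return Data frame with columns `gene_id`, `pattern_id`, `start`, `end`
#'   (1-based inclusive), ordered by `start` then `end`; zero rows when
#'   there is no match.
#' @examples
#' prosite_match("H-x(3)-H", "AHAAAHA")
#' @export
prosite_match <- function(pattern, sequence, gene_id = NA_character_) {
  if (is.character(pattern)) pattern <- parse_prosite_pattern(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  empty <- data.frame(gene_id = character(), pattern_id = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L || pattern_span(pattern)[1] > n) return(empty)
  k <- length(pattern$elements)
  ok <- matrix(FALSE, nrow = n, ncol = k)
  for (j in seq_len(k)) ok[, j] <- element_eligible(pattern$elements[[j]], chars)
  starts <- if (pattern$n_anchored) 1L else seq_len(n)
  out_start <- integer(); out_end <- integer()
  for (st in starts) {
    pos <- st  # candidate positions of the next unmatched residue
    for (j in seq_len(k)) {
      e <- pattern$elements[[j]]
      nxt <- integer()
      for (p in pos) {
        # longest run of eligible residues starting at p, capped at max_rep
        r <- 0L
        while (r < e$max_rep && p + r <= n && ok[p + r, j]) r <- r + 1L
        if (r >= e$min_rep) nxt <- c(nxt, p + seq.int(e$min_rep, r))
      }
      pos <- unique(nxt)
      if (length(pos) == 0L) break
    }
    ends <- pos - 1L
    if (pattern$c_anchored) ends <- ends[ends == n]
    if (length(ends)) {
      out_start <- c(out_start, rep.int(st, length(ends)))
      out_end <- c(out_end, sort(ends))
    }
  }
  if (length(out_start) == 0L) return(empty)
  data.frame(gene_id = gene_id, pattern_id = pattern$id,
             start = out_start, end = out_end, stringsAsFactors = FALSE)
}

#' Scan a gene collection with a list of consensus patterns
#'
#' A gene is flagged for a pattern when [prosite_match()] finds at least
#' one span in its protein sequence. Genes lacking a sequence are skipped
#' with a warning.
#'
#' @param patterns List of `prosite_pattern` objects (or pattern strings;
#'   strings are parsed with their names as IDs).
#' @param genes A [gene_collection()] whose records carry `protein_seq`,
#'   or a named character vector of protein sequences.
#' @return Object of class `prosite_scan`: list with `matches` (data frame
#'   `gene_id`, `pattern_id`, `start`, `end`, `matched`), `by_gene` (named
#'   list mapping gene id to the character vector of matched pattern IDs)
#'   and `skipped` (ids of genes without sequences).
#' @export
scan_genes <- function(patterns, genes) {
  if (inherits(genes, "gene_collection")) {
    seqs <- genes$protein_seq
    names(seqs) <- genes$gene_id
  } else {
    seqs <- unlist(genes)
  }
  if (is.character(patterns)) patterns <- as.list(patterns)
  patterns <- lapply(seq_along(patterns), function(i) {
    p <- patterns[[i]]
    if (is.character(p))
      p <- parse_prosite_pattern(p, id = names(patterns)[i])
    p
  })
  skipped <- names(seqs)[is.na(seqs)]
  if (length(skipped))
    warning(length(skipped), " gene(s) lack a protein sequence and were skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ...")
  live <- names(seqs)[!is.na(seqs)]
  res <- vector("list", length(live) * length(patterns))
  idx <- 0L
  for (g in live) {
    for (p in patterns) {
      m <- prosite_match(p, seqs[[g]], gene_id = g)
      if (nrow(m)) {
        idx <- idx + 1L
        res[[idx]] <- m
      }
    }
  }
  matches <- if (idx) do.call(rbind, res[seq_len(idx)]) else
    data.frame(gene_id = character(), pattern_id = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  matches$matched <- substring(seqs[matches$gene_id], matches$start, matches$end)
  by_gene <- lapply(split(matches$pattern_id, matches$gene_id), function(x)
    sort(unique(x)))
  structure(list(matches = matches, by_gene = by_gene, skipped = skipped),
            class = "prosite_scan")
}

#' @export
print.prosite_scan <- function(x, ...) {
  cat("PROSITE scan: ", nrow(x$matches), " match(es) in ",
      length(x$by_gene), " gene(s)",
      if (length(x$skipped)) paste0(" (", length(x$skipped), " skipped)"),
      "\n", sep = "")
  invisible(x)
}

#' Write pattern matches to TSV
#'
#' @param scan A `prosite_scan` result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(scan$matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read PROSITE-release-style pattern entries
#'
#' Parses a minimal subset of the PROSITE flat-file dialect: `ID` lines
#' (`ID NAME; PATTERN.`), `AC` accession lines (`AC PS00042;`), `DE`
#' description lines, multi-line `PA` pattern lines (concatenated; the
#' terminal `.` closes the pattern) and `//` entry terminators. E.C.
#' cross-references embedded in `DE` lines as `(EC 1.1.1.1)` are extracted
#' for descriptor mapping.
#'
#' @param path File path, or a character vector of lines.
#' @return Data frame with columns `ac`, `name`, `de`, `pattern_text` and a
#'   list column `ec` (character vector of referenced E.C. numbers), plus a
#'   list column `pattern` of parsed `prosite_pattern` objects.
#' @export
read_prosite_dat <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  recs <- list()
  cur <- list(ac = NA_character_, name = NA_character_, de = "", pa = "")
  flush <- function(cur, recs) {
    if (!is.na(cur$ac) || nzchar(cur$pa)) recs[[length(recs) + 1L]] <- cur
    recs
  }
  for (ln in lines) {
    tag <- substring(ln, 1L, 2L)
    body <- sub("^..[[:space:]]+", "", ln)
    if (tag == "//") {
      recs <- flush(cur, recs)
      cur <- list(ac = NA_character_, name = NA_character_, de = "", pa = "")
    } else if (tag == "ID") {
      cur$name <- sub(";.*$", "", body)
    } else if (tag == "AC") {
      cur$ac <- sub(";.*$", "", body)
    } else if (tag == "DE") {
      cur$de <- paste0(cur$de, if (nzchar(cur$de)) " ", body)
    } else if (tag == "PA") {
      cur$pa <- paste0(cur$pa, body)
    }
  }
  recs <- flush(cur, recs)
  if (length(recs) == 0L)
    return(data.frame(ac = character(), name = character(), de = character(),
                      pattern_text = character(), stringsAsFactors = FALSE))
  out <- data.frame(
    ac = vapply(recs, `[[`, "", "ac"),
    name = vapply(recs, `[[`, "", "name"),
    de = vapply(recs, `[[`, "", "de"),
    pattern_text = vapply(recs, `[[`, "", "pa"),
    stringsAsFactors = FALSE)
  out$ec <- lapply(out$de, function(d) {
    m <- regmatches(d, gregexpr("\\(EC ([0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9n*]+)\\)", d))[[1]]
    sub("^\\(EC (.*)\\)$", "\\1", m)
  })
  out$pattern <- Map(function(txt, ac) {
    if (nzchar(txt)) parse_prosite_pattern(txt, id = ac) else NULL
  }, out$pattern_text, out$ac)
  out
}

#' Evaluate pattern reliability against labelled truth
#'
#' Computes per-pattern confusion statistics over a scanned collection:
#' `hits` is the number of flagged genes; `tp_pct` the percentage of
#' flagged genes that carry the pattern's function label; `fp_pct` its
#' complement (`tp_pct + fp_pct = 100` over reported hits); `fn` the count
#' of labelled genes the pattern missed and
#' `fn_pct = 100 * fn / (fn + true positives)`.
#'
#' @param scan A `prosite_scan` result (or its `by_gene` list).
#' @param truth Named list: gene id to character vector of true function
#'   labels. Must cover all genes of the collection (unlabelled genes get
#'   `character(0)`).
#' @param pattern_to_label Named character vector mapping pattern IDs to
#'   the function label each one signals.
#' @return Data frame `pattern_id`, `hits`, `tp_pct`, `fp_pct`, `fn`,
#'   `fn_pct`. Rates are `NA` when no gene is flagged (undefined, not 0).
#' @export
evaluate_reliability <- function(scan, truth, pattern_to_label) {
  by_gene <- if (inherits(scan, "prosite_scan")) scan$by_gene else scan
  flagged <- list()
  for (g in names(by_gene))
    for (p in by_gene[[g]]) flagged[[p]] <- c(flagged[[p]], g)
  pats <- names(pattern_to_label)
  res <- lapply(pats, function(p) {
    lab <- pattern_to_label[[p]]
    fl <- unique(flagged[[p]])
    labelled <- names(truth)[vapply(truth, function(x) lab %in% x, logical(1))]
    tp <- sum(fl %in% labelled)
    fn <- sum(!(labelled %in% fl))
    if (length(fl) == 0L) {
      tp_pct <- NA_real_; fp_pct <- NA_real_
    } else {
      tp_pct <- 100 * tp / length(fl); fp_pct <- 100 - tp_pct
    }
    fn_pct <- if (fn + tp == 0L) NA_real_ else 100 * fn / (fn + tp)
    data.frame(pattern_id = p, hits = length(fl), tp_pct = tp_pct,
               fp_pct = fp_pct, fn = fn, fn_pct = fn_pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
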