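# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the match oracle enumerates every repeat
# assignment exhaustively, the distance oracle tallies columns one by one.

# Exhaustive pattern-match oracle: every (start, repeat-assignment) pair is
# checked residue by residue.
oracle_match <- function(pattern, sequence) {
  empty <- data.frame(start = integer(), end = integer())
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n == 0L) return(empty)
  elems <- pattern$elements
  elig1 <- function(e, ch) switch(e$kind,
    any = ch %in% c(AA_ALPHABET, "X", "B", "Z"),
    fixed = ch == e$residues,
    any_of = ch %in% e$residues,
    none_of = (ch %in% AA_ALPHABET) && !(ch %in% e$residues))
  elig <- matrix(FALSE, n, length(elems))
  for (j in seq_along(elems))
    elig[, j] <- vapply(chars, elig1, e = elems[[j]], logical(1))
  grid <- as.matrix(expand.grid(lapply(elems, function(e) e$min_rep:e$max_rep)))
  starts <- if (pattern$n_anchored) 1L else seq_len(n)
  out <- list()
  for (st in starts) {
    for (gi in seq_len(nrow(grid))) {
      r <- grid[gi, ]
      en <- st + sum(r) - 1L
      if (en > n) next
      if (pattern$c_anchored && en != n) next
      pos <- st
      good <- TRUE
      for (j in seq_along(elems)) {
        if (r[j] > 0L && !all(elig[pos:(pos + r[j] - 1L), j])) {
          good <- FALSE
          break
        }
        pos <- pos + r[j]
      }
      if (good) out[[length(out) + 1L]] <- c(st, en)
    }
  }
  if (length(out) == 0L) return(empty)
  spans <- unique(do.call(rbind, out))
  spans <- spans[order(spans[, 1], spans[, 2]), , drop = FALSE]
  data.frame(start = spans[, 1], end = spans[, 2])
}

# Random pattern generator for property tests (<= 6 elements, repeats <= 4).
random_pattern <- function() {
  k <- sample(1:6, 1)
  toks <- vapply(seq_len(k), function(i) {
    kind <- sample(c("any", "fixed", "any_of", "none_of"), 1,
                   prob = c(0.35, 0.3, 0.2, 0.15))
    body <- switch(kind,
      any = "x",
      fixed = sample(AA_ALPHABET, 1),
      any_of = paste0("[", paste(sample(AA_ALPHABET, sample(2:4, 1)),
                                 collapse = ""), "]"),
      none_of = paste0("{", paste(sample(AA_ALPHABET, sample(10:16, 1)),
                                  collapse = ""), "}"))
    mn <- sample(1:3, 1)
    mx <- min(mn + sample(0:2, 1, prob = c(0.6, 0.3, 0.1)), 4L)
    if (mn == 1L && mx == 1L) body
    else if (mn == mx) paste0(body, "(", mn, ")")
    else paste0(body, "(", mn, ",", mx, ")")
  }, character(1))
  txt <- paste(toks, collapse = "-")
  if (stats::runif(1) < 0.15) txt <- paste0("<", txt)
  if (stats::runif(1) < 0.15) txt <- paste0(txt, ">")
  parse_prosite_pattern(txt, id = "RND")
}

random_protein <- function(max_len = 40L, ambiguity = TRUE) {
  pool <- if (ambiguity) c(AA_ALPHABET, "X", "B", "Z") else AA_ALPHABET
  paste(sample(pool, sample(0:max_len, 1), replace = TRUE,
               prob = c(rep(1, 20), if (ambiguity) rep(0.2, 3))),
        collapse = "")
}

# Independent per-column p-distance tally under complete deletion.
oracle_p_distance <- function(aln) {
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  drop <- logical(ncol(mat))
  for (j in seq_len(ncol(mat)))
    drop[j] <- any(mat[, j] %in% c("-", ".", "?", "X", "B", "Z", "*"))
  mat <- mat[, !drop, drop = FALSE]
  n <- nrow(mat)
  p <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diff <- 0L
    for (s in seq_len(ncol(mat))) if (mat[i, s] != mat[j, s]) diff <- diff + 1L
    p[i, j] <- diff / ncol(mat)
  }
  list(p = p, n_sites = ncol(mat))
}

# Random additive tree instance: a random topology with positive branch
# lengths and its exact path-length matrix.
random_additive_instance <- function(n_leaves) {
  tr <- ape::rtree(n_leaves)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# Small annotated collection with randomized lengths/completeness for
# filter-property tests.
random_gene_fixture <- function(n = 40L) {
  go_pool <- sprintf("GO:%07d", 1:5)
  ps_pool <- sprintf("PS%05d", 1:5)
  gene_collection(
    gene_id = sprintf("r%03d", seq_len(n)),
    nt_length = sample(c(90:500, 2000), n, replace = TRUE),
    complete = sample(c(TRUE, TRUE, FALSE), n, replace = TRUE),
    go_terms = lapply(seq_len(n), function(i)
      sample(go_pool, sample(0:2, 1))),
    prosite_ids = lapply(seq_len(n), function(i)
      sample(ps_pool, sample(0:2, 1))))
}
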