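# Derivation of relaxed consensus patterns from an archetype's functional
# residues and a set of aligned candidate sequences, plus minimal
# relaxation of existing patterns.

#' Specify functional positions for pattern derivation
#'
#' @param index 1-based residue numbers in the archetype (strictly
#'   increasing).
#' @param role One of `"metal_binding"`, `"catalytic"`, `"structural"` per
#'   position.
#' @param residue Archetype residue letter per position.
#' @return Data frame with the three columns, validated.
#' @export
functional_positions <- function(index, role, residue) {
  role <- match.arg(role, c("metal_binding", "catalytic", "structural"),
                    several.ok = TRUE)
  stopifnot(length(index) == length(role), length(index) == length(residue),
            all(diff(index) > 0), all(residue %in% AA_ALPHABET))
  data.frame(index = as.integer(index), role = role, residue = residue,
             stringsAsFactors = FALSE)
}

# archetype residue index -> alignment column
archetype_columns <- function(archetype_row) {
  chars <- strsplit(archetype_row, "")[[1]]
  which(chars != "-" & chars != ".")
}

#' Derive consensus patterns from functional residues and an alignment
#'
#' For each segment (a pair of archetype residue indices bracketing
#' functional positions), a PROSITE-syntax pattern is derived: at each
#' functional position the union of residues observed across the archetype
#' and all candidates becomes a fixed element (singleton) or an any-of
#' class (archetype residue first, then additions in observation order);
#' positions whose observed class exceeds `breadth` distinct residues are
#' judged uninformative and degrade to `x`, merging into the surrounding
#' spacer. Spacers between retained positions record the per-sequence
#' count of non-gap residues and are rendered `x(n)` when constant or
#' `x(n,m)` with the observed minimum/maximum.
#'
#' @param alignment Named character vector of aligned sequences (equal
#'   lengths, `-` for gaps), or an `AAStringSet`. Must contain
#'   `archetype_id` and all `candidate_ids`.
#' @param archetype_id Name of the archetype sequence.
#' @param positions Data frame from [functional_positions()].
#' @param segments List of integer pairs `c(first, last)` of archetype
#'   indices; every functional position must fall inside exactly one
#'   segment.
#' @param candidate_ids Names of candidate sequences (default: all
#'   non-archetype rows of the alignment; may be empty for the
#'   single-sequence case).
#' @param breadth Maximal number of distinct residues a position may show
#'   before degrading to `x` (default 4).
#' @return List of objects of class `derived_pattern` (one per segment),
#'   each with `pattern` (a `prosite_pattern`), `per_position_classes`
#'   (observed residue sets by archetype index, with roles),
#'   `gap_ranges` (observed spacer length ranges) and `verification`
#'   (logical vector: does the pattern match each input sequence).
#' @export
derive_patterns <- function(alignment, archetype_id, positions, segments,
                            candidate_ids = NULL, breadth = 4L) {
  aln <- as_alignment(alignment)
  if (!archetype_id %in% names(aln))
    stop("archetype ", sQuote(archetype_id), " missing from alignment")
  if (is.null(candidate_ids)) candidate_ids <- setdiff(names(aln), archetype_id)
  missing <- setdiff(candidate_ids, names(aln))
  if (length(missing))
    stop("candidate(s) missing from alignment: ",
         paste(missing, collapse = ", "))
  cols <- archetype_columns(aln[[archetype_id]])
  mat <- do.call(rbind, strsplit(unlist(aln[c(archetype_id, candidate_ids)]), ""))
  rownames(mat) <- c(archetype_id, candidate_ids)
  seg_of <- vapply(positions$index, function(i) {
    inside <- which(vapply(segments, function(s) i >= s[1] && i <= s[2],
                           logical(1)))
    if (length(inside) != 1L)
      stop("functional position ", i, " lies in ", length(inside),
           " segments; expected exactly one")
    inside
  }, 1L)
  lapply(seq_along(segments), function(si) {
    pos <- positions[seg_of == si, , drop = FALSE]
    if (nrow(pos) == 0L)
      stop("segment ", si, " contains no functional position")
    derive_one_segment(pos, cols, mat, archetype_id, candidate_ids, breadth)
  })
}

derive_one_segment <- function(pos, cols, mat, archetype_id, candidate_ids,
                               breadth) {
  seqs <- rownames(mat)
  observe <- function(idx) {
    if (idx > length(cols))
      stop("archetype index ", idx, " beyond the archetype sequence")
    col <- cols[idx]
    res <- mat[, col]
    if (all(res %in% c("-", ".")))
      stop("functional position ", idx, " falls in an all-gap alignment column")
    if (any(res %in% c("-", ".")))
      stop("gap at functional position ", idx, " in sequence(s) ",
           paste(seqs[res %in% c("-", ".")], collapse = ", "))
    res
  }
  observed <- lapply(pos$index, observe)
  # archetype residue first, then additions in candidate observation order
  classes <- lapply(observed, function(r) unique(r))
  keep <- vapply(classes, length, 1L) <= breadth
  if (any(!keep))
    message("position(s) ", paste(pos$index[!keep], collapse = ", "),
            " degraded to 'x' (more than ", breadth, " residues observed)")
  kept_idx <- pos$index[keep]
  kept_classes <- classes[keep]
  if (length(kept_idx) == 0L)
    stop("all functional positions of the segment degraded to 'x'")
  spacer_range <- function(i_from, i_to) {
    # non-gap residues strictly between the two archetype-index columns
    c_from <- cols[i_from]; c_to <- cols[i_to]
    if (c_to <= c_from + 1L) return(c(0L, 0L))
    block <- mat[, (c_from + 1L):(c_to - 1L), drop = FALSE]
    lens <- apply(block, 1L, function(r) sum(r != "-" & r != "."))
    c(min(lens), max(lens))
  }
  elems <- character(); gap_ranges <- list()
  for (k in seq_along(kept_idx)) {
    if (k > 1L) {
      rng <- spacer_range(kept_idx[k - 1L], kept_idx[k])
      gap_ranges[[length(gap_ranges) + 1L]] <- rng
      if (rng[2] > 0L)
        elems <- c(elems, if (rng[1] == rng[2]) {
          if (rng[1] == 1L) "x" else paste0("x(", rng[1], ")")
        } else paste0("x(", rng[1], ",", rng[2], ")"))
    }
    cl <- kept_classes[[k]]
    elems <- c(elems,
               if (length(cl) == 1L) cl
               else paste0("[", paste(cl, collapse = ""), "]"))
  }
  pattern <- parse_prosite_pattern(paste(elems, collapse = "-"))
  ungapped <- vapply(seqs, function(s)
    paste(mat[s, ][!(mat[s, ] %in% c("-", "."))], collapse = ""), "")
  verification <- vapply(ungapped, function(s)
    nrow(prosite_match(pattern, s)) > 0L, logical(1))
  if (!all(verification))
    warning("derived pattern ", format(pattern), " fails to match: ",
            paste(seqs[!verification], collapse = ", "))
  ppc <- kept_classes
  names(ppc) <- kept_idx
  structure(list(pattern = pattern, per_position_classes = ppc,
                 roles = stats::setNames(pos$role, pos$index),
                 gap_ranges = gap_ranges, verification = verification),
            class = "derived_pattern")
}

#' @export
print.derived_pattern <- function(x, ...) {
  cat("Derived consensus pattern: ", format(x$pattern), "\n",
      "  matches ", sum(x$verification), "/", length(x$verification),
      " input sequence(s)\n", sep = "")
  invisible(x)
}

#' Relax a consensus pattern to admit observed exceptions
#'
#' Minimally widens a pattern so that everything it matched still matches
#' and the supplied exceptions match too: observed residues are appended
#' to fixed/any-of elements (a fixed element becomes an any-of class) and
#' observed spacer lengths widen the repeat range of the targeted element
#' just enough to include them.
#'
#' @param pattern A `prosite_pattern`.
#' @param exceptions Data frame with columns `element` (1-based element
#'   index), and one of `residue` (a letter, for residue exceptions) or
#'   `spacer` (an observed repeat length, for spacer exceptions); the
#'   unused column holds `NA`.
#' @return The relaxed `prosite_pattern` (a superset matcher).
#' @export
relax_pattern <- function(pattern, exceptions) {
  stopifnot(inherits(pattern, "prosite_pattern"),
            all(c("element") %in% names(exceptions)))
  for (i in seq_len(nrow(exceptions))) {
    j <- exceptions$element[i]
    if (is.na(j) || j < 1L || j > length(pattern$elements))
      stop("exception targets element ", j, " but the pattern has ",
           length(pattern$elements),
           " elements (anchors cannot take exceptions)")
    e <- pattern$elements[[j]]
    res <- if ("residue" %in% names(exceptions)) exceptions$residue[i] else NA
    spc <- if ("spacer" %in% names(exceptions)) exceptions$spacer[i] else NA
    if (!is.na(res)) {
      if (!(res %in% AA_ALPHABET)) stop("invalid residue ", sQuote(res))
      if (e$kind == "fixed") {
        e$kind <- "any_of"; e$residues <- unique(c(e$residues, res))
      } else if (e$kind == "any_of") {
        e$residues <- unique(c(e$residues, res))
      } else if (e$kind == "none_of") {
        e$residues <- setdiff(e$residues, res)
      }  # "any" already admits everything
    }
    if (!is.na(spc)) {
      spc <- as.integer(spc)
      if (spc < 1L) stop("spacer length must be >= 1")
      e$min_rep <- min(e$min_rep, spc)
      e$max_rep <- max(e$max_rep, spc)
    }
    pattern$elements[[j]] <- e
  }
  pattern$source_text <- format(pattern)
  pattern
}
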