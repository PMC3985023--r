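# Within-set phylogenetics: Poisson-corrected protein distances under
# complete deletion, neighbor-joining trees, branch-length clustering and
# representative selection.

# Accept a named character vector, a list, or a Biostrings AAStringSet;
# return a named character vector of equal-length aligned sequences.
as_alignment <- function(x) {
  if (inherits(x, "AAStringSet") || inherits(x, "XStringSet"))
    x <- as.character(x)
  if (is.list(x)) x <- unlist(x)
  stopifnot(is.character(x), length(x) >= 1L, !is.null(names(x)))
  if (length(unique(nchar(x))) != 1L)
    stop("aligned sequences must have equal length")
  x
}

#' Read / write an aligned FASTA file
#'
#' Thin wrappers over Biostrings returning (taking) a named character
#' vector, the alignment representation used throughout this package.
#'
#' @param path FASTA file.
#' @return `read_alignment()`: named character vector of aligned
#'   sequences.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("[[:space:]].*$", "", names(aa))
  out
}

#' @rdname read_alignment
#' @param aln Named character vector of sequences.
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(aln), path)
  invisible(path)
}

MISSING_CHARS <- c("-", ".", "?", "X", "B", "Z", "*")

#' Poisson-corrected pairwise distances under complete deletion
#'
#' Every alignment column containing a gap or a missing/ambiguous symbol
#' (`-`, `.`, `?`, `X`, `B`, `Z`, `*`) in *any* sequence is removed
#' globally (complete deletion). On the retained sites, `p` is the
#' proportion of differing positions per pair and the corrected distance
#' is `d = -ln(1 - p)`, in units of amino-acid substitutions per site.
#'
#' @param alignment Named character vector of aligned protein sequences
#'   (or an `AAStringSet`); at least two sequences of equal aligned
#'   length.
#' @return Object of class `ppm_dist`: list with `labels`, symmetric
#'   matrices `p` and `d` (zero diagonal) and `n_sites` (columns retained).
#' @export
pairwise_distances <- function(alignment) {
  aln <- as_alignment(alignment)
  if (length(aln) < 2L) stop("need at least two sequences")
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(mat) <- names(aln)
  bad <- apply(mat, 2L, function(col) any(col %in% MISSING_CHARS))
  mat <- mat[, !bad, drop = FALSE]
  n_sites <- ncol(mat)
  if (n_sites == 0L)
    stop("no alignment columns remain after complete deletion")
  n <- nrow(mat)
  p <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pij <- sum(mat[i, ] != mat[j, ]) / n_sites
      p[i, j] <- p[j, i] <- pij
    }
  }
  if (any(p >= 1))
    stop("pairwise proportion of differences reached 1; ",
         "Poisson correction -ln(1-p) is undefined")
  d <- -log(1 - p)
  structure(list(labels = names(aln), p = p, d = d, n_sites = n_sites),
            class = "ppm_dist")
}

#' @export
print.ppm_dist <- function(x, ...) {
  cat("Poisson-corrected distance matrix: ", length(x$labels),
      " sequences, ", x$n_sites, " sites after complete deletion\n", sep = "")
  print(round(x$d, 4))
  invisible(x)
}

#' Neighbor-joining tree from a corrected distance matrix
#'
#' Standard neighbor-joining agglomeration (via \pkg{ape}) on the
#' Poisson-corrected distances. Negative branch lengths are clamped to 0;
#' the total clamped deficit is recorded in attribute `clamped`.
#'
#' @param dm A `ppm_dist` from [pairwise_distances()] (or a symmetric
#'   numeric matrix / `dist`).
#' @return An unrooted `phylo` tree with branch lengths in substitutions
#'   per site.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "ppm_dist")) stats::as.dist(dm$d)
    else stats::as.dist(dm)
  if (attr(d, "Size") < 3L)
    stop("neighbor joining needs at least 3 sequences; ",
         "with 2 the tree is a single branch of length d (trivial output)")
  tree <- ape::nj(d)
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- deficit
  tree
}

#' Cut long branches and extract phylogenetic clusters
#'
#' Removes every branch longer than `threshold`; the leaves of each
#' remaining connected component form one cluster. The default threshold
#' of 0.1 substitutions per site matches the scale at which closely
#' related within-family groups separate in practice; it is a tunable, not
#' an estimate.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param threshold Branch-length cut in substitutions per site.
#' @return List of character vectors (the partition of the leaf labels),
#'   ordered by each cluster's smallest member label; blocks are disjoint,
#'   covering and non-empty.
#' @export
extract_clusters <- function(tree, threshold = 0.1) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  parent <- seq_len(n_nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  keep <- tree$edge.length <= threshold
  for (k in which(keep)) {
    a <- find(tree$edge[k, 1]); b <- find(tree$edge[k, 2])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n_tip), find, 1L)
  blocks <- split(tree$tip.label, comp)
  blocks <- lapply(blocks, sort)
  blocks <- blocks[order(vapply(blocks, `[`, "", 1L))]
  names(blocks) <- NULL
  blocks
}

FUNCTIONAL_SIDE_CHAINS <- c("C", "D", "E", "H", "K", "N", "Q", "R",
                            "S", "T", "W", "Y")

#' Select a cluster's representative sequence
#'
#' Cascade mirroring manual curation practice: (1) *containment* — if a
#' unique member's aligned residues cover every other member (at every
#' column where another member has a residue, it has the same residue),
#' that member is chosen; (2) otherwise the member with the highest
#' external similarity score (e.g. from a BLASTp run supplied as a table)
#' if scores are given; (3) otherwise the member whose sequence offers the
#' most functional side chains (C, D, E, H, K, N, Q, R, S, T, W, Y —
#' hydrogen bonding, metal complexation). Remaining ties break
#' lexicographically on the gene ID.
#'
#' @param cluster Character vector of member gene IDs (non-empty).
#' @param alignment Named character vector of aligned sequences covering
#'   the cluster.
#' @param external_scores Optional named numeric vector of similarity
#'   scores.
#' @return The chosen gene ID, with attribute `criterion` naming the
#'   winning rule (`"containment"`, `"similarity"` or `"side_chains"`).
#' @export
select_representative <- function(cluster, alignment, external_scores = NULL) {
  if (length(cluster) == 0L) stop("empty cluster")
  aln <- as_alignment(alignment)
  missing <- setdiff(cluster, names(aln))
  if (length(missing))
    stop("cluster member(s) missing from alignment: ",
         paste(missing, collapse = ", "))
  if (length(cluster) == 1L)
    return(structure(cluster, criterion = "singleton"))
  mat <- do.call(rbind, strsplit(aln[cluster], ""))
  rownames(mat) <- cluster
  is_res <- matrix(!(mat %in% c("-", ".")), nrow = nrow(mat),
                   dimnames = dimnames(mat))
  contains <- function(a, b) {
    cols <- which(is_res[b, ])
    all(mat[a, cols] == mat[b, cols])
  }
  covers_all <- vapply(cluster, function(a)
    all(vapply(setdiff(cluster, a), function(b) contains(a, b), logical(1))),
    logical(1))
  if (sum(covers_all) == 1L)
    return(structure(cluster[covers_all], criterion = "containment"))
  pool <- cluster
  if (!is.null(external_scores)) {
    sc <- external_scores[pool]
    if (any(!is.na(sc))) {
      best <- pool[!is.na(sc) & sc == max(sc, na.rm = TRUE)]
      if (length(best) == 1L)
        return(structure(best, criterion = "similarity"))
      pool <- best
    }
  }
  counts <- vapply(pool, function(g)
    sum(strsplit(gsub("-|\\.", "", aln[[g]]), "")[[1]] %in%
          FUNCTIONAL_SIDE_CHAINS), 1L)
  best <- sort(pool[counts == max(counts)])
  structure(best[1], criterion = "side_chains")
}

#' Cluster a PPM set phylogenetically and pick representatives
#'
#' Convenience wrapper running [pairwise_distances()],
#' [neighbor_joining()], [extract_clusters()] and
#' [select_representative()] over one alignment.
#'
#' @param alignment Named character vector of aligned member sequences.
#' @param threshold Branch-length cut (see [extract_clusters()]).
#' @param external_scores Optional similarity scores (see
#'   [select_representative()]).
#' @return List with `distances`, `tree`, `clusters` and `representatives`
#'   (data frame: cluster, size, representative, criterion).
#' @export
cluster_set <- function(alignment, threshold = 0.1, external_scores = NULL) {
  aln <- as_alignment(alignment)
  dm <- pairwise_distances(aln)
  if (length(aln) == 2L) {
    clusters <- if (dm$d[1, 2] <= threshold) list(sort(names(aln)))
      else list(names(aln)[1], names(aln)[2])
    tree <- NULL
  } else {
    tree <- neighbor_joining(dm)
    clusters <- extract_clusters(tree, threshold)
  }
  reps <- lapply(clusters, select_representative, alignment = aln,
                 external_scores = external_scores)
  structure(list(
    distances = dm, tree = tree, clusters = clusters,
    representatives = data.frame(
      cluster = seq_along(clusters),
      size = vapply(clusters, length, 1L),
      representative = vapply(reps, as.character, ""),
      criterion = vapply(reps, attr, "", "criterion"),
      stringsAsFactors = FALSE)),
    class = "ppm_clustering")
}

#' @export
print.ppm_clustering <- function(x, ...) {
  cat("Phylogenetic clustering: ", length(x$clusters), " cluster(s) over ",
      length(x$distances$labels), " sequences\n", sep = "")
  print(x$representatives, row.names = FALSE)
  invisible(x)
}
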