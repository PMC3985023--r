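# Poisson-corrected distances, neighbor joining, branch-cut clustering and
# representative selection.

test_that("Poisson correction matches the closed form on hand-built pairs", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAACCCCC")
  dm <- pairwise_distances(aln)
  expect_equal(dm$n_sites, 10L)
  expect_equal(dm$p["a", "b"], 0.5)
  expect_equal(dm$d["a", "b"], log(2))
  expect_equal(diag(dm$d), c(a = 0, b = 0))
  # identical sequences
  dm0 <- pairwise_distances(c(x = "MKWC", y = "MKWC"))
  expect_equal(dm0$d["x", "y"], 0)
})

test_that("complete deletion removes every column with a gap or ambiguity", {
  aln <- c(a = "AC-DEXF", b = "ACCD-AF", c = "ACCDEAF")
  dm <- pairwise_distances(aln)
  # columns 3 (gap in a), 5 (gap in b) and 6 (X in a) are gone
  expect_equal(dm$n_sites, 4L)
  set.seed(71)
  for (i in 1:10) {
    n <- sample(3:6, 1); len <- sample(20:60, 1)
    pool <- c(AA_ALPHABET, "-", "X")
    aln <- vapply(seq_len(n), function(j)
      paste(sample(pool, len, replace = TRUE, prob = c(rep(1, 20), .5, .2)),
            collapse = ""), "")
    names(aln) <- paste0("s", seq_len(n))
    got <- try(pairwise_distances(aln), silent = TRUE)
    want <- oracle_p_distance(aln)
    if (inherits(got, "try-error")) {
      expect_true(want$n_sites == 0 || any(want$p >= 1))
    } else {
      expect_equal(got$p, want$p)
      expect_equal(got$n_sites, want$n_sites)
      # corrected distances dominate p, equality only at zero
      expect_true(all(got$d >= got$p))
      expect_true(all((got$d == got$p) == (got$p == 0)))
    }
  }
})

test_that("degenerate alignments are rejected", {
  expect_error(pairwise_distances(c(a = "A-", b = "-A")), "no alignment columns")
  expect_error(pairwise_distances(c(a = "AAAA", b = "CCCC")),
               "undefined")
  expect_error(pairwise_distances(c(a = "AA")), "two sequences")
  expect_error(neighbor_joining(matrix(c(0, 1, 1, 0), 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
})

test_that("three taxa solve the unique star topology", {
  D <- matrix(c(0, .3, .4,
                .3, 0, .5,
                .4, .5, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(D)
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd[letters[1:3], letters[1:3]], D, tolerance = 1e-12)
  # closed-form branch lengths
  lens <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(lens[1], (.3 + .4 - .5) / 2)
  expect_equal(lens[2], (.3 + .5 - .4) / 2)
  expect_equal(lens[3], (.4 + .5 - .3) / 2)
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(5)
  for (i in 1:20) {
    inst <- random_additive_instance(sample(4:8, 1))
    tr <- neighbor_joining(inst$D)
    pd <- ape::cophenetic.phylo(tr)
    expect_lt(max(abs(pd[rownames(inst$D), colnames(inst$D)] - inst$D)), 1e-9)
  }
})

test_that("label permutation yields an isomorphic tree", {
  set.seed(8)
  inst <- random_additive_instance(6)
  perm <- sample(rownames(inst$D))
  t1 <- neighbor_joining(inst$D)
  t2 <- neighbor_joining(inst$D[perm, perm])
  pd1 <- ape::cophenetic.phylo(t1)
  pd2 <- ape::cophenetic.phylo(t2)
  expect_equal(pd2[rownames(pd1), colnames(pd1)], pd1, tolerance = 1e-12)
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
})

test_that("branch-cut clustering returns a partition of the leaves", {
  cl <- simulate_cluster_alignment(c(5, 4, 3, 2), seed = 2)
  tree <- neighbor_joining(pairwise_distances(cl$alignment))
  blocks <- extract_clusters(tree, 0.1)
  expect_length(blocks, 4)
  expect_setequal(unlist(blocks), names(cl$alignment))
  expect_equal(anyDuplicated(unlist(blocks)), 0)
  got <- lapply(blocks, sort)
  want <- lapply(cl$partition, sort)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))
  # threshold above every branch: one cluster
  expect_length(extract_clusters(tree, Inf), 1)
  # threshold 0 on generic distances: singletons
  expect_length(extract_clusters(tree, 0), length(cl$alignment))
})

test_that("representative selection follows the three-rule cascade", {
  # containment: the long sequence covers all shorter ones
  aln <- c(long = "MKTAYIAKQR", mid = "--TAYIAKQ-", short = "---AYIAK--")
  rep1 <- select_representative(names(aln), aln)
  expect_equal(as.character(rep1), "long")
  expect_equal(attr(rep1, "criterion"), "containment")
  # singleton cluster
  rep0 <- select_representative("mid", aln)
  expect_equal(as.character(rep0), "mid")
  # external similarity decides when containment is ambiguous
  aln2 <- c(a = "AKTA", b = "ACTA", c = "AGTA")
  rep2 <- select_representative(names(aln2), aln2,
                                external_scores = c(a = 10, b = 30, c = 20))
  expect_equal(as.character(rep2), "b")
  expect_equal(attr(rep2, "criterion"), "similarity")
  # functional side chains decide otherwise; equal length and score
  aln3 <- c(a = "AAAAGGGGLL", b = "DDEEHHKKAA")
  rep3 <- select_representative(names(aln3), aln3)
  expect_equal(as.character(rep3), "b")
  expect_equal(attr(rep3, "criterion"), "side_chains")
  # lexicographic tie-break on identical side-chain counts
  aln4 <- c(z = "DDEE", y = "DDEE")
  expect_equal(as.character(select_representative(names(aln4), aln4)), "y")
  expect_error(select_representative(character(), aln), "empty cluster")
})

test_that("cluster_set wires distances, tree, clusters and representatives", {
  cl <- simulate_cluster_alignment(c(4, 3), len = 150, seed = 6)
  res <- cluster_set(cl$alignment)
  expect_length(res$clusters, 2)
  expect_equal(nrow(res$representatives), 2)
  expect_true(all(res$representatives$representative %in%
                    names(cl$alignment)))
  # Newick round trip preserves the topology
  nwk <- tempfile(fileext = ".nwk")
  ape::write.tree(res$tree, nwk)
  back <- ape::read.tree(nwk)
  expect_equal(ape::dist.topo(ape::unroot(res$tree), ape::unroot(back))[1], 0)
})
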