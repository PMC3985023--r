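# PROSITE pattern grammar, the scanner and reliability bookkeeping.

test_that("pattern grammar parses elements, repeats and anchors", {
  p <- parse_prosite_pattern("H-x(3)-H")
  expect_length(p$elements, 3)
  expect_equal(vapply(p$elements, `[[`, "", "kind"), c("fixed", "any", "fixed"))
  expect_equal(p$elements[[2]]$min_rep, 3L)
  expect_equal(unname(pattern_span(p)), c(5L, 5L))

  q <- parse_prosite_pattern("R-x-D-x(10,11)-[NC]-x-[QK]-x(5)-H-x(2)-[ED]")
  expect_length(q$elements, 11)
  expect_equal(unname(pattern_span(q)), c(25L, 26L))
  expect_equal(q$elements[[5]]$residues, c("N", "C"))

  a <- parse_prosite_pattern("<A-{PG}(2)-C>.")
  expect_true(a$n_anchored)
  expect_true(a$c_anchored)
  expect_equal(a$elements[[2]]$kind, "none_of")
})

test_that("malformed patterns raise positioned parse errors", {
  expect_error(parse_prosite_pattern("A-["), "position 2")
  expect_error(parse_prosite_pattern("A-J-C"), "non-amino-acid")
  expect_error(parse_prosite_pattern("A-x(3,2)"), "repeat range")
  expect_error(parse_prosite_pattern("A--C"), "empty element")
  expect_error(parse_prosite_pattern("A-[DE>]"), "unsupported")
  expect_error(parse_prosite_pattern(""), "empty pattern")
})

test_that("rendering a parsed pattern reparses to an equal element list", {
  set.seed(42)
  for (i in 1:50) {
    p <- random_pattern()
    q <- parse_prosite_pattern(format(p))
    expect_equal(q$elements, p$elements)
    expect_equal(q$n_anchored, p$n_anchored)
    expect_equal(q$c_anchored, p$c_anchored)
  }
})

test_that("matching reports all distinct spans with 1-based coordinates", {
  m <- prosite_match("H-x(3)-H", "AHAAAHA")
  expect_equal(m[, c("start", "end")], data.frame(start = 2L, end = 6L))
  expect_equal(nrow(prosite_match("H-x(3)-H", "HAAH")), 0)
  # flexible spacer: only one repeat assignment can complete the match
  seq26 <- paste0("RAD", strrep("A", 11), "NAQ", strrep("A", 5), "HAAE")
  m2 <- prosite_match("R-x-D-x(10,11)-[NC]-x-[QK]-x(5)-H-x(2)-[ED]", seq26)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$start, 1L)
  expect_equal(m2$end, nchar(seq26))
  # overlapping spans are all reported
  m3 <- prosite_match("H-x(1,3)-H", "HAHAH")
  expect_equal(nrow(m3), 3)
})

test_that("ambiguity codes satisfy only the wildcard element", {
  expect_equal(nrow(prosite_match("H-x-H", "HXH")), 1)
  expect_equal(nrow(prosite_match("H-A-H", "HXH")), 0)
  expect_equal(nrow(prosite_match("[HW]-A", "BA")), 0)
  expect_equal(nrow(prosite_match("{P}-A", "XA")), 0)
})

test_that("matcher agrees with the exhaustive enumeration oracle", {
  set.seed(7)
  for (i in 1:200) {
    p <- random_pattern()
    s <- random_protein()
    got <- prosite_match(p, s)[, c("start", "end")]
    want <- oracle_match(p, s)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                 label = paste("pattern", format(p), "on", s))
  }
})

test_that("anchored matches are a subset of unanchored matches", {
  set.seed(13)
  for (i in 1:50) {
    p <- random_pattern()
    body <- sub("^<", "", sub(">$", "", format(p)))
    s <- random_protein()
    free <- prosite_match(parse_prosite_pattern(body), s)
    anch <- prosite_match(parse_prosite_pattern(paste0("<", body, ">")), s)
    key <- function(m) paste(m$start, m$end)
    expect_true(all(key(anch) %in% key(free)))
  }
})

test_that("a minimal greedy realization of a pattern matches it", {
  set.seed(99)
  for (i in 1:50) {
    p <- random_pattern()
    s <- paste(unlist(lapply(p$elements, function(e) {
      ch <- switch(e$kind, any = "A", fixed = e$residues,
                   any_of = e$residues[1],
                   none_of = setdiff(AA_ALPHABET, e$residues)[1])
      rep(ch, e$min_rep)
    })), collapse = "")
    expect_gt(nrow(prosite_match(p, s)), 0)
  }
})

test_that("scanning flags exactly the genes carrying planted sites", {
  pats <- list(parse_prosite_pattern("H-x(3)-H", id = "LOC01"),
               parse_prosite_pattern("C-[DE](2)-W", id = "LOC02"))
  sim <- simulate_planted_proteins(pats, n_genes = 40, n_planted = 8,
                                   seed = 5)
  sc <- scan_genes(pats, sim$proteins)
  expect_setequal(names(sc$by_gene), sim$planted)
  # the recorded spans are reproduced by the matcher
  for (i in seq_len(nrow(sim$truth))) {
    row <- sim$truth[i, ]
    m <- sc$matches[sc$matches$gene_id == row$gene_id &
                      sc$matches$pattern_id == row$pattern_id, ]
    expect_true(any(m$start == row$start & m$end == row$end))
  }
  expect_length(scan_genes(list(), sim$proteins)$by_gene, 0)
})

test_that("a gene matching two patterns reports both IDs", {
  pats <- list(parse_prosite_pattern("H-x(3)-H", id = "A1"),
               parse_prosite_pattern("W-W", id = "A2"))
  sc <- scan_genes(pats, c(g1 = "HAAAHCWWC"))
  expect_setequal(sc$by_gene$g1, c("A1", "A2"))
})

test_that("genes without sequences are skipped with a warning in scan mode", {
  gc <- gene_collection(gene_id = c("a", "b"),
                        protein_seq = c("HAAAH", NA), nt_length = c(NA, 60))
  expect_warning(sc <- scan_genes(list(parse_prosite_pattern("H-x(3)-H",
                                                             id = "Z")), gc),
                 "skipped")
  expect_equal(sc$skipped, "b")
  expect_equal(names(sc$by_gene), "a")
})

test_that("reliability rates follow the confusion-matrix definitions", {
  by_gene <- list(g1 = "P1", g2 = "P1", g3 = "P1", g4 = "P1")
  truth <- c(lapply(sprintf("g%d", 1:10), function(i) "lab"),
             list(character()))
  names(truth) <- c(sprintf("g%d", 1:10), "g99")
  # all flagged genes carry the label
  r <- evaluate_reliability(by_gene, truth, c(P1 = "lab"))
  expect_equal(r$tp_pct, 100)
  expect_equal(r$fp_pct, 0)
  # 10 labelled genes, 1 flagged true positive, 9 missed -> FN% = 90
  r2 <- evaluate_reliability(list(g1 = "P1"), truth, c(P1 = "lab"))
  expect_equal(r2$fn, 9L)
  expect_equal(r2$fn_pct, 90)
  # mixed flags: independent tally
  by3 <- list(g1 = "P1", g2 = "P1", g99 = "P1")
  r3 <- evaluate_reliability(by3, truth, c(P1 = "lab"))
  expect_equal(r3$hits, 3L)
  expect_equal(r3$tp_pct, 100 * 2 / 3)
  expect_equal(r3$fp_pct + r3$tp_pct, 100)
  expect_equal(r3$fn, 8L)
  expect_equal(r3$fn_pct, 100 * 8 / 10)
  # zero flagged genes: undefined rates, not zero
  r0 <- evaluate_reliability(list(), truth, c(P1 = "lab"))
  expect_true(is.na(r0$tp_pct))
  expect_true(is.na(r0$fp_pct))
})

test_that("PROSITE release entries parse with multi-line PA and EC refs", {
  dat <- c("ID   TEST_1; PATTERN.",
           "AC   PS00001;",
           "DE   Synthetic signature (EC 1.1.1.1) (EC 1.1.1.2).",
           "PA   H-x(3)-",
           "PA   H.",
           "//")
  ps <- read_prosite_dat(dat)
  expect_equal(ps$ac, "PS00001")
  expect_equal(ps$pattern_text, "H-x(3)-H.")
  expect_equal(ps$ec[[1]], c("1.1.1.1", "1.1.1.2"))
  expect_equal(format(ps$pattern[[1]]), "H-x(3)-H")
  links <- prosite_ec_links(ps)
  expect_equal(links$ps, c("PS00001", "PS00001"))
})
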