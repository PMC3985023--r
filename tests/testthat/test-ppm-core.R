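# The PPM processor: filters, deduplication, set building, ranking and
# meta-set condensation, exercised mostly on the worked-example replay.

demo_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_annotated_genes(seed = 1)
      cache <<- list(sim = sim,
                     fit = ppm(sim$collection, sim$go_profile,
                               sim$prosite_list,
                               family_map = sim$family_map))
    }
    cache
  }
})

test_that("profile and pattern filters emit one hit per gene-descriptor pair", {
  gc <- gene_collection(
    gene_id = c("a", "b", "c"),
    nt_length = c(500, 500, 500), complete = TRUE,
    go_terms = list(c("GO:0004665", "GO:0008977"), "GO:0004665", character()),
    prosite_ids = list(character(), c("PS00136", "PS00137"), "PS99999"))
  hp <- profile_filter(gc, c("GO:0004665", "GO:0008977"))
  expect_equal(nrow(hp), 3)
  expect_equal(sum(hp$gene_id == "a"), 2)
  hs <- pattern_filter(gc, c("PS00136", "PS00137"))
  expect_equal(nrow(hs), 2)
  expect_true(all(hs$gene_id == "b"))
  expect_equal(nrow(profile_filter(gc, character())), 0)
})

test_that("deduplication carries the full sorted combination per gene", {
  hits <- data.frame(
    gene_id = c("a", "a", "a", "b"),
    descriptor_id = c("GO:0000002", "GO:0000001", "PS00001", "GO:0000001"),
    kind = c("profile", "profile", "pattern", "profile"),
    stringsAsFactors = FALSE)
  dd <- dedupe_hits(hits)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$go_combo[[1]], c("GO:0000001", "GO:0000002"))
  expect_equal(dd$prosite_combo[[1]], "PS00001")
  # oracle: brute-force grouping by gene gives identical combos
  for (g in dd$gene_id) {
    expect_setequal(
      c(dd$go_combo[[which(dd$gene_id == g)]],
        dd$prosite_combo[[which(dd$gene_id == g)]]),
      unique(hits$descriptor_id[hits$gene_id == g]))
  }
})

test_that("the worked-example replay reproduces the published set structure", {
  d <- demo_fit()
  s <- d$fit$stages
  man <- d$sim$manifest
  expect_equal(unname(s["profile_hits_raw"]), man$profile_pairs_raw)
  expect_equal(unname(s["profile_hits_filtered"]), man$profile_pairs_filtered)
  expect_equal(unname(s["profile_genes_nonredundant"]), 106L)
  expect_equal(unname(s["pattern_genes_nonredundant"]), 142L)
  expect_equal(unname(s["deduped_genes"]), 234L)
  tab <- table(d$fit$sets$ppm_class)
  expect_equal(unname(tab[["profile"]]), 5L)
  expect_equal(unname(tab[["pattern"]]), 17L)
  expect_equal(unname(tab[["profile_and_pattern"]]), 1L)
  pp <- d$fit$sets[d$fit$sets$ppm_class == "profile_and_pattern", ]
  expect_equal(pp$go_combo, "GO:0008839")
  expect_equal(pp$prosite_combo, "PS01298")
  expect_equal(pp$n_members, 14L)
  expect_equal(unname(s["reliable_genes"]), 117L)
})

test_that("set classes partition the deduplicated genes", {
  d <- demo_fit()
  members <- unlist(d$fit$sets$members)
  expect_equal(length(members), nrow(d$fit$deduped))
  expect_equal(anyDuplicated(members), 0)
  # class assignment matches the combo contents
  for (i in seq_len(nrow(d$fit$sets))) {
    row <- d$fit$sets[i, ]
    has_go <- nzchar(row$go_combo); has_ps <- nzchar(row$prosite_combo)
    want <- if (has_go && has_ps) "profile_and_pattern"
      else if (has_go) "profile" else "pattern"
    expect_equal(row$ppm_class, want)
  }
})

test_that("ranking is sound and deterministic under input permutation", {
  d <- demo_fit()
  nd <- d$fit$sets$n_descriptors
  expect_true(all(diff(nd) <= 0))
  # ties broken by member count within equal descriptor counts
  for (k in unique(nd)) {
    nm <- d$fit$sets$n_members[nd == k]
    expect_true(all(diff(nm) <= 0))
  }
  # permuting the input leaves sets and ranking unchanged
  gc <- d$sim$collection
  perm <- gc[rev(seq_len(nrow(gc))), ]
  class(perm) <- class(gc)
  fit2 <- ppm(perm, d$sim$go_profile, d$sim$prosite_list)
  expect_equal(fit2$sets$go_combo, d$fit$sets$go_combo)
  expect_equal(fit2$sets$prosite_combo, d$fit$sets$prosite_combo)
  expect_equal(fit2$sets$n_members, d$fit$sets$n_members)
  expect_equal(lapply(fit2$sets$members, sort),
               lapply(d$fit$sets$members, sort))
})

test_that("set identifiers are assigned per class in rank order", {
  d <- demo_fit()
  sets <- d$fit$sets
  for (cls in c("profile", "pattern", "profile_and_pattern")) {
    ids <- sets$set_id[sets$ppm_class == cls]
    prefix <- c(profile = "Pro", pattern = "Pat",
                profile_and_pattern = "PP")[[cls]]
    expect_equal(ids, paste(prefix, seq_along(ids)))
  }
})

test_that("meta-set condensation merges families and passes unmapped through", {
  d <- demo_fit()
  multi <- d$fit$sets[d$fit$sets$reliable, ]
  class(multi) <- class(d$fit$sets)
  expect_equal(nrow(multi), 12L)
  meta <- condense_meta_sets(multi, d$sim$family_map)
  expect_equal(nrow(meta), 9L)
  subt <- meta[meta$family == "Subtilisin [3.4.21.*]", ]
  expect_equal(subt$n_sets, 3L)
  expect_equal(subt$n_members, 7L)  # disjoint 2 + 4 + 1
  # identity map: one meta-set per set
  ident <- condense_meta_sets(multi, NULL)
  expect_equal(nrow(ident), nrow(multi))
  expect_equal(sort(ident$n_members), sort(multi$n_members))
})

test_that("the ranked report reconciles across TSV and JSON", {
  d <- demo_fit()
  dir <- tempfile()
  write_ppm_report(d$fit, dir)
  sets <- read.delim(file.path(dir, "sets.tsv"), stringsAsFactors = FALSE)
  members <- read.delim(file.path(dir, "members.tsv"), stringsAsFactors = FALSE)
  stages <- read.delim(file.path(dir, "stages.tsv"), stringsAsFactors = FALSE)
  js <- jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
  expect_equal(nrow(sets), nrow(d$fit$sets))
  expect_equal(nrow(members), sum(sets$n_members))
  expect_equal(sum(sets$n_members[sets$reliable]), 117L)
  expect_equal(js$sets$set_id, sets$set_id)
  expect_equal(nrow(js$members), nrow(members))
  expect_equal(js$stages$deduped_genes,
               stages$count[stages$stage == "deduped_genes"])
})

test_that("empty inputs yield empty but well-formed results", {
  gc <- gene_collection("solo", nt_length = 400, complete = TRUE,
                        go_terms = list("GO:0000001"),
                        prosite_ids = list("PS00001"))
  fit0 <- ppm(gc, character(), character())
  expect_equal(nrow(fit0$sets), 0)
  expect_equal(nrow(fit0$meta_sets), 0)
  dir <- tempfile()
  write_ppm_report(fit0, dir)
  expect_equal(nrow(read.delim(file.path(dir, "sets.tsv"))), 0)
  # a single gene with one GO and one PROSITE ID: one reliable PP set
  fit1 <- ppm(gc, "GO:0000001", "PS00001")
  expect_equal(fit1$sets$ppm_class, "profile_and_pattern")
  expect_true(fit1$sets$reliable)
  expect_equal(fit1$sets$set_id, "PP 1")
})

test_that("scan mode reproduces annotation mode on a planted fixture", {
  pats <- list(parse_prosite_pattern("H-x(3)-H", id = "PS11111"),
               parse_prosite_pattern("C-[DE](2)-W", id = "PS22222"))
  sim <- simulate_planted_proteins(pats, n_genes = 30, n_planted = 6, seed = 9)
  anno <- lapply(names(sim$proteins), function(g)
    sort(unique(sim$truth$pattern_id[sim$truth$gene_id == g])))
  gc <- gene_collection(gene_id = names(sim$proteins),
                        complete = TRUE, nt_length = NA,
                        protein_seq = sim$proteins, prosite_ids = anno)
  ids <- c("PS11111", "PS22222")
  h_scan <- pattern_filter(gc, ids, mode = "scan", patterns = pats)
  h_anno <- pattern_filter(gc, ids, mode = "annotation")
  key <- function(h) sort(paste(h$gene_id, h$descriptor_id))
  expect_identical(key(h_scan), key(h_anno))
  # scan mode without sequences fails loudly
  gc2 <- gc; gc2$protein_seq[1] <- NA
  class(gc2) <- class(gc)
  expect_error(pattern_filter(gc2, ids, mode = "scan", patterns = pats),
               "missing")
})

test_that("descriptor-first and fragment-first orders agree on the final sets", {
  d <- demo_fit()
  fit2 <- ppm(d$sim$collection, d$sim$go_profile, d$sim$prosite_list,
              fragment_first = TRUE)
  expect_equal(fit2$sets$go_combo, d$fit$sets$go_combo)
  expect_equal(fit2$sets$n_members, d$fit$sets$n_members)
  expect_equal(unname(fit2$stages["deduped_genes"]), 234L)
})
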