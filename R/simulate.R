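# Seeded generators for every test surface: descriptor-combination gene
# collections replaying the published worked example, a full POI-to-
# descriptor translation study, planted pattern occurrences in random
# proteins, planted-cluster alignments and the gamma-carbonic-anhydrase
# derivation scenario. All outputs are synthetic; manifests record the
# ground truth the generator planted.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' The worked-example descriptor-combination plan
#'
#' The published demonstration run of the PPM workflow grouped 234
#' surviving genes into 5 profile sets, 17 pattern sets and one
#' profile-and-pattern set; this table encodes those descriptor
#' combinations, member counts and (for the 12 multi-descriptor sets) the
#' enzyme-family labels used in manual condensation.
#'
#' @return Data frame with columns `go_combo`, `prosite_combo`
#'   (`";"`-joined), `n_members` and `family` (`NA` for single-descriptor
#'   sets).
#' @export
demo_descriptor_plan <- function() {
  plan <- rbind(
    data.frame(go_combo = c("GO:0008839", "GO:0009326", "GO:0018492",
                            "GO:0043115"),
               prosite_combo = "", n_members = c(3L, 25L, 17L, 31L),
               family = NA_character_, stringsAsFactors = FALSE),
    data.frame(go_combo = "GO:0004665;GO:0008977", prosite_combo = "",
               n_members = 16L, family = "Prephenate DH [1.3.1.13]",
               stringsAsFactors = FALSE),
    data.frame(go_combo = "",
               prosite_combo = c("PS00059", "PS00061", "PS00136", "PS00137",
                                 "PS00138", "PS00141", "PS00501"),
               n_members = c(15L, 3L, 3L, 1L, 2L, 11L, 6L),
               family = NA_character_, stringsAsFactors = FALSE),
    data.frame(go_combo = "",
               prosite_combo = c("PS00060;PS00913",
                                 "PS00062;PS00063;PS00798",
                                 "PS00065;PS00670;PS00671",
                                 "PS00381;PS00382",
                                 "PS00490;PS00551;PS00932",
                                 "PS00090;PS00699",
                                 "PS00692;PS00746",
                                 "PS00136;PS00137",
                                 "PS00136;PS00138",
                                 "PS00137;PS00138"),
               n_members = c(4L, 19L, 27L, 2L, 11L, 10L, 7L, 2L, 4L, 1L),
               family = c("Fe-ADH [1.1.1.1]", "dkgA [1.1.1.274]",
                          "Glyoxylate reductase [1.1.1.26]",
                          "Clp protease [3.4.21.92]",
                          "Molybdopterin oxidoreductase [1.2.2.1]",
                          "Nitrogenase [1.18.6.1]", "Nitrogenase [1.18.6.1]",
                          "Subtilisin [3.4.21.*]", "Subtilisin [3.4.21.*]",
                          "Subtilisin [3.4.21.*]"),
               stringsAsFactors = FALSE),
    data.frame(go_combo = "GO:0008839", prosite_combo = "PS01298",
               n_members = 14L, family = "DHPR [1.3.1.26]",
               stringsAsFactors = FALSE))
  rownames(plan) <- NULL
  plan
}

plan_family_map <- function(plan) {
  multi <- plan[!is.na(plan$family), , drop = FALSE]
  data.frame(
    combo = vapply(seq_len(nrow(multi)), function(i) combo_key(
      if (nzchar(multi$go_combo[i])) strsplit(multi$go_combo[i], ";")[[1]] else character(),
      if (nzchar(multi$prosite_combo[i])) strsplit(multi$prosite_combo[i], ";")[[1]] else character()),
      ""),
    family = multi$family, stringsAsFactors = FALSE)
}

#' Simulate an annotated SAG gene collection with known PPM structure
#'
#' Generates a deterministic gene collection whose complete, full-length
#' genes carry exactly the descriptor combinations of `plan`, plus
#' fragmentary hit genes (removed by the gene-fragment filter; each
#' carries a single descriptor, alternating too-short and
#' not-annotated-complete) and descriptor-free background genes. The
#' defaults replay the published demonstration: 234 surviving hit genes in
#' 23 combinations, 168 fragmentary profile hits and 539 fragmentary
#' pattern hits (the counts the gene-fragment filter removed in that
#' study), and a background of 150 genes.
#'
#' @param plan Combination plan (see [demo_descriptor_plan()]).
#' @param n_profile_fragment,n_pattern_fragment Numbers of fragmentary
#'   genes carrying one profile / pattern descriptor each.
#' @param n_background Descriptor-free complete genes.
#' @param n_genomes Genomes (SAG identifiers) the genes are spread over.
#' @param seed Integer seed; fully determines the output.
#' @return List with `collection` (a [gene_collection()]), `go_profile`
#'   and `prosite_list` (the filter lists covering the plan),
#'   `family_map` (for [condense_meta_sets()]) and `manifest`, the
#'   ground-truth expectation list (hit-pair counts before/after the
#'   fragment filter, non-redundant genes per branch, set and family
#'   counts).
#' @export
simulate_annotated_genes <- function(plan = demo_descriptor_plan(),
                                     n_profile_fragment = 168L,
                                     n_pattern_fragment = 539L,
                                     n_background = 150L,
                                     n_genomes = 58L, seed = 1L) {
  with_seed(seed, {
    go_sets <- lapply(plan$go_combo, function(s)
      if (nzchar(s)) strsplit(s, ";")[[1]] else character())
    ps_sets <- lapply(plan$prosite_combo, function(s)
      if (nzchar(s)) strsplit(s, ";")[[1]] else character())
    go_profile <- unique(unlist(go_sets))
    prosite_list <- unique(unlist(ps_sets))
    n_hit <- sum(plan$n_members)
    n_total <- n_hit + n_profile_fragment + n_pattern_fragment + n_background
    ids <- sprintf("g%05d", sample.int(9 * n_total, n_total))
    genomes <- sprintf("SAG%02d", sample.int(n_genomes, n_total, replace = TRUE))
    row_of <- rep(seq_len(nrow(plan)), plan$n_members)
    hit_go <- go_sets[row_of]
    hit_ps <- ps_sets[row_of]
    frag_go <- go_profile[1L + (seq_len(n_profile_fragment) - 1L) %%
                            length(go_profile)]
    frag_ps <- prosite_list[1L + (seq_len(n_pattern_fragment) - 1L) %%
                              length(prosite_list)]
    n_frag <- n_profile_fragment + n_pattern_fragment
    # alternate removal reasons: too short vs not annotated complete
    frag_short <- seq_len(n_frag) %% 2L == 1L
    nt <- c(sample(300:3000, n_hit, replace = TRUE),
            ifelse(frag_short, sample(90:297, n_frag, replace = TRUE),
                   sample(300:3000, n_frag, replace = TRUE)),
            sample(300:3000, n_background, replace = TRUE))
    complete <- c(rep(TRUE, n_hit), !(!frag_short), rep(TRUE, n_background))
    complete[n_hit + which(!frag_short)] <- FALSE
    go_terms <- c(hit_go, as.list(frag_go),
                  rep(list(character()), n_pattern_fragment + n_background))
    prosite_ids <- c(hit_ps, rep(list(character()), n_profile_fragment),
                     as.list(frag_ps), rep(list(character()), n_background))
    product <- c(rep("hypothetical protein", n_hit + n_frag + n_background))
    ord <- sample.int(n_total)
    gc <- gene_collection(
      gene_id = ids[ord], genome_id = genomes[ord],
      taxon = ifelse(as.integer(sub("SAG", "", genomes[ord])) %% 2L == 0L,
                     "Bacteria", "Archaea"),
      nt_length = nt[ord], complete = complete[ord], product = product[ord],
      go_terms = go_terms[ord], prosite_ids = prosite_ids[ord])
    surviving_profile_pairs <- sum(lengths(hit_go))
    surviving_pattern_pairs <- sum(lengths(hit_ps))
    multi_pattern <- !is.na(plan$family) & nzchar(plan$prosite_combo) &
      !nzchar(plan$go_combo)
    manifest <- list(
      n_genes = n_total,
      profile_pairs_raw = surviving_profile_pairs + n_profile_fragment,
      profile_pairs_filtered = surviving_profile_pairs,
      profile_pairs_removed = n_profile_fragment,
      pattern_pairs_raw = surviving_pattern_pairs + n_pattern_fragment,
      pattern_pairs_filtered = surviving_pattern_pairs,
      pattern_pairs_removed = n_pattern_fragment,
      profile_genes_nonredundant =
        sum(plan$n_members[nzchar(plan$go_combo)]),
      pattern_genes_nonredundant =
        sum(plan$n_members[nzchar(plan$prosite_combo)]),
      deduped_genes = n_hit,
      n_profile_sets = sum(nzchar(plan$go_combo) & !nzchar(plan$prosite_combo)),
      n_pattern_sets = sum(!nzchar(plan$go_combo) & nzchar(plan$prosite_combo)),
      n_pp_sets = sum(nzchar(plan$go_combo) & nzchar(plan$prosite_combo)),
      multi_pattern_genes = sum(plan$n_members[multi_pattern]),
      reliable_genes = sum(plan$n_members[
        lengths(go_sets) + lengths(ps_sets) >= 2L]),
      pp_members = sum(plan$n_members[nzchar(plan$go_combo) &
                                        nzchar(plan$prosite_combo)]),
      n_families = length(unique(plan$family[!is.na(plan$family)])))
    list(collection = gc, go_profile = go_profile,
         prosite_list = prosite_list,
         family_map = plan_family_map(plan), manifest = manifest)
  })
}

#' Simulate proteins with planted consensus-pattern occurrences
#'
#' Background residues are drawn uniformly from the 20-letter alphabet;
#' accidental matches are excluded by rejection sampling against the
#' matcher itself, so the scan ground truth is exact: background genes
#' match no pattern, and each planted gene's matches are precisely the
#' planted span.
#'
#' @param patterns One `prosite_pattern` (or pattern string) or a list of
#'   them; planted genes cycle through the list.
#' @param n_genes Total genes.
#' @param n_planted Genes receiving one planted occurrence each.
#' @param length_range Protein length range (uniform draw).
#' @param seed Integer seed.
#' @return List with `proteins` (named character vector), `truth` (data
#'   frame `gene_id`, `pattern_id`, `start`, `end`) and `planted`
#'   (the planted gene ids).
#' @export
simulate_planted_proteins <- function(patterns, n_genes = 50L,
                                      n_planted = 5L,
                                      length_range = c(80L, 150L),
                                      seed = 1L) {
  if (inherits(patterns, "prosite_pattern") || is.character(patterns) &&
      length(patterns) == 1L)
    patterns <- list(patterns)
  patterns <- lapply(seq_along(patterns), function(i) {
    p <- patterns[[i]]
    if (is.character(p)) p <- parse_prosite_pattern(p, id = paste0("PAT", i))
    if (is.na(p$id)) p$id <- paste0("PAT", i)
    p
  })
  stopifnot(n_planted <= n_genes)
  with_seed(seed, {
    rand_bg <- function(len, forbid) {
      repeat {
        s <- paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
        if (!any(vapply(forbid, function(p) nrow(prosite_match(p, s)) > 0L,
                        logical(1))))
          return(s)
      }
    }
    realize <- function(p) {
      paste(unlist(lapply(p$elements, function(e) {
        r <- sample(e$min_rep:e$max_rep, 1L)
        pool <- switch(e$kind, any = AA_ALPHABET, fixed = e$residues,
                       any_of = e$residues,
                       none_of = setdiff(AA_ALPHABET, e$residues))
        sample(pool, r, replace = TRUE)
      })), collapse = "")
    }
    ids <- sprintf("p%04d", seq_len(n_genes))
    planted_ids <- if (n_planted) sort(sample(ids, n_planted)) else character()
    seqs <- character(n_genes); names(seqs) <- ids
    truth <- list()
    for (i in seq_len(n_genes)) {
      len <- sample(length_range[1]:length_range[2], 1L)
      if (ids[i] %in% planted_ids) {
        k <- 1L + (match(ids[i], planted_ids) - 1L) %% length(patterns)
        p <- patterns[[k]]
        if (pattern_span(p)[1] > len)
          stop("pattern ", p$id, " minimal span exceeds the sequence length")
        repeat {
          inst <- realize(p)
          pad <- len  # background residues around the instance
          at <- if (p$n_anchored) 1L
            else if (p$c_anchored) pad + 1L
            else sample.int(pad + 1L, 1L)
          s <- paste0(rand_bg(at - 1L, patterns), inst,
                      rand_bg(pad - at + 1L, patterns))
          m <- prosite_match(p, s)
          others <- vapply(patterns[-k], function(q)
            nrow(prosite_match(q, s)) > 0L, logical(1))
          ok <- nrow(m) >= 1L && all(m$start >= at) &&
            all(m$end <= at + nchar(inst) - 1L) && !any(others)
          if (ok) {
            seqs[i] <- s
            truth[[length(truth) + 1L]] <- data.frame(
              gene_id = ids[i], pattern_id = p$id,
              start = at, end = at + nchar(inst) - 1L,
              stringsAsFactors = FALSE)
            break
          }
        }
      } else {
        seqs[i] <- rand_bg(len, patterns)
      }
    }
    list(proteins = seqs,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(gene_id = character(), pattern_id = character(),
                      start = integer(), end = integer()),
         planted = planted_ids)
  })
}

mutate_seq <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA_ALPHABET, a), 1L), "")
  chars
}

#' Simulate an alignment with planted phylogenetic clusters
#'
#' Cluster ancestors are mutated copies of a common root (per-site
#' substitution probability `between`); members are mutated copies of
#' their ancestor (probability `within`). With `within` well below
#' `between`, neighbor joining plus a branch-length cut recovers the
#' planted partition.
#'
#' @param sizes Integer vector of cluster sizes.
#' @param len Alignment length (no gaps are introduced).
#' @param within,between Per-site substitution probabilities
#'   (`within < between` required unless both are 0).
#' @param seed Integer seed.
#' @return List with `alignment` (named character vector) and `partition`
#'   (list of member-id vectors, the planted truth).
#' @export
simulate_cluster_alignment <- function(sizes = c(5L, 4L, 3L, 2L),
                                       len = 200L, within = 0.02,
                                       between = 0.3, seed = 1L) {
  stopifnot(all(sizes >= 1L), len >= 1L)
  if (within >= between && between > 0)
    stop("infeasible cluster plan: within-cluster rate must be below ",
         "the between-cluster rate")
  with_seed(seed, {
    root <- sample(AA_ALPHABET, len, replace = TRUE)
    aln <- character(); partition <- list()
    for (k in seq_along(sizes)) {
      anc <- mutate_seq(root, between)
      members <- sprintf("c%d_m%d", k, seq_len(sizes[k]))
      for (m in seq_len(sizes[k]))
        aln[members[m]] <- paste(mutate_seq(anc, within), collapse = "")
      partition[[k]] <- members
    }
    list(alignment = aln, partition = partition)
  })
}

#' The gamma-carbonic-anhydrase derivation scenario
#'
#' A synthetic archetype plus six candidate sequences encoding the kind of
#' curated variation seen when a strict active-site pattern is relaxed
#' against distant homologs: the spacer between the structural D and the
#' first hydrogen-bonding position shortened by one residue in every
#' candidate, a highly variable catalytic position that degrades to `x`,
#' N->C and Q->K substitutions at hydrogen-bonding positions, E->D at the
#' final catalytic position, and fully conserved structural arginine and
#' metal-binding histidines. Deriving patterns from this fixture yields
#' `R-x-D-x(10,11)-[NC]-x-[QK]-x(5)-H-x(2)-[ED]` and `H-x(3)-H`.
#'
#' @return List with `alignment` (7 aligned sequences), `archetype_id`,
#'   `candidate_ids`, `positions` ([functional_positions()]) and
#'   `segments`.
#' @export
gamma_ca_fixture <- function() {
  filler <- strsplit(paste(rep("ASGTVLKEIM", 13), collapse = ""), "")[[1]]
  arche <- filler
  arche[59:84] <- strsplit("RSDEGMPIFVGDRSNVQDGVVLHALE", "")[[1]]
  arche[117:121] <- strsplit("HQSQH", "")[[1]]
  cand_62 <- c("S", "T", "A", "G", "L", "V")
  cand_73 <- c("C", "C", "N", "C", "N", "C")
  cand_75 <- c("K", "Q", "K", "Q", "K", "K")
  cand_84 <- c("D", "D", "D", "D", "E", "E")
  aln <- list(gCA_archetype = paste(arche, collapse = ""))
  for (i in 1:6) {
    cand <- arche
    cand[62] <- cand_62[i]
    cand[62 + i] <- "-"   # one-residue deletion inside the 63-72 stretch
    cand[73] <- cand_73[i]
    cand[75] <- cand_75[i]
    cand[84] <- cand_84[i]
    cand[10] <- AA_ALPHABET[i]       # benign variation outside the segments
    cand[100] <- AA_ALPHABET[20 - i]
    aln[[paste0("gCA_cand_", i)]] <- paste(cand, collapse = "")
  }
  list(alignment = unlist(aln),
       archetype_id = "gCA_archetype",
       candidate_ids = paste0("gCA_cand_", 1:6),
       positions = functional_positions(
         index = c(59L, 61L, 62L, 73L, 75L, 81L, 84L, 117L, 121L),
         role = c("structural", "structural", "catalytic", "catalytic",
                  "catalytic", "metal_binding", "catalytic",
                  "metal_binding", "metal_binding"),
         residue = c("R", "D", "E", "N", "Q", "H", "E", "H", "H")),
       segments = list(c(59L, 84L), c(117L, 121L)))
}

#' Simulate a full POI-to-descriptor translation study
#'
#' Builds, deterministically, the complete input surface of the
#' translation step: a redundant E.C.-number list of 2576 entries over 13
#' POI groups (433 non-redundant; 264 surviving after removal of
#' preliminary, transferred and deleted entries), an ENZYME-dialect status
#' table, ec2go-dialect GO links (173 assignments, 171 non-redundant
#' terms), PROSITE-dialect entries with embedded E.C. references (92
#' assignments; 52 non-redundant patterns of which the 3 low-specificity
#' IDs PS00198, PS00455 and PS00143 are dropped, leaving 49) and the
#' supplemental descriptors of the non-enzymatic aquaporin group. The
#' per-group totals replay the published stepwise conversion overview.
#'
#' @param seed Integer seed (the construction is deterministic; the seed
#'   only shuffles descriptor allocation where arbitrary).
#' @return List with `ec_lines`, `enzyme_dat`, `ec2go_lines`,
#'   `prosite_dat` (character vectors, the four flat files),
#'   `supplemental` (data frame), `low_specificity` and `expected` (the
#'   per-group count table plus totals).
#' @export
simulate_poi_study <- function(seed = 1L) {
  groups <- data.frame(
    group = c("Alcohol DH", "Formate DH", "Formaldehyde DH",
              "Carbon monoxide DH", "Ene reductase", "Protease",
              "Terpene synthase", "Nitrogenase", "Lipase",
              "Carbonic anhydrase", "Acetylene hydratase",
              "Acetyl-CoA synthetase", "Aquaporin"),
    ec_total = c(101L, 29L, 23L, 19L, 1162L, 741L, 35L, 18L, 380L, 58L,
                 2L, 8L, 0L),
    ec_nonredundant = c(32L, 6L, 9L, 4L, 107L, 217L, 23L, 4L, 26L, 1L,
                        1L, 3L, 0L),
    ec_active = c(25L, 6L, 4L, 4L, 65L, 111L, 17L, 2L, 25L, 1L, 1L, 3L, 0L),
    go_total = c(20L, 4L, 3L, 4L, 61L, 39L, 9L, 2L, 24L, 1L, 1L, 3L, 2L),
    go_nonredundant = c(20L, 4L, 2L, 4L, 61L, 39L, 9L, 2L, 24L, 1L, 1L,
                        2L, 2L),
    prosite_total = c(12L, 7L, 0L, 1L, 9L, 45L, 0L, 4L, 9L, 3L, 0L, 1L, 1L),
    prosite_nonredundant = c(8L, 6L, 0L, 0L, 1L, 20L, 0L, 4L, 6L, 3L, 0L,
                             0L, 1L),
    stringsAsFactors = FALSE)
  low_spec <- c("PS00198", "PS00455", "PS00143")
  # which group absorbs each low-specificity pattern occurrence
  low_spec_group <- c("Protease", "Carbon monoxide DH", "Acetyl-CoA synthetase")
  with_seed(seed, {
    ec_lines <- character()
    enzyme_dat <- character()
    ec2go_lines <- character()
    ps_entries <- list()   # ps id -> list(ec = ..., de base)
    go_counter <- 0L; ps_counter <- 0L
    statuses <- c("transferred", "deleted", "preliminary")
    for (g in seq_len(nrow(groups))) {
      row <- groups[g, ]
      if (row$ec_nonredundant > 0L) {
        k <- seq_len(row$ec_nonredundant)
        serial <- 1L + (k - 1L) %% 60L
        status <- rep("active", row$ec_nonredundant)
        dead <- which(k > row$ec_active)
        status[dead] <- statuses[1L + (seq_along(dead) - 1L) %% 3L]
        serial_txt <- ifelse(status == "preliminary",
                             paste0("n", serial), as.character(serial))
        ecs <- sprintf("%d.%d.%d.%s", ((g - 1L) %% 7L) + 1L, g,
                       1L + (k - 1L) %/% 60L, serial_txt)
        for (i in k) {
          de <- switch(status[i],
            active = sprintf("Synthetic %s enzyme %d.", row$group, i),
            preliminary = sprintf("Synthetic preliminary %s enzyme %d.",
                                  row$group, i),
            transferred = sprintf("Transferred entry: %s.", ecs[1]),
            deleted = "Deleted entry.")
          enzyme_dat <- c(enzyme_dat, paste0("ID   ", ecs[i]),
                          paste0("DE   ", de), "//")
        }
        # input list: distinct entries first, then duplicates cycling
        dup <- row$ec_total - row$ec_nonredundant
        toks <- c(ecs, ecs[1L + (seq_len(dup) - 1L) %% row$ec_nonredundant])
        ec_lines <- c(ec_lines, paste0(toks, "\t", row$group))
        active_ecs <- ecs[status == "active"]
        # GO assignments: distinct terms round-robin, then duplicates
        assigned_go <- list()
        for (i in seq_len(row$go_nonredundant)) {
          go_counter <- go_counter + 1L
          go <- sprintf("GO:%07d", go_counter)
          ec <- active_ecs[1L + (i - 1L) %% length(active_ecs)]
          assigned_go[[ec]] <- c(assigned_go[[ec]], go)
          ec2go_lines <- c(ec2go_lines, sprintf(
            "EC:%s > GO:synthetic term %d ; %s", ec, go_counter, go))
        }
        for (j in seq_len(row$go_total - row$go_nonredundant)) {
          go <- assigned_go[[active_ecs[1]]][1]
          home <- vapply(active_ecs, function(e) go %in% assigned_go[[e]],
                         logical(1))
          ec <- active_ecs[which(!home)[1]]
          assigned_go[[ec]] <- c(assigned_go[[ec]], go)
          ec2go_lines <- c(ec2go_lines, sprintf(
            "EC:%s > GO:synthetic term dup ; %s", ec, go))
        }
        # PROSITE assignments
        n_low <- sum(low_spec_group == row$group)
        n_dup <- row$prosite_total - row$prosite_nonredundant - n_low
        group_ps <- character()
        for (i in seq_len(row$prosite_nonredundant)) {
          ps_counter <- ps_counter + 1L
          ps <- sprintf("PS9%04d", ps_counter)
          ec <- active_ecs[1L + (i - 1L) %% length(active_ecs)]
          ps_entries[[ps]] <- list(ec = ec, name = sprintf("SYN_%d", ps_counter))
          group_ps <- c(group_ps, ps)
        }
        for (j in seq_len(n_dup)) {
          ps <- group_ps[1L + (j - 1L) %% length(group_ps)]
          used <- ps_entries[[ps]]$ec
          ec <- setdiff(active_ecs, used)[1]
          ps_entries[[ps]]$ec <- c(used, ec)
        }
        if (n_low) {
          ps <- low_spec[match(row$group, low_spec_group)]
          ps_entries[[ps]] <- list(ec = active_ecs[length(active_ecs)],
                                   name = paste0("LOWSPEC_", ps))
        }
      }
    }
    # supplemental descriptors for the non-enzymatic aquaporin group
    sup_go <- sprintf("GO:%07d", go_counter + 1:2)
    ps_counter <- ps_counter + 1L
    sup_ps <- sprintf("PS9%04d", ps_counter)
    ps_entries[[sup_ps]] <- list(ec = character(), name = "SYN_AQP")
    supplemental <- data.frame(
      group = "Aquaporin", kind = c("go", "go", "prosite"),
      id = c(sup_go, sup_ps), stringsAsFactors = FALSE)
    prosite_dat <- unlist(lapply(names(ps_entries), function(ps) {
      e <- ps_entries[[ps]]
      de <- paste0("Synthetic signature ",
                   paste(sprintf("(EC %s)", e$ec), collapse = " "), ".")
      c(sprintf("ID   %s; PATTERN.", e$name),
        sprintf("AC   %s;", ps),
        sprintf("DE   %s", de),
        "PA   A-x(2)-C.",
        "//")
    }))
    expected <- list(
      groups = groups,
      ec_total = sum(groups$ec_total),
      ec_nonredundant = sum(groups$ec_nonredundant),
      ec_active = sum(groups$ec_active),
      go_terms = sum(groups$go_nonredundant),
      prosite_patterns = sum(groups$prosite_nonredundant),
      prosite_before_low_specificity =
        sum(groups$prosite_nonredundant) + length(low_spec),
      dropped_low_specificity = length(low_spec))
    list(ec_lines = ec_lines, enzyme_dat = enzyme_dat,
         ec2go_lines = ec2go_lines, prosite_dat = prosite_dat,
         supplemental = supplemental, low_specificity = low_spec,
         expected = expected)
  })
}

#' Write the simulated POI study to flat files
#'
#' @param study Output of [simulate_poi_study()].
#' @param dir Destination directory (created if needed).
#' @return Named character vector of the written file paths.
#' @export
write_poi_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ec_list = file.path(dir, "poi_ec_list.txt"),
             enzyme = file.path(dir, "enzyme_synthetic.dat"),
             ec2go = file.path(dir, "ec2go_synthetic.txt"),
             prosite = file.path(dir, "prosite_synthetic.dat"),
             supplemental = file.path(dir, "supplemental_descriptors.tsv"))
  writeLines(study$ec_lines, paths["ec_list"])
  writeLines(study$enzyme_dat, paths["enzyme"])
  writeLines(study$ec2go_lines, paths["ec2go"])
  writeLines(study$prosite_dat, paths["prosite"])
  utils::write.table(study$supplemental, paths["supplemental"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Run the translation step over a simulated POI study
#'
#' Convenience wrapper: writes nothing, parses the in-memory flat-file
#' lines with the package loaders and runs [expand_and_filter()] plus
#' [translate_descriptors()].
#'
#' @param study Output of [simulate_poi_study()].
#' @return The completed `ec_translation`.
#' @export
translate_poi_study <- function(study) {
  ecs <- parse_ec_list(study$ec_lines)
  enzyme <- read_enzyme_dat(study$enzyme_dat)
  ec2go <- read_ec2go(study$ec2go_lines)
  prosite <- read_prosite_dat(study$prosite_dat)
  mapping <- descriptor_mapping(enzyme, ec2go, prosite_ec_links(prosite),
                                low_specificity = study$low_specificity)
  tr <- expand_and_filter(ecs, mapping)
  translate_descriptors(tr, mapping, supplemental = study$supplemental)
}
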