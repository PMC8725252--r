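test_that("simulation config validates its invariants", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_per_condition = 2), ">= 3")
  expect_error(simulation_config(noise_sd = 0), "> 0")
  expect_error(simulation_config(n_mirna = 0), "positive")
  expect_error(simulation_config(triplet_coupling = 1), "\\[0, 1\\)")
  expect_error(simulation_config(mirna_length = 10), "18-26")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_sim_config(seed = 9)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  sa <- simulate_sequences(cfg, a$truth)
  sb <- simulate_sequences(cfg, b$truth)
  expect_identical(sa, sb)
  ga <- simulate_genesets(cfg, sa$truth)
  gb <- simulate_genesets(cfg, sb$truth)
  expect_identical(ga, gb)
  # and written artifacts are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_expression(a$bundle, d1); write_expression(b$bundle, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_false(identical(
    simulate_expression(small_sim_config(seed = 10)), a))
})

test_that("noiseless limit is analytic: exact fold change, |r| -> 1", {
  cfg <- small_sim_config(seed = 4, noise_sd = 1e-9)
  sim <- simulate_expression(cfg)
  rec <- suppressWarnings(two_class_de(sim$bundle, "lncrna"))
  planted_up <- sim$truth$de$feature_id[sim$truth$de$class == "lncRNA" &
                                        sim$truth$de$direction == "up"]
  fc <- rec$signed_fold_change[rec$feature_id %in% planted_up]
  expect_equal(fc, rep(2^2.5, length(fc)), tolerance = 1e-6)
  tr <- sim$truth$triplets[1, ]
  expect_equal(
    abs(cor(sim$bundle$lncrna[tr$lncrna_id, ],
            sim$bundle$mrna[tr$mrna_id, ])), 1, tolerance = 1e-6)
  expect_equal(
    cor(sim$bundle$mirna[tr$mirna_id, ],
        sim$bundle$mrna[tr$mrna_id, ]), -1, tolerance = 1e-6)
})

test_that("planted signs and correlations have the designed structure", {
  cfg <- small_sim_config(seed = 1)
  sim <- simulate_expression(cfg)
  b <- sim$bundle
  ind <- b$condition == "induced"
  rs <- c()
  for (i in seq_len(nrow(sim$truth$triplets))) {
    tr <- sim$truth$triplets[i, ]
    l <- b$lncrna[tr$lncrna_id, ]; g <- b$mrna[tr$mrna_id, ]
    mi <- b$mirna[tr$mirna_id, ]
    s <- if (tr$stratum == "UP") 1 else -1
    expect_gt(s * (mean(l[ind]) - mean(l[!ind])), 0)
    expect_lt(s * (mean(mi[ind]) - mean(mi[!ind])), 0)
    expect_gt(cor(l, g), 0)
    expect_lt(cor(mi, l), 0)
    expect_lt(cor(mi, g), 0)
    rs <- c(rs, cor(l, g))
  }
  expect_gte(mean(rs), 0.90)
})

test_that("no planted triplets means no recovered triplets above chance", {
  false_triplets <- 0
  for (seed in 1:5) {
    cfg <- simulation_config(n_lncrna = 15, n_mirna = 8, n_mrna = 25,
                             n_planted_triplets = 0,
                             seq_length_target = 200, seed = seed)
    sim <- simulate_expression(cfg)
    expect_identical(nrow(sim$truth$triplets), 0L)
    strata <- lapply(setNames(nm = c("lncrna", "mirna", "mrna")),
                     function(cls) stratify(two_class_de(sim$bundle, cls)))
    false_triplets <- false_triplets +
      length(strata$lncrna$up) + length(strata$lncrna$down)
  }
  # background features pass the joint FC/p filter essentially never
  expect_lte(false_triplets, 2)
})

test_that("planted binding sites are exact reverse complements at their coordinates", {
  cfg <- small_sim_config(seed = 6)
  sim <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, sim$truth)
  sites <- seqs$truth$sites
  expect_identical(nrow(sites), 2L * nrow(sim$truth$triplets))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    expect_identical(s$end - s$start + 1L, cfg$mirna_length)
    sub <- substr(seqs$target_seqs[[s$target_id]], s$start, s$end)
    expect_identical(sub, ceRNAnet:::rna_revcomp(seqs$mirna_seqs[[s$mirna_id]]))
  }
})

test_that("decoy targets carry no 8-mer complement to any miRNA (brute force)", {
  cfg <- small_sim_config(seed = 7)
  sim <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, sim$truth)
  decoys <- setdiff(names(seqs$target_seqs), seqs$truth$sites$target_id)
  expect_gt(length(decoys), 0)
  for (d in sample(decoys, min(10, length(decoys)))) {
    tg <- seqs$target_seqs[[d]]
    for (m in seqs$mirna_seqs) {
      rc <- ceRNAnet:::rna_revcomp(m)
      for (st in seq_len(nchar(rc) - 7L))
        expect_false(grepl(substr(rc, st, st + 7L), tg, fixed = TRUE))
    }
  }
})

test_that("two planted sites per target are recorded and non-overlapping", {
  cfg <- small_sim_config(seed = 8, sites_per_target = 2)
  sim <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, sim$truth)
  sites <- seqs$truth$sites
  for (tg in unique(sites$target_id)) {
    s <- sites[sites$target_id == tg, ]
    expect_identical(nrow(s), 2L)
    s <- s[order(s$start), ]
    expect_gt(s$start[2], s$end[1])
  }
})

test_that("gene-set simulation packs the enriched term as configured", {
  cfg <- small_sim_config(seed = 5)
  sim <- simulate_expression(cfg)
  gs <- simulate_genesets(cfg, sim$truth)
  term <- gs$collection[[1]]
  expect_identical(term$term_id, "TERM_ENRICHED")
  planted_up <- sim$truth$de$feature_id[sim$truth$de$class == "mRNA" &
                                        sim$truth$de$direction == "up"]
  expect_identical(sum(term$members %in% planted_up),
                   gs$truth$enriched_terms$n_planted)
  expect_length(gs$collection, 1L + cfg$n_background_terms)
  expect_error(simulate_genesets(small_sim_config(geneset_size = 1000),
                                 sim$truth), "exceeds")
})

test_that("ground truth survives a JSON round trip", {
  cfg <- small_sim_config(seed = 3)
  sim <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, sim$truth)
  gs <- simulate_genesets(cfg, seqs$truth)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gs$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$triplets, gs$truth$triplets)
  expect_equal(back$sites, gs$truth$sites)
  expect_equal(back$de, gs$truth$de)
})
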