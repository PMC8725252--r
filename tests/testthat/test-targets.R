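rc <- function(s) paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]),
                        collapse = "")
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                     replace = TRUE), collapse = "")

test_that("a planted perfect complement is found at its coordinates", {
  set.seed(41)
  mi <- rand_rna(22)
  tg <- paste0(rand_rna(100), rc(mi), rand_rna(100))
  sites <- align_duplex(mi, tg)
  best <- sites[[1]]
  expect_identical(best$target_start, 101L)
  expect_identical(best$target_end, 122L)
  # perfect 22-mer: 7 seed positions at 5*4 plus 15 at 5
  scheme <- scoring_scheme()
  expect_equal(best$score, 7 * scheme$match * scheme$seed_weight +
                 15 * scheme$match)
  expect_equal(rescore_alignment(best, scheme), best$score)
  expect_identical(best$pairing, strrep("|", 22))
})

test_that("stored alignments re-score exactly and pairing marks only real pairs", {
  set.seed(43)
  scheme <- scoring_scheme()
  for (i in 1:25) {
    mi <- rand_rna(22)
    tg <- rand_rna(300)
    for (s in align_duplex(mi, tg, scheme)) {
      expect_equal(rescore_alignment(s, scheme), s$score, tolerance = 1e-9)
      qa <- strsplit(s$mirna_aln, "")[[1]]
      ta <- strsplit(s$target_aln, "")[[1]]
      marked <- strsplit(s$pairing, "")[[1]] != " "
      sym <- ceRNAnet:::pair_symbol(qa, ta)
      expect_true(all(sym[marked] %in% c("|", ":")))
      expect_true(all(qa[marked] != "-" & ta[marked] != "-"))
      expect_true(s$target_start >= 1 && s$target_end <= nchar(tg))
    }
  }
})

test_that("kernel score equals exhaustive local-alignment enumeration (tiny)", {
  set.seed(47)
  for (i in 1:40) {
    m <- sample(2:4, 1); n <- sample(3:6, 1)
    q <- rand_rna(m); tg <- rand_rna(n)
    w <- sample(c(1, 2, 4), m, replace = TRUE)
    got <- ceRNAnet:::.cpp_best_local_duplex(q, tg, w, 5, 2, -3, -9, -4)
    expect_equal(got$score,
                 oracle_local_align_bruteforce(q, tg, w, 5, 2, -3, -9, -4))
  }
})

test_that("kernel score equals an independent DP oracle at realistic sizes", {
  set.seed(53)
  for (i in 1:60) {
    m <- sample(4:10, 1); n <- sample(10:30, 1)
    q <- rand_rna(m); tg <- rand_rna(n)
    w <- sample(c(1, 2, 4), m, replace = TRUE)
    got <- ceRNAnet:::.cpp_best_local_duplex(q, tg, w, 5, 2, -3, -9, -4)
    expect_equal(got$score,
                 oracle_local_align(q, tg, w, 5, 2, -3, -9, -4))
  }
})

test_that("weak or empty targets yield no passing site", {
  scheme <- scoring_scheme()
  mi <- paste(rep("A", 22), collapse = "")
  # poly-A target has no complement pair at all
  sites <- align_duplex(mi, paste(rep("A", 100), collapse = ""), scheme)
  expect_true(all(vapply(sites, `[[`, 0, "score") < scheme$score_min))
  expect_length(align_duplex(mi, "", scheme), 0L)
  expect_error(align_duplex("ACGU", "ACGU"), "18-26")
  expect_error(align_duplex(strrep("A", 22), "ACGX"), "non-RNA")
  expect_warning(align_duplex(strrep("A", 22), "ACGT"), "transcribing")
})

test_that("duplex energy: stacks sum from the shipped table plus initiation", {
  tab <- duplex_stack_table()
  # strand-flip symmetry of the table
  swap <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (p1 in rownames(tab)) for (p2 in colnames(tab))
    expect_equal(tab[p1, p2], tab[swap(p2), swap(p1)])
  # hand-built perfect duplex: target GGCA / miRNA (3'->5') CCGU
  site <- structure(list(mirna_aln = "CCGU", target_aln = "GGCA",
                         pairing = "||||", mirna_end = 4L),
                    class = "duplex_site")
  expected <- tab["GC", "GC"] + tab["GC", "CG"] + tab["CG", "AU"] + 4.09
  expect_equal(duplex_energy(site), expected)
  # zero stacked pairs: initiation only
  iso <- structure(list(mirna_aln = "A", target_aln = "U", pairing = "|",
                        mirna_end = 1L), class = "duplex_site")
  expect_equal(duplex_energy(iso), 4.09)
  expect_gt(duplex_energy(iso), -30)   # an isolated pair can never pass
  # a gap interrupts stacking between the flanking stacks
  gapped <- structure(list(mirna_aln = "CC-GU", target_aln = "GGCCA",
                           pairing = "|| ||", mirna_end = 4L),
                      class = "duplex_site")
  expect_equal(duplex_energy(gapped),
               tab["GC", "GC"] + tab["CG", "AU"] + 4.09)
  # 22-nt perfect complement passes the -30 kcal/mol threshold
  set.seed(59)
  mi <- rand_rna(22)
  tg <- paste0(rand_rna(50), rc(mi), rand_rna(50))
  best <- align_duplex(mi, tg)[[1]]
  expect_lte(duplex_energy(best), -30)
})

test_that("predict_targets applies both thresholds with deterministic tie-breaks", {
  set.seed(61)
  mi <- c(mirA = rand_rna(22))
  hit <- paste0(rand_rna(40), rc(mi[[1]]), rand_rna(40))
  miss <- rand_rna(102)
  pairs <- predict_targets(mi, c(T1 = hit, T2 = miss),
                           target_class = "lncRNA")
  expect_identical(pairs$target_id, "T1")
  expect_identical(pairs$target_class, "lncRNA")
  expect_identical(pairs$target_start, 41L)
  expect_gte(pairs$n_sites, 1L)
  # two identical planted sites: best site is the left-most
  two <- paste0(rand_rna(30), rc(mi[[1]]), rand_rna(30), rc(mi[[1]]),
                rand_rna(30))
  p2 <- predict_targets(mi, c(T3 = two))
  expect_identical(p2$target_start, 31L)
  expect_identical(p2$n_sites, 2L)
  # empty miRNA input
  expect_identical(nrow(predict_targets(character(), c(T1 = hit))), 0L)
  # duplicate ids rejected
  expect_error(predict_targets(c(a = mi[[1]], a = mi[[1]]), c(T1 = hit)),
               "duplicate")
})

test_that("tightening score or energy thresholds yields pair subsets", {
  set.seed(67)
  mis <- setNames(replicate(3, rand_rna(22)), paste0("m", 1:3))
  tgs <- setNames(c(replicate(4, rand_rna(300)),
                    paste0(rand_rna(100), rc(mis[[1]]), rand_rna(100)),
                    paste0(rand_rna(100), rc(mis[[2]]), rand_rna(100))),
                  paste0("t", 1:6))
  key <- function(p) paste(p$mirna_id, p$target_id)
  loose <- predict_targets(mis, tgs, scoring_scheme(score_min = 100,
                                                    energy_max = -20))
  for (sm in c(140, 180, 215)) {
    tight <- predict_targets(mis, tgs, scoring_scheme(score_min = sm,
                                                      energy_max = -20))
    expect_true(all(key(tight) %in% key(loose)))
  }
  for (em in c(-25, -32, -40)) {
    tight <- predict_targets(mis, tgs, scoring_scheme(score_min = 100,
                                                      energy_max = em))
    expect_true(all(key(tight) %in% key(loose)))
  }
})
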