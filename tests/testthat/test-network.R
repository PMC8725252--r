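minimal_instance <- function() {
  strata <- list(lncrna = list(up = "L1", down = character()),
                 mirna = list(up = character(), down = "M1"),
                 mrna = list(up = "G1", down = character()))
  pairs <- data.frame(
    mirna_id = "M1", target_id = c("L1", "G1"),
    target_class = c("lncRNA", "mRNA"), r = c(-0.95, -0.96),
    target_start = 10L, target_end = 31L, stringsAsFactors = FALSE)
  edges <- data.frame(a_id = "L1", a_class = "lncRNA", b_id = "G1",
                      b_class = "mRNA", r = 0.97, p = 1e-6,
                      n_samples = 12L, stringsAsFactors = FALSE)
  list(strata = strata, pairs = pairs, edges = edges)
}

test_that("triplet assembly on the minimal positive and negative cases", {
  inst <- minimal_instance()
  tri <- assemble_triplets(inst$strata, inst$pairs, inst$edges, "UP")
  expect_identical(nrow(tri), 1L)
  expect_identical(tri$lncrna_id, "L1")
  expect_equal(tri$lnc_mrna_r, 0.97)
  expect_equal(tri$mir_lnc_r, -0.95)
  # missing coexpression edge kills the triplet
  expect_identical(
    nrow(assemble_triplets(inst$strata, inst$pairs, inst$edges[0, ], "UP")),
    0L)
  # wrong stratum finds nothing
  expect_identical(
    nrow(assemble_triplets(inst$strata, inst$pairs, inst$edges, "DOWN")),
    0L)
})

test_that("triplet assembly equals the brute-force triple loop", {
  for (seed in 1:12) {
    inst <- random_assembly_instance(seed)
    for (stratum in c("UP", "DOWN")) {
      got <- assemble_triplets(inst$strata, inst$pairs, inst$edges, stratum)
      want <- oracle_assemble_triplets(inst$strata, inst$pairs,
                                       inst$edges, stratum)
      expect_identical(got$lncrna_id, want$lncrna_id)
      expect_identical(got$mirna_id, want$mirna_id)
      expect_identical(got$mrna_id, want$mrna_id)
    }
  }
})

test_that("network construction: degrees, dedup, tripartiteness, sign labels", {
  # single triplet: lncRNA 1, miRNA 2, mRNA 1
  net1 <- build_network(star_triplets(1))
  deg <- node_degrees(net1)
  expect_identical(deg[["L1"]], 1L)
  expect_identical(deg[["M1"]], 2L)
  expect_identical(deg[["G01"]], 1L)
  # star: one miRNA with k mRNAs and 1 lncRNA -> miRNA degree k+1
  k <- 7L
  netk <- build_network(star_triplets(k))
  expect_identical(node_degrees(netk)[["M1"]], k + 1L)
  expect_identical(sum(node_degrees(netk)), 2L * nrow(netk$edges))
  # two triplets sharing a miRNA: edges deduplicated
  tri2 <- rbind(star_triplets(2), star_triplets(1, lnc = "L2"))
  net2 <- build_network(tri2)
  expect_identical(sum(net2$nodes$class == "miRNA"), 1L)
  expect_identical(nrow(net2$edges), nrow(unique(net2$edges)))
  expect_identical(sum(node_degrees(net2)), 2L * nrow(net2$edges))
  # direction labels follow the stratum
  expect_identical(net2$nodes$direction[net2$nodes$class == "miRNA"],
                   "down")
  dnet <- build_network(star_triplets(2, stratum = "DOWN"))
  expect_identical(unique(dnet$nodes$direction[dnet$nodes$class == "mRNA"]),
                   "down")
  # mixed strata are rejected
  expect_error(build_network(rbind(star_triplets(1),
                                   star_triplets(1, stratum = "DOWN"))),
               "mix strata")
  # empty network
  net0 <- build_network(star_triplets(0))
  expect_identical(nrow(net0$nodes), 0L)
  expect_length(node_degrees(net0), 0L)
})

test_that("deleting a triplet and rebuilding never leaves orphan edges", {
  for (seed in 1:8) {
    inst <- random_assembly_instance(seed)
    tri <- assemble_triplets(inst$strata, inst$pairs, inst$edges, "UP")
    if (nrow(tri) < 2) next
    tri$stratum <- "UP"
    drop <- sample(nrow(tri), 1)
    sub <- build_network(tri[-drop, , drop = FALSE])
    expect_silent(validate_cerna_network(sub))
    covered <- unique(c(paste(sub$triplets$lncrna_id,
                              sub$triplets$mirna_id),
                        paste(sub$triplets$mirna_id,
                              sub$triplets$mrna_id)))
    expect_true(all(paste(sub$edges$from, sub$edges$to) %in% covered))
  }
})

test_that("hub extraction is strict at degree 8 and matches the oracle", {
  # lncRNA with degree exactly 8 is not a hub; 9 is
  net8 <- build_network(lnc_star_triplets(8))
  expect_identical(node_degrees(net8)[["L1"]], 8L)
  expect_identical(nrow(extract_hub_subnetwork(net8)$nodes), 0L)
  net9 <- build_network(lnc_star_triplets(9))
  hub <- extract_hub_subnetwork(net9)
  expect_true("L1" %in% hub$nodes$id)
  expect_identical(nrow(hub$triplets), 9L)
  # oracle equivalence on random instances at several cuts
  for (seed in 1:10) {
    inst <- random_assembly_instance(seed, n_lnc = 3, n_mir = 8,
                                     n_mrna = 14)
    tri <- assemble_triplets(inst$strata, inst$pairs, inst$edges, "UP")
    if (!nrow(tri)) next
    net <- build_network(tri)
    for (cut in c(1, 3, 8)) {
      got <- extract_hub_subnetwork(net, cut)$triplets
      want <- oracle_hub_extract(net, cut)
      expect_identical(got$lncrna_id, want$lncrna_id)
      expect_identical(got$mrna_id, want$mrna_id)
    }
  }
})

test_that("hub tightening yields node and edge subsets", {
  for (seed in 1:6) {
    inst <- random_assembly_instance(seed, n_lnc = 3, n_mir = 8,
                                     n_mrna = 14)
    tri <- assemble_triplets(inst$strata, inst$pairs, inst$edges, "UP")
    if (!nrow(tri)) next
    net <- build_network(tri)
    prev <- net
    for (cut in c(0, 2, 4, 8)) {
      sub <- extract_hub_subnetwork(net, cut)
      expect_true(all(sub$nodes$id %in% prev$nodes$id))
      expect_true(all(paste(sub$edges$from, sub$edges$to) %in%
                      paste(prev$edges$from, prev$edges$to)))
      prev <- sub
    }
  }
})

test_that("gene-set anchored subnetworks keep exactly the matching triplets", {
  tri <- rbind(star_triplets(1, mi = "M1"),
               data.frame(lncrna_id = "L2", mirna_id = "M2",
                          mrna_id = c("SMAD6", "ALPL"), stratum = "UP",
                          lnc_mrna_r = 0.95, mir_lnc_r = -0.9,
                          mir_mrna_r = -0.9, lnc_site_start = 1L,
                          lnc_site_end = 22L, mrna_site_start = 1L,
                          mrna_site_end = 22L, stringsAsFactors = FALSE))
  net <- build_network(tri)
  osteo <- c("SMAD6", "ALPL", "COL6A1", "SEMA7A", "COL1A1", "BMP6",
             "SNAI2", "FBN2", "IGFBP5")
  sub <- extract_geneset_subnetwork(net, osteo)
  expect_setequal(sub$triplets$mrna_id, c("SMAD6", "ALPL"))
  expect_false("L1" %in% sub$nodes$id)
  # disjoint gene set -> empty network with warning
  expect_warning(empty <- extract_geneset_subnetwork(net, "ELSEWHERE"),
                 "does not intersect")
  expect_identical(nrow(empty$nodes), 0L)
  # full mRNA set -> identity on nodes and edges
  all_sub <- extract_geneset_subnetwork(net, net$nodes$id)
  expect_identical(all_sub$nodes, net$nodes)
  expect_identical(all_sub$edges, net$edges)
})
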