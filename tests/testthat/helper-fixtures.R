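# Small fixtures built in code.

toy_matrix <- function(ids, samples, values = NULL) {
  if (is.null(values)) values <- seq_len(length(ids) * length(samples))
  matrix(as.numeric(values), nrow = length(ids),
         dimnames = list(ids, samples))
}

toy_bundle <- function(n_samples_per_cond = 2, seed = 42) {
  set.seed(seed)
  samples <- paste0("S", seq_len(2 * n_samples_per_cond))
  mk <- function(ids) toy_matrix(ids, samples,
                                 rnorm(length(ids) * length(samples), 8, 1))
  expression_bundle(mk(c("L1", "L2", "L3")), mk(c("M1", "M2")),
                    mk(c("G1", "G2", "G3", "G4")),
                    condition = rep(c("induced", "control"),
                                    each = n_samples_per_cond))
}

# Fast small simulation config for unit tests.
small_sim_config <- function(seed = 1, ...) {
  simulation_config(n_lncrna = 10, n_mirna = 5, n_mrna = 20,
                    n_planted_triplets = 3, seq_length_target = 200,
                    seed = seed, ...)
}

# A hand-built network with k mRNAs sharing one miRNA and one lncRNA.
star_triplets <- function(k, lnc = "L1", mi = "M1", stratum = "UP") {
  if (k == 0)
    return(data.frame(lncrna_id = character(), mirna_id = character(),
                      mrna_id = character(), stratum = character(),
                      lnc_mrna_r = numeric(), mir_lnc_r = numeric(),
                      mir_mrna_r = numeric(), lnc_site_start = integer(),
                      lnc_site_end = integer(), mrna_site_start = integer(),
                      mrna_site_end = integer(), stringsAsFactors = FALSE))
  data.frame(lncrna_id = lnc, mirna_id = mi,
             mrna_id = sprintf("G%02d", seq_len(k)), stratum = stratum,
             lnc_mrna_r = 0.99, mir_lnc_r = -0.95, mir_mrna_r = -0.95,
             lnc_site_start = 1L, lnc_site_end = 22L,
             mrna_site_start = 1L, mrna_site_end = 22L,
             stringsAsFactors = FALSE)
}

# One lncRNA sponging k distinct miRNAs (one mRNA each): lncRNA degree k.
lnc_star_triplets <- function(k, lnc = "L1", stratum = "UP") {
  if (k == 0) return(star_triplets(0))
  data.frame(lncrna_id = lnc, mirna_id = sprintf("M%02d", seq_len(k)),
             mrna_id = sprintf("G%02d", seq_len(k)), stratum = stratum,
             lnc_mrna_r = 0.99, mir_lnc_r = -0.95, mir_mrna_r = -0.95,
             lnc_site_start = 1L, lnc_site_end = 22L,
             mrna_site_start = 1L, mrna_site_end = 22L,
             stringsAsFactors = FALSE)
}

# Random consistent instance for assembly/monotonicity property tests:
# strata sets, binding pairs and coexpression edges drawn at random.
random_assembly_instance <- function(seed, n_lnc = 8, n_mir = 6,
                                     n_mrna = 10) {
  set.seed(seed)
  lnc <- sprintf("L%02d", 1:n_lnc)
  mir <- sprintf("M%02d", 1:n_mir)
  mrna <- sprintf("G%02d", 1:n_mrna)
  halve <- function(x) {
    pick <- sample(c(TRUE, FALSE), length(x), replace = TRUE)
    list(up = x[pick], down = x[!pick])
  }
  strata <- list(lncrna = halve(lnc), mirna = halve(mir),
                 mrna = halve(mrna))
  rand_pairs <- function(targets, cls, p = 0.4) {
    grid <- expand.grid(mirna_id = mir, target_id = targets,
                        stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) < p, , drop = FALSE]
    if (!nrow(grid)) return(cbind(grid, target_class = character(),
                                  r = numeric(), target_start = integer(),
                                  target_end = integer()))
    grid$target_class <- cls
    grid$r <- runif(nrow(grid), -1, -0.1)
    grid$target_start <- sample(100L, nrow(grid), replace = TRUE)
    grid$target_end <- grid$target_start + 21L
    grid
  }
  pairs <- rbind(rand_pairs(lnc, "lncRNA"), rand_pairs(mrna, "mRNA"))
  eg <- expand.grid(a_id = lnc, b_id = mrna, stringsAsFactors = FALSE)
  eg <- eg[runif(nrow(eg)) < 0.4, , drop = FALSE]
  edges <- data.frame(a_id = eg$a_id, a_class = "lncRNA", b_id = eg$b_id,
                      b_class = "mRNA",
                      r = runif(nrow(eg), 0.905, 0.999),
                      p = runif(nrow(eg), 0, 1e-4),
                      n_samples = 12L, stringsAsFactors = FALSE)
  list(strata = strata, pairs = pairs, edges = edges)
}
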