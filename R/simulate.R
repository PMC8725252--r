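#' Configuration of the synthetic multi-omic simulator
#'
#' Defines the two-condition study the simulator emulates: a balanced
#' induced-vs-control design with planted ceRNA triplets whose expression
#' and sequences carry recoverable signal for every pipeline filter.
#'
#' Defaults: 6 samples per condition (so that a pooled-sample Pearson
#' r > 0.90 at P < 0.001 over n = 12 is attainable), a log2 effect of 2.5
#' for planted differential features (linear fold change 2^2.5 ~ 5.66),
#' per-feature Gaussian noise sd 0.4 in log2 units, and 40 planted
#' triplets per stratum.
#'
#' `triplet_coupling` is the fraction (in [0, 1)) of each planted
#' feature's noise sd loaded on a per-triplet shared latent factor, with
#' the opposite sign on the miRNA; it controls within-triplet correlation
#' beyond the condition shift while keeping every feature's marginal
#' noise sd at `noise_sd`. The default 0.9 yields expected pooled
#' lncRNA-mRNA correlations around 0.98 (>= 0.95).
#'
#' @param n_per_condition samples per condition (>= 3).
#' @param n_lncrna,n_mirna,n_mrna background (non-planted) feature counts.
#' @param n_planted_triplets planted triplets per stratum (UP and DOWN).
#' @param de_effect log2 mean shift of planted DE features.
#' @param noise_sd per-feature Gaussian sd, log2 units (> 0).
#' @param triplet_coupling shared-factor loading fraction in [0, 1).
#' @param seq_length_target target (lncRNA/mRNA) sequence length, nt.
#' @param mirna_length miRNA length, nt (18-26).
#' @param sites_per_target planted binding sites per (miRNA, target).
#' @param geneset_size size of the planted enriched term.
#' @param geneset_overlap fraction of the enriched term drawn from
#'   planted upregulated mRNAs.
#' @param n_background_terms number of background gene sets.
#' @param seed integer RNG seed; all outputs are deterministic given the
#'   config.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_condition = 6,
                              n_lncrna = 150, n_mirna = 40, n_mrna = 300,
                              n_planted_triplets = 40,
                              de_effect = 2.5, noise_sd = 0.4,
                              triplet_coupling = 0.9,
                              seq_length_target = 500, mirna_length = 22,
                              sites_per_target = 1,
                              geneset_size = 10, geneset_overlap = 0.8,
                              n_background_terms = 50, seed = 1) {
  cfg <- list(n_per_condition = as.integer(n_per_condition),
              n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_planted_triplets = as.integer(n_planted_triplets),
              de_effect = de_effect, noise_sd = noise_sd,
              triplet_coupling = triplet_coupling,
              seq_length_target = as.integer(seq_length_target),
              mirna_length = as.integer(mirna_length),
              sites_per_target = as.integer(sites_per_target),
              geneset_size = as.integer(geneset_size),
              geneset_overlap = geneset_overlap,
              n_background_terms = as.integer(n_background_terms),
              seed = as.integer(seed))
  if (cfg$n_per_condition < 3L)
    stop("n_per_condition must be >= 3", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$n_lncrna < 1L || cfg$n_mirna < 1L || cfg$n_mrna < 1L)
    stop("feature counts must be positive", call. = FALSE)
  if (cfg$n_planted_triplets < 0L)
    stop("n_planted_triplets must be >= 0", call. = FALSE)
  if (cfg$triplet_coupling < 0 || cfg$triplet_coupling >= 1)
    stop("triplet_coupling must be in [0, 1)", call. = FALSE)
  if (cfg$mirna_length < 18L || cfg$mirna_length > 26L)
    stop("mirna_length must be 18-26", call. = FALSE)
  if (cfg$seq_length_target < 2L * cfg$mirna_length)
    stop("seq_length_target too short for planted sites", call. = FALSE)
  if (cfg$geneset_overlap < 0 || cfg$geneset_overlap > 1)
    stop("geneset_overlap must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

planted_feature_ids <- function(config) {
  k <- config$n_planted_triplets
  mk <- function(prefix, stratum, i) sprintf("%s_%s%02d", prefix, stratum, i)
  list(
    UP = list(lncrna = if (k) mk("LNC", "U", 1:k) else character(),
              mirna = if (k) mk("MIR", "U", 1:k) else character(),
              mrna = if (k) mk("GENE", "U", 1:k) else character()),
    DOWN = list(lncrna = if (k) mk("LNC", "D", 1:k) else character(),
                mirna = if (k) mk("MIR", "D", 1:k) else character(),
                mrna = if (k) mk("GENE", "D", 1:k) else character()))
}

#' Simulate an expression bundle with planted ceRNA triplets
#'
#' Background features are condition-free Gaussian noise around a
#' per-feature baseline. Each planted UP-stratum triplet couples its
#' lncRNA and mRNA to a condition shift of `+de_effect` log2 units
#' (induced minus control) and its miRNA to `-de_effect`, plus a shared
#' per-sample latent factor loaded with opposite sign on the miRNA, so
#' that across pooled samples corr(lncRNA, mRNA) > 0 while
#' corr(miRNA, lncRNA) and corr(miRNA, mRNA) < 0. The DOWN stratum is
#' the mirror image. Deterministic given the config (including its seed).
#'
#' @param config [simulation_config()].
#' @return list with `bundle` ([expression_bundle()]) and `truth`
#'   (object of class `cerna_ground_truth`: data.frames `de`
#'   (feature_id, class, direction) and `triplets`
#'   (lncrna_id, mirna_id, mrna_id, stratum); `sites` and
#'   `enriched_terms` are filled by the sequence and gene-set
#'   simulators).
#' @export
simulate_expression <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    k <- config$n_planted_triplets
    ns <- config$n_per_condition
    samples <- sprintf("S%02d", seq_len(2L * ns))
    condition <- stats::setNames(rep(c("induced", "control"), each = ns),
                                 samples)
    csign <- ifelse(condition == "induced", 1, -1)

    ids <- planted_feature_ids(config)
    feat <- list(
      lncrna = c(ids$UP$lncrna, ids$DOWN$lncrna,
                 sprintf("LNC_B%03d", seq_len(config$n_lncrna))),
      mirna = c(ids$UP$mirna, ids$DOWN$mirna,
                sprintf("MIR_B%03d", seq_len(config$n_mirna))),
      mrna = c(ids$UP$mrna, ids$DOWN$mrna,
               sprintf("GENE_B%03d", seq_len(config$n_mrna))))

    mats <- lapply(feat, function(f) {
      base <- stats::runif(length(f), 6, 12)
      m <- base + matrix(stats::rnorm(length(f) * length(samples),
                                      sd = config$noise_sd),
                         nrow = length(f))
      dimnames(m) <- list(f, samples)
      m
    })

    theta <- config$triplet_coupling
    resid <- sqrt(1 - theta^2)
    plant <- function(stratum) {
      s <- if (stratum == "UP") 1 else -1
      for (i in seq_len(k)) {
        g <- stats::rnorm(length(samples))  # shared latent factor
        shift <- s * csign * config$de_effect / 2
        shared <- theta * config$noise_sd * g
        noise <- function() stats::rnorm(length(samples),
                                         sd = resid * config$noise_sd)
        base <- stats::runif(3, 6, 12)
        mats$lncrna[ids[[stratum]]$lncrna[i], ] <<-
          base[1] + shift + shared + noise()
        mats$mrna[ids[[stratum]]$mrna[i], ] <<-
          base[2] + shift + shared + noise()
        mats$mirna[ids[[stratum]]$mirna[i], ] <<-
          base[3] - shift - shared + noise()
      }
    }
    plant("UP"); plant("DOWN")

    bundle <- expression_bundle(mats$lncrna, mats$mirna, mats$mrna,
                                condition)
    de <- rbind(
      data.frame(feature_id = c(ids$UP$lncrna, ids$UP$mrna),
                 class = rep(c("lncRNA", "mRNA"), each = k),
                 direction = rep_len("up", 2L * k),
                 stringsAsFactors = FALSE),
      data.frame(feature_id = ids$UP$mirna,
                 class = rep_len("miRNA", k),
                 direction = rep_len("down", k), stringsAsFactors = FALSE),
      data.frame(feature_id = c(ids$DOWN$lncrna, ids$DOWN$mrna),
                 class = rep(c("lncRNA", "mRNA"), each = k),
                 direction = rep_len("down", 2L * k),
                 stringsAsFactors = FALSE),
      data.frame(feature_id = ids$DOWN$mirna,
                 class = rep_len("miRNA", k),
                 direction = rep_len("up", k), stringsAsFactors = FALSE))
    triplets <- rbind(
      data.frame(lncrna_id = ids$UP$lncrna, mirna_id = ids$UP$mirna,
                 mrna_id = ids$UP$mrna, stratum = rep_len("UP", k),
                 stringsAsFactors = FALSE),
      data.frame(lncrna_id = ids$DOWN$lncrna, mirna_id = ids$DOWN$mirna,
                 mrna_id = ids$DOWN$mrna, stratum = rep_len("DOWN", k),
                 stringsAsFactors = FALSE))
    truth <- structure(list(de = de, triplets = triplets,
                            sites = NULL, enriched_terms = NULL),
                       class = "cerna_ground_truth")
    list(bundle = bundle, truth = truth)
  })
}

random_rna <- function(n, gc_range = NULL) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
               collapse = "")
    if (is.null(gc_range)) return(s)
    gc <- (nchar(s) - nchar(gsub("[GC]", "", s))) / nchar(s)
    if (gc >= gc_range[1] && gc <= gc_range[2]) return(s)
  }
}

# All min_len-mers of the reverse complements of a miRNA set. A target
# contains a >= min_len exact complement to some miRNA iff it contains
# one of these k-mers.
complement_kmers <- function(mirnas, min_len = 8L) {
  unique(unlist(lapply(mirnas, function(m) {
    rc <- rna_revcomp(m)
    substring(rc, seq_len(nchar(rc) - min_len + 1L), min_len:nchar(rc))
  })))
}

has_seed_complement <- function(target, kmers, min_len = 8L) {
  n <- nchar(target)
  if (n < min_len) return(FALSE)
  any(substring(target, seq_len(n - min_len + 1L), min_len:n) %in% kmers)
}

# Starts of min_len windows of `target` that match a forbidden k-mer.
seed_complement_starts <- function(target, kmers, min_len = 8L) {
  n <- nchar(target)
  if (n < min_len) return(integer())
  which(substring(target, seq_len(n - min_len + 1L), min_len:n) %in% kmers)
}

# Draw a sequence free of forbidden k-mers by repair: start random, then
# repeatedly mutate one base inside each offending window. With many
# miRNAs a random 500-mer almost surely contains some complement k-mer,
# so whole-sequence rejection would not terminate; local repair converges
# in a handful of sweeps. `frozen` positions (planted sites) are never
# touched; windows overlapping them are masked out of the scan by the
# caller via `mask`.
repair_decoy <- function(s, kmers, frozen = integer(), min_len = 8L,
                         max_sweeps = 200L) {
  chars <- strsplit(s, "")[[1]]
  for (sweep in seq_len(max_sweeps)) {
    masked <- chars
    masked[frozen] <- "N"
    bad <- seed_complement_starts(paste(masked, collapse = ""), kmers,
                                  min_len)
    if (!length(bad)) return(paste(chars, collapse = ""))
    for (b in bad) {
      window <- setdiff(b:(b + min_len - 1L), frozen)
      pos <- window[sample.int(length(window), 1L)]
      chars[pos] <- sample(setdiff(c("A", "C", "G", "U"), chars[pos]), 1L)
    }
  }
  stop("decoy repair did not converge", call. = FALSE)
}

#' Simulate miRNA and target sequences with planted binding sites
#'
#' Every planted triplet's lncRNA and mRNA receives the exact reverse
#' complement (RNA alphabet) of the triplet's miRNA embedded at a
#' recorded 1-based position; all other (decoy) targets are
#' rejection-sampled to contain no exact complement of length >= 8 nt to
#' any miRNA, and planted targets carry no such complement outside their
#' recorded sites. miRNAs are sampled with GC fraction in [0.35, 0.65]
#' (the realistic range; an extreme AU-only miRNA would form a duplex
#' too weak for any stability threshold). Deterministic given the config.
#'
#' @param config [simulation_config()].
#' @param truth `cerna_ground_truth` from [simulate_expression()].
#' @return list with `mirna_seqs`, `target_seqs` (named character
#'   vectors; targets are all lncRNAs and mRNAs), `target_class` (named
#'   vector), and `truth` with `$sites` filled (mirna_id, target_id,
#'   target_class, start, end).
#' @export
simulate_sequences <- function(config = simulation_config(), truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "cerna_ground_truth"))
  withr::with_seed(config$seed + 1L, {
    ids <- planted_feature_ids(config)
    mirna_ids <- c(ids$UP$mirna, ids$DOWN$mirna,
                   sprintf("MIR_B%03d", seq_len(config$n_mirna)))
    L <- config$mirna_length
    mirna_seqs <- stats::setNames(
      vapply(mirna_ids, function(i) random_rna(L, c(0.35, 0.65)), ""),
      mirna_ids)

    target_ids <- c(ids$UP$lncrna, ids$DOWN$lncrna,
                    sprintf("LNC_B%03d", seq_len(config$n_lncrna)),
                    ids$UP$mrna, ids$DOWN$mrna,
                    sprintf("GENE_B%03d", seq_len(config$n_mrna)))
    target_class <- stats::setNames(
      ifelse(grepl("^LNC", target_ids), "lncRNA", "mRNA"), target_ids)

    # map planted target -> its miRNA
    tr <- truth$triplets
    site_mirna <- c(stats::setNames(tr$mirna_id, tr$lncrna_id),
                    stats::setNames(tr$mirna_id, tr$mrna_id))

    n <- config$seq_length_target
    kmers <- complement_kmers(mirna_seqs)
    sites <- list()
    target_seqs <- stats::setNames(character(length(target_ids)),
                                   target_ids)
    for (tg in target_ids) {
      mi <- site_mirna[tg]
      if (is.na(mi)) {
        # decoy: no >= 8-nt complement to any miRNA
        target_seqs[[tg]] <- repair_decoy(random_rna(n), kmers)
      } else {
        insert <- rna_revcomp(mirna_seqs[[mi]])
        nsit <- config$sites_per_target
        # non-overlapping slots for the planted site(s)
        starts <- sort(sample.int(n - nsit * L + 1L, nsit))
        starts <- starts + (seq_len(nsit) - 1L) * L
        s <- random_rna(n)
        for (st in starts)
          substr(s, st, st + L - 1L) <- insert
        # flanks must carry no spurious complement to any miRNA; the
        # planted sites themselves are frozen during repair
        frozen <- unlist(lapply(starts, function(st) st:(st + L - 1L)))
        target_seqs[[tg]] <- repair_decoy(s, kmers, frozen = frozen)
        for (st in starts)
          sites[[length(sites) + 1L]] <- data.frame(
            mirna_id = unname(mi), target_id = tg,
            target_class = unname(target_class[tg]),
            start = st, end = st + L - 1L, stringsAsFactors = FALSE)
      }
    }
    truth$sites <- if (length(sites)) do.call(rbind, sites) else
      data.frame(mirna_id = character(), target_id = character(),
                 target_class = character(), start = integer(),
                 end = integer(), stringsAsFactors = FALSE)
    list(mirna_seqs = mirna_seqs, target_seqs = target_seqs,
         target_class = target_class, truth = truth)
  })
}

#' Simulate gene-set collections with one planted enriched term
#'
#' One "enriched" term is packed with planted upregulated mRNAs
#' (`geneset_overlap` fraction of its members; the rest drawn from the
#' background mRNA universe) plus `n_background_terms` terms sampled
#' uniformly from the whole mRNA universe. Deterministic given config.
#'
#' @param config [simulation_config()].
#' @param truth `cerna_ground_truth` with planted DE mRNAs.
#' @return list with `collection` ([geneset_collection()]) and `truth`
#'   with `$enriched_terms` filled.
#' @export
simulate_genesets <- function(config = simulation_config(), truth) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "cerna_ground_truth"))
  withr::with_seed(config$seed + 2L, {
    ids <- planted_feature_ids(config)
    universe <- c(ids$UP$mrna, ids$DOWN$mrna,
                  sprintf("GENE_B%03d", seq_len(config$n_mrna)))
    size <- config$geneset_size
    if (size > length(universe))
      stop("geneset_size exceeds mRNA universe", call. = FALSE)
    planted_up <- ids$UP$mrna
    n_in <- as.integer(min(round(config$geneset_overlap * size),
                           length(planted_up)))
    members <- c(sample(planted_up, n_in),
                 sample(setdiff(universe, planted_up), size - n_in))
    term_ids <- c("TERM_ENRICHED",
                  sprintf("TERM_BG%03d", seq_len(config$n_background_terms)))
    term_names <- c("planted enriched process",
                    sprintf("background process %03d",
                            seq_len(config$n_background_terms)))
    all_members <- c(list(members),
                     lapply(seq_len(config$n_background_terms), function(i)
                       sample(universe, min(size, length(universe)))))
    collection <- geneset_collection(term_ids, term_names, all_members,
                                     namespace = "GO-BP")
    truth$enriched_terms <- data.frame(
      term_id = "TERM_ENRICHED", n_planted = n_in, size = size,
      stringsAsFactors = FALSE)
    list(collection = collection, truth = truth)
  })
}

#' Write ground truth as JSON
#'
#' @param truth `cerna_ground_truth`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read ground truth JSON written by [write_ground_truth()]
#'
#' @param path JSON path.
#' @return `cerna_ground_truth`.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("de", "triplets", "sites", "enriched_terms"))
    if (!is.null(x[[f]])) x[[f]] <- as.data.frame(x[[f]],
                                                  stringsAsFactors = FALSE)
  structure(x[c("de", "triplets", "sites", "enriched_terms")],
            class = "cerna_ground_truth")
}
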