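#' Pipeline run configuration
#'
#' Collects every stage threshold of the ceRNA pipeline with the
#' published screening defaults: differential expression (fold change
#' > 2, P < 0.05), target prediction (alignment score > 160, duplex
#' energy <= -30 kcal/mol), lncRNA-mRNA coexpression (r > 0.90,
#' P < 0.001), miRNA-target anticorrelation (r < 0, P < 0.05), hub
#' degree (> 8) and enrichment reporting (P < 0.05, top 30). All
#' thresholds are validated up front and echoed in the run summary so a
#' run is reproducible from its summary plus inputs.
#'
#' @param fc_threshold linear fold-change threshold (strict `>`).
#' @param de_p differential-expression p threshold (strict `<`).
#' @param score_min alignment score threshold (strict `>`).
#' @param energy_max duplex free-energy threshold, kcal/mol (`<=`).
#' @param r_min lncRNA-mRNA correlation threshold (strict `>`), in (0,1).
#' @param coexpr_p lncRNA-mRNA correlation p threshold (strict `<`).
#' @param anticorr_p miRNA-target anticorrelation p threshold.
#' @param hub_degree hub degree threshold (strict `>`).
#' @param enrich_p enrichment reporting p threshold.
#' @param top_n maximal reported enrichment records.
#' @param require_lnc_anticorr require miRNA-lncRNA anticorrelation in
#'   addition to miRNA-mRNA (the literal published filter; default TRUE).
#' @param ease use the EASE-adjusted enrichment score.
#' @param scheme [scoring_scheme()] used for target prediction;
#'   `score_min`/`energy_max` override its thresholds.
#' @return object of class `run_config`.
#' @export
run_config <- function(fc_threshold = 2.0, de_p = 0.05,
                       score_min = 160, energy_max = -30,
                       r_min = 0.90, coexpr_p = 0.001,
                       anticorr_p = 0.05, hub_degree = 8,
                       enrich_p = 0.05, top_n = 30,
                       require_lnc_anticorr = TRUE, ease = FALSE,
                       scheme = scoring_scheme()) {
  for (p in c(de_p = de_p, coexpr_p = coexpr_p, anticorr_p = anticorr_p,
              enrich_p = enrich_p))
    if (p <= 0 || p >= 1)
      stop("probability thresholds must lie in (0, 1)", call. = FALSE)
  if (r_min <= 0 || r_min >= 1)
    stop("r_min must lie in (0, 1)", call. = FALSE)
  if (fc_threshold < 1) stop("fc_threshold must be >= 1", call. = FALSE)
  if (score_min <= 0) stop("score_min must be positive", call. = FALSE)
  if (hub_degree < 0) stop("hub_degree must be >= 0", call. = FALSE)
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  scheme$score_min <- score_min
  scheme$energy_max <- energy_max
  structure(list(fc_threshold = fc_threshold, de_p = de_p,
                 score_min = score_min, energy_max = energy_max,
                 r_min = r_min, coexpr_p = coexpr_p,
                 anticorr_p = anticorr_p, hub_degree = hub_degree,
                 enrich_p = enrich_p, top_n = top_n,
                 require_lnc_anticorr = require_lnc_anticorr,
                 ease = ease, scheme = scheme),
            class = "run_config")
}

#' Run the full ceRNA network inference pipeline
#'
#' Executes, in order: two-class differential screening of the three RNA
#' classes; miRNA target prediction (differentially expressed miRNAs
#' against differentially expressed lncRNAs and mRNAs); miRNA-target
#' anticorrelation filtering; lncRNA-mRNA coexpression; triplet assembly
#' and network construction for both strata (UP: up-lncRNA / down-miRNA
#' / up-mRNA; DOWN mirrored); hub-lncRNA subnetwork extraction; and
#' hypergeometric enrichment of each network's mRNAs against the gene
#' sets. All stages are deterministic, so identical inputs and config
#' give identical outputs.
#'
#' @param bundle [expression_bundle()].
#' @param mirna_seqs,target_seqs named RNA sequence vectors (or FASTA
#'   paths); targets must cover the differentially expressed lncRNAs and
#'   mRNAs.
#' @param collection [geneset_collection()] (or GMT path); `NULL` skips
#'   enrichment.
#' @param config [run_config()].
#' @param output_dir if non-NULL, stage artifacts (TSV tables, SIF and
#'   GraphML exports, JSON summary) are written there.
#' @return object of class `cerna_run`: list with `de` (per-class
#'   records), `strata`, `pairs` (predicted), `pairs_filtered`,
#'   `coexpr` (per stratum), `networks` (per stratum `cerna_network`),
#'   `hub_networks`, `enrichment` (per stratum), `summary` (plain list,
#'   also written as JSON), `config`.
#' @export
run_pipeline <- function(bundle, mirna_seqs, target_seqs,
                         collection = NULL, config = run_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "run_config"),
            inherits(bundle, "expression_bundle"))
  if (is.character(mirna_seqs) && length(mirna_seqs) == 1L)
    mirna_seqs <- read_rna_fasta(mirna_seqs)
  if (is.character(target_seqs) && length(target_seqs) == 1L)
    target_seqs <- read_rna_fasta(target_seqs)
  if (is.character(collection) && length(collection) == 1L)
    collection <- read_gmt(collection)

  # 1. differential screening
  de <- lapply(stats::setNames(nm = c("lncrna", "mirna", "mrna")),
               function(cls) two_class_de(bundle, cls,
                                          fc_threshold = config$fc_threshold,
                                          p_threshold = config$de_p))
  strata <- lapply(de, stratify, fc_threshold = config$fc_threshold,
                   p_threshold = config$de_p)

  # 2. target prediction on the DE features only
  de_mirnas <- unique(c(strata$mirna$up, strata$mirna$down))
  de_lnc <- unique(c(strata$lncrna$up, strata$lncrna$down))
  de_mrna <- unique(c(strata$mrna$up, strata$mrna$down))
  missing_seq <- setdiff(c(de_mirnas, de_lnc, de_mrna),
                         c(names(mirna_seqs), names(target_seqs)))
  if (length(missing_seq))
    warning("no sequence for ", length(missing_seq),
            " DE feature(s); they cannot enter the network",
            call. = FALSE)
  pairs_lnc <- predict_targets(mirna_seqs[intersect(de_mirnas,
                                                    names(mirna_seqs))],
                               target_seqs[intersect(de_lnc,
                                                     names(target_seqs))],
                               scheme = config$scheme,
                               target_class = "lncRNA")
  pairs_mrna <- predict_targets(mirna_seqs[intersect(de_mirnas,
                                                     names(mirna_seqs))],
                                target_seqs[intersect(de_mrna,
                                                      names(target_seqs))],
                                scheme = config$scheme,
                                target_class = "mRNA")
  pairs <- rbind(as.data.frame(pairs_lnc), as.data.frame(pairs_mrna))

  # 3. anticorrelation filter
  pairs_filtered <- mirna_anticorrelation_filter(bundle, pairs,
                                                 p_max = config$anticorr_p)

  # 4. coexpression, 5. assembly + networks per stratum
  networks <- list(); coexpr <- list(); triplets <- list()
  for (stratum in c("UP", "DOWN")) {
    lnc_set <- if (stratum == "UP") strata$lncrna$up else strata$lncrna$down
    mrna_set <- if (stratum == "UP") strata$mrna$up else strata$mrna$down
    ce <- lncrna_mrna_edges(bundle, lnc_set, mrna_set,
                            r_min = config$r_min, p_max = config$coexpr_p)
    tri <- assemble_triplets(strata, pairs_filtered, ce, stratum,
                             require_lnc_anticorr =
                               config$require_lnc_anticorr,
                             unfiltered_pairs = pairs)
    coexpr[[stratum]] <- ce
    triplets[[stratum]] <- tri
    networks[[stratum]] <- build_network(tri)
  }

  # 6. hub subnetworks (post-hoc extraction from the finished networks)
  hub_networks <- lapply(networks, extract_hub_subnetwork,
                         min_degree_exclusive = config$hub_degree)

  # 7. enrichment of each network's mRNAs
  enrichment <- NULL
  if (!is.null(collection)) {
    universe <- rownames(bundle$mrna)
    enrichment <- lapply(networks, function(net) {
      sel <- net$nodes$id[net$nodes$class == "mRNA"]
      rec <- enrich(sel, collection, universe, ease = config$ease)
      list(records = rec,
           top = report_top(rec, p_max = config$enrich_p,
                            top_n = config$top_n))
    })
  }

  run_summary <- list(
    parameters = config_as_list(config),
    de_counts = lapply(strata, function(s)
      list(up = length(s$up), down = length(s$down))),
    n_predicted_pairs = nrow(pairs),
    n_filtered_pairs = nrow(pairs_filtered),
    strata = lapply(stats::setNames(nm = c("UP", "DOWN")), function(st) {
      net <- networks[[st]]
      hubs <- summary.cerna_network(net,
                                    hub_degree = config$hub_degree)$hub_lncrnas
      list(n_triplets = nrow(net$triplets),
           n_nodes = as.list(table(factor(net$nodes$class,
                                          c("lncRNA", "miRNA", "mRNA")))),
           n_edges = nrow(net$edges),
           hub_lncrnas = as.list(hubs),
           top_terms = if (!is.null(enrichment))
             as.list(utils::head(enrichment[[st]]$top$report$term_id, 5L))
           else list())
    }))

  run <- structure(list(de = de, strata = strata, pairs = pairs,
                        pairs_filtered = pairs_filtered, coexpr = coexpr,
                        networks = networks, hub_networks = hub_networks,
                        enrichment = enrichment, summary = run_summary,
                        config = config),
                   class = "cerna_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' Load a pipeline configuration from a flat YAML file
#'
#' The file holds flat `key: value` pairs matching the arguments of
#' [run_config()] (thresholds, flags); unknown keys are an error.
#' Explicit `overrides` (e.g. from a command line) win over file values.
#'
#' @param path YAML file path.
#' @param overrides named list of values overriding the file.
#' @return [run_config()] object.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$scheme <- unclass(out$scheme)
  out
}

#' @export
print.cerna_run <- function(x, ...) {
  cat("ceRNA pipeline run\n")
  for (cls in names(x$strata))
    cat(sprintf("  DE %-6s: %d up / %d down\n", cls,
                length(x$strata[[cls]]$up), length(x$strata[[cls]]$down)))
  cat(sprintf("  predicted pairs: %d (%d after anticorrelation filter)\n",
              nrow(x$pairs), nrow(x$pairs_filtered)))
  for (st in names(x$networks)) {
    s <- x$summary$strata[[st]]
    cat(sprintf("  %s network: %d triplets, %d lncRNA / %d miRNA / %d mRNA nodes, %d edges\n",
                st, s$n_triplets, s$n_nodes$lncRNA, s$n_nodes$miRNA,
                s$n_nodes$mRNA, s$n_edges))
  }
  invisible(x)
}

# Write all stage artifacts of a run: TSV result tables, SIF + GraphML
# exports per stratum, and the JSON run summary.
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cls in names(run$de))
    utils::write.table(run$de[[cls]], file.path(dir, paste0("de_", cls,
                                                            ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$pairs, file.path(dir, "target_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$pairs_filtered,
                     file.path(dir, "target_pairs_filtered.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (st in names(run$networks)) {
    write_triplets(run$networks[[st]]$triplets,
                   file.path(dir, paste0("triplets_", st, ".tsv")))
    write_network(run$networks[[st]],
                  file.path(dir, paste0("network_", st, ".sif")), "sif")
    write_network(run$networks[[st]],
                  file.path(dir, paste0("network_", st, ".graphml")),
                  "graphml")
    write_network(run$hub_networks[[st]],
                  file.path(dir, paste0("hub_network_", st, ".sif")), "sif")
    if (!is.null(run$enrichment))
      utils::write.table(run$enrichment[[st]]$records,
                         file.path(dir, paste0("enrichment_", st, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
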