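#' Hypergeometric gene-set over-representation analysis
#'
#' For each term, tests whether the selected genes overlap the term's
#' members more than expected under sampling without replacement from the
#' universe: the upper-tail hypergeometric probability
#' `P(X >= k)` with `N` universe genes, `K` term genes in the universe,
#' `n` selected genes and overlap `k`. Term membership is intersected
#' with the universe before testing; terms with no member in the universe
#' are dropped. The universe should be the genes measurable on the
#' platform, not the genome — the standard over-representation choice.
#'
#' `ease = TRUE` applies the conservative EASE adjustment (one overlap
#' gene is discounted, i.e. the test uses `k - 1`), mimicking
#' DAVID-style scores; the default is the exact test.
#'
#' @param selected character vector of selected gene ids (must be a
#'   subset of `universe`).
#' @param collection [geneset_collection()].
#' @param universe character vector of all assayable gene ids.
#' @param ease use the EASE-adjusted score instead of the exact test.
#' @return data.frame of class `enrichment_records`, sorted by ascending
#'   p then term_id: term_id, term_name, namespace, N, K, n, k,
#'   fold_enrichment, p_hypergeom, bh_q, overlap (comma-joined gene ids).
#' @export
enrich <- function(selected, collection, universe, ease = FALSE) {
  stopifnot(inherits(collection, "geneset_collection"))
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  offenders <- setdiff(selected, universe)
  if (length(offenders))
    stop("selected gene(s) not in universe: ",
         paste(utils::head(offenders, 10L), collapse = ", "), call. = FALSE)
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(unclass(collection), function(term) {
    members <- intersect(term$members, universe)
    K <- length(members)
    if (K < 1L) return(NULL)
    overlap <- intersect(selected, members)
    k <- length(overlap)
    kk <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(kk - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term$term_id, term_name = term$term_name,
               namespace = term$namespace, N = N, K = K, n = n, k = k,
               fold_enrichment = if (n > 0L) (k / n) / (K / N) else 0,
               p_hypergeom = p,
               overlap = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(), term_name = character(),
               namespace = character(), N = integer(), K = integer(),
               n = integer(), k = integer(), fold_enrichment = numeric(),
               p_hypergeom = numeric(), overlap = character(),
               stringsAsFactors = FALSE)
  res$bh_q <- stats::p.adjust(res$p_hypergeom, method = "BH")
  res <- res[order(res$p_hypergeom, res$term_id), , drop = FALSE]
  res <- res[, c("term_id", "term_name", "namespace", "N", "K", "n", "k",
                 "fold_enrichment", "p_hypergeom", "bh_q", "overlap")]
  rownames(res) <- NULL
  class(res) <- c("enrichment_records", "data.frame")
  res
}

#' Report the top significant enrichment records
#'
#' Keeps records with raw `p < p_max` (strict) and truncates to the first
#' `top_n` (the records are already sorted by p). Counts of significant
#' terms are reported per namespace before truncation.
#'
#' @param records `enrichment_records` from [enrich()].
#' @param p_max raw p-value cut (strict `<`).
#' @param top_n maximal number of reported records.
#' @return list with `report` (the truncated data.frame),
#'   `n_significant` (total significant count) and
#'   `n_significant_by_namespace` (named integer vector).
#' @export
report_top <- function(records, p_max = 0.05, top_n = 30) {
  sig <- records[records$p_hypergeom < p_max, , drop = FALSE]
  by_ns <- table(sig$namespace)
  list(report = utils::head(sig, top_n),
       n_significant = nrow(sig),
       n_significant_by_namespace =
         stats::setNames(as.integer(by_ns), names(by_ns)))
}
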