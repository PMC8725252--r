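#' Two-class differential screening of one RNA class
#'
#' Pooled-variance ("Student's") two-sample t-test on log2 values,
#' feature by feature, induced vs control. The signed linear fold change
#' is computed from the difference of log2 means (the geometric-mean
#' ratio, the microarray convention): `+2^D` for `D >= 0` and `-2^(-D)`
#' otherwise, where `D = mean_induced - mean_control`, so its magnitude
#' is always >= 1. Welch's unequal-variance test is available via
#' `var_equal = FALSE`.
#'
#' Degenerate features are handled so that noiseless simulated data can
#' flow through the pipeline: zero variance in both conditions with equal
#' means gives t = 0, p = 1; zero pooled variance with unequal means is
#' reported as p = 0 with `degenerate = TRUE`.
#'
#' No multiple-testing correction is applied to the screening decision
#' (the published filter uses raw P); a Benjamini-Hochberg column `bh_q`
#' is emitted for information.
#'
#' @param bundle [expression_bundle()].
#' @param rna_class one of "lncrna", "mirna", "mrna".
#' @param fc_threshold fold-change threshold (exclusive) for the
#'   up/down call.
#' @param p_threshold raw p-value threshold (exclusive).
#' @param var_equal pooled-variance t (default) or Welch.
#' @return data.frame of class `de_records`: feature_id, feature_class,
#'   mean_induced, mean_control, signed_fold_change, t_statistic, p_value,
#'   bh_q, degenerate, direction ("up"/"down"/"ns").
#' @export
two_class_de <- function(bundle, rna_class = c("lncrna", "mirna", "mrna"),
                         fc_threshold = 2.0, p_threshold = 0.05,
                         var_equal = TRUE) {
  stopifnot(inherits(bundle, "expression_bundle"))
  rna_class <- match.arg(rna_class)
  m <- bundle[[rna_class]]
  ind <- bundle$condition == "induced"
  ctl <- bundle$condition == "control"
  n1 <- sum(ind); n2 <- sum(ctl)
  if (n1 < 2L || n2 < 2L)
    stop("need >= 2 samples per condition", call. = FALSE)

  x1 <- m[, ind, drop = FALSE]; x2 <- m[, ctl, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  delta <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep_len(n1 + n2 - 2L, nrow(m))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  t_stat <- delta / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  degenerate <- !is.finite(t_stat)
  # zero pooled variance: equal means -> t=0/p=1; unequal -> p=0 + flag
  zero_eq <- degenerate & delta == 0
  zero_ne <- degenerate & delta != 0
  t_stat[zero_eq] <- 0; p[zero_eq] <- 1
  t_stat[zero_ne] <- sign(delta[zero_ne]) * Inf; p[zero_ne] <- 0
  degenerate <- zero_ne
  if (any(degenerate))
    warning(sum(degenerate), " feature(s) with zero within-condition ",
            "variance and unequal means; p reported as 0", call. = FALSE)

  sfc <- ifelse(delta >= 0, 2^delta, -(2^(-delta)))
  direction <- ifelse(sfc > fc_threshold & p < p_threshold, "up",
               ifelse(sfc < -fc_threshold & p < p_threshold, "down", "ns"))
  res <- data.frame(
    feature_id = rownames(m),
    feature_class = c(lncrna = "lncRNA", mirna = "miRNA",
                      mrna = "mRNA")[[rna_class]],
    mean_induced = m1, mean_control = m2,
    signed_fold_change = sfc, t_statistic = t_stat, p_value = p,
    bh_q = stats::p.adjust(p, method = "BH"),
    degenerate = degenerate, direction = direction,
    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_records", "data.frame")
  res
}

#' Stratify differential records into up/down id sets
#'
#' Both thresholds are exclusive (strict inequalities): a feature with
#' fold change exactly equal to `fc_threshold` is not called.
#'
#' @param records `de_records` from [two_class_de()].
#' @param fc_threshold linear fold-change threshold (strict `>`).
#' @param p_threshold raw p threshold (strict `<`).
#' @return list with character vectors `up` and `down`.
#' @export
stratify <- function(records, fc_threshold = 2.0, p_threshold = 0.05) {
  up <- records$signed_fold_change > fc_threshold &
    records$p_value < p_threshold
  down <- records$signed_fold_change < -fc_threshold &
    records$p_value < p_threshold
  list(up = records$feature_id[up], down = records$feature_id[down])
}
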