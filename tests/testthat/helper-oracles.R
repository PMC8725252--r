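# Independent oracles used to cross-check the package's computations.
# Each is written as a direct transcription of the defining formula or an
# explicit enumeration, deliberately sharing no code with the package.

# Textbook pooled-variance two-sample t-test, scalar form.
oracle_pooled_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
}

# Product-moment correlation from the raw definition plus t-transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else
    2 * pt(abs(r * sqrt((n - 2) / (1 - r^2))), n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, n) draws. Feasible for the small grids used in tests.
oracle_hypergeom_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  in_term <- draws <= K  # wlog term genes are 1..K
  mean(colSums(in_term) >= k)
}

# --- alignment oracles -----------------------------------------------------

align_base_score <- function(q, t, match, wobble, mismatch) {
  if ((q == "A" && t == "U") || (q == "U" && t == "A") ||
      (q == "G" && t == "C") || (q == "C" && t == "G")) return(match)
  if ((q == "G" && t == "U") || (q == "U" && t == "G")) return(wobble)
  mismatch
}

# Best local alignment score by bottom-up dynamic programming in R,
# written independently of the compiled kernel (same affine gap model:
# first gap base gap_open, each further gap_extend; gaps cannot switch
# strands without reopening).
oracle_local_align <- function(query, target, qweight, match, wobble,
                               mismatch, gap_open, gap_extend) {
  qs <- strsplit(query, "")[[1]]; ts <- strsplit(target, "")[[1]]
  m <- length(qs); n <- length(ts)
  if (m == 0 || n == 0) return(0)
  NEG <- -Inf
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 1:m) for (j in 1:n) {
    X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open, X[i, j + 1] + gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open, Y[i + 1, j] + gap_extend)
    s <- qweight[i] * align_base_score(qs[i], ts[j], match, wobble, mismatch)
    M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
    if (M[i + 1, j + 1] < 0) M[i + 1, j + 1] <- 0
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# True exhaustive enumeration of every local alignment path (each path a
# sequence of diagonal/gap moves ending anywhere), for very small inputs.
oracle_local_align_bruteforce <- function(query, target, qweight, match,
                                          wobble, mismatch, gap_open,
                                          gap_extend) {
  qs <- strsplit(query, "")[[1]]; ts <- strsplit(target, "")[[1]]
  m <- length(qs); n <- length(ts)
  best <- 0
  # extend(i, j, state): best over all continuations after having just
  # consumed an alignment column ending at (i, j); state "" none-open,
  # "q"/"t" an open gap run on that strand
  extend <- function(i, j, score, state) {
    best <<- max(best, score)
    if (i < m && j < n) {
      s <- qweight[i + 1] *
        align_base_score(qs[i + 1], ts[j + 1], match, wobble, mismatch)
      extend(i + 1, j + 1, score + s, "")
    }
    if (i < m)
      extend(i + 1, j,
             score + if (state == "q") gap_extend else gap_open, "q")
    if (j < n)
      extend(i, j + 1,
             score + if (state == "t") gap_extend else gap_open, "t")
  }
  for (i in 0:(m - 1)) for (j in 0:(n - 1)) {
    s <- qweight[i + 1] *
      align_base_score(qs[i + 1], ts[j + 1], match, wobble, mismatch)
    extend(i + 1, j + 1, s, "")
  }
  best
}

# --- network oracles -------------------------------------------------------

# Brute-force triple loop applying the triplet predicate directly.
oracle_assemble_triplets <- function(strata, pairs, edges, stratum) {
  lnc_set <- if (stratum == "UP") strata$lncrna$up else strata$lncrna$down
  mir_set <- if (stratum == "UP") strata$mirna$down else strata$mirna$up
  mrna_set <- if (stratum == "UP") strata$mrna$up else strata$mrna$down
  has_pair <- function(mi, tg, cls)
    any(pairs$mirna_id == mi & pairs$target_id == tg &
        pairs$target_class == cls)
  has_edge <- function(l, g) any(edges$a_id == l & edges$b_id == g)
  out <- NULL
  for (l in lnc_set) for (mi in mir_set) for (g in mrna_set)
    if (has_pair(mi, l, "lncRNA") && has_pair(mi, g, "mRNA") &&
        has_edge(l, g))
      out <- rbind(out, data.frame(lncrna_id = l, mirna_id = mi,
                                   mrna_id = g, stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(lncrna_id = character(), mirna_id = character(),
                      mrna_id = character(), stringsAsFactors = FALSE)
  out[order(out$lncrna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
}

# Filter-and-induce oracle for hub extraction: recompute degrees by
# counting incident edges, pick lncRNAs above the cut, keep exactly the
# triplets containing one.
oracle_hub_extract <- function(net, cut) {
  ids <- c(net$edges$from, net$edges$to)
  lnc <- net$nodes$id[net$nodes$class == "lncRNA"]
  hubs <- lnc[vapply(lnc, function(x) sum(ids == x), 0L) > cut]
  net$triplets[net$triplets$lncrna_id %in% hubs, , drop = FALSE]
}
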