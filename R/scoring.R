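#' Duplex alignment scoring scheme
#'
#' Parameters of the seed-weighted local duplex alignment and the two
#' pass thresholds used for target prediction. The two thresholds
#' (`score_min = 160`, `energy_max = -30` kcal/mol) are the published
#' screening cut-offs; the internal alignment weights are this package's
#' own defaults, all configurable and echoed in every run summary.
#'
#' The seed region (miRNA positions `seed_start`..`seed_end`, 5'->3')
#' has all its substitution scores multiplied by `seed_weight`, reflecting
#' the dominant contribution of seed pairing to miRNA targeting. With the
#' defaults a perfect 22-nt complement scores 7*5*4 + 15*5 = 215.
#'
#' @param match score of a Watson-Crick pair (A:U, G:C).
#' @param wobble score of a G:U wobble pair.
#' @param mismatch score of a non-pairing column.
#' @param gap_open cost of the first base of a gap (negative).
#' @param gap_extend cost of each further gap base (negative).
#' @param seed_start,seed_end 1-based miRNA positions of the seed region.
#' @param seed_weight multiplier applied to substitution scores at seed
#'   positions.
#' @param score_min minimal alignment score (exclusive) for a site to pass.
#' @param energy_max maximal duplex free energy in kcal/mol (inclusive)
#'   for a site to pass; more negative = more stable.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, wobble = 2, mismatch = -3,
                           gap_open = -9, gap_extend = -4,
                           seed_start = 2, seed_end = 8, seed_weight = 4,
                           score_min = 160, energy_max = -30) {
  if (gap_open >= 0 || gap_extend >= 0)
    stop("gap penalties must be negative", call. = FALSE)
  if (score_min <= 0) stop("score_min must be positive", call. = FALSE)
  if (seed_start < 1 || seed_end < seed_start)
    stop("invalid seed region", call. = FALSE)
  structure(list(match = match, wobble = wobble, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed_start = seed_start, seed_end = seed_end,
                 seed_weight = seed_weight,
                 score_min = score_min, energy_max = energy_max),
            class = "scoring_scheme")
}

# Normalise a sequence to the RNA alphabet. DNA (T) is transcribed to U
# with a warning; anything outside {A,C,G,U} is an error.
as_rna <- function(seq, what = "sequence") {
  seq <- toupper(as.character(seq))
  if (grepl("T", seq, fixed = TRUE)) {
    warning("DNA alphabet detected in ", what, "; transcribing T -> U",
            call. = FALSE)
    seq <- chartr("T", "U", seq)
  }
  bad <- gsub("[ACGU]", "", seq)
  if (nzchar(bad))
    stop("non-RNA character(s) '", substr(bad, 1, 5), "' in ", what,
         call. = FALSE)
  seq
}

rna_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "")[[1]]), collapse = "")
}

pair_symbol <- function(q, t) {
  wc <- (q == "A" & t == "U") | (q == "U" & t == "A") |
        (q == "G" & t == "C") | (q == "C" & t == "G")
  wob <- (q == "G" & t == "U") | (q == "U" & t == "G")
  ifelse(wc, "|", ifelse(wob, ":", " "))
}

#' Predict miRNA binding sites on one target by local duplex alignment
#'
#' Aligns the reversed miRNA (3'->5') against the target (5'->3') with a
#' Smith-Waterman/Gotoh local alignment under the complementarity scoring
#' of `scheme`. All non-overlapping local alignments with score > 0 are
#' reported, found greedily by score (best site first, then the target is
#' split at that site and the flanks re-searched).
#'
#' @param mirna_seq miRNA sequence, 5'->3', length 18-26 nt.
#' @param target_seq target sequence, 5'->3'.
#' @param scheme [scoring_scheme()].
#' @param min_score only sites scoring strictly above this value are
#'   reported (default 0: all positive local maxima). Because the best
#'   alignment within any sub-segment cannot out-score the segment's own
#'   best, raising this is a lossless pruning for downstream threshold
#'   filters.
#' @return list of `duplex_site` objects sorted by decreasing score
#'   (ties by target_start); each has target 1-based inclusive coordinates
#'   `target_start`/`target_end`, miRNA coordinates (5'->3'), `score`,
#'   the aligned miRNA string (3'->5'), the pairing line (`|` Watson-Crick,
#'   `:` wobble, space otherwise) and the aligned target string (5'->3').
#' @export
align_duplex <- function(mirna_seq, target_seq, scheme = scoring_scheme(),
                         min_score = 0) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  mirna_seq <- as_rna(mirna_seq, "miRNA")
  L <- nchar(mirna_seq)
  if (L < 18 || L > 26)
    stop("miRNA length must be 18-26 nt, got ", L, call. = FALSE)
  target_seq <- as_rna(target_seq, "target")
  if (!nchar(target_seq)) return(list())
  # query = reversed miRNA; reversed index i maps to miRNA position L-i+1
  query <- paste(rev(strsplit(mirna_seq, "")[[1]]), collapse = "")
  pos <- L - seq_len(L) + 1L
  qweight <- ifelse(pos >= scheme$seed_start & pos <= scheme$seed_end,
                    scheme$seed_weight, 1)

  sites <- list()
  search <- function(lo, hi) {
    if (hi - lo + 1L < 1L) return(invisible())
    hit <- .cpp_best_local_duplex(query, substr(target_seq, lo, hi), qweight,
                                  scheme$match, scheme$wobble,
                                  scheme$mismatch, scheme$gap_open,
                                  scheme$gap_extend)
    if (hit$score <= min_score) return(invisible())
    tstart <- lo + hit$tstart - 1L
    tend <- lo + hit$tend - 1L
    qa <- strsplit(hit$qaln, "")[[1]]
    ta <- strsplit(hit$taln, "")[[1]]
    site <- structure(list(
      mirna_id = NA_character_, target_id = NA_character_,
      target_class = NA_character_,
      target_start = tstart, target_end = tend,
      mirna_start = L - hit$qend + 1L, mirna_end = L - hit$qstart + 1L,
      score = hit$score,
      mirna_aln = hit$qaln,
      pairing = paste(ifelse(qa == "-" | ta == "-", " ",
                             pair_symbol(qa, ta)), collapse = ""),
      target_aln = hit$taln), class = "duplex_site")
    sites[[length(sites) + 1L]] <<- site
    search(lo, tstart - 1L)
    search(tend + 1L, hi)
    invisible()
  }
  search(1L, nchar(target_seq))
  if (!length(sites)) return(list())
  ord <- order(-vapply(sites, `[[`, 0, "score"),
               vapply(sites, `[[`, 0L, "target_start"))
  sites[ord]
}

#' @export
print.duplex_site <- function(x, ...) {
  cat(sprintf("duplex site  score %.1f  target %s:%d-%d  miRNA %s:%d-%d\n",
              x$score, x$target_id, x$target_start, x$target_end,
              x$mirna_id, x$mirna_start, x$mirna_end))
  cat("  target 5' ", x$target_aln, " 3'\n", sep = "")
  cat("            ", x$pairing, "\n", sep = "")
  cat("  miRNA  3' ", x$mirna_aln, " 5'\n", sep = "")
  invisible(x)
}

#' Re-score a stored duplex alignment under a scoring scheme
#'
#' Walks the stored aligned strings column by column and recomputes the
#' alignment score (seed weighting by miRNA position, affine gap costs).
#' For any site produced by [align_duplex()] this reproduces `site$score`
#' exactly.
#'
#' @param site `duplex_site`.
#' @param scheme [scoring_scheme()].
#' @return numeric score.
#' @export
rescore_alignment <- function(site, scheme = scoring_scheme()) {
  qa <- strsplit(site$mirna_aln, "")[[1]]
  ta <- strsplit(site$target_aln, "")[[1]]
  stopifnot(length(qa) == length(ta))
  base <- function(q, t) {
    sym <- pair_symbol(q, t)
    if (sym == "|") scheme$match else if (sym == ":") scheme$wobble
    else scheme$mismatch
  }
  score <- 0
  pos <- site$mirna_end  # leftmost column is the miRNA 3' end of the site
  in_gap <- ""          # "", "q" or "t": which strand the open gap run is on
  for (k in seq_along(qa)) {
    if (qa[k] == "-" || ta[k] == "-") {
      strand <- if (qa[k] == "-") "q" else "t"
      score <- score +
        if (identical(in_gap, strand)) scheme$gap_extend else scheme$gap_open
      in_gap <- strand
      if (ta[k] == "-") pos <- pos - 1L  # miRNA base consumed opposite a gap
    } else {
      w <- if (pos >= scheme$seed_start && pos <= scheme$seed_end)
        scheme$seed_weight else 1
      score <- score + w * base(qa[k], ta[k])
      pos <- pos - 1L
      in_gap <- ""
    }
  }
  score
}
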