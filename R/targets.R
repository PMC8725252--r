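#' Read a FASTA file as named RNA sequences
#'
#' Sequences are uppercased and transcribed to the RNA alphabet (T -> U
#' with a warning). Duplicate ids are an error.
#'
#' @param path FASTA path.
#' @return named character vector of RNA sequences.
#' @export
read_rna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- as.character(set)
  names(seqs) <- ids
  vapply(seqs, as_rna, "", what = paste0("sequence in ", basename(path)))
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_rna_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Predict miRNA-target pairs passing the score and energy thresholds
#'
#' Runs [align_duplex()] for every (miRNA, target) combination, computes
#' each site's duplex free energy, and keeps the pairs having at least one
#' site with alignment score strictly above `scheme$score_min` and energy
#' at most `scheme$energy_max` kcal/mol. Each pair carries its best site
#' (highest score; ties broken by lower energy, then smaller target
#' start — total determinism) and the number of passing sites.
#'
#' @param mirnas named character vector of miRNA sequences (or a FASTA
#'   path), 5'->3'.
#' @param targets named character vector of target sequences (or a FASTA
#'   path), 5'->3'.
#' @param scheme [scoring_scheme()].
#' @param target_class class label recorded for the targets ("lncRNA" or
#'   "mRNA").
#' @return data.frame of class `target_pairs` with one row per passing
#'   pair: mirna_id, target_id, target_class, score, energy, target_start,
#'   target_end, n_sites. The full per-site table (all passing sites) is
#'   attached as attribute `"sites"`; the site objects as `"site_objects"`.
#' @export
predict_targets <- function(mirnas, targets, scheme = scoring_scheme(),
                            target_class = "mRNA") {
  if (is.character(mirnas) && length(mirnas) == 1L && file.exists(mirnas))
    mirnas <- read_rna_fasta(mirnas)
  if (is.character(targets) && length(targets) == 1L && file.exists(targets))
    targets <- read_rna_fasta(targets)
  if (anyDuplicated(names(mirnas)))
    stop("duplicate miRNA id", call. = FALSE)
  if (anyDuplicated(names(targets)))
    stop("duplicate target id", call. = FALSE)
  stack <- duplex_stack_table()

  rows <- list()
  site_rows <- list()
  site_objects <- list()
  for (mi in names(mirnas)) {
    for (tg in names(targets)) {
      sites <- align_duplex(mirnas[[mi]], targets[[tg]], scheme,
                            min_score = scheme$score_min)
      if (!length(sites)) next
      sites <- lapply(sites, function(s) {
        s$energy <- duplex_energy(s, stack)
        s$mirna_id <- mi; s$target_id <- tg; s$target_class <- target_class
        s
      })
      keep <- Filter(function(s)
        s$score > scheme$score_min && s$energy <= scheme$energy_max, sites)
      if (!length(keep)) next
      ord <- order(-vapply(keep, `[[`, 0, "score"),
                   vapply(keep, `[[`, 0, "energy"),
                   vapply(keep, `[[`, 0L, "target_start"))
      keep <- keep[ord]
      best <- keep[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mi, target_id = tg, target_class = target_class,
        score = best$score, energy = best$energy,
        target_start = best$target_start, target_end = best$target_end,
        n_sites = length(keep), stringsAsFactors = FALSE)
      for (s in keep) {
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          mirna_id = mi, target_id = tg, target_class = target_class,
          target_start = s$target_start, target_end = s$target_end,
          mirna_start = s$mirna_start, mirna_end = s$mirna_end,
          score = s$score, energy = s$energy, stringsAsFactors = FALSE)
        site_objects[[length(site_objects) + 1L]] <- s
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), target_id = character(),
               target_class = character(), score = numeric(),
               energy = numeric(), target_start = integer(),
               target_end = integer(), n_sites = integer(),
               stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$mirna_id, pairs$target_id), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "sites") <- if (length(site_rows)) do.call(rbind, site_rows)
    else NULL
  attr(pairs, "site_objects") <- site_objects
  class(pairs) <- c("target_pairs", "data.frame")
  pairs
}
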