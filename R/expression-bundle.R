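#' Expression bundle: three aligned feature-by-sample matrices
#'
#' An `expression_bundle` holds log2 abundance matrices for the three RNA
#' classes (lncRNA, miRNA, mRNA) over one common ordered set of samples,
#' together with a two-level condition label (`induced` vs `control`) per
#' sample. It is the primary input of the ceRNA pipeline.
#'
#' Matrices are declared log2-scale by contract; no automatic log detection
#' is performed (silent re-logging is a classic corruption source). Missing
#' values are rejected rather than imputed.
#'
#' @param lncrna,mirna,mrna numeric matrices (features x samples) with
#'   rownames (feature ids) and colnames (sample ids), log2 scale.
#' @param condition character or factor of per-sample labels, values in
#'   `c("induced", "control")`, named by or ordered as the shared samples.
#' @return An object of class `expression_bundle`: a list with elements
#'   `lncrna`, `mirna`, `mrna`, `samples`, `condition`.
#' @examples
#' m <- function(ids) matrix(rnorm(length(ids) * 4), nrow = length(ids),
#'   dimnames = list(ids, paste0("S", 1:4)))
#' b <- expression_bundle(m(c("L1", "L2")), m("M1"), m(c("G1", "G2")),
#'   condition = c("induced", "induced", "control", "control"))
#' @export
expression_bundle <- function(lncrna, mirna, mrna, condition) {
  mats <- list(lncrna = lncrna, mirna = mirna, mrna = mrna)
  for (cls in names(mats)) {
    m <- mats[[cls]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("'", cls, "' must be a numeric matrix", call. = FALSE)
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop("'", cls, "' must have feature rownames and sample colnames",
           call. = FALSE)
    if (anyDuplicated(rownames(m)))
      stop("duplicate feature id in class '", cls, "': ",
           paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
           call. = FALSE)
    if (!all(is.finite(m)))
      stop("non-finite values in '", cls, "' matrix", call. = FALSE)
  }
  samples <- colnames(lncrna)
  for (cls in c("mirna", "mrna"))
    if (!identical(colnames(mats[[cls]]), samples))
      stop("sample columns of '", cls, "' do not match lncRNA matrix",
           call. = FALSE)
  condition <- as.character(condition)
  if (!is.null(names(condition))) condition <- condition[samples]
  if (length(condition) != length(samples) || anyNA(condition))
    stop("'condition' must give one label per sample", call. = FALSE)
  if (!all(condition %in% c("induced", "control")))
    stop("condition labels must be 'induced' or 'control'", call. = FALSE)
  if (any(table(factor(condition, c("induced", "control"))) < 2))
    stop("need >= 2 samples per condition", call. = FALSE)
  structure(list(lncrna = lncrna, mirna = mirna, mrna = mrna,
                 samples = samples,
                 condition = stats::setNames(condition, samples)),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat("ceRNA expression bundle\n")
  for (cls in c("lncrna", "mirna", "mrna"))
    cat(sprintf("  %-6s %5d features\n", cls, nrow(x[[cls]])))
  tab <- table(factor(x$condition, c("induced", "control")))
  cat(sprintf("  %d samples (%d induced / %d control)\n",
              length(x$samples), tab[["induced"]], tab[["control"]]))
  invisible(x)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id` and `condition`
#'   (`induced`/`control`).
#' @return data.frame with columns `sample_id`, `condition`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(sheet)))
    stop("sample sheet must have columns 'sample_id' and 'condition': ", path,
         call. = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet: ", path, call. = FALSE)
  if (!all(sheet$condition %in% c("induced", "control")))
    stop("sample sheet conditions must be 'induced' or 'control'",
         call. = FALSE)
  if (length(unique(sheet$condition)) < 2)
    stop("sample sheet must contain both conditions", call. = FALSE)
  sheet[, c("sample_id", "condition")]
}

# Read one feature-by-sample TSV; strict numeric parse, cells named on error.
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2)
    stop("expression table needs a feature column plus samples: ", path,
         call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L,
              dimnames = list(ids, names(raw)[-1L]))
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s' in %s",
                   raw[[j + 1L]][bad[1L]], ids[bad[1L]], colnames(m)[j], path),
           call. = FALSE)
    m[, j] <- v
  }
  m
}

#' Read an expression bundle from three TSV matrices plus a sample sheet
#'
#' Each TSV has a header row of sample ids and a first column of feature
#' ids (one file per RNA class, mirroring the separate source platforms).
#' Columns are reordered to the sample-sheet order; every sheet sample must
#' be present in every matrix.
#'
#' @param lncrna_path,mirna_path,mrna_path paths to the three class TSVs.
#' @param sheet_path path to the sample sheet TSV, or a data.frame as
#'   returned by [read_sample_sheet()].
#' @return [expression_bundle()] object.
#' @export
read_expression <- function(lncrna_path, mirna_path, mrna_path, sheet_path) {
  sheet <- if (is.data.frame(sheet_path)) sheet_path
           else read_sample_sheet(sheet_path)
  mats <- lapply(c(lncrna = lncrna_path, mirna = mirna_path,
                   mrna = mrna_path), read_expression_matrix)
  for (cls in names(mats)) {
    missing <- setdiff(sheet$sample_id, colnames(mats[[cls]]))
    if (length(missing))
      stop("sample(s) ", paste(missing, collapse = ", "),
           " from sheet absent in ", cls, " matrix", call. = FALSE)
    mats[[cls]] <- mats[[cls]][, sheet$sample_id, drop = FALSE]
  }
  expression_bundle(mats$lncrna, mats$mirna, mats$mrna,
                    condition = stats::setNames(sheet$condition,
                                                sheet$sample_id))
}

#' Write an expression bundle to three TSVs plus a sample sheet
#'
#' Inverse of [read_expression()]: reading the written files back
#' reproduces the bundle's values, ids and condition labels.
#'
#' @param bundle [expression_bundle()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_expression <- function(bundle, dir, prefix = "expr") {
  stopifnot(inherits(bundle, "expression_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(lncrna = file.path(dir, paste0(prefix, "_lncrna.tsv")),
             mirna = file.path(dir, paste0(prefix, "_mirna.tsv")),
             mrna = file.path(dir, paste0(prefix, "_mrna.tsv")),
             sheet = file.path(dir, paste0(prefix, "_samples.tsv")))
  for (cls in c("lncrna", "mirna", "mrna")) {
    df <- data.frame(feature_id = rownames(bundle[[cls]]),
                     bundle[[cls]], check.names = FALSE)
    utils::write.table(df, paths[[cls]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(
    data.frame(sample_id = bundle$samples,
               condition = unname(bundle$condition)),
    paths[["sheet"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
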