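#' Gene-set collection
#'
#' Ordered collection of named gene sets (GO terms, pathways) used for
#' over-representation analysis. Construct directly or via [read_gmt()].
#'
#' @param term_id character vector of term ids.
#' @param term_name character vector of human-readable names.
#' @param members list of character vectors of member gene ids.
#' @param namespace per-term namespace label (e.g. "GO-BP", "pathway");
#'   recycled if length 1.
#' @return `geneset_collection`: a list of terms, each a list with
#'   `term_id`, `term_name`, `namespace`, `members`.
#' @export
geneset_collection <- function(term_id, term_name, members,
                               namespace = "geneset") {
  stopifnot(length(term_id) == length(term_name),
            length(term_id) == length(members))
  namespace <- rep_len(as.character(namespace), length(term_id))
  terms <- vector("list", length(term_id))
  for (i in seq_along(term_id)) {
    mem <- unique(as.character(members[[i]]))
    if (length(term_id) && !length(mem))
      stop("term '", term_id[i], "' has no members", call. = FALSE)
    terms[[i]] <- list(term_id = term_id[i], term_name = term_name[i],
                       namespace = namespace[i], members = mem)
  }
  structure(terms, class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("geneset_collection with", length(x), "terms\n")
  for (t in utils::head(x, 5L))
    cat(sprintf("  %s (%s): %d genes\n", t$term_id, t$namespace,
                length(t$members)))
  if (length(x) > 5L) cat("  ...\n")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one term per line, tab-separated
#' `term_id<TAB>description<TAB>member...`. Term order is preserved.
#' Duplicate members within a line are deduplicated with a warning.
#'
#' @param path GMT file path.
#' @param namespace namespace label attached to every term.
#' @return [geneset_collection()].
#' @export
read_gmt <- function(path, namespace = "geneset") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(geneset_collection(character(), character(), list(), namespace))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields: ", path,
         call. = FALSE)
  members <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(members, function(m) sum(duplicated(m)), integer(1)))
  if (ndup > 0L)
    warning(ndup, " duplicate member(s) within GMT lines deduplicated: ",
            path, call. = FALSE)
  geneset_collection(vapply(fields, `[[`, "", 1L),
                     vapply(fields, `[[`, "", 2L),
                     lapply(members, unique), namespace)
}

#' Write gene sets in GMT format
#'
#' @param collection [geneset_collection()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(collection, function(t)
    paste(c(t$term_id, t$term_name, t$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
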