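#' Assemble sign-stratified ceRNA triplets
#'
#' A ceRNA triplet (lncRNA, miRNA, mRNA) of stratum `"UP"` requires an
#' upregulated lncRNA, a downregulated miRNA and an upregulated mRNA
#' (`"DOWN"` is the mirror image), both (miRNA, lncRNA) and (miRNA, mRNA)
#' among the anticorrelation-filtered predicted target pairs, and a
#' passing lncRNA-mRNA coexpression edge. The strict sign pattern encodes
#' the sponge model: when the sponge lncRNA rises, the shared miRNA falls
#' and its mRNA target is de-repressed.
#'
#' By default the miRNA must be negatively coexpressed with BOTH the
#' lncRNA and the mRNA (the literal reading of the published filter);
#' `require_lnc_anticorr = FALSE` relaxes the lncRNA side to predicted
#' binding only.
#'
#' @param strata list with per-class up/down id sets:
#'   `list(lncrna = list(up=, down=), mirna = ..., mrna = ...)`, as
#'   produced by [stratify()] per class.
#' @param pairs anticorrelation-filtered `target_pairs` covering both
#'   lncRNA and mRNA targets (rows carry `target_class` and, if available,
#'   `r` from the filter plus best-site columns).
#' @param coexpr_edges `coexpression_edges` from [lncrna_mrna_edges()].
#' @param stratum `"UP"` or `"DOWN"`.
#' @param require_lnc_anticorr require the miRNA-lncRNA pair to have
#'   passed the anticorrelation filter (default) rather than binding only.
#' @param unfiltered_pairs only used when `require_lnc_anticorr = FALSE`:
#'   the pre-filter `target_pairs` to look up miRNA-lncRNA binding in.
#' @return data.frame of class `cerna_triplets`, sorted lexicographically
#'   by (lncrna_id, mirna_id, mrna_id): ids, stratum, lnc_mrna_r,
#'   mir_lnc_r, mir_mrna_r, and the best-site coordinates for both arms.
#' @export
assemble_triplets <- function(strata, pairs, coexpr_edges,
                              stratum = c("UP", "DOWN"),
                              require_lnc_anticorr = TRUE,
                              unfiltered_pairs = NULL) {
  stratum <- match.arg(stratum)
  lnc_set <- if (stratum == "UP") strata$lncrna$up else strata$lncrna$down
  mir_set <- if (stratum == "UP") strata$mirna$down else strata$mirna$up
  mrna_set <- if (stratum == "UP") strata$mrna$up else strata$mrna$down

  lnc_pairs <- pairs[pairs$target_class == "lncRNA", , drop = FALSE]
  if (!require_lnc_anticorr && !is.null(unfiltered_pairs)) {
    lnc_pairs <- unfiltered_pairs[
      unfiltered_pairs$target_class == "lncRNA", , drop = FALSE]
    if (is.null(lnc_pairs$r)) lnc_pairs$r <- NA_real_
  }
  mrna_pairs <- pairs[pairs$target_class == "mRNA", , drop = FALSE]

  lnc_pairs <- lnc_pairs[lnc_pairs$mirna_id %in% mir_set &
                         lnc_pairs$target_id %in% lnc_set, , drop = FALSE]
  mrna_pairs <- mrna_pairs[mrna_pairs$mirna_id %in% mir_set &
                           mrna_pairs$target_id %in% mrna_set, , drop = FALSE]
  ce <- coexpr_edges[coexpr_edges$a_id %in% lnc_set &
                     coexpr_edges$b_id %in% mrna_set, , drop = FALSE]

  empty <- data.frame(lncrna_id = character(), mirna_id = character(),
                      mrna_id = character(), stratum = character(),
                      lnc_mrna_r = numeric(), mir_lnc_r = numeric(),
                      mir_mrna_r = numeric(),
                      lnc_site_start = integer(), lnc_site_end = integer(),
                      mrna_site_start = integer(), mrna_site_end = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("cerna_triplets", "data.frame")
  if (!nrow(lnc_pairs) || !nrow(mrna_pairs) || !nrow(ce)) return(empty)

  # join on the shared miRNA, then require the lncRNA-mRNA coexpression edge
  lm <- merge(lnc_pairs[, c("mirna_id", "target_id", "r",
                            "target_start", "target_end")],
              mrna_pairs[, c("mirna_id", "target_id", "r",
                             "target_start", "target_end")],
              by = "mirna_id", suffixes = c("_lnc", "_mrna"))
  key <- paste(lm$target_id_lnc, lm$target_id_mrna, sep = "\r")
  ce_key <- paste(ce$a_id, ce$b_id, sep = "\r")
  hit <- match(key, ce_key)
  lm <- lm[!is.na(hit), , drop = FALSE]
  hit <- hit[!is.na(hit)]
  out <- data.frame(
    lncrna_id = lm$target_id_lnc, mirna_id = lm$mirna_id,
    mrna_id = lm$target_id_mrna, stratum = rep_len(stratum, nrow(lm)),
    lnc_mrna_r = ce$r[hit], mir_lnc_r = lm$r_lnc, mir_mrna_r = lm$r_mrna,
    lnc_site_start = lm$target_start_lnc, lnc_site_end = lm$target_end_lnc,
    mrna_site_start = lm$target_start_mrna,
    mrna_site_end = lm$target_end_mrna, stringsAsFactors = FALSE)
  out <- out[order(out$lncrna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cerna_triplets", "data.frame")
  out
}

#' Build a tripartite ceRNA network from triplets
#'
#' Nodes are the union of triplet members (typed lncRNA/miRNA/mRNA with
#' their stratum direction); edges are the deduplicated union of
#' lncRNA-miRNA and miRNA-mRNA arms. The lncRNA-mRNA coexpression is
#' triplet evidence, not a drawn edge (the two drawn edge types match the
#' published network figures). Provenance (the contributing triplets) is
#' retained so subnetwork extraction can reason per triplet.
#'
#' @param triplets `cerna_triplets`, all of one stratum.
#' @return object of class `cerna_network`: list with `nodes`
#'   (data.frame id, class, direction), `edges` (data.frame from, to,
#'   type), `triplets` (provenance), `stratum`.
#' @export
build_network <- function(triplets) {
  stratum <- unique(triplets$stratum)
  if (length(stratum) > 1L)
    stop("triplets mix strata: ", paste(stratum, collapse = ", "),
         call. = FALSE)
  if (!length(stratum)) stratum <- NA_character_
  dir_of <- function(cls) {
    if (is.na(stratum)) return(NA_character_)
    if (stratum == "UP") c(lncRNA = "up", miRNA = "down", mRNA = "up")[[cls]]
    else c(lncRNA = "down", miRNA = "up", mRNA = "down")[[cls]]
  }
  nodes <- unique(rbind(
    data.frame(id = triplets$lncrna_id,
               class = rep_len("lncRNA", nrow(triplets)),
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mirna_id,
               class = rep_len("miRNA", nrow(triplets)),
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mrna_id,
               class = rep_len("mRNA", nrow(triplets)),
               stringsAsFactors = FALSE)))
  nodes$direction <- vapply(nodes$class, dir_of, "")
  nodes <- nodes[order(nodes$class, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- unique(rbind(
    data.frame(from = triplets$lncrna_id, to = triplets$mirna_id,
               type = rep_len("lncRNA_miRNA", nrow(triplets)),
               stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna_id, to = triplets$mrna_id,
               type = rep_len("miRNA_mRNA", nrow(triplets)),
               stringsAsFactors = FALSE)))
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  net <- structure(list(nodes = nodes, edges = edges, triplets = triplets,
                        stratum = stratum), class = "cerna_network")
  validate_cerna_network(net)
  net
}

#' Validate the structural invariants of a ceRNA network
#'
#' Asserts strict tripartiteness (only lncRNA-miRNA and miRNA-mRNA edge
#' types, endpoints of the declared classes), sign consistency with the
#' stratum, and that every edge is covered by at least one provenance
#' triplet whose members are exactly the node set.
#'
#' @param net `cerna_network`.
#' @return invisibly `net`; errors on violation.
#' @export
validate_cerna_network <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  cls <- stats::setNames(net$nodes$class, net$nodes$id)
  tr <- net$triplets
  with(net$edges, {
    lm <- type == "lncRNA_miRNA"
    if (!all(cls[from[lm]] == "lncRNA") || !all(cls[to[lm]] == "miRNA"))
      stop("tripartiteness violated on lncRNA_miRNA edges", call. = FALSE)
    if (!all(cls[from[!lm]] == "miRNA") || !all(cls[to[!lm]] == "mRNA"))
      stop("tripartiteness violated on miRNA_mRNA edges", call. = FALSE)
  })
  member_ids <- sort(unique(c(tr$lncrna_id, tr$mirna_id, tr$mrna_id)))
  if (!identical(sort(net$nodes$id), member_ids))
    stop("node set differs from union of triplet members", call. = FALSE)
  cov <- unique(rbind(
    data.frame(from = tr$lncrna_id, to = tr$mirna_id,
               type = rep_len("lncRNA_miRNA", nrow(tr)),
               stringsAsFactors = FALSE),
    data.frame(from = tr$mirna_id, to = tr$mrna_id,
               type = rep_len("miRNA_mRNA", nrow(tr)),
               stringsAsFactors = FALSE)))
  if (nrow(net$edges) != nrow(cov) ||
      !identical(nrow(merge(net$edges, cov)), nrow(net$edges)))
    stop("edge without provenance triplet", call. = FALSE)
  invisible(net)
}

#' @export
print.cerna_network <- function(x, ...) {
  tab <- table(factor(x$nodes$class, c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf("ceRNA network (stratum %s): %d lncRNA / %d miRNA / %d mRNA nodes, %d edges, %d triplets\n",
              x$stratum, tab[["lncRNA"]], tab[["miRNA"]], tab[["mRNA"]],
              nrow(x$edges), nrow(x$triplets)))
  invisible(x)
}

#' @export
summary.cerna_network <- function(object, hub_degree = 8, ...) {
  deg <- node_degrees(object)
  lnc <- object$nodes$id[object$nodes$class == "lncRNA"]
  hubs <- names(deg)[deg > hub_degree & names(deg) %in% lnc]
  out <- list(
    stratum = object$stratum,
    n_nodes = as.list(table(factor(object$nodes$class,
                                   c("lncRNA", "miRNA", "mRNA")))),
    n_edges = nrow(object$edges),
    n_triplets = nrow(object$triplets),
    hub_lncrnas = sort(hubs))
  class(out) <- "summary.cerna_network"
  out
}

#' @export
print.summary.cerna_network <- function(x, ...) {
  cat(sprintf("ceRNA network, stratum %s\n", x$stratum))
  cat(sprintf("  nodes: %d lncRNA, %d miRNA, %d mRNA\n",
              x$n_nodes$lncRNA, x$n_nodes$miRNA, x$n_nodes$mRNA))
  cat(sprintf("  edges: %d   triplets: %d\n", x$n_edges, x$n_triplets))
  cat(sprintf("  hub lncRNAs (degree > 8): %s\n",
              if (length(x$hub_lncrnas)) paste(x$hub_lncrnas, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Node degrees of a ceRNA network
#'
#' Degree = number of incident typed edges; the degree sum equals twice
#' the edge count.
#'
#' @param net `cerna_network`.
#' @return named integer vector (node id -> degree), every node included.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  counts <- table(factor(c(net$edges$from, net$edges$to),
                         levels = net$nodes$id))
  stats::setNames(as.integer(counts), names(counts))
}

#' Extract the hub-lncRNA subnetwork
#'
#' Hub lncRNAs are those whose degree strictly exceeds
#' `min_degree_exclusive` ("a degree exceeding 8": a degree of exactly 8
#' does not qualify). The subnetwork is rebuilt from the provenance
#' triplets containing a hub lncRNA, so it keeps the hubs, the miRNAs
#' linked to them and the mRNAs reached through those triplets. Hub
#' status is assessed for lncRNAs only.
#'
#' @param net `cerna_network`.
#' @param min_degree_exclusive degree threshold (strict `>`).
#' @return `cerna_network` of the kept triplets.
#' @export
extract_hub_subnetwork <- function(net, min_degree_exclusive = 8) {
  stopifnot(inherits(net, "cerna_network"))
  deg <- node_degrees(net)
  lnc <- net$nodes$id[net$nodes$class == "lncRNA"]
  hubs <- intersect(names(deg)[deg > min_degree_exclusive], lnc)
  build_network(net$triplets[net$triplets$lncrna_id %in% hubs, ,
                             drop = FALSE])
}

#' Extract the subnetwork anchored on a gene set
#'
#' Keeps the provenance triplets whose mRNA belongs to `gene_ids` (for
#' example the member genes of an enriched GO term) and rebuilds the
#' network from them.
#'
#' @param net `cerna_network`.
#' @param gene_ids non-empty character vector of mRNA ids.
#' @return `cerna_network`; empty (with a warning) if no triplet matches.
#' @export
extract_geneset_subnetwork <- function(net, gene_ids) {
  stopifnot(inherits(net, "cerna_network"), length(gene_ids) > 0)
  keep <- net$triplets[net$triplets$mrna_id %in% gene_ids, , drop = FALSE]
  if (!nrow(keep))
    warning("gene set does not intersect the network's mRNAs",
            call. = FALSE)
  build_network(keep)
}
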