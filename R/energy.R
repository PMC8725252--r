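#' Nearest-neighbour stacking free-energy table for RNA duplexes
#'
#' 6x6 matrix of stack free energies (DeltaG at 37C, kcal/mol) indexed by
#' consecutive base pairs of a duplex. A pair is written `XY` = target
#' base X (top strand, 5'->3') paired with miRNA base Y (bottom strand);
#' the stack `(p1, p2)` is the dinucleotide step 5'-t1 t2-3' over
#' 3'-m1 m2-5'. Watson-Crick/Watson-Crick steps carry the published
#' Turner 2004 DeltaG37 values; steps involving G:U wobble pairs carry
#' approximate Turner-style values. The table satisfies the strand-flip
#' symmetry E(p1, p2) = E(swap(p2), swap(p1)).
#'
#' @return named 6x6 numeric matrix (rows = first pair, cols = second
#'   pair; pair codes AU, UA, CG, GC, GU, UG).
#' @seealso [duplex_energy()]
#' @export
duplex_stack_table <- function() {
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  E <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  set <- function(p1, p2, v) E[p1, p2] <<- v
  # Watson-Crick stacks, Turner 2004 DeltaG37
  set("AU", "AU", -0.93); set("AU", "UA", -1.10)
  set("UA", "AU", -1.33); set("UA", "UA", -0.93)
  set("AU", "CG", -2.24); set("AU", "GC", -2.08)
  set("UA", "CG", -2.35); set("UA", "GC", -2.11)
  set("CG", "AU", -2.11); set("CG", "UA", -2.08)
  set("GC", "AU", -2.35); set("GC", "UA", -2.24)
  set("CG", "CG", -3.26); set("CG", "GC", -2.36)
  set("GC", "CG", -3.42); set("GC", "GC", -3.26)
  # wobble-containing stacks (approximate Turner-style values)
  set("AU", "GU", -0.55); set("AU", "UG", -1.36)
  set("UA", "GU", -1.27); set("UA", "UG", -1.00)
  set("CG", "GU", -1.41); set("CG", "UG", -2.11)
  set("GC", "GU", -2.51); set("GC", "UG", -1.53)
  set("GU", "GU", -0.50); set("UG", "UG", -0.50)
  set("GU", "UG", +0.47); set("UG", "GU", -0.30)
  # complete by strand-flip symmetry E(p1,p2) = E(swap(p2), swap(p1))
  swap <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (p1 in pairs) for (p2 in pairs)
    if (is.na(E[p1, p2])) E[p1, p2] <- E[swap(p2), swap(p1)]
  E
}

#' Estimate the free energy of a predicted duplex site
#'
#' Nearest-neighbour estimate: the sum of stack free energies over
#' consecutive paired alignment columns (Watson-Crick or G:U wobble),
#' plus a constant duplex-initiation penalty. Columns that are gapped or
#' mismatched contribute nothing and interrupt stacking. Helix-end A:U
#' penalties and loop entropies are not modelled; the estimate is used as
#' a screening statistic, not as a folding prediction.
#'
#' @param site `duplex_site` from [align_duplex()].
#' @param stack_table stacking table, see [duplex_stack_table()].
#' @param initiation duplex initiation penalty, kcal/mol.
#' @return free energy in kcal/mol (more negative = more stable). An
#'   alignment with no stacked pair returns the initiation penalty alone.
#' @export
duplex_energy <- function(site, stack_table = duplex_stack_table(),
                          initiation = 4.09) {
  qa <- strsplit(site$mirna_aln, "")[[1]]
  ta <- strsplit(site$target_aln, "")[[1]]
  paired <- qa != "-" & ta != "-" & pair_symbol(qa, ta) != " "
  energy <- initiation
  for (k in seq_len(length(qa) - 1L)) {
    if (paired[k] && paired[k + 1L]) {
      p1 <- paste0(ta[k], qa[k])
      p2 <- paste0(ta[k + 1L], qa[k + 1L])
      energy <- energy + stack_table[p1, p2]
    }
  }
  energy
}
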