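#' Perturbation specification: which elastic interactions to switch off
#'
#' Defines a set of residue pairs whose non-bonded springs are removed
#' before re-solving the transition pathway, to probe which interactions
#' dictate the order of structural events. Two rules:
#' \describe{
#'   \item{`intra`}{same-chain pairs with one member in selection A and the
#'     other in selection B (e.g. all intra-subunit contacts between the
#'     transmembrane and extracellular domains, or between one interface
#'     loop and the transmembrane domain).}
#'   \item{`inter`}{different-chain pairs with one member in A (on one
#'     chain) and the other in B (on the other), e.g. contacts between the
#'     extracellular domains of adjacent subunits.}
#' }
#' Selections are residue-number sets applied on every chain. Chemically
#' bonded pairs are never severed, whatever the rule.
#'
#' @param name label for the perturbation.
#' @param rule `"intra"` or `"inter"`.
#' @param set_A,set_B integer vectors of residue numbers (or `motif_table`
#'   rows expanded via [motif_residues()]).
#' @return a `perturbation_spec` list.
#' @export
perturbation_spec <- function(name, rule = c("intra", "inter"), set_A, set_B) {
  rule <- match.arg(rule)
  structure(list(name = name, rule = rule,
                 set_A = as.integer(set_A), set_B = as.integer(set_B)),
            class = "perturbation_spec")
}

#' Residue numbers covered by motifs
#' @param motifs a `motif_table` (any subset of rows).
#' @return integer vector of residue numbers.
#' @export
motif_residues <- function(motifs) {
  unique(unlist(lapply(seq_len(nrow(motifs)), function(r)
    motifs$start[r]:motifs$end[r])))
}

#' Expand a perturbation specification to an explicit masked-pair set
#'
#' Enumerates every global-index pair matching the rule; the result feeds the
#' `masked_pairs` argument of [build_enm()] / [double_well_spec()]. Pairs are
#' canonical (i < j) and symmetric by construction.
#'
#' @param spec a `perturbation_spec`.
#' @param structure a `calpha` structure.
#' @return 2-column integer matrix of (i, j) pairs (possibly empty, with a
#'   warning).
#' @export
expand_mask <- function(spec, structure) {
  inA <- which(structure$resno %in% spec$set_A)
  inB <- which(structure$resno %in% spec$set_B)
  if (!length(inA) || !length(inB)) {
    warning("perturbation '", spec$name, "' matches no residue pairs (no-op)")
    return(matrix(integer(0), 0, 2))
  }
  grid <- expand.grid(i = inA, j = inB)
  same <- structure$chain[grid$i] == structure$chain[grid$j]
  keep <- if (spec$rule == "intra") same else !same
  grid <- grid[keep & grid$i != grid$j, , drop = FALSE]
  if (!nrow(grid)) {
    warning("perturbation '", spec$name, "' matches no residue pairs (no-op)")
    return(matrix(integer(0), 0, 2))
  }
  canonical_pairs(cbind(grid$i, grid$j))
}

#' Re-solve the pathway with masked interactions and report order shifts
#'
#' Runs the interpolated pathway with the perturbation's spring mask removed
#' from both wells (or one well via `mask_wells`), recomputes the per-residue
#' crossover table and motif averages, and reports signed shifts against an
#' unperturbed run.
#'
#' @param begin,end `calpha` structures.
#' @param map an `alignment_map` (default identity).
#' @param spec a `perturbation_spec`.
#' @param motifs a `motif_table` for aggregation.
#' @param settings an `ienm_settings`.
#' @param reference optional unperturbed result from [run_transition()]
#'   (computed if missing).
#' @param floor crossover displacement floor (Angstrom).
#' @param mask_wells which wells the mask applies to (default `"both"`).
#' @param ... further arguments to [double_well_spec()].
#' @return list with `perturbed` (a [run_transition()] result), `motif_delta`
#'   (data.frame name, mean_f, mean_f_unperturbed, delta), `mask` (pair
#'   matrix), `reference`.
#' @export
perturbed_progress <- function(begin, end, map = NULL, spec, motifs,
                               settings = ienm_settings(),
                               reference = NULL, floor = 0.5,
                               mask_wells = "both", ...) {
  if (is.null(reference))
    reference <- run_transition(begin, end, map = map, motifs = motifs,
                                settings = settings, floor = floor, ...)
  mask <- expand_mask(spec, begin)
  perturbed <- run_transition(begin, end, map = map, motifs = motifs,
                              settings = settings, floor = floor,
                              masked_pairs = mask, mask_wells = mask_wells, ...)
  md <- merge(perturbed$motif_means[, c("name", "mean_f")],
              reference$motif_means[, c("name", "mean_f")],
              by = "name", suffixes = c("", "_unperturbed"))
  md$delta <- md$mean_f - md$mean_f_unperturbed
  ord <- match(reference$motif_means$name, md$name)
  md <- md[ord[!is.na(ord)], , drop = FALSE]
  rownames(md) <- NULL
  list(perturbed = perturbed, motif_delta = md, mask = mask,
       reference = reference)
}

#' One-call transition analysis: pathway plus motional order
#'
#' Convenience wrapper running [double_well_spec()], [solve_pathway()],
#' [progress_table()] and (optionally) [motif_mean()] in one step — the
#' standard unit of both the unperturbed analysis and each perturbation
#' re-run.
#'
#' @param begin,end `calpha` structures.
#' @param map alignment map (default identity).
#' @param motifs optional `motif_table`.
#' @param settings an `ienm_settings`.
#' @param floor crossover displacement floor (Angstrom).
#' @param ... further arguments to [double_well_spec()] (cutoff, force
#'   constants, `masked_pairs`, `mask_wells`, ...).
#' @return list with `spec`, `pathway`, `progress`, `motif_means` (NULL when
#'   no motifs given).
#' @export
run_transition <- function(begin, end, map = NULL, motifs = NULL,
                           settings = ienm_settings(), floor = 0.5, ...) {
  spec <- double_well_spec(begin, end, map = map, ...)
  pathway <- solve_pathway(spec, settings)
  progress <- progress_table(pathway, begin, end_xyz = spec$end_mapped,
                             floor = floor)
  mm <- if (!is.null(motifs)) motif_mean(progress, motifs, begin) else NULL
  list(spec = spec, pathway = pathway, progress = progress, motif_means = mm)
}
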