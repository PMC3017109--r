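#' Fractional progress of a conformation along a pathway
#'
#' Arc-length position of a pathway conformation: the path length from the
#' begin conformation to it, divided by the total path length, both computed
#' by summing RMSDs between consecutive conformations. 0 at the begin
#' conformation, 1 at the end.
#'
#' @param pathway an `ienm_pathway`.
#' @param conformation_index index into the pathway (1-based).
#' @return fractional progress in [0, 1].
#' @export
f_progress <- function(pathway, conformation_index) {
  L <- max(pathway$cumulative_length)
  if (L <= 0) stop("zero-length pathway has no defined progress")
  stopifnot(conformation_index >= 1,
            conformation_index <= length(pathway$conformations))
  pathway$cumulative_length[conformation_index] / L
}

#' Crossover progress of one residue
#'
#' Finds the pathway point at which a residue's C-alpha is equidistant from
#' its begin and end positions and returns the fractional progress of that
#' point (linearly interpolated between the bracketing conformations). A low
#' crossover value means the residue completes half of its displacement
#' early in the transition. Undefined (`NA`) when the residue's begin-to-end
#' displacement is below `floor` or its distance difference never changes
#' sign along the path.
#'
#' Each pathway conformation is used as stored (the solver already removes
#' rigid-body drift against the begin structure), and the first sign change
#' is taken when there are several.
#'
#' @param pathway an `ienm_pathway`.
#' @param residue global residue index.
#' @param begin_xyz,end_xyz per-residue reference positions; default the
#'   first and last pathway conformations. Rows of `end_xyz` may be NA for
#'   residues without an end-state position (unaligned), giving `NA`.
#' @param floor minimum begin-to-end displacement in Angstrom for a defined
#'   crossover (default 0.5).
#' @return crossover fractional progress in [0, 1], or `NA`.
#' @export
crossover_f <- function(pathway, residue, begin_xyz = NULL, end_xyz = NULL,
                        floor = 0.5) {
  K <- length(pathway$conformations)
  stopifnot(K >= 2)
  if (is.null(begin_xyz)) begin_xyz <- pathway$conformations[[1]]
  if (is.null(end_xyz)) end_xyz <- pathway$conformations[[K]]
  b <- begin_xyz[residue, ]
  e <- end_xyz[residue, ]
  if (anyNA(e)) return(NA_real_)
  if (sqrt(sum((e - b)^2)) < floor) return(NA_real_)
  g <- vapply(seq_len(K), function(m) {
    p <- pathway$conformations[[m]][residue, ]
    sqrt(sum((p - b)^2)) - sqrt(sum((p - e)^2))
  }, numeric(1))
  L <- max(pathway$cumulative_length)
  f <- pathway$cumulative_length / L
  if (g[1] >= 0) return(f[1])        # already past midpoint at the start
  cross <- which(g[-K] < 0 & g[-1] >= 0)
  if (!length(cross)) return(NA_real_)
  m <- cross[1]
  w <- -g[m] / (g[m + 1] - g[m])
  f[m] + w * (f[m + 1] - f[m])
}

#' Per-residue crossover table for a pathway
#'
#' Computes displacement magnitudes and crossover progress for every residue
#' and, optionally, motif averages.
#'
#' @param pathway an `ienm_pathway`.
#' @param structure the begin `calpha` structure (atom identities).
#' @param end_xyz optional end positions on begin indexing (e.g. the
#'   `end_mapped` matrix of an `ienm_spec`); default the last conformation.
#' @param floor displacement floor in Angstrom (default 0.5).
#' @return a `progress_table` data.frame with columns `index`, `chain`,
#'   `resno`, `displacement`, `f_cross`.
#' @export
progress_table <- function(pathway, structure, end_xyz = NULL, floor = 0.5) {
  n <- n_atoms(structure)
  K <- length(pathway$conformations)
  if (is.null(end_xyz)) end_xyz <- pathway$conformations[[K]]
  begin_xyz <- pathway$conformations[[1]]
  disp <- sqrt(rowSums((end_xyz - begin_xyz)^2))
  f <- vapply(seq_len(n), function(r)
    crossover_f(pathway, r, begin_xyz, end_xyz, floor), numeric(1))
  structure(data.frame(index = seq_len(n), chain = structure$chain,
                       resno = structure$resno, displacement = disp,
                       f_cross = f, stringsAsFactors = FALSE),
            class = c("progress_table", "data.frame"))
}

#' Motif-average crossover progress
#'
#' Arithmetic mean of defined crossover values over the member residues of
#' each motif, across all chains in the motif's scope. Motifs whose members
#' are all undefined get `NA` with a warning.
#'
#' @param progress a `progress_table`.
#' @param motifs a `motif_table`.
#' @param structure the begin `calpha` structure.
#' @return data.frame with columns `name`, `mean_f`, `n_defined`, `n_members`.
#' @export
motif_mean <- function(progress, motifs, structure) {
  rows <- lapply(seq_len(nrow(motifs)), function(r) {
    idx <- motif_indices(motifs[r, ], structure)
    if (!length(idx)) stop("motif ", motifs$name[r],
                           " matches no residues in the structure")
    v <- progress$f_cross[idx]
    nd <- sum(is.finite(v))
    if (nd == 0)
      warning("motif ", motifs$name[r], " has no residue with defined crossover")
    data.frame(name = motifs$name[r],
               mean_f = if (nd) mean(v[is.finite(v)]) else NA_real_,
               n_defined = nd, n_members = length(idx),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation between predicted motional order and experimental Phi values
#'
#' Pearson correlation between motif-average crossover progress and 1 - Phi
#' over the motifs common to both tables. High-Phi elements move early, so a
#' faithful pathway shows a strong positive correlation with 1 - Phi.
#'
#' @param motif_means data.frame from [motif_mean()] (columns `name`,
#'   `mean_f`).
#' @param phi a `phi_table` (columns `name`, `phi`).
#' @return list with `r` (Pearson coefficient), `n` (motifs used), and the
#'   merged table.
#' @export
order_correlation <- function(motif_means, phi) {
  merged <- merge(motif_means, phi, by = "name")
  merged <- merged[is.finite(merged$mean_f), , drop = FALSE]
  if (nrow(merged) < 3)
    stop("need at least 3 motifs common to both tables")
  if (stats::sd(merged$mean_f) == 0 || stats::sd(merged$phi) == 0)
    stop("constant input: correlation undefined")
  list(r = stats::cor(merged$mean_f, 1 - merged$phi),
       n = nrow(merged), table = merged)
}

#' Construct a pathway from explicit conformations
#'
#' Wraps a list of coordinate matrices (e.g. a straight-line Cartesian
#' interpolation, or a reversed solved pathway) as an `ienm_pathway` so the
#' progress machinery applies to it.
#'
#' @param conformations list of N x 3 matrices.
#' @param lambdas optional interpolation parameters (default: uniform 1 to 0).
#' @return an `ienm_pathway`.
#' @export
as_pathway <- function(conformations, lambdas = NULL) {
  K <- length(conformations)
  stopifnot(K >= 1)
  if (is.null(lambdas)) lambdas <- seq(1, 0, length.out = max(K, 2))[seq_len(K)]
  steps <- if (K > 1)
    vapply(2:K, function(m) rmsd_xyz(conformations[[m]], conformations[[m - 1]]),
           numeric(1)) else numeric(0)
  structure(list(conformations = conformations, lambdas = lambdas,
                 cumulative_length = c(0, cumsum(steps)),
                 residuals = rep(NA_real_, K), settings = NULL),
            class = "ienm_pathway")
}

#' Straight-line Cartesian interpolation between two conformations
#'
#' @param begin_xyz,end_xyz N x 3 matrices.
#' @param n_points number of conformations including both endpoints.
#' @return an `ienm_pathway`.
#' @export
linear_pathway <- function(begin_xyz, end_xyz, n_points = 21) {
  stopifnot(n_points >= 2)
  ts <- seq(0, 1, length.out = n_points)
  as_pathway(lapply(ts, function(t) (1 - t) * begin_xyz + t * end_xyz),
             lambdas = 1 - ts)
}

#' Reverse a pathway (swap begin and end roles)
#' @param pathway an `ienm_pathway`.
#' @return the reversed `ienm_pathway`.
#' @export
reverse_pathway <- function(pathway) {
  as_pathway(rev(pathway$conformations), lambdas = rev(1 - pathway$lambdas))
}
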