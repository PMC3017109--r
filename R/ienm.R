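#' Double-well transition specification
#'
#' Builds the two single-well ENM potentials anchored at the begin and end
#' conformations of a transition, plus the steric collision term, for the
#' interpolated saddle-point pathway solver. The end conformation is first
#' superposed onto the begin conformation over the aligned residue pairs and
#' re-expressed on the begin structure's atom indexing.
#'
#' Residues of the begin structure without an aligned partner have no
#' coordinates in the end state, so the end-well potential carries no
#' non-bonded spring touching them; their bonded springs are kept with rest
#' lengths copied from the begin conformation, so the chain stays intact in
#' both wells.
#'
#' The collision penalty is a one-sided quadratic,
#' E_coll = sum over non-bonded pairs of (k_coll/2) (d_ij - d_c)^2 for
#' d_ij < d_c, zero otherwise: smooth, active only below the collision
#' distance, and vanishing continuously at d = d_c. By construction d_c is
#' the minimal non-bonded C-alpha distance over both endpoint conformations,
#' so both endpoints are collision-free.
#'
#' @param begin,end `calpha` structures (the transition endpoints).
#' @param map an `alignment_map` from begin to end (default: identity map).
#' @param cutoff,k_bonded,k_nonbonded passed to [build_enm()] for both wells.
#' @param k_coll collision force constant (default 10, model units).
#' @param d_c collision distance in Angstrom; `NULL` (default) computes the
#'   minimal non-bonded C-alpha distance over both endpoint conformations.
#' @param masked_pairs optional (i, j) pairs (begin indexing) whose
#'   non-bonded springs are removed.
#' @param mask_wells which wells the mask applies to: `"both"` (default),
#'   `"begin"` or `"end"`.
#' @return an `ienm_spec`: list with `enm1`, `enm2`, `begin`, `end_mapped`
#'   (N x 3, NA rows for unaligned residues), `aligned` (logical length N),
#'   `k_coll`, `d_c`, `bonded` (bonded pair matrix), `superpose_rmsd`.
#' @export
double_well_spec <- function(begin, end, map = NULL, cutoff = 10,
                             k_bonded = 10, k_nonbonded = 1,
                             k_coll = 10, d_c = NULL,
                             masked_pairs = NULL,
                             mask_wells = c("both", "begin", "end")) {
  mask_wells <- match.arg(mask_wells)
  if (is.null(map)) map <- identity_alignment(begin, end)
  sup <- superpose(end, begin,
                   map = alignment_map(map$pairs$j, map$pairs$i, end, begin))
  end_sup <- sup$structure
  n <- n_atoms(begin)
  end_mapped <- matrix(NA_real_, n, 3)
  end_mapped[map$pairs$i, ] <- end_sup$xyz[map$pairs$j, , drop = FALSE]
  aligned <- seq_len(n) %in% map$pairs$i

  m1 <- if (mask_wells %in% c("both", "begin")) masked_pairs else NULL
  m2 <- if (mask_wells %in% c("both", "end")) masked_pairs else NULL
  enm1 <- build_enm(begin, cutoff, k_bonded, k_nonbonded, masked_pairs = m1)
  enm2 <- build_end_well(begin, end_mapped, aligned, cutoff,
                         k_bonded, k_nonbonded, masked_pairs = m2)

  bonded <- bonded_pairs(begin)
  if (is.null(d_c)) {
    d_c <- min(min_nonbonded_distance(begin$xyz, bonded),
               min_nonbonded_distance(end_sup$xyz, bonded_pairs(end_sup)))
  }
  stopifnot(d_c > 0)
  structure(list(enm1 = enm1, enm2 = enm2, begin = begin,
                 end_mapped = end_mapped, aligned = aligned,
                 k_coll = k_coll, d_c = d_c, bonded = bonded,
                 superpose_rmsd = sup$rmsd, map = map),
            class = "ienm_spec")
}

#' @export
print.ienm_spec <- function(x, ...) {
  cat(sprintf(paste0("iENM double-well spec: %d atoms (%d aligned), ",
                     "endpoint RMSD %.3f A, d_c %.3f A\n"),
              n_atoms(x$begin), sum(x$aligned), x$superpose_rmsd, x$d_c))
  invisible(x)
}

## end-state ENM on begin indexing: non-bonded springs only between aligned
## residues (rest lengths from the end conformation); bonded springs always,
## falling back to begin rest lengths where an end distance is unavailable.
build_end_well <- function(begin, end_mapped, aligned, cutoff,
                           k_bonded, k_nonbonded, masked_pairs = NULL) {
  n <- nrow(end_mapped)
  filled <- end_mapped
  filled[!aligned, ] <- begin$xyz[!aligned, , drop = FALSE]
  ref <- begin
  ref$xyz <- filled
  ref$label <- "end (mapped)"
  model <- build_enm(ref, cutoff, k_bonded, k_nonbonded,
                     masked_pairs = masked_pairs)
  s <- model$springs
  keep_nb <- aligned[s$i] & aligned[s$j]
  s <- s[s$bonded | keep_nb, , drop = FALSE]
  ## bonded rest lengths: end distance if both ends aligned, else begin distance
  fix <- s$bonded & !(aligned[s$i] & aligned[s$j])
  if (any(fix)) {
    d0b <- sqrt(rowSums((begin$xyz[s$i[fix], , drop = FALSE] -
                           begin$xyz[s$j[fix], , drop = FALSE])^2))
    s$d0[fix] <- d0b
  }
  rownames(s) <- NULL
  model$springs <- s
  model
}

min_nonbonded_distance <- function(xyz, bonded) {
  n <- nrow(xyz)
  dm <- as.matrix(stats::dist(xyz))
  dm[cbind(bonded[, 1], bonded[, 2])] <- Inf
  dm[cbind(bonded[, 2], bonded[, 1])] <- Inf
  diag(dm) <- Inf
  min(dm)
}

## non-bonded pairs currently within the collision distance
colliding_pairs <- function(spec, xyz) {
  pr <- pairs_within(xyz, spec$d_c)
  if (nrow(pr) == 0) return(pr)
  n <- nrow(xyz)
  bkey <- pair_key(spec$bonded[, 1], spec$bonded[, 2], n)
  pr[!(pair_key(pr[, 1], pr[, 2], n) %in% bkey), , drop = FALSE]
}

#' Steric collision energy and gradient
#'
#' One-sided quadratic penalty over non-bonded residue pairs closer than the
#' collision distance d_c. Zero (with zero gradient) whenever no non-bonded
#' pair is closer than d_c — in particular at both transition endpoints.
#'
#' @param spec an `ienm_spec`.
#' @param xyz N x 3 coordinates.
#' @return list with `energy`, `gradient` (N x 3), `n_collisions`.
#' @export
collision_energy_gradient <- function(spec, xyz) {
  xyz <- as_xyz_matrix(xyz, n_atoms(spec$begin))
  pr <- colliding_pairs(spec, xyz)
  if (nrow(pr) == 0)
    return(list(energy = 0, gradient = matrix(0, nrow(xyz), 3),
                n_collisions = 0L))
  out <- pair_energy_gradient(pr[, 1], pr[, 2], spec$d_c, spec$k_coll, xyz)
  out$n_collisions <- nrow(pr)
  out
}

collision_hessian <- function(spec, xyz) {
  pr <- colliding_pairs(spec, xyz)
  n <- nrow(xyz)
  pair_hessian(pr[, 1], pr[, 2], rep(spec$d_c, nrow(pr)),
               rep(spec$k_coll, nrow(pr)), xyz, n)
}

#' Solver settings for the interpolated pathway
#'
#' @param n_lambda number of uniform interpolation steps from 1 to 0
#'   (default 201); adaptive bisection refines wherever consecutive solutions
#'   move more than twice the sampling increment.
#' @param newton_tolerance convergence threshold on the max-norm of the
#'   interpolated gradient (model units / Angstrom, default 1e-8).
#' @param max_newton_iterations per-lambda iteration cap (default 100).
#' @param sampling_increment minimum RMSD between retained consecutive
#'   conformations in Angstrom (default 0.1).
#' @param max_step RMSD jump between consecutive lambda solutions above
#'   which the schedule is bisected (default twice the sampling increment).
#' @param regularization relative diagonal shift for the (rigid-body
#'   singular) Newton linear systems (default 1e-8 of the max diagonal).
#' @return a `ienm_settings` list.
#' @export
ienm_settings <- function(n_lambda = 201, newton_tolerance = 1e-8,
                          max_newton_iterations = 100,
                          sampling_increment = 0.1,
                          max_step = 2 * sampling_increment,
                          regularization = 1e-8) {
  stopifnot(n_lambda >= 2, newton_tolerance > 0, sampling_increment > 0,
            max_step > 0)
  structure(list(n_lambda = as.integer(n_lambda),
                 newton_tolerance = newton_tolerance,
                 max_newton_iterations = as.integer(max_newton_iterations),
                 sampling_increment = sampling_increment,
                 max_step = max_step,
                 regularization = regularization),
            class = "ienm_settings")
}

interp_energy_gradient <- function(spec, lambda, xyz) {
  g1 <- enm_energy_gradient(spec$enm1, xyz)
  g2 <- enm_energy_gradient(spec$enm2, xyz)
  gc <- collision_energy_gradient(spec, xyz)
  list(energy = lambda * g1$energy + (1 - lambda) * g2$energy + gc$energy,
       gradient = lambda * g1$gradient + (1 - lambda) * g2$gradient +
         gc$gradient)
}

interp_gradient <- function(spec, lambda, xyz)
  interp_energy_gradient(spec, lambda, xyz)$gradient

#' Minimise the interpolated potential at one value of lambda
#'
#' Newton-Raphson minimisation of lambda * E1 + (1 - lambda) * E2 + E_coll
#' from a warm start, solving the sparse linear system with an adaptive
#' (Levenberg-style) diagonal damping that also regularises the rigid-body
#' null space, and accepting steps on energy descent. Convergence is
#' declared at a gradient max-norm at or below `newton_tolerance`, or within
#' 10x of it when floating-point precision admits no further descent (the
#' residual reported alongside the solution is always the re-evaluated
#' one). The stationary points of this interpolated potential are
#' exactly the saddle points of any double-well potential built from E1 and
#' E2, whatever its mixing form. The solution is re-superposed onto the
#' begin structure to remove rigid-body drift.
#'
#' @param spec an `ienm_spec`.
#' @param lambda interpolation parameter in [0, 1] (1 = begin well).
#' @param start_xyz warm-start coordinates (N x 3).
#' @param settings an `ienm_settings`.
#' @return list with `xyz`, `residual` (max-norm of the interpolated
#'   gradient), `iterations`.
#' @export
interpolated_minimize <- function(spec, lambda, start_xyz,
                                  settings = ienm_settings()) {
  stopifnot(lambda >= 0, lambda <= 1)
  n <- n_atoms(spec$begin)
  x <- as_xyz_matrix(start_xyz, n)
  eg <- interp_energy_gradient(spec, lambda, x)
  res <- max(abs(eg$gradient))
  it <- 0
  mu <- settings$regularization   # adaptive Levenberg-style damping
  while (res > settings$newton_tolerance) {
    if (it >= settings$max_newton_iterations)
      stop(sprintf("Newton did not converge at lambda = %.6f (residual %.3g)",
                   lambda, res))
    H <- lambda * enm_hessian(spec$enm1, x) +
      (1 - lambda) * enm_hessian(spec$enm2, x) +
      collision_hessian(spec, x)
    dmax <- max(Matrix::diag(H))
    accepted <- FALSE
    while (!accepted) {
      dx <- tryCatch(
        as.vector(Matrix::solve(H + mu * dmax * Matrix::Diagonal(3 * n),
                                -as_flat(eg$gradient))),
        error = function(e) NULL)
      if (!is.null(dx)) {
        step <- matrix(dx, ncol = 3, byrow = TRUE)
        t_ <- 1
        while (t_ >= 1 / 1024) {
          xn <- x + t_ * step
          egn <- interp_energy_gradient(spec, lambda, xn)
          rn <- max(abs(egn$gradient))
          ## accept on energy descent (this is a minimisation at fixed
          ## lambda); near the minimum accept on gradient descent instead,
          ## where energy differences fall below float precision
          if (egn$energy < eg$energy - 1e-14 * abs(eg$energy) ||
              (egn$energy <= eg$energy && rn < res)) {
            x <- xn; eg <- egn; res <- rn
            accepted <- TRUE
            mu <- max(settings$regularization, mu / 10)
            break
          }
          t_ <- t_ / 2
        }
      }
      if (!accepted) {
        mu <- mu * 100   # singular or non-descending: damp harder
        if (mu > 1e10) {
          ## no descent step exists in float precision; accept the solution
          ## if it sits within a small factor of the tolerance
          if (res <= 10 * settings$newton_tolerance) break
          stop(sprintf(
            "Newton stalled at lambda = %.6f (residual %.3g, damping %.1g)",
            lambda, res, mu))
        }
      }
    }
    if (!accepted) break
    it <- it + 1
  }
  ## remove rigid-body drift
  tr <- kabsch(x, spec$begin$xyz)
  x <- apply_rigid(x, tr)
  list(xyz = x, residual = max(abs(interp_gradient(spec, lambda, x))),
       iterations = it)
}

#' Solve the full interpolated transition pathway
#'
#' Sweeps lambda from 1 to 0, warm-starting each minimisation from the
#' previous solution, bisecting the schedule wherever consecutive solutions
#' jump by more than twice the sampling increment, and subsampling the
#' converged sweep so retained consecutive conformations are at least the
#' sampling increment apart (begin and end always retained). The sweep is
#' fully deterministic.
#'
#' @param spec an `ienm_spec`.
#' @param settings an `ienm_settings`.
#' @return an `ienm_pathway`: list with `conformations` (list of N x 3
#'   matrices), `lambdas` (descending), `cumulative_length` (Angstrom,
#'   starting at 0), `residuals`, `spec_summary`.
#' @export
solve_pathway <- function(spec, settings = ienm_settings()) {
  n <- n_atoms(spec$begin)
  grid <- seq(1, 0, length.out = settings$n_lambda)
  confs <- list(spec$begin$xyz)
  lambdas <- c(1)
  residuals <- c(max(abs(interp_gradient(spec, 1, spec$begin$xyz))))
  x <- spec$begin$xyz
  pending <- as.list(grid[-1])
  min_gap <- 1e-6
  while (length(pending)) {
    lam <- pending[[1]]
    sol <- interpolated_minimize(spec, lam, x, settings)
    jump <- rmsd_xyz(sol$xyz, x)
    lam_prev <- lambdas[length(lambdas)]
    if (jump > settings$max_step && (lam_prev - lam) > min_gap) {
      pending <- c(list((lam_prev + lam) / 2), pending)
      next
    }
    pending <- pending[-1]
    confs[[length(confs) + 1]] <- sol$xyz
    lambdas <- c(lambdas, lam)
    residuals <- c(residuals, sol$residual)
    x <- sol$xyz
  }
  ## subsample at the RMSD increment; keep first and last
  keep <- 1
  last <- confs[[1]]
  for (m in 2:length(confs)) {
    if (rmsd_xyz(confs[[m]], last) >= settings$sampling_increment ||
        m == length(confs)) {
      keep <- c(keep, m)
      last <- confs[[m]]
    }
  }
  confs <- confs[keep]
  lambdas <- lambdas[keep]
  residuals <- residuals[keep]
  steps <- vapply(seq_along(confs)[-1], function(m)
    rmsd_xyz(confs[[m]], confs[[m - 1]]), numeric(1))
  structure(list(conformations = confs, lambdas = lambdas,
                 cumulative_length = c(0, cumsum(steps)),
                 residuals = residuals,
                 settings = settings),
            class = "ienm_pathway")
}

#' @export
print.ienm_pathway <- function(x, ...) {
  cat(sprintf("iENM pathway: %d conformations (%d intermediate), length %.2f A\n",
              length(x$conformations), max(length(x$conformations) - 2, 0),
              max(x$cumulative_length)))
  invisible(x)
}

#' Per-conformation energy decomposition of a pathway
#'
#' Diagnostic table of the two well energies, the collision energy and
#' lambda along a solved pathway. Along a well-behaved sweep the begin-well
#' energy is non-decreasing and the end-well energy non-increasing as lambda
#' drops (reported, not enforced), and the collision energy vanishes at both
#' endpoints.
#'
#' @param spec an `ienm_spec`.
#' @param pathway an `ienm_pathway`.
#' @return data.frame with columns `index`, `lambda`, `f_progress`, `E1`,
#'   `E2`, `E_coll`, `residual`.
#' @export
pathway_energy_profile <- function(spec, pathway) {
  K <- length(pathway$conformations)
  E1 <- E2 <- Ec <- numeric(K)
  for (m in seq_len(K)) {
    xyz <- pathway$conformations[[m]]
    E1[m] <- enm_energy_gradient(spec$enm1, xyz)$energy
    E2[m] <- enm_energy_gradient(spec$enm2, xyz)$energy
    Ec[m] <- collision_energy_gradient(spec, xyz)$energy
  }
  L <- max(pathway$cumulative_length)
  data.frame(index = seq_len(K), lambda = pathway$lambdas,
             f_progress = if (L > 0) pathway$cumulative_length / L
                          else rep(0, K),
             E1 = E1, E2 = E2, E_coll = Ec,
             residual = pathway$residuals)
}

#' Verify the saddle-point condition along a pathway
#'
#' Independently re-evaluates the interpolated gradient at every stored
#' conformation and returns its max-norm per conformation; all values should
#' sit within 10x of the solver tolerance (endpoints included, since the
#' endpoint structures are the exact minima of their wells up to the
#' collision term).
#'
#' @param spec an `ienm_spec`.
#' @param pathway an `ienm_pathway`.
#' @return numeric vector of residuals, one per conformation.
#' @export
saddle_residuals <- function(spec, pathway) {
  vapply(seq_along(pathway$conformations), function(m)
    max(abs(interp_gradient(spec, pathway$lambdas[m],
                            pathway$conformations[[m]]))),
    numeric(1))
}
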