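#' Build a C-alpha elastic network model
#'
#' Connects every residue pair whose reference C-alpha distance lies below a
#' cutoff with a Hookean spring whose rest length is the reference distance.
#' Chemically bonded pairs (sequential residues of the same chain) always get
#' a spring with the bonded force constant, even beyond the cutoff, so the
#' chain stays intact; all other pairs use the non-bonded constant. The
#' reference structure is the minimum of the resulting potential. Force
#' constants are in arbitrary model units: they set the energy scale only,
#' not the geometry of anything derived from it.
#'
#' @param structure a `calpha` structure (the model's reference/minimum).
#' @param cutoff interaction cutoff R_c in Angstrom (default 10).
#' @param k_bonded spring constant for sequential same-chain pairs (default 10).
#' @param k_nonbonded spring constant for all other pairs in range (default 1).
#' @param masked_pairs optional 2-column matrix/data.frame of (i, j) global
#'   index pairs whose non-bonded springs are removed (perturbation analysis).
#'   Bonded springs are never severed; a masked bonded pair is kept with a
#'   message.
#' @return an `enm_model`: list with `reference` (structure), `springs`
#'   (data.frame i, j, d0, k, bonded), `cutoff`, `k_bonded`, `k_nonbonded`,
#'   `natoms`.
#' @export
build_enm <- function(structure, cutoff = 10, k_bonded = 10, k_nonbonded = 1,
                      masked_pairs = NULL) {
  stopifnot(cutoff > 0)
  xyz <- structure$xyz
  n <- nrow(xyz)
  pr <- pairs_within(xyz, cutoff)
  bonded <- bonded_pairs(structure)
  bkey <- pair_key(bonded[, 1], bonded[, 2], n)
  pkey <- pair_key(pr[, 1], pr[, 2], n)
  ## non-bonded in-range pairs + all bonded pairs
  nb <- pr[!(pkey %in% bkey), , drop = FALSE]
  if (!is.null(masked_pairs) && NROW(masked_pairs) > 0) {
    mp <- canonical_pairs(masked_pairs)
    mkey <- pair_key(mp[, 1], mp[, 2], n)
    if (any(mkey %in% bkey))
      message(sum(mkey %in% bkey),
              " masked pair(s) are chemically bonded and are kept")
    nb <- nb[!(pair_key(nb[, 1], nb[, 2], n) %in% mkey), , drop = FALSE]
  }
  i <- c(bonded[, 1], nb[, 1])
  j <- c(bonded[, 2], nb[, 2])
  k <- c(rep(k_bonded, nrow(bonded)), rep(k_nonbonded, nrow(nb)))
  isb <- c(rep(TRUE, nrow(bonded)), rep(FALSE, nrow(nb)))
  d0 <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  if (any(d0 <= 0)) stop("coincident connected atoms in reference structure")
  ord <- order(i, j)
  springs <- data.frame(i = i, j = j, d0 = d0, k = k, bonded = isb)[ord, ]
  rownames(springs) <- NULL
  if (nrow(springs) == 0) warning("elastic network has no springs")
  structure(list(reference = structure, springs = springs, cutoff = cutoff,
                 k_bonded = k_bonded, k_nonbonded = k_nonbonded, natoms = n),
            class = "enm_model")
}

#' @export
print.enm_model <- function(x, ...) {
  cat(sprintf("ENM: %d atoms, %d springs (%d bonded), cutoff %.1f A\n",
              x$natoms, nrow(x$springs), sum(x$springs$bonded), x$cutoff))
  invisible(x)
}

## all i<j pairs with distance < cutoff, via a cell list (O(N) for fixed density)
pairs_within <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  if (n <= 400) {
    dm <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(dm) & dm < cutoff, arr.ind = TRUE)
    return(cbind(idx[, 1], idx[, 2]))
  }
  cell <- pmax(cutoff, 1e-6)
  g <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  key <- paste(g[, 1], g[, 2], g[, 3])
  buckets <- split(seq_len(n), key)
  coords <- unique(g)
  lookup <- buckets
  out_i <- integer(0); out_j <- integer(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (b in seq_along(buckets)) {
    ii <- buckets[[b]]
    gb <- g[ii[1], ]
    neigh <- integer(0)
    for (r in seq_len(nrow(offs))) {
      kk <- paste(gb[1] + offs[r, 1], gb[2] + offs[r, 2], gb[3] + offs[r, 3])
      nb <- lookup[[kk]]
      if (!is.null(nb)) neigh <- c(neigh, nb)
    }
    for (a in ii) {
      cand <- neigh[neigh > a]
      if (!length(cand)) next
      d2 <- rowSums((xyz[cand, , drop = FALSE] -
                       matrix(xyz[a, ], length(cand), 3, byrow = TRUE))^2)
      hit <- cand[d2 < cutoff^2]
      out_i <- c(out_i, rep.int(a, length(hit)))
      out_j <- c(out_j, hit)
    }
  }
  cbind(out_i, out_j)
}

bonded_pairs <- function(structure) {
  n <- n_atoms(structure)
  if (n < 2) return(matrix(integer(0), 0, 2))
  i <- seq_len(n - 1)
  ok <- structure$chain[i] == structure$chain[i + 1] &
    abs(structure$resno[i + 1] - structure$resno[i]) == 1
  cbind(i[ok], i[ok] + 1L)
}

canonical_pairs <- function(p) {
  p <- as.matrix(p)[, 1:2, drop = FALSE]
  storage.mode(p) <- "integer"
  out <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  unique(out[out[, 1] != out[, 2], , drop = FALSE])
}

pair_key <- function(i, j, n) (pmin(i, j) - 1) * n + pmax(i, j)

## shared harmonic pair machinery: energy/gradient/Hessian of
## sum k/2 (d - d0)^2 over a pair list at arbitrary coordinates
pair_energy_gradient <- function(i, j, d0, k, xyz) {
  dx <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  if (any(d < 1e-8)) stop("coincident interacting atoms (zero distance)")
  e <- sum(0.5 * k * (d - d0)^2)
  cf <- k * (d - d0) / d
  gi <- dx * cf
  n <- nrow(xyz)
  g <- rowsum(rbind(gi, -gi), group = c(i, j), reorder = FALSE)
  grad <- matrix(0, n, 3)
  grad[as.integer(rownames(g)), ] <- g
  list(energy = e, gradient = grad)
}

pair_hessian <- function(i, j, d0, k, xyz, n) {
  ns <- length(i)
  if (ns == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(3 * n, 3 * n), symmetric = FALSE))
  dx <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  if (any(d < 1e-8)) stop("coincident interacting atoms (zero distance)")
  u <- dx / d
  c1 <- k              # along-bond stiffness
  c2 <- k * (d - d0) / d  # transverse (tension) stiffness
  ## 3x3 block B(ab) = c2 * delta_ab + (c1 - c2) * u_a u_b, column-major S x 9
  B <- matrix(0, ns, 9)
  for (a in 1:3) for (b in 1:3) {
    val <- (c1 - c2) * u[, a] * u[, b]
    if (a == b) val <- val + c2
    B[, (b - 1) * 3 + a] <- val
  }
  ri <- 3 * (i - 1); rj <- 3 * (j - 1)
  aa <- rep(1:3, times = 3); bb <- rep(1:3, each = 3)
  II <- c(); JJ <- c(); XX <- c()
  for (cidx in 1:9) {
    a <- aa[cidx]; b <- bb[cidx]; v <- B[, cidx]
    II <- c(II, ri + a, rj + a, ri + a, rj + a)
    JJ <- c(JJ, ri + b, rj + b, rj + b, ri + b)
    XX <- c(XX, v, v, -v, -v)
  }
  Matrix::sparseMatrix(i = II, j = JJ, x = XX, dims = c(3 * n, 3 * n))
}

#' Potential energy and analytic gradient of an ENM
#'
#' @param model an `enm_model`.
#' @param xyz N x 3 coordinate matrix (or 3N vector).
#' @return list with `energy` (model units) and `gradient` (N x 3 matrix).
#' @export
enm_energy_gradient <- function(model, xyz) {
  xyz <- as_xyz_matrix(xyz, model$natoms)
  s <- model$springs
  if (nrow(s) == 0) return(list(energy = 0, gradient = matrix(0, model$natoms, 3)))
  pair_energy_gradient(s$i, s$j, s$d0, s$k, xyz)
}

#' Sparse analytic Hessian of an ENM at arbitrary coordinates
#'
#' Each spring contributes the standard 3 x 3 super-element to the (i,i),
#' (j,j), (i,j), (j,i) blocks only, so the matrix inherits the contact
#' topology's sparsity. At the reference structure the Hessian is positive
#' semidefinite with a six-dimensional rigid-body null space for a connected
#' network.
#'
#' @param model an `enm_model`.
#' @param xyz N x 3 coordinates (defaults to the reference).
#' @return a sparse symmetric 3N x 3N `Matrix`.
#' @export
enm_hessian <- function(model, xyz = NULL) {
  if (is.null(xyz)) xyz <- model$reference$xyz
  xyz <- as_xyz_matrix(xyz, model$natoms)
  s <- model$springs
  pair_hessian(s$i, s$j, s$d0, s$k, xyz, model$natoms)
}

as_xyz_matrix <- function(xyz, n) {
  if (is.matrix(xyz)) {
    stopifnot(nrow(xyz) == n, ncol(xyz) == 3)
    return(xyz)
  }
  stopifnot(length(xyz) == 3 * n)
  matrix(xyz, ncol = 3, byrow = TRUE)
}

as_flat <- function(xyz) as.vector(t(xyz))

## connected components of the spring graph (BFS over adjacency lists)
network_components <- function(model) {
  n <- model$natoms
  adj <- vector("list", n)
  for (r in seq_len(nrow(model$springs))) {
    i <- model$springs$i[r]; j <- model$springs$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cur <- 0
  for (start in seq_len(n)) {
    if (comp[start] != 0) next
    cur <- cur + 1
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Normal mode analysis of an ENM
#'
#' Diagonalises the reference-state Hessian (uniform unit masses) and returns
#' the lowest non-rigid modes in ascending eigenvalue order. The six
#' smallest-magnitude eigenvalues are the rigid translations/rotations and
#' are excluded; a connected network must show a gap of at least a factor
#' 1e6 between the 6th and 7th magnitude, otherwise the network is
#' disconnected and an error names the components. Eigenvector signs are
#' fixed so the first non-negligible coordinate of each mode is positive.
#'
#' @param model an `enm_model`.
#' @param n_modes number of non-rigid modes to return.
#' @param method `"dense"` (LAPACK on the full matrix), `"sparse"`
#'   (shift-invert subspace iteration on the sparse Hessian), or `"auto"`
#'   (dense for 3N <= 1200).
#' @return an `enm_modes` object: `values` (ascending eigenvalues),
#'   `vectors` (3N x n_modes, orthonormal columns), `rigid_values`,
#'   `n_excluded_rigid = 6`.
#' @export
normal_modes <- function(model, n_modes = 10, method = c("auto", "dense", "sparse")) {
  method <- match.arg(method)
  n3 <- 3 * model$natoms
  ## rigid-body dimension: 6 in general, 5 for collinear point sets
  cen <- sweep(model$reference$xyz, 2, colMeans(model$reference$xyz))
  rank <- qr(cen, tol = 1e-9)$rank
  n_rigid <- if (rank <= 1) 5L else 6L
  n_modes <- min(n_modes, n3 - n_rigid)
  stopifnot(n_modes >= 1)
  H <- enm_hessian(model)
  if (method == "auto") method <- if (n3 <= 1200) "dense" else "sparse"
  if (method == "dense") {
    eig <- eigen(as.matrix(Matrix::symmpart(H)), symmetric = TRUE)
    vals <- rev(eig$values)
    vecs <- eig$vectors[, rev(seq_len(n3)), drop = FALSE]
  } else {
    si <- shift_invert_modes(H, n_modes + n_rigid)
    vals <- si$values
    vecs <- si$vectors
  }
  rigid <- vals[seq_len(n_rigid)]
  if (abs(vals[n_rigid + 1]) < 1e6 * max(abs(vals[n_rigid]), 1e-300)) {
    comp <- network_components(model)
    if (max(comp) > 1)
      stop("elastic network is disconnected (", max(comp),
           " components; sizes ", paste(tabulate(comp), collapse = ", "),
           "); rigid-body null space exceeds dimension ", n_rigid)
    stop("elastic network is connected but underconstrained (floppy modes ",
         "beyond the ", n_rigid, " rigid-body ones); densify contacts or ",
         "raise the cutoff")
  }
  sel <- (n_rigid + 1):(n_rigid + n_modes)
  vecs <- vecs[, sel, drop = FALSE]
  vecs <- apply(vecs, 2, fix_sign)
  if (!is.matrix(vecs)) vecs <- matrix(vecs, ncol = n_modes)
  structure(list(values = vals[sel], vectors = vecs,
                 rigid_values = rigid, n_excluded_rigid = n_rigid,
                 natoms = model$natoms),
            class = "enm_modes")
}

#' @export
print.enm_modes <- function(x, ...) {
  cat(sprintf("%d normal modes (%d atoms); eigenvalues %.4g .. %.4g\n",
              length(x$values), x$natoms, x$values[1],
              x$values[length(x$values)]))
  invisible(x)
}

fix_sign <- function(v) {
  k <- which(abs(v) > 1e-9)[1]
  if (is.na(k) || v[k] >= 0) v else -v
}

## lowest eigenpairs of a sparse symmetric PSD matrix by shift-invert
## subspace iteration: factor (H + sigma I) once, iterate an orthonormal
## block through the inverse, Rayleigh-Ritz until eigenvalues settle.
shift_invert_modes <- function(H, k, tol = 1e-11, max_iter = 500) {
  n <- nrow(H)
  sigma <- 1e-6 * max(Matrix::diag(H))
  A <- methods::as(H + sigma * Matrix::Diagonal(n), "symmetricMatrix")
  ch <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  m <- min(n, k + min(10, k))   # guard vectors speed convergence
  ## deterministic start block: fixed congruential sequence, no RNG state touched
  x0 <- (seq_len(n * m) * 2654435761) %% 2^32 / 2^32 - 0.5
  X <- qr.Q(qr(matrix(x0, n, m)))
  old <- rep(Inf, k)
  for (it in seq_len(max_iter)) {
    Y <- as.matrix(Matrix::solve(ch, X, system = "A"))
    X <- qr.Q(qr(Y))
    T_ <- crossprod(X, as.matrix(H %*% X))
    eg <- eigen((T_ + t(T_)) / 2, symmetric = TRUE)
    ord <- order(eg$values)
    vals <- eg$values[ord][1:k]
    scale <- max(abs(vals), 1e-12)
    X <- X %*% eg$vectors[, ord, drop = FALSE]
    if (max(abs(vals - old)) < tol * scale) {
      ## explicit eigenpair residual check so eigenVECTORS are converged too
      Rres <- as.matrix(H %*% X[, 1:k, drop = FALSE]) -
        sweep(X[, 1:k, drop = FALSE], 2, vals, "*")
      if (max(sqrt(colSums(Rres^2))) < 1e-9 * scale)
        return(list(values = vals, vectors = X[, 1:k, drop = FALSE]))
    }
    old <- vals
  }
  warning("subspace iteration reached max_iter; eigenpairs may be inaccurate")
  list(values = old, vectors = X[, 1:k, drop = FALSE])
}

#' Overlap of a normal mode with an observed displacement
#'
#' Normalised absolute projection |m . d| / (|m| |d|) of a mode eigenvector
#' onto the displacement between two superposed conformations; 1 means the
#' mode points exactly along the observed change.
#'
#' @param mode a 3N vector (or N x 3 matrix).
#' @param delta displacement 3N vector (or N x 3 matrix), non-zero.
#' @return overlap in [0, 1].
#' @export
overlap <- function(mode, delta) {
  m <- if (is.matrix(mode)) as_flat(mode) else as.numeric(mode)
  d <- if (is.matrix(delta)) as_flat(delta) else as.numeric(delta)
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("zero displacement vector")
  abs(sum(m * d)) / (sqrt(sum(m^2)) * nd)
}

#' Cumulative overlap of the lowest M modes with a displacement
#'
#' Quadrature aggregate sqrt(sum of squared overlaps) over the lowest M
#' non-rigid modes: the fraction of the observed conformational change
#' captured by that mode subset. Non-decreasing in M; reaches 1 over the
#' complete non-rigid basis when the displacement has no rigid component.
#'
#' @param modes an `enm_modes` object.
#' @param delta displacement (3N vector or N x 3 matrix).
#' @param M number of modes to accumulate (default: all available).
#' @return cumulative overlap in [0, 1].
#' @export
cumulative_overlap <- function(modes, delta, M = ncol(modes$vectors)) {
  stopifnot(M >= 1, M <= ncol(modes$vectors))
  d <- if (is.matrix(delta)) as_flat(delta) else as.numeric(delta)
  ov <- vapply(seq_len(M), function(m) overlap(modes$vectors[, m], d),
               numeric(1))
  min(sqrt(sum(ov^2)), 1)
}

#' Displace a structure along a mode by a prescribed RMSD
#'
#' Adds a * mode to the coordinates with amplitude a = rmsd * sqrt(N), so the
#' displaced structure sits exactly `target_rmsd` from the original.
#'
#' @param structure a `calpha` structure.
#' @param mode unit 3N vector (renormalised with a warning if not unit).
#' @param target_rmsd displacement RMSD in Angstrom, >= 0.
#' @return the displaced `calpha` structure.
#' @export
displace_along_mode <- function(structure, mode, target_rmsd) {
  stopifnot(target_rmsd >= 0)
  m <- if (is.matrix(mode)) as_flat(mode) else as.numeric(mode)
  nm <- sqrt(sum(m^2))
  if (abs(nm - 1) > 1e-8) {
    warning("mode vector is not unit length; renormalising")
    m <- m / nm
  }
  n <- n_atoms(structure)
  stopifnot(length(m) == 3 * n)
  out <- structure
  out$xyz <- structure$xyz + target_rmsd * sqrt(n) * matrix(m, ncol = 3, byrow = TRUE)
  out
}

#' Scan the ENM cutoff for cumulative-overlap maximisation
#'
#' Rebuilds the network over a grid of cutoffs and reports the cumulative
#' overlap of the lowest `n_modes` modes with a given displacement — the
#' diagnostic used to pick the interaction cutoff for a specific transition.
#'
#' @param structure begin `calpha` structure.
#' @param delta displacement to the (superposed) end conformation.
#' @param cutoffs grid of cutoffs in Angstrom (default 8 to 16 by 1).
#' @param n_modes number of modes in the cumulative overlap.
#' @param ... passed to [build_enm()].
#' @return data.frame with columns `cutoff`, `cumulative_overlap`.
#' @export
cutoff_scan <- function(structure, delta, cutoffs = 8:16, n_modes = 10, ...) {
  co <- vapply(cutoffs, function(rc) {
    md <- normal_modes(build_enm(structure, cutoff = rc, ...), n_modes = n_modes)
    cumulative_overlap(md, delta)
  }, numeric(1))
  data.frame(cutoff = cutoffs, cumulative_overlap = co)
}
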