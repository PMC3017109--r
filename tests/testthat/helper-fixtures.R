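## Shared fixtures and one-time solver runs, cached across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache))
    assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

fix_barrel <- function() cached("barrel", make_two_state("c5-barrel", n_res = 12))
fix_hinge <- function() cached("hinge",
                               make_two_state("hinge-dimer", n_res = 60,
                                              hinge_angle = 30))
fix_chain <- function() cached("chain",
                               make_two_state("two-phase-chain", n_res = 40))

## solved iENM runs (the expensive bits)
barrel_spec <- function() cached("barrel_spec",
  double_well_spec(fix_barrel()$begin, fix_barrel()$end))
barrel_path <- function() cached("barrel_path",
  solve_pathway(barrel_spec(), ienm_settings(n_lambda = 101)))
hinge_spec <- function() cached("hinge_spec",
  double_well_spec(fix_hinge()$begin, fix_hinge()$end))
hinge_path <- function() cached("hinge_path",
  solve_pathway(hinge_spec(), ienm_settings(n_lambda = 101)))

## worst-case alignment error between two mode sets, grouping eigenvalues
## into near-degenerate clusters (relative gap < `gap`) and comparing the
## spanned subspaces; for isolated eigenvalues this is the usual
## sign-insensitive vector comparison
mode_subspace_dev <- function(a, b, gap = 1e-3) {
  stopifnot(length(a$values) == length(b$values))
  rel <- abs(diff(a$values)) / pmax(abs(a$values[-1]), 1e-12)
  cl <- cumsum(c(1, as.integer(rel >= gap)))
  worst <- 0
  for (g in unique(cl)) {
    idx <- which(cl == g)
    Va <- a$vectors[, idx, drop = FALSE]
    Vb <- b$vectors[, idx, drop = FALSE]
    resid <- Va - Vb %*% crossprod(Vb, Va)   # component of span(a) outside span(b)
    worst <- max(worst, sqrt(max(colSums(resid^2))))
  }
  worst
}

## central-difference gradient of any scalar function of N x 3 coords
numerical_gradient <- function(f, xyz, h = 1e-6) {
  g <- matrix(0, nrow(xyz), 3)
  for (i in seq_len(nrow(xyz))) for (a in 1:3) {
    xp <- xyz; xp[i, a] <- xp[i, a] + h
    xm <- xyz; xm[i, a] <- xm[i, a] - h
    g[i, a] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

## small toy PDB text (three residues, two chains)
toy_pdb_lines <- function() c(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
  "ATOM      3  CA  GLY A   2      12.967   8.793  -3.700  1.00 11.00           C",
  "ATOM      4  O   GLY A   2      13.000   9.000  -3.000  1.00  0.00           O",
  "ATOM      5  CA  SER B   1      15.000   2.000  -1.000  1.00 12.00           C",
  "END")

write_toy_pdb <- function(lines = toy_pdb_lines()) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

## deterministic pseudo-random spherical cage around the z axis
cage_structure <- function(n = 40, radius = 9, height = 12, seed = 7) {
  set.seed(seed)
  z <- runif(n, -height / 2, height / 2)
  th <- runif(n, 0, 2 * pi)
  r <- radius + rnorm(n, sd = 0.5)
  calpha_structure(rep("A", n), seq_len(n),
                   xyz = cbind(r * cos(th), r * sin(th), z),
                   label = "cage")
}

## brute-force pore radius at one axial height: 0.05 A grid over in-plane
## centres, radius = max over centres of (min atom distance - atom radius)
grid_pore_radius <- function(xyz, atom_radius, z, half_width = 4, by = 0.05) {
  g <- seq(-half_width, half_width, by = by)
  best <- -Inf
  for (cx in g) {
    cen <- cbind(cx, g, z)
    for (k in seq_along(g)) {
      d <- sqrt(colSums((t(xyz) - c(cx, g[k], z))^2))
      best <- max(best, min(d) - atom_radius)
    }
  }
  best
}
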