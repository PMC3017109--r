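test_that("spring construction follows the bonded/cutoff rules", {
  ## two sequential residues: bonded spring with k = 10 regardless of cutoff
  two <- calpha_structure(c("A", "A"), 1:2, xyz = rbind(c(0, 0, 0), c(3.8, 0, 0)))
  m <- build_enm(two, cutoff = 10)
  expect_equal(nrow(m$springs), 1)
  expect_equal(m$springs$k, 10)
  expect_true(m$springs$bonded)
  m2 <- build_enm(two, cutoff = 2)   # bonded pair survives a tiny cutoff
  expect_equal(nrow(m2$springs), 1)

  ## two non-bonded residues beyond the cutoff: no spring
  far <- calpha_structure(c("A", "B"), c(1, 1),
                          xyz = rbind(c(0, 0, 0), c(12, 0, 0)))
  expect_warning(m3 <- build_enm(far, cutoff = 10), "no springs")
  expect_equal(nrow(m3$springs), 0)

  ## ring fixture: spring count matches a brute-force O(N^2) scan
  n <- 10
  th <- 2 * pi * (0:(n - 1)) / n
  ring <- calpha_structure(rep("A", n), 1:n,
                           xyz = cbind(6 * cos(th), 6 * sin(th), 0))
  cutoff <- 5  # spans nearest + next-nearest neighbours
  m4 <- build_enm(ring, cutoff = cutoff)
  dm <- as.matrix(dist(ring$xyz))
  brute <- sum(dm[upper.tri(dm)] < cutoff)
  bonded_beyond <- sum(dm[cbind(1:(n - 1), 2:n)] >= cutoff)
  expect_equal(nrow(m4$springs), brute + bonded_beyond)
})

test_that("energy and gradient match closed forms and finite differences", {
  fx <- fix_chain()
  m <- build_enm(fx$begin)

  ## reference is the exact minimum
  eg0 <- enm_energy_gradient(m, fx$begin$xyz)
  expect_equal(eg0$energy, 0)
  expect_equal(max(abs(eg0$gradient)), 0)

  ## one spring k = 1, d0 = 1, stretched to 2: E = 1/2
  two <- calpha_structure(c("A", "A"), 1:2, xyz = rbind(c(0, 0, 0), c(1, 0, 0)))
  m1 <- build_enm(two, cutoff = 5, k_bonded = 1)
  e <- enm_energy_gradient(m1, rbind(c(0, 0, 0), c(2, 0, 0)))$energy
  expect_equal(e, 0.5)

  ## analytic gradient vs central differences at a perturbed conformation
  x <- fx$begin$xyz + 0.1 * sin(seq_len(3 * n_atoms(fx$begin)))
  eg <- enm_energy_gradient(m, x)
  num <- numerical_gradient(function(z) enm_energy_gradient(m, z)$energy, x)
  expect_lt(max(abs(num - eg$gradient)) / max(abs(eg$gradient)), 1e-6)

  ## coincident connected atoms are a hard error
  bad <- fx$begin$xyz
  bad[2, ] <- bad[1, ]
  expect_error(enm_energy_gradient(m, bad), "coincident")
})

test_that("Hessian is consistent with the gradient and rigid motions", {
  fx <- make_two_state("two-phase-chain", n_res = 8)
  m <- build_enm(fx$begin)
  n <- n_atoms(fx$begin)
  x <- fx$begin$xyz + 0.05 * cos(seq_len(3 * n))
  H <- as.matrix(enm_hessian(m, x))
  expect_true(isSymmetric(H, tol = 1e-12))

  ## finite differences of the gradient
  h <- 1e-5
  num <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (a in 1:3) {
    xp <- x; xp[i, a] <- xp[i, a] + h
    xm <- x; xm[i, a] <- xm[i, a] - h
    gd <- enm_energy_gradient(m, xp)$gradient - enm_energy_gradient(m, xm)$gradient
    num[, 3 * (i - 1) + a] <- as.vector(t(gd)) / (2 * h)
  }
  expect_lt(max(abs(num - H)) / max(abs(H)), 1e-5)

  ## translation invariance at the reference: H t = 0 exactly
  H0 <- enm_hessian(m)
  tx <- rep(c(1, 0, 0), n)
  expect_equal(max(abs(H0 %*% tx)), 0)

  ## infinitesimal rotation generator is in the null space at the reference
  cen <- sweep(fx$begin$xyz, 2, colMeans(fx$begin$xyz))
  rotgen <- as.vector(t(cbind(-cen[, 2], cen[, 1], 0)))
  rotgen <- rotgen / sqrt(sum(rotgen^2))
  expect_lt(max(abs(H0 %*% rotgen)), 1e-8)
})

test_that("normal modes: closed form, dense/sparse agreement, sign convention", {
  ## two atoms, one spring k: single nonzero eigenvalue 2k along the bond
  two <- calpha_structure(c("A", "A"), 1:2, xyz = rbind(c(0, 0, 0), c(1.5, 0, 0)))
  m <- build_enm(two, cutoff = 5, k_bonded = 3)
  md <- normal_modes(m, n_modes = 1)
  expect_equal(md$values, 6, tolerance = 1e-10)
  v <- matrix(md$vectors[, 1], ncol = 3, byrow = TRUE)
  expect_equal(abs(v[, 1]), rep(sqrt(0.5), 2), tolerance = 1e-8)
  expect_lt(max(abs(v[, 2:3])), 1e-10)

  ## sparse shift-invert equals dense eigendecomposition (the helix backbone
  ## has near-degenerate doublets, so vectors are compared per eigen-cluster)
  fx <- fix_chain()
  mdl <- build_enm(fx$begin)
  k <- 8
  de <- normal_modes(mdl, k, method = "dense")
  sp <- normal_modes(mdl, k, method = "sparse")
  expect_equal(de$values, sp$values, tolerance = 1e-8)
  expect_lt(mode_subspace_dev(de, sp), 1e-6)

  ## orthonormality and the fixed sign convention
  G <- crossprod(de$vectors)
  expect_equal(G, diag(k), tolerance = 1e-8)
  firsts <- apply(de$vectors, 2, function(v) v[which(abs(v) > 1e-9)[1]])
  expect_true(all(firsts > 0))

  ## rigid eigenvalues are tiny; 6 excluded in general, 5 for the collinear
  ## two-atom system (no rotation about the bond axis)
  expect_equal(md$n_excluded_rigid, 5L)
  expect_equal(de$n_excluded_rigid, 6L)
  expect_lt(max(abs(de$rigid_values)), 1e-8)

  ## disconnected network: error naming components
  apart <- calpha_structure(c("A", "B"), c(1, 1),
                            xyz = rbind(c(0, 0, 0), c(50, 0, 0)))
  frag <- make_two_state("two-phase-chain", n_res = 12)$begin
  frag$xyz[7:12, 1] <- frag$xyz[7:12, 1] + 100
  frag$chain[7:12] <- "B"
  mfrag <- build_enm(frag)
  expect_error(normal_modes(mfrag, 2), "disconnected")
})

test_that("overlap, cumulative overlap and mode displacement behave as defined", {
  fx <- fix_chain()
  mdl <- build_enm(fx$begin)
  md <- normal_modes(mdl, 12)
  v1 <- md$vectors[, 1]

  expect_equal(overlap(v1, 2.5 * v1), 1, tolerance = 1e-10)
  expect_equal(overlap(v1, md$vectors[, 2]), 0, tolerance = 1e-8)
  expect_error(overlap(v1, numeric(length(v1))), "zero")

  ## sign-flip invariance
  delta <- fx$end$xyz - fx$begin$xyz
  expect_equal(overlap(v1, delta), overlap(-v1, delta))

  ## M = 1 reduces to the single-mode overlap; non-decreasing in M
  co <- vapply(1:12, function(M) cumulative_overlap(md, delta, M), numeric(1))
  expect_equal(co[1], overlap(v1, delta))
  expect_true(all(diff(co) >= -1e-12))

  ## complete non-rigid basis captures a rigid-free displacement exactly
  small <- make_two_state("two-phase-chain", n_res = 6)
  msm <- build_enm(small$begin)
  all_md <- normal_modes(msm, 3 * 6 - 6)
  d <- sin(seq_len(18))
  d_proj <- as.vector(all_md$vectors %*% crossprod(all_md$vectors, d))
  expect_equal(cumulative_overlap(all_md, d_proj), 1, tolerance = 1e-8)

  ## displacement along a mode hits the target RMSD exactly and is reversible
  s0 <- fx$begin
  s3 <- displace_along_mode(s0, v1, 3)
  expect_equal(sqrt(mean(rowSums((s3$xyz - s0$xyz)^2))), 3, tolerance = 1e-10)
  back <- displace_along_mode(s3, -v1, 3)
  expect_equal(back$xyz, s0$xyz, tolerance = 1e-10)
  expect_equal(displace_along_mode(s0, v1, 0)$xyz, s0$xyz)
  expect_warning(displace_along_mode(s0, 2 * v1, 1), "unit")
})

test_that("removing a spring never increases an eigenvalue", {
  fx <- make_two_state("two-phase-chain", n_res = 10)
  mdl <- build_enm(fx$begin)
  de <- normal_modes(mdl, 10, method = "dense")
  nb <- mdl$springs[!mdl$springs$bonded, ]
  pick <- nb[c(1, nrow(nb) %/% 2, nrow(nb)), c("i", "j")]
  for (r in seq_len(nrow(pick))) {
    masked <- build_enm(fx$begin, masked_pairs = pick[r, , drop = FALSE])
    expect_equal(nrow(masked$springs), nrow(mdl$springs) - 1)
    dm <- normal_modes(masked, 10, method = "dense")
    expect_true(all(dm$values <= de$values + 1e-10))
  }
})
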