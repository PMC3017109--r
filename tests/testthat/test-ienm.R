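test_that("collision term is zero at the endpoints and repulsive below d_c", {
  spec <- barrel_spec()
  fx <- fix_barrel()

  ## d_c is the minimal non-bonded distance, so both endpoints are clean
  e_b <- collision_energy_gradient(spec, fx$begin$xyz)
  e_e <- collision_energy_gradient(spec, spec$enm2$reference$xyz)
  expect_equal(e_b$energy, 0)
  expect_equal(e_e$energy, 0)
  expect_equal(max(abs(e_b$gradient)), 0)

  ## push one non-bonded pair to d_c / 2: positive energy, pair pushed apart
  nb <- spec$enm1$springs[!spec$enm1$springs$bonded, ][1, ]
  x <- fx$begin$xyz
  mid <- (x[nb$i, ] + x[nb$j, ]) / 2
  dir <- (x[nb$j, ] - x[nb$i, ]) / sqrt(sum((x[nb$j, ] - x[nb$i, ])^2))
  x[nb$i, ] <- mid - dir * spec$d_c / 4
  x[nb$j, ] <- mid + dir * spec$d_c / 4
  cc <- collision_energy_gradient(spec, x)
  expect_gt(cc$energy, 0)
  expect_gt(cc$n_collisions, 0)
  ## force (-gradient) on atom i points away from j: repulsion
  expect_gt(sum(-cc$gradient[nb$i, ] * (-dir)), 0)
  expect_gt(sum(-cc$gradient[nb$j, ] * dir), 0)

  ## finite-difference check at the colliding configuration
  num <- numerical_gradient(function(z) collision_energy_gradient(spec, z)$energy, x)
  expect_lt(max(abs(num - cc$gradient)) / max(abs(cc$gradient)), 1e-6)
})

test_that("interpolated minimisation solves the two trivial wells", {
  spec <- barrel_spec()
  fx <- fix_barrel()
  settings <- ienm_settings(n_lambda = 101)

  ## lambda = 1 from the begin coordinates: already at the minimum
  s1 <- interpolated_minimize(spec, 1, fx$begin$xyz, settings)
  expect_equal(s1$iterations, 0)
  expect_equal(s1$xyz, fx$begin$xyz, tolerance = 1e-12)

  ## lambda = 0 via the warm-started sweep reaches the end target
  pw <- barrel_path()
  final <- pw$conformations[[length(pw$conformations)]]
  expect_lt(sqrt(mean(rowSums((final - spec$end_mapped)^2))), 1e-4)
})

test_that("pathway conformations satisfy the saddle-point equation", {
  spec <- barrel_spec()
  pw <- barrel_path()
  res <- saddle_residuals(spec, pw)
  expect_true(all(res <= 10 * pw$settings$newton_tolerance))
  expect_equal(pw$lambdas[1], 1)
  expect_equal(pw$lambdas[length(pw$lambdas)], 0)
  expect_true(all(diff(pw$lambdas) < 0))
  expect_true(all(diff(pw$cumulative_length) > 0))

  ## consecutive RMSDs respect the sampling increment (final step excepted)
  steps <- diff(pw$cumulative_length)
  if (length(steps) > 1)
    expect_true(all(steps[-length(steps)] >=
                      pw$settings$sampling_increment - 1e-12))
})

test_that("degenerate and hinge transitions behave as metric paths", {
  ## identical begin and end: two conformations, zero length
  fx <- fix_barrel()
  spec0 <- double_well_spec(fx$begin, fx$begin)
  pw0 <- solve_pathway(spec0, ienm_settings(n_lambda = 11))
  expect_equal(max(pw0$cumulative_length), 0, tolerance = 1e-9)
  expect_lte(length(pw0$conformations), 2)

  ## hinge path connects the inputs; arc length >= straight-line RMSD
  spec <- hinge_spec()
  pw <- hinge_path()
  expect_equal(pw$conformations[[1]], fix_hinge()$begin$xyz)
  straight <- sqrt(mean(rowSums((spec$end_mapped - fix_hinge()$begin$xyz)^2)))
  expect_gte(max(pw$cumulative_length), straight - 1e-9)
})

test_that("well energies are monotone along the sweep and zero at their minima", {
  spec <- barrel_spec()
  prof <- pathway_energy_profile(spec, barrel_path())
  expect_equal(prof$E1[1], 0, tolerance = 1e-12)
  expect_equal(prof$E2[nrow(prof)], 0, tolerance = 1e-8)
  expect_equal(prof$E_coll[1], 0)
  expect_equal(prof$E_coll[nrow(prof)], 0, tolerance = 1e-10)
  expect_true(all(diff(prof$E1) >= -1e-8))
  expect_true(all(diff(prof$E2) <= 1e-8))
})

test_that("the sampled path is independent of the lambda schedule", {
  fx <- fix_chain()
  spec <- double_well_spec(fx$begin, fx$end)
  keep_all <- function(n) ienm_settings(n_lambda = n,
                                        sampling_increment = 1e-9,
                                        max_step = Inf)
  pa <- solve_pathway(spec, keep_all(41))
  pb <- solve_pathway(spec, keep_all(21))
  ## the coarse schedule's lambdas all occur in the fine schedule
  for (m in seq_along(pb$lambdas)) {
    k <- which.min(abs(pa$lambdas - pb$lambdas[m]))
    expect_lt(abs(pa$lambdas[k] - pb$lambdas[m]), 1e-9)
    expect_lt(sqrt(mean(rowSums((pa$conformations[[k]] -
                                   pb$conformations[[m]])^2))), 1e-6)
  }
})

test_that("C5-symmetric endpoints give a C5-symmetric pathway", {
  fx <- fix_barrel()
  expect_lt(c5_deviation(fx$begin$xyz), 1e-10)
  expect_lt(c5_deviation(fx$end$xyz), 1e-10)
  devs <- vapply(barrel_path()$conformations, c5_deviation, numeric(1))
  expect_lt(max(devs), 1e-6)
})

test_that("unaligned residues are excluded from the end well's non-bonded terms", {
  fx <- make_two_state("c5-barrel", n_res = 12, delete_end_resnos = 5:6)
  spec <- double_well_spec(fx$begin, fx$end, map = fx$map)
  un <- fx$map$unaligned_begin
  s2 <- spec$enm2$springs
  touching <- s2$i %in% un | s2$j %in% un
  expect_true(all(s2$bonded[touching]))
  ## bonded springs touching unaligned residues keep begin rest lengths
  tb <- s2[touching, ]
  d_begin <- sqrt(rowSums((fx$begin$xyz[tb$i, , drop = FALSE] -
                             fx$begin$xyz[tb$j, , drop = FALSE])^2))
  expect_equal(tb$d0, d_begin, tolerance = 1e-12)

  ## the sweep still reaches the end target on aligned residues; the final
  ## frame follows the all-atom fit onto the begin structure (unaligned
  ## residues included), so compare modulo a rigid transform
  pw <- solve_pathway(spec, ienm_settings(n_lambda = 51))
  final <- pw$conformations[[length(pw$conformations)]]
  al <- fx$map$pairs$i
  sfin <- fx$begin
  sfin$xyz <- final
  starg <- fx$begin
  starg$xyz <- spec$end_mapped
  starg$xyz[!spec$aligned, ] <- final[!spec$aligned, ]
  fit <- superpose(sfin, starg,
                   map = alignment_map(al, al, sfin, starg))
  expect_lt(fit$rmsd, 1e-3)
})
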