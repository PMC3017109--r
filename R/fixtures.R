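#' Synthetic two-state structures with known motional order
#'
#' Generates small multi-chain C-alpha assemblies whose begin and end states
#' differ by a documented rigid-body/hinge motion, so every stage of the
#' pathway/progress/perturbation/pore machinery can be exercised and checked
#' against construction ground truth without downloading real structures.
#' Backbones are idealised C-alpha helices (rise 1.5 Angstrom, 100 degree
#' twist, helix radius 2.3 Angstrom): the elastic network needs plausible
#' neighbour distances, not chemistry.
#'
#' Topologies:
#' \describe{
#'   \item{`hinge-dimer`}{chain A (a long stalk) is static in the
#'     construction frame; chain B (a short arm, `n_res %/% 8` residues)
#'     rotates rigidly about a hinge at the stalk top. The end state is
#'     returned already least-squares-superposed onto the begin state, which
#'     redistributes a little of the arm motion into the stalk, so the truth
#'     groups `static` (displacement < 0.4 Angstrom) and `moving`
#'     (> 1 Angstrom) are derived from the superposed displacement field.}
#'   \item{`two-phase-chain`}{one chain; an early segment A displaces by
#'     `displacement` and a late segment B by twice that. The default
#'     `phase_split = 0.8` makes the two phases of the constructed
#'     two-phase path (see [two_phase_path()]) equal in arc length, so A
#'     crosses at fractional progress 0.25 and B at 0.75.}
#'   \item{`c5-barrel`}{five identical chains on a ring (C5 symmetric);
#'     the end state expands the ring radius by `expansion`. Both states
#'     and any faithful pathway are exactly five-fold symmetric.}
#' }
#'
#' @param topology `"hinge-dimer"`, `"two-phase-chain"` or `"c5-barrel"`.
#' @param n_res residues per chain (default 40).
#' @param hinge_angle arm rotation in degrees (hinge-dimer, default 25).
#' @param displacement segment-A displacement in Angstrom (two-phase-chain,
#'   default 3; segment B moves twice as far).
#' @param phase_split fraction of the chain in segment A (default 0.8).
#' @param barrel_radius ring radius in Angstrom (c5-barrel, default 8;
#'   small enough that adjacent chains share several contacts at the default
#'   cutoff, so the network has no floppy inter-chain modes).
#' @param expansion radial expansion in Angstrom (c5-barrel, default 2).
#' @param delete_end_resnos residue numbers to delete from the end structure
#'   (exercises unaligned-residue handling; default none).
#' @param jitter amplitude of deterministic coordinate perturbation in
#'   Angstrom (default 0; breaks exact symmetry when positive).
#' @param seed integer controlling the jitter pattern (default 1).
#' @return list with `begin`, `end` (`calpha` structures), `map`
#'   (`alignment_map`), `truth` (list of index groups and expected order).
#' @export
make_two_state <- function(topology = c("hinge-dimer", "two-phase-chain",
                                        "c5-barrel"),
                           n_res = 40, hinge_angle = 25, displacement = 3,
                           phase_split = 0.8, barrel_radius = 8,
                           expansion = 2, delete_end_resnos = NULL,
                           jitter = 0, seed = 1) {
  topology <- match.arg(topology)
  out <- switch(topology,
    "hinge-dimer" = fixture_hinge(n_res, hinge_angle),
    "two-phase-chain" = fixture_two_phase(n_res, displacement, phase_split),
    "c5-barrel" = fixture_barrel(n_res, barrel_radius, expansion))
  if (jitter > 0) {
    ## deterministic low-discrepancy jitter; same seed, same bits
    nb <- n_atoms(out$begin)
    h <- ((seq_len(3 * nb) + as.integer(seed)) * 2654435761) %% 2^32 / 2^32
    J <- jitter * (matrix(h, ncol = 3) - 0.5)
    out$begin$xyz <- out$begin$xyz + J
    out$end$xyz <- out$end$xyz + J
  }
  end <- out$end
  if (!is.null(delete_end_resnos)) {
    keep <- !(end$resno %in% delete_end_resnos)
    end <- calpha_structure(end$chain[keep], end$resno[keep],
                            end$resid[keep], end$xyz[keep, , drop = FALSE],
                            label = end$label)
  }
  map <- identity_alignment(out$begin, end)
  list(begin = out$begin, end = end, map = map, truth = out$truth)
}

## idealised C-alpha helix along +z starting at the origin
helix_xyz <- function(n, rise = 1.5, twist = 100 * pi / 180, radius = 2.3) {
  t <- seq_len(n) - 1
  cbind(radius * cos(twist * t), radius * sin(twist * t), rise * t)
}

rot_z <- function(theta)
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)

rot_y <- function(theta)
  matrix(c(cos(theta), 0, -sin(theta), 0, 1, 0, sin(theta), 0, cos(theta)), 3, 3)

fixture_hinge <- function(n_res, hinge_angle) {
  n_arm <- max(6L, n_res %/% 8L)
  stalk <- helix_xyz(n_res)
  hinge <- c(0, 0, max(stalk[, 3]) + 1.5)
  arm <- sweep(helix_xyz(n_arm), 2, hinge + c(3.8, 0, 0), "+")
  chain <- c(rep("A", n_res), rep("B", n_arm))
  resno <- c(seq_len(n_res), seq_len(n_arm))
  begin <- calpha_structure(chain, resno, xyz = rbind(stalk, arm),
                            label = "hinge-dimer begin")
  R <- rot_y(hinge_angle * pi / 180)
  arm2 <- sweep(sweep(arm, 2, hinge) %*% R, 2, hinge, "+")
  end <- calpha_structure(chain, resno, xyz = rbind(stalk, arm2),
                          label = "hinge-dimer end")
  ## a least-squares fit of the end state onto the begin state redistributes
  ## a little of the arm motion into the stalk; truth groups are therefore
  ## derived from the superposed displacement field, not the raw construction
  end <- superpose(end, begin)$structure
  d <- sqrt(rowSums((end$xyz - begin$xyz)^2))
  list(begin = begin, end = end,
       truth = list(stalk = seq_len(n_res),
                    arm = n_res + seq_len(n_arm),
                    static = which(d < 0.4),
                    moving = which(d > 1)))
}

fixture_two_phase <- function(n_res, displacement, phase_split) {
  xyz <- helix_xyz(n_res)
  nA <- round(phase_split * n_res)
  A <- seq_len(nA)
  B <- (nA + 1):n_res
  shift <- matrix(0, n_res, 3)
  shift[A, 1] <- displacement
  shift[B, 1] <- 2 * displacement
  begin <- calpha_structure(rep("A", n_res), seq_len(n_res), xyz = xyz,
                            label = "two-phase begin")
  end <- calpha_structure(rep("A", n_res), seq_len(n_res), xyz = xyz + shift,
                          label = "two-phase end")
  list(begin = begin, end = end,
       truth = list(early = A, late = B,
                    expected_f = c(early = 0.25, late = 0.75)))
}

fixture_barrel <- function(n_res, barrel_radius, expansion) {
  build <- function(radial) {
    xyz <- NULL
    for (k in 0:4) {
      chain_xyz <- sweep(helix_xyz(n_res), 2, c(barrel_radius + radial, 0, 0), "+")
      xyz <- rbind(xyz, chain_xyz %*% t(rot_z(2 * pi * k / 5)))
    }
    xyz
  }
  chain <- rep(LETTERS[1:5], each = n_res)
  resno <- rep(seq_len(n_res), 5)
  begin <- calpha_structure(chain, resno, xyz = build(0), label = "C5 barrel begin")
  end <- calpha_structure(chain, resno, xyz = build(expansion),
                          label = "C5 barrel end")
  list(begin = begin, end = end,
       truth = list(expansion = expansion, n_chains = 5,
                    axis = c(0, 0, 1)))
}

#' Construct the two-phase reference path for the two-phase-chain fixture
#'
#' Moves segment A from its begin to its end position over the first
#' `n_points` conformations while B stays put, then moves B over the second
#' half: a path with a known early/late motional order, used to check
#' crossover recovery (A crosses at 0.25, B at 0.75 when the two phases have
#' equal arc length).
#'
#' @param fixture result of `make_two_state("two-phase-chain", ...)`.
#' @param n_points conformations per phase (default 21).
#' @return an `ienm_pathway`.
#' @export
two_phase_path <- function(fixture, n_points = 21) {
  b <- fixture$begin$xyz
  e <- fixture$end$xyz
  A <- fixture$truth$early
  B <- fixture$truth$late
  confs <- list()
  for (t in seq(0, 1, length.out = n_points)) {
    x <- b
    x[A, ] <- (1 - t) * b[A, , drop = FALSE] + t * e[A, , drop = FALSE]
    confs[[length(confs) + 1]] <- x
  }
  for (t in seq(0, 1, length.out = n_points)[-1]) {
    x <- b
    x[A, ] <- e[A, , drop = FALSE]
    x[B, ] <- (1 - t) * b[B, , drop = FALSE] + t * e[B, , drop = FALSE]
    confs[[length(confs) + 1]] <- x
  }
  as_pathway(confs)
}

#' Apply the C5 rotation to a coordinate set
#'
#' Rotates coordinates by k * 72 degrees about +z and permutes chains
#' cyclically, the symmetry operation of the barrel fixture; used to measure
#' how symmetric a pathway conformation is.
#'
#' @param xyz N x 3 coordinates of a 5-chain barrel (chains contiguous,
#'   equal length).
#' @param k number of 72-degree steps (default 1).
#' @return the rotated-and-permuted N x 3 matrix.
#' @export
c5_apply <- function(xyz, k = 1) {
  n <- nrow(xyz)
  stopifnot(n %% 5 == 0)
  per_chain <- n / 5
  rot <- xyz %*% t(rot_z(2 * pi * k / 5))
  if (k %% 5 == 0) rot else rot[order_c5(n, per_chain, k), , drop = FALSE]
}

## permutation sending chain c to chain c+k (cyclic), preserving residue order
order_c5 <- function(n, per_chain, k) {
  src <- integer(n)
  for (c_ in 0:4) {
    dst <- (c_ + k) %% 5
    src[dst * per_chain + seq_len(per_chain)] <- c_ * per_chain + seq_len(per_chain)
  }
  src
}

#' Maximum C5 symmetry deviation of a conformation
#'
#' Largest atomic distance between a conformation and its image under the
#' five-fold symmetry operation (rotation by 72 degrees with cyclic chain
#' relabelling). Exactly symmetric conformations give 0.
#'
#' @param xyz N x 3 coordinates of a 5-chain barrel.
#' @return maximum deviation in Angstrom.
#' @export
c5_deviation <- function(xyz) {
  img <- c5_apply(xyz, 1)
  max(sqrt(rowSums((xyz - img)^2)))
}
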