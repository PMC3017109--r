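#' Determine the pore axis of a multi-chain assembly
#'
#' Auto mode takes the principal symmetry axis of the assembly: the line
#' through the overall centroid along the direction of smallest variance of
#' the chain centroids (exact for ring-like arrangements, where the chain
#' centroids are equidistant from the true axis). Orientation is fixed by a
#' positive dot product with +z (ties: +y, then +x).
#'
#' @param structure a `calpha` structure with at least 3 chains (auto mode).
#' @param origin,direction explicit axis (3-vectors); when given they pass
#'   through unchanged (direction normalised).
#' @return list with `origin` and unit `direction`.
#' @export
pore_axis <- function(structure, origin = NULL, direction = NULL) {
  if (!is.null(direction)) {
    d <- direction / sqrt(sum(direction^2))
    if (is.null(origin)) origin <- colMeans(structure$xyz)
    return(list(origin = as.numeric(origin), direction = as.numeric(d)))
  }
  chains <- unique(structure$chain)
  if (length(chains) < 3)
    stop("auto pore axis needs >= 3 chains; give an explicit direction")
  cen <- t(vapply(chains, function(ch)
    colMeans(structure$xyz[structure$chain == ch, , drop = FALSE]),
    numeric(3)))
  ev <- eigen(stats::cov(cen), symmetric = TRUE)
  d <- ev$vectors[, 3]   # smallest-variance direction
  ref <- c(0, 0, 1)
  s <- sum(d * ref)
  if (abs(s) < 1e-9) { ref <- c(0, 1, 0); s <- sum(d * ref) }
  if (abs(s) < 1e-9) { ref <- c(1, 0, 0); s <- sum(d * ref) }
  if (s < 0) d <- -d
  list(origin = colMeans(structure$xyz), direction = as.numeric(d))
}

## largest probe radius at one axial station: maximise over in-plane centre c
## of min_i (||c - atom_i|| - atom_radius) by compass pattern search.
pore_radius_at <- function(xyz, atom_radius, origin, direction, u, v,
                           start = c(0, 0), tol = 0.01, max_radius = 50,
                           max_offset = 5) {
  xyz_t <- t(xyz)
  f <- function(p) {
    c3 <- origin + p[1] * u + p[2] * v
    min(sqrt(colSums((xyz_t - c3)^2))) - atom_radius
  }
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
               c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  search <- function(p, step) {
    best <- f(p)
    while (step > tol) {
      moved <- FALSE
      for (d in dirs) {
        cand <- p + step * d
        val <- f(cand)
        if (val > best + 1e-12) {
          p <- cand; best <- val; moved <- TRUE
        }
      }
      ## expand after success, contract after failure (pattern search)
      step <- if (moved) min(2 * step, 1) else step / 2
    }
    list(p = p, best = best)
  }
  ## the clearance landscape is multi-modal with ridge-top optima: scan the
  ## offset domain coarsely, refine from several well-separated top
  ## candidates plus the warm start, and keep the best optimum found
  g <- seq(-max_offset, max_offset, by = 0.5)
  coarse <- as.matrix(expand.grid(x = g, y = g))
  vals <- vapply(seq_len(nrow(coarse)), function(r) f(coarse[r, ]), numeric(1))
  ord <- order(vals, decreasing = TRUE)
  starts <- list(start)
  for (r in ord) {
    if (length(starts) >= 6) break
    p <- coarse[r, ]
    if (all(vapply(starts, function(s) sum((s - p)^2) >= 1, logical(1))))
      starts <- c(starts, list(p))
  }
  best <- NULL
  for (s in starts) {
    cand <- search(s, 1)
    if (is.null(best) || cand$best > best$best) best <- cand
  }
  list(radius = min(best$best, max_radius), center = best$p)
}

#' Pore radius profile along an axis
#'
#' At each axial station the pore radius is the largest probe sphere radius
#' whose centre, optimised within the perpendicular plane, overlaps no
#' C-alpha sphere. Each C-alpha atom carries a fixed atomic radius
#' (default 3 Angstrom). The in-plane optimisation is a deterministic
#' coarse grid scan (0.5 Angstrom spacing, within `max_offset` of the axis)
#' followed by pattern-search refinement, also seeded from the previous
#' station's centre; this replaces the Monte Carlo wobble of HOLE-style
#' tools. Stations where even the optimal probe
#' overlaps (negative clearance) are clamped to radius 0 and flagged
#' occluded; stations with no atom within reach are capped at `max_radius`
#' (open channel mouth).
#'
#' @param structure a `calpha` structure.
#' @param axis from [pore_axis()] (default: auto).
#' @param atom_radius C-alpha sphere radius in Angstrom (default 3).
#' @param step axial sampling step in Angstrom (default 0.5).
#' @param span optional numeric(2) axial window (relative to the axis
#'   origin); default the structure's full projected range.
#' @param max_radius cap for unbounded stations (default 50).
#' @param max_offset half-width in Angstrom of the in-plane centre search
#'   domain around the axis (default 5).
#' @return a `pore_profile` data.frame with columns `z`, `radius`,
#'   `occluded`, `cx`, `cy` (in-plane centre offsets).
#' @export
pore_radius_profile <- function(structure, axis = pore_axis(structure),
                                atom_radius = 3, step = 0.5, span = NULL,
                                max_radius = 50, max_offset = 5) {
  stopifnot(step > 0)
  d <- axis$direction
  ## orthonormal in-plane basis
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  proj <- as.vector(sweep(structure$xyz, 2, axis$origin) %*% d)
  if (is.null(span)) span <- range(proj)
  zs <- seq(span[1], span[2], by = step)
  radius <- numeric(length(zs))
  occluded <- logical(length(zs))
  cx <- cy <- numeric(length(zs))
  center <- c(0, 0)
  for (k in seq_along(zs)) {
    o <- axis$origin + zs[k] * d
    res <- pore_radius_at(structure$xyz, atom_radius, o, d, u, v,
                          start = center, max_radius = max_radius,
                          max_offset = max_offset)
    center <- res$center
    r <- res$radius
    occluded[k] <- r < 0
    radius[k] <- max(r, 0)
    cx[k] <- center[1]; cy[k] <- center[2]
  }
  structure(data.frame(z = zs, radius = radius, occluded = occluded,
                       cx = cx, cy = cy),
            class = c("pore_profile", "data.frame"))
}

#' Minimal pore radius over an axial window
#'
#' @param profile a `pore_profile`.
#' @param window numeric(2) axial interval; default the full profile.
#' @return minimum radius (Angstrom) over the stations inside the window.
#' @export
min_pore_radius <- function(profile, window = NULL) {
  sel <- if (is.null(window)) rep(TRUE, nrow(profile))
         else profile$z >= window[1] & profile$z <= window[2]
  if (!any(sel)) stop("axial window contains no profile samples")
  min(profile$radius[sel])
}
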