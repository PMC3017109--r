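#' C-alpha structure objects
#'
#' A `calpha` object is the universal currency of the package: an ordered set
#' of C-alpha coordinates with chain and residue identity. The row order of
#' the coordinate matrix defines the global 1-based atom index used by every
#' downstream module (springs, modes, pathways, progress tables).
#'
#' @param chain character vector of chain identifiers.
#' @param resno integer vector of residue numbers.
#' @param resid character vector of 3-letter residue names.
#' @param xyz numeric N x 3 matrix of coordinates in Angstrom.
#' @param label free-text label for the structure.
#'
#' @return An object of class `calpha` with elements `chain`, `resno`,
#'   `resid`, `xyz` (N x 3 matrix) and `label`.
#' @export
calpha_structure <- function(chain, resno, resid = NULL, xyz, label = "") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- length(chain)
  if (is.null(resid)) resid <- rep("ALA", n)
  stopifnot(length(resno) == n, length(resid) == n,
            is.matrix(xyz), nrow(xyz) == n, ncol(xyz) == 3)
  if (!all(is.finite(xyz)))
    stop("all coordinates must be finite")
  key <- paste(chain, resno)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue number) after resolution: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(list(chain = as.character(chain),
                 resno = as.integer(resno),
                 resid = as.character(resid),
                 xyz = xyz,
                 label = as.character(label)),
            class = "calpha")
}

#' @export
print.calpha <- function(x, ...) {
  cat(sprintf("C-alpha structure '%s': %d residues, %d chain(s) [%s]\n",
              x$label, n_atoms(x), length(unique(x$chain)),
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

#' Number of C-alpha atoms in a structure
#' @param x a `calpha` structure.
#' @return integer atom (= residue) count.
#' @export
n_atoms <- function(x) nrow(x$xyz)

#' Read the C-alpha trace of a PDB file
#'
#' Extracts one C-alpha atom per residue from a PDB file. Alternate locations
#' are resolved to the highest-occupancy record (ties broken by altloc
#' letter); when a residue number carries several insertion codes the first
#' C-alpha record in file order wins and a warning is issued. The resulting
#' atom order (file order) defines the global atom index.
#'
#' @param path path to a PDB file.
#' @param chain_filter optional character vector of chain ids to keep.
#' @param multi logical; read all MODEL records (used by pathway round-trip).
#' @return a `calpha` structure (or, if `multi = TRUE` and the file has
#'   several models, a list with the structure and a list of coordinate
#'   matrices `models`).
#' @export
read_calpha_pdb <- function(path, chain_filter = NULL, multi = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  at <- pdb$atom
  sel <- at$elety == "CA" & at$type == "ATOM"
  if (!is.null(chain_filter)) sel <- sel & at$chain %in% chain_filter
  at <- at[sel, , drop = FALSE]
  if (nrow(at) == 0) stop("no C-alpha atoms found in ", path)
  xyz_idx <- which(sel)

  ## altloc: highest occupancy, ties by altloc letter
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  grp <- paste(at$chain, at$resno, at$insert)
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(grp, levels = unique(grp))),
                        function(ii) {
                          if (length(ii) == 1) return(ii)
                          occ <- at$o[ii]
                          cand <- ii[occ == max(occ)]
                          cand[order(at$alt[cand])][1]
                        }), use.names = FALSE)
  keep <- sort(keep)
  at <- at[keep, , drop = FALSE]
  xyz_idx <- xyz_idx[keep]

  ## insertion codes: first C-alpha record per (chain, resno) wins
  key <- paste(at$chain, at$resno)
  if (anyDuplicated(key)) {
    warning("insertion codes at ",
            paste(unique(key[duplicated(key)]), collapse = ", "),
            ": keeping the first C-alpha record of each residue")
    first <- !duplicated(key)
    at <- at[first, , drop = FALSE]
    xyz_idx <- xyz_idx[first]
  }

  s <- calpha_structure(chain = at$chain, resno = at$resno, resid = at$resid,
                        xyz = cbind(at$x, at$y, at$z),
                        label = basename(path))
  if (multi && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1) {
    cols <- as.vector(rbind(3 * (xyz_idx - 1) + 1,
                            3 * (xyz_idx - 1) + 2,
                            3 * (xyz_idx - 1) + 3))
    models <- lapply(seq_len(nrow(pdb$xyz)), function(m)
      matrix(pdb$xyz[m, cols], ncol = 3, byrow = TRUE))
    return(list(structure = s, models = models))
  }
  s
}

## Kabsch least-squares rotation of `mobile` rows onto `target` rows.
## Returns list(R, t) such that mobile %*% R + t approximates target.
kabsch <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  A <- sweep(mobile, 2, cm)
  B <- sweep(target, 2, ct)
  sv <- svd(crossprod(A, B))
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  list(R = R, t = ct - drop(cm %*% R))
}

apply_rigid <- function(xyz, tr) sweep(xyz %*% tr$R, 2, tr$t, "+")

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Superpose one structure onto another over aligned residues
#'
#' Least-squares rigid-body superposition (Kabsch) of `mobile` onto `target`
#' using only the residue pairs of an alignment map, with uniform weights, so
#' that all aligned parts of the assembly contribute equally. The whole
#' mobile structure (aligned and unaligned residues alike) is transformed.
#'
#' @param mobile,target `calpha` structures.
#' @param map an `alignment_map` between `mobile` (begin side) and `target`
#'   (end side); defaults to the identity map when both structures have the
#'   same residues.
#' @return list with `structure` (transformed mobile), `rmsd` (Angstrom, over
#'   aligned pairs), `rotation`, `translation`.
#' @export
superpose <- function(mobile, target, map = NULL) {
  if (is.null(map)) map <- identity_alignment(mobile, target)
  pi <- map$pairs$i
  pj <- map$pairs$j
  if (length(pi) < 3) stop("need at least 3 aligned pairs to superpose")
  A <- mobile$xyz[pi, , drop = FALSE]
  B <- target$xyz[pj, , drop = FALSE]
  if (qr(sweep(A, 2, colMeans(A)))$rank < 2)
    stop("aligned atoms are collinear; superposition is degenerate")
  tr <- kabsch(A, B)
  out <- mobile
  out$xyz <- apply_rigid(mobile$xyz, tr)
  list(structure = out,
       rmsd = rmsd_xyz(out$xyz[pi, , drop = FALSE], B),
       rotation = tr$R, translation = tr$t)
}

#' Write a pathway (or any set of conformations) as a multi-model PDB
#'
#' Each conformation becomes one MODEL/ENDMDL block with fixed-width ATOM
#' records carrying the template's chain/residue identity, suitable for
#' trajectory viewers.
#'
#' @param pathway an `ienm_pathway`, or a list of N x 3 coordinate matrices.
#' @param template a `calpha` structure providing atom identities.
#' @param path output file path.
#' @export
write_pathway_pdb <- function(pathway, template, path) {
  confs <- if (inherits(pathway, "ienm_pathway")) pathway$conformations
           else pathway
  if (length(confs) == 0) stop("empty pathway")
  n <- n_atoms(template)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(confs)) {
    xyz <- confs[[m]]
    if (!is.matrix(xyz) || nrow(xyz) != n)
      stop("conformation ", m, " does not match the template atom count")
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                     seq_len(n), substr(template$resid, 1, 3),
                     substr(template$chain, 1, 1), template$resno,
                     xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write per-residue values into the B-factor column of a PDB file
#'
#' Convenience for colouring residues by crossover progress in a molecular
#' viewer; `NA` values are written as 0.
#'
#' @param structure a `calpha` structure.
#' @param values numeric vector, one per residue.
#' @param path output file path.
#' @export
write_bfactor_pdb <- function(structure, values, path) {
  stopifnot(length(values) == n_atoms(structure))
  v <- ifelse(is.finite(values), values, 0)
  con <- file(path, "w")
  on.exit(close(con))
  lines <- sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
                   seq_len(n_atoms(structure)), substr(structure$resid, 1, 3),
                   substr(structure$chain, 1, 1), structure$resno,
                   structure$xyz[, 1], structure$xyz[, 2], structure$xyz[, 3], v)
  writeLines(c(lines, "END"), con)
  invisible(path)
}
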