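#' Residue-level alignment maps
#'
#' An `alignment_map` records which residues of a begin structure correspond
#' to which residues of an end structure, by global atom index. The map is
#' one-to-one; residues without a partner are listed in the unaligned sets.
#' Alignments come from external structural-alignment programs (DALI, SSAP,
#' CE, ...) — this package ingests them, it does not compute them.
#'
#' @param i,j integer vectors of equal length: begin-side and end-side global
#'   atom indices of the aligned pairs.
#' @param begin,end the `calpha` structures the indices refer to.
#' @return an `alignment_map` with elements `pairs` (data.frame with columns
#'   `i`, `j`), `unaligned_begin`, `unaligned_end` (integer index vectors).
#' @export
alignment_map <- function(i, j, begin, end) {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(length(i) == length(j))
  if (anyDuplicated(i) || anyDuplicated(j))
    stop("alignment is not one-to-one")
  if (length(i) && (min(i) < 1 || max(i) > n_atoms(begin) ||
                    min(j) < 1 || max(j) > n_atoms(end)))
    stop("alignment refers to residues outside the structures")
  cc <- unique(data.frame(b = begin$chain[i], e = end$chain[j]))
  if (anyDuplicated(cc$b))
    stop("a begin chain maps to more than one end chain: ",
         paste(cc$b[duplicated(cc$b)], collapse = ", "))
  structure(list(pairs = data.frame(i = i, j = j),
                 unaligned_begin = setdiff(seq_len(n_atoms(begin)), i),
                 unaligned_end = setdiff(seq_len(n_atoms(end)), j)),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("alignment map: %d pairs, %d/%d unaligned (begin/end)\n",
              nrow(x$pairs), length(x$unaligned_begin), length(x$unaligned_end)))
  invisible(x)
}

#' Identity alignment between two structures with matching residues
#'
#' Pairs residues with equal (chain, residue number); both structures must
#' cover the same residue set for a full identity map, otherwise the
#' complement goes to the unaligned sets.
#' @param begin,end `calpha` structures.
#' @return an `alignment_map`.
#' @export
identity_alignment <- function(begin, end) {
  kb <- paste(begin$chain, begin$resno)
  ke <- paste(end$chain, end$resno)
  m <- match(kb, ke)
  i <- which(!is.na(m))
  alignment_map(i, m[i], begin, end)
}

#' Parse an alignment map from a four-column TSV
#'
#' The dialect is a header-bearing TSV with columns `begin_chain`,
#' `begin_resnum`, `end_chain`, `end_resnum`, one aligned residue pair per
#' row. Rows referring to residues absent from either structure, or mapping
#' a residue twice, are hard errors.
#'
#' @param path TSV file path.
#' @param begin,end `calpha` structures.
#' @return an `alignment_map`.
#' @export
parse_alignment <- function(path, begin, end) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer",
                                          "character", "integer"))
  need <- c("begin_chain", "begin_resnum", "end_chain", "end_resnum")
  if (!all(need %in% names(tab)))
    stop("alignment TSV must have columns ", paste(need, collapse = ", "))
  i <- match(paste(tab$begin_chain, tab$begin_resnum),
             paste(begin$chain, begin$resno))
  j <- match(paste(tab$end_chain, tab$end_resnum),
             paste(end$chain, end$resno))
  if (anyNA(i))
    stop("alignment refers to begin residues absent from the structure: ",
         paste(head(paste(tab$begin_chain, tab$begin_resnum)[is.na(i)], 5),
               collapse = ", "))
  if (anyNA(j))
    stop("alignment refers to end residues absent from the structure: ",
         paste(head(paste(tab$end_chain, tab$end_resnum)[is.na(j)], 5),
               collapse = ", "))
  alignment_map(i, j, begin, end)
}

#' Write an alignment map to the package's TSV dialect
#' @param map an `alignment_map`.
#' @param begin,end the structures it refers to.
#' @param path output path.
#' @export
write_alignment <- function(map, begin, end, path) {
  tab <- data.frame(begin_chain = begin$chain[map$pairs$i],
                    begin_resnum = begin$resno[map$pairs$i],
                    end_chain = end$chain[map$pairs$j],
                    end_resnum = end$resno[map$pairs$j])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a gapped pairwise FASTA alignment to an alignment map
#'
#' Reads a two-sequence FASTA (gaps as `-`) in which the first sequence runs
#' over the residues of `begin_chain` in `begin` (in structure order) and the
#' second over `end_chain` in `end`. Columns where both sequences have a
#' residue become aligned pairs. Call once per chain pair and concatenate.
#'
#' @param path FASTA file with exactly two gapped sequences.
#' @param begin,end `calpha` structures.
#' @param begin_chain,end_chain the chains the two sequences describe.
#' @return data.frame with columns `i`, `j` (global indices) to feed
#'   [alignment_map()].
#' @export
alignment_pairs_from_fasta <- function(path, begin, end, begin_chain, end_chain) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) != 2) stop("expected exactly two sequences in ", path)
  seqs <- vapply(seq_along(hdr), function(k) {
    from <- hdr[k] + 1
    to <- if (k < length(hdr)) hdr[k + 1] - 1 else length(lines)
    paste(gsub("\\s", "", lines[from:to]), collapse = "")
  }, character(1))
  a <- strsplit(toupper(seqs[1]), "")[[1]]
  b <- strsplit(toupper(seqs[2]), "")[[1]]
  if (length(a) != length(b)) stop("gapped sequences differ in length")
  ia <- which(begin$chain == begin_chain)
  ib <- which(end$chain == end_chain)
  if (sum(a != "-") != length(ia))
    stop("sequence 1 has ", sum(a != "-"), " residues but chain ",
         begin_chain, " has ", length(ia))
  if (sum(b != "-") != length(ib))
    stop("sequence 2 has ", sum(b != "-"), " residues but chain ",
         end_chain, " has ", length(ib))
  pa <- cumsum(a != "-")
  pb <- cumsum(b != "-")
  both <- a != "-" & b != "-"
  data.frame(i = ia[pa[both]], j = ib[pb[both]])
}

#' Motif definitions
#'
#' A motif is a named inclusive residue-number range, scoped to all chains
#' (`chain = "*"`) or to one chain. Motifs are how per-residue crossover
#' values are aggregated into the per-element averages of the transition
#' analysis.
#'
#' @param name motif name.
#' @param start,end inclusive residue-number interval.
#' @param chain chain id or `"*"` for all chains.
#' @return a one-row data.frame of class `motif_table`.
#' @export
motif <- function(name, start, end, chain = "*") {
  if (end < start) stop("empty motif range for ", name)
  structure(data.frame(name = name, chain = chain,
                       start = as.integer(start), end = as.integer(end),
                       stringsAsFactors = FALSE),
            class = c("motif_table", "data.frame"))
}

#' Read motif definitions from TSV (columns name, chain_scope, start, end)
#' @param path TSV path.
#' @return a `motif_table` data.frame.
#' @export
read_motifs <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "chain_scope", "start", "end")
  if (!all(need %in% names(tab)))
    stop("motif TSV must have columns ", paste(need, collapse = ", "))
  out <- do.call(rbind, Map(motif, tab$name, tab$start, tab$end, tab$chain_scope))
  rownames(out) <- NULL
  structure(out, class = c("motif_table", "data.frame"))
}

#' Residue indices of a motif in a structure
#' @param m one row of a `motif_table`.
#' @param structure a `calpha` structure.
#' @return integer vector of global indices.
#' @export
motif_indices <- function(m, structure) {
  sel <- structure$resno >= m$start & structure$resno <= m$end
  if (m$chain != "*") sel <- sel & structure$chain == m$chain
  which(sel)
}

#' Key structural elements of the ELIC pentamer
#'
#' Residue ranges (ELIC numbering, applied to all five chains) of the binding
#' loops, interface loops and transmembrane helices used to summarise the
#' gating transition: loops A, B, C in the extracellular domain, interface
#' loops 2, 7, 9, helices M1-M4 and the M2-M3 linker.
#'
#' @return a `motif_table` data.frame.
#' @export
elic_motifs <- function() {
  tab <- rbind(
    motif("loop A", 79, 82),
    motif("loop B", 132, 137),
    motif("loop C", 174, 185),
    motif("loop 2", 28, 31),
    motif("loop 7", 112, 122),
    motif("loop 9", 147, 159),
    motif("M1", 201, 219),
    motif("M2", 227, 251),
    motif("M3", 260, 282),
    motif("M4", 296, 316),
    motif("M2-M3 linker", 252, 259))
  rownames(tab) <- NULL
  structure(tab, class = c("motif_table", "data.frame"))
}

#' Motif-level experimental Phi values for the nicotinic AChR alpha subunit
#'
#' Rate-equilibrium free-energy-relationship (Phi) values from single-channel
#' kinetics of receptor mutants, summarised at the motif level. High Phi
#' means the element moves early during channel opening, so motif-average
#' crossover progress is compared against 1 - Phi.
#'
#' @return a `phi_table` data.frame with columns `name` and `phi`.
#' @export
achr_phi_motifs <- function() {
  structure(data.frame(
    name = c("loop A", "loop B", "loop C", "loop 2", "loop 7",
             "M2", "M4", "M3"),
    phi = c(0.93, 0.93, 0.93, 0.75, 0.75, 0.65, 0.54, 0.32),
    stringsAsFactors = FALSE),
    class = c("phi_table", "data.frame"))
}

#' Read a Phi-value table from TSV (columns name, phi)
#' @param path TSV path.
#' @return a `phi_table` data.frame.
#' @export
read_phi_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("name", "phi") %in% names(tab)))
    stop("phi TSV must have columns name, phi")
  if (any(tab$phi < 0 | tab$phi > 1)) stop("phi values must lie in [0, 1]")
  structure(tab[, c("name", "phi")], class = c("phi_table", "data.frame"))
}
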