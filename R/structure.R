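#' Parse a PDB structure into a residue/atom table
#'
#' Reads `ATOM` records of one chain (first model of multi-model files) into
#' an ordered residue list.  Waters, `HETATM` records and hydrogens are
#' skipped; alternate locations are resolved to the highest-occupancy copy
#' (ties: first encountered); insertion codes are flattened so residue
#' indices are sequential 1-based positions along the chain.
#'
#' @param pdb_text Character scalar (or vector of lines) of PDB-format text.
#' @param chain Chain identifier.  `NULL` selects the first chain found.
#' @param source_id Free-text identifier stored on the result (e.g. a PDB or
#'   SCOP code).
#' @return An object of class `cg_structure`: a list with `atoms` (tibble
#'   with `res_index`, `resno`, `resname`, `elety`, `x`, `y`, `z`), `chain`
#'   and `source_id`.
#' @export
parse_structure <- function(pdb_text, chain = NULL, source_id = "unknown") {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("not parseable as PDB: ", conditionMessage(e),
                             call. = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("input error: no ATOM records", call. = FALSE)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("input error: chain '", chain, "' is empty", call. = FALSE)
  ## drop hydrogens/deuteriums (heavy atoms only)
  ele <- toupper(trimws(at$elesy))
  guess_h <- grepl("^[0-9]*[HD]", trimws(at$elety))
  at <- at[!(ele %in% c("H", "D") | (ele == "" & guess_h)), , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  ## residue key in file order; flatten insertion codes
  key <- paste(at$resno, at$insert, sep = "_")
  res_index <- match(key, unique(key))
  at$res_index <- res_index
  ## alternate locations: highest occupancy wins, then first encountered
  ord <- order(at$res_index, at$elety, -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(at[c("res_index", "elety")]), , drop = FALSE]
  at <- at[order(at$res_index, as.integer(rownames(at))), , drop = FALSE]
  atoms <- tibble::tibble(res_index = at$res_index, resno = at$resno,
                          resname = at$resid, elety = at$elety,
                          x = at$x, y = at$y, z = at$z)
  atoms <- atoms[order(atoms$res_index), , drop = FALSE]
  s <- structure(list(atoms = atoms, chain = chain, source_id = source_id),
                 class = "cg_structure")
  validate_structure(s)
  s
}

#' Read a structure from a PDB file
#' @param path Path to a PDB file.
#' @inheritParams parse_structure
#' @return A `cg_structure`.
#' @export
read_structure <- function(path, chain = NULL,
                           source_id = basename(path)) {
  parse_structure(readLines(path, warn = FALSE), chain = chain,
                  source_id = source_id)
}

validate_structure <- function(s) {
  a <- s$atoms
  if (!all(is.finite(c(a$x, a$y, a$z))))
    stop("structural error: non-finite coordinates", call. = FALSE)
  for (ri in unique(a$res_index)) {
    sub <- a[a$res_index == ri, ]
    if (!"CA" %in% sub$elety)
      stop(sprintf("structural error: residue %d (%s %s) has no CA atom",
                   ri, sub$resname[1], sub$resno[1]), call. = FALSE)
  }
  if (is.unsorted(unique(a$res_index), strictly = TRUE))
    stop("structural error: residue indices not strictly increasing",
         call. = FALSE)
  invisible(s)
}

#' @export
print.cg_structure <- function(x, ...) {
  cat(sprintf("<cg_structure> %s chain %s: %d residues, %d heavy atoms\n",
              x$source_id, x$chain, n_residues(x), nrow(x$atoms)))
  invisible(x)
}

#' Number of residues in a structure
#' @param s A `cg_structure`.
#' @return Integer count.
#' @export
n_residues <- function(s) length(unique(s$atoms$res_index))

#' Extract the C-alpha trace
#' @param s A `cg_structure`.
#' @return `n x 3` numeric matrix of C-alpha coordinates (Angstrom).
#' @export
ca_coords <- function(s) {
  ca <- s$atoms[s$atoms$elety == "CA", ]
  ca <- ca[order(ca$res_index), ]
  m <- as.matrix(ca[c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Residue names (3-letter codes) in chain order
#' @param s A `cg_structure`.
#' @return Character vector, one 3-letter code per residue.
#' @export
residue_names <- function(s) {
  a <- s$atoms[!duplicated(s$atoms$res_index), ]
  a$resname[order(a$res_index)]
}

#' In-silico truncation of a side chain to alanine
#'
#' Reproduces the manual construction of hydrophobic point mutants used for
#' homologue comparison: all side-chain atoms beyond C-beta are removed and
#' the residue is renamed `ALA`.  The backbone (N, CA, C, O) and CB are kept
#' untouched, so the C-alpha trace -- and hence any backbone/CA RMSD to the
#' parent structure -- is exactly preserved.
#'
#' @param s A `cg_structure`.
#' @param residue_index 1-based sequential residue index to mutate.
#' @return A new `cg_structure`; the input is not modified.
#' @export
mutate_side_chain_to_ala <- function(s, residue_index) {
  a <- s$atoms
  sel <- a$res_index == residue_index
  if (!any(sel))
    stop("input error: no residue with index ", residue_index, call. = FALSE)
  if (!"CB" %in% a$elety[sel])
    stop(sprintf(
      "input error: residue %d (%s) has no CB atom (glycine cannot be truncated to alanine)",
      residue_index, a$resname[sel][1]), call. = FALSE)
  keep <- !sel | a$elety %in% c("N", "CA", "C", "O", "CB")
  a <- a[keep, , drop = FALSE]
  a$resname[a$res_index == residue_index] <- "ALA"
  out <- s
  out$atoms <- a
  out$source_id <- paste0(s$source_id, "_",
                          sprintf("x%dA", residue_index))
  validate_structure(out)
  out
}

#' Optimal-superposition RMSD between two structures
#'
#' Least-squares rigid superposition (rotation + translation, reflections
#' excluded) of the selected atoms, then root-mean-square distance.
#'
#' @param a,b `cg_structure` objects with equal residue counts.
#' @param atom_selection `"CA"` (default) or `"backbone"` (N, CA, C, O).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b, atom_selection = c("CA", "backbone")) {
  atom_selection <- match.arg(atom_selection)
  xa <- selection_coords(a, atom_selection)
  xb <- selection_coords(b, atom_selection)
  if (nrow(xa) != nrow(xb))
    stop("input error: structures have different atom counts for selection '",
         atom_selection, "' (", nrow(xa), " vs ", nrow(xb), ")",
         call. = FALSE)
  kabsch_rmsd_xyz(xa, xb)
}

selection_coords <- function(s, atom_selection) {
  want <- if (atom_selection == "CA") "CA" else c("N", "CA", "C", "O")
  a <- s$atoms[s$atoms$elety %in% want, ]
  miss <- setdiff(want, unique(a$elety))
  a <- a[order(a$res_index, match(a$elety, want)), ]
  as.matrix(a[c("x", "y", "z")])
}

## Kabsch superposition of two point sets (rows = points)
kabsch_rmsd_xyz <- function(xa, xb) {
  stopifnot(nrow(xa) == nrow(xb), ncol(xa) == 3, ncol(xb) == 3)
  ca <- colMeans(xa); cb <- colMeans(xb)
  pa <- sweep(xa, 2, ca); pb <- sweep(xb, 2, cb)
  h <- crossprod(pa, pb)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diff <- pb - pa %*% t(rot)
  sqrt(sum(diff^2) / nrow(xa))
}

#' Pairwise RMSD table for a set of structures
#'
#' Computes the mutual backbone and C-alpha RMSD for every unordered pair of
#' the supplied structures, after optimal superposition.
#'
#' @param structures Named list of `cg_structure` objects.
#' @return Tibble with columns `a`, `b`, `backbone`, `ca` (Angstrom).
#' @export
rmsd_matrix <- function(structures) {
  stopifnot(is.list(structures), length(structures) >= 2)
  nm <- names(structures)
  if (is.null(nm)) nm <- paste0("s", seq_along(structures))
  pairs <- utils::combn(seq_along(structures), 2)
  tibble::tibble(
    a = nm[pairs[1, ]],
    b = nm[pairs[2, ]],
    backbone = apply(pairs, 2, function(ij)
      kabsch_rmsd(structures[[ij[1]]], structures[[ij[2]]], "backbone")),
    ca = apply(pairs, 2, function(ij)
      kabsch_rmsd(structures[[ij[1]]], structures[[ij[2]]], "CA")))
}

#' Write a structure as PDB-format text
#'
#' Minimal single-chain `ATOM`-record writer, sufficient to round-trip the
#' package's own structures and export fixtures.
#'
#' @param s A `cg_structure`.
#' @param file Optional path; when `NULL` the text is returned invisibly.
#' @return Character vector of PDB lines (invisibly when written to file).
#' @export
write_pdb <- function(s, file = NULL) {
  a <- s$atoms
  ele <- substr(trimws(a$elety), 1, 1)
  name4 <- ifelse(nchar(a$elety) >= 4, sprintf("%-4s", a$elety),
                  sprintf(" %-3s", a$elety))
  lines <- sprintf(
    "ATOM  %5d %s%s%3s %1s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name4, " ", a$resname, substr(s$chain, 1, 1),
    a$res_index, " ", a$x, a$y, a$z, 1, 0, ele)
  lines <- c(lines, "TER", "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
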