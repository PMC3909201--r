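#' Detect native contacts in a structure
#'
#' A residue pair (i, j) forms a native contact when the minimum distance
#' over all heavy-atom pairs of the two residues is below `cutoff` and the
#' sequence separation satisfies `j - i >= min_separation`.  The contact
#' distance `r0` stored for the pair is the native C-alpha--C-alpha
#' distance (the coarse-grained interaction acts on C-alpha beads; the
#' all-atom minimum distance is only the detection criterion).
#'
#' @param s A `cg_structure`.
#' @param cutoff Detection cutoff in Angstrom (default 5.5).
#' @param min_separation Minimum sequence separation `j - i` (default 4;
#'   closer pairs are governed by the bonded terms).
#' @return Tibble with columns `i`, `j`, `r0` (weights unset).
#' @export
compute_native_contacts <- function(s, cutoff = 5.5, min_separation = 4L) {
  stopifnot(cutoff > 0, min_separation >= 1)
  n <- n_residues(s)
  if (n < 2) stop("input error: structure has fewer than 2 residues",
                  call. = FALSE)
  a <- s$atoms
  xyz <- as.matrix(a[c("x", "y", "z")])
  res <- a$res_index
  ca <- ca_coords(s)
  ## distance between every atom pair once; min-reduce per residue pair
  d <- as.matrix(stats::dist(xyz))
  out_i <- integer(0); out_j <- integer(0); out_r0 <- numeric(0)
  for (i in seq_len(n - min_separation)) {
    ai <- which(res == i)
    for (j in seq.int(i + min_separation, n)) {
      aj <- which(res == j)
      if (min(d[ai, aj]) < cutoff) {
        out_i <- c(out_i, i); out_j <- c(out_j, j)
        out_r0 <- c(out_r0, sqrt(sum((ca[i, ] - ca[j, ])^2)))
      }
    }
  }
  tibble::tibble(i = out_i, j = out_j, r0 = out_r0)
}

#' Load the bundled Miyazawa--Jernigan contact-energy table
#'
#' @return Symmetric 20x20 matrix of contact energies (RT units), dimnames
#'   are 1-letter amino-acid codes.
#' @export
mj_energy_table <- function() {
  path <- system.file("extdata", "miyazawa_jernigan_1996.tsv",
                      package = "frustfold", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  aa <- unique(c(tab$res_i, tab$res_j))
  m <- matrix(NA_real_, 20, 20, dimnames = list(aa, aa))
  m[cbind(tab$res_i, tab$res_j)] <- tab$e_ij
  m[cbind(tab$res_j, tab$res_i)] <- tab$e_ij
  stopifnot(!anyNA(m), isSymmetric(m))
  m
}

aa_3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Assign MJ-flavoured contact weights
#'
#' Each native contact gets a dimensionless depth coefficient proportional
#' to the magnitude of the Miyazawa--Jernigan contact energy of its residue
#' pair, rescaled so the mean weight over the contact list is exactly 1
#' (so the total native-contact energy at the native state is `-NC * eps`).
#' Unknown residue types fall back to raw magnitude equal to the table mean
#' before normalisation, with a warning.
#'
#' @param contacts Tibble from [compute_native_contacts()].
#' @param sequence Character vector of residue codes (1- or 3-letter),
#'   one per residue.
#' @return The contacts tibble with a `weight` column added; mean(weight)
#'   is 1 to machine precision.
#' @export
assign_mj_weights <- function(contacts, sequence) {
  if (nrow(contacts) == 0L) return(tibble::tibble(contacts, weight = numeric(0)))
  one <- if (all(nchar(sequence) == 1L)) toupper(sequence)
         else unname(aa_3to1[toupper(sequence)])
  mj <- mj_energy_table()
  raw <- numeric(nrow(contacts))
  for (k in seq_len(nrow(contacts))) {
    a <- one[contacts$i[k]]; b <- one[contacts$j[k]]
    if (is.na(a) || is.na(b) || !a %in% rownames(mj) || !b %in% rownames(mj)) {
      warning("unknown residue type in contact (", contacts$i[k], ",",
              contacts$j[k], "); using unit raw weight", call. = FALSE)
      raw[k] <- mean(abs(mj))
    } else raw[k] <- abs(mj[a, b])
  }
  out <- contacts
  out$weight <- raw * (length(raw) / sum(raw))
  out
}

angle_3pt <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

dihedral_4pt <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Build the native topology of a structure
#'
#' Measures the native C-alpha geometry (bond lengths, bond angles,
#' dihedrals) and attaches the MJ-weighted native-contact list; this is the
#' complete ground truth the Go-like potential is built from.
#'
#' @param s A `cg_structure`.
#' @inheritParams compute_native_contacts
#' @return An object of class `cg_topology`: list with `n`, `ca0` (n x 3),
#'   `r0` (n-1), `theta0` (n-2), `phi0` (n-3, in (-pi, pi]), `contacts`
#'   (tibble `i`, `j`, `r0`, `weight`), `sequence` (3-letter codes),
#'   `min_separation`, `cutoff`.
#' @export
build_topology <- function(s, cutoff = 5.5, min_separation = 4L) {
  ca <- ca_coords(s)
  n <- nrow(ca)
  if (n < 4) stop("input error: need at least 4 residues", call. = FALSE)
  r0 <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  if (any(r0 < 2.5 | r0 > 4.5))
    stop("structural error: C-alpha virtual bond length outside 2.5-4.5 A ",
         "(broken chain or non-trans peptide?)", call. = FALSE)
  theta0 <- vapply(seq_len(n - 2),
                   function(i) angle_3pt(ca[i, ], ca[i + 1, ], ca[i + 2, ]),
                   0)
  phi0 <- vapply(seq_len(n - 3),
                 function(i) dihedral_4pt(ca[i, ], ca[i + 1, ],
                                          ca[i + 2, ], ca[i + 3, ]), 0)
  contacts <- assign_mj_weights(
    compute_native_contacts(s, cutoff = cutoff,
                            min_separation = min_separation),
    residue_names(s))
  structure(list(n = n, ca0 = ca, r0 = r0, theta0 = theta0, phi0 = phi0,
                 contacts = contacts, sequence = residue_names(s),
                 min_separation = as.integer(min_separation),
                 cutoff = cutoff),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf(
    "<cg_topology> %d beads, %d bonds, %d angles, %d dihedrals, %d native contacts\n",
    x$n, length(x$r0), length(x$theta0), length(x$phi0), nrow(x$contacts)))
  invisible(x)
}

#' Build the non-native hydrophobic (frustration) pair set
#'
#' All residue pairs in which both members are hydrophobic, that respect the
#' same sequence-separation exclusion as native contacts, and that are *not*
#' native contacts.  These are the pairs eligible for the energetic
#' frustration attraction.
#'
#' @param s A `cg_structure`.
#' @param topo The `cg_topology` built from `s`.
#' @param hydrophobic Character vector of 3-letter codes treated as
#'   hydrophobic; defaults to [hydrophobic_residues()].
#' @return Object of class `cg_frustration`: list with `pairs` (tibble
#'   `i`, `j`) and `hydrophobic_index` (integer vector).
#' @export
build_frustration_set <- function(s, topo,
                                  hydrophobic = hydrophobic_residues()) {
  res <- residue_names(s)
  hyd <- which(toupper(res) %in% toupper(hydrophobic))
  n <- topo$n
  pairs_i <- integer(0); pairs_j <- integer(0)
  if (length(hyd) >= 2) {
    cmb <- utils::combn(sort(hyd), 2)
    sep_ok <- (cmb[2, ] - cmb[1, ]) >= topo$min_separation
    cmb <- cmb[, sep_ok, drop = FALSE]
    if (ncol(cmb)) {
      key <- paste(cmb[1, ], cmb[2, ])
      in_native <- key %in% paste(topo$contacts$i, topo$contacts$j)
      pairs_i <- cmb[1, !in_native]; pairs_j <- cmb[2, !in_native]
    }
  }
  structure(list(pairs = tibble::tibble(i = pairs_i, j = pairs_j),
                 hydrophobic_index = hyd),
            class = "cg_frustration")
}

#' @export
print.cg_frustration <- function(x, ...) {
  cat(sprintf("<cg_frustration> %d non-native hydrophobic pairs over %d hydrophobic residues\n",
              nrow(x$pairs), length(x$hydrophobic_index)))
  invisible(x)
}

#' Declare a secondary-structure segment map
#'
#' Segments are user-declared labelled residue ranges (e.g. Coil I, Helix I,
#' ...) that must tile the chain: non-overlapping, increasing, jointly
#' covering residues 1..n.
#'
#' @param elements Data frame / tibble with columns `label`, `first`, `last`.
#' @param n_residues Chain length the map must cover.
#' @return Object of class `cg_ss_map` (the validated tibble).
#' @export
ss_map <- function(elements, n_residues) {
  el <- tibble::as_tibble(elements)
  stopifnot(all(c("label", "first", "last") %in% names(el)))
  el <- el[order(el$first), ]
  if (el$first[1] != 1L || el$last[nrow(el)] != n_residues ||
      any(el$first > el$last) ||
      (nrow(el) > 1 && any(el$first[-1] != el$last[-nrow(el)] + 1L)))
    stop("input error: segments must tile residues 1..", n_residues,
         " without gaps or overlaps", call. = FALSE)
  structure(el, class = c("cg_ss_map", class(el)))
}

## residue index -> element label lookup
ss_element_of <- function(ss, residues) {
  lab <- rep(NA_character_, max(ss$last))
  for (k in seq_len(nrow(ss))) lab[ss$first[k]:ss$last[k]] <- ss$label[k]
  out <- lab[residues]
  if (anyNA(out))
    stop("input error: residues outside the secondary-structure map",
         call. = FALSE)
  out
}
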