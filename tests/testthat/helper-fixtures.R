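## Shared fixtures, built once per test session.

.cache <- new.env(parent = emptyenv())

toy_structure <- function() {
  if (is.null(.cache$s)) .cache$s <- make_toy_hairpin()
  .cache$s
}

toy_topology <- function() {
  if (is.null(.cache$topo)) .cache$topo <- build_topology(toy_structure())
  .cache$topo
}

toy_frustration <- function() {
  if (is.null(.cache$fset))
    .cache$fset <- build_frustration_set(toy_structure(), toy_topology())
  .cache$fset
}

## hand-built minimal structure: residues from a list of atom matrices
## (rows named by atom type), bypassing the PDB path entirely
mini_structure <- function(res_atoms, resnames = NULL, chain = "A",
                           source_id = "mini") {
  if (is.null(resnames)) resnames <- rep("ALA", length(res_atoms))
  rows <- lapply(seq_along(res_atoms), function(i) {
    m <- res_atoms[[i]]
    tibble::tibble(res_index = i, resno = i, resname = resnames[i],
                   elety = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3])
  })
  structure(list(atoms = dplyr::bind_rows(rows), chain = chain,
                 source_id = source_id),
            class = "cg_structure")
}

## straight CA-only chain along x with given spacing
straight_chain <- function(n, spacing = 3.8) {
  mini_structure(lapply(seq_len(n) - 1, function(k) {
    m <- matrix(c(k * spacing, 0, 0), 1, 3)
    rownames(m) <- "CA"
    m
  }))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}
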