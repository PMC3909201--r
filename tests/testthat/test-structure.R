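test_that("PDB round-trip preserves the fixture structure", {
  s <- toy_structure()
  txt <- write_pdb(s)
  s2 <- parse_structure(txt, chain = "A", source_id = "roundtrip")
  expect_equal(n_residues(s2), 19)
  counts <- table(s2$atoms$res_index)
  expect_true(all(counts >= 4))
  expect_equal(residue_names(s2), residue_names(s))
  ## coordinates survive to PDB precision (1e-3 A)
  expect_equal(ca_coords(s2), ca_coords(s), tolerance = 1e-3)
})

test_that("parsing rejects empty chains and structures without CA atoms", {
  het <- c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
           "END")
  expect_error(parse_structure(het, chain = "A"), "no ATOM")
  no_ca <- c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
             "ATOM      2  CB  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
             "END")
  expect_error(parse_structure(no_ca, chain = "A"), "no CA")
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  txt <- c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA ASER A   1       1.000   0.000   0.000  0.30  0.00           C",
    "ATOM      3  CA BSER A   1       2.000   0.000   0.000  0.70  0.00           C",
    "END")
  s <- parse_structure(txt, chain = "A")
  ca <- s$atoms[s$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 2.0)  # occupancy 0.70 wins
})

test_that("hydrogens are excluded from parsed structures", {
  txt <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  HA  ALA A   1       0.500   0.000   0.000  1.00  0.00           H",
    "ATOM      3  CB  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "END")
  s <- parse_structure(txt, chain = "A")
  expect_setequal(s$atoms$elety, c("CA", "CB"))
})

test_that("native-contact detection matches the brute-force oracle", {
  s <- toy_structure()
  ct <- compute_native_contacts(s)
  bf <- brute_force_contacts(s)
  expect_identical(paste(ct$i, ct$j), paste(bf$i, bf$j))
  ## each unordered pair once, deterministic re-run
  expect_false(any(duplicated(paste(ct$i, ct$j))))
  expect_identical(ct, compute_native_contacts(s))
  ## r0 is the CA-CA distance, not the minimum atom distance
  ca <- ca_coords(s)
  expect_equal(ct$r0,
               sqrt(rowSums((ca[ct$i, , drop = FALSE] -
                               ca[ct$j, , drop = FALSE])^2)))
})

test_that("contact cutoff and sequence separation are honoured", {
  ## two CA-only residues at controlled distance, 10 apart in sequence
  two_res <- function(d) {
    atoms <- lapply(1:11, function(i) {
      m <- matrix(c(if (i == 11) d else (i - 1) * 3.8 * 1e3, 0, 0), 1, 3)
      rownames(m) <- "CA"
      m
    })
    ## park intermediate residues far away so only pair (1, 11) can touch
    atoms[[1]] <- matrix(c(0, 0, 0), 1, 3,
                         dimnames = list("CA", NULL))
    mini_structure(atoms)
  }
  near <- compute_native_contacts(two_res(5.4))
  expect_true(any(near$i == 1 & near$j == 11))
  far <- compute_native_contacts(two_res(6.0))
  expect_false(any(far$i == 1 & far$j == 11))
  ## separation: adjacent helical residues are never contacts
  ct <- compute_native_contacts(toy_structure(), min_separation = 4L)
  expect_true(all(ct$j - ct$i >= 4))
})

test_that("MJ weights normalise to unit mean and match the closed form", {
  ct <- compute_native_contacts(toy_structure())
  w <- assign_mj_weights(ct, residue_names(toy_structure()))
  expect_equal(mean(w$weight), 1, tolerance = 1e-12)
  ## single contact: weight forced to exactly 1
  w1 <- assign_mj_weights(ct[1, ], residue_names(toy_structure()))
  expect_equal(w1$weight, 1)
  ## two contacts: closed form 2 m_k / (m1 + m2)
  mj <- mj_energy_table()
  seqs <- c("LEU", "LEU", "SER", "SER")
  two <- tibble::tibble(i = c(1L, 3L), j = c(2L, 4L), r0 = c(5, 5))
  w2 <- assign_mj_weights(two, seqs)
  m <- c(abs(mj["L", "L"]), abs(mj["S", "S"]))
  expect_equal(w2$weight, 2 * m / sum(m))
  ## unknown residue: unit raw weight with a warning
  expect_warning(wu <- assign_mj_weights(two, c("LEU", "XXX", "SER", "SER")),
                 "unknown residue")
  expect_equal(mean(wu$weight), 1, tolerance = 1e-12)
})

test_that("topology geometry matches independent vector algebra", {
  ## collinear chain: all bond lengths 3.8, all angles pi
  st <- straight_chain(6)
  topo <- suppressWarnings(build_topology(st))
  expect_equal(topo$r0, rep(3.8, 5))
  expect_equal(topo$theta0, rep(pi, 4))
  ## chain combinatorics on the fixture
  topo <- toy_topology()
  expect_equal(length(topo$r0), topo$n - 1)
  expect_equal(length(topo$theta0), topo$n - 2)
  expect_equal(length(topo$phi0), topo$n - 3)
  ## right-angle zig: known angle and dihedral
  zig <- mini_structure(lapply(list(c(0, 0, 0), c(3.8, 0, 0),
                                    c(3.8, 3.8, 0), c(3.8, 3.8, 3.8)),
                               function(p) {
                                 m <- matrix(p, 1, 3)
                                 rownames(m) <- "CA"
                                 m
                               }))
  tz <- build_topology(zig)
  expect_equal(tz$theta0, c(pi / 2, pi / 2))
  expect_equal(abs(tz$phi0), pi / 2)
  ## dihedrals recomputed by the reference implementation
  ca <- toy_topology()$ca0
  ref <- vapply(seq_len(nrow(ca) - 3), function(i)
    ref_dihedral(ca[i, ], ca[i + 1, ], ca[i + 2, ], ca[i + 3, ]), 0)
  expect_equal(toy_topology()$phi0, ref, tolerance = 1e-12)
})

test_that("bond-length sanity check rejects broken chains", {
  st <- straight_chain(5, spacing = 6.0)
  expect_error(build_topology(st), "2.5-4.5")
})

test_that("frustration set is the hydrophobic non-native complement", {
  s <- toy_structure(); topo <- toy_topology()
  fset <- toy_frustration()
  hyd <- which(residue_names(s) %in% hydrophobic_residues())
  ## brute-force enumeration oracle
  exp_pairs <- list()
  for (i in hyd) for (j in hyd) {
    if (j - i < topo$min_separation) next
    if (any(topo$contacts$i == i & topo$contacts$j == j)) next
    exp_pairs[[length(exp_pairs) + 1]] <- c(i, j)
  }
  exp_df <- do.call(rbind, exp_pairs)
  expect_equal(nrow(fset$pairs), nrow(exp_df))
  expect_identical(paste(fset$pairs$i, fset$pairs$j),
                   paste(exp_df[, 1], exp_df[, 2]))
  ## no overlap with native contacts
  expect_length(intersect(paste(fset$pairs$i, fset$pairs$j),
                          paste(topo$contacts$i, topo$contacts$j)), 0)
  ## no hydrophobic residues -> empty set
  s_polar <- s
  s_polar$atoms$resname <- "SER"
  expect_equal(nrow(build_frustration_set(s_polar, topo)$pairs), 0L)
})

test_that("side-chain truncation to alanine behaves like the manual mutant", {
  s <- toy_structure()
  ## LEU residue 1 keeps exactly N, CA, C, O, CB and is renamed
  m <- mutate_side_chain_to_ala(s, 1)
  r1 <- m$atoms[m$atoms$res_index == 1, ]
  expect_setequal(r1$elety, c("N", "CA", "C", "O", "CB"))
  expect_true(all(r1$resname == "ALA"))
  ## original untouched
  expect_equal(residue_names(s)[1], "LEU")
  ## mutation can only lose contacts
  ct0 <- compute_native_contacts(s)
  ct1 <- compute_native_contacts(m)
  expect_true(all(paste(ct1$i, ct1$j) %in% paste(ct0$i, ct0$j)))
  ## residue without CB is rejected
  g <- s
  g$atoms <- g$atoms[!(g$atoms$res_index == 2 & g$atoms$elety == "CB"), ]
  expect_error(mutate_side_chain_to_ala(g, 2), "no CB")
})

test_that("Kabsch RMSD removes rigid motion and matches bio3d", {
  s <- toy_structure()
  expect_equal(kabsch_rmsd(s, s), 0)
  ## rigidly moved copy: RMSD 0 for both selections
  r <- random_rotation(7)
  moved <- s
  xyz <- as.matrix(moved$atoms[c("x", "y", "z")]) %*% t(r)
  moved$atoms$x <- xyz[, 1] + 11.2
  moved$atoms$y <- xyz[, 2] - 3.7
  moved$atoms$z <- xyz[, 3] + 0.4
  expect_lt(kabsch_rmsd(s, moved, "CA"), 1e-9)
  expect_lt(kabsch_rmsd(s, moved, "backbone"), 1e-9)
  ## random clouds: agree with the bio3d superposition oracle
  set.seed(42)
  for (rep in 1:3) {
    a <- matrix(rnorm(30, sd = 5), 10, 3)
    b <- a + matrix(rnorm(30, sd = 0.8), 10, 3)
    ours <- frustfold:::kabsch_rmsd_xyz(a, b)
    theirs <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)),
                          fit = TRUE)
    expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d prints 3 decimals
    expect_equal(ours, frustfold:::kabsch_rmsd_xyz(b, a),
                 tolerance = 1e-9)
  }
  ## mismatched sizes rejected
  short <- s
  short$atoms <- short$atoms[short$atoms$res_index <= 10, ]
  expect_error(kabsch_rmsd(s, short), "different atom counts")
})

test_that("topology JSON round-trips losslessly", {
  tf <- tempfile(fileext = ".json")
  write_topology(toy_topology(), tf, toy_frustration())
  back <- read_topology(tf)
  expect_equal(back$topology$ca0, toy_topology()$ca0)
  expect_equal(back$topology$contacts, toy_topology()$contacts)
  expect_equal(back$topology$phi0, toy_topology()$phi0)
  expect_equal(back$frustration$pairs, toy_frustration()$pairs)
  unlink(tf)
})
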