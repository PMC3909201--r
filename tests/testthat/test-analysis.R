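## small synthetic TSE: kept matrices over a hand-enumerable contact list
toy_tse <- function(kept) structure(
  list(indices = seq_len(nrow(kept)), window = c(0L, 100L),
       peaks = c(NA_integer_, NA_integer_), valley = NA_integer_,
       t_avg = 1, delta = 0.5, kept = kept),
  class = "cg_tse")

test_that("contact-kept criterion uses r <= lambda r0 inclusively", {
  expect_true(contact_kept(5, 5))
  expect_true(contact_kept(6, 5, lambda = 1.2))   # boundary kept
  expect_false(contact_kept(6.0001, 5, lambda = 1.2))
  expect_false(contact_kept(10, 5))
  expect_error(contact_kept(5, 5, lambda = 0.9))
})

test_that("free-energy profile matches hand arithmetic and is offset to 0", {
  q <- new_q_trace(c(rep(10L, 40), rep(30L, 10), rep(55L, 50)), 60L)
  fe <- free_energy_profile(q, t_avg = 1)
  expect_equal(fe$q_count, c(10, 30, 55))
  expect_equal(fe$f, -log(c(0.4, 0.1, 0.5)) - (-log(0.5)),
               tolerance = 1e-12)
  expect_equal(round(fe$f, 3), c(0.223, 1.609, 0))
  ## uniform counts: flat profile at 0
  qu <- new_q_trace(rep(0:9, each = 10), 10L)
  expect_true(all(abs(free_energy_profile(qu, 1)$f) < 1e-12))
  ## temperature factor scales linearly
  fe2 <- free_energy_profile(q, t_avg = 0.5)
  expect_equal(fe2$f, fe$f * 0.5)
  ## degenerate single-bin histogram warns
  expect_warning(free_energy_profile(new_q_trace(rep(5L, 30), 10L), 1),
                 "degenerate")
})

test_that("free-energy profile inverts back to the empirical P(Q)", {
  set.seed(4)
  qc <- as.integer(pmin(20, pmax(0, round(c(rnorm(500, 4, 2),
                                            rnorm(500, 16, 2))))))
  fe <- free_energy_profile(new_q_trace(qc, 20L), t_avg = 0.37)
  p_back <- exp(-fe$f / 0.37)
  p_back <- p_back / sum(p_back)
  expect_equal(p_back, fe$p / sum(fe$p), tolerance = 1e-12)
})

test_that("TSE selection brackets the valley of a two-Gaussian mixture", {
  set.seed(2)
  nc <- 40L
  qc <- as.integer(pmin(nc, pmax(0, round(c(rnorm(4000, 8, 2.5),
                                            rnorm(4000, 30, 2.5))))))
  q <- new_q_trace(qc, nc)
  tse <- select_tse(q, t_avg = 1)
  ## analytic density minimum of the symmetric mixture is at the midpoint
  expect_lte(abs(tse$valley - 19), 2)
  expect_true(tse$window[1] > 8 && tse$window[2] < 30)
  expect_true(tse$valley >= tse$window[1] && tse$valley <= tse$window[2])
  ## selected snapshots are exactly those inside the window
  qsel <- qc[tse$indices]
  expect_true(all(qsel >= tse$window[1] & qsel <= tse$window[2]))
  ## wider delta never shrinks the selection
  tse2 <- select_tse(q, t_avg = 1, delta = 2)
  expect_gte(length(tse2$indices), length(tse$indices))
})

test_that("TSE selection fails loudly on unimodal distributions", {
  set.seed(3)
  q <- new_q_trace(as.integer(pmax(0, round(rnorm(3000, 30, 2)))), 40L)
  expect_error(select_tse(q, 1), "not bimodal")
  ## all-folded trace
  expect_error(select_tse(new_q_trace(rep(40L, 1000), 40L), 1),
               "not bimodal")
})

test_that("phi-values are exact per-residue contact fractions", {
  topo <- toy_topology()
  m <- nrow(topo$contacts)
  ## native snapshot: every contact kept -> phi = 1 wherever defined
  phi1 <- phi_values(toy_tse(matrix(TRUE, 1, m)), topo)
  expect_true(all(phi1$phi[phi1$n_native > 0] == 1))
  ## fully broken -> phi = 0
  phi0 <- phi_values(toy_tse(matrix(FALSE, 3, m)), topo)
  expect_true(all(phi0$phi[phi0$n_native > 0] == 0))
  ## residues without native contacts are flagged undefined
  expect_true(all(is.na(phi1$phi[phi1$n_native == 0])))
  ## 3-snapshot enumeration oracle
  set.seed(9)
  kept <- matrix(runif(3 * m) < 0.6, 3, m)
  phi <- phi_values(toy_tse(kept), topo)
  for (res in seq_len(topo$n)) {
    inc <- which(topo$contacts$i == res | topo$contacts$j == res)
    if (length(inc) == 0) next
    manual <- mean(vapply(1:3, function(s) sum(kept[s, inc]), 0)) /
      length(inc)
    expect_equal(phi$phi[res], manual, tolerance = 1e-12)
  }
  expect_true(all(phi$phi >= 0 & phi$phi <= 1, na.rm = TRUE))
})

test_that("phi comparison reports correlation and Table-2-style increments", {
  prof <- function(phi) structure(
    tibble::tibble(residue = seq_along(phi),
                   n_native = rep(2L, length(phi)), phi = phi),
    class = c("cg_phi_profile", class(tibble::tibble())))
  a <- prof(c(0.1, 0.5, 0.9))
  b <- prof(c(0.2, 0.6, 1.0))
  cmp <- compare_phi(a, b)
  expect_equal(cmp$r, 1)
  expect_equal(cmp$mean_increment, 0.10)
  expect_equal(cmp$sd_increment, 0)
  ## identical profiles
  self <- compare_phi(a, a)
  expect_equal(self$r, 1)
  expect_equal(self$mean_increment, 0)
  ## Pearson against the direct covariance formula on random profiles
  set.seed(12)
  pa <- prof(runif(50)); pb <- prof(runif(50))
  cmp2 <- compare_phi(pa, pb)
  x <- pa$phi; y <- pb$phi
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cmp2$r, r_manual, tolerance = 1e-12)
  ## undefined residues are excluded pairwise
  pa$phi[5] <- NA
  cmp3 <- compare_phi(pa, pb)
  expect_equal(cmp3$n_defined, 49)
  expect_error(compare_phi(prof(c(NA, NA, 0.5)), prof(c(0.1, 0.2, 0.3))),
               "fewer than 3")
  expect_error(compare_phi(a, prof(runif(5))), "different residue counts")
  ## broom interface
  expect_equal(glance(cmp)$mean_increment, 0.10)
  expect_equal(nrow(tidy(cmp)), 3)
})

test_that("contact probability increases equal exhaustive counting", {
  topo <- toy_topology()
  m <- nrow(topo$contacts)
  set.seed(5)
  ka <- matrix(runif(10 * m) < 0.5, 10, m)
  kb <- matrix(runif(10 * m) < 0.7, 10, m)
  dp <- contact_probability_increase(toy_tse(ka), toy_tse(kb), topo)
  for (k in seq_len(m)) {
    expect_equal(dp$dprob[k],
                 sum(kb[, k]) / 10 - sum(ka[, k]) / 10,
                 tolerance = 1e-12)
  }
  ## identical TSEs -> all zero
  dp0 <- contact_probability_increase(toy_tse(ka), toy_tse(ka), topo)
  expect_true(all(dp0$dprob == 0))
  ## 6/10 vs 9/10 -> 0.3
  k1 <- matrix(FALSE, 10, m); k1[1:6, 1] <- TRUE
  k2 <- matrix(FALSE, 10, m); k2[1:9, 1] <- TRUE
  expect_equal(contact_probability_increase(toy_tse(k1), toy_tse(k2),
                                            topo)$dprob[1], 0.3)
})

test_that("h_p tables count thresholded increases by element pair", {
  topo <- toy_topology()
  ss <- ss_map(tibble::tibble(label = c("Helix I", "Loop", "Helix II"),
                              first = c(1L, 9L, 12L),
                              last = c(8L, 11L, 19L)), topo$n)
  dp <- contact_probability_increase(
    toy_tse(matrix(FALSE, 4, nrow(topo$contacts))),
    toy_tse(matrix(FALSE, 4, nrow(topo$contacts))), topo)
  ## all-zero increases -> every cell 0 for p > 0
  hp0 <- h_p_table(dp, topo, ss, c(0.05, 0.10))
  expect_true(all(hp0$h == 0))
  ## hand-set increments: {0.12, 0.07, 0.03} in one cell -> h_.05=2, h_.10=1
  dp$dprob[] <- 0
  cell <- which(dp$i <= 8 & dp$j >= 12)[1:3]
  dp$dprob[cell] <- c(0.12, 0.07, 0.03)
  hp <- h_p_table(dp, topo, ss, c(0.05, 0.10))
  c05 <- hp[hp$element_a == "Helix I" & hp$element_b == "Helix II" &
              hp$p == 0.05, ]
  c10 <- hp[hp$element_a == "Helix I" & hp$element_b == "Helix II" &
              hp$p == 0.10, ]
  expect_equal(c05$h, 2L)
  expect_equal(c10$h, 1L)
  ## signed variant counts decreases with opposite sign
  dp$dprob[cell] <- c(0.12, -0.07, -0.20)
  hps <- h_p_table(dp, topo, ss, 0.05)
  cs <- hps[hps$element_a == "Helix I" & hps$element_b == "Helix II", ]
  expect_equal(cs$h, 1L)
  expect_equal(cs$h_signed, 1L - 2L)
  ## totals are row sums over partners (diagonal once)
  set.seed(8)
  dp$dprob <- runif(nrow(dp), -0.3, 0.3)
  hp2 <- h_p_table(dp, topo, ss, c(0.05, 0.10, 0.15))
  tot <- h_p_totals(hp2)
  for (e in attr(hp2, "elements")) for (pv in c(0.05, 0.10, 0.15)) {
    cells <- hp2[hp2$p == pv & (hp2$element_a == e | hp2$element_b == e), ]
    expect_equal(tot$h[tot$element == e & tot$p == pv], sum(cells$h))
  }
  ## monotone in p for every cell and total
  for (key in unique(paste(hp2$element_a, hp2$element_b))) {
    hh <- hp2$h[paste(hp2$element_a, hp2$element_b) == key]
    expect_true(all(diff(hh) <= 0))
  }
  for (e in unique(tot$element)) {
    expect_true(all(diff(tot$h[tot$element == e]) <= 0))
  }
})

test_that("secondary-structure maps must tile the chain", {
  expect_error(ss_map(tibble::tibble(label = c("a", "b"),
                                     first = c(1L, 9L), last = c(7L, 19L)),
                      19L), "tile")
  expect_error(ss_map(tibble::tibble(label = "a", first = 1L, last = 18L),
                      19L), "tile")
  ok <- ss_map(tibble::tibble(label = c("a", "b"), first = c(1L, 9L),
                              last = c(8L, 19L)), 19L)
  expect_s3_class(ok, "cg_ss_map")
  expect_error(frustfold:::ss_element_of(ok, 25L), "outside")
})

test_that("window-transferred TSEs select exactly the requested band", {
  topo <- toy_topology()
  tr <- run_constant_temperature(topo, NULL, cg_params(),
                                 sim_config(0.7, 5e4, stride = 100L,
                                            seed = 13))
  tse <- tse_from_window(tr, c(8L, 12L), t_avg = 0.7)
  expect_true(all(tr$q[tse$indices] >= 8 & tr$q[tse$indices] <= 12))
  expect_equal(nrow(tse$kept), length(tse$indices))
  expect_error(tse_from_window(tr, c(-5L, -1L)), "no snapshots")
})
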