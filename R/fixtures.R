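#' Specification of the deterministic helical-hairpin fixture
#'
#' Two ideal alpha-helices (rise 1.5 A/residue, C-alpha radius 2.3 A,
#' 100 degrees/residue) packed antiparallel at a fixed axis separation and
#' joined by a short loop.  Backbone N, C, O and a C-beta are placed from
#' the C-alpha trace by ideal local geometry -- enough for an all-heavy-atom
#' contact map, with no claim of rotamer realism.  The structure is a pure
#' function of its spec: identical specs give bit-identical coordinates.
#'
#' @param n_helix Residues per helix.
#' @param loop_len Residues in the connecting loop.
#' @param rise,radius,twist_deg Ideal helix internal coordinates.
#' @param axis_sep Distance between the two helix axes, Angstrom.
#' @param phase1_deg,phase2_deg Azimuthal phase of each helix (controls
#'   which face points at the partner helix).
#' @param sequence_pattern Residue codes recycled along the chain, or
#'   `"amphipathic"` (default): interface-facing helix positions (judged
#'   from the radial C-beta direction) become LEU, the loop SER, and the
#'   solvent-facing remainder alternates GLU/LYS.  The amphipathic default
#'   concentrates the MJ contact weight on the helix--helix interface --
#'   a hydrophobic core -- which is what gives the toy cooperative
#'   two-state (un)docking; a plain alternating pattern fights the
#'   3.6-residue helical period and spreads the weight diffusely.
#' @return A `toy_hairpin_spec` list.
#' @export
toy_hairpin_spec <- function(n_helix = 8L, loop_len = 3L, rise = 1.5,
                             radius = 2.3, twist_deg = 100,
                             axis_sep = 8.5, phase1_deg = 0,
                             phase2_deg = 90,
                             sequence_pattern = "amphipathic") {
  stopifnot(n_helix >= 5, loop_len >= 1)
  structure(list(n_helix = as.integer(n_helix),
                 loop_len = as.integer(loop_len), rise = rise,
                 radius = radius, twist_deg = twist_deg,
                 axis_sep = axis_sep, phase1_deg = phase1_deg,
                 phase2_deg = phase2_deg,
                 sequence_pattern = sequence_pattern),
            class = "toy_hairpin_spec")
}

helix_ca <- function(n, radius, rise, twist_deg, phase_deg, x0, z0, dirz) {
  k <- seq_len(n) - 1
  ang <- (phase_deg + dirz * k * twist_deg) * pi / 180
  cbind(x0 + radius * cos(ang), radius * sin(ang), z0 + dirz * k * rise)
}

## equal-arclength points on a quadratic Bezier from p to q bulging along +z
bezier_loop <- function(p, q, n_pts, target_gap) {
  eval_bez <- function(t, bump) {
    ctrl <- (p + q) / 2 + c(0, 0, bump)
    s <- sapply(seq_along(p), function(c_)
      (1 - t)^2 * p[c_] + 2 * (1 - t) * t * ctrl[c_] + t^2 * q[c_])
    matrix(s, ncol = 3)
  }
  arc_len <- function(bump) {
    pts <- eval_bez(seq(0, 1, length.out = 201), bump)
    sum(sqrt(rowSums(diff(pts)^2)))
  }
  target <- target_gap * (n_pts + 1)
  bump <- if (arc_len(0) >= target) 0 else
    stats::uniroot(function(b) arc_len(b) - target, c(0, 40))$root
  dense <- eval_bez(seq(0, 1, length.out = 2001), bump)
  cum <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  want <- cum[length(cum)] * seq_len(n_pts) / (n_pts + 1)
  dense[vapply(want, function(w) which.min(abs(cum - w)), 0L), , drop = FALSE]
}

place_backbone <- function(ca, resnames) {
  n <- nrow(ca)
  unit <- function(v) v / sqrt(sum(v^2))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    u <- if (i > 1) unit(ca[i - 1, ] - ca[i, ]) else unit(ca[i, ] - ca[i + 1, ])
    v <- if (i < n) unit(ca[i + 1, ] - ca[i, ]) else unit(ca[i, ] - ca[i - 1, ])
    nrm <- if (abs(sum(u * v)) < 0.999) unit(pracma_cross(u, v))
           else unit(pracma_cross(u, c(0, 0, 1) + 1e-3))
    Npos <- ca[i, ] + 1.46 * u
    Cpos <- ca[i, ] + 1.52 * v
    Opos <- Cpos + 1.23 * nrm
    b <- ca[i, ] - Npos; cc <- Cpos - ca[i, ]
    a <- pracma_cross(b, cc)
    CBpos <- ca[i, ] - 0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
    ats <- rbind(Npos, ca[i, ], Cpos, Opos, CBpos)
    rows[[i]] <- tibble::tibble(res_index = i, resno = i,
                                resname = resnames[i],
                                elety = c("N", "CA", "C", "O", "CB"),
                                x = ats[, 1], y = ats[, 2], z = ats[, 3])
  }
  dplyr::bind_rows(rows)
}

## hydrophobic-in, polar-out sequence assignment from the CA geometry:
## helix residues whose radial (outward) direction points at the partner
## helix axis get LEU (strong MJ weight: the docking interface is the
## hydrophobic core); the loop gets SER; the rest alternates ALA/LYS --
## ALA is hydrophobic but MJ-weak, so it feeds the non-native frustration
## pair list without adding strong native weight off the interface
amphipathic_sequence <- function(ca, n_helix, loop_len, axis_sep) {
  n <- nrow(ca)
  res <- character(n)
  polar <- c("ALA", "LYS")
  pk <- 1L
  for (i in seq_len(n)) {
    in_h1 <- i <= n_helix
    in_h2 <- i > n_helix + loop_len
    if (!in_h1 && !in_h2) { res[i] <- "SER"; next }
    axis_x <- if (in_h1) 0 else axis_sep
    radial <- c(ca[i, 1] - axis_x, ca[i, 2])
    radial <- radial / sqrt(sum(radial^2))
    toward <- if (in_h1) c(1, 0) else c(-1, 0)
    if (sum(radial * toward) > 0.4) res[i] <- "LEU"
    else { res[i] <- polar[pk]; pk <- 3L - pk }
  }
  res
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the deterministic toy helical hairpin
#'
#' @param spec A [toy_hairpin_spec()].
#' @return A `cg_structure` with `2 * n_helix + loop_len` residues, each
#'   with N, CA, C, O, CB atoms.
#' @export
make_toy_hairpin <- function(spec = toy_hairpin_spec()) {
  stopifnot(inherits(spec, "toy_hairpin_spec"))
  n1 <- spec$n_helix
  h1 <- helix_ca(n1, spec$radius, spec$rise, spec$twist_deg,
                 spec$phase1_deg, 0, 0, +1)
  z_top <- (n1 - 1) * spec$rise
  h2 <- helix_ca(n1, spec$radius, spec$rise, spec$twist_deg,
                 spec$phase2_deg, spec$axis_sep, z_top, -1)
  gap <- 3.8
  loop <- bezier_loop(h1[n1, ], h2[1, ], spec$loop_len, gap)
  ca <- rbind(h1, loop, h2)
  n <- nrow(ca)
  d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  if (any(d < 2.5 | d > 4.5))
    stop("spec error: loop of ", spec$loop_len, " residues cannot bridge ",
         "the helices with ~3.8 A virtual bonds at this axis separation",
         call. = FALSE)
  resnames <- if (identical(spec$sequence_pattern, "amphipathic"))
    amphipathic_sequence(ca, n1, spec$loop_len, spec$axis_sep)
  else rep(spec$sequence_pattern, length.out = n)
  atoms <- place_backbone(ca, resnames)
  s <- structure(list(atoms = atoms, chain = "A",
                      source_id = "toy_hairpin"),
                 class = "cg_structure")
  validate_structure(s)
  ## fixture contract: must be simulatable and have a real contact network
  topo <- build_topology(s)
  if (nrow(topo$contacts) < 10)
    stop("spec error: hairpin forms fewer than 10 native contacts ",
         "(helices too short or too far apart)", call. = FALSE)
  s
}

#' Brute-force native-contact oracle
#'
#' Naive O(atoms^2) re-implementation of the native-contact rule (minimum
#' heavy-atom distance below cutoff, sequence separation respected), used
#' as the independent oracle for [compute_native_contacts()] in tests.
#'
#' @inheritParams compute_native_contacts
#' @return Tibble with columns `i`, `j`.
#' @export
brute_force_contacts <- function(s, cutoff = 5.5, min_separation = 4L) {
  a <- s$atoms
  n <- n_residues(s)
  oi <- integer(0); oj <- integer(0)
  if (cutoff <= 0 || n < 2)
    return(tibble::tibble(i = oi, j = oj))
  for (i in seq_len(n - 1)) {
    xi <- a[a$res_index == i, ]
    for (j in seq.int(i + 1, n)) {
      if (j - i < min_separation) next
      xj <- a[a$res_index == j, ]
      found <- FALSE
      for (p in seq_len(nrow(xi))) {
        for (q in seq_len(nrow(xj))) {
          dd <- sqrt((xi$x[p] - xj$x[q])^2 + (xi$y[p] - xj$y[q])^2 +
                     (xi$z[p] - xj$z[q])^2)
          if (dd < cutoff) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) { oi <- c(oi, i); oj <- c(oj, j) }
    }
  }
  tibble::tibble(i = oi, j = oj)
}

#' Specification of the double-well controller testbed
#'
#' A 1-D Langevin particle in a piecewise quartic double well, continuously
#' differentiable at the barrier top x = 0: the left ("unfolded") well is
#' \eqn{h(x^2-1)^2} with its minimum at x = -1, the right ("native") well
#' \eqn{(h+d)((x/w)^2-1)^2 - d} with its minimum at x = w.  With `depth`
#' d > 0 and `width` w < 1 the native well is deeper but narrower, so it
#' dominates at low temperature while the wider unfolded well wins at high
#' temperature; the occupancies cross at a finite temperature computable
#' by Boltzmann quadrature -- the closed-form two-state target the
#' adaptive-temperature controller must find.
#'
#' @param barrier Barrier height h of the unfolded well (reduced energy).
#' @param depth Extra depth d of the native well.
#' @param width Native-well half-width w (its minimum sits at x = w).
#' @param dt,gamma,mass Langevin settings.
#' @return A `double_well_spec` list.
#' @export
double_well_spec <- function(barrier = 1, depth = 0.6, width = 0.3,
                             dt = 0.01, gamma = 1, mass = 1) {
  stopifnot(barrier > 0, depth >= 0, width > 0)
  structure(list(barrier = barrier, depth = depth, width = width,
                 dt = dt, gamma = gamma, mass = mass),
            class = "double_well_spec")
}

dw_potential <- function(x, spec) {
  ifelse(x <= 0,
         spec$barrier * (x^2 - 1)^2,
         (spec$barrier + spec$depth) * ((x / spec$width)^2 - 1)^2 -
           spec$depth)
}

#' Equilibrium right-well occupancy of the double-well toy
#'
#' Boltzmann quadrature: \eqn{P(x>0) = \int_0^\infty e^{-V/T} /
#' \int_{-\infty}^\infty e^{-V/T}}.
#' @param temperature Reduced temperature.
#' @param spec A [double_well_spec()].
#' @return Probability in (0, 1).
#' @export
dw_right_probability <- function(temperature, spec = double_well_spec()) {
  w <- function(x) exp(-(dw_potential(x, spec) -
                           dw_potential(spec$width, spec)) / temperature)
  right <- stats::integrate(w, 0, Inf, rel.tol = 1e-10)$value
  left <- stats::integrate(w, -Inf, 0, rel.tol = 1e-10)$value
  right / (right + left)
}

#' Temperature at which the double-well occupancies are equal
#'
#' The closed-form (quadrature) two-state answer the adaptive controller
#' should converge to.
#' @param spec A [double_well_spec()].
#' @param interval Search interval for the root of `P(right) = 1/2`.
#' @return Temperature (reduced units).
#' @export
dw_equal_occupancy_temperature <- function(spec = double_well_spec(),
                                           interval = c(0.05, 5)) {
  stats::uniroot(function(tt) dw_right_probability(tt, spec) - 0.5,
                 interval, tol = 1e-8)$root
}

#' Double-well sampler with the folding-simulator histogram interface
#'
#' Returns a stateful sampler whose `run(n_steps, temperature)` advances
#' the particle and returns the per-well step counts, mapped onto a
#' two-bin Q histogram (left well = Q 0 = non-native, right well = Q 1 =
#' native), so [update_temperature()] can drive it exactly like the
#' folding simulator.
#'
#' @param spec A [double_well_spec()].
#' @param x0,v0 Initial state.
#' @return List with `run(n_steps, temperature)` -> integer vector
#'   `c(nonnative, native)` and `state()` -> c(x, v).
#' @export
make_double_well_sampler <- function(spec = double_well_spec(),
                                     x0 = spec$width, v0 = 0) {
  x <- x0; v <- v0
  list(
    run = function(n_steps, temperature) {
      res <- dw_run_cpp(x, v, spec$barrier, spec$depth, spec$width,
                        spec$dt, spec$gamma, temperature, spec$mass,
                        n_steps)
      x <<- res$x; v <<- res$v
      c(nonnative = res$n_total - res$n_right, native = res$n_right)
    },
    state = function() c(x = x, v = v))
}

#' Run the adaptive-temperature controller on the double-well toy
#'
#' @param spec A [double_well_spec()].
#' @param t_init Starting temperature.
#' @param delta_t Temperature increment per window.
#' @param n_t Steps per window.
#' @param n_windows Number of adjustment windows.
#' @param seed Integer seed.
#' @param cumulative Use cumulative counts (default) or per-window counts.
#' @param burn_in Fraction of windows discarded by [estimate_T_theta()].
#' @return A `cg_temperature_trace` tibble (window, temperature).
#' @export
dw_variable_temperature <- function(spec = double_well_spec(),
                                    t_init = 0.5, delta_t = 0.01,
                                    n_t = 2000L, n_windows = 200L,
                                    seed = 1L, cumulative = TRUE,
                                    burn_in = 0.3) {
  set.seed(seed)
  sampler <- make_double_well_sampler(spec)
  temp <- t_init
  counts <- c(0, 0)
  temps <- numeric(n_windows)
  for (w in seq_len(n_windows)) {
    temps[w] <- temp
    cw <- sampler$run(n_t, temp)
    counts <- if (cumulative) counts + cw else cw
    temp <- as.numeric(update_temperature(counts, temp, delta_t))
  }
  structure(tibble::tibble(window = seq_len(n_windows),
                           temperature = temps),
            class = c("cg_temperature_trace", class(tibble::tibble())),
            t_init = t_init, delta_t = delta_t, n_t = n_t,
            burn_in = burn_in)
}
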