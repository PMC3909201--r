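new_trajectory <- function(run, stride, nc, config, seed, mode,
                           temperature_trace = NULL) {
  structure(list(step = as.numeric(run$snap_index) * stride,
                 temperature = run$temperature,
                 q = as.integer(run$q),
                 kept = run$kept,
                 coords = run$coords,
                 nc = as.integer(nc),
                 stride = as.integer(stride),
                 config = config, seed = seed, mode = mode),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %s: %d snapshots (stride %d), %d native contacts, seed %d\n",
              x$mode, length(x$step), x$stride, x$nc, x$seed))
  cat(sprintf("  <Q> = %.2f / %d; T range [%g, %g]\n",
              mean(x$q), x$nc, min(x$temperature), max(x$temperature)))
  invisible(x)
}

maxwell_velocities <- function(n, temperature, mass) {
  matrix(stats::rnorm(3 * n, sd = sqrt(temperature / mass)), n, 3)
}

#' Constant-temperature Langevin folding simulation
#'
#' Propagates the model from its native state with the BAOAB Langevin
#' integrator at fixed bath temperature, recording thinned snapshots with
#' per-native-contact kept/broken flags.  The (topology, parameters, seed)
#' triple fully determines every snapshot.
#'
#' @param topo A `cg_topology`.
#' @param fset Optional `cg_frustration` set (used when
#'   `params$frustration` is `TRUE`).
#' @param params A [cg_params()] object.
#' @param cfg A [sim_config()] object.
#' @param x0,v0 Optional starting coordinates/velocities (default: native
#'   coordinates and Maxwell--Boltzmann velocities at `cfg$temperature`).
#' @return A `cg_trajectory`.
#' @export
run_constant_temperature <- function(topo, fset = NULL,
                                     params = cg_params(), cfg,
                                     x0 = NULL, v0 = NULL) {
  stopifnot(inherits(cfg, "cg_sim_config"))
  set.seed(cfg$seed)
  if (is.null(x0)) x0 <- topo$ca0
  if (is.null(v0)) v0 <- maxwell_velocities(topo$n, cfg$temperature,
                                            cfg$mass)
  core <- topo_for_core(topo, fset, params)
  run <- cg_run_cpp(x0, v0, core, unclass(params), cfg$dt, cfg$gamma,
                    cfg$temperature, cfg$mass, cfg$n_steps, cfg$stride,
                    0, params$kept_lambda)
  new_trajectory(run, cfg$stride, nrow(topo$contacts), cfg, cfg$seed,
                 "constant-T")
}

#' One adaptive temperature update from a Q histogram
#'
#' Locates the unfolded (low-Q) and folded (high-Q) peaks of the
#' native-contact-count histogram (bin width 1, lightly smoothed with a
#' 3-bin moving average) and moves the temperature by `delta_t` toward
#' equal peak heights: down when the unfolded peak is higher (cool to
#' favour folding), up when the folded peak is higher, and in a random
#' direction when the peaks tie.  The temperature is floored at `delta_t`.
#' A histogram with no two separated peaks falls back to a median split
#' with a notice.
#'
#' @param counts Numeric vector of histogram counts over consecutive
#'   Q-count bins (first bin = smallest Q observed).
#' @param temperature Current temperature.
#' @param delta_t Temperature increment.
#' @return The new temperature (scalar), with attribute `"diagnostics"`
#'   (list: peak bins, valley bin, direction, fallback flag).
#' @export
update_temperature <- function(counts, temperature, delta_t) {
  stopifnot(delta_t >= 0, length(counts) >= 1)
  nb <- length(counts)
  fallback <- FALSE
  if (nb < 5) {
    sm <- as.numeric(counts)
    half <- max(1L, nb %/% 2L)
    p_lo <- which.max(sm[seq_len(half)])
    p_hi <- half + which.max(sm[seq.int(half + 1L, nb)])
    valley <- NA_integer_
  } else {
    sm <- vapply(seq_len(nb), function(k)
      mean(counts[max(1, k - 1):min(nb, k + 1)]), 0)
    left <- c(-Inf, sm[-nb]); right <- c(sm[-1], -Inf)
    locmax <- which(sm > left & sm >= right)
    if (length(locmax) < 2) {
      message("update_temperature: histogram not bimodal; median split fallback")
      fallback <- TRUE
      qv <- seq_len(nb)
      med <- min(which(cumsum(counts) >= sum(counts) / 2))
      half <- max(1L, min(med, nb - 1L))
      p_lo <- which.max(sm[seq_len(half)])
      p_hi <- half + which.max(sm[seq.int(half + 1L, nb)])
    } else {
      ord <- locmax[order(sm[locmax], decreasing = TRUE)]
      two <- sort(ord[1:2])
      p_lo <- two[1]; p_hi <- two[2]
    }
    between <- seq.int(p_lo, p_hi)
    valley <- between[which.min(sm[between])]
  }
  h_lo <- sm[p_lo]; h_hi <- sm[p_hi]
  if (isTRUE(all.equal(h_lo, h_hi, tolerance = 1e-9))) {
    direction <- if (stats::runif(1) < 0.5) -1 else 1
  } else if (h_lo > h_hi) {
    direction <- -1          # unfolded dominates: cool
  } else {
    direction <- 1           # folded dominates: heat
  }
  out <- max(temperature + direction * delta_t, delta_t)
  attr(out, "diagnostics") <- list(peak_low = p_lo, peak_high = p_hi,
                                   valley = valley, direction = direction,
                                   fallback = fallback)
  out
}

#' Variable-temperature folding simulation
#'
#' Runs Langevin dynamics in windows of `vt$n_t` steps; after each window
#' the histogram of the native-contact count Q over the up-to-now (or, with
#' `vt$cumulative = FALSE`, the latest-window) snapshots is fed to
#' [update_temperature()], so the bath temperature walks in steps of
#' `vt$delta_t` and settles around the transition temperature where folded
#' and unfolded states are equally visited.  With `vt$delta_t = 0` the
#' controller is bypassed and the run is bit-identical to
#' [run_constant_temperature()] at `vt$t_init` with the same seed.
#'
#' @inheritParams run_constant_temperature
#' @param vt A [vt_config()] object.
#' @return List with `trajectory` (a `cg_trajectory` over all windows) and
#'   `trace` (a `cg_temperature_trace`: tibble of per-window temperatures
#'   with the protocol settings as attributes).
#' @export
run_variable_temperature <- function(topo, fset = NULL,
                                     params = cg_params(), cfg, vt) {
  stopifnot(inherits(cfg, "cg_sim_config"), inherits(vt, "cg_vt_config"))
  if (vt$n_t %% cfg$stride != 0)
    stop("input error: n_t must be a multiple of the snapshot stride",
         call. = FALSE)
  n_windows <- floor(cfg$n_steps / vt$n_t)
  if (n_windows < 1) stop("input error: fewer steps than one window",
                          call. = FALSE)
  set.seed(cfg$seed)
  temp <- vt$t_init
  x <- topo$ca0
  v <- maxwell_velocities(topo$n, temp, cfg$mass)
  core <- topo_for_core(topo, fset, params)
  nc <- nrow(topo$contacts)
  qs <- integer(0)
  windows <- numeric(n_windows)
  pieces <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    windows[w] <- temp
    run <- cg_run_cpp(x, v, core, unclass(params), cfg$dt, cfg$gamma,
                      temp, cfg$mass, vt$n_t, cfg$stride,
                      (w - 1) * vt$n_t, params$kept_lambda)
    x <- run$x; v <- run$v
    pieces[[w]] <- run
    if (vt$delta_t > 0) {
      qs_w <- as.integer(run$q)
      qs <- if (vt$cumulative) c(qs, qs_w) else qs_w
      counts <- tabulate(qs + 1L, nbins = nc %/% vt$bin_width + 1L)
      temp <- as.numeric(update_temperature(counts, temp, vt$delta_t))
    }
  }
  run_all <- list(
    snap_index = unlist(lapply(pieces, `[[`, "snap_index")),
    temperature = unlist(lapply(pieces, `[[`, "temperature")),
    q = unlist(lapply(pieces, `[[`, "q")),
    kept = do.call(rbind, lapply(pieces, `[[`, "kept")),
    coords = bind_coords(lapply(pieces, `[[`, "coords")))
  traj <- new_trajectory(run_all, cfg$stride, nc, cfg, cfg$seed,
                         "variable-T")
  trace <- structure(
    tibble::tibble(window = seq_len(n_windows), temperature = windows),
    class = c("cg_temperature_trace", class(tibble::tibble())),
    t_init = vt$t_init, delta_t = vt$delta_t, n_t = vt$n_t,
    burn_in = vt$burn_in)
  list(trajectory = traj, trace = trace)
}

bind_coords <- function(arrs) {
  ss <- vapply(arrs, function(a) dim(a)[1], 0L)
  n <- dim(arrs[[1]])[2]
  out <- array(0, c(sum(ss), n, 3))
  at <- 0L
  for (a in arrs) {
    s <- dim(a)[1]
    if (s > 0) out[at + seq_len(s), , ] <- a
    at <- at + s
  }
  out
}

#' Estimate the transition temperature from a temperature trace
#'
#' Mean of the post-burn-in window temperatures of a variable-temperature
#' run; once the controller has equilibrated, the trace fluctuates around
#' the two-state transition temperature.
#'
#' @param trace A `cg_temperature_trace` (or tibble with a `temperature`
#'   column).
#' @param burn_in Fraction of initial windows to discard; defaults to the
#'   value carried by the trace, else 0.3.
#' @return The estimate (scalar), with attributes `se` (standard error over
#'   the retained windows) and `n_windows`.
#' @export
estimate_T_theta <- function(trace, burn_in = NULL) {
  temps <- trace$temperature
  if (is.null(burn_in)) burn_in <- attr(trace, "burn_in") %||% 0.3
  first <- floor(length(temps) * burn_in) + 1
  keep <- if (first > length(temps)) numeric(0)
          else temps[seq.int(first, length(temps))]
  if (length(keep) < 1)
    stop("input error: no windows left after burn-in", call. = FALSE)
  out <- mean(keep)
  attr(out, "se") <- stats::sd(keep) / sqrt(length(keep))
  attr(out, "n_windows") <- length(keep)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
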