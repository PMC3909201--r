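#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cg_phi_comparison <- function(x, ...) x$table

#' @export
glance.cg_phi_comparison <- function(x, ...) {
  tibble::tibble(r = x$r, mean_increment = x$mean_increment,
                 sd_increment = x$sd_increment, n_defined = x$n_defined)
}

#' @export
tidy.cg_topology <- function(x, ...) x$contacts

#' @export
glance.cg_topology <- function(x, ...) {
  tibble::tibble(n_residues = x$n, n_bonds = length(x$r0),
                 n_angles = length(x$theta0), n_dihedrals = length(x$phi0),
                 n_contacts = nrow(x$contacts),
                 mean_weight = mean(x$contacts$weight))
}

#' @export
glance.cg_trajectory <- function(x, ...) {
  tibble::tibble(n_snapshots = length(x$step), stride = x$stride,
                 nc = x$nc, mean_q = mean(x$q),
                 mean_q_frac = mean(x$q) / x$nc,
                 t_min = min(x$temperature), t_max = max(x$temperature),
                 seed = x$seed, mode = x$mode)
}

#' @export
tidy.cg_tse <- function(x, ...) {
  tibble::tibble(n_snapshots = length(x$indices),
                 q_low = x$window[1], q_high = x$window[2],
                 peak_unfolded = x$peaks[1], peak_folded = x$peaks[2],
                 valley = x$valley, t_avg = x$t_avg, delta = x$delta)
}
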