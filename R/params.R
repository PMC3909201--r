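#' Model parameters for the frustrated Go-like potential
#'
#' All energies are in reduced units of \eqn{\epsilon} (the uniform native
#' contact depth before Miyazawa--Jernigan flavouring), lengths in Angstrom,
#' and \eqn{k_B = 1} so temperatures are in \eqn{\epsilon}.
#'
#' The potential is the standard C-alpha Go-model Hamiltonian: harmonic bonds
#' and angles, a 1+3 cosine dihedral term, a 12--10 Lennard-Jones well per
#' native contact (depth \eqn{e_{ij}\epsilon}, minimum at the native distance),
#' and a \eqn{(\sigma/r)^{12}} repulsion for all other remote pairs.  When
#' `frustration = TRUE`, non-native hydrophobic pairs are removed from the
#' repulsion list and instead feel a 12--6 Lennard-Jones well of depth
#' `eps_f` with its minimum at `c_f` (5.5 Angstrom, the native-contact
#' detection cutoff) -- the energetic-frustration term.
#'
#' @param epsilon Reduced energy unit (leave at 1).
#' @param k_bond Bond stiffness, \eqn{\epsilon/\mathrm{\AA}^2} (energy is
#'   \eqn{K_b (r - r_0)^2}, no 1/2 factor).
#' @param k_angle Angle stiffness, \eqn{\epsilon/\mathrm{rad}^2}.
#' @param k_dih1,k_dih3 Dihedral coefficients for
#'   \eqn{K_1[1-\cos(\phi-\phi_0)] + K_3[1-\cos 3(\phi-\phi_0)]}.
#' @param sigma_rep Repulsion length scale, Angstrom.
#' @param eps_f Depth of the non-native hydrophobic attraction, \eqn{\epsilon}.
#' @param c_f Location of the frustration-well minimum, Angstrom.
#' @param frustration Logical; switch the frustration term on or off.  Off,
#'   hydrophobic non-native pairs are ordinary repulsive pairs (the
#'   conventional Go model).
#' @param contact_form `"12-10"` (default, Go-model convention) or `"12-6"`
#'   for the native-contact well.
#' @param kept_lambda Tolerance factor for the contact-kept criterion: a
#'   native contact is counted as formed when \eqn{r \le \lambda r_0}.
#' @return An object of class `cg_params` (a validated list).
#' @export
cg_params <- function(epsilon = 1, k_bond = 100, k_angle = 20,
                      k_dih1 = 1, k_dih3 = 0.5, sigma_rep = 4.0,
                      eps_f = 0.2, c_f = 5.5, frustration = FALSE,
                      contact_form = c("12-10", "12-6"),
                      kept_lambda = 1.2) {
  contact_form <- match.arg(contact_form)
  p <- list(epsilon = epsilon, k_bond = k_bond, k_angle = k_angle,
            k_dih1 = k_dih1, k_dih3 = k_dih3, sigma_rep = sigma_rep,
            eps_f = eps_f, c_f = c_f, frustration = isTRUE(frustration),
            contact_form = contact_form, kept_lambda = kept_lambda)
  stopifnot(p$epsilon > 0, p$k_bond > 0, p$k_angle > 0,
            p$sigma_rep > 0, p$eps_f >= 0, p$c_f > 0, p$kept_lambda > 1)
  structure(p, class = "cg_params")
}

#' @export
print.cg_params <- function(x, ...) {
  cat("<cg_params> reduced units (k_B = 1)\n")
  cat(sprintf("  bonds K=%g  angles K=%g  dihedrals K1=%g K3=%g\n",
              x$k_bond, x$k_angle, x$k_dih1, x$k_dih3))
  cat(sprintf("  native contacts: %s well, depth e_ij*eps\n", x$contact_form))
  cat(sprintf("  repulsion sigma=%g A; frustration %s (eps_f=%g, c_f=%g A)\n",
              x$sigma_rep, if (x$frustration) "ON" else "off",
              x$eps_f, x$c_f))
  cat(sprintf("  contact kept when r <= %g * r0\n", x$kept_lambda))
  invisible(x)
}

#' Langevin dynamics configuration
#'
#' @param temperature Bath temperature in reduced units (\eqn{k_B = 1}).
#' @param n_steps Total number of integration steps.
#' @param dt Time step in reduced time units \eqn{\tau}.
#' @param gamma Friction coefficient, \eqn{1/\tau}.
#' @param mass Bead mass (reduced; 1 by convention).
#' @param stride Thinning stride: one snapshot (coordinates, temperature,
#'   per-contact kept flags, Q) is stored every `stride` steps.
#' @param seed Integer seed; together with the topology and parameters it
#'   fully determines the trajectory.
#' @return An object of class `cg_sim_config`.
#' @export
sim_config <- function(temperature, n_steps, dt = 0.005, gamma = 1,
                       mass = 1, stride = 100L, seed = 1L) {
  stopifnot(dt > 0, gamma > 0, temperature > 0, mass > 0,
            n_steps >= 1, stride >= 1)
  structure(list(temperature = temperature, n_steps = as.double(n_steps),
                 dt = dt, gamma = gamma, mass = mass,
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "cg_sim_config")
}

#' Variable-temperature protocol configuration
#'
#' Every `n_t` steps the cumulative histogram of the native-contact count Q
#' (bin width `bin_width`, normally 1) is examined; the temperature moves by
#' `delta_t` toward equalising the heights of the folded and unfolded peaks
#' (down when the unfolded peak is higher, up when the folded peak is higher,
#' at random when they tie).
#'
#' @param t_init Initial (guessed) transition temperature, reduced units.
#' @param delta_t Temperature increment per adjustment window.  `delta_t = 0`
#'   degenerates to a constant-temperature run (the controller is bypassed).
#' @param n_t Steps per adjustment window (>= 1000).
#' @param bin_width Histogram bin width in native-contact counts.
#' @param burn_in Fraction of initial windows discarded when averaging the
#'   temperature trace into the transition-temperature estimate.
#' @param cumulative Use the cumulative (up-to-now) trajectory histogram
#'   (default) or only the most recent window (`FALSE`).
#' @return An object of class `cg_vt_config`.
#' @export
vt_config <- function(t_init = 0.3, delta_t = 0.002, n_t = 10000L,
                      bin_width = 1L, burn_in = 0.3, cumulative = TRUE) {
  stopifnot(t_init > 0, delta_t >= 0, n_t >= 1000, bin_width >= 1,
            burn_in >= 0, burn_in < 1)
  structure(list(t_init = t_init, delta_t = delta_t, n_t = as.integer(n_t),
                 bin_width = as.integer(bin_width), burn_in = burn_in,
                 cumulative = isTRUE(cumulative)),
            class = "cg_vt_config")
}

#' Default hydrophobic residue set
#'
#' Three-letter codes of the residues treated as hydrophobic when building
#' the non-native frustration pair list (Kyte--Doolittle-positive core).
#' @return Character vector of 3-letter codes.
#' @export
hydrophobic_residues <- function() {
  c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "CYS")
}
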