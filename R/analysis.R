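#' Native-contact kept criterion
#'
#' A native contact is counted as formed (kept) in a snapshot when the
#' C-alpha--C-alpha distance satisfies \eqn{r \le \lambda r_0}.
#'
#' @param r Instantaneous C-alpha distance(s), Angstrom.
#' @param r0 Native contact distance(s), Angstrom.
#' @param lambda Tolerance factor (> 1; default 1.2).
#' @return Logical vector.
#' @export
contact_kept <- function(r, r0, lambda = 1.2) {
  stopifnot(lambda > 1)
  r <= lambda * r0
}

#' Extract the Q trace of a trajectory
#'
#' @param traj A `cg_trajectory`.
#' @return A `cg_q_trace`: tibble with `snapshot`, `q_count`, `q_frac`
#'   (count normalised by the total number of native contacts, carried as
#'   attribute `nc`).
#' @export
q_trace <- function(traj) {
  new_q_trace(traj$q, traj$nc)
}

#' Construct a Q trace from raw counts
#' @param q_count Integer vector of native-contact counts per snapshot.
#' @param nc Total number of native contacts.
#' @return A `cg_q_trace`.
#' @export
new_q_trace <- function(q_count, nc) {
  stopifnot(all(q_count >= 0), all(q_count <= nc))
  structure(tibble::tibble(snapshot = seq_along(q_count),
                           q_count = as.integer(q_count),
                           q_frac = q_count / nc),
            nc = as.integer(nc),
            class = c("cg_q_trace", class(tibble::tibble())))
}

as_q_trace <- function(x) {
  if (inherits(x, "cg_q_trace")) x
  else if (inherits(x, "cg_trajectory")) q_trace(x)
  else stop("expected a cg_trajectory or cg_q_trace", call. = FALSE)
}

#' Apparent free-energy profile -ln P(Q)
#'
#' Histograms the native-contact count (bin width 1) and converts it to an
#' apparent free energy \eqn{F(Q) = -k_B T_{avg} \ln P(Q)}, offset so the
#' minimum over populated bins is 0.  For variable-temperature runs,
#' `t_avg` is the averaged transition temperature from the trace.
#'
#' @param q A `cg_trajectory` or `cg_q_trace`.
#' @param t_avg Temperature factor (reduced units).
#' @return A `cg_free_energy`: tibble with `q_count`, `q_frac`, `count`,
#'   `p`, `f` over populated bins only; attribute `t_avg`.
#' @export
free_energy_profile <- function(q, t_avg) {
  q <- as_q_trace(q)
  nc <- attr(q, "nc")
  counts <- tabulate(q$q_count + 1L, nbins = nc + 1L)
  pop <- which(counts > 0) - 1L
  if (length(pop) == 1L)
    warning("degenerate profile: all snapshots in a single Q bin")
  p <- counts[pop + 1L] / sum(counts)
  f <- -t_avg * log(p)
  structure(tibble::tibble(q_count = pop, q_frac = pop / nc,
                           count = counts[pop + 1L], p = p,
                           f = f - min(f)),
            t_avg = t_avg, nc = nc,
            class = c("cg_free_energy", class(tibble::tibble())))
}

## two-peak/valley search over smoothed Q-count histogram counts
find_barrier <- function(counts) {
  nb <- length(counts)
  if (nb < 3) return(NULL)
  sm <- vapply(seq_len(nb), function(k)
    mean(counts[max(1, k - 1):min(nb, k + 1)]), 0)
  left <- c(-Inf, sm[-nb]); right <- c(sm[-1], -Inf)
  locmax <- which(sm > left & sm >= right)
  locmax <- locmax[sm[locmax] > 0]
  if (length(locmax) < 2) return(NULL)
  ord <- locmax[order(sm[locmax], decreasing = TRUE)]
  two <- sort(ord[1:2])
  between <- seq.int(two[1], two[2])
  ## flat (e.g. unpopulated) valleys: take the minimum closest to the
  ## midpoint between the peaks
  cand <- between[sm[between] == min(sm[between])]
  valley <- cand[which.min(abs(cand - mean(two)))]
  if (valley == two[1] || valley == two[2]) return(NULL)
  list(p_lo = two[1], p_hi = two[2], valley = valley, smoothed = sm)
}

#' Select the transition-state ensemble from a bimodal Q distribution
#'
#' Finds the folded and unfolded peaks of P(Q) and the valley between them
#' (the apparent free-energy barrier), then selects the snapshots whose
#' Q falls in the barrier region: bins strictly between the two peaks with
#' \eqn{F(Q) \ge F(\mathrm{valley}) - \delta}.
#'
#' @param x A `cg_trajectory` (preferred; the selection then carries the
#'   per-contact kept flags needed for phi-values) or a `cg_q_trace`.
#' @param t_avg Temperature factor used for the free-energy scale.
#' @param delta Band below the barrier top included in the TSE, in energy
#'   units (default `0.5 * t_avg`).
#' @return A `cg_tse`: list with `indices` (snapshot numbers), `window`
#'   (inclusive Q-count range), `peaks`, `valley`, `kept` (logical matrix,
#'   only when `x` is a trajectory), `t_avg`, `delta`.
#' @export
select_tse <- function(x, t_avg, delta = 0.5 * t_avg) {
  q <- as_q_trace(x)
  nc <- attr(q, "nc")
  counts <- tabulate(q$q_count + 1L, nbins = nc + 1L)
  bar <- find_barrier(counts)
  if (is.null(bar))
    stop("selection error: P(Q) is not bimodal (no valley between two peaks); ",
         "adjust the temperature protocol or frustration strength",
         call. = FALSE)
  qvals <- seq(0L, nc)
  p <- counts / sum(counts)
  f <- ifelse(counts > 0, -t_avg * log(p), Inf)
  f <- f - min(f[is.finite(f)])
  between <- seq.int(bar$p_lo + 1L, bar$p_hi - 1L)
  ## barrier top = highest apparent free energy among populated bins
  ## between the peaks (the valley bin itself may be unpopulated)
  f_barrier <- max(f[between][is.finite(f[between])])
  sel_bins <- between[is.finite(f[between]) & f[between] >= f_barrier - delta]
  idx <- q$snapshot[q$q_count %in% qvals[sel_bins]]
  if (length(idx) == 0)
    stop("selection error: empty TSE window", call. = FALSE)
  out <- list(indices = idx,
              window = range(qvals[sel_bins]),
              peaks = qvals[c(bar$p_lo, bar$p_hi)],
              valley = qvals[bar$valley],
              t_avg = t_avg, delta = delta,
              kept = NULL)
  if (inherits(x, "cg_trajectory"))
    out$kept <- x$kept[idx, , drop = FALSE]
  structure(out, class = "cg_tse")
}

#' @export
print.cg_tse <- function(x, ...) {
  cat(sprintf("<cg_tse> %d snapshots, Q window [%d, %d] (peaks %d/%d, valley %d)\n",
              length(x$indices), x$window[1], x$window[2],
              x$peaks[1], x$peaks[2], x$valley))
  invisible(x)
}

#' Build a TSE from an explicit Q window
#'
#' Selects the snapshots of a trajectory whose native-contact count falls
#' in a caller-specified window.  This supports transferring a barrier
#' window identified on one ensemble (e.g. the bimodal cumulative
#' histogram of a variable-temperature run) onto another ensemble of the
#' same system (e.g. a constant-temperature run whose own fixed-T
#' histogram is too shallow to resolve the valley) -- both ensembles are
#' then probed over the same barrier region.
#'
#' @param traj A `cg_trajectory`.
#' @param window Length-2 integer vector: inclusive Q-count range.
#' @param t_avg Temperature factor recorded on the selection.
#' @return A `cg_tse` with kept flags for the selected snapshots.
#' @export
tse_from_window <- function(traj, window, t_avg = NA_real_) {
  stopifnot(inherits(traj, "cg_trajectory"), length(window) == 2)
  idx <- which(traj$q >= window[1] & traj$q <= window[2])
  if (length(idx) == 0)
    stop("selection error: no snapshots in the requested Q window",
         call. = FALSE)
  structure(list(indices = idx, window = as.integer(window),
                 peaks = c(NA_integer_, NA_integer_),
                 valley = NA_integer_, t_avg = t_avg, delta = NA_real_,
                 kept = traj$kept[idx, , drop = FALSE]),
            class = "cg_tse")
}

tse_kept <- function(tse) {
  if (is.matrix(tse)) return(tse)
  if (inherits(tse, "cg_tse")) {
    if (is.null(tse$kept))
      stop("input error: TSE carries no kept flags (was it selected from a ",
           "q-trace instead of a trajectory?)", call. = FALSE)
    return(tse$kept)
  }
  stop("expected a cg_tse or a logical kept matrix", call. = FALSE)
}

#' Residue phi-values over a transition-state ensemble
#'
#' \eqn{\phi_i = \langle N_i \rangle_{TSE} / N_i^{native}}, where
#' \eqn{N_i} counts the kept native contacts incident on residue i in a
#' TSE snapshot and the denominator is the native per-residue contact
#' count.  \eqn{\phi_i = 1} means the residue is as structured at the
#' barrier as in the native state; 0 means fully unfolded there.  Residues
#' with no native contacts have undefined phi (`NA`), excluded from
#' averages downstream.
#'
#' @param tse A `cg_tse` from [select_tse()] on a trajectory, or a logical
#'   snapshots-by-contacts kept matrix.
#' @param topo The `cg_topology` the trajectory was run with.
#' @return A `cg_phi_profile`: tibble with `residue`, `n_native`, `phi`;
#'   attribute `tse_size`.
#' @export
phi_values <- function(tse, topo) {
  kept <- tse_kept(tse)
  if (nrow(kept) == 0) stop("input error: empty TSE", call. = FALSE)
  ct <- topo$contacts
  if (ncol(kept) != nrow(ct))
    stop("input error: kept-flag matrix does not match the contact list",
         call. = FALSE)
  n <- topo$n
  n_native <- tabulate(c(ct$i, ct$j), nbins = n)
  mean_kept <- colMeans(kept)
  n_tse <- numeric(n)
  for (k in seq_len(nrow(ct))) {
    n_tse[ct$i[k]] <- n_tse[ct$i[k]] + mean_kept[k]
    n_tse[ct$j[k]] <- n_tse[ct$j[k]] + mean_kept[k]
  }
  phi <- ifelse(n_native > 0, n_tse / n_native, NA_real_)
  structure(tibble::tibble(residue = seq_len(n), n_native = n_native,
                           phi = phi),
            tse_size = nrow(kept),
            class = c("cg_phi_profile", class(tibble::tibble())))
}

#' Compare two phi-profiles
#'
#' Pearson correlation and per-residue increments between two phi-profiles
#' over the same chain (e.g. conventional vs frustrated model, or
#' constant-T vs variable-T protocol).  Residues with undefined phi in
#' either profile are excluded pairwise.
#'
#' @param a,b `cg_phi_profile` objects with the same residue count.
#'   Increments are `b - a`.
#' @return A `cg_phi_comparison`: list with `table` (tibble `residue`,
#'   `phi_a`, `phi_b`, `increment`), `r`, `mean_increment`,
#'   `sd_increment`, `n_defined`.
#' @export
compare_phi <- function(a, b) {
  if (nrow(a) != nrow(b))
    stop("input error: profiles have different residue counts", call. = FALSE)
  tab <- tibble::tibble(residue = a$residue, phi_a = a$phi, phi_b = b$phi,
                        increment = b$phi - a$phi)
  ok <- stats::complete.cases(tab)
  if (sum(ok) < 3)
    stop("input error: fewer than 3 residues with defined phi in both profiles",
         call. = FALSE)
  structure(list(table = tab,
                 r = stats::cor(tab$phi_a[ok], tab$phi_b[ok]),
                 mean_increment = mean(tab$increment[ok]),
                 sd_increment = stats::sd(tab$increment[ok]),
                 n_defined = sum(ok)),
            class = "cg_phi_comparison")
}

#' @export
print.cg_phi_comparison <- function(x, ...) {
  cat(sprintf("<cg_phi_comparison> %d residues: Pearson r = %.2f, mean increment %.2f (sd %.2f)\n",
              x$n_defined, x$r, x$mean_increment, x$sd_increment))
  invisible(x)
}

#' Per-contact change in native-state probability between two TSEs
#'
#' The native-state probability of a contact in a TSE is the fraction of
#' TSE snapshots in which it is kept.  Returns `prob_b - prob_a` per
#' contact (e.g. b = frustrated model, a = conventional), the quantity the
#' representative-contact-number tables are built from.
#'
#' @param tse_a,tse_b `cg_tse` objects (or kept matrices) over the same
#'   contact list.
#' @param topo The shared `cg_topology`.
#' @return Tibble with `i`, `j`, `prob_a`, `prob_b`, `dprob`.
#' @export
contact_probability_increase <- function(tse_a, tse_b, topo) {
  ka <- tse_kept(tse_a); kb <- tse_kept(tse_b)
  m <- nrow(topo$contacts)
  if (ncol(ka) != m || ncol(kb) != m)
    stop("input error: contact-list mismatch between TSEs and topology",
         call. = FALSE)
  if (nrow(ka) == 0 || nrow(kb) == 0)
    stop("input error: empty TSE", call. = FALSE)
  tibble::tibble(i = topo$contacts$i, j = topo$contacts$j,
                 prob_a = colMeans(ka), prob_b = colMeans(kb),
                 dprob = colMeans(kb) - colMeans(ka))
}

#' Representative native-contact numbers by secondary-structure pair
#'
#' For each unordered pair of secondary-structure elements and each
#' threshold p, counts the native contacts between the two elements whose
#' native-state probability increased by at least p (`h`).  Because table
#' entries with probability *decreases* are also of interest, a signed
#' variant is reported too: `h_signed = #\{dprob >= p\} - #\{dprob <= -p\}`.
#'
#' @param dprob Tibble from [contact_probability_increase()].
#' @param topo The `cg_topology`.
#' @param ss A [ss_map()] covering the chain.
#' @param thresholds Numeric vector of probability thresholds in (0, 1).
#' @return A `cg_hp_table`: tibble with `element_a`, `element_b` (in map
#'   order, a before b), `p`, `h`, `h_signed`; attribute `elements`.
#' @export
h_p_table <- function(dprob, topo, ss, thresholds = c(0.05, 0.10)) {
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  el_i <- ss_element_of(ss, dprob$i)
  el_j <- ss_element_of(ss, dprob$j)
  ord <- match(el_i, ss$label) <= match(el_j, ss$label)
  ea <- ifelse(ord, el_i, el_j)
  eb <- ifelse(ord, el_j, el_i)
  cells <- expand.grid(ai = seq_len(nrow(ss)), bi = seq_len(nrow(ss)))
  cells <- cells[cells$ai <= cells$bi, ]
  out <- do.call(rbind, lapply(thresholds, function(p) {
    up <- dprob$dprob >= p
    dn <- dprob$dprob <= -p
    h <- mapply(function(ai, bi) {
      in_cell <- ea == ss$label[ai] & eb == ss$label[bi]
      sum(up & in_cell)
    }, cells$ai, cells$bi)
    hs <- mapply(function(ai, bi) {
      in_cell <- ea == ss$label[ai] & eb == ss$label[bi]
      sum(up & in_cell) - sum(dn & in_cell)
    }, cells$ai, cells$bi)
    tibble::tibble(element_a = ss$label[cells$ai],
                   element_b = ss$label[cells$bi],
                   p = p, h = as.integer(h), h_signed = as.integer(hs))
  }))
  structure(tibble::as_tibble(out), elements = ss$label,
            class = c("cg_hp_table", class(tibble::tibble())))
}

#' Per-element totals of a representative-contact-number table
#'
#' Sums each element's cells over all partners (the diagonal cell counted
#' once), mirroring the "Total" row of the per-domain tables.
#'
#' @param hp A `cg_hp_table`.
#' @return Tibble with `element`, `p`, `h`, `h_signed`.
#' @export
h_p_totals <- function(hp) {
  els <- attr(hp, "elements")
  do.call(rbind, lapply(unique(hp$p), function(pv) {
    sub <- hp[hp$p == pv, ]
    tibble::tibble(
      element = els, p = pv,
      h = vapply(els, function(e)
        sum(sub$h[sub$element_a == e | sub$element_b == e]), 0L,
        USE.NAMES = FALSE),
      h_signed = vapply(els, function(e)
        sum(sub$h_signed[sub$element_a == e | sub$element_b == e]), 0L,
        USE.NAMES = FALSE))
  }))
}
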