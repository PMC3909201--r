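## Independent R reference implementation of every energy term, used as the
## oracle for the compiled kernels (values + finite-difference gradients).

ref_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

ref_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

## total reference energy; terms selectable
ref_energy <- function(x, topo, fset = NULL, params = cg_params(),
                       terms = c("bond", "angle", "dihedral",
                                 "native_contact", "repulsion",
                                 "frustration")) {
  n <- topo$n
  e <- 0
  dist_ij <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  if ("bond" %in% terms)
    for (i in seq_len(n - 1))
      e <- e + params$k_bond * (dist_ij(i, i + 1) - topo$r0[i])^2
  if ("angle" %in% terms)
    for (i in seq_len(n - 2))
      e <- e + params$k_angle *
        (ref_angle(x[i, ], x[i + 1, ], x[i + 2, ]) - topo$theta0[i])^2
  if ("dihedral" %in% terms)
    for (i in seq_len(n - 3)) {
      dphi <- ref_dihedral(x[i, ], x[i + 1, ], x[i + 2, ], x[i + 3, ]) -
        topo$phi0[i]
      e <- e + params$k_dih1 * (1 - cos(dphi)) +
        params$k_dih3 * (1 - cos(3 * dphi))
    }
  ct <- topo$contacts
  if ("native_contact" %in% terms && nrow(ct) > 0)
    for (k in seq_len(nrow(ct))) {
      s <- ct$r0[k] / dist_ij(ct$i[k], ct$j[k])
      e <- e + ct$weight[k] * params$epsilon *
        (if (params$contact_form == "12-10") 5 * s^12 - 6 * s^10
         else s^12 - 2 * s^6)
    }
  ## repulsion over all remote pairs not contact / not active frustration
  frus_on <- params$frustration && !is.null(fset) && params$eps_f > 0
  ckey <- paste(ct$i, ct$j)
  fkey <- if (frus_on) paste(fset$pairs$i, fset$pairs$j) else character(0)
  if ("repulsion" %in% terms)
    for (i in seq_len(n - 1)) for (j in seq_len(n)) {
      if (j - i < topo$min_separation) next
      if (j > n) next
      key <- paste(i, j)
      if (key %in% ckey || key %in% fkey) next
      e <- e + params$epsilon * (params$sigma_rep / dist_ij(i, j))^12
    }
  if ("frustration" %in% terms && frus_on)
    for (k in seq_len(nrow(fset$pairs))) {
      s <- params$c_f / dist_ij(fset$pairs$i[k], fset$pairs$j[k])
      e <- e + params$eps_f * (s^12 - 2 * s^6)
    }
  e
}

## central finite-difference force for any scalar energy function
fd_forces <- function(x, efun, h = 1e-5) {
  g <- matrix(0, nrow(x), 3)
  for (i in seq_len(nrow(x))) for (c_ in 1:3) {
    xp <- x; xp[i, c_] <- xp[i, c_] + h
    xm <- x; xm[i, c_] <- xm[i, c_] - h
    g[i, c_] <- -(efun(xp) - efun(xm)) / (2 * h)
  }
  g
}
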