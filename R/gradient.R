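# Analytic gradients of the MMFF94 terms with respect to Cartesian
# coordinates. Each kernel returns dE/dx accumulated into an N x 3 matrix;
# correctness is pinned to central finite differences in the test suite.

accumulate <- function(grad, idx, contrib) {
  # rowsum-based scatter-add: contrib is length(idx) x 3
  agg <- rowsum(contrib, group = idx)
  rows <- as.integer(rownames(agg))
  grad[rows, ] <- grad[rows, , drop = FALSE] + agg
  grad
}

unit_diff <- function(coords, i, j) {
  d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  r <- pmax(sqrt(rowSums(d * d)), R_EPS)
  list(u = d / r, r = r)
}

g_bond <- function(grad, coords, B) {
  if (nrow(B) == 0) return(grad)
  ud <- unit_diff(coords, B[, 1], B[, 2])
  dr <- ud$r - B[, 4]
  dEdr <- (MDYNE_A_TO_KCAL / 2) * B[, 3] *
    (2 * dr + 3 * CS_CUBIC * dr^2 + 4 * (7 / 12) * CS_CUBIC^2 * dr^3)
  grad <- accumulate(grad, B[, 1], dEdr * ud$u)
  accumulate(grad, B[, 2], -dEdr * ud$u)
}

# d(theta)/dx for angle i-j-k (theta in radians); g from angle_geometry()
angle_dtheta <- function(g) {
  ah <- g$a / g$la
  bh <- g$b / g$lb
  sth <- pmax(g$sth, 1e-8)
  di <- (g$cth * ah - bh) / (g$la * sth)
  dk <- (g$cth * bh - ah) / (g$lb * sth)
  list(di = di, dk = dk, dj = -(di + dk))
}

g_angle <- function(grad, coords, A) {
  if (nrow(A) == 0) return(grad)
  g <- angle_geometry(coords, A[, 1], A[, 2], A[, 3])
  lin <- A[, 6] > 0.5
  dEdtheta <- numeric(nrow(A))  # per radian
  if (any(!lin)) {
    dt <- g$theta[!lin] * RAD2DEG - A[!lin, 5]
    dEdtheta[!lin] <- (ANGLE_PREF / 2) * A[!lin, 4] *
      (2 * dt + 3 * CB_CUBIC * dt^2) * RAD2DEG
  }
  if (any(lin)) {
    # E = k (1 + cos theta): dE/dtheta = -k sin theta
    dEdtheta[lin] <- -MDYNE_A_TO_KCAL * A[lin, 4] * g$sth[lin]
  }
  dth <- angle_dtheta(g)
  grad <- accumulate(grad, A[, 1], dEdtheta * dth$di)
  grad <- accumulate(grad, A[, 2], dEdtheta * dth$dj)
  accumulate(grad, A[, 3], dEdtheta * dth$dk)
}

g_stretch_bend <- function(grad, coords, S) {
  if (nrow(S) == 0) return(grad)
  u1 <- unit_diff(coords, S[, 1], S[, 2])
  u2 <- unit_diff(coords, S[, 3], S[, 2])
  dr1 <- u1$r - S[, 6]
  dr2 <- u2$r - S[, 7]
  g <- angle_geometry(coords, S[, 1], S[, 2], S[, 3])
  dt <- g$theta * RAD2DEG - S[, 8]
  dth <- angle_dtheta(g)
  # E = SB_PREF (k1 dr1 + k2 dr2) dt
  dEddr1 <- SB_PREF * S[, 4] * dt
  dEddr2 <- SB_PREF * S[, 5] * dt
  dEdtheta <- SB_PREF * (S[, 4] * dr1 + S[, 5] * dr2) * RAD2DEG  # per rad
  grad <- accumulate(grad, S[, 1], dEddr1 * u1$u + dEdtheta * dth$di)
  grad <- accumulate(grad, S[, 3], dEddr2 * u2$u + dEdtheta * dth$dk)
  accumulate(grad, S[, 2],
             -dEddr1 * u1$u - dEddr2 * u2$u + dEdtheta * dth$dj)
}

cross3 <- function(x, y) {
  cbind(x[, 2] * y[, 3] - x[, 3] * y[, 2],
        x[, 3] * y[, 1] - x[, 1] * y[, 3],
        x[, 1] * y[, 2] - x[, 2] * y[, 1])
}

g_oop <- function(grad, coords, O) {
  if (nrow(O) == 0) return(grad)
  g <- oop_geometry(coords, O[, 1], O[, 2], O[, 3], O[, 4])
  chi_deg <- g$chi * RAD2DEG
  # dE/dchi (radians)
  dEdchi <- ANGLE_PREF * O[, 5] * chi_deg * RAD2DEG
  # chi = asin(s), s = [(u x v) . w] / (lu lv lw sin(theta_uv))
  dchids <- 1 / sqrt(pmax(1 - g$s^2, 1e-10))
  Tp <- rowSums(g$uxv * g$w)          # scalar triple product
  D <- g$lu * g$lv * g$lw
  sth <- pmax(g$sth, 1e-8)
  uh <- g$u / g$lu; vh <- g$v / g$lv; wh <- g$w / g$lw
  # d(sin theta)/du etc.
  dcth_du <- (vh - g$cth * uh) / g$lu
  dcth_dv <- (uh - g$cth * vh) / g$lv
  dsth_du <- -(g$cth / sth) * dcth_du
  dsth_dv <- -(g$cth / sth) * dcth_dv
  denom <- D * sth
  # ds/du = [ (v x w) denom - T (lv lw uh sth + D dsth_du) ] / denom^2
  ds_du <- (cross3(g$v, g$w) * denom -
              Tp * (g$lv * g$lw * uh * sth + D * dsth_du)) / denom^2
  ds_dv <- (cross3(g$w, g$u) * denom -
              Tp * (g$lu * g$lw * vh * sth + D * dsth_dv)) / denom^2
  ds_dw <- (g$uxv * denom - Tp * (g$lu * g$lv * wh * sth)) / denom^2
  f <- dEdchi * dchids
  gi <- f * ds_du
  gk <- f * ds_dv
  gl <- f * ds_dw
  grad <- accumulate(grad, O[, 1], gi)
  grad <- accumulate(grad, O[, 3], gk)
  grad <- accumulate(grad, O[, 4], gl)
  accumulate(grad, O[, 2], -(gi + gk + gl))
}

g_torsion <- function(grad, coords, Tt) {
  if (nrow(Tt) == 0) return(grad)
  g <- torsion_geometry(coords, Tt[, 1], Tt[, 2], Tt[, 3], Tt[, 4])
  phi <- g$phi
  dEdphi <- 0.5 * (-Tt[, 5] * sin(phi) + 2 * Tt[, 6] * sin(2 * phi) -
                     3 * Tt[, 7] * sin(3 * phi))
  n1sq <- pmax(rowSums(g$n1 * g$n1), R_EPS)
  n2sq <- pmax(rowSums(g$n2 * g$n2), R_EPS)
  lb2 <- g$lb2
  dphi_di <- -(lb2 / n1sq) * g$n1
  dphi_dl <- (lb2 / n2sq) * g$n2
  p <- rowSums(g$b1 * g$b2) / lb2^2
  q <- rowSums(g$b3 * g$b2) / lb2^2
  dphi_dj <- -(1 + p) * dphi_di + q * dphi_dl
  dphi_dk <- p * dphi_di - (1 + q) * dphi_dl
  grad <- accumulate(grad, Tt[, 1], dEdphi * dphi_di)
  grad <- accumulate(grad, Tt[, 2], dEdphi * dphi_dj)
  grad <- accumulate(grad, Tt[, 3], dEdphi * dphi_dk)
  accumulate(grad, Tt[, 4], dEdphi * dphi_dl)
}

g_vdw <- function(grad, coords, V) {
  if (nrow(V) == 0) return(grad)
  ud <- unit_diff(coords, V[, 1], V[, 2])
  dEdr <- vdw_pair_dEdr(ud$r, V[, 3], V[, 4])
  grad <- accumulate(grad, V[, 1], dEdr * ud$u)
  accumulate(grad, V[, 2], -dEdr * ud$u)
}

g_elec <- function(grad, coords, E, charges, dielectric = 1) {
  if (nrow(E) == 0) return(grad)
  ud <- unit_diff(coords, E[, 1], E[, 2])
  qq <- charges[E[, 1]] * charges[E[, 2]] * E[, 3]
  dEdr <- coulomb_pair_dEdr(ud$r, qq, dielectric)
  grad <- accumulate(grad, E[, 1], dEdr * ud$u)
  accumulate(grad, E[, 2], -dEdr * ud$u)
}

#' Gradient of the intramolecular MMFF94 energy
#'
#' Analytic derivative of [energy_intra()] with respect to all Cartesian
#' coordinates.
#'
#' @inheritParams energy_intra
#' @return N x 3 matrix of dE/dx, kcal/mol/Angstrom.
#' @export
gradient_intra <- function(coords, params, dielectric = 1) {
  coords <- check_coords(coords, params)
  grad <- matrix(0, params$natoms, 3)
  grad <- g_bond(grad, coords, params$bonds)
  grad <- g_angle(grad, coords, params$angles)
  grad <- g_stretch_bend(grad, coords, params$stretch_bends)
  grad <- g_oop(grad, coords, params$oops)
  grad <- g_torsion(grad, coords, params$torsions)
  grad <- g_vdw(grad, coords, params$vdw_pairs)
  g_elec(grad, coords, params$elec_pairs, params$charges, dielectric)
}
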