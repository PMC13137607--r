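# MMFF94 intramolecular energy. All seven terms of the original
# formulation, evaluated as vectorized pure-R kernels over an
# `mmff_params` table set. Energies in kcal/mol, coordinates in Angstrom.

# unit-bridging constants of the MMFF94 functional forms
MDYNE_A_TO_KCAL <- 143.9325          # md/A -> kcal/mol/A^2 energy prefactor
DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi
ANGLE_PREF <- MDYNE_A_TO_KCAL * DEG2RAD^2    # 0.043844
SB_PREF <- MDYNE_A_TO_KCAL * DEG2RAD         # 2.51210
CS_CUBIC <- -2.0                     # cubic bond-stretch constant, 1/A
CB_CUBIC <- -0.006981317                   # cubic angle-bend constant, 1/deg
COULOMB_K <- 332.0716                # e^2/A -> kcal/mol
COULOMB_DELTA <- 0.05                # electrostatic buffering, A
R_EPS <- 1e-12                       # distance guard for degenerate input

pair_dist <- function(coords, i, j) {
  d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  pmax(sqrt(rowSums(d * d)), R_EPS)
}

# interior angle i-j-k at j, radians; returns list(theta, cos, sin, a, b,
# la, lb) for reuse by gradients
angle_geometry <- function(coords, i, j, k) {
  a <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  b <- coords[k, , drop = FALSE] - coords[j, , drop = FALSE]
  la <- pmax(sqrt(rowSums(a * a)), R_EPS)
  lb <- pmax(sqrt(rowSums(b * b)), R_EPS)
  cth <- pmin(pmax(rowSums(a * b) / (la * lb), -1), 1)
  list(theta = acos(cth), cth = cth,
       sth = sqrt(pmax(1 - cth^2, 1e-16)),
       a = a, b = b, la = la, lb = lb)
}

e_bond <- function(coords, B) {
  if (nrow(B) == 0) return(0)
  dr <- pair_dist(coords, B[, 1], B[, 2]) - B[, 4]
  sum((MDYNE_A_TO_KCAL / 2) * B[, 3] * dr^2 *
        (1 + CS_CUBIC * dr + (7 / 12) * CS_CUBIC^2 * dr^2))
}

e_angle <- function(coords, A) {
  if (nrow(A) == 0) return(0)
  g <- angle_geometry(coords, A[, 1], A[, 2], A[, 3])
  lin <- A[, 6] > 0.5
  e <- numeric(nrow(A))
  if (any(!lin)) {
    dt <- g$theta[!lin] * RAD2DEG - A[!lin, 5]
    e[!lin] <- (ANGLE_PREF / 2) * A[!lin, 4] * dt^2 * (1 + CB_CUBIC * dt)
  }
  if (any(lin)) {
    e[lin] <- MDYNE_A_TO_KCAL * A[lin, 4] * (1 + g$cth[lin])
  }
  sum(e)
}

e_stretch_bend <- function(coords, S) {
  if (nrow(S) == 0) return(0)
  dr1 <- pair_dist(coords, S[, 1], S[, 2]) - S[, 6]
  dr2 <- pair_dist(coords, S[, 3], S[, 2]) - S[, 7]
  g <- angle_geometry(coords, S[, 1], S[, 2], S[, 3])
  dt <- g$theta * RAD2DEG - S[, 8]
  sum(SB_PREF * (S[, 4] * dr1 + S[, 5] * dr2) * dt)
}

# Wilson out-of-plane angle chi for term (i, j, k; l), center j: the angle
# between bond j-l and the plane i-j-k.
oop_geometry <- function(coords, i, j, k, l) {
  u <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  v <- coords[k, , drop = FALSE] - coords[j, , drop = FALSE]
  w <- coords[l, , drop = FALSE] - coords[j, , drop = FALSE]
  lu <- pmax(sqrt(rowSums(u * u)), R_EPS)
  lv <- pmax(sqrt(rowSums(v * v)), R_EPS)
  lw <- pmax(sqrt(rowSums(w * w)), R_EPS)
  cth <- pmin(pmax(rowSums(u * v) / (lu * lv), -1), 1)
  sth <- sqrt(pmax(1 - cth^2, 1e-16))
  uxv <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  s <- pmin(pmax(rowSums(uxv * w) / (lu * lv * lw * sth), -1), 1)
  list(u = u, v = v, w = w, lu = lu, lv = lv, lw = lw,
       cth = cth, sth = sth, uxv = uxv, s = s, chi = asin(s))
}

e_oop <- function(coords, O) {
  if (nrow(O) == 0) return(0)
  g <- oop_geometry(coords, O[, 1], O[, 2], O[, 3], O[, 4])
  chi_deg <- g$chi * RAD2DEG
  sum((ANGLE_PREF / 2) * O[, 5] * chi_deg^2)
}

# signed dihedral i-j-k-l, radians, and intermediates for the gradient
torsion_geometry <- function(coords, i, j, k, l) {
  b1 <- coords[j, , drop = FALSE] - coords[i, , drop = FALSE]
  b2 <- coords[k, , drop = FALSE] - coords[j, , drop = FALSE]
  b3 <- coords[l, , drop = FALSE] - coords[k, , drop = FALSE]
  cross <- function(x, y) cbind(x[, 2] * y[, 3] - x[, 3] * y[, 2],
                                x[, 3] * y[, 1] - x[, 1] * y[, 3],
                                x[, 1] * y[, 2] - x[, 2] * y[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  lb2 <- pmax(sqrt(rowSums(b2 * b2)), R_EPS)
  phi <- atan2(rowSums(cross(n1, n2) * b2) / lb2, rowSums(n1 * n2))
  list(b1 = b1, b2 = b2, b3 = b3, n1 = n1, n2 = n2, lb2 = lb2, phi = phi)
}

e_torsion <- function(coords, Tt) {
  if (nrow(Tt) == 0) return(0)
  phi <- torsion_geometry(coords, Tt[, 1], Tt[, 2], Tt[, 3], Tt[, 4])$phi
  sum(0.5 * (Tt[, 5] * (1 + cos(phi)) + Tt[, 6] * (1 - cos(2 * phi)) +
               Tt[, 7] * (1 + cos(3 * phi))))
}

# buffered 14-7 van der Waals, scalar kernel shared by intra and cross terms
vdw_pair_energy <- function(r, rstar, eps) {
  a <- (1.07 * rstar / (r + 0.07 * rstar))^7
  b <- 1.12 * rstar^7 / (r^7 + 0.12 * rstar^7)
  eps * a * (b - 2)
}

vdw_pair_dEdr <- function(r, rstar, eps) {
  a <- (1.07 * rstar / (r + 0.07 * rstar))^7
  da <- -7 * a / (r + 0.07 * rstar)
  denom <- r^7 + 0.12 * rstar^7
  b <- 1.12 * rstar^7 / denom
  db <- -1.12 * rstar^7 * 7 * r^6 / denom^2
  eps * (da * (b - 2) + a * db)
}

# buffered Coulomb, distance exponent 1
coulomb_pair_energy <- function(r, qq, dielectric = 1,
                                delta = COULOMB_DELTA) {
  COULOMB_K * qq / (dielectric * (r + delta))
}

coulomb_pair_dEdr <- function(r, qq, dielectric = 1,
                              delta = COULOMB_DELTA) {
  -COULOMB_K * qq / (dielectric * (r + delta)^2)
}

e_vdw <- function(coords, V) {
  if (nrow(V) == 0) return(0)
  r <- pair_dist(coords, V[, 1], V[, 2])
  sum(vdw_pair_energy(r, V[, 3], V[, 4]))
}

e_elec <- function(coords, E, charges, dielectric = 1) {
  if (nrow(E) == 0) return(0)
  r <- pair_dist(coords, E[, 1], E[, 2])
  qq <- charges[E[, 1]] * charges[E[, 2]] * E[, 3]
  sum(coulomb_pair_energy(r, qq, dielectric))
}

new_energy_breakdown <- function(bond = 0, angle = 0, stretch_bend = 0,
                                 oop = 0, torsion = 0, vdw = 0,
                                 electrostatic = 0, cross_vdw = 0,
                                 cross_electrostatic = 0) {
  x <- list(bond = bond, angle = angle, stretch_bend = stretch_bend,
            oop = oop, torsion = torsion, vdw = vdw,
            electrostatic = electrostatic, cross_vdw = cross_vdw,
            cross_electrostatic = cross_electrostatic)
  x$total <- sum(unlist(x))
  structure(x, class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("MMFF94 energy breakdown (kcal/mol)\n")
  for (f in setdiff(names(x), "total")) {
    if (!(f %in% c("cross_vdw", "cross_electrostatic")) || x[[f]] != 0) {
      cat(sprintf("  %-20s %12.6f\n", f, x[[f]]))
    }
  }
  cat(sprintf("  %-20s %12.6f\n", "total", x$total))
  invisible(x)
}

check_coords <- function(coords, params) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != params$natoms || ncol(coords) != 3) {
    stop("coords must be ", params$natoms, " x 3 to match the parameter set")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  coords
}

#' Intramolecular MMFF94 energy
#'
#' Evaluates the seven MMFF94 terms (cubic bond stretch, cubic-corrected
#' angle bend with a linear-angle special case, stretch-bend coupling,
#' Wilson out-of-plane bend, 3-fold torsion cosine series, buffered 14-7
#' van der Waals, buffered Coulomb with 0.75 scaling on 1-4 pairs) at the
#' supplied coordinates.
#'
#' @param coords Numeric N x 3 coordinate matrix, Angstrom.
#' @param params An [parameterize()]d `mmff_params` object for the same
#'   molecule.
#' @param dielectric Dielectric constant for the electrostatic term.
#' @return An `energy_breakdown`: per-term energies plus `total`, kcal/mol.
#' @export
energy_intra <- function(coords, params, dielectric = 1) {
  coords <- check_coords(coords, params)
  new_energy_breakdown(
    bond = e_bond(coords, params$bonds),
    angle = e_angle(coords, params$angles),
    stretch_bend = e_stretch_bend(coords, params$stretch_bends),
    oop = e_oop(coords, params$oops),
    torsion = e_torsion(coords, params$torsions),
    vdw = e_vdw(coords, params$vdw_pairs),
    electrostatic = e_elec(coords, params$elec_pairs, params$charges,
                           dielectric))
}
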