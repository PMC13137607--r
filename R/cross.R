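# Protein-ligand cross-terms: buffered 14-7 van der Waals and buffered
# Coulomb interactions between every ligand atom and every pocket atom.
# No cutoffs, no exclusions, no 1-4 scaling across the interface; the
# pocket is rigid, so gradients are taken with respect to ligand
# coordinates only.

#' Cross-term specification
#'
#' Controls how per-atom nonbonded parameters combine into pair parameters
#' at the ligand-pocket interface, and the electrostatic model.
#'
#' The minimum-energy radius follows the MMFF94 combination rule
#' \eqn{R^*_{ij} = \tfrac12 (R^*_i + R^*_j)(1 + 0.2 (1 - e^{-12\gamma^2}))}
#' with \eqn{\gamma = (R^*_i - R^*_j)/(R^*_i + R^*_j)}; the well depth uses
#' the geometric mean \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}}
#' (the exact MMFF94 well-depth rule needs atomic polarizabilities, which
#' per-atom \eqn{(\epsilon, R^*)} tables do not carry). The Coulomb term
#' uses the same buffering constant as the intramolecular term.
#'
#' @param dielectric Dielectric constant D (unitless, > 0). Default 1.
#' @param buffering_delta Electrostatic distance buffer, Angstrom.
#' @return An object of class `cross_term_spec`.
#' @export
cross_term_spec <- function(dielectric = 1, buffering_delta = COULOMB_DELTA) {
  if (!is.numeric(dielectric) || dielectric <= 0) {
    stop("dielectric must be > 0")
  }
  structure(list(dielectric = dielectric,
                 buffering_delta = buffering_delta),
            class = "cross_term_spec")
}

combine_rstar <- function(ri, rj) {
  gamma <- (ri - rj) / (ri + rj)
  0.5 * (ri + rj) * (1 + 0.2 * (1 - exp(-12 * gamma^2)))
}

cross_pair_tables <- function(ligand_params, pocket) {
  n <- ligand_params$natoms
  m <- nrow(pocket$coords)
  ri <- ligand_params$vdw_self[, 1]
  ei <- ligand_params$vdw_self[, 2]
  rstar <- outer(ri, pocket$vdw_rstar, combine_rstar)
  eps <- sqrt(outer(ei, pocket$vdw_epsilon))
  qq <- outer(ligand_params$charges, pocket$charges)
  list(rstar = rstar, eps = eps, qq = qq, n = n, m = m)
}

check_pocket <- function(pocket) {
  if (is.null(pocket)) stop("pocket is required here; got NULL")
  stopifnot(inherits(pocket, "pocket_structure"))
  if (nrow(pocket$coords) == 0) stop("pocket is empty")
  pocket
}

#' Ligand-pocket interaction energy
#'
#' Sums the buffered 14-7 van der Waals and buffered Coulomb energies over
#' all ligand-atom x pocket-atom pairs.
#'
#' @param ligand_coords N x 3 ligand coordinates, Angstrom.
#' @param ligand_params [parameterize()]d parameters of the ligand.
#' @param pocket A [pocket_structure()]; must be non-empty.
#' @param spec A [cross_term_spec()].
#' @return List with components `vdw` and `elec`, kcal/mol.
#' @export
cross_energy <- function(ligand_coords, ligand_params, pocket,
                         spec = cross_term_spec()) {
  coords <- check_coords(ligand_coords, ligand_params)
  check_pocket(pocket)
  tab <- cross_pair_tables(ligand_params, pocket)
  d <- outer(rowSums(coords^2), rowSums(pocket$coords^2), "+") -
    2 * tcrossprod(coords, pocket$coords)
  r <- sqrt(pmax(d, R_EPS^2))
  e_v <- sum(vdw_pair_energy(r, tab$rstar, tab$eps))
  e_q <- sum(COULOMB_K * tab$qq / (spec$dielectric *
                                     (r + spec$buffering_delta)))
  list(vdw = e_v, elec = e_q)
}

cross_gradient <- function(ligand_coords, ligand_params, pocket,
                           spec = cross_term_spec()) {
  coords <- check_coords(ligand_coords, ligand_params)
  check_pocket(pocket)
  tab <- cross_pair_tables(ligand_params, pocket)
  grad <- matrix(0, tab$n, 3)
  d2 <- outer(rowSums(coords^2), rowSums(pocket$coords^2), "+") -
    2 * tcrossprod(coords, pocket$coords)
  r <- sqrt(pmax(d2, R_EPS^2))
  dEdr <- vdw_pair_dEdr(r, tab$rstar, tab$eps) -
    COULOMB_K * tab$qq / (spec$dielectric *
                            (r + spec$buffering_delta)^2)
  w <- dEdr / r                     # N x M
  for (axis in 1:3) {
    diff <- outer(coords[, axis], pocket$coords[, axis], "-")
    grad[, axis] <- rowSums(w * diff)
  }
  grad
}

#' Total (protein-conditioned) energy
#'
#' The extended potential: intramolecular MMFF94 energy of the ligand plus,
#' when a pocket is supplied, the ligand-pocket van der Waals and
#' electrostatic cross-terms. With `pocket = NULL` this is exactly
#' [energy_intra()].
#'
#' @inheritParams cross_energy
#' @param pocket A [pocket_structure()] or `NULL` for an unconditioned
#'   (gas-phase) evaluation.
#' @return An `energy_breakdown` with `cross_vdw` and `cross_electrostatic`
#'   filled in (zero when no pocket is supplied).
#' @export
total_energy <- function(ligand_coords, ligand_params, pocket = NULL,
                         spec = cross_term_spec()) {
  intra <- energy_intra(ligand_coords, ligand_params,
                        dielectric = spec$dielectric)
  if (is.null(pocket)) return(intra)
  cr <- cross_energy(ligand_coords, ligand_params, pocket, spec)
  new_energy_breakdown(
    bond = intra$bond, angle = intra$angle,
    stretch_bend = intra$stretch_bend, oop = intra$oop,
    torsion = intra$torsion, vdw = intra$vdw,
    electrostatic = intra$electrostatic,
    cross_vdw = cr$vdw, cross_electrostatic = cr$elec)
}

#' Gradient of the total energy with respect to ligand coordinates
#'
#' The pocket is rigid: only ligand-coordinate derivatives are returned.
#' With `pocket = NULL` this equals [gradient_intra()].
#'
#' @inheritParams total_energy
#' @return N x 3 matrix, kcal/mol/Angstrom.
#' @export
gradient_total <- function(ligand_coords, ligand_params, pocket = NULL,
                           spec = cross_term_spec()) {
  g <- gradient_intra(ligand_coords, ligand_params,
                      dielectric = spec$dielectric)
  if (is.null(pocket)) return(g)
  g + cross_gradient(ligand_coords, ligand_params, pocket, spec)
}
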