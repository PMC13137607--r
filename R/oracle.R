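# Cross-validation helpers: the reference toolkit's own MMFF94 single
# point and minimizer, exposed so tests, vignettes and the acceptance
# script can compare the R kernels against an independent implementation
# of the same force field.

#' Reference MMFF94 single-point energies
#'
#' Evaluates the RDKit implementation of MMFF94 on the given structures.
#' This is an independent code path from [energy_intra()] (the R kernels
#' never call it); it exists to pin the equivalence of the two.
#'
#' @param ligands A [ligand_graph()] or list of them (or mol block
#'   strings).
#' @param coords Optional list of N x 3 matrices overriding each
#'   structure's coordinates.
#' @return Numeric vector of total energies, kcal/mol (`NA` where the
#'   reference could not type the molecule).
#' @export
mmff_reference_energy <- function(ligands, coords = NULL) {
  blocks <- normalize_blocks(ligands)
  req <- list(mode = "reference_energy", molblocks = blocks)
  if (!is.null(coords)) {
    req$coords <- lapply(coords, function(m) {
      m <- as.matrix(m)
      lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    })
  }
  res <- adapter_call(req)
  vapply(res$results, function(r) {
    if (!is.null(r$error)) NA_real_ else as.numeric(r$energy)
  }, numeric(1))
}

#' Reference MMFF94 minimization
#'
#' Runs the RDKit MMFF94 minimizer from the supplied geometries.
#'
#' @inheritParams mmff_reference_energy
#' @param max_its Iteration cap for the reference minimizer.
#' @return List with `energies` (kcal/mol) and `ligands` (minimized
#'   [ligand_graph()]s).
#' @export
mmff_reference_minimize <- function(ligands, max_its = 5000) {
  blocks <- normalize_blocks(ligands)
  res <- adapter_call(list(mode = "reference_minimize", molblocks = blocks,
                           max_its = max_its))
  energies <- vapply(res$results, function(r) {
    if (!is.null(r$error)) NA_real_ else as.numeric(r$energy)
  }, numeric(1))
  ligs <- lapply(res$results, function(r) {
    if (!is.null(r$error)) return(NULL)
    lig <- molblock_to_ligand(r$molblock)
    lig$coords <- as_index_matrix(r$coords, 3)  # full precision
    lig
  })
  list(energies = energies, ligands = ligs)
}

normalize_blocks <- function(ligands) {
  if (inherits(ligands, "ligand_graph")) ligands <- list(ligands)
  if (is.character(ligands)) ligands <- as.list(ligands)
  lapply(ligands, function(l) {
    if (inherits(l, "ligand_graph")) as_molblock(l) else as.character(l)
  })
}
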