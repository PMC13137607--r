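# Pose quality metrics: ligand strain energy per heavy atom, and
# force-field validity of generated records.

#' Ligand strain energy per heavy atom
#'
#' The gap between the intramolecular MMFF94 energy of the input
#' conformation and that of its force-field-minimized geometry, divided by
#' the number of heavy (non-hydrogen) atoms. The generated-pose energy and
#' the relaxation are both intramolecular by default; set
#' `conditional = TRUE` to evaluate and relax under the pocket-conditioned
#' total energy instead.
#'
#' @param ligand A [ligand_graph()].
#' @param pocket Optional [pocket_structure()]; only used when
#'   `conditional = TRUE`.
#' @param conditional Use the pocket-conditioned total energy (default
#'   `FALSE`: intramolecular only).
#' @param max_iters,tol_grad Passed to [minimize()].
#' @param params Optional pre-computed `mmff_params` for the ligand's
#'   graph (parameters are conformation-independent, so one set serves
#'   any pose of the same molecule; this avoids re-typing in scoring
#'   loops).
#' @return An object of class `strain_result` with fields `e_generated`,
#'   `e_optimized` (kcal/mol), `n_heavy` and `strain_per_heavy`
#'   (kcal/mol per heavy atom).
#' @export
strain_energy <- function(ligand, pocket = NULL, conditional = FALSE,
                          max_iters = 1000, tol_grad = 0.01,
                          params = NULL) {
  stopifnot(inherits(ligand, "ligand_graph"))
  if (is.null(params)) params <- parameterize(ligand)
  pk <- if (conditional) pocket else NULL
  params$coords <- ligand$coords  # full precision, not mol-block rounded
  e_gen <- total_energy(ligand$coords, params, pk)$total
  opt <- minimize(params, pocket = pk, max_iters = max_iters,
                  tol_grad = tol_grad)
  e_opt <- opt$energy$total
  nh <- n_heavy_atoms(ligand)
  structure(list(e_generated = e_gen, e_optimized = e_opt,
                 n_heavy = nh,
                 strain_per_heavy = (e_gen - e_opt) / nh),
            class = "strain_result")
}

#' @export
print.strain_result <- function(x, ...) {
  cat(sprintf(paste0("strain: %.4f kcal/mol per heavy atom ",
                     "(E_pose %.3f, E_min %.3f, %d heavy atoms)\n"),
              x$strain_per_heavy, x$e_generated, x$e_optimized, x$n_heavy))
  invisible(x)
}

#' Force-field validity of a molecule record
#'
#' `TRUE` iff the record parses, sanitizes, and an MMFF94 parameter set
#' can be initialized for it. Never errors.
#'
#' @param x A [ligand_graph()], a mol block string, or a path to an
#'   SDF file (first record).
#' @return Logical flag.
#' @export
validity <- function(x) {
  block <- tryCatch({
    if (inherits(x, "ligand_graph")) {
      as_molblock(x)
    } else if (is.character(x) && length(x) == 1 && !grepl("\n", x) &&
               file.exists(x)) {
      as_molblock(read_ligand(x))
    } else {
      as.character(x)
    }
  }, error = function(e) NULL)
  if (is.null(block)) return(FALSE)
  tryCatch({
    parameterize(block)
    TRUE
  }, error = function(e) FALSE)
}
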