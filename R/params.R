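# MMFF94 parameter container. Parameter acquisition is delegated to the
# RDKit typing adapter; the tables stored here are plain matrices so the
# energy/gradient kernels are pure numerics, independent of the toolkit.

as_index_matrix <- function(lst, ncol) {
  if (length(lst) == 0) return(matrix(numeric(0), 0, ncol))
  do.call(rbind, lapply(lst, function(r) as.numeric(unlist(r))))
}

#' Condition class for atom-typing failures
#' @param message Error text.
#' @param atom 1-based index of the offending atom (`NA` if unknown).
#' @keywords internal
parameterization_error <- function(message, atom = NA_integer_) {
  structure(
    class = c("ffguide_parameterization_error", "error", "condition"),
    list(message = message, call = sys.call(-1), atom = atom))
}

#' Assign MMFF94 parameters to a ligand
#'
#' Runs MMFF94 atom typing and parameter assignment (through the bundled
#' RDKit adapter) and returns the complete per-molecule parameter tables:
#' bond stretch, angle bend (with linear-angle flags), stretch-bend,
#' out-of-plane, torsion, van der Waals pair parameters, partial charges,
#' and the 1-2/1-3 exclusion plus 1-4 scaling topology. Molecules with
#' implicit hydrogens should be protonated before calling; fixture
#' generators always produce explicit-H structures.
#'
#' @param mol A [ligand_graph()] or a V2000/V3000 mol block string.
#' @return An object of class `mmff_params`.
#' @seealso [energy_intra()], [gradient_intra()], [total_energy()]
#' @export
parameterize <- function(mol) {
  parameterize_set(list(mol))[[1]]
}

#' Parameterize a batch of ligands in one adapter call
#'
#' Identical to [parameterize()] applied element-wise, but amortizes the
#' adapter process spawn over the whole set.
#'
#' @param mols List of [ligand_graph()]s or mol block strings.
#' @return List of `mmff_params` objects.
#' @export
parameterize_set <- function(mols) {
  blocks <- lapply(mols, function(m) {
    if (inherits(m, "ligand_graph")) as_molblock(m) else as.character(m)
  })
  res <- adapter_call(list(mode = "parameterize", molblocks = blocks))
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    p <- res$params[[b]]
    if (!is.null(p$error)) {
      stop(parameterization_error(
        paste0("MMFF94 parameterization failed (molecule ", b, "): ",
               p$error),
        atom = if (!is.null(p$atom) && p$atom > 0) as.integer(p$atom)
               else NA_integer_))
    }
    out[[b]] <- params_from_adapter(p, blocks[[b]])
  }
  out
}

params_from_adapter <- function(p, block) {
  params <- list(
    natoms = as.integer(p$natoms),
    elements = as.character(unlist(p$elements)),
    atom_types = as.integer(unlist(p$atom_types)),
    charges = as.numeric(unlist(p$charges)),
    formal_charges = as.integer(unlist(p$formal_charges)),
    coords = as_index_matrix(p$coords, 3),
    bonds = as_index_matrix(p$bonds, 4),            # i j kb r0
    angles = as_index_matrix(p$angles, 6),          # i j k ka theta0 linear
    stretch_bends = as_index_matrix(p$stretch_bends, 8),
    oops = as_index_matrix(p$oops, 5),              # i j k l koop
    torsions = as_index_matrix(p$torsions, 7),      # i j k l V1 V2 V3
    vdw_pairs = as_index_matrix(p$vdw_pairs, 4),    # i j R*ij eps_ij
    elec_pairs = as_index_matrix(p$elec_pairs, 3),  # i j scale
    vdw_self = as_index_matrix(p$vdw_self, 2),      # R*ii eps_ii per atom
    excluded_12 = as_index_matrix(p$excluded_12, 2),
    excluded_13 = as_index_matrix(p$excluded_13, 2),
    molblock = block)
  class(params) <- "mmff_params"
  validate_mmff_params(params)
  params
}

validate_mmff_params <- function(params) {
  n <- params$natoms
  stopifnot(length(params$charges) == n, nrow(params$vdw_self) == n)
  idx <- c(params$bonds[, 1:2], params$angles[, 1:3],
           params$torsions[, 1:4], params$oops[, 1:4],
           params$vdw_pairs[, 1:2], params$elec_pairs[, 1:2])
  if (length(idx) && (min(idx) < 1 || max(idx) > n)) {
    stop("parameter table indices out of range")
  }
  invisible(params)
}

#' @export
print.mmff_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<mmff_params> %d atoms | %d bonds, %d angles, %d stretch-bends, ",
    "%d oop, %d torsions | %d vdW pairs\n"),
    x$natoms, nrow(x$bonds), nrow(x$angles), nrow(x$stretch_bends),
    nrow(x$oops), nrow(x$torsions), nrow(x$vdw_pairs)))
  invisible(x)
}

#' Serialize / restore an MMFF94 parameter set as JSON
#'
#' Useful for building hand-crafted parameter fixtures and for the CLI.
#' @param params An `mmff_params` object.
#' @param path File path.
#' @return `params_to_json` returns `path` invisibly; `params_from_json`
#'   returns an `mmff_params` object.
#' @export
params_to_json <- function(params, path) {
  x <- unclass(params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  widths <- c(coords = 3, bonds = 4, angles = 6, stretch_bends = 8,
              oops = 5, torsions = 7, vdw_pairs = 4, elec_pairs = 3,
              vdw_self = 2, excluded_12 = 2, excluded_13 = 2)
  for (f in names(widths)) {
    m <- x[[f]]
    if (is.null(m) || length(m) == 0) {
      m <- matrix(numeric(0), 0, widths[[f]])
    } else if (is.null(dim(m))) {
      m <- matrix(as.numeric(m), nrow = 1)
    }
    storage.mode(m) <- "double"
    x[[f]] <- m
  }
  x$natoms <- as.integer(x$natoms)
  class(x) <- "mmff_params"
  validate_mmff_params(x)
  x
}
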