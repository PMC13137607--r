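# Pocket representation, PDB/PQR input, and pocket extraction.

# Element-default MMFF94-style nonbonded parameters for pocket atoms
# (self-pair R* in Angstrom and epsilon in kcal/mol of a representative
# MMFF94 atom type per element). Used when no per-atom typing is available,
# which is the normal situation for a truncated protein pocket.
POCKET_VDW_DEFAULTS <- list(
  H  = c(rstar = 2.9698, eps = 0.0216),
  C  = c(rstar = 3.9377, eps = 0.0678),
  N  = c(rstar = 4.0283, eps = 0.0721),
  O  = c(rstar = 3.5581, eps = 0.0763),
  S  = c(rstar = 4.3694, eps = 0.2681),
  P  = c(rstar = 4.5731, eps = 0.2596),
  F  = c(rstar = 2.9920, eps = 0.0801),
  Cl = c(rstar = 4.0886, eps = 0.2763),
  Br = c(rstar = 4.3317, eps = 0.3889),
  I  = c(rstar = 4.7167, eps = 0.5514),
  X  = c(rstar = 3.8, eps = 0.1)  # anything else
)

#' Create a pocket structure
#'
#' A rigid set of protein atoms: coordinates, elements, partial charges and
#' per-atom van der Waals parameters, plus per-atom residue labels used by
#' [extract_pocket()].
#'
#' @param coords Numeric matrix, M x 3, Angstrom.
#' @param elements Character vector of element symbols.
#' @param charges Numeric partial charges (e).
#' @param residue_ids Per-atom residue labels (character or integer).
#' @param vdw_epsilon,vdw_rstar Optional per-atom van der Waals well depth
#'   (kcal/mol) and minimum-energy radius (Angstrom); element defaults are
#'   used when omitted.
#' @return An object of class `pocket_structure`.
#' @export
pocket_structure <- function(coords, elements, charges,
                             residue_ids = NULL,
                             vdw_epsilon = NULL, vdw_rstar = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  m <- nrow(coords)
  if (m == 0) stop("pocket has no atoms")
  if (ncol(coords) != 3) stop("coords must be M x 3")
  if (!all(is.finite(coords))) stop("pocket coordinates must be finite")
  elements <- as.character(elements)
  charges <- as.numeric(charges)
  if (length(elements) != m || length(charges) != m) {
    stop("elements/charges length mismatch")
  }
  if (!all(is.finite(charges))) stop("pocket charges must be finite")
  if (is.null(residue_ids)) residue_ids <- rep("RES1", m)
  residue_ids <- as.character(residue_ids)
  if (length(residue_ids) != m) stop("residue_ids length mismatch")
  if (is.null(vdw_epsilon) || is.null(vdw_rstar)) {
    defaults <- t(vapply(elements, function(el) {
      if (!is.null(POCKET_VDW_DEFAULTS[[el]])) POCKET_VDW_DEFAULTS[[el]]
      else POCKET_VDW_DEFAULTS$X
    }, c(rstar = 0, eps = 0)))
    if (is.null(vdw_rstar)) vdw_rstar <- defaults[, "rstar"]
    if (is.null(vdw_epsilon)) vdw_epsilon <- defaults[, "eps"]
  }
  vdw_epsilon <- as.numeric(vdw_epsilon)
  vdw_rstar <- as.numeric(vdw_rstar)
  if (any(vdw_epsilon <= 0) || any(vdw_rstar <= 0)) {
    stop("van der Waals parameters must be positive")
  }
  structure(
    list(coords = coords, elements = elements, charges = charges,
         residue_ids = residue_ids, vdw_epsilon = unname(vdw_epsilon),
         vdw_rstar = unname(vdw_rstar)),
    class = "pocket_structure")
}

#' @export
print.pocket_structure <- function(x, ...) {
  cat(sprintf("<pocket_structure> %d atoms, %d residues, total charge %.3f e\n",
              nrow(x$coords), length(unique(x$residue_ids)),
              sum(x$charges)))
  invisible(x)
}

guess_element <- function(elesy, atom_name) {
  el <- trimws(elesy)
  if (nzchar(el)) {
    return(paste0(toupper(substr(el, 1, 1)),
                  tolower(substr(el, 2, nchar(el)))))
  }
  nm <- gsub("[0-9']", "", trimws(atom_name))
  if (!nzchar(nm)) return(NA_character_)
  two <- c("Cl", "Br", "Fe", "Zn", "Mg", "Mn", "Na", "Ca", "Se")
  cand <- paste0(toupper(substr(nm, 1, 1)), tolower(substr(nm, 2, 2)))
  if (cand %in% two) cand else toupper(substr(nm, 1, 1))
}

#' Read a protein or pocket from a PDB or PQR file
#'
#' ATOM/HETATM records are read with bio3d. Partial charges are taken, in
#' order of preference, from (1) a sidecar CSV with columns `atom_serial`
#' and `charge`, (2) the PQR occupancy-style charge column for `.pqr` files,
#' or (3) a Gasteiger fallback assigner run on the PDB block. Van der Waals
#' parameters are assigned from an element-default MMFF94-style table.
#'
#' @param path PDB or PQR file.
#' @param charges Optional path to a sidecar CSV (`atom_serial`, `charge`)
#'   or a numeric vector of per-atom charges in file order.
#' @return A [pocket_structure()].
#' @export
read_pocket <- function(path, charges = NULL) {
  is_pqr <- grepl("\\.pqr$", path, ignore.case = TRUE)
  pdb <- if (is_pqr) bio3d::read.pqr(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM/HETATM records in ", path)
  coords <- as.matrix(at[, c("x", "y", "z")])
  elements <- vapply(seq_len(nrow(at)),
                     function(k) guess_element(
                       if ("elesy" %in% names(at)) at$elesy[k] else "",
                       at$elety[k]),
                     character(1))
  if (any(is.na(elements))) {
    stop("element could not be determined for atom(s) ",
         paste(which(is.na(elements)), collapse = ", "))
  }
  resid <- paste0(at$chain, ":", at$resno)
  q <- NULL
  if (!is.null(charges)) {
    if (is.character(charges)) {
      tab <- utils::read.csv(charges)
      if (!all(c("atom_serial", "charge") %in% names(tab))) {
        stop("charge sidecar must have columns atom_serial, charge")
      }
      q <- tab$charge[match(at$eleno, tab$atom_serial)]
      if (any(is.na(q))) stop("sidecar is missing charges for some atoms")
    } else {
      q <- as.numeric(charges)
      if (length(q) != nrow(at)) stop("charge vector length mismatch")
    }
  } else if (is_pqr && "o" %in% names(at)) {
    q <- as.numeric(at$o)  # PQR stores the charge in the occupancy column
  } else {
    q <- gasteiger_pdb_charges(paste(readLines(path, warn = FALSE),
                                     collapse = "\n"))
    if (is.null(q) || length(q) != nrow(at)) {
      warning("fallback charge assignment failed; using zero charges",
              call. = FALSE)
      q <- numeric(nrow(at))
    }
  }
  pocket_structure(coords, elements, q, residue_ids = resid)
}

gasteiger_pdb_charges <- function(pdb_block) {
  res <- tryCatch(
    adapter_call(list(mode = "pdb_gasteiger", pdb = pdb_block)),
    error = function(e) NULL)
  if (is.null(res) || is.null(res$charges)) return(NULL)
  as.numeric(unlist(res$charges))
}

#' Extract the binding pocket around a native ligand
#'
#' Keeps exactly those residues that (a) have at least one atom within
#' `radius` (closed bound) of any ligand atom and (b) contain strictly more
#' than `min_atoms` atoms in total.
#'
#' @param protein A [pocket_structure()] with residue labels.
#' @param native_ligand A [ligand_graph()] defining the binding site.
#' @param radius Distance threshold in Angstrom (default 3.5).
#' @param min_atoms Residues must have strictly more atoms than this
#'   (default 10).
#' @return A [pocket_structure()] restricted to the pocket residues.
#' @export
extract_pocket <- function(protein, native_ligand, radius = 3.5,
                           min_atoms = 10) {
  stopifnot(inherits(protein, "pocket_structure"),
            inherits(native_ligand, "ligand_graph"))
  p <- protein$coords
  l <- native_ligand$coords
  # squared min distance of each protein atom to the ligand
  d2 <- outer(rowSums(p^2), rowSums(l^2), "+") - 2 * tcrossprod(p, l)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  res_sizes <- table(protein$residue_ids)
  near <- tapply(mind <= radius, protein$residue_ids, any)
  keep_res <- names(near)[near & as.vector(res_sizes[names(near)]) > min_atoms]
  sel <- protein$residue_ids %in% keep_res
  if (!any(sel)) {
    stop("no pocket residues within ", radius, " Angstrom satisfy the ",
         "size rule")
  }
  pocket_structure(protein$coords[sel, , drop = FALSE],
                   protein$elements[sel], protein$charges[sel],
                   residue_ids = protein$residue_ids[sel],
                   vdw_epsilon = protein$vdw_epsilon[sel],
                   vdw_rstar = protein$vdw_rstar[sel])
}
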