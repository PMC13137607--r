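# Ligand representation and SDF I/O.

BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' Create a ligand graph
#'
#' The molecular representation used throughout the package: explicit atoms
#' with 3D coordinates (Angstrom), chemical element, integer formal charge,
#' and typed bonds (single, double, triple or aromatic).
#'
#' @param coords Numeric matrix, N x 3, Angstrom.
#' @param elements Character vector of element symbols, length N.
#' @param formal_charges Integer vector of formal charges (e), length N.
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (one of `"single"`, `"double"`, `"triple"`, `"aromatic"`).
#' @param name Molecule name.
#' @return An object of class `ligand_graph`.
#' @examples
#' # a hydrogen molecule
#' h2 <- ligand_graph(rbind(c(0, 0, 0), c(0.74, 0, 0)), c("H", "H"),
#'                    c(0L, 0L), data.frame(i = 1, j = 2, order = "single"))
#' @export
ligand_graph <- function(coords, elements, formal_charges = NULL,
                         bonds = NULL, name = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  if (!all(is.finite(coords))) stop("ligand coordinates must be finite")
  elements <- as.character(elements)
  if (length(elements) != n) stop("elements length must match atom count")
  if (is.null(formal_charges)) formal_charges <- integer(n)
  formal_charges <- as.integer(formal_charges)
  if (length(formal_charges) != n) stop("formal_charges length mismatch")
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = character())
  }
  bonds <- as.data.frame(bonds)
  bonds$i <- as.integer(bonds$i)
  bonds$j <- as.integer(bonds$j)
  bonds$order <- as.character(bonds$order)
  if (nrow(bonds) > 0) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)) {
      stop("bond indices out of range")
    }
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    if (!all(bonds$order %in% BOND_ORDERS)) {
      stop("bond order must be one of: ", paste(BOND_ORDERS, collapse = ", "))
    }
  }
  lig <- structure(
    list(coords = coords, elements = elements,
         formal_charges = formal_charges, bonds = bonds, name = name),
    class = "ligand_graph")
  if (n > 1 && !ligand_is_connected(lig)) {
    warning("ligand graph is not connected", call. = FALSE)
  }
  lig
}

ligand_is_connected <- function(lig) {
  n <- nrow(lig$coords)
  if (n <= 1 || nrow(lig$bonds) == 0) return(n <= 1)
  adj <- vector("list", n)
  for (r in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[r]; j <- lig$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  all(seen)
}

#' @export
print.ligand_graph <- function(x, ...) {
  cat(sprintf("<ligand_graph> %s: %d atoms, %d bonds\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$coords), nrow(x$bonds)))
  invisible(x)
}

#' Number of heavy (non-hydrogen) atoms
#' @param lig A [ligand_graph()].
#' @export
n_heavy_atoms <- function(lig) {
  sum(lig$elements != "H")
}

order_to_code <- function(order) {
  match(order, BOND_ORDERS)  # single=1, double=2, triple=3
  # aromatic maps to 4 below
}

#' Read a ligand from an SDF/MOL file
#'
#' Parses the first record of a V2000 (natively) or V3000 (via the RDKit
#' adapter) SD file. Element symbols, 3D coordinates, formal charges
#' (`M CHG` property lines) and bond orders -- including aromatic flags
#' (order 4) exactly as written in the file -- are transferred to the
#' [ligand_graph()].
#'
#' @param path Path to an SDF or MOL file with 3D coordinates.
#' @return A [ligand_graph()].
#' @export
read_ligand <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("SDF parse failure: file too short")
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE)) {
    end <- which(lines == "$$$$")
    block <- paste(lines[seq_len(if (length(end)) end[1] - 1 else length(lines))],
                   collapse = "\n")
    conv <- adapter_call(list(mode = "convert", molblocks = list(block)))
    v2k <- conv$molblocks[[1]]
    if (is.null(v2k)) stop("SDF parse failure: V3000 record not readable")
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c(v2k, "$$$$"), tmp)
    lig <- read_ligand(tmp)
    lig$name <- trimws(lines[1])
    return(lig)
  }
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb)) stop("SDF parse failure: bad counts line")
  if (length(lines) < 4 + na + nb) stop("SDF parse failure: truncated record")
  atom_lines <- lines[4 + seq_len(na)]
  coords <- matrix(0, na, 3)
  elements <- character(na)
  old_charges <- integer(na)
  for (k in seq_len(na)) {
    ln <- atom_lines[k]
    coords[k, ] <- as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                                substr(ln, 21, 30)))
    elements[k] <- trimws(substr(ln, 32, 34))
    cc <- suppressWarnings(as.integer(trimws(substr(ln, 37, 39))))
    # legacy atom-block charge codes: 1..3 -> +3..+1, 5..7 -> -1..-3
    if (!is.na(cc) && cc > 0 && cc != 4) {
      old_charges[k] <- if (cc <= 3) 4L - cc else 4L - cc
    }
  }
  if (any(!is.finite(coords))) stop("SDF parse failure: bad coordinates")
  dim_flag <- if (length(lines) >= 2) substr(lines[2], 21, 22) else ""
  if (identical(trimws(dim_flag), "2D") || all(abs(coords[, 3]) < 1e-8 & na > 3)) {
    stop("ligand record has 2D-only coordinates; 3D coordinates are required")
  }
  bond_lines <- lines[4 + na + seq_len(nb)]
  bonds <- data.frame(
    i = as.integer(substr(bond_lines, 1, 3)),
    j = as.integer(substr(bond_lines, 4, 6)),
    code = as.integer(substr(bond_lines, 7, 9)))
  if (any(is.na(bonds$i)) || any(!bonds$code %in% 1:4)) {
    stop("SDF parse failure: bad bond block")
  }
  bonds$order <- BOND_ORDERS[ifelse(bonds$code == 4, 4L, bonds$code)]
  charges <- old_charges
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charges <- integer(na)  # M CHG supersedes legacy codes entirely
    for (ln in chg_lines) {
      toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                  "[[:space:]]+")[[1]])
      npairs <- toks[1]
      for (p in seq_len(npairs)) {
        charges[toks[2 * p]] <- toks[2 * p + 1]
      }
    }
  }
  ligand_graph(coords, elements, charges,
               bonds[, c("i", "j", "order")], name = trimws(lines[1]))
}

#' Serialize a ligand graph to a V2000 mol block
#' @param lig A [ligand_graph()].
#' @return A single string (no terminating `$$$$`).
#' @export
as_molblock <- function(lig) {
  n <- nrow(lig$coords)
  nb <- nrow(lig$bonds)
  # dimension flag must sit in columns 21-22 of the second header line
  header <- c(lig$name, "     ffguide        3D", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  atoms <- vapply(seq_len(n), function(k) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            lig$coords[k, 1], lig$coords[k, 2], lig$coords[k, 3],
            lig$elements[k])
  }, character(1))
  bonds <- character(0)
  if (nb > 0) {
    codes <- ifelse(lig$bonds$order == "aromatic", 4L,
                    match(lig$bonds$order, BOND_ORDERS))
    bonds <- sprintf("%3d%3d%3d  0", lig$bonds$i, lig$bonds$j, codes)
  }
  props <- character(0)
  charged <- which(lig$formal_charges != 0L)
  if (length(charged)) {
    # M CHG lines hold at most 8 (atom, charge) pairs each
    for (start in seq(1, length(charged), by = 8)) {
      idx <- charged[start:min(start + 7, length(charged))]
      props <- c(props, paste0(
        sprintf("M  CHG%3d", length(idx)),
        paste0(sprintf("%4d%4d", idx, lig$formal_charges[idx]),
               collapse = "")))
    }
  }
  paste(c(header, counts, atoms, bonds, props, "M  END"), collapse = "\n")
}

#' Write a ligand to an SDF file
#'
#' @param lig A [ligand_graph()] (or a list of them).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ligand <- function(lig, path) {
  if (inherits(lig, "ligand_graph")) lig <- list(lig)
  blocks <- vapply(lig, function(l) paste0(as_molblock(l), "\n$$$$"),
                   character(1))
  writeLines(blocks, path)
  invisible(path)
}

molblock_to_ligand <- function(block, name = NULL) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c(block, "$$$$"), tmp)
  lig <- read_ligand(tmp)
  if (!is.null(name)) lig$name <- name
  lig
}
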