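# Shared test fixtures and independent oracles. Fixture molecules are
# embedded once per session (the adapter memoises identical requests).

fx_cache <- new.env(parent = emptyenv())

fx_set <- function(n, seed = 0) {
  key <- paste0("set_", n, "_", seed)
  if (is.null(fx_cache[[key]])) {
    fx_cache[[key]] <- make_fixture_set(n, seed = seed)
  }
  fx_cache[[key]]
}

fx_params <- function(n, seed = 0) {
  key <- paste0("params_", n, "_", seed)
  if (is.null(fx_cache[[key]])) {
    fx_cache[[key]] <- parameterize_set(fx_set(n, seed))
  }
  fx_cache[[key]]
}

# central finite differences of an arbitrary scalar function of coords
fd_gradient <- function(fn, x, h = 1e-5) {
  g <- matrix(0, nrow(x), 3)
  for (a in seq_len(nrow(x))) {
    for (d in 1:3) {
      xp <- x; xp[a, d] <- xp[a, d] + h
      xm <- x; xm[a, d] <- xm[a, d] - h
      g[a, d] <- (fn(xp) - fn(xm)) / (2 * h)
    }
  }
  g
}

# independent scalar transcriptions of the two nonbonded forms (kept
# deliberately separate from the package kernels)
oracle_vdw_147 <- function(r, rstar, eps) {
  eps * (1.07 * rstar / (r + 0.07 * rstar))^7 *
    (1.12 * rstar^7 / (r^7 + 0.12 * rstar^7) - 2)
}
oracle_coulomb <- function(r, qi, qj, D = 1, delta = 0.05) {
  332.0716 * qi * qj / (D * (r + delta))
}

random_rigid_transform <- function(seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(9), 3, 3)
    Q <- qr.Q(qr(A))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    list(R = Q, t = rnorm(3, sd = 5))
  })
}

apply_rigid <- function(coords, tr) {
  sweep(coords %*% t(tr$R), 2, tr$t, "+")
}

# brute-force O(N*M) re-statement of the pocket rule
oracle_extract_pocket <- function(protein, ligand, radius = 3.5,
                                  min_atoms = 10) {
  keep <- character(0)
  for (res in unique(protein$residue_ids)) {
    rows <- which(protein$residue_ids == res)
    near <- FALSE
    for (a in rows) {
      for (b in seq_len(nrow(ligand$coords))) {
        if (sqrt(sum((protein$coords[a, ] - ligand$coords[b, ])^2)) <= radius) {
          near <- TRUE
          break
        }
      }
      if (near) break
    }
    if (near && length(rows) > min_atoms) keep <- c(keep, res)
  }
  sort(keep)
}

# hand-built minimal parameter set (no adapter): a diatomic with one bond
hand_diatomic_params <- function(kb = 5, r0 = 1.5, q = c(0, 0),
                                 rstar = 3.9, eps = 0.07) {
  structure(list(
    natoms = 2L, elements = c("C", "C"), atom_types = c(1L, 1L),
    charges = q, formal_charges = c(0L, 0L),
    coords = rbind(c(0, 0, 0), c(r0, 0, 0)),
    bonds = matrix(c(1, 2, kb, r0), 1, 4),
    angles = matrix(numeric(0), 0, 6),
    stretch_bends = matrix(numeric(0), 0, 8),
    oops = matrix(numeric(0), 0, 5),
    torsions = matrix(numeric(0), 0, 7),
    vdw_pairs = matrix(numeric(0), 0, 4),
    elec_pairs = matrix(numeric(0), 0, 3),
    vdw_self = matrix(c(rstar, rstar, eps, eps), 2, 2),
    excluded_12 = matrix(c(1, 2), 1, 2),
    excluded_13 = matrix(numeric(0), 0, 2),
    molblock = NULL), class = "mmff_params")
}

write_tiny_pdb <- function(path, coords, elements, resnos = NULL) {
  if (is.null(resnos)) resnos <- seq_len(nrow(coords))
  lines <- vapply(seq_len(nrow(coords)), function(k) {
    sprintf("ATOM  %5d  %-3sRES A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            k, elements[k], resnos[k], coords[k, 1], coords[k, 2],
            coords[k, 3], elements[k])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}
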