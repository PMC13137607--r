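# Synthetic fixtures: a packaged drug-like SMILES list with seeded 3D
# embedding, toy pockets, toy denoisers satisfying the denoiser contract,
# and randomized synthetic proteins for pocket-extraction tests. Everything
# is generated in code; no external data is ever downloaded.

# ~50 common drug-like and fragment-like molecules; all type cleanly under
# MMFF94 and embed reliably with ETKDG
FIXTURE_SMILES <- c(
  "CCO", "CC(C)O", "CC(C)(C)O", "CCOCC", "C1CCOC1", "C1CCCCC1",
  "c1ccccc1", "Cc1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1",
  "c1cc[nH]c1", "CC(=O)C", "CC(=O)OC", "CC(=O)N", "CC(=O)NC",
  "CCN(CC)CC", "CN1CCCC1", "C1CCNCC1", "CC#N", "CC(C)C#N",
  "CCS", "CCSSCC", "CS(=O)(=O)C", "CCOP(=O)(OCC)OCC",
  "CC(=O)Oc1ccccc1C(=O)O", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CC(=O)Nc1ccc(O)cc1",
  "c1ccc(cc1)C(=O)O", "c1ccc(cc1)CO", "c1ccc(cc1)CN",
  "Nc1ccc(cc1)S(=O)(=O)N", "Clc1ccccc1", "FC(F)(F)c1ccccc1",
  "Oc1ccccc1", "COc1ccccc1", "CN(C)c1ccccc1", "O=C1CCCN1",
  "O=C1CCCCN1", "c1ccc2c(c1)cccn2", "c1ccc2c(c1)[nH]cn2",
  "OCC(O)CO", "OCCO", "NCCO", "NCCN", "OC(=O)CCC(=O)O",
  "CC(N)C(=O)O", "CNC(=O)c1ccco1", "CC1CCC(CC1)C(C)C")

#' Deterministic drug-like molecule fixture set
#'
#' Embeds the first `n` molecules of the packaged SMILES list in 3D (ETKDG
#' through the RDKit adapter, explicit hydrogens, seeded) and returns them
#' as ligand graphs. Recycles the list if `n` exceeds its length, with a
#' different embedding seed per pass.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer seed controlling the embeddings.
#' @return List of `n` [ligand_graph()] objects, each parameterizable.
#' @export
make_fixture_set <- function(n, seed = 0) {
  stopifnot(n >= 1)
  reps <- split(seq_len(n) - 1L, (seq_len(n) - 1L) %/% length(FIXTURE_SMILES))
  out <- vector("list", n)
  for (pass in seq_along(reps)) {
    idx <- reps[[pass]]
    smi <- FIXTURE_SMILES[(idx %% length(FIXTURE_SMILES)) + 1L]
    emb <- adapter_call(list(
      mode = "embed", smiles = as.list(smi),
      seed = (seed + 104729L * (pass - 1L)) %% (2^31 - 1)))
    for (q in seq_along(idx)) {
      block <- emb$molblocks[[q]]
      if (is.null(block)) {
        stop("embedding failed for fixture SMILES ", smi[q])
      }
      out[[idx[q] + 1L]] <- molblock_to_ligand(block, name = smi[q])
    }
  }
  out
}

#' Toy pockets for cross-term and guidance tests
#'
#' Small synthetic pockets (at most 60 atoms) with controlled geometry and
#' charges:
#' * `point_charges`: atoms scattered on a sphere of radius ~6 A with
#'   alternating +/- charges;
#' * `ring_cage`: a 12-atom carbon ring of radius 5 A in the xy-plane,
#'   weakly charged;
#' * `shell`: a 40-atom neutral-ish shell of radius 15 A (negligible vdW
#'   contact with a centered small ligand).
#'
#' @param kind One of `"point_charges"`, `"ring_cage"`, `"shell"`.
#' @param seed Integer seed.
#' @param charge Magnitude of the point charges (e); `0` gives an
#'   uncharged pocket.
#' @return A [pocket_structure()].
#' @export
make_toy_pocket <- function(kind = c("point_charges", "ring_cage", "shell"),
                            seed = 0, charge = 0.3) {
  kind <- match.arg(kind)
  withr::with_seed(seed, {
    if (kind == "point_charges") {
      m <- 8
      dirs <- matrix(stats::rnorm(3 * m), m, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      coords <- dirs * (6 + stats::runif(m, -0.5, 0.5))
      q <- charge * rep_len(c(1, -1), m)
      pocket_structure(coords, rep(c("O", "N"), length.out = m), q,
                       residue_ids = paste0("P:", seq_len(m)))
    } else if (kind == "ring_cage") {
      m <- 12
      ang <- 2 * pi * (seq_len(m) - 1) / m
      coords <- cbind(5 * cos(ang), 5 * sin(ang), 0)
      q <- charge / 3 * rep_len(c(1, -1), m)
      pocket_structure(coords, rep("C", m), q,
                       residue_ids = rep("R:1", m))
    } else {
      m <- 40
      dirs <- matrix(stats::rnorm(3 * m), m, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      coords <- dirs * 15
      pocket_structure(coords, rep("C", m), rep(charge / 3, m),
                       residue_ids = paste0("S:", ceiling(seq_len(m) / 4)))
    }
  })
}

#' Randomized synthetic protein for pocket-extraction tests
#'
#' Residues of random size (4 to 16 atoms) placed at random distances from
#' the origin, so that extraction against a ligand centered there
#' exercises both the distance and the residue-size rule.
#'
#' @param n_residues Number of residues.
#' @param seed Integer seed.
#' @param spread Maximum residue-center distance from the origin, Angstrom.
#' @return A [pocket_structure()] with per-atom residue labels.
#' @export
make_synthetic_protein <- function(n_residues = 50, seed = 0, spread = 12) {
  withr::with_seed(seed, {
    coords <- NULL
    resid <- character(0)
    elements <- character(0)
    for (r in seq_len(n_residues)) {
      sz <- sample(4:16, 1)
      center <- stats::runif(3, -spread, spread)
      atoms <- sweep(matrix(stats::rnorm(3 * sz, sd = 1.2), sz, 3), 2,
                     center, "+")
      coords <- rbind(coords, atoms)
      resid <- c(resid, rep(sprintf("A:%d", r), sz))
      elements <- c(elements, sample(c("C", "N", "O"), sz, replace = TRUE,
                                     prob = c(0.6, 0.2, 0.2)))
    }
    pocket_structure(coords, elements,
                     stats::rnorm(length(elements), sd = 0.2),
                     residue_ids = resid)
  })
}

# deterministic noise that depends only on (seed, t): safe to call in any
# order, so denoisers honouring the contract stay deterministic in (x, t)
det_noise <- function(n, m, seed, t) {
  withr::with_seed((seed + round(t * 1e6)) %% (2^31 - 1),
                   matrix(stats::rnorm(n * m), n, m))
}

#' Toy denoisers for sampler tests
#'
#' Deterministic stand-ins for a trained clean-sample predictor. All
#' satisfy the denoiser contract: a function `(x_t, t, pocket)` returning
#' coordinates with the same dimensions, deterministic given `(x_t, t)`.
#'
#' * `perfect`: always returns the target coordinates.
#' * `noisy_target`: target plus `(1 - t)`-scaled seeded Gaussian noise and
#'   a weak pull toward the current noisy state (the prediction sharpens
#'   as t -> 1 and, like a trained denoiser, depends on its input).
#' * `strained_target`: like `noisy_target` but centered on a deliberately
#'   strained conformer of the target (a fixed seeded distortion of
#'   `strain_sd` Angstrom), emulating a generator that proposes
#'   high-energy poses.
#'
#' @param kind One of `"perfect"`, `"noisy_target"`, `"strained_target"`.
#' @param target A [ligand_graph()] with 3D coordinates.
#' @param seed Integer seed for the denoiser's noise stream.
#' @param noise_sd Standard deviation of the t-scaled prediction noise, A.
#' @param strain_sd Standard deviation of the fixed distortion defining
#'   the strained conformer, A.
#' @param pull Strength of the `(1 - t)`-scaled pull toward the noisy
#'   input state.
#' @return A denoiser function.
#' @export
make_toy_denoiser <- function(kind = c("perfect", "noisy_target",
                                       "strained_target"),
                              target, seed = 0, noise_sd = 0.15,
                              strain_sd = 0.25, pull = 0.1) {
  kind <- match.arg(kind)
  stopifnot(inherits(target, "ligand_graph"))
  x1 <- target$coords
  if (kind == "perfect") {
    return(function(xt, t, pocket = NULL) x1)
  }
  center <- x1
  if (kind == "strained_target") {
    center <- x1 + strain_sd * det_noise(nrow(x1), 3, seed + 13L, 0.5)
  }
  function(xt, t, pocket = NULL) {
    center + pull * (1 - t) * (as.matrix(xt) - center) +
      noise_sd * (1 - t) * det_noise(nrow(x1), 3, seed, t)
  }
}
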