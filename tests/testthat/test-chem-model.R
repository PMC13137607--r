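# Ligand/pocket domain types, SDF and PDB I/O, pocket extraction.

hexagon_benzene <- function() {
  ang <- 2 * pi * (0:5) / 6
  cc <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0.01 * (1:6))
  hh <- cbind(2.47 * cos(ang), 2.47 * sin(ang), 0.01 * (1:6))
  bonds <- data.frame(
    i = c(1:6, 1:6), j = c(2:6, 1, 7:12),
    order = c(rep("aromatic", 6), rep("single", 6)))
  ligand_graph(rbind(cc, hh), c(rep("C", 6), rep("H", 6)),
               bonds = bonds, name = "benzene")
}

test_that("SDF round-trip preserves graph, coordinates and aromatic flags", {
  benz <- hexagon_benzene()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_ligand(benz, path)
  back <- read_ligand(path)
  expect_equal(sum(back$bonds$order == "aromatic"), 6)
  expect_identical(back$elements, benz$elements)
  expect_equal(back$coords, benz$coords, tolerance = 1e-4,
               ignore_attr = TRUE)

  for (lig in fx_set(6, seed = 3)[4:6]) {
    p2 <- withr::local_tempfile(fileext = ".sdf")
    write_ligand(lig, p2)
    again <- read_ligand(p2)
    expect_identical(again$elements, lig$elements)
    expect_identical(again$bonds$order, lig$bonds$order)
    expect_identical(again$formal_charges, lig$formal_charges)
    expect_lt(max(abs(again$coords - lig$coords)), 1e-4 + 1e-12)
  }
})

test_that("formal charges survive the M CHG property block", {
  lig <- make_fixture_set(1, seed = 5)[[1]]
  lig$formal_charges[1] <- 1L
  lig$formal_charges[2] <- -1L
  path <- withr::local_tempfile(fileext = ".sdf")
  write_ligand(lig, path)
  back <- read_ligand(path)
  expect_identical(back$formal_charges[1:2], c(1L, -1L))
  # and through an external writer: a protonated amine from the adapter
  emb <- adapter_call(list(mode = "embed", smiles = list("C[NH3+]"),
                           seed = 1))
  amine <- ffguide:::molblock_to_ligand(emb$molblocks[[1]])
  expect_identical(sum(amine$formal_charges), 1L)
  expect_identical(amine$formal_charges[amine$elements == "N"], 1L)
})

test_that("degenerate ligand records are rejected with clear errors", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("junk", "", ""), path)
  expect_error(read_ligand(path), "parse|short")
  # 2D-flagged record
  lig <- fx_set(1)[[1]]
  block <- as_molblock(lig)
  block <- sub("3D", "2D", block)
  writeLines(c(block, "$$$$"), path)
  expect_error(read_ligand(path), "2D")
  expect_error(ligand_graph(rbind(c(0, 0, NA)), "C"), "finite")
  expect_error(
    ligand_graph(rbind(c(0, 0, 0), c(1, 0, 0)), c("C", "C"),
                 bonds = data.frame(i = 1, j = 1, order = "single")),
    "self-bond")
  expect_warning(
    ligand_graph(rbind(c(0, 0, 0), c(9, 0, 0)), c("C", "C")),
    "not connected")
})

test_that("pocket charges come from sidecar, PQR column, or fallback", {
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0))
  pdb <- write_tiny_pdb(withr::local_tempfile(fileext = ".pdb"),
                        coords, c("O", "C", "N"))
  sidecar <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(atom_serial = 1:3, charge = c(0.1, -0.2, 0.1)),
            sidecar, row.names = FALSE)
  pk <- read_pocket(pdb, charges = sidecar)
  expect_equal(pk$charges, c(0.1, -0.2, 0.1))
  expect_true(all(pk$vdw_epsilon > 0) && all(pk$vdw_rstar > 0))

  # fallback assigner: finite charges, right length
  pk2 <- suppressWarnings(read_pocket(pdb))
  expect_length(pk2$charges, 3)
  expect_true(all(is.finite(pk2$charges)))

  # empty PDB errors
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(suppressWarnings(read_pocket(empty)))
})

test_that("pocket extraction follows the closed 3.5 A / strictly >10 rule", {
  # residue A: 12 atoms, nearest 2.0 A; residue B: 12 atoms, nearest 5.0 A;
  # residue C: exactly 10 atoms at 1.0 A (excluded: 10 is not > 10)
  lig <- ligand_graph(rbind(c(0, 0, 0)), "C")
  mk_res <- function(n, dist, label) {
    coords <- cbind(dist + 0.1 * (seq_len(n) - 1), 0, 0)
    list(coords = coords, resid = rep(label, n))
  }
  a <- mk_res(12, 2.0, "A"); b <- mk_res(12, 5.0, "B")
  cc <- mk_res(10, 1.0, "C")
  prot <- pocket_structure(rbind(a$coords, b$coords, cc$coords),
                           rep("C", 34), numeric(34),
                           residue_ids = c(a$resid, b$resid, cc$resid))
  pk <- extract_pocket(prot, lig, radius = 3.5, min_atoms = 10)
  expect_setequal(unique(pk$residue_ids), "A")

  # boundary: an atom at exactly 3.5 A counts (closed bound)
  d <- mk_res(12, 3.5, "D")
  prot2 <- pocket_structure(d$coords, rep("C", 12), numeric(12),
                            residue_ids = d$resid)
  expect_silent(pk2 <- extract_pocket(prot2, lig))
  expect_equal(nrow(pk2$coords), 12)

  # nothing qualifies -> explicit error
  expect_error(extract_pocket(
    pocket_structure(b$coords, rep("C", 12), numeric(12),
                     residue_ids = b$resid), lig), "no pocket residues")
})

centered_fixture <- function() {
  lig <- fx_set(1)[[1]]
  lig$coords <- sweep(lig$coords, 2, colMeans(lig$coords))
  lig
}

test_that("pocket extraction equals the brute-force distance oracle", {
  lig <- centered_fixture()
  for (seed in 1:5) {
    prot <- make_synthetic_protein(n_residues = 30, seed = seed, spread = 8)
    got <- tryCatch(
      sort(unique(extract_pocket(prot, lig)$residue_ids)),
      error = function(e) character(0))
    expect_identical(got, oracle_extract_pocket(prot, lig))
  }
})

test_that("pocket extraction is invariant under joint rigid transforms", {
  lig <- centered_fixture()
  prot <- make_synthetic_protein(n_residues = 25, seed = 9, spread = 8)
  base <- sort(unique(extract_pocket(prot, lig)$residue_ids))
  expect_gt(length(base), 0)
  for (seed in 1:3) {
    tr <- random_rigid_transform(seed)
    prot2 <- prot; prot2$coords <- apply_rigid(prot$coords, tr)
    lig2 <- lig; lig2$coords <- apply_rigid(lig$coords, tr)
    expect_identical(sort(unique(extract_pocket(prot2, lig2)$residue_ids)),
                     base)
  }
})
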