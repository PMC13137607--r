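Package: ffguide
Title: Force-Field Guidance for 3D Molecular Generators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A training-free, physics-based guidance framework for 3D molecular
    generative models. Implements a differentiable MMFF94 intramolecular force
    field (bond stretch, angle bend, stretch-bend, out-of-plane, torsion,
    buffered 14-7 van der Waals and buffered Coulomb terms) with analytic
    gradients, extended with rigid protein-ligand van der Waals and
    electrostatic cross-terms. The energy gradient is injected as a correction
    step into Euler flow-matching and DDPM-style diffusion sampling loops, and
    drives a protein-conditioned post-optimization minimizer. Ships pose
    quality metrics (ligand strain energy per heavy atom, force-field
    validity), pocket extraction from PDB structures, and synthetic fixture
    generators (drug-like molecule sets, toy pockets, toy denoisers) so the
    whole pipeline is testable without external data. MMFF94 atom typing and
    parameter assignment are delegated to the RDKit toolkit through a bundled
    Python adapter; all energy and gradient kernels are implemented in R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the rdkit package, available as
    'python' on the PATH (used for MMFF94 atom typing, 3D embedding and as an
    independent reference implementation).
Config/testthat/edition: 3
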