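Package: rodgate
Title: Elastic-Rod Continuum Model of MscL Mechanosensitive Channel Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale continuum simulator of tension-driven gating of the
    bacterial mechanosensitive channel MscL. Transmembrane and amphipathic
    N-terminal helices are represented as elastic rods joined by a glycine
    hinge and nonlinear loop springs; the lipid bilayer acts on the rods
    through a depth-resolved lateral pressure profile and a Hamaker-type van
    der Waals surface traction law, all nondimensionalized by the protein
    Young's modulus. Includes helix-axis fitting and crossing-angle analysis
    for PDB structures, an idealized C5-symmetric pentamer builder, a
    quasi-static corotational beam solver with von Mises stress output,
    gating observables (helix tilt, effective pore radius, N-terminal radial
    displacement, bilayer thinning), in-silico deletion and glycine-linker
    variants, and sequence-level amphipathicity analysis (hydrophobic
    moments, helical wheels, PROSITE-style motif scanning).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    bio3d,
    minpack.lm,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
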