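Package: parapore
Title: Analysis of Paracellular Ion-Channel Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trajectory analysis toolkit for paracellular (tight-junction)
    ion-channel models such as claudin pore assemblies. Provides residue
    contact-map fingerprints, interface metrics (backbone hydrogen-bond
    counts, atom-pair distance series, persistence-thresholded electrostatic
    pair counts, Shrake-Rupley solvent-accessible surface area, backbone
    RMSD), a maximal-inscribed-sphere pore diameter profiler, bespoke ion
    permeation statistics (bottleneck-crossing detection, cuboid filtering,
    total axial displacement, mean ion counts, ion contact-time profiles,
    and displacement-versus-voltage selectivity regression), and a pore
    net-charge fingerprint. A synthetic toy-pore generator produces
    drift-diffusion ion trajectories with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
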