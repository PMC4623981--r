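Package: molssao
Title: Multi-Scale Screen-Space Ambient Occlusion for Molecular Graphics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A CPU reference implementation of multi-scale screen-space
    ambient occlusion (SSAO) for molecular scenes. Renders van der Waals
    sphere models read from PDB files and isosurfaces extracted from
    MRC/CCP4 density maps into color and linear eye-space depth buffers,
    then darkens pixels by a post-process occlusion estimate obtained by
    point or line sampling inside a user-tunable sampling sphere. The
    sampling-sphere diameter selects the spatial scale (cavities, pockets,
    grooves) that the shading emphasizes. Includes a cosine-weighted
    hemisphere ray-casting oracle against analytic scenes for validating
    the screen-space approximation, deterministic synthetic-fixture
    generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
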