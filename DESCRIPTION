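Package: titania
Title: TiO2 Nanosurface Construction and Phospholipid Adsorption Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds anatase and rutile TiO2 slabs and spherical nanoparticles
    with a coordination census of undercoordinated surface titanium, applies a
    coordination-based surface hydroxylation rule with charge accounting,
    computes lipid/water/ion system compositions, generates synthetic
    lipid-surface distance trajectories with known binding-mode structure, and
    analyses trajectories into number-density profiles, binding-mode
    probabilities, residence times, and adsorbed-lipid fractions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
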