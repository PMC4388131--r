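Package: modulogrid
Title: Grid Cells by Modulo Compression of Path Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulator and analysis suite for a neural architecture
    that generates entorhinal grid-cell activity by compressing a path-integration
    neural field through discretization and modulo projection.  Includes a 2D
    agent/arena simulator with noisy odometry and compass, visual place cells
    built from landmark-azimuth constellations, visual recalibration of path
    integration, NLMS association of grid activity with visual place cells,
    multimodal place-cell fusion, winner-take-all place cells learned from grids,
    and a spatial analysis pipeline (occupancy-normalised rate maps, spatial
    autocorrelograms, rotational-correlation curves and gridness scores).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
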