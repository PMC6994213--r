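Package: curiodrop
Title: Curiosity-Driven Exploration of Self-Propelled Droplet Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop exploration of multicomponent oil-in-water droplet
    formulations with a curiosity algorithm (random goal exploration): a
    locally weighted linear regression forward model, CMA-ES goal inversion
    on the oil-mixture simplex, and a random parameter-search baseline, run
    against a synthetic droplet environment that emulates rare high-activity
    formulation regions and a sharp temperature regime shift. Includes
    droplet tracking from image sequences (thresholding, centroid
    extraction, proximity-rule identity linking), behavior-space coverage
    analytics, Welch group comparison, behavior-based temperature inference,
    and derivation of time-temperature phase diagrams for six modes of
    droplet motion from speed and acceleration profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
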