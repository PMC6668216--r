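Package: onhvol
Title: Optic Nerve Head and Peripapillary Bruch's Membrane Volumetry from
    Radial OCT Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes optic nerve head volume, Bruch's membrane displacement
    volume and cup volume from segmented radial optical coherence tomography
    (OCT) B-scans (6 scans at 30 degree increments) by trapezoidal-prism
    interpolation across the 12 half-scan wedges, under three representations
    of Bruch's membrane in the artifact-prone peripapillary region
    (traditional, estimated, excluded). Includes macular ganglion cell
    complex disk volumetry, an analytic phantom generator with closed-form
    oracle volumes, cohort simulation, and clustered association models
    (identity-link generalized estimating equations with robust standard
    errors, one-eye linear regressions, Pearson correlations) linking the
    volumes to intracranial pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
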