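Package: larvadrift
Title: Larval Drift, Water-Mass Transport and Seabird Chick-Growth Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating the transport of cod (Gadus morhua) eggs
    and larvae along the Norwegian coast into the Barents Sea and linking
    the resulting larval supply near a seabird colony to common guillemot
    chick growth. Provides a synthetic ocean-field generator (coastal and
    Atlantic jets with seasonal and interannual variability), a
    water-mass-classified volume-transport diagnostic for hydrographic
    sections, an individual-based model of egg buoyancy, larval vertical
    migration, temperature- and size-dependent growth and Lagrangian drift,
    foraging-box accumulation statistics, and the statistical linkage stage
    (trend testing, detrending, arcsin transforms, backward AICc covariate
    selection and regression with autoregressive errors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
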