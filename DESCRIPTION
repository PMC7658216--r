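Package: nbudget
Title: Reactive-Nitrogen Input Budgeting and Mass-Conserving Spatial Disaggregation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes per-region reactive-nitrogen (Nr) input fluxes to six
    land-use types (cropland, forest, grassland, surface water, built-up,
    unused) from administrative activity data and coefficient libraries,
    spatially disaggregates regional totals onto an analysis grid by proxy
    surfaces with exact mass conservation, composites daily satellite
    trace-gas columns into monthly means to weight atmospheric deposition,
    derives surface-water N inputs and watershed budgets, and emits
    budget tables and maps. Includes a seeded synthetic-country generator
    with machine-readable ground truth so every pipeline stage has an
    exact oracle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
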