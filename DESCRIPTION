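Package: isps
Title: Inter-Subject Phase Synchronization Analysis for Blocked-Design fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exploratory analysis of multi-subject task fMRI by inter-subject
    phase synchronization (ISPS): per-voxel instantaneous phases from the
    Hilbert analytic signal, a group synchronization time series defined as
    one minus the circular variance of phases across subjects, spatial
    independent component analysis of the synchronization matrix with
    split-half replicability model-order selection, and association of
    component synchronization time courses with hemodynamic reference
    functions (Pearson correlation, Bonferroni correction, Fisher r-to-z
    contrasts with Cohen's q). Includes a blocked-design paradigm builder, a
    synthetic multi-subject data generator with planted synchronized networks
    and controllable inter-subject heterogeneity, a minimal mass-univariate
    GLM baseline for method comparison, and atlas overlap reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    signal,
    yaml,
    withr
Config/testthat/edition: 3
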