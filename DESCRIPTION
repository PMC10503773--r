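Package: hcsfoci
Title: High-Content Screening Analysis of DNA Damage Foci and Micronucleus Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for automated-microscopy genotoxicity assays:
    nuclei segmentation from a DNA counterstain channel with size, circularity
    and border quality-control filters; detection and counting of bright
    sub-nuclear DNA-repair foci (53BP1 or gamma-H2AX type) with a guard
    against pan-nuclear staining artifacts; scoring of binucleated cells and
    micronucleus frequency for the cytokinesis-block micronucleus assay;
    plate-level aggregation (replicate wells by independent experiments) with
    the Kruskal-Wallis / Mann-Whitney nonparametric test battery; WST-1
    viability and Cmax concentration-series rules; and DHR123 reactive oxygen
    species kinetics.  A two-channel synthetic fluorescence field generator
    with full planted ground truth makes every stage of the pipeline
    verifiable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
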