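Package: veasl
Title: Vessel-Encoded Pseudo-Continuous Arterial Spin Labeling Simulation and Encoding Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for vessel-encoded pseudo-continuous arterial spin labeling
    (VEASL) perfusion imaging. Includes a Bloch-equation simulator of the PCASL
    flow-driven inversion process with laminar-flow averaging and a parameter
    grid search for thin labeling planes, simulation of the spatial modulation
    of inversion efficiency produced by unipolar and bipolar vessel-encoding
    gradient blips, Hadamard-based encoding design with a Fourier cycle matcher
    and a randomized-column improved optimized encoding scheme (IOES),
    theoretical SNR-efficiency and motion-robustness evaluation, a simplified
    maximum a posteriori decoder of multi-cycle image stacks into vascular
    territory maps, and synthetic vessel geometries and perfusion phantoms for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
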