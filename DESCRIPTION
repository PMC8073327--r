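Package: blsentropy
Title: Branch Length Similarity Entropy Profiles for Binary Time Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Feature extraction for binary time series via branch length
    similarity (BLS) entropy. The "1" signals of a series are mapped onto a
    time circle; each signal defines a star network whose branch lengths are
    the circular time distances to every other signal, and the normalized
    Shannon entropy of the branch-length distribution yields a per-signal
    entropy profile. The package extracts the profile's characteristic
    features (local extrema, slope, inflection points), computes a
    cyclic-shift correlation similarity between profiles, binarizes planar
    movement trajectories through eight-way turning-angle coding, and
    provides seeded generators for uniform, triangular, random, and
    fractal-landscape binary series so every analysis is reproducible
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
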