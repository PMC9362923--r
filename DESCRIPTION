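Package: mtvf
Title: Annual Cultivated-Land Mapping with Time-Series Vector Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies satellite image time series into land-cover maps
    using time-series vector features. Per-pixel sequences of spectral
    band reflectances and vegetation indices across acquisition dates are
    treated as vectors, reduced to five features each (maximum, minimum,
    range, cosine against a unit reference vector, and distance from it),
    ranked by normalized Gini importance, pruned with an importance-group
    and out-of-bag-error selection procedure, and classified with a
    random forest. Includes a Gaussian maximum-likelihood classifier and
    thin support-vector-machine and neural-network comparators, a
    confusion-matrix accuracy module (overall, producer's and user's
    accuracy, kappa), and a seedable synthetic multi-date multispectral
    scene generator with class-specific phenology profiles for end-to-end
    testing without external imagery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    e1071,
    nnet,
    tiff,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
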