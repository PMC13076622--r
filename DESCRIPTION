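Package: crowncluster
Title: Unsupervised Tree Species Clustering from LiDAR Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Groups individually delineated tree point clouds by species
    without training data. Rotation-invariant 3D shape descriptors (principal
    component spreads, voxel-grid rotational-symmetry measures, and
    spline-compressed vertical profiles) are extracted per tree, fused into a
    weighted graph through rank-product edge weights, and partitioned by
    greedy modularity community detection. Includes semi-automatic species
    labelling by majority vote, mean-weight outlier scoring, Rand/Adjusted
    Rand evaluation, and a synthetic forest simulator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
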