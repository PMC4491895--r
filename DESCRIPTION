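Package: jrpnet
Title: Joint-Recurrence Weighted Protein Residue Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted protein residue interaction networks from
    per-residue scalar time series (e.g. C-alpha RMSD traces over a molecular
    dynamics trajectory). Each residue's series is delay-embedded (delay from
    the first minimum of the mutual information, dimension by false nearest
    neighbors), a recurrence matrix is computed with the threshold calibrated
    to a target recurrence rate, and joint recurrences between residue pairs,
    divided by the C-alpha distance, define edge weights. Betweenness and
    closeness centrality z-scores rank residues as candidate functional
    hotspots. Comparison networks (unweighted distance-cutoff and
    contact-count weighted), relative solvent accessibility classification,
    a synthetic coupled-oscillator generator for validation, and an
    end-to-end pipeline are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
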