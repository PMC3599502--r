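Package: rmsdalign
Title: Exact Protein Structure Alignment Under the RMSD
Version: 0.1.0
Authors@R:
    person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Algorithms for protein structure alignment of C-alpha traces
    under the root mean square deviation (RMSD): the largest common point
    set (LCP) and minimum aligned distance (MAD) problems.  Includes the
    optimal fixed-transformation dynamic program and its non-sequential
    min-cost-flow counterpart, the exact translation-space arrangement
    algorithm for model superposition (known residue correspondence),
    analytic lower and upper bounds on the RMSD, the binary-search
    reduction from MAD to LCP for integral coordinates, and the
    pseudo-polynomial lattice-enumeration algorithm for integer-coordinate
    chains with bounded consecutive-point distances.  A synthetic-data
    module generates protein-like integer random-walk chains with planted
    transformed fragments, and brute-force reference solvers serve as
    ground truth oracles for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
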