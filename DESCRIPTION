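Package: hdxresolve
Title: Residue-Level Exchange-Rate Classes from Overlapping HDX-MS Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-fragment counts of slow/medium/fast-exchanging amide
    hydrogens, measured by solution-phase hydrogen/deuterium exchange mass
    spectrometry on overlapping proteolytic fragments, into minimum-error
    assignments of exchange-rate classes to single residues. Provides an exact
    integer-programming solver with exhaustive enumeration of all optimal
    assignments (represented compactly as equivalence classes over parts), a
    polynomial-time minimum-cost-circulation solver for the two-class case, a
    recursive color-merging heuristic, a Lagrangian-relaxation branch-and-bound
    enumerator, consensus post-processing (single solution, majority vote,
    arithmetic mean) with per-part agreement scoring against reference rates,
    and a generator of synthetic digestion instances with planted colorings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    boot,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
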