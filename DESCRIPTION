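Package: mrsub
Title: Time to the Most Recent Substitution from Multiple Alignment Columns
Version: 0.1.0
Authors@R:
    person("mrsub", "developers", email = "mrsub@example.org", role = c("aut", "cre"))
Description: Estimates, for each column of a multiple genome alignment and a
    chosen target species, the expected evolutionary time to the most recent
    nucleotide substitution on the target lineage (t_MRS), its posterior
    standard deviation (sigma), and the probability q that no substitution
    occurred anywhere on the lineage.  Estimation is exact under a
    strand-symmetric (or GTR) continuous-time Markov substitution model on a
    rooted phylogenetic tree, using inside-outside dynamic programming with
    matrix-exponential integral kernels.  Also provides maximum-likelihood
    training of rate parameters and branch lengths with exact gradients,
    forward simulation with true substitution histories, posterior sampling
    of histories for validation, concestor-interval assignment of confident
    sites, and hypergeometric tissue-by-interval enrichment tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
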