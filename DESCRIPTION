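Package: girsanov
Type: Package
Title: Girsanov Path Reweighting for Langevin Dynamics and Markov State Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Splitting integrators (ABO/RVO families) for underdamped Langevin
    dynamics that record Girsanov path-reweighting factors on the fly,
    sliding-window assembly of path weights, and reweighted Markov state model
    estimation (transition counts, transition matrices, spectra and implied
    timescales). Ships the Mueller-Brown benchmark surface with linear and
    polynomial biases, harmonic and double-well toy potentials, columnar
    trajectory file formats, and config-driven experiment runners that compare
    direct, biased and reweighted estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, utils, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
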