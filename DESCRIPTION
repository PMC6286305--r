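Package: ribotunnel
Title: Nascent-Chain Compaction in the Ribosome Exit Tunnel
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale analysis of alpha-helix formation by nascent peptide
    chains inside the ribosome exit tunnel. Builds idealized helical and
    extended peptide conformers from internal coordinates, computes
    solvent-accessible surface area by Shrake-Rupley point sampling together
    with the hydrophobic-burial statistics dSASA and ddSASA, simulates
    glycosylation-mapping gel experiments, fits logistic
    glycosylation-versus-distance profiles to call nascent-chain compaction,
    and scores transmembrane segments for in-tunnel folding propensity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
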