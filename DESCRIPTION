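Package: aismiles
Title: Atom-in-SMILES Tokenization, Repetition Metrics and Token Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Environment-aware tokenization of SMILES strings. Rewrites each
    atomic token as an atom-in-SMILES (AIS) token carrying the central-atom
    descriptor, ring membership and sorted heavy-atom neighbors, and projects
    such token streams losslessly back to SMILES. Includes token-level
    repetition statistics (rep-l and normalized repetition rates) for
    comparing tokenization schemes, count-based AIS token fingerprints with
    Tanimoto similarity, bundled fixture molecule sets, a random SMILES
    enumerator and a canonicalization-pair builder for sequence-model
    training data, plus a command-line interface over all of it.
    Canonical SMILES are produced with OpenBabel via ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
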