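# Parser-level behavior: strict validation and agreement of per-atom
# perception (hydrogen counts, ring membership, aromaticity, charge) with
# an independent cheminformatics toolkit.

test_that("invalid SMILES are rejected with positional messages", {
  expect_error(atomwise_tokenize("CC("), "unmatched")
  expect_error(atomwise_tokenize("C1CC"), "unclosed ring")
  expect_error(atomwise_tokenize("CxC"), "position 2")
  expect_error(atomwise_tokenize("C=("), "dangling bond")
  expect_error(atomwise_tokenize("=CC"), "no preceding atom")
  expect_error(atomwise_tokenize("C%1C"), "two digits")
  expect_error(atomwise_tokenize(""), "non-empty")
  expect_error(atomwise_tokenize("[CH3:1]C"), "not supported")
})

test_that("per-atom perception matches an independent toolkit (RDKit)", {
  smiles <- c("Clc1csc2nc3ncncn3c12", "NCC(=O)O", "c1cc[nH]c1",
              "CC(=O)Oc1ccccc1C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
              "O=[N+]([O-])c1ccccc1", "N[C@@H](C)C(=O)O",
              "c1ccc2[nH]ccc2c1", "C1CC2CCC1C2", "CC(C)(C)c1ccccc1",
              "O=c1cc[nH]c(=O)[nH]1", "c1cnc2[nH]cnc2n1",
              "CCS", "CC#N", "OCC1OC(O)C(O)C(O)C1O")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "from rdkit import Chem",
    "out = []",
    "for smi in sys.stdin.read().split():",
    "    m = Chem.MolFromSmiles(smi, sanitize=True)",
    "    atoms = [{'el': a.GetSymbol(), 'h': a.GetTotalNumHs(),",
    "              'ring': a.IsInRing(), 'arom': a.GetIsAromatic(),",
    "              'q': a.GetFormalCharge()} for a in m.GetAtoms()]",
    "    out.append(atoms)",
    "print(json.dumps(out))"
  ), script)
  res <- system2("python", script, input = smiles, stdout = TRUE)
  ref <- jsonlite::fromJSON(paste(res, collapse = ""),
                            simplifyVector = FALSE)
  for (i in seq_along(smiles)) {
    seq <- ais_tokenize(smiles[[i]])
    toks <- seq$tokens[seq$atom_positions]
    expect_length(toks, length(ref[[i]]))
    for (j in seq_along(toks)) {
      p <- ref[[i]][[j]]
      body <- sub("^\\[(.*)\\]$", "\\1", toks[[j]])
      parts <- strsplit(body, ";", fixed = TRUE)[[1L]]
      central <- parts[[1L]]
      # element symbol (case carries aromaticity)
      m <- regmatches(central, regexec(
        "^([0-9]+)?([A-Za-z][a-z]?)(@@|@)?(H([0-9]+)?)?([+-][0-9]+|\\+|-)?$",
        central))[[1L]]
      sym <- m[[3L]]
      expect_equal(toupper(substr(sym, 1, 1)) == substr(sym, 1, 1),
                   !p$arom,
                   label = sprintf("%s atom %d aromatic case", smiles[[i]], j))
      expect_equal(toupper(substr(sym, 1, 1)), toupper(substr(p$el, 1, 1)))
      h_tok <- if (is.na(m[[5L]]) || !nzchar(m[[5L]])) 0L
               else if (nzchar(m[[6L]])) as.integer(m[[6L]]) else 1L
      expect_equal(h_tok, p$h,
                   label = sprintf("%s atom %d H count", smiles[[i]], j))
      expect_equal(parts[[2L]] == "R", p$ring,
                   label = sprintf("%s atom %d ring flag", smiles[[i]], j))
      q_tok <- if (is.na(m[[7L]]) || !nzchar(m[[7L]])) 0L
               else switch(m[[7L]], "+" = 1L, "-" = -1L,
                           as.integer(m[[7L]]))
      expect_equal(q_tok, p$q,
                   label = sprintf("%s atom %d charge", smiles[[i]], j))
    }
  }
})

test_that("explicit hydrogens are folded into the central atom", {
  a <- ais_tokenize("C([H])([H])([H])[H]")
  expect_equal(a$tokens, "[CH4;!R;]")
  expect_equal(a$source_smiles, "C")
  b <- ais_tokenize("[H]OC([H])([H])O[H]")
  expect_setequal(unique(b$tokens[b$atom_positions]),
                  c("[OH;!R;C]", "[CH2;!R;OO]"))
  expect_error(ais_tokenize("[2H]OC"), "unsupported explicit hydrogen")
})
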