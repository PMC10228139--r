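# Tokenizer behavior under both schemes, and the structural properties
# that make AIS a refinement of atom-wise tokenization.

test_that("atom-wise tokenization follows the SMILES token grammar", {
  expect_equal(
    atomwise_tokenize("Clc1csc2nc3ncncn3c12")$tokens,
    c("Cl", "c", "1", "c", "s", "c", "2", "n", "c", "3", "n", "c", "n",
      "c", "n", "3", "c", "1", "2"))
  expect_equal(atomwise_tokenize("CCO")$tokens, c("C", "C", "O"))
  expect_equal(atomwise_tokenize("C(Br)Cl")$tokens,
               c("C", "(", "Br", ")", "Cl"))
  # bracket atoms and %nn closures are single tokens
  expect_equal(atomwise_tokenize("[nH]1cccc1")$tokens[[1L]], "[nH]")
  expect_equal(atomwise_tokenize("C%10CCCCC%10")$tokens[[2L]], "%10")
  # concatenation reproduces the input exactly
  for (s in c("CC(=O)Oc1ccccc1C(=O)O", "N[C@@H](C)C(=O)O", "C/C=C\\C",
              "O=[N+]([O-])c1ccccc1")) {
    expect_identical(paste(atomwise_tokenize(s)$tokens, collapse = ""), s)
  }
})

test_that("AIS tokens carry central atom, ring flag and sorted neighbors", {
  expect_equal(ais_tokenize("C")$tokens, "[CH4;!R;]")
  expect_equal(ais_tokenize("CC")$tokens[c(1, 2)],
               c("[CH3;!R;C]", "[CH3;!R;C]"))
  g <- ais_tokenize("NCC(=O)O")
  atoms <- g$tokens[g$atom_positions]
  # both carbons distinct, both oxygens distinct
  expect_false(atoms[[2L]] == atoms[[3L]])
  expect_false(atoms[[4L]] == atoms[[5L]])
  # neighbor field is sorted and upper-case
  expect_equal(atoms[[3L]], "[C;!R;COO]")
})

test_that("carbon/nitrogen swap in fused aromatics is visible to AIS only", {
  a <- "Clc1csc2nc3ncncn3c12"
  b <- "Clc1csc2nc3nnccn3c12"
  expect_setequal(atomic_token_set(atomwise_tokenize(a)),
                  atomic_token_set(atomwise_tokenize(b)))
  sa <- atomic_token_set(ais_tokenize(a))
  sb <- atomic_token_set(ais_tokenize(b))
  sym_diff <- union(setdiff(sa, sb), setdiff(sb, sa))
  expect_length(sym_diff, 3L)
  expect_setequal(sym_diff, c("[cH;R;CN]", "[cH;R;NN]", "[n;R;CN]"))
})

test_that("token set operations behave as set algebra", {
  s <- atomic_token_set(ais_tokenize("CCO"))
  expect_setequal(union(setdiff(s, s), setdiff(s, s)), character(0L))
  s2 <- atomic_token_set(ais_tokenize("c1ccccc1"))
  expect_length(intersect(s, s2), 0L)
  expect_setequal(union(setdiff(s, s2), setdiff(s2, s)), union(s, s2))
})

test_that("AIS and atom-wise sequences align structurally", {
  for (s in all_fixture_smiles()) {
    aw <- atomwise_tokenize(s)
    ai <- ais_tokenize(s)
    expect_length(ai$tokens, length(aw$tokens))
    expect_identical(ai$atom_positions, aw$atom_positions)
    struct <- setdiff(seq_along(aw$tokens), aw$atom_positions)
    expect_identical(ai$tokens[struct], aw$tokens[struct])
    # atom_positions address atomic tokens only
    expect_true(all(startsWith(ai$tokens[ai$atom_positions], "[")))
  }
})

test_that("AIS tokens refine atom-wise tokens", {
  # The @/@@ suffix of an atom-wise token is an artifact of the traversal
  # (the same stereocenter reads @ or @@ depending on neighbor order), and
  # AIS stores chirality traversal-invariantly, so refinement is asserted
  # modulo the chirality notation.
  strip_chir <- function(v) gsub("@", "", v, fixed = TRUE)
  for (s in all_fixture_smiles()) {
    aw <- atomwise_tokenize(s)
    ai <- ais_tokenize(s)
    # two atoms sharing an AIS token always share the atom-wise token
    map <- split(strip_chir(aw$tokens[aw$atom_positions]),
                 strip_chir(ai$tokens[ai$atom_positions]))
    expect_true(all(vapply(map, function(v) length(unique(v)) == 1L,
                           logical(1L))), label = s)
    # hence AIS vocabularies are at least as large
    expect_gte(length(unique(strip_chir(atomic_token_set(ai)))),
               length(unique(strip_chir(atomic_token_set(aw)))))
    expect_gte(length(atomic_token_set(ai)), length(atomic_token_set(aw)))
  }
})

test_that("the AIS token multiset is invariant under SMILES enumeration", {
  mols <- c("CC(=O)Oc1ccccc1C(=O)O", "N[C@@H](C)C(=O)O",
            "Clc1csc2nc3ncncn3c12", "C1CC2CCC1C2", "CCCCO")
  for (i in seq_along(mols)) {
    ref <- sort(table(ais_tokenize(mols[[i]])$tokens[
      ais_tokenize(mols[[i]])$atom_positions]))
    for (e in enumerate_random_smiles(mols[[i]], 10L, seed = 100L + i)) {
      seq <- ais_tokenize(e)
      expect_identical(sort(table(seq$tokens[seq$atom_positions])), ref,
                       label = sprintf("enumeration %s of %s", e, mols[[i]]))
    }
  }
})
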