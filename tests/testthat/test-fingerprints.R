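# Count fingerprints and Tanimoto similarity: worked examples, metric
# axioms against a brute-force oracle, enumeration invariance,
# distribution determinism.

test_that("fingerprints count atomic AIS tokens only", {
  fp <- ais_fingerprint("CC")
  expect_equal(unclass(fp)[["[CH3;!R;C]"]], 2L)
  expect_equal(attr(fp, "n_atoms"), 2L)
  # n_atoms equals the heavy-atom count; structural tokens contribute 0
  for (s in c("CC(=O)Oc1ccccc1C(=O)O", "Clc1csc2nc3ncncn3c12", "C")) {
    fp <- ais_fingerprint(s)
    seq <- ais_tokenize(s)
    expect_equal(attr(fp, "n_atoms"), length(seq$atom_positions))
    expect_equal(sum(fp), attr(fp, "n_atoms"))
    expect_true(all(fp >= 1L))
  }
})

test_that("tanimoto reproduces direct min/max sums", {
  expect_equal(tanimoto(c(x = 2, y = 1), c(x = 1, z = 1), "count"), 0.25)
  f <- ais_fingerprint("CCO")
  expect_equal(tanimoto(f, f), 1.0)
  expect_equal(tanimoto(c(a = 1), c(b = 2)), 0)
  expect_error(tanimoto(numeric(0L), numeric(0L)), "undefined")
  expect_equal(tanimoto(c(a = 1), numeric(0L)), 0)
})

test_that("tanimoto satisfies the metric axioms on random fingerprints", {
  set.seed(31415)
  for (i in 1:1000) {
    a <- random_fingerprint(sample(1:8, 1L))
    b <- random_fingerprint(sample(1:8, 1L))
    for (mode in c("count", "binary")) {
      t_ab <- tanimoto(a, b, mode)
      expect_equal(t_ab, brute_tanimoto(a, b, mode))
      expect_equal(t_ab, tanimoto(b, a, mode))   # symmetry
      expect_gte(t_ab, 0); expect_lte(t_ab, 1)   # bounds
    }
    # count-mode similarity is 1 iff the maps are equal
    maps_equal <- setequal(names(a), names(b)) &&
      all(a[names(a)] == b[names(a)])
    expect_equal(tanimoto(a, b, "count") == 1, maps_equal)
  }
})

test_that("fingerprints are invariant under SMILES enumeration", {
  smiles <- load_fixture_set("druglike_small")$smiles[1:20]
  for (i in seq_along(smiles)) {
    ref <- ais_fingerprint(smiles[[i]])
    for (e in enumerate_random_smiles(smiles[[i]], 5L, seed = 900L + i)) {
      fp <- ais_fingerprint(e)
      expect_identical(sort(unclass(fp)), sort(unclass(ref)),
                       label = sprintf("%s vs %s", smiles[[i]], e))
    }
  }
})

test_that("pairwise similarity distributions are seeded and deterministic", {
  ms <- load_fixture_set("druglike_small")
  d1 <- pairwise_similarity_distribution(ms, n_pairs = 300L, seed = 11L)
  d2 <- pairwise_similarity_distribution(ms, n_pairs = 300L, seed = 11L)
  expect_identical(d1$histogram, d2$histogram)
  expect_identical(d1$similarities, d2$similarities)
  d3 <- pairwise_similarity_distribution(ms, n_pairs = 300L, seed = 12L)
  expect_false(identical(d1$similarities, d3$similarities))
  expect_equal(sum(d1$histogram$count), 300L)
  expect_true(all(d1$similarities >= 0 & d1$similarities <= 1))
  # diverse drug-like molecules: random pairs are mostly dissimilar
  expect_lt(d1$mode_similarity, 0.5)
})

test_that("degenerate sets give a point mass at 1 with a warning", {
  expect_warning(
    d <- pairwise_similarity_distribution(rep("CCO", 4L), n_pairs = 6L,
                                          seed = 5L),
    "degenerate")
  expect_true(all(d$similarities == 1))
})

test_that("pair sampling covers all unordered pairs exactly once at full draw", {
  ms <- c("C", "CC", "CCC", "CCCC", "CCCCC")
  d <- pairwise_similarity_distribution(ms, n_pairs = 10L, seed = 3L)
  expect_equal(length(d$similarities), choose(5, 2))
  expect_error(pairwise_similarity_distribution(ms, n_pairs = 11L, seed = 3L),
               "choose")
})
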