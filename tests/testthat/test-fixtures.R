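# Bundled sets, the random enumerator and the canonicalization-pair
# builder: registry contracts, chemical identities, determinism.

test_that("fixture registry loads pinned sets and rejects unknown names", {
  for (set in c("druglike_small", "linear_chains", "ring_probes",
                "octane_isomers")) {
    ms <- load_fixture_set(set)
    expect_s3_class(ms, "molecule_set")
    expect_identical(ms$origin, "fixture")
    expect_gt(length(ms), 0L)
  }
  expect_error(load_fixture_set("gdb13"), "available")
})

test_that("octane_isomers holds 18 distinct C8H18 constitutional isomers", {
  ms <- load_fixture_set("octane_isomers")
  expect_length(ms$smiles, 18L)
  expect_length(unique(canonical_smiles(ms)), 18L)
  for (s in ms$smiles) {
    seq <- ais_tokenize(s)
    atoms <- seq$tokens[seq$atom_positions]
    expect_length(atoms, 8L)                        # C8
    expect_true(all(grepl("^\\[C", atoms)))
    h <- vapply(atoms, function(t) {
      m <- regmatches(t, regexec("^\\[C(H([0-9]+)?)?;", t))[[1L]]
      if (!nzchar(m[[2L]])) 0L
      else if (nzchar(m[[3L]])) as.integer(m[[3L]]) else 1L
    }, 1L)
    expect_equal(sum(h), 18L, label = s)            # H18
  }
})

test_that("random enumerations are equivalent, seeded and reproducible", {
  out <- enumerate_random_smiles("CC(=O)Oc1ccccc1C(=O)O", 10L, seed = 77L)
  expect_length(out, 10L)
  expect_length(unique(canonical_smiles(out)), 1L)
  expect_identical(out,
                   enumerate_random_smiles("CC(=O)Oc1ccccc1C(=O)O", 10L,
                                           seed = 77L))
  expect_false(identical(
    out, enumerate_random_smiles("CC(=O)Oc1ccccc1C(=O)O", 10L, seed = 78L)))
  expect_identical(unique(enumerate_random_smiles("C", 5L, seed = 1L)), "C")
  expect_error(enumerate_random_smiles("C(", 3L, seed = 1L),
               class = "ais_parse_error")
})

test_that("pair builder emits k aligned, consistent pairs per molecule", {
  ms <- load_fixture_set("octane_isomers")$smiles[1:5]
  ps <- make_canonicalization_pairs(ms, augmentation = 10L, seed = 123L)
  expect_equal(nrow(ps$pairs), 50L)
  expect_identical(canonical_smiles(ps$pairs$source), ps$pairs$target)
  expect_identical(ps$pairs$target,
                   rep(canonical_smiles(ms), each = 10L))
  # k = 1 on m molecules gives exactly m pairs
  p1 <- make_canonicalization_pairs(ms, augmentation = 1L, seed = 123L)
  expect_equal(nrow(p1$pairs), 5L)
})

test_that("pair files are aligned and byte-identical under repeated seeds", {
  ms <- load_fixture_set("octane_isomers")$smiles[1:5]
  d1 <- tempfile(); d2 <- tempfile()
  ps1 <- make_canonicalization_pairs(ms, 10L, seed = 42L)
  ps2 <- make_canonicalization_pairs(rev(ms), 10L, seed = 42L)
  write_pair_files(ps1, d1, scheme = "ais")
  files <- paste0(d1, c(".src.smi", ".tgt.smi", ".src.tok", ".tgt.tok"))
  expect_true(all(file.exists(files)))
  expect_length(readLines(files[[1L]]), 50L)
  expect_length(readLines(files[[3L]]), 50L)
  # per-molecule substreams: reordering the set reorders but does not
  # change any molecule's sources
  expect_setequal(ps1$pairs$source, ps2$pairs$source)
  # byte-identical regeneration
  write_pair_files(make_canonicalization_pairs(ms, 10L, seed = 42L), d2,
                   scheme = "ais")
  for (ext in c(".src.smi", ".tgt.smi", ".src.tok", ".tgt.tok")) {
    expect_identical(readLines(paste0(d2, ext)), readLines(paste0(d1, ext)))
  }
  # source tokens detokenize back to the source line, bit-exactly
  src <- readLines(files[[1L]])
  tok <- read_token_file(files[[3L]])
  expect_identical(vapply(tok, ais_detokenize, ""), src)
})

test_that("molecules with little enumeration freedom fall back gracefully", {
  expect_message(
    ps <- make_canonicalization_pairs("C", augmentation = 5L, seed = 9L),
    "replacement")
  expect_equal(nrow(ps$pairs), 5L)
  expect_true(all(ps$pairs$source == "C"))
})

test_that("token-length filter drops over-long records", {
  long <- paste(rep("C", 200L), collapse = "")
  ms <- filter_by_token_length(c("CCO", long, "CCC"), max_tokens = 150L,
                               scheme = "atomwise")
  expect_equal(ms$smiles, c("CCO", "CCC"))
  expect_equal(attr(ms, "n_dropped"), 1L)
  expect_error(filter_by_token_length(long, max_tokens = 10L), "survive")
})
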