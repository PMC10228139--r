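---
title: "Atom-in-SMILES tokenization: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-in-SMILES tokenization: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aismiles)
```

## The token model

Atom-wise SMILES tokenization maps a molecule's string to atoms and
structural symbols one token each. All atoms with the same symbol become
indistinguishable in token space, although their chemistry differs with
their surroundings. AIS tokenization keeps the token *stream* (structural
tokens stay where they are) but replaces each atomic token with a
serialization of the atom's radius-1 environment:

```
[central;ring;neighbors]
```

Formally the map `f` acts token-wise: atomic tokens go to their atom
environment restricted to the central atom; every other token is fixed.
Because the structural skeleton is untouched and each AIS token records
everything needed to re-emit the atom (including its hydrogen count),
`f` is invertible: `ais_detokenize(ais_tokenize(s))` parses to the same
molecular graph as `s`, and reproduces `s` character-for-character when
`s` is in the pinned canonical dialect.

```{r}
ais_tokenize("NCC(=O)O")$tokens
ais_detokenize(ais_tokenize("Clc1csc2nc3ncncn3c12"))
```

## Serialization conventions

These conventions are fixed (not user parameters) so that every token is
deterministic and the projection back to SMILES is a string operation:

* **Central field order** — isotope, element symbol, chirality, hydrogen
  count, formal charge: exactly SMILES bracket-atom order, so the bracket
  projection of a token is `"[" + central + "]"`.
* **Aromaticity** — lower-case central symbol, as in SMILES itself. The
  parser takes aromaticity as written (no Hückel re-perception); the
  pinned canonical dialect (OpenBabel canonical SMILES, via ChemmineOB)
  writes aromatic form, so canonical inputs are always aromatic-form.
  Kekulé inputs tokenize and round-trip self-consistently as a different
  string dialect of the same graph.
* **Hydrogens** — always on the central atom (`H`, `H2`, ...; omitted
  when zero). Bare-atom hydrogen counts follow the standard default
  valences (B 3; C 4; N 3,5; O 2; P 3,5; S 2,4,6; halogens 1); bare
  aromatic atoms get `max(0, v_min − degree − 1)` with aromatic bonds
  counting one — the usual lowest-valence aromatic convention, verified
  against an independent toolkit in the test suite. Explicit `[H]` atoms
  are folded into their neighbor's count before tokenization (isotopic or
  charged hydrogens are rejected as unsupported).
* **Ring flag** — `R` when the atom lies on any cycle (equivalent to
  SSSR membership for atoms), `!R` otherwise, by analogy with SMARTS.
  Computed via graph bridges (igraph).
* **Neighbors** — heavy atoms only, radius 1, element symbols upper-case
  regardless of aromaticity, sorted lexicographically with multiplicity.
  Radius is fixed at 1 in this release.
* **Chirality** — stored traversal-invariantly. The as-written `@`/`@@`
  depends on the order neighbors appear in the string, so the same
  stereocenter would get different tokens in different enumerations of
  the same molecule. Tokens instead store the parity relative to a
  reference neighbor ordering (neighbors sorted by Morgan-refined atom
  rank, implicit hydrogen last); detokenization converts back to the
  as-written convention for whatever skeleton the tokens land in. When
  refinement cannot totally order the neighbors (then the marker is not
  a genuine stereocenter, or a rare meso-like tie), the suffix passes
  through unchanged on both paths. One consequence: a `[C@H]`/`[C@@H]`
  pair that differs only by traversal maps to one AIS token, so the
  refinement of atom-wise tokens holds modulo chirality markers.

## Repetition statistics

Token repetition is quantified per sequence as the number of positions
whose token already occurs among the preceding `w` tokens; the rate is
normalized by sequence length. With unbounded `w` (the default,
"as large as the sequence") this is length minus the number of distinct
tokens. The statistic is computed over **all** tokens, structural
included, because it is a property of the sequence a model must emit;
an atoms-only variant is available for sensitivity checks. Dataset
summaries report the arithmetic mean of per-molecule rates and their
sample standard deviation as the "deviation" statistic.

```{r}
normalized_repetition("CCCCCCCC", "atomwise")
normalized_repetition("CCCCCCCC", "ais")
dataset_rep_summary(load_fixture_set("octane_isomers"), "ais")
```

Because AIS tokens subdivide atom-wise tokens, the per-molecule AIS rate
never exceeds the atom-wise rate, and dataset means are strictly lower on
chemically diverse sets. For prediction screening,
`excess_repetition()` compares a predicted sequence with its ground
truth; pairs with two or more excess repeats are flagged by
`is_excess_repetition()`.

## Fingerprints

Dropping the structural tokens from an AIS sequence leaves a multiset of
atomic environments — a count fingerprint with no hashing and hence no
collisions. Similarity uses the Tanimoto coefficient; **count mode**
(min/max over the key union) is the default since the fingerprint is
count-valued, and **binary mode** (set Tanimoto) is provided for
comparability with bit-vector fingerprints. The pairwise similarity
distribution of a set is estimated from seeded uniform sampling of
unordered pairs without replacement, binned into 100 equal bins on
[0, 1]; the mode is reported as the densest bin's center. On the bundled
drug-like set the modal similarity of random pairs is far below 0.5,
i.e. unrelated molecules rarely share environments — the resolution
property that makes the fingerprint usable.

## Fixtures and generators

The bundled sets (`druglike_small` 60, `linear_chains` 60, `ring_probes`
45, `octane_isomers` 18 — the complete C8H18 constitutional isomers)
are chosen to span ring-rich, chain-rich and isomer-dense regimes at a
size where every test runs in seconds. They emulate the structural
variety of public corpora, not their scale or their exact chemistry:
results on them demonstrate correctness and direction of effects, not
corpus-level magnitudes (the modal similarity of a 2000-molecule public
screening set, for instance, is a property of that set).

`enumerate_random_smiles()` rewrites a parsed molecule along random
depth-first traversals; draws are independent, so duplicates can occur
for small molecules. `make_canonicalization_pairs()` reproduces the
structure of a canonicalization training protocol: for each molecule,
`k` enumerated sources paired with the pinned canonical target, the
×k augmentation level being the dial that makes the mapping task harder.
Per-molecule randomness derives from a stable hash of the canonical
form, so reordering a set never changes any molecule's pairs, and equal
seeds give byte-identical files. A token-length filter
(`filter_by_token_length()`, default 150 tokens) mirrors the usual
sequence-model preprocessing cutoff.

## Numerical and degenerate-input choices

* Unbounded windows use the identity rep-l = length − distinct count;
  windowed counting is an explicit loop. Position 1 is never a repeat.
* A window reading of "the previous `w` tokens" is pinned in tests;
  `w ≥ length − 1` coincides with the unbounded statistic.
* Single-atom molecules have repetition 0 under both schemes; the empty
  token sequence is a usage error, not a zero.
* Tanimoto of two empty fingerprints is an error (0/0); one empty
  fingerprint gives 0. A degenerate all-identical molecule set yields a
  point mass at 1 with a warning.
* Invalid SMILES fail fast with positions; OpenBabel is never used for
  validation because it silently repairs malformed input. Unsupported
  constructs (atom classes, decorated hydrogens, >2-letter or unknown
  elements) are rejected with descriptive errors rather than guessed at.

## Scope and limitations

* Environment radius is fixed at 1; symmetric substructures beyond the
  nearest neighborhood are not distinguished (long chains remain
  repetitive under every scheme).
* Aromaticity and canonical form are pinned to one toolkit's perception;
  cross-toolkit dialects (e.g. RDKit canonical SMILES) tokenize fine but
  string-level round-trip guarantees apply only to the pinned dialect.
* Polymer/reaction extensions (BigSMILES, CXSMILES, atom maps) and
  alternative string representations (SELFIES, DeepSMILES) are out of
  scope; the repetition machinery accepts any pre-tokenized sequence, so
  external schemes can be compared through token files.
* Test problem sizes (183 fixture molecules, 20 enumerations each, 10^3
  random sequences/fingerprints) were chosen as the package's own
  desk-scale defaults; all are parameters of the corresponding functions.
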