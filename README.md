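# aismiles

Atom-in-SMILES (AIS) tokenization for chemical language processing, in R.

## The problem

SMILES strings are the lingua franca for feeding molecules to sequence
models, and the standard preprocessing step tokenizes them *atom-wise*:
every carbon becomes the same token `C`, every aromatic nitrogen the same
`n`. That throws away exactly what chemistry cares about — two carbons in
glycine (`NCC(=O)O`) are chemically nothing alike, yet their tokens are
identical. The tiny vocabulary and highly repetitive token streams that
result are one driver of the degenerate, repetitive outputs that plague
neural sequence models.

AIS tokenization replaces each atomic token by an *environment-aware*
token built from the atom's radius-1 environment:

```
[central;ring;neighbors]
```

* **central** — the central-atom descriptor in SMILES bracket order:
  isotope, element symbol (lower-case iff aromatic), chirality (`@`/`@@`,
  stored traversal-invariantly), explicit hydrogen count, formal charge;
* **ring** — `R` if the atom is a ring member (SSSR sense), else `!R`;
* **neighbors** — heavy-atom neighbor element symbols, upper-case, sorted
  lexicographically, with multiplicity.

Structural tokens (ring digits, bonds, parentheses, dots) pass through
unchanged, so the mapping is a bijection on token streams and AIS
sequences project back to SMILES losslessly (`ais_detokenize()`).

The package also implements the analytics used to compare tokenization
schemes: the token-level repetition count **rep-l**
(`rep_l`, `normalized_repetition`, `dataset_rep_summary`,
`excess_repetition`), count-based **AIS fingerprints** with Tanimoto
similarity (`ais_fingerprint`, `tanimoto`,
`pairwise_similarity_distribution`), bundled fixture molecule sets, a
seeded random-SMILES enumerator and a canonicalization-pair builder for
sequence-model training data (`load_fixture_set`,
`enumerate_random_smiles`, `make_canonicalization_pairs`), plus a CLI.
Canonical SMILES (the pinned reference dialect) come from OpenBabel via
ChemmineOB.

## Worked example

```r
library(aismiles)

# Two fused aromatics that differ only by a C/N swap in one ring
a <- "Clc1csc2nc3ncncn3c12"
b <- "Clc1csc2nc3nnccn3c12"

setequal(atomic_token_set(atomwise_tokenize(a)),
         atomic_token_set(atomwise_tokenize(b)))
#> [1] TRUE                      # atom-wise tokens cannot see the swap

sa <- atomic_token_set(ais_tokenize(a))
sb <- atomic_token_set(ais_tokenize(b))
union(setdiff(sa, sb), setdiff(sb, sa))
#> [1] "[cH;R;NN]" "[n;R;CN]"  "[cH;R;CN]"   # AIS sees it: 3 tokens differ

ais_tokenize("NCC(=O)O")$tokens
#> [1] "[NH2;!R;C]"  "[CH2;!R;CN]" "[C;!R;COO]"  "("  "="
#> [6] "[O;!R;C]"    ")"           "[OH;!R;C]"   # glycine: both C and both O distinct

ais_detokenize(ais_tokenize(a))
#> [1] "Clc1csc2nc3ncncn3c12"    # lossless round trip

normalized_repetition("CCCCCCCC", "atomwise")   # octane
#> [1] 0.875                     # 7 of 8 tokens are repeats
normalized_repetition("CCCCCCCC", "ais")
#> [1] 0.75                      # AIS: two distinct environments

tanimoto(ais_fingerprint("CCO"), ais_fingerprint("CCCO"))
#> [1] 0.75
```

The drop from 0.875 to 0.75 on octane is the package's headline statistic
in miniature: across the bundled drug-like set the mean normalized
repetition rate falls from about 0.57 (atom-wise) to about 0.39 (AIS),
and it is never higher molecule-wise.

## Command line

```sh
AISTOK=$(Rscript -e 'cat(system.file("cli/aistok.R", package="aismiles"))')
Rscript $AISTOK tokenize --scheme ais --in mols.smi --out mols.tok
Rscript $AISTOK detokenize --in mols.tok --out back.smi
Rscript $AISTOK repstats --scheme ais --in mols.smi --window inf --out rep.tsv --summary
Rscript $AISTOK similarity --in mols.smi --pairs 1000 --seed 1 --out hist.tsv
Rscript $AISTOK make-pairs --in mols.smi --aug 10 --seed 1 --scheme ais --out-prefix train
```

Exit codes: 0 success, 1 usage error, 2 data error (with line numbers).

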