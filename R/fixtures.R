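#' Canonical SMILES (pinned dialect)
#'
#' Canonicalizes SMILES with OpenBabel (via \pkg{ChemmineOB}), the
#' package's pinned canonical dialect: aromatic rings are written in
#' lower-case aromatic form. Inputs are validated with the package's own
#' strict reader first, because OpenBabel silently repairs or drops
#' malformed records.
#'
#' @param smiles Character vector of SMILES (or a \code{molecule_set}).
#' @return Character vector of canonical SMILES, same length and order.
#' @export
canonical_smiles <- function(smiles) {
  smiles <- as_smiles_vector(smiles)
  if (length(smiles) == 0L) ais_usage_error("no SMILES given")
  for (i in seq_along(smiles)) {
    e <- tryCatch({ parse_smiles_graph(smiles[[i]]); NULL },
                  ais_error = function(e) conditionMessage(e))
    if (!is.null(e)) {
      ais_parse_error(sprintf("entry %d: %s (%s)", i, smiles[[i]], e))
    }
  }
  out <- ChemmineOB::convertFormat(
    "SMI", "CAN", paste0(paste(smiles, collapse = "\n"), "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
  lines <- sub("[ \t]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) != length(smiles)) {
    ais_parse_error(sprintf(
      "canonicalizer returned %d records for %d inputs",
      length(lines), length(smiles)))
  }
  lines
}

.FIXTURE_SETS <- c("druglike_small", "linear_chains", "ring_probes",
                   "octane_isomers")

#' Load a bundled fixture molecule set
#'
#' Small, versioned molecule sets shipped with the package so that every
#' analysis is runnable without downloads: \code{druglike_small} (60 small
#' organic drug molecules), \code{linear_chains} (60 chain-dominated
#' molecules: alkanes, alcohols, acids, ...), \code{ring_probes} (45 ring
#' systems: carbo- and heteroaromatics, fused and saturated rings) and
#' \code{octane_isomers} (the 18 constitutional isomers of
#' C\eqn{_8}H\eqn{_{18}}).
#'
#' @param name One of \code{"druglike_small"}, \code{"linear_chains"},
#'   \code{"ring_probes"}, \code{"octane_isomers"}.
#' @return A \code{molecule_set} with \code{origin = "fixture"}.
#' @examples
#' length(load_fixture_set("octane_isomers"))  # 18
#' @export
load_fixture_set <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% .FIXTURE_SETS)) {
    ais_usage_error(sprintf(
      "unknown fixture set '%s'; available: %s",
      if (is.character(name) && length(name) == 1L) name else "<not a name>",
      paste(.FIXTURE_SETS, collapse = ", ")))
  }
  path <- system.file("extdata", paste0(name, ".smi"), package = "aismiles",
                      mustWork = TRUE)
  ms <- read_smi(path, name = name, validate = TRUE)
  ms$origin <- "fixture"
  ms
}

#' Random SMILES enumerations of one molecule
#'
#' Writes \code{n} alternative SMILES strings for the same molecule by
#' serializing the parsed graph along random depth-first traversals
#' (random start atom, random neighbor order). Draws are independent, so
#' the same string can recur ("with replacement" across the enumeration
#' space); every output parses back to the same canonical form as the
#' input. Deterministic given \code{seed}.
#'
#' @param smiles A single SMILES string.
#' @param n Number of enumerations (>= 1).
#' @param seed Integer seed.
#' @return Character vector of length \code{n}.
#' @export
enumerate_random_smiles <- function(smiles, n, seed) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    ais_usage_error("n must be >= 1")
  }
  mol <- parse_smiles_normalized(smiles)
  with_seed(as.integer(seed), {
    vapply(seq_len(as.integer(n)),
           function(i) write_smiles(mol, order = "random"), "")
  })
}

#' Build canonicalization training pairs with augmentation
#'
#' For each molecule, emits \code{augmentation} (source, target) pairs:
#' the source a random SMILES enumeration, the target the pinned canonical
#' form. This is the input--output equivalent-mapping protocol used to
#' train sequence models that canonicalize SMILES, reproduced at fixture
#' scale. Sources are drawn per molecule from a substream seeded by a
#' stable hash of the canonical form, so reordering the input set does not
#' change any molecule's pairs. Distinct sources are preferred; molecules
#' admitting fewer distinct enumerations than \code{augmentation} fall
#' back to sampling with replacement (with a message).
#'
#' @param mols A \code{molecule_set} or character vector of SMILES.
#' @param augmentation Pairs per molecule (k >= 1).
#' @param seed Integer master seed.
#' @return A \code{canon_pair_set}: list with \code{pairs} (data frame:
#'   source, target), \code{augmentation}, \code{seed}.
#' @seealso [write_pair_files()]
#' @export
make_canonicalization_pairs <- function(mols, augmentation, seed) {
  if (!is.numeric(augmentation) || augmentation < 1) {
    ais_usage_error("augmentation must be >= 1")
  }
  k <- as.integer(augmentation)
  smiles <- as_smiles_vector(mols)
  targets <- canonical_smiles(smiles)
  src <- character(0L)
  tgt <- character(0L)
  for (i in seq_along(smiles)) {
    sub_seed <- derive_seed(as.integer(seed), targets[[i]])
    draws <- enumerate_random_smiles(smiles[[i]], 4L * k, sub_seed)
    uniq <- unique(draws)
    sources <- if (length(uniq) >= k) {
      uniq[seq_len(k)]
    } else {
      message(sprintf(
        "molecule %d (%s): only %d distinct enumerations for k = %d; sampling with replacement",
        i, smiles[[i]], length(uniq), k))
      draws[seq_len(k)]
    }
    chk <- canonical_smiles(sources)
    if (!all(chk == targets[[i]])) {
      ais_parse_error(sprintf(
        "internal consistency error: enumeration of '%s' changed the molecule",
        smiles[[i]]))
    }
    src <- c(src, sources)
    tgt <- c(tgt, rep(targets[[i]], k))
  }
  structure(
    list(pairs = data.frame(source = src, target = tgt,
                            stringsAsFactors = FALSE),
         augmentation = k, seed = as.integer(seed)),
    class = "canon_pair_set"
  )
}

#' @export
print.canon_pair_set <- function(x, ...) {
  cat(sprintf(
    "<canon_pair_set> %d pairs (augmentation x%d, seed %d)\n",
    nrow(x$pairs), x$augmentation, x$seed))
  invisible(x)
}

# Stable 31-bit seed derived from a master seed and a string key.
derive_seed <- function(seed, key) {
  h <- seed %% 2147483647L
  for (v in utf8ToInt(key)) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}

#' Write aligned pair files
#'
#' Writes a \code{canon_pair_set} as four aligned files:
#' \code{<prefix>.src.smi} / \code{<prefix>.tgt.smi} (one SMILES per line)
#' and \code{<prefix>.src.tok} / \code{<prefix>.tgt.tok} (space-separated
#' tokens under the chosen scheme), aligned by line number.
#'
#' @param pairs A \code{canon_pair_set}.
#' @param prefix Output path prefix.
#' @param scheme Tokenization scheme for the .tok files.
#' @return Invisibly, the four paths written.
#' @export
write_pair_files <- function(pairs, prefix, scheme = c("ais", "atomwise")) {
  scheme <- match.arg(scheme)
  if (!inherits(pairs, "canon_pair_set")) {
    ais_usage_error("pairs must be a canon_pair_set")
  }
  paths <- paste0(prefix, c(".src.smi", ".tgt.smi", ".src.tok", ".tgt.tok"))
  writeLines(pairs$pairs$source, paths[[1L]], useBytes = TRUE)
  writeLines(pairs$pairs$target, paths[[2L]], useBytes = TRUE)
  write_token_file(lapply(pairs$pairs$source,
                          function(s) tokenize_scheme(s, scheme)), paths[[3L]])
  write_token_file(lapply(pairs$pairs$target,
                          function(s) tokenize_scheme(s, scheme)), paths[[4L]])
  invisible(paths)
}

#' Drop over-long records
#'
#' Sequence models are commonly trained with a token-length cutoff;
#' this utility drops molecules whose token sequence under \code{scheme}
#' exceeds \code{max_tokens} (default 150).
#'
#' @param mols A \code{molecule_set} or character vector.
#' @param max_tokens Maximum allowed token count (default 150).
#' @param scheme Tokenization scheme used for counting.
#' @return A \code{molecule_set} with the surviving molecules, with
#'   attribute \code{n_dropped}.
#' @export
filter_by_token_length <- function(mols, max_tokens = 150L,
                                   scheme = c("ais", "atomwise")) {
  scheme <- match.arg(scheme)
  smiles <- as_smiles_vector(mols)
  len <- vapply(smiles,
                function(s) length(tokenize_scheme(s, scheme)$tokens), 1L)
  keep <- len <= max_tokens
  if (!any(keep)) ais_usage_error("no molecules survive the length filter")
  out <- molecule_set(smiles[keep],
                      name = if (inherits(mols, "molecule_set"))
                        mols$name else "filtered",
                      origin = if (inherits(mols, "molecule_set"))
                        mols$origin else "fixture",
                      validate = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
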