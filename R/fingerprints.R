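#' AIS token-frequency fingerprint
#'
#' Converts a molecule into its count fingerprint: the frequency of each
#' distinct atomic AIS token in the tokenized string. Structural tokens
#' contribute nothing and no hashing is applied, so the fingerprint is a
#' direct, collision-free readout of the atomic environments (radius-1
#' atom-centered fragments) present in the molecule.
#'
#' @param smiles A single SMILES string.
#' @return An \code{ais_fingerprint}: named integer vector of counts
#'   (names are AIS token strings), with attribute \code{n_atoms} equal to
#'   the heavy-atom count.
#' @examples
#' ais_fingerprint("CC")  # {"[CH3;!R;C]": 2}
#' @export
ais_fingerprint <- function(smiles) {
  seq <- ais_tokenize(smiles)
  toks <- seq$tokens[seq$atom_positions]
  tab <- table(toks)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(counts, n_atoms = sum(counts), class = "ais_fingerprint")
}

#' @export
print.ais_fingerprint <- function(x, ...) {
  cat(sprintf("<ais_fingerprint> %d atoms, %d distinct tokens\n",
              attr(x, "n_atoms"), length(x)))
  for (k in names(x)) cat(sprintf("  %-24s %d\n", k, x[[k]]))
  invisible(x)
}

#' Tanimoto similarity between fingerprints
#'
#' Count mode (the default) is the generalized min/max Tanimoto
#' coefficient over the union of keys,
#' \eqn{\sum_k \min(a_k, b_k) / \sum_k \max(a_k, b_k)}; binary mode is the
#' classical set Tanimoto \eqn{|A \cap B| / |A \cup B|} on key sets. Count
#' mode is the default because the AIS fingerprint is defined by token
#' frequencies; binary mode is kept for comparability with bit
#' fingerprints.
#'
#' @param a,b \code{ais_fingerprint}s, or named non-negative integer
#'   vectors.
#' @param mode \code{"count"} or \code{"binary"}.
#' @return Similarity in \[0, 1\]; symmetric; 1 iff the count maps are
#'   equal (count mode). Both fingerprints empty is an error; one empty
#'   gives 0.
#' @examples
#' tanimoto(c(x = 2, y = 1), c(x = 1, z = 1))  # 1/4
#' @export
tanimoto <- function(a, b, mode = c("count", "binary")) {
  mode <- match.arg(mode)
  a <- as_fp_counts(a); b <- as_fp_counts(b)
  if (length(a) == 0L && length(b) == 0L) {
    ais_usage_error("tanimoto of two empty fingerprints is undefined")
  }
  if (length(a) == 0L || length(b) == 0L) return(0)
  keys <- union(names(a), names(b))
  av <- ifelse(keys %in% names(a), a[keys], 0L)
  bv <- ifelse(keys %in% names(b), b[keys], 0L)
  av[is.na(av)] <- 0L; bv[is.na(bv)] <- 0L
  if (mode == "binary") {
    sum(av > 0L & bv > 0L) / sum(av > 0L | bv > 0L)
  } else {
    sum(pmin(av, bv)) / sum(pmax(av, bv))
  }
}

as_fp_counts <- function(x) {
  if (inherits(x, "ais_fingerprint")) return(unclass(x))
  if (is.numeric(x)) {
    if (length(x) > 0L && (is.null(names(x)) || any(!nzchar(names(x))))) {
      ais_usage_error("fingerprint vectors must be fully named")
    }
    if (any(x < 0)) ais_usage_error("fingerprint counts must be >= 0")
    return(x[x > 0])
  }
  ais_usage_error("expected an ais_fingerprint or named count vector")
}

#' Pairwise similarity distribution over a molecule set
#'
#' Samples unordered pairs of distinct molecules uniformly without
#' replacement, computes their AIS-fingerprint Tanimoto similarities and
#' bins them on \[0, 1\]. The modal similarity (densest bin center) of a
#' diverse set characterizes the resolution of the fingerprint: lower
#' modes mean random pairs look less alike, i.e. better resolving power.
#'
#' @param mols A \code{molecule_set} or character vector (at least 2
#'   molecules).
#' @param n_pairs Number of unordered pairs to sample (at most
#'   \code{choose(m, 2)}).
#' @param seed Integer seed; runs are deterministic given
#'   \code{(mols, n_pairs, seed)}.
#' @param mode Tanimoto mode, see [tanimoto()].
#' @param bins Number of equal-width bins on \[0, 1\] (default 100).
#' @return A \code{similarity_distribution}: list with \code{histogram}
#'   (data frame: bin_low, bin_high, bin_center, count, density),
#'   \code{mode_similarity} (densest bin center), \code{similarities},
#'   \code{n_pairs}, \code{mode} and \code{seed}.
#' @export
pairwise_similarity_distribution <- function(mols, n_pairs, seed,
                                             mode = c("count", "binary"),
                                             bins = 100L) {
  mode <- match.arg(mode)
  smiles <- as_smiles_vector(mols)
  m <- length(smiles)
  if (m < 2L) ais_usage_error("need at least 2 molecules")
  total <- m * (m - 1) / 2
  if (!is.numeric(n_pairs) || n_pairs < 1L || n_pairs > total) {
    ais_usage_error(sprintf(
      "n_pairs must be between 1 and choose(m, 2) = %.0f", total))
  }
  n_pairs <- as.integer(n_pairs)
  fps <- lapply(smiles, ais_fingerprint)

  ks <- with_seed(as.integer(seed), {
    if (total <= 2^31 - 1) sample.int(as.integer(total), n_pairs)
    else floor(stats::runif(n_pairs, 1, total + 1))  # not reached at desk scale
  })
  # unrank pair index k (1-based, pairs ordered (1,2),(1,3),...,(2,3),...)
  cum <- cumsum(seq.int(m - 1L, 1L))
  i <- findInterval(ks - 1L, c(0L, cum), rightmost.closed = FALSE,
                    left.open = FALSE)
  offset <- ks - c(0L, cum)[i]
  j <- i + offset
  sims <- vapply(seq_len(n_pairs),
                 function(t) tanimoto(fps[[i[[t]]]], fps[[j[[t]]]],
                                      mode = mode),
                 numeric(1L))
  if (all(sims == sims[[1L]]) && n_pairs > 1L) {
    warning("degenerate molecule set: all sampled similarities are identical",
            call. = FALSE)
  }
  breaks <- seq(0, 1, length.out = bins + 1L)
  cnt <- tabulate(pmin(findInterval(sims, breaks, rightmost.closed = TRUE),
                       bins), nbins = bins)
  hist <- data.frame(
    bin_low = breaks[-(bins + 1L)],
    bin_high = breaks[-1L],
    bin_center = (breaks[-(bins + 1L)] + breaks[-1L]) / 2,
    count = cnt,
    density = cnt / n_pairs * bins
  )
  structure(
    list(histogram = hist,
         mode_similarity = hist$bin_center[[which.max(cnt)]],
         similarities = sims, n_pairs = n_pairs, mode = mode,
         seed = as.integer(seed)),
    class = "similarity_distribution"
  )
}

#' @export
print.similarity_distribution <- function(x, ...) {
  cat(sprintf(
    "<similarity_distribution> %d pairs (%s Tanimoto), modal similarity %.3f, median %.3f\n",
    x$n_pairs, x$mode, x$mode_similarity, stats::median(x$similarities)))
  invisible(x)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
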