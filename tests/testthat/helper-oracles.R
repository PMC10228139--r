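# Shared helpers: independent brute-force oracles and small generators.
# Oracles deliberately avoid the implementation paths they check.

# Brute-force rep-l: literal double loop over (position, preceding window).
brute_rep_l <- function(tokens, window = Inf) {
  n <- length(tokens)
  cnt <- 0L
  for (t in seq_len(n)) {
    w <- if (is.infinite(window)) t - 1L else min(window, t - 1L)
    if (w >= 1L) {
      prev <- tokens[(t - w):(t - 1L)]
      if (tokens[[t]] %in% prev) cnt <- cnt + 1L
    }
  }
  cnt
}

# Brute-force Tanimoto over explicit key unions.
brute_tanimoto <- function(a, b, mode = "count") {
  keys <- union(names(a), names(b))
  av <- vapply(keys, function(k) if (k %in% names(a)) a[[k]] else 0, 1)
  bv <- vapply(keys, function(k) if (k %in% names(b)) b[[k]] else 0, 1)
  if (mode == "binary") {
    sum(av > 0 & bv > 0) / sum(av > 0 | bv > 0)
  } else {
    s_min <- 0; s_max <- 0
    for (i in seq_along(keys)) {
      s_min <- s_min + min(av[[i]], bv[[i]])
      s_max <- s_max + max(av[[i]], bv[[i]])
    }
    s_min / s_max
  }
}

random_token_sequence <- function(len, alphabet_size = 6L) {
  sample(LETTERS[seq_len(alphabet_size)], len, replace = TRUE)
}

random_fingerprint <- function(n_keys, key_pool = paste0("k", 1:12)) {
  keys <- sample(key_pool, n_keys)
  counts <- sample(1:5, n_keys, replace = TRUE)
  names(counts) <- keys
  counts
}

all_fixture_smiles <- function() {
  unlist(lapply(c("druglike_small", "linear_chains", "ring_probes",
                  "octane_isomers"),
                function(s) load_fixture_set(s)$smiles),
         use.names = FALSE)
}
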