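#' Token-level repetition count (rep-l)
#'
#' Counts positions whose token already occurs among the preceding
#' \code{window} tokens:
#' \deqn{\mathrm{rep\text{-}l} = \sum_{t=1}^{|s|} [\, s_t \in
#'   s_{t-w:t-1} \,]}{rep-l = sum_t [ s_t in s_(t-w):(t-1) ]}
#' where \eqn{s} is the token sequence, \eqn{|s|} its length and \eqn{w}
#' the window. With an unbounded window (the default, and the convention
#' used for dataset comparisons) this equals \eqn{|s|} minus the number of
#' distinct tokens. Repetition is counted over all tokens, structural ones
#' included, since the statistic is defined on the sequence; set
#' \code{atoms_only} upstream by passing only atomic tokens if desired.
#'
#' @param tokens Character vector of tokens (or a \code{token_sequence}).
#' @param window Number of preceding tokens considered; \code{Inf} for
#'   unbounded.
#' @return A \code{repetition_report}: list with \code{rep_l},
#'   \code{length}, \code{window} and \code{normalized} (= rep_l / length).
#' @examples
#' rep_l(c("C", "O", "C", "O"), window = 2)$rep_l
#' @export
rep_l <- function(tokens, window = Inf) {
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  if (!is.character(tokens) || length(tokens) == 0L) {
    ais_usage_error("tokens must be a non-empty character vector")
  }
  if (!(is.infinite(window) || (is.numeric(window) && window >= 1))) {
    ais_usage_error("window must be >= 1 or Inf")
  }
  n <- length(tokens)
  r <- if (is.infinite(window)) {
    n - length(unique(tokens))
  } else {
    w <- as.integer(window)
    cnt <- 0L
    for (t in seq_len(n)) {
      lo <- max(1L, t - w)
      if (t > 1L && tokens[[t]] %in% tokens[lo:(t - 1L)]) cnt <- cnt + 1L
    }
    cnt
  }
  structure(
    list(rep_l = as.integer(r), length = n, window = window,
         normalized = r / n),
    class = "repetition_report"
  )
}

#' @export
print.repetition_report <- function(x, ...) {
  cat(sprintf("<repetition_report> rep-l = %d / %d tokens (window %s), normalized = %.4f\n",
              x$rep_l, x$length,
              if (is.infinite(x$window)) "unbounded" else x$window,
              x$normalized))
  invisible(x)
}

#' Normalized repetition rate of a molecule under a tokenization scheme
#'
#' Tokenizes the SMILES under the given scheme and returns rep-l divided by
#' sequence length, with an unbounded window. Lower rates indicate a more
#' diverse, expressive token stream; AIS rates are never higher than
#' atom-wise rates for the same molecule because AIS tokens refine
#' atom-wise tokens.
#'
#' @param smiles A single SMILES string.
#' @param scheme \code{"atomwise"} or \code{"ais"}.
#' @param window Preceding-token window; default unbounded.
#' @param atoms_only Count repetition over atomic tokens only (default
#'   \code{FALSE}: all tokens, structural included).
#' @return Fraction in \[0, 1).
#' @examples
#' normalized_repetition("CCCCCCCC", "atomwise")  # 7/8
#' normalized_repetition("CCCCCCCC", "ais")       # 6/8
#' @export
normalized_repetition <- function(smiles, scheme = c("ais", "atomwise"),
                                  window = Inf, atoms_only = FALSE) {
  scheme <- match.arg(scheme)
  seq <- tokenize_scheme(smiles, scheme)
  toks <- if (atoms_only) seq$tokens[seq$atom_positions] else seq$tokens
  rep_l(toks, window = window)$normalized
}

tokenize_scheme <- function(smiles, scheme) {
  switch(scheme,
         atomwise = atomwise_tokenize(smiles),
         ais = ais_tokenize(smiles),
         ais_usage_error(sprintf("unknown scheme '%s'", scheme)))
}

#' Repetition summary over a molecule set
#'
#' Per-molecule repetition reports under one scheme, plus the arithmetic
#' mean of the normalized rates and their deviation (sample standard
#' deviation). Any unparseable member is an error listing the offending
#' entries; nothing is skipped silently.
#'
#' @param mols A \code{molecule_set} (see [molecule_set()]) or character
#'   vector of SMILES.
#' @inheritParams normalized_repetition
#' @return A \code{dataset_rep_summary}: list with \code{per_molecule}
#'   (data frame: smiles, length, rep_l, normalized), \code{mean},
#'   \code{deviation}, \code{scheme}, \code{window}.
#' @export
dataset_rep_summary <- function(mols, scheme = c("ais", "atomwise"),
                                window = Inf, atoms_only = FALSE) {
  scheme <- match.arg(scheme)
  smiles <- as_smiles_vector(mols)
  reports <- vector("list", length(smiles))
  bad <- character(0L)
  for (i in seq_along(smiles)) {
    r <- tryCatch({
      seq <- tokenize_scheme(smiles[[i]], scheme)
      toks <- if (atoms_only) seq$tokens[seq$atom_positions] else seq$tokens
      rep_l(toks, window = window)
    }, ais_error = function(e) e)
    if (inherits(r, "error")) {
      bad <- c(bad, sprintf("line %d: %s (%s)", i, smiles[[i]],
                            conditionMessage(r)))
    } else {
      reports[[i]] <- r
    }
  }
  if (length(bad) > 0L) {
    ais_parse_error(paste0("unparseable molecules:\n  ",
                           paste(bad, collapse = "\n  ")))
  }
  normalized <- vapply(reports, `[[`, numeric(1L), "normalized")
  structure(
    list(
      per_molecule = data.frame(
        smiles = smiles,
        length = vapply(reports, `[[`, integer(1L), "length"),
        rep_l = vapply(reports, `[[`, integer(1L), "rep_l"),
        normalized = normalized,
        stringsAsFactors = FALSE
      ),
      mean = mean(normalized),
      deviation = if (length(normalized) > 1L) stats::sd(normalized) else 0,
      scheme = scheme, window = window
    ),
    class = "dataset_rep_summary"
  )
}

#' @export
print.dataset_rep_summary <- function(x, ...) {
  cat(sprintf(
    "<dataset_rep_summary> %d molecules, scheme %s\n  mean normalized repetition = %.4f (sd %.4f)\n",
    nrow(x$per_molecule), x$scheme, x$mean, x$deviation))
  invisible(x)
}

#' Excess repetition of a prediction over its ground truth
#'
#' Difference in rep-l (unbounded window) between a predicted token
#' sequence and the ground-truth sequence. Predictions from sequence models
#' frequently degenerate into repetitive loops; a screening threshold of
#' two or more excess repeats flags such predictions.
#'
#' @param pred_tokens,gt_tokens Non-empty character vectors (or
#'   \code{token_sequence}s).
#' @return Integer: \code{rep_l(pred) - rep_l(gt)}.
#' @seealso [is_excess_repetition()]
#' @export
excess_repetition <- function(pred_tokens, gt_tokens) {
  rep_l(pred_tokens)$rep_l - rep_l(gt_tokens)$rep_l
}

#' @rdname excess_repetition
#' @param threshold Flagging threshold (default 2).
#' @return \code{is_excess_repetition}: logical, \code{TRUE} when the
#'   excess is at least \code{threshold}.
#' @export
is_excess_repetition <- function(pred_tokens, gt_tokens, threshold = 2L) {
  excess_repetition(pred_tokens, gt_tokens) >= threshold
}
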