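#' Tokenize a SMILES string atom-wise
#'
#' Splits a SMILES string into the standard token classes: atoms (bracket
#' atoms, two-letter halogens and aromatic lower-case symbols are single
#' tokens), ring-closure digits and \code{\%nn} labels, bond symbols
#' (\code{- = # $ : / \\}), branch parentheses and the dot. Concatenating
#' the tokens in order reproduces the input exactly. The input must be
#' valid SMILES; syntactic problems raise a parse error naming the
#' offending position.
#'
#' @param smiles A single SMILES string.
#' @return A \code{token_sequence} object: a list with \code{tokens}
#'   (character vector), \code{scheme} (\code{"atomwise"}),
#'   \code{source_smiles} and \code{atom_positions} (1-based indices of the
#'   atomic tokens, in SMILES reading order).
#' @examples
#' atomwise_tokenize("C(Br)Cl")$tokens
#' @seealso [ais_tokenize()], [ais_detokenize()]
#' @export
atomwise_tokenize <- function(smiles) {
  mol <- parse_smiles_graph(smiles)  # full parse: validation
  new_token_sequence(mol$tokens, "atomwise", smiles,
                     which(!is.na(mol$token_atom)))
}

#' Tokenize a SMILES string into atom-in-SMILES tokens
#'
#' Rewrites every atomic token of the SMILES string as an environment-aware
#' atom-in-SMILES (AIS) token \code{[central;ring;neighbors]}, where
#' \code{central} is the central-atom descriptor (isotope, element symbol in
#' lower case iff aromatic, chirality, explicit hydrogen count, formal
#' charge), \code{ring} is \code{R} for ring members and \code{!R}
#' otherwise, and \code{neighbors} are the heavy-atom neighbor element
#' symbols, upper-case, sorted lexicographically. Structural tokens
#' (ring digits, bonds, parentheses, dots) are kept verbatim in the same
#' positions as in [atomwise_tokenize()].
#'
#' Explicit \code{[H]} atoms are folded into the implicit hydrogen count of
#' their heavy neighbor first (the AIS descriptor carries hydrogens on the
#' central atom); in that case the token positions refer to the normalized
#' string, available as \code{source_smiles}.
#'
#' @inheritParams atomwise_tokenize
#' @return A \code{token_sequence} with \code{scheme = "ais"}.
#' @examples
#' ais_tokenize("NCC(=O)O")$tokens
#' @export
ais_tokenize <- function(smiles) {
  mol <- parse_smiles_normalized(smiles)
  toks <- mol$tokens
  idx <- which(!is.na(mol$token_atom))
  # chirality suffixes are stored traversal-invariantly (see chirality.R)
  ranks <- if (any(mol$chiral != "")) atom_ranks(mol) else NULL
  for (k in idx) {
    toks[[k]] <- render_ais_token(mol, mol$token_atom[[k]], ranks)
  }
  new_token_sequence(toks, "ais", mol$smiles, idx)
}

# Serialize the AIS token for atom a of a parsed molecule.
render_ais_token <- function(mol, a, ranks = NULL) {
  nbrs <- atom_neighbors(mol, a)
  nb <- if (length(nbrs) == 0L) "" else
    paste(sort(mol$element[nbrs], method = "radix"), collapse = "")
  chir <- if (is.null(ranks)) mol$chiral[[a]]
          else invariant_chirality(mol, a, ranks)
  sprintf("[%s;%s;%s]", central_descriptor(mol, a, chiral = chir),
          if (mol$in_ring[[a]]) "R" else "!R", nb)
}

new_token_sequence <- function(tokens, scheme, source_smiles, atom_positions) {
  structure(
    list(tokens = as.character(tokens), scheme = scheme,
         source_smiles = source_smiles,
         atom_positions = as.integer(atom_positions)),
    class = "token_sequence"
  )
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence: %s, %d tokens (%d atomic)>\n  %s\n",
              x$scheme, length(x$tokens), length(x$atom_positions),
              paste(x$tokens, collapse = " ")))
  invisible(x)
}

#' @export
format.token_sequence <- function(x, ...) paste(x$tokens, collapse = " ")

#' @export
as.character.token_sequence <- function(x, ...) x$tokens

is_ais_atom_token <- function(tok) {
  startsWith(tok, "[") & endsWith(tok, "]") &
    lengths(regmatches(tok, gregexpr(";", tok, fixed = TRUE))) == 2L
}

# Parse one AIS atomic token into its fields.
parse_ais_token <- function(tok) {
  if (length(tok) != 1L || !is_ais_atom_token(tok)) {
    ais_parse_error(sprintf(
      "malformed AIS token '%s': expected [central;ring;neighbors]", tok))
  }
  body <- substr(tok, 2L, nchar(tok) - 1L)
  parts <- strsplit(body, ";", fixed = TRUE)[[1L]]
  if (length(parts) == 2L) parts <- c(parts, "")  # empty neighbor field
  if (length(parts) != 3L) {
    ais_parse_error(sprintf("malformed AIS token '%s': wrong field count", tok))
  }
  if (!(parts[[2L]] %in% c("R", "!R"))) {
    ais_parse_error(sprintf(
      "malformed AIS token '%s': ring flag must be R or !R", tok))
  }
  central <- parse_bracket_atom(parts[[1L]])
  list(central = parts[[1L]], ring = parts[[2L]], neighbors = parts[[3L]],
       isotope = central$isotope, symbol = central$symbol,
       aromatic = central$aromatic, chiral = central$chiral,
       hcount = central$hcount, charge = central$charge)
}

#' Project an AIS token sequence back to SMILES
#'
#' The inverse of [ais_tokenize()]: structural tokens are emitted verbatim
#' and every AIS atomic token is projected to a SMILES atom. A bare
#' organic-subset symbol is emitted when the descriptor carries no isotope,
#' chirality or charge and its hydrogen annotation matches the implicit
#' count a SMILES reader derives in context; otherwise a bracket atom is
#' emitted (for example central \code{nH} becomes \code{[nH]}). The result
#' is validated by re-parsing: per-atom hydrogen counts must match the
#' token annotations.
#'
#' For inputs produced by [ais_tokenize()] the projection recovers a SMILES
#' that parses to the same molecular graph, and reproduces the input string
#' character-for-character whenever no bracket promotion or demotion is
#' needed (in particular for canonical SMILES of [canonical_smiles()]).
#'
#' @param seq A \code{token_sequence} with \code{scheme = "ais"}, or a
#'   character vector of tokens following the AIS grammar.
#' @return A single SMILES string.
#' @examples
#' ais_detokenize(ais_tokenize("Clc1csc2nc3ncncn3c12"))
#' @export
ais_detokenize <- function(seq) {
  toks <- if (inherits(seq, "token_sequence")) {
    if (!identical(seq$scheme, "ais")) {
      ais_usage_error("ais_detokenize() expects an AIS token sequence")
    }
    seq$tokens
  } else if (is.character(seq)) {
    seq
  } else {
    ais_usage_error("seq must be a token_sequence or a character vector")
  }
  if (length(toks) == 0L) ais_usage_error("empty token sequence")

  stray <- startsWith(toks, "[") & !is_ais_atom_token(toks)
  if (any(stray)) {
    ais_parse_error(sprintf(
      "malformed AIS token '%s': expected [central;ring;neighbors]",
      toks[stray][[1L]]))
  }
  atom_idx <- which(is_ais_atom_token(toks))
  if (length(atom_idx) == 0L) {
    ais_parse_error("token sequence contains no AIS atomic tokens")
  }
  parsed <- lapply(toks[atom_idx], parse_ais_token)
  force_bracket <- rep(FALSE, length(atom_idx))
  # chirality suffix to write at each position; starts as the invariant
  # token suffix and is converted to the as-written convention below
  suffix <- vapply(parsed, `[[`, "", "chiral")

  rebuild_central <- function(p, sfx) {
    paste0(
      if (!is.na(p$isotope)) p$isotope else "",
      if (p$aromatic) tolower(p$symbol) else p$symbol,
      sfx,
      if (p$hcount == 1L) "H" else if (p$hcount > 1L)
        paste0("H", p$hcount) else "",
      if (p$charge == 0L) "" else if (p$charge == 1L) "+"
      else if (p$charge == -1L) "-" else if (p$charge > 1L)
        paste0("+", p$charge) else paste0("-", abs(p$charge))
    )
  }

  project <- function() {
    out <- toks
    for (j in seq_along(atom_idx)) {
      p <- parsed[[j]]
      bare_ok <- !force_bracket[[j]] && is.na(p$isotope) &&
        p$chiral == "" && p$charge == 0L &&
        ((p$aromatic && tolower(p$symbol) %in% .AROMATIC_ORGANIC) ||
         (!p$aromatic && p$symbol %in% .ORGANIC_SUBSET))
      out[[atom_idx[[j]]]] <- if (bare_ok) {
        if (p$aromatic) tolower(p$symbol) else p$symbol
      } else {
        paste0("[", rebuild_central(p, suffix[[j]]), "]")
      }
    }
    paste(out, collapse = "")
  }

  validate <- function(smi) {
    mol <- tryCatch(parse_smiles_graph(smi), error = function(e) e)
    if (inherits(mol, "error")) {
      ais_parse_error(sprintf(
        "projection produced unparseable SMILES '%s': %s",
        smi, conditionMessage(mol)))
    }
    if (mol$n_atoms != length(atom_idx)) {
      ais_parse_error("projection changed the number of atoms")
    }
    # atoms are created in reading order, so atom j is the j-th atomic token
    vapply(seq_along(atom_idx),
           function(j) mol$hcount[[j]] == parsed[[j]]$hcount, logical(1L))
  }

  smi <- project()
  ok <- validate(smi)
  if (!all(ok)) {
    force_bracket[!ok] <- TRUE
    smi <- project()
    ok <- validate(smi)
    if (!all(ok)) {
      ais_parse_error(
        "internal consistency error: hydrogen counts cannot be realized")
    }
  }
  # convert invariant chirality suffixes to the as-written convention of
  # the skeleton just produced (same graph, so same atom ranks)
  chiral_j <- which(nzchar(suffix))
  if (length(chiral_j) > 0L) {
    molC <- parse_smiles_graph(smi)
    ranks <- atom_ranks(molC)
    changed <- FALSE
    for (j in chiral_j) {
      s <- written_chirality(molC, j, ranks, parsed[[j]]$chiral)
      if (!identical(s, suffix[[j]])) {
        suffix[[j]] <- s
        changed <- TRUE
      }
    }
    if (changed) smi <- project()
  }
  smi
}

#' Distinct atomic tokens of a sequence
#'
#' Returns the set of distinct atomic tokens of a token sequence, excluding
#' structural tokens. Comparing such sets between closely related molecules
#' is how AIS tokenization exposes substitutions that atom-wise tokens
#' cannot see: the symmetric difference of the AIS token sets is non-empty
#' whenever any atomic environment changed.
#'
#' @param seq A \code{token_sequence}.
#' @return Character vector of distinct atomic tokens (unordered set).
#' @examples
#' atomic_token_set(ais_tokenize("NCC(=O)O"))
#' @export
atomic_token_set <- function(seq) {
  if (!inherits(seq, "token_sequence")) {
    ais_usage_error("seq must be a token_sequence")
  }
  unique(seq$tokens[seq$atom_positions])
}
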