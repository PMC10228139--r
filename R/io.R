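#' Create a molecule set
#'
#' A named collection of SMILES strings, the carrier for dataset-level
#' analyses. Every entry is validated at construction; invalid entries are
#' an error listing the offending positions.
#'
#' @param smiles Character vector of SMILES (no empty strings).
#' @param name Set name.
#' @param origin \code{"fixture"} or \code{"file"}.
#' @param validate Parse-check every entry (default \code{TRUE}).
#' @return A \code{molecule_set}.
#' @export
molecule_set <- function(smiles, name = "unnamed",
                         origin = c("fixture", "file"), validate = TRUE) {
  origin <- match.arg(origin)
  if (!is.character(smiles) || length(smiles) == 0L) {
    ais_usage_error("smiles must be a non-empty character vector")
  }
  if (any(is.na(smiles) | !nzchar(smiles))) {
    ais_usage_error("molecule sets may not contain empty SMILES")
  }
  if (validate) {
    bad <- character(0L)
    for (i in seq_along(smiles)) {
      e <- tryCatch({ parse_smiles_graph(smiles[[i]]); NULL },
                    ais_error = function(e) conditionMessage(e))
      if (!is.null(e)) bad <- c(bad, sprintf("line %d: %s (%s)",
                                             i, smiles[[i]], e))
    }
    if (length(bad) > 0L) {
      ais_parse_error(paste0("invalid molecules:\n  ",
                             paste(bad, collapse = "\n  ")))
    }
  }
  structure(list(name = name, smiles = unname(smiles), origin = origin),
            class = "molecule_set")
}

#' @export
print.molecule_set <- function(x, ...) {
  cat(sprintf("<molecule_set '%s'> %d molecules (origin: %s)\n",
              x$name, length(x$smiles), x$origin))
  invisible(x)
}

#' @export
length.molecule_set <- function(x) length(x$smiles)

as_smiles_vector <- function(x) {
  if (inherits(x, "molecule_set")) x$smiles
  else if (is.character(x)) x
  else ais_usage_error("expected a molecule_set or character vector of SMILES")
}

#' Read / write .smi files
#'
#' One record per line: a SMILES string, optionally followed by whitespace
#' and a name. Lines starting with \code{#} and blank lines are ignored on
#' input. Output is UTF-8, LF-terminated.
#'
#' @param path File path.
#' @param name Set name; defaults to the file name.
#' @param validate Parse-check entries (default \code{TRUE}); errors carry
#'   original line numbers.
#' @return \code{read_smi}: a \code{molecule_set} (molecule names, when
#'   present, in \code{attr(, "mol_names")}).
#' @export
read_smi <- function(path, name = NULL, validate = TRUE) {
  if (!file.exists(path)) ais_usage_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0L) ais_parse_error(sprintf("%s: no records", path))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  smiles <- vapply(fields, `[[`, "", 1L)
  mol_names <- vapply(fields, function(f)
    if (length(f) > 1L) paste(f[-1L], collapse = " ") else "", "")
  if (validate) {
    for (i in seq_along(smiles)) {
      e <- tryCatch({ parse_smiles_graph(smiles[[i]]); NULL },
                    ais_error = function(e) conditionMessage(e))
      if (!is.null(e)) {
        ais_parse_error(sprintf("%s: line %d: %s", path, keep[[i]], e))
      }
    }
  }
  ms <- molecule_set(smiles, name = if (is.null(name)) basename(path) else name,
                     origin = "file", validate = FALSE)
  attr(ms, "mol_names") <- mol_names
  ms
}

#' @rdname read_smi
#' @param mols A \code{molecule_set} or character vector of SMILES.
#' @param names Optional molecule names written after each SMILES.
#' @export
write_smi <- function(mols, path, names = NULL) {
  smiles <- as_smiles_vector(mols)
  lines <- if (is.null(names)) smiles else {
    ifelse(nzchar(names), paste(smiles, names), smiles)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write token files
#'
#' One molecule per line, tokens separated by single spaces. AIS tokens
#' contain no spaces, so the format is unambiguous and bit-exact.
#'
#' @param path File path.
#' @return \code{read_token_file}: list of character vectors, one per line.
#' @export
read_token_file <- function(path) {
  if (!file.exists(path)) ais_usage_error(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) ais_parse_error(sprintf("%s: no records", path))
  strsplit(lines, " ", fixed = TRUE)
}

#' @rdname read_token_file
#' @param seqs List of character vectors or \code{token_sequence}s.
#' @export
write_token_file <- function(seqs, path) {
  if (inherits(seqs, "token_sequence")) seqs <- list(seqs)
  lines <- vapply(seqs, function(s) {
    toks <- if (inherits(s, "token_sequence")) s$tokens else s
    paste(toks, collapse = " ")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
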