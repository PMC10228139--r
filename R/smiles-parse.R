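# Strict SMILES reader: longest-match token scan plus molecular graph
# construction. This is the substrate for both tokenization schemes; the
# scan must preserve the input string exactly (concatenating tokens
# reproduces it), so positions of atomic tokens can be replaced in situ.

# Elements writable without brackets, and their aromatic (lower-case) forms.
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
# Aromatic symbols permitted inside brackets.
.AROMATIC_BRACKET <- c("b", "c", "n", "o", "p", "s", "se", "as")

# Default (Daylight) valences used to derive implicit hydrogen counts.
.DEFAULT_VALENCE <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), F = 1L, Cl = 1L, Br = 1L, I = 1L
)

# Recognized element symbols for bracket atoms (main-group coverage is what
# matters for the bundled fixture chemistry; extend as needed).
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "Pt", "Au", "Hg", "Tl", "Pb", "Bi"
)

ais_parse_error <- function(msg, position = NA_integer_) {
  stop(structure(
    class = c("ais_parse_error", "ais_data_error", "ais_error",
              "error", "condition"),
    list(message = msg, call = NULL, position = position)
  ))
}

ais_usage_error <- function(msg) {
  stop(structure(
    class = c("ais_usage_error", "ais_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# --- token scan ------------------------------------------------------------

# Scan a SMILES string into tokens with classes. Classes:
#   atom, ring (closure digit or %nn), bond (- = # $ : / \), open, close, dot
scan_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    ais_usage_error("input SMILES must be a single non-empty string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  text <- character(0L)
  class <- character(0L)
  pos <- integer(0L)
  i <- 1L
  push <- function(tok, cl) {
    text[[length(text) + 1L]] <<- tok
    class[[length(class) + 1L]] <<- cl
    pos[[length(pos) + 1L]] <<- i
  }
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[[j]] != "]") j <- j + 1L
      if (j > n) ais_parse_error(
        sprintf("unclosed bracket atom starting at position %d", i), i)
      push(substr(smiles, i, j), "atom")
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n &&
               ((ch == "C" && chars[[i + 1L]] == "l") ||
                (ch == "B" && chars[[i + 1L]] == "r"))) {
      push(paste0(ch, chars[[i + 1L]]), "atom")
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I") ||
               ch %in% .AROMATIC_ORGANIC) {
      push(ch, "atom")
      i <- i + 1L
    } else if (ch >= "0" && ch <= "9") {
      push(ch, "ring")
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(smiles, i + 1L, i + 2L))) {
        ais_parse_error(sprintf(
          "'%%' at position %d must be followed by two digits", i), i)
      }
      push(substr(smiles, i, i + 2L), "ring")
      i <- i + 3L
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      push(ch, "bond")
      i <- i + 1L
    } else if (ch == "(") {
      push(ch, "open"); i <- i + 1L
    } else if (ch == ")") {
      push(ch, "close"); i <- i + 1L
    } else if (ch == ".") {
      push(ch, "dot"); i <- i + 1L
    } else {
      ais_parse_error(sprintf(
        "invalid character '%s' at position %d", ch, i), i)
    }
  }
  list(text = text, class = class, pos = pos)
}

# --- bracket atom grammar --------------------------------------------------

# Parse the contents of a bracket atom (without the enclosing []).
# Returns list(isotope, symbol, aromatic, chiral, hcount, charge).
parse_bracket_atom <- function(body, position = NA_integer_) {
  m <- regmatches(body, regexec(
    "^([0-9]+)?([A-Z][a-z]?|[a-z]{1,2})(@@|@)?(H([0-9]+)?)?([+-][0-9]+|\\+\\+|--|\\+|-)?$",
    body))[[1L]]
  if (length(m) == 0L) {
    ais_parse_error(sprintf("malformed bracket atom '[%s]'%s", body,
      if (grepl(":", body, fixed = TRUE))
        " (atom-class annotations are not supported)" else ""), position)
  }
  symbol <- m[[3L]]
  aromatic <- symbol %in% .AROMATIC_BRACKET
  elem <- if (aromatic) {
    paste0(toupper(substr(symbol, 1L, 1L)), substring(symbol, 2L))
  } else symbol
  if (!aromatic && !(symbol %in% .ELEMENTS)) {
    # A lone lower-case letter not in the aromatic set, or unknown element.
    ais_parse_error(sprintf("unknown element '%s' in bracket atom '[%s]'",
                            symbol, body), position)
  }
  if (aromatic && !(elem %in% .ELEMENTS)) {
    ais_parse_error(sprintf("unknown aromatic symbol '%s'", symbol), position)
  }
  hcount <- if (is.na(m[[5L]]) || !nzchar(m[[5L]])) 0L
            else if (nzchar(m[[6L]])) as.integer(m[[6L]]) else 1L
  chg_s <- m[[7L]]
  charge <- if (is.na(chg_s) || !nzchar(chg_s)) 0L
            else switch(chg_s, "+" = 1L, "-" = -1L, "++" = 2L, "--" = -2L,
                        as.integer(chg_s))
  list(
    isotope = if (nzchar(m[[2L]])) as.integer(m[[2L]]) else NA_integer_,
    symbol = elem, aromatic = aromatic,
    chiral = if (is.na(m[[4L]])) "" else m[[4L]],
    hcount = hcount, charge = charge
  )
}

# --- graph construction ----------------------------------------------------

.BOND_ORDER <- c("-" = 1L, "=" = 2L, "#" = 3L, "$" = 4L,
                 ":" = 1L, "/" = 1L, "\\" = 1L)

#' @keywords internal
#' @noRd
parse_smiles_graph <- function(smiles) {
  sc <- scan_smiles(smiles)
  ntok <- length(sc$text)

  # atom columns
  element <- character(0L); aromatic <- logical(0L)
  isotope <- integer(0L); chiral <- character(0L)
  hexplicit <- integer(0L); charge <- integer(0L); bracket <- logical(0L)
  # bonds
  b_a <- integer(0L); b_b <- integer(0L); b_sym <- character(0L)
  token_atom <- rep(NA_integer_, ntok)

  # per-atom ordered neighbor slots for chirality bookkeeping:
  # entries are atom ids, 0L for the implicit H, or NA to be filled by a
  # ring closure. Kept for every atom (cheap) so the writer can reuse them.
  nbr_slots <- list()

  prev <- 0L                 # current attachment atom (0 = none)
  pending <- NULL            # pending bond symbol
  stack <- integer(0L)
  ring_open <- list()        # digit -> list(atom, sym, slot)

  add_bond <- function(a, b, sym) {
    if (a == b) ais_parse_error("ring closure bonds an atom to itself")
    b_a[[length(b_a) + 1L]] <<- a
    b_b[[length(b_b) + 1L]] <<- b
    b_sym[[length(b_sym) + 1L]] <<- if (is.null(sym)) "" else sym
    length(b_sym)
  }

  for (k in seq_len(ntok)) {
    tok <- sc$text[[k]]
    cls <- sc$class[[k]]
    p <- sc$pos[[k]]
    if (cls == "atom") {
      if (startsWith(tok, "[")) {
        at <- parse_bracket_atom(substr(tok, 2L, nchar(tok) - 1L), p)
        br <- TRUE
      } else {
        at <- list(
          isotope = NA_integer_,
          symbol = if (tok %in% .AROMATIC_ORGANIC)
            toupper(tok) else tok,
          aromatic = tok %in% .AROMATIC_ORGANIC,
          chiral = "", hcount = NA_integer_, charge = 0L
        )
        br <- FALSE
      }
      element[[length(element) + 1L]] <- at$symbol
      aromatic[[length(aromatic) + 1L]] <- at$aromatic
      isotope[[length(isotope) + 1L]] <- at$isotope
      chiral[[length(chiral) + 1L]] <- at$chiral
      hexplicit[[length(hexplicit) + 1L]] <- at$hcount
      charge[[length(charge) + 1L]] <- at$charge
      bracket[[length(bracket) + 1L]] <- br
      id <- length(element)
      token_atom[[k]] <- id
      slots <- integer(0L)
      if (prev > 0L) {
        add_bond(prev, id, pending)
        nbr_slots[[prev]] <- c(nbr_slots[[prev]], id)
        slots <- c(slots, prev)
      } else if (!is.null(pending)) {
        ais_parse_error(sprintf(
          "bond symbol with no preceding atom near position %d", p), p)
      }
      # implicit-H slot right after the "from" atom (OpenSMILES order)
      if (br && at$hcount >= 1L) slots <- c(slots, 0L)
      nbr_slots[[id]] <- slots
      pending <- NULL
      prev <- id
    } else if (cls == "ring") {
      if (prev == 0L) ais_parse_error(sprintf(
        "ring closure '%s' with no preceding atom at position %d", tok, p), p)
      key <- if (startsWith(tok, "%")) substring(tok, 2L) else tok
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        if (op$atom == prev) ais_parse_error(sprintf(
          "ring closure '%s' bonds atom to itself at position %d", tok, p), p)
        sym <- ""
        if (nzchar(op$sym) && !is.null(pending) && nzchar(pending) &&
            op$sym != pending) {
          # complementary directional symbols describe the same bond
          flip <- c("/" = "\\", "\\" = "/")
          if (!identical(unname(flip[op$sym]), pending)) {
            ais_parse_error(sprintf(
              "conflicting bond symbols on ring closure '%s'", tok), p)
          }
        }
        if (nzchar(op$sym)) sym <- op$sym
        else if (!is.null(pending)) sym <- pending
        bid <- add_bond(op$atom, prev, if (nzchar(sym)) sym else NULL)
        # fill the reserved slots on both atoms
        nbr_slots[[op$atom]][[op$slot]] <- prev
        nbr_slots[[prev]] <- c(nbr_slots[[prev]], op$atom)
        ring_open[[key]] <- NULL
        pending <- NULL
      } else {
        nbr_slots[[prev]] <- c(nbr_slots[[prev]], NA_integer_)
        ring_open[[key]] <- list(
          atom = prev,
          sym = if (is.null(pending)) "" else pending,
          slot = length(nbr_slots[[prev]])
        )
        pending <- NULL
      }
    } else if (cls == "bond") {
      if (!is.null(pending)) ais_parse_error(sprintf(
        "two consecutive bond symbols at position %d", p), p)
      if (prev == 0L) ais_parse_error(sprintf(
        "bond symbol '%s' with no preceding atom at position %d", tok, p), p)
      pending <- tok
    } else if (cls == "open") {
      if (prev == 0L) ais_parse_error(sprintf(
        "branch opened with no preceding atom at position %d", p), p)
      if (!is.null(pending)) ais_parse_error(sprintf(
        "dangling bond before '(' at position %d", p), p)
      stack <- c(stack, prev)
    } else if (cls == "close") {
      if (length(stack) == 0L) ais_parse_error(sprintf(
        "unmatched ')' at position %d", p), p)
      if (!is.null(pending)) ais_parse_error(sprintf(
        "dangling bond before ')' at position %d", p), p)
      prev <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
    } else if (cls == "dot") {
      if (!is.null(pending)) ais_parse_error(sprintf(
        "dangling bond before '.' at position %d", p), p)
      prev <- 0L
    }
  }
  if (length(stack) > 0L) ais_parse_error("unmatched '(' in SMILES")
  if (!is.null(pending)) ais_parse_error("SMILES ends with a dangling bond")
  open_keys <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_keys) > 0L) ais_parse_error(sprintf(
    "unclosed ring closure(s): %s", paste(open_keys, collapse = ", ")))
  if (length(element) == 0L) ais_parse_error("SMILES contains no atoms")

  n_atoms <- length(element)
  n_bonds <- length(b_a)

  # bond order / aromatic bond flags
  b_order <- rep(1L, n_bonds)
  b_arom <- rep(FALSE, n_bonds)
  b_dir <- rep("", n_bonds)
  for (i in seq_len(n_bonds)) {
    s <- b_sym[[i]]
    if (s == "") {
      if (aromatic[[b_a[[i]]]] && aromatic[[b_b[[i]]]]) b_arom[[i]] <- TRUE
    } else if (s == ":") {
      b_arom[[i]] <- TRUE
    } else if (s %in% c("/", "\\")) {
      b_dir[[i]] <- s
    } else {
      b_order[[i]] <- .BOND_ORDER[[s]]
    }
  }

  mol <- list(
    smiles = smiles,
    tokens = sc$text, token_class = sc$class, token_pos = sc$pos,
    token_atom = token_atom,
    n_atoms = n_atoms,
    element = element, aromatic = aromatic, isotope = isotope,
    chiral = chiral, hexplicit = hexplicit, charge = charge,
    bracket = bracket,
    bond_a = b_a, bond_b = b_b, bond_order = b_order,
    bond_aromatic = b_arom, bond_dir = b_dir,
    nbr_slots = nbr_slots
  )
  mol$hcount <- compute_hcounts(mol)
  mol$in_ring <- compute_ring_membership(mol)
  class(mol) <- "smiles_mol"
  mol
}

# Implicit/total hydrogen count per atom. Bracket atoms carry their explicit
# count; bare atoms fill to the smallest default valence that accommodates
# the bond-order sum, with aromatic atoms reserving one valence unit for the
# aromatic system (no valence bumping for aromatic atoms).
compute_hcounts <- function(mol) {
  degsum <- numeric(mol$n_atoms)
  for (i in seq_along(mol$bond_a)) {
    o <- if (mol$bond_aromatic[[i]]) 1L else mol$bond_order[[i]]
    degsum[[mol$bond_a[[i]]]] <- degsum[[mol$bond_a[[i]]]] + o
    degsum[[mol$bond_b[[i]]]] <- degsum[[mol$bond_b[[i]]]] + o
  }
  h <- integer(mol$n_atoms)
  for (a in seq_len(mol$n_atoms)) {
    if (mol$bracket[[a]]) {
      h[[a]] <- mol$hexplicit[[a]]
    } else {
      vs <- .DEFAULT_VALENCE[[mol$element[[a]]]]
      d <- degsum[[a]] + if (mol$aromatic[[a]]) 1L else 0L
      if (mol$aromatic[[a]]) {
        h[[a]] <- max(0L, vs[[1L]] - as.integer(d))
      } else {
        v <- vs[vs >= d]
        h[[a]] <- if (length(v) == 0L) 0L else as.integer(v[[1L]] - d)
      }
    }
  }
  h
}

# Ring membership by SSSR-equivalent cycle test: an atom is in a ring iff it
# has an incident bond that is not a graph bridge.
compute_ring_membership <- function(mol) {
  in_ring <- rep(FALSE, mol$n_atoms)
  if (length(mol$bond_a) == 0L) return(in_ring)
  g <- igraph::graph_from_edgelist(cbind(mol$bond_a, mol$bond_b),
                                   directed = FALSE)
  if (igraph::vcount(g) < mol$n_atoms) {
    g <- igraph::add_vertices(g, mol$n_atoms - igraph::vcount(g))
  }
  br <- as.integer(igraph::bridges(g))
  cyc <- setdiff(seq_along(mol$bond_a), br)
  in_ring[unique(c(mol$bond_a[cyc], mol$bond_b[cyc]))] <- TRUE
  in_ring
}

# Neighbor atom ids (heavy atoms; the parse graph never holds H except
# explicit [H] atoms prior to normalization).
atom_neighbors <- function(mol, a) {
  c(mol$bond_b[mol$bond_a == a], mol$bond_a[mol$bond_b == a])
}

#' @export
print.smiles_mol <- function(x, ...) {
  cat(sprintf("<smiles_mol> %s\n  %d atoms, %d bonds, %d in rings\n",
              x$smiles, x$n_atoms, length(x$bond_a), sum(x$in_ring)))
  invisible(x)
}
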