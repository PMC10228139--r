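# SMILES writer: serializes a parsed molecule back to a string along a
# depth-first traversal. Traversal order is either the original atom order
# (deterministic, used after explicit-H normalization) or randomized (the
# random-enumeration generator). Atom renderings are order-invariant except
# for tetrahedral parity, which is recomputed per traversal.

# Render one atom as it should appear in output SMILES.
# Bare when possible (organic subset, no isotope/chirality/charge, and the
# implicit-H the reader would derive equals the atom's H count), otherwise
# a bracket atom.
render_atom <- function(mol, a, h_context = NULL) {
  el <- mol$element[[a]]
  sym <- if (mol$aromatic[[a]]) tolower(el) else el
  plain <- is.na(mol$isotope[[a]]) && mol$chiral[[a]] == "" &&
    mol$charge[[a]] == 0L
  if (plain && ((mol$aromatic[[a]] && tolower(el) %in% .AROMATIC_ORGANIC) ||
                (!mol$aromatic[[a]] && el %in% .ORGANIC_SUBSET))) {
    hc <- if (is.null(h_context)) implied_hcount(mol, a) else h_context
    if (hc == mol$hcount[[a]]) return(sym)
  }
  paste0("[", central_descriptor(mol, a), "]")
}

# What the reader would infer for atom a written bare in its bond context.
implied_hcount <- function(mol, a) {
  d <- 0L
  for (i in seq_along(mol$bond_a)) {
    if (mol$bond_a[[i]] == a || mol$bond_b[[i]] == a) {
      d <- d + if (mol$bond_aromatic[[i]]) 1L else mol$bond_order[[i]]
    }
  }
  vs <- .DEFAULT_VALENCE[[mol$element[[a]]]]
  if (is.null(vs)) return(-1L)
  if (mol$aromatic[[a]]) return(max(0L, vs[[1L]] - (d + 1L)))
  v <- vs[vs >= d]
  if (length(v) == 0L) 0L else as.integer(v[[1L]] - d)
}

# The central-atom descriptor: isotope, symbol (lower-case iff aromatic),
# chirality, explicit-H annotation, formal charge -- SMILES bracket order,
# so a bracket atom is "[" + descriptor + "]".
central_descriptor <- function(mol, a, chiral = NULL) {
  el <- mol$element[[a]]
  sym <- if (mol$aromatic[[a]]) tolower(el) else el
  ch <- if (is.null(chiral)) mol$chiral[[a]] else chiral
  h <- mol$hcount[[a]]
  paste0(
    if (!is.na(mol$isotope[[a]])) mol$isotope[[a]] else "",
    sym, ch,
    if (h == 1L) "H" else if (h > 1L) paste0("H", h) else "",
    format_charge(mol$charge[[a]])
  )
}

format_charge <- function(q) {
  if (q == 0L) ""
  else if (q == 1L) "+"
  else if (q == -1L) "-"
  else if (q > 1L) paste0("+", q)
  else paste0("-", abs(q))
}

# Permutation parity between two orderings of the same neighbor ids.
# Returns TRUE when the permutation is even.
perm_is_even <- function(from, to) {
  p <- match(to, from)
  if (anyNA(p)) stop("internal error: neighbor lists do not match")
  inversions <- 0L
  np <- length(p)
  if (np >= 2L) {
    for (i in seq_len(np - 1L)) {
      inversions <- inversions + sum(p[(i + 1L):np] < p[[i]])
    }
  }
  inversions %% 2L == 0L
}

bond_symbol_out <- function(mol, bid, from) {
  if (mol$bond_dir[[bid]] != "") {
    # directional symbols are relative to traversal direction
    if (mol$bond_a[[bid]] == from) return(mol$bond_dir[[bid]])
    return(c("/" = "\\", "\\" = "/")[[mol$bond_dir[[bid]]]])
  }
  if (mol$bond_aromatic[[bid]]) {
    # default between two aromatic atoms; ':' never needs emitting here
    return("")
  }
  o <- mol$bond_order[[bid]]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  if (o == 4L) return("$")
  # single: needs explicit '-' only between two aromatic atoms
  if (mol$aromatic[[mol$bond_a[[bid]]]] && mol$aromatic[[mol$bond_b[[bid]]]])
    return("-")
  ""
}

#' @keywords internal
#' @noRd
write_smiles <- function(mol, order = c("original", "random")) {
  order <- match.arg(order)
  n <- mol$n_atoms
  # adjacency: per atom, incident bond ids
  adj <- vector("list", n)
  for (i in seq_along(mol$bond_a)) {
    adj[[mol$bond_a[[i]]]] <- c(adj[[mol$bond_a[[i]]]], i)
    adj[[mol$bond_b[[i]]]] <- c(adj[[mol$bond_b[[i]]]], i)
  }
  other_end <- function(bid, a) {
    if (mol$bond_a[[bid]] == a) mol$bond_b[[bid]] else mol$bond_a[[bid]]
  }

  visited <- rep(FALSE, n)
  bond_used <- rep(FALSE, length(mol$bond_a))
  # pass 1 results
  children <- vector("list", n)    # tree-child bond ids, in traversal order
  ring_at <- vector("list", n)     # ring bond ids in digit-emission order
  parent_bond <- rep(NA_integer_, n)

  classify <- function(root) {
    stk <- list(list(atom = root, from = 0L))
    visited[[root]] <<- TRUE
    while (length(stk) > 0L) {
      fr <- stk[[length(stk)]]
      stk[[length(stk)]] <- NULL
      a <- fr$atom
      bs <- adj[[a]]
      if (order == "random" && length(bs) > 1L) bs <- sample(bs)
      tree_next <- list()
      for (bid in bs) {
        if (bond_used[[bid]]) next
        b <- other_end(bid, a)
        if (visited[[b]]) {
          # ring closure discovered at the later-visited end; digit order on
          # each atom follows discovery order
          bond_used[[bid]] <<- TRUE
          ring_at[[a]] <<- c(ring_at[[a]], bid)
          ring_at[[b]] <<- c(ring_at[[b]], bid)
        } else {
          bond_used[[bid]] <<- TRUE
          visited[[b]] <<- TRUE
          parent_bond[[b]] <<- bid
          children[[a]] <<- c(children[[a]], bid)
          tree_next[[length(tree_next) + 1L]] <- list(atom = b, from = a)
        }
      }
      # depth-first: push children in reverse so the first child is emitted
      # first (matters only for ring-digit discovery order, which must match
      # the emission pass)
      for (j in rev(seq_along(tree_next))) {
        stk[[length(stk) + 1L]] <- tree_next[[j]]
      }
    }
  }

  # Pass 1 is breadth-insensitive for ring digit *pairing* but the emission
  # pass below assigns actual digits, so discovery order only fixes the
  # per-atom order of closures.

  digits_active <- list()  # bond id (as character) -> list(num, s)

  emit_atom <- function(a, from_atom) {
    # ring digits for this atom, in ring_at order
    ring_txt <- ""
    ring_partners <- integer(0L)
    for (bid in ring_at[[a]]) {
      key <- as.character(bid)
      if (!is.null(digits_active[[key]])) {
        d <- digits_active[[key]]
        digits_active[[key]] <<- NULL
        ring_txt <- paste0(ring_txt, d$s)
      } else {
        taken <- if (length(digits_active) == 0L) integer(0L) else
          vapply(digits_active, function(x) x$num, 1L)
        cand <- min(setdiff(1:99, taken))
        d <- list(num = cand,
                  s = if (cand <= 9L) as.character(cand)
                      else sprintf("%%%02d", cand))
        digits_active[[key]] <<- d
        ring_txt <- paste0(ring_txt, bond_symbol_out(mol, bid, a), d$s)
      }
      ring_partners <- c(ring_partners, other_end(bid, a))
    }
    # chirality: recompute parity for the new neighbor order
    chiral <- mol$chiral[[a]]
    if (chiral != "") {
      new_order <- integer(0L)
      if (!is.na(from_atom) && from_atom > 0L) new_order <- c(new_order, from_atom)
      if (mol$hcount[[a]] >= 1L) new_order <- c(new_order, 0L)
      kid_atoms <- if (length(children[[a]]) == 0L) integer(0L) else
        vapply(children[[a]], function(b) other_end(b, a), 1L)
      new_order <- c(new_order, ring_partners, kid_atoms)
      old_order <- mol$nbr_slots[[a]]
      if (anyNA(old_order) || length(new_order) != length(old_order) ||
          !setequal(new_order, old_order)) {
        stop("internal error: inconsistent chiral neighbor ordering")
      }
      if (!perm_is_even(old_order, new_order)) {
        chiral <- if (chiral == "@") "@@" else "@"
      }
      atom_txt <- paste0("[", central_descriptor(mol, a, chiral = chiral), "]")
    } else {
      atom_txt <- render_atom(mol, a)
    }
    paste0(atom_txt, ring_txt)
  }

  emit_tree <- function(root) {
    out <- character(0L)
    # iterative pre-order with branch parentheses
    stk <- list(list(kind = "atom", atom = root, from = 0L, bond = NA_integer_))
    while (length(stk) > 0L) {
      fr <- stk[[length(stk)]]
      stk[[length(stk)]] <- NULL
      if (fr$kind == "text") { out <- c(out, fr$text); next }
      a <- fr$atom
      if (!is.na(fr$bond)) {
        out <- c(out, bond_symbol_out(mol, fr$bond, fr$from))
      }
      out <- c(out, emit_atom(a, fr$from))
      kids <- children[[a]]
      nk <- length(kids)
      if (nk > 0L) {
        frames <- list()
        for (j in seq_len(nk)) {
          b <- other_end(kids[[j]], a)
          kid_frame <- list(kind = "atom", atom = b, from = a,
                            bond = kids[[j]])
          if (j < nk) {
            frames[[length(frames) + 1L]] <- list(kind = "text", text = "(")
            frames[[length(frames) + 1L]] <- kid_frame
            frames[[length(frames) + 1L]] <- list(kind = "text", text = ")")
          } else {
            frames[[length(frames) + 1L]] <- kid_frame
          }
        }
        for (j in rev(seq_along(frames))) {
          stk[[length(stk) + 1L]] <- frames[[j]]
        }
      }
    }
    paste(out, collapse = "")
  }

  roots <- integer(0L)
  atom_order <- if (order == "random") sample.int(n) else seq_len(n)
  for (a in atom_order) {
    if (!visited[[a]]) {
      roots <- c(roots, a)
      classify(a)
    }
  }
  pieces <- vapply(roots, emit_tree, "")
  paste(pieces, collapse = ".")
}
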