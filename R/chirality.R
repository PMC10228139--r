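# Traversal-invariant chirality for AIS tokens.
#
# The @/@@ suffix in a SMILES string is defined relative to the order in
# which the neighbors happen to be written, so the same stereocenter can
# read @ in one enumeration and @@ in another. Inside an AIS token the
# suffix must be a property of the atom, not of the traversal: the token
# stores the parity relative to a reference neighbor ordering -- heavy
# neighbors sorted by Morgan-refined atom rank, implicit hydrogen last.
# Detokenization converts back to the as-written convention for whatever
# skeleton the tokens are embedded in, so round trips stay exact.
#
# When the refinement cannot distinguish the neighbors (symmetric
# environments; the marker is then not a genuine stereocenter, or a meso
# edge case), the as-written suffix is kept unchanged on both paths.

# Morgan-style iterative refinement; returns an integer rank per atom,
# identical across isomorphic traversal relabelings of the same molecule.
atom_ranks <- function(mol) {
  n <- mol$n_atoms
  nbrs <- vector("list", n)
  for (i in seq_along(mol$bond_a)) {
    nbrs[[mol$bond_a[[i]]]] <- c(nbrs[[mol$bond_a[[i]]]], mol$bond_b[[i]])
    nbrs[[mol$bond_b[[i]]]] <- c(nbrs[[mol$bond_b[[i]]]], mol$bond_a[[i]])
  }
  bond_key <- function(i) {
    if (mol$bond_aromatic[[i]]) "a" else as.character(mol$bond_order[[i]])
  }
  # per-atom multiset of (bond type to neighbor) for the seed invariant
  inc <- vapply(seq_len(n), function(a) {
    ks <- character(0L)
    for (i in seq_along(mol$bond_a)) {
      if (mol$bond_a[[i]] == a || mol$bond_b[[i]] == a) {
        ks <- c(ks, bond_key(i))
      }
    }
    paste(sort(ks, method = "radix"), collapse = "")
  }, "")
  seed <- paste(mol$element, mol$aromatic, mol$charge,
                ifelse(is.na(mol$isotope), 0L, mol$isotope),
                mol$hcount, lengths(nbrs), mol$in_ring, inc, sep = "|")
  r <- match(seed, sort(unique(seed), method = "radix"))
  repeat {
    key <- vapply(seq_len(n), function(a) {
      paste(r[[a]],
            paste(sort(r[nbrs[[a]]], method = "radix"), collapse = ","),
            sep = ":")
    }, "")
    r2 <- match(key, sort(unique(key), method = "radix"))
    if (length(unique(r2)) == length(unique(r))) break
    r <- r2
  }
  r
}

# Reference neighbor ordering for a chiral atom: heavy neighbors sorted by
# rank, implicit H (id 0) last. NULL when neighbors cannot be totally
# ordered (rank ties).
reference_order <- function(mol, a, ranks) {
  slots <- mol$nbr_slots[[a]]
  heavy <- slots[slots != 0L]
  if (anyNA(heavy)) return(NULL)
  if (any(duplicated(ranks[heavy]))) return(NULL)
  c(heavy[order(ranks[heavy])], if (0L %in% slots) 0L)
}

# Chirality suffix of atom a relative to the reference ordering (the form
# stored in AIS tokens). Falls back to the as-written suffix on ties.
invariant_chirality <- function(mol, a, ranks) {
  s <- mol$chiral[[a]]
  if (s == "") return("")
  ref <- reference_order(mol, a, ranks)
  if (is.null(ref)) return(s)
  if (perm_is_even(mol$nbr_slots[[a]], ref)) s
  else if (s == "@") "@@" else "@"
}

# Inverse: given the invariant suffix from a token and the as-written
# neighbor order of the skeleton the token landed in, produce the suffix
# to write at that position.
written_chirality <- function(mol, a, ranks, invariant_suffix) {
  if (invariant_suffix == "") return("")
  ref <- reference_order(mol, a, ranks)
  if (is.null(ref)) return(invariant_suffix)
  if (perm_is_even(ref, mol$nbr_slots[[a]])) invariant_suffix
  else if (invariant_suffix == "@") "@@" else "@"
}
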