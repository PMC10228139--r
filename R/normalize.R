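# Input normalization: explicit [H] atoms are folded into the implicit
# hydrogen count of their heavy neighbor before AIS tokenization, because
# the AIS descriptor carries hydrogens on the central atom. Isotopic,
# charged or otherwise decorated hydrogens cannot be folded and are
# rejected as unsupported.

fold_explicit_h <- function(mol) {
  hs <- which(mol$element == "H")
  if (length(hs) == 0L) return(mol)
  drop_bond <- logical(length(mol$bond_a))
  for (h in hs) {
    bonds_h <- which(mol$bond_a == h | mol$bond_b == h)
    ok <- is.na(mol$isotope[[h]]) && mol$charge[[h]] == 0L &&
      mol$chiral[[h]] == "" && mol$hcount[[h]] == 0L &&
      length(bonds_h) == 1L && mol$bond_order[[bonds_h]] == 1L &&
      !mol$bond_aromatic[[bonds_h]] && mol$bond_dir[[bonds_h]] == ""
    nb <- if (length(bonds_h) == 1L) {
      if (mol$bond_a[[bonds_h]] == h) mol$bond_b[[bonds_h]]
      else mol$bond_a[[bonds_h]]
    } else NA_integer_
    if (!ok || is.na(nb) || mol$element[[nb]] == "H") {
      ais_parse_error(
        "unsupported explicit hydrogen: only plain [H] bonded once to a heavy atom can be folded")
    }
    if (mol$bracket[[nb]]) {
      mol$hexplicit[[nb]] <- mol$hexplicit[[nb]] + 1L
    }
    # chirality bookkeeping: the folded H becomes the implicit-H slot
    if (mol$chiral[[nb]] != "") {
      if (0L %in% mol$nbr_slots[[nb]]) {
        ais_parse_error(
          "unsupported: chiral atom with more than one hydrogen")
      }
      mol$nbr_slots[[nb]][mol$nbr_slots[[nb]] == h] <- 0L
    } else {
      mol$nbr_slots[[nb]] <- mol$nbr_slots[[nb]][mol$nbr_slots[[nb]] != h]
    }
    drop_bond[[bonds_h]] <- TRUE
  }
  keep <- setdiff(seq_len(mol$n_atoms), hs)
  if (length(keep) == 0L) {
    ais_parse_error("molecule consists only of explicit hydrogens")
  }
  newid <- rep(NA_integer_, mol$n_atoms)
  newid[keep] <- seq_along(keep)
  remap_slots <- function(v) {
    ifelse(v == 0L, 0L, newid[pmax(v, 1L)])
  }
  kb <- !drop_bond
  out <- mol
  for (f in c("element", "aromatic", "isotope", "chiral", "hexplicit",
              "charge", "bracket")) {
    out[[f]] <- mol[[f]][keep]
  }
  out$n_atoms <- length(keep)
  out$bond_a <- newid[mol$bond_a[kb]]
  out$bond_b <- newid[mol$bond_b[kb]]
  out$bond_order <- mol$bond_order[kb]
  out$bond_aromatic <- mol$bond_aromatic[kb]
  out$bond_dir <- mol$bond_dir[kb]
  # bond ids changed; nbr_slots hold atom ids (or 0), just remap
  out$nbr_slots <- lapply(mol$nbr_slots[keep], remap_slots)
  out$hcount <- compute_hcounts(out)
  out$in_ring <- compute_ring_membership(out)
  # token arrays are stale after folding; the caller re-writes and re-parses
  out$tokens <- NULL; out$token_class <- NULL
  out$token_pos <- NULL; out$token_atom <- NULL
  out
}

# Parse with normalization: returns a smiles_mol whose token arrays are in
# sync with $smiles (the normalized string when folding occurred).
parse_smiles_normalized <- function(smiles) {
  mol <- parse_smiles_graph(smiles)
  if (any(mol$element == "H")) {
    folded <- fold_explicit_h(mol)
    mol <- parse_smiles_graph(write_smiles(folded, order = "original"))
  }
  mol
}
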