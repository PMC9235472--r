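# Molecular graphs: SMILES -> heavy-atom graph with 78-d binary atom features.

#' Atom symbol vocabulary for the one-hot featurizer
#'
#' The 44-slot element vocabulary used by the atom featurizer: 43 element
#' symbols common in drug-like and metabolic chemistry plus a terminal
#' \code{"other"} slot that absorbs anything unlisted. The list is frozen:
#' changing it changes feature indices, so it is versioned with the package.
#'
#' @return Character vector of length 44; the last entry is \code{"other"}.
#' @export
atom_symbol_vocabulary <- function() {
  c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca",
    "Fe", "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag",
    "Pd", "Co", "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni",
    "Cd", "In", "Mn", "Zr", "Cr", "Pt", "Hg", "Pb", "other")
}

#' Number of atom feature dimensions
#' @return Integer, 78 (44 symbol + 11 degree + 11 hydrogen-count +
#'   11 implicit-valence + 1 aromatic).
#' @export
atom_feature_width <- function() 78L

one_hot <- function(index, width) {
  v <- numeric(width)
  v[index] <- 1
  v
}

# Count buckets are 0..10; anything larger clamps to the last bucket.
count_bucket <- function(x) min(max(as.integer(x), 0L), 10L) + 1L

#' Featurize a single atom
#'
#' Builds the 78-dimensional binary atom feature vector: a 44-d one-hot over
#' the element vocabulary (unknown symbols map to the \code{"other"} slot),
#' three 11-d one-hots over counts 0--10 (heavy-atom degree, attached
#' hydrogens, implicit valence; values above 10 clamp to the last bucket),
#' and a single aromaticity bit.
#'
#' @param symbol Element symbol, e.g. \code{"C"}.
#' @param degree Number of adjacent heavy atoms.
#' @param num_h Number of attached hydrogens.
#' @param implicit_valence Implicit valence of the atom.
#' @param aromatic Logical; is the atom part of an aromatic system?
#' @return Numeric binary vector of length 78 with exactly 4 ones in the
#'   one-hot blocks plus the optional aromatic bit.
#' @export
featurize_atom <- function(symbol, degree, num_h, implicit_valence,
                           aromatic = FALSE) {
  vocab <- atom_symbol_vocabulary()
  idx <- match(symbol, vocab)
  if (is.na(idx)) idx <- length(vocab)
  c(one_hot(idx, 44L),
    one_hot(count_bucket(degree), 11L),
    one_hot(count_bucket(num_h), 11L),
    one_hot(count_bucket(implicit_valence), 11L),
    as.numeric(isTRUE(aromatic)))
}

# Parse the ATOM/BOND blocks of a single-molecule MOL2 string into
# atom types and a bond table.
parse_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  atom_at <- which(lines == "@<TRIPOS>ATOM")
  bond_at <- which(lines == "@<TRIPOS>BOND")
  if (length(atom_at) != 1L || length(bond_at) != 1L) return(NULL)
  section_end <- function(start) {
    nxt <- which(startsWith(lines, "@<TRIPOS>") & seq_along(lines) > start)
    if (length(nxt)) min(nxt) - 1L else length(lines)
  }
  atom_lines <- lines[seq(atom_at + 1L, section_end(atom_at))]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  if (!length(atom_lines)) return(NULL)
  atom_fields <- lapply(strsplit(trimws(atom_lines), "\\s+"), identity)
  types <- vapply(atom_fields, `[[`, character(1), 6L)
  bonds <- NULL
  if (bond_at + 1L <= section_end(bond_at)) {
    bond_lines <- lines[seq(bond_at + 1L, section_end(bond_at))]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines)) {
      bf <- strsplit(trimws(bond_lines), "\\s+")
      bonds <- data.frame(
        i = vapply(bf, function(x) as.integer(x[2]), integer(1)),
        j = vapply(bf, function(x) as.integer(x[3]), integer(1)),
        type = vapply(bf, `[[`, character(1), 4L)
      )
    }
  }
  list(types = types, bonds = bonds)
}

convert_smiles <- function(smiles, add_h = FALSE) {
  src <- paste0(smiles, "\n")
  out <- tryCatch(
    suppressWarnings(if (add_h) {
      ChemmineOB::convertFormat("SMI", "MOL2", source = src,
                                options = data.frame(names = "h", args = ""))
    } else {
      ChemmineOB::convertFormat("SMI", "MOL2", source = src)
    }),
    error = function(e) "")
  if (!nzchar(trimws(out))) return(NULL)
  parse_mol2(out)
}

#' Convert a SMILES string to a molecular graph
#'
#' Parses a SMILES string into a heavy-atom graph: hydrogens are implicit
#' and contribute only to the per-atom hydrogen count. Each atom carries the
#' 78-d binary feature vector of \code{\link{featurize_atom}}; aromaticity is
#' perceived by the chemistry toolkit (MOL2 \code{.ar} atom types). The atom
#' order is the toolkit's deterministic output order for the input string.
#'
#' @param smiles A SMILES string.
#' @return An object of class \code{molecule_graph}: a list with
#'   \code{n_atoms}, \code{atom_features} (N x 78 binary matrix),
#'   \code{adjacency} (N x N symmetric binary, zero diagonal),
#'   \code{bond_list} (two-column matrix of atom index pairs, i < j),
#'   \code{symbols}, and \code{smiles}.
#' @examples
#' \donttest{
#' g <- smiles_to_graph("CCO")
#' g$n_atoms            # 3 heavy atoms
#' g$bond_list          # bonds (1,2) and (2,3)
#' }
#' @export
smiles_to_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mol <- convert_smiles(smiles, add_h = FALSE)
  if (is.null(mol)) {
    stop(structure(
      class = c("smiles_parse_error", "error", "condition"),
      list(message = sprintf("cannot parse SMILES: %s", smiles),
           call = sys.call(-1))))
  }
  molh <- convert_smiles(smiles, add_h = TRUE)

  elements <- sub("\\..*$", "", mol$types)
  heavy <- which(elements != "H")
  n <- length(heavy)
  if (n == 0L) {
    stop(structure(
      class = c("smiles_parse_error", "error", "condition"),
      list(message = sprintf("no heavy atoms in SMILES: %s", smiles),
           call = sys.call(-1))))
  }
  remap <- match(seq_along(elements), heavy)  # old index -> heavy index

  adj <- matrix(0, n, n)
  aromatic <- grepl("\\.ar$", mol$types[heavy])
  if (!is.null(mol$bonds) && nrow(mol$bonds)) {
    for (b in seq_len(nrow(mol$bonds))) {
      bi <- remap[mol$bonds$i[b]]; bj <- remap[mol$bonds$j[b]]
      if (!is.na(bi) && !is.na(bj)) {
        adj[bi, bj] <- 1; adj[bj, bi] <- 1
        if (mol$bonds$type[b] == "ar") aromatic[c(bi, bj)] <- TRUE
      }
    }
  }

  # Hydrogen counts from the explicit-H conversion (same heavy-atom order).
  num_h <- integer(n)
  if (!is.null(molh)) {
    h_elements <- sub("\\..*$", "", molh$types)
    h_heavy <- which(h_elements != "H")
    if (length(h_heavy) == n && !is.null(molh$bonds) && nrow(molh$bonds)) {
      h_remap <- match(seq_along(h_elements), h_heavy)
      for (b in seq_len(nrow(molh$bonds))) {
        bi <- molh$bonds$i[b]; bj <- molh$bonds$j[b]
        if (h_elements[bi] == "H" && h_elements[bj] != "H")
          num_h[h_remap[bj]] <- num_h[h_remap[bj]] + 1L
        if (h_elements[bj] == "H" && h_elements[bi] != "H")
          num_h[h_remap[bi]] <- num_h[h_remap[bi]] + 1L
      }
    }
  }

  degree <- as.integer(rowSums(adj))
  symbols <- elements[heavy]
  feats <- t(vapply(seq_len(n), function(i) {
    featurize_atom(symbols[i], degree[i], num_h[i],
                   implicit_valence = num_h[i], aromatic = aromatic[i])
  }, numeric(atom_feature_width())))

  bl <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  bond_list <- if (nrow(bl)) {
    unname(cbind(pmin(bl[, 1], bl[, 2]), pmax(bl[, 1], bl[, 2])))
  } else {
    matrix(integer(0), 0, 2)
  }
  bond_list <- bond_list[order(bond_list[, 1], bond_list[, 2]), , drop = FALSE]

  structure(list(
    n_atoms = n,
    atom_features = feats,
    adjacency = adj,
    bond_list = bond_list,
    symbols = symbols,
    aromatic = aromatic,
    smiles = smiles
  ), class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("molecule_graph: %s (%d atoms, %d bonds)\n",
              x$smiles, x$n_atoms, nrow(x$bond_list)))
  invisible(x)
}

#' Test whether a SMILES string yields a valid molecular graph
#' @param smiles A SMILES string.
#' @return Logical.
#' @export
is_valid_smiles <- function(smiles) {
  !inherits(tryCatch(smiles_to_graph(smiles), error = identity), "error")
}
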