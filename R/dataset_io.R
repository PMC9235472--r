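# Reading, writing, filtering and synthesizing labeled compound tables.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a labeled compound table
#'
#' Validates and assembles the package's central data container: compound
#' identifiers, SMILES strings and a binary pathway-membership matrix.
#' Every compound must carry at least one positive label and identifiers
#' must be unique.
#'
#' @param ids Character vector of unique compound identifiers.
#' @param smiles Character vector of SMILES strings.
#' @param labels n x C binary matrix of pathway memberships.
#' @param pathway_names Character vector of C pathway names.
#' @return A \code{compound_table}.
#' @export
new_compound_table <- function(ids, smiles, labels, pathway_names) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  stopifnot(length(ids) == length(smiles), nrow(labels) == length(ids),
            ncol(labels) == length(pathway_names))
  if (anyDuplicated(ids)) stop("compound ids must be unique")
  if (ncol(labels) < 2L) stop("need at least 2 pathway labels")
  if (nrow(labels) && any(rowSums(labels) == 0L))
    stop("every compound must have at least one positive pathway label")
  dimnames(labels) <- list(ids, pathway_names)
  structure(list(ids = as.character(ids), smiles = as.character(smiles),
                 labels = labels, pathway_names = as.character(pathway_names)),
            class = "compound_table")
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("compound_table: %d compounds x %d pathway labels\n",
              length(x$ids), ncol(x$labels)))
  cat(" pathways:", paste(x$pathway_names, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a compound table by record index
#' @param table A \code{compound_table}.
#' @param idx Integer (or logical) record indices.
#' @return A \code{compound_table} with the selected records.
#' @export
subset_compound_table <- function(table, idx) {
  new_compound_table(table$ids[idx], table$smiles[idx],
                     table$labels[idx, , drop = FALSE], table$pathway_names)
}

#' Read a compound-pathway table from CSV
#'
#' Expects a header row with an \code{id} column, a \code{smiles} column and
#' one binary column per pathway label. Pathway names are taken from the
#' label column headers, in file order.
#'
#' @param path Path to a CSV file.
#' @param label_columns Character vector naming the label columns; by default
#'   every column other than \code{id} and \code{smiles}.
#' @return A \code{compound_table}.
#' @export
read_dataset <- function(path, label_columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("id", "smiles")) {
    if (!col %in% names(df))
      stop(sprintf("format error: missing required column '%s'", col))
  }
  if (is.null(label_columns))
    label_columns <- setdiff(names(df), c("id", "smiles"))
  missing <- setdiff(label_columns, names(df))
  if (length(missing))
    stop(sprintf("format error: missing label column(s): %s",
                 paste(missing, collapse = ", ")))
  lab <- as.matrix(df[, label_columns, drop = FALSE])
  bad <- which(!(lab %in% c(0, 1)), arr.ind = FALSE)
  if (length(bad)) {
    row <- ((bad[1] - 1) %% nrow(lab)) + 1
    stop(sprintf("validation error: non-binary label value '%s' at row %d",
                 lab[bad[1]], row))
  }
  new_compound_table(df$id, df$smiles, lab, label_columns)
}

#' Write a compound-pathway table to CSV
#' @param table A \code{compound_table}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_dataset <- function(table, path) {
  df <- data.frame(id = table$ids, smiles = table$smiles,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$labels, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove compounds whose SMILES cannot be parsed into molecular graphs
#'
#' The compound encoder needs a valid molecular graph per compound, so
#' records whose SMILES the chemistry toolkit rejects are dropped (not
#' fatal) and their ids returned for logging.
#'
#' @param table A \code{compound_table}.
#' @return A list with \code{table} (retained records) and
#'   \code{removed_ids}.
#' @export
filter_valid_structures <- function(table) {
  stopifnot(inherits(table, "compound_table"), length(table$ids) > 0L)
  ok <- vapply(table$smiles, is_valid_smiles, logical(1), USE.NAMES = FALSE)
  list(table = subset_compound_table(table, which(ok)),
       removed_ids = table$ids[!ok])
}

#' Summarize the label structure of a compound table
#'
#' @param table A \code{compound_table}.
#' @return A list with \code{per_label} (named positive counts),
#'   \code{single_label} / \code{multi_label} / \code{all_label} compound
#'   counts, and \code{total_entries} (total positive compound-pathway
#'   entries).
#' @export
label_statistics <- function(table) {
  stopifnot(inherits(table, "compound_table"), length(table$ids) > 0L)
  per_label <- colSums(table$labels)
  n_pos <- rowSums(table$labels)
  list(per_label = per_label,
       single_label = sum(n_pos == 1L),
       multi_label = sum(n_pos > 1L),
       all_label = sum(n_pos == ncol(table$labels)),
       total_entries = sum(per_label))
}

#' Assign compounds to cross-validation folds
#'
#' Uniform random assignment at the compound level (no label
#' stratification); fold sizes differ by at most one and the assignment is
#' deterministic given \code{seed}.
#'
#' @param table A \code{compound_table}.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A list with \code{fold} (0-based fold index per compound),
#'   \code{k}, and \code{seed}.
#' @export
make_cv_split <- function(table, k, seed) {
  stopifnot(inherits(table, "compound_table"), k >= 2)
  n <- length(table$ids)
  if (k > n) stop("k exceeds the number of compounds")
  fold <- with_local_seed(seed, sample(rep(seq_len(k) - 1L, length.out = n)))
  list(fold = fold, k = as.integer(k), seed = as.integer(seed))
}

# --- synthetic fixture generation ------------------------------------------

# Curated known-valid SMILES fragments, grouped by chemical family. The
# sulfur/phosphorus family carries the plantable "energy-like" substructure
# signal; the others provide C/N/O backbones.
fixture_vocabulary <- function() {
  list(
    alkane = c("CC", "CCC", "CCCC", "CCCCC", "CC(C)C", "CCCCCC",
               "CC(C)CC", "CCC(C)C"),
    alcohol = c("CO", "CCO", "CCCO", "OCCO", "CC(O)C", "CCC(O)C",
                "OCC(O)CO", "CCCCO"),
    amine = c("CN", "CCN", "NCCN", "CC(N)C", "CCCN", "CNC", "CCNCC"),
    acid = c("CC(=O)O", "CCC(=O)O", "OC(=O)CC(=O)O", "CC(N)C(=O)O",
             "NCC(=O)O", "CCCC(=O)O"),
    aromatic = c("c1ccccc1", "Cc1ccccc1", "c1ccncc1", "Oc1ccccc1",
                 "Nc1ccccc1", "c1ccc2ccccc2c1", "CCc1ccccc1"),
    sulfur_phosphate = c("CS", "CCS", "SCC(N)C(=O)O", "CSC", "CCSCC",
                         "OP(=O)(O)O", "COP(=O)(O)O", "CCOP(=O)(O)O",
                         "OCC(O)COP(=O)(O)O", "CSCC(N)C(=O)O", "CCCS",
                         "OP(=O)(O)OP(=O)(O)O")
  )
}

# Bivariate standard-normal orthant probability P(Z1 > a, Z2 > b | rho),
# by one-dimensional numeric integration.
binorm_orthant <- function(a, b, rho) {
  if (rho >= 1 - 1e-9)  return(min(stats::pnorm(-a), stats::pnorm(-b)))
  if (rho <= -1 + 1e-9) return(max(0, stats::pnorm(-a) + stats::pnorm(-b) - 1))
  f <- function(x) stats::dnorm(x) *
    stats::pnorm((rho * x - b) / sqrt(1 - rho^2))
  stats::integrate(f, a, Inf, rel.tol = 1e-9)$value
}

# Solve for the latent correlation that reproduces a target pairwise joint
# probability under thresholded Gaussians.
solve_latent_correlation <- function(p_i, p_j, joint) {
  a <- stats::qnorm(1 - p_i); b <- stats::qnorm(1 - p_j)
  lo <- max(0, p_i + p_j - 1); hi <- min(p_i, p_j)
  if (joint >= hi - 1e-9) return(1)
  if (joint <= lo + 1e-9) return(-1)
  stats::uniroot(function(r) binorm_orthant(a, b, r) - joint,
                 lower = -0.999, upper = 0.999, tol = 1e-8)$root
}

# Sample multivariate normal rows from a (possibly rank-deficient)
# correlation matrix via eigendecomposition with negative-eigenvalue clamp.
sample_latent <- function(n, R) {
  eg <- eigen(R, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  L <- eg$vectors %*% diag(sqrt(vals), nrow = length(vals))
  matrix(stats::rnorm(n * ncol(R)), n) %*% t(L)
}

#' Generate a synthetic labeled-compound fixture
#'
#' Produces a valid \code{compound_table} without touching any external
#' resource. Label vectors are drawn from a thresholded Gaussian copula
#' calibrated so that empirical marginals and pairwise co-occurrence
#' converge to \code{cooccurrence_spec} as \code{n_compounds} grows
#' (all-zero label rows are redrawn, which perturbs the targets slightly).
#'
#' SMILES mirror how structure determines pathway membership in real data:
#' each pathway label is assigned a fragment family from a curated
#' vocabulary of known-valid fragments (a label whose name contains
#' "energy" gets the sulfur/phosphorus family, planting the
#' substructure-label association used by the interpretability
#' experiments), and each positive label contributes a fragment from its
#' family with probability \code{structure_strength}; the fragments are
#' concatenated via single bonds into one molecule. With
#' \code{structure_strength = 0} the SMILES are unrelated to the labels.
#'
#' @param n_compounds Number of compounds.
#' @param n_pathways Number of pathway labels (>= 2).
#' @param cooccurrence_spec Symmetric matrix: diagonal holds marginal
#'   probabilities, off-diagonal entries pairwise joint probabilities.
#'   Default: marginals 0.4, independent pairs.
#' @param seed Integer seed; the fixture is deterministic given it.
#' @param structure_strength Probability in [0, 1] that a positive label
#'   contributes a fragment of its family to the compound (default 0.9).
#'   A vector (recycled to C) gives per-label strengths, so some pathways
#'   can be made weakly structure-determined -- the crosstalk scenario
#'   where label-dependence information matters most.
#' @param pathway_names Optional label names; defaults to built-in
#'   metabolism-style names whose tokens appear in the bundled mini word
#'   vector file.
#' @return A \code{compound_table}.
#' @export
generate_fixture <- function(n_compounds, n_pathways,
                             cooccurrence_spec = NULL, seed = 1L,
                             structure_strength = 0.9,
                             pathway_names = NULL) {
  stopifnot(n_pathways >= 2L, n_compounds >= 1L)
  C <- as.integer(n_pathways)
  if (is.null(cooccurrence_spec)) {
    cooccurrence_spec <- matrix(0.4 * 0.4, C, C)
    diag(cooccurrence_spec) <- 0.4
  }
  J <- as.matrix(cooccurrence_spec)
  stopifnot(nrow(J) == C, ncol(J) == C)
  p <- diag(J)
  if (any(p <= 0) || any(p >= 1))
    stop("infeasible spec: marginals must lie strictly in (0,1)")
  for (i in seq_len(C - 1L)) for (j in seq(i + 1L, C)) {
    if (J[i, j] > min(p[i], p[j]) + 1e-12 ||
        J[i, j] < max(0, p[i] + p[j] - 1) - 1e-12)
      stop(sprintf("infeasible spec: joint probability (%d,%d) violates Frechet bounds",
                   i, j))
  }

  R <- diag(C)
  for (i in seq_len(C - 1L)) for (j in seq(i + 1L, C)) {
    R[i, j] <- R[j, i] <- solve_latent_correlation(p[i], p[j], J[i, j])
  }
  thr <- stats::qnorm(1 - p)

  if (is.null(pathway_names)) pathway_names <- default_pathway_names(C)
  strength <- rep_len(structure_strength, C)
  stopifnot(all(strength >= 0), all(strength <= 1))

  with_local_seed(seed, {
    labels <- matrix(0L, 0, C)
    while (nrow(labels) < n_compounds) {
      Z <- sample_latent(2L * (n_compounds - nrow(labels)) + 8L, R)
      draw <- matrix(as.integer(t(t(Z) > thr)), nrow(Z), C)
      draw <- draw[rowSums(draw) > 0L, , drop = FALSE]
      labels <- rbind(labels, draw)
    }
    labels <- labels[seq_len(n_compounds), , drop = FALSE]

    vocab <- fixture_vocabulary()
    families <- assign_label_families(pathway_names)
    backbone <- unlist(vocab[setdiff(names(vocab), "sulfur_phosphate")],
                       use.names = FALSE)
    smiles <- character(n_compounds)
    for (i in seq_len(n_compounds)) {
      pos <- which(labels[i, ] == 1L)
      frags <- character(0)
      for (j in pos[seq_len(min(3L, length(pos)))]) {
        if (stats::runif(1) < strength[j])
          frags <- c(frags, sample(vocab[[families[j]]], 1L))
      }
      if (!length(frags)) frags <- sample(backbone, 1L)
      s <- paste(frags, collapse = "")
      # single vocabulary fragments are curated valid; only check joins
      if (length(frags) > 1L && !is_valid_smiles(s)) s <- frags[1]
      smiles[i] <- s
    }
    new_compound_table(sprintf("cpd%05d", seq_len(n_compounds)), smiles,
                       labels, pathway_names)
  })
}

# Map each label to a fragment family: "energy"-named labels get the
# sulfur/phosphorus family; the rest cycle through the C/N/O families.
assign_label_families <- function(pathway_names) {
  others <- c("alkane", "alcohol", "amine", "acid", "aromatic")
  fam <- rep(others, length.out = length(pathway_names))
  energy <- grepl("energy", tolower(pathway_names))
  fam[energy] <- "sulfur_phosphate"
  fam[!energy] <- rep(others, length.out = sum(!energy))
  fam
}

default_pathway_names <- function(C) {
  base <- c("carbohydrate metabolism", "energy metabolism",
            "lipid metabolism", "nucleotide metabolism",
            "amino acid metabolism", "glycan biosynthesis and metabolism",
            "metabolism of cofactors and vitamins",
            "metabolism of terpenoids and polyketides",
            "biosynthesis of other secondary metabolites",
            "xenobiotics biodegradation and metabolism",
            "metabolism of other amino acids")
  if (C <= length(base)) base[seq_len(C)]
  else c(base, sprintf("synthetic pathway %d", seq_len(C - length(base))))
}
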