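## SMILES -> attributed molecular graph.
##
## Parsing, canonicalisation and ring/aromaticity perception are delegated to
## OpenBabel through ChemmineOB/ChemmineR; this file only assembles the fixed
## featurisation used by the models.

ELEMENT_VOCAB <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "other")
DEGREE_LEVELS <- 0:4
HCOUNT_LEVELS <- 0:4
BOND_ORDERS <- 1:3

DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, F = 1, P = 3,
                     Cl = 1, Br = 1, I = 1)

#' Atom and bond feature dimensions
#'
#' The atom featurisation is a fixed, documented set: one-hot element type
#' over `C,N,O,F,P,S,Cl,Br,I,other` (10), one-hot heavy-atom degree 0--4 (5),
#' formal charge (1), aromaticity flag (1) and one-hot implicit hydrogen
#' count 0--4 (5), giving `atom_feature_dim() == 22`. Bond features are
#' one-hot kekulised bond order 1--3 (3), an aromatic-bond flag and a
#' ring-membership flag, giving `bond_feature_dim() == 5`.
#'
#' @return Integer scalar.
#' @export
atom_feature_dim <- function() {
  length(ELEMENT_VOCAB) + length(DEGREE_LEVELS) + 1L + 1L + length(HCOUNT_LEVELS)
}

#' @rdname atom_feature_dim
#' @export
bond_feature_dim <- function() length(BOND_ORDERS) + 2L

# cache: canonical smiles / parsed graphs are deterministic, parse each once
.graph_cache <- new.env(parent = emptyenv())

#' Canonicalise a SMILES string
#'
#' @param smiles A single SMILES string.
#' @return The OpenBabel canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  key <- paste0("can::", smiles)
  if (!is.null(.graph_cache[[key]])) return(.graph_cache[[key]])
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  out <- sub("[\t\n ].*$", "", out)
  if (!nzchar(out)) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  .graph_cache[[key]] <- out
  out
}

#' Parse a SMILES string into an attributed molecular graph
#'
#' Builds the heavy-atom graph (hydrogens implicit) with the fixed atom/bond
#' featurisation described in [atom_feature_dim()]. Parsing is deterministic;
#' results are cached per canonical SMILES.
#'
#' @param smiles A single SMILES string describing one connected, neutral
#'   molecule.
#' @return An object of class `molecule_graph`: a list with `smiles`
#'   (canonical), `n_atoms`, `elements`, `atom_features` (`n_atoms x 22`
#'   matrix), `bonds` (`n_bonds x 2` integer matrix, undirected, 1-based),
#'   `bond_features` (`n_bonds x 5` matrix) and `aromatic` (logical per atom).
#' @examples
#' g <- smiles_to_graph("CCO")
#' g$n_atoms        # 3 heavy atoms
#' nrow(g$bonds)    # 2 bonds
#' @export
smiles_to_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  can <- canonical_smiles(smiles)
  if (grepl(".", can, fixed = TRUE)) {
    stop("multi-fragment SMILES not supported: '", smiles, "'", call. = FALSE)
  }
  key <- paste0("graph::", can)
  if (!is.null(.graph_cache[[key]])) return(.graph_cache[[key]])

  sdf_txt <- suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", can))
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }

  if (n_atoms == 1L) {
    ## ChemmineR::read.SDFset drops the element of single-heavy-atom
    ## molecules, so take it from the V2000 atom line directly (workaround
    ## for that parsing bug, not a parser).
    elements <- trimws(substr(lines[5], 32, 34))
    bonds <- matrix(integer(0), ncol = 2)
    orders <- integer(0)
    ring_atoms <- arom_atoms <- character(0)
    rings_list <- list()
  } else {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(lines)))[[1]]
    ab <- ChemmineR::atomblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bb <- ChemmineR::bondblock(sdf)
    if (n_bonds > 0) {
      bb <- matrix(as.integer(bb[, 1:3, drop = FALSE]), ncol = 3)
      bonds <- bb[, 1:2, drop = FALSE]
      orders <- bb[, 3]
    } else {
      bonds <- matrix(integer(0), ncol = 2)
      orders <- integer(0)
    }
    rng <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                    error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    rings_list <- lapply(rng$RINGS %||% list(),
                         function(r) as.integer(sub("^.*_", "", r)))
    ring_atoms <- unique(unlist(rings_list))
    arom_rings <- rings_list[which(rng$AROMATIC %||% logical(0))]
    arom_atoms <- unique(unlist(arom_rings))
  }
  stopifnot(length(elements) == n_atoms, nrow(bonds) == n_bonds)
  if (n_bonds > 0 &&
      (any(bonds < 1L) || any(bonds > n_atoms) || any(bonds[, 1] == bonds[, 2]))) {
    stop("invalid bond table for SMILES '", smiles, "'", call. = FALSE)
  }

  degree <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n_atoms)
  order_sum <- rep(0L, n_atoms)
  if (n_bonds > 0) {
    for (b in seq_len(n_bonds)) {
      order_sum[bonds[b, 1]] <- order_sum[bonds[b, 1]] + orders[b]
      order_sum[bonds[b, 2]] <- order_sum[bonds[b, 2]] + orders[b]
    }
  }
  valence <- DEFAULT_VALENCE[elements]
  valence[is.na(valence)] <- order_sum[is.na(valence)]  # 'other' elements: no implicit H
  h_count <- pmax(0L, as.integer(valence) - order_sum)
  aromatic <- seq_len(n_atoms) %in% (if (length(arom_atoms)) arom_atoms else integer(0))
  in_ring_atom <- seq_len(n_atoms) %in% (if (length(ring_atoms)) ring_atoms else integer(0))

  one_hot <- function(values, levels) {
    m <- matrix(0, length(values), length(levels))
    m[cbind(seq_along(values), match(values, levels))] <- 1
    m
  }
  elem_idx <- ifelse(elements %in% ELEMENT_VOCAB, elements, "other")
  atom_features <- cbind(
    one_hot(elem_idx, ELEMENT_VOCAB),
    one_hot(pmin(degree, max(DEGREE_LEVELS)), DEGREE_LEVELS),
    0,  # formal charge (library molecules are neutral)
    as.numeric(aromatic),
    one_hot(pmin(h_count, max(HCOUNT_LEVELS)), HCOUNT_LEVELS)
  )
  colnames(atom_features) <- c(
    paste0("elem_", ELEMENT_VOCAB), paste0("deg_", DEGREE_LEVELS),
    "charge", "aromatic", paste0("nH_", HCOUNT_LEVELS))

  bond_in_ring <- bond_arom <- rep(FALSE, n_bonds)
  if (n_bonds > 0 && length(rings_list)) {
    arom_which <- which(vapply(rings_list, function(r) {
      length(arom_atoms) > 0 && all(r %in% arom_atoms)
    }, logical(1)))
    for (b in seq_len(n_bonds)) {
      for (i in seq_along(rings_list)) {
        r <- rings_list[[i]]
        if (bonds[b, 1] %in% r && bonds[b, 2] %in% r) {
          bond_in_ring[b] <- TRUE
          if (i %in% arom_which) bond_arom[b] <- TRUE
        }
      }
    }
  }
  bond_features <- cbind(
    one_hot(pmin(orders, max(BOND_ORDERS)), BOND_ORDERS),
    as.numeric(bond_arom),
    as.numeric(bond_in_ring)
  )
  if (n_bonds == 0) bond_features <- matrix(0, 0, bond_feature_dim())
  colnames(bond_features) <- c(paste0("order_", BOND_ORDERS), "aromatic", "in_ring")

  g <- structure(list(
    smiles = can,
    n_atoms = n_atoms,
    elements = elements,
    atom_features = atom_features,
    bonds = bonds,
    bond_features = bond_features,
    aromatic = aromatic
  ), class = "molecule_graph")
  .graph_cache[[key]] <- g
  g
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat("<molecule_graph> ", x$smiles, ": ", x$n_atoms, " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Graph-derived molecular descriptors
#'
#' Two scalar descriptors used by the synthetic data generator and for split
#' stratification: a polarity proxy (heteroatom fraction plus normalised
#' hydrogen-bond donor/acceptor counts, averaged) and a size proxy (heavy
#' atom count / 10). Both are deterministic functions of the molecular graph.
#'
#' @param graph A `molecule_graph`, or a SMILES string.
#' @return A named numeric vector `c(polarity =, size =)`.
#' @export
molecule_descriptors <- function(graph) {
  if (is.character(graph)) graph <- smiles_to_graph(graph)
  stopifnot(inherits(graph, "molecule_graph"))
  n <- graph$n_atoms
  het <- graph$elements %in% c("N", "O", "F", "P", "S", "Cl", "Br", "I")
  hc_cols <- paste0("nH_", HCOUNT_LEVELS)
  h_count <- as.vector(graph$atom_features[, hc_cols, drop = FALSE] %*% HCOUNT_LEVELS)
  hba <- sum(graph$elements %in% c("N", "O"))
  hbd <- sum(graph$elements %in% c("N", "O") & h_count > 0)
  polarity <- (sum(het) / n + (hba + hbd) / (2 * n)) / 2
  c(polarity = polarity, size = n / 10)
}

#' Read a plain-text compound library file
#'
#' One SMILES per line, with an optional tab-separated name.
#'
#' @param path File path.
#' @return A tibble with columns `smiles` and `name`.
#' @export
read_compound_library <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    smiles = vapply(parts, `[[`, "", 1),
    name = vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_, "")
  )
}
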