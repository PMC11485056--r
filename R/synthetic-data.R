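## Synthetic binary-mixture activity-coefficient datasets.
##
## The generator emulates the shape of composition-resolved COSMO-RS-style
## training data: a library of small organic compounds, sampled unordered
## pairs, a fixed composition grid whose end points 0 and 1 denote infinite
## dilution, and ln(gamma) labels from classical excess-Gibbs models whose
## parameters are a smooth deterministic function of graph-derived
## descriptors -- so a graph neural network can in principle learn the
## label-generating map.

# 50 small, neutral, single-fragment organic molecules spanning alkanes,
# aromatics, alcohols, ethers, ketones, esters, amines, nitriles, halides
# and sulfur compounds; chosen to spread the polarity proxy over [0, ~0.8].
DEFAULT_COMPOUNDS <- c(
  "C",            "CC",           "CCC",          "CCCC",         "CCCCC",
  "CCCCCC",       "CC(C)C",       "CC(C)(C)C",    "C1CCCCC1",     "C1CCCC1",
  "c1ccccc1",     "Cc1ccccc1",    "Cc1ccccc1C",   "Cc1ccc(C)cc1", "CCc1ccccc1",
  "O",            "CO",           "CCO",          "CCCO",         "CC(C)O",
  "CCCCO",        "CC(C)(C)O",    "OCCO",         "CCOCC",        "COC",
  "C1CCOC1",      "C1CCOCC1",     "CC(C)=O",      "CCC(C)=O",     "CC(=O)CC(C)C",
  "CC=O",         "CCC=O",        "C(=O)O",       "CC(=O)O",      "CCC(=O)O",
  "COC=O",        "CC(=O)OC",     "CC(=O)OCC",    "CCN",          "CCCN",
  "CCNCC",        "CCCCN",        "c1ccncc1",     "CC#N",         "CCC#N",
  "CCl",          "CCCl",         "ClCCl",        "ClC(Cl)Cl",    "CS"
)

#' Build a compound library with graph-derived descriptors
#'
#' @param smiles Character vector of SMILES (defaults to the built-in set of
#'   50 small organics). Duplicates (after canonicalisation) are dropped.
#' @return A tibble with columns `smiles` (canonical), `polarity`, `size`.
#' @examples
#' lib <- compound_library()
#' nrow(lib)   # 50
#' @export
compound_library <- function(smiles = DEFAULT_COMPOUNDS) {
  graphs <- lapply(smiles, smiles_to_graph)
  desc <- t(vapply(graphs, molecule_descriptors, numeric(2)))
  out <- tibble::tibble(
    smiles = vapply(graphs, `[[`, "", "smiles"),
    polarity = desc[, "polarity"],
    size = desc[, "size"]
  )
  dplyr::distinct(out, .data$smiles, .keep_all = TRUE)
}

#' Map two compounds' descriptors to excess-Gibbs model parameters
#'
#' Parameters are a smooth deterministic function of the polarity and size
#' descriptors. Writing `dp = p1 - p2` (polarity difference) and
#' `sf = |z1 - z2| / (z1 + z2)` (size contrast), the symmetric magnitude is
#' `S = 3 dp^2 (1 + sf / 2)` and the antisymmetric part `D = 0.6 dp S`, with
#' `A12 = S + D`, `A21 = S - D`. Consequences, by construction: identical
#' descriptors give `A12 = A21`; zero polarity difference gives the ideal
#' mixture (all parameters zero); swapping the two compounds swaps
#' `A12 <-> A21` (and `tau12 <-> tau21`). For `nrtl`, `tau12 = A12`,
#' `tau21 = A21` and the non-randomness parameter is fixed at
#' `alpha = 0.3`. Optional zero-mean Gaussian noise (sd `noise_sd`) is added
#' to `(S, D)` using a seed derived from the unordered pair, so the swap
#' property is preserved exactly.
#'
#' @param descriptors_1,descriptors_2 Named vectors as returned by
#'   [molecule_descriptors()].
#' @param family Excess-Gibbs family name.
#' @param seed Integer master seed (only used when `noise_sd > 0`).
#' @param noise_sd Standard deviation of parameter noise; default 0 (off).
#' @param pair_key Optional character identifying the unordered pair, used
#'   to derive the noise seed.
#' @return An [analytic_ge_model()].
#' @export
assign_ge_model <- function(descriptors_1, descriptors_2,
                            family = "margules2", seed = 0L,
                            noise_sd = 0, pair_key = NULL) {
  p1 <- descriptors_1[["polarity"]]; z1 <- descriptors_1[["size"]]
  p2 <- descriptors_2[["polarity"]]; z2 <- descriptors_2[["size"]]
  dp <- p1 - p2
  sf <- if (z1 + z2 > 0) abs(z1 - z2) / (z1 + z2) else 0
  S <- 3 * dp^2 * (1 + sf / 2)
  D <- 0.6 * dp * S
  if (noise_sd > 0) {
    ## noise must respect the swap property: draw it once per unordered pair
    ## (seed from the sorted key) and flip the antisymmetric part's sign with
    ## the pair orientation
    if (!is.null(pair_key)) {
      parts <- strsplit(pair_key, "|", fixed = TRUE)[[1]]
      swapped <- length(parts) == 2 && parts[1] > parts[2]
      key <- paste(sort(parts), collapse = "|")
    } else {
      swapped <- dp < 0
      key <- "pair"
    }
    eps <- withr::with_seed(derive_seed(seed, key), stats::rnorm(2, 0, noise_sd))
    S <- abs(S + eps[1])
    D <- D + if (swapped) -eps[2] else eps[2]
  }
  A12 <- S + D
  A21 <- S - D
  params <- if (family == "nrtl") {
    c(tau12 = A12, tau21 = A21, alpha = 0.3)
  } else {
    c(A12 = A12, A21 = A21)
  }
  analytic_ge_model(family, params)
}

DEFAULT_GRID <- c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1)

#' Generate a labeled synthetic mixture dataset
#'
#' Samples `n_mixtures` unordered compound pairs from the library, assigns
#' each an analytic excess-Gibbs model via [assign_ge_model()], and labels
#' every composition on `grid` with the closed-form `ln gamma` values. The
#' default grid is `{0, 0.1, 0.3, 0.5, 0.7, 0.9, 1}`; compositions 0 and 1
#' are infinite-dilution points, where the dilute component's label is its
#' infinite-dilution value and the pure component's label is exactly 0.
#'
#' @param library A tibble from [compound_library()].
#' @param n_mixtures Number of unordered pairs to sample (default 400).
#' @param grid Composition grid (mole fractions of component 1).
#' @param family Excess-Gibbs family for the labels.
#' @param seed Integer seed; the dataset is a deterministic function of
#'   (library, n_mixtures, grid, family, seed, noise_sd).
#' @param noise_sd Parameter noise passed to [assign_ge_model()].
#' @param pairs Optional 2-column matrix/data frame of explicit library row
#'   indices; duplicates (as unordered pairs) are dropped with a warning.
#' @return A tibble with columns `mixture_id`, `smiles_1`, `smiles_2`, `x1`,
#'   `ln_gamma_1`, `ln_gamma_2`, `is_infinite_dilution`, carrying the
#'   per-mixture generating models in `attr(, "ge_models")` and the library
#'   in `attr(, "library")`.
#' @examples
#' lib <- compound_library()
#' d <- generate_dataset(lib, n_mixtures = 10, seed = 1)
#' nrow(d)   # 70
#' @export
generate_dataset <- function(library, n_mixtures = 400, grid = DEFAULT_GRID,
                             family = "margules2", seed = 0L, noise_sd = 0,
                             pairs = NULL) {
  stopifnot(is.data.frame(library), nrow(library) >= 2)
  check_x1(grid)
  n <- nrow(library)
  if (is.null(pairs)) {
    all_pairs <- utils::combn(n, 2)
    if (n_mixtures > ncol(all_pairs)) {
      stop("n_mixtures (", n_mixtures, ") exceeds the number of unordered ",
           "compound pairs (", ncol(all_pairs), ")", call. = FALSE)
    }
    sel <- withr::with_seed(derive_seed(seed, "pairs"),
                            sample.int(ncol(all_pairs), n_mixtures))
    pairs <- t(all_pairs[, sel, drop = FALSE])
  } else {
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) == 2, all(pairs >= 1), all(pairs <= n))
    key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    if (anyDuplicated(key)) {
      warning("duplicate compound pairs requested; deduplicated")
      pairs <- pairs[!duplicated(key), , drop = FALSE]
    }
  }

  models <- vector("list", nrow(pairs))
  recs <- vector("list", nrow(pairs))
  for (m in seq_len(nrow(pairs))) {
    i <- pairs[m, 1]; j <- pairs[m, 2]
    d1 <- c(polarity = library$polarity[i], size = library$size[i])
    d2 <- c(polarity = library$polarity[j], size = library$size[j])
    key <- paste(c(library$smiles[i], library$smiles[j]), collapse = "|")
    mod <- assign_ge_model(d1, d2, family = family, seed = seed,
                           noise_sd = noise_sd, pair_key = key)
    models[[m]] <- mod
    lg <- analytic_lngamma(mod, grid)
    recs[[m]] <- tibble::tibble(
      mixture_id = m,
      smiles_1 = library$smiles[i],
      smiles_2 = library$smiles[j],
      x1 = grid,
      ln_gamma_1 = lg$ln_gamma_1,
      ln_gamma_2 = lg$ln_gamma_2,
      is_infinite_dilution = grid %in% c(0, 1)
    )
  }
  out <- dplyr::bind_rows(recs)
  attr(out, "ge_models") <- models
  attr(out, "library") <- library
  attr(out, "grid") <- grid
  out
}

#' Write / read the mixture-record CSV schema
#'
#' The on-disk schema (`mixture_id, smiles_1, smiles_2, x1, ln_gamma_1,
#' ln_gamma_2`) is shared between the generator and the training functions,
#' so externally produced activity-coefficient tables can be dropped in.
#'
#' @param data A mixture-record tibble.
#' @param path CSV file path.
#' @return `read_mixture_csv()` returns a tibble in the generator's schema.
#' @export
write_mixture_csv <- function(data, path) {
  cols <- c("mixture_id", "smiles_1", "smiles_2", "x1",
            "ln_gamma_1", "ln_gamma_2")
  stopifnot(all(cols %in% names(data)))
  utils::write.csv(data[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mixture_csv
#' @export
read_mixture_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("mixture_id", "smiles_1", "smiles_2", "x1",
            "ln_gamma_1", "ln_gamma_2")
  if (!all(cols %in% names(d))) {
    stop("mixture CSV must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(d[cols])
  out$is_infinite_dilution <- out$x1 %in% c(0, 1)
  out
}
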