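## Evaluation split protocols for composition-resolved mixture data.
##
## comp_inter: tests interpolation across compositions -- for every mixture,
##   its interior grid compositions are dealt one-per-fold (seeded
##   permutation), so each fold withholds a random composition from every
##   mixture while every mixture keeps most of its curve in training.
## comp_extra: tests extrapolation to unseen compositions -- a stated set of
##   compositions is withheld from training across ALL mixtures (single
##   split, no folding).
## mixt_extra: tests generalisation to unseen component pairs -- whole
##   mixtures are held out, stratified over polarity-bin combinations so
##   every polarity pairing occurs in both train and test.

SPLIT_PROTOCOLS <- c("comp_inter", "comp_extra", "mixt_extra")

#' Create a train/test split assignment
#'
#' @param data A mixture-record tibble (from [generate_dataset()] or
#'   [read_mixture_csv()]).
#' @param protocol One of `"comp_inter"`, `"comp_extra"`, `"mixt_extra"`.
#' @param fold_count Number of folds (default 5; forced to 1 for
#'   `comp_extra`, which has one split per exclusion set).
#' @param excluded_compositions For `comp_extra` only: the compositions
#'   withheld from training for every mixture, e.g. `c(0.5)`,
#'   `c(0.3, 0.7)`, `c(0.1, 0.9)` or `c(0, 1)`.
#' @param seed Integer seed; the assignment is deterministic given
#'   `(data, protocol, fold_count, excluded_compositions, seed)`.
#' @return An object of class `split_assignment` with the per-record test
#'   fold (`NA` = never withheld, i.e. always in training).
#' @examples
#' lib <- compound_library()
#' d <- generate_dataset(lib, n_mixtures = 20, seed = 1)
#' sp <- make_split(d, "comp_inter", seed = 1)
#' nrow(split_test(sp, d, fold = 1))
#' @export
make_split <- function(data, protocol = SPLIT_PROTOCOLS, fold_count = 5L,
                       excluded_compositions = NULL, seed = 0L) {
  protocol <- match.arg(protocol)
  stopifnot(is.data.frame(data), nrow(data) > 0,
            all(c("mixture_id", "smiles_1", "smiles_2", "x1") %in% names(data)))
  if (protocol != "comp_extra" && !is.null(excluded_compositions)) {
    stop("excluded_compositions is only meaningful for protocol 'comp_extra'",
         call. = FALSE)
  }
  fold_count <- as.integer(fold_count)
  assignments <- switch(protocol,
    comp_inter = split_comp_inter(data, fold_count, seed),
    comp_extra = {
      if (is.null(excluded_compositions)) {
        stop("protocol 'comp_extra' requires excluded_compositions",
             call. = FALSE)
      }
      fold_count <- 1L
      split_comp_extra(data, excluded_compositions)
    },
    mixt_extra = split_mixt_extra(data, fold_count, seed)
  )
  sp <- structure(list(
    protocol = protocol,
    fold_count = fold_count,
    excluded_compositions = excluded_compositions,
    assignments = assignments,
    seed = seed
  ), class = "split_assignment")
  verify_split(sp, data)
  sp
}

split_comp_inter <- function(data, k, seed) {
  interior <- data$x1 > 0 & data$x1 < 1
  fold <- rep(NA_integer_, nrow(data))
  withr::with_seed(derive_seed(seed, "comp_inter"), {
    for (m in unique(data$mixture_id)) {
      idx <- which(data$mixture_id == m & interior)
      if (length(idx) == 0) next
      perm <- idx[sample.int(length(idx))]  # not sample(idx): length-1 gotcha
      fold[perm] <- rep_len(seq_len(k), length(perm))
    }
  })
  tibble::tibble(mixture_id = data$mixture_id, x1 = data$x1, fold = fold)
}

split_comp_extra <- function(data, excluded) {
  check_x1(excluded)
  test <- vapply(data$x1, function(x) any(abs(x - excluded) < 1e-9), logical(1))
  tibble::tibble(mixture_id = data$mixture_id, x1 = data$x1,
                 fold = ifelse(test, 1L, NA_integer_))
}

split_mixt_extra <- function(data, k, seed) {
  mix <- dplyr::distinct(data, .data$mixture_id, .data$smiles_1, .data$smiles_2)
  strata <- polarity_strata(mix)
  mix_fold <- rep(NA_integer_, nrow(mix))
  withr::with_seed(derive_seed(seed, "mixt_extra"), {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      perm <- idx[sample.int(length(idx))]
      mix_fold[perm] <- rep_len(seq_len(k), length(perm))
    }
  })
  fold <- mix_fold[match(data$mixture_id, mix$mixture_id)]
  tibble::tibble(mixture_id = data$mixture_id, x1 = data$x1, fold = fold)
}

# unordered pair of polarity tertile bins; used for stratified folding
polarity_strata <- function(mix) {
  compounds <- unique(c(mix$smiles_1, mix$smiles_2))
  pol <- vapply(compounds, function(s) molecule_descriptors(s)[["polarity"]],
                numeric(1))
  qs <- stats::quantile(pol, c(1 / 3, 2 / 3), names = FALSE)
  bin <- findInterval(pol, qs) + 1L  # 1..3
  names(bin) <- compounds
  b1 <- bin[mix$smiles_1]; b2 <- bin[mix$smiles_2]
  paste(pmin(b1, b2), pmax(b1, b2), sep = "-")
}

#' @export
print.split_assignment <- function(x, ...) {
  n_test <- sum(!is.na(x$assignments$fold))
  cat("<split_assignment> ", x$protocol, ", ", x$fold_count, " fold(s), ",
      nrow(x$assignments), " records (", n_test, " ever withheld)\n", sep = "")
  invisible(x)
}

# post-hoc invariant checks; violations are implementation errors
verify_split <- function(sp, data) {
  a <- sp$assignments
  if (sp$protocol == "comp_inter") {
    for (m in unique(a$mixture_id)) {
      sub <- a[a$mixture_id == m, ]
      for (f in seq_len(sp$fold_count)) {
        if (all(!is.na(sub$fold) & sub$fold == f)) {
          stop("comp_inter split withheld every composition of mixture ", m,
               " in fold ", f, call. = FALSE)
        }
      }
    }
  }
  if (sp$protocol == "comp_extra") {
    excl <- vapply(a$x1, function(x) {
      any(abs(x - sp$excluded_compositions) < 1e-9)
    }, logical(1))
    if (!all(excl == !is.na(a$fold))) {
      stop("comp_extra split must withhold exactly the excluded compositions",
           call. = FALSE)
    }
  }
  if (sp$protocol == "mixt_extra") {
    for (f in seq_len(sp$fold_count)) {
      test_mix <- unique(a$mixture_id[!is.na(a$fold) & a$fold == f])
      train_mix <- unique(a$mixture_id[is.na(a$fold) | a$fold != f])
      if (length(intersect(test_mix, train_mix)) > 0) {
        stop("mixt_extra split leaks mixtures between train and test",
             call. = FALSE)
      }
    }
  }
  invisible(sp)
}

#' Extract the training or test records of one fold
#'
#' @param split A `split_assignment`.
#' @param data The mixture-record tibble the split was built from (same row
#'   order).
#' @param fold Fold index in `1:fold_count`.
#' @return A tibble of records.
#' @export
split_train <- function(split, data, fold = 1L) {
  check_fold(split, data, fold)
  data[is.na(split$assignments$fold) | split$assignments$fold != fold, ]
}

#' @rdname split_train
#' @export
split_test <- function(split, data, fold = 1L) {
  check_fold(split, data, fold)
  data[!is.na(split$assignments$fold) & split$assignments$fold == fold, ]
}

check_fold <- function(split, data, fold) {
  stopifnot(inherits(split, "split_assignment"),
            nrow(data) == nrow(split$assignments),
            length(fold) == 1, fold >= 1, fold <= split$fold_count)
  if (!all(data$mixture_id == split$assignments$mixture_id) ||
      !all(abs(data$x1 - split$assignments$x1) < 1e-12)) {
    stop("data does not match the records this split was built from",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a split manifest CSV
#'
#' Long-format manifest with one row per (record, fold):
#' `mixture_id, x1, fold, role` where `role` is `"train"` or `"test"`;
#' fully reproduces the split assignment on the same data.
#'
#' @param split A `split_assignment`.
#' @param path CSV path.
#' @return `read_split_manifest()` returns the manifest tibble.
#' @export
write_split_manifest <- function(split, path) {
  a <- split$assignments
  rows <- lapply(seq_len(split$fold_count), function(f) {
    tibble::tibble(
      mixture_id = a$mixture_id, x1 = a$x1, fold = f,
      role = ifelse(!is.na(a$fold) & a$fold == f, "test", "train")
    )
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mixture_id", "x1", "fold", "role") %in% names(d)))
  tibble::as_tibble(d)
}
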