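make_data <- function(n_mixtures = 20, seed = 7) {
  tiny_dataset(n_mixtures = n_mixtures, seed = seed)
}

test_that("comp_inter folds partition the interior records", {
  d <- make_data(10)
  sp <- make_split(d, "comp_inter", seed = 1)
  interior <- which(d$x1 > 0 & d$x1 < 1)
  test_sets <- lapply(1:5, function(f) which(!is.na(sp$assignments$fold) &
                                               sp$assignments$fold == f))
  expect_equal(sort(unlist(test_sets)), interior)     # union = withheld set
  expect_equal(sum(duplicated(unlist(test_sets))), 0) # pairwise disjoint
  # every mixture keeps training records in every fold
  for (f in 1:5) {
    tr <- split_train(sp, d, f)
    expect_setequal(unique(tr$mixture_id), unique(d$mixture_id))
    # boundary (infinite-dilution) records are never withheld
    expect_true(all(split_test(sp, d, f)$x1 %in% c(0.1, 0.3, 0.5, 0.7, 0.9)))
  }
})

test_that("comp_extra withholds exactly the stated compositions", {
  d <- make_data(8)
  for (excl in list(0.5, c(0.3, 0.7), c(0.1, 0.9), c(0, 1))) {
    sp <- make_split(d, "comp_extra", excluded_compositions = excl)
    expect_equal(sp$fold_count, 1L)
    te <- split_test(sp, d, 1)
    tr <- split_train(sp, d, 1)
    expect_setequal(unique(te$x1), excl)
    expect_true(all(!tr$x1 %in% excl))
    # across every mixture
    expect_equal(nrow(te), length(excl) * length(unique(d$mixture_id)))
  }
})

test_that("mixt_extra test mixtures never occur in training", {
  d <- make_data(20)
  sp <- make_split(d, "mixt_extra", seed = 2)
  for (f in 1:5) {
    tr <- split_train(sp, d, f); te <- split_test(sp, d, f)
    expect_length(intersect(unique(tr$mixture_id), unique(te$mixture_id)), 0)
    # whole mixtures move together: test set holds full 7-point curves
    expect_true(all(table(te$mixture_id) == 7))
  }
  # every mixture is tested in exactly one fold
  expect_setequal(unique(sp$assignments$fold), 1:5)
  expect_true(all(!is.na(sp$assignments$fold)))
})

test_that("mixt_extra folds are stratified over polarity combinations", {
  d <- make_data(30, seed = 9)
  sp <- make_split(d, "mixt_extra", seed = 3)
  mix <- dplyr::distinct(d, mixture_id, smiles_1, smiles_2)
  strata <- gegnn:::polarity_strata(mix)
  fold_of_mix <- sp$assignments$fold[match(mix$mixture_id,
                                           sp$assignments$mixture_id)]
  for (s in unique(strata)) {
    counts <- table(factor(fold_of_mix[strata == s], levels = 1:5))
    expect_lte(max(counts) - min(counts), 1)
  }
})

test_that("splits are deterministic and validate their inputs", {
  d <- make_data(6)
  sp1 <- make_split(d, "comp_inter", seed = 5)
  sp2 <- make_split(d, "comp_inter", seed = 5)
  expect_identical(sp1$assignments, sp2$assignments)

  expect_error(make_split(d, "mixt_extra", excluded_compositions = 0.5),
               "comp_extra")
  expect_error(make_split(d, "comp_extra"), "excluded_compositions")
  expect_error(split_test(sp1, d, fold = 9))
  expect_error(split_train(sp1, d[1:10, ], fold = 1))
})

test_that("split manifests round-trip through CSV", {
  d <- make_data(5)
  sp <- make_split(d, "comp_inter", seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split_manifest(sp, path)
  man <- read_split_manifest(path)
  expect_equal(nrow(man), nrow(d) * 5)
  for (f in 1:5) {
    te <- man[man$fold == f & man$role == "test", ]
    expect_equal(nrow(te), nrow(split_test(sp, d, f)))
  }
})
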