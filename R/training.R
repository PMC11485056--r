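## End-to-end training. Three modes share the encoder architecture:
##   ge     -- the excess-Gibbs head: labels supervise ln gamma values
##             derived from g and its exact composition derivative; no
##             consistency term exists because consistency is architectural.
##   gdi    -- direct two-output head trained with the prediction loss plus
##             a soft Gibbs-Duhem penalty (squared residual) evaluated at
##             labeled interior compositions and at seeded random
##             augmentation compositions.
##   direct -- direct head, prediction loss only.
## Batches are whole mixtures: every labeled composition of a mixture is
## processed in one forward pass, since the thermodynamic head
## differentiates per-composition anyway.

#' Training configuration
#'
#' @param epochs Number of passes over the training mixtures (default 100).
#' @param batch_size Mixtures per optimisation step (default 5).
#' @param learning_rate Adam step size (default 3e-3).
#' @param optimizer Only `"adam"` is implemented.
#' @param lr_decay `"none"` (constant step size) or `"cosine"` (smooth decay
#'   of the step size to zero over the training budget; helps the final
#'   convergence on the synthetic task).
#' @param seed Integer seed controlling shuffling and augmentation.
#' @param mode One of `"ge"`, `"gdi"`, `"direct"`.
#' @param gdi_weight Nonnegative Gibbs-Duhem penalty weight (lambda);
#'   `gdi` mode only, ignored otherwise.
#' @param gdi_augmentation Random interior compositions drawn per mixture
#'   per epoch for the penalty (`gdi` mode only).
#' @return An object of class `gegnn_train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 5L,
                         learning_rate = 3e-3, optimizer = "adam",
                         lr_decay = c("cosine", "none"),
                         seed = 0L, mode = c("ge", "gdi", "direct"),
                         gdi_weight = 1, gdi_augmentation = 5L) {
  mode <- match.arg(mode)
  optimizer <- match.arg(optimizer, "adam")
  lr_decay <- match.arg(lr_decay)
  if (gdi_weight < 0) stop("gdi_weight (lambda) must be >= 0", call. = FALSE)
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, optimizer = optimizer,
    lr_decay = lr_decay, seed = as.integer(seed), mode = mode,
    gdi_weight = gdi_weight, gdi_augmentation = as.integer(gdi_augmentation)
  ), class = "gegnn_train_config")
}

#' Prediction loss on activity-coefficient labels
#'
#' Mean squared error pooled over both components at all labeled
#' (mixture, composition) points, including the infinite-dilution boundary
#' points. This is the full training loss of the `ge` mode: no consistency
#' term appears because consistency holds by construction.
#'
#' @param predictions,labels Aligned data frames with columns
#'   `ln_gamma_1`, `ln_gamma_2` (and `x1`, used for the alignment check).
#' @return Scalar loss.
#' @examples
#' p <- tibble::tibble(x1 = 0.5, ln_gamma_1 = 0, ln_gamma_2 = 0)
#' y <- tibble::tibble(x1 = 0.5, ln_gamma_1 = 1, ln_gamma_2 = 1)
#' loss_ge(p, y)   # 1
#' @export
loss_ge <- function(predictions, labels) {
  check_aligned(predictions, labels)
  mean(c((predictions$ln_gamma_1 - labels$ln_gamma_1)^2,
         (predictions$ln_gamma_2 - labels$ln_gamma_2)^2))
}

#' Soft-constrained (Gibbs-Duhem-informed) loss
#'
#' Prediction MSE plus `lambda` times the mean squared Gibbs-Duhem residual
#' of a direct activity-coefficient predictor, audited at the supplied
#' interior compositions.
#'
#' @inheritParams loss_ge
#' @param lambda Nonnegative penalty weight.
#' @param activity_fn The predictor as a function of `x1` (see
#'   [model_activity_fn()]); used to evaluate residuals unless
#'   `gd_residuals` is given.
#' @param audit_compositions Interior compositions at which the residual is
#'   audited.
#' @param gd_residuals Optional precomputed residuals (overrides
#'   `activity_fn`).
#' @return Scalar loss.
#' @export
loss_gdi <- function(predictions, labels, lambda,
                     activity_fn = NULL, audit_compositions = NULL,
                     gd_residuals = NULL) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  base <- loss_ge(predictions, labels)
  if (lambda == 0) return(base)
  if (is.null(gd_residuals)) {
    if (is.null(activity_fn) || is.null(audit_compositions)) {
      stop("loss_gdi() needs gd_residuals, or an activity_fn plus ",
           "audit_compositions", call. = FALSE)
    }
    gd_residuals <- gibbs_duhem_residual(activity_fn, audit_compositions)
  }
  base + lambda * mean(gd_residuals^2)
}

check_aligned <- function(predictions, labels) {
  if (nrow(predictions) != nrow(labels) ||
      ("x1" %in% names(predictions) && "x1" %in% names(labels) &&
       any(abs(predictions$x1 - labels$x1) > 1e-12))) {
    stop("predictions and labels are misaligned", call. = FALSE)
  }
  invisible(TRUE)
}

#' Train a model on mixture records
#'
#' @param data Mixture-record tibble (columns `mixture_id`, `smiles_1`,
#'   `smiles_2`, `x1`, `ln_gamma_1`, `ln_gamma_2`).
#' @param split Optional [make_split()] assignment; training uses the
#'   training records of `fold`. `NULL` trains on all records.
#' @param fold Fold index when `split` is given.
#' @param config A [model_config()].
#' @param control A [train_config()]; `control$mode` selects the head and
#'   loss (`ge`, `gdi`, `direct`).
#' @return A `gegnn_fit`: list with `model`, `history` (per-epoch losses),
#'   `control`, `fold`, `n_train`. Fully deterministic given
#'   (data, split, config, control).
#' @examples
#' \donttest{
#' lib <- compound_library()
#' d <- generate_dataset(lib, n_mixtures = 10, seed = 1)
#' fit <- train_gegnn(d, config = model_config(hidden_dim = 8, seed = 1),
#'                    control = train_config(epochs = 2, seed = 1))
#' fit$history
#' }
#' @export
train_gegnn <- function(data, split = NULL, fold = 1L,
                        config = model_config(),
                        control = train_config()) {
  stopifnot(inherits(config, "gegnn_config"),
            inherits(control, "gegnn_train_config"))
  train_data <- if (is.null(split)) data else split_train(split, data, fold)
  if (nrow(train_data) == 0) stop("empty training set", call. = FALSE)
  mode <- control$mode
  head <- if (mode == "ge") "ge" else "direct"
  model <- gegnn_model(config, head = head)

  mixtures <- prepare_mixtures(train_data)
  n_mix <- length(mixtures)
  ## parameters and optimiser state are kept flat (one numeric vector) in
  ## the hot loop; the nested list view is rebuilt once per update
  skeleton <- model$params
  theta <- unlist(model$params, use.names = FALSE)
  opt <- adam_init(theta, control$learning_rate)
  n_steps_total <- control$epochs *
    max(1L, ceiling(n_mix / control$batch_size))
  history <- tibble::tibble(epoch = integer(), loss = numeric(),
                            gd_penalty = numeric())

  for (epoch in seq_len(control$epochs)) {
    ord <- withr::with_seed(derive_seed(control$seed, paste0("shuffle", epoch)),
                            sample.int(n_mix))
    aug <- NULL
    if (mode == "gdi" && control$gdi_augmentation > 0) {
      aug <- withr::with_seed(
        derive_seed(control$seed, paste0("aug", epoch)),
        matrix(stats::runif(n_mix * control$gdi_augmentation, 0.01, 0.99),
               nrow = n_mix))
    }
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    ep_sq <- 0; ep_n <- 0; ep_pen <- 0; ep_pen_n <- 0
    for (batch in batches) {
      acc <- numeric(length(theta))
      n_pts <- sum(vapply(mixtures[batch], function(m) length(m$xs), 0L))
      n_aud <- if (mode == "gdi") {
        sum(vapply(mixtures[batch], function(m) sum(m$interior), 0L)) +
          length(batch) * (control$gdi_augmentation %||% 0L)
      } else 0L
      for (mi in batch) {
        mx <- mixtures[[mi]]
        res <- if (mode == "ge") {
          mixture_step_ge(model, mx, n_pts)
        } else {
          mixture_step_direct(model, mx, n_pts, mode, control,
                              if (is.null(aug)) NULL else aug[mi, ], n_aud)
        }
        acc <- acc + unlist(res$grads, use.names = FALSE)
        ep_sq <- ep_sq + res$sq; ep_pen <- ep_pen + res$pen
      }
      ep_n <- ep_n + n_pts; ep_pen_n <- ep_pen_n + n_aud
      lr_scale <- if (control$lr_decay == "cosine") {
        0.5 * (1 + cos(pi * opt$t / n_steps_total))
      } else 1
      opt <- adam_step(opt, acc, lr_scale)
      theta <- opt$theta
      model$params <- utils::relist(theta, skeleton)
      if (!all(is.finite(theta))) {
        stop("training diverged (non-finite parameters) at epoch ", epoch,
             call. = FALSE)
      }
    }
    loss <- ep_sq / (2 * ep_n)
    pen <- if (mode == "gdi" && ep_pen_n > 0) ep_pen / ep_pen_n else NA_real_
    if (!is.finite(loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch,
           call. = FALSE)
    }
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, loss = loss, gd_penalty = pen))
  }

  structure(list(model = model, history = history, control = control,
                 config = config, fold = fold, n_train = nrow(train_data),
                 temperature = 298.15),
            class = "gegnn_fit")
}

#' @export
print.gegnn_fit <- function(x, ...) {
  cat("<gegnn_fit> mode=", x$control$mode, ", ", x$control$epochs,
      " epochs on ", x$n_train, " records; final loss ",
      signif(utils::tail(x$history$loss, 1), 4), "\n", sep = "")
  invisible(x)
}

# group records into per-mixture tensors; graph tensors cached per SMILES
prepare_mixtures <- function(data) {
  gt_cache <- new.env(parent = emptyenv())
  get_gt <- function(s) {
    if (is.null(gt_cache[[s]])) gt_cache[[s]] <- graph_tensors(smiles_to_graph(s))
    gt_cache[[s]]
  }
  ids <- unique(data$mixture_id)
  lapply(ids, function(m) {
    rows <- data[data$mixture_id == m, ]
    list(gt1 = get_gt(rows$smiles_1[1]), gt2 = get_gt(rows$smiles_2[1]),
         xs = rows$x1, y1 = rows$ln_gamma_1, y2 = rows$ln_gamma_2,
         interior = rows$x1 > 0 & rows$x1 < 1)
  })
}

# one mixture's gradient contribution, GE head.
# Loss share: sum_i (e1^2 + e2^2) / (2 n_pts) over the batch.
mixture_step_ge <- function(model, mx, n_pts) {
  fw <- ge_forward(model, mx$gt1, mx$gt2, mx$xs, order = 1)
  lg1 <- fw$g + (1 - mx$xs) * fw$dg
  lg2 <- fw$g - mx$xs * fw$dg
  e1 <- lg1 - mx$y1; e2 <- lg2 - mx$y2
  sc <- 1 / (2 * n_pts)
  d_lg1 <- 2 * sc * e1; d_lg2 <- 2 * sc * e2
  dLdg <- d_lg1 + d_lg2
  dLddg <- d_lg1 * (1 - mx$xs) - d_lg2 * mx$xs
  list(grads = ge_backward(model, fw, dLdg, dLddg),
       sq = sum(e1^2 + e2^2), pen = 0)
}

# one mixture's gradient contribution, direct head ("direct" or "gdi").
mixture_step_direct <- function(model, mx, n_pts, mode, control, aug, n_aud) {
  gdi <- mode == "gdi" && control$gdi_weight > 0 && n_aud > 0
  xs_all <- if (gdi) c(mx$xs, aug) else mx$xs
  fw <- direct_forward(model, mx$gt1, mx$gt2, xs_all,
                       order = if (gdi) 1 else 0)
  nl <- length(mx$xs)
  e1 <- fw$lg1[seq_len(nl)] - mx$y1
  e2 <- fw$lg2[seq_len(nl)] - mx$y2
  sc <- 1 / (2 * n_pts)
  d_lg1 <- d_lg2 <- numeric(length(xs_all))
  d_lg1[seq_len(nl)] <- 2 * sc * e1
  d_lg2[seq_len(nl)] <- 2 * sc * e2
  pen <- 0
  if (gdi) {
    audit <- c(which(mx$interior), seq.int(nl + 1, length.out = length(aug)))
    xa <- xs_all[audit]
    r <- xa * fw$dlg1[audit] + (1 - xa) * fw$dlg2[audit]
    pen <- sum(r^2)
    d_dlg1 <- d_dlg2 <- numeric(length(xs_all))
    lsc <- control$gdi_weight / n_aud
    d_dlg1[audit] <- 2 * lsc * r * xa
    d_dlg2[audit] <- 2 * lsc * r * (1 - xa)
    grads <- direct_backward(model, fw, d_lg1, d_lg2, d_dlg1, d_dlg2)
  } else {
    grads <- direct_backward(model, fw, d_lg1, d_lg2)
  }
  list(grads = grads, sq = sum(e1^2 + e2^2), pen = pen)
}

## ---- Adam ---------------------------------------------------------------

# flat-vector Adam
adam_init <- function(theta, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(theta = theta, m = numeric(length(theta)), v = numeric(length(theta)),
       lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L)
}

adam_step <- function(opt, grad, lr_scale = 1) {
  opt$t <- opt$t + 1L
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * grad
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * grad * grad
  mhat <- opt$m / (1 - opt$beta1^opt$t)
  vhat <- opt$v / (1 - opt$beta2^opt$t)
  opt$theta <- opt$theta - opt$lr * lr_scale * mhat / (sqrt(vhat) + opt$eps)
  opt
}

#' Ensemble predictions by averaging fold models
#'
#' Averages `gE_RT`, `dgE_RT_dx1`, `ln_gamma_1`, `ln_gamma_2` (and
#' `gd_residual`) from [predict_activity()] over a list of fits, the usual
#' way per-fold models are combined into a single predictor.
#'
#' @param fits List of `gegnn_fit` or `gegnn_model` objects.
#' @param newdata Data frame with `smiles_1`, `smiles_2`, `x1`.
#' @return A prediction tibble like [predict_activity()]'s.
#' @export
predict_ensemble <- function(fits, newdata) {
  stopifnot(length(fits) >= 1)
  preds <- lapply(fits, predict_activity, newdata = newdata)
  out <- preds[[1]]
  cols <- c("gE_RT", "dgE_RT_dx1", "ln_gamma_1", "ln_gamma_2", "gd_residual")
  for (cl in cols) {
    out[[cl]] <- Reduce(`+`, lapply(preds, `[[`, cl)) / length(preds)
  }
  out
}
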