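# Training loop (Adam + early stopping), evaluation metrics, experiment
# runner and checkpoints.

#' Pearson correlation coefficient
#'
#' Centered product-moment correlation between true and predicted responses,
#' computed directly from its definition:
#' `sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2) sum((y - mean(y))^2))`.
#'
#' @param x,y Numeric vectors of equal length (at least 2), each with
#'   nonzero variance.
#' @return Correlation in \[-1, 1\].
#' @examples
#' pcc(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 points")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    stop(structure(
      class = c("gf_undefined_metric", "error", "condition"),
      list(message = "correlation undefined: zero variance input",
           call = sys.call(-1))
    ))
  }
  sum(dx * dy) / sqrt(sx * sy)
}

#' Root mean square error
#'
#' @param x,y Numeric vectors of equal length.
#' @return `sqrt(mean((x - y)^2))`.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!length(x)) stop("need at least 1 point")
  sqrt(mean((x - y)^2))
}

adam_state <- function(theta) {
  list(m = lapply(theta, function(p) p * 0),
       v = lapply(theta, function(p) p * 0),
       t = 0L)
}

adam_step <- function(theta, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- theta[[nm]] * 0
    g <- g + weight_decay * theta[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    theta[[nm]] <- theta[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(theta = theta, state = state)
}

#' Train the drug-response model
#'
#' Fits the full model (or an ablation variant) on the training part of a
#' split with Adam (learning rate 5e-4, L2 weight decay 5e-4 by default),
#' MSE loss on the normalized response, dropout 0.3 in training mode, Xavier
#' initialization, and early stopping when the validation loss has not
#' improved (strictly) for `patience` consecutive epochs within the
#' `max_epochs` budget. All randomness (initialization, shuffling, dropout)
#' derives from `config$seed`.
#'
#' @param featurized Featurized drug table from [featurize_drugs()].
#' @param cells Cell-line feature table.
#' @param split A `gf_split` with train/validation/test parts.
#' @param config A [gf_config()].
#' @param verbose Print per-epoch progress.
#' @return A `gf_fit`: list with `params` (best-validation parameters),
#'   `config`, `history` (per-epoch tibble: train_loss, val_loss, val_pcc,
#'   val_rmse, best_val_loss), `best_epoch`, `best_val_loss`,
#'   `epochs_trained`, `split_kind` and `model_data`.
#' @export
gf_train <- function(featurized, cells, split, config = gf_config(),
                     verbose = FALSE) {
  cfg <- config
  data <- gf_model_data(featurized, cells, split, cfg)
  train_rows <- which(data$part == "train")
  val_rows <- which(data$part == "validation")
  if (!length(train_rows)) stop("split has an empty training part")
  if (!length(val_rows)) stop("split has an empty validation part")
  set.seed(cfg$seed)
  theta <- init_model_params(cfg)
  state <- adam_state(theta)
  best <- list(val = Inf, theta = theta, epoch = 0L)
  stale <- 0L
  hist <- vector("list", cfg$max_epochs)
  bs <- cfg$batch_size
  n_tr <- length(train_rows)
  y <- data$y
  for (epoch in seq_len(cfg$max_epochs)) {
    order_rows <- train_rows[sample.int(n_tr)]
    batches <- if (!is.finite(bs) || bs >= n_tr) list(order_rows) else
      split(order_rows, ceiling(seq_along(order_rows) / bs))
    ep_loss <- 0
    for (b in batches) {
      fw <- forward_tape(theta, data, b, training = TRUE, target = y[b])
      loss_val <- fw$loss$value[1L]
      if (!is.finite(loss_val)) {
        stop("training aborted: non-finite loss at epoch ", epoch)
      }
      grads <- ad_backward(fw$tape, fw$loss)
      upd <- adam_step(theta, grads, state, cfg$learning_rate,
                       cfg$weight_decay)
      theta <- upd$theta
      state <- upd$state
      ep_loss <- ep_loss + loss_val * length(b)
    }
    ep_loss <- ep_loss / n_tr
    val_pred <- predict_rows(theta, data, val_rows)
    val_loss <- mean((val_pred - y[val_rows])^2)
    val_pcc <- tryCatch(pcc(y[val_rows], val_pred),
                        gf_undefined_metric = function(e) NA_real_)
    improved <- val_loss < best$val
    if (improved) {
      best <- list(val = val_loss, theta = theta, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = ep_loss, val_loss = val_loss,
      val_pcc = val_pcc, val_rmse = sqrt(val_loss),
      best_val_loss = best$val
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f%s", epoch, ep_loss,
                      val_loss, if (improved) " *" else ""))
    }
    if (stale >= cfg$patience) break
  }
  history <- dplyr::bind_rows(hist)
  structure(
    list(params = best$theta, config = cfg, history = history,
         best_epoch = best$epoch, best_val_loss = best$val,
         epochs_trained = nrow(history),
         split_kind = attr(split, "split_kind"),
         model_data = data),
    class = "gf_fit"
  )
}

#' @export
print.gf_fit <- function(x, ...) {
  cat("<gf_fit> variant '", x$config$variant, "', ", x$epochs_trained,
      " epochs (best validation loss ", signif(x$best_val_loss, 4),
      " at epoch ", x$best_epoch, ")\n", sep = "")
  invisible(x)
}

#' Predict normalized responses for response records
#'
#' Evaluation-mode (deterministic, no dropout) predictions for the given
#' part of the fitted split, or for new records against the same drug and
#' cell tables.
#'
#' @param object A `gf_fit`.
#' @param part Which split part to predict (`"test"` default; `"all"` for
#'   every record).
#' @param records Optional new response records (must reference drugs and
#'   cells known to the fit).
#' @param ... Unused.
#' @return Tibble `(drug_id, cell_id, y, .pred)`.
#' @export
predict.gf_fit <- function(object, part = "test", records = NULL, ...) {
  data <- object$model_data
  if (!is.null(records)) {
    di <- match(records$drug_id, data$drug_ids)
    ci <- match(records$cell_id, data$cell_ids)
    if (anyNA(di) || anyNA(ci)) {
      stop("records reference drugs or cells unknown to the fitted model")
    }
    nd <- data
    nd$drug_idx <- di; nd$cell_idx <- ci
    nd$y <- if ("y" %in% names(records)) as.numeric(records$y) else
      rep(NA_real_, nrow(records))
    rows <- seq_len(nrow(records))
    preds <- predict_rows(object$params, nd, rows)
    return(tibble::tibble(drug_id = records$drug_id,
                          cell_id = records$cell_id,
                          y = nd$y, .pred = preds))
  }
  rows <- if (identical(part, "all")) seq_along(data$y) else
    which(data$part == part)
  if (!length(rows)) stop("no records in part '", part, "'")
  preds <- predict_rows(object$params, data, rows)
  tibble::tibble(drug_id = data$drug_ids[data$drug_idx[rows]],
                 cell_id = data$cell_ids[data$cell_idx[rows]],
                 y = data$y[rows], .pred = preds)
}

#' Evaluate a fitted model
#'
#' Computes PCC and RMSE between true and predicted normalized responses on
#' a split part (test by default). A constant predictor on varying targets
#' raises the classed `gf_undefined_metric` error rather than reporting a
#' silent zero.
#'
#' @param fit A `gf_fit`.
#' @param part Split part (default `"test"`) or `"all"`.
#' @param records Optional explicit records (see [predict.gf_fit()]).
#' @return A one-row `gf_report` tibble `(pcc, rmse, n, split_kind, seed)`
#'   with the per-pair predictions attached as attribute `predictions`.
#' @export
gf_evaluate <- function(fit, part = "test", records = NULL) {
  preds <- stats::predict(fit, part = part, records = records)
  if (anyNA(preds$y)) stop("records carry no true responses to score")
  report <- tibble::tibble(
    pcc = pcc(preds$y, preds$.pred),
    rmse = rmse(preds$y, preds$.pred),
    n = nrow(preds),
    split_kind = fit$split_kind %||% NA_character_,
    seed = fit$config$seed
  )
  structure(report, class = c("gf_report", class(report)),
            predictions = preds)
}

#' Run a multi-variant / multi-seed experiment
#'
#' Trains and evaluates the model for every combination of ablation variant,
#' layer count and seed on a dataset, under one split regime; all variants
#' of a given seed share the identical split (and therefore identical test
#' pairs), making reports directly comparable.
#'
#' @param dataset A `gf_dataset` from [simulate_drug_response()], or a list
#'   with `drugs`, `cells`, `responses`.
#' @param variants Character subset of
#'   `c("full", "no_multichannel", "concat_fusion")`.
#' @param split_kind `"mixed"` or `"new_cell_line"`.
#' @param layers Integer vector of layer counts to sweep (default 3).
#' @param seeds Integer vector of seeds.
#' @param config Base configuration; variant, layer count and seed are
#'   overridden per run.
#' @param out_dir Optional directory for `summary.csv` and per-run metrics
#'   JSON files.
#' @return Tibble with one row per (variant, layers, seed): pcc, rmse, n,
#'   epochs trained; the across-seed mean and sd per condition are attached
#'   as attribute `summary`.
#' @export
run_experiment <- function(dataset, variants = "full",
                           split_kind = "mixed", layers = NULL,
                           seeds = 1L, config = gf_config(),
                           out_dir = NULL) {
  ok <- c("full", "no_multichannel", "concat_fusion")
  if (!all(variants %in% ok)) {
    stop("unknown variant(s): ", paste(setdiff(variants, ok), collapse = ", "))
  }
  if (is.null(layers)) layers <- config$n_layers
  featurized <- featurize_drugs(dataset$drugs, n_bits = config$fp_bits,
                                radius = config$fp_radius)
  grid <- expand.grid(variant = variants, layers = layers, seed = seeds,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    split <- make_split(dataset$responses, split_kind = split_kind,
                        seed = g$seed)
    cfg <- config
    cfg$variant <- g$variant
    cfg$n_layers <- as.integer(g$layers)
    cfg$seed <- as.integer(g$seed)
    fit <- gf_train(featurized, dataset$cells, split, cfg)
    rep_ <- gf_evaluate(fit, part = "test")
    rows[[i]] <- tibble::tibble(
      variant = g$variant, layers = g$layers, seed = g$seed,
      split_kind = split_kind, pcc = rep_$pcc, rmse = rep_$rmse,
      n = rep_$n, epochs = fit$epochs_trained
    )
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      jsonlite::write_json(
        as.list(rows[[i]]),
        file.path(out_dir, sprintf("metrics_%s_L%d_seed%d.json",
                                   g$variant, g$layers, g$seed)),
        auto_unbox = TRUE, digits = NA
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  summary_tbl <- out |>
    dplyr::group_by(.data$variant, .data$layers, .data$split_kind) |>
    dplyr::summarise(
      mean_pcc = mean(.data$pcc), sd_pcc = stats::sd(.data$pcc),
      mean_rmse = mean(.data$rmse), sd_rmse = stats::sd(.data$rmse),
      n_seeds = dplyr::n(), .groups = "drop"
    )
  if (!is.null(out_dir)) {
    utils::write.csv(summary_tbl, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  structure(out, summary = summary_tbl)
}

#' Save or load a model checkpoint
#'
#' A checkpoint is a single file holding the parameter set, the embedded
#' configuration and the training history. Loading verifies the stored
#' configuration against an expected one when provided, and errors on any
#' mismatch.
#'
#' @param fit A `gf_fit`.
#' @param path Checkpoint file path.
#' @param config Optional expected `gf_config` to validate against.
#' @return `gf_load()` returns the `gf_fit` (without the packed model data;
#'   re-attach via [gf_model_data()] for prediction on the original tables).
#' @export
gf_save <- function(fit, path) {
  slim <- fit
  slim$model_data <- NULL
  saveRDS(slim, path)
  invisible(path)
}

#' @rdname gf_save
#' @export
gf_load <- function(path, config = NULL) {
  fit <- readRDS(path)
  if (!inherits(fit, "gf_fit")) stop("file is not a model checkpoint")
  if (!is.null(config)) {
    stored <- fit$config
    for (nm in names(stored)) {
      if (!identical(unclass(stored)[[nm]], unclass(config)[[nm]])) {
        stop("checkpoint config mismatch in field '", nm, "'")
      }
    }
  }
  fit
}
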