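# Classification metrics and the cross-condition / sweep experiment grids.

#' Confusion-matrix classification metrics
#'
#' @param labels True binary labels (0/1 vector).
#' @param calls Predicted binary calls (0/1 vector, same length).
#' @return A `meth_metrics` list: TP, FP, FN, TN, accuracy, precision, recall,
#'   f1 (ratios with zero denominators are NA and flagged in `$degenerate`).
#' @export
compute_metrics <- function(labels, calls) {
  if (length(labels) == 0L) stop("empty input")
  stopifnot(length(labels) == length(calls),
            all(labels %in% c(0, 1)), all(calls %in% c(0, 1)))
  tp <- sum(labels == 1 & calls == 1)
  fp <- sum(labels == 0 & calls == 1)
  fn <- sum(labels == 1 & calls == 0)
  tn <- sum(labels == 0 & calls == 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 accuracy = (tp + tn) / length(labels),
                 precision = precision, recall = recall, f1 = f1,
                 n = length(labels),
                 degenerate = (tp + fp == 0) || (tp + fn == 0)),
            class = "meth_metrics")
}

#' @export
print.meth_metrics <- function(x, ...) {
  cat(sprintf(paste0("accuracy %.4f | precision %s | recall %s | F1 %s ",
                     "(TP %d FP %d FN %d TN %d)\n"),
              x$accuracy, format(x$precision, digits = 4),
              format(x$recall, digits = 4), format(x$f1, digits = 4),
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Cross-condition accuracy grid
#'
#' Trains one model per row condition on that condition's train/validation
#' partitions and evaluates it on every column condition's test partition.
#' Conditions are typically contexts (CG/CHG/CHH/ALL) or species-level
#' fixtures; all conditions must share the model input width (e.g. the same
#' W_s, and the shared annotation subset when fixtures differ in available
#' tracks).
#'
#' @param conditions Named list of `meth_split` objects.
#' @param model_fun Function(condition name) returning an untrained model.
#' @param config A [train_config()]; the per-row seed is offset by the row
#'   index so each cell's model is an independent draw.
#' @return Accuracy matrix (rows = training condition, columns = testing
#'   condition) with the full long-format metric table in attribute `"long"`
#'   and the trained models in attribute `"models"`.
#' @export
run_cross_grid <- function(conditions, model_fun, config = train_config()) {
  stopifnot(length(conditions) >= 1L, !is.null(names(conditions)))
  widths <- vapply(conditions, function(s) ncol(s$train$X), numeric(1))
  if (length(unique(widths)) != 1L)
    stop("conditions have incompatible input widths: ",
         paste(widths, collapse = ", "))
  nms <- names(conditions)
  acc <- matrix(NA_real_, length(nms), length(nms),
                dimnames = list(train = nms, test = nms))
  long <- list()
  models <- list()
  for (i in seq_along(nms)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    model <- train_model(model_fun(nms[i]), conditions[[i]], cfg)
    models[[nms[i]]] <- model
    for (j in seq_along(nms)) {
      pred <- predict(model, conditions[[j]]$test)
      m <- compute_metrics(conditions[[j]]$test$y, pred$call)
      acc[i, j] <- m$accuracy
      long[[length(long) + 1L]] <- data.table::data.table(
        train = nms[i], test = nms[j], accuracy = m$accuracy,
        precision = m$precision, recall = m$recall, f1 = m$f1, n = m$n)
    }
  }
  structure(acc, long = data.table::rbindlist(long), models = models)
}

#' Accuracy sweep over window size or dataset size
#'
#' Trains one model per axis value with everything else fixed and reports a
#' long-format accuracy table. The data for each value are produced by a
#' caller-supplied builder so the sweep is agnostic to fixture/species.
#'
#' @param axis `"window_size"` or `"dataset_size"` (recorded in the output).
#' @param values Numeric axis values (window sizes must be even).
#' @param split_fun Function(value) returning a named list of `meth_split`
#'   objects (e.g. one per context) for that axis value.
#' @param model_fun Function(value, condition name, split) returning an
#'   untrained model matching the split.
#' @param config A [train_config()].
#' @return data.table(value, condition, accuracy, precision, recall, f1, n).
#' @export
run_sweep <- function(axis = c("window_size", "dataset_size"), values,
                      split_fun, model_fun, config = train_config()) {
  axis <- match.arg(axis)
  stopifnot(all(values > 0))
  if (axis == "window_size" && any(values %% 2 != 0))
    stop("window sizes must be even")
  rows <- list()
  for (v in values) {
    splits <- split_fun(v)
    if (is.null(names(splits))) stop("split_fun must return a named list")
    for (nm in names(splits)) {
      model <- train_model(model_fun(v, nm, splits[[nm]]), splits[[nm]],
                           config)
      pred <- predict(model, splits[[nm]]$test)
      m <- compute_metrics(splits[[nm]]$test$y, pred$call)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        axis = axis, value = v, condition = nm, accuracy = m$accuracy,
        precision = m$precision, recall = m$recall, f1 = m$f1, n = m$n)
    }
  }
  data.table::rbindlist(rows)
}
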