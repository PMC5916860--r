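#' Assemble a modeling dataset from dynamic characteristics
#'
#' Builds the plant-level design matrix for diagnosis: one row per plant,
#' columns the dynamic characteristics of the requested leaf position(s) and
#' period(s) concatenated in time order. Columns that are structurally
#' missing for the subset (e.g. etiolation RGR on positions other than the
#' 3rd leaf, or before the etiolation onset) are dropped when more than
#' `col_na_max` of their entries are missing; remaining rows with any
#' missing cell are then dropped and counted. Feature scaling to \[0, 1\] is
#' not applied here — it is fitted on each training fold at modeling time to
#' avoid leakage.
#'
#' @param dyn a [dynamic_features()] table (or the row-bound union of
#'   several).
#' @param periods character vector of period ids (e.g. `c("P1","P2")`).
#' @param positions leaf positions to include.
#' @param features optional subset of dynamic-characteristic column names.
#' @param col_na_max drop a feature column when more than this fraction of
#'   its entries is missing (default 0.25).
#' @return a `modeling_dataset`: `x` (matrix), `y` (factor of treatments),
#'   `plant_id`, `n_used`, `dropped_rows`, `dropped_cols`, `provenance`.
#' @export
assemble_dataset <- function(dyn, periods, positions, features = NULL,
                             col_na_max = 0.25) {
  feat_cols <- grep("^(RGR|ACR)_", names(dyn), value = TRUE)
  if (!is.null(features)) feat_cols <- intersect(feat_cols, features)
  missing_periods <- setdiff(periods, unique(dyn$period))
  if (length(missing_periods)) stop("periods not in table: ",
                                    paste(missing_periods, collapse = ", "))
  missing_pos <- setdiff(positions, unique(dyn$leaf_position))
  if (length(missing_pos)) stop("positions not in table: ",
                                paste(missing_pos, collapse = ", "))
  plants <- unique(dyn[, c("plant_id", "year", "treatment")])
  plants$key <- paste(plants$plant_id, plants$year, sep = "/")
  blocks <- list()
  for (pos in positions) {
    for (per in periods) {
      sub <- dyn[dyn$leaf_position == pos & dyn$period == per, ]
      sub$key <- paste(sub$plant_id, sub$year, sep = "/")
      m <- as.matrix(sub[match(plants$key, sub$key), feat_cols, drop = FALSE])
      colnames(m) <- paste(pos, per, feat_cols, sep = "_")
      blocks[[paste(pos, per)]] <- m
    }
  }
  x <- do.call(cbind, blocks)
  rownames(x) <- plants$key
  na_frac <- colMeans(is.na(x))
  dropped_cols <- colnames(x)[na_frac > col_na_max]
  x <- x[, na_frac <= col_na_max, drop = FALSE]
  if (ncol(x) == 0) stop_empty_dataset("all feature columns were dropped")
  complete <- stats::complete.cases(x)
  dropped_rows <- plants$key[!complete]
  x <- x[complete, , drop = FALSE]
  y <- factor(plants$treatment[complete])
  if (nrow(x) == 0) stop_empty_dataset()
  structure(list(
    x = x, y = y, plant_id = plants$key[complete],
    n_used = nrow(x), dropped_rows = dropped_rows, dropped_cols = dropped_cols,
    provenance = list(periods = periods, positions = positions)
  ), class = "modeling_dataset")
}

#' @export
print.modeling_dataset <- function(x, ...) {
  cat(sprintf("<modeling_dataset %d plants x %d features (%d rows, %d cols dropped) [%s | %s]>\n",
              x$n_used, ncol(x$x), length(x$dropped_rows), length(x$dropped_cols),
              paste(x$provenance$positions, collapse = "+"),
              paste(x$provenance$periods, collapse = " ")))
  invisible(x)
}

#' Train the multi-class nitrogen diagnosis SVM
#'
#' RBF-kernel soft-margin SVM with one-vs-one multi-class handling (libsvm
#' via e1071), after rescaling every feature to \[0, 1\] on the training
#' data. The default RBF width is the variance-scaled convention
#' `gamma = 1/(n_features * mean(var(x_scaled)))`: with min-max-scaled
#' features and the very small samples of this design, the plain
#' `1/n_features` width makes the kernel nearly constant, which degenerates
#' the one-vs-one votes into majority voting (and collapses leave-one-out
#' accuracy); `gamma = "nfeatures"` selects that plain width anyway.
#' `tune = TRUE` replaces the fixed hyperparameters by a coarse grid search
#' over cost and width selected by leave-one-out accuracy on the training
#' data only, so it stays fold-confined when called inside [loocv()].
#'
#' @param ds a `modeling_dataset` (or a list with `x`, `y`).
#' @param cost soft-margin cost C.
#' @param gamma RBF width: a number, `"scale"` (default) or `"nfeatures"`.
#' @param tune grid-search cost and gamma on the training data.
#' @return a `diagnosis_model` wrapping the svm fit and the scaler.
#' @export
train_svm <- function(ds, cost = 1, gamma = NULL, tune = FALSE) {
  x <- ds$x
  y <- droplevels(ds$y)
  if (nlevels(y) < 2) stop_degenerate_labels()
  scaler <- fit_minmax(x)
  xs <- apply_minmax(scaler, x)
  gamma <- resolve_gamma(gamma, xs)
  if (tune) {
    grid <- expand.grid(cost = 2^c(-5, -1, 3, 7, 11, 15),
                        gamma = gamma * 2^c(-4, -2, 0, 2))
    acc <- vapply(seq_len(nrow(grid)), function(i) {
      e1071::svm(xs, y, kernel = "radial", cost = grid$cost[i],
                 gamma = grid$gamma[i], scale = FALSE,
                 cross = nrow(xs))$tot.accuracy
    }, 0)
    best <- which.max(acc)
    cost <- grid$cost[best]
    gamma <- grid$gamma[best]
  }
  fit <- e1071::svm(xs, y, kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, scaler = scaler, levels = levels(ds$y),
                 cost = cost, gamma = gamma), class = "diagnosis_model")
}

resolve_gamma <- function(gamma, xs) {
  if (is.numeric(gamma)) return(gamma)
  if (is.null(gamma) || identical(gamma, "scale")) {
    v <- mean(apply(xs, 2, stats::var))
    if (!is.finite(v) || v <= 0) v <- 1
    return(1 / (ncol(xs) * v))
  }
  if (identical(gamma, "nfeatures")) return(1 / ncol(xs))
  stop("gamma must be numeric, \"scale\" or \"nfeatures\"")
}

#' @export
predict.diagnosis_model <- function(object, newdata, ...) {
  p <- stats::predict(object$fit, apply_minmax(object$scaler, newdata))
  factor(as.character(p), levels = object$levels)
}

#' Leave-one-out cross-validation of the diagnosis model
#'
#' Each plant is predicted by a model trained on all other plants; the
#' \[0, 1\] feature scaling is refitted inside every fold on its training
#' part only, so the held-out row never leaks into preprocessing. Training
#' accuracy is the resubstitution accuracy of the model fitted on all rows.
#'
#' @param ds a `modeling_dataset`.
#' @param cost,gamma,tune hyperparameters passed to [train_svm()]; with
#'   `tune = TRUE` the grid search is re-run inside every fold on its
#'   training part only.
#' @return a `cv_result`: `training_accuracy`, `validation_accuracy`,
#'   `confusion` (true x predicted), `n_used`, `dropped_rows`,
#'   `fold_flags` (folds whose training part lost a class),
#'   `hyperparameters`.
#' @export
loocv <- function(ds, cost = 1, gamma = NULL, tune = FALSE) {
  n <- nrow(ds$x)
  if (n < nlevels(droplevels(ds$y)) + 1) {
    rld_error("rld_too_few_rows", "too few rows for LOOCV")
  }
  full <- train_svm(ds, cost = cost, gamma = gamma, tune = tune)
  train_pred <- predict(full, ds$x)
  training_accuracy <- mean(train_pred == ds$y)
  pred <- factor(rep(NA_character_, n), levels = levels(ds$y))
  fold_flags <- integer()
  for (i in seq_len(n)) {
    tr <- list(x = ds$x[-i, , drop = FALSE], y = ds$y[-i])
    if (nlevels(droplevels(tr$y)) < nlevels(droplevels(ds$y))) {
      fold_flags <- c(fold_flags, i)
    }
    m <- train_svm(tr, cost = cost, gamma = gamma, tune = tune)
    pred[i] <- predict(m, ds$x[i, , drop = FALSE])
  }
  validation_accuracy <- mean(pred == ds$y)
  confusion <- table(true = ds$y, predicted = pred)
  structure(list(
    training_accuracy = training_accuracy,
    validation_accuracy = validation_accuracy,
    predictions = pred, confusion = confusion, n_used = n,
    dropped_rows = ds$dropped_rows, fold_flags = fold_flags,
    hyperparameters = list(cost = full$cost, gamma = full$gamma)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result n=%d training %.1f%% validation %.1f%%>\n",
              x$n_used, 100 * x$training_accuracy, 100 * x$validation_accuracy))
  invisible(x)
}

# Table-2 style enumeration: every single period plus the cumulative
# time-ordered combinations (P1P2, P1P2P3, ...).
dataset_combinations <- function(scheme) {
  ids <- scheme$id
  singles <- lapply(ids, identity)
  cumulative <- if (length(ids) >= 2) {
    lapply(2:length(ids), function(i) ids[seq_len(i)])
  } else {
    list()
  }
  combos <- c(singles, cumulative)
  names(combos) <- vapply(combos, paste, "", collapse = "")
  combos
}

#' Evaluate the diagnosis grid over periods and leaf positions
#'
#' Runs LOOCV for every single period and every cumulative time-ordered
#' combination of periods, for each leaf position and (optionally) the
#' FIL + 3rd leaf combination, over both interval spacings. This is the
#' full evaluation design: which scan window and which leaf diagnose the
#' nitrogen level best.
#'
#' @param dyn_list named list of dynamic-feature tables, e.g.
#'   `list(\"3d\" = dyn3, \"6d\" = dyn6)`.
#' @param positions leaf positions evaluated singly.
#' @param combined_positions list of position sets evaluated jointly
#'   (default FIL + 3rd; `NULL` to skip).
#' @param cost,gamma,tune hyperparameters passed to [loocv()].
#' @return list with `report` (one row per spacing x data set x position
#'   set) and `confusions` (named list of confusion matrices).
#' @export
evaluate_grid <- function(dyn_list,
                          positions = c("FIL", "1st", "2nd", "3rd"),
                          combined_positions = list(c("FIL", "3rd")),
                          cost = 1, gamma = NULL, tune = FALSE) {
  rows <- list()
  confusions <- list()
  pos_sets <- c(as.list(positions), combined_positions)
  for (spacing in names(dyn_list)) {
    dyn <- dyn_list[[spacing]]
    scheme <- attr(dyn, "scheme")
    combos <- dataset_combinations(scheme)
    for (ps in pos_sets) {
      pos_label <- paste(ps, collapse = "+")
      for (ci in seq_along(combos)) {
        label <- names(combos)[ci]
        res <- tryCatch({
          ds <- assemble_dataset(dyn, combos[[ci]], ps)
          loocv(ds, cost = cost, gamma = gamma, tune = tune)
        }, riceleafdyn_error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            spacing = spacing, data_set = label, positions = pos_label,
            single = length(combos[[ci]]) == 1, n_used = 0L, dropped = NA_integer_,
            training_acc = NA_real_, validation_acc = NA_real_,
            note = conditionMessage(res), stringsAsFactors = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          spacing = spacing, data_set = label, positions = pos_label,
          single = length(combos[[ci]]) == 1, n_used = res$n_used,
          dropped = length(res$dropped_rows),
          training_acc = res$training_accuracy,
          validation_acc = res$validation_accuracy,
          note = "", stringsAsFactors = FALSE)
        confusions[[paste(spacing, label, pos_label, sep = "|")]] <-
          unclass(res$confusion)
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(report = report, confusions = confusions)
}

#' Best leaf position per data set
#'
#' @param report the `report` component of [evaluate_grid()].
#' @return one row per spacing x data set with the position achieving the
#'   highest validation accuracy.
#' @export
best_position_summary <- function(report) {
  single_pos <- report[!grepl("\\+", report$positions) & !is.na(report$validation_acc), ]
  keys <- unique(single_pos[, c("spacing", "data_set")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- single_pos[single_pos$spacing == keys$spacing[i] &
                        single_pos$data_set == keys$data_set[i], ]
    sub[which.max(sub$validation_acc), c("spacing", "data_set", "positions",
                                         "training_acc", "validation_acc")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
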