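#' Relative growth rate
#'
#' Hunt's log-ratio growth rate per day,
#' `RGR = (ln W2 - ln W1) / (t2 - t1)`, applied to the leaf shape
#' characteristics (LA, LP, EA, ED).
#'
#' @param w1,w2 characteristic value at the start and end of the period
#'   (must be positive).
#' @param t1,t2 period endpoints in days (`t2 > t1`).
#' @return growth rate in 1/day.
#' @export
rgr <- function(w1, w2, t1, t2) {
  if (t2 <= t1) stop_bad_interval()
  if (w1 <= 0 || w2 <= 0) stop_nonpositive()
  (log(w2) - log(w1)) / (t2 - t1)
}

#' Average changing rate
#'
#' Linear rate of change per day, `ACR = (X2 - X1) / (t2 - t1)`, applied to
#' the leaf color characteristics (G, NRI, DGCI, ExG, ExR).
#'
#' @param x1,x2 characteristic value at the start and end of the period.
#' @param t1,t2 period endpoints in days (`t2 > t1`).
#' @return rate in units of X per day.
#' @export
acr <- function(x1, x2, t1, t2) {
  if (t2 <= t1) stop_bad_interval()
  (x2 - x1) / (t2 - t1)
}

#' Build the interval scheme over a scan schedule
#'
#' With spacing equal to the schedule step the periods are the consecutive
#' scan pairs (overlapping at their endpoints); with spacing twice the step
#' they are non-overlapping pairs tiling the schedule. By default the final
#' period is dropped, reflecting the loss of senescing leaves late in the
#' campaign: on the standard DAT 20..44 schedule this yields 7 three-day
#' periods (P1..P7) and 3 six-day periods (P1'..P3').
#'
#' @param schedule strictly increasing DAT vector.
#' @param spacing period length in days; must be a multiple of the schedule
#'   step and land on scheduled days.
#' @param drop_final drop the last period (default `TRUE`).
#' @return an `interval_scheme` data.frame with columns `id`, `t1`, `t2` and
#'   attributes `spacing`, `schedule`.
#' @export
build_interval_scheme <- function(schedule, spacing, drop_final = TRUE) {
  if (any(diff(schedule) <= 0)) stop("schedule must be strictly increasing")
  step <- unique(diff(schedule))
  if (length(step) != 1 || spacing %% step != 0 || spacing <= 0) stop_bad_spacing()
  starts <- seq(schedule[1], max(schedule) - spacing, by = spacing)
  if (!all(starts %in% schedule) || !all((starts + spacing) %in% schedule)) {
    stop_bad_spacing()
  }
  prime <- if (spacing > step) "'" else ""
  per <- data.frame(
    id = paste0("P", seq_along(starts), prime),
    t1 = starts, t2 = starts + spacing,
    stringsAsFactors = FALSE)
  if (drop_final && nrow(per) > 0) per <- per[-nrow(per), , drop = FALSE]
  rownames(per) <- NULL
  structure(per, spacing = spacing, schedule = schedule,
            class = c("interval_scheme", "data.frame"))
}

.rgr_features <- c("LA", "LP", "EA", "ED")
.acr_features <- c("G", "NRI", "DGCI", "ExG", "ExR")

#' Dynamic characteristics per plant, period and leaf position
#'
#' Applies [rgr()] to the shape characteristics (LA, LP, EA, ED) and [acr()]
#' to the color characteristics (G, NRI, DGCI, ExG, ExR) over each period of
#' an interval scheme. A cell is `NA` when either endpoint observation is
#' missing or when an RGR precondition fails (e.g. EA = 0 before the
#' etiolation onset, where the log-ratio is undefined); no imputation is
#' done.
#'
#' @param features per-observation feature table (schema of
#'   [extract_features()], plus `year`).
#' @param scheme an [build_interval_scheme()] result.
#' @return a `data.frame` keyed by (`plant_id`, `year`, `leaf_position`,
#'   `period`) with columns `RGR_LA`, `RGR_LP`, `RGR_EA`, `RGR_ED`, `ACR_G`,
#'   `ACR_NRI`, `ACR_DGCI`, `ACR_ExG`, `ACR_ExR` and the treatment label.
#' @export
dynamic_features <- function(features, scheme) {
  if (is.null(features$year)) features$year <- 1L
  keys <- unique(features[, c("plant_id", "year", "treatment", "leaf_position")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- features[features$plant_id == keys$plant_id[i] &
                      features$year == keys$year[i] &
                      features$leaf_position == keys$leaf_position[i], ]
    for (j in seq_len(nrow(scheme))) {
      r1 <- sub[sub$dat == scheme$t1[j], ]
      r2 <- sub[sub$dat == scheme$t2[j], ]
      row <- data.frame(
        plant_id = keys$plant_id[i], year = keys$year[i],
        treatment = keys$treatment[i], leaf_position = keys$leaf_position[i],
        period = scheme$id[j], t1 = scheme$t1[j], t2 = scheme$t2[j],
        stringsAsFactors = FALSE)
      both <- nrow(r1) == 1 && nrow(r2) == 1
      for (f in .rgr_features) {
        col <- paste0("RGR_", f)
        row[[col]] <- NA_real_
        if (both && !is.na(r1[[f]]) && !is.na(r2[[f]]) &&
            r1[[f]] > 0 && r2[[f]] > 0) {
          row[[col]] <- rgr(r1[[f]], r2[[f]], scheme$t1[j], scheme$t2[j])
        }
      }
      for (f in .acr_features) {
        col <- paste0("ACR_", f)
        row[[col]] <- NA_real_
        if (both && !is.na(r1[[f]]) && !is.na(r2[[f]])) {
          row[[col]] <- acr(r1[[f]], r2[[f]], scheme$t1[j], scheme$t2[j])
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "scheme") <- scheme
  res
}

## ---- growth-model fitting --------------------------------------------------

growth_model_forms <- function() {
  list(
    power = list(
      formula = y ~ a * t^b, npar = 2,
      start = function(t, y) {
        cf <- unname(stats::coef(stats::lm(log(y) ~ log(t))))
        # second start nudged off the log-linear solution in case the
        # gradient is degenerate there (e.g. constant data)
        list(list(a = exp(cf[1]), b = cf[2]),
             list(a = exp(cf[1]) * 0.9, b = cf[2] + 0.05))
      }),
    exponential = list(
      formula = y ~ a * exp(b * t), npar = 2,
      start = function(t, y) {
        cf <- unname(stats::coef(stats::lm(log(y) ~ t)))
        list(list(a = exp(cf[1]), b = cf[2]),
             list(a = exp(cf[1]) * 0.9, b = cf[2] + 0.01))
      }),
    logistic = list(
      formula = y ~ A / (1 + exp(-k * (t - t0))), npar = 3,
      start = function(t, y) {
        grid <- expand.grid(A = max(y) * c(1.0, 1.2, 1.6),
                            k = c(0.05, 0.15, 0.3, 0.6, 1.0),
                            t0 = unname(stats::quantile(t, c(0.25, 0.5, 0.75))))
        lapply(seq_len(nrow(grid)), function(i) as.list(grid[i, ]))
      })
  )
}

#' Fit one growth model to a leaf time series
#'
#' Nonlinear least squares (Levenberg-Marquardt) for one of three candidate
#' growth laws: power `a t^b`, exponential `a e^(b t)`, or sigmoidal
#' logistic `A / (1 + exp(-k (t - t0)))`. The logistic fit uses a small
#' multi-start grid and keeps the best-RSS solution. Goodness of fit is
#' `R^2 = 1 - RSS/TSS`; model quality is `AIC = n ln(RSS/n) + 2p` with `p`
#' fitted parameters (the least-squares form used by common statistics
#' packages, whose value can be negative). A perfect fit (RSS = 0) reports
#' `AIC = -Inf`.
#'
#' @param times observation days.
#' @param values characteristic values (positive for power/exponential).
#' @param model `"power"`, `"exponential"` or `"logistic"`.
#' @return a `growth_fit` list: `model`, `par`, `rss`, `r2`, `aic`, `n`,
#'   `npar`.
#' @export
fit_growth_model <- function(times, values, model = c("power", "exponential", "logistic")) {
  model <- match.arg(model)
  forms <- growth_model_forms()[[model]]
  n <- length(values)
  if (n != length(times)) stop("times and values differ in length")
  if (n < forms$npar + 1) stop_fit_failure(sprintf(
    "need at least %d points for the %s model", forms$npar + 1, model))
  if (model %in% c("power", "exponential") && any(values <= 0)) {
    stop_nonpositive("power/exponential fits require positive values")
  }
  dat <- data.frame(t = times, y = values)
  best <- NULL
  fails <- character()
  for (st in forms$start(times, values)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(forms$formula, data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      fails <- c(fails, conditionMessage(fit))
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop_fit_failure(
    sprintf("no %s start converged", model), diagnostics = fails)
  rss <- best$rss
  tss <- sum((values - mean(values))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  aic <- if (rss <= 0) -Inf else n * log(rss / n) + 2 * forms$npar
  structure(list(model = model, par = stats::coef(best$fit), rss = rss,
                 r2 = r2, aic = aic, n = n, npar = forms$npar),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit %s: %s | RSS %.4g R2 %.4f AIC %.4g (n=%d)>\n",
              x$model, paste(names(x$par), signif(x$par, 4), sep = "=",
                             collapse = " "), x$rss, x$r2, x$aic, x$n))
  invisible(x)
}

#' Fit all candidate growth models to one series
#'
#' @param times,values as in [fit_growth_model()].
#' @param models subset of the three model names.
#' @return named list of `growth_fit` objects (models whose fit failed are
#'   dropped with a warning).
#' @export
fit_growth_models <- function(times, values,
                              models = c("power", "exponential", "logistic")) {
  fits <- list()
  for (m in models) {
    f <- tryCatch(fit_growth_model(times, values, m),
                  riceleafdyn_error = function(e) {
                    warning(sprintf("%s fit failed: %s", m, conditionMessage(e)))
                    NULL
                  })
    if (!is.null(f)) fits[[m]] <- f
  }
  fits
}

#' Select the best growth model by AIC
#'
#' Lower AIC wins; exact ties are broken toward the model with fewer
#' parameters.
#'
#' @param fits list of `growth_fit` objects on the same data.
#' @return the winning `growth_fit`.
#' @export
select_growth_model <- function(fits) {
  if (!length(fits)) stop("empty fit list")
  aic <- vapply(fits, function(f) f$aic, 0)
  npar <- vapply(fits, function(f) f$npar, 0)
  best_aic <- min(aic)
  tied <- which(aic <= best_aic + 1e-10)
  fits[[tied[which.min(npar[tied])]]]
}

#' Growth-model comparison per treatment and leaf position
#'
#' Fits the three candidate models to the treatment-mean trajectory of a
#' shape characteristic and tabulates parameters, R^2 and AIC — the growth
#' pattern screen that motivates using the sigmoidal logistic law.
#'
#' @param features per-observation feature table.
#' @param characteristic column to model (default `"LA"`).
#' @param position leaf position to model (default `"FIL"`, the expanding
#'   leaf).
#' @return data.frame with one row per treatment x model.
#' @export
growth_fit_report <- function(features, characteristic = "LA", position = "FIL") {
  sub <- features[features$leaf_position == position & !is.na(features[[characteristic]]), ]
  out <- list()
  for (lev in sort(unique(sub$treatment))) {
    s2 <- sub[sub$treatment == lev, ]
    agg <- stats::aggregate(s2[[characteristic]], list(dat = s2$dat), mean)
    fits <- fit_growth_models(agg$dat, agg$x)
    if (!length(fits)) next
    sel <- select_growth_model(fits)$model
    for (m in names(fits)) {
      f <- fits[[m]]
      out[[length(out) + 1L]] <- data.frame(
        treatment = lev, characteristic = characteristic,
        leaf_position = position, model = m,
        params = paste(names(f$par), signif(f$par, 6), sep = "=", collapse = ";"),
        r2 = f$r2, aic = f$aic, n = f$n, selected = m == sel,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
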