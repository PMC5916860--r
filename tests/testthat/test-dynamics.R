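test_that("relative growth rate follows the log-ratio definition", {
  expect_equal(rgr(5, 5, 20, 23), 0)
  expect_equal(rgr(100, 200, 20, 23), log(2) / 3)
  expect_equal(rgr(100, 200, 20, 23), 0.23105, tolerance = 1e-4)
  expect_error(rgr(0, 10, 20, 23), class = "rld_nonpositive")
  expect_error(rgr(10, -1, 20, 23), class = "rld_nonpositive")
  expect_error(rgr(10, 20, 23, 23), class = "rld_bad_interval")
})

test_that("RGR is unit invariant and chains by duration weighting", {
  set.seed(4)
  for (i in 1:20) {
    w <- stats::runif(3, 1, 50)
    t <- sort(stats::runif(3, 0, 40))
    c_ <- stats::runif(1, 0.01, 100)
    expect_equal(rgr(c_ * w[1], c_ * w[2], t[1], t[2]),
                 rgr(w[1], w[2], t[1], t[2]), tolerance = 1e-12)
    whole <- rgr(w[1], w[3], t[1], t[3])
    parts <- (rgr(w[1], w[2], t[1], t[2]) * (t[2] - t[1]) +
                rgr(w[2], w[3], t[2], t[3]) * (t[3] - t[2])) / (t[3] - t[1])
    expect_equal(whole, parts, tolerance = 1e-12)
  }
})

test_that("average changing rate is the linear slope per day", {
  expect_equal(acr(0.4, 0.4, 20, 26), 0)
  expect_equal(acr(0.30, 0.36, 20, 23), 0.02)
  expect_error(acr(1, 2, 23, 23), class = "rld_bad_interval")
  # linearity in the difference, inverse scaling with the interval
  expect_equal(acr(0, 3, 0, 2) + acr(0, 5, 0, 2), acr(0, 8, 0, 2))
  expect_equal(acr(0, 6, 0, 6), acr(0, 6, 0, 3) / 2)
})

test_that("interval schemes reproduce the 7 + 3 data-set design", {
  schedule <- seq(20, 44, by = 3)
  s3 <- build_interval_scheme(schedule, 3)
  expect_equal(nrow(s3), 7)
  expect_equal(s3$id, paste0("P", 1:7))
  expect_equal(s3$t1, seq(20, 38, 3))
  expect_equal(s3$t2, s3$t1 + 3)

  s6 <- build_interval_scheme(schedule, 6)
  expect_equal(nrow(s6), 3)
  expect_equal(s6$id, c("P1'", "P2'", "P3'"))
  expect_equal(s6$t1, c(20, 26, 32))
  expect_equal(s6$t2, c(26, 32, 38))

  expect_equal(nrow(build_interval_scheme(schedule, 3, drop_final = FALSE)), 8)
  expect_equal(nrow(build_interval_scheme(schedule, 6, drop_final = FALSE)), 4)
  expect_equal(nrow(build_interval_scheme(c(20, 23), 3)), 0)
  expect_error(build_interval_scheme(schedule, 4), class = "rld_bad_spacing")
})

test_that("dynamic feature cells honor missingness and preconditions", {
  base <- data.frame(
    plant_id = "p1", treatment = "N1", year = 1, leaf_position = "3rd",
    dat = c(20, 23, 26), LA = c(100, 200, 250), LP = c(40, 50, 55),
    EA = c(0, 10, 20), ED = c(0, 0.05, 0.08), G = c(120, 120, 130),
    NRI = 0.35, DGCI = c(0.3, 0.33, 0.36), ExG = 0.4, ExR = 0.02,
    stringsAsFactors = FALSE)
  scheme <- build_interval_scheme(c(20, 23, 26), 3, drop_final = FALSE)
  dyn <- dynamic_features(base, scheme)
  expect_equal(nrow(dyn), 2)
  expect_equal(dyn$RGR_LA[1], log(2) / 3)
  expect_true(is.na(dyn$RGR_EA[1]))  # EA = 0 at the period start
  expect_equal(dyn$RGR_EA[2], log(2) / 3)
  expect_equal(dyn$ACR_NRI, c(0, 0))  # constant color
  expect_equal(dyn$ACR_G[2], 10 / 3)

  # a missing endpoint empties the whole period row
  gap <- base[base$dat != 23, ]
  dyn2 <- dynamic_features(gap, scheme)
  expect_true(all(is.na(dyn2$RGR_LA)))
  expect_true(all(is.na(dyn2$ACR_G)))
})

test_that("noise-free curves are recovered exactly by their own model", {
  t <- seq(20, 44, by = 3)
  y_log <- 10 / (1 + exp(-0.8 * (t - 27)))
  fl <- fit_growth_model(t, y_log, "logistic")
  expect_equal(unname(fl$par["A"]), 10, tolerance = 1e-6)
  expect_equal(unname(fl$par["k"]), 0.8, tolerance = 1e-6)
  expect_equal(unname(fl$par["t0"]), 27, tolerance = 1e-6)
  expect_gt(fl$r2, 1 - 1e-9)

  y_pow <- 2 * t^1.5
  fp <- fit_growth_model(t, y_pow, "power")
  expect_equal(unname(fp$par["a"]), 2, tolerance = 1e-6)
  expect_equal(unname(fp$par["b"]), 1.5, tolerance = 1e-6)
  expect_gt(fp$r2, 1 - 1e-9)

  fe <- fit_growth_model(t, rep(5, length(t)), "exponential")
  expect_equal(unname(fe$par["b"]), 0, tolerance = 1e-6)
  expect_equal(unname(fe$par["a"]), 5, tolerance = 1e-6)

  expect_error(fit_growth_model(t, y_pow - 400, "power"),
               class = "rld_nonpositive")
  expect_error(fit_growth_model(20:22, c(1, 2, 3), "logistic"),
               class = "rld_fit_failure")
})

test_that("model selection prefers low AIC and breaks ties by parsimony", {
  mk <- function(model, aic, npar) {
    structure(list(model = model, aic = aic, npar = npar), class = "growth_fit")
  }
  fits <- list(mk("power", 5, 2), mk("logistic", -10, 3), mk("exponential", 0, 2))
  expect_equal(select_growth_model(fits)$model, "logistic")
  tie <- list(mk("logistic", 1.0, 3), mk("exponential", 1.0, 2))
  expect_equal(select_growth_model(tie)$model, "exponential")
  expect_equal(select_growth_model(list(mk("power", 3, 2)))$model, "power")
  expect_error(select_growth_model(list()))
})

test_that("logistic parameters are recovered from noisy nine-point series", {
  # 2% of A per-point noise: at this 9-point schedule the rate parameter k
  # loses identifiability for much larger noise (see the methods vignette)
  t <- seq(20, 44, by = 3)
  A <- 25; k <- 0.4; t0 <- 28
  ok <- 0
  n_rep <- 200
  set.seed(17)
  for (i in seq_len(n_rep)) {
    y <- A / (1 + exp(-k * (t - t0))) + stats::rnorm(length(t), 0, 0.02 * A)
    f <- tryCatch(fit_growth_model(t, pmax(y, 0.01), "logistic"),
                  rld_fit_failure = function(e) NULL)
    if (is.null(f)) next
    if (abs(f$par["A"] - A) / A < 0.05 && abs(f$par["k"] - k) / k < 0.10) ok <- ok + 1
  }
  expect_gte(ok, 0.8 * n_rep)
})

test_that("treatment-level growth comparison favors the logistic law", {
  ex <- small_cohort(seed = 55, replicates = 5, years = 1, positions = "FIL")
  rep_tab <- growth_fit_report(ex$features, "LA", "FIL")
  expect_setequal(unique(rep_tab$treatment), c("N1", "N2", "N3", "N4"))
  sel <- rep_tab[rep_tab$selected, ]
  expect_true(all(sel$model == "logistic"))
  expect_true(all(sel$r2 > 0.99))
  # AIC of the logistic is below the alternatives for every treatment
  for (lev in unique(rep_tab$treatment)) {
    sub <- rep_tab[rep_tab$treatment == lev, ]
    expect_equal(sub$model[which.min(sub$aic)], "logistic")
  }
})
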