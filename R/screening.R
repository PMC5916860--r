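#' One-way ANOVA across treatment groups
#'
#' Classical equal-variance one-way ANOVA of one dynamic characteristic
#' across the nitrogen treatments. Missing values are dropped; a group left
#' with fewer than two values is excluded (with a warning) and the degrees
#' of freedom adjusted. Degenerate layouts are handled explicitly: when the
#' between-group variance is zero the result is F = 0, p = 1; when the
#' within-group variance is zero but groups differ, F is unbounded and is
#' reported as `Inf` with p = 0 and a `zero_within_variance` flag.
#'
#' @param groups named list of numeric vectors, one per treatment.
#' @return list with `F`, `p`, `df_between`, `df_within`, `group_means`,
#'   `n`, `flags`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- vapply(groups, length, 0L)
  if (any(sizes < 2)) {
    drop <- names(groups)[sizes < 2]
    if (length(drop)) warning("excluding groups with < 2 values: ",
                              paste(drop, collapse = ", "))
    groups <- groups[sizes >= 2]
  }
  k <- length(groups)
  if (k < 2) stop("need at least two groups with two or more values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)))
  n <- length(values)
  flags <- character()
  means <- vapply(groups, mean, 0)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  ssb <- sum(vapply(groups, function(x) length(x) * (mean(x) - mean(values))^2, 0))
  df_b <- k - 1L
  df_w <- n - k
  if (ssb <= .Machine$double.eps * max(ssw, 1)) {
    f <- 0
    p <- 1
  } else if (ssw <= .Machine$double.eps * ssb) {
    f <- Inf
    p <- 0
    flags <- c(flags, "zero_within_variance")
  } else {
    ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
    f <- unname(ow$statistic)
    p <- unname(ow$p.value)
  }
  list(F = f, p = p, df_between = df_b, df_within = df_w,
       group_means = means, n = n, flags = flags)
}

#' Screen dynamic characteristics by ANOVA
#'
#' Runs [one_way_anova()] for every dynamic characteristic x leaf position x
#' period in a dynamic-feature table, flags characteristics whose p-value
#' falls below `alpha`, and ranks them by F within each leaf position and
#' period. With the study design of 4 treatments x 5 replicates the
#' significance boundary at alpha = 0.05 sits at F(3, 30) = 2.92 when years
#' are pooled over two seasons.
#'
#' @param dyn a [dynamic_features()] table.
#' @param alpha significance level (default 0.05).
#' @param adjust optional p-value adjustment method (default `"none"`,
#'   matching a raw-p screen; `"BH"` available).
#' @return tidy data.frame: `feature`, `leaf_position`, `period`, `F`, `p`,
#'   dfs, `significant`, `rank_F`, `n`.
#' @export
screen_features <- function(dyn, alpha = 0.05, adjust = "none") {
  feat_cols <- grep("^(RGR|ACR)_", names(dyn), value = TRUE)
  out <- list()
  for (pos in unique(dyn$leaf_position)) {
    for (per in unique(dyn$period)) {
      sub <- dyn[dyn$leaf_position == pos & dyn$period == per, ]
      for (f in feat_cols) {
        groups <- split(sub[[f]], sub$treatment)
        sizes <- vapply(groups, function(g) sum(!is.na(g)), 0L)
        if (sum(sizes >= 2) < 2) next
        res <- suppressWarnings(one_way_anova(groups))
        out[[length(out) + 1L]] <- data.frame(
          feature = f, leaf_position = pos, period = per,
          F = res$F, p = res$p, df_between = res$df_between,
          df_within = res$df_within, n = res$n,
          flags = paste(res$flags, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  if (adjust != "none") res$p <- stats::p.adjust(res$p, method = adjust)
  res$significant <- res$p < alpha
  res$rank_F <- stats::ave(-res$F, res$leaf_position, res$period,
                           FUN = function(x) rank(x, ties.method = "first"))
  rownames(res) <- NULL
  res
}

#' ANOVA results in a wide grid
#'
#' Reshapes a [screen_features()] table into the feature x period by
#' leaf-position grid used for reporting, with significance stars
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#'
#' @param screened output of [screen_features()].
#' @return data.frame with one row per feature x period and one column per
#'   leaf position.
#' @export
anova_wide_table <- function(screened) {
  stars <- function(p) ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                              ifelse(p < 0.05, "*", "")))
  screened$cell <- sprintf("%.2f%s", screened$F, stars(screened$p))
  positions <- unique(screened$leaf_position)
  keys <- unique(screened[, c("period", "feature")])
  for (pos in positions) {
    sub <- screened[screened$leaf_position == pos, c("period", "feature", "cell")]
    names(sub)[3] <- pos
    keys <- merge(keys, sub, by = c("period", "feature"), all.x = TRUE, sort = FALSE)
  }
  keys[order(keys$period, keys$feature), ]
}
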