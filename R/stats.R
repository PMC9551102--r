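# Cohort-level statistics ----------------------------------------------------

.merge_feature <- function(features, metadata, feature, column) {
  for (df in list(features, metadata))
    if (!is.data.frame(df) || !"sample_id" %in% names(df))
      stop("features and metadata must be data frames keyed by sample_id",
           call. = FALSE)
  if (!feature %in% names(features))
    stop(sprintf("feature \"%s\" not found in feature table", feature),
         call. = FALSE)
  if (!column %in% names(metadata))
    stop(sprintf("column \"%s\" not found in metadata", column),
         call. = FALSE)
  merge(features[, c("sample_id", feature)],
        metadata[, c("sample_id", column)], by = "sample_id")
}

#' Correlate a glycan feature with a cytokine concentration
#'
#' Pearson product-moment correlation between a glycan feature (e.g. the
#' non-fucosylated proportion of the 2-LacNAc stratum) and a cytokine
#' concentration across samples, with the ordinary least-squares regression
#' of cytokine on feature. Samples missing either value are dropped pairwise;
#' at least 3 complete pairs are required. The two-sided p value comes from
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param features Feature table (one row per sample, `sample_id` column; see
#'   [cohort_features()]).
#' @param metadata Sample metadata with `sample_id` and cytokine
#'   concentration columns in pg/mL.
#' @param feature,cytokine Column names to correlate.
#' @param log_cytokine Correlate against `log(concentration + 1)` instead of
#'   the raw concentration.
#' @return An object of class `glycan_correlation`: a list with `feature`,
#'   `cytokine`, `n`, `r`, `p`, `slope`, `intercept`. When either variable
#'   has zero variance, `r` and `p` are `NA` with a warning.
#' @export
correlate_feature <- function(features, metadata, feature, cytokine,
                              log_cytokine = FALSE) {
  d <- .merge_feature(features, metadata, feature, cytokine)
  x <- d[[feature]]
  y <- d[[cytokine]]
  if (isTRUE(log_cytokine)) y <- log(y + 1)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 samples with both values present", call. = FALSE)
  out <- list(feature = feature, cytokine = cytokine, n = n,
              r = NA_real_, p = NA_real_,
              slope = NA_real_, intercept = NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in ", if (stats::sd(x) == 0) feature else cytokine,
            "; correlation undefined")
  } else {
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    fit <- stats::lm(y ~ x)
    out$r <- unname(ct$estimate)
    out$p <- ct$p.value
    out$slope <- unname(stats::coef(fit)[2])
    out$intercept <- unname(stats::coef(fit)[1])
  }
  structure(out, class = "glycan_correlation")
}

#' @export
print.glycan_correlation <- function(x, ...) {
  cat(sprintf("Pearson correlation: %s ~ %s\n", x$cytokine, x$feature))
  cat(sprintf("  n = %d, r = %.4f, two-sided p = %.4g\n", x$n, x$r, x$p))
  cat(sprintf("  OLS: %s = %.4g + %.4g * %s\n",
              x$cytokine, x$intercept, x$slope, x$feature))
  invisible(x)
}

#' Correlate several features against several cytokines
#'
#' Convenience wrapper running [correlate_feature()] over the cross product
#' of features and cytokines, returning a tidy table. No multiple-testing
#' correction is applied by default; set `p_adjust = "BH"` for
#' Benjamini-Hochberg adjusted values in `p_adj`.
#'
#' @inheritParams correlate_feature
#' @param feature,cytokine Character vectors of column names.
#' @param p_adjust Method passed to [stats::p.adjust()]; default `"none"`.
#' @return A data frame with one row per feature x cytokine pair.
#' @export
correlate_features <- function(features, metadata, feature, cytokine,
                               log_cytokine = FALSE, p_adjust = "none") {
  grid <- expand.grid(feature = feature, cytokine = cytokine,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- correlate_feature(features, metadata, grid$feature[i],
                           grid$cytokine[i], log_cytokine = log_cytokine)
    data.frame(feature = r$feature, cytokine = r$cytokine, n = r$n, r = r$r,
               p = r$p, slope = r$slope, intercept = r$intercept,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Compare a glycan feature between two phenotype groups
#'
#' Two-sample Student's t test (pooled variance by default, Welch behind the
#' `welch` flag) of a glycan feature between the two levels of a phenotype
#' grouping — pregnancy status, delivery outcome or community state type.
#' Group means and sizes are always reported; the t statistic and two-sided
#' p value require both groups to have at least 2 samples and are `NA`
#' otherwise. Samples with missing group labels (`NA` or `"n/a"`) or missing
#' feature values are excluded.
#'
#' @inheritParams correlate_feature
#' @param grouping Metadata column holding the group labels.
#' @param ref Optional label to use as the first group (t is computed as
#'   first minus second); defaults to the first level in sorted order.
#' @param welch Use the Welch unequal-variance t test instead of the pooled
#'   (classical Student) test.
#' @return An object of class `glycan_group_test`: a list with `feature`,
#'   `grouping`, `levels`, `means`, `n`, `t`, `p`, `welch`.
#' @export
compare_groups <- function(features, metadata, feature, grouping,
                           ref = NULL, welch = FALSE) {
  d <- .merge_feature(features, metadata, feature, grouping)
  g <- as.character(d[[grouping]])
  keep <- !is.na(d[[feature]]) & !is.na(g) & !g %in% c("n/a", "NA", "")
  d <- d[keep, , drop = FALSE]
  g <- g[keep]
  lev <- sort(unique(g))
  if (!is.null(ref)) {
    if (!ref %in% lev)
      stop(sprintf("group \"%s\" is empty or absent for grouping \"%s\"",
                   ref, grouping), call. = FALSE)
    lev <- c(ref, setdiff(lev, ref))
  }
  if (length(lev) != 2L)
    stop(sprintf("grouping \"%s\" must yield exactly two non-empty groups (found: %s)",
                 grouping, paste(lev, collapse = ", ")), call. = FALSE)
  x <- d[[feature]][g == lev[1]]
  y <- d[[feature]][g == lev[2]]
  out <- list(feature = feature, grouping = grouping, levels = lev,
              means = stats::setNames(c(mean(x), mean(y)), lev),
              n = stats::setNames(c(length(x), length(y)), lev),
              t = NA_real_, p = NA_real_, welch = isTRUE(welch))
  if (length(x) >= 2L && length(y) >= 2L) {
    tt <- stats::t.test(x, y, var.equal = !isTRUE(welch),
                        alternative = "two.sided")
    out$t <- unname(tt$statistic)
    out$p <- tt$p.value
  }
  structure(out, class = "glycan_group_test")
}

#' @export
print.glycan_group_test <- function(x, ...) {
  cat(sprintf("%s t test: %s by %s\n",
              if (x$welch) "Welch" else "Student (pooled)",
              x$feature, x$grouping))
  for (i in 1:2)
    cat(sprintf("  %s: n = %d, mean = %.4g\n",
                x$levels[i], x$n[i], x$means[i]))
  if (is.na(x$t)) cat("  t, p undefined (a group has fewer than 2 samples)\n")
  else cat(sprintf("  t = %.4f, two-sided p = %.4g\n", x$t, x$p))
  invisible(x)
}
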