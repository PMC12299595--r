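#' Summarize an APTw map over ROIs for one subject
#'
#' Mean APTw over the valid voxels of each ROI, plus the left/right
#' average ("avg"): the mean of the two hippocampal ROI means, which is the
#' per-subject statistic the group comparison runs on. An ROI with no
#' valid voxels is recorded as missing with a warning rather than an error.
#'
#' @param map an [APTwMap-class].
#' @param masks named list of logical ROI masks (shapes matching the map).
#' @param subject_id,group subject metadata carried into the output.
#' @return data.frame with columns `subject_id`, `group`, `roi`,
#'   `mean_aptw_percent`, `n_valid_voxels`; one row per ROI plus one
#'   `"avg"` row when at least two ROIs have valid voxels.
#' @export
summarizeROI <- function(map, masks, subject_id = "subj", group = NA) {
  stopifnot(is(map, "APTwMap"), is.list(masks), length(masks) >= 1)
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    stopifnot(identical(dim(m), dim(map@aptw)))
    sel <- m & map@valid
    if (!any(sel)) {
      warning("ROI '", nm, "' has no valid voxels; recorded as missing")
      return(NULL)
    }
    data.frame(subject_id = subject_id, group = group, roi = nm,
               mean_aptw_percent = mean(map@aptw[sel]),
               n_valid_voxels = sum(sel))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out) >= 2) {
    out <- rbind(out, data.frame(
      subject_id = subject_id, group = group, roi = "avg",
      mean_aptw_percent = mean(out$mean_aptw_percent),
      n_valid_voxels = sum(out$n_valid_voxels)))
  }
  out
}

#' Group comparison of per-subject ROI summaries
#'
#' The statistical battery run on per-subject values: one-way ANOVA across
#' groups followed by Tukey HSD pairwise comparisons (studentized-range
#' adjusted), a Lilliefors-corrected Kolmogorov-Smirnov normality test per
#' group (the normal's mean/SD are estimated from the data, so the
#' Lilliefors correction applies), and within each group an independent
#' two-sample t-test of left vs right ROI means (pooled variance by
#' default). The comparison unit is the per-subject `"avg"` value; the
#' left/right ROIs enter only the laterality t-tests.
#'
#' @param summaries data.frame as returned by (rbound) [summarizeROI()]
#'   calls; needs >= 2 groups with >= 2 subjects each.
#' @param alpha significance threshold (default 0.05).
#' @param welch use Welch's t-test for the laterality comparison instead
#'   of the pooled-variance test.
#' @param left_roi,right_roi the ROI labels entering the laterality tests.
#' @return list of class `group_comparison`: `anova_F`, `anova_p`,
#'   `pairwise` (data.frame `group_a`, `group_b`, `diff`, `p_adj`,
#'   `significant`), `normality_p`, `lr_p`, `group_means`, `group_sd`,
#'   `alpha`, `n_per_group`.
#' @export
compareGroups <- function(summaries, alpha = 0.05, welch = FALSE,
                          left_roi = "left_hippocampus",
                          right_roi = "right_hippocampus") {
  stopifnot(is.data.frame(summaries))
  avg <- summaries[summaries$roi == "avg", ]
  if (!nrow(avg)) stop("summaries contain no 'avg' rows")
  avg$group <- factor(avg$group)
  if (nlevels(avg$group) < 2) stop("need at least 2 groups")
  ns <- table(avg$group)
  if (any(ns < 2)) {
    stop("every group needs >= 2 subjects; got: ",
         paste(sprintf("%s=%d", names(ns), ns), collapse = ", "))
  }
  fit <- stats::aov(mean_aptw_percent ~ group, data = avg)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairwise <- data.frame(group_a = pairs[, 2], group_b = pairs[, 1],
                         diff = tk[, "diff"], p_adj = tk[, "p adj"],
                         significant = tk[, "p adj"] < alpha,
                         row.names = NULL)

  normality_p <- vapply(levels(avg$group), function(g) {
    v <- avg$mean_aptw_percent[avg$group == g]
    if (length(v) < 5 || stats::sd(v) == 0) return(NA_real_)
    nortest::lillie.test(v)$p.value
  }, numeric(1))

  lr_p <- vapply(levels(avg$group), function(g) {
    l <- summaries$mean_aptw_percent[summaries$group == g &
                                       summaries$roi == left_roi]
    r <- summaries$mean_aptw_percent[summaries$group == g &
                                       summaries$roi == right_roi]
    if (length(l) < 2 || length(r) < 2) return(NA_real_)
    stats::t.test(l, r, var.equal = !welch)$p.value
  }, numeric(1))

  mu <- tapply(avg$mean_aptw_percent, avg$group, mean)
  sdv <- tapply(avg$mean_aptw_percent, avg$group, stats::sd)
  structure(list(
    anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
    pairwise = pairwise, normality_p = normality_p, lr_p = lr_p,
    group_means = mu, group_sd = sdv, alpha = alpha,
    n_per_group = as.vector(ns)), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.4g\n", x$anova_F, x$anova_p))
  cat("Group means (%):\n")
  print(round(x$group_means, 3))
  cat("Tukey HSD:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
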