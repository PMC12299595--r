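#' Process one subject's phantom through the imaging chain
#'
#' Convenience wrapper running b0 estimation, APTw mapping and ROI
#' summarization for a subject from [simulateCohort()] or a bare
#' `cest_phantom`. The processing mask defaults to the phantom's brain
#' mask; for large simulation experiments it can be restricted to the ROI
#' union, which leaves the ROI statistics unchanged while skipping voxels
#' no statistic reads.
#'
#' @param phantom a `cest_phantom` from [buildPhantom()].
#' @param config a `cest_config`.
#' @param mask processing mask; `"brain"` (default) or `"roi"`.
#' @param subject_id,group metadata for the summary rows.
#' @return list with `b0` ([B0Map-class]), `aptw` ([APTwMap-class]) and
#'   `summary` (data.frame from [summarizeROI()]).
#' @export
processSubject <- function(phantom, config = pipelineConfig(),
                           mask = c("brain", "roi"),
                           subject_id = "subj", group = NA) {
  stopifnot(inherits(phantom, "cest_phantom"))
  mask <- match.arg(mask)
  m <- if (mask == "brain") phantom$truth$brain_mask
       else Reduce(`|`, phantom$truth$roi_masks)
  b0 <- b0Map(phantom$wassr, m, config)
  ap <- aptwMap(phantom$aptw, b0, m, config)
  sm <- summarizeROI(ap, phantom$truth$roi_masks, subject_id, group)
  list(b0 = b0, aptw = ap, summary = sm)
}

# run one simulated cohort end to end and return the comparison
.runCohortComparison <- function(group_specs, n_per_group, seed, config,
                                 between_subject_sd, mask = "roi") {
  subjects <- simulateCohort(group_specs, n_per_group, seed,
                             between_subject_sd = between_subject_sd)
  summaries <- do.call(rbind, lapply(subjects, function(s) {
    processSubject(s$phantom, config, mask = mask,
                   subject_id = s$subject_id, group = s$group)$summary
  }))
  compareGroups(summaries, alpha = config$alpha)
}

#' Rejection-rate experiment over simulated cohorts
#'
#' Repeats the full simulate -> B0 -> APTw -> summarize -> compare chain
#' and tabulates how often the ANOVA and each Tukey pairwise comparison
#' reject at the configured alpha. With identical group specifications
#' this measures the pipeline's type-I error; with separated amide
#' settings it measures power.
#'
#' @param group_specs named list of [phantomSpec()]s.
#' @param n_per_group subjects per group per replicate.
#' @param replicates number of simulated cohorts.
#' @param seed master seed; replicate seeds derive from it.
#' @param config a `cest_config` (supplies alpha and the processing
#'   parameters; `between_subject_sd` is taken from it too).
#' @param mask processing mask passed to [processSubject()]; default
#'   `"roi"` restricts computation to the voxels the statistics read.
#' @return list of class `power_result`: `anova_p` (vector, one per
#'   replicate), `pairwise_p` (replicates x pairs matrix),
#'   `anova_rejection_rate`, `pairwise_rejection_rates`, `alpha`,
#'   `replicates`.
#' @export
powerExperiment <- function(group_specs, n_per_group = 7, replicates = 200,
                            seed = 1L, config = pipelineConfig(),
                            mask = "roi") {
  stopifnot(replicates >= 1)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  anova_p <- numeric(replicates)
  pairwise_p <- NULL
  for (r in seq_len(replicates)) {
    cmp <- .runCohortComparison(group_specs, n_per_group, rep_seeds[r],
                                config, config$between_subject_sd, mask)
    anova_p[r] <- cmp$anova_p
    if (is.null(pairwise_p)) {
      pairwise_p <- matrix(NA_real_, replicates, nrow(cmp$pairwise),
                           dimnames = list(NULL,
                             paste(cmp$pairwise$group_a,
                                   cmp$pairwise$group_b, sep = ":")))
    }
    pairwise_p[r, ] <- cmp$pairwise$p_adj
  }
  structure(list(
    anova_p = anova_p, pairwise_p = pairwise_p,
    anova_rejection_rate = mean(anova_p < config$alpha),
    pairwise_rejection_rates = colMeans(pairwise_p < config$alpha),
    alpha = config$alpha, replicates = replicates), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("%d replicates, alpha = %g\n", x$replicates, x$alpha))
  cat(sprintf("ANOVA rejection rate: %.3f\n", x$anova_rejection_rate))
  cat("Tukey pairwise rejection rates:\n")
  print(round(x$pairwise_rejection_rates, 3))
  invisible(x)
}
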