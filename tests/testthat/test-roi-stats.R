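mkMap <- function(values, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(values), ncol(values))
  vals <- values; vals[!valid] <- NA_real_
  new("APTwMap", aptw = vals, valid = valid)
}

mkMasks <- function(nr = 6, nc = 6) {
  l <- matrix(FALSE, nr, nc); l[2:3, 2:3] <- TRUE
  r <- matrix(FALSE, nr, nc); r[4:5, 4:5] <- TRUE
  list(left_hippocampus = l, right_hippocampus = r)
}

test_that("ROI summaries: means, masking contract, left/right average", {
  masks <- mkMasks()
  s <- summarizeROI(mkMap(matrix(-1.5, 6, 6)), masks, "s1", "CTRL")
  expect_equal(s$mean_aptw_percent[s$roi != "avg"], c(-1.5, -1.5))
  expect_equal(s$mean_aptw_percent[s$roi == "avg"], -1.5)

  # half the left ROI invalid: mean over the valid half only
  vals <- matrix(0, 6, 6); vals[2, 2:3] <- -2; vals[3, 2:3] <- -4
  valid <- matrix(TRUE, 6, 6); valid[3, 2:3] <- FALSE
  s2 <- summarizeROI(mkMap(vals, valid), masks, "s2", "CTRL")
  expect_equal(s2$mean_aptw_percent[s2$roi == "left_hippocampus"], -2)
  expect_equal(s2$n_valid_voxels[s2$roi == "left_hippocampus"], 2)

  # avg is the mean of the two ROI means
  vals3 <- matrix(0, 6, 6); vals3[masks$left_hippocampus] <- -2
  vals3[masks$right_hippocampus] <- -1.8
  s3 <- summarizeROI(mkMap(vals3), masks, "s3", "CTRL")
  expect_equal(s3$mean_aptw_percent[s3$roi == "avg"], -1.9)

  # an all-invalid ROI is recorded as missing with a warning
  valid4 <- matrix(TRUE, 6, 6); valid4[masks$left_hippocampus] <- FALSE
  expect_warning(s4 <- summarizeROI(mkMap(vals3, valid4), masks, "s4", "C"),
                 "no valid voxels")
  expect_false("left_hippocampus" %in% s4$roi)
})

fakeSummaries <- function(groups, lr_jitter = 0) {
  # groups: named list of per-subject avg values; left/right built as
  # avg -/+ lr_jitter
  do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(seq_along(groups[[g]]), function(i) {
      v <- groups[[g]][i]
      data.frame(subject_id = sprintf("%s%d", g, i), group = g,
                 roi = c("left_hippocampus", "right_hippocampus", "avg"),
                 mean_aptw_percent = c(v - lr_jitter, v + lr_jitter, v),
                 n_valid_voxels = 10L)
    }))
  }))
}

test_that("identical groups give F ~ 0, p ~ 1", {
  cmp <- compareGroups(fakeSummaries(list(a = c(1, 2, 3), b = c(1, 2, 3))))
  expect_equal(cmp$anova_F, 0, tolerance = 1e-12)
  expect_equal(cmp$anova_p, 1, tolerance = 1e-12)
})

test_that("ANOVA and Tukey match hand-computed closed forms", {
  set.seed(10)
  g <- list(a = c(0.01, -0.02, 0.005, 0.002),
            b = c(1.01, 0.99, 1.02, 0.98),
            c = c(0.52, 0.48, 0.50, 0.51))
  cmp <- compareGroups(fakeSummaries(g))

  # between/within sums of squares, written out
  all_v <- unlist(g); k <- 3; n <- 4; N <- 12
  gm <- mean(all_v)
  ss_between <- n * sum((vapply(g, mean, 0) - gm)^2)
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  F_hand <- (ss_between / (k - 1)) / (ss_within / (N - k))
  expect_equal(cmp$anova_F, F_hand, tolerance = 1e-6)
  expect_equal(cmp$anova_p, stats::pf(F_hand, k - 1, N - k, lower.tail = FALSE),
               tolerance = 1e-6)

  # Tukey adjusted p from the studentized range distribution
  s_pooled <- sqrt(ss_within / (N - k))
  for (r in seq_len(nrow(cmp$pairwise))) {
    d <- abs(mean(g[[cmp$pairwise$group_a[r]]]) -
               mean(g[[cmp$pairwise$group_b[r]]]))
    q <- d / (s_pooled / sqrt(n))
    p_hand <- stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
    expect_equal(cmp$pairwise$p_adj[r], p_hand, tolerance = 1e-6)
  }
})

test_that("laterality t-test matches the pooled-variance closed form", {
  g <- list(a = c(-1.9, -2.1, -1.8, -2.0, -2.2), b = c(-0.5, -0.4, -0.6, -0.5, -0.3))
  sm <- fakeSummaries(g, lr_jitter = 0.1)
  # perturb one side so the test is non-degenerate
  set.seed(3)
  il <- sm$roi == "left_hippocampus"
  sm$mean_aptw_percent[il] <- sm$mean_aptw_percent[il] + rnorm(sum(il), 0, 0.1)
  cmp <- compareGroups(sm)
  for (gn in names(g)) {
    l <- sm$mean_aptw_percent[sm$group == gn & sm$roi == "left_hippocampus"]
    r <- sm$mean_aptw_percent[sm$group == gn & sm$roi == "right_hippocampus"]
    n1 <- length(l); n2 <- length(r)
    sp2 <- ((n1 - 1) * var(l) + (n2 - 1) * var(r)) / (n1 + n2 - 2)
    t_hand <- (mean(l) - mean(r)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p_hand <- 2 * stats::pt(-abs(t_hand), n1 + n2 - 2)
    expect_equal(unname(cmp$lr_p[gn]), p_hand, tolerance = 1e-9)
  }
})

test_that("normality p-values are reported per group and lie in [0, 1]", {
  set.seed(8)
  g <- list(a = rnorm(7, -1.9, 0.2), b = rnorm(7, -0.5, 0.3),
            c = rnorm(7, -0.5, 0.3))
  cmp <- compareGroups(fakeSummaries(g))
  expect_named(cmp$normality_p, c("a", "b", "c"))
  expect_true(all(cmp$normality_p >= 0 & cmp$normality_p <= 1))
})

test_that("group size guards", {
  expect_error(compareGroups(fakeSummaries(list(a = c(1, 2)))), "2 groups")
  expect_error(compareGroups(fakeSummaries(list(a = c(1, 2), b = 3))),
               ">= 2 subjects")
})

test_that("group mean difference is recovered within sampling error", {
  # two-group cohort with a known true APTw separation; the estimated
  # difference must land within 3 standard errors of it
  cfg <- pipelineConfig()
  specs <- list(CTRL = quickSpec(b0_amplitude_ppm = 0.15, noise_sd = 0.005),
                LPS05 = quickSpec(group = "LPS05", b0_amplitude_ppm = 0.15,
                                  noise_sd = 0.005))
  delta_true <-
    trueMtrAsym(specs$LPS05$tissues$hippocampus$pools) -
    trueMtrAsym(specs$CTRL$tissues$hippocampus$pools)
  subj <- simulateCohort(specs, n_per_group = 7, base_seed = 17,
                         between_subject_sd = cfg$between_subject_sd)
  sm <- do.call(rbind, lapply(subj, function(s)
    processSubject(s$phantom, cfg, mask = "roi", s$subject_id, s$group)$summary))
  cmp <- compareGroups(sm)
  est <- unname(cmp$group_means["LPS05"] - cmp$group_means["CTRL"])
  se <- sqrt(sum(cmp$group_sd^2 / 7))
  expect_lt(abs(est - delta_true), 3 * se)
})
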