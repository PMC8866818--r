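test_that("volume normalization is the exact ICV quotient with guards", {
  expect_equal(normalize_volume(3700, 1480000), 0.0025)
  expect_warning(r <- normalize_volume(5, 5), "plausibility")
  expect_equal(r, 1.0)
  expect_error(normalize_volume(3700, 0), "domain error")
  expect_error(normalize_volume(-1, 100), "domain error")
})

test_that("stratification partitions PD by threshold and never splits HC", {
  s <- stratify_by_threshold(c("PD", "PD", "HC"), c(24, 27, 28))
  expect_equal(as.character(s), c("PD_below", "PD_at_or_above", "HC"))
  s2 <- stratify_by_threshold(c("PD", "PD"), c(27, 30))
  expect_equal(sum(s2 == "PD_below"), 0L)
  # HC below threshold stays HC
  s3 <- stratify_by_threshold(c("HC", "HC"), c(20, 29))
  expect_true(all(s3 == "HC"))
  # partition law on a generated cohort
  coh <- generate_cohorts(small_config(seed = 31))
  tr <- coh$truth
  st <- stratify_by_threshold(tr$group, tr$moca_total)
  pd <- tr$group == "PD"
  expect_equal(sum(st[pd] == "PD_below") + sum(st[pd] == "PD_at_or_above"),
               sum(pd))
  # missing scores are excluded and reported
  expect_message(s4 <- stratify_by_threshold(c("PD", "HC"), c(NA, 28)),
                 "excluded")
  expect_true(is.na(s4[[1]]))
  expect_equal(attr(s4, "excluded"), 1L)
})

test_that("ANOVA matches closed-form cases and an independent lm/anova oracle", {
  # identical group means -> F = 0, p = 1
  fit0 <- one_way_anova(list(a = c(1, 2, 3), b = c(0, 2, 4)))
  expect_equal(fit0$F, 0)
  expect_equal(fit0$p, 1)
  # fixed 3 groups x 5 values vs independent oracle
  groups <- list(g1 = c(4.1, 5.2, 3.9, 4.8, 5.0),
                 g2 = c(5.6, 6.1, 5.9, 6.4, 5.2),
                 g3 = c(4.9, 5.1, 5.3, 4.7, 5.5))
  fit <- one_way_anova(groups)
  df <- data.frame(y = unlist(groups),
                   g = rep(names(groups), times = lengths(groups)))
  oracle <- anova(lm(y ~ g, data = df))
  expect_equal(fit$F, oracle[1, "F value"], tolerance = 1e-10)
  expect_equal(fit$p, oracle[1, "Pr(>F)"], tolerance = 1e-10)
  expect_equal(fit$df_between, oracle[1, "Df"])
  expect_equal(fit$df_within, oracle[2, "Df"])
  expect_equal(fit$ms_within, oracle[2, "Mean Sq"], tolerance = 1e-12)
  # error contracts
  expect_error(one_way_anova(list(c(1, 2))), "at least 2 groups")
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least 2 observations")
  expect_error(one_way_anova(list(a = c(1, NA), b = c(1, 2))), "finite")
  # degenerate: zero within-group variance, unequal means
  dg <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_true(dg$degenerate)
  expect_equal(dg$F, Inf)
  expect_equal(dg$p, 0)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::local_seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1), mean = 0, sd = runif(1, 0.5, 2))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1), sd = sd(x))
    fit <- one_way_anova(list(x = x, y = y))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(fit$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("ANOVA F is invariant under location shifts and positive scaling", {
  withr::local_seed(8)
  groups <- lapply(1:3, function(i) rnorm(8, mean = i))
  f0 <- one_way_anova(groups)$F
  expect_equal(one_way_anova(lapply(groups, function(x) x + 100))$F, f0,
               tolerance = 1e-9)
  expect_equal(one_way_anova(lapply(groups, function(x) x * 3.7))$F, f0,
               tolerance = 1e-9)
})

test_that("Fisher's LSD matches pooled pairwise t tests without adjustment", {
  groups <- list(g1 = c(4.1, 5.2, 3.9, 4.8, 5.0),
                 g2 = c(5.6, 6.1, 5.9, 6.4, 5.2),
                 g3 = c(4.9, 5.1, 5.3, 4.7, 5.5))
  fit <- one_way_anova(groups)
  lsd <- fisher_lsd(groups, fit)
  # independent oracle: pairwise t from pooled MSW of the lm fit
  df <- data.frame(y = unlist(groups),
                   g = rep(names(groups), times = lengths(groups)))
  msw <- anova(lm(y ~ g, data = df))[2, "Mean Sq"]
  dfw <- anova(lm(y ~ g, data = df))[2, "Df"]
  for (i in seq_len(nrow(lsd$pairs))) {
    gi <- groups[[lsd$pairs$group_i[[i]]]]
    gj <- groups[[lsd$pairs$group_j[[i]]]]
    t_oracle <- (mean(gi) - mean(gj)) /
      sqrt(msw * (1 / length(gi) + 1 / length(gj)))
    expect_equal(lsd$pairs$t[[i]], t_oracle, tolerance = 1e-10)
    expect_equal(lsd$pairs$p[[i]], 2 * pt(-abs(t_oracle), dfw),
                 tolerance = 1e-12)
  }
  # symmetry: swapping the pair flips t and preserves p
  rev_groups <- rev(groups)
  lsd_rev <- fisher_lsd(rev_groups, one_way_anova(rev_groups))
  key <- function(x) paste(pmin(x$group_i, x$group_j), pmax(x$group_i, x$group_j))
  m <- match(key(lsd$pairs), key(lsd_rev$pairs))
  expect_equal(lsd$pairs$p, lsd_rev$pairs$p[m], tolerance = 1e-12)
  # identical pair means -> t = 0, p = 1
  eq <- list(a = c(1, 2, 3), b = c(0, 2, 4), c = c(5, 6, 7))
  lsd_eq <- fisher_lsd(eq, one_way_anova(eq))
  ab <- lsd_eq$pairs[lsd_eq$pairs$group_i == "a" & lsd_eq$pairs$group_j == "b", ]
  expect_equal(ab$t, 0)
  expect_equal(ab$p, 1)
  expect_error(fisher_lsd(groups, one_way_anova(eq)), "do not match")
})

test_that("volume_group_analysis runs the two endpoints on a harmonized cohort", {
  fix <- make_cohort(small_config(seed = 33, n = c(20, 15, 25, 15)), graph = FALSE)
  va <- suppressMessages(volume_group_analysis(fix$harmonized$data))
  expect_s3_class(va, "volume_comparison")
  expect_equal(va$two_group$df_between, 1L)
  expect_equal(va$three_group$df_between, 2L)
  expect_equal(nrow(va$lsd$pairs), 3L)
  expect_setequal(names(va$three_group$group_ns),
                  c("PD_below", "PD_at_or_above", "HC"))
  # report writers
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".txt")
  write_stats_report(va, jp, tp)
  rep <- jsonlite::read_json(jp)
  expect_equal(rep$anova_three_group$F, va$three_group$F, tolerance = 1e-12)
  expect_length(rep$strata, 3L)
  expect_true(any(grepl("Fisher", readLines(tp))))
  # bilateral sum is what is analyzed by default
  d <- fix$harmonized$data
  manual <- normalize_volume(d$volume_left_hippocampus + d$volume_right_hippocampus,
                             d$icv)
  expect_equal(va$normalized, manual)
})
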