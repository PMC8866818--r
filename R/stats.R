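# Volumetric group comparison: ICV normalization, MoCA-threshold
# stratification, one-way ANOVA, and Fisher's LSD post-hoc tests.

#' Normalize a regional volume by intracranial volume
#'
#' @param volume_mm3 Regional volume in cubic millimetres (> 0).
#' @param icv_mm3 Total intracranial volume in cubic millimetres (> 0).
#' @return The dimensionless ratio `volume_mm3 / icv_mm3`. Values where the
#'   volume reaches or exceeds the ICV trigger a plausibility warning.
#' @export
normalize_volume <- function(volume_mm3, icv_mm3) {
  ok <- !is.na(volume_mm3) & !is.na(icv_mm3)
  if (any(ok & (volume_mm3 <= 0 | icv_mm3 <= 0)))
    stop("domain error: volume_mm3 and icv_mm3 must be positive", call. = FALSE)
  if (any(ok & volume_mm3 >= icv_mm3))
    warning("plausibility warning: regional volume >= intracranial volume",
            call. = FALSE)
  volume_mm3 / icv_mm3
}

#' Stratify subjects by cognitive-impairment threshold
#'
#' Partitions subjects into three strata: PD subjects scoring below the
#' threshold (`PD_below`), PD subjects at or above it (`PD_at_or_above`),
#' and all healthy controls (`HC`, never split by score). Subjects with a
#' missing score are excluded and reported.
#'
#' @param group Character vector of `"PD"`/`"HC"` labels.
#' @param moca_total Numeric scores (0-30).
#' @param threshold Impairment threshold; scores strictly below it count as
#'   impaired (default 26).
#' @return Factor with levels `PD_below`, `PD_at_or_above`, `HC` and `NA`
#'   for excluded subjects; attribute `excluded` holds the indices of
#'   subjects dropped for missing scores (a message reports how many).
#' @export
stratify_by_threshold <- function(group, moca_total, threshold = 26) {
  stopifnot(length(group) == length(moca_total))
  if (!all(group %in% c("PD", "HC")))
    stop("stratification error: group labels must be 'PD' or 'HC'", call. = FALSE)
  excluded <- which(is.na(moca_total))
  stratum <- ifelse(group == "HC", "HC",
                    ifelse(moca_total < threshold, "PD_below", "PD_at_or_above"))
  stratum[excluded] <- NA
  if (length(excluded) > 0)
    message(sprintf("stratify_by_threshold: %d subject(s) excluded for missing scores",
                    length(excluded)))
  structure(factor(stratum, levels = c("PD_below", "PD_at_or_above", "HC")),
            excluded = excluded)
}

#' One-way analysis of variance
#'
#' Fixed-effects one-way ANOVA computed from sums of squares:
#' `F = [sum n_i (m_i - m)^2 / (k - 1)] / [sum (x_ij - m_i)^2 / (N - k)]`,
#' with the p-value from the F distribution on `(k - 1, N - k)` degrees of
#' freedom.
#'
#' @param groups Named list of numeric vectors, one per group (k >= 2,
#'   each with n >= 2 finite values).
#' @return Object of class `oneway_anova` with fields `F`, `df_between`,
#'   `df_within`, `p`, `group_means`, `group_ns`, `ms_between`, `ms_within`,
#'   `grand_mean`, and `degenerate` (`TRUE` when the within-group variance is
#'   zero with unequal means, reported as `F = Inf`, `p = 0`).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("input error: need at least 2 groups", call. = FALSE)
  groups <- lapply(groups, function(x) as.numeric(x))
  if (any(vapply(groups, function(x) any(!is.finite(x)), logical(1))))
    stop("input error: all values must be finite (drop missing values first)",
         call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L))
    stop("input error: every group needs at least 2 observations", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  degenerate <- msw == 0 && ssb > 0
  Fv <- if (degenerate) Inf else if (ssb == 0) 0 else msb / msw
  p <- if (degenerate) 0 else if (Fv == 0) 1
       else stats::pf(Fv, df1, df2, lower.tail = FALSE)
  structure(list(F = Fv, df_between = df1, df_within = df2, p = p,
                 group_means = means, group_ns = ns,
                 ms_between = msb, ms_within = msw, grand_mean = grand,
                 ss_between = ssb, ss_within = ssw,
                 degenerate = degenerate),
            class = "oneway_anova")
}

#' @export
print.oneway_anova <- function(x, digits = 4, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %s, p = %s%s\n",
              x$df_between, x$df_within,
              format(x$F, digits = digits), format(x$p, digits = digits),
              if (x$degenerate) "  [degenerate: zero within-group variance]" else ""))
  m <- data.frame(n = x$group_ns, mean = signif(x$group_means, digits))
  print(m)
  invisible(x)
}

#' Fisher's LSD post-hoc comparisons
#'
#' Unadjusted pairwise comparisons using the ANOVA's pooled within-group
#' mean square: `t = (m_i - m_j) / sqrt(MSW (1/n_i + 1/n_j))`, two-sided
#' p-values on the ANOVA's within-group degrees of freedom. No multiplicity
#' adjustment is applied (that is the definition of the LSD procedure).
#'
#' @param groups The same named list of numeric vectors passed to
#'   [one_way_anova()].
#' @param anova The corresponding `oneway_anova` fit.
#' @return Object of class `lsd_result`: data.frame `pairs` with columns
#'   `group_i`, `group_j`, `mean_diff`, `t`, `p`, plus attribute
#'   `degenerate` when `ms_within` is zero.
#' @export
fisher_lsd <- function(groups, anova) {
  stopifnot(inherits(anova, "oneway_anova"))
  ns <- vapply(groups, length, integer(1))
  means <- vapply(groups, function(x) mean(as.numeric(x)), numeric(1))
  if (!isTRUE(all.equal(unname(means), unname(anova$group_means))) ||
      !identical(unname(ns), unname(anova$group_ns)))
    stop("input error: groups do not match the fitted ANOVA", call. = FALSE)
  degenerate <- anova$ms_within == 0
  if (degenerate)
    warning("fisher_lsd: zero pooled within-group variance; t undefined",
            call. = FALSE)
  nm <- names(groups)
  combs <- utils::combn(seq_along(groups), 2L)
  pairs <- data.frame(
    group_i = nm[combs[1, ]], group_j = nm[combs[2, ]],
    mean_diff = means[combs[1, ]] - means[combs[2, ]],
    stringsAsFactors = FALSE)
  se <- sqrt(anova$ms_within * (1 / ns[combs[1, ]] + 1 / ns[combs[2, ]]))
  pairs$t <- ifelse(se == 0, ifelse(pairs$mean_diff == 0, 0, Inf * sign(pairs$mean_diff)),
                    pairs$mean_diff / se)
  pairs$p <- ifelse(pairs$t == 0, 1,
                    2 * stats::pt(-abs(pairs$t), df = anova$df_within))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, df = anova$df_within,
                 ms_within = anova$ms_within, degenerate = degenerate),
            class = "lsd_result")
}

#' @export
print.lsd_result <- function(x, digits = 4, ...) {
  cat(sprintf("Fisher's LSD (pooled MSW, df = %d)%s\n", x$df,
              if (x$degenerate) "  [degenerate]" else ""))
  out <- x$pairs
  out$mean_diff <- signif(out$mean_diff, digits)
  out$t <- signif(out$t, digits)
  out$p <- signif(out$p, digits)
  print(out)
  invisible(x)
}

#' Volumetric group comparison for a harmonized cohort
#'
#' The end-point analysis: ICV-normalized hippocampal volumes are compared
#' (i) between PD and HC and (ii) across three strata after splitting the PD
#' group at the MoCA impairment threshold, by one-way ANOVA with Fisher's
#' LSD post-hoc comparisons (run regardless of omnibus significance and
#' reported alongside the omnibus p).
#'
#' @param cohort Data frame with columns `group_label`, `moca_total`,
#'   `volume_left_hippocampus`, `volume_right_hippocampus`, `icv` (e.g. the
#'   `$data` of a `harmonized_cohort`).
#' @param volume Which volume enters the analysis: the bilateral sum
#'   (default), or a single side.
#' @param threshold MoCA impairment threshold (default 26; strictly-below
#'   counts as impaired).
#' @return Object of class `volume_comparison` with fields `two_group`
#'   (PD vs HC `oneway_anova`), `three_group` (`oneway_anova` across
#'   strata), `lsd` (`lsd_result` for the strata), `strata` (the stratum
#'   factor), `normalized` (the analyzed ratios), `excluded` (row indices
#'   dropped for missing values).
#' @export
volume_group_analysis <- function(cohort,
                                  volume = c("bilateral", "left", "right"),
                                  threshold = 26) {
  volume <- match.arg(volume)
  vol <- switch(volume,
                bilateral = cohort$volume_left_hippocampus +
                  cohort$volume_right_hippocampus,
                left = cohort$volume_left_hippocampus,
                right = cohort$volume_right_hippocampus)
  normalized <- normalize_volume(vol, cohort$icv)
  strata <- suppressMessages(
    stratify_by_threshold(cohort$group_label, cohort$moca_total, threshold))
  usable <- !is.na(normalized) & !is.na(strata)
  excluded <- which(!usable)
  if (length(excluded) > 0)
    message(sprintf("volume_group_analysis: %d subject(s) excluded for missing scores or volumes",
                    length(excluded)))
  two_groups <- split(normalized[usable], cohort$group_label[usable])[c("PD", "HC")]
  three_groups <- split(normalized[usable], strata[usable])
  two <- one_way_anova(two_groups)
  three <- one_way_anova(three_groups)
  lsd <- fisher_lsd(three_groups, three)
  structure(list(two_group = two, three_group = three, lsd = lsd,
                 strata = strata, normalized = normalized,
                 volume = volume, threshold = threshold, excluded = excluded),
            class = "volume_comparison")
}

#' @export
print.volume_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("ICV-normalized hippocampal volume (%s), MoCA threshold < %s\n",
              x$volume, format(x$threshold)))
  cat("\nPD vs HC:\n  ")
  print(x$two_group, digits = digits)
  cat("\nPD_below vs PD_at_or_above vs HC:\n  ")
  print(x$three_group, digits = digits)
  cat("\n")
  print(x$lsd, digits = digits)
  invisible(x)
}

#' @export
summary.volume_comparison <- function(object, ...) {
  keep <- setdiff(seq_along(object$strata), object$excluded)
  structure(list(comparison = object,
                 strata_n = table(object$strata[keep]),
                 strata_means = tapply(object$normalized[keep],
                                       object$strata[keep], mean)),
            class = "summary.volume_comparison")
}

#' @export
print.summary.volume_comparison <- function(x, ...) {
  print(x$comparison)
  cat("\nStratum sizes:\n")
  print(x$strata_n)
  invisible(x)
}

#' Write the statistics report
#'
#' @param x A `volume_comparison`.
#' @param json_path,text_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the report list written as JSON.
#' @export
write_stats_report <- function(x, json_path = NULL, text_path = NULL) {
  stopifnot(inherits(x, "volume_comparison"))
  rep <- list(
    volume = x$volume,
    threshold = x$threshold,
    strata = lapply(seq_along(x$three_group$group_ns), function(i) list(
      stratum = names(x$three_group$group_ns)[[i]],
      n = unname(x$three_group$group_ns[[i]]),
      mean_normalized_volume = unname(x$three_group$group_means[[i]]))),
    anova_two_group = list(F = x$two_group$F, df = c(x$two_group$df_between,
                                                     x$two_group$df_within),
                           p = x$two_group$p),
    anova_three_group = list(F = x$three_group$F,
                             df = c(x$three_group$df_between,
                                    x$three_group$df_within),
                             p = x$three_group$p),
    fisher_lsd = lapply(seq_len(nrow(x$lsd$pairs)), function(i)
      as.list(x$lsd$pairs[i, ])),
    excluded_subjects = length(x$excluded))
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    sink(con); on.exit({ sink(); close(con) })
    print(x)
  }
  invisible(rep)
}
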