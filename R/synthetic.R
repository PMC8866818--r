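# Deterministic two-source synthetic cohort generator.
#
# Emulates two study sources with different CSV header dialects, PD/HC group
# structure, MoCA totals straddling the impairment threshold, and a
# plantable hippocampal-volume deficit in cognitively impaired PD subjects.
# MoCA scores are generated as an exact mixture decomposition: the
# sub-threshold count per group is fixed first (plantable), then scores are
# drawn from the matching truncated normal on each side of the threshold, so
# sub-threshold counts are exact by construction while sample means stay
# calibrated to the configured group means.

group_defaults <- function(n, moca_mean, female_fraction, age_mean, hy_mean,
                           education_mean, n_below = NULL) {
  list(n = n, moca_mean = moca_mean, moca_sd = 3,
       fluency_mean = if (hy_mean > 0) 16 else 20, fluency_sd = 4,
       female_fraction = female_fraction,
       age_mean = age_mean, age_sd = 8,
       education_mean = education_mean, education_sd = 2.5,
       hy_mean = hy_mean, hy_sd = if (hy_mean > 0) 0.5 else 0,
       volume_mean = 3700, volume_sd = 400,
       icv_mean = 1450000, icv_sd = 130000,
       n_below = n_below)
}

#' Synthetic cohort configuration
#'
#' Per-source, per-group generator parameters. The defaults are calibrated
#' to the demographic margins of the two study sources the pipeline is
#' modeled on: source 1 with 29 PD / 21 HC and source 2 with 69 PD / 31 HC,
#' group mean MoCA totals 25 / 26.6 / 26.9 / 28.1, the corresponding female
#' fractions, ages, education and Hoehn-Yahr means. Volume priors (not
#' reported per group in the source material) default to plausible values:
#' hippocampus ~ N(3700, 400) mm^3 per side, ICV ~ N(1.45e6, 1.3e5) mm^3.
#'
#' @param sources Named list of two sources, each a named list with `pd` and
#'   `hc` group parameter lists (see [cohort_config()] defaults for fields).
#'   Group lists may override any of: `n`, `moca_mean`, `moca_sd`,
#'   `fluency_mean`, `fluency_sd`, `female_fraction`, `age_mean`, `age_sd`,
#'   `education_mean`, `education_sd`, `hy_mean`, `hy_sd`, `volume_mean`,
#'   `volume_sd`, `icv_mean`, `icv_sd`, `n_below` (planted count of
#'   sub-threshold subjects; default `round(n * P(score < threshold))`).
#' @param planted_effect_delta Standardized volume deficit applied to
#'   sub-threshold PD subjects (default 0.8 SD per side).
#' @param threshold MoCA impairment threshold (default 26).
#' @param seed Integer RNG seed; the generator is fully reproducible.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(sources = NULL, planted_effect_delta = 0.8,
                          threshold = 26, seed = 1L) {
  if (is.null(sources)) {
    sources <- list(
      dataset1 = list(
        pd = group_defaults(29, 25.0, 0.28, 67.1, 2.29, 17.9),
        hc = group_defaults(21, 26.6, 0.62, 69.7, 0, 17.1)),
      dataset2 = list(
        pd = group_defaults(69, 26.9, 0.34, 61.8, 1.65, 16.4),
        hc = group_defaults(31, 28.1, 0.39, 58.7, 0, 17.2)))
  }
  cfg <- structure(list(sources = sources,
                        planted_effect_delta = planted_effect_delta,
                        threshold = threshold, seed = as.integer(seed)),
                   class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))
  if (length(cfg$sources) != 2L || is.null(names(cfg$sources)) ||
      anyDuplicated(names(cfg$sources)))
    note("sources: exactly two uniquely named sources required")
  for (sn in names(cfg$sources)) for (gn in c("pd", "hc")) {
    g <- cfg$sources[[sn]][[gn]]
    if (is.null(g)) { note("%s/%s: missing group", sn, gn); next }
    if (is.null(g$n) || g$n <= 0) note("%s/%s: n must be > 0", sn, gn)
    for (f in grep("_sd$", names(g), value = TRUE))
      if (!is.null(g[[f]]) && g[[f]] < 0) note("%s/%s: %s must be >= 0", sn, gn, f)
    if (!is.null(g$moca_mean) && (g$moca_mean < 0 || g$moca_mean > 30))
      note("%s/%s: moca_mean outside [0, 30]", sn, gn)
    if (!is.null(g$n_below) && !is.null(g$n) &&
        (g$n_below < 0 || g$n_below > g$n))
      note("%s/%s: n_below outside [0, n]", sn, gn)
    if (!is.null(g$female_fraction) &&
        (g$female_fraction < 0 || g$female_fraction > 1))
      note("%s/%s: female_fraction outside [0, 1]", sn, gn)
    if (!is.null(g$volume_mean) && !is.null(g$icv_mean) &&
        g$volume_mean * 2 >= g$icv_mean)
      note("%s/%s: icv_mean must exceed the bilateral volume mean", sn, gn)
  }
  if (cfg$planted_effect_delta < 0) note("planted_effect_delta must be >= 0")
  if (length(problems) > 0)
    stop("validation error in cohort config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(cfg)
}

#' Table-style default configuration
#'
#' The default study-condition preset (see [cohort_config()]).
#'
#' @param seed Integer seed.
#' @param planted_effect_delta Standardized sub-threshold PD volume deficit.
#' @return A `cohort_config`.
#' @export
table1_config <- function(seed = 1L, planted_effect_delta = 0.8) {
  cohort_config(seed = seed, planted_effect_delta = planted_effect_delta)
}

#' Conservation-check configuration
#'
#' Preset that plants per-source sub-threshold counts of 78 and 32 (110
#' total), so the end-to-end cohort query count is fixed by construction.
#' Group sizes are enlarged so each source can hold its planted count.
#'
#' @param seed Integer seed.
#' @return A `cohort_config`.
#' @export
conservation_config <- function(seed = 1L) {
  cfg <- cohort_config(seed = seed)
  s <- cfg$sources
  s$dataset1$pd$n <- 110; s$dataset1$pd$n_below <- 70
  s$dataset1$hc$n <- 40;  s$dataset1$hc$n_below <- 8
  s$dataset2$pd$n <- 69;  s$dataset2$pd$n_below <- 28
  s$dataset2$hc$n <- 31;  s$dataset2$hc$n_below <- 4
  cohort_config(sources = s, planted_effect_delta = cfg$planted_effect_delta,
                threshold = cfg$threshold, seed = seed)
}

# truncated normal draws via inverse CDF, below/above a cutpoint
rtrunc_norm <- function(n, mean, sd, cut, side) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  pc <- stats::pnorm(cut, mean, sd)
  u <- stats::runif(n)
  q <- if (side == "below") u * pc else pc + u * (1 - pc)
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  stats::qnorm(q, mean, sd)
}

generate_group <- function(source_name, group, g, id_offset, threshold, delta) {
  n <- g$n
  cut <- threshold - 0.5  # scores are rounded; x < 25.5 rounds below 26
  p_below <- if (g$moca_sd == 0) NA else stats::pnorm(cut, g$moca_mean, g$moca_sd)
  n_below <- g$n_below
  if (is.null(n_below))
    n_below <- if (g$moca_sd == 0) sum(rep(round(g$moca_mean), n) < threshold)
               else round(n * p_below)
  if (g$moca_sd == 0) {
    moca <- rep(min(30L, max(0L, round(g$moca_mean))), n)
    below <- moca < threshold
  } else {
    below <- rep(FALSE, n)
    below[sample.int(n, n_below)] <- TRUE
    moca <- numeric(n)
    moca[below] <- rtrunc_norm(sum(below), g$moca_mean, g$moca_sd, cut, "below")
    moca[!below] <- rtrunc_norm(sum(!below), g$moca_mean, g$moca_sd, cut, "above")
    moca <- pmin(30L, pmax(0L, round(moca)))
    moca[below] <- pmin(moca[below], threshold - 1L)
    moca[!below] <- pmax(moca[!below], threshold)
  }
  fluency <- pmin(60L, pmax(0L, round(stats::rnorm(n, g$fluency_mean, g$fluency_sd))))
  sex <- ifelse(stats::runif(n) < g$female_fraction, "F", "M")
  age <- round(stats::rnorm(n, g$age_mean, g$age_sd), 1)
  edu <- round(pmax(0, stats::rnorm(n, g$education_mean, g$education_sd)), 1)
  hy <- if (g$hy_mean == 0) rep(0, n)
        else round(pmax(0, stats::rnorm(n, g$hy_mean, g$hy_sd)), 1)
  planted <- group == "PD" & below
  shift <- ifelse(planted, delta * g$volume_sd, 0)
  volL <- round(pmax(1500, stats::rnorm(n, g$volume_mean - shift, g$volume_sd)), 1)
  volR <- round(pmax(1500, stats::rnorm(n, g$volume_mean - shift, g$volume_sd)), 1)
  icv <- round(pmax(1e6, stats::rnorm(n, g$icv_mean, g$icv_sd)), 0)
  data.frame(
    source = source_name,
    subject_id = sprintf("%s-%04d", toupper(substr(source_name, nchar(source_name), nchar(source_name))),
                         id_offset + seq_len(n)),
    group = group, sex = sex, age = age, education = edu, hoehn_yahr = hy,
    moca_total = as.integer(moca), moca_fluency = as.integer(fluency),
    vol_left = volL, vol_right = volR, icv = icv,
    true_below = below, planted_effect = planted,
    stringsAsFactors = FALSE)
}

#' Generate the two-source synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return Object of class `generated_cohort`: list with `tables` (two
#'   data.frames in their distinct header dialects), `truth` (per-subject
#'   latent values: true stratum and planted-effect indicator), and
#'   `config`. Fully reproducible from `config$seed`; the caller's RNG
#'   state is left untouched.
#' @export
generate_cohorts <- function(config = cohort_config()) {
  validate_cohort_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  parts <- list(); offset <- 0L
  for (sn in names(config$sources)) {
    src <- config$sources[[sn]]
    pd <- generate_group(sn, "PD", src$pd, offset, config$threshold,
                         config$planted_effect_delta)
    hc <- generate_group(sn, "HC", src$hc, offset + src$pd$n, config$threshold,
                         0)
    parts[[sn]] <- rbind(pd, hc)
    offset <- offset + src$pd$n + src$hc$n
  }
  raw <- do.call(rbind, parts)
  rownames(raw) <- NULL

  src_names <- names(config$sources)
  d1 <- raw[raw$source == src_names[[1]], , drop = FALSE]
  d2 <- raw[raw$source == src_names[[2]], , drop = FALSE]
  tables <- list(
    data.frame(SUBJECT_ID = d1$subject_id, GROUP = d1$group, SEX = d1$sex,
               AGE = d1$age, EDUCATION_YRS = d1$education,
               HOEHN_YAHR = d1$hoehn_yahr, MOCA_total = d1$moca_total,
               MOCA_words_total = d1$moca_fluency,
               LHIPPO_VOL_MM3 = d1$vol_left, RHIPPO_VOL_MM3 = d1$vol_right,
               ICV_MM3 = d1$icv, stringsAsFactors = FALSE),
    data.frame(PATNO = d2$subject_id, CONDX = d2$group, GENDER = d2$sex,
               AGE = d2$age, EDUCYRS = d2$education, NHY = d2$hoehn_yahr,
               MCATOT = d2$moca_total, MCAVF = d2$moca_fluency,
               HIPPL = d2$vol_left, HIPPR = d2$vol_right, EICV = d2$icv,
               stringsAsFactors = FALSE))
  names(tables) <- src_names
  truth <- raw[, c("source", "subject_id", "group", "moca_total",
                   "true_below", "planted_effect")]
  truth$stratum <- ifelse(raw$group == "HC", "HC",
                          ifelse(raw$true_below, "PD_below", "PD_at_or_above"))
  structure(list(tables = tables, truth = truth, config = config),
            class = "generated_cohort")
}

#' @export
print.generated_cohort <- function(x, ...) {
  ns <- vapply(x$tables, nrow, integer(1))
  cat(sprintf("<generated_cohort> %s (seed %d)\n",
              paste(sprintf("%s: %d rows", names(ns), ns), collapse = ", "),
              x$config$seed))
  cat(sprintf("  sub-threshold subjects: %d of %d\n",
              sum(x$truth$true_below), nrow(x$truth)))
  invisible(x)
}

#' Write generated cohort CSVs
#'
#' Writes the two dialect CSVs and the latent-truth CSV. Re-loading the
#' dialect files via [load_source_table()] reproduces the tables cell for
#' cell.
#'
#' @param cohort A `generated_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths (`dataset1`, `dataset2`,
#'   `truth`).
#' @export
write_source_files <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "generated_cohort"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("IO error: cannot create output directory: ", out_dir, call. = FALSE)
  src_names <- names(cohort$tables)
  paths <- c(file.path(out_dir, paste0(src_names, ".csv")),
             file.path(out_dir, "truth.csv"))
  names(paths) <- c(src_names, "truth")
  for (i in 1:2) {
    ok <- tryCatch({
      utils::write.csv(cohort$tables[[i]], paths[[i]], row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("IO error writing ", paths[[i]], ": ", conditionMessage(ok),
           call. = FALSE)
  }
  utils::write.csv(cohort$truth, paths[["truth"]], row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  paths
}

#' Read or write a cohort configuration as YAML
#'
#' The YAML schema mirrors [cohort_config()]: top-level keys `sources`
#' (a map of source name to `{pd: {...}, hc: {...}}` group parameter maps),
#' `planted_effect_delta`, `threshold`, `seed`. A shipped preset with the
#' default study conditions is at
#' `system.file("extdata", "table1.yaml", package = "cohortkg")`.
#'
#' @param path YAML file path.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  defaults <- cohort_config()$sources
  sources <- raw$sources
  for (sn in names(sources)) for (gn in c("pd", "hc")) {
    base <- if (sn %in% names(defaults)) defaults[[sn]][[gn]]
            else group_defaults(10, 26, 0.5, 65, 0, 16)
    sources[[sn]][[gn]] <- utils::modifyList(base, sources[[sn]][[gn]])
  }
  cohort_config(
    sources = sources,
    planted_effect_delta = raw$planted_effect_delta %||% 0.8,
    threshold = raw$threshold %||% 26,
    seed = raw$seed %||% 1L)
}

#' @rdname read_cohort_config
#' @param config A `cohort_config` to serialize.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(list(sources = config$sources,
                        planted_effect_delta = config$planted_effect_delta,
                        threshold = config$threshold, seed = config$seed),
                   path)
  invisible(path)
}

#' Subject-id column per synthetic dialect
#' @param source_name `"dataset1"` or `"dataset2"` (or the configured names,
#'   in order).
#' @param config The `cohort_config` used.
#' @return Header name of the subject-id column.
#' @export
subject_id_column <- function(source_name, config = cohort_config()) {
  src_names <- names(config$sources)
  c("SUBJECT_ID", "PATNO")[match(source_name, src_names)]
}
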