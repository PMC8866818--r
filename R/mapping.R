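# Source-table loading, header harmonization to shared pattern keys, and
# pseudonymous subject IRI minting.

#' Catalogue of harmonized pattern keys
#'
#' The shared semantic keys that source headers may map to, with value types
#' and valid ranges. MoCA total and category fluency are the harmonized
#' assessment keys; other instruments are admissible but ship unmapped.
#'
#' @return data.frame with columns `pattern_key`, `value_type`, `min`, `max`.
#' @export
pattern_catalogue <- function() {
  data.frame(
    pattern_key = c("subject_id", "group_label", "sex", "age_years",
                    "education_years", "hoehn_yahr",
                    "moca_total", "moca_category_fluency",
                    "volume_left_hippocampus", "volume_right_hippocampus",
                    "icv",
                    "rbans_total", "hvlt_total", "upsit_total"),
    value_type = c("text", "text", "text", "decimal",
                   "decimal", "decimal",
                   "integer", "integer",
                   "decimal", "decimal", "decimal",
                   "integer", "integer", "integer"),
    min = c(NA, NA, NA, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    max = c(NA, NA, NA, 120, 30, 5, 30, 60, Inf, Inf, Inf, 160, 36, 40),
    stringsAsFactors = FALSE)
}

#' Load a source CSV table
#'
#' Reads an RFC-4180 CSV with a header row; all cells are kept as text until
#' typed by the field mapping.
#'
#' @param path CSV file path.
#' @param source_name Name of the source study (e.g. `"dataset1"`).
#' @param subject_id_column Header of the column holding raw subject ids.
#' @return Object of class `source_table`: list with `source_name`,
#'   `headers`, `rows` (character data.frame), `subject_id_column`.
#' @export
load_source_table <- function(path, source_name, subject_id_column) {
  if (!file.exists(path)) stop("load error: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  headers <- names(df)
  if (anyDuplicated(headers))
    stop("load error: duplicate headers in ", path, ": ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "),
         call. = FALSE)
  if (!subject_id_column %in% headers)
    stop(sprintf("load error: declared subject id column '%s' not among headers of %s",
                 subject_id_column, path), call. = FALSE)
  structure(list(source_name = source_name, headers = headers, rows = df,
                 subject_id_column = subject_id_column),
            class = "source_table")
}

#' @export
print.source_table <- function(x, ...) {
  cat(sprintf("<source_table> %s: %d rows x %d columns (id: %s)\n",
              x$source_name, nrow(x$rows), length(x$headers),
              x$subject_id_column))
  invisible(x)
}

#' Read and validate a field-mapping configuration
#'
#' The mapping config is YAML or JSON: a list of entries with fields
#' `source`, `header`, `pattern_key`, and optional `type`, `min`, `max`
#' (defaults come from [pattern_catalogue()]).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` mapping file.
#' @return A validated data.frame of class `field_mapping` with columns
#'   `source_name`, `source_header`, `pattern_key`, `value_type`,
#'   `min`, `max`.
#' @export
read_mapping_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  if (!is.null(raw$mappings)) raw <- raw$mappings
  rows <- lapply(raw, function(e) {
    data.frame(source_name = e$source, source_header = e$header,
               pattern_key = e$pattern_key,
               value_type = if (is.null(e$type)) NA_character_ else e$type,
               min = if (is.null(e$min)) NA_real_ else as.numeric(e$min),
               max = if (is.null(e$max)) NA_real_ else as.numeric(e$max),
               stringsAsFactors = FALSE)
  })
  validate_field_mapping(do.call(rbind, rows))
}

#' Build a field mapping in code
#'
#' @param source_name,source_header,pattern_key Character vectors (recycled).
#' @param value_type,min,max Optional overrides; defaults from
#'   [pattern_catalogue()].
#' @return A `field_mapping` data.frame.
#' @export
field_mapping <- function(source_name, source_header, pattern_key,
                          value_type = NA_character_, min = NA_real_,
                          max = NA_real_) {
  n <- max(length(source_name), length(source_header), length(pattern_key))
  validate_field_mapping(data.frame(
    source_name = rep_len(source_name, n),
    source_header = rep_len(source_header, n),
    pattern_key = rep_len(pattern_key, n),
    value_type = rep_len(value_type, n),
    min = rep_len(min, n), max = rep_len(max, n),
    stringsAsFactors = FALSE))
}

validate_field_mapping <- function(m) {
  cat_df <- pattern_catalogue()
  unknown <- setdiff(m$pattern_key, cat_df$pattern_key)
  if (length(unknown) > 0)
    stop("config error: pattern key(s) not in the catalogue: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  key <- paste(m$source_name, m$source_header, sep = "\x1f")
  if (anyDuplicated(key))
    stop("config error: ambiguous duplicate mapping for (source, header): ",
         paste(unique(paste0(m$source_name, "/", m$source_header)[duplicated(key)]),
               collapse = ", "), call. = FALSE)
  idx <- match(m$pattern_key, cat_df$pattern_key)
  m$value_type <- ifelse(is.na(m$value_type), cat_df$value_type[idx], m$value_type)
  m$min <- ifelse(is.na(m$min), cat_df$min[idx], m$min)
  m$max <- ifelse(is.na(m$max), cat_df$max[idx], m$max)
  class(m) <- c("field_mapping", "data.frame")
  rownames(m) <- NULL
  m
}

#' Resolve a source header to its harmonized pattern key
#'
#' @param source_name,header The source and column header to look up.
#' @param config A `field_mapping`.
#' @return The pattern key (character scalar), or `NA_character_` when the
#'   header is unmapped.
#' @export
resolve_field <- function(source_name, header, config) {
  hit <- config$pattern_key[config$source_name == source_name &
                            config$source_header == header]
  if (length(hit) == 0L) NA_character_ else hit[[1]]
}

#' Pseudonymization policy
#'
#' @param secret_salt Non-empty secret used to key the digest.
#' @param namespace Absolute IRI prefix for minted subject IRIs.
#' @return Object of class `pseudonym_policy`.
#' @export
pseudonym_policy <- function(secret_salt, namespace = SUBJ_NS) {
  if (!is.character(secret_salt) || length(secret_salt) != 1L || !nzchar(secret_salt))
    stop("policy error: secret_salt must be a non-empty string", call. = FALSE)
  if (!grepl("^[a-z][a-z0-9+.-]*://", namespace))
    stop("policy error: namespace must be an absolute IRI prefix", call. = FALSE)
  structure(list(secret_salt = secret_salt, namespace = namespace),
            class = "pseudonym_policy")
}

# keyed one-way digest: salted MD5, truncated to 96 bits, re-encoded with the
# letters g-v so numeric source ids can never appear as substrings of the IRI
keyed_digest <- function(keys) {
  dir <- tempfile("mint")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- file.path(dir, sprintf("k%06d", seq_along(keys)))
  for (i in seq_along(keys)) writeLines(keys[[i]], paths[[i]], useBytes = TRUE)
  hex <- unname(tools::md5sum(paths))
  hex24 <- substr(hex, 1L, 24L)
  chartr("0123456789abcdef", "ghijklmnopqrstuv", hex24)
}

#' Mint a pseudonymous subject IRI
#'
#' Deterministic keyed digest of `(salt, source_name, source_subject_id)`
#' embedded in the policy namespace. The same inputs always yield the same
#' IRI; different salts decouple the pseudonym spaces; the raw subject id is
#' never recoverable from, nor a substring of, the IRI.
#'
#' @param source_name,source_subject_id Character vectors (recycled).
#' @param policy A [pseudonym_policy()].
#' @return Character vector of absolute subject IRIs.
#' @export
mint_subject_iri <- function(source_name, source_subject_id, policy) {
  stopifnot(inherits(policy, "pseudonym_policy"))
  if (any(!nzchar(source_name)) || any(!nzchar(source_subject_id)))
    stop("mint error: source_name and source_subject_id must be non-empty",
         call. = FALSE)
  n <- max(length(source_name), length(source_subject_id))
  keys <- paste(policy$secret_salt, rep_len(source_name, n),
                rep_len(source_subject_id, n), sep = "\x1f")
  paste0(policy$namespace, keyed_digest(keys))
}

#' Pseudonymous display label for a subject IRI
#' @param subject_iri Minted subject IRI(s).
#' @return The local (post-namespace) part, used as the identifier label.
#' @export
subject_label <- function(subject_iri) sub(".*/", "", subject_iri)

#' Harmonize heterogeneous source tables
#'
#' Resolves every header of every source through the field mapping, types
#' the mapped cells, quarantines out-of-range values to an exceptions
#' report (they are never ingested), and mints pseudonymous subject IRIs.
#' Unmapped headers are reported, never silently dropped.
#'
#' @param tables List of `source_table` objects.
#' @param config A `field_mapping`.
#' @param policy A [pseudonym_policy()].
#' @return Object of class `harmonized_cohort`: list with
#'   `data` (one row per subject, one column per pattern key, plus
#'   `source`, `subject_id`, `subject_iri`, `id_label`),
#'   `mapping_report` (per source/header: pattern key or unmapped), and
#'   `exceptions` (quarantined out-of-range cells).
#' @export
harmonize_sources <- function(tables, config, policy) {
  stopifnot(length(tables) > 0)
  keys <- setdiff(pattern_catalogue()$pattern_key, "subject_id")
  report <- list(); exceptions <- list(); out <- list()
  for (tab in tables) {
    stopifnot(inherits(tab, "source_table"))
    mapped_key <- vapply(tab$headers, resolve_field, character(1),
                         source_name = tab$source_name, config = config)
    report[[tab$source_name]] <- data.frame(
      source = tab$source_name, header = tab$headers,
      pattern_key = mapped_key,
      status = ifelse(is.na(mapped_key), "unmapped", "mapped"),
      stringsAsFactors = FALSE)
    n <- nrow(tab$rows)
    rec <- data.frame(source = rep(tab$source_name, n),
                      subject_id = tab$rows[[tab$subject_id_column]],
                      stringsAsFactors = FALSE)
    for (k in keys) rec[[k]] <- if (k %in% c("group_label", "sex"))
      NA_character_ else NA_real_
    for (j in seq_along(tab$headers)) {
      k <- mapped_key[[j]]
      if (is.na(k) || k == "subject_id") next
      cfg <- config[config$source_name == tab$source_name &
                    config$source_header == tab$headers[[j]], ]
      cells <- tab$rows[[j]]
      if (cfg$value_type == "text") {
        rec[[k]] <- ifelse(nzchar(trimws(cells)), trimws(cells), NA_character_)
      } else {
        val <- suppressWarnings(as.numeric(cells))
        val[!nzchar(trimws(cells))] <- NA_real_
        bad_parse <- nzchar(trimws(cells)) & is.na(val)
        oor <- !is.na(val) & ((!is.na(cfg$min) & val < cfg$min) |
                              (!is.na(cfg$max) & val > cfg$max))
        quarantine <- bad_parse | oor
        if (any(quarantine)) {
          exceptions[[length(exceptions) + 1L]] <- data.frame(
            source = tab$source_name, row = which(quarantine),
            subject_id = rec$subject_id[quarantine],
            header = tab$headers[[j]], pattern_key = k,
            value = cells[quarantine],
            reason = ifelse(bad_parse[quarantine], "unparseable", "out_of_range"),
            stringsAsFactors = FALSE)
          val[quarantine] <- NA_real_
        }
        if (cfg$value_type == "integer") val <- ifelse(is.na(val), val, round(val))
        rec[[k]] <- val
      }
    }
    if (any(!nzchar(trimws(rec$subject_id))))
      stop("harmonization error: empty subject id in source ", tab$source_name,
           call. = FALSE)
    rec$subject_iri <- mint_subject_iri(tab$source_name, rec$subject_id, policy)
    rec$id_label <- subject_label(rec$subject_iri)
    out[[tab$source_name]] <- rec
  }
  data <- do.call(rbind, out)
  rownames(data) <- NULL
  if (anyDuplicated(data$subject_iri))
    stop("harmonization error: pseudonym collision detected", call. = FALSE)
  structure(list(
    data = data,
    mapping_report = do.call(rbind, c(report, list(make.row.names = FALSE))),
    exceptions = if (length(exceptions) > 0)
      do.call(rbind, exceptions)
    else data.frame(source = character(0), row = integer(0),
                    subject_id = character(0), header = character(0),
                    pattern_key = character(0), value = character(0),
                    reason = character(0), stringsAsFactors = FALSE)),
    class = "harmonized_cohort")
}

#' @export
print.harmonized_cohort <- function(x, ...) {
  cat(sprintf("<harmonized_cohort> %d subjects from %d source(s)\n",
              nrow(x$data), length(unique(x$data$source))))
  unm <- sum(x$mapping_report$status == "unmapped")
  cat(sprintf("  headers: %d mapped, %d unmapped; %d quarantined cell(s)\n",
              sum(x$mapping_report$status == "mapped"), unm, nrow(x$exceptions)))
  invisible(x)
}

#' Default field mapping for the bundled synthetic dialects
#'
#' Covers the two header dialects emitted by [generate_cohorts()]:
#' descriptive headers for source `dataset1` (e.g. `MOCA_words_total`) and
#' opaque abbreviations for source `dataset2` (e.g. `MCAVF`).
#'
#' @return A `field_mapping`.
#' @export
default_field_mapping <- function() {
  d1 <- c(SUBJECT_ID = "subject_id", GROUP = "group_label", SEX = "sex",
          AGE = "age_years", EDUCATION_YRS = "education_years",
          HOEHN_YAHR = "hoehn_yahr", MOCA_total = "moca_total",
          MOCA_words_total = "moca_category_fluency",
          LHIPPO_VOL_MM3 = "volume_left_hippocampus",
          RHIPPO_VOL_MM3 = "volume_right_hippocampus",
          ICV_MM3 = "icv")
  d2 <- c(PATNO = "subject_id", CONDX = "group_label", GENDER = "sex",
          AGE = "age_years", EDUCYRS = "education_years", NHY = "hoehn_yahr",
          MCATOT = "moca_total", MCAVF = "moca_category_fluency",
          HIPPL = "volume_left_hippocampus", HIPPR = "volume_right_hippocampus",
          EICV = "icv")
  field_mapping(
    source_name = c(rep("dataset1", length(d1)), rep("dataset2", length(d2))),
    source_header = c(names(d1), names(d2)),
    pattern_key = c(unname(d1), unname(d2)))
}

#' Write a field mapping to YAML
#' @param config A `field_mapping`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_mapping_config <- function(config, path) {
  entries <- lapply(seq_len(nrow(config)), function(i) {
    list(source = config$source_name[[i]], header = config$source_header[[i]],
         pattern_key = config$pattern_key[[i]], type = config$value_type[[i]],
         min = if (is.finite(config$min[[i]])) config$min[[i]] else NULL,
         max = if (is.finite(config$max[[i]])) config$max[[i]] else NULL)
  })
  yaml::write_yaml(list(mappings = entries), path)
  invisible(path)
}
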