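#' Read a cohort CSV
#'
#' Expects the header `patient_id,parsonnet,time_days,censored,group`
#' (`censored` coded 0/1, "." decimal separator). Each row is validated;
#' errors name the offending data row.
#'
#' @param path CSV file path.
#' @return a `cohort` data.frame (see [generate_cohort()]; no
#'   `true_time_days` column unless present in the file).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "parsonnet", "time_days", "censored", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("parsonnet", "time_days", "censored")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric `%s` at row %d", col, bad[1L]),
           call. = FALSE)
    df[[col]] <- v
  }
  bad <- which(is.na(df$parsonnet) | df$parsonnet < 0 | df$parsonnet > 100)
  if (length(bad))
    stop("parsonnet out of [0, 100] at row ", bad[1L], call. = FALSE)
  bad <- which(is.na(df$time_days) | df$time_days <= 0)
  if (length(bad))
    stop("non-positive time_days at row ", bad[1L], call. = FALSE)
  bad <- which(!df$censored %in% c(0, 1))
  if (length(bad))
    stop("censored must be 0 or 1 at row ", bad[1L], call. = FALSE)
  df$parsonnet <- as.integer(df$parsonnet)
  df$censored <- df$censored == 1
  df$group <- as.character(df$group)
  df$group[!nzchar(df$group) | is.na(df$group)] <- NA_character_
  class(df) <- c("cohort", "data.frame")
  df
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]; `censored` is written as 0/1 and missing
#' groups as empty strings. The latent `true_time_days` column (synthetic
#' cohorts) is not written, so files carry only what a real registry would.
#'
#' @param cohort cohort data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort_frame(cohort)
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(cohort)) cohort$patient_id
                 else seq_len(nrow(cohort)),
    parsonnet = cohort$parsonnet,
    time_days = cohort$time_days,
    censored = as.integer(cohort$censored),
    group = ifelse(is.na(cohort$group), "", cohort$group))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a residual pool CSV
#'
#' Single-column CSV `residual` plus a comment-free header; the pool's
#' source and standardization constants travel in a JSON sidecar written by
#' the CLI manifest instead, keeping the CSV trivially interoperable.
#'
#' @param rs a `residual_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_residuals <- function(rs, path) {
  stopifnot(inherits(rs, "residual_series"))
  write.csv(data.frame(residual = rs$values), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_residuals
#' @param source residual source label for the re-read series.
#' @export
read_residuals <- function(path, source = c("SR_AFT", "SR_SVM")) {
  source <- match.arg(source)
  df <- read.csv(path)
  if (!"residual" %in% names(df))
    stop("residual file must have a `residual` column", call. = FALSE)
  residual_series(df$residual, source = source)
}

#' Write a shift table CSV
#'
#' Column order `shift,ARL,SDRL,P05,P10,P25,P50,P75,P90,P95`, the layout of
#' published run-length tables.
#'
#' @param tab a [shift_table()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(tab, path) {
  cols <- c("shift", "ARL", "SDRL",
            "P05", "P10", "P25", "P50", "P75", "P90", "P95")
  write.csv(as.data.frame(tab)[, cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' The published shift grid
#'
#' The grid of residual shift magnitudes used in the run-length studies.
#'
#' @return numeric vector of 14 shifts.
#' @export
default_shift_grid <- function() {
  c(0, 0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.09, 0.10,
    0.40, 1.00, 2.00)
}

# deterministic per-stage seed derivation from one root seed
derive_seed <- function(root, stage) {
  stages <- c(generate = 1L, fit = 2L, calibrate = 3L, profile = 4L,
              compare = 5L, estimate = 6L)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  (as.integer(root) * 48271L + stages[[stage]] * 1013L) %% 2147483399L
}

# run manifest: config snapshot + seeds + version + timings, one per command
write_manifest <- function(path, command, config, seeds, timings,
                           results = NULL) {
  m <- list(tool = "svmewma",
            version = as.character(packageVersion("svmewma")),
            command = command,
            config = config,
            seeds = seeds,
            timings_sec = timings,
            results = results)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
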