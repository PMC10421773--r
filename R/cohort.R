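#' @keywords internal
molar_fdi <- function() c(16L, 17L, 26L, 27L, 36L, 37L, 46L, 47L)

# First molars end in 6, second molars in 7 (FDI position digit).
fdi_molar_type <- function(fdi) ifelse(fdi %% 10L == 6L, "m1", "m2")

#' Validate a cohort table
#'
#' The cohort schema is long format, one row per participant-tooth:
#' `participant_id`, `sex` (`"F"`/`"M"`), `age_years` (decimal years),
#' `tooth_fdi` (FDI two-digit code of a 1st/2nd molar), and the three
#' segmented volumes `hard_ml`, `hsst_ml`, `lsst_ml` (all strictly
#' positive).
#'
#' @param df data frame to validate.
#' @return the validated data frame (invisibly usable), with `sex` as
#'   character and `tooth_fdi` as integer.
#' @export
validate_cohort <- function(df) {
  need <- c("participant_id", "sex", "age_years", "tooth_fdi",
            "hard_ml", "hsst_ml", "lsst_ml")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sex <- as.character(df$sex)
  df$tooth_fdi <- as.integer(df$tooth_fdi)
  bad_row <- function(cond, what) {
    if (any(cond))
      stop("cohort row(s) ", paste(which(cond), collapse = ", "), ": ", what,
           call. = FALSE)
  }
  bad_row(!df$sex %in% c("F", "M"), "sex must be 'F' or 'M'")
  bad_row(!is.finite(df$age_years) | df$age_years <= 0,
          "age_years must be positive")
  bad_row(!df$tooth_fdi %in% molar_fdi(),
          "tooth_fdi must be a 1st/2nd molar FDI code (16,17,26,27,36,37,46,47)")
  for (v in c("hard_ml", "hsst_ml", "lsst_ml"))
    bad_row(!is.finite(df[[v]]) | df[[v]] <= 0,
            paste0(v, " must be strictly positive (all tissues are segmented",
                   " in every included tooth)"))
  key <- paste(df$participant_id, df$tooth_fdi)
  if (anyDuplicated(key))
    stop("duplicate (participant_id, tooth_fdi): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  # one sex and age per participant
  per <- unique(df[, c("participant_id", "sex", "age_years")])
  if (anyDuplicated(per$participant_id))
    stop("participant(s) with inconsistent sex/age across rows", call. = FALSE)
  df[need]
}

#' Read a cohort CSV
#'
#' @param path path to a UTF-8 CSV with the schema of [validate_cohort()].
#' @return validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Write a cohort CSV
#'
#' Numeric fields are written with 15 significant digits so that a
#' write/read round trip is lossless.
#'
#' @param cohort validated cohort data frame.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- cohort
  for (v in c("age_years", "hard_ml", "hsst_ml", "lsst_ml"))
    out[[v]] <- formatC(cohort[[v]], digits = 15, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
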