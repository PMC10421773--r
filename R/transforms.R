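#' The ten transformation outcome codes
#'
#' The response variables explored for the age regression: four families of
#' transformations of the three tissue volumes (`hard`, `hsst`, `lsst`,
#' `total = hard + hsst + lsst`) giving ten outcomes.
#'
#' * `1`  total
#' * `2a` hsst / (total - hsst), `2b` lsst / (total - lsst),
#'   `2c` hard / (total - hard)
#' * `3a` hsst / total, `3b` lsst / total, `3c` hard / total
#' * `4a` (hsst + lsst) / total, `4b` (hsst + hard) / total,
#'   `4c` (lsst + hard) / total
#'
#' @return character vector of the ten codes.
#' @export
outcome_codes <- function() {
  c("1", "2a", "2b", "2c", "3a", "3b", "3c", "4a", "4b", "4c")
}

#' Compute the ten transformation outcomes
#'
#' Vectorized over rows: accepts either a `tooth_volumes` object or a
#' data frame with columns `hard_ml`, `hsst_ml`, `lsst_ml` (the cohort
#' schema), or three numeric vectors.
#'
#' @param hard either hard-tissue volumes (ml), a `tooth_volumes`, or a
#'   cohort-style data frame.
#' @param hsst,lsst soft-tissue volumes (ml) when `hard` is numeric.
#' @param log if `TRUE` return natural logarithms (the regression response
#'   scale) instead of the raw outcomes.
#' @return numeric matrix, one row per tooth, columns named by
#'   [outcome_codes()].
#' @examples
#' compute_outcomes(hard = 1.1, hsst = 0.070, lsst = 0.028)
#' @export
compute_outcomes <- function(hard, hsst = NULL, lsst = NULL, log = FALSE) {
  if (inherits(hard, "tooth_volumes")) {
    hsst <- hard$hsst; lsst <- hard$lsst; hard <- hard$hard
  } else if (is.data.frame(hard)) {
    df <- hard
    need <- c("hard_ml", "hsst_ml", "lsst_ml")
    if (!all(need %in% names(df)))
      stop("data frame must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    hard <- df$hard_ml; hsst <- df$hsst_ml; lsst <- df$lsst_ml
  }
  if (anyNA(c(hard, hsst, lsst)) || any(c(hard, hsst, lsst) <= 0))
    stop("all tissue volumes must be strictly positive", call. = FALSE)
  total <- hard + hsst + lsst
  M <- cbind(
    "1"  = total,
    "2a" = hsst / (total - hsst),
    "2b" = lsst / (total - lsst),
    "2c" = hard / (total - hard),
    "3a" = hsst / total,
    "3b" = lsst / total,
    "3c" = hard / total,
    "4a" = (hsst + lsst) / total,
    "4b" = (hsst + hard) / total,
    "4c" = (lsst + hard) / total)
  if (log) base::log(M) else M
}

#' Pearson redundancy screen over the transformation outcomes
#'
#' Computes pairwise Pearson correlations of the natural-log outcomes and
#' flags a pair as overlapping when `|R| >= threshold`. Within an
#' overlapping pair a family-2 outcome is dropped in favour of the other
#' member; on cohorts with realistic soft-tissue fractions this retains
#' seven of the ten outcomes (2a--c are redundant with 3a, 3b and 4a).
#'
#' Correlation is taken on the log scale (the stated response scale) and in
#' absolute value: `2c` and `4a` are near-perfectly negatively related on
#' the log scale, so a signed rule could never flag that pair.
#'
#' @param outcomes matrix from [compute_outcomes()] (raw scale; logs are
#'   taken internally) with at least 3 rows, or a cohort data frame.
#' @param threshold overlap bound in (0, 1], default 0.999.
#' @return list with `retained` (character codes), `dropped`, `pairs`
#'   (data frame of flagged pairs with their correlation) and
#'   `indeterminate` (codes with zero variance, for which the correlation
#'   is undefined).
#' @export
screen_redundancy <- function(outcomes, threshold = 0.999) {
  if (is.data.frame(outcomes)) outcomes <- compute_outcomes(outcomes)
  stopifnot(is.matrix(outcomes))
  if (nrow(outcomes) < 3L)
    stop("need at least 3 rows to screen correlations", call. = FALSE)
  if (!(threshold > 0 && threshold <= 1))
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  L <- base::log(outcomes)
  codes <- colnames(L)
  sds <- apply(L, 2, stats::sd)
  indeterminate <- codes[sds == 0 | !is.finite(sds)]
  ok <- setdiff(codes, indeterminate)
  R <- suppressWarnings(stats::cor(L[, ok, drop = FALSE]))
  pairs <- data.frame(a = character(), b = character(), r = numeric())
  for (i in seq_along(ok)) for (j in seq_along(ok)) {
    if (i < j && abs(R[i, j]) >= threshold)
      pairs <- rbind(pairs, data.frame(a = ok[i], b = ok[j], r = R[i, j]))
  }
  fam2 <- c("2a", "2b", "2c")
  dropped <- character()
  for (k in seq_len(nrow(pairs))) {
    pr <- c(pairs$a[k], pairs$b[k])
    in2 <- pr %in% fam2
    if (any(in2) && !all(in2)) dropped <- union(dropped, pr[in2])
    else if (all(in2)) dropped <- union(dropped, pr[2])  # keep the first
  }
  list(retained = setdiff(codes, union(dropped, indeterminate)),
       dropped = dropped, pairs = pairs, indeterminate = indeterminate,
       threshold = threshold)
}
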