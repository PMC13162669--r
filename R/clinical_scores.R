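#' ALBI score and modified ALBI grade
#'
#' Albumin-bilirubin measure of hepatic reserve:
#' `ALBI = 0.66 * log10(bilirubin umol/L) - 0.085 * albumin g/L`.
#' Inputs in conventional units are converted first (bilirubin mg/dL x 17.104,
#' the bilirubin molar-mass factor; albumin g/dL x 10). Grades use the
#' modified (four-level) boundaries, closed on the lower-grade side:
#' grade 1 <= -2.60 < grade 2a <= -2.270 < grade 2b <= -1.39 < grade 3.
#'
#' @param bilirubin Total bilirubin values (positive); vectorized.
#' @param albumin Serum albumin values (positive); vectorized (recycled
#'   against `bilirubin`).
#' @param bilirubin_unit `"mg/dL"` (default) or `"umol/L"`.
#' @param albumin_unit `"g/dL"` (default) or `"g/L"`.
#' @return Tibble with `albi_score` and `malbi_grade`
#'   (factor `"1" < "2a" < "2b" < "3"`).
#' @export
albi_score <- function(bilirubin, albumin,
                       bilirubin_unit = c("mg/dL", "umol/L"),
                       albumin_unit = c("g/dL", "g/L")) {
  bilirubin_unit <- match.arg(bilirubin_unit)
  albumin_unit <- match.arg(albumin_unit)
  if (any(!is.finite(bilirubin)) || any(bilirubin <= 0))
    stop("bilirubin must be positive", call. = FALSE)
  if (any(!is.finite(albumin)) || any(albumin <= 0))
    stop("albumin must be positive", call. = FALSE)
  bili_umol <- if (bilirubin_unit == "mg/dL") bilirubin * 17.104 else bilirubin
  alb_gl <- if (albumin_unit == "g/dL") albumin * 10 else albumin
  score <- 0.66 * log10(bili_umol) - 0.085 * alb_gl
  grade <- cut(score, breaks = c(-Inf, -2.60, -2.270, -1.39, Inf),
               labels = c("1", "2a", "2b", "3"), right = TRUE,
               ordered_result = TRUE)
  tibble::tibble(albi_score = score, malbi_grade = grade)
}

#' Append ALBI columns to a patient table
#'
#' Computes [albi_score()] from the table's `bilirubin_mg_dl` and
#' `albumin_g_dl` columns and appends `albi_score` and `malbi_grade`.
#'
#' @param patients Data frame with `bilirubin_mg_dl` and `albumin_g_dl`.
#' @return The table with the two columns appended.
#' @export
add_albi <- function(patients) {
  stopifnot(all(c("bilirubin_mg_dl", "albumin_g_dl") %in% names(patients)))
  res <- albi_score(patients$bilirubin_mg_dl, patients$albumin_g_dl)
  patients$albi_score <- res$albi_score
  patients$malbi_grade <- res$malbi_grade
  patients
}
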