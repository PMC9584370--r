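#' The eight measured duction directions
#'
#' Monocular excursions measured on a Goldmann perimeter: the four cardinal
#' ductions and the four oblique combinations.
#'
#' @return Character vector of direction names.
#' @export
duction_directions <- function() {
  c("elevation", "depression", "adduction", "abduction",
    "elevation_in_abduction", "elevation_in_adduction",
    "depression_in_abduction", "depression_in_adduction")
}

#' Normative duction reference values
#'
#' Normal adult monocular duction ranges in degrees, per direction.  The
#' shipped table holds conventional Goldmann-perimeter normal values and is
#' deliberately editable configuration: studies citing different normative
#' sources can point `path` at their own CSV (columns `direction`, `degrees`).
#'
#' @param path CSV path; defaults to the packaged table.
#' @return Named numeric vector of reference degrees.
#' @export
duction_reference <- function(path = NULL) {
  path <- path %||% system.file("extdata", "duction_reference.csv",
                                package = "blebquant", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  ref <- tab$degrees
  names(ref) <- tab$direction
  missing <- setdiff(duction_directions(), names(ref))
  if (length(missing))
    .stop2("reference table lacks direction(s): %s",
           paste(missing, collapse = ", "), class = "bq_incomplete")
  if (any(!is.finite(ref)) || any(ref <= 0))
    .stop2("reference degrees must be positive", class = "bq_input")
  ref[duction_directions()]
}

#' Hodapp-Parrish-Anderson visual-field classification
#'
#' Bands the visual-field mean deviation (MD, dB; more negative = worse):
#' mild above -6 dB, moderate down to -12 dB, severe at or below -12 dB.
#' Boundary values are assigned to the worse category.
#'
#' @param md Mean deviation(s) in dB; must be finite.
#' @return Factor with levels `mild < moderate < severe`.
#' @export
classify_vf <- function(md) {
  if (any(!is.finite(md)))
    .stop2("md must be finite", class = "bq_input")
  out <- ifelse(md > -6, "mild", ifelse(md > -12, "moderate", "severe"))
  factor(out, levels = c("mild", "moderate", "severe"), ordered = TRUE)
}

#' Duction restriction rule
#'
#' A direction is significantly restricted when at least 10 degrees of
#' duction are lost relative to the normal adult range (threshold based on
#' measurement repeatability and age effects).  All restricted directions are
#' reported, matching the study's use of every restriction in analysis.
#'
#' @param measured Named numeric vector of measured ductions in degrees; must
#'   contain all eight [duction_directions()].
#' @param reference Named reference vector, see [duction_reference()].
#' @param threshold Loss threshold in degrees (closed: exactly 10 counts).
#' @return List: `restricted` (any direction flagged), `directions`
#'   (character vector of flagged directions), `loss` (degrees lost per
#'   flagged direction), `total_loss` (sum of losses over flagged directions,
#'   the "total amount of motility restriction" used in correlations).
#' @export
restricted_ductions <- function(measured, reference = duction_reference(),
                                threshold = 10) {
  dirs <- duction_directions()
  missing <- setdiff(dirs, names(measured))
  if (length(missing))
    .stop2("measured ductions missing direction(s): %s",
           paste(missing, collapse = ", "), class = "bq_incomplete")
  measured <- measured[dirs]
  if (any(!is.finite(measured)) || any(measured < 0) || any(measured > 120))
    .stop2("measured ductions must lie in [0, 120] degrees", class = "bq_input")
  loss <- reference[dirs] - measured
  flagged <- loss >= threshold
  list(restricted = any(flagged),
       directions = dirs[flagged],
       loss = loss[flagged],
       total_loss = sum(loss[flagged]))
}
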