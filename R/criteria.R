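#' The default eleven-criterion framework
#'
#' Returns the criterion set used throughout the package: eleven quantifiable
#' criteria grouped into three categories of unmet medical need — four on
#' patient suffering, four on the current standard of care, and three on
#' accessibility of that standard of care. Every criterion is scored on a
#' 1--5 scale with higher scores indicating greater unmet need.
#'
#' @return A data frame with columns `name`, `category`
#'   (`patient_suffering`, `standard_of_care`, or `accessibility`), and
#'   `description`, one row per criterion, in canonical order.
#' @examples
#' default_criteria()
#' @export
default_criteria <- function() {
  data.frame(
    name = c(
      "Commonality", "Duration", "QALYs lost", "Mortality",
      "Disease modification", "Adverse events", "Route of administration",
      "Frequency of administration",
      "Cost to patients", "Robust supply", "Regulatory barriers"
    ),
    category = rep(
      c("patient_suffering", "standard_of_care", "accessibility"),
      times = c(4L, 4L, 3L)
    ),
    description = c(
      "How rare the disease is (prevalence per 100,000); rarer diseases have greater unmet need under the rare-disease weighting intent",
      "Typical duration of illness (weeks/months/years/lifelong)",
      "Quality-adjusted life years lost per year of illness (morbidity)",
      "Five-year mortality rate of the disease",
      "Disease-modifying activity of the current standard of care (curative through none)",
      "Adverse events / side-effect burden of the standard of care",
      "Route of administration of the standard of care (oral through implanted/infused)",
      "Dosing frequency of the standard of care",
      "Annual out-of-pocket cost of the standard of care to patients",
      "Robustness of the supply chain for the standard of care",
      "Regulatory barriers limiting access to the standard of care"
    ),
    stringsAsFactors = FALSE
  )
}

#' Validate a criterion set
#'
#' Checks the structural invariants of a criterion set: exactly eleven
#' criteria with unique names and categories drawn from the three recognised
#' categories.
#'
#' @param criteria A data frame shaped like [default_criteria()].
#' @return `criteria`, invisibly, if valid; otherwise an error.
#' @export
validate_criteria <- function(criteria) {
  stopifnot(is.data.frame(criteria))
  if (!all(c("name", "category") %in% names(criteria))) {
    stop_umni("criterion set needs 'name' and 'category' columns")
  }
  if (nrow(criteria) != 11L) {
    stop_umni("criterion set must contain exactly 11 criteria, got ", nrow(criteria))
  }
  if (anyDuplicated(criteria$name)) {
    stop_umni("criterion names must be unique")
  }
  bad <- setdiff(
    unique(criteria$category),
    c("patient_suffering", "standard_of_care", "accessibility")
  )
  if (length(bad)) {
    stop_umni("unknown criterion category: ", paste(bad, collapse = ", "))
  }
  invisible(criteria)
}

#' Default criterion weights
#'
#' The default weighting scheme emphasises rare diseases lacking an
#' effective, disease-modifying standard of care with high
#' mortality/morbidity: Mortality and Disease modification carry the largest
#' weight (1), the accessibility criteria the smallest (0.25 each). The
#' eleven weights sum to 5.75, so a composite total under this scheme lies
#' in \[5.75, 28.75\].
#'
#' @return A named numeric vector, one non-negative weight per criterion of
#'   [default_criteria()], in criterion order.
#' @examples
#' w <- default_weights()
#' sum(w) # 5.75
#' @export
default_weights <- function() {
  c(
    "Commonality" = 0.25,
    "Duration" = 0.5,
    "QALYs lost" = 0.75,
    "Mortality" = 1,
    "Disease modification" = 1,
    "Adverse events" = 0.75,
    "Route of administration" = 0.5,
    "Frequency of administration" = 0.25,
    "Cost to patients" = 0.25,
    "Robust supply" = 0.25,
    "Regulatory barriers" = 0.25
  )
}

#' Validate a weight scheme against a criterion set
#'
#' @param weights Named numeric vector of non-negative weights.
#' @param criteria Criterion set the weights must cover exactly.
#' @return `weights`, invisibly, if valid.
#' @export
validate_weights <- function(weights, criteria = default_criteria()) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop_umni("weights must be a named vector")
  }
  missing <- setdiff(criteria$name, names(weights))
  extra <- setdiff(names(weights), criteria$name)
  if (length(missing)) {
    stop_umni("weights missing for: ", paste(missing, collapse = ", "))
  }
  if (length(extra)) {
    stop_umni("weights given for unknown criteria: ", paste(extra, collapse = ", "))
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop_umni("weights must be finite and non-negative")
  }
  invisible(weights)
}

#' Read and write weight schemes as JSON
#'
#' Weight schemes are stored as a flat JSON object mapping criterion name to
#' weight.
#'
#' @param path File path.
#' @param weights Named numeric weight vector.
#' @param criteria Criterion set used for validation on read.
#' @return `read_weights_json()` returns a named numeric vector;
#'   `write_weights_json()` returns `path` invisibly.
#' @export
read_weights_json <- function(path, criteria = default_criteria()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- unlist(obj)
  storage.mode(w) <- "double"
  validate_weights(w, criteria)
  w[criteria$name]
}

#' @rdname read_weights_json
#' @export
write_weights_json <- function(weights, path) {
  jsonlite::write_json(as.list(weights), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
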