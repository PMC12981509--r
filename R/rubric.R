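#' Enumerations for categorical disease-profile attributes
#'
#' Ordered category levels for each categorical attribute of a disease
#' profile, listed from lowest to highest unmet need.
#'
#' @return Named list of character vectors.
#' @export
profile_levels <- function() {
  list(
    soc_disease_modification = c("curative", "substantial", "moderate", "partial", "none"),
    soc_adverse_event_burden = c("none", "mild", "moderate", "severe", "intolerable"),
    admin_route = c("oral", "topical", "self_injection", "clinic_infusion", "implanted"),
    annual_cost_band = c("minimal", "low", "moderate", "high", "catastrophic"),
    supply_robustness = c("robust", "mostly_stable", "occasional_shortage",
                          "frequent_shortage", "chronic_shortage"),
    regulatory_barrier = c("none", "minimal", "moderate", "high", "prohibitive")
  )
}

duration_units <- c("weeks", "months", "years", "lifelong")

#' Build a structured disease attribute profile
#'
#' A disease profile holds the raw measurable attributes that the rubric
#' maps to 1--5 criterion scores: epidemiology (prevalence per 100,000,
#' typical duration, QALY loss per year of illness, five-year mortality)
#' and standard-of-care / access attributes (disease-modifying activity,
#' adverse-event burden, administration route and frequency, cost band,
#' supply robustness, regulatory barriers).
#'
#' @param disease_id CURIE identifier.
#' @param prevalence_per_100k Non-negative prevalence per 100,000 persons.
#' @param typical_duration_value,typical_duration_unit Typical illness
#'   duration; unit one of `"weeks"`, `"months"`, `"years"`, `"lifelong"`
#'   (value ignored for `"lifelong"`).
#' @param qaly_loss_fraction QALY loss per year of illness, in \[0, 1\].
#' @param five_year_mortality_pct Five-year mortality, percent in \[0, 100\].
#' @param soc_disease_modification,soc_adverse_event_burden,admin_route,annual_cost_band,supply_robustness,regulatory_barrier
#'   Categorical attributes; see [profile_levels()].
#' @param admin_doses_per_week Standard-of-care dosing frequency, doses per
#'   week (non-negative).
#' @return One-row data frame of class `disease_profile`.
#' @export
disease_profile <- function(disease_id,
                            prevalence_per_100k,
                            typical_duration_value,
                            typical_duration_unit,
                            qaly_loss_fraction,
                            five_year_mortality_pct,
                            soc_disease_modification,
                            soc_adverse_event_burden,
                            admin_route,
                            admin_doses_per_week,
                            annual_cost_band,
                            supply_robustness,
                            regulatory_barrier) {
  p <- data.frame(
    disease_id = disease_id,
    prevalence_per_100k = prevalence_per_100k,
    typical_duration_value = typical_duration_value,
    typical_duration_unit = typical_duration_unit,
    qaly_loss_fraction = qaly_loss_fraction,
    five_year_mortality_pct = five_year_mortality_pct,
    soc_disease_modification = soc_disease_modification,
    soc_adverse_event_burden = soc_adverse_event_burden,
    admin_route = admin_route,
    admin_doses_per_week = admin_doses_per_week,
    annual_cost_band = annual_cost_band,
    supply_robustness = supply_robustness,
    regulatory_barrier = regulatory_barrier,
    stringsAsFactors = FALSE
  )
  validate_profiles(p)
}

#' Validate disease profiles
#'
#' @param profiles Data frame of profiles (one row each).
#' @return `profiles` with class `disease_profile`, or an error naming the
#'   first offending attribute.
#' @export
validate_profiles <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  num_ok <- function(col, lo, hi) {
    x <- profiles[[col]]
    if (any(!is.finite(x) | x < lo | x > hi)) {
      stop_umni("profile attribute '", col, "' outside [", lo, ", ", hi, "]")
    }
  }
  num_ok("prevalence_per_100k", 0, Inf)
  num_ok("qaly_loss_fraction", 0, 1)
  num_ok("five_year_mortality_pct", 0, 100)
  num_ok("admin_doses_per_week", 0, Inf)
  if (any(!profiles$typical_duration_unit %in% duration_units)) {
    stop_umni("typical_duration_unit must be one of: ",
              paste(duration_units, collapse = ", "))
  }
  lv <- profile_levels()
  for (col in names(lv)) {
    bad <- !profiles[[col]] %in% lv[[col]]
    if (any(bad)) {
      stop_umni("profile attribute '", col, "' has unknown level: ",
                paste(unique(profiles[[col]][bad]), collapse = ", "))
    }
  }
  if (!inherits(profiles, "disease_profile")) {
    class(profiles) <- c("disease_profile", class(profiles))
  }
  profiles
}

# Duration expressed in years; lifelong maps to Inf.
duration_years <- function(value, unit) {
  ifelse(unit == "lifelong", Inf,
    value / c(weeks = 52, months = 12, years = 1)[unit]
  )
}

#' The default scoring rubric
#'
#' Maps each of the eleven criteria to a measurable profile attribute with
#' either four strictly increasing numeric cut-points (defining five
#' half-open, lower-inclusive bands on the attribute scale) or an explicit
#' category-to-score map. Direction flags state whether greater attribute
#' values mean greater need (`"increasing"`) or the reverse
#' (`"decreasing"`; commonality is need-inverted relative to prevalence, so
#' rarer diseases score higher). All anchors are configuration, never
#' constants: load an alternative rubric with [read_rubric_json()].
#'
#' Default numeric bands:
#' * Mortality (5-year, %): <1 / 1–10 / 10–30 / 30–60 / >=60
#' * Commonality (prevalence per 100,000, descending): >=500 / 50–500 /
#'   5–50 / 0.5–5 / <0.5
#' * Duration (years): <0.1 / 0.1–1 / 1–5 / 5–20 / >=20 or lifelong
#' * QALYs lost (fraction/year): <0.1 / 0.1–0.3 / 0.3–0.5 / 0.5–0.7 / >=0.7
#' * Frequency (doses/week): <0.25 / 0.25–1 / 1–7 / 7–21 / >=21
#'
#' @return A `rubric_config` named list, one entry per criterion.
#' @export
default_rubric <- function() {
  lv <- profile_levels()
  cat_map <- function(attribute) {
    list(type = "categorical", attribute = attribute,
         map = stats::setNames(1:5, lv[[attribute]]))
  }
  r <- list(
    "Commonality" = list(
      type = "numeric", attribute = "prevalence_per_100k",
      cuts = c(0.5, 5, 50, 500), direction = "decreasing",
      domain = c(0, 5000)
    ),
    "Duration" = list(
      type = "numeric", attribute = "typical_duration_years",
      cuts = c(0.1, 1, 5, 20), direction = "increasing",
      domain = c(0, 80)
    ),
    "QALYs lost" = list(
      type = "numeric", attribute = "qaly_loss_fraction",
      cuts = c(0.1, 0.3, 0.5, 0.7), direction = "increasing",
      domain = c(0, 1)
    ),
    "Mortality" = list(
      type = "numeric", attribute = "five_year_mortality_pct",
      cuts = c(1, 10, 30, 60), direction = "increasing",
      domain = c(0, 100)
    ),
    "Disease modification" = cat_map("soc_disease_modification"),
    "Adverse events" = cat_map("soc_adverse_event_burden"),
    "Route of administration" = cat_map("admin_route"),
    "Frequency of administration" = list(
      type = "numeric", attribute = "admin_doses_per_week",
      cuts = c(0.25, 1, 7, 21), direction = "increasing",
      domain = c(0, 56)
    ),
    "Cost to patients" = cat_map("annual_cost_band"),
    "Robust supply" = cat_map("supply_robustness"),
    "Regulatory barriers" = cat_map("regulatory_barrier")
  )
  structure(r, class = "rubric_config")
}

#' Check a rubric for gaps and overlaps
#'
#' An empty report means every criterion's map is total and single-valued
#' over its attribute domain: numeric criteria have exactly four strictly
#' increasing cut-points (so each score 1--5 has a non-empty band) and
#' categorical criteria map every admissible category to exactly one score
#' with every score reachable.
#'
#' @param rubric A `rubric_config`.
#' @param criteria Criterion set the rubric must cover.
#' @return Data frame with columns `criterion`, `kind` (`"gap"` or
#'   `"overlap"`), `detail`; zero rows when the rubric is total.
#' @export
rubric_coverage_check <- function(rubric, criteria = default_criteria()) {
  out <- list()
  note <- function(criterion, kind, detail) {
    out[[length(out) + 1L]] <<- data.frame(
      criterion = criterion, kind = kind, detail = detail,
      stringsAsFactors = FALSE
    )
  }
  for (cn in criteria$name) {
    entry <- rubric[[cn]]
    if (is.null(entry)) {
      note(cn, "gap", "criterion missing from rubric")
      next
    }
    if (identical(entry$type, "numeric")) {
      cuts <- entry$cuts
      if (length(cuts) < 4L) {
        note(cn, "gap", sprintf("only %d cut-point(s); score band(s) missing", length(cuts)))
      }
      if (length(cuts) > 4L) {
        note(cn, "overlap", "more than four cut-points: bands exceed the 1-5 scale")
      }
      if (length(cuts) >= 2L && any(diff(cuts) <= 0)) {
        note(cn, "overlap", "cut-points not strictly increasing")
      }
      dom <- entry$domain %||% c(-Inf, Inf)
      if (length(cuts) && (cuts[1L] <= dom[1L] || cuts[length(cuts)] >= dom[2L])) {
        note(cn, "gap", "cut-points leave an empty extreme band within the domain")
      }
    } else if (identical(entry$type, "categorical")) {
      map <- entry$map
      lv <- profile_levels()[[entry$attribute]]
      unmapped <- setdiff(lv, names(map))
      if (length(unmapped)) {
        note(cn, "gap", paste("unmapped level(s):", paste(unmapped, collapse = ", ")))
      }
      if (anyDuplicated(names(map))) {
        note(cn, "overlap", "level mapped more than once")
      }
      missing_scores <- setdiff(1:5, map)
      if (length(missing_scores)) {
        note(cn, "gap", paste("score(s) with no level:", paste(missing_scores, collapse = ", ")))
      }
      if (any(!map %in% 1:5)) {
        note(cn, "overlap", "map assigns a score outside 1-5")
      }
    } else {
      note(cn, "gap", "unknown rubric entry type")
    }
  }
  if (!length(out)) {
    return(data.frame(criterion = character(0), kind = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Extract the rubric attribute values for a set of profiles, deriving
# typical_duration_years from the stored value + unit.
rubric_attribute <- function(profiles, attribute) {
  if (attribute == "typical_duration_years") {
    return(duration_years(profiles$typical_duration_value,
                          profiles$typical_duration_unit))
  }
  if (!attribute %in% names(profiles)) {
    stop_umni("profiles lack attribute '", attribute, "'")
  }
  profiles[[attribute]]
}

score_one_criterion <- function(profiles, entry, criterion) {
  x <- rubric_attribute(profiles, entry$attribute)
  if (identical(entry$type, "numeric")) {
    dom <- entry$domain %||% c(-Inf, Inf)
    bad <- is.na(x) | x < dom[1L] | (is.finite(dom[2L]) & x > dom[2L] & !is.infinite(x))
    if (any(bad)) {
      stop_umni("attribute '", entry$attribute, "' value ", x[which(bad)[1L]],
                " outside rubric domain for criterion '", criterion, "'")
    }
    band <- findInterval(x, entry$cuts) + 1L # lower-inclusive, half-open
    if (identical(entry$direction, "decreasing")) band <- 6L - band
    band
  } else {
    s <- entry$map[x]
    if (any(is.na(s))) {
      stop_umni("attribute '", entry$attribute, "' value '", x[which(is.na(s))[1L]],
                "' outside rubric map for criterion '", criterion, "'")
    }
    unname(as.integer(s))
  }
}

#' Score a disease profile with a rubric
#'
#' Deterministically maps a structured disease attribute profile to eleven
#' integer criterion scores in 1--5 via the rubric's threshold tables.
#' `score_profiles()` is the vectorised form, producing a [score_matrix()]
#' for a profile table.
#'
#' @param profile A one-row `disease_profile`.
#' @param profiles A `disease_profile` data frame (one row per disease).
#' @param rubric A `rubric_config`; default [default_rubric()].
#' @param criteria Criterion set fixing output order.
#' @param rater Rater id attached to the resulting matrix.
#' @return `score_profile()`: named integer vector of length 11;
#'   `score_profiles()`: a `score_matrix`.
#' @export
score_profile <- function(profile, rubric = default_rubric(),
                          criteria = default_criteria()) {
  m <- score_profiles(profile, rubric, criteria)
  stats::setNames(as.integer(m[1L, ]), colnames(m))
}

#' @rdname score_profile
#' @export
score_profiles <- function(profiles, rubric = default_rubric(),
                           criteria = default_criteria(), rater = "rubric") {
  profiles <- validate_profiles(profiles)
  cov <- rubric_coverage_check(rubric, criteria)
  if (nrow(cov)) {
    stop_umni("rubric fails coverage check; first issue: ",
              cov$criterion[1L], " (", cov$detail[1L], ")")
  }
  scores <- vapply(
    criteria$name,
    function(cn) score_one_criterion(profiles, rubric[[cn]], cn),
    numeric(nrow(profiles))
  )
  if (nrow(profiles) == 1L) scores <- matrix(scores, nrow = 1L,
                                             dimnames = list(NULL, criteria$name))
  rownames(scores) <- profiles$disease_id
  score_matrix(scores, rater_id = rater)
}

#' Read and write rubric configurations as JSON
#'
#' @param path File path.
#' @param rubric A `rubric_config`.
#' @return `read_rubric_json()` returns a `rubric_config`;
#'   `write_rubric_json()` returns `path` invisibly.
#' @export
read_rubric_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- lapply(obj, function(e) {
    if (identical(e$type, "categorical")) {
      e$map <- stats::setNames(as.integer(unlist(e$map)), names(e$map))
    } else {
      e$cuts <- as.numeric(e$cuts)
      e$domain <- as.numeric(e$domain)
    }
    e
  })
  structure(r, class = "rubric_config")
}

#' @rdname read_rubric_json
#' @export
write_rubric_json <- function(rubric, path) {
  obj <- lapply(unclass(rubric), function(e) {
    if (identical(e$type, "categorical")) e$map <- as.list(e$map)
    e
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write disease profile tables as CSV
#'
#' Column dictionary: `disease_id`, `prevalence_per_100k`,
#' `typical_duration_value`, `typical_duration_unit`, `qaly_loss_fraction`,
#' `five_year_mortality_pct`, `soc_disease_modification`,
#' `soc_adverse_event_burden`, `admin_route`, `admin_doses_per_week`,
#' `annual_cost_band`, `supply_robustness`, `regulatory_barrier`.
#'
#' @param path File path.
#' @param profiles Profile data frame.
#' @return `read_profiles_csv()` returns a validated `disease_profile`
#'   data frame; `write_profiles_csv()` returns `path` invisibly.
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_profiles(df)
}

#' @rdname read_profiles_csv
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
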