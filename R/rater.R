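#' Default prompt templates for language-model raters
#'
#' The system template sets the rater's role (a medical doctor and
#' epidemiology professor prioritising diseases for research and
#' development), names the criterion being extracted, and constrains the
#' reply to a bare JSON object with the key `"response"`. The user template
#' asks for a single number from 1 to 5, spelling out the five score
#' anchors, the concept of interest, and the disease name (with synonyms
#' when configured), followed by optional classification guidance.
#'
#' @return A `prompt_spec` list with `system_template` and `user_template`.
#' @export
default_prompt_spec <- function() {
  structure(list(
    system_template = paste0(
      "You are a medical doctor and Professor of Epidemiology trying to ",
      "determine the unmet medical need for a disease. You wish to do this ",
      "to determine the priority of diseases for research and development.\n",
      "For each disease name, extract the following feature:\n",
      "\"{new_feature_name}: {feature_description}\".\n",
      "Return ONLY a JSON object with the key \"response\" and the ",
      "extracted values.\nNo explanations or other text."
    ),
    user_template = paste0(
      "Output only a number from 1 to 5; 1 = {anchor_1}, 2 = {anchor_2}, ",
      "3 = {anchor_3}, 4 = {anchor_4}, 5 = {anchor_5}. ",
      "Categorize the {concept} for disease {disease} into the above ",
      "categories. {guidance}"
    )
  ), class = "prompt_spec")
}

#' Score anchors for the default criteria
#'
#' Human-readable descriptions of what each score level 1--5 means per
#' criterion, phrased in the measurable units of the default rubric. Used
#' to fill the five anchor placeholders of the user prompt.
#'
#' @return Named list: criterion name -> character vector of length 5.
#' @export
default_score_anchors <- function() {
  list(
    "Commonality" = c(
      "common (prevalence 500 or more per 100,000)",
      "prevalence 50 to 500 per 100,000",
      "prevalence 5 to 50 per 100,000",
      "prevalence 0.5 to 5 per 100,000",
      "ultra-rare (prevalence below 0.5 per 100,000)"
    ),
    "Duration" = c(
      "illness shorter than about a month",
      "illness lasting months (under a year)",
      "illness lasting one to five years",
      "illness lasting five to twenty years",
      "lifelong illness"
    ),
    "QALYs lost" = c(
      "minimal QALY loss (under 10% per year of illness)",
      "QALY loss 10-30% per year",
      "QALY loss 30-50% per year",
      "QALY loss 50-70% per year",
      "severe QALY loss (70% or more per year)"
    ),
    "Mortality" = c(
      "5-year mortality below 1%",
      "5-year mortality 1-10%",
      "5-year mortality 10-30%",
      "5-year mortality 30-60%",
      "5-year mortality 60% or higher"
    ),
    "Disease modification" = c(
      "standard of care is curative",
      "standard of care substantially modifies the disease",
      "standard of care moderately modifies the disease",
      "standard of care only partially modifies the disease",
      "no disease-modifying standard of care"
    ),
    "Adverse events" = c(
      "no meaningful side effects", "mild side effects",
      "moderate side effects", "severe side effects",
      "intolerable side effects"
    ),
    "Route of administration" = c(
      "oral administration", "topical administration",
      "self-administered injection", "clinic-administered infusion",
      "implanted or continuously infused"
    ),
    "Frequency of administration" = c(
      "dosing monthly or less often", "dosing weekly to monthly",
      "dosing daily to weekly", "dosing one to three times daily",
      "dosing three or more times daily"
    ),
    "Cost to patients" = c(
      "minimal annual cost to patients", "low annual cost",
      "moderate annual cost", "high annual cost",
      "catastrophic annual cost"
    ),
    "Robust supply" = c(
      "robust supply chain", "mostly stable supply",
      "occasional shortages", "frequent shortages", "chronic shortages"
    ),
    "Regulatory barriers" = c(
      "no regulatory barriers to access", "minimal regulatory barriers",
      "moderate regulatory barriers", "high regulatory barriers",
      "prohibitive regulatory barriers"
    )
  )
}

render_template <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{", key, "}"), values[[key]], template, fixed = TRUE)
  }
  left <- regmatches(template, gregexpr("\\{[A-Za-z_0-9]+\\}", template))[[1L]]
  if (length(left)) {
    stop_umni("unresolved prompt placeholder: ", left[1L])
  }
  template
}

#' Assemble the rater prompt for one disease x criterion cell
#'
#' @param criterion Criterion name (a row of [default_criteria()]).
#' @param disease Either a disease label string or a one-row registry entry
#'   (list/data frame with `label` and optional `synonyms`).
#' @param spec A `prompt_spec`; default [default_prompt_spec()].
#' @param criteria Criterion set supplying the feature description.
#' @param anchors Five anchor strings; default looked up in
#'   [default_score_anchors()].
#' @param include_synonyms Append synonyms to the disease name as
#'   `"name (also known as: s1; s2)"`.
#' @param guidance Trailing classification guidance appended to the user
#'   prompt (used to correct systematic biases found during prompt
#'   development).
#' @return List with `system` and `user` strings, no unresolved
#'   placeholders.
#' @export
build_prompt <- function(criterion, disease, spec = default_prompt_spec(),
                         criteria = default_criteria(),
                         anchors = NULL, include_synonyms = TRUE,
                         guidance = "") {
  row <- criteria[criteria$name == criterion, ]
  if (!nrow(row)) stop_umni("unknown criterion: ", criterion)
  anchors <- anchors %||% default_score_anchors()[[criterion]]
  if (length(anchors) != 5L) stop_umni("need exactly five score anchors")
  if (is.character(disease)) {
    label <- disease
    synonyms <- character(0)
  } else {
    label <- disease$label
    synonyms <- unlist(disease$synonyms)
  }
  disease_txt <- label
  if (include_synonyms && length(synonyms)) {
    disease_txt <- paste0(label, " (also known as: ",
                          paste(synonyms, collapse = "; "), ")")
  }
  system <- render_template(spec$system_template, list(
    new_feature_name = criterion,
    feature_description = row$description
  ))
  user <- render_template(spec$user_template, list(
    anchor_1 = anchors[1L], anchor_2 = anchors[2L], anchor_3 = anchors[3L],
    anchor_4 = anchors[4L], anchor_5 = anchors[5L],
    concept = row$description, disease = disease_txt,
    guidance = guidance
  ))
  list(system = system, user = trimws(user))
}

#' Parse a structured rater reply
#'
#' A valid reply is a JSON object whose `"response"` value is — or cleanly
#' coerces to — an integer in \[1, 5\]. Integer-valued strings (`"4"`) and
#' integer-valued decimals (`3.0`) are accepted; true non-integers are
#' rejected. Failures are values consumed by the audit loop, never
#' exceptions.
#'
#' @param text Raw reply text.
#' @return List with `ok` (logical), `score` (integer or `NA`), and
#'   `failure` (`NA` or one of `"not-json"`, `"missing-key"`,
#'   `"noninteger"`, `"out-of-range"`).
#' @examples
#' parse_response('{"response": 3}')$score
#' parse_response("The score is 3")$failure
#' @export
parse_response <- function(text) {
  fail <- function(why) list(ok = FALSE, score = NA_integer_, failure = why)
  obj <- tryCatch(jsonlite::fromJSON(text), error = function(e) NULL)
  if (is.null(obj)) return(fail("not-json"))
  if (!is.list(obj) || is.null(obj[["response"]])) return(fail("missing-key"))
  v <- obj[["response"]]
  if (is.character(v) && length(v) == 1L) {
    v <- suppressWarnings(as.numeric(v))
  }
  if (!is.numeric(v) || length(v) != 1L || !is_wholenumber(v)) {
    return(fail("noninteger"))
  }
  if (v < 1 || v > 5) return(fail("out-of-range"))
  list(ok = TRUE, score = as.integer(round(v)), failure = NA_character_)
}

#' Serialize a score as a structured rater reply
#'
#' Inverse of [parse_response()] for valid scores: round-tripping any score
#' 1--5 through `serialize_response()` then [parse_response()] is the
#' identity.
#'
#' @param score Integer in 1--5.
#' @return JSON string `{"response": <score>}`.
#' @export
serialize_response <- function(score) {
  stopifnot(is_wholenumber(score), score >= 1, score <= 5)
  sprintf('{"response": %d}', as.integer(score))
}

#' Rater configuration
#'
#' @param model_name Identifier of the backing model or rater.
#' @param temperature Sampling temperature; the default 0 minimises
#'   sampling variability for near-deterministic outputs.
#' @param max_regenerations Maximum re-queries per failing cell in the
#'   audit loop (default 1: a single regeneration step).
#' @param seed Seed for the mock rater.
#' @param disagreement_rates Named numeric: probability of a +-1 and +-2
#'   point perturbation per cell (mock rater only), e.g.
#'   `c("1" = 0.2045, "2" = 0.0545)`. Probabilities must sum to <= 1.
#' @return A `rater_config` list.
#' @export
rater_config <- function(model_name = "offline", temperature = 0,
                         max_regenerations = 1L, seed = NULL,
                         disagreement_rates = c("1" = 0, "2" = 0)) {
  stopifnot(temperature >= 0, max_regenerations >= 0)
  if (sum(disagreement_rates) > 1 + 1e-12) {
    stop_umni("disagreement rates must sum to at most 1")
  }
  if (any(disagreement_rates < 0)) {
    stop_umni("disagreement rates must be non-negative")
  }
  structure(list(
    model_name = model_name, temperature = temperature,
    max_regenerations = as.integer(max_regenerations), seed = seed,
    disagreement_rates = disagreement_rates
  ), class = "rater_config")
}

#' Query a rater over a disease x criterion grid with output auditing
#'
#' Runs a rater callback over every cell, parses each reply with
#' [parse_response()], and re-queries failing cells up to
#' `config$max_regenerations` times (default: a single regeneration step
#' with the initial prompt parameters). Cells still failing afterwards are
#' left `NA` and flagged unresolved in the log; no cell is ever queried
#' more than `1 + max_regenerations` times.
#'
#' @param diseases Character vector of disease ids (or a registry, whose
#'   `id` column is used).
#' @param criteria Character vector of criterion names, or a criterion set.
#' @param rater Function `(disease_id, criterion) -> reply text`.
#' @param config A [rater_config()].
#' @return List with `scores` (a [score_matrix()], `NA` where unresolved),
#'   `log` (data frame: one row per query with `disease_id`, `criterion`,
#'   `attempt`, `status`, `reply`), and `complete` (logical).
#' @export
audit_and_regenerate <- function(diseases, criteria = default_criteria(),
                                 rater, config = rater_config()) {
  if (is.data.frame(diseases)) diseases <- diseases$id
  if (is.data.frame(criteria)) criteria <- criteria$name
  scores <- matrix(NA_real_, length(diseases), length(criteria),
                   dimnames = list(diseases, criteria))
  log <- list()
  for (d in diseases) {
    for (cn in criteria) {
      for (attempt in seq_len(1L + config$max_regenerations)) {
        reply <- rater(d, cn)
        parsed <- parse_response(reply)
        log[[length(log) + 1L]] <- data.frame(
          disease_id = d, criterion = cn, attempt = attempt,
          status = if (parsed$ok) "ok" else parsed$failure,
          reply = as.character(reply), stringsAsFactors = FALSE
        )
        if (parsed$ok) {
          scores[d, cn] <- parsed$score
          break
        }
      }
    }
  }
  log <- do.call(rbind, log)
  unresolved <- is.na(scores)
  if (any(unresolved)) {
    idx <- which(unresolved, arr.ind = TRUE)
    log <- rbind(log, data.frame(
      disease_id = rownames(scores)[idx[, 1L]],
      criterion = colnames(scores)[idx[, 2L]],
      attempt = NA_integer_, status = "unresolved", reply = NA_character_,
      stringsAsFactors = FALSE
    ))
  }
  list(
    scores = score_matrix(scores, rater_id = config$model_name),
    log = log,
    complete = !any(unresolved)
  )
}

#' Write an audit log as JSON lines
#'
#' @param log Audit log data frame from [audit_and_regenerate()].
#' @param path Output path; one JSON record per query.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Perturb a score matrix with a controlled-disagreement mock rater
#'
#' Emulates a second, imperfect rater: each cell is independently shifted
#' by +-1 point with probability `rates["1"]`, by +-2 points with
#' probability `rates["2"]` (sign uniform), and left unchanged otherwise.
#' Results are clamped to \[1, 5\] so the perturbed marginal stays on the
#' score scale — a deliberate deviation from unbounded noise. Reproducible
#' per seed; with all rates zero it is the identity.
#'
#' @param base A [score_matrix()] of true/base scores, no missing cells.
#' @param rates Named numeric perturbation probabilities by shift
#'   magnitude, summing to at most 1.
#' @param seed Integer seed.
#' @param rater Rater id for the perturbed matrix.
#' @return A `score_matrix` of the same shape as `base`.
#' @export
mock_rate <- function(base, rates = c("1" = 0.2045, "2" = 0.0545),
                      seed = NULL, rater = "mock") {
  stopifnot(is.matrix(base))
  if (anyNA(base)) stop_umni("mock_rate requires a complete base matrix")
  if (sum(rates) > 1 + 1e-12) stop_umni("disagreement rates must sum to at most 1")
  if (any(rates < 0)) stop_umni("disagreement rates must be non-negative")
  p1 <- unname(rates["1"]) %||% 0
  p2 <- unname(rates["2"]) %||% 0
  if (is.na(p1)) p1 <- 0
  if (is.na(p2)) p2 <- 0
  n <- length(base)
  with_seed(seed, {
    u <- stats::runif(n)
    sign <- sample(c(-1, 1), n, replace = TRUE)
    shift <- ifelse(u < p1, 1, ifelse(u < p1 + p2, 2, 0))
    out <- pmin(pmax(as.numeric(base) + shift * sign, 1), 5)
    perturbed <- matrix(out, nrow(base), ncol(base), dimnames = dimnames(base))
    score_matrix(perturbed, rater_id = rater)
  })
}

#' Offline rater callbacks
#'
#' Factories producing rater functions for [audit_and_regenerate()] without
#' any network access. `make_matrix_rater()` replies from a precomputed
#' score matrix (e.g. rubric scores or a mock-perturbed matrix) serialized
#' as valid JSON; `make_fixture_rater()` replies from a recorded table of
#' raw reply strings, standing in for a live language-model adapter
#' (`send(system, user) -> text`) in tests.
#'
#' @param m A complete [score_matrix()].
#' @param replies Data frame with columns `disease_id`, `criterion`,
#'   `reply` (raw text); repeated rows for a cell are returned in order
#'   across retries, the last being repeated thereafter.
#' @return A function `(disease_id, criterion) -> reply text`.
#' @export
make_matrix_rater <- function(m) {
  force(m)
  function(disease_id, criterion) serialize_response(m[disease_id, criterion])
}

#' @rdname make_matrix_rater
#' @export
make_fixture_rater <- function(replies) {
  force(replies)
  seen <- new.env(parent = emptyenv())
  function(disease_id, criterion) {
    key <- paste(disease_id, criterion, sep = "\r")
    rows <- which(replies$disease_id == disease_id & replies$criterion == criterion)
    if (!length(rows)) stop_umni("fixture rater has no reply for ", disease_id, " / ", criterion)
    k <- (seen[[key]] %||% 0L) + 1L
    assign(key, k, envir = seen)
    replies$reply[rows[min(k, length(rows))]]
  }
}
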