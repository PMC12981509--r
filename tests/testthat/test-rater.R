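test_that("prompts carry the role preamble, anchors, and disease synonyms", {
  disease <- list(label = "multiple system atrophy",
                  synonyms = list(c("MSA", "Shy-Drager syndrome")))
  p <- build_prompt("Mortality", disease)
  expect_match(p$system, "You are a medical doctor and Professor of Epidemiology",
               fixed = TRUE)
  expect_match(p$system, "\"response\"", fixed = TRUE)
  expect_match(p$user, "^Output only a number from 1 to 5")
  for (anchor in default_score_anchors()[["Mortality"]]) {
    expect_match(p$user, anchor, fixed = TRUE)
  }
  expect_equal(lengths(regmatches(p$user, gregexpr("MSA", p$user))), 1L)
  expect_match(p$user, "also known as: MSA; Shy-Drager syndrome", fixed = TRUE)

  bare <- build_prompt("Mortality", "common wart")
  expect_false(grepl("also known as", bare$user))
})

test_that("unresolved placeholders are reported by name", {
  spec <- default_prompt_spec()
  spec$user_template <- paste(spec$user_template, "{mystery_slot}")
  expect_error(build_prompt("Mortality", "stroke", spec = spec),
               "mystery_slot")
})

test_that("response parsing accepts clean coercions and types failures", {
  expect_equal(parse_response('{"response": 3}')$score, 3L)
  expect_equal(parse_response('{"response": "4"}')$score, 4L)
  expect_equal(parse_response('{"response": 3.0}')$score, 3L)
  expect_equal(parse_response("The score is 3")$failure, "not-json")
  expect_equal(parse_response('{"score": 3}')$failure, "missing-key")
  expect_equal(parse_response('{"response": 3.5}')$failure, "noninteger")
  expect_equal(parse_response('{"response": "high"}')$failure, "noninteger")
  expect_equal(parse_response('{"response": 7}')$failure, "out-of-range")
  for (s in 1:5) {
    expect_equal(parse_response(serialize_response(s))$score, s)
  }
})

test_that("audit loop retries each failing cell at most max_regenerations times", {
  diseases <- sprintf("MONDO:%07d", 9000001:9000002)
  crits <- c("Mortality", "Duration")

  ok <- audit_and_regenerate(diseases, crits, function(d, cn) '{"response": 2}')
  expect_true(ok$complete)
  expect_true(all(ok$log$attempt == 1L))
  expect_true(all(ok$log$status == "ok"))
  expect_equal(unclass(ok$scores)[, ], matrix(2, 2, 2, dimnames = list(diseases, crits))[, ])

  # fails on first attempt for one cell, then succeeds
  calls <- new.env(); calls$n <- 0L
  flaky <- function(d, cn) {
    if (d == diseases[1] && cn == "Mortality") {
      calls$n <- calls$n + 1L
      if (calls$n == 1L) return("garbled")
    }
    '{"response": 4}'
  }
  res <- audit_and_regenerate(diseases, crits, flaky)
  expect_true(res$complete)
  cell_log <- res$log[res$log$disease_id == diseases[1] &
                        res$log$criterion == "Mortality", ]
  expect_equal(cell_log$attempt, c(1L, 2L))
  expect_equal(cell_log$status, c("not-json", "ok"))

  # always fails on one cell -> unresolved after one regeneration
  stubborn <- function(d, cn) {
    if (d == diseases[2] && cn == "Duration") "no" else '{"response": 1}'
  }
  res2 <- audit_and_regenerate(diseases, crits, stubborn,
                               config = rater_config(max_regenerations = 1L))
  expect_false(res2$complete)
  expect_true(is.na(res2$scores[diseases[2], "Duration"]))
  bad_log <- res2$log[res2$log$disease_id == diseases[2] &
                        res2$log$criterion == "Duration", ]
  expect_equal(sum(!is.na(bad_log$attempt)), 2L) # 1 + max_regenerations
  expect_true("unresolved" %in% bad_log$status)
})

test_that("fixture rater replays recorded replies across retries", {
  replies <- data.frame(
    disease_id = rep("MONDO:9000001", 2), criterion = rep("Mortality", 2),
    reply = c("garbled", '{"response": 5}'), stringsAsFactors = FALSE
  )
  rater <- make_fixture_rater(replies)
  res <- audit_and_regenerate("MONDO:9000001", "Mortality", rater)
  expect_true(res$complete)
  expect_equal(unname(res$scores[1, 1]), 5)
})

test_that("mock rater is the identity at zero rates and seed-reproducible", {
  base <- gen_rater_pair(20, seed = 5)$expert
  same <- mock_rate(base, rates = c("1" = 0, "2" = 0), seed = 9)
  expect_equal(unclass(same)[, ], unclass(base)[, ])

  a <- mock_rate(base, seed = 31)
  b <- mock_rate(base, seed = 31)
  expect_identical(unclass(a)[, ], unclass(b)[, ])
  c <- mock_rate(base, seed = 32)
  expect_false(identical(unclass(a)[, ], unclass(c)[, ]))
})

test_that("mock perturbations are clamped to the score scale", {
  top <- flat_scores(30, fill = 5)
  shifted <- mock_rate(top, rates = c("1" = 1), seed = 3)
  expect_true(all(shifted >= 1 & shifted <= 5))
  expect_true(all(shifted %in% c(4, 5))) # +1 clamps at 5, -1 lands on 4

  bottom <- flat_scores(30, fill = 1)
  shifted2 <- mock_rate(bottom, rates = c("2" = 1), seed = 3)
  expect_true(all(shifted2 %in% c(1, 3)))
})

test_that("invalid disagreement configurations are rejected", {
  expect_error(rater_config(disagreement_rates = c("1" = 0.8, "2" = 0.4)),
               "at most 1")
  expect_error(mock_rate(flat_scores(2), rates = c("1" = 0.9, "2" = 0.2)),
               "at most 1")
  expect_error(mock_rate(flat_scores(2), rates = c("1" = -0.1)))
})
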