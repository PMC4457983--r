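toy_rules <- function() {
  list(
    parameters = list(
      equality_tolerance = list(value = 0.5),
      P_kitchen = list(value = "kitchen"),
      P_occ = list(value = 0.5),
      P_temp_slope = list(value = 0.03),
      P_zero = list(value = 0)
    ),
    rules = list(
      list(id = "presence", level = "likely", priority = 1,
           conclusion = list(fact = "kitchen_occupied"),
           when = list(list(summary = "room", op = "=", param = "P_kitchen"),
                       list(summary = "mean", channel = "pir", op = ">",
                            param = "P_occ"))),
      list(id = "cooking", level = "must", priority = 9,
           conclusion = list(adl = "cooking"),
           when = list(list(fact = "kitchen_occupied"),
                       list(summary = "slope", channel = "temperature",
                            op = ">", param = "P_temp_slope")))
    )
  )
}

cooking_segment <- function() {
  n <- 361 # 30 min
  fixture_segment(
    list(temperature = 21 + seq(0, 3, length.out = n), pir = rep(1, n)),
    room = "kitchen", node_id = 1L
  )
}

test_that("parser builds a resolved lookup table and reports errors", {
  empty <- parse_rules(list())
  expect_s3_class(empty, "rule_table")
  expect_length(empty$rules, 0)

  cfg <- toy_rules()
  tab <- parse_rules(cfg)
  expect_length(tab$rules, 2)
  expect_equal(tab$by_conclusion$cooking, "cooking")
  expect_true("temperature" %in% names(tab$by_channel))

  bad <- cfg
  bad$rules[[2]]$when[[2]]$param <- "P_x"
  expect_error(parse_rules(bad), "P_x")

  dup <- cfg
  dup$rules[[2]]$id <- "presence"
  expect_error(parse_rules(dup), "duplicate")

  badop <- cfg
  badop$rules[[1]]$when[[1]]$op <- "~"
  expect_error(parse_rules(badop), "comparator")

  nopred <- cfg
  nopred$rules[[1]]$when <- list()
  expect_error(parse_rules(nopred), "predicates")
})

test_that("the shipped repository has a must-level rule for every ADL", {
  tab <- parse_rules(default_rules_file())
  for (adl in adl_levels()) {
    ids <- tab$by_conclusion[[adl]]
    expect_true(length(ids) >= 1, label = paste("rules for", adl))
    lev <- vapply(ids, function(id) tab$rules[[id]]$level, character(1))
    expect_true(any(lev == "must"), label = paste("must rule for", adl))
  }
  expect_true(!is.null(tab$adl_windows))
})

test_that("rule evaluation is a conjunction over segment summaries", {
  tab <- parse_rules(toy_rules())
  srow <- as.list(segment_summaries(list(cooking_segment()))[1, ])
  bed <- cooking_segment(); bed$room <- "bedroom"
  brow <- as.list(segment_summaries(list(bed))[1, ])

  room_rule <- tab$rules$presence
  expect_true(evaluate_rule(room_rule, srow, tab))
  expect_false(evaluate_rule(room_rule, brow, tab)) # cooking room only

  # tautological predicates hold on any segment
  taut <- list(id = "t", level = "must", priority = 1,
               conclusion = list(adl = "cooking"),
               when = list(list(summary = "duration", op = ">=",
                                param = "P_zero")))
  expect_true(evaluate_rule(taut, srow, parse_rules(toy_rules())))
  expect_true(evaluate_rule(taut, brow, parse_rules(toy_rules())))

  # humidity-rise predicate on a rising vs a flat segment
  slope_rule <- list(id = "s", level = "must", priority = 1,
                     conclusion = list(adl = "grooming"),
                     when = list(list(summary = "slope",
                                      channel = "humidity", op = ">",
                                      param = "P_temp_slope")))
  rising <- fixture_segment(list(humidity = seq(8, 12, length.out = 121),
                                 pir = rep(1, 121)))
  flat <- fixture_segment(list(humidity = rep(8, 121),
                               pir = rep(1, 121)))
  expect_true(evaluate_rule(slope_rule,
                            as.list(segment_summaries(list(rising))[1, ]),
                            tab))
  expect_false(evaluate_rule(slope_rule,
                             as.list(segment_summaries(list(flat))[1, ]),
                             tab))
})

test_that("forward chaining derives facts then conclusions, and halts", {
  tab <- parse_rules(toy_rules())
  summ <- segment_summaries(list(cooking_segment()))

  res <- forward_chain(summ, tab, subject = 1)
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$adl, "cooking")
  # the two-step chain needs the derived fact before the ADL rule can fire
  expect_true("kitchen_occupied" %in% res$facts[[1]])
  expect_true("adl:cooking" %in% res$facts[[1]])
  # quiescence well below the cap
  expect_lte(res$iterations, length(tab$rules) + 1)

  # no rules, no events
  none <- forward_chain(summ, parse_rules(list()))
  expect_equal(nrow(none$events), 0)

  # determinism
  res2 <- forward_chain(summ, tab, subject = 1)
  expect_identical(res$events, res2$events)
})

test_that("conflict resolution prefers the higher-priority rule", {
  cfg <- toy_rules()
  cfg$rules <- c(cfg$rules[1], list(
    list(id = "a_low", level = "must", priority = 5,
         conclusion = list(adl = "eating"),
         when = list(list(fact = "kitchen_occupied"))),
    list(id = "b_high", level = "must", priority = 9,
         conclusion = list(adl = "cooking"),
         when = list(list(fact = "kitchen_occupied")))
  ))
  tab <- parse_rules(cfg)
  summ <- segment_summaries(list(cooking_segment()))
  res <- forward_chain(summ, tab)
  expect_equal(res$events$adl, "cooking")
  expect_equal(res$events$rule_id, "b_high")

  # must-level beats likely even at lower priority
  cfg$rules[[2]]$level <- "likely"
  cfg$rules[[2]]$priority <- 99L
  res2 <- forward_chain(summ, parse_rules(cfg))
  expect_equal(res2$events$adl, "cooking")
})

test_that("the iteration cap yields a warning and a partial result", {
  tab <- parse_rules(toy_rules())
  summ <- segment_summaries(list(cooking_segment()))
  expect_warning(forward_chain(summ, tab, max_iterations = 1),
                 "max_iterations")
})
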