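test_that("log merging fuses same-ADL overlaps and resolves conflicts in
           the device log's favour", {
  dev <- fixture_events("cooking", 10 * 3600, 10.5 * 3600)
  pap <- fixture_events("cooking", 10 * 3600 + 1200, 10 * 3600 + 2400)

  ident <- merge_logs(dev, dev)
  expect_equal(nrow(ident$events), 1)
  expect_equal(ident$events$start, dev$start)
  expect_equal(ident$events$end, dev$end)

  m <- merge_logs(dev, pap)
  expect_equal(nrow(m$events), 1)
  expect_equal(as.numeric(m$events$end - m$events$start, units = "secs"),
               2400) # envelope 10:00-10:40
  expect_equal(m$conflicts, 0L)

  pap2 <- fixture_events("eating", 10 * 3600, 10.5 * 3600)
  m2 <- merge_logs(dev, pap2)
  expect_equal(m2$events$adl, "cooking")
  expect_equal(m2$conflicts, 1L)
})

test_that("the false-positive threshold removes strictly-shorter events", {
  ev <- rbind(fixture_events("toileting", 0, 19),
              fixture_events("toileting", 100, 120),
              fixture_events("toileting", 200, 260))
  out <- threshold_filter(ev)
  expect_equal(nrow(out), 2) # 19 s removed, 20 s boundary kept
  expect_equal(as.numeric(out$end - out$start, units = "secs"), c(20, 60))
  expect_equal(nrow(threshold_filter(ev[0, ])), 0)

  # monotonicity: a larger threshold never keeps more events
  n20 <- nrow(threshold_filter(ev, 20))
  n30 <- nrow(threshold_filter(ev, 30))
  n100 <- nrow(threshold_filter(ev, 100))
  expect_true(n20 >= n30 && n30 >= n100)
})

test_that("epoch confusion metrics match a direct counting oracle", {
  t0 <- origin_utc()
  # truth: 10 positive epochs of 90+10; prediction: 8 TP + 5 FP
  truth <- fixture_events("cooking", 0, 50)            # epochs 1..10
  pred <- rbind(fixture_events("cooking", 10, 50),     # 8 TP
                fixture_events("cooking", 100, 125))   # 5 FP
  cm <- confusion_metrics(pred, truth, span_start = t0,
                          span_end = t0 + 500) # 100 epochs
  row <- cm$per_adl[cm$per_adl$adl == "cooking", ]
  expect_equal(row$tp, 8); expect_equal(row$fp, 5)
  expect_equal(row$fn, 2); expect_equal(row$tn, 85)
  expect_equal(row$sensitivity, 80)
  expect_equal(row$specificity, 100 * 85 / 90, tolerance = 1e-9)

  perfect <- confusion_metrics(truth, truth, span_start = t0,
                               span_end = t0 + 500)
  prow <- perfect$per_adl[perfect$per_adl$adl == "cooking", ]
  expect_equal(prow$sensitivity, 100)
  expect_equal(prow$specificity, 100)
  # a never-true ADL has undefined sensitivity, reported as such
  expect_true(is.na(perfect$per_adl$sensitivity[
    perfect$per_adl$adl == "eating"]))
})

test_that("macro mean is the unweighted average and equals a common value
           under equality", {
  expect_equal(macro_mean(rep(93.5, 8)), 93.5)
  expect_equal(macro_mean(c(80, 100)), 90)
  expect_equal(macro_mean(c(80, NA, 100)), 90)
})

test_that("event-level outcomes use the half-overlap matching rule", {
  truth <- rbind(fixture_events("cooking", 0, 600),
                 fixture_events("eating", 1000, 1600))
  # covers 60% of cooking, 0% of eating
  pred <- fixture_events("cooking", 240, 700)
  oc <- count_outcomes(pred, truth)
  expect_equal(oc$total, 2)
  expect_equal(oc$correct, 1)
  expect_equal(oc$missed, 1)
  # covering only 40% does not count
  oc2 <- count_outcomes(fixture_events("cooking", 360, 700), truth)
  expect_equal(oc2$correct, 0)
  oc3 <- count_outcomes(truth, truth)
  expect_equal(oc3$missed, 0)
})

test_that("leave-one-out folds exclude the test subject and the guard
           catches leakage", {
  set.seed(51)
  dat <- data.table::data.table(
    subject = rep(1:10, each = 20),
    label = rep(rep(c("a", "b"), each = 10), 10),
    f1 = rnorm(200), f2 = rnorm(200)
  )
  dat$f1 <- dat$f1 + ifelse(dat$label == "a", 0, 3)
  res <- loo_cv(dat, nb_train, nb_predict)
  expect_equal(length(unique(res$fold)), 10)
  expect_equal(nrow(res), 200)
  # each fold predicts exactly its held-out subject
  expect_true(all(tapply(res$subject, res$fold,
                         function(s) length(unique(s))) == 1))

  two <- loo_cv(dat[dat$subject <= 2], nb_train, nb_predict)
  expect_equal(length(unique(two$fold)), 2)

  bad_folds <- list(list(train = 1:10, test = 1))
  expect_error(loo_cv(dat, nb_train, nb_predict, folds = bad_folds),
               "leakage")
  expect_error(loo_cv(dat[dat$subject == 1], nb_train, nb_predict),
               ">= 2 subjects")
})

test_that("activity maps are deterministic grids that differ exactly where
           labels differ", {
  ev <- rbind(
    fixture_events("sleeping", 0, 6 * 3600, room = "bedroom"),
    fixture_events("sleeping", 86400, 86400 + 6 * 3600, room = "bedroom"),
    fixture_events("cooking", 11 * 3600, 12 * 3600),
    fixture_events("cooking", 86400 + 11 * 3600, 86400 + 12 * 3600)
  )
  m <- activity_map(ev, n_days = 2)
  expect_equal(dim(m), c(2, 288))
  expect_identical(m[1, ], m[2, ]) # identical daily routine

  blank <- activity_map(ev[0, ], n_days = 2)
  expect_true(all(blank == "none"))

  ev2 <- data.table::copy(ev)
  ev2$adl[3:4] <- "eating"
  m2 <- activity_map(ev2, n_days = 2,
                     origin = attr(m, "origin"))
  diff_cells <- which(unclass(m) != unclass(m2))
  expect_true(all(m[diff_cells] == "cooking" & m2[diff_cells] == "eating"))
  expect_equal(length(diff_cells), 2 * 12) # one hour of 5-min cells per day

  path <- withr::local_tempfile(fileext = ".txt")
  write_activity_map(m, path)
  lines <- readLines(path)
  expect_equal(nchar(lines), c(288, 288))
  expect_identical(lines[1], lines[2])
})

test_that("event logs round-trip through the delimited text format", {
  ev <- rbind(fixture_events("cooking", 0, 600),
              fixture_events("sleeping", 82800, 108000, room = "bedroom"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$adl, ev$adl)
  expect_equal(as.numeric(back$start), as.numeric(ev$start))
  expect_equal(as.numeric(back$end), as.numeric(ev$end))
})
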