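test_that("z-transform standardizes with the sample SD and flags
           degenerate channels", {
  seg <- fixture_segment(list(humidity = c(0, 2), pir = c(5, 5)))
  std <- ztransform(seg)
  # mean 1, sample SD (n-1) = sqrt(2); |(-1)|/sqrt(2) twice... with [0,2]:
  # mean 1, SD sqrt(((0-1)^2+(2-1)^2)/1) = sqrt(2)
  expect_equal(unname(std$samples["humidity", ]),
               c(1, 1) / sqrt(2))
  expect_equal(unname(std$samples["pir", ]), c(0, 0))
  expect_true(std$sd_zero[["pir"]])
  expect_false(std$sd_zero[["humidity"]])

  seg3 <- fixture_segment(list(temperature = c(5, 5, 5)))
  expect_equal(unname(ztransform(seg3)$samples["temperature", ]),
               c(0, 0, 0))

  one <- fixture_segment(list(pir = 1))
  expect_error(ztransform(one), "length")
})

test_that("z-transform is invariant under positive affine rescaling", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(50)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 100)
    s1 <- ztransform(fixture_segment(list(temperature = x)))
    s2 <- ztransform(fixture_segment(list(temperature = a * x + b)))
    expect_equal(s1$samples["temperature", ], s2$samples["temperature", ],
                 tolerance = 1e-10)
  }
})

test_that("emphasis is the temporal centroid", {
  e1 <- emphasis(fixture_segment(list(pir = c(0, 0, 1, 0))))
  expect_equal(unname(e1["pir"]), 2)

  e2 <- emphasis(fixture_segment(list(pir = c(1, 2, 1))))
  expect_equal(unname(e2["pir"]), 1)

  e3 <- emphasis(fixture_segment(list(pir = c(1, 3))))
  expect_equal(unname(e3["pir"]), 0.75)

  ez <- emphasis(fixture_segment(list(pir = c(0, 0, 0))))
  expect_true(is.na(ez["pir"]))
  expect_false(attr(ez, "defined")[["pir"]])

  # centroid bounded by the segment extent for non-negative signals
  set.seed(8)
  for (i in 1:5) {
    v <- abs(rnorm(20))
    e <- emphasis(fixture_segment(list(pir = v)))
    expect_gte(unname(e["pir"]), 0)
    expect_lte(unname(e["pir"]), 19)
  }
})

test_that("emphasis clock time shifts with the segment (equivariance)", {
  v <- c(0, 1, 3, 1, 0)
  s1 <- fixture_segment(list(pir = v), t0 = origin_utc(time = "08:00:00"))
  s2 <- fixture_segment(list(pir = v), t0 = origin_utc(time = "09:30:00"))
  c1 <- adlsense:::emphasis_clock_h(s1, emphasis(s1))
  c2 <- adlsense:::emphasis_clock_h(s2, emphasis(s2))
  expect_equal(c2 - c1, 1.5, tolerance = 1e-9)
})

test_that("behavioural windows gate pattern candidacy", {
  tab <- parse_rules(default_rules_file())
  win <- tab$adl_windows

  # 2 s segment can never reach a 5 min duration window
  tiny <- fixture_segment(list(pir = c(1, 1)),
                          t0 = origin_utc(time = "07:30:00"))
  expect_false(as.logical(match_behavior(tiny, win)))

  groom <- fixture_segment(
    list(humidity = seq(8, 12, length.out = 181), pir = rep(1, 181)),
    t0 = origin_utc(time = "07:30:00"), room = "bathroom"
  )
  flag <- match_behavior(groom, win)
  expect_true(as.logical(flag))
  expect_true("grooming" %in% attr(flag, "candidates"))

  expect_false(as.logical(match_behavior(groom, list())))
})

test_that("map building separates rooms and keeps singletons", {
  mk_candidate <- function(room, t0) {
    seg <- fixture_segment(list(pir = rep(1, 121),
                                humidity = seq(8, 10, length.out = 121)),
                           t0 = t0, room = room)
    std <- ztransform(seg)
    emp <- emphasis(std)
    list(segment = seg, std = std, emphasis = emp,
         clock_h = adlsense:::emphasis_clock_h(seg, emp),
         profile = adlsense:::resample_profile(std$samples, 64),
         duration_min = 10.083, candidates = "toileting")
  }
  a <- mk_candidate("bathroom", origin_utc(time = "13:00:00"))
  b <- mk_candidate("kitchen", origin_utc(time = "13:00:00"))
  maps <- build_car_map(list(a, b))
  expect_length(maps, 2) # same time, same shape, different rooms

  expect_length(build_car_map(list(a)), 1)
  expect_length(build_car_map(list(a))[[1]]$members, 1)

  # identical recurring pattern on consecutive days joins one map
  a2 <- mk_candidate("bathroom",
                     origin_utc(day = "2015-01-06", time = "13:10:00"))
  maps2 <- build_car_map(list(a, a2))
  expect_length(maps2, 1)
  expect_length(maps2[[1]]$members, 2)
})

test_that("the Gaussian broad-band kernel matches its closed form and
           conserves mass", {
  w <- gaussian_kernel(1)
  off <- attr(w, "offsets")
  expect_equal(w[off == 0], 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(w[off == 1], exp(-1 / 2) / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(sum(gaussian_kernel(2, normalized = TRUE)), 1)

  # constant profile is unchanged (unit-sum kernel, edge renormalized)
  expect_equal(gaussian_filter(rep(3.5, 40), sd = 2), rep(3.5, 40))

  # impulse reproduces a symmetric, unimodal kernel shape
  n <- 41
  imp <- numeric(n); imp[21] <- 1
  sm <- gaussian_filter(imp, sd = 1.5)
  expect_equal(sm[21 - (1:5)], sm[21 + (1:5)], tolerance = 1e-12)
  expect_true(all(diff(sm[1:21]) >= 0) && all(diff(sm[21:n]) <= 0))
  expect_error(gaussian_filter(imp, sd = 0))
})

test_that("maps are allotted ADL by occurrence time and relative duration", {
  tab <- parse_rules(default_rules_file())
  mk_map <- function(room, clock_h, dur_min, id) {
    structure(list(id = id, room = room,
                   members = list(list(segment = fixture_segment(
                     list(pir = rep(1, 10)), room = room),
                     duration_min = dur_min, clock_h = clock_h)),
                   profile = matrix(0, 8, 64), clock_h = clock_h,
                   duration_min = dur_min), class = "car_map")
  }
  night_bed <- mk_map("bedroom", 2.4, 7 * 60, 1L)
  noon_bath <- mk_map("bathroom", 13.4, 10, 2L)
  res <- assign_adl(list(night_bed, noon_bath), tab$adl_windows,
                    subject = 1)
  lab <- vapply(res$maps, `[[`, character(1), "adl")
  expect_equal(lab, c("sleeping", "toileting"))

  # a map outside every window stays unlabeled and emits nothing
  off <- mk_map("balcony", 3, 10, 3L)
  res2 <- assign_adl(list(off), tab$adl_windows)
  expect_equal(nrow(res2$events), 0)
  expect_equal(res2$unlabeled, 3L)
})
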