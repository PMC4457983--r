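#' Standardize a segment (absolute z-transform)
#'
#' Per channel, replaces the values by `|(x - mean) / SD|` with the sample
#' SD (n - 1) taken over that segment's channel. A zero-variance channel is
#' mapped to all zeros and flagged. The absolute z-shape is what the rhythm
#' classifier compares across days: it is invariant under positive affine
#' rescaling of the raw channel, removing inter-subject level differences.
#'
#' @param segment An `adl_segment` (length >= 2 samples).
#' @return A `std_segment`: the segment with standardized `samples` and
#'   stored `channel_mean`, `channel_sd`, `sd_zero` flags.
#' @export
ztransform <- function(segment) {
  if (ncol(segment$samples) < 2) {
    stop("ztransform needs a segment of length >= 2")
  }
  m <- segment$samples
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  z <- m
  for (i in seq_len(nrow(m))) {
    z[i, ] <- if (sdv[i] == 0) 0 else abs((m[i, ] - mu[i]) / sdv[i])
  }
  out <- segment
  out$samples <- z
  out$channel_mean <- mu
  out$channel_sd <- sdv
  out$sd_zero <- sdv == 0
  class(out) <- c("std_segment", "adl_segment")
  out
}

#' Temporal emphasis (centroid) of a segment
#'
#' Per channel, the centroid `sum(t * s_t) / sum(s_t)` with `t` the offset
#' from the segment start in samples: the point in time where the channel's
#' signal mass concentrates, used to locate a pattern within its segment
#' and align occurrences across days. Undefined (NA, flagged) for an
#' all-zero channel, which cannot anchor a pattern.
#'
#' @param segment A (typically standardized) segment.
#' @return An `adl_emphasis` object: named numeric vector of per-channel
#'   centroids in sample offsets, with attributes `defined` (logical per
#'   channel) and `t_start`.
#' @export
emphasis <- function(segment) {
  m <- segment$samples
  t_off <- seq_len(ncol(m)) - 1
  tot <- rowSums(m)
  cen <- ifelse(tot > 0, as.numeric(m %*% t_off) / tot, NA_real_)
  names(cen) <- rownames(m)
  structure(cen, defined = tot > 0, t_start = segment$t_start,
            class = "adl_emphasis")
}

# absolute clock time (decimal hours) of the segment's emphasis, taken on
# the PIR channel (occupancy) with fallback to the mean of defined channels
emphasis_clock_h <- function(segment, emp) {
  cen <- if (!is.na(emp["pir"])) emp[["pir"]]
         else mean(emp[attr(emp, "defined")], na.rm = TRUE)
  if (is.na(cen)) cen <- (ncol(segment$samples) - 1) / 2
  tnum <- as.numeric(segment$t_start) + cen * 5
  (tnum %% 86400) / 3600
}

circ_diff_h <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

circ_mean_h <- function(h) {
  ang <- h / 24 * 2 * pi
  (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * 24) %% 24
}

#' Match a segment's emphasis against the behavioural parameter windows
#'
#' A segment is a potential ADL pattern iff its room, duration and emphasis
#' clock time fall inside the parameter windows of at least one ADL; an ADL
#' window may additionally constrain the relative emphasis position within
#' the segment on a named channel. The candidate ADL list is attached.
#'
#' @param segment An `adl_segment`.
#' @param emp Its [emphasis()] (computed if missing).
#' @param windows ADL parameter windows (the `adl_windows` element of a
#'   parsed rule table).
#' @return Logical flag; attribute `candidates` holds the matching ADLs.
#' @export
match_behavior <- function(segment, windows, emp = NULL) {
  if (is.null(windows) || length(windows) == 0) {
    return(structure(FALSE, candidates = character(0)))
  }
  if (is.null(emp)) emp <- emphasis(segment)
  dur_min <- (as.numeric(segment$t_end) - as.numeric(segment$t_start) + 5) / 60
  clock <- emphasis_clock_h(segment, emp)
  cand <- character(0)
  for (adl in names(windows)) {
    w <- windows[[adl]]
    if (!(segment$room %in% unlist(w$rooms))) next
    if (dur_min < w$duration_min[[1]] || dur_min > w$duration_min[[2]]) next
    if (!is.null(w$clock_center_h) &&
        circ_diff_h(clock, w$clock_center_h) > w$clock_halfwidth_h) next
    if (!is.null(w$emphasis_channel)) {
      rel <- emp[[w$emphasis_channel]] / max(1, ncol(segment$samples) - 1)
      if (is.na(rel) || rel < w$emphasis_rel[[1]] ||
          rel > w$emphasis_rel[[2]]) next
    }
    cand <- c(cand, adl)
  }
  structure(length(cand) > 0, candidates = cand)
}

resample_profile <- function(samples, n_points = 64) {
  nc <- ncol(samples)
  if (nc == 1) {
    return(matrix(samples[, 1], nrow = nrow(samples), ncol = n_points,
                  dimnames = list(rownames(samples), NULL)))
  }
  xout <- seq(0, 1, length.out = n_points)
  xin <- seq(0, 1, length.out = nc)
  out <- matrix(0, nrow = nrow(samples), ncol = n_points,
                dimnames = list(rownames(samples), NULL))
  for (i in seq_len(nrow(samples))) {
    out[i, ] <- stats::approx(xin, samples[i, ], xout = xout)$y
  }
  out
}

profile_distance <- function(a, b) sqrt(mean((a - b)^2))

#' Group recurring similar segments across days into CAR maps
#'
#' Greedy agglomeration of candidate segments into circadian activity
#' pattern maps: a candidate joins the closest existing map that (a) lives
#' in the same room, (b) whose emphasis clock time of day is within
#' `clock_window_min`, and (c) whose representative standardized profile is
#' within `profile_threshold` (root-mean-square distance on profiles
#' resampled to `n_points`); otherwise it founds a new map. Every candidate
#' ends up in exactly one map.
#'
#' @param candidates List of candidate entries as built by [car_classify()]:
#'   each a list with `segment`, `std`, `emphasis`, `clock_h`, `profile`,
#'   `duration_min`, `candidates`.
#' @param clock_window_min Clock-time window (minutes, default 60).
#' @param profile_threshold Profile distance threshold (default 0.5).
#' @return List of `car_map` objects: `id`, `room`, `members` (candidate
#'   entries), `profile` (mean member profile), `clock_h`, `duration_min`
#'   (median).
#' @export
build_car_map <- function(candidates, clock_window_min = 60,
                          profile_threshold = 0.5) {
  maps <- list()
  ord <- order(vapply(candidates,
                      function(cd) as.numeric(cd$segment$t_start),
                      numeric(1)))
  for (k in ord) {
    cd <- candidates[[k]]
    best <- 0L
    best_d <- Inf
    for (j in seq_along(maps)) {
      mp <- maps[[j]]
      if (!identical(mp$room, cd$segment$room)) next
      if (circ_diff_h(mp$clock_h, cd$clock_h) * 60 > clock_window_min) next
      d <- profile_distance(mp$profile, cd$profile)
      if (d <= profile_threshold && d < best_d) {
        best <- j
        best_d <- d
      }
    }
    if (best == 0L) {
      maps[[length(maps) + 1]] <- structure(list(
        id = length(maps) + 1L, room = cd$segment$room,
        members = list(cd), profile = cd$profile, clock_h = cd$clock_h,
        duration_min = cd$duration_min
      ), class = "car_map")
    } else {
      mp <- maps[[best]]
      mp$members <- c(mp$members, list(cd))
      profs <- lapply(mp$members, `[[`, "profile")
      mp$profile <- Reduce(`+`, profs) / length(profs)
      mp$clock_h <- circ_mean_h(vapply(mp$members, `[[`, numeric(1),
                                       "clock_h"))
      mp$duration_min <- median(vapply(mp$members, `[[`, numeric(1),
                                       "duration_min"))
      maps[[best]] <- mp
    }
  }
  maps
}

#' @export
print.car_map <- function(x, ...) {
  cat(sprintf("<CAR map %d: %s, %d members, clock %.2f h, %.1f min%s>\n",
              x$id, x$room, length(x$members), x$clock_h, x$duration_min,
              if (!is.null(x$adl)) paste0(", ", x$adl) else ""))
  invisible(x)
}

#' Gaussian broad-band smoothing kernel
#'
#' The discrete kernel `w(i) = exp(-i^2 / (2 SD^4)) / (SD^2 sqrt(2 pi))`
#' over integer offsets `|i| <= ceil(4 SD^2)`, used to suppress sensor
#' fluctuation and transmission-error outliers in map profiles. Note the
#' effective bandwidth is `SD^2`, so the kernel value at `i = 0` with
#' `SD = 1` is `1 / sqrt(2 pi)`.
#'
#' @param sd Kernel SD parameter (> 0).
#' @param normalized If `TRUE`, renormalize the truncated kernel to unit
#'   sum (the form used for filtering, which conserves profile mass).
#' @return Numeric vector of kernel weights; attribute `offsets` holds the
#'   integer offsets.
#' @export
gaussian_kernel <- function(sd, normalized = FALSE) {
  stopifnot(sd > 0)
  half <- as.integer(ceiling(4 * sd^2))
  i <- (-half):half
  w <- exp(-i^2 / (2 * sd^4)) / (sd^2 * sqrt(2 * pi))
  if (normalized) w <- w / sum(w)
  structure(w, offsets = i)
}

#' Smooth a profile with the Gaussian broad-band filter
#'
#' Convolution with the unit-sum truncated kernel of [gaussian_kernel()];
#' at the boundaries the kernel is renormalized over the in-range support,
#' so a constant profile passes through unchanged.
#'
#' @param profile Numeric vector or channels-by-points matrix.
#' @param sd Kernel SD parameter (> 0).
#' @return Smoothed profile of the same shape.
#' @export
gaussian_filter <- function(profile, sd) {
  stopifnot(sd > 0)
  if (is.matrix(profile)) {
    out <- profile
    for (i in seq_len(nrow(profile))) {
      out[i, ] <- gaussian_filter(profile[i, ], sd)
    }
    return(out)
  }
  w <- gaussian_kernel(sd, normalized = TRUE)
  off <- attr(w, "offsets")
  n <- length(profile)
  out <- numeric(n)
  for (j in seq_len(n)) {
    idx <- j + off
    keep <- idx >= 1 & idx <= n
    out[j] <- sum(profile[idx[keep]] * w[keep]) / sum(w[keep])
  }
  out
}

score_map_adl <- function(mp, w, rel_dur) {
  if (!(mp$room %in% unlist(w$rooms))) return(NA_real_)
  if (mp$duration_min < w$duration_min[[1]] ||
      mp$duration_min > w$duration_min[[2]]) return(NA_real_)
  cd <- circ_diff_h(mp$clock_h, w$clock_center_h)
  if (cd > w$clock_halfwidth_h) return(NA_real_)
  if (!is.null(w$min_rel_duration) && rel_dur < w$min_rel_duration) {
    return(NA_real_)
  }
  dmid <- (w$duration_min[[1]] + w$duration_min[[2]]) / 2
  dhw <- (w$duration_min[[2]] - w$duration_min[[1]]) / 2
  (1 - cd / w$clock_halfwidth_h) +
    0.5 * (1 - abs(mp$duration_min - dmid) / dhw)
}

#' Allot an ADL to each CAR map
#'
#' Scores every map against every ADL's parameter windows on room, median
#' duration, median clock time of occurrence and duration relative to the
#' longest co-occurring map; the best-scoring ADL is allotted and every
#' member segment is emitted as a labelled event. Maps matching no window
#' are left unlabelled and reported, never force-assigned.
#'
#' @param maps List of `car_map` objects (one subject).
#' @param windows ADL parameter windows.
#' @param subject Subject id stamped on the events.
#' @return List: `events` (ADL event table), `maps` (with `adl` fields
#'   filled), `unlabeled` (ids of unlabelled maps).
#' @export
assign_adl <- function(maps, windows, subject = NA_integer_) {
  if (length(maps) == 0) {
    return(list(events = empty_events(), maps = maps,
                unlabeled = integer(0)))
  }
  max_dur <- max(vapply(maps, `[[`, numeric(1), "duration_min"))
  events <- list()
  unlabeled <- integer(0)
  for (j in seq_along(maps)) {
    mp <- maps[[j]]
    rel_dur <- mp$duration_min / max_dur
    scores <- vapply(names(windows), function(adl) {
      score_map_adl(mp, windows[[adl]], rel_dur)
    }, numeric(1))
    if (all(is.na(scores))) {
      unlabeled <- c(unlabeled, mp$id)
      next
    }
    adl <- names(windows)[which.max(scores)]
    maps[[j]]$adl <- adl
    for (cd in mp$members) {
      events[[length(events) + 1]] <- list(
        subject = subject, adl = adl, room = mp$room,
        start = cd$segment$t_start, end = cd$segment$t_end + 5,
        map_id = mp$id
      )
    }
  }
  ev <- if (length(events) > 0) rbindlist(events) else empty_events()
  if (nrow(ev) > 0) setorder(ev, start)
  list(events = ev, maps = maps, unlabeled = unlabeled)
}

#' Classify segments with the circadian activity rhythm classifier
#'
#' Full pipeline: standardize each segment, compute its temporal emphasis,
#' keep segments matching some behavioural window as pattern candidates,
#' agglomerate recurring similar candidates across days into CAR maps,
#' smooth map profiles with the Gaussian broad-band filter, and allot an
#' ADL to each map by occurrence time and relative duration. Requires no
#' training data.
#'
#' @param segments List of `adl_segment` objects (one subject).
#' @param table Parsed rule table supplying the `adl_windows`.
#' @param subject Subject id for the emitted events.
#' @param clock_window_min,profile_threshold,n_points Map-building
#'   similarity parameters (see [build_car_map()]).
#' @param filter_sd Gaussian filter SD parameter (default 2).
#' @return List: `events`, `maps`, `unlabeled`, `n_candidates`.
#' @export
car_classify <- function(segments,
                         table = parse_rules(default_rules_file()),
                         subject = NA_integer_, clock_window_min = 60,
                         profile_threshold = 0.5, n_points = 64,
                         filter_sd = 2) {
  windows <- table$adl_windows
  candidates <- list()
  for (s in segments) {
    if (ncol(s$samples) < 2) next
    std <- ztransform(s)
    emp <- emphasis(std)
    flag <- match_behavior(s, windows, emp)
    if (!flag) next
    candidates[[length(candidates) + 1]] <- list(
      segment = s, std = std, emphasis = emp,
      clock_h = emphasis_clock_h(s, emp),
      profile = resample_profile(std$samples, n_points),
      duration_min = (as.numeric(s$t_end) - as.numeric(s$t_start) + 5) / 60,
      candidates = attr(flag, "candidates")
    )
  }
  maps <- build_car_map(candidates, clock_window_min, profile_threshold)
  maps <- lapply(maps, function(mp) {
    mp$profile <- gaussian_filter(mp$profile, filter_sd)
    mp
  })
  res <- assign_adl(maps, windows, subject)
  res$n_candidates <- length(candidates)
  res
}
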