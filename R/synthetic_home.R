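#' The eight ADL labels
#'
#' The eight activities of daily living the classifiers recognise: sleeping,
#' grooming, toileting, getting ready for bed, cooking, eating, watching TV
#' and seated activity.
#'
#' @return Character vector of the eight ADL labels, fixed order.
#' @export
adl_levels <- function() {
  c("sleeping", "grooming", "toileting", "getting_ready_for_bed",
    "cooking", "eating", "watching_tv", "seated_activity")
}

#' Default room layout
#'
#' Ten rooms, one sensor box per room (node ids 1..10).
#'
#' @return data.frame with columns `room` and `node_id`.
#' @export
default_rooms <- function() {
  data.frame(
    room = c("kitchen", "bathroom", "bedroom", "living_room", "dining_room",
             "hallway", "office", "guest_room", "laundry", "balcony"),
    node_id = 1:10
  )
}

#' Home configuration
#'
#' Describes one single-occupant home: rooms and their sensor nodes, the
#' sampling rate, the recording span, and which rooms each ADL may occur in.
#'
#' @param rooms data.frame with `room`, `node_id` (unique ids in 1..10).
#' @param sampling_rate Samples per second per node (default 0.2 Hz).
#' @param n_days Recording duration in days (default 20).
#' @param origin Start of the recording (POSIXct, midnight UTC).
#' @param adl_room_map Named list mapping each ADL to the rooms it may occur
#'   in; every ADL must map to at least one room.
#' @return A `home_config` object.
#' @export
home_config <- function(rooms = default_rooms(), sampling_rate = 0.2,
                        n_days = 20,
                        origin = as.POSIXct("2015-01-05 00:00:00",
                                            tz = "UTC"),
                        adl_room_map = default_adl_room_map()) {
  stopifnot(!anyDuplicated(rooms$node_id), all(rooms$node_id %in% 1:10))
  missing_map <- setdiff(adl_levels(), names(adl_room_map))
  if (length(missing_map) > 0) {
    stop("adl_room_map must cover every ADL; missing: ",
         paste(missing_map, collapse = ", "))
  }
  if (any(lengths(adl_room_map[adl_levels()]) < 1)) {
    stop("every ADL must map to at least one room")
  }
  structure(list(rooms = rooms, sampling_rate = sampling_rate,
                 n_days = n_days, origin = origin,
                 adl_room_map = adl_room_map),
            class = "home_config")
}

#' @rdname home_config
#' @export
default_adl_room_map <- function() {
  list(
    sleeping = "bedroom",
    grooming = "bathroom",
    toileting = "bathroom",
    getting_ready_for_bed = "bathroom",
    cooking = "kitchen",
    eating = "dining_room",
    watching_tv = "living_room",
    seated_activity = "living_room"
  )
}

#' Default behavioural profile of the simulated occupant
#'
#' One entry per ADL: preferred clock time, day-to-day timing jitter
#' (stationary SD, minutes), duration distribution (minutes), daily
#' occurrence count, room, occupancy level on the passive-infrared channel,
#' and the additive ambient channel signature the activity leaves in its
#' room. Getting ready for bed is anchored immediately before sleeping.
#'
#' The timing jitter follows a stationary AR(1) process across days
#' (`rho`, default 0.4) so that start times drift slowly rather than jump
#' independently; its stationary SD equals `jitter_sd_min`, which is what
#' the circadian-regularity assumption of the rhythm classifier describes.
#'
#' @param jitter_sd_min Stationary SD of daily start-time jitter in minutes
#'   (applied to every ADL; default 15).
#' @param rho Day-to-day AR(1) correlation of the jitter (default 0.4).
#' @return Named list (one element per ADL) of profile entries.
#' @export
default_adl_profile <- function(jitter_sd_min = 15, rho = 0.4) {
  sig <- function(...) list(...)
  entry <- function(pref_h, dur_mean, dur_sd, room, pir_level = 1,
                    signature = list(), anchor = NA_character_) {
    list(pref_h = pref_h, jitter_sd_min = jitter_sd_min, rho = rho,
         dur_mean_min = dur_mean, dur_sd_min = dur_sd, per_day = 1L,
         room = room, pir_level = pir_level, signature = signature,
         anchor = anchor)
  }
  list(
    sleeping = entry(23.0, 420, 30, "bedroom", pir_level = 0.3),
    grooming = entry(7.33, 15, 3, "bathroom", signature = list(
      sig(channel = "humidity", shape = "ramp", amplitude = 4))),
    toileting = entry(13.5, 8, 2, "bathroom", signature = list(
      sig(channel = "humidity", shape = "pulse", amplitude = 1))),
    getting_ready_for_bed = entry(22.75, 12, 3, "bathroom",
      signature = list(
        sig(channel = "humidity", shape = "pulse", amplitude = 1.2),
        sig(channel = "luminescence", shape = "step", amplitude = 30)),
      anchor = "sleeping"),
    cooking = entry(11.5, 40, 8, "kitchen", signature = list(
      sig(channel = "temperature", shape = "ramp", amplitude = 3),
      sig(channel = "humidity", shape = "ramp", amplitude = 2))),
    eating = entry(12.4, 30, 5, "dining_room", pir_level = 0.9,
      signature = list(
        sig(channel = "accel_x", shape = "pulse", amplitude = 0.3))),
    watching_tv = entry(20.0, 90, 15, "living_room", pir_level = 0.8,
      signature = list(
        sig(channel = "luminescence", shape = "flicker", amplitude = 45))),
    seated_activity = entry(15.0, 60, 10, "living_room", pir_level = 0.8,
      signature = list(
        sig(channel = "accel_y", shape = "pulse", amplitude = 0.2)))
  )
}

#' Default per-channel sensor noise (SD, channel units)
#' @return Named numeric vector over [ambient_channels()].
#' @export
default_noise <- function() {
  c(temperature = 0.15, humidity = 0.15, luminescence = 4, pir = 0.02,
    accel_node = 0.05, accel_x = 0.05, accel_y = 0.05, accel_z = 0.05)
}

# Named, reproducible substreams derived from one master seed, so schedule
# generation, sensor rendering and loss injection can be varied independently.
sub_seed <- function(seed, stream, subject_id = 0L) {
  offset <- c(schedule = 101L, render = 211L, loss = 307L,
              subjects = 401L)[[stream]]
  as.integer((as.numeric(seed) + 7919 * subject_id + offset) %%
               .Machine$integer.max)
}

ar1_offsets <- function(n, sd, rho) {
  if (sd <= 0 || n == 0) return(rep(0, n))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  innov_sd <- sd * sqrt(1 - rho^2)
  for (d in seq_len(n)[-1]) x[d] <- rho * x[d - 1] + rnorm(1, 0, innov_sd)
  x
}

#' Generate a ground-truth ADL schedule
#'
#' Draws, for every day, each ADL at its preferred clock time plus AR(1)
#' circadian jitter with a Gaussian duration; anchored activities (getting
#' ready for bed) are placed immediately before their anchor. Because the
#' home has a single occupant, overlapping events are resolved by shifting
#' later events to start at least one minute after the previous event ends.
#' Events are clipped to the recording span.
#'
#' @param profile Behavioural profile ([default_adl_profile()]).
#' @param home Home configuration ([home_config()]).
#' @param subject_id Integer subject identifier.
#' @param seed Integer seed (schedule substream derived from it).
#' @return `data.table` of ADL events: `subject`, `adl`, `room`, `start`,
#'   `end` (POSIXct), sorted by start time.
#' @export
generate_schedule <- function(profile, home, subject_id = 1L, seed = 1L) {
  total_min <- sum(vapply(profile, `[[`, numeric(1), "dur_mean_min"))
  if (total_min > 24 * 60) {
    stop("infeasible profile: mean daily activity exceeds 24 h")
  }
  set.seed(sub_seed(seed, "schedule", subject_id))
  n_days <- home$n_days
  origin <- as.numeric(home$origin)

  # per-subject habitual shift of all preferred times (inter-subject
  # variability), plus per-ADL AR(1) daily jitter
  subject_shift_min <- rnorm(1, 0, 10)
  adls <- names(profile)
  offsets <- lapply(profile, function(p) {
    ar1_offsets(n_days, p$jitter_sd_min, p$rho)
  })
  durations <- lapply(profile, function(p) {
    pmax(2, rnorm(n_days, p$dur_mean_min, p$dur_sd_min))
  })

  rows <- vector("list", length(adls) * n_days)
  k <- 0L
  for (d in seq_len(n_days)) {
    day0 <- origin + (d - 1) * 86400
    starts <- numeric(length(adls))
    names(starts) <- adls
    for (a in adls) {
      p <- profile[[a]]
      if (!is.na(p$anchor)) next
      starts[a] <- day0 + p$pref_h * 3600 +
        (subject_shift_min + offsets[[a]][d]) * 60
    }
    for (a in adls) {
      p <- profile[[a]]
      if (is.na(p$anchor)) next
      starts[a] <- starts[p$anchor] - durations[[a]][d] * 60 - 120
    }
    for (a in adls) {
      k <- k + 1L
      rows[[k]] <- list(adl = a, room = profile[[a]]$room,
                        start = starts[a],
                        end = starts[a] + durations[[a]][d] * 60)
    }
  }
  ev <- rbindlist(rows)
  setorder(ev, start)
  # single occupant: shift later events past overlaps, keeping durations
  min_gap <- 60
  st <- ev$start; en <- ev$end
  for (i in seq_len(nrow(ev))[-1]) {
    if (st[i] < en[i - 1] + min_gap) {
      dur <- en[i] - st[i]
      st[i] <- en[i - 1] + min_gap
      en[i] <- st[i] + dur
    }
  }
  # journal resolution equals the sensing resolution: snap to the 5 s grid
  st <- round(st / 5) * 5
  en <- round(en / 5) * 5
  ev$start <- st; ev$end <- en
  # events only partially inside the recording span are dropped outright:
  # a half-recorded activity has no well-defined ground truth
  span_end <- origin + n_days * 86400
  ev <- ev[st >= origin & en <= span_end]
  data.table(
    subject = as.integer(subject_id),
    adl = ev$adl, room = ev$room,
    start = as.POSIXct(ev$start, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(ev$end, origin = "1970-01-01", tz = "UTC")
  )
}

baseline_channel <- function(channel, hour) {
  switch(channel,
    temperature = 21 + 1.5 * sin(2 * pi * (hour - 10) / 24),
    humidity = 8 + 0.8 * sin(2 * pi * (hour - 16) / 24),
    luminescence = 280 * pmax(0, sin(pi * (hour - 7) / 12)) *
      (hour >= 7 & hour <= 19),
    pir = rep(0, length(hour)),
    accel_node = rep(9.81, length(hour)),
    accel_x = rep(0, length(hour)),
    accel_y = rep(0, length(hour)),
    accel_z = rep(0, length(hour))
  )
}

signature_shape <- function(shape, amplitude, rel_pos, t_s) {
  switch(shape,
    step = rep(amplitude, length(rel_pos)),
    # an onset step of a tenth of the amplitude, then a linear rise: the
    # deflection is strictly positive from the first in-event sample on
    ramp = amplitude * (0.1 + 0.9 * rel_pos),
    pulse = amplitude * sin(pi * rel_pos),
    flicker = amplitude * (0.75 + 0.25 * sin(2 * pi * t_s / 30)),
    stop("unknown signature shape: ", shape)
  )
}

#' Render an ADL schedule into ambient sensor packets
#'
#' Produces the 0.2 Hz packet stream of every sensor node over the recording
#' span: a deterministic diurnal baseline per channel, plus each event's
#' channel signature added in its own room only, elevated passive-infrared
#' during occupancy, and i.i.d. Gaussian channel noise.
#'
#' @param schedule Event table from [generate_schedule()].
#' @param home Home configuration.
#' @param profile Behavioural profile supplying per-ADL signatures.
#' @param noise_sd Named per-channel noise SD ([default_noise()]); use 0 for
#'   a noise-free stream.
#' @param seed Integer seed (render substream derived from it).
#' @return Packet `data.table` (all nodes, chronological within node) with
#'   `time`, `date`, `node_id`, `room`, integrity words and the eight
#'   channels.
#' @export
render_sensors <- function(schedule, home, profile = default_adl_profile(),
                           noise_sd = default_noise(), seed = 1L) {
  subject_id <- if (nrow(schedule) > 0) schedule$subject[1] else 0L
  set.seed(sub_seed(seed, "render", subject_id))
  if (length(noise_sd) == 1 && is.null(names(noise_sd))) {
    noise_sd <- stats::setNames(rep(noise_sd, length(CHANNELS)), CHANNELS)
  }
  origin <- as.numeric(home$origin)
  n_slots <- as.integer(home$n_days * 86400 * home$sampling_rate)
  period <- 1 / home$sampling_rate
  tsec <- origin + (seq_len(n_slots) - 1) * period
  hour <- ((tsec - origin) %% 86400) / 3600
  base <- lapply(CHANNELS, function(ch) baseline_channel(ch, hour))
  names(base) <- CHANNELS

  sched_start <- as.numeric(schedule$start)
  sched_end <- as.numeric(schedule$end)

  out <- vector("list", nrow(home$rooms))
  for (r in seq_len(nrow(home$rooms))) {
    room <- home$rooms$room[r]
    vals <- lapply(base, identity)
    idx_ev <- which(schedule$room == room)
    for (i in idx_ev) {
      s0 <- sched_start[i]; s1 <- sched_end[i]
      lo <- ceiling((s0 - origin) / period) + 1
      hi <- floor((s1 - origin - 1e-9) / period) + 1
      if (hi < lo) next
      lo <- max(1L, lo); hi <- min(n_slots, hi)
      sl <- lo:hi
      rel <- (tsec[sl] - s0) / (s1 - s0)
      p <- profile[[schedule$adl[i]]]
      vals$pir[sl] <- vals$pir[sl] + p$pir_level
      for (sg in p$signature) {
        vals[[sg$channel]][sl] <- vals[[sg$channel]][sl] +
          signature_shape(sg$shape, sg$amplitude, rel, tsec[sl] - s0)
      }
    }
    for (ch in CHANNELS) {
      sdv <- if (ch %in% names(noise_sd)) noise_sd[[ch]] else 0
      if (sdv > 0) vals[[ch]] <- vals[[ch]] + rnorm(n_slots, 0, sdv)
    }
    vals$luminescence <- pmax(0, vals$luminescence)
    tm <- as.POSIXct(tsec, origin = "1970-01-01", tz = "UTC")
    out[[r]] <- data.table(
      date = as.Date(tm, tz = "UTC"),
      time = tm,
      node_id = home$rooms$node_id[r],
      room = room,
      supply_voltage = 3.0,
      status_word = 0L,
      handshake_word = HANDSHAKE_WORD,
      temperature = vals$temperature,
      humidity = vals$humidity,
      luminescence = vals$luminescence,
      pir = vals$pir,
      accel_node = vals$accel_node,
      accel_x = vals$accel_x,
      accel_y = vals$accel_y,
      accel_z = vals$accel_z
    )
  }
  rbindlist(out)
}

#' Drop packets uniformly at random (transmission loss)
#'
#' Each packet is independently dropped with probability `loss_prob`,
#' emulating wireless transmission loss (observed near 0.47% in home
#' deployments of this sensor system).
#'
#' @param stream Packet table.
#' @param loss_prob Loss probability in `[0, 1)`.
#' @param seed Integer seed (loss substream derived from it).
#' @param subject_id Subject identifier folded into the substream seed.
#' @return The degraded packet table.
#' @export
inject_loss <- function(stream, loss_prob, seed = 1L, subject_id = 0L) {
  stopifnot(loss_prob >= 0, loss_prob < 1)
  if (loss_prob == 0) return(stream)
  set.seed(sub_seed(seed, "loss", subject_id))
  keep <- runif(nrow(stream)) >= loss_prob
  stream[keep]
}

#' Simulate one subject end to end
#'
#' Convenience wrapper: schedule, render, loss.
#'
#' @inheritParams generate_schedule
#' @inheritParams render_sensors
#' @param loss_prob Packet loss probability (default 0.0047).
#' @return List with `truth` (event table), `stream` (packet table after
#'   loss) and `n_rendered` (packet count before loss).
#' @export
simulate_subject <- function(subject_id, home, profile = default_adl_profile(),
                             noise_sd = default_noise(), loss_prob = 0.0047,
                             seed = 1L) {
  truth <- generate_schedule(profile, home, subject_id, seed)
  stream <- render_sensors(truth, home, profile, noise_sd, seed)
  n0 <- nrow(stream)
  stream <- inject_loss(stream, loss_prob, seed, subject_id)
  list(truth = truth, stream = stream, n_rendered = n0)
}
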