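# Fixture builders shared across the test files. Everything is generated in
# code; no stored data.

origin_utc <- function(day = "2015-01-05", time = "00:00:00") {
  as.POSIXct(paste(day, time), tz = "UTC")
}

# n random valid packets at random grid times and nodes
random_packets <- function(n, seed = 1) {
  set.seed(seed)
  t0 <- origin_utc()
  make_packets(
    time = t0 + sample.int(20 * 17280, n, replace = TRUE) * 5,
    node_id = sample.int(10, n, replace = TRUE),
    supply_voltage = runif(n, 2.7, 3.3),
    temperature = rnorm(n, 21, 2),
    humidity = rnorm(n, 8, 1),
    luminescence = runif(n, 0, 300),
    pir = runif(n, 0, 1),
    accel_node = rnorm(n, 9.81, 0.1),
    accel_x = rnorm(n), accel_y = rnorm(n), accel_z = rnorm(n)
  )
}

# build an adl_segment from named channel vectors (5 s spacing); channels
# not given are constant zero
fixture_segment <- function(channels, t0 = origin_utc(), room = "bathroom",
                            node_id = 2L) {
  n <- length(channels[[1]])
  m <- matrix(0, nrow = length(ambient_channels()), ncol = n,
              dimnames = list(ambient_channels(), NULL))
  for (ch in names(channels)) m[ch, ] <- channels[[ch]]
  structure(list(
    node_id = node_id, room = room,
    t_start = t0, t_end = t0 + (n - 1) * 5,
    times = t0 + (seq_len(n) - 1) * 5,
    samples = m
  ), class = "adl_segment")
}

# a single-node stream at 5 s spacing from named channel vectors
fixture_stream <- function(channels, t0 = origin_utc(), node_id = 2L,
                           room = "bathroom") {
  n <- length(channels[[1]])
  p <- make_packets(time = t0 + (seq_len(n) - 1) * 5, node_id = node_id)
  p$room <- room
  for (ch in names(channels)) p[[ch]] <- channels[[ch]]
  p
}

# events table helper
fixture_events <- function(adl, start_s, end_s, room = "kitchen",
                           subject = 1L, t0 = origin_utc()) {
  data.table::data.table(
    subject = subject, adl = adl, room = room,
    start = t0 + start_s, end = t0 + end_s
  )
}
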