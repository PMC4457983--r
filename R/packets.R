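#' @importFrom data.table fread fwrite data.table as.data.table rbindlist setDT setorder :=
#' @importFrom stats predict approx cov
#' @importFrom stats rnorm runif sd median var aggregate acf dnorm
#' @importFrom utils head tail
NULL

# Canonical field order of one sensor data packet as transmitted by a sensor
# box: identity and integrity words first, then the five ambient channels
# (acceleration occupies four values: node magnitude plus x/y/z axes).
PACKET_FIELDS <- c(
  "date", "time", "node_id", "supply_voltage", "status_word",
  "handshake_word", "temperature", "humidity", "luminescence", "pir",
  "accel_node", "accel_x", "accel_y", "accel_z"
)

CHANNELS <- c(
  "temperature", "humidity", "luminescence", "pir",
  "accel_node", "accel_x", "accel_y", "accel_z"
)

# Constant expected in the handshake word; receivers drop frames that
# collided mid-air, which manifests as a corrupted handshake.
HANDSHAKE_WORD <- 42405L # 0xA5A5

SAMPLING_PERIOD_S <- 5 # 0.2 Hz

#' Sensor packet field order
#'
#' Field order of the delimited text serialization of one sensor data packet:
#' date, time, node id, supply voltage, status word, handshake word, then the
#' ambient channels (temperature, humidity, luminescence, passive infrared,
#' and the four acceleration values).
#'
#' @return Character vector of field names in serialization order.
#' @export
packet_fields <- function() PACKET_FIELDS

#' Ambient channel names
#'
#' @return Character vector naming the eight ambient value channels carried
#'   by every packet.
#' @export
ambient_channels <- function() CHANNELS

#' Construct sensor data packets
#'
#' Builds a packet table (one row per packet) with all integrity fields
#' populated. `time` is the packet timestamp (POSIXct, UTC, 5 s resolution at
#' the 0.2 Hz sampling rate); channel values are recycled to the length of
#' `time`.
#'
#' @param time POSIXct timestamps.
#' @param node_id Integer sensor-box identifier in 1..10 (one box per room).
#' @param supply_voltage Battery voltage in volts.
#' @param status_word 16-bit unsigned status word; must have even parity to
#'   be accepted by the decoder.
#' @param handshake_word Frame-collision detection word; checked for equality
#'   with the fixed expected constant.
#' @param temperature,humidity,luminescence,pir Ambient channel values
#'   (degrees C, g/m^3, lx, V).
#' @param accel_node,accel_x,accel_y,accel_z Acceleration values (m/s^2).
#' @return A `data.table` with the fields of [packet_fields()] (`date` and
#'   `time` combined into one POSIXct `time` column plus a `date` column).
#' @export
make_packets <- function(time, node_id, supply_voltage = 3.0,
                         status_word = 0L, handshake_word = HANDSHAKE_WORD,
                         temperature = 21, humidity = 8, luminescence = 0,
                         pir = 0, accel_node = 9.81, accel_x = 0,
                         accel_y = 0, accel_z = 0) {
  stopifnot(inherits(time, "POSIXct"))
  data.table(
    date = as.Date(time, tz = "UTC"),
    time = time,
    node_id = as.integer(node_id),
    supply_voltage = as.numeric(supply_voltage),
    status_word = as.integer(status_word),
    handshake_word = as.integer(handshake_word),
    temperature = as.numeric(temperature),
    humidity = as.numeric(humidity),
    luminescence = as.numeric(luminescence),
    pir = as.numeric(pir),
    accel_node = as.numeric(accel_node),
    accel_x = as.numeric(accel_x),
    accel_y = as.numeric(accel_y),
    accel_z = as.numeric(accel_z)
  )
}

#' Even-parity check
#'
#' A status word passes when it carries an even number of set bits, the
#' convention used by the sensor boxes for error detection. Computed over the
#' low 16 bits.
#'
#' @param word Integer vector of status words (0..65535).
#' @return Logical vector: `TRUE` where parity is even.
#' @export
parity_even <- function(word) {
  w <- as.integer(word)
  bits <- 0L
  for (k in 0:15) bits <- bits + bitwAnd(bitwShiftR(w, k), 1L)
  bits %% 2L == 0L
}

format_num <- function(x) {
  # round-trip-exact decimal rendering of doubles
  formatC(x, digits = 17, format = "g")
}

#' Encode one packet as a delimited text record
#'
#' Serializes a packet into one comma-separated line with fields in
#' [packet_fields()] order, ISO-8601 date and time. `decode_packet()` inverts
#' this encoding exactly.
#'
#' @param packet A one-row packet table as produced by [make_packets()].
#' @return A single character string (no trailing newline).
#' @export
encode_packet <- function(packet) {
  stopifnot(nrow(packet) == 1L)
  t <- packet$time
  paste(
    format(as.Date(t, tz = "UTC"), "%Y-%m-%d"),
    format(t, "%H:%M:%S", tz = "UTC"),
    packet$node_id,
    format_num(packet$supply_voltage),
    packet$status_word,
    packet$handshake_word,
    format_num(packet$temperature),
    format_num(packet$humidity),
    format_num(packet$luminescence),
    format_num(packet$pir),
    format_num(packet$accel_node),
    format_num(packet$accel_x),
    format_num(packet$accel_y),
    format_num(packet$accel_z),
    sep = ","
  )
}

packet_rejection <- function(reason, detail = NULL) {
  structure(list(ok = FALSE, reason = reason, detail = detail),
            class = "packet_rejection")
}

#' @export
print.packet_rejection <- function(x, ...) {
  cat("<packet rejected:", x$reason,
      if (!is.null(x$detail)) paste0("(", x$detail, ")"), ">\n")
  invisible(x)
}

#' Test for a rejected packet
#' @param x Object returned by [decode_packet()].
#' @return `TRUE` if `x` is a typed rejection.
#' @export
is_rejection <- function(x) inherits(x, "packet_rejection")

#' Decode a delimited packet record
#'
#' Parses one text record back into a packet, enforcing the integrity checks
#' a receiver applies: field count and numeric parse
#' (`"malformed-field"`), node id in 1..10 (`"node-out-of-range"`), even
#' parity of the status word (`"parity-failure"`), and handshake-word match
#' (`"handshake-mismatch"`). The first failed check names the rejection.
#'
#' @param record One character string as produced by [encode_packet()].
#' @return A one-row packet `data.table`, or a `packet_rejection` object
#'   whose `reason` field names the failed check.
#' @export
decode_packet <- function(record) {
  parts <- strsplit(record, ",", fixed = TRUE)[[1]]
  if (length(parts) != length(PACKET_FIELDS)) {
    return(packet_rejection("malformed-field",
                            sprintf("expected %d fields, got %d",
                                    length(PACKET_FIELDS), length(parts))))
  }
  t <- as.POSIXct(paste(parts[1], parts[2]), tz = "UTC",
                  format = "%Y-%m-%d %H:%M:%S")
  num <- suppressWarnings(as.numeric(parts[3:14]))
  if (is.na(t) || anyNA(num)) {
    return(packet_rejection("malformed-field", "unparseable field"))
  }
  node <- as.integer(num[1])
  if (is.na(node) || node < 1L || node > 10L) {
    return(packet_rejection("node-out-of-range", as.character(parts[3])))
  }
  status <- as.integer(num[3])
  if (status < 0 || status > 65535 || !parity_even(status)) {
    return(packet_rejection("parity-failure", as.character(status)))
  }
  if (as.integer(num[4]) != HANDSHAKE_WORD) {
    return(packet_rejection("handshake-mismatch", as.character(num[4])))
  }
  make_packets(
    time = t, node_id = node, supply_voltage = num[2], status_word = status,
    handshake_word = as.integer(num[4]), temperature = num[5],
    humidity = num[6], luminescence = num[7], pir = num[8],
    accel_node = num[9], accel_x = num[10], accel_y = num[11],
    accel_z = num[12]
  )
}

#' Acquisition statistics
#'
#' Summary of one acquisition run: packets captured, packets lost
#' (schedule gaps plus rejected records), and the resulting transmission
#' reliability, `100 * captured / (captured + lost)`.
#'
#' @param captured Number of packets captured (accepted).
#' @param lost Number of packets lost or rejected.
#' @param rejected_by_reason Optional named integer vector breaking rejected
#'   records down by rejection reason.
#' @return An `acquisition_stats` object (list with `captured`, `lost`,
#'   `loss_pct`, `reliability_pct`).
#' @export
acquisition_stats <- function(captured, lost, rejected_by_reason = NULL) {
  stopifnot(captured >= 0, lost >= 0)
  expected <- captured + lost
  structure(list(
    captured = captured,
    lost = lost,
    expected = expected,
    loss_pct = if (expected > 0) 100 * lost / expected else 0,
    reliability_pct = if (expected > 0) 100 * captured / expected else 100,
    rejected_by_reason = rejected_by_reason
  ), class = "acquisition_stats")
}

#' @export
print.acquisition_stats <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.acquisition_stats <- function(x, ...) {
  c(sprintf("captured: %d", as.integer(x$captured)),
    sprintf("lost: %d", as.integer(x$lost)),
    sprintf("loss_pct: %.2f", x$loss_pct),
    sprintf("reliability_pct: %.2f", x$reliability_pct))
}

#' Write acquisition statistics as a key-value report
#' @param stats An `acquisition_stats` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_acquisition_stats <- function(stats, path) {
  writeLines(format(stats), path)
  invisible(path)
}

#' Write a packet log
#'
#' One comma-separated record per line with a header, fields in
#' [packet_fields()] order. Paths ending in `.gz` are compressed.
#'
#' @param packets Packet table ([make_packets()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_packet_log <- function(packets, path) {
  out <- data.table(
    date = format(as.Date(packets$time, tz = "UTC"), "%Y-%m-%d"),
    time = format(packets$time, "%H:%M:%S", tz = "UTC")
  )
  for (f in PACKET_FIELDS[-(1:2)]) out[[f]] <- packets[[f]]
  fwrite(out, path, col.names = TRUE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read and validate a packet log
#'
#' Reads a delimited packet log (gzip-transparent), applies the decoder's
#' integrity checks vectorized over all records, and reports acquisition
#' statistics. Lost packets are counted as gaps on the per-node 5 s sampling
#' grid (between each node's first and last sample) plus rejected records;
#' alternatively an `expected` total can be supplied (e.g. the simulator's
#' schedule size), in which case `lost = expected - captured`.
#'
#' @param path Packet log file.
#' @param expected Optional total number of packets the acquisition schedule
#'   should have produced.
#' @return List with `packets` (valid packets, file order), `stats`
#'   (an [acquisition_stats()] object) and `rejected` (count by reason).
#' @export
read_packet_log <- function(path, expected = NULL) {
  if (!file.exists(path)) stop("packet log not found: ", path)
  raw <- fread(path, header = TRUE, colClasses = list(character = "date"))
  if (!all(PACKET_FIELDS %in% names(raw))) {
    stop("packet log missing fields: ",
         paste(setdiff(PACKET_FIELDS, names(raw)), collapse = ", "))
  }
  t <- as.POSIXct(paste(raw$date, raw$time), tz = "UTC",
                  format = "%Y-%m-%d %H:%M:%S")
  num_ok <- !is.na(t)
  for (f in PACKET_FIELDS[-(1:2)]) {
    num_ok <- num_ok & !is.na(suppressWarnings(as.numeric(raw[[f]])))
  }
  node <- suppressWarnings(as.integer(raw$node_id))
  status <- suppressWarnings(as.integer(raw$status_word))
  hand <- suppressWarnings(as.integer(raw$handshake_word))

  reason <- rep(NA_character_, nrow(raw))
  reason[!num_ok] <- "malformed-field"
  ok <- num_ok
  bad_node <- ok & (is.na(node) | node < 1L | node > 10L)
  reason[bad_node] <- "node-out-of-range"
  ok <- ok & !bad_node
  bad_parity <- ok & (is.na(status) | status < 0L | status > 65535L |
                        !parity_even(ifelse(is.na(status), 0L, status)))
  reason[bad_parity] <- "parity-failure"
  ok <- ok & !bad_parity
  bad_hand <- ok & (is.na(hand) | hand != HANDSHAKE_WORD)
  reason[bad_hand] <- "handshake-mismatch"
  ok <- ok & !bad_hand

  packets <- raw[ok]
  packets$time <- t[ok]
  packets$date <- as.Date(t[ok], tz = "UTC")
  packets$node_id <- node[ok]
  setDT(packets)

  rejected <- table(reason[!ok])
  n_rej <- sum(!ok)
  captured <- sum(ok)
  if (is.null(expected)) {
    gaps <- 0
    if (captured > 0) {
      slot <- as.numeric(packets$time) / SAMPLING_PERIOD_S
      by_node <- split(slot, packets$node_id)
      gaps <- sum(vapply(by_node, function(s) {
        (max(s) - min(s) + 1) - length(s)
      }, numeric(1)))
    }
    lost <- gaps + n_rej
  } else {
    lost <- max(0, expected - captured)
  }
  list(
    packets = packets,
    stats = acquisition_stats(captured, lost,
                              rejected_by_reason = rejected),
    rejected = rejected
  )
}
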