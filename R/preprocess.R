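#' Stratify packets by room (bucket sort)
#'
#' Places every packet in the bucket of its sensor node in one linear pass;
#' within-bucket input order is preserved (stable). The node number carries
#' the room information, so this is the room stratification step that
#' precedes chronological sorting.
#'
#' @param packets Packet table with a `node_id` column.
#' @return Named list of packet tables, one per node id `"1"`..`"10"`
#'   (possibly zero-row).
#' @export
bucketsort_by_room <- function(packets) {
  idx <- split(seq_len(nrow(packets)),
               factor(packets$node_id, levels = 1:10))
  lapply(idx, function(i) packets[i, , drop = FALSE])
}

# One stable counting-sort pass on a digit vector (values 0..base-1):
# split() preserves within-group order, which is exactly the stable
# scatter step of counting sort.
counting_pass <- function(ord, digit, base) {
  unlist(split(ord, factor(digit[ord], levels = 0:(base - 1))),
         use.names = FALSE)
}

#' Sort packets chronologically (LSD radix sort)
#'
#' Least-significant-digit radix sort on the packet timestamp expressed as
#' whole seconds since the earliest packet, in two stable counting-sort
#' passes over 16-bit digits. Stable: packets with equal timestamps keep
#' their input order, so room stratification survives the sort.
#'
#' @param packets Packet table with a POSIXct `time` column.
#' @return The packets reordered by non-decreasing `(date, time)`.
#' @export
radixsort_chrono <- function(packets) {
  n <- nrow(packets)
  if (n <= 1) return(packets)
  key <- round(as.numeric(packets$time) - min(as.numeric(packets$time)))
  if (max(key) >= 2^32) stop("timestamp span too large for 32-bit radix key")
  base <- 65536L
  lo <- as.integer(key %% base)
  hi <- as.integer(key %/% base)
  ord <- seq_len(n)
  ord <- counting_pass(ord, lo, base)
  ord <- counting_pass(ord, hi, base)
  packets[ord, , drop = FALSE]
}

#' Compose sorted samples into segments (ambient value matrices)
#'
#' Builds the classification unit of both ad-hoc classifiers: maximal runs
#' of chronologically consecutive non-null samples from one room, stored as
#' a channels-by-time matrix. What counts as a null sample is configurable:
#'
#' * `"grid"`: a sample is null only if it is missing from the 5 s sampling
#'   grid (lost or rejected packet). Every present sample is kept.
#' * `"occupancy"`: additionally, a present sample whose passive-infrared
#'   value is below `pir_threshold` is null — the sensor reads ~0 V when
#'   nobody is in the room, so an inactive sample carries no activity
#'   signal. This is the rule the classification pipeline uses: it makes
#'   segments correspond to occupancy episodes rather than whole days.
#'
#' A run is also terminated after `max_duration_s` to bound matrix size.
#' `gap_tolerance` grid gaps (missing samples) are bridged without
#' terminating a run, so isolated transmission losses do not shatter long
#' activities; present-but-inactive samples always terminate a run under the
#' occupancy rule.
#'
#' @param stream Chronologically sorted packet table of a single node.
#' @param room Room name attached to the produced segments (defaults to the
#'   stream's `room` column if present).
#' @param null_rule `"grid"` or `"occupancy"` (see above).
#' @param pir_threshold Occupancy threshold on the PIR channel, volts.
#' @param gap_tolerance Number of consecutive missing grid samples bridged
#'   inside a run (default 0: any gap terminates, the strict reading).
#' @param max_duration_s Maximum segment span in seconds (default 12 h).
#' @param period_s Sampling period (default 5 s).
#' @return List of `adl_segment` objects: `node_id`, `room`, `t_start`,
#'   `t_end`, `times`, and `samples` (channels x time matrix).
#' @export
compose_segments <- function(stream, room = NULL,
                             null_rule = c("grid", "occupancy"),
                             pir_threshold = 0.05, gap_tolerance = 0,
                             max_duration_s = 12 * 3600, period_s = 5) {
  null_rule <- match.arg(null_rule)
  n <- nrow(stream)
  if (n == 0) return(list())
  if (length(unique(stream$node_id)) > 1) {
    stop("compose_segments expects packets of a single node")
  }
  if (is.null(room)) {
    room <- if ("room" %in% names(stream)) stream$room[1] else NA_character_
  }
  tnum <- as.numeric(stream$time)
  slot <- round(tnum / period_s)
  active <- if (null_rule == "occupancy") stream$pir >= pir_threshold
            else rep(TRUE, n)
  ai <- which(active)
  if (length(ai) == 0) return(list())

  # break between consecutive active samples when present-but-null samples
  # intervene, when more than gap_tolerance grid samples are missing, or
  # when the running span would exceed max_duration_s
  breaks <- logical(length(ai))
  if (length(ai) > 1) {
    slot_gap <- diff(slot[ai]) - 1
    present_between <- diff(ai) - 1
    missing_between <- slot_gap - present_between
    breaks[-1] <- present_between > 0 | missing_between > gap_tolerance
  }
  run_id <- cumsum(breaks) + 1
  # enforce max duration by splitting runs on span
  seg_list <- list()
  mat <- t(as.matrix(as.data.frame(stream)[ai, CHANNELS, drop = FALSE]))
  dimnames(mat) <- list(CHANNELS, NULL)
  for (g in split(seq_along(ai), run_id)) {
    if (tnum[ai[g[length(g)]]] - tnum[ai[g[1]]] <= max_duration_s) {
      seg_list[[length(seg_list) + 1]] <- g
      next
    }
    cur <- g[1]
    for (j in g[-1]) {
      if (tnum[ai[j]] - tnum[ai[cur[1]]] > max_duration_s) {
        seg_list[[length(seg_list) + 1]] <- cur
        cur <- j
      } else {
        cur <- c(cur, j)
      }
    }
    seg_list[[length(seg_list) + 1]] <- cur
  }
  lapply(seg_list, function(ix) {
    sel <- ai[ix]
    structure(list(
      node_id = stream$node_id[1],
      room = room,
      t_start = stream$time[sel[1]],
      t_end = stream$time[sel[length(sel)]],
      times = stream$time[sel],
      samples = mat[, ix, drop = FALSE]
    ), class = "adl_segment")
  })
}

#' @export
print.adl_segment <- function(x, ...) {
  cat(sprintf("<segment %s node %d: %s .. %s, %d samples>\n",
              x$room, x$node_id, format(x$t_start), format(x$t_end),
              ncol(x$samples)))
  invisible(x)
}

#' Segment a whole-home packet stream
#'
#' Full preprocessing chain: bucket sort by room, radix sort each bucket
#' chronologically, compose segments per room, and return the segments of
#' all rooms in chronological order of their start time.
#'
#' @param stream Packet table (all nodes).
#' @param home Home configuration supplying node-to-room names (optional if
#'   the stream has a `room` column).
#' @param ... Passed to [compose_segments()].
#' @return List of `adl_segment` objects sorted by `t_start`.
#' @export
segment_stream <- function(stream, home = NULL, ...) {
  buckets <- bucketsort_by_room(stream)
  segs <- list()
  for (b in buckets) {
    if (nrow(b) == 0) next
    b <- radixsort_chrono(b)
    room <- if ("room" %in% names(b)) b$room[1]
            else if (!is.null(home)) {
      home$rooms$room[match(b$node_id[1], home$rooms$node_id)]
    } else NA_character_
    segs <- c(segs, compose_segments(b, room = room, ...))
  }
  segs[order(vapply(segs, function(s) as.numeric(s$t_start), numeric(1)))]
}

channel_slope <- function(x, t_min) {
  v <- var(t_min)
  if (length(x) < 2 || v == 0) return(0)
  cov(t_min, x) / v
}

#' Summarise segments for rule evaluation and feature extraction
#'
#' Computes, per segment, the channel summaries the rule predicates and the
#' baseline features operate on: per-channel mean, SD, min, max and slope
#' (channel units per minute, least-squares), plus duration (minutes),
#' clock time of the segment start (decimal hours) and room.
#'
#' @param segments List of `adl_segment` objects.
#' @return `data.table`, one row per segment, with `segment_id`, `room`,
#'   `node_id`, `t_start`, `t_end`, `duration_min`, `clock_start_h`,
#'   `n_samples` and `<channel>_<stat>` columns.
#' @export
segment_summaries <- function(segments) {
  if (length(segments) == 0) {
    return(data.table(segment_id = integer(0)))
  }
  rows <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    tnum <- as.numeric(s$times)
    t_min <- (tnum - tnum[1]) / 60
    dur_min <- (tnum[length(tnum)] - tnum[1] + 5) / 60
    clock <- (tnum[1] %% 86400) / 3600
    out <- list(segment_id = i, room = s$room, node_id = s$node_id,
                t_start = s$t_start, t_end = s$t_end,
                duration_min = dur_min, clock_start_h = clock,
                n_samples = ncol(s$samples))
    for (ch in rownames(s$samples)) {
      x <- s$samples[ch, ]
      out[[paste0(ch, "_mean")]] <- mean(x)
      out[[paste0(ch, "_sd")]] <- if (length(x) > 1) sd(x) else 0
      out[[paste0(ch, "_min")]] <- min(x)
      out[[paste0(ch, "_max")]] <- max(x)
      out[[paste0(ch, "_slope")]] <- channel_slope(x, t_min)
    }
    out
  })
  rbindlist(rows)
}

#' Export segments as columnar text, one file per room
#'
#' @param segments List of `adl_segment` objects.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_segments <- function(segments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rooms <- unique(vapply(segments, `[[`, character(1), "room"))
  paths <- character(0)
  for (rm in rooms) {
    segs <- Filter(function(s) identical(s$room, rm), segments)
    tabs <- lapply(seq_along(segs), function(i) {
      s <- segs[[i]]
      dt <- data.table(segment = i,
                       time = format(s$times, "%Y-%m-%d %H:%M:%S",
                                     tz = "UTC"))
      for (ch in rownames(s$samples)) dt[[ch]] <- s$samples[ch, ]
      dt
    })
    p <- file.path(dir, paste0("segments_", rm, ".csv"))
    fwrite(rbindlist(tabs), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
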