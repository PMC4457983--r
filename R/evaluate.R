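#' Read / write ADL event logs
#'
#' Delimited text with columns `subject`, `adl`, `room`, `start`, `end`
#' (ISO-8601, UTC). Used for ground-truth journals, predictions and
#' simulator schedules alike.
#'
#' @param events Event table.
#' @param path File path.
#' @return `read_events`: an event `data.table`; `write_events`: `path`,
#'   invisibly.
#' @export
write_events <- function(events, path) {
  out <- data.table(
    subject = events$subject, adl = events$adl, room = events$room,
    start = format(events$start, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    end = format(events$end, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  )
  fwrite(out, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  raw <- fread(path)
  raw$start <- as.POSIXct(raw$start, tz = "UTC")
  raw$end <- as.POSIXct(raw$end, tz = "UTC")
  bad <- is.na(raw$start) | is.na(raw$end) | is.na(raw$adl)
  if (any(bad)) {
    warning(sum(bad), " malformed event rows skipped")
    raw <- raw[!bad]
  }
  raw
}

fuse_same_adl <- function(ev) {
  # fuse overlapping/touching same-ADL events to their envelope
  if (nrow(ev) <= 1) return(ev)
  setorder(ev, adl, start)
  out <- list()
  cur <- as.list(ev[1, ])
  for (i in seq_len(nrow(ev))[-1]) {
    row <- as.list(ev[i, ])
    if (identical(row$adl, cur$adl) && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
    } else {
      out[[length(out) + 1]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1]] <- cur
  res <- rbindlist(out)
  setorder(res, start)
  res
}

#' Merge the electronic and paper activity logs into one journal
#'
#' Union of both logs with two resolution rules: overlapping entries of the
#' same ADL are fused to their envelope; where entries of different ADL
#' overlap, the electronic device log wins (it has trustworthy timestamps)
#' and the paper entry is dropped with the conflict counted.
#'
#' @param device_log Event table from the wireless protocol device.
#' @param paper_log Event table from the paper-pencil log book.
#' @return List: `events` (the journalized log), `conflicts` (count of
#'   different-ADL overlaps resolved in the device log's favour).
#' @export
merge_logs <- function(device_log, paper_log) {
  conflicts <- 0L
  keep <- logical(nrow(paper_log))
  for (i in seq_len(nrow(paper_log))) {
    p <- paper_log[i, ]
    ov <- device_log$start < p$end & device_log$end > p$start
    if (any(ov & device_log$adl != p$adl)) {
      conflicts <- conflicts + 1L
    } else {
      keep[i] <- TRUE
    }
  }
  merged <- rbindlist(list(device_log, paper_log[keep]), fill = TRUE)
  list(events = fuse_same_adl(merged), conflicts = conflicts)
}

#' Remove short predicted activities (false-positive threshold)
#'
#' Drops every predicted activity that lasted less than `min_duration_s`
#' (strictly less: a 20 s activity survives the default threshold). Short
#' spurious segments are the dominant false-positive mode of
#' occupancy-segmented sensor streams.
#'
#' @param events Predicted event table.
#' @param min_duration_s Threshold in seconds (default 20).
#' @return The filtered event table.
#' @export
threshold_filter <- function(events, min_duration_s = 20) {
  if (nrow(events) == 0) return(events)
  dur <- as.numeric(events$end) - as.numeric(events$start)
  events[dur >= min_duration_s]
}

events_to_epochs <- function(events, span_start, span_end, epoch_s = 5) {
  n <- as.integer(ceiling((as.numeric(span_end) - as.numeric(span_start)) /
                            epoch_s))
  lab <- rep("none", n)
  if (nrow(events) == 0) return(lab)
  s0 <- as.numeric(span_start)
  for (i in seq_len(nrow(events))) {
    a <- floor((as.numeric(events$start[i]) - s0) / epoch_s) + 1
    b <- ceiling((as.numeric(events$end[i]) - s0) / epoch_s)
    a <- max(1L, a); b <- min(n, b)
    if (b >= a) lab[a:b] <- events$adl[i]
  }
  lab
}

#' Epoch-level confusion metrics against a journalized log
#'
#' Discretizes the time axis into epochs (default 5 s, the sampling
#' period), labels every epoch from the predicted and the truth events, and
#' computes a one-vs-rest confusion per ADL: sensitivity
#' `100 * TP / (TP + FN)` and specificity `100 * TN / (TN + FP)`, plus the
#' unweighted macro mean over the eight ADL. A metric with zero denominator
#' is reported as `NA` (undefined) and excluded from the macro mean.
#'
#' @param predicted Predicted event table.
#' @param truth Journalized ground-truth event table (same subject/span).
#' @param span_start,span_end Evaluation span (defaults to the envelope of
#'   both logs).
#' @param epoch_s Epoch length in seconds.
#' @param levels ADL labels to evaluate (default the eight ADL).
#' @return A `confusion_summary`: `per_adl` table (tp/fp/tn/fn,
#'   sensitivity, specificity) and `mean_sensitivity`/`mean_specificity`.
#' @export
confusion_metrics <- function(predicted, truth, span_start = NULL,
                              span_end = NULL, epoch_s = 5,
                              levels = adl_levels()) {
  if (is.null(span_start)) {
    span_start <- min(c(predicted$start, truth$start))
  }
  if (is.null(span_end)) span_end <- max(c(predicted$end, truth$end))
  p <- events_to_epochs(predicted, span_start, span_end, epoch_s)
  t <- events_to_epochs(truth, span_start, span_end, epoch_s)
  counts <- confusion_counts(p, t, levels)
  confusion_summary(counts)
}

confusion_counts <- function(pred_lab, truth_lab, levels = adl_levels()) {
  rows <- lapply(levels, function(adl) {
    pp <- pred_lab == adl
    tt <- truth_lab == adl
    list(adl = adl,
         tp = sum(pp & tt), fp = sum(pp & !tt),
         tn = sum(!pp & !tt), fn = sum(!pp & tt))
  })
  rbindlist(rows)
}

#' Build a confusion summary from per-ADL epoch counts
#'
#' @param counts Table with columns `adl`, `tp`, `fp`, `tn`, `fn` (one row
#'   per ADL); rows of the same ADL are summed, so per-subject counts can
#'   be pooled.
#' @return A `confusion_summary` object.
#' @export
confusion_summary <- function(counts) {
  counts <- as.data.table(counts)[, lapply(.SD, sum), by = "adl",
                                  .SDcols = c("tp", "fp", "tn", "fn")]
  counts$sensitivity <- ifelse(counts$tp + counts$fn > 0,
                               100 * counts$tp / (counts$tp + counts$fn),
                               NA_real_)
  counts$specificity <- ifelse(counts$tn + counts$fp > 0,
                               100 * counts$tn / (counts$tn + counts$fp),
                               NA_real_)
  structure(list(
    per_adl = counts,
    mean_sensitivity = mean(counts$sensitivity, na.rm = TRUE),
    mean_specificity = mean(counts$specificity, na.rm = TRUE)
  ), class = "confusion_summary")
}

#' Unweighted macro mean of per-ADL metric values
#'
#' @param values Numeric vector of per-ADL percentages (NA = undefined,
#'   excluded).
#' @return The unweighted mean.
#' @export
macro_mean <- function(values) mean(values, na.rm = TRUE)

#' @export
print.confusion_summary <- function(x, ...) {
  df <- as.data.frame(x$per_adl)
  df$sensitivity <- round(df$sensitivity, 2)
  df$specificity <- round(df$specificity, 2)
  print(df, row.names = FALSE)
  cat(sprintf("mean: sensitivity %.2f%%, specificity %.2f%%\n",
              x$mean_sensitivity, x$mean_specificity))
  invisible(x)
}

#' Write a confusion summary as a machine-readable report
#' @param x A `confusion_summary`.
#' @param path Output CSV (per-ADL rows plus a `mean` row).
#' @return `path`, invisibly.
#' @export
write_confusion_summary <- function(x, path) {
  df <- as.data.frame(x$per_adl)
  mean_row <- data.frame(adl = "mean", tp = NA, fp = NA, tn = NA, fn = NA,
                         sensitivity = x$mean_sensitivity,
                         specificity = x$mean_specificity)
  fwrite(rbind(df, mean_row), path)
  invisible(path)
}

#' Event-level outcome counts
#'
#' Matches predictions to truth events: a truth event counts as correctly
#' determined when same-ADL predictions cover at least `min_overlap` of its
#' duration. `missed = total - correct`.
#'
#' @param predicted Predicted event table.
#' @param truth Ground-truth event table.
#' @param min_overlap Required covered fraction of the truth event
#'   (default 0.5).
#' @return List with `total`, `correct`, `missed`.
#' @export
count_outcomes <- function(predicted, truth, min_overlap = 0.5) {
  total <- nrow(truth)
  correct <- 0L
  for (i in seq_len(total)) {
    tr <- truth[i, ]
    same <- predicted[predicted$adl == tr$adl]
    if (nrow(same) == 0) next
    ov <- pmin(as.numeric(same$end), as.numeric(tr$end)) -
      pmax(as.numeric(same$start), as.numeric(tr$start))
    covered <- sum(pmax(0, ov)) # same-ADL predictions never overlap
    if (covered >= min_overlap *
        (as.numeric(tr$end) - as.numeric(tr$start))) {
      correct <- correct + 1L
    }
  }
  list(total = total, correct = correct, missed = total - correct)
}

assert_no_leakage <- function(train_subjects, test_subject) {
  if (test_subject %in% train_subjects) {
    stop("leave-one-out leakage: test subject ", test_subject,
         " present in training data")
  }
  invisible(TRUE)
}

#' Leave-one-out cross-validation over subjects
#'
#' N folds for N subjects: fold k trains on all subjects but k and predicts
#' subject k. A leakage guard verifies that no test-subject row reaches the
#' training set. Classifiers that need no training (the rule-based and
#' rhythm classifiers) are applied per subject directly, without folds.
#'
#' @param data data.frame/data.table with a subject column, features and a
#'   label column.
#' @param train_fun `function(x, y)` returning a model.
#' @param predict_fun `function(model, x)` returning labels.
#' @param subject_col,label_col Column names (defaults `"subject"`,
#'   `"label"`).
#' @param feature_cols Feature columns (default: all others).
#' @param folds Optional list of per-fold train/test subject sets (each a
#'   list with `train`, `test`); mainly for testing the leakage guard.
#' @return `data.table` with `subject`, `fold`, `truth`, `predicted`, row
#'   order matching `data` within subject.
#' @export
loo_cv <- function(data, train_fun, predict_fun, subject_col = "subject",
                   label_col = "label", feature_cols = NULL, folds = NULL) {
  data <- as.data.table(data)
  subjects <- sort(unique(data[[subject_col]]))
  if (length(subjects) < 2) stop("leave-one-out needs >= 2 subjects")
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(data), c(subject_col, label_col))
  }
  if (is.null(folds)) {
    folds <- lapply(subjects, function(s) {
      list(train = setdiff(subjects, s), test = s)
    })
  }
  out <- list()
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    assert_no_leakage(f$train, f$test)
    tr <- data[data[[subject_col]] %in% f$train]
    te <- data[data[[subject_col]] == f$test]
    model <- train_fun(tr[, feature_cols, with = FALSE], tr[[label_col]])
    pred <- predict_fun(model, te[, feature_cols, with = FALSE])
    out[[k]] <- data.table(subject = te[[subject_col]], fold = k,
                           truth = te[[label_col]],
                           predicted = as.character(pred))
  }
  rbindlist(out)
}

#' Render recognized ADL as a day-by-time activity map
#'
#' Discretizes the recording span into a days x time-of-day grid and fills
#' every cell with the ADL covering the cell centre (`"none"` otherwise):
#' the visualization that makes the whole recording inspectable at once
#' and exposes day-to-day regularity as vertical banding.
#'
#' @param events Event table of one subject.
#' @param n_days Number of days on the vertical axis.
#' @param origin Start of day 1 (default: midnight of the earliest event).
#' @param bin_min Cell width in minutes (default 5).
#' @return An `activity_map`: character matrix `n_days` x bins with
#'   attributes `origin`, `bin_min`, `levels`.
#' @export
activity_map <- function(events, n_days, origin = NULL, bin_min = 5) {
  if (is.null(origin)) {
    origin <- if (nrow(events) > 0) {
      as.POSIXct(trunc(min(events$start), "days"), tz = "UTC")
    } else {
      as.POSIXct("1970-01-01", tz = "UTC")
    }
  }
  bins <- as.integer(24 * 60 / bin_min)
  grid <- matrix("none", nrow = n_days, ncol = bins)
  s0 <- as.numeric(origin)
  if (nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      a <- as.numeric(events$start[i]) - s0
      b <- as.numeric(events$end[i]) - s0
      cells <- seq(floor(a / (bin_min * 60)), ceiling(b / (bin_min * 60)) - 1)
      centres <- (cells + 0.5) * bin_min * 60
      cells <- cells[centres >= a & centres < b]
      cells <- cells[cells >= 0 & cells < n_days * bins]
      if (length(cells) == 0) next
      grid[cbind(cells %/% bins + 1, cells %% bins + 1)] <- events$adl[i]
    }
  }
  structure(grid, origin = origin, bin_min = bin_min,
            levels = c("none", adl_levels()), class = "activity_map")
}

#' Write an activity map as a plain-text matrix
#'
#' One row per day, one single-character symbol per time bin (`.` = none,
#' then the first letters `s g t b c e w a` of the eight ADL in
#' [adl_levels()] order).
#'
#' @param map An `activity_map`.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_activity_map <- function(map, path) {
  symbols <- c(none = ".", sleeping = "s", grooming = "g", toileting = "t",
               getting_ready_for_bed = "b", cooking = "c", eating = "e",
               watching_tv = "w", seated_activity = "a")
  lines <- apply(map, 1, function(row) {
    paste(symbols[row], collapse = "")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Plot an activity map
#'
#' @param x An `activity_map`.
#' @param main Plot title.
#' @param ... Ignored.
#' @return The palette used, invisibly.
#' @export
plot.activity_map <- function(x, main = "Activity map", ...) {
  lev <- attr(x, "levels")
  pal <- c("grey95", grDevices::hcl.colors(length(lev) - 1, "Dark 3"))
  z <- matrix(match(unclass(x), lev), nrow = nrow(x))
  graphics::image(x = seq_len(ncol(x)) * attr(x, "bin_min") / 60,
                  y = seq_len(nrow(x)),
                  z = t(z)[, rev(seq_len(nrow(x))), drop = FALSE],
                  col = pal, zlim = c(1, length(lev)),
                  xlab = "time of day [h]", ylab = "day", main = main,
                  useRaster = TRUE)
  invisible(stats::setNames(pal, lev))
}
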