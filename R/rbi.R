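RULE_COMPARATORS <- c(">", ">=", "=", "<=", "!=", "<")
RULE_SUMMARIES <- c("mean", "sd", "max", "min", "slope", "duration",
                    "clock_start", "room")

#' Path to the shipped default behavioural-knowledge repository
#'
#' The original deployment's rule values were defined by a medical team and
#' are not published; the package ships its own documented default
#' repository expressing the behavioural statements that are domain facts
#' (cooking can only take place in the kitchen, humidity rises during
#' grooming, sleeping has a minimum duration, meals fall in mealtime
#' windows), with every threshold exposed as a named behavioural parameter.
#'
#' @return Path to the installed YAML rule repository.
#' @export
default_rules_file <- function() {
  system.file("extdata", "default_rules.yaml", package = "adlsense",
              mustWork = TRUE)
}

#' Parse a rule repository into a lookup table
#'
#' Reads a YAML configuration holding named behavioural parameters, rules
#' (conjunctions of threshold predicates over segment summaries, each with a
#' level, priority and conclusion) and the ADL parameter windows used by the
#' rhythm classifier. Every parameter reference is resolved at parse time;
#' the returned table is indexed by conclusion and by referenced channel.
#'
#' Parse errors name the offending rule: unknown parameter, unknown
#' comparator, unknown summary, duplicate rule id, or a rule with no
#' predicates.
#'
#' @param path YAML file, or a list already parsed from YAML.
#' @return A `rule_table` object: `params` (named list with `value`,
#'   `units`, `description`), `rules`, `by_conclusion`, `by_channel`,
#'   `adl_windows`.
#' @export
parse_rules <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  params <- cfg$parameters
  if (is.null(params)) params <- list()
  for (nm in names(params)) {
    if (is.null(params[[nm]]$value)) {
      stop("parameter ", nm, " has no value")
    }
  }
  rules <- cfg$rules
  if (is.null(rules)) rules <- list()
  ids <- vapply(rules, function(r) as.character(r$id %||% ""), character(1))
  if (anyDuplicated(ids[ids != ""])) {
    stop("duplicate rule id: ", ids[duplicated(ids)][1])
  }
  rules <- lapply(rules, function(r) {
    if (is.null(r$id)) stop("rule without id")
    if (is.null(r$when) || length(r$when) == 0) {
      stop("rule ", r$id, ": no predicates")
    }
    r$level <- match.arg(r$level %||% "must", c("must", "likely"))
    r$priority <- as.integer(r$priority %||% 1L)
    if (is.null(r$conclusion) ||
        (is.null(r$conclusion$adl) && is.null(r$conclusion$fact))) {
      stop("rule ", r$id, ": conclusion must name an adl or a fact")
    }
    r$when <- lapply(r$when, function(p) {
      if (!is.null(p$fact)) return(list(fact = as.character(p$fact)))
      if (is.null(p$summary) || !(p$summary %in% RULE_SUMMARIES)) {
        stop("rule ", r$id, ": unknown summary '", p$summary %||% "?", "'")
      }
      if (is.null(p$op) || !(p$op %in% RULE_COMPARATORS)) {
        stop("rule ", r$id, ": unknown comparator '", p$op %||% "?", "'")
      }
      if (p$summary %in% c("mean", "sd", "max", "min", "slope") &&
          is.null(p$channel)) {
        stop("rule ", r$id, ": summary '", p$summary, "' needs a channel")
      }
      if (is.null(p$param) || !(p$param %in% names(params))) {
        stop("rule ", r$id, ": unknown parameter '", p$param %||% "?", "'")
      }
      p
    })
    r
  })
  names(rules) <- vapply(rules, `[[`, character(1), "id")
  concl <- vapply(rules, function(r) {
    r$conclusion$adl %||% r$conclusion$fact
  }, character(1))
  chans <- lapply(rules, function(r) {
    unique(unlist(lapply(r$when, `[[`, "channel")))
  })
  by_channel <- list()
  for (i in seq_along(rules)) {
    for (ch in chans[[i]]) by_channel[[ch]] <- c(by_channel[[ch]], names(rules)[i])
  }
  structure(list(
    params = params,
    rules = rules,
    by_conclusion = split(names(rules), concl),
    by_channel = by_channel,
    adl_windows = cfg$adl_windows
  ), class = "rule_table")
}

#' @export
print.rule_table <- function(x, ...) {
  cat(sprintf("<rule table: %d rules, %d parameters, %d ADL windows>\n",
              length(x$rules), length(x$params),
              length(x$adl_windows)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

param_value <- function(table, name) table$params[[name]]$value

compare_values <- function(value, op, target, tol) {
  if (is.na(value) || is.null(value)) return(FALSE)
  if (is.character(target) || is.character(value)) {
    return(switch(op,
      "=" = identical(as.character(value), as.character(target)),
      "!=" = !identical(as.character(value), as.character(target)),
      FALSE))
  }
  switch(op,
    ">" = value > target,
    ">=" = value >= target,
    "<" = value < target,
    "<=" = value <= target,
    "=" = abs(value - target) <= tol,
    "!=" = abs(value - target) > tol
  )
}

#' Evaluate one rule against one segment
#'
#' A rule holds iff every predicate of its conjunction holds on the
#' segment's summaries (and derived facts). A predicate on a channel the
#' segment does not carry is false. Equality on continuous summaries means
#' agreement within the `equality_tolerance` behavioural parameter (exact
#' equality of noisy sensor values would never fire).
#'
#' @param rule One rule from a parsed [parse_rules()] table.
#' @param summary_row One row of [segment_summaries()] (as a list).
#' @param table The `rule_table` (for parameter resolution).
#' @param facts Character vector of facts derived for this segment.
#' @return `TRUE` iff the rule fires.
#' @export
evaluate_rule <- function(rule, summary_row, table, facts = character(0)) {
  tol <- param_value(table, "equality_tolerance") %||% 1e-9
  for (p in rule$when) {
    if (!is.null(p$fact)) {
      if (!(p$fact %in% facts)) return(FALSE)
      next
    }
    value <- switch(p$summary,
      room = summary_row$room,
      duration = summary_row$duration_min,
      clock_start = summary_row$clock_start_h,
      summary_row[[paste0(p$channel, "_", p$summary)]]
    )
    if (is.null(value)) return(FALSE)
    if (!compare_values(value, p$op, param_value(table, p$param), tol)) {
      return(FALSE)
    }
  }
  TRUE
}

rule_rank <- function(rules, fired_ids) {
  # conflict resolution: must-level first, then priority, then specificity
  # (predicate count), then rule id for a deterministic total order
  must <- vapply(fired_ids, function(id) rules[[id]]$level == "must",
                 logical(1))
  prio <- vapply(fired_ids, function(id) rules[[id]]$priority, integer(1))
  npred <- vapply(fired_ids, function(id) length(rules[[id]]$when),
                  integer(1))
  fired_ids[order(-must, -prio, -npred, fired_ids)][1]
}

#' Forward-chaining inference over a fact base
#'
#' Data-driven inference: each iteration fires every rule whose premises
#' hold on a segment, adding fact conclusions to that segment's fact set
#' and collecting ADL conclusions as proposals, until no new fact or
#' proposal appears (quiescence) or `max_iterations` is reached (warning,
#' partial result). The fact set only grows, so chaining terminates.
#' Conclusions of earlier segments persist as historical facts
#' (`"history:<adl>"`) visible to later segments within the same run; facts
#' never leak across subjects because a run is one subject's data.
#'
#' Each segment receives at most one final ADL through conflict resolution:
#' among the rules that fired, must-level beats likely, then higher
#' priority, then more predicates (specificity), then lexicographic rule id.
#'
#' @param summaries Segment summary table ([segment_summaries()]).
#' @param table Parsed `rule_table`.
#' @param max_iterations Iteration cap (default 10).
#' @param subject Subject id stamped on the emitted events.
#' @return List: `events` (ADL event table: subject, adl, room, start, end,
#'   segment_id, rule_id), `facts` (per-segment fact sets), `iterations`.
#' @export
forward_chain <- function(summaries, table, max_iterations = 10,
                          subject = NA_integer_) {
  n <- nrow(summaries)
  if (n == 0 || length(table$rules) == 0) {
    return(list(events = empty_events(), facts = list(), iterations = 0L))
  }
  rows <- lapply(seq_len(n), function(i) as.list(summaries[i, ]))
  ord <- order(summaries$t_start)
  facts <- replicate(n, character(0), simplify = FALSE)
  fired <- matrix(FALSE, nrow = n, ncol = length(table$rules),
                  dimnames = list(NULL, names(table$rules)))
  adl_fired <- replicate(n, character(0), simplify = FALSE)
  history <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    changed <- FALSE
    for (i in ord) {
      for (id in names(table$rules)) {
        if (fired[i, id]) next
        r <- table$rules[[id]]
        if (evaluate_rule(r, rows[[i]], table,
                          facts = c(facts[[i]], history))) {
          fired[i, id] <- TRUE
          changed <- TRUE
          if (!is.null(r$conclusion$fact)) {
            facts[[i]] <- union(facts[[i]], r$conclusion$fact)
          } else {
            adl_fired[[i]] <- union(adl_fired[[i]], id)
            facts[[i]] <- union(facts[[i]],
                                paste0("adl:", r$conclusion$adl))
            history <- union(history,
                             paste0("history:", r$conclusion$adl))
          }
        }
      }
    }
    if (!changed) break
    if (iter >= max_iterations) {
      warning("forward chaining stopped at max_iterations with facts ",
              "still changing; partial result")
      break
    }
  }
  events <- list()
  for (i in seq_len(n)) {
    if (length(adl_fired[[i]]) == 0) next
    win <- rule_rank(table$rules, adl_fired[[i]])
    events[[length(events) + 1]] <- list(
      subject = subject,
      adl = table$rules[[win]]$conclusion$adl,
      room = rows[[i]]$room,
      start = rows[[i]]$t_start,
      end = rows[[i]]$t_end + 5,
      segment_id = rows[[i]]$segment_id,
      rule_id = win
    )
  }
  ev <- if (length(events) > 0) rbindlist(events) else empty_events()
  list(events = ev, facts = facts, iterations = iter)
}

empty_events <- function() {
  data.table(subject = integer(0), adl = character(0), room = character(0),
             start = as.POSIXct(character(0), tz = "UTC"),
             end = as.POSIXct(character(0), tz = "UTC"))
}

#' Classify segments with the rule-based inference engine
#'
#' Convenience wrapper: summarise segments, forward chain against the rule
#' table, and return the time-stamped ADL events.
#'
#' @param segments List of `adl_segment` objects (one subject).
#' @param table Parsed rule table (default: shipped repository).
#' @param subject Subject id for the emitted events.
#' @param max_iterations Iteration cap for the chaining loop.
#' @return ADL event `data.table` (subject, adl, room, start, end, ...).
#' @export
rbi_classify <- function(segments, table = parse_rules(default_rules_file()),
                         subject = NA_integer_, max_iterations = 10) {
  summaries <- segment_summaries(segments)
  forward_chain(summaries, table, max_iterations = max_iterations,
                subject = subject)$events
}
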