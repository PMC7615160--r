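## Temporal event-history categories.
##
## The analysis represents each adverse-event type by a mutually exclusive
## "time since qualifying occurrence" category.  Two clocks are used:
##   * QoL model   — time from the LAST occurrence of the event to the QoL
##                   measurement day (recent events matter most for QoL);
##   * cost model  — annual periods relative to the FIRST occurrence since
##                   randomization (costs track disease onset).
## A year is 365.25 days throughout; the "within 1 year" bin is closed on
## the right (a gap of exactly 1.0 year is <=1 year).

DAYS_PER_YEAR <- 365.25

#' Adverse-event types
#'
#' The ten event types tracked by the analysis: myocardial infarction
#' (`mi`), nonhemorrhagic stroke (`stroke`), urgent and nonurgent coronary
#' revascularization (`ucrv`, `ncrv`), heart-failure admission (`hf`),
#' noncoronary revascularization (`ncr`), incident cancer (`cancer`),
#' incident diabetes (`diabetes`), vascular death (`vdeath`) and
#' nonvascular death (`nvdeath`).
#'
#' @return Character vector of the ten event-type codes.
#' @export
event_types <- function() {
  c("mi", "stroke", "ucrv", "ncrv", "hf", "ncr",
    "cancer", "diabetes", "vdeath", "nvdeath")
}

#' @rdname event_types
#' @details `death_types()` returns the two terminal types;
#'   `certain_admission_types()` the types whose occurrence always entails
#'   a hospital admission (so the probability of any cost in their event
#'   year is 1 by definition).
#' @export
death_types <- function() c("vdeath", "nvdeath")

#' @rdname event_types
#' @export
certain_admission_types <- function() c("ucrv", "ncrv", "hf")

#' Temporal category levels
#'
#' The five unmerged levels: `no_event`, `y0` (event within 1 year /
#' in current annual period), `y1_2`, `y2_3` and `gt3y`.  The F-test
#' merging procedure can replace adjacent event levels by union levels
#' (e.g. `gt1y` for `y1_2 + y2_3 + gt3y`); `no_event` is never merged.
#'
#' @return Character vector of the five base levels, ordered from
#'   `no_event` to `gt3y`.
#' @export
temporal_levels <- function() c("no_event", "y0", "y1_2", "y2_3", "gt3y")

# label for a merged run of consecutive base levels (indices into the four
# event levels y0..gt3y, i.e. 1..4)
merged_label <- function(lo, hi) {
  if (lo == hi) return(c("y0", "y1_2", "y2_3", "gt3y")[lo])
  if (lo == 1L && hi == 4L) return("any")       # "any history"
  if (hi == 4L) return(paste0("gt", lo - 1L, "y"))
  paste0("y", lo - 1L, "_", hi)
}

#' Temporal category on the QoL clock (last occurrence)
#'
#' Bins the gap between the last occurrence of an event and the QoL
#' measurement day.  Events after the measurement day are ignored; if all
#' events fall after it the category is `no_event` with a warning.
#'
#' @param event_days numeric vector of event days (since randomization)
#'   for one participant and one event type; may be empty.
#' @param qol_day day of the QoL measurement (>= 0).
#' @return One of [temporal_levels()].
#' @examples
#' qol_category(numeric(0), 1460)        # "no_event"
#' qol_category(c(100, 600), 1460)       # gap 2.35y -> "y2_3"
#' qol_category(1440, 1460)              # "y0"
#' @export
qol_category <- function(event_days, qol_day) {
  stopifnot(length(qol_day) == 1L, qol_day >= 0)
  if (length(event_days) == 0L) return("no_event")
  eligible <- event_days[event_days <= qol_day]
  if (length(eligible) == 0L) {
    warning("all events fall after the QoL measurement day; ",
            "treating as no_event", call. = FALSE)
    return("no_event")
  }
  gap <- (qol_day - max(eligible)) / DAYS_PER_YEAR
  if (gap <= 1) "y0" else if (gap <= 2) "y1_2" else if (gap <= 3) "y2_3" else "gt3y"
}

#' Temporal category on the cost clock (first occurrence)
#'
#' Annual period `k` covers days `[365.25 k, 365.25 (k + 1))`.  A period
#' before the first occurrence (or with no event at all) is `no_event`;
#' the period containing the first occurrence is `y0`; subsequent periods
#' advance through `y1_2`, `y2_3` and `gt3y`.
#'
#' @param first_event_day day of first occurrence, or `NA`/`NULL` if the
#'   event never occurred.
#' @param period_index integer period index `k >= 0`.  Vectorised over
#'   both arguments.
#' @return Character vector of categories.
#' @examples
#' cost_category(400, 1)  # event in period 1, same period -> "y0"
#' cost_category(400, 3)  # two periods later -> "y2_3"
#' cost_category(400, 0)  # before the event -> "no_event"
#' @export
cost_category <- function(first_event_day, period_index) {
  if (is.null(first_event_day) || length(first_event_day) == 0L)
    first_event_day <- NA_real_
  if (any(period_index < 0)) stop("period_index must be >= 0", call. = FALSE)
  if (any(first_event_day < 0, na.rm = TRUE))
    stop("first_event_day must be >= 0", call. = FALSE)
  n <- max(length(first_event_day), length(period_index))
  fd <- rep_len(as.numeric(first_event_day), n)
  k <- rep_len(as.integer(period_index), n)
  ev_period <- floor(fd / DAYS_PER_YEAR)
  lag <- k - ev_period
  out <- rep("no_event", n)
  out[!is.na(fd) & lag == 0] <- "y0"
  out[!is.na(fd) & lag == 1] <- "y1_2"
  out[!is.na(fd) & lag == 2] <- "y2_3"
  out[!is.na(fd) & lag >= 3] <- "gt3y"
  out
}

#' Fatal / nonfatal classification of an event
#'
#' An event is *fatal* if a death occurs in the same annual period as the
#' event, otherwise nonfatal.
#'
#' @param event_day day of the event.
#' @param death_day day of death, or `NA` if the participant survived.
#' @return Logical vector.
#' @examples
#' classify_fatal(100, 200)  # TRUE  (both in period 0)
#' classify_fatal(100, 500)  # FALSE (death in period 1)
#' classify_fatal(100, NA)   # FALSE
#' @export
classify_fatal <- function(event_day, death_day) {
  n <- max(length(event_day), length(death_day))
  ed <- rep_len(as.numeric(event_day), n)
  dd <- rep_len(as.numeric(death_day), n)
  out <- !is.na(dd) & floor(ed / DAYS_PER_YEAR) == floor(dd / DAYS_PER_YEAR)
  out[is.na(ed)] <- NA
  out
}

# ---- bulk builders -------------------------------------------------------

#' Build QoL-clock categories for a cohort
#'
#' One row per participant; one factor column `cat_<type>` per event type,
#' holding the last-occurrence temporal category relative to that
#' participant's QoL measurement day.
#'
#' @param events data frame with columns `id`, `type`, `day`.
#' @param qol_days named numeric vector of QoL measurement days, names are
#'   participant ids (only these participants are returned).
#' @param types event types to build columns for.
#' @return Data frame with `id` and `cat_<type>` factor columns.
#' @export
build_qol_categories <- function(events, qol_days,
                                 types = setdiff(event_types(), death_types())) {
  ids <- names(qol_days)
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  lv <- temporal_levels()
  for (tp in types) {
    ev <- events[events$type == tp & events$id %in% ids, , drop = FALSE]
    # last occurrence at or before the QoL day, per participant
    ev <- ev[ev$day <= qol_days[match(ev$id, ids)], , drop = FALSE]
    last <- tapply(ev$day, factor(ev$id, levels = ids), max)
    gap <- (qol_days - as.numeric(last)) / DAYS_PER_YEAR
    cat <- rep("no_event", length(ids))
    cat[!is.na(gap) & gap <= 1] <- "y0"
    cat[!is.na(gap) & gap > 1 & gap <= 2] <- "y1_2"
    cat[!is.na(gap) & gap > 2 & gap <= 3] <- "y2_3"
    cat[!is.na(gap) & gap > 3] <- "gt3y"
    out[[paste0("cat_", tp)]] <- factor(cat, levels = lv)
  }
  out
}

#' Build cost-clock categories for a person-period table
#'
#' Adds, per event type, the first-occurrence temporal category for each
#' (participant, period) row, plus `occ_<type>` indicators of *any*
#' occurrence of the type in the period (used for the certain-admission
#' rule and fatal classification).
#'
#' @param py data frame with columns `id`, `period`.
#' @param events data frame with columns `id`, `type`, `day`.
#' @param types event types to build columns for.
#' @return `py` with added `cat_<type>` factors and `occ_<type>` logicals.
#' @export
build_cost_categories <- function(py, events, types = event_types()) {
  lv <- temporal_levels()
  key <- paste(py$id, py$period)
  for (tp in types) {
    ev <- events[events$type == tp, , drop = FALSE]
    first <- tapply(ev$day, ev$id, min)
    fd <- as.numeric(first[as.character(py$id)])
    py[[paste0("cat_", tp)]] <-
      factor(cost_category(fd, py$period), levels = lv)
    occ_key <- unique(paste(ev$id, floor(ev$day / DAYS_PER_YEAR)))
    py[[paste0("occ_", tp)]] <- key %in% occ_key
  }
  py
}
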