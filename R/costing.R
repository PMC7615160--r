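## Hospital episodes -> merged episodes -> annual cost series.

#' Merge overlapping hospital episodes
#'
#' Admissions with overlapping stays are combined into a single episode
#' whose interval is the union and whose cost is the sum.  "Overlapping"
#' means sharing at least one day, so a same-day readmission (discharge
#' day equal to the next admission day) is merged; episodes that abut
#' without sharing a day (discharge 5, next admission 6) are not.
#'
#' @param episodes data frame with columns `admission_day`,
#'   `discharge_day`, `unit_cost` (one participant's episodes; extra
#'   columns are dropped).  May have zero rows.
#' @return Data frame of non-overlapping episodes sorted by admission day.
#' @examples
#' e <- data.frame(admission_day = c(0, 5), discharge_day = c(10, 15),
#'                 unit_cost = c(100, 50))
#' merge_overlapping(e)  # one episode [0, 15], cost 150
#' @export
merge_overlapping <- function(episodes) {
  cols <- c("admission_day", "discharge_day", "unit_cost")
  stopifnot(all(cols %in% names(episodes)))
  e <- episodes[cols]
  if (nrow(e) == 0L) return(e)
  if (any(e$discharge_day < e$admission_day))
    stop("episode with discharge before admission", call. = FALSE)
  e <- e[order(e$admission_day, e$discharge_day), , drop = FALSE]
  adm <- e$admission_day; dis <- e$discharge_day; cost <- e$unit_cost
  out_a <- out_d <- out_c <- numeric(nrow(e))
  j <- 1L
  out_a[1L] <- adm[1L]; out_d[1L] <- dis[1L]; out_c[1L] <- cost[1L]
  for (i in seq_len(nrow(e))[-1L]) {
    if (adm[i] <= out_d[j]) {        # shares at least one day
      out_d[j] <- max(out_d[j], dis[i])
      out_c[j] <- out_c[j] + cost[i]
    } else {
      j <- j + 1L
      out_a[j] <- adm[i]; out_d[j] <- dis[i]; out_c[j] <- cost[i]
    }
  }
  data.frame(admission_day = out_a[1:j], discharge_day = out_d[1:j],
             unit_cost = out_c[1:j])
}

#' Aggregate episodes into annual cost periods
#'
#' Assigns each (merged) episode to the annual period containing its
#' admission day — episodes spanning a period boundary are not pro-rated —
#' applies the price-year inflation factor and the professional-fee
#' uplift, and truncates follow-up at death or administrative end with the
#' residual exposure recorded.
#'
#' @param episodes one participant's episodes (see [merge_overlapping()]);
#'   assumed already merged.
#' @param death_day day of death or `NA`.
#' @param followup_end end of follow-up in days.
#' @param inflation multiplicative price-index factor to the target price
#'   year (> 0).
#' @param fee_uplift multiplicative professional-fee uplift (>= 1); e.g.
#'   1.2 for the 20% uplift used with US Medicare payments.
#' @return Data frame with one row per annual period: `period`,
#'   `exposure` (fraction of year at risk), `cost`, `any_cost`,
#'   `death_period`.
#' @export
annualize <- function(episodes, death_day = NA, followup_end,
                      inflation = 1, fee_uplift = 1) {
  stopifnot(inflation > 0, fee_uplift >= 1, followup_end > 0)
  end <- if (!is.na(death_day)) min(death_day, followup_end) else followup_end
  n_per <- max(1L, ceiling(end / DAYS_PER_YEAR - 1e-9))
  period <- seq_len(n_per) - 1L
  exposure <- pmin(end / DAYS_PER_YEAR - period, 1)
  cost <- numeric(n_per)
  if (nrow(episodes) > 0L) {
    if (any(episodes$admission_day > end))
      stop("episode starting after end of follow-up", call. = FALSE)
    k <- floor(episodes$admission_day / DAYS_PER_YEAR)
    k <- pmin(k, n_per - 1L)          # admission on the boundary day
    amt <- episodes$unit_cost * inflation * fee_uplift
    agg <- tapply(amt, factor(k, levels = period), sum)
    cost <- ifelse(is.na(agg), 0, as.numeric(agg))
  }
  dp <- !is.na(death_day) && death_day <= followup_end
  data.frame(period = period, exposure = exposure, cost = cost,
             any_cost = cost > 0,
             death_period = dp & period == n_per - 1L)
}

#' Build the person-year analysis table
#'
#' Combines a cohort's annual cost series, adverse events and baseline
#' covariates into the person-period data frame consumed by
#' [two_part_glm()]: cost-clock temporal categories per event type,
#' occurrence indicators, the certain-admission flag (an urgent/nonurgent
#' coronary revascularisation or heart-failure admission occurred in the
#' period) and participant covariates.
#'
#' @param annual_costs data frame with `id`, `period`, `exposure`,
#'   `cost`, `any_cost`, `death_period` (as produced by the generator or
#'   by [annualize()] row-bound across participants).
#' @param events data frame with `id`, `type`, `day`.
#' @param participants baseline covariate table with an `id` column;
#'   its columns are merged onto the person-years.
#' @return Data frame, one row per person-period.
#' @export
person_year_table <- function(annual_costs, events, participants) {
  py <- build_cost_categories(annual_costs, events)
  cert <- rep(FALSE, nrow(py))
  for (tp in certain_admission_types())
    cert <- cert | py[[paste0("occ_", tp)]]
  py$certain_admission <- cert
  if (any(py$certain_admission & !py$any_cost))
    stop("certain-admission period with zero cost: inconsistent inputs",
         call. = FALSE)
  m <- match(py$id, participants$id)
  for (cl in setdiff(names(participants), "id"))
    py[[cl]] <- participants[[cl]][m]
  py
}
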