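#' @keywords internal
"_PACKAGE"

EQ5D_DIMENSIONS <- c("mobility", "self_care", "usual_activities",
                     "pain_discomfort", "anxiety_depression")

#' Construct and validate EQ-5D-5L profiles
#'
#' An EQ-5D-5L profile describes a health state by the level (1 = no
#' problems, ..., 5 = extreme problems) reported on each of five
#' dimensions: mobility, self-care, usual activities, pain/discomfort and
#' anxiety/depression.  Profiles are represented as a data frame with one
#' integer column per dimension.
#'
#' @param mobility,self_care,usual_activities,pain_discomfort,anxiety_depression
#'   integer vectors of equal length with levels in 1..5.
#' @return A data frame of class `eq5d_profile` with the five dimension
#'   columns.
#' @examples
#' eq5d_profile(1, 1, 1, 1, 1)          # full health
#' eq5d_profile(c(2, 5), c(1, 5), c(1, 5), c(1, 5), c(1, 5))
#' @export
eq5d_profile <- function(mobility, self_care, usual_activities,
                         pain_discomfort, anxiety_depression) {
  x <- data.frame(mobility = as.integer(mobility),
                  self_care = as.integer(self_care),
                  usual_activities = as.integer(usual_activities),
                  pain_discomfort = as.integer(pain_discomfort),
                  anxiety_depression = as.integer(anxiety_depression))
  validate_eq5d(x)
  class(x) <- c("eq5d_profile", "data.frame")
  x
}

#' Validate a table of EQ-5D-5L profiles
#'
#' Checks that all five dimension columns are present and that every level
#' lies in 1..5.  Rows that are entirely `NA` (e.g. a missing final visit)
#' are permitted; partially missing rows are not.
#'
#' @param x data frame with the five EQ-5D dimension columns.
#' @return `x`, invisibly, after validation.
#' @export
validate_eq5d <- function(x) {
  missing_cols <- setdiff(EQ5D_DIMENSIONS, names(x))
  if (length(missing_cols))
    stop("profile table lacks dimension column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- as.matrix(x[EQ5D_DIMENSIONS])
  all_na <- rowSums(is.na(m)) == ncol(m)
  some_na <- rowSums(is.na(m)) > 0 & !all_na
  if (any(some_na))
    stop("profiles with partially missing dimensions at row(s): ",
         paste(utils::head(which(some_na), 5L), collapse = ", "),
         call. = FALSE)
  bad <- !all_na & (rowSums(m < 1L | m > 5L, na.rm = TRUE) > 0)
  if (any(bad))
    stop("EQ-5D levels outside 1..5 at row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Read an EQ-5D value set (tariff) from CSV
#'
#' A tariff maps each (dimension, level) cell to a utility decrement;
#' the utility of a profile is `1 - sum(decrements)` (plus any constant
#' adjustment terms).  The CSV must have columns `dimension`, `level` and
#' `decrement`, covering all 25 cells, with zero decrement at level 1.
#' An optional row with `dimension == "constant"` supplies an
#' intercept-style term subtracted whenever any dimension is above level 1
#' (as in value sets with an "any problem" constant).
#'
#' Licensed country value sets (e.g. the UK EEPRU-based set, the US set)
#' are not redistributed with this package; obtain them from the EuroQol
#' foundation and supply them through this reader.  The bundled tariffs
#' (see [eq5d_tariff()]) are synthetic stand-ins for testing and
#' simulation.
#'
#' @param path path to a tariff CSV.
#' @param name tariff label; defaults to the file name.
#' @return An object of class `eq5d_tariff`: a list with `name`,
#'   `decrements` (5x5 matrix, dimensions x levels) and `constant`.
#' @export
read_tariff <- function(path, name = basename(path)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dimension", "level", "decrement")
  if (!all(need %in% names(tab)))
    stop("tariff CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  const <- 0
  is_const <- tab$dimension == "constant"
  if (any(is_const)) {
    const <- sum(tab$decrement[is_const])
    tab <- tab[!is_const, , drop = FALSE]
  }
  dec <- matrix(NA_real_, 5L, 5L,
                dimnames = list(EQ5D_DIMENSIONS, paste0("L", 1:5)))
  idx <- cbind(match(tab$dimension, EQ5D_DIMENSIONS), tab$level)
  if (anyNA(idx[, 1L]))
    stop("unknown dimension name(s): ",
         paste(unique(tab$dimension[is.na(idx[, 1L])]), collapse = ", "),
         call. = FALSE)
  dec[idx] <- tab$decrement
  new_tariff(name, dec, const)
}

new_tariff <- function(name, decrements, constant = 0) {
  if (anyNA(decrements))
    stop("tariff does not cover all 25 (dimension, level) cells",
         call. = FALSE)
  if (any(abs(decrements[, 1L]) > 1e-12))
    stop("tariff decrement at level 1 must be 0 for every dimension",
         call. = FALSE)
  t <- list(name = name, decrements = decrements, constant = constant)
  class(t) <- "eq5d_tariff"
  t
}

#' Bundled synthetic tariffs
#'
#' Returns one of the value-set tables shipped with the package:
#' * `"toy"` — a uniform 0.05 decrement per level step on every dimension;
#'   used in unit tests because utilities are simple arithmetic.
#' * `"synthetic_uk"` — a synthetic tariff whose decrement magnitudes are
#'   loosely UK-like (larger weights on mobility and pain) but which is
#'   *not* any licensed value set.
#' * `"synthetic_us"` — as above with a US-like, somewhat flatter pattern.
#'
#' @param name one of `"toy"`, `"synthetic_uk"`, `"synthetic_us"`.
#' @return An `eq5d_tariff` object.
#' @export
eq5d_tariff <- function(name = c("toy", "synthetic_uk", "synthetic_us")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("tariff_", name, ".csv"),
                      package = "cvdimpact", mustWork = TRUE)
  read_tariff(path, name = name)
}

#' @export
print.eq5d_tariff <- function(x, ...) {
  cat("EQ-5D-5L tariff:", x$name, "\n")
  cat("  worst-state utility:",
      format(1 - x$constant - sum(x$decrements[, 5L]), digits = 3), "\n")
  if (x$constant != 0) cat("  any-problem constant:", x$constant, "\n")
  invisible(x)
}

#' Score EQ-5D-5L profiles under a tariff
#'
#' Computes `utility = 1 - constant * any_problem - sum(decrements)` for
#' each profile row.  Full health (1,1,1,1,1) always scores exactly 1.
#' Utilities can be negative (states worse than death).  Rows that are
#' entirely `NA` score `NA`.
#'
#' @param profiles data frame of EQ-5D profiles (see [eq5d_profile()]).
#' @param tariff an `eq5d_tariff`.
#' @return Numeric vector of utilities, one per row.
#' @examples
#' score_eq5d(eq5d_profile(1, 1, 1, 1, 1), eq5d_tariff("toy"))  # 1
#' score_eq5d(eq5d_profile(2, 1, 1, 1, 1), eq5d_tariff("toy"))  # 0.95
#' @export
score_eq5d <- function(profiles, tariff) {
  validate_eq5d(profiles)
  stopifnot(inherits(tariff, "eq5d_tariff"))
  m <- as.matrix(profiles[EQ5D_DIMENSIONS])
  u <- rep(NA_real_, nrow(m))
  ok <- rowSums(is.na(m)) == 0
  if (any(ok)) {
    dec <- numeric(sum(ok))
    for (d in seq_along(EQ5D_DIMENSIONS))
      dec <- dec + tariff$decrements[d, m[ok, d]]
    any_prob <- rowSums(m[ok, , drop = FALSE] > 1L) > 0
    u[ok] <- 1 - dec - tariff$constant * any_prob
  }
  u
}

# All 3125 profiles with their utilities under a tariff, sorted by utility.
# Used for nearest-profile inversion; memoised per tariff name in a local
# environment because generation calls it once per cohort.
tariff_grid <- local({
  cache <- new.env(parent = emptyenv())
  function(tariff) {
    key <- paste0(tariff$name, "#",
                  format(sum(tariff$decrements) + tariff$constant, digits = 15))
    if (!is.null(cache[[key]])) return(cache[[key]])
    g <- expand.grid(mobility = 1:5, self_care = 1:5, usual_activities = 1:5,
                     pain_discomfort = 1:5, anxiety_depression = 1:5)
    # lexicographic order with mobility most significant, for tie-breaking
    g <- g[order(g$mobility, g$self_care, g$usual_activities,
                 g$pain_discomfort, g$anxiety_depression), ]
    u <- score_eq5d(g, tariff)
    # keep the lexicographically smallest profile for each duplicated utility
    o <- order(u, seq_along(u))
    g <- g[o, ]; u <- u[o]
    keep <- !duplicated(u)  # first occurrence = lexicographically smallest
    out <- list(profiles = g[keep, , drop = FALSE], utilities = u[keep])
    cache[[key]] <- out
    out
  }
})

#' Nearest EQ-5D profile for a target utility
#'
#' Inverts a tariff: returns, for each target utility, the profile whose
#' tariff score is nearest to it.  Exact midpoint ties are broken in
#' favour of the lexicographically smallest profile (mobility most
#' significant).  Used by the synthetic cohort generator to emit profiles
#' consistent with generated utilities.
#'
#' @param utility numeric vector of target utilities (NA allowed).
#' @param tariff an `eq5d_tariff`.
#' @return A data frame of profiles with a `utility` column holding the
#'   achieved (scored) utility.
#' @export
nearest_profile <- function(utility, tariff) {
  grid <- tariff_grid(tariff)
  gu <- grid$utilities
  idx <- rep(NA_integer_, length(utility))
  ok <- !is.na(utility)
  if (any(ok)) {
    j <- findInterval(utility[ok], gu, all.inside = TRUE)
    # candidate j (below or equal) and j+1 (above); pick nearer, tie -> the
    # lexicographically smaller, i.e. the one with *higher* utility is not
    # necessarily smaller: compare profiles explicitly on exact ties.
    lo_d <- abs(utility[ok] - gu[j])
    hi_d <- abs(gu[j + 1L] - utility[ok])
    pick_hi <- hi_d < lo_d
    tie <- abs(hi_d - lo_d) < 1e-12
    if (any(tie)) {
      p <- grid$profiles
      lex <- function(i) ((((p$mobility[i] * 5 + p$self_care[i]) * 5 +
        p$usual_activities[i]) * 5 + p$pain_discomfort[i]) * 5 +
        p$anxiety_depression[i])
      pick_hi[tie] <- lex(j[tie] + 1L) < lex(j[tie])
    }
    idx[ok] <- j + as.integer(pick_hi)
  }
  out <- grid$profiles[idx, , drop = FALSE]
  rownames(out) <- NULL
  out$utility <- grid$utilities[idx]
  out
}

#' Summarise a set of utilities
#'
#' @param profiles data frame of EQ-5D profiles; rows that are entirely
#'   `NA` are dropped with a count.
#' @param tariff an `eq5d_tariff`.
#' @return A list with `n`, `mean`, `sd`, `full_health_fraction` (share of
#'   profiles equal to (1,1,1,1,1)) and `n_missing`.
#' @examples
#' p <- eq5d_profile(c(1, 5), c(1, 5), c(1, 5), c(1, 5), c(1, 5))
#' summarize_utilities(p, eq5d_tariff("toy"))
#' @export
summarize_utilities <- function(profiles, tariff) {
  validate_eq5d(profiles)
  m <- as.matrix(profiles[EQ5D_DIMENSIONS])
  miss <- rowSums(is.na(m)) == ncol(m)
  if (all(miss) || nrow(m) == 0L)
    stop("no non-missing profiles to summarise", call. = FALSE)
  u <- score_eq5d(profiles[!miss, , drop = FALSE], tariff)
  full <- rowSums(m[!miss, , drop = FALSE] == 1L) == 5L
  list(n = sum(!miss), mean = mean(u), sd = stats::sd(u),
       full_health_fraction = mean(full), n_missing = sum(miss))
}
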