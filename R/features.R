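# Canonical predictor column layout: 20 ward-level + 88 patient-level = 108.
ward_feature_names <- function() {
  c("dow", "month", "trend",
    sprintf("adm_lag_%d", 1:7),
    sprintf("dis_lag_%d", 1:7),
    "dis_lag_14", "dis_lag_21", "occ_lag_1")
}

patient_feature_names <- function(vocab = ward_vocab()) {
  c(paste0("n_", vocab$admission_type),
    paste0("n_", vocab$referral),
    paste0("n_", vocab$patient_class),
    paste0("n_", vocab$age_band),
    paste0("n_", vocab$wards_visited),
    "mean_elapsed_los")
}

#' Predictor column manifest
#'
#' One row per predictor column of the feature matrix, with its group
#' (`ward` or `patient`) and a short description of its origin. The layout is
#' fixed: 20 ward-level columns (day of week and month of the forecast day, a
#' locally weighted polynomial trend of same-weekday discharges, admission
#' and discharge lags 1..7, discharge lags 14 and 21, previous-day occupancy)
#' and 88 patient-level columns (counts of the previous-day roster by
#' admission type, referral source, patient class, age band and wards-visited
#' band, plus the mean elapsed length of stay of patients currently in ward).
#'
#' @param vocab Vocabulary, see [ward_vocab()].
#' @return A tibble with columns `column`, `group`, `origin`.
#' @export
feature_manifest <- function(vocab = ward_vocab()) {
  wf <- ward_feature_names()
  pf <- patient_feature_names(vocab)
  origin_w <- c(
    "day of week of the forecast day (Mon=1..Sun=7)",
    "month of the forecast day (1..12)",
    "locally weighted polynomial regression trend of same-weekday discharges",
    rep("admissions lag (past 7 days)", 7),
    rep("discharges lag (past 7 days)", 7),
    "discharges on previous 14th day", "discharges on previous 21st day",
    "ward occupancy on previous day")
  origin_p <- c(
    rep("roster count by admission type", length(vocab$admission_type)),
    rep("roster count by referral source", length(vocab$referral)),
    rep("roster count by patient class", length(vocab$patient_class)),
    rep("roster count by age band", length(vocab$age_band)),
    rep("roster count by wards-visited band", length(vocab$wards_visited)),
    "mean elapsed length of stay of patients in ward")
  tibble::tibble(
    column = c(wf, pf),
    group = c(rep("ward", length(wf)), rep("patient", length(pf))),
    origin = c(origin_w, origin_p)
  )
}

#' Trend of same-weekday discharges by locally weighted polynomial regression
#'
#' Fits a locally weighted polynomial regression (degree 2, tricube weights)
#' to the sequence of past discharges observed on the same weekday and
#' evaluates the fit at the next same-weekday index, i.e. extrapolates the
#' smooth one step. With fewer than 5 past observations the fit is
#' ill-conditioned and the plain mean is returned instead.
#'
#' @param y Ordered numeric vector of past same-weekday discharges (oldest
#'   first).
#' @param span Smoothing span passed to [stats::loess()] (default 0.75).
#' @return The trend estimate for the next same-weekday occurrence.
#' @export
#' @examples
#' trend_feature(c(6, 6, 6, 6, 6, 6))
#' trend_feature(c(2, 4, 6, 8, 10, 12))  # close to 14
trend_feature <- function(y, span = 0.75) {
  if (length(y) == 0L)
    abort("`y` must contain at least one observation.",
          class = "wardflow_validation_error")
  if (length(y) < 5L) return(mean(y))
  i <- seq_along(y)
  fit <- tryCatch(
    loess(y ~ i, span = span, degree = 2, family = "gaussian",
          control = stats::loess.control(surface = "direct")),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(mean(y))
  out <- tryCatch(as.numeric(predict(fit, newdata = data.frame(i = length(y) + 1))),
                  error = function(e) NA_real_)
  if (!is.finite(out)) mean(y) else out
}

#' Patient-level predictors from a ward roster
#'
#' Computes the 88 patient-level predictors for one forecast day from the
#' roster of patients in ward at the information cutoff: 87 category counts
#' (admission type, referral source, patient class, age band, wards-visited
#' band -- categories absent from the roster count 0; rows with `"UNKNOWN"`
#' values stay in the roster but do not increment any declared category) and
#' the mean elapsed length of stay, in days, of the patients currently in
#' ward (0 by convention for an empty ward). Each block of counts over a
#' fully observed attribute sums to the roster size, i.e. to previous-day
#' occupancy.
#'
#' @param roster Visit records in ward at the cutoff, from [ward_roster()].
#' @param at_date The cutoff date (elapsed stay is counted through this day;
#'   a patient entering on `at_date` has elapsed stay 1).
#' @param vocab Vocabulary, see [ward_vocab()].
#' @param elapsed_agg Aggregate for elapsed stay: `"mean"` (default) or
#'   `"median"`.
#' @return Named numeric vector of length 88.
#' @export
patient_level_counts <- function(roster, at_date, vocab = ward_vocab(),
                                 elapsed_agg = c("mean", "median")) {
  elapsed_agg <- match.arg(elapsed_agg)
  cols <- patient_feature_names(vocab)
  out <- setNames(numeric(length(cols)), cols)
  attr_map <- list(admission_type = "admission_type", referral = "referral",
                   patient_class = "patient_class", age_band = "age_band",
                   wards_visited = "wards_visited")
  for (att in names(attr_map)) {
    vals <- as.character(roster[[attr_map[[att]]]])
    unknown <- vals == "UNKNOWN" | is.na(vals)
    bad <- !unknown & !(vals %in% vocab[[att]])
    if (any(bad))
      abort(sprintf("Roster has %s value(s) outside the vocabulary: %s",
                    att, paste(unique(vals[bad]), collapse = ", ")),
            class = "wardflow_validation_error")
    counts <- table(factor(vals[!unknown], levels = vocab[[att]]))
    out[paste0("n_", vocab[[att]])] <- as.numeric(counts)
  }
  if (nrow(roster) > 0L) {
    elapsed <- as.numeric(as.Date(at_date) - roster$entry_date) + 1
    out["mean_elapsed_los"] <-
      if (elapsed_agg == "mean") mean(elapsed) else median(elapsed)
  }
  out
}

#' Build the 108-column predictor matrix with next-day target
#'
#' Produces one row per forecastable day `d`. Every predictor is computable
#' from data available at the end of day `d - 1` (the information cutoff for
#' a next-day forecast); the target is the discharge count of day `d` itself.
#' Ward-level predictors are the day of week and month of `d` (known in
#' advance), the same-weekday trend ([trend_feature()]), admission and
#' discharge lags 1..7, discharge lags 14 and 21, and previous-day occupancy.
#' Patient-level predictors are the roster counts of
#' [patient_level_counts()] evaluated on the end-of-day-`d-1` roster. Rows
#' start at the 22nd day of the series, the first day with a complete lag-21
#' history.
#'
#' @param visits A `ward_visits` tibble from [read_ward_tables()].
#' @param daily Optional precomputed [derive_daily_series()] result; derived
#'   from `visits` when `NULL`.
#' @param dates Optional `Date` vector of target days to build rows for
#'   (defaults to every forecastable day in the series). Dates at most one
#'   day past the series end are allowed; the target is `NA` when the
#'   target-day outcome is not part of `daily`.
#' @param span Trend smoothing span, see [trend_feature()].
#' @param elapsed_agg Elapsed-stay aggregate, see [patient_level_counts()].
#' @param vocab Vocabulary, see [ward_vocab()].
#' @return A tibble (class `ward_features`) with columns `date`, `target`,
#'   and the 108 predictors of [feature_manifest()], in manifest order.
#' @export
build_feature_matrix <- function(visits, daily = NULL, dates = NULL,
                                 span = 0.75,
                                 elapsed_agg = c("mean", "median"),
                                 vocab = ward_vocab()) {
  elapsed_agg <- match.arg(elapsed_agg)
  if (is.null(daily)) daily <- derive_daily_series(visits)
  n <- nrow(daily)
  if (is.null(dates)) {
    if (n < 23L)
      abort("Need at least 23 days of daily series to build features.",
            class = "wardflow_validation_error")
    dates <- daily$date[22:n]
  }
  dates <- as.Date(dates)
  pos <- as.integer(dates - daily$date[1]) + 1L
  if (any(pos < 22L) || any(pos > n + 1L))
    abort("Feature rows need a complete 21-day lag history and at most one day beyond the series end.",
          class = "wardflow_validation_error")

  y <- daily$discharges
  a <- daily$admissions
  o <- daily$occupancy
  wf <- ward_feature_names()
  pf <- patient_feature_names(vocab)

  row_for <- function(p, d) {
    lagv <- function(v, l) as.numeric(v[p - l])
    dow_d <- iso_dow(d)
    # Same-weekday discharges strictly before day d.
    past_idx <- seq_len(p - 1L)
    same_dow <- past_idx[iso_dow(daily$date[past_idx]) == dow_d]
    ward_vals <- c(
      dow_d, month_of(d),
      trend_feature(y[same_dow], span = span),
      vapply(1:7, function(l) lagv(a, l), numeric(1)),
      vapply(1:7, function(l) lagv(y, l), numeric(1)),
      lagv(y, 14L), lagv(y, 21L), lagv(o, 1L)
    )
    names(ward_vals) <- wf
    roster <- ward_roster(visits, d - 1L)
    c(ward_vals,
      patient_level_counts(roster, d - 1L, vocab, elapsed_agg))
  }

  mat <- matrix(NA_real_, nrow = length(dates), ncol = length(wf) + length(pf),
                dimnames = list(NULL, c(wf, pf)))
  for (j in seq_along(dates)) mat[j, ] <- row_for(pos[j], dates[j])

  target <- ifelse(pos <= n, y[pmin(pos, n)], NA_real_)
  fm <- tibble::tibble(date = dates, target = as.numeric(target))
  fm <- dplyr::bind_cols(fm, tibble::as_tibble(mat))
  structure(fm, class = c("ward_features", class(tibble::tibble())),
            manifest = feature_manifest(vocab))
}

#' Write the feature-matrix column-group manifest as YAML
#'
#' @param features A `ward_features` tibble.
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_feature_manifest <- function(features, path) {
  man <- attr(features, "manifest") %||% feature_manifest()
  yaml::write_yaml(
    lapply(seq_len(nrow(man)), function(i)
      list(column = man$column[i], group = man$group[i], origin = man$origin[i])),
    path
  )
  invisible(path)
}

# Predictor columns of a feature matrix (everything except date/target).
predictor_columns <- function(features) {
  setdiff(names(features), c("date", "target"))
}
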