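# Shared fixtures: all built in code at test time.

# Hand-built visit records with sensible categorical defaults.
make_visits <- function(entry_date, exit_date,
                        entry_hour = 10L, exit_hour = 11L,
                        referral = "REF_01", patient_class = "PC_01",
                        admission_type = "AT_01", gender = "F",
                        age = 70, n_prior_wards = 0L) {
  n <- length(entry_date)
  entry_date <- as.Date(entry_date)
  exit_date <- as.Date(exit_date)
  vocab <- ward_vocab()
  tibble::tibble(
    patient_id = sprintf("PAT_%03d", seq_len(n)),
    admission_id = sprintf("ADM_%03d", seq_len(n)),
    age = rep_len(age, n),
    gender = rep_len(gender, n),
    ward_entry = as.POSIXct(entry_date, tz = "UTC") +
      rep_len(entry_hour, n) * 3600,
    ward_exit = as.POSIXct(exit_date, tz = "UTC") +
      rep_len(exit_hour, n) * 3600,
    entry_date = entry_date,
    exit_date = exit_date,
    patient_class = rep_len(patient_class, n),
    admission_type = rep_len(admission_type, n),
    referral = rep_len(referral, n),
    n_prior_wards = rep_len(n_prior_wards, n),
    age_band = wardflow:::age_to_band(rep_len(age, n), vocab),
    wards_visited = wardflow:::wards_to_band(rep_len(n_prior_wards, n) + 1L,
                                             vocab)
  )
}

# Simulated ward of moderate size, ingested, with its daily series.
sim_fixture <- function(n_days = 200L, seed = 42L, ...) {
  cfg <- sim_config(n_days = n_days, seed = seed, ...)
  visits <- read_ward_tables(simulate_ward(cfg))
  daily <- derive_daily_series(
    visits, c(cfg$start_date, cfg$start_date + cfg$n_days - 1L))
  list(config = cfg, visits = visits, daily = daily)
}

# Independent brute-force kNN oracle: plain double loop, no shared code with
# the implementation.
knn_oracle <- function(y, p, k, loss = "robust_median", weights = NULL) {
  n <- length(y)
  query <- y[(n - p + 1):n]
  starts <- 1:(n - p)
  d <- numeric(length(starts))
  nxt <- numeric(length(starts))
  for (j in seq_along(starts)) {
    i <- starts[j]
    d[j] <- sqrt(sum((y[i:(i + p - 1)] - query)^2))
    nxt[j] <- y[i + p]
  }
  ord <- order(d, starts)
  matched <- nxt[ord[1:k]]
  if (loss == "robust_median") {
    median(matched)
  } else {
    w <- if (is.null(weights)) rep(1 / k, k) else weights
    sum(w * matched)
  }
}
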