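# wardflow

Forecasting how many patients will leave a hospital ward **tomorrow**, using
only the administrative data every hospital information system already holds
— no real-time clinical information.

General wards rarely have usable real-time clinical data: diagnosis coding
happens after discharge, so at the moment a bed manager needs a forecast,
all that exists are admission records, ward-stay timestamps and coarse
patient attributes. Yet next-day discharge counts drive staffing, discharge
preparation and emergency-department boarding. `wardflow` implements a
complete, tested pipeline for this problem, aimed at health-services
researchers and hospital analytics teams:

1. **Simulate** raw three-table ward data (`patients`, `ward_stay`,
   `admissions`) with realistic structure: Poisson admissions with weekday
   and annual modulation, a geometric daily discharge hazard whose weekday
   multipliers produce the familiar Friday discharge peak and weekend
   trough, and the coarse categorical vocabularies of an administrative
   extract. Every run is seeded and bit-reproducible.
2. **Ingest** the three tables (CSV or in-memory), validate them, and derive
   the daily series of discharges `y_t`, admissions `a_t` and end-of-day
   occupancy `o_t`, which satisfy the conservation identity
   `o_t = o_{t-1} + a_t − y_t` exactly.
3. **Build features**: a 108-column predictor matrix per forecastable day —
   20 ward-level columns (day of week and month of the forecast day, a
   locally weighted polynomial trend of same-weekday discharges, admission
   and discharge lags 1–7, discharge lags 14 and 21, previous-day occupancy)
   and 88 patient-level columns (counts of the patients currently in ward by
   admission type, referral source, patient class, age band and
   wards-visited band, plus their mean elapsed length of stay).
4. **Forecast** with eight models behind one interface: three naive
   baselines (same weekday last week; mean of last 7 days; mean of last 21
   days), a from-scratch pattern-matching k-nearest-neighbour regressor,
   rolling ARIMA/ARMAX adapters (90-day refit window; day-of-week and
   previous-day occupancy as exogenous regressors for ARMAX), and
   random-forest / support-vector-regression adapters fit on the full
   feature matrix with out-of-bag and grid-search tuning.
5. **Evaluate** with a rolling one-step-ahead harness over a
   time-separated test block, scored by MFE, MAE, RMSE and sMAPE, with MAE
   improvement over the strongest naive baseline, per-weekday error tables,
   permutation feature importance, and an information-cutoff audit that
   recomputes forecasts from truncated inputs to prove nothing leaked.

## The pattern-matching kNN forecaster

The package's bespoke model treats the last *p* discharge counts as a query
vector `disch_vec = [y_{d−p+1}, …, y_d]`, finds the *k* training windows of
length *p* nearest in Euclidean distance, and combines their next-day
successors `(y_match)_i`, *i* ∈ 1…*k*. Minimising the weighted quadratic
loss Σ w_i ((y_match)_i − ŷ)² gives a weighted mean; because daily discharge
counts are noisy and outlier-prone, the default instead minimises the
robust absolute loss Σ |(y_match)_i − ŷ|, whose minimiser is the **median**
of the matched successors. (*p*, *k*) are tuned by one-step-ahead RMSE on
the tail of the training series.

The error metrics are the standard ones: `MFE = mean(y_t − f_t)`,
`MAE = mean|y_t − f_t|`, `RMSE = √mean(y_t − f_t)²`, and
`sMAPE = mean(200·|y_t − f_t|/(y_t + f_t))`, which is scale-free, defined
when the true count is zero, and bounded by 200 for nonnegative series.

## Worked example

```r
library(wardflow)

ev <- run_ward_pipeline(
  sim_config(n_days = 730, seed = 11),          # two simulated years
  models = c("naive_lw", "naive_m3w", "knn", "rf"),
  split_date = as.Date("2011-07-01"))           # train 1.5y, test 0.5y

tidy(ev)
#> # A tibble: 4 × 7
#>   model         n     mfe   mae  rmse smape mae_improvement
#>   <chr>     <int>   <dbl> <dbl> <dbl> <dbl>           <dbl>
#> 1 naive_lw    183 -0.0383  2.96  3.85  49.8            25.0
#> 2 naive_m3w   183 -0.0752  3.94  4.79  58.7            NA
#> 3 knn         183 -0.615   2.24  3.01  37.2            43.2
#> 4 rf          183 -0.0446  1.86  2.43  33.3            52.8

head(ev$importance, 5)
#> # A tibble: 5 × 4
#>    rank column     group importance
#>   <int> <chr>      <chr>      <dbl>
#> 1     1 dow        ward       23.4
#> 2     2 trend      ward        3.14
#> 3     3 occ_lag_1  ward        2.40
#> 4     4 dis_lag_14 ward        2.08
#> 5     5 dis_lag_21 ward        2.06
```

Reading the output: each row scores one model over the 183 held-out test
days. The mean-of-3-weeks baseline (`naive_m3w`, the improvement reference,
hence `NA` in its own improvement column) is blind to the weekly rhythm and
pays for it (MAE 3.94). Repeating last week's same weekday (`naive_lw`)
captures the rhythm crudely. The pattern-matching kNN cuts the error to
2.24 discharges/day, and the random forest — which also sees the ward's
current composition — reaches MAE 1.86, a 52.8% improvement over the
baseline. Its importance ranking recovers the drivers the simulator planted:
day of week first, then the same-weekday trend, previous-day occupancy and
the two-and three-week-old discharge lags. `autoplot(ev)`,
`plot_weekday_mae(ev)` and `plot_importance(ev)` draw the corresponding
figures.

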