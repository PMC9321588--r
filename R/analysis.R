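#' Coefficient of mixing (volume-weighted coefficient of variation)
#'
#' `CoM = sqrt( sum_i ((C_i - Cbar)/Cbar)^2 * V_i / sum(V_i) )` with `Cbar`
#' the volume-weighted mean. A perfectly homogeneous field gives 0; all
#' tracer concentrated in one of `Nc` equal compartments gives
#' `sqrt(Nc - 1)`. The conventional 95-percent-mixed threshold is
#' `CoM < 0.0283`.
#'
#' @param values Per-compartment concentrations.
#' @param volumes Compartment volumes (same length).
#' @return The coefficient of mixing (dimensionless).
#' @export
coefficient_of_mixing <- function(values, volumes) {
  stopifnot(length(values) == length(volumes))
  w <- volumes / sum(volumes)
  cbar <- sum(values * w)
  if (cbar == 0) {
    abort_lagcm("coefficient of mixing undefined for a zero-mean field",
                class = "lagcm_validation_error")
  }
  sqrt(sum(((values - cbar) / cbar)^2 * w))
}

#' Coefficient-of-mixing time series
#'
#' @param data A data frame with columns `time`, `compartment`, `value`
#'   (long format), or a numeric matrix with one row per time point and one
#'   column per compartment (then supply `times`).
#' @param volumes Compartment volumes.
#' @param times Time stamps when `data` is a matrix.
#' @return A tibble (time, com).
#' @export
com_curve <- function(data, volumes, times = NULL) {
  if (is.data.frame(data)) {
    wide <- tidyr::pivot_wider(data, id_cols = "time",
                               names_from = "compartment", values_from = "value")
    times <- wide$time
    m <- as.matrix(wide[, -1, drop = FALSE])
    m <- m[, order(as.integer(colnames(m))), drop = FALSE]
  } else {
    m <- data
    if (is.null(times)) times <- seq_len(nrow(m))
  }
  tibble::tibble(
    time = times,
    com = apply(m, 1, coefficient_of_mixing, volumes = volumes)
  )
}

#' Probe-based 95 percent mixing time
#'
#' The mixing time is the time after which the normalized probe signal
#' `Cs_probe / Cs_bar` stays inside the `[1 - band, 1 + band]` interval,
#' i.e. the *last* exit from the band (linearly interpolated between
#' samples).
#'
#' @param time Sample times (s), increasing.
#' @param values Normalized probe signal.
#' @param band Half-width of the acceptance band (default 0.05).
#' @return The mixing time (s); 0 if the signal never leaves the band;
#'   `NA` (never settles) if the series ends outside the band.
#' @examples
#' t <- seq(0, 80, by = 0.01)
#' probe_tau95(t, 1 + 0.2 * exp(-t / 10)) # -10 * log(0.05 / 0.2) = 13.86
#' @export
probe_tau95 <- function(time, values, band = 0.05) {
  stopifnot(length(time) == length(values), !is.unsorted(time))
  outside <- abs(values - 1) > band
  if (!any(outside)) return(0)
  k <- max(which(outside))
  if (k == length(values)) return(NA_real_)
  edge <- if (values[k] > 1) 1 + band else 1 - band
  w <- (edge - values[k]) / (values[k + 1] - values[k])
  time[k] + w * (time[k + 1] - time[k])
}

#' Classify uptake ratios into Excess / Limitation / Starvation regimes
#'
#' Excess when `qs/qs_max > upper` (default 0.95), Starvation when
#' `< lower` (default 0.05), Limitation in between. Inequalities are
#' strict: a ratio exactly at a threshold is Limitation.
#'
#' @param ratio Vector of `qs / qs_max` values.
#' @param upper,lower Regime thresholds.
#' @return Character vector of labels `"E"`, `"L"`, `"S"`.
#' @export
classify_regimes <- function(ratio, upper = 0.95, lower = 0.05) {
  out <- rep("L", length(ratio))
  out[ratio > upper] <- "E"
  out[ratio < lower] <- "S"
  out
}

# centered moving average with shrinking windows at the edges
moving_average <- function(v, k) {
  n <- length(v)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth and label a lifeline with the regime filters
#'
#' Applies the two anti-chatter filters before regime labeling: a centered
#' moving average over a `window` of 0.36 s (7 samples at the default
#' 0.06 s sampling; shrinking windows at the series edges), and a fuzzy
#' regime boundary implemented as hysteresis of half-width `fuzzy`: the
#' Excess regime is entered only above `upper + fuzzy` and left only below
#' `upper - fuzzy` (mirrored for Starvation around `lower`). Together they
#' remove short, low-amplitude regime transitions. The filters can remove
#' regime visits present in the raw labeling but never create new ones.
#'
#' @param lifeline A data frame with columns `time` and `ratio` (uniformly
#'   sampled), or a numeric ratio vector with `dt` supplied.
#' @param window Moving-average window length (s).
#' @param fuzzy Hysteresis half-width on the regime thresholds.
#' @param upper,lower Regime thresholds.
#' @param dt Sampling interval (s) when `lifeline` is a vector.
#' @return A tibble (time, ratio, smoothed, label).
#' @export
filter_lifeline <- function(lifeline, window = 0.36, fuzzy = 0.01,
                            upper = 0.95, lower = 0.05, dt = NULL) {
  if (is.data.frame(lifeline)) {
    time <- lifeline$time
    ratio <- lifeline$ratio
    dt <- if (length(time) > 1L) time[2] - time[1] else dt %||% 1
  } else {
    ratio <- lifeline
    if (is.null(dt)) abort_lagcm("supply `dt` with a ratio vector",
                                 class = "lagcm_validation_error")
    time <- (seq_along(ratio) - 1L) * dt
  }
  n <- length(ratio)
  k <- max(1L, round(window / dt))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > n) abort_lagcm("moving-average window longer than the series",
                         class = "lagcm_validation_error")
  sm <- moving_average(ratio, k)
  lab <- character(n)
  state <- classify_regimes(sm[1], upper, lower)
  lab[1] <- state
  for (i in seq_len(n)[-1]) {
    x <- sm[i]
    state <- switch(state,
      E = if (x < upper - fuzzy) {
            if (x < lower - fuzzy) "S" else "L"
          } else "E",
      S = if (x > lower + fuzzy) {
            if (x > upper + fuzzy) "E" else "L"
          } else "S",
      L = if (x > upper + fuzzy) "E" else if (x < lower - fuzzy) "S" else "L"
    )
    lab[i] <- state
  }
  tibble::tibble(time = time, ratio = ratio, smoothed = sm, label = lab)
}

#' Regime visits keyed by their flanking regimes
#'
#' A visit is a maximal run of one regime whose previous and next regimes
#' are both observed (runs truncated by the series ends are discarded). The
#' transition pattern is `previous-regime, regime, next-regime`: an `LEL`
#' visit is an Excess excursion flanked by Limitation, `SLS` a Limitation
#' passage from Starvation back to Starvation, and so on.
#'
#' @param labels Character vector of regime labels, or a data frame with
#'   columns `label` and optionally `parcel` (visits are computed per
#'   parcel).
#' @param dt Sampling interval (s).
#' @return A tibble (parcel, pattern, regime, duration).
#' @export
regime_visits <- function(labels, dt) {
  if (is.data.frame(labels)) {
    parcels <- labels$parcel %||% rep(1L, nrow(labels))
    chunks <- split(labels$label, parcels)
    return(purrr::imap_dfr(chunks, function(l, p) {
      dplyr::mutate(regime_visits(l, dt), parcel = p, .before = 1)
    }))
  }
  r <- rle(labels)
  n <- length(r$lengths)
  if (n < 3L) {
    return(tibble::tibble(pattern = character(0), regime = character(0),
                          duration = numeric(0)))
  }
  mid <- 2:(n - 1L)
  tibble::tibble(
    pattern = paste0(r$values[mid - 1L], r$values[mid], r$values[mid + 1L]),
    regime = r$values[mid],
    duration = r$lengths[mid] * dt
  )
}

#' Mean regime residence times per transition pattern
#'
#' @inheritParams regime_visits
#' @return A tibble (pattern, regime, n, mean_s) sorted by pattern.
#' @export
residence_time_stats <- function(labels, dt) {
  visits <- regime_visits(labels, dt)
  dplyr::arrange(
    dplyr::summarise(dplyr::group_by(visits, .data$pattern, .data$regime),
                     n = dplyr::n(), mean_s = mean(.data$duration),
                     .groups = "drop"),
    .data$pattern)
}

#' Regime time fractions with window-to-window uncertainty
#'
#' Splits the samples into consecutive time windows (default 1800 s, about
#' 30 mixing times, which averages out the spurious concentration
#' fluctuations induced by finite parcel numbers), computes the fraction of
#' (optionally weighted) sample time spent in each regime per window, and
#' reports the mean with a 2-standard-deviation margin across windows.
#'
#' @param data A data frame with columns `time`, `label`, and optionally
#'   `compartment`.
#' @param window Window length (s).
#' @param weights Optional per-compartment weights (e.g. compartment
#'   volumes) for volume-weighted Eulerian fractions; requires a
#'   `compartment` column.
#' @return A tibble (regime, mean_pct, sd2_pct, n_windows); fractions sum
#'   to 100 within round-off.
#' @export
regime_fractions <- function(data, window = 1800, weights = NULL) {
  w <- if (is.null(weights)) rep(1, nrow(data)) else weights[data$compartment]
  win <- floor(data$time / window)
  df <- tibble::tibble(win = win, label = data$label, w = w)
  per_win <- dplyr::summarise(
    dplyr::group_by(df, .data$win, .data$label),
    w = sum(.data$w), .groups = "drop_last")
  per_win <- dplyr::mutate(per_win, pct = 100 * .data$w / sum(.data$w))
  per_win <- dplyr::ungroup(per_win)
  full <- tidyr::complete(per_win, win = unique(win),
                          label = c("E", "L", "S"), fill = list(pct = 0))
  out <- dplyr::summarise(
    dplyr::group_by(full, regime = .data$label),
    mean_pct = mean(.data$pct),
    sd2_pct = if (dplyr::n() > 1) 2 * stats::sd(.data$pct) else 0,
    n_windows = dplyr::n(), .groups = "drop")
  out[match(c("E", "L", "S"), out$regime), ]
}

#' Intracellular pool distributions across the parcel population
#'
#' Summarizes population heterogeneity at a snapshot: per-pool mean,
#' population standard deviation (the heterogeneity metric) and a
#' histogram.
#'
#' @param pop A `parcel_population` with pools, or a numeric matrix with
#'   one row per parcel and named pool columns.
#' @param pools Pool names (or indices) to summarize; default all.
#' @param bins Number of histogram bins.
#' @return A tibble (pool, mean, sd, n) with list-columns `breaks` and
#'   `counts`.
#' @export
pool_histograms <- function(pop, pools = NULL, bins = 30) {
  X <- if (inherits(pop, "parcel_population")) pop$pools else pop
  if (is.null(X) || nrow(X) < 2L) {
    abort_lagcm("need at least 2 parcels with pools", class = "lagcm_validation_error")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("pool", seq_len(ncol(X)))
  pools <- pools %||% colnames(X)
  purrr::map_dfr(pools, function(p) {
    v <- X[, p]
    h <- if (stats::sd(v) > 0) graphics::hist(v, breaks = bins, plot = FALSE)
         else list(breaks = c(v[1] - 0.5, v[1] + 0.5), counts = length(v))
    tibble::tibble(
      pool = as.character(p), mean = mean(v),
      sd = sqrt(mean((v - mean(v))^2)), # population SD
      n = length(v),
      breaks = list(h$breaks), counts = list(h$counts)
    )
  })
}
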