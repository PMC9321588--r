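test_that("coefficient of mixing matches hand-evaluated cases", {
  expect_equal(coefficient_of_mixing(rep(3.2, 10), runif(10, 1, 2)), 0)
  # all tracer in one of Nc equal compartments: sqrt(Nc - 1)
  for (nc in c(4, 156)) {
    v <- rep(1, nc)
    x <- c(1, rep(0, nc - 1))
    expect_equal(coefficient_of_mixing(x, v), sqrt(nc - 1), tolerance = 1e-12)
  }
  # two equal compartments at +-5 percent
  expect_equal(coefficient_of_mixing(c(1.05, 0.95), c(1, 1)), 0.05, tolerance = 1e-12)
  expect_error(coefficient_of_mixing(c(0, 0), c(1, 1)), class = "lagcm_validation_error")
})

test_that("com_curve handles long tables and matrices identically", {
  vols <- c(1, 2, 3)
  m <- rbind(c(1, 1, 1), c(2, 1, 0.5), c(0, 0, 6))
  a <- com_curve(m, vols, times = c(0, 1, 2))
  long <- tidyr::expand_grid(time = c(0, 1, 2), compartment = 1:3)
  long$value <- as.vector(t(m))
  b <- com_curve(long, vols)
  expect_equal(a, b)
  expect_equal(a$com[1], 0)
})

test_that("probe mixing time is the last exit from the 5 percent band", {
  t <- seq(0, 100, by = 0.001)
  expect_equal(probe_tau95(t, rep(1, length(t))), 0)
  # closed form: 1 + 0.2 exp(-t/10) crosses 1.05 at -10 log(0.05/0.2)
  expect_equal(probe_tau95(t, 1 + 0.2 * exp(-t / 10)), -10 * log(0.05 / 0.2),
               tolerance = 1e-4)
  expect_equal(probe_tau95(t, 1 + 0.2 * exp(-t / 10)), 13.86, tolerance = 1e-3)
  # oscillatory decaying signal: compare against a brute-force scan oracle
  v <- 1 + 0.3 * exp(-t / 15) * cos(t / 2)
  got <- probe_tau95(t, v)
  outside <- which(abs(v - 1) > 0.05)
  scan <- t[max(outside)] # scan oracle: last sample outside the band
  expect_gte(got, scan)
  expect_lt(got - scan, 0.01)
  expect_true(all(abs(v[t > got + 0.01] - 1) <= 0.05))
  # never settles
  expect_true(is.na(probe_tau95(t, 1 + 0.2 * cos(t))))
})

test_that("regime thresholds are strict and classify the documented cases", {
  expect_equal(classify_regimes(c(0.96, 0.5, 0.04)), c("E", "L", "S"))
  expect_equal(classify_regimes(c(0.95, 0.05)), c("L", "L")) # boundary -> L
  expect_equal(classify_regimes(1), "E")
  expect_equal(classify_regimes(0), "S")
})

test_that("moving average and hysteresis remove short low-amplitude excursions", {
  dt <- 0.06
  # constant series: unchanged by both filters
  const <- filter_lifeline(rep(0.5, 100), dt = dt)
  expect_equal(const$smoothed, rep(0.5, 100))
  expect_true(all(const$label == "L"))
  # single-sample spike 0.90 -> 0.955 -> 0.90: 7-point average stays below
  # 0.96, so no Excess visit survives the filters
  v <- rep(0.90, 60); v[30] <- 0.955
  spike <- filter_lifeline(v, dt = dt)
  expect_lt(max(spike$smoothed), 0.96)
  expect_true(all(spike$label == "L"))
  # without smoothing the raw labels would also stay L (0.955 > 0.95 though):
  expect_equal(classify_regimes(0.955), "E") # raw spike is an E sample
  # clean step 0.5 -> 1.0 held for >> 0.36 s: exactly one L -> E transition
  step <- filter_lifeline(c(rep(0.5, 50), rep(1, 50)), dt = dt)
  r <- rle(step$label)
  expect_equal(r$values, c("L", "E"))
  # window longer than the series errors
  expect_error(filter_lifeline(rep(0.5, 3), dt = dt), class = "lagcm_validation_error")
})

test_that("hysteresis requires crossing the outer band edges", {
  dt <- 0.06
  # hold long enough that the 7-point average reaches the plateau values
  v <- c(rep(0.5, 20), rep(0.955, 20), rep(0.5, 20), rep(0.97, 20),
         rep(0.945, 20), rep(0.93, 20))
  lab <- filter_lifeline(v, dt = dt)$label
  # 0.955 plateau never enters E (needs > 0.96); 0.97 does; 0.945 stays E
  # (leaves only below 0.94); 0.93 finally exits
  expect_equal(unique(lab[15:40]), "L")
  expect_true(any(lab[61:80] == "E"))
  expect_true(all(lab[85:95] == "E"))
  expect_equal(tail(lab, 5), rep("L", 5))
})

test_that("filtering never creates regime visits absent from the raw labels", {
  set.seed(8)
  for (i in 1:10) {
    v <- pmin(pmax(cumsum(rnorm(400, sd = 0.1)) / 3 + 0.5, 0), 1)
    raw <- classify_regimes(v)
    filt <- filter_lifeline(v, dt = 0.06)$label
    expect_lte(sum(rle(filt)$values == "E"), sum(rle(raw)$values == "E"))
    expect_lte(sum(rle(filt)$values == "S"), sum(rle(raw)$values == "S"))
  }
})

test_that("regime visits are keyed by their flanking regimes", {
  dt <- 0.06
  v <- regime_visits(c("S", "L", "L", "E"), dt)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pattern, "SLE")
  expect_equal(v$duration, 0.12, tolerance = 1e-12)
  # periodic E/L square wave: interior L visits are all ELE with duration
  # equal to the half period
  lab <- rep(rep(c("E", "L"), 10), each = 25)
  st <- residence_time_stats(lab, dt)
  expect_equal(st$mean_s[st$pattern == "ELE"], 25 * dt)
  expect_equal(st$mean_s[st$pattern == "LEL"], 25 * dt)
  # truncated end runs are discarded
  expect_equal(sum(st$n), 18L)
})

test_that("pattern statistics match a brute-force run enumeration", {
  set.seed(12)
  dt <- 0.06
  lab <- sample(c("E", "L", "S"), 2000, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  got <- regime_visits(lab, dt)
  # independent oracle: walk the sequence directly
  runs <- rle(lab)
  oracle <- list()
  for (k in seq_along(runs$lengths)[-c(1, length(runs$lengths))]) {
    oracle[[length(oracle) + 1L]] <-
      data.frame(pattern = paste0(runs$values[k - 1], runs$values[k], runs$values[k + 1]),
                 duration = runs$lengths[k] * dt)
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(nrow(got), nrow(oracle))
  agg_got <- tapply(got$duration, got$pattern, mean)
  agg_or <- tapply(oracle$duration, oracle$pattern, mean)
  expect_equal(agg_got[names(agg_or)], agg_or, tolerance = 1e-12)
})

test_that("regime fractions partition to 100 percent with windowed margins", {
  dt <- 0.06
  d <- tibble::tibble(parcel = 1, time = seq(0, by = dt, length.out = 1000),
                      label = "S")
  fr <- regime_fractions(d, window = 20)
  expect_equal(fr$mean_pct, c(0, 0, 100))
  # two windows with E-fractions 8 and 10 percent -> mean 9, 2 SD = 2.83
  d2 <- tibble::tibble(
    time = c(seq_len(100), 1800 + seq_len(100)),
    label = c(rep("E", 8), rep("L", 92), rep("E", 10), rep("L", 90)))
  fr2 <- regime_fractions(d2, window = 1800)
  expect_equal(fr2$mean_pct[fr2$regime == "E"], 9)
  expect_equal(fr2$sd2_pct[fr2$regime == "E"], 2 * stats::sd(c(8, 10)), tolerance = 1e-12)
  expect_equal(fr2$sd2_pct[fr2$regime == "E"], 2.828, tolerance = 1e-3)
  expect_equal(sum(fr2$mean_pct), 100, tolerance = 1e-12)
  # volume weighting
  d3 <- tibble::tibble(time = rep(1, 2), compartment = c(1L, 2L),
                       label = c("E", "S"))
  fr3 <- regime_fractions(d3, window = 10, weights = c(3, 1))
  expect_equal(fr3$mean_pct, c(75, 0, 25))
})

test_that("pool histograms report the population heterogeneity metric", {
  X <- cbind(a = c(1, 3), b = c(2, 2))
  h <- pool_histograms(X, bins = 4)
  expect_equal(h$mean, c(2, 2))
  expect_equal(h$sd, c(1, 0)) # population SD, and zero spread collapses
  expect_equal(h$n, c(2L, 2L))
  expect_error(pool_histograms(X[1, , drop = FALSE]), class = "lagcm_validation_error")
})
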