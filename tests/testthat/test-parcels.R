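test_that("jump probability follows the exponential escape law", {
  expect_equal(jump_probability(3, 3), 1 - exp(-1))
  expect_equal(jump_probability(0, 5), 0)
  expect_equal(jump_probability(0.03, 3), 1 - exp(-0.01), tolerance = 1e-12)
  expect_equal(jump_probability(0.03, 3), 0.0099502, tolerance = 1e-5)
  expect_error(jump_probability(0.1, 0), class = "lagcm_validation_error")
  expect_error(jump_probability(-1, 1), class = "lagcm_validation_error")
})

test_that("compartment escape times are exponential with rate 1/tau", {
  set.seed(2024)
  m <- two_box_model(flux = 500) # tau = 2 s
  tau <- m$tau[1]
  dt <- tau / 100
  n <- 1e4
  idx <- rep(1L, n)
  alive <- rep(TRUE, n)
  steps <- integer(n)
  for (k in 1:2000) {
    if (!any(alive)) break
    moved <- lagcm:::jump_compartments(idx[alive], m, dt) != 1L
    steps[alive][moved] <- k
    alive[alive] <- !moved
  }
  expect_lt(sum(alive), 5) # essentially everyone escaped within 20 tau
  # the event occurred somewhere within its step: uniform attribution
  t_esc <- (steps[!alive] - runif(sum(!alive))) * dt
  ks <- suppressWarnings(stats::ks.test(t_esc, "pexp", rate = 1 / tau))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(t_esc), tau, tolerance = 0.05)
})

test_that("destination frequencies match the flux ratios", {
  set.seed(7)
  m <- star_model(3, 1) # P(dest) = 0.75 / 0.25
  n <- 1e5
  idx <- rep(1L, n)
  # large dt so most parcels jump once; count first destinations
  out <- lagcm:::jump_compartments(idx, m, dt = 5 * m$tau[1])
  moved <- out != 1L
  counts <- table(factor(out[moved], levels = c(2, 3)))
  chi <- stats::chisq.test(as.vector(counts), p = c(0.75, 0.25))
  expect_gt(chi$p.value, 0.01)
})

test_that("one uniform deviate drives both the jump and the destination", {
  m <- star_model(3, 1)
  # psi just below P_jump gives Q near 0 -> first neighbor; near 0 gives Q
  # near 1 -> last neighbor
  p_jump <- jump_probability(1, m$tau[1])
  with_seed_draw <- function(psi) {
    # replicate the algorithm arithmetic by hand
    q <- (p_jump - psi) / p_jump
    d <- m$dest
    i1 <- (d$ptr[1] + 1):d$ptr[2]
    d$idx[i1][which(d$cum[i1] >= q)[1]]
  }
  expect_equal(with_seed_draw(p_jump * 0.999), 2L) # Q ~ 0.001 -> cum 0.75 first
  expect_equal(with_seed_draw(p_jump * 0.01), 3L)  # Q ~ 0.99 -> second neighbor
})

test_that("parcels stay put in a single-compartment model and counts are conserved", {
  f <- small_field()
  m1 <- build_compartment_model(f, c(1, 1, 1))
  pop <- parcel_population(m1, 50, start = 1)
  set.seed(1)
  pop2 <- step_parcels(pop, m1, 0.1)
  expect_identical(pop2$compartment, pop$compartment)
  m <- ring_model(4)
  pop <- parcel_population(m, 1000, start = "proportional")
  set.seed(1)
  for (i in 1:20) pop <- step_parcels(pop, m, 1)
  expect_length(pop$compartment, 1000L)
  expect_true(all(pop$compartment %in% 1:4))
  expect_equal(pop$n_parcels, 1000L)
})

test_that("jumps follow the outflow direction on asymmetric networks", {
  # directed ring: every mover from compartment 1 must land in 2, never 3
  m <- ring_model(3, flux = 100)
  set.seed(6)
  out <- lagcm:::jump_compartments(rep(1L, 1e4), m, dt = 50)
  expect_setequal(unique(out[out != 1L]), 2L)
  # and the exact one-step law matches the chain-matrix oracle
  P <- jump_chain_matrix(m, dt = 5)
  obs <- tabulate(lagcm:::jump_compartments(rep(1L, 1e5), m, dt = 5), 3) / 1e5
  expect_lt(max(abs(obs - P[1, ])), 4 * sqrt(max(P[1, ] * (1 - P[1, ])) / 1e5))
})

test_that("expected mover fraction approaches dt/tau for small steps", {
  set.seed(11)
  m <- two_box_model(flux = 500) # tau = 2
  n <- 1e6
  out <- lagcm:::jump_compartments(rep(1L, n), m, dt = 0.002)
  frac <- mean(out != 1L)
  p <- 1 - exp(-0.001)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - 0.001), 3 * se + (0.001 - p))
})

test_that("long-run parcel distribution matches the jump-chain stationary law", {
  set.seed(99)
  # unequal volumes: stationary mass proportional to 1/P_jump, not exactly M
  m <- ring_model(4, volumes = c(1, 2, 3, 4), flux = 100)
  dt <- min(m$tau) / 2
  pi_star <- chain_stationary(m, dt)
  n <- 1e5
  idx <- rep(1L, n)
  for (k in 1:400) idx <- lagcm:::jump_compartments(idx, m, dt)
  obs <- tabulate(idx, 4) / n
  tv <- sum(abs(obs - pi_star)) / 2
  tv_se <- sum(sqrt(2 * pi_star * (1 - pi_star) / (pi * n))) / 2
  expect_lt(tv, 3 * tv_se)
  # closed form for the single-destination ring: pi proportional to 1/P_jump
  expect_equal(pi_star,
               (1 / jump_probability(dt, m$tau)) / sum(1 / jump_probability(dt, m$tau)),
               tolerance = 1e-10)
})

test_that("stationary check reports uniformity against liquid mass", {
  set.seed(5)
  m <- ring_model(4, volumes = rep(1, 4), flux = 100) # tau = 10 s each
  pop <- parcel_population(m, 2e4, start = 1)
  chk <- stationary_distribution_check(pop, m, horizon = 300, dt = 1)
  expect_equal(attr(chk, "status"), "ok")
  expect_lt(attr(chk, "tv_distance"), 3 * attr(chk, "tv_stderr"))
  expect_equal(sum(chk$observed), 1)
  # equal ring: stationary = 25 percent each by symmetry
  expect_true(all(abs(chk$observed - 0.25) < 0.02))
  # too few parcels for statistics: flagged, not failed
  tiny <- parcel_population(m, 4, start = 1)
  chk2 <- stationary_distribution_check(tiny, m, horizon = 50, dt = 1)
  expect_equal(attr(chk2, "status"), "insufficient statistics")
})

test_that("large steps bias residence times long; bias vanishes as dt shrinks", {
  set.seed(31)
  m <- two_box_model(flux = 500) # tau = 2
  tau <- m$tau[1]
  mean_residence <- function(dt, n = 2e4) {
    idx <- rep(1L, n)
    alive <- rep(TRUE, n)
    steps <- integer(n)
    for (k in 1:5000) {
      if (!any(alive)) break
      moved <- lagcm:::jump_compartments(idx[alive], m, dt) != 1L
      steps[alive][moved] <- k
      alive[alive] <- !moved
    }
    mean(steps[steps > 0]) * dt
  }
  # analytic discrete-chain mean: dt / (1 - exp(-dt/tau)) >= tau, decreasing
  dts <- c(2, 0.6, 0.2, 0.02)
  means <- vapply(dts, mean_residence, numeric(1))
  analytic <- dts / (1 - exp(-dts / tau))
  expect_equal(means, analytic, tolerance = 0.03)
  expect_true(all(diff(means) < 0))
  expect_gt(means[1], tau * 1.5) # strong long bias at dt = tau
  expect_lt(abs(means[4] - tau), 0.05 * tau) # gone at dt = tau/100
})

test_that("population initialization follows the biomass bookkeeping", {
  m <- base_model()
  pop <- parcel_population(m, 1000, biomass_conc = 55)
  # Cx,p = Cx * rho * VT / Np
  expect_equal(pop$biomass[1], 55 * 1000 * sum(m$volume) / 1000, tolerance = 1e-9)
  expect_true(all(pop$compartment >= 1 & pop$compartment <= m$n_compartments))
  expect_error(parcel_population(m, 10, start = 999),
               class = "lagcm_validation_error")
})
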