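#' Initialize a parcel population
#'
#' Parcels are computational particles representing a fixed quantity of
#' biomass: each carries `Cx,p = Cx * rho_l * VT / Np` grams, an (optional)
#' intracellular pool vector, and its current compartment index. Parcels are
#' ideal flow-followers; their transport is driven purely by the compartment
#' flux matrix via [step_parcels()].
#'
#' @param model A `compartment_model`.
#' @param n_parcels Number of parcels Np.
#' @param biomass_conc Overall biomass concentration Cx (g per kg broth).
#' @param start Either `"proportional"` (random initial placement with
#'   probability proportional to compartment mass — the stationary law of the
#'   jump chain in the small-step limit), or a vector of compartment indices
#'   recycled over parcels (e.g. a single index to release all parcels at an
#'   injection point).
#' @param pools Optional numeric matrix (`n_parcels` x `n_pools`) or a single
#'   vector recycled to all parcels, holding intracellular pool values
#'   (umol/gx).
#' @return A `parcel_population`: list with `n_parcels`, `compartment`
#'   (integer vector), `biomass` (g per parcel), `pools` (matrix or NULL).
#' @examples
#' field <- build_stirred_tank_field(dims = c(16, 4, 1))
#' model <- build_compartment_model(field, c(8, 2, 1))
#' pop <- parcel_population(model, 100, start = 1)
#' @export
parcel_population <- function(model, n_parcels, biomass_conc = 55,
                              start = "proportional", pools = NULL) {
  stopifnot(inherits(model, "compartment_model"))
  n_parcels <- check_count(n_parcels, "n_parcels")
  check_positive(biomass_conc, "biomass_conc")
  total_mass <- sum(model$mass) # kg broth
  cx_p <- biomass_conc * total_mass / n_parcels # g biomass per parcel
  if (identical(start, "proportional")) {
    compartment <- sample.int(model$n_compartments, n_parcels, replace = TRUE,
                              prob = model$mass)
  } else {
    compartment <- as.integer(rep_len(start, n_parcels))
    if (any(compartment < 1L | compartment > model$n_compartments)) {
      abort_lagcm("start compartments out of range", class = "lagcm_validation_error")
    }
  }
  if (!is.null(pools)) {
    if (is.null(dim(pools))) pools <- matrix(pools, nrow = n_parcels,
                                             ncol = length(pools), byrow = TRUE)
    stopifnot(nrow(pools) == n_parcels)
  }
  structure(
    list(n_parcels = n_parcels, compartment = compartment,
         biomass = rep(cx_p, n_parcels), pools = pools),
    class = "parcel_population"
  )
}

#' @export
print.parcel_population <- function(x, ...) {
  cat(sprintf("<parcel_population> Np = %d, Cx,p = %.3g g, %s\n",
              x$n_parcels, x$biomass[1],
              if (is.null(x$pools)) "no intracellular pools"
              else sprintf("%d intracellular pools", ncol(x$pools))))
  invisible(x)
}

#' Probability that a parcel escapes its compartment within a step
#'
#' Assuming ideal mixing inside each compartment, escape is a Poisson event
#' with rate `1 / tau_i`, so `P_jump = 1 - exp(-dt / tau_i)`.
#'
#' @param dt Timestep (s, >= 0).
#' @param tau Compartment residence time(s) (s, > 0).
#' @return Jump probability in `[0, 1)`, vectorized over `tau`.
#' @examples
#' jump_probability(0.03, 3) # about 0.00995
#' @export
jump_probability <- function(dt, tau) {
  if (any(dt < 0)) abort_lagcm("`dt` must be >= 0", class = "lagcm_validation_error")
  if (any(tau <= 0)) abort_lagcm("`tau` must be > 0", class = "lagcm_validation_error")
  -expm1(-dt / tau)
}

#' Advance parcel positions by one stochastic jump step
#'
#' For every parcel one uniform deviate `psi` is drawn (in fixed parcel
#' order, so runs are bit-reproducible at a fixed seed). The parcel leaves
#' its compartment iff `psi < P_jump`; conditional on jumping, the jump
#' quantifier `Q = (P_jump - psi) / P_jump` is uniform on (0, 1] and selects
#' the destination as the first neighbor whose cumulative flux probability
#' `phi_ji / |phi_ii|` reaches `Q`. At most one jump per parcel per step, so
#' for `dt` comparable to `tau_i` residence times are biased long; the bias
#' vanishes as `dt -> 0` and is controlled via the maximum step size.
#'
#' @param pop A `parcel_population`.
#' @param model The `compartment_model` the population lives on.
#' @param dt Timestep (s, > 0).
#' @return The population with updated compartment indices; all other state
#'   untouched.
#' @export
step_parcels <- function(pop, model, dt) {
  stopifnot(inherits(pop, "parcel_population"), inherits(model, "compartment_model"))
  if (any(pop$compartment < 1L | pop$compartment > model$n_compartments)) {
    abort_lagcm("parcel in an invalid compartment", class = "lagcm_validation_error")
  }
  if (model$no_transport) {
    runif(pop$n_parcels) # keep the RNG stream aligned with the general case
    return(pop)
  }
  pop$compartment <- jump_compartments(pop$compartment, model, dt)
  pop
}

# vectorized core of the jump algorithm; also used inside the simulator
jump_compartments <- function(idx, model, dt) {
  psi <- runif(length(idx))
  p_jump <- jump_probability(dt, model$tau)[idx]
  movers <- which(psi < p_jump)
  if (length(movers)) {
    q <- (p_jump[movers] - psi[movers]) / p_jump[movers] # uniform on (0, 1]
    # cumulative destination tables are concatenated per compartment; block
    # for compartment i occupies (i-1, i], so a single findInterval resolves
    # the first neighbor with cumulative probability >= q
    pos <- findInterval(idx[movers] - 1 + q, model$dest$gcum, left.open = TRUE) + 1L
    idx[movers] <- model$dest$idx[pos]
  }
  idx
}

#' Compare the long-run parcel distribution with the liquid mass distribution
#'
#' Steps the population for `horizon` seconds with a fixed `dt` and compares
#' per-compartment parcel counts with the liquid mass fractions
#' `M_i / sum(M)`. Because parcels are ideal flow-followers, the two must
#' agree (within multinomial sampling error) for flux-balanced models.
#'
#' @param pop A `parcel_population`.
#' @param model A `compartment_model`.
#' @param horizon Simulated time (s); should be much larger than `max(tau)`.
#' @param dt Step size (s); defaults to `min(tau) / 10`.
#' @return A tibble (compartment, count, observed, expected) of compartment
#'   occupancy fractions with attributes `tv_distance` (total variation),
#'   `tv_stderr` (multinomial sampling scale of the TV distance) and
#'   `status` (`"ok"` or `"insufficient statistics"` when expected counts
#'   are too small to compare).
#' @export
stationary_distribution_check <- function(pop, model, horizon, dt = NULL) {
  dt <- dt %||% (min(model$tau) / 10)
  steps <- ceiling(horizon / dt)
  idx <- pop$compartment
  for (s in seq_len(steps)) idx <- jump_compartments(idx, model, dt)
  counts <- tabulate(idx, nbins = model$n_compartments)
  expected <- model$mass / sum(model$mass)
  observed <- counts / pop$n_parcels
  tv <- sum(abs(observed - expected)) / 2
  # expected TV under multinomial sampling: E|p_hat - p| ~ sqrt(2 p(1-p)/(pi Np))
  tv_se <- sum(sqrt(2 * expected * (1 - expected) / (pi * pop$n_parcels))) / 2
  out <- tibble::tibble(compartment = seq_len(model$n_compartments),
                        count = counts, observed = observed, expected = expected)
  attr(out, "tv_distance") <- tv
  attr(out, "tv_stderr") <- tv_se
  attr(out, "status") <- if (min(expected) * pop$n_parcels < 5) "insufficient statistics" else "ok"
  out
}
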