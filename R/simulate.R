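#' Run a compartment-model simulation
#'
#' Drives the coupled Eulerian-Lagrangian system: the per-compartment
#' species balances
#' `dCs_i/dt = (sum_j phi_ij Cs_j + phi_ii Cs_i)/M_i + Fs_i/M_i - Rs_i`
#' are integrated with an adaptive embedded Runge-Kutta 3(2)
#' (Bogacki-Shampine) scheme, steps capped at `dt_max`, and after every
#' accepted step of size `dt` all parcels perform one stochastic jump pass
#' with that `dt`. Reaction sources are recomputed from the current parcel
#' assignment inside every right-hand-side evaluation, so they are
#' continuous in `Cs` and piecewise-constant in the assignment. Runs are
#' deterministic given (seed, config, model).
#'
#' @param model A `compartment_model`.
#' @param config A [sim_config()].
#' @param kinetics A `kinetic_model` ([monod_model()] or [pool_model()]);
#'   not needed for the two mixing modes.
#' @return A `mixing_result` for modes `"mixing"`/`"parcel_mixing"`, else a
#'   `cm_sim` (see [run_protocol()]).
#' @export
simulate_cm <- function(model, config, kinetics = NULL) {
  switch(config$mode,
    mixing = run_mixing(model, config),
    parcel_mixing = run_parcel_mixing(model, config),
    run_protocol(model, config, kinetics)
  )
}

# total substrate feed (mol/s) and its compartment
feed_setup <- function(model, feed) {
  comp <- find_compartment(model, feed$y, feed$r, feed$theta)
  vt <- sum(model$volume)
  list(comp = comp, mol_per_rate = vt / feed$molar_mass) # mol/s per (g/m^3/s)
}

#' Eulerian tracer mixing study
#'
#' Injects an inert tracer (`Cs = 1 mol/kg`) into the compartment containing
#' the injection point at `t = 0` and integrates pure transport
#' (no parcels, no reaction). Records the normalized probe concentration at
#' the probe compartment and the coefficient of mixing after every accepted
#' step; mixing times are extracted with [probe_tau95()] and the CoM
#' threshold.
#'
#' @param model A `compartment_model`.
#' @param config A [sim_config()] with `mode = "mixing"`.
#' @return A `mixing_result`: list with `series` (tibble: time, probe, com),
#'   `cbar`, `tau95_probe`, `tau95_com`, compartment indices and `kind`.
#' @export
run_mixing <- function(model, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  nc <- model$n_compartments
  inj <- find_compartment(model, config$injection["y"], config$injection["r"],
                          config$injection[["theta"]] %||% 0)
  prb <- find_compartment(model, config$probe["y"], config$probe["r"],
                          config$probe[["theta"]] %||% 0)
  cs0 <- numeric(nc)
  cs0[inj] <- 1
  cbar <- sum(cs0 * model$mass) / sum(model$mass)
  if (nc == 1L) {
    series <- tibble::tibble(time = c(0, config$duration), probe = 1, com = 0)
    return(new_mixing_result(series, cbar, model, config, inj, prb, "tracer"))
  }
  phi <- model$phi
  mass <- model$mass
  rhs <- function(t, y) as.numeric(phi %*% y) / mass
  times <- probe <- com <- numeric(0)
  w <- model$volume / sum(model$volume)
  rec <- function(t, y) {
    times <<- c(times, t)
    probe <<- c(probe, y[prb] / cbar)
    com <<- c(com, sqrt(sum(((y - cbar) / cbar)^2 * w)))
  }
  rec(0, cs0)
  bs23_run(rhs, cs0, 0, config$duration,
           rel_tol = config$rel_tol, abs_tol = config$abs_tol,
           dt_max = config$dt_max,
           after_step = function(t, dt, y) { rec(t, y); NULL })
  series <- tibble::tibble(time = times, probe = probe, com = com)
  new_mixing_result(series, cbar, model, config, inj, prb, "tracer")
}

#' Lagrangian (parcel-based) tracer mixing study
#'
#' Releases all parcels in the injection compartment and steps them with a
#' fixed step `dt_max`, monitoring the local parcel concentration
#' `Cp_i = Np_i / V_i` and its coefficient of mixing (normalized by the tank
#' mean `Np / VT`). For large `Np` the CoM curve tracks the Eulerian tracer
#' curve; for small `Np` the multinomial statistical floor, about
#' `sqrt((Nc - 1) / Np)` once mixed, keeps the CoM from reaching the
#' threshold.
#'
#' @param model A `compartment_model`.
#' @param config A [sim_config()] with `mode = "parcel_mixing"`.
#' @return A `mixing_result` with `kind = "parcel"`; the `probe` column is
#'   `NA` and the series carries two CoM columns: `com`, the raw
#'   coefficient of mixing of the parcel concentration field (this is what
#'   the threshold and `tau95_com` use, and it saturates at the statistical
#'   floor), and `com_debiased`, an unbiased estimate of the underlying
#'   field CoM obtained by subtracting the known multinomial counting
#'   variance of each occupancy term.
#' @export
run_parcel_mixing <- function(model, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (config$n_parcels < 1L) {
    abort_lagcm("parcel mixing needs at least one parcel",
                class = "lagcm_validation_error")
  }
  inj <- find_compartment(model, config$injection["y"], config$injection["r"],
                          config$injection[["theta"]] %||% 0)
  np <- config$n_parcels
  idx <- rep(inj, np)
  vt <- sum(model$volume)
  w <- model$volume / vt
  cpbar <- np / vt
  dt <- config$dt_max
  n_out <- max(1L, ceiling(config$output_interval / dt))
  steps <- ceiling(config$duration / dt)
  n_rec <- floor(steps / n_out) + 1L
  times <- com <- com_deb <- numeric(n_rec)
  gv <- (vt / model$volume)
  com_of_counts <- function(ix) {
    q <- tabulate(ix, nbins = model$n_compartments) / np
    raw <- sqrt(sum(((q * gv - 1))^2 * w))
    # unbiased estimate of the underlying field CoM^2: subtract the known
    # multinomial counting variance from each occupancy term
    s_hat <- sum(w * gv^2 * (q^2 - q * (1 - q) / max(np - 1, 1))) - 1
    c(raw, sqrt(max(s_hat, 0)))
  }
  times[1] <- 0
  cc <- com_of_counts(idx)
  com[1] <- cc[1]; com_deb[1] <- cc[2]
  k <- 1L
  for (s in seq_len(steps)) {
    idx <- jump_compartments(idx, model, dt)
    if (s %% n_out == 0L) {
      k <- k + 1L
      times[k] <- s * dt
      cc <- com_of_counts(idx)
      com[k] <- cc[1]; com_deb[k] <- cc[2]
    }
  }
  series <- tibble::tibble(time = times[1:k], probe = NA_real_,
                           com = com[1:k], com_debiased = com_deb[1:k])
  new_mixing_result(series, cpbar, model, config, inj, NA_integer_, "parcel")
}

new_mixing_result <- function(series, cbar, model, config, injection, probe_comp, kind) {
  thr <- config$com_threshold
  below <- series$com < thr
  tau95_com <- if (length(below) && below[length(below)]) {
    last_above <- max(c(0L, which(!below)))
    if (last_above == 0L) 0 else series$time[last_above + 1L]
  } else NA_real_
  tau95_probe <- if (kind == "tracer" && model$n_compartments > 1L) {
    probe_tau95(series$time, series$probe)
  } else if (kind == "tracer") 0 else NA_real_
  structure(
    list(series = series, cbar = cbar, tau95_probe = tau95_probe,
         tau95_com = tau95_com, com_threshold = thr,
         injection = injection, probe_compartment = probe_comp,
         kind = kind, layout = model$layout$code,
         n_parcels = if (kind == "parcel") config$n_parcels else 0L),
    class = "mixing_result"
  )
}

#' @export
print.mixing_result <- function(x, ...) {
  cat(sprintf("<mixing_result> %s (%s): tau95_probe = %s s, tau95_CoM = %s s\n",
              x$layout, x$kind,
              format(x$tau95_probe, digits = 4), format(x$tau95_com, digits = 4)))
  if (is.na(x$tau95_com)) {
    cat("  CoM threshold not reached (statistical floor or run too short)\n")
  }
  invisible(x)
}

#' Run a reaction protocol (black-box, chemostat or fed-batch)
#'
#' Dispatches on `config$mode`:
#' * `"blackbox_euler"` — Monod kinetics coupled to the liquid phase
#'   (`Rs_i = Cx qs(Cs_i)`); parcels, if any, are passive concentration
#'   readers.
#' * `"blackbox_lagrange"` — Monod kinetics coupled to the parcel phase
#'   (`Rs_i = sum_p qs_p Cx_p / M_i`), fixed biomass.
#' * `"chemostat"` — structured kinetics per parcel with fixed overall
#'   biomass and fixed transporter pool, constant feed; with a
#'   [monod_model()] this reduces to the black-box coupling.
#' * `"fedbatch"` — structured kinetics with growing per-parcel biomass
#'   (`dCx_p/dt = mu_p Cx_p`), dynamic transporter pool, feed profile
#'   sampled every `feed$sample_interval` s; total liquid volume fixed.
#'
#' @param model A `compartment_model`.
#' @param config A [sim_config()].
#' @param kinetics A [monod_model()] or [pool_model()].
#' @return A `cm_sim` object: list with `scalars` (tibble: time, cs_vol_mean,
#'   cs_parcel_mean, cx, mu, qp, substrate_mass, cum_feed, cum_uptake),
#'   `lifelines` (tibble: parcel, time, compartment, ratio — if requested),
#'   `final` state, `conservation_defect` (relative), and the run metadata.
#' @export
run_protocol <- function(model, config, kinetics) {
  mode <- config$mode
  if (!mode %in% c("blackbox_euler", "blackbox_lagrange", "chemostat", "fedbatch")) {
    abort_lagcm("run_protocol handles the reaction modes only",
                class = "lagcm_validation_error")
  }
  if (is.null(kinetics) || !inherits(kinetics, "kinetic_model")) {
    abort_lagcm("`kinetics` must be a kinetic_model", class = "lagcm_validation_error")
  }
  structured <- inherits(kinetics, "pool_model")
  if (mode == "fedbatch" && !structured) {
    abort_lagcm("fed-batch mode requires a structured (pool) model",
                class = "lagcm_validation_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  nc <- model$n_compartments
  mass <- model$mass
  total_mass <- sum(mass)
  phi <- model$phi
  fs <- feed_setup(model, config$feed)
  np <- if (mode == "blackbox_euler" && config$n_parcels == 0L) 0L else config$n_parcels
  lagrangian <- mode %in% c("blackbox_lagrange", "chemostat", "fedbatch")
  if (lagrangian && np < 1L) {
    abort_lagcm("Lagrangian coupling needs n_parcels >= 1",
                class = "lagcm_validation_error")
  }
  npool <- if (structured && mode != "blackbox_euler") kinetics$n_pools else 0L
  chemostat_pools <- mode == "chemostat"
  dyn_biomass <- mode == "fedbatch"

  pop <- if (np > 0L) {
    pools0 <- if (npool > 0L) {
      config$initial_pools %||%
        structured_fixed_point(kinetics,
                               cs = max(config$initial_cs, kinetics$params$ks))
    }
    parcel_population(model, np, biomass_conc = config$biomass_conc,
                      start = "proportional", pools = pools0)
  } else NULL

  # state packing: [cs (nc) | cum_feed | cum_uptake | pools (np*npool) | cxp (np)]
  i_cs <- seq_len(nc)
  i_feed <- nc + 1L
  i_upt <- nc + 2L
  i_pool <- if (npool > 0L) nc + 2L + seq_len(np * npool) else integer(0)
  i_cx <- if (dyn_biomass) nc + 2L + np * npool + seq_len(np) else integer(0)
  y0 <- c(rep(config$initial_cs, nc), 0, 0,
          if (npool > 0L) as.numeric(pop$pools),
          if (dyn_biomass) pop$biomass)

  env <- new.env(parent = emptyenv())
  env$idx <- if (np > 0L) pop$compartment else integer(0)
  env$bx <- if (np > 0L) {
    bx <- numeric(nc); agg <- rowsum(pop$biomass, env$idx)
    bx[as.integer(rownames(agg))] <- agg[, 1]; bx
  } else numeric(nc)

  qs_max_ref <- kinetics$qs_max # mol/gdw/s at reference conditions
  cx_p0 <- if (np > 0L) pop$biomass[1] else NA_real_

  rhs <- function(t, y) {
    cs <- y[i_cs]
    f_rate <- feed_rate_at(config$feed, t)
    f_mol <- f_rate * fs$mol_per_rate
    dcs <- as.numeric(phi %*% cs) / mass
    dcs[fs$comp] <- dcs[fs$comp] + f_mol / mass[fs$comp]
    if (mode == "blackbox_euler") {
      rs <- eulerian_reaction(cs, kinetics)
      dy_extra <- NULL
    } else if (!structured) { # blackbox_lagrange / chemostat with Monod
      rs <- monod_uptake(cs, kinetics) * env$bx / mass
      dy_extra <- NULL
    } else {
      X <- matrix(y[i_pool], nrow = np, ncol = npool)
      pr <- structured_pool_rhs(X, cs[env$idx], kinetics,
                                chemostat = chemostat_pools)
      cxp <- if (dyn_biomass) y[i_cx] else pop$biomass
      rs <- numeric(nc)
      agg <- rowsum(pr$qs * cxp, env$idx)
      rs[as.integer(rownames(agg))] <- agg[, 1]
      rs <- rs / mass
      dy_extra <- c(as.numeric(pr$dX) / 3600,
                    if (dyn_biomass) pr$mu / 3600 * cxp)
    }
    c(dcs - rs, f_mol, sum(rs * mass), dy_extra)
  }

  # per-parcel uptake ratio qs/qs_max for lifeline recording
  ratio_of <- function(y, ids) {
    cs <- pmax(y[i_cs][env$idx[ids]], 0)
    if (!structured || mode == "blackbox_euler") {
      cs / (kinetics$ks + cs)
    } else {
      X <- matrix(y[i_pool], nrow = np, ncol = npool)
      structured_uptake(cs, X[ids, , drop = FALSE], kinetics) / qs_max_ref
    }
  }

  # recording state
  n_track <- config$lifelines
  track <- seq_len(n_track)
  n_samp <- if (n_track > 0L) floor(config$duration / config$dt_sample) + 1L else 0L
  ll_ratio <- if (n_track > 0L) matrix(NA_real_, n_samp, n_track)
  ll_comp <- if (n_track > 0L) matrix(NA_integer_, n_samp, n_track)
  ll_k <- 0L
  prev_t <- 0
  prev_ratio <- if (n_track > 0L) ratio_of(y0, track)
  if (n_track > 0L) {
    ll_k <- 1L
    ll_ratio[1L, ] <- prev_ratio
    ll_comp[1L, ] <- env$idx[track]
    next_samp <- config$dt_sample
  }

  out_rows <- list()
  liquid_rows <- list()
  record_scalars <- function(t, y) {
    cs <- y[i_cs]
    if (structured && mode != "blackbox_euler") {
      X <- matrix(y[i_pool], nrow = np, ncol = npool)
      pr <- structured_pool_rhs(X, cs[env$idx], kinetics, chemostat = chemostat_pools)
      mu_mean <- mean(pr$mu)
      qp_mean <- mean(pr$qp)
    } else {
      mu_mean <- NA_real_
      qp_mean <- NA_real_
    }
    cx <- if (dyn_biomass) sum(y[i_cx]) / total_mass
          else if (np > 0L) sum(env$bx) / total_mass else kinetics$cx
    tibble::tibble(
      time = t,
      cs_vol_mean = sum(cs * mass) / total_mass,
      cs_parcel_mean = if (np > 0L) mean(cs[env$idx]) else NA_real_,
      cx = cx, mu = mu_mean, qp = qp_mean,
      substrate_mass = sum(cs * mass),
      cum_feed = y[i_feed], cum_uptake = y[i_upt]
    )
  }
  record_liquid <- function(t, y) {
    if (isTRUE(config$store_liquid)) {
      liquid_rows[[length(liquid_rows) + 1L]] <<-
        tibble::tibble(time = t, compartment = i_cs, value = y[i_cs])
    }
  }
  out_rows[[1]] <- record_scalars(0, y0)
  record_liquid(0, y0)
  next_out <- config$output_interval

  after_step <- function(t, dt, y) {
    # lifeline sampling before the jump pass: during (prev_t, t] parcels sat
    # in their pre-jump compartments while Cs evolved continuously
    if (n_track > 0L) {
      new_ratio <- ratio_of(y, track)
      while (next_samp <= t + 1e-12) {
        wgt <- if (t > prev_t) (next_samp - prev_t) / (t - prev_t) else 1
        ll_k <<- ll_k + 1L
        ll_ratio[ll_k, ] <<- prev_ratio + wgt * (new_ratio - prev_ratio)
        ll_comp[ll_k, ] <<- env$idx[track]
        next_samp <<- next_samp + config$dt_sample
      }
      prev_ratio <<- new_ratio
      prev_t <<- t
    }
    if (np > 0L && !model$no_transport) {
      env$idx <- jump_compartments(env$idx, model, dt)
      cxp <- if (dyn_biomass) y[i_cx] else pop$biomass
      bx <- numeric(nc)
      agg <- rowsum(cxp, env$idx)
      bx[as.integer(rownames(agg))] <- agg[, 1]
      env$bx <- bx
    }
    if (t >= next_out - 1e-12) {
      out_rows[[length(out_rows) + 1L]] <<- record_scalars(t, y)
      record_liquid(t, y)
      next_out <<- (floor(t / config$output_interval) + 1) * config$output_interval
    }
    NULL
  }

  res <- bs23_run(rhs, y0, 0, config$duration,
                  rel_tol = config$rel_tol, abs_tol = config$abs_tol,
                  dt_max = config$dt_max, after_step = after_step)
  out_rows[[length(out_rows) + 1L]] <- record_scalars(res$t, res$y)
  scalars <- dplyr::distinct(dplyr::bind_rows(out_rows), .data$time, .keep_all = TRUE)

  lifelines <- if (n_track > 0L) {
    tibble::tibble(
      parcel = rep(track, each = ll_k),
      time = rep(seq(0, by = config$dt_sample, length.out = ll_k), times = n_track),
      compartment = as.integer(ll_comp[seq_len(ll_k), ]),
      ratio = as.numeric(ll_ratio[seq_len(ll_k), ])
    )
  }

  y_end <- res$y
  sub0 <- sum(y0[i_cs] * mass)
  defect <- (sum(y_end[i_cs] * mass) - sub0) - (y_end[i_feed] - y_end[i_upt])
  denom <- max(abs(y_end[i_feed]), abs(y_end[i_upt]), abs(sub0), 1e-300)

  final_pop <- if (np > 0L) {
    pop$compartment <- env$idx
    if (npool > 0L) pop$pools <- matrix(y_end[i_pool], nrow = np, ncol = npool,
                                        dimnames = list(NULL, kinetics$pool_names))
    if (dyn_biomass) pop$biomass <- y_end[i_cx]
    pop
  }

  liquid <- if (length(liquid_rows)) dplyr::bind_rows(liquid_rows)
  structure(
    list(scalars = scalars, lifelines = lifelines, liquid = liquid,
         final = list(cs = y_end[i_cs], population = final_pop,
                      cum_feed = y_end[i_feed], cum_uptake = y_end[i_upt]),
         conservation_defect = abs(defect) / denom,
         n_accept = res$n_accept, n_reject = res$n_reject,
         mode = mode, layout = model$layout$code, config = config,
         kinetics = kinetics),
    class = "cm_sim"
  )
}

#' @export
print.cm_sim <- function(x, ...) {
  last <- x$scalars[nrow(x$scalars), ]
  cat(sprintf("<cm_sim> %s on %s: %g s simulated, %d accepted steps (%d rejected)\n",
              x$mode, x$layout, last$time, x$n_accept, x$n_reject))
  cat(sprintf("  final Cs (vol mean) = %.4g mol/kg, conservation defect = %.2g\n",
              last$cs_vol_mean, x$conservation_defect))
  invisible(x)
}
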