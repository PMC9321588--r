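#' Structured multi-pool kinetic model (synthetic stand-in)
#'
#' An eight-pool structured model of glucose-limited penicillin fermentation
#' used to exercise the parcel-bound reaction framework: four metabolic
#' pools (glycolytic intermediates, amino acids, storage carbohydrate,
#' product precursor) following `dX/dt = S r - mu X`, and four enzymatic
#' pools (glucose transporter `e_glc` = XE,11, amino-acid synthesis,
#' product synthesis, maintenance enzymes) following zero-order synthesis
#' with first-order turnover plus growth dilution. ATP is handled
#' algebraically (no ATP state). All pool values are in umol per g dry
#' weight, rates in umol/gdw/h, growth rate in 1/h.
#'
#' This is a synthetic, documented stand-in: its rate constants are chosen
#' for realistic time-scale separation (a fast glycolytic pool turning over
#' in seconds, slow amino-acid and enzyme pools turning over in hours), not
#' fitted to any organism. The uptake kinetics, however, use the two
#' published transporter parameterizations: `"TU-A"` with
#' `k11 * XE,11 = 1.13 mmol/gdw/h`, `Ks = 9.8 umol/kg`, and `"TU-B"` with
#' `k11 * XE,11 = 1.6 mmol/gdw/h`, `Ks = 7.8 umol/kg`. Uptake is
#' `qs = k11 * XE,11 * Cs / (Ks + Cs)`, scaled by the current transporter
#' pool relative to its reference value.
#'
#' @param parameter_set `"TU-A"`, `"TU-B"` or `"custom"` (then supply
#'   `uptake_vmax` and `ks`).
#' @param uptake_vmax Maximum uptake `k11 * XE,11` (mmol/gdw/h).
#' @param ks Uptake affinity (umol/kg).
#' @param cx Biomass concentration (g/kg) used when the model is run with a
#'   fixed biomass (chemostat closures).
#' @param params Named list overriding individual internal rate constants
#'   (see Details in the package vignette).
#' @return A `kinetic_model` of subclass `pool_model` with fields
#'   `n_pools`, `pool_names`, `pool_class` (metabolic/enzymatic), the
#'   stoichiometric matrix `stoich` (metabolic rows x 6 rates), and `x0`, a
#'   reference initial pool vector.
#' @examples
#' km <- pool_model("TU-A")
#' structured_uptake(1e-4, km$x0, km) * 3600 * 1e3 # close to 1.13 mmol/gdw/h
#' @export
pool_model <- function(parameter_set = c("TU-A", "TU-B", "custom"),
                       uptake_vmax = NULL, ks = NULL, cx = 55,
                       params = list()) {
  parameter_set <- match.arg(parameter_set)
  preset <- switch(parameter_set,
    "TU-A" = list(uptake_vmax = 1.13, ks = 9.8),
    "TU-B" = list(uptake_vmax = 1.6, ks = 7.8),
    "custom" = list(uptake_vmax = uptake_vmax, ks = ks)
  )
  uptake_vmax <- uptake_vmax %||% preset$uptake_vmax
  ks <- ks %||% preset$ks
  check_positive(uptake_vmax, "uptake_vmax"); check_positive(ks, "ks")

  p <- list(
    # uptake (via transporter pool e_glc)
    vmax = uptake_vmax * 1e3, # umol/gdw/h at reference transporter level
    ks = ks * 1e-6,           # mol/kg
    # metabolic rate constants (per h unless noted)
    k_aa = 500, k_gly_m = 1,   # amino-acid synthesis: k_aa * e_aa * gly/(K + gly)
    k_gly = 180,               # glycolytic drain (maintenance/energy)
    k_pre = 160, k_aa_m = 5,   # precursor synthesis from amino acids
    k_p = 8, k_pre_m = 2,      # product synthesis (penicillin), rate = qp
    k_sto_in = 20, k_sto_out = 20, # reversible storage exchange
    y_aa = 0.6,                # umol amino acid per umol glycolytic flux
    y_pre = 0.05,              # umol precursor per umol amino-acid drain
    y_x = 1.2e-4,              # g biomass per umol amino-acid flux -> mu
    # enzymatic pools: zero-order synthesis, first-order turnover
    e_syn = 0.08, e_deg = 0.05, e_ref = 1
  )
  p[names(params)] <- params
  p$cx <- cx

  pool_names <- c("gly", "aa", "sto", "pre", "e_glc", "e_aa", "e_pen", "e_mnt")
  stoich <- rbind(
    gly = c(qs = 1, r_aa = -1, r_gly = -1, r_pre = 0, r_p = 0, r_sto = -1),
    aa  = c(0, p$y_aa, 0, -1, 0, 0),
    sto = c(0, 0, 0, 0, 0, 1),
    pre = c(0, 0, 0, p$y_pre, -1, 0)
  )
  structure(
    list(
      type = "structured",
      parameter_set = parameter_set,
      n_pools = 8L,
      pool_names = pool_names,
      pool_class = c(rep("metabolic", 4), rep("enzymatic", 4)),
      stoich = stoich,
      params = p,
      cx = cx,
      qs_max = uptake_vmax * 1e-3 / 3600, # mol/gdw/s at reference transporter
      x0 = c(gly = 1, aa = 100, sto = 1, pre = 30,
             e_glc = 1, e_aa = 1, e_pen = 1, e_mnt = 1)
    ),
    class = c("pool_model", "kinetic_model")
  )
}

#' @export
print.pool_model <- function(x, ...) {
  cat(sprintf(
    "<pool_model> %s: 8 pools (4 metabolic, 4 enzymatic), k11*XE11 = %.3g mmol/gdw/h, Ks = %.3g umol/kg\n",
    x$parameter_set, x$params$vmax / 1e3, x$params$ks * 1e6))
  invisible(x)
}

# X as a matrix (n x 8); returns rates (n x 6, umol/gdw/h), mu (1/h), qp
structured_rates <- function(cs, X, model) {
  p <- model$params
  X <- pmax(X, 0)
  cs <- pmax(cs, 0)
  gly <- X[, 1]; aa <- X[, 2]; sto <- X[, 3]; pre <- X[, 4]
  e_glc <- X[, 5]; e_aa <- X[, 6]; e_pen <- X[, 7]; e_mnt <- X[, 8]
  qs <- p$vmax * (e_glc / p$e_ref) * cs / (p$ks + cs)
  r_aa <- p$k_aa * (e_aa / p$e_ref) * gly / (p$k_gly_m + gly)
  r_gly <- p$k_gly * (e_mnt / p$e_ref) * gly
  r_pre <- p$k_pre * aa / (p$k_aa_m + aa)
  r_p <- p$k_p * (e_pen / p$e_ref) * pre / (p$k_pre_m + pre)
  r_sto <- p$k_sto_in * gly - p$k_sto_out * sto
  rates <- cbind(qs = qs, r_aa = r_aa, r_gly = r_gly,
                 r_pre = r_pre, r_p = r_p, r_sto = r_sto)
  list(rates = rates, mu = p$y_x * r_aa, qp = r_p)
}

as_pool_matrix <- function(X, model) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$n_pools) {
    abort_lagcm(sprintf("pool vector must have %d entries", model$n_pools),
                class = "lagcm_validation_error")
  }
  X
}

#' Specific uptake rate of the structured model
#'
#' `qs = k11 * XE,11 * Cs / (Ks + Cs)`, scaled by the current transporter
#' pool.
#'
#' @param cs Substrate concentration (mol/kg); vectorized.
#' @param X Pool vector, or matrix with one row per parcel.
#' @param model A [pool_model()].
#' @return Uptake rate (mol per g dry weight per second).
#' @export
structured_uptake <- function(cs, X, model) {
  X <- as_pool_matrix(X, model)
  p <- model$params
  qs <- p$vmax * (pmax(X[, 5], 0) / p$e_ref) * pmax(cs, 0) / (p$ks + pmax(cs, 0))
  qs * 1e-6 / 3600 # umol/g/h -> mol/g/s
}

#' Right-hand side of the intracellular pool balances
#'
#' Metabolic pools follow `dX/dt = S r - mu X`; enzymatic pools follow
#' zero-order synthesis with first-order turnover plus growth dilution,
#' `dE/dt = alpha - beta E - mu E`. In chemostat mode the transporter pool
#' `e_glc` (XE,11) is held fixed.
#'
#' @param X Pool vector (umol/gx), or matrix with one row per parcel.
#' @param cs Substrate concentration (mol/kg), scalar or one per row of `X`.
#' @param model A [pool_model()].
#' @param chemostat Hold the transporter pool fixed?
#' @return A list with `dX` (same shape as `X`, umol/gx/h), `mu` (1/h),
#'   `qs` (mol/gdw/s) and `qp` (umol/gdw/h).
#' @examples
#' km <- pool_model("TU-A")
#' structured_pool_rhs(km$x0, 1e-5, km)$mu
#' @export
structured_pool_rhs <- function(X, cs, model, chemostat = FALSE) {
  vec_in <- is.null(dim(X))
  X <- as_pool_matrix(X, model)
  p <- model$params
  sr <- structured_rates(cs, X, model)
  d_met <- sr$rates %*% t(model$stoich) - sr$mu * X[, 1:4, drop = FALSE]
  e <- pmax(X[, 5:8, drop = FALSE], 0)
  d_enz <- p$e_syn - (p$e_deg + sr$mu) * e
  if (chemostat) d_enz[, 1] <- 0
  dX <- cbind(d_met, d_enz)
  colnames(dX) <- model$pool_names
  if (vec_in) dX <- dX[1, ]
  list(dX = dX, mu = sr$mu, qs = sr$rates[, "qs"] * 1e-6 / 3600, qp = sr$qp)
}

#' Fixed point of the structured model at a given substrate level
#'
#' Solves `dX/dt = 0` by damped Newton iteration (via [pracma::fsolve()])
#' from the reference initial pools.
#'
#' @param model A [pool_model()].
#' @param cs Substrate concentration (mol/kg) at which to solve.
#' @param chemostat Hold the transporter pool at its reference value?
#' @return Named pool vector at the fixed point.
#' @export
structured_fixed_point <- function(model, cs, chemostat = TRUE) {
  free <- if (chemostat) c(1:4, 6:8) else 1:8
  x_full <- model$x0
  fn <- function(x) {
    xf <- x_full
    xf[free] <- x
    structured_pool_rhs(xf, cs, model, chemostat = chemostat)$dX[free]
  }
  sol <- pracma::fsolve(fn, x0 = unname(model$x0[free]), tol = 1e-12)
  x_full[free] <- sol$x
  x_full
}
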