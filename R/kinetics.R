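#' Black-box Monod uptake kinetics
#'
#' The simplest reaction coupling: specific glucose uptake is an
#' instantaneous saturable function of the local substrate concentration,
#' `qs = qs_max * Cs / (Ks + Cs)`, with no intracellular state. Default
#' parameters are chemostat-derived values for *Penicillium chrysogenum*:
#' `qs_max = 1.6 mmol/gdw/h`, `Ks = 7.8 umol/kg`, at a fixed biomass
#' concentration `Cx = 55 g/kg`.
#'
#' @param qs_max Maximum specific uptake rate (mmol glucose per g dry weight
#'   per hour).
#' @param ks Affinity constant (umol per kg broth).
#' @param cx Biomass concentration (g dry weight per kg broth), fixed in
#'   black-box runs.
#' @return A `kinetic_model` of subclass `monod_model`.
#' @examples
#' km <- monod_model()
#' monod_uptake(7.8e-6, km) * 3600 * 1e3 # 0.8 mmol/gdw/h at Cs = Ks
#' @export
monod_model <- function(qs_max = 1.6, ks = 7.8, cx = 55) {
  check_positive(qs_max, "qs_max"); check_positive(ks, "ks"); check_positive(cx, "cx")
  structure(
    list(
      type = "monod",
      n_pools = 0L,
      qs_max = qs_max * 1e-3 / 3600, # mol/gdw/s
      ks = ks * 1e-6,                # mol/kg
      cx = cx
    ),
    class = c("monod_model", "kinetic_model")
  )
}

#' @export
print.monod_model <- function(x, ...) {
  cat(sprintf("<monod_model> qs_max = %.3g mmol/gdw/h, Ks = %.3g umol/kg, Cx = %g g/kg\n",
              x$qs_max * 3600 * 1e3, x$ks * 1e6, x$cx))
  invisible(x)
}

#' Monod specific uptake rate
#'
#' @param cs Substrate concentration(s) (mol per kg broth); negative inputs
#'   are clipped to zero in the rate evaluation.
#' @param model A [monod_model()].
#' @return Specific uptake rate qs (mol per g dry weight per second),
#'   monotone in `cs` and bounded by `qs_max`.
#' @export
monod_uptake <- function(cs, model) {
  cs <- pmax(cs, 0)
  model$qs_max * cs / (model$ks + cs)
}

#' Eulerian (liquid-phase) reaction rate
#'
#' Volumetric substrate consumption with biomass treated as a uniform field:
#' `Rs_i = Cx * qs(Cs_i)`.
#'
#' @inheritParams monod_uptake
#' @return Reaction rate vector Rs (mol per kg broth per second).
#' @export
eulerian_reaction <- function(cs, model) {
  model$cx * monod_uptake(cs, model)
}

#' Lagrangian (parcel-summed) reaction rate
#'
#' Sums the uptake of all parcels residing in each compartment:
#' `Rs_i = sum_{p in i} qs_p * Cx_p / M_i` with `M_i` the broth mass of the
#' compartment. Compartments without parcels consume nothing — the origin of
#' the positive offset of the volumetric mean substrate concentration at
#' small parcel numbers.
#'
#' @param pop A `parcel_population`.
#' @param qs_p Per-parcel specific uptake rates (mol/gdw/s).
#' @param model A `compartment_model`.
#' @return Reaction rate vector Rs (mol per kg broth per second), length
#'   `n_compartments`.
#' @export
lagrangian_reaction <- function(pop, qs_p, model) {
  stopifnot(length(qs_p) == pop$n_parcels)
  rs <- numeric(model$n_compartments)
  if (pop$n_parcels == 0L) return(rs)
  agg <- rowsum(qs_p * pop$biomass, pop$compartment)
  rs[as.integer(rownames(agg))] <- agg[, 1]
  rs / model$mass
}
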