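#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

compartment_table <- function(model) {
  dplyr::mutate(model$centers,
                volume = model$volume,
                mass = model$mass,
                outflow = model$outflow,
                tau = if (model$no_transport) NA_real_ else model$tau)
}

#' Tidiers for lagcm objects
#'
#' `tidy()` returns the tabular heart of each object as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A `flow_field`, `compartment_model`, `mixing_result` or
#'   `cm_sim`.
#' @param ... Unused.
#' @return A tibble.
#' @name lagcm-tidiers
NULL

#' @rdname lagcm-tidiers
#' @method tidy flow_field
#' @export
tidy.flow_field <- function(x, ...) x$cells

#' @rdname lagcm-tidiers
#' @method glance flow_field
#' @export
glance.flow_field <- function(x, ...) {
  div <- check_divergence(x)
  tibble::tibble(
    n_cells = nrow(x$cells), n_faces = nrow(x$faces),
    total_volume = sum(x$cells$volume),
    mean_abs_flux = attr(div, "mean_abs_flux"),
    max_imbalance = attr(div, "max_abs_imbalance")
  )
}

#' @rdname lagcm-tidiers
#' @method tidy compartment_model
#' @export
tidy.compartment_model <- function(x, ...) compartment_table(x)

#' @rdname lagcm-tidiers
#' @method glance compartment_model
#' @export
glance.compartment_model <- function(x, ...) {
  tibble::tibble(
    layout = x$layout$code,
    n_compartments = x$n_compartments,
    total_volume = sum(x$volume),
    tau_min = if (x$no_transport) NA_real_ else min(x$tau),
    tau_max = if (x$no_transport) NA_real_ else max(x$tau),
    col_imbalance = max(abs(Matrix::colSums(x$phi))),
    conv_row_imbalance = max(abs(Matrix::rowSums(x$phi_conv)))
  )
}

#' @rdname lagcm-tidiers
#' @method tidy mixing_result
#' @export
tidy.mixing_result <- function(x, ...) x$series

#' @rdname lagcm-tidiers
#' @method glance mixing_result
#' @export
glance.mixing_result <- function(x, ...) {
  tibble::tibble(
    layout = x$layout, kind = x$kind, n_parcels = x$n_parcels,
    tau95_probe = x$tau95_probe, tau95_com = x$tau95_com,
    com_threshold = x$com_threshold,
    final_com = x$series$com[nrow(x$series)]
  )
}

#' @rdname lagcm-tidiers
#' @method tidy cm_sim
#' @export
tidy.cm_sim <- function(x, ...) x$scalars

#' @rdname lagcm-tidiers
#' @method glance cm_sim
#' @export
glance.cm_sim <- function(x, ...) {
  last <- x$scalars[nrow(x$scalars), ]
  tibble::tibble(
    mode = x$mode, layout = x$layout,
    n_parcels = x$config$n_parcels,
    duration = last$time,
    cs_vol_mean = last$cs_vol_mean,
    cs_parcel_mean = last$cs_parcel_mean,
    cx = last$cx, mu = last$mu, qp = last$qp,
    conservation_defect = x$conservation_defect,
    n_accept = x$n_accept, n_reject = x$n_reject
  )
}
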