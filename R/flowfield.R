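#' Circulation-loop specification for the synthetic flow generator
#'
#' Each Rushton impeller drives a radial discharge that rolls up into two
#' counter-rotating circulation loops, one below and one above the impeller
#' plane. The generator encodes every loop as a smooth stream-function bump
#' on the axial-radial plane; `strength` is the peak of the bump and hence
#' the mass circulation rate carried by the loop.
#'
#' @param strength Circulation strength per loop (kg/s, >= 0); defaults to
#'   a Rushton pumping-number estimate (Nq = 0.72) of the impeller pumping
#'   rate.
#' @param geometry A [tank_geometry()] used for the default strength.
#' @param r_center Radial position of the loop centers as a fraction of the
#'   tank radius.
#' @param sigma_y,sigma_r Gaussian widths of the stream-function bumps (m);
#'   `sigma_y` acts as a lower bound, each loop otherwise scaling its axial
#'   extent to the zone between its impeller and the adjacent flow boundary
#'   (vessel bottom, impeller midplane, liquid surface).
#' @param swirl_frac Tangential velocity at the tank wall as a fraction of
#'   impeller tip speed; drives azimuthal (solid-body style) fluxes when the
#'   grid has more than one azimuthal division.
#' @return A `loop_spec` list.
#' @export
loop_spec <- function(strength = NULL, geometry = tank_geometry(),
                      r_center = 0.65,
                      sigma_y = 0.5, sigma_r = 0.45, swirl_frac = 0.2) {
  if (is.null(strength)) {
    nq <- 0.72 # Rushton pumping number
    pumping <- nq * (geometry$stir_rpm / 60) * geometry$impeller_diameter^3
    strength <- geometry$density * pumping
  }
  if (!is.numeric(strength) || length(strength) != 1L || is.na(strength) || strength < 0) {
    abort_lagcm("circulation `strength` must be a non-negative number (kg/s)",
                class = "lagcm_validation_error")
  }
  check_positive(sigma_y, "sigma_y"); check_positive(sigma_r, "sigma_r")
  structure(list(strength = strength, r_center = r_center,
                 sigma_y = sigma_y, sigma_r = sigma_r,
                 swirl_frac = swirl_frac),
            class = "loop_spec")
}

#' Turbulence specification for the synthetic flow generator
#'
#' Turbulent kinetic energy kt is modeled as Gaussian peaks centered at each
#' impeller plane (near the blade tip radius) decaying to a uniform positive
#' floor. Only the relative spatial structure matters for the turbulent flux
#' matrix; the absolute scale is a configuration knob, by default tied to the
#' impeller tip speed.
#'
#' @param peak Peak kt at the impeller planes (m^2/s^2); default
#'   0.08 * tip_speed^2.
#' @param floor Background kt far from the impellers (m^2/s^2, > 0); default
#'   0.01 m^2/s^2.
#' @param geometry A [tank_geometry()] used for the default peak.
#' @param sigma_y,sigma_r Gaussian decay lengths (m).
#' @param r_center Radial position of the peaks (m); defaults to the blade
#'   tip radius D/2.
#' @return A `kt_spec` list.
#' @export
kt_spec <- function(peak = NULL, floor = 0.01, geometry = tank_geometry(),
                    sigma_y = 0.5, sigma_r = 0.5, r_center = NULL) {
  peak <- peak %||% (0.08 * geometry$tip_speed^2)
  r_center <- r_center %||% (geometry$impeller_diameter / 2)
  check_positive(peak, "peak", strict = FALSE)
  check_positive(floor, "floor")
  structure(list(peak = peak, floor = floor, sigma_y = sigma_y,
                 sigma_r = sigma_r, r_center = r_center),
            class = "kt_spec")
}

# linear cell index on the (nax, nr, ntheta) grid, axial index fastest
cell_index <- function(ia, ir, ik, dims) {
  ia + (ir - 1L) * dims[1] + (ik - 1L) * dims[1] * dims[2]
}

# stream-function bump table: one signed bump per loop, two loops per
# impeller. Each loop spans the region between its impeller plane and the
# adjacent flow boundary (vessel bottom, the midplane between neighboring
# impellers, or the liquid surface), so stacked Rushton loops tile the tank.
loop_bumps <- function(geometry, loops) {
  h <- geometry$impeller_heights
  bounds <- c(0, (h[-length(h)] + h[-1]) / 2, geometry$liquid_height)
  purrr::map_dfr(seq_along(h), function(k) {
    lo <- bounds[k]; hi <- bounds[k + 1]
    tibble::tibble(
      y = c((lo + h[k]) / 2, (h[k] + hi) / 2),
      r = loops$r_center * geometry$diameter / 2,
      strength = c(loops$strength, -loops$strength),
      sigma_y = pmax(c(h[k] - lo, hi - h[k]) / 2.2, loops$sigma_y),
      sigma_r = loops$sigma_r
    )
  })
}

# evaluate the nodal stream function (kg/s per azimuthal slice).
# A boundary-vanishing polynomial envelope multiplies each Gaussian bump and
# the result is rescaled so the signed peak equals the requested strength;
# boundary nodes are exactly zero, so no convective flux crosses the wall,
# bottom or surface.
eval_psi <- function(y_nodes, r_nodes, bumps, geometry, ntheta) {
  hl <- geometry$liquid_height
  rr <- geometry$diameter / 2
  yy <- matrix(y_nodes, nrow = length(y_nodes), ncol = length(r_nodes))
  rm <- matrix(r_nodes, nrow = length(y_nodes), ncol = length(r_nodes), byrow = TRUE)
  env <- 16 * (yy / hl) * (1 - yy / hl) * (rm / rr) * (1 - rm / rr)
  psi <- matrix(0, nrow = length(y_nodes), ncol = length(r_nodes))
  for (b in seq_len(nrow(bumps))) {
    g <- env * exp(-((yy - bumps$y[b]) / bumps$sigma_y[b])^2 -
                     ((rm - bumps$r[b]) / bumps$sigma_r[b])^2)
    peak <- max(abs(g))
    if (peak > 0 && bumps$strength[b] != 0) {
      psi <- psi + g * (bumps$strength[b] / peak)
    }
  }
  psi / ntheta
}

eval_kt <- function(y, r, geometry, kt) {
  val <- rep(kt$floor, length(y))
  for (h in geometry$impeller_heights) {
    val <- val + kt$peak *
      exp(-((y - h) / kt$sigma_y)^2 - ((r - kt$r_center) / kt$sigma_r)^2)
  }
  val
}

#' Generate a synthetic stirred-tank flow field
#'
#' Builds a discretely divergence-free flow field on a structured cylindrical
#' grid: cell volumes, signed convective mass fluxes on interior cell faces,
#' and turbulent kinetic energy at face centers. The axial-radial fluxes
#' derive from a discrete stream function evaluated on grid nodes, so every
#' cell's mass balance closes exactly by telescoping; azimuthal fluxes (when
#' `dims[3] > 1`) are theta-uniform solid-body style and individually
#' divergence-free. The field plays the role of a resolved CFD solution as
#' input to [assign_compartments()] and [build_compartment_model()].
#'
#' @param geometry A [tank_geometry()].
#' @param dims Grid divisions `c(nax, nr, ntheta)`; at least `c(8, 4, 1)`.
#' @param loops A [loop_spec()]; defaults to two counter-rotating loops per
#'   impeller.
#' @param kt A [kt_spec()].
#' @return A `flow_field` object: a list with `geometry`, `dims`, a `cells`
#'   tibble (cell, ia, ir, ik, y, r, theta, volume) and a `faces` tibble
#'   (face, cell_a, cell_b, orientation, area, flux, kt). `flux` is the
#'   signed convective mass flux (kg/s), positive from `cell_a` to `cell_b`.
#' @examples
#' field <- build_stirred_tank_field(tank_geometry(), dims = c(26, 6, 1))
#' sum(field$cells$volume) # 54.4 m^3
#' max(abs(check_divergence(field)$imbalance))
#' @export
build_stirred_tank_field <- function(geometry = tank_geometry(),
                                     dims = c(52, 12, 1),
                                     loops = loop_spec(geometry = geometry),
                                     kt = kt_spec(geometry = geometry)) {
  if (!inherits(geometry, "tank_geometry")) {
    abort_lagcm("`geometry` must be a tank_geometry", class = "lagcm_validation_error")
  }
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || dims[1] < 8L || dims[2] < 4L || dims[3] < 1L) {
    abort_lagcm("`dims` must be c(nax, nr, ntheta) with nax >= 8, nr >= 4, ntheta >= 1",
                class = "lagcm_validation_error")
  }
  nax <- dims[1]; nr <- dims[2]; nth <- dims[3]
  hl <- geometry$liquid_height; rr <- geometry$diameter / 2
  rho <- geometry$density
  dy <- hl / nax; dr <- rr / nr; dth <- 2 * pi / nth

  ia <- rep(seq_len(nax), times = nr * nth)
  ir <- rep(rep(seq_len(nr), each = nax), times = nth)
  ik <- rep(seq_len(nth), each = nax * nr)
  cells <- tibble::tibble(
    cell = cell_index(ia, ir, ik, dims),
    ia = ia, ir = ir, ik = ik,
    y = (ia - 0.5) * dy,
    r = (ir - 0.5) * dr,
    theta = (ik - 0.5) * dth,
    volume = dr^2 * (2 * ir - 1) / 2 * dth * dy
  )
  cells <- dplyr::arrange(cells, .data$cell)

  psi <- eval_psi(seq(0, hl, by = dy), seq(0, rr, by = dr),
                  loop_bumps(geometry, loops), geometry, nth)

  # axial faces between (i, j) and (i + 1, j): flux = psi(i, j) - psi(i, j - 1)
  fa_i <- rep(seq_len(nax - 1L), times = nr)
  fa_j <- rep(seq_len(nr), each = nax - 1L)
  ax_flux <- psi[cbind(fa_i + 1L, fa_j + 1L)] - psi[cbind(fa_i + 1L, fa_j)]
  ax_area <- (((fa_j) * dr)^2 - ((fa_j - 1L) * dr)^2) / 2 * dth
  ax_y <- fa_i * dy
  ax_r <- (fa_j - 0.5) * dr

  # radial faces between (i, j) and (i, j + 1): flux = psi(i - 1, j) - psi(i, j)
  fr_i <- rep(seq_len(nax), times = nr - 1L)
  fr_j <- rep(seq_len(nr - 1L), each = nax)
  rad_flux <- psi[cbind(fr_i, fr_j + 1L)] - psi[cbind(fr_i + 1L, fr_j + 1L)]
  rad_area <- (fr_j * dr) * dth * dy
  rad_y <- (fr_i - 0.5) * dy
  rad_r <- fr_j * dr

  faces <- purrr::map_dfr(seq_len(nth), function(k) {
    dplyr::bind_rows(
      tibble::tibble(
        cell_a = cell_index(fa_i, fa_j, k, dims),
        cell_b = cell_index(fa_i + 1L, fa_j, k, dims),
        orientation = "axial", area = ax_area, flux = ax_flux,
        y = ax_y, r = ax_r
      ),
      tibble::tibble(
        cell_a = cell_index(fr_i, fr_j, k, dims),
        cell_b = cell_index(fr_i, fr_j + 1L, k, dims),
        orientation = "radial", area = rad_area, flux = rad_flux,
        y = rad_y, r = rad_r
      )
    )
  })

  if (nth > 1L) {
    az_i <- rep(seq_len(nax), times = nr)
    az_j <- rep(seq_len(nr), each = nax)
    az_area <- dr * dy
    vt <- loops$swirl_frac * geometry$tip_speed * ((az_j - 0.5) * dr) / rr
    az <- purrr::map_dfr(seq_len(nth), function(k) {
      tibble::tibble(
        cell_a = cell_index(az_i, az_j, k, dims),
        cell_b = cell_index(az_i, az_j, if (k == nth) 1L else k + 1L, dims),
        orientation = "azimuthal", area = az_area, flux = rho * vt * az_area,
        y = (az_i - 0.5) * dy, r = az_j * dr - 0.5 * dr
      )
    })
    faces <- dplyr::bind_rows(faces, az)
  }

  faces$kt <- eval_kt(faces$y, faces$r, geometry, kt)
  faces <- dplyr::mutate(faces,
                         face = dplyr::row_number(),
                         .before = "cell_a")
  faces <- dplyr::select(faces, -"y", -"r")

  structure(
    list(geometry = geometry, dims = dims, cells = cells, faces = faces),
    class = "flow_field"
  )
}

#' Per-cell mass-balance imbalance of a flow field
#'
#' Sums the signed convective face fluxes around every grid cell. For fields
#' produced by [build_stirred_tank_field()] the imbalance is zero to
#' round-off by construction; for externally supplied fields this is the
#' diagnostic to run before compartmentization.
#'
#' @param field A `flow_field`.
#' @return A tibble (cell, imbalance) in kg/s, with attributes
#'   `max_abs_imbalance` and `mean_abs_flux`.
#' @export
check_divergence <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  n <- nrow(field$cells)
  net <- numeric(n)
  out_sum <- rowsum(field$faces$flux, field$faces$cell_a)
  in_sum <- rowsum(field$faces$flux, field$faces$cell_b)
  net[as.integer(rownames(out_sum))] <- net[as.integer(rownames(out_sum))] + out_sum[, 1]
  net[as.integer(rownames(in_sum))] <- net[as.integer(rownames(in_sum))] - in_sum[, 1]
  out <- tibble::tibble(cell = field$cells$cell, imbalance = net[field$cells$cell])
  attr(out, "max_abs_imbalance") <- max(abs(net))
  attr(out, "mean_abs_flux") <- mean(abs(field$faces$flux))
  out
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d x %d x %d grid, %d cells, %d faces, V = %.2f m^3\n",
              x$dims[1], x$dims[2], x$dims[3], nrow(x$cells), nrow(x$faces),
              sum(x$cells$volume)))
  invisible(x)
}
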