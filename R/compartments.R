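#' Assign grid cells to a cylindrical compartment layout
#'
#' Clusters grid cells into `Nax x Nr x Ntheta` homogeneous cylindrical bins
#' by their center coordinates. Compartment boundaries are restricted to
#' grid planes: the divisions must divide the grid dimensions evenly, so no
#' cell straddles a compartment interface.
#'
#' @param field A `flow_field`.
#' @param divisions Integer vector `c(Nax, Nr, Ntheta)`.
#' @return A `compartment_layout`: list with `divisions`, `n_compartments`,
#'   the layout `code` (e.g. `"A26R6T1"`), and `map`, the cell-to-compartment
#'   index vector (1-based, ordered by cell index).
#' @examples
#' field <- build_stirred_tank_field(dims = c(52, 12, 1))
#' assign_compartments(field, c(26, 6, 1))
#' @export
assign_compartments <- function(field, divisions) {
  stopifnot(inherits(field, "flow_field"))
  divisions <- as.integer(divisions)
  if (length(divisions) != 3L || any(is.na(divisions)) || any(divisions < 1L)) {
    abort_lagcm("`divisions` must be three positive integers",
                class = "lagcm_validation_error")
  }
  if (any(divisions > field$dims)) {
    abort_lagcm("`divisions` cannot exceed the grid dimensions",
                class = "lagcm_validation_error")
  }
  if (any(field$dims %% divisions != 0L)) {
    abort_lagcm(sprintf(
      "`divisions` (%s) must divide the grid dimensions (%s) evenly so compartment boundaries coincide with grid planes",
      paste(divisions, collapse = "x"), paste(field$dims, collapse = "x")),
      class = "lagcm_validation_error")
  }
  geo <- field$geometry
  widths <- c(geo$liquid_height, geo$diameter / 2, 2 * pi) / divisions
  bin_ax <- pmin(divisions[1], floor(field$cells$y / widths[1]) + 1L)
  bin_r <- pmin(divisions[2], floor(field$cells$r / widths[2]) + 1L)
  bin_th <- pmin(divisions[3], floor(field$cells$theta / widths[3]) + 1L)
  map_by_cell <- integer(nrow(field$cells))
  map_by_cell[field$cells$cell] <-
    cell_index(bin_ax, bin_r, bin_th, divisions)
  structure(
    list(
      divisions = divisions,
      n_compartments = prod(divisions),
      code = sprintf("A%dR%dT%d", divisions[1], divisions[2], divisions[3]),
      map = map_by_cell
    ),
    class = "compartment_layout"
  )
}

#' @export
print.compartment_layout <- function(x, ...) {
  cat(sprintf("<compartment_layout> %s: %d compartments\n", x$code, x$n_compartments))
  invisible(x)
}

#' Aggregate cell volumes per compartment
#'
#' @param field A `flow_field`.
#' @param layout A `compartment_layout`.
#' @return Numeric vector of compartment volumes Vi (m^3), summing to the
#'   grid volume.
#' @export
aggregate_volumes <- function(field, layout) {
  stopifnot(inherits(layout, "compartment_layout"))
  v <- numeric(layout$n_compartments)
  agg <- rowsum(field$cells$volume, layout$map[field$cells$cell])
  v[as.integer(rownames(agg))] <- agg[, 1]
  v
}

# faces crossing a compartment interface, with compartment ids attached
interface_faces <- function(field, layout) {
  fa <- field$faces
  ca <- layout$map[fa$cell_a]
  cb <- layout$map[fa$cell_b]
  keep <- ca != cb
  dplyr::mutate(fa[keep, ], comp_a = ca[keep], comp_b = cb[keep])
}

#' Convective inter-compartment flux matrix
#'
#' Sums signed convective face fluxes over each compartment interface,
#' split by direction: entry `[i, j]` accumulates only faces whose flux
#' runs from compartment j to i, so the matrix is directional and
#' `phi_c[i, j] != phi_c[j, i]` in general. The diagonal holds minus the
#' total convective outflow, making every column sum to zero.
#'
#' @param field A `flow_field`.
#' @param layout A `compartment_layout`.
#' @return A sparse `dgCMatrix` (kg/s), `n_compartments` square.
#' @export
convective_fluxes <- function(field, layout) {
  nc <- layout$n_compartments
  fa <- interface_faces(field, layout)
  fwd <- fa$flux > 0 # flux runs comp_a -> comp_b
  i <- c(fa$comp_b[fwd], fa$comp_a[!fwd])
  j <- c(fa$comp_a[fwd], fa$comp_b[!fwd])
  x <- c(fa$flux[fwd], -fa$flux[!fwd])
  phi <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nc, nc))
  Matrix::diag(phi) <- -Matrix::colSums(phi)
  methods::as(phi, "CsparseMatrix")
}

#' Turbulent inter-compartment flux matrix
#'
#' Per grid face, the bidirectional turbulent mass flux is
#' `ft = rho * A_face * sqrt(2 * kt / 3)` (face area times the RMS turbulent
#' velocity fluctuation), summed over each compartment interface. The
#' off-diagonal is symmetric by construction; the diagonal holds minus the
#' total turbulent outflow.
#'
#' @inheritParams convective_fluxes
#' @return A sparse symmetric-off-diagonal `dgCMatrix` (kg/s).
#' @export
turbulent_fluxes <- function(field, layout) {
  nc <- layout$n_compartments
  fa <- interface_faces(field, layout)
  if (any(fa$kt < 0)) {
    abort_lagcm("face turbulent kinetic energy must be non-negative",
                class = "lagcm_validation_error")
  }
  ft <- field$geometry$density * fa$area * sqrt(2 * fa$kt / 3)
  phi <- Matrix::sparseMatrix(
    i = c(fa$comp_a, fa$comp_b), j = c(fa$comp_b, fa$comp_a),
    x = c(ft, ft), dims = c(nc, nc))
  Matrix::diag(phi) <- -Matrix::colSums(phi)
  methods::as(phi, "CsparseMatrix")
}

# flatten per-compartment destination lists (ascending index) with
# cumulative probabilities phi_ji / |phi_ii|; final cumulative forced to 1
build_destinations <- function(phi) {
  nc <- nrow(phi)
  outflow <- abs(Matrix::diag(phi))
  dest_idx <- integer(0)
  dest_cum <- numeric(0)
  ptr <- integer(nc + 1L)
  phi <- methods::as(phi, "CsparseMatrix")
  for (i in seq_len(nc)) {
    # column i of phi holds the outflows of i: entry [j, i] is the flux i -> j
    cols <- (phi@p[i] + 1L):phi@p[i + 1L]
    if (phi@p[i + 1L] == phi@p[i]) cols <- integer(0)
    j <- phi@i[cols] + 1L
    x <- phi@x[cols]
    keep <- j != i & x > 0
    j <- j[keep]; x <- x[keep]
    ord <- order(j)
    j <- j[ord]; x <- x[ord]
    cum <- cumsum(x) / outflow[i]
    if (length(cum)) cum[length(cum)] <- 1
    dest_idx <- c(dest_idx, j)
    dest_cum <- c(dest_cum, cum)
    ptr[i + 1L] <- length(dest_idx)
  }
  # global lookup key: block for compartment i occupies (i-1, i]
  gcum <- dest_cum + rep(seq_len(nc) - 1L, times = diff(ptr))
  list(idx = dest_idx, cum = dest_cum, ptr = ptr, gcum = gcum)
}

#' Build a compartment model from a flow field and layout
#'
#' Aggregates volumes and flux matrices and derives the quantities the
#' stochastic parcel tracker needs: the total flux matrix
#' `Phi = Phi_c + Phi_t`, compartment residence times
#' `tau_i = M_i / |phi_ii|` on a mass basis (`M_i = rho_l * V_i`), and
#' per-compartment destination tables with cumulative jump probabilities
#' `phi_ji / |phi_ii|`, ordered by ascending compartment index for
#' reproducible stochastic runs.
#'
#' @param field A `flow_field`.
#' @param layout A `compartment_layout`, or `divisions` to pass to
#'   [assign_compartments()].
#' @return A `compartment_model` with elements `n_compartments`, `layout`,
#'   `geometry`, `volume`, `mass`, `centers` (tibble: compartment, y, r,
#'   theta), `phi_conv`, `phi_turb`, `phi` (sparse, kg/s), `outflow`, `tau`
#'   (s), and the flattened destination table `dest`.
#' @examples
#' field <- build_stirred_tank_field(dims = c(52, 12, 1))
#' model <- build_compartment_model(field, c(26, 6, 1))
#' range(model$tau)
#' @export
build_compartment_model <- function(field, layout) {
  if (!inherits(layout, "compartment_layout")) {
    layout <- assign_compartments(field, layout)
  }
  nc <- layout$n_compartments
  vol <- aggregate_volumes(field, layout)
  if (any(vol <= 0)) {
    abort_lagcm("every compartment must be non-empty", class = "lagcm_validation_error")
  }
  phi_c <- convective_fluxes(field, layout)
  phi_t <- turbulent_fluxes(field, layout)
  phi <- methods::as(phi_c + phi_t, "CsparseMatrix")
  outflow <- abs(Matrix::diag(phi))
  rho <- field$geometry$density
  mass <- rho * vol
  no_transport <- nc == 1L
  if (!no_transport && any(outflow <= 0)) {
    abort_lagcm("compartment with zero total outflow: residence time is infinite",
                class = "lagcm_validation_error")
  }
  tau <- if (no_transport) NA_real_ else mass / outflow

  centers <- tibble::tibble(
    compartment = seq_len(nc),
    y = as.vector(rowsum(field$cells$y * field$cells$volume, layout$map[field$cells$cell])) / vol,
    r = as.vector(rowsum(field$cells$r * field$cells$volume, layout$map[field$cells$cell])) / vol,
    theta = as.vector(rowsum(field$cells$theta * field$cells$volume, layout$map[field$cells$cell])) / vol
  )

  structure(
    list(
      n_compartments = nc,
      layout = layout,
      geometry = field$geometry,
      volume = vol,
      mass = mass,
      centers = centers,
      phi_conv = phi_c,
      phi_turb = phi_t,
      phi = phi,
      outflow = outflow,
      tau = tau,
      dest = if (no_transport) list(idx = integer(0), cum = numeric(0),
                                    ptr = c(0L, 0L), gcum = numeric(0))
             else build_destinations(phi),
      no_transport = no_transport
    ),
    class = "compartment_model"
  )
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf("<compartment_model> %s: %d compartments, V = %.2f m^3\n",
              x$layout$code, x$n_compartments, sum(x$volume)))
  if (!x$no_transport) {
    cat(sprintf("  residence times: %.3g .. %.3g s\n", min(x$tau), max(x$tau)))
  } else {
    cat("  single compartment: no transport\n")
  }
  invisible(x)
}

#' Assemble a compartment model directly from flux matrices
#'
#' Constructor for hand-specified or externally derived models: supply the
#' convective and turbulent flux matrices (kg/s; entry `[i, j]` = flux from
#' j to i, diagonals = minus total outflow, or zero diagonals which are
#' then filled in) and compartment volumes. Invariants are enforced:
#' non-negative off-diagonals, non-positive diagonals consistent with the
#' column sums, symmetric turbulent part.
#'
#' @param phi_conv,phi_turb Square matrices (dense or sparse), kg/s.
#' @param volumes Compartment volumes (m^3).
#' @param geometry A [tank_geometry()]; defaults to a generic vessel whose
#'   volume matches `sum(volumes)` (used only for density and coordinates).
#' @param centers Optional tibble of compartment center coordinates.
#' @param code Layout code label.
#' @return A `compartment_model`.
#' @export
compartment_model_from_matrices <- function(phi_conv, phi_turb = NULL, volumes,
                                            geometry = NULL, centers = NULL,
                                            code = "custom") {
  nc <- length(volumes)
  as_flux <- function(m, name) {
    m <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                     "CsparseMatrix")
    if (any(dim(m) != nc)) abort_lagcm(sprintf("`%s` must be %d x %d", name, nc, nc),
                                       class = "lagcm_validation_error")
    d <- Matrix::diag(m)
    if (any(d > 0)) abort_lagcm(sprintf("`%s` has a positive diagonal entry", name),
                                class = "lagcm_validation_error")
    off <- m - Matrix::Diagonal(nc, d)
    if (any(off@x < 0)) abort_lagcm(sprintf("`%s` has a negative off-diagonal entry", name),
                                    class = "lagcm_validation_error")
    if (all(d == 0)) Matrix::diag(m) <- -Matrix::colSums(off)
    m
  }
  phi_c <- as_flux(phi_conv, "phi_conv")
  phi_t <- if (is.null(phi_turb)) {
    methods::as(Matrix::Matrix(0, nc, nc, sparse = TRUE), "CsparseMatrix")
  } else {
    m <- as_flux(phi_turb, "phi_turb")
    if (!Matrix::isSymmetric(m - Matrix::Diagonal(nc, Matrix::diag(m)), tol = 0)) {
      abort_lagcm("turbulent off-diagonal must be exactly symmetric",
                  class = "lagcm_validation_error")
    }
    m
  }
  if (is.null(geometry)) {
    vt <- sum(volumes)
    d <- (4 * vt / (2.5 * pi))^(1 / 3) # generic Hl/T = 2.5 vessel
    geometry <- tank_geometry(diameter = d, liquid_height = 2.5 * d,
                              impeller_diameter = d / 2.5, clearance = d / 2.5,
                              impeller_spacing = d, n_impellers = 1)
  }
  phi <- methods::as(phi_c + phi_t, "CsparseMatrix")
  outflow <- abs(Matrix::diag(phi))
  mass <- geometry$density * volumes
  no_transport <- nc == 1L
  if (!no_transport && any(outflow <= 0)) {
    abort_lagcm("compartment with zero total outflow: residence time is infinite",
                class = "lagcm_validation_error")
  }
  structure(
    list(n_compartments = nc,
         layout = structure(list(divisions = c(nc, 1L, 1L), n_compartments = nc,
                                 code = code, map = NULL),
                            class = "compartment_layout"),
         geometry = geometry, volume = volumes, mass = mass,
         centers = centers %||% tibble::tibble(
           compartment = seq_len(nc),
           y = (seq_len(nc) - 0.5) / nc * geometry$liquid_height,
           r = geometry$diameter / 4, theta = 0),
         phi_conv = phi_c, phi_turb = phi_t, phi = phi, outflow = outflow,
         tau = if (no_transport) NA_real_ else mass / outflow,
         dest = if (no_transport) list(idx = integer(0), cum = numeric(0),
                                       ptr = c(0L, 0L), gcum = numeric(0))
                else build_destinations(phi),
         no_transport = no_transport),
    class = "compartment_model"
  )
}

#' Locate the compartment containing a point
#'
#' @param model A `compartment_model`.
#' @param y Axial coordinate (m).
#' @param r Radial coordinate (m).
#' @param theta Azimuthal coordinate (rad).
#' @return Compartment index (1-based).
#' @export
find_compartment <- function(model, y, r, theta = 0) {
  geo <- model$geometry
  div <- model$layout$divisions
  theta <- theta %% (2 * pi)
  if (y < 0 || y > geo$liquid_height || r < 0 || r > geo$diameter / 2) {
    abort_lagcm("point lies outside the vessel", class = "lagcm_validation_error")
  }
  widths <- c(geo$liquid_height, geo$diameter / 2, 2 * pi) / div
  bin <- pmin(div, c(floor(y / widths[1]), floor(r / widths[2]), floor(theta / widths[3])) + 1L)
  cell_index(bin[1], bin[2], bin[3], div)
}
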