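# shared fixture builders (everything generated in code)

small_field <- function(dims = c(8, 4, 1), geometry = tank_geometry(), ...) {
  build_stirred_tank_field(geometry, dims = dims, ...)
}

# directed ring with constant circulating flux: flux-balanced for any volumes
ring_model <- function(n = 4, volumes = rep(1, n), flux = 100, turb = 0) {
  phi_c <- matrix(0, n, n)
  for (j in seq_len(n)) phi_c[j %% n + 1L, j] <- flux
  phi_t <- if (turb > 0) {
    m <- matrix(0, n, n)
    for (j in seq_len(n)) {
      m[j %% n + 1L, j] <- turb
      m[j, j %% n + 1L] <- turb
    }
    m
  } else NULL
  compartment_model_from_matrices(phi_c, phi_t, volumes)
}

# two well-mixed boxes exchanging `flux` kg/s in both directions
two_box_model <- function(flux = 500, volumes = c(1, 1)) {
  phi_c <- matrix(c(0, flux, flux, 0), 2, 2)
  compartment_model_from_matrices(phi_c, NULL, volumes)
}

# a star: compartment 1 feeds 2 and 3 (3:1), which feed back
star_model <- function(f2 = 3, f3 = 1) {
  phi_c <- matrix(0, 3, 3)
  phi_c[2, 1] <- f2
  phi_c[3, 1] <- f3
  phi_c[1, 2] <- f2
  phi_c[1, 3] <- f3
  compartment_model_from_matrices(phi_c, NULL, rep(1, 3))
}

# single-step transition matrix of the discrete jump chain (oracle)
jump_chain_matrix <- function(model, dt) {
  n <- model$n_compartments
  p_jump <- jump_probability(dt, model$tau)
  P <- matrix(0, n, n)
  phi <- as.matrix(model$phi)
  for (i in seq_len(n)) {
    dest <- phi[, i]
    dest[i] <- 0
    P[i, ] <- p_jump[i] * dest / model$outflow[i]
    P[i, i] <- 1 - p_jump[i]
  }
  P
}

# stationary law of the jump chain via the eigenvector oracle
chain_stationary <- function(model, dt) {
  P <- jump_chain_matrix(model, dt)
  e <- eigen(t(P))
  v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
  v / sum(v)
}

# cache for fixtures shared across test files (built once per run)
.fixtures <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

base_field <- function() cached("base_field", small_field(c(52, 12, 1)))
base_model <- function() cached("base_model",
                                build_compartment_model(base_field(), c(26, 6, 1)))
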