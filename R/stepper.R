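# Embedded Bogacki-Shampine 3(2) adaptive stepper.
#
# Written in-package because the coupling scheme interleaves stochastic
# parcel jumps after every *accepted* step: rejected trial steps must not
# consume random numbers, and the jump pass changes the right-hand side
# discontinuously (parcel reassignment), so the usual FSAL reuse of the last
# stage is deliberately not applied when a post-step hook is present.
#
# rhs(t, y) returns dy/dt; after_step(t_new, dt, y_new), if given, is called
# once per accepted step (this is where parcel jumps, lifeline sampling and
# output recording live) and may return a modified state vector.
bs23_run <- function(rhs, y0, t0, t1, rel_tol = 1e-3, abs_tol = 1e-9,
                     dt_max = 0.03, dt0 = NULL, after_step = NULL) {
  stopifnot(t1 > t0, rel_tol > 0, dt_max > 0)
  t <- t0
  y <- y0
  dt <- min(dt0 %||% (dt_max / 10), dt_max, t1 - t0)
  n_accept <- 0L
  n_reject <- 0L
  k1 <- rhs(t, y)
  repeat {
    if (t >= t1 - 1e-12 * (t1 - t0)) break
    dt <- min(dt, dt_max, t1 - t)
    if (dt < 1e-12 * (t1 - t0)) {
      abort_lagcm(sprintf("step size underflow at t = %.6g (stiffness?)", t),
                  class = "lagcm_integration_error")
    }
    k2 <- rhs(t + dt / 2, y + dt / 2 * k1)
    k3 <- rhs(t + 3 * dt / 4, y + 3 * dt / 4 * k2)
    y3 <- y + dt * (2 / 9 * k1 + 1 / 3 * k2 + 4 / 9 * k3)
    k4 <- rhs(t + dt, y3)
    # 2nd-order embedded solution for the error estimate
    y2 <- y + dt * (7 / 24 * k1 + 1 / 4 * k2 + 1 / 3 * k3 + 1 / 8 * k4)
    if (any(!is.finite(y3))) {
      abort_lagcm(sprintf("non-finite state at t = %.6g", t),
                  class = "lagcm_integration_error")
    }
    scale <- abs_tol + rel_tol * pmax(abs(y), abs(y3))
    err <- sqrt(mean(((y3 - y2) / scale)^2))
    if (err <= 1) {
      t <- t + dt
      y <- y3
      n_accept <- n_accept + 1L
      if (!is.null(after_step)) {
        res <- after_step(t, dt, y)
        if (is.numeric(res)) y <- res
        k1 <- rhs(t, y) # state/assignment may have changed discontinuously
      } else {
        k1 <- k4 # FSAL
      }
    } else {
      n_reject <- n_reject + 1L
    }
    fac <- if (err > 0) 0.9 * err^(-1 / 3) else 5
    dt <- dt * min(5, max(0.2, fac))
  }
  list(t = t, y = y, n_accept = n_accept, n_reject = n_reject)
}
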