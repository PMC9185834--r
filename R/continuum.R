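# Deterministic twin of the lattice model: method-of-lines solver for the
# reduced column-density equation
#   dC/dt = d/dx( D(C) dC/dx ) + lambda * C * F(C)
# on a periodic 1D domain, plus the well-mixed ODE reference.

#' Uniform periodic 1D grid
#'
#' Nodes `x_k = k h`, `k = 0..n-1`, on the half-open periodic domain `[0, L)`.
#'
#' @param L domain length.
#' @param h node spacing; `L/h` must be an integer.
#' @return An object of class `grid_1d`.
#' @export
grid_1d <- function(L, h = 0.5) {
  stopifnot(L > 0, h > 0)
  n <- L / h
  if (abs(n - round(n)) > 1e-9) stop("L/h must be an integer", call. = FALSE)
  n <- as.integer(round(n))
  structure(list(L = L, h = h, n = n, x = (0:(n - 1)) * h), class = "grid_1d")
}

#' 1D density profile on a periodic grid
#'
#' @param values node values `C(x_k)`.
#' @param grid a [grid_1d].
#' @return An object of class `density_profile`.
#' @export
density_profile <- function(values, grid) {
  stopifnot(inherits(grid, "grid_1d"), length(values) == grid$n)
  structure(list(values = as.numeric(values), grid = grid),
            class = "density_profile")
}

#' Strip initial profile
#'
#' The exact indicator of the central strip `[(L-w)/2, (L+w)/2)` sampled at
#' the nodes (no smoothing), matching the lattice strip initial condition.
#'
#' @param grid a [grid_1d].
#' @param w strip width, `0 <= w <= L`.
#' @return A [density_profile].
#' @export
strip_profile <- function(grid, w) {
  stopifnot(w >= 0, w <= grid$L)
  density_profile(as.numeric(grid$x >= (grid$L - w) / 2 &
                             grid$x < (grid$L + w) / 2), grid)
}

#' Total (domain-averaged) density of a profile
#'
#' `C(t) = (1/L) \int_0^L C(x,t) dx`; on a uniform periodic grid the
#' trapezoid rule is the exact node mean.
#'
#' @param profile a [density_profile] or a numeric vector of node values.
#' @return A scalar in `[0, 1]`.
#' @export
total_density <- function(profile) {
  v <- if (inherits(profile, "density_profile")) profile$values else profile
  mean(v)
}

# right-hand side of the method-of-lines system: conservative finite-volume
# divergence with arithmetic-mean interface diffusivities, periodic wrap.
# D and F are evaluated at the state clamped to [0, 1]: adaptive steps may
# transiently leave the physical range by the integrator tolerance, and the
# model functions are only defined on [0, 1].
make_pde_rhs <- function(D, F_fn, lambda, h) {
  force(D); force(F_fn); force(lambda); force(h)
  function(t, y, parms) {
    yc <- pmin(pmax(y, 0), 1)
    Dv <- D$value(yc)
    if (any(Dv < -1e-12)) {
      stop("negative diffusivity encountered during integration", call. = FALSE)
    }
    yp <- c(y[-1], y[1])
    ym <- c(y[length(y)], y[-length(y)])
    Dp <- 0.5 * (Dv + c(Dv[-1], Dv[1]))
    Dm <- 0.5 * (Dv + c(Dv[length(Dv)], Dv[-length(Dv)]))
    dy <- (Dp * (yp - y) - Dm * (y - ym)) / h^2
    if (!is.null(F_fn) && lambda != 0) {
      dy <- dy + lambda * yc * F_fn$value(yc)
    }
    list(dy)
  }
}

# one adaptive integration pass over `times`; returns the deSolve matrix
integrate_pde <- function(y0, times, rhs, rtol, atol) {
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 500000)
  if (attr(out, "istate")[1] < 0) {
    stop("PDE integration failed (tolerance not met); istate = ",
         attr(out, "istate")[1], call. = FALSE)
  }
  out
}

#' Solve the reduced column-density equation
#'
#' Conservative method-of-lines discretization of
#' `dC/dt = d/dx(D(C) dC/dx) + lambda C F(C)` with periodic boundaries:
#' finite-volume flux differences with arithmetic-mean interface
#' diffusivities, integrated by the stiff-capable adaptive `lsoda` solver.
#'
#' Small negative undershoots (degenerate diffusivities produce sharp fronts)
#' are clipped to zero between integrator outputs; undershoots beyond `1e-7`
#' trigger a warning, as does any overshoot beyond `1 + 1e-7`.
#'
#' @param D a [diffusivity_fn].
#' @param F_fn a [crowding_f] source modulation, or `NULL` for pure
#'   diffusion.
#' @param lambda growth rate constant (`lambda = P/tau`).
#' @param init a [density_profile] initial condition with values in `[0, 1]`.
#' @param t_end end time.
#' @param record_times output times (defaults to `c(0, t_end)`).
#' @param rtol,atol integration tolerances.
#' @return An object of class `pde_solution`: `times`, `profiles` (times x
#'   nodes matrix), `grid`, `total_density` per time, and solver
#'   `diagnostics`.
#' @export
solve_column_pde <- function(D, F_fn = NULL, lambda = 0, init,
                             t_end, record_times = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(D, "diffusivity_fn"), inherits(init, "density_profile"),
            t_end >= 0)
  if (!is.null(F_fn)) stopifnot(inherits(F_fn, "crowding_f"))
  stopifnot(all(init$values >= 0), all(init$values <= 1))
  if (is.null(record_times)) record_times <- c(0, t_end)
  record_times <- sort(unique(c(0, record_times)))
  stopifnot(max(record_times) <= t_end + 1e-9)

  grid <- init$grid
  rhs <- make_pde_rhs(D, F_fn, lambda, grid$h)
  out <- integrate_pde(init$values, record_times, rhs, rtol, atol)
  profiles <- unname(out[, -1, drop = FALSE])

  tol_neg <- 1e-7
  if (min(profiles) < -tol_neg) {
    warning("density undershoot below -1e-7 (min = ", signif(min(profiles), 3),
            "); clipped to 0", call. = FALSE)
  }
  if (max(profiles) > 1 + tol_neg) {
    warning("density overshoot above 1 + 1e-7 (max = ",
            signif(max(profiles), 3), ")", call. = FALSE)
  }
  profiles[profiles < 0] <- 0

  structure(list(times = record_times,
                 profiles = profiles,
                 grid = grid,
                 total_density = rowMeans(profiles),
                 diagnostics = list(method = "lsoda", rtol = rtol, atol = atol,
                                    istate = attr(out, "istate"))),
            class = "pde_solution")
}

#' @export
print.pde_solution <- function(x, ...) {
  cat(sprintf("<pde solution> %d nodes, t in [%g, %g]\n",
              x$grid$n, min(x$times), max(x$times)))
  cat("  total density:",
      paste(sprintf("t=%g: %.4f", x$times, x$total_density), collapse = ", "),
      "\n")
  invisible(x)
}

#' Extract a profile from a PDE solution
#'
#' @param sol a `pde_solution`.
#' @param time one of the recorded times.
#' @return A [density_profile].
#' @export
profile_at <- function(sol, time) {
  k <- which(abs(sol$times - time) < 1e-9)
  if (length(k) != 1) stop("time ", time, " was not recorded", call. = FALSE)
  density_profile(sol$profiles[k, ], sol$grid)
}

#' Analytic diffusive flux of a density profile
#'
#' `J_x = -D(C) dC/dx` with the gradient by central differences on the
#' periodic grid, together with the equivalent linear-plus-correction
#' decomposition `J_x = -D0 (1 + H(C)) dC/dx`.
#'
#' @param profile a [density_profile].
#' @param D a [diffusivity_fn].
#' @return A data frame with columns `x`, `C`, `dCdx`, `Jx` and
#'   `Jx_decomposed` (algebraically identical to `Jx`).
#' @export
analytic_flux <- function(profile, D) {
  stopifnot(inherits(profile, "density_profile"),
            inherits(D, "diffusivity_fn"))
  y <- profile$values
  n <- length(y)
  h <- profile$grid$h
  dCdx <- (c(y[-1], y[1]) - c(y[n], y[-n])) / (2 * h)
  H <- flux_correction(D)
  data.frame(x = profile$grid$x, C = y, dCdx = dCdx,
             Jx = -D$value(y) * dCdx,
             Jx_decomposed = -D$D0 * (1 + H(y)) * dCdx)
}

#' Well-mixed (spatially uniform) growth dynamics
#'
#' The ODE `dC/dt = lambda C F(C)`.  With the strong Allee growth law this is
#' bistable: trajectories starting below the Allee threshold `A` decay to 0,
#' trajectories starting above `A` approach the carrying capacity 1.
#'
#' @param F_fn a [crowding_f].
#' @param lambda growth rate constant.
#' @param C0 initial density in `[0, 1]`.
#' @param t_end end time.
#' @param record_times output times (default: 101 uniform times).
#' @return A data frame with columns `t` and `C`.
#' @export
solve_wellmixed_ode <- function(F_fn, lambda, C0, t_end, record_times = NULL) {
  stopifnot(inherits(F_fn, "crowding_f"), C0 >= 0, C0 <= 1, t_end > 0)
  if (is.null(record_times)) record_times <- seq(0, t_end, length.out = 101)
  record_times <- sort(unique(c(0, record_times)))
  rhs <- function(t, y, parms) {
    yc <- pmin(pmax(y, 0), 1)
    list(lambda * yc * F_fn$value(yc))
  }
  out <- deSolve::ode(y = C0, times = record_times, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  data.frame(t = out[, 1], C = pmin(pmax(out[, 2], 0), 1))
}
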