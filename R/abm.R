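# Stochastic simulation: configuration, single sweeps, ensembles and
# empirical flux measurement.

#' Configuration of the stochastic lattice model
#'
#' @param rates a [rate_constants] object (movement and growth attempt
#'   probabilities `M`, `P` with lattice spacing and time step).
#' @param G a [crowding_g] movement crowding function.
#' @param F_fn a [crowding_f] growth crowding function.
#' @param geometry a [hex_geometry].
#' @param init initial condition: a [hex_state], or a function
#'   `geometry -> hex_state` (drawn inside each realization's seed, e.g.
#'   [init_uniform()]).
#' @param r_move template diameter for movement (nearest neighbours by
#'   default).
#' @param r_growth template diameter for growth; daughters are placed on the
#'   same template used to measure the local density of the mother.
#' @param V number of identically prepared realizations.
#' @param base_seed integer; realization `v` uses seed `base_seed + v`.
#' @param t_end end time.
#' @param record_times times at which column densities are recorded
#'   (rounded to multiples of `tau`; defaults to `c(0, t_end)`).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(rates, G, F_fn, geometry, init,
                              r_move = 1L, r_growth = 4L,
                              V = 1L, base_seed = 1L,
                              t_end, record_times = NULL) {
  stopifnot(inherits(rates, "rate_constants"),
            inherits(G, "crowding_g"), inherits(F_fn, "crowding_f"),
            inherits(geometry, "hex_geometry"),
            r_move >= 1, r_growth >= 1, V >= 1, t_end >= 0)
  if (is.null(record_times)) record_times <- c(0, t_end)
  record_times <- sort(unique(record_times))
  stopifnot(all(record_times >= 0), all(record_times <= t_end + 1e-9))
  structure(list(rates = rates, G = G, F_fn = F_fn, geometry = geometry,
                 init = init, r_move = as.integer(r_move),
                 r_growth = as.integer(r_growth), V = as.integer(V),
                 base_seed = as.integer(base_seed), t_end = t_end,
                 record_times = record_times,
                 cache = new.env(parent = emptyenv())),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation config> M = %g, P = %g, r_move = %d, r_growth = %d, V = %d, t_end = %g\n",
    x$rates$M, x$rates$P, x$r_move, x$r_growth, x$V, x$t_end))
  invisible(x)
}

# crowding tables over the discrete local densities k/|N_r|, with the
# probability contracts enforced
crowding_tables <- function(config) {
  size_m <- 3L * config$r_move * (config$r_move + 1L)
  size_g <- 3L * config$r_growth * (config$r_growth + 1L)
  g_tab <- config$G$value((0:size_m) / size_m)
  if (any(!is.finite(g_tab)) || any(g_tab < 0) || any(g_tab > 1)) {
    stop("G(K) outside [0, 1] at a reachable local density; ",
         "movement probabilities would overflow", call. = FALSE)
  }
  f_tab <- config$F_fn$value((0:size_g) / size_g)
  if (any(!is.finite(f_tab)) || config$rates$P * max(abs(f_tab)) > 1 + 1e-12) {
    stop("P * |F(K)| exceeds 1 at a reachable local density", call. = FALSE)
  }
  list(g = g_tab, f = f_tab)
}

engine_inputs <- function(config) {
  if (!is.null(config$cache) && !is.null(config$cache$inputs)) {
    return(config$cache$inputs)
  }
  geom <- config$geometry
  tabs <- crowding_tables(config)
  inputs <- list(tabs = tabs,
                 nbr_move = t(neighbor_table(geom, config$r_move)),
                 nbr_grow = t(neighbor_table(geom, config$r_growth)),
                 xpos = (hex_coordinates(geom)$x) / geom$delta)
  if (!is.null(config$cache)) config$cache$inputs <- inputs
  inputs
}

resolve_init <- function(config) {
  st <- if (is.function(config$init)) config$init(config$geometry)
        else config$init
  stopifnot(inherits(st, "hex_state"),
            st$geometry$n_sites == config$geometry$n_sites)
  st
}

run_engine <- function(state, config, inputs, n_steps, record_steps,
                       do_movement = TRUE, do_growth = TRUE,
                       flux_window = c(-1L, -1L)) {
  geom <- config$geometry
  .run_lattice_engine(state$occupancy, geom$I, geom$J,
                      inputs$nbr_move, inputs$nbr_grow,
                      inputs$tabs$g, inputs$tabs$f,
                      config$rates$M, config$rates$P,
                      as.integer(n_steps), as.integer(record_steps),
                      do_movement, do_growth,
                      as.integer(flux_window[1]), as.integer(flux_window[2]),
                      inputs$xpos)
}

sweep_once <- function(state, config, do_movement, do_growth) {
  inputs <- engine_inputs(config)
  res <- run_engine(state, config, inputs, n_steps = 1L,
                    record_steps = integer(0),
                    do_movement = do_movement, do_growth = do_growth)
  out <- hex_state(state$geometry, res$final_occ)
  attr(out, "audit") <- list(moves = res$moves, births = res$births,
                             deaths = res$deaths)
  out
}

#' Perform one movement sweep
#'
#' `Q(t)` agents are selected at random with replacement; each selected agent
#' moves with probability `M * G(K)` (local density `K` on the movement
#' template) to a uniformly chosen vacant site of its template.  The agent
#' count is conserved.  Uses the current R RNG state.
#'
#' @param state a [hex_state].
#' @param config a [simulation_config].
#' @return The updated [hex_state], with an `audit` attribute counting events.
#' @export
movement_sweep <- function(state, config) {
  sweep_once(state, config, do_movement = TRUE, do_growth = FALSE)
}

#' Perform one growth sweep
#'
#' `Q(t)` selections (count fixed at sweep start) with replacement from the
#' live-agent list; a selected agent with local density `K` on the growth
#' template gives birth with probability `P * F(K)` when `F(K) > 0` (daughter
#' placed on a uniformly chosen vacant template site) and dies with
#' probability `P * |F(K)|` when `F(K) < 0`.
#'
#' @inheritParams movement_sweep
#' @return The updated [hex_state] with an `audit` attribute.
#' @export
growth_sweep <- function(state, config) {
  sweep_once(state, config, do_movement = FALSE, do_growth = TRUE)
}

#' Advance the lattice model by one time step
#'
#' A movement sweep followed by a growth sweep; time advances by `tau`.
#'
#' @inheritParams movement_sweep
#' @return The updated [hex_state] with an `audit` attribute.
#' @export
abm_step <- function(state, config) {
  sweep_once(state, config, do_movement = TRUE, do_growth = TRUE)
}

#' Simulate an ensemble of realizations
#'
#' Runs `V` identically prepared realizations (realization `v` seeded with
#' `base_seed + v`) and aggregates the average column density
#' `<C(x,t)>`, the total density `<C(t)>` and the average final-time site
#' occupancy.
#'
#' @param config a [simulation_config].
#' @param flux_window optional `c(t0, t1)`: tally net column-interface
#'   crossings of movement events during `(t0, t1]` (see [measure_flux()]).
#' @return An object of class `ensemble_result` with fields
#'   `times`, `x`, `column_density` (times x columns matrix),
#'   `column_density_se`, `total_density` (data frame `t, mean, se`),
#'   `site_occupancy`, `Q` (times x V matrix), `audit`, and `flux`
#'   (`NULL` unless a window was given).
#' @export
simulate_ensemble <- function(config, flux_window = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  geom <- config$geometry
  tau <- config$rates$tau
  inputs <- engine_inputs(config)
  record_steps <- sort(unique(as.integer(round(config$record_times / tau))))
  n_steps <- max(as.integer(round(config$t_end / tau)), record_steps)
  fw <- if (is.null(flux_window)) c(-1L, -1L)
        else as.integer(round(flux_window / tau))
  n_rec <- length(record_steps)

  col_sum <- matrix(0, n_rec, geom$I)
  col_sq <- matrix(0, n_rec, geom$I)
  tot <- matrix(0, n_rec, config$V)
  occ_sum <- numeric(geom$n_sites)
  flux_net <- matrix(0, config$V, geom$I)
  Qm <- matrix(0L, n_rec, config$V)
  audit <- c(moves = 0, births = 0, deaths = 0)

  for (v in seq_len(config$V)) {
    set.seed(config$base_seed + v)
    st <- resolve_init(config)
    res <- run_engine(st, config, inputs, n_steps, record_steps,
                      flux_window = fw)
    col_sum <- col_sum + res$col_density
    col_sq <- col_sq + res$col_density^2
    tot[, v] <- res$total_density
    occ_sum <- occ_sum + res$final_occ
    flux_net[v, ] <- res$flux_net
    Qm[, v] <- res$Q
    audit <- audit + c(res$moves, res$births, res$deaths)
  }

  V <- config$V
  cd <- col_sum / V
  cd_se <- if (V > 1) sqrt(pmax(col_sq / V - cd^2, 0) / (V - 1)) else cd * NA
  tot_mean <- rowMeans(tot)
  tot_se <- if (V > 1) apply(tot, 1, stats::sd) / sqrt(V) else rep(NA_real_, n_rec)

  flux <- NULL
  if (!is.null(flux_window)) {
    duration <- (fw[2] - fw[1]) * tau
    # net crossings per unit time per lattice row, converted to the
    # column-density flux J_x = -D(C) dC/dx (factor delta / J)
    jx <- flux_net * geom$delta / (duration * geom$J)
    flux <- data.frame(
      x = ((0:(geom$I - 1)) + 0.75) * geom$delta,
      Jx = colMeans(jx),
      se = if (V > 1) apply(jx, 2, stats::sd) / sqrt(V)
           else rep(NA_real_, geom$I))
    attr(flux, "per_realization") <- jx
  }

  structure(list(times = record_steps * tau,
                 x = (0:(geom$I - 1)) * geom$delta,
                 column_density = cd,
                 column_density_se = cd_se,
                 total_density = data.frame(t = record_steps * tau,
                                            mean = tot_mean, se = tot_se),
                 site_occupancy = occ_sum / V,
                 Q = Qm,
                 audit = audit,
                 flux = flux,
                 config = config),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "<ensemble result> V = %d realizations, %d recorded times (t in [%g, %g])\n",
    x$config$V, length(x$times), min(x$times), max(x$times)))
  td <- x$total_density
  cat("  total density:",
      paste(sprintf("t=%g: %.4f", td$t, td$mean), collapse = ", "), "\n")
  invisible(x)
}

#' Measure the empirical horizontal flux profile
#'
#' Runs an ensemble and tallies the net number of movement events whose
#' horizontal displacement carries the agent across the vertical lines
#' `x* = (k + 3/4) delta` (lines offset from both staggered site columns, so
#' every crossing is unambiguous).  The net crossing count divided by the
#' window duration and the number of lattice rows estimates the column
#' density flux, comparable to the continuum `J_x = -D(C) dC/dx`.
#'
#' @param config a [simulation_config].
#' @param window `c(t0, t1)` tally window; at least 100 steps are required
#'   for a usable signal.
#' @return A data frame with columns `x` (line positions) and `Jx`, plus the
#'   full `ensemble_result` as attribute `ensemble`.
#' @export
measure_flux <- function(config, window = c(0, config$t_end)) {
  stopifnot(length(window) == 2, window[2] > window[1])
  if ((window[2] - window[1]) / config$rates$tau < 100) {
    warning("flux window shorter than 100 steps; expect a noisy profile",
            call. = FALSE)
  }
  res <- simulate_ensemble(config, flux_window = window)
  out <- res$flux
  attr(out, "ensemble") <- res
  out
}
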