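# Long-term fate classification and the (w, P/M) survival/extinction phase
# diagram, including critical-width extraction by bisection.

resolve_model <- function(model, D0) {
  if (inherits(model, "crowding_pair")) return(model)
  if (is.character(model)) return(crowding_catalogue(model, D0 = D0))
  stop("model must be a catalogue name or a crowding_pair", call. = FALSE)
}

undecided_condition <- function(C_final, T, dCdt) {
  structure(class = c("crowdfate_undecided", "error", "condition"),
            list(message = sprintf(
              "fate undecided at T = %g: total density %.4f with |dC/dt| = %.2e",
              T, C_final, abs(dCdt)),
              call = NULL, C_final = C_final))
}

# continuum-engine fate: chunked adaptive integration with early exit
continuum_fate <- function(pair, F_fn, lambda, w, L, h, T,
                           guard_lo = 0.01, guard_hi = 0.99,
                           chunk = 250, rtol = 1e-8, atol = 1e-10) {
  grid <- grid_1d(L, h)
  y <- strip_profile(grid, w)$values
  rhs <- make_pde_rhs(pair$D, F_fn, lambda, h)
  t_now <- 0
  cbar <- mean(y)
  repeat {
    if (cbar < guard_lo) {
      return(list(outcome = "extinct", C_final = cbar, time = t_now))
    }
    if (cbar > guard_hi) {
      return(list(outcome = "survive", C_final = cbar, time = t_now))
    }
    if (t_now >= T) break
    t_next <- min(t_now + chunk, T)
    out <- integrate_pde(y, c(t_now, t_next), rhs, rtol, atol)
    y <- pmax(out[nrow(out), -1], 0)
    cbar_prev <- cbar
    cbar <- mean(y)
    dCdt <- (cbar - cbar_prev) / (t_next - t_now)
    t_now <- t_next
  }
  list(outcome = if (cbar > 0.5) "survive" else "extinct",
       C_final = cbar, time = t_now,
       undecided = cbar > 0.05 && cbar < 0.95 && abs(dCdt) > 1e-6,
       dCdt = dCdt)
}

# discrete-engine fate for one realization, chunked with early exit
discrete_fate_one <- function(config, inputs, T, chunk_steps = 500,
                              guard_lo = 0.01, guard_hi = 0.99) {
  st <- resolve_init(config)
  n_sites <- config$geometry$n_sites
  tau <- config$rates$tau
  steps_total <- as.integer(round(T / tau))
  done <- 0L
  state <- st
  repeat {
    cbar <- state$Q / n_sites
    if (cbar < guard_lo || state$Q == 0L)
      return(list(outcome = "extinct", C_final = cbar, time = done * tau))
    if (cbar > guard_hi)
      return(list(outcome = "survive", C_final = cbar, time = done * tau))
    if (done >= steps_total) break
    n <- min(chunk_steps, steps_total - done)
    res <- run_engine(state, config, inputs, n, integer(0))
    state <- hex_state(config$geometry, res$final_occ)
    done <- done + n
  }
  cbar <- state$Q / n_sites
  list(outcome = if (cbar > 0.5) "survive" else "extinct",
       C_final = cbar, time = done * tau,
       undecided = cbar > 0.05 && cbar < 0.95)
}

#' Classify the long-term fate of a strip initial condition
#'
#' Runs either the continuum solver or the stochastic lattice model from the
#' central-strip initial condition of width `w` until the total density
#' crosses an extinction guard (`< 0.01`) or a survival guard (`> 0.99`), or
#' until the decision time `T` is reached.  The fate is the guard that was
#' crossed; a run still mid-range at `T` with a non-negligible rate of change
#' is reported as undecided.
#'
#' @param model a catalogue name or `crowding_pair`.
#' @param w initial strip width.
#' @param M,P movement and growth attempt probabilities (continuum constants
#'   `D0 = M/4`, `lambda = P` with unit spacing and time step).
#' @param T decision time.
#' @param engine `"continuum"` (deterministic, default) or `"discrete"`
#'   (majority vote over `V` realizations).
#' @param L domain width; `h` continuum node spacing; `A` Allee threshold.
#' @param V,base_seed discrete-engine ensemble size and seed.
#' @param on_undecided `"error"` raises a `crowdfate_undecided` condition;
#'   `"classify"` falls back to the `C(T) > 0.5` rule (used internally by
#'   the bisection, which brackets ever closer to the threshold).
#' @return An object of class `fate_outcome` with fields `w`, `P_over_M`,
#'   `outcome` (`"survive"`/`"extinct"`), `C_final` (total density at
#'   decision time), `C_limit` (the limiting density the classification
#'   rounds to: 1 for survival, 0 for extinction), `decision_time`, `engine`
#'   and, for the discrete engine, `survival_fraction`.
#' @export
classify_fate <- function(model, w, M = 1, P, T = 1e4,
                          engine = c("continuum", "discrete"),
                          L = 100, h = 0.5, A = 0.4,
                          V = 20, base_seed = 1,
                          on_undecided = c("error", "classify")) {
  engine <- match.arg(engine)
  on_undecided <- match.arg(on_undecided)
  stopifnot(w >= 0, w <= L, M > 0, P > 0, T > 0)
  D0 <- M / 4
  pair <- resolve_model(model, D0)
  F_fn <- strong_allee_growth(A)
  surv_frac <- NA_real_

  if (engine == "continuum") {
    res <- continuum_fate(pair, F_fn, lambda = P, w = w, L = L, h = h, T = T)
    if (isTRUE(res$undecided) && on_undecided == "error") {
      stop(undecided_condition(res$C_final, T, res$dCdt))
    }
  } else {
    geom <- hex_geometry(as.integer(round(L)), as.integer(round(L)))
    config <- simulation_config(
      rates = suppressWarnings(rate_constants(M, P)),
      G = pair$G, F_fn = F_fn, geometry = geom,
      init = init_strip(geom, w), V = as.integer(V),
      base_seed = as.integer(base_seed), t_end = T)
    inputs <- engine_inputs(config)
    fates <- vector("list", config$V)
    for (v in seq_len(config$V)) {
      set.seed(config$base_seed + v)
      fates[[v]] <- discrete_fate_one(config, inputs, T)
    }
    surv <- vapply(fates, function(f) f$outcome == "survive", logical(1))
    surv_frac <- mean(surv)
    res <- list(outcome = if (surv_frac > 0.5) "survive" else "extinct",
                C_final = mean(vapply(fates, `[[`, numeric(1), "C_final")),
                time = max(vapply(fates, `[[`, numeric(1), "time")))
    if (surv_frac > 0.05 && surv_frac < 0.95 &&
        any(vapply(fates, function(f) isTRUE(f$undecided), logical(1))) &&
        on_undecided == "error") {
      stop(undecided_condition(res$C_final, T, NA))
    }
  }

  structure(list(w = w, P_over_M = P / M, outcome = res$outcome,
                 C_final = res$C_final,
                 C_limit = as.numeric(res$outcome == "survive"),
                 decision_time = res$time, engine = engine,
                 model = pair$name, survival_fraction = surv_frac),
            class = "fate_outcome")
}

#' @export
print.fate_outcome <- function(x, ...) {
  cat(sprintf(
    "<fate> model %s, w = %g, P/M = %g [%s]: %s (C = %.4f at t = %g)\n",
    x$model, x$w, x$P_over_M, x$engine, x$outcome, x$C_final,
    x$decision_time))
  invisible(x)
}

#' Critical strip width separating extinction from survival
#'
#' Bisection on the initial width `w` with the continuum fate classifier:
#' populations started from strips narrower than `w*` go extinct, wider
#' strips survive.
#'
#' @param model a catalogue name or `crowding_pair`.
#' @param P_over_M rate ratio; `M` fixes the scale (`P = P_over_M * M`).
#' @param M movement probability.
#' @param tol_w bisection tolerance on `w`.
#' @param w_range search range `c(w_lo, w_hi)`; `w_lo` must be extinct and
#'   `w_hi` survive, otherwise the absence of a bracket is reported.
#' @param ... passed to [classify_fate()] (e.g. `T`, `L`, `h`).
#' @return A list of class `critical_width` with `w_star`, the final
#'   `bracket`, and the number of classifier calls.
#' @export
critical_width <- function(model, P_over_M, M = 1, tol_w = 0.25,
                           w_range = c(0, 40), ...) {
  fate <- function(w) classify_fate(model, w = w, M = M, P = P_over_M * M,
                                    on_undecided = "classify", ...)$outcome
  lo <- w_range[1]; hi <- w_range[2]
  calls <- 0L
  if (lo > 0 && fate(lo) != "extinct") {
    stop("no bracket: w = ", lo, " already survives", call. = FALSE)
  }
  if (fate(hi) != "survive") {
    stop("no bracket: w = ", hi, " goes extinct ",
         "(survival may be impossible at this P/M)", call. = FALSE)
  }
  calls <- calls + 2L
  while (hi - lo > tol_w) {
    mid <- (lo + hi) / 2
    if (fate(mid) == "survive") hi <- mid else lo <- mid
    calls <- calls + 1L
  }
  structure(list(w_star = (lo + hi) / 2, bracket = c(lo, hi),
                 tol_w = tol_w, model = resolve_model(model, 1)$name,
                 P_over_M = P_over_M, classifier_calls = calls),
            class = "critical_width")
}

#' @export
print.critical_width <- function(x, ...) {
  cat(sprintf("<critical width> model %s, P/M = %g: w* = %.3f (+/- %.3f)\n",
              x$model, x$P_over_M, x$w_star, diff(x$bracket) / 2))
  invisible(x)
}

#' Survival/extinction phase diagram over (w, P/M)
#'
#' Classifies every node of a rectangular `(w, P/M)` mesh with the continuum
#' engine and extracts, per model and rate ratio, the critical width by
#' linear interpolation between the last extinct and first surviving node.
#' Nodes whose fate is undecided at `T` are reported and excluded from the
#' boundary; non-monotone rows (survival not monotone non-decreasing in `w`)
#' are flagged.
#'
#' @param models character vector of catalogue names (or list of
#'   `crowding_pair`s).
#' @param w_range,ratio_range ranges of the mesh.
#' @param resolution `c(n_w, n_ratio)` mesh size.
#' @param M movement probability (`P = ratio * M` per node).
#' @param T decision time.
#' @param ... further arguments to [classify_fate()].
#' @return An object of class `phase_diagram` with the mesh, an
#'   `outcomes` array (`n_w x n_ratio x n_models`, 1 survive / 0 extinct /
#'   NA undecided), the `boundary` data frame (`model, P_over_M, w_star`),
#'   undecided node list and monotonicity flags.
#' @export
phase_diagram <- function(models, w_range = c(0, 40),
                          ratio_range = c(1 / 1000, 4 / 100),
                          resolution = c(41L, 40L),
                          M = 1, T = 1e4, ...) {
  if (!is.list(models)) models <- as.list(models)
  w_grid <- seq(w_range[1], w_range[2], length.out = resolution[1])
  ratio_grid <- seq(ratio_range[1], ratio_range[2],
                    length.out = resolution[2])
  model_names <- vapply(models, function(m) resolve_model(m, 1)$name,
                        character(1))
  nm <- length(models)
  outcomes <- array(NA_real_, c(length(w_grid), length(ratio_grid), nm),
                    dimnames = list(NULL, NULL, model_names))
  undecided <- data.frame(model = character(), w = numeric(),
                          P_over_M = numeric())
  for (k in seq_len(nm)) {
    for (j in seq_along(ratio_grid)) {
      for (i in seq_along(w_grid)) {
        if (w_grid[i] == 0) { outcomes[i, j, k] <- 0; next }
        f <- tryCatch(
          classify_fate(models[[k]], w = w_grid[i], M = M,
                        P = ratio_grid[j] * M, T = T, ...),
          crowdfate_undecided = function(e) NULL)
        if (is.null(f)) {
          undecided <- rbind(undecided,
                             data.frame(model = model_names[k],
                                        w = w_grid[i],
                                        P_over_M = ratio_grid[j]))
        } else {
          outcomes[i, j, k] <- as.numeric(f$outcome == "survive")
        }
      }
    }
  }

  boundary <- data.frame(model = character(), P_over_M = numeric(),
                         w_star = numeric())
  monotone <- matrix(TRUE, length(ratio_grid), nm,
                     dimnames = list(NULL, model_names))
  for (k in seq_len(nm)) {
    for (j in seq_along(ratio_grid)) {
      oc <- outcomes[, j, k]
      known <- !is.na(oc)
      if (any(diff(oc[known]) < 0)) monotone[j, k] <- FALSE
      le <- max(which(known & oc == 0), -Inf)   # last extinct
      fs <- min(which(known & oc == 1), Inf)    # first survive
      if (is.finite(le) && is.finite(fs) && fs > le) {
        boundary <- rbind(boundary,
                          data.frame(model = model_names[k],
                                     P_over_M = ratio_grid[j],
                                     w_star = (w_grid[le] + w_grid[fs]) / 2))
      }
    }
  }
  if (!all(monotone)) {
    warning("survival is not monotone in w on some mesh rows; flagged in ",
            "$monotone", call. = FALSE)
  }
  structure(list(w_grid = w_grid, ratio_grid = ratio_grid,
                 models = model_names, outcomes = outcomes,
                 boundary = boundary, undecided = undecided,
                 monotone = monotone),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase diagram> %d x %d mesh, models: %s\n",
              length(x$w_grid), length(x$ratio_grid),
              paste(x$models, collapse = ", ")))
  if (nrow(x$undecided)) cat("  undecided nodes:", nrow(x$undecided), "\n")
  invisible(x)
}

#' @describeIn phase_diagram heatmap of outcomes with boundary curves.
#' @param x a `phase_diagram`.
#' @export
plot.phase_diagram <- function(x, ...) {
  k <- 1L
  graphics::image(x$w_grid, x$ratio_grid, x$outcomes[, , k],
                  col = c("#d95f02", "#1b9e77"),
                  xlab = "initial strip width w", ylab = "P/M",
                  main = paste("survival (green) vs extinction:",
                               x$models[k]), ...)
  for (m in x$models) {
    b <- x$boundary[x$boundary$model == m, ]
    if (nrow(b)) graphics::lines(b$w_star, b$P_over_M, lwd = 2)
  }
  invisible(x)
}
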