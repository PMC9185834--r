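# Crowding-function algebra: movement crowding functions G(C), growth crowding
# functions F(C), nonlinear diffusivities D(C), and the maps between them.

# ---------------------------------------------------------------------------
# numeric differentiation (used for user-supplied G without a derivative)

#' Fourth-order finite-difference derivative on [0, 1]
#'
#' Central five-point stencil in the interior, one-sided five-point stencils
#' near the endpoints so that `f` is never evaluated outside `[0, 1]`.
#'
#' @param f function of a single numeric argument, defined on `[0, 1]`.
#' @param step stencil spacing.
#' @return A vectorised function returning `df/dC`.
#' @keywords internal
#' @noRd
fd_derivative <- function(f, step = 1e-5) {
  h <- step
  function(C) {
    vapply(C, function(x) {
      if (x >= 2 * h && x <= 1 - 2 * h) {
        (-f(x + 2 * h) + 8 * f(x + h) - 8 * f(x - h) + f(x - 2 * h)) / (12 * h)
      } else if (x < 2 * h) {
        (-25 * f(x) + 48 * f(x + h) - 36 * f(x + 2 * h) +
           16 * f(x + 3 * h) - 3 * f(x + 4 * h)) / (12 * h)
      } else {
        (25 * f(x) - 48 * f(x - h) + 36 * f(x - 2 * h) -
           16 * f(x - 3 * h) + 3 * f(x - 4 * h)) / (12 * h)
      }
    }, numeric(1))
  }
}

# ---------------------------------------------------------------------------
# domain types

#' Movement crowding function G(C)
#'
#' A movement crowding function quantifies how local crowding reduces the
#' motility of an individual: an agent surrounded by local density `K` moves
#' with probability `M * G(K)` per time step, so `G` must map `[0, 1]` into
#' `[0, 1]`.  `G(0) = 1` means isolated agents move unhindered and `G(1) = 0`
#' means a fully packed neighbourhood blocks movement.
#'
#' @param value function `C -> G(C)` on `[0, 1]`.
#' @param derivative function `C -> dG/dC`, or `NULL` to use fourth-order
#'   finite differences (step `1e-5`, one-sided at the endpoints).
#' @param label short description used in printing and output files.
#' @param ratio optional function `C -> G(C) / (1 - C)`.  When the crowding
#'   function contains an explicit factor `(1 - C)` this cancelled form lets
#'   the diffusivity map evaluate the `(1 + C) G(C) / (1 - C)` term exactly at
#'   `C = 1` instead of through a limit.
#' @param check if `TRUE`, sample `value` densely and warn (setting the
#'   `valid` field to `FALSE`) when it leaves `[0, 1]`.
#' @return An object of class `crowding_g` with fields `value`, `derivative`,
#'   `ratio`, `label` and `valid`.
#' @examples
#' G <- crowding_g(function(C) 1 - C, function(C) rep(-1, length(C)),
#'                 label = "1 - C")
#' G$value(0.25)
#' @export
crowding_g <- function(value, derivative = NULL, label = "",
                       ratio = NULL, check = TRUE) {
  stopifnot(is.function(value))
  if (is.null(derivative)) derivative <- fd_derivative(value)
  valid <- TRUE
  if (check) {
    Cs <- seq(0, 1, length.out = 201)
    v <- value(Cs)
    if (any(!is.finite(v)) || any(v < -1e-9) || any(v > 1 + 1e-9)) {
      warning("movement crowding function leaves [0, 1] on [0, 1]; ",
              "marked invalid", call. = FALSE)
      valid <- FALSE
    }
  }
  structure(list(value = value, derivative = derivative, ratio = ratio,
                 label = label, valid = valid),
            class = "crowding_g")
}

#' @export
print.crowding_g <- function(x, ...) {
  cat("<movement crowding function>", if (nzchar(x$label)) x$label else "",
      "\n  G(0) =", format(x$value(0)), "  G(1) =", format(x$value(1)),
      "  valid:", x$valid, "\n")
  invisible(x)
}

#' Growth crowding function F(C)
#'
#' Modulates the birth/death mechanism: a selected agent with local density
#' `K` undergoes a growth event with probability `P * |F(K)|`; the event is a
#' birth when `F(K) > 0` and a death when `F(K) < 0`.  `F` must therefore map
#' `[0, 1]` into `[-1, 1]`.
#'
#' @param value function `C -> F(C)` on `[0, 1]` with values in `[-1, 1]`.
#' @param allee_threshold the Allee threshold density `A` (may be `NA` for
#'   non-bistable growth laws).
#' @param label short description.
#' @return An object of class `crowding_f`.
#' @seealso [strong_allee_growth()]
#' @export
crowding_f <- function(value, allee_threshold = NA_real_, label = "") {
  stopifnot(is.function(value))
  Cs <- seq(0, 1, length.out = 401)
  v <- value(Cs)
  if (any(!is.finite(v)) || max(abs(v)) > 1 + 1e-9) {
    stop("growth crowding function must map [0, 1] into [-1, 1] ",
         "(values scale event probabilities)", call. = FALSE)
  }
  structure(list(value = value, allee_threshold = allee_threshold,
                 label = label),
            class = "crowding_f")
}

#' @export
print.crowding_f <- function(x, ...) {
  cat("<growth crowding function>", if (nzchar(x$label)) x$label else "", "\n")
  if (!is.na(x$allee_threshold))
    cat("  Allee threshold A =", x$allee_threshold, "\n")
  invisible(x)
}

#' Strong Allee growth crowding function
#'
#' The bistable growth law `F(C) = 2.5 (1 - C)(C - A)`: per-capita growth is
#' negative below the Allee threshold `A` and positive between `A` and the
#' carrying capacity `C = 1`.  With `A = 0.4` this gives `F(0) = -1`, i.e.
#' isolated individuals have the largest probability of dying.
#'
#' @param A Allee threshold, `0 < A < 1`.  Values of `A` for which
#'   `|F| > 1` somewhere on `[0, 1]` (i.e. `A > 0.4`) are rejected because
#'   `F` scales an event probability.
#' @return A [crowding_f] object.
#' @examples
#' F <- strong_allee_growth(0.4)
#' F$value(c(0, 0.4, 0.7, 1))
#' @export
strong_allee_growth <- function(A = 0.4) {
  stopifnot(is.numeric(A), length(A) == 1, A > 0, A < 1)
  f <- function(C) 2.5 * (1 - C) * (C - A)
  ex <- max(abs(f(seq(0, 1, length.out = 401))))
  if (ex > 1 + 1e-9) {
    stop("strong Allee growth with A = ", A, " has max |F| = ",
         signif(ex, 4), " > 1; event probabilities would overflow",
         call. = FALSE)
  }
  crowding_f(f, allee_threshold = A,
             label = sprintf("2.5(1-C)(C-%g) strong Allee", A))
}

#' Nonlinear diffusivity function D(C)
#'
#' @param value function `C -> D(C)` (units length^2/time).
#' @param D0 reference (free-agent) diffusivity constant.
#' @param label short description.
#' @return An object of class `diffusivity_fn`.
#' @export
diffusivity_fn <- function(value, D0, label = "") {
  stopifnot(is.function(value), is.numeric(D0), length(D0) == 1, D0 > 0)
  structure(list(value = value, D0 = D0, label = label),
            class = "diffusivity_fn")
}

#' @export
print.diffusivity_fn <- function(x, ...) {
  cat("<nonlinear diffusivity>", if (nzchar(x$label)) x$label else "",
      "\n  D0 =", x$D0, "  D(0) =", format(x$value(0)),
      "  D(1) =", format(x$value(1)), "\n")
  invisible(x)
}

#' Rate constants of the lattice model and their continuum counterparts
#'
#' Per-step attempt probabilities `M` (movement) and `P` (growth) on a lattice
#' with spacing `delta` and time step `tau` give the continuum-limit constants
#' `D0 = M delta^2 / (4 tau)` and `lambda = P / tau`.  With `delta = tau = 1`
#' this is `D0 = M/4`, `lambda = P`.  The continuum limit requires growth to
#' be slow relative to movement (`P << M`); a warning is issued when
#' `P > M/10`.
#'
#' @param M movement attempt probability per step, in `[0, 1]`.
#' @param P growth attempt probability per step, in `[0, 1]`.
#' @param delta lattice spacing (length).
#' @param tau time step (time).
#' @return An object of class `rate_constants` with derived fields `D0` and
#'   `lambda`.
#' @export
rate_constants <- function(M, P, delta = 1, tau = 1) {
  stopifnot(is.numeric(M), M >= 0, M <= 1,
            is.numeric(P), P >= 0, P <= 1,
            delta > 0, tau > 0)
  if (P > M / 10) {
    warning("P = ", P, " is not small relative to M = ", M,
            "; the continuum limit is only valid when P << M", call. = FALSE)
  }
  structure(list(M = M, P = P, delta = delta, tau = tau,
                 D0 = M * delta^2 / (4 * tau), lambda = P / tau),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf(
    "<rate constants> M = %g, P = %g, delta = %g, tau = %g (D0 = %g, lambda = %g)\n",
    x$M, x$P, x$delta, x$tau, x$D0, x$lambda))
  invisible(x)
}

# ---------------------------------------------------------------------------
# forward map G -> D

#' Map a movement crowding function to its nonlinear diffusivity
#'
#' The discrete-to-continuum limit of the crowding-modulated random walk gives
#' the population-level diffusivity
#' \deqn{D(C) = D_0 \left[ C G'(C) + \frac{1+C}{1-C} G(C) \right].}
#' The `(1+C)/(1-C)` factor is an apparent singularity: every physically
#' admissible `G` has `G(1) = 0`, so the product has a finite limit at
#' `C = 1`.  When `G` carries a cancelled `ratio` form `G(C)/(1-C)` the limit
#' is evaluated exactly; otherwise the value at `C = 1` is approximated at
#' `C = 1 - 1e-9` and a warning diagnoses crowding functions with
#' `G(1) != 0` (value exceeding `1e6`).
#'
#' @param G a [crowding_g] object.
#' @param D0 reference diffusivity constant.
#' @return A [diffusivity_fn].  Non-finite values at interior densities raise
#'   an error at construction (the map is sampled densely to validate).
#' @examples
#' cat_lin <- crowding_catalogue("linear")
#' D <- diffusivity_from_crowding(cat_lin$G, D0 = 1)
#' D$value(c(0, 0.5, 0.9))  # constant: linear diffusion
#' @export
diffusivity_from_crowding <- function(G, D0 = 1) {
  stopifnot(inherits(G, "crowding_g"), is.numeric(D0), D0 > 0)
  eps <- 1e-9
  if (!is.null(G$ratio)) {
    val <- function(C) D0 * (C * G$derivative(C) + (1 + C) * G$ratio(C))
  } else {
    val <- function(C) {
      C1 <- pmin(C, 1 - eps)  # G(1)=0 cancels the pole; approach it instead
      D0 * (C1 * G$derivative(C1) + (1 + C1) / (1 - C1) * G$value(C1))
    }
  }
  probe <- val(seq(0, 1 - 1e-6, length.out = 257))
  if (any(!is.finite(probe))) {
    stop("diffusivity map produced non-finite values at interior densities; ",
         "the crowding function is invalid (e.g. G(1) != 0 with no ",
         "cancelling factor)", call. = FALSE)
  }
  v1 <- val(1)
  if (!is.finite(v1) || abs(v1) > 1e6 * D0) {
    warning("diffusivity near C = 1 exceeds 1e6 * D0; the crowding function ",
            "likely has G(1) != 0", call. = FALSE)
  }
  diffusivity_fn(val, D0 = D0,
                 label = paste0("from crowding map",
                                if (nzchar(G$label)) paste0(" of ", G$label)))
}

#' Flux correction of a nonlinear diffusivity
#'
#' Rewriting the diffusive flux as `Jx = -D0 (1 + H(C)) dC/dx` defines the
#' correction `H(C) = D(C)/D0 - 1` relative to linear diffusion.  `H > 0`
#' means crowding enhances the flux (faster spreading than linear diffusion),
#' `H < 0` suppresses it.
#'
#' @param D a [diffusivity_fn].
#' @return A vectorised function `C -> H(C)`.
#' @export
flux_correction <- function(D) {
  stopifnot(inherits(D, "diffusivity_fn"), D$D0 > 0)
  function(C) D$value(C) / D$D0 - 1
}

# ---------------------------------------------------------------------------
# inverse map for power-law diffusivities

#' Gauss hypergeometric function 2F1 by series summation
#'
#' Direct Gauss series for `|z| < 1`; intended for the parameter ranges used
#' by the power-law inverse map, where `c > b > 0` and the series converges.
#'
#' @param a,b,cc parameters.
#' @param z argument, `0 <= z < 1`.
#' @param tol termination tolerance on the relative term size.
#' @param max_terms series length cap.
#' @return The sum of the series.
#' @keywords internal
hyp2f1_series <- function(a, b, cc, z, tol = 1e-15, max_terms = 200000L) {
  vapply(z, function(zz) {
    if (zz == 0) return(1)
    term <- 1
    s <- 1
    for (k in 0:max_terms) {
      term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * zz
      s <- s + term
      if (abs(term) < tol * abs(s)) return(s)
    }
    stop("2F1 series did not converge at z = ", zz, call. = FALSE)
  }, numeric(1))
}

# B(C) = (1-C) log(1-C) / C and (1 + B)/C, with series for small C where the
# direct forms lose accuracy by cancellation.
powerlaw_gbits <- function(C) {
  B <- numeric(length(C))
  onepB <- numeric(length(C))  # (1 + B)/C
  small <- C < 1e-3
  ks <- 1:9
  for (i in which(small)) {
    x <- C[i]
    pow <- x^(ks - 1)
    onepB[i] <- sum(pow / (ks * (ks + 1)))
    B[i] <- -1 + x * onepB[i]
  }
  big <- !small & C < 1
  W <- log1p(-C[big]) / C[big]
  B[big] <- (1 - C[big]) * W
  onepB[big] <- (1 + B[big]) / C[big]
  one <- C >= 1
  B[one] <- 0
  onepB[one] <- 1
  list(B = B, onepB_over_C = onepB)
}

#' Crowding function associated with a power-law diffusivity
#'
#' Inverting the crowding-to-diffusivity map for the power-law diffusivity
#' `D(C) = D0 C^m` gives
#' \deqn{G(C) = \frac{(C^{m+2} - 2C^{m+1} + C^m)\,
#'   {}_2F_1(2, m+1; m+2; C)}{m+1},}
#' where \eqn{{}_2F_1} is the Gauss hypergeometric function.  For
#' `m = 1, 2, 3` closed log forms are used; for other `m` the Euler-transformed
#' series \eqn{{}_2F_1(2,m+1;m+2;C) = (1-C)^{-1} {}_2F_1(m,1;m+2;C)} keeps
#' the evaluation stable as `C -> 1`.  Endpoints are returned as analytic
#' limits: `G(0) = G(1) = 0` for `m > 0` (and `G = 1 - C` for `m = 0`).
#'
#' @param m power-law exponent, `m >= 0`.
#' @param C densities in `[0, 1]`.
#' @return `G(C)`, vectorised over `C`.
#' @examples
#' crowding_from_powerlaw(1, 0.5)  # 0.5 * (1 + log(0.5))
#' crowding_from_powerlaw(2, c(0, 1))
#' @export
crowding_from_powerlaw <- function(m, C) {
  stopifnot(is.numeric(m), length(m) == 1, m >= 0, all(C >= 0), all(C <= 1))
  if (m == 0) return(1 - C)
  if (m %in% c(1, 2, 3)) {
    bits <- powerlaw_gbits(C)
    g <- powerlaw_g_reduced(m, C, bits$B)
    out <- (1 - C) * g
    out[C == 0] <- 0
    return(out)
  }
  out <- numeric(length(C))
  interior <- C > 0 & C < 1
  z <- C[interior]
  S <- hyp2f1_series(m, 1, m + 2, z)
  out[interior] <- z^m * (1 - z) * S / (m + 1)
  out  # endpoints are 0 for m > 0
}

# reduced form g(C) = G(C)/(1-C) for the integer power-law cases, written in
# terms of B = (1-C) log(1-C)/C
powerlaw_g_reduced <- function(m, C, B) {
  switch(as.character(m),
         "1" = 1 + B,
         "2" = 2 - C + 2 * B,
         "3" = (6 - 3 * C - C^2) / 2 + 3 * B,
         stop("no closed form for m = ", m))
}

# derivative of G for the integer power-law cases, grouped so the log
# singularity in g'(C) is cancelled by the (1-C) factor before evaluation
powerlaw_g_derivative <- function(m, C) {
  bits <- powerlaw_gbits(C)
  B <- bits$B
  Bp1 <- -B - (1 - C) * bits$onepB_over_C  # (1-C) * dB/dC
  g <- powerlaw_g_reduced(m, C, B)
  omc_gp <- switch(as.character(m),  # (1-C) * dg/dC
                   "1" = Bp1,
                   "2" = -(1 - C) + 2 * Bp1,
                   "3" = (1 - C) * (-3 - 2 * C) / 2 + 3 * Bp1)
  -g + omc_gp
}

# crowding_g object for a power-law diffusivity exponent
powerlaw_crowding_g <- function(m) {
  if (m %in% c(1, 2, 3)) {
    crowding_g(
      value = function(C) crowding_from_powerlaw(m, C),
      derivative = function(C) powerlaw_g_derivative(m, C),
      ratio = function(C) powerlaw_g_reduced(m, C, powerlaw_gbits(C)$B),
      label = sprintf("inverse of D = D0*C^%g", m),
      check = FALSE)
  } else {
    val <- function(C) crowding_from_powerlaw(m, C)
    crowding_g(
      value = val,
      derivative = fd_derivative(val),
      ratio = function(C) {
        r <- numeric(length(C))
        r[C == 0] <- if (m > 0) 0 else 1
        r[C == 1] <- 1
        i <- C > 0 & C < 1
        r[i] <- C[i]^m * hyp2f1_series(m, 1, m + 2, C[i]) / (m + 1)
        r
      },
      label = sprintf("inverse of D = D0*C^%g", m),
      check = FALSE)
  }
}

# ---------------------------------------------------------------------------
# catalogue

.catalogue_names <- c("linear", "increasing", "decreasing",
                      "powerlaw-m1", "powerlaw-m2", "powerlaw-m3")

#' Names of the built-in crowding function / diffusivity pairs
#' @return Character vector of catalogue names.
#' @export
catalogue_names <- function() .catalogue_names

#' Built-in catalogue of crowding function / diffusivity pairs
#'
#' Six closed-form pairs `(G, D)`:
#' \describe{
#'   \item{`linear`}{`G = 1 - C`, `D = D0` (linear diffusion).}
#'   \item{`increasing`}{`G = (1-C)(1+C/2)`, `D = D0[1 + C(1 - C/2)]`:
#'     crowding reduces motility less than linearly, so the diffusivity
#'     increases with density.}
#'   \item{`decreasing`}{`G = (1-C)(1-C/2)`, `D = D0[1 - C(1 - C/2)]`.}
#'   \item{`powerlaw-m1`, `powerlaw-m2`, `powerlaw-m3`}{the crowding
#'     functions obtained by inverting `D = D0 C^m`; degenerate diffusivities
#'     with `D(0) = 0` and `G(0) = G(1) = 0`.}
#' }
#'
#' @param name one of [catalogue_names()].
#' @param D0 reference diffusivity attached to the returned pair.
#' @return A list of class `crowding_pair` with elements `G` ([crowding_g]),
#'   `D` ([diffusivity_fn]), `H` (flux-correction function) and `name`.
#' @examples
#' p <- crowding_catalogue("increasing")
#' p$D$value(0.5) # 1.375 with D0 = 1
#' @export
crowding_catalogue <- function(name, D0 = 1) {
  name <- match.arg(name, .catalogue_names)
  entry <- switch(name,
    linear = list(
      G = crowding_g(function(C) 1 - C,
                     function(C) rep(-1, length(C)),
                     label = "1 - C",
                     ratio = function(C) rep(1, length(C)), check = FALSE),
      Dval = function(C) rep(D0, length(C)),
      Dlab = "D0"),
    increasing = list(
      G = crowding_g(function(C) (1 - C) * (1 + C / 2),
                     function(C) -1 / 2 - C,
                     label = "(1-C)(1+C/2)",
                     ratio = function(C) 1 + C / 2, check = FALSE),
      Dval = function(C) D0 * (1 + C * (1 - C / 2)),
      Dlab = "D0[1 + C(1 - C/2)]"),
    decreasing = list(
      G = crowding_g(function(C) (1 - C) * (1 - C / 2),
                     function(C) -3 / 2 + C,
                     label = "(1-C)(1-C/2)",
                     ratio = function(C) 1 - C / 2, check = FALSE),
      Dval = function(C) D0 * (1 - C * (1 - C / 2)),
      Dlab = "D0[1 - C(1 - C/2)]"),
    {
      m <- as.numeric(sub("powerlaw-m", "", name))
      list(G = powerlaw_crowding_g(m),
           Dval = function(C) D0 * C^m,
           Dlab = sprintf("D0*C^%d", m))
    })
  D <- diffusivity_fn(entry$Dval, D0 = D0, label = entry$Dlab)
  structure(list(G = entry$G, D = D, H = flux_correction(D), name = name),
            class = "crowding_pair")
}

#' @export
print.crowding_pair <- function(x, ...) {
  cat("<crowding pair>", x$name, "\n  G:", x$G$label, "\n  D:", x$D$label, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# serialization and tabulation

#' Serialize a crowding model to a small configuration record
#'
#' @param x a `crowding_pair`, or a list as returned by
#'   [crowding_from_config()].
#' @return A list `(kind, name/m/expression, D0)` suitable for JSON or
#'   key-value storage.
#' @export
crowding_config <- function(x) {
  stopifnot(inherits(x, "crowding_pair"))
  if (x$name %in% c("linear", "increasing", "decreasing")) {
    list(kind = "catalogue", name = x$name, D0 = x$D$D0)
  } else if (grepl("^powerlaw-m", x$name)) {
    list(kind = "powerlaw", m = as.numeric(sub("powerlaw-m", "", x$name)),
         D0 = x$D$D0)
  } else {
    list(kind = "expression", expression = attr(x, "expression"), D0 = x$D$D0)
  }
}

# restricted arithmetic grammar for user-supplied expressions in C
.allowed_calls <- c("+", "-", "*", "/", "^", "(", "exp", "log", "log1p", "sqrt")

check_expression_ast <- function(e) {
  if (is.numeric(e)) return(invisible(TRUE))
  if (is.symbol(e)) {
    if (identical(as.character(e), "C")) return(invisible(TRUE))
    stop("expression may only reference the variable C, found: ",
         as.character(e), call. = FALSE)
  }
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    if (!fn %in% .allowed_calls) {
      stop("function not allowed in crowding expression: ", fn, call. = FALSE)
    }
    for (i in seq_along(e)[-1]) check_expression_ast(e[[i]])
    return(invisible(TRUE))
  }
  stop("unsupported element in crowding expression", call. = FALSE)
}

#' Build a movement crowding function from an arithmetic expression in C
#'
#' The grammar is restricted to numbers, the variable `C`, the operators
#' `+ - * / ^` and the functions `exp`, `log`, `log1p`, `sqrt`.
#'
#' @param text expression string, e.g. `"(1 - C) * (1 + C/2)"`.
#' @return A [crowding_g] with a finite-difference derivative.
#' @export
crowding_from_expression <- function(text) {
  e <- tryCatch(parse(text = text)[[1]],
                error = function(err) stop("cannot parse crowding expression: ",
                                           conditionMessage(err), call. = FALSE))
  check_expression_ast(e)
  env_fns <- mget(.allowed_calls, envir = baseenv())
  val <- function(C) {
    ev <- list2env(c(list(C = C), env_fns), parent = emptyenv())
    eval(e, envir = ev)
  }
  G <- crowding_g(val, label = text)
  attr(G, "expression") <- text
  G
}

#' Rebuild a crowding model from its configuration record
#'
#' @param cfg list with fields `kind` (`"catalogue"`, `"powerlaw"` or
#'   `"expression"`), one of `name`/`m`/`expression`, and `D0`.
#' @return A `crowding_pair` (for expression models the diffusivity is
#'   obtained through [diffusivity_from_crowding()]).
#' @export
crowding_from_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$kind))
  D0 <- if (is.null(cfg$D0)) 1 else as.numeric(cfg$D0)
  switch(cfg$kind,
    catalogue = crowding_catalogue(cfg$name, D0 = D0),
    powerlaw = {
      m <- as.numeric(cfg$m)
      if (m %in% 1:3) {
        crowding_catalogue(sprintf("powerlaw-m%d", as.integer(m)), D0 = D0)
      } else {
        G <- powerlaw_crowding_g(m)
        D <- diffusivity_fn(function(C) D0 * C^m, D0 = D0,
                            label = sprintf("D0*C^%g", m))
        structure(list(G = G, D = D, H = flux_correction(D),
                       name = sprintf("powerlaw-m%g", m)),
                  class = "crowding_pair")
      }
    },
    expression = {
      G <- crowding_from_expression(cfg$expression)
      D <- diffusivity_from_crowding(G, D0 = D0)
      out <- structure(list(G = G, D = D, H = flux_correction(D),
                            name = "expression"),
                       class = "crowding_pair")
      attr(out, "expression") <- cfg$expression
      out
    },
    stop("unknown crowding config kind: ", cfg$kind, call. = FALSE))
}

#' Tabulate a crowding model over a density grid
#'
#' @param x a `crowding_pair` or a catalogue name.
#' @param file optional CSV path; when given the table is also written there.
#' @param D0 reference diffusivity (used when `x` is a name).
#' @param n number of grid points on `[0, 1]`.
#' @return A data frame with columns `C`, `G`, `dGdC`, `D`, `H`.
#' @export
tabulate_crowding <- function(x, file = NULL, D0 = 1, n = 101L) {
  if (is.character(x)) x <- crowding_catalogue(x, D0 = D0)
  stopifnot(inherits(x, "crowding_pair"))
  Cs <- seq(0, 1, length.out = n)
  tab <- data.frame(C = Cs,
                    G = x$G$value(Cs),
                    dGdC = x$G$derivative(Cs),
                    D = x$D$value(Cs),
                    H = x$H(Cs))
  if (!is.null(file)) utils::write.csv(tab, file, row.names = FALSE)
  tab
}
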