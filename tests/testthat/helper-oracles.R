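# Independent oracles used across the test files.

# Direct Gauss-series evaluation of the power-law inverse map
#   G(C) = (C^(m+2) - 2 C^(m+1) + C^m) 2F1(2, m+1; m+2; C) / (m+1)
# summed term by term (term_k = (k+1)(m+1)/(m+1+k) C^k), independent of the
# closed-form / Euler-transformed paths used by the package.
oracle_powerlaw_G <- function(m, C, terms = 20000L) {
  vapply(C, function(z) {
    if (z == 0) return(if (m > 0) 0 else 1)
    if (z == 1) return(0)
    k <- 0:terms
    s <- sum((k + 1) * (m + 1) / (m + 1 + k) * z^k)
    (z^(m + 2) - 2 * z^(m + 1) + z^m) * s / (m + 1)
  }, numeric(1))
}

# Brute-force lattice adjacency from Cartesian coordinates: two sites are
# nearest neighbours iff their periodic minimal-image distance equals delta.
oracle_hex_adjacency <- function(geom) {
  co <- hex_coordinates(geom)
  H <- geom$J * sqrt(3) / 2 * geom$delta
  lapply(seq_len(geom$n_sites), function(s) {
    dx <- abs(co$x - co$x[s]); dx <- pmin(dx, geom$L - dx)
    dy <- abs(co$y - co$y[s]); dy <- pmin(dy, H - dy)
    which(abs(sqrt(dx^2 + dy^2) - geom$delta) < 1e-9)
  })
}

# BFS shells on the oracle adjacency: all sites at graph distance 1..r of s.
oracle_template_sites <- function(adj, s, r) {
  dist <- rep(Inf, length(adj))
  dist[s] <- 0
  frontier <- s
  for (d in seq_len(r)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), which(is.finite(dist)))
    dist[frontier] <- d
  }
  sort(which(dist >= 1 & dist <= r))
}

# Independent line-crossing bookkeeping: which tally line (k + 3/4) * delta
# does a move from x1 to x2 cross, and in which direction?  Interval logic on
# the periodic domain, written without the engine's integer arithmetic.
oracle_crossing <- function(x1, x2, L, delta = 1) {
  dx <- x2 - x1
  if (dx > L / 2) dx <- dx - L
  if (dx < -L / 2) dx <- dx + L
  lines <- ((seq_len(round(L / delta)) - 1) + 0.75) * delta
  hit <- function(l) {
    if (dx > 0) ((l - x1) %% L) > 0 && ((l - x1) %% L) < dx
    else ((x1 - l) %% L) > 0 && ((x1 - l) %% L) < -dx
  }
  crossed <- which(vapply(lines, hit, logical(1)))
  if (!length(crossed)) return(NULL)
  data.frame(line = crossed, sign = sign(dx))
}

# Exact expected net crossing rate per movement sweep at every tally line,
# by enumerating the 2^6 neighbourhood configurations of every site under
# independent Bernoulli occupancies `probs` (one probability per site).
# Each agent is selected once per sweep in expectation.
oracle_expected_crossings <- function(geom, probs, G, M) {
  nb <- neighbor_table(geom, 1)
  co <- hex_coordinates(geom)
  flux <- numeric(geom$I)
  configs <- as.matrix(expand.grid(rep(list(0:1), 6)))
  for (s in seq_len(geom$n_sites)) {
    ns <- nb[s, ]
    pn <- probs[ns]
    for (cf in seq_len(nrow(configs))) {
      occv <- configs[cf, ]
      pcfg <- prod(ifelse(occv == 1, pn, 1 - pn)) * probs[s]
      if (pcfg == 0) next
      k <- sum(occv)
      nv <- 6 - k
      if (nv == 0) next
      p_each <- M * G$value(k / 6) / nv
      for (t in which(occv == 0)) {
        cr <- oracle_crossing(co$x[s], co$x[ns[t]], geom$L, geom$delta)
        if (!is.null(cr)) {
          flux[cr$line] <- flux[cr$line] + pcfg * p_each * cr$sign
        }
      }
    }
  }
  flux
}

# shared small helpers -------------------------------------------------------

zero_growth <- function() crowding_f(function(C) rep(0, length(C)),
                                     label = "no growth")

make_config <- function(geom, G, F_fn, M, P, init, V = 1, seed = 1,
                        t_end, record_times = NULL, ...) {
  simulation_config(rates = suppressWarnings(rate_constants(M, P)),
                    G = G, F_fn = F_fn, geometry = geom, init = init,
                    V = V, base_seed = seed, t_end = t_end,
                    record_times = record_times, ...)
}
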