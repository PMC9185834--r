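# Stochastic engine: sweep semantics, conservation, ensemble statistics and
# the empirical flux tally.

test_that("movement sweeps conserve the agent count and growth sweeps audit it", {
  geom <- hex_geometry(20, 20)
  set.seed(11)
  st <- init_uniform(geom, 0.4)
  cfg <- make_config(geom, crowding_catalogue("linear")$G,
                     strong_allee_growth(0.4), M = 1, P = 0.2,
                     init = st, t_end = 1)
  set.seed(1)
  cur <- st
  for (k in 1:20) {
    nxt <- movement_sweep(cur, cfg)
    expect_identical(nxt$Q, cur$Q)
    cur <- nxt
  }
  for (k in 1:20) {
    nxt <- growth_sweep(cur, cfg)
    a <- attr(nxt, "audit")
    expect_identical(nxt$Q, cur$Q + as.integer(a$births - a$deaths))
    cur <- nxt
  }
  expect_true(all(cur$occupancy %in% c(0L, 1L)))
  expect_identical(cur$Q, sum(cur$occupancy))
})

test_that("an isolated agent moves with probability M, uniformly over its six neighbours", {
  geom <- hex_geometry(9, 10)
  occ <- integer(geom$n_sites)
  centre <- crowdfate:::site_id(geom, 4L, 4L)
  occ[centre] <- 1L
  st <- hex_state(geom, occ)
  cfg <- make_config(geom, crowding_catalogue("linear")$G, zero_growth(),
                     M = 0.7, P = 0, init = st, t_end = 1)
  nb <- neighbor_table(geom, 1)
  set.seed(99)
  n_sweeps <- 4000
  moved <- 0
  dest_counts <- integer(6)
  for (k in seq_len(n_sweeps)) {
    out <- movement_sweep(st, cfg)
    if (attr(out, "audit")$moves == 1) {
      moved <- moved + 1
      dest <- which(out$occupancy == 1L)
      dest_counts[match(dest, nb[centre, ])] <-
        dest_counts[match(dest, nb[centre, ])] + 1L
    }
  }
  frac <- moved / n_sweeps
  se <- sqrt(0.7 * 0.3 / n_sweeps)
  expect_lt(abs(frac - 0.7), 4 * se)
  expect_gt(chisq.test(dest_counts)$p.value, 1e-3)
})

test_that("fully occupied and empty lattices are invariant states", {
  geom <- hex_geometry(10, 10)
  full <- hex_state(geom, rep(1L, geom$n_sites))
  cfg <- make_config(geom, crowding_catalogue("increasing")$G,
                     strong_allee_growth(0.4), M = 1, P = 0.1,
                     init = full, t_end = 1)
  set.seed(5)
  cur <- full
  for (k in 1:10) cur <- abm_step(cur, cfg)
  expect_identical(cur$occupancy, full$occupancy)
  empty <- hex_state(geom, integer(geom$n_sites))
  cur <- empty
  for (k in 1:5) cur <- abm_step(cur, cfg)
  expect_identical(cur$occupancy, empty$occupancy)
  # M = P = 0 is the identity on any state
  set.seed(6)
  st <- init_uniform(geom, 0.5)
  cfg0 <- make_config(geom, crowding_catalogue("linear")$G,
                      strong_allee_growth(0.4), M = 0, P = 0,
                      init = st, t_end = 1)
  expect_identical(abm_step(st, cfg0)$occupancy, st$occupancy)
})

test_that("isolated agents die at rate P when F(0) = -1", {
  # agents spaced farther apart than the growth template never interact
  geom <- hex_geometry(40, 20)
  occ <- integer(geom$n_sites)
  for (i in seq(0, 39, by = 10)) {
    for (j in seq(0, 19, by = 10)) {
      occ[crowdfate:::site_id(geom, as.integer(i), as.integer(j))] <- 1L
    }
  }
  st <- hex_state(geom, occ)
  Q0 <- st$Q
  P <- 0.02
  cfg <- make_config(geom, crowding_catalogue("linear")$G,
                     strong_allee_growth(0.4), M = 0, P = P,
                     init = st, t_end = 1)
  set.seed(21)
  reps <- 2000
  q_after <- numeric(reps)
  for (k in seq_len(reps)) q_after[k] <- growth_sweep(st, cfg)$Q
  expected <- Q0 * (1 - P)
  se <- sd(q_after) / sqrt(reps)
  # allow the O(P^2) with-replacement correction on top of 4 standard errors
  expect_lt(abs(mean(q_after) - expected), 4 * se + Q0 * P^2)
})

test_that("ensemble statistics are internally consistent and reproducible", {
  geom <- hex_geometry(30, 30)
  pair <- crowding_catalogue("increasing", D0 = 0.25)
  cfg <- make_config(geom, pair$G, strong_allee_growth(0.4),
                     M = 1, P = 0.006, init = init_strip(geom, 8),
                     V = 5, seed = 17, t_end = 50,
                     record_times = c(0, 25, 50))
  res1 <- simulate_ensemble(cfg)
  res2 <- simulate_ensemble(cfg)
  expect_identical(res1$column_density, res2$column_density)
  expect_identical(res1$Q, res2$Q)
  # densities lie in [0, 1] and the total density is the column mean
  expect_true(all(res1$column_density >= 0 & res1$column_density <= 1))
  expect_equal(res1$total_density$mean, rowMeans(res1$column_density),
               tolerance = 1e-12)
  # a different seed gives different realizations
  cfg2 <- make_config(geom, pair$G, strong_allee_growth(0.4),
                      M = 1, P = 0.006, init = init_strip(geom, 8),
                      V = 5, seed = 18, t_end = 50,
                      record_times = c(0, 25, 50))
  expect_false(identical(simulate_ensemble(cfg2)$column_density,
                         res1$column_density))
  # V = 1 with M = P = 0 keeps the initial strip indicator exactly
  cfg0 <- make_config(geom, pair$G, strong_allee_growth(0.4),
                      M = 0, P = 0, init = init_strip(geom, 8),
                      V = 1, seed = 1, t_end = 20)
  res0 <- simulate_ensemble(cfg0)
  expect_equal(res0$column_density[2, ],
               unname(column_density(init_strip(geom, 8))))
})

test_that("column dynamics are independent of the number of lattice rows", {
  pair <- crowding_catalogue("linear", D0 = 0.25)
  run <- function(J) {
    geom <- hex_geometry(60, J)
    cfg <- make_config(geom, pair$G, strong_allee_growth(0.4),
                       M = 1, P = 0.006, init = init_strip(geom, 10),
                       V = 30, seed = 31, t_end = 200)
    simulate_ensemble(cfg)
  }
  a <- run(60L)
  b <- run(120L)
  prof_a <- a$column_density[nrow(a$column_density), ]
  prof_b <- b$column_density[nrow(b$column_density), ]
  expect_lt(max(abs(prof_a - prof_b)), 0.08)
  expect_lt(abs(a$total_density$mean[2] - b$total_density$mean[2]), 0.02)
})

test_that("the expected movement flux matches the transition-probability enumeration", {
  # exact expectation over Bernoulli occupancies vs the continuum law
  # Jx = -D(C) dC/dx, on a gentle sinusoidal profile
  geom <- hex_geometry(40, 6)
  co <- hex_coordinates(geom)
  Cfun <- function(x) 0.5 + 0.2 * sin(2 * pi * x / geom$L)
  probs <- Cfun(co$x)
  M <- 1
  for (nm in c("linear", "increasing")) {
    pair <- crowding_catalogue(nm, D0 = M / 4)
    # expected net crossings per sweep over all rows -> column-density flux
    flux_counts <- oracle_expected_crossings(geom, probs, pair$G, M)
    jx <- flux_counts * geom$delta / geom$J
    xl <- ((0:(geom$I - 1)) + 0.75) * geom$delta
    dCdx <- 0.2 * (2 * pi / geom$L) * cos(2 * pi * xl / geom$L)
    jx_cont <- -pair$D$value(Cfun(xl)) * dCdx
    expect_lt(max(abs(jx - jx_cont)), 0.05 * max(abs(jx_cont)),
              label = paste("flux enumeration", nm))
  }
})

test_that("the engine's crossing tally agrees with the interval-logic oracle", {
  # single agent forced to move every step; accumulate its crossings and
  # compare with oracle bookkeeping replayed from the trajectory
  geom <- hex_geometry(12, 10)
  occ <- integer(geom$n_sites)
  occ[crowdfate:::site_id(geom, 3L, 2L)] <- 1L
  st <- hex_state(geom, occ)
  cfg <- make_config(geom, crowding_catalogue("linear")$G, zero_growth(),
                     M = 1, P = 0, init = st, V = 1, seed = 55, t_end = 400)
  res <- simulate_ensemble(cfg, flux_window = c(0, 400))
  co <- hex_coordinates(geom)
  # replay the same trajectory step by step
  set.seed(cfg$base_seed + 1)
  inputs <- crowdfate:::engine_inputs(cfg)
  cur <- st
  net <- numeric(geom$I)
  for (k in 1:400) {
    nxt <- hex_state(geom, crowdfate:::run_engine(cur, cfg, inputs, 1L,
                                                  integer(0))$final_occ)
    s_from <- which(cur$occupancy == 1L)
    s_to <- which(nxt$occupancy == 1L)
    if (s_from != s_to) {
      cr <- oracle_crossing(co$x[s_from], co$x[s_to], geom$L, geom$delta)
      if (!is.null(cr)) net[cr$line] <- net[cr$line] + cr$sign
    }
    cur <- nxt
  }
  measured_counts <- res$flux$Jx * 400 * geom$J / geom$delta
  expect_equal(measured_counts, net, tolerance = 1e-10)
})

test_that("uniform occupancy has zero net flux and G(K) overflow is caught", {
  geom <- hex_geometry(40, 40)
  pair <- crowding_catalogue("linear", D0 = 0.25)
  cfg <- make_config(geom, pair$G, zero_growth(), M = 1, P = 0,
                     init = function(g) init_uniform(g, 0.4),
                     V = 8, seed = 12, t_end = 150)
  fx <- measure_flux(cfg, window = c(0, 150))
  # domain-averaged flux: per-realization means are independent, lines are not
  jm <- rowMeans(attr(fx, "per_realization"))
  expect_lt(abs(mean(jm)), 4 * sd(jm) / sqrt(length(jm)))
  expect_true(all(abs(fx$Jx) < 5 * fx$se))
  # a G outside [0,1] must abort before any probability overflows
  bad <- suppressWarnings(crowding_g(function(C) 1.2 * (1 - C)))
  cfgb <- make_config(geom, bad, zero_growth(), M = 1, P = 0,
                      init = init_strip(geom, 10), t_end = 1)
  expect_error(simulate_ensemble(cfgb), "overflow")
})
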