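# Synthetic-data generators.

test_that("zero-noise killing curves reproduce the model exactly", {
  m <- triphasic_model()
  tt <- 0:6
  kc <- simulate_multiexp_samples(m, tt, noise_sd_log10 = 0, replicates = 3,
                                  seed = 1)
  # all replicates identical and equal to log10 f(t) to machine precision
  expect_equal(kc$summary$se_log10, rep(0, 7))
  expect_equal(kc$summary$mean_log10, log10(multiexp_eval(m, tt)),
               tolerance = 1e-14)
  expect_equal(kc$summary$mean_log10[1], log10(7.46e6 + 1.42e6 + 64.1),
               tolerance = 1e-14)
  expect_error(simulate_multiexp_samples(m, numeric(0), 0, 3, 1), "non-empty")
  expect_error(simulate_multiexp_samples(m, 0:2, -0.1, 3, 1), "non-negative")
})

test_that("killing-curve noise has the configured log10 scale", {
  m <- multiexp_model(1e6, 1)
  kc <- simulate_multiexp_samples(m, 1, noise_sd_log10 = 0.1,
                                  replicates = 1000, seed = 4)
  sd_obs <- sd(log10(kc$curve$density))
  expect_lt(abs(sd_obs - 0.1), 0.01)
  # deterministic given the seed
  kc2 <- simulate_multiexp_samples(m, 1, noise_sd_log10 = 0.1,
                                   replicates = 1000, seed = 4)
  expect_identical(kc$curve, kc2$curve)
})

test_that("limiting-dilution wells follow the Poisson emptiness probability", {
  # no viable cells: every well stays non-turbid
  p0 <- simulate_limiting_dilution(0, c(1e-3, 1e-6), 12, seed = 1)
  expect_equal(p0$non_turbid, p0$wells)
  # saturation: k = 0 essentially surely
  ps <- simulate_limiting_dilution(1e9, 1, 12, seed = 1)
  expect_equal(ps$non_turbid, 0L)
  # closed form: Nv = 6.93e6, d = 1e-6, y = 0.2 -> P(empty) = exp(-1.386) = 0.25
  big <- simulate_limiting_dilution(6.93e6, rep(1e-6, 1000), 10, seed = 2)
  frac <- sum(big$non_turbid) / sum(big$wells)
  p_true <- exp(-1e-6 * 0.2 * 6.93e6)
  expect_lt(abs(frac - p_true), 3 * sqrt(p_true * (1 - p_true) / 1e4))
  expect_error(simulate_limiting_dilution(-1, 1e-6), "true_density")
  expect_error(simulate_limiting_dilution(10, 2), "dilutions")
})

test_that("degenerate lineage config: all founders non-growing, no divisions", {
  cfg <- pop_sim_config(n_founders = 200, p_nongrowing = 1,
                        division_rate = 2.26, s_growing = 0,
                        s_nongrowing = 0.5, seed = 3)
  sim <- simulate_chamber_lineages(cfg)
  expect_true(all(sim$truth$true_state_at_exposure == "non_growing"))
  pre_div <- sim$table$fate == "division" & sim$table$end_h < cfg$t_pre
  expect_equal(sum(pre_div), 0)
})

test_that("persister fractions follow the state-dependent survival probabilities", {
  # s_growing = 0, s_nongrowing = 1: persister fraction = p_nongrowing
  cfg <- pop_sim_config(n_founders = 4000, p_nongrowing = 0.5,
                        s_growing = 0, s_nongrowing = 1, seed = 5)
  sim <- simulate_chamber_lineages(cfg)
  fr <- mean(sim$truth$true_persister)
  expect_lt(abs(fr - 0.5), 3 * sqrt(0.25 / 4000))
  # non-growing persisters all regrow: a division after exposure end
  t_off <- cfg$t_pre + cfg$t_exposure
  pers_founders <- sim$truth$founder_id[sim$truth$true_persister &
    sim$truth$true_state_at_exposure == "non_growing"]
  rows <- sim$table[sim$table$cell_id %in% pers_founders, ]
  expect_true(all(rows$fate == "division" & rows$end_h > t_off))
})

test_that("forward Eq-1 composition: persister frequency ~ s * Pn", {
  cfg <- pop_sim_config(n_founders = 20000, p_nongrowing = 0.61,
                        s_growing = 0, s_nongrowing = 0.084,
                        division_rate = 0, seed = 6)
  sim <- simulate_chamber_lineages(cfg)
  fr <- mean(sim$truth$true_persister)
  expect_lt(abs(fr - 0.61 * 0.084), 4 * sqrt(0.0512 * 0.949 / 20000))
})

test_that("with zero switching rates the exposure state equals the founder state", {
  cfg <- pop_sim_config(n_founders = 500, p_nongrowing = 0.4,
                        s_growing = 0.05, s_nongrowing = 0.1, seed = 7)
  sim <- simulate_chamber_lineages(cfg)
  # founder state is recoverable from the division record
  divided <- tapply(sim$table$fate == "division" &
                      sim$table$end_h < cfg$t_pre,
                    sim$table$chamber_id, any)
  founder_rows <- sim$table[is.na(sim$table$parent_id), ]
  inferred <- ifelse(divided[as.character(founder_rows$chamber_id)] |
                       founder_rows$area_end_um2 > founder_rows$area_birth_um2 * 1.01,
                     "growing", "non_growing")
  truth <- sim$truth$true_state_at_exposure[
    match(founder_rows$cell_id, sim$truth$founder_id)]
  expect_true(all(inferred == truth))
  # labels cover every founder
  expect_setequal(sim$truth$founder_id, founder_rows$cell_id)
})

test_that("the general (switching) simulator produces valid forests", {
  cfg <- pop_sim_config(n_founders = 150, p_nongrowing = 0.3,
                        switch_gn = 0.3, switch_ng = 0.2,
                        s_growing = 0.02, s_nongrowing = 0.2, seed = 8)
  sim <- simulate_chamber_lineages(cfg)
  expect_silent(validate_lineage_table(sim$table))
  expect_equal(nrow(sim$truth), 150)
  expect_true(all(sim$truth$true_state_at_exposure %in%
                    c("growing", "non_growing")))
  # persister founders always show a post-exposure regrowth division
  t_off <- cfg$t_pre + cfg$t_exposure
  for (fid in sim$truth$founder_id[sim$truth$true_persister]) {
    sub <- sim$table[sim$table$chamber_id ==
                       sim$table$chamber_id[sim$table$cell_id == fid], ]
    expect_true(any(sub$fate == "division" & sub$end_h > t_off))
  }
})

test_that("simulations are bit-reproducible given (config, seed)", {
  cfg <- pop_sim_config(n_founders = 100, p_nongrowing = 0.2, seed = 11)
  s1 <- simulate_chamber_lineages(cfg)
  s2 <- simulate_chamber_lineages(cfg)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth, s2$truth)
  cfg2 <- pop_sim_config(n_founders = 100, p_nongrowing = 0.2, seed = 12)
  s3 <- simulate_chamber_lineages(cfg2)
  expect_false(identical(s1$table, s3$table))
})

test_that("frame emission grows areas only before exposure", {
  cfg <- pop_sim_config(n_founders = 20, p_nongrowing = 0.5,
                        s_growing = 0, s_nongrowing = 0.3, seed = 14)
  sim <- simulate_chamber_lineages(cfg, frames = TRUE)
  expect_true(all(c("cell_id", "t_h", "area_um2") %in% names(sim$frames)))
  expect_true(all(sim$frames$area_um2 > 0))
  post <- sim$frames[sim$frames$t_h > cfg$t_pre, ]
  if (nrow(post)) {
    rng <- tapply(post$area_um2, post$cell_id, function(a) diff(range(a)))
    expect_true(all(rng < 1e-9))
  }
})

test_that("pop_sim_config validates its parameters", {
  expect_error(pop_sim_config(n_founders = 0), "n_founders")
  expect_error(pop_sim_config(p_nongrowing = 1.2), "probabilities")
  expect_error(pop_sim_config(division_rate = -1), "rates")
  expect_error(pop_sim_config(t_pre = -0.5), "durations")
})

test_that("simulated outlines match spherocylinder geometry", {
  # length = 4, width = 1: area 3 + pi/4, perimeter 6 + pi
  p <- simulate_cell_outline(4, 1, 400)
  expect_equal(attr(p, "area"), 3 + pi / 4)
  expect_equal(attr(p, "perimeter"), 6 + pi)
  m <- shape_metrics(p, check_simple = FALSE)
  expect_rel_equal(m$area, 3 + pi / 4, 1e-3)
  expect_rel_equal(m$perimeter, 6 + pi, 1e-3)

  # closed polygon, counter-clockwise (positive signed area)
  expect_equal(p[1, ], p[nrow(p), ])
  x <- p[-nrow(p), 1]; y <- p[-nrow(p), 2]
  signed <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  expect_gt(signed, 0)

  # circle limit: circularity -> 1 with vertex count
  circ <- vapply(c(16, 64, 256), function(nv)
    shape_metrics(simulate_cell_outline(1, 1, nv),
                  check_simple = FALSE)$circularity, numeric(1))
  expect_true(all(diff(circ) > 0))
  expect_gt(circ[3], 0.999)
  expect_error(simulate_cell_outline(1, 2), "length >= width")
  expect_error(simulate_cell_outline(4, 1, 4), "n_vertices")
})
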