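# Synthetic tunnel geometry, ensembles, sequences and gel simulation.

test_that("default tunnel reproduces the stated lumen dimensions", {
  tun <- make_tunnel(seed = 1)
  z <- seq(0, 100, by = 0.25)
  diam <- 2 * tun$radius_profile(z)
  expect_equal(min(diam), 10, tolerance = 1e-6)
  expect_equal(z[which.min(diam)], 30, tolerance = 0.5)
  expect_equal(max(diam), 20, tolerance = 1e-6)
})

test_that("wall atoms lie near the offset surface", {
  tun <- make_tunnel(seed = 4, jitter_sd = 0.2)
  a <- tun$atoms
  radial <- sqrt(a$x^2 + a$y^2)
  target <- tun$radius_profile(a$z) + 1.8
  # within a few jitter SDs of the surface (z-jitter feeds through r(z) too)
  expect_lt(max(abs(radial - target)), 1.2)
  expect_lt(mean(abs(radial - target)), 0.3)
})

test_that("tunnel generation is seed-deterministic and validates input", {
  t1 <- make_tunnel(seed = 7)
  t2 <- make_tunnel(seed = 7)
  expect_identical(t1$atoms, t2$atoms)
  t3 <- make_tunnel(seed = 8)
  expect_false(isTRUE(all.equal(t1$atoms$x, t3$atoms$x)))
  expect_error(make_tunnel(d_min = 30, d_max = 20), "non-physical")
  expect_error(make_tunnel(constriction_at = 150), "non-physical")
})

test_that("hydrophobic wall flags follow the configured fraction", {
  expect_false(any(make_tunnel(hydrophobic_fraction = 0, seed = 1)$atoms$hydrophobic))
  expect_true(all(make_tunnel(hydrophobic_fraction = 1, seed = 1)$atoms$hydrophobic))
  rings <- make_tunnel(hydrophobic_rings = TRUE, seed = 1)
  hz <- rings$atoms$z[rings$atoms$hydrophobic]
  expect_true(all(abs(hz - 28) < 3.5 | abs(hz - 32) < 3.5 | abs(hz - 85) < 3.5))
})

test_that("jitter_ensemble: zero noise is the identity, seeds reproduce", {
  conf <- build_conformer(make_test_sequences("tm", seed = 5), "helical")
  tun <- make_tunnel(seed = 1)
  still <- ensemble_spec(n_frames = 3, jitter_sd = 0, axial_range = c(0, 0),
                         tilt_sd_deg = 0, seed = 2)
  frames <- jitter_ensemble(conf, tun, still)
  base <- place_in_tunnel(conf)
  for (fr in frames) expect_equal(fr$x, base$x, tolerance = 1e-12)
  a <- jitter_ensemble(conf, tun, ensemble_spec(n_frames = 4, seed = 3))
  b <- jitter_ensemble(conf, tun, ensemble_spec(n_frames = 4, seed = 3))
  expect_identical(a, b)
})

test_that("an oversized conformer triggers a placement error", {
  conf <- build_conformer(make_test_sequences("tm", seed = 5), "helical")
  slim <- make_tunnel(d_min = 4, d_max = 6, seed = 1)
  expect_error(jitter_ensemble(conf, slim), "placement error")
})

test_that("extended frames protrude further toward the exit", {
  seq <- make_test_sequences("tm", seed = 5)
  tun <- make_tunnel(seed = 1)
  fh <- jitter_ensemble(build_conformer(seq, "helical"), tun,
                        ensemble_spec(n_frames = 5, seed = 4))
  fe <- jitter_ensemble(build_conformer(seq, "extended"), tun,
                        ensemble_spec(n_frames = 5, seed = 4))
  max_h <- vapply(fh, function(f) max(f$z), numeric(1))
  max_e <- vapply(fe, function(f) max(f$z), numeric(1))
  expect_true(all(max_e > max_h + 20))
  # the extended chain reaches the exit-pore region and out into solvent
  expect_gt(mean(max_e), tun$length)
  expect_true(all(max_e > tun$length - 4))
})

test_that("designed test sequences have the advertised structure", {
  tm <- make_test_sequences("tm", seed = 2)
  expect_true(all(hydrophobic_mask(tm)))
  expect_true(length(tm$residues) %in% 20:22)

  sol <- make_test_sequences("soluble", seed = 2)
  expect_lt(mean(hydrophobic_mask(sol)), 0.35)

  half <- make_test_sequences("half_tm", seed = 2)
  expect_equal(length(half$residues), length(tm$residues))
  expect_equal(max(hydrophobic_runs(half)$length), 11)

  mut <- make_test_sequences("mutant_pair", base = tm, replacement = "P")
  diffs <- which(mut$residues != tm$residues)
  expect_equal(diffs, c(11L, 12L))
  expect_identical(mut$residues[diffs], c("P", "P"))

  expect_error(make_test_sequences("mutant_pair", base = tm,
                                   replacement = "Q"), "replacement")
  expect_identical(make_test_sequences("tm", seed = 9)$residues,
                   make_test_sequences("tm", seed = 9)$residues)
})

test_that("simulate_gel follows the logistic law exactly at sigma = 0", {
  spec <- gel_sim_spec(d = 60:76, d50 = 68, sigma = 0, seed = 1)
  gel <- simulate_gel(spec)
  prof <- build_profile(gel)
  expect_equal(prof$summary$mean,
               glyc_law(prof$summary$d, 68, 1.2, 5, 95), tolerance = 1e-9)
  # midpoint and upper asymptote
  expect_equal(prof$summary$mean[prof$summary$d == 68], 50)
  far <- simulate_gel(gel_sim_spec(d = 200, d50 = 68, sigma = 0, seed = 1))
  expect_equal(build_profile(far, min_n = 1)$summary$mean, 95,
               tolerance = 1e-6)
})

test_that("extended-law lanes outglycosylate helical-law lanes at d = 67", {
  ext <- simulate_gel(gel_sim_spec(d50 = 64, seed = 31))
  hel <- simulate_gel(gel_sim_spec(d50 = 70, seed = 32))
  p_ext <- build_profile(ext)$summary
  p_hel <- build_profile(hel)$summary
  expect_gt(p_ext$mean[p_ext$d == 67], p_hel$mean[p_hel$d == 67] + 30)
})

test_that("replicate means converge to the generating law (LLN)", {
  spec <- gel_sim_spec(d = c(64, 68, 72), replicates = 1e4, d50 = 68,
                       sigma = 0.15, seed = 6)
  gel <- simulate_gel(spec)
  wide <- stats::reshape(as.data.frame(gel), direction = "wide",
                         idvar = c("construct", "d", "replicate"),
                         timevar = "band")
  # on the log band-ratio (logit) scale the noise is exactly zero-mean
  for (d0 in spec$d) {
    lr <- log(wide$intensity.glyc / wide$intensity.nonglyc)[wide$d == d0]
    g <- glyc_law(d0, 68, 1.2, 5, 95)
    se <- sd(lr) / sqrt(length(lr))
    expect_lt(abs(mean(lr) - log(g / (100 - g))), 3 * se)
  }
  # and the percent means land on the law at the symmetric midpoint
  prof <- build_profile(gel)
  mid <- prof$summary[prof$summary$d == 68, ]
  expect_lt(abs(mid$mean - 50), 3 * mid$sd / sqrt(mid$n))
})

test_that("substream seeds are deterministic and name-sensitive", {
  expect_identical(substream_seed(1, "tunnel"), substream_seed(1, "tunnel"))
  expect_false(substream_seed(1, "tunnel") == substream_seed(1, "frames"))
  expect_false(substream_seed(1, "tunnel") == substream_seed(2, "tunnel"))
  expect_true(substream_seed(123456789, "x") < 2^31)
})
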