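# Glycosylation-mapping analysis.

make_construct <- function(total_len, asn_pos) {
  res <- rep("G", total_len)
  res[asn_pos:(asn_pos + 2)] <- c("N", "S", "T")
  glyc_construct(paste(res, collapse = ""), asn_pos)
}

test_that("P-NST distance follows the exclusive-of-Asn convention", {
  expect_equal(pnst_distance(make_construct(100, 33)), 67)
  expect_equal(pnst_distance(make_construct(100, 27)), 73)
  # Asn at the final possible position of an intact sequon
  c0 <- glyc_construct("AANST", 3, truncation_length = 3)
  expect_equal(pnst_distance(c0), 0)
  expect_error(glyc_construct("AAAAA", 2), "N-S-T")
  expect_error(glyc_construct("AANST", 3, truncation_length = 2),
               "removes the acceptor")
})

test_that("percent_glyc is correct, scale invariant and guarded", {
  expect_equal(percent_glyc(160, 840), 16)
  expect_equal(percent_glyc(0, 10), 0)
  withr::local_seed(5)
  for (k in 1:20) {
    a <- runif(1, 1, 500); b <- runif(1, 1, 500); s <- runif(1, 0.01, 100)
    expect_equal(percent_glyc(a, b), percent_glyc(s * a, s * b),
                 tolerance = 1e-12)
  }
  expect_error(percent_glyc(0, 0), "zero intensity")
  expect_error(percent_glyc(-1, 5), "negative")
})

test_that("build_profile summarizes replicates with sample SD", {
  gel <- data.frame(construct = "x", d = 67,
                    replicate = rep(1:3, 2),
                    band = rep(c("glyc", "nonglyc"), each = 3),
                    intensity = c(10, 20, 30, 90, 80, 70))
  prof <- build_profile(gel)
  expect_equal(prof$summary$mean, 20)
  expect_equal(prof$summary$sd, 10)
  expect_equal(prof$summary$n, 3L)

  single <- gel[gel$replicate == 1, ]
  expect_warning(p1 <- build_profile(single), "fewer than 3")
  expect_equal(p1$summary$mean, 10)
  expect_true(is.na(p1$summary$sd))
  expect_error(build_profile(gel[0, ]), "empty")
})

test_that("fit_sigmoid recovers noiseless parameters almost exactly", {
  for (d50 in c(64, 70)) {
    gel <- simulate_gel(gel_sim_spec(d50 = d50, sigma = 0, seed = 1))
    fit <- fit_sigmoid(build_profile(gel))
    expect_true(fit$converged)
    expect_equal(fit$d50, d50, tolerance = 0.01 / d50)
    expect_equal(fit$slope, 1.2, tolerance = 0.01)
    expect_equal(fit$g_max, 95, tolerance = 0.01)
  }
})

test_that("flat and undersized profiles are flagged, not fitted", {
  flat <- data.frame(d = 60:70, mean = rep(50, 11))
  fit <- fit_sigmoid(flat)
  expect_false(fit$converged)
  expect_match(fit$reason, "non-identifiable")
  expect_error(fit_sigmoid(data.frame(d = 1:3, mean = c(1, 50, 99))),
               ">= 4 distinct")
})

test_that("critical_stat separates compact from extended profiles", {
  hel <- build_profile(simulate_gel(gel_sim_spec(d50 = 70, seed = 41)))
  ext <- build_profile(simulate_gel(gel_sim_spec(d50 = 64, seed = 42)))
  expect_gt(critical_stat(hel), 50)
  expect_lt(critical_stat(ext), 15)
  even <- list(summary = data.frame(d = c(67, 73), mean = c(80, 80), sd = 0,
                                    n = 3))
  class(even) <- "GlycProfile"
  expect_equal(critical_stat(even), 0)
  expect_error(critical_stat(list()), "input error")
})

test_that("infer_folded implements the rise-conversion closed form", {
  expect_equal(infer_folded(0), 0)
  expect_equal(infer_folded(6), 3.4 * 6 / 1.9, tolerance = 1e-12) # 10.74
  expect_equal(infer_folded(1, rise_ext = 3, rise_helix = 1.5), 2)
  expect_warning(n <- infer_folded(-2), "negative")
  expect_equal(n, 0)
  # linearity in the shift
  expect_equal(infer_folded(8), 2 * infer_folded(4), tolerance = 1e-12)
  # divergence as the two rises approach each other
  expect_gt(infer_folded(1, 3.4, 3.3), 30)
})

test_that("helix_span_residues matches the membrane-span arithmetic", {
  expect_equal(helix_span_residues(30, 1.5)$raw, 20)
  expect_equal(helix_span_residues(30, 3.4)$raw, 30 / 3.4) # ~8.8 extended
  expect_equal(helix_span_residues(0, 1.5)$raw, 0)
  expect_equal(helix_span_residues(30, 1.5)$residues, 20)
})

test_that("compare_conditions runs a Welch test with stars", {
  expect_equal(compare_conditions(c(16, 16, 16, 16), c(16, 16, 16, 16))$p_value, 1)
  withr::local_seed(8)
  a <- 16 + rnorm(4, 0, 0.5)
  b <- 40 + rnorm(4, 0, 0.5)
  res <- compare_conditions(a, b)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$stars, "***")
  expect_equal(res$p_value, compare_conditions(b, a)$p_value)
  expect_error(compare_conditions(c(1, 2), c(3, 4, 5)), ">= 3 replicates")
})

test_that("gel_mass_model adds the per-glycan shift", {
  expect_equal(gel_mass_model(50, 1) - gel_mass_model(50, 0), 2.5)
  expect_equal(gel_mass_model(50, 2) - gel_mass_model(50, 0), 5)
  expect_equal(gel_mass_model(50, 0), 50)
  expect_error(gel_mass_model(50, 3))
})

test_that("call_compaction classifies the two canonical laws", {
  hel <- build_profile(simulate_gel(gel_sim_spec(d50 = 70, seed = 51)))
  ext <- build_profile(simulate_gel(gel_sim_spec(d50 = 64, seed = 52)))
  call_h <- call_compaction(fit_sigmoid(hel), hel)
  call_e <- call_compaction(fit_sigmoid(ext), ext)
  expect_equal(call_h$state, "compact")
  expect_equal(call_e$state, "extended")
  expect_gt(call_h$n_folded, 8)
  expect_equal(call_e$n_folded, 0, tolerance = 3)
})
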