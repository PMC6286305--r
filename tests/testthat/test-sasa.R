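# Shrake-Rupley SASA engine and burial statistics.

test_that("isolated-sphere SASA matches the closed form within 1%", {
  for (r in c(1.2, 1.7, 2.4)) {
    s <- sphere_set(matrix(0, 1, 3), r)
    expect_equal(sasa(s)$total, 4 * pi * (r + 1.4)^2, tolerance = 0.01)
  }
})

test_that("two-sphere SASA matches the analytic cap oracle within 1%", {
  cases <- expand.grid(r1 = c(1.5, 1.7), r2 = c(1.2, 2.0),
                       d = c(2.0, 3.0, 4.5))
  for (k in seq_len(nrow(cases))) {
    r1 <- cases$r1[k]; r2 <- cases$r2[k]; d <- cases$d[k]
    s <- sphere_set(rbind(c(0, 0, 0), c(d, 0, 0)), c(r1, r2))
    expect_equal(sasa(s)$total, two_sphere_oracle(r1, r2, d, 1.4),
                 tolerance = 0.01)
  }
})

test_that("atoms beyond the occlusion cutoff do not interact", {
  s <- sphere_set(rbind(c(0, 0, 0), c(10, 0, 0)), c(1.7, 1.5))
  expect_equal(sasa(s)$total,
               4 * pi * (1.7 + 1.4)^2 + 4 * pi * (1.5 + 1.4)^2,
               tolerance = 1e-9)
})

test_that("quadrature error decreases as n_points doubles", {
  s <- sphere_set(rbind(c(0, 0, 0), c(2.5, 0, 0)), c(1.7, 1.5))
  truth <- two_sphere_oracle(1.7, 1.5, 2.5, 1.4)
  errs <- vapply(c(120, 240, 480, 960, 1920), function(n) {
    abs(sasa(s, n_points = n)$total - truth)
  }, numeric(1))
  # monotone on average: each error below the mean of the coarser ones
  expect_lt(errs[5], mean(errs[1:2]))
  expect_lt(errs[4], errs[1])
})

test_that("sasa validates inputs and handles empty selections", {
  s <- sphere_set(matrix(0, 1, 3), 1.7)
  expect_error(sasa(s, probe = -1), "probe")
  expect_error(sasa(s, n_points = 16), "n_points")
  empty <- sasa(s, selection = logical(1))
  expect_equal(empty$total, 0)
})

test_that("per-atom areas are bounded and totals are consistent", {
  withr::local_seed(11)
  xyz <- matrix(rnorm(30, sd = 3), ncol = 3)
  r <- runif(10, 1.2, 2.2)
  res <- sasa(sphere_set(xyz, r, residue = rep(1:5, each = 2)))
  expect_true(all(res$per_atom$area >= 0))
  expect_true(all(res$per_atom$area <= 4 * pi * (r + 1.4)^2 + 1e-9))
  expect_equal(sum(res$per_atom$area), res$total, tolerance = 1e-6)
  expect_equal(sum(res$per_residue$area), res$total, tolerance = 1e-6)
})

test_that("totals are translation invariant and rotation stable", {
  withr::local_seed(3)
  xyz <- matrix(rnorm(24, sd = 2.5), ncol = 3)
  ss <- sphere_set(xyz, runif(8, 1.3, 2.0))
  base <- sasa(ss)$total
  expect_equal(sasa(transform_sphere_set(ss, t = c(50, -20, 13)))$total,
               base, tolerance = 1e-9)
  # the lattice is fixed in the atom frame: rotation stable only to ~0.5%
  for (k in 1:3) {
    rot <- sasa(transform_sphere_set(ss, R = random_rotation()))$total
    expect_equal(rot, base, tolerance = 5e-3)
  }
})

test_that("delta_sasa is zero without effective context and never positive", {
  conf <- build_conformer(poly_peptide("L", 8), "helical")
  pep <- as_sphere_set(conf)
  none <- sphere_set(matrix(c(500, 500, 500), 1, 3), 1.8, owner = "context")
  expect_equal(delta_sasa(pep, none)$delta, 0, tolerance = 1e-12)
  # seeded random context placements: burial is never positive
  withr::local_seed(21)
  for (k in 1:20) {
    ctx <- sphere_set(matrix(rnorm(15, sd = 6), ncol = 3), 1.8,
                      owner = "context")
    expect_lte(delta_sasa(pep, ctx, n_points = 240)$delta, 1e-9)
  }
})

test_that("delta_sasa rejects selections touching context atoms", {
  pep <- as_sphere_set(build_conformer(poly_peptide("L", 4), "helical"))
  ctx <- sphere_set(matrix(0, 2, 3) + 30, 1.8, owner = "context")
  expect_error(delta_sasa(pep, ctx, selection = seq_len(nrow(pep) + 1)),
               "peptide atoms only")
})

test_that("a narrower tunnel buries at least as much surface", {
  conf <- build_conformer(make_test_sequences("tm", seed = 5), "helical")
  narrow <- make_tunnel(d_min = 10, d_max = 14, seed = 2)
  wide <- make_tunnel(d_min = 16, d_max = 20, seed = 2)
  pep <- place_in_tunnel(conf)
  d_narrow <- delta_sasa(pep, narrow, n_points = 240)$delta
  d_wide <- delta_sasa(pep, wide, n_points = 240)$delta
  expect_lte(d_narrow, d_wide)
})

test_that("dd_sasa is antisymmetric and zero for identical ensembles", {
  conf <- build_conformer(make_test_sequences("tm", seed = 5), "helical")
  tun <- make_tunnel(seed = 2)
  frames <- jitter_ensemble(conf, tun, ensemble_spec(n_frames = 3, seed = 9))
  sel <- burial_selection(conf)
  same <- dd_sasa(frames, frames, tun, sel, sel, n_points = 120)
  expect_equal(same$ddsasa, 0, tolerance = 1e-12)
  other <- jitter_ensemble(conf, tun, ensemble_spec(n_frames = 3, seed = 10))
  ab <- dd_sasa(frames, other, tun, sel, sel, n_points = 120)
  ba <- dd_sasa(other, frames, tun, sel, sel, n_points = 120)
  expect_equal(ab$ddsasa, -ba$ddsasa, tolerance = 1e-9)
  # window = 1 with equal counts: difference of means = mean of differences
  full <- dd_sasa(frames, other, tun, sel, sel, n_points = 120, window = 1)
  expect_equal(full$ddsasa,
               mean(full$delta_helical - full$delta_extended),
               tolerance = 1e-9)
})

test_that("burial_energy converts area linearly", {
  expect_equal(burial_energy(-100)$dG, -1.5)
  expect_equal(burial_energy(0)$dG, 0)
  expect_equal(burial_energy(-50, coefficient = 0.030)$dG, -1.5)
  dsr <- structure(list(delta = -200), class = "DeltaSASAResult")
  expect_equal(burial_energy(dsr)$dG, -3)
  expect_error(burial_energy(-10, coefficient = -1))
})

test_that("occluder attribution splits burial by context class", {
  conf <- build_conformer(poly_peptide("L", 6), "helical")
  pep <- as_sphere_set(conf)
  # all-hydrophobic context: polar attribution must vanish
  withr::local_seed(13)
  ctx_h <- sphere_set(matrix(rnorm(9, sd = 5), ncol = 3), 1.8,
                      owner = "context", hydrophobic = TRUE)
  att <- occluder_attribution(pep, ctx_h, n_points = 240)
  expect_equal(att$polar, 0)
  # empty context: everything zero
  ctx_0 <- sphere_set(matrix(0, 0, 3), numeric(0), owner = "context")
  att0 <- occluder_attribution(pep, ctx_0, n_points = 240)
  expect_equal(att0$hydrophobic + att0$polar, 0)
})

test_that("attribution class totals match a brute-force recount and |dSASA|", {
  withr::local_seed(17)
  conf <- build_conformer(poly_peptide("V", 4), "helical")
  pep <- as_sphere_set(conf)
  ctx <- sphere_set(matrix(rnorm(12, sd = 4), ncol = 3), 1.8,
                    owner = "context",
                    hydrophobic = c(TRUE, FALSE, TRUE, FALSE))
  sel <- which(pep$hydrophobic)
  att <- occluder_attribution(pep, ctx, selection = sel, n_points = 120)
  oracle <- attribution_oracle(pep, ctx, sel, probe = 1.4, n_points = 120)
  expect_equal(att$hydrophobic, oracle$hydrophobic, tolerance = 1e-9)
  expect_equal(att$polar, oracle$polar, tolerance = 1e-9)
  ds <- delta_sasa(pep, ctx, selection = sel, n_points = 120)
  expect_equal(att$hydrophobic + att$polar, abs(ds$delta), tolerance = 1e-6)
})
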