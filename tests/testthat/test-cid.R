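fake_invariants <- function(beta2, betaG2, betaA2, wavelength_nm = 532) {
  structure(
    list(beta2 = beta2, betaG2 = betaG2, betaA2 = betaA2,
         alpha_iso = beta2, omega = wavelength_to_omega(wavelength_nm),
         wavelength_nm = wavelength_nm, label = "manual"),
    class = "rayoa_invariants"
  )
}

test_that("the CID formula satisfies its algebraic identities exactly", {
  c_au <- rayoa_constants$c_au
  # magnetic-dipole term alone: 24*(c/2)/(12*c) = 1
  expect_identical(delta_scp90(fake_invariants(1, c_au / 2, 0))$delta, 1)
  # quadrupole term alone: -8*(3c/2)/(12*c) = -1
  expect_identical(delta_scp90(fake_invariants(1, 0, 1.5 * c_au))$delta, -1)
})

test_that("an isotropic scatterer has no depolarized CID", {
  expect_error(delta_scp90(fake_invariants(0, 1, 1)),
               class = "rayoa_degenerate_molecule")
  expect_error(delta_scp90(make_tensor_set(1, chirality = "isotropic")),
               class = "rayoa_degenerate_molecule")
})

test_that("enantiomers give equal magnitudes and opposite signs", {
  for (s in 1:10) {
    pair <- make_enantiomer_pair(seed = s)
    d1 <- delta_scp90(pair$plus)$delta
    d2 <- delta_scp90(pair$minus)$delta
    expect_lt(rel_diff(d2, -d1), 1e-12)
    expect_lt(rel_diff(beta2(pair$plus), beta2(pair$minus)), 1e-12)
  }
})

test_that("the CID is invariant under proper rotations of the molecule", {
  set.seed(99)
  t0 <- make_tensor_set(seed = 12)
  d0 <- delta_scp90(t0)$delta
  for (rep in 1:100) {
    expect_lt(rel_diff(delta_scp90(transform_tensors(t0, random_rotation()))$delta,
                       d0), 1e-10)
  }
})

test_that("the CID scales linearly in (G', A) and inversely in alpha", {
  set.seed(31)
  t0 <- make_tensor_set(seed = 14)
  d0 <- delta_scp90(t0)$delta
  for (s in c(0.5, 2, 7)) {
    tg <- t0
    tg$gprime <- t0$gprime * s
    tg$aquad <- t0$aquad * s
    expect_lt(rel_diff(delta_scp90(tg)$delta, s * d0), 1e-12)
    ta <- t0
    ta$alpha <- t0$alpha * s
    expect_lt(rel_diff(delta_scp90(ta)$delta, d0 / s), 1e-12)
  }
})

test_that("mirror-symmetric molecules scatter with zero CID", {
  for (s in 1:8) {
    t0 <- make_tensor_set(seed = s, chirality = "achiral-mirror")
    expect_lt(abs(delta_scp90(t0)$delta), 1e-10)
  }
})

test_that("wavelength rescaling follows the 1/lambda law", {
  p <- delta_scp90(make_tensor_set(seed = 2, target_delta = 3.6e-4))
  # identity at the same wavelength
  expect_identical(rescale_wavelength(p, 532)$delta, p$delta)
  # doubling the wavelength exactly halves the CID
  p2 <- rescale_wavelength(p, 1064)
  expect_identical(p2$delta, p$delta / 2)
  expect_identical(p2$wavelength_nm, 1064)
  expect_match(p2$method_label, "rescaled from 532")
  # round trip through 365 nm is the identity to floating precision
  p3 <- rescale_wavelength(rescale_wavelength(p, 365), 532)
  expect_lt(rel_diff(p3$delta, p$delta), 1e-15)
  # extrapolating beyond a factor of 2 raises the far-off-resonance caution
  expect_message(rescale_wavelength(p, 1200), "factor of 2")
  expect_error(rescale_wavelength(p, -5), class = "rayoa_invalid_wavelength")
})

test_that("prediction ensembles summarize min, mean and max", {
  one <- delta_scp90(make_tensor_set(seed = 5), method_label = "m1")
  e1 <- aggregate_predictions(one)
  expect_identical(e1$summary$delta_min, one$delta)
  expect_identical(e1$summary$delta_max, one$delta)
  expect_identical(e1$summary$delta_mean, one$delta)

  two <- one
  two$delta <- 3.84e-4
  two$method_label <- "m2"
  one$delta <- 3.56e-4
  e2 <- aggregate_predictions(dplyr::bind_rows(one, two))
  expect_equal(e2$summary$delta_mean, 3.70e-4)

  set.seed(6)
  six <- dplyr::bind_rows(lapply(1:6, function(s)
    delta_scp90(make_tensor_set(seed = s), method_label = paste0("m", s))))
  e6 <- aggregate_predictions(six)
  expect_lt(rel_diff(e6$summary$delta_mean, sum(six$delta) / 6), 1e-15)
  expect_lte(e6$summary$delta_min, e6$summary$delta_mean)
  expect_lte(e6$summary$delta_mean, e6$summary$delta_max)
  expect_identical(tidy(e6), e6$predictions)
  expect_identical(glance(e6), e6$summary)
})

test_that("ensembles refuse mixed wavelengths or geometries", {
  a <- delta_scp90(make_tensor_set(seed = 1))
  b <- delta_scp90(make_tensor_set(seed = 2, wavelength_nm = 633))
  expect_error(aggregate_predictions(dplyr::bind_rows(a, b)),
               class = "rayoa_mixed_ensemble")
  b2 <- delta_scp90(make_tensor_set(seed = 2))
  b2$geometry <- "other"
  expect_error(aggregate_predictions(dplyr::bind_rows(a, b2)),
               class = "rayoa_mixed_ensemble")
  expect_error(aggregate_predictions(a[0, ]),
               class = "rayoa_invalid_prediction")
})

test_that("ensemble and measurement plots build without error", {
  six <- dplyr::bind_rows(lapply(1:4, function(s)
    delta_scp90(make_tensor_set(seed = s), method_label = paste0("m", s))))
  p1 <- autoplot(aggregate_predictions(six))
  expect_s3_class(p1, "ggplot")
  cfg <- instrument_config(exposure_h = 1, count_rate_per_s = 1e6, seed = 2)
  p2 <- autoplot(simulate_scp(3.6e-4, cfg, n_rep = 100), true_delta = 3.6e-4)
  expect_s3_class(p2, "ggplot")
})
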