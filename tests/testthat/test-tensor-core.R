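test_that("constructor enforces the index symmetries by projection", {
  al <- diag(c(3, 2, 1))
  al[1, 2] <- 0.5
  al[2, 1] <- 0.5
  gp <- matrix(seq_len(9) / 10, 3)
  aq <- array(rnorm(27), c(3, 3, 3))

  expect_warning(
    t1 <- tensor_set(al, gp, aq, 532),
    "quadrupole-pair"
  )
  # projected A is symmetric and traceless in the quadrupole pair
  expect_equal(t1$aquad, aperm(t1$aquad, c(1, 3, 2)))
  expect_equal(t1$aquad[, 1, 1] + t1$aquad[, 2, 2] + t1$aquad[, 3, 3],
               rep(0, 3), tolerance = 1e-14)

  al_bad <- al
  al_bad[1, 3] <- 0.2   # asymmetric beyond tolerance
  expect_warning(
    t2 <- tensor_set(al_bad, gp, t1$aquad, 532),
    "asymmetric"
  )
  expect_equal(t2$alpha, (al_bad + t(al_bad)) / 2)

  expect_error(tensor_set(matrix(1, 2, 2), gp, t1$aquad, 532),
               class = "rayoa_invalid_tensor")
  expect_error(tensor_set(al, gp, t1$aquad, -5),
               class = "rayoa_invalid_wavelength")
})

test_that("omega follows the fixed unit conversion from the wavelength", {
  # lambda = 2*pi*c/omega in a.u.: invert and compare round trip
  for (wl in c(365, 532, 1064)) {
    om <- wavelength_to_omega(wl)
    lambda_au <- 2 * pi * rayoa_constants$c_au / om
    expect_equal(lambda_au / rayoa_constants$bohr_per_nm, wl,
                 tolerance = 1e-12)
  }
  expect_gt(wavelength_to_omega(532), wavelength_to_omega(1064))
})

test_that("transform_tensors matches the componentwise brute-force rule", {
  set.seed(101)
  for (rep in 1:20) {
    t0 <- random_raw_tensor_set()
    g <- random_rotation()
    if (rep %% 2 == 0) g <- spatial_transform(-g$matrix)  # improper branch
    got <- transform_tensors(t0, g)
    want <- transform_oracle(t0, g$matrix)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-12)
    expect_equal(got$gprime, want$gprime, tolerance = 1e-12)
    expect_equal(got$aquad, want$aquad, tolerance = 1e-12)
    expect_identical(got$omega, t0$omega)
    expect_identical(got$wavelength_nm, t0$wavelength_nm)
  }
})

test_that("identity and inversion transforms act as the theory demands", {
  set.seed(7)
  t0 <- random_raw_tensor_set()
  expect_equal(transform_tensors(t0, diag(3)), t0, tolerance = 1e-15)

  inv <- transform_tensors(t0, spatial_transform(-diag(3)))
  expect_equal(inv$alpha, t0$alpha)          # polar even rank: unchanged
  expect_equal(inv$gprime, -t0$gprime)       # axial rank 2: flips
  expect_equal(inv$aquad, -t0$aquad)         # polar odd rank: flips
})

test_that("transforms form a group: inverse recovery and closure", {
  set.seed(11)
  t0 <- random_raw_tensor_set()
  for (rep in 1:10) {
    g1 <- random_rotation()
    g2 <- random_rotation()
    back <- transform_tensors(transform_tensors(t0, g1),
                              spatial_transform(t(g1$matrix)))
    expect_equal(back$alpha, t0$alpha, tolerance = 1e-12)
    expect_equal(back$gprime, t0$gprime, tolerance = 1e-12)
    expect_equal(back$aquad, t0$aquad, tolerance = 1e-12)

    seq_ <- transform_tensors(transform_tensors(t0, g1), g2)
    prod_ <- transform_tensors(t0, spatial_transform(g2$matrix %*% g1$matrix))
    expect_equal(seq_$alpha, prod_$alpha, tolerance = 1e-12)
    expect_equal(seq_$gprime, prod_$gprime, tolerance = 1e-12)
    expect_equal(seq_$aquad, prod_$aquad, tolerance = 1e-12)
  }
})

test_that("non-orthogonal matrices are rejected as transforms", {
  expect_error(spatial_transform(matrix(rnorm(9, sd = 2), 3)),
               class = "rayoa_invalid_transform")
  expect_error(transform_tensors(make_tensor_set(1), diag(3) * 2),
               class = "rayoa_invalid_transform")
})

test_that("origin shifts leave alpha alone and preserve A's symmetries", {
  set.seed(21)
  t0 <- random_raw_tensor_set()
  d <- rnorm(3)
  ts <- shift_origin(t0, d)
  expect_identical(ts$alpha, t0$alpha)
  expect_equal(ts$aquad, aperm(ts$aquad, c(1, 3, 2)), tolerance = 1e-13)
  expect_equal(ts$aquad[, 1, 1] + ts$aquad[, 2, 2] + ts$aquad[, 3, 3],
               rep(0, 3), tolerance = 1e-12)
  # zero displacement is the identity
  expect_equal(shift_origin(t0, c(0, 0, 0)), t0, tolerance = 1e-15)
})

test_that("origin shift demands a symmetric polarizability", {
  t0 <- make_tensor_set(seed = 4)
  t0$alpha[1, 2] <- t0$alpha[1, 2] + 0.3   # deliberately asymmetrized
  expect_error(shift_origin(t0, c(1, 0, 0)),
               class = "rayoa_asymmetric_alpha")
})

test_that("tensor JSON round trip is bit-faithful and honours gprime_sign", {
  t0 <- make_tensor_set(seed = 9, target_delta = 3.6e-4)
  f <- withr::local_tempfile(fileext = ".json")
  write_tensor_set(t0, f)
  t1 <- read_tensor_set(f)
  expect_identical(t1$alpha, t0$alpha)
  expect_identical(t1$gprime, t0$gprime)
  expect_identical(t1$aquad, t0$aquad)
  expect_identical(t1$wavelength_nm, t0$wavelength_nm)
  expect_identical(t1$label, t0$label)

  t2 <- read_tensor_set(f, gprime_sign = -1)
  expect_identical(t2$gprime, -t0$gprime)
  expect_equal(delta_scp90(t2)$delta,
               -delta_scp90(t0)$delta + 2 *
                 (-8 * beta_a2(t0)) / (12 * beta2(t0) * rayoa_constants$c_au),
               tolerance = 1e-12)

  # malformed files are refused
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  doc$units <- "SI"
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_tensor_set(f2), class = "rayoa_invalid_tensor_file")
})
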