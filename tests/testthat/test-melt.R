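test_that("simulated melt curves follow the protocol grid and seed", {
  mc <- simulate_melt_curve(t_dissoc = 50, amplitude = 500, baseline = 50,
                            width = 2, noise_sd = 0)
  expect_equal(mc$temperature, seq(20, 95, by = 1.5))
  # noiseless curve sits exactly on the logistic
  expect_equal(mc$fluorescence,
               50 + 500 / (1 + exp(-(mc$temperature - 50) / 2)))

  a <- simulate_melt_curve(noise_sd = 10, seed = 7)
  b <- simulate_melt_curve(noise_sd = 10, seed = 7)
  c <- simulate_melt_curve(noise_sd = 10, seed = 8)
  expect_identical(a$fluorescence, b$fluorescence)
  expect_false(identical(a$fluorescence, c$fluorescence))

  flat <- simulate_melt_curve(amplitude = 0, baseline = 77, noise_sd = 0)
  expect_equal(unique(flat$fluorescence), 77)
  expect_error(simulate_melt_curve(width = 0), "width")
  expect_error(simulate_melt_curve(noise_sd = -1), "noise_sd")
})

test_that("melt-curve containers validate their series", {
  expect_error(melt_curve(1:10, 1:9), "differ in length")
  expect_error(melt_curve(c(1:4, 4), 1:5), "at least 8")
  expect_error(melt_curve(c(1:7, 7), rep(0, 8)), "strictly increasing")
  f <- tempfile(fileext = ".tsv")
  writeLines(c("temperature\tsignal",
               paste(seq(20, 50, 2), seq(100, 400, 20), sep = "\t")), f)
  mc <- read_melt_curve(f)
  expect_equal(mc$temperature, seq(20, 50, 2))
})

test_that("noiseless curves are recovered to numerical precision", {
  for (true in list(c(50, 2), c(42.3, 1.2), c(61.7, 3.5))) {
    mc <- simulate_melt_curve(t_dissoc = true[1], amplitude = 800,
                              baseline = 120, width = true[2], noise_sd = 0)
    fit <- fit_melt_curve(mc)
    expect_true(fit$converged)
    expect_equal(fit$t_dissoc, true[1], tolerance = 1e-6)
    expect_equal(fit$width, true[2], tolerance = 1e-6)
    expect_equal(fit$amplitude, 800, tolerance = 1e-6)
    expect_equal(fit$baseline, 120, tolerance = 1e-6)
  }
})

test_that("a flat curve is flagged as not converged", {
  flat <- simulate_melt_curve(amplitude = 0, baseline = 100, noise_sd = 0)
  expect_false(fit_melt_curve(flat)$converged)
  noisy_flat <- simulate_melt_curve(amplitude = 0, baseline = 100,
                                    noise_sd = 5, seed = 3)
  expect_false(fit_melt_curve(noisy_flat)$converged)
})

test_that("midpoint recovery stays within 0.1 degrees at 1% noise", {
  set.seed(1)
  errs <- vapply(1:100, function(i) {
    td <- runif(1, 40, 60)
    mc <- simulate_melt_curve(t_dissoc = td, amplitude = 1000,
                              baseline = 100, width = 2,
                              noise_sd = 10, seed = i)
    fit_melt_curve(mc)$t_dissoc - td
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.1)
})

test_that("relative flavin content is the amplitude ratio and scale-invariant", {
  wt <- fit_melt_curve(simulate_melt_curve(noise_sd = 0))
  expect_equal(relative_flavin_content(wt, wt), 1)

  half <- fit_melt_curve(simulate_melt_curve(amplitude = 500, noise_sd = 0))
  expect_equal(relative_flavin_content(half, wt), 0.5, tolerance = 1e-8)

  # variant with ~0.75 of the wild-type flavin complement
  v <- simulate_melt_curve(t_dissoc = 49, amplitude = 750, noise_sd = 8,
                           seed = 21)
  w <- simulate_melt_curve(t_dissoc = 51.9, amplitude = 1000, noise_sd = 8,
                           seed = 22)
  r <- relative_flavin_content(fit_melt_curve(v), fit_melt_curve(w))
  expect_equal(r, 0.75, tolerance = 0.05)

  # multiplying both curves by a positive constant leaves the ratio alone
  scale_curve <- function(mc, k) melt_curve(mc$temperature, mc$fluorescence * k)
  r2 <- relative_flavin_content(fit_melt_curve(scale_curve(v, 3.7)),
                                fit_melt_curve(scale_curve(w, 3.7)))
  expect_equal(r2, r, tolerance = 1e-6)

  zero <- structure(list(amplitude = 0), class = "melt_fit")
  expect_error(relative_flavin_content(wt, zero), "positive")
})

test_that("rates follow Beer-Lambert scaling", {
  # unit identity: slope epsilon*1e-3 A/min over 1 cm is 1 uM/min;
  # at 1 mg/ml this is 1e-3 umol/min/mg
  p <- assay_params(epsilon = 4.81, path_length_cm = 1, protein_mg_ml = 1)
  expect_equal(rate_from_trace(4.81e-3, p), 1e-3)
  expect_equal(rate_from_trace(0, p), 0)

  set.seed(5)
  for (i in 1:20) {
    eps <- runif(1, 0.5, 60); path <- runif(1, 0.2, 1); prot <- runif(1, 0.1, 5)
    rate <- runif(1, 0, 10) # umol/min/mg, forward-simulated slope inverts
    slope <- rate * eps * path * prot
    p <- assay_params(eps, path, prot)
    expect_equal(rate_from_trace(slope, p), rate, tolerance = 1e-12)
    # linear in slope, inverse-linear in epsilon and path
    expect_equal(rate_from_trace(2 * slope, p), 2 * rate, tolerance = 1e-12)
    expect_equal(rate_from_trace(slope, assay_params(2 * eps, path, prot)),
                 rate / 2, tolerance = 1e-12)
    expect_equal(rate_from_trace(slope, assay_params(eps, 2 * path, prot)),
                 rate / 2, tolerance = 1e-12)
  }
  # a falling absorbance with sign -1 gives a positive rate
  pneg <- assay_params(4.81, 1, 1, sign = -1)
  expect_gt(rate_from_trace(-0.01, pneg), 0)
  expect_error(assay_params(0, 1, 1), "positive")
})
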