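test_that("saturation-curve fit recovers known parameters", {
  p <- seq(0.5, 40, length.out = 15)
  truth <- list(P_half = 10, epsilon = 1.0, scale = 3)
  amp <- truth$scale * sqrt(p) *
    (1 + (2^(1 / truth$epsilon) - 1) * p / truth$P_half)^(-truth$epsilon)
  fit <- fit_saturation_curve(data.frame(power = p, amplitude = amp))
  expect_equal(fit$P_half, 10, tolerance = 1e-6)
  expect_equal(fit$epsilon, 1.0, tolerance = 1e-5)
  expect_false(fit$unsaturated)

  # pure sqrt(P) growth: no saturation, P_half runs to its bound
  fit2 <- fit_saturation_curve(data.frame(power = p, amplitude = 2 * sqrt(p)))
  expect_true(fit2$unsaturated)

  expect_error(fit_saturation_curve(data.frame(power = p[1:4],
                                               amplitude = amp[1:4])),
               "5")
})

test_that("noisy saturation curves recover P_half within 5% in the median", {
  p <- seq(0.5, 40, length.out = 15)
  clean <- 3 * sqrt(p) * (1 + (2 - 1) * p / 10)^(-1)
  est <- withr::with_seed(11, vapply(1:200, function(k) {
    amp <- clean + rnorm(length(p), 0, 0.02 * max(clean))
    fit_saturation_curve(data.frame(power = p, amplitude = amp))$P_half
  }, numeric(1)))
  expect_lt(abs(median(est) - 10) / 10, 0.05)
})

test_that("accessibility parameter follows its defining arithmetic", {
  expect_equal(accessibility_parameter(10, 10, 2), 0)
  expect_equal(accessibility_parameter(20, 10, 2, 2.5), 2.0)
  expect_error(accessibility_parameter(5, 10, 2), "relaxant")
})

test_that("simulated saturation pipeline reproduces a target Pi end-to-end", {
  # forward-simulate control and relaxant curves so that Pi = 0.25
  p <- seq(0.5, 50, length.out = 18)
  dhpp <- 2
  ref <- 2
  p_ctrl <- 8
  p_rel <- p_ctrl + 0.25 * dhpp * ref
  curve <- function(ph) 3 * sqrt(p) * (1 + (2 - 1) * p / ph)^(-1)
  f_ctrl <- fit_saturation_curve(data.frame(power = p,
                                            amplitude = curve(p_ctrl)))
  f_rel <- fit_saturation_curve(data.frame(power = p,
                                           amplitude = curve(p_rel)))
  pi_hat <- accessibility_parameter(f_rel$P_half, f_ctrl$P_half, dhpp, ref)
  expect_equal(pi_hat, 0.25, tolerance = 0.02 * 0.25)
})

test_that("depth parameter matches printed table values and ln identities", {
  # ln-ratios of the printed table values, against their printed Phi
  expect_equal(depth_parameter(0.27, 0.53), -0.6745, tolerance = 1e-3)
  expect_lt(abs(depth_parameter(0.27, 0.53) - (-0.68)), 0.02)
  expect_equal(depth_parameter(0.21, 1.00), -1.5606, tolerance = 1e-3)
  expect_lt(abs(depth_parameter(0.21, 1.00) - (-1.57)), 0.02)
  expect_equal(depth_parameter(0.26, 0.19), 0.3137, tolerance = 1e-3)
  expect_lt(abs(depth_parameter(0.26, 0.19) - 0.30), 0.02)
  expect_equal(depth_parameter(0.42, 0.42), 0)
  expect_error(depth_parameter(0, 1), "positive")
})

test_that("depth parameter is antisymmetric and monotone", {
  set.seed(4)
  a <- runif(50, 0.05, 2)
  b <- runif(50, 0.05, 2)
  expect_equal(depth_parameter(a, b), -depth_parameter(b, a))
  expect_true(all(diff(depth_parameter(sort(a), 0.5)) > 0))
  expect_true(all(diff(depth_parameter(0.5, sort(b))) < 0))
})

test_that("first-order SEM propagation matches Monte-Carlo at small SEMs", {
  expect_equal(depth_parameter_sem(1, 0, 1, 0), 0)
  expect_equal(depth_parameter_sem(1, 0.1, 1, 0), 0.1)
  cases <- data.frame(po = c(0.25, 0.5, 1.2), so = c(0.01, 0.05, 0.1),
                      pn = c(0.17, 0.8, 2.0), sn = c(0.02, 0.06, 0.15))
  for (k in seq_len(nrow(cases))) {
    with(cases[k, ], {
      analytic <- depth_parameter_sem(po, so, pn, sn)
      mc <- withr::with_seed(42 + k, {
        o <- rnorm(1e5, po, so)
        n <- rnorm(1e5, pn, sn)
        keep <- o > 0 & n > 0
        sd(log(o[keep] / n[keep]))
      })
      expect_lt(abs(analytic - mc) / mc, 0.05)
    })
  }
})

test_that("table-wide depth parameters agree with the printed column", {
  tabs <- read_accessibility_table(table1_path())
  phi <- depth_parameter_table(tabs$protein)
  err <- abs(phi$phi - tabs$protein$phi_printed)
  expect_equal(nrow(phi), 18)
  expect_true(all(err < 0.08))
})
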