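test_that("delay distributions expose consistent density, survival and hazard", {
  e <- exp_delay(0.5)
  expect_equal(e$survival(2), exp(-1))
  expect_equal(e$hazard(c(0.5, 1, 3)), rep(0.5, 3))

  f2 <- fixed_delay(2)
  expect_equal(f2$survival(c(0, 1.99, 2, 2.5)), c(1, 1, 0, 0))
  expect_equal(f2$atoms, data.frame(location = 2, weight = 1))

  tn <- tnorm_delay(2, 0.75)
  mass <- stats::integrate(tn$density, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-8)
  expect_equal(tn$survival(0), 1)

  for (d in list(e, tn, make_delay_distribution("gamma",
                                                list(shape = 2, scale = 0.7)),
                 make_delay_distribution("weibull",
                                         list(shape = 1.5, scale = 1)))) {
    a <- c(0.3, 1, 2.5)
    expect_equal(d$density(a), d$hazard(a) * d$survival(a), tolerance = 1e-10)
    # hazard-survival round trip on the continuous part
    for (aa in a) {
      cumhaz <- stats::integrate(d$hazard, 0, aa, rel.tol = 1e-9)$value
      expect_equal(exp(-cumhaz), d$survival(aa), tolerance = 1e-6)
    }
  }
  expect_error(make_delay_distribution("exponential", list(rate = -1)), "rate")
  expect_error(make_delay_distribution("empirical",
                                       list(delays = c(-1, 2),
                                            probs = c(0.5, 0.5))),
               "negative")
})

test_that("competing-risk kernels f and g match closed forms and are exhaustive", {
  m <- markov_mod(0.3, 0.5)
  a <- c(0, 0.5, 1, 2)
  expect_equal(f_and_g(m, a)$f, 0.3 * exp(-0.8 * a))
  expect_equal(f_and_g(m, a)$g, 0.5 * exp(-0.8 * a))

  mf <- disease_model(exp_delay(0.3), fixed_delay(2))
  expect_equal(mf$f(c(0.5, 1.9)), 0.3 * exp(-0.3 * c(0.5, 1.9)))
  expect_equal(mf$f(c(2, 3)), c(0, 0))
  expect_equal(mf$g_atoms$weight, exp(-0.3 * 2))

  taus <- list(exp_delay(0.3), fixed_delay(1.5), tnorm_delay(1, 0.5),
               make_delay_distribution("gamma", list(shape = 2, scale = 0.7)))
  qs <- list(exp_delay(0.5), fixed_delay(2), tnorm_delay(2, 0.75),
             make_delay_distribution("weibull", list(shape = 2, scale = 1.5)),
             make_delay_distribution("empirical",
                                     list(delays = c(1, 2),
                                          probs = c(0.3, 0.7))))
  for (tau in taus) for (q in qs) {
    mod <- disease_model(tau, q)
    up <- max(tau$upper, q$upper)
    total <- kernel_mass(mod$f, mod$f_atoms, up) +
      kernel_mass(mod$g, mod$g_atoms, up)
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("transmissibility agrees with closed forms and Monte Carlo", {
  expect_equal(transmissibility(markov_mod(0.3, 0.5)), 0.375,
               tolerance = 1e-8)
  expect_equal(transmissibility(disease_model(exp_delay(0.3),
                                              fixed_delay(2))),
               1 - exp(-0.6), tolerance = 1e-8)
  # recovery far beyond the transmission support: everything transmits
  slow_rec <- fixed_delay(200)
  expect_equal(transmissibility(disease_model(exp_delay(5), slow_rec)), 1,
               tolerance = 1e-6)

  # paired-sample Monte Carlo on one edge
  mod <- disease_model(exp_delay(0.4), tnorm_delay(2, 0.75))
  Tt <- transmissibility(mod)
  set.seed(99)
  n <- 1e5
  hits <- mean(sample_delay(mod$transmission, n) < sample_delay(mod$recovery, n))
  se <- sqrt(Tt * (1 - Tt) / n)
  expect_lt(abs(hits - Tt), 3 * se)
})

test_that("sampling is reproducible and matches the stated laws", {
  expect_equal(sample_delay(fixed_delay(2), 10), rep(2, 10))
  set.seed(5); a <- sample_delay(exp_delay(0.5), 20)
  set.seed(5); b <- sample_delay(exp_delay(0.5), 20)
  expect_identical(a, b)
  set.seed(7)
  x <- sample_delay(exp_delay(0.5), 2e4)
  expect_gt(stats::ks.test(x, stats::pexp, 0.5)$p.value, 0.01)
  set.seed(8)
  y <- sample_delay(tnorm_delay(2, 0.75), 2e4)
  expect_true(all(y >= 0))
  cdf <- function(v) (stats::pnorm(v, 2, 0.75) - stats::pnorm(0, 2, 0.75)) /
    stats::pnorm(2 / 0.75)
  expect_gt(stats::ks.test(y, cdf)$p.value, 0.01)
})

test_that("delay means integrate the survival function, atoms included", {
  expect_equal(delay_mean(exp_delay(0.5)), 2, tolerance = 1e-8)
  expect_equal(delay_mean(fixed_delay(2)), 2, tolerance = 1e-10)
  expect_equal(delay_mean(tnorm_delay(2, 0.75)), tnorm_delay(2, 0.75)$mean,
               tolerance = 1e-7)
  emp <- make_delay_distribution("empirical",
                                 list(delays = c(1, 3), probs = c(0.5, 0.5)))
  expect_equal(delay_mean(emp), 2, tolerance = 1e-9)
})

test_that("textual delay specs parse to the right distributions", {
  expect_equal(parse_delay_spec("exp:0.5")$params$rate, 0.5)
  expect_equal(parse_delay_spec("fixed:2")$params$sigma, 2)
  tn <- parse_delay_spec("normal:2,0.75")
  expect_equal(c(tn$params$mean, tn$params$sd), c(2, 0.75))
  expect_equal(parse_delay_spec("gamma:2,0.7")$kind, "gamma")
  expect_error(parse_delay_spec("cauchy:1"), "unknown")
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("1\t0.25", "2\t0.75"), tmp)
  emp <- parse_delay_spec(paste0("empirical:", tmp))
  expect_equal(emp$atoms$weight, c(0.25, 0.75))
})
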