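test_that("magnitude rescaling is the linear min-max map onto [1, 10]", {
  expect_equal(rescale_magnitudes(c(10, 90)), c(1, 10))
  expect_equal(rescale_magnitudes(c(10, 50, 90)), c(1, 5.5, 10))
  set.seed(4)
  x <- sample(10:90, 50, replace = TRUE)
  x[1:2] <- c(10, 90)
  out <- rescale_magnitudes(x)
  expect_true(all(out >= 1 & out <= 10))
  expect_error(rescale_magnitudes(rep(5, 4)), "constant")
})

test_that("probability weighting matches an independent log-space evaluation", {
  # oracle: w(p) = exp(gamma*log(p) - (1/gamma)*log(p^gamma + (1-p)^gamma))
  w_oracle <- function(p, g)
    exp(g * log(p) - (1 / g) * log(p^g + (1 - p)^g))
  for (g in c(0.3, 0.61, 1, 1.7, 3)) {
    p <- seq(0.05, 0.95, by = 0.05)
    expect_equal(weight_probability(p, g), w_oracle(p, g), tolerance = 1e-12)
    expect_true(all(diff(weight_probability(p, g)) > 0))  # strictly increasing
  }
  expect_equal(weight_probability(c(0, 1), 0.7), c(0, 1))
  expect_equal(weight_probability(0:10 / 10, 1), 0:10 / 10)
  expect_lt(abs(weight_probability(0.1, 0.61) - 0.186), 5e-4)
  expect_error(weight_probability(0.5, 0), "positive")
  expect_error(weight_probability(0.5, -1), "positive")
})

test_that("utility is a power law", {
  m <- c(1, 4, 9, 10)
  expect_equal(utility(m, 1), m)
  expect_equal(utility(9, 0.5), 3)
  expect_equal(utility(m, 0), rep(1, 4))
  expect_error(utility(-1, 0.5))
})

test_that("model specs encode the family/distortion free-parameter structure", {
  expect_setequal(value_model_spec("multiplicative", "SU",
                                   fixed = list(omega_mult = 6.62))$free,
                  c("alpha", "gamma"))
  expect_setequal(value_model_spec("multiplicative", "EV")$free, "omega_mult")
  expect_setequal(value_model_spec("additive", "EU")$free,
                  c("alpha", "omega_m", "omega_p"))
  expect_setequal(value_model_spec("hybrid", "EVPW")$free,
                  c("gamma", "omega_m", "omega_p", "omega_mult"))
  expect_error(value_model_spec("additive", "SU", fixed = list(omega_mult = 1)),
               "not in the additive family")
})

test_that("option values follow the family formulas", {
  mult <- value_model_spec("multiplicative", "SU")
  expect_equal(option_value(1, 1, list(alpha = 1, gamma = 1, omega_mult = 6.62),
                            mult), 6.62)
  add <- value_model_spec("additive", "SU")
  v <- option_value(c(2, 9), c(0.3, 0.3),
                    list(alpha = 1, gamma = 1, omega_m = 0, omega_p = 2), add)
  expect_equal(v[1], v[2])  # magnitude has no effect with omega_m = 0

  # hybrid with omega_mult = 0 reduces to the additive form
  hyb <- value_model_spec("hybrid", "SU")
  set.seed(9)
  for (i in 1:20) {
    pars <- list(alpha = runif(1, 0.3, 2), gamma = runif(1, 0.3, 2),
                 omega_m = runif(1, 0.5, 5), omega_p = runif(1, 0.5, 5),
                 omega_mult = 0)
    m <- runif(1, 1, 10); p <- sample(1:9, 1) / 10
    expect_equal(option_value(m, p, pars, hyb),
                 option_value(m, p, pars, add), tolerance = 1e-12)
  }
  expect_error(option_value(5, 0.5, list(alpha = 1, gamma = 1, omega_m = 0,
                                         omega_p = 0, omega_mult = 1), hyb),
               "omega_m \\+ omega_p")
})

test_that("softmax choice probabilities are symmetric and overflow-safe", {
  expect_equal(choice_probability(3, 3), 0.5)
  expect_equal(choice_probability(0, 20), 1, tolerance = 1e-8)
  expect_equal(choice_probability(0, 1000), 1)
  dv <- seq(-5, 5, by = 0.5)
  expect_equal(choice_probability(0, dv), 1 - choice_probability(0, -dv))
})

test_that("the likelihood matches a hand-rolled per-trial sum", {
  spec <- value_model_spec("multiplicative", "SU")
  pars <- list(alpha = 0.7, gamma = 0.8, omega_mult = 6.62)
  dat <- data.frame(m_left = c(2, 8, 5, 1, 10), m_right = c(7, 3, 6, 9, 2),
                    p_left = c(0.3, 0.8, 0.5, 0.9, 0.2),
                    p_right = c(0.7, 0.2, 0.4, 0.1, 0.6),
                    choice_right = c(1, 0, 0, 1, 0))
  manual <- 0
  for (i in 1:5) {
    vl <- 6.62 * dat$m_left[i]^0.7 *
      (dat$p_left[i]^0.8 / (dat$p_left[i]^0.8 + (1 - dat$p_left[i])^0.8)^(1 / 0.8))
    vr <- 6.62 * dat$m_right[i]^0.7 *
      (dat$p_right[i]^0.8 / (dat$p_right[i]^0.8 + (1 - dat$p_right[i])^0.8)^(1 / 0.8))
    pr <- 1 / (1 + exp(-(vr - vl)))
    manual <- manual - log(if (dat$choice_right[i] == 1) pr else 1 - pr)
  }
  expect_equal(negative_log_likelihood(dat, pars, spec), manual,
               tolerance = 1e-12)

  # a value-indifferent model scores n*log(2)
  chance <- list(alpha = 1, gamma = 1, omega_mult = 0)
  dat320 <- dat[rep(1:5, 64), ]
  expect_equal(negative_log_likelihood(dat320, chance, spec), 320 * log(2))
  expect_error(negative_log_likelihood(dat[0, ], pars, spec), "empty")
})

test_that("NLL is invariant to relabelling the two sides", {
  spec <- value_model_spec("multiplicative", "SU")
  pars <- list(alpha = 0.9, gamma = 1.2, omega_mult = 4)
  s <- default_session()
  dat <- patchval:::prepare_fit_data(s)
  flipped <- data.frame(m_left = dat$m_right, m_right = dat$m_left,
                        p_left = dat$p_right, p_right = dat$p_left,
                        choice_right = 1 - dat$choice_right)
  expect_equal(negative_log_likelihood(dat, pars, spec),
               negative_log_likelihood(flipped, pars, spec))
})

test_that("multi-start fitting is deterministic, bounded and respects nesting", {
  s <- default_session()
  f1 <- fit_value_model(s, value_model_spec("multiplicative", "SU",
                                            fixed = list(omega_mult = 6.62),
                                            n_starts = 20), seed = 5)
  f2 <- fit_value_model(s, value_model_spec("multiplicative", "SU",
                                            fixed = list(omega_mult = 6.62),
                                            n_starts = 20), seed = 5)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$nll, f2$nll)
  expect_equal(f1$nll, min(f1$per_start$nll))
  expect_identical(f1$k, 2L)
  b <- f1$spec$bounds
  expect_true(f1$params$alpha >= b$alpha[1] && f1$params$alpha <= b$alpha[2])

  # nesting: EV (1 free) <= EU (2 free) <= SU (3 free) in best NLL
  fits <- lapply(c("EV", "EU", "SU"), function(d)
    fit_value_model(s, value_model_spec("multiplicative", d, n_starts = 20),
                    seed = 7))
  expect_gte(fits[[1]]$nll + 1e-4, fits[[2]]$nll)
  expect_gte(fits[[2]]$nll + 1e-4, fits[[3]]$nll)

  # BIC arithmetic: k log(n) + 2 NLL
  expect_equal(f1$bic, 2 * log(320) + 2 * f1$nll)
})

test_that("BIC comparison ranks ascending and breaks ties toward parsimony", {
  fake_fit <- function(nll, k, n, label) {
    structure(list(params = list(), nll = nll, bic = k * log(n) + 2 * nll,
                   k = k, n = n, per_start = NULL, convergence = 0L,
                   spec = list(label = label), seed = 1L),
              class = "value_fit")
  }
  # identical NLL, k = 2 vs k = 4: the smaller model wins on BIC
  cmp <- compare_models_bic(list(big = fake_fit(100, 4, 320, "big"),
                                 small = fake_fit(100, 2, 320, "small")))
  expect_identical(cmp$ranking$model[1], "small")
  # exact BIC tie: fewer parameters preferred
  cmp2 <- compare_models_bic(list(
    a = fake_fit(100, 4, 320, "a"),
    b = fake_fit(100 + log(320), 2, 320, "b")))
  expect_identical(cmp2$ranking$model[1], "b")
  one <- compare_models_bic(list(solo = fake_fit(10, 1, 320, "solo")))
  expect_identical(one$winner$spec$label, "solo")
  expect_error(compare_models_bic(list(fake_fit(1, 1, 320, "x"),
                                       fake_fit(1, 1, 100, "y"))),
               "different trial counts")
})

test_that("parameter recovery reports one reproducible correlation per free parameter", {
  spec <- value_model_spec("multiplicative", "SU",
                           fixed = list(omega_mult = 6.62), n_starts = 10)
  s <- default_session()
  r1 <- recover_parameters(spec, 8, s, seed = 77)
  r2 <- recover_parameters(spec, 8, s, seed = 77)
  expect_identical(r1$correlations, r2$correlations)
  expect_named(r1$correlations, c("alpha", "gamma"))
  expect_identical(nrow(r1$table), 8L)
  expect_true(all(is.finite(r1$correlations)))
})
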