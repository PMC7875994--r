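make_measurements <- function(n = 12, seed = 101) {
  generate_cohort(cohort_spec(n_participants = n), seed = seed)$metabolites
}

test_that("QC thresholds exclude noisy measurements and drop participants listwise", {
  m <- make_measurements(4)
  m$CRLB_GABA[1] <- 25
  m$FWHM[7] <- 30
  m$SNR[12] <- 5
  qc <- qc_filter(m)
  expect_identical(qc$measurements$reason[1], "CRLB")
  expect_identical(qc$measurements$reason[7], "FWHM")
  expect_identical(qc$measurements$reason[12], "SNR")
  expect_true(qc$measurements$included[2])
  # rows 1, 7, 12 belong to participants 1, 2, 3
  expect_setequal(qc$excluded_participants, c(1, 2, 3))
  expect_setequal(unique(qc$included$participant), 4)
  expect_error(qc_filter(m[setdiff(names(m), "SNR")]), "SNR")
})

test_that("metabolite normalization follows the GM and creatine chain", {
  m <- data.frame(participant = 1, region = "dACC",
                  GABA_abs = 2, Glu_abs = 6, Cr_abs = 8,
                  CRLB_GABA = 5, CRLB_Glu = 5, FWHM = 10, SNR = 20,
                  GM_frac = 0.5, WM_frac = 0.3)
  out <- normalize_metabolites(m)
  expect_equal(out$GABA_norm, (2 / 0.5) / (8 / 0.8))  # 0.4
  expect_equal(out$Glu_norm, (6 / 0.5) / (8 / 0.8))

  # pure grey matter: plain creatine ratio
  m2 <- m; m2$GM_frac <- 1; m2$WM_frac <- 0
  expect_equal(normalize_metabolites(m2)$GABA_norm, 2 / 8)

  # doubling creatine halves both outputs
  m3 <- m; m3$Cr_abs <- 16
  expect_equal(normalize_metabolites(m3)$GABA_norm, out$GABA_norm / 2)
  m4 <- m; m4$GM_frac <- 0
  expect_error(normalize_metabolites(m4), "tissue fractions")
})

test_that("E/I balance is the glutamate-to-GABA ratio, invariant to calibration", {
  expect_equal(compute_ei(0.6, 1.2), 2)
  expect_equal(compute_ei(0.7, 0.7), 1)
  expect_error(compute_ei(0, 1), "GABA")
  # common creatine scaling cancels in the ratio
  m <- make_measurements(3)
  ei1 <- ei_profiles(normalize_metabolites(m))$ei
  m2 <- m; m2$Cr_abs <- m2$Cr_abs * 3
  ei2 <- ei_profiles(normalize_metabolites(m2))$ei
  expect_equal(ei1, ei2, tolerance = 1e-12)
})

test_that("the five-region GLM reduces to a simple slope when other regions are constant", {
  set.seed(110)
  n <- 24
  ei <- data.frame(dACC = rnorm(n), vmPFC = 1, dlPFC = 2, lM1 = 3, rM1 = 4)
  dv <- 0.6 * ei$dACC + rnorm(n, 0, 0.5)
  expect_warning(g <- ei_glm(dv, ei), "constant region")
  expect_identical(g$regions, "dACC")
  simple <- coef(lm(scale(dv) ~ scale(ei$dACC)))[[2]]
  expect_equal(g$table$beta, simple, tolerance = 1e-10)

  ei_bad <- data.frame(a = rnorm(n), b = rnorm(n))
  ei_bad$c <- ei_bad$a + ei_bad$b
  expect_error(ei_glm(dv, ei_bad), "collinear")
})

test_that("gated partial correlations agree with the GLM in sign and detect identity", {
  set.seed(111)
  n <- 40
  ei <- as.data.frame(matrix(rnorm(n * 5), n,
                             dimnames = list(NULL, c("dACC", "vmPFC", "dlPFC",
                                                     "lM1", "rM1"))))
  dv <- ei$dACC  # dv identical to target, orthogonal nuisance
  pr <- partial_correlation_region(dv, ei, "dACC")
  expect_equal(pr$r, 1, tolerance = 1e-10)

  dv2 <- 0.5 * ei$dACC - 0.4 * ei$vmPFC + rnorm(n, 0, 0.7)
  g <- ei_glm(dv2, ei)
  for (rg in c("dACC", "vmPFC")) {
    p_rg <- partial_correlation_region(dv2, ei, rg)
    expect_equal(sign(p_rg$r), sign(g$table$beta[g$table$region == rg]))
  }

  # with population-orthogonal nuisance, partial r tracks the zero-order r
  set.seed(112)
  nbig <- 1e4
  eib <- as.data.frame(matrix(rnorm(nbig * 5), nbig,
                              dimnames = list(NULL, names(ei))))
  dvb <- 0.5 * eib$dACC + rnorm(nbig, 0, sqrt(1 - 0.25))
  prb <- partial_correlation_region(dvb, eib, "dACC")
  expect_equal(prb$r, cor(dvb, eib$dACC), tolerance = 0.01)
})

test_that("transmitter partial correlations isolate the driving metabolite", {
  set.seed(113)
  n <- 60
  regions <- c("dACC", "vmPFC", "dlPFC", "lM1", "rM1")
  tx <- data.frame(matrix(rnorm(n * 10), n))
  names(tx) <- as.vector(outer(regions, c("GABA", "Glu"), paste, sep = "_"))
  dv <- -0.7 * tx$dACC_GABA + rnorm(n, 0, 0.5)  # pure GABA effect
  g_gaba <- partial_correlation_transmitter(dv, tx, "dACC", "GABA")
  g_glu <- partial_correlation_transmitter(dv, tx, "dACC", "Glu")
  expect_lt(g_gaba$r, -0.5)
  expect_lt(abs(g_glu$r), 0.35)
  # invariant to nuisance column order
  tx_perm <- tx[, sample(names(tx))]
  g2 <- partial_correlation_transmitter(dv, tx_perm, "dACC", "GABA")
  expect_equal(g_gaba$r, g2$r, tolerance = 1e-10)
  expect_error(partial_correlation_transmitter(dv[1:10], tx[1:10, ],
                                               "dACC", "GABA"),
               "too few participants")
})

test_that("region contrasts match a reparameterized refit", {
  set.seed(114)
  n <- 30
  ei <- as.data.frame(matrix(rnorm(n * 5), n,
                             dimnames = list(NULL, c("dACC", "vmPFC", "dlPFC",
                                                     "lM1", "rM1"))))
  dv <- 0.8 * ei$dACC + 0.1 * ei$vmPFC + rnorm(n, 0, 0.6)
  ct <- region_coefficient_contrast(dv, ei, "dACC", "vmPFC")
  ct_rev <- region_coefficient_contrast(dv, ei, "vmPFC", "dACC")
  expect_equal(ct$t, -ct_rev$t)
  self <- region_coefficient_contrast(dv, ei, "dACC", "dACC")
  expect_equal(self$t, 0)

  # oracle: reparameterize with sum and difference columns; the coefficient
  # on the (half) difference equals beta_a - beta_b
  Z <- data.frame(lapply(ei, scale))
  dvz <- drop(scale(dv))
  rep_fit <- lm(dvz ~ I((Z$dACC + Z$vmPFC) / 2) + I((Z$dACC - Z$vmPFC) / 2) +
                  Z$dlPFC + Z$lM1 + Z$rM1)
  s <- summary(rep_fit)$coefficients
  expect_equal(ct$estimate, s[3, "Estimate"], tolerance = 1e-10)
  expect_equal(ct$t, s[3, "t value"], tolerance = 1e-10)
})

test_that("the hierarchy emits follow-ups only for significant regions", {
  regions <- c("dACC", "vmPFC", "dlPFC", "lM1", "rM1")
  n <- 29

  # null: no region should be followed up
  set.seed(115)
  ei0 <- cbind(participant = 1:n,
               as.data.frame(matrix(rnorm(n * 5), n,
                                    dimnames = list(NULL, regions))))
  dvs0 <- data.frame(participant = 1:n, mean_pla = rnorm(n))
  link0 <- run_testing_hierarchy(dvs0, ei0,
                                 config = list(dv_names = "mean_pla"))
  node0 <- link0$mean_pla
  max_p <- min(node0$glm$p)
  if (max_p >= 0.05) {
    expect_length(node0$followups, 0)
    expect_match(node0$reason, "no region significant")
  } else {
    expect_identical(names(node0$followups),
                     node0$glm$region[node0$glm$p < 0.05])
  }

  # planted dACC effect: dACC followed up, follow-ups agree with the GLM
  set.seed(116)
  ei1 <- ei0
  dv <- 0.9 * ei1$dACC + rnorm(n, 0, 0.4)
  dvs1 <- data.frame(participant = 1:n, mean_pla = dv)
  link1 <- run_testing_hierarchy(dvs1, ei1,
                                 config = list(dv_names = "mean_pla"))
  node1 <- link1$mean_pla
  expect_true("dACC" %in% names(node1$followups))
  expect_identical(names(node1$followups),
                   node1$glm$region[node1$glm$p < 0.05])
  fu <- node1$followups$dACC
  expect_equal(sign(fu$partial$r),
               sign(node1$glm$beta[node1$glm$region == "dACC"]))
  expect_named(fu$contrasts, setdiff(regions, names(node1$followups)[1]),
               ignore.order = TRUE)

  # step-1 behavioural gate
  gated <- run_testing_hierarchy(dvs1, ei1,
                                 config = list(dv_names = "mean_pla",
                                               behavioural_p = c(mean_pla = 0.4)))
  expect_false(gated$mean_pla$tested)
})

test_that("a fully mediating covariate removes the region effect", {
  set.seed(117)
  n <- 29
  regions <- c("dACC", "vmPFC", "dlPFC", "lM1", "rM1")
  ei <- cbind(participant = 1:n,
              as.data.frame(matrix(rnorm(n * 5), n,
                                   dimnames = list(NULL, regions))))
  mediator <- 0.9 * ei$vmPFC + rnorm(n, 0, 0.3)
  dv <- mediator + rnorm(n, 0, 0.2)  # vmPFC acts on dv only through mediator
  dvs <- data.frame(participant = 1:n, pct_correct = dv, alpha = mediator,
                    gamma = rnorm(n), nb_share = runif(n, 0.3, 0.45))
  link <- run_testing_hierarchy(dvs, ei,
                                config = list(dv_names = "pct_correct"))
  node <- link$pct_correct
  expect_true("vmPFC" %in% names(node$followups))
  expect_false(is.null(node$mediation))
  p_before <- node$glm$p[node$glm$region == "vmPFC"]
  p_after <- node$mediation$p[node$mediation$region == "vmPFC"]
  expect_lt(p_before, 0.05)
  expect_gt(p_after, 0.05)
})
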