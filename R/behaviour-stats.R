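#' Patch-leaving advantage (PLA) at leave trials
#'
#' For every leave trial, `PLA = (alternative - current patch value from
#' the previous trial) - current cost`: the updated values are revealed only
#' after the patch choice, so the values informing trial `t`'s decision are
#' those of trial `t - 1`. A leave on the very first trial (where no
#' previous values exist) is excluded.
#'
#' @param trials A session table.
#' @return List with `pla` (data frame: `trial`, `pla`) and `mean_pla`.
#'   With no leave trials, `mean_pla` is `NA` with a warning.
#' @export
compute_patch_leaving_advantage <- function(trials) {
  idx <- which(trials$switch & trials$trial > 1)
  if (length(idx) == 0L) {
    warning("no leave trials; mean PLA is NA")
    return(list(pla = data.frame(trial = integer(0), pla = numeric(0)),
                mean_pla = NA_real_))
  }
  prev <- match(trials$trial[idx] - 1L, trials$trial)
  pla <- (trials$val_alt[prev] - trials$val_cur[prev]) - trials$cost[idx]
  list(pla = data.frame(trial = trials$trial[idx], pla = pla),
       mean_pla = mean(pla))
}

#' Median patch value difference at leaving, per cost level
#'
#' For each cost level, the median of the previous-trial value difference
#' (alternative minus current patch) over leave trials at that cost. Cost
#' levels at which a participant never left (or was never presented) yield
#' `NA`.
#'
#' @param trials A session table.
#' @param cost_levels Cost levels to evaluate.
#' @return Named numeric vector of medians, one per cost level.
#' @export
median_leave_vdiff_by_cost <- function(trials, cost_levels = c(5, 10, 15, 20)) {
  idx <- which(trials$switch & trials$trial > 1)
  prev <- match(trials$trial[idx] - 1L, trials$trial)
  vdiff <- trials$val_alt[prev] - trials$val_cur[prev]
  cost <- trials$cost[idx]
  out <- vapply(cost_levels, function(cl) {
    v <- vdiff[cost == cl]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
  stats::setNames(out, paste0("cost_", cost_levels))
}

#' One-way repeated-measures ANOVA with a linear trend contrast
#'
#' Tests whether the per-participant leave thresholds differ across the
#' four cost levels. Rows with any missing level are removed listwise. The
#' F statistic uses the within-subject decomposition
#' (`df = (k - 1, (n - 1)(k - 1))`); the effect size is
#' `eta^2 = SS_condition / SS_total` with the total including the
#' between-subject sum of squares. The linear trend regresses each
#' participant's medians on the cost levels (plus a constant) and tests the
#' slopes against zero with a two-tailed one-sample t-test.
#'
#' @param mat Numeric matrix, participants x cost levels.
#' @param cost_levels Numeric values of the levels (trend regressor).
#' @return List with `F`, `df`, `p`, `eta_sq`, `n`, and `trend` (a
#'   [group_level_ttest()] result on the per-participant slopes).
#' @export
rm_anova_linear_trend <- function(mat, cost_levels = c(5, 10, 15, 20)) {
  mat <- as.matrix(mat)
  keep <- stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3) stop("need at least 3 complete participants", call. = FALSE)

  gm <- mean(mat)
  ss_total <- sum((mat - gm)^2)
  ss_subj <- k * sum((rowMeans(mat) - gm)^2)
  ss_cond <- n * sum((colMeans(mat) - gm)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  f <- if (ss_cond == 0) 0 else (ss_cond / df1) / (ss_err / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  eta <- if (ss_total == 0) 0 else ss_cond / ss_total

  slopes <- apply(mat, 1, function(y)
    stats::coef(stats::lm(y ~ cost_levels))[[2L]])
  trend <- if (stats::sd(slopes) > 0) group_level_ttest(slopes)
           else list(mean = mean(slopes), t = NA_real_, df = n - 1,
                     p = NA_real_, ci95 = c(NA_real_, NA_real_),
                     u3_1 = mean(slopes < 0), n = n)
  list(F = f, df = c(df1, df2), p = p, eta_sq = eta, n = n, trend = trend)
}

#' Trial-level design matrix for participant regressions
#'
#' Builds the z-scored design matrix (plus a constant column) and the
#' dependent variable for one of the three per-participant regressions:
#'
#' * `patch_rt` — log patch-stage RT (z-scored within participant) on
#'   previous-trial patch value difference, leave-trial flag, cost, trial
#'   number, side-change flag, and previous-trial reward (6 predictors).
#' * `value_choice` — right-option choice (0/1) on expected-value difference
#'   (right minus left), expected-value sum, current patch value difference,
#'   cost, previous value choice, chosen-patch side, previous reward,
#'   no-brainer flag, trial number, and leave-trial flag (10 predictors).
#' * `value_rt` — log value-stage RT (z-scored) on the same variables but
#'   with the absolute expected-value difference.
#'
#' The first trial is dropped (previous-trial regressors are undefined
#' there). A zero-variance predictor is an error naming the column.
#'
#' @param trials A session table.
#' @param stage `"patch_rt"`, `"value_choice"` or `"value_rt"`.
#' @return List with `X` (matrix incl. `constant` column) and `y`.
#' @export
build_design_matrix <- function(trials,
                                stage = c("patch_rt", "value_choice",
                                          "value_rt")) {
  stage <- match.arg(stage)
  n <- nrow(trials)
  stopifnot(n >= 3)
  rows <- 2:n
  prev <- rows - 1L

  if (stage == "patch_rt") {
    cols <- list(
      pvd_prev = trials$val_alt[prev] - trials$val_cur[prev],
      switch = as.numeric(trials$switch[rows]),
      cost = trials$cost[rows],
      trial = trials$trial[rows],
      side_change = as.numeric(trials$side_cur[rows] != trials$side_cur[prev]),
      prev_reward = as.numeric(trials$reward[prev] > 0)
    )
    y <- zscore(log(trials$rt_patch[rows]), "log(rt_patch)")
  } else {
    ev_l <- trials$m_left * trials$p_left
    ev_r <- trials$m_right * trials$p_right
    ev_diff <- if (stage == "value_rt") abs(ev_r - ev_l) else ev_r - ev_l
    cols <- list(
      ev_diff = ev_diff[rows],
      ev_sum = (ev_r + ev_l)[rows],
      pvd = trials$val_alt[rows] - trials$val_cur[rows],
      cost = trials$cost[rows],
      prev_choice = as.numeric(trials$value_choice[prev] == "right"),
      patch_side = as.numeric(trials$side_cur[rows] == "right"),
      prev_reward = as.numeric(trials$reward[prev] > 0),
      no_brainer = as.numeric(trials$no_brainer[rows] != "none"),
      trial = trials$trial[rows],
      switch = as.numeric(trials$switch[rows])
    )
    y <- if (stage == "value_choice")
      as.numeric(trials$value_choice[rows] == "right")
    else zscore(log(trials$rt_value[rows]), "log(rt_value)")
  }
  X <- vapply(names(cols), function(nm) zscore(cols[[nm]], nm),
              numeric(length(rows)))
  X <- cbind(X, constant = 1)
  list(X = X, y = y)
}

#' Per-participant regression (linear or logistic)
#'
#' Linear fits use ordinary least squares. Logistic fits use Newton
#' iterations with a tiny ridge penalty on the slope coefficients
#' (starting at 1e-6 and escalating tenfold up to 1e-2) so that complete
#' separation yields finite estimates rather than divergence.
#'
#' @param y Dependent variable (numeric; 0/1 for logistic).
#' @param X Design matrix including a `constant` column.
#' @param link `"linear"` or `"logistic"`.
#' @return Named coefficient vector.
#' @export
fit_participant_regression <- function(y, X, link = c("linear", "logistic")) {
  link <- match.arg(link)
  stopifnot(nrow(X) == length(y))
  if (link == "linear") {
    fit <- stats::lm.fit(X, y)
    return(fit$coefficients)
  }
  stopifnot(all(y %in% c(0, 1)))
  penalized <- colnames(X) != "constant"
  ridge <- 1e-6
  repeat {
    b <- ridge_logistic(y, X, ridge, penalized)
    if (!is.null(b)) return(b)
    ridge <- ridge * 10
    if (ridge > 1e-2)
      stop("logistic regression failed to converge even at ridge 1e-2",
           call. = FALSE)
  }
}

ridge_logistic <- function(y, X, ridge, penalized, max_iter = 100L) {
  b <- rep(0, ncol(X))
  D <- diag(ridge * as.numeric(penalized), ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, y - mu)) - drop(D %*% b)
    if (max(abs(g)) < 1e-8) {
      names(b) <- colnames(X)
      return(b)
    }
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + D
    step <- try(solve(H, g), silent = TRUE)
    if (inherits(step, "try-error")) return(NULL)
    if (any(!is.finite(step)) || max(abs(step)) > 1e6) return(NULL)
    b <- b + step
  }
  NULL
}

#' Group-level one-sample t-test of per-participant coefficients
#'
#' Two-tailed one-sample t-test against zero, the 95% confidence interval
#' of the mean, and Cohen's U3 for one sample — here the proportion of
#' participants whose coefficient falls below the null value zero (so that
#' a strongly positive group effect gives a U3 near 0 and a strongly
#' negative one a U3 near 1).
#'
#' @param coefficients Numeric vector, one value per participant.
#' @return List with `mean`, `t`, `df`, `p`, `ci95`, `u3_1`, `n`.
#' @export
group_level_ttest <- function(coefficients) {
  x <- coefficients
  stopifnot(length(x) >= 3, all(is.finite(x)))
  if (stats::sd(x) == 0)
    stop("coefficients have zero variance", call. = FALSE)
  tt <- stats::t.test(x, mu = 0)
  list(mean = mean(x), t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci95 = as.numeric(tt$conf.int), u3_1 = mean(x < 0),
       n = length(x))
}

#' Accuracy of value-guided choice
#'
#' Percentage of trials on which the option with the higher objective
#' expected value (magnitude times probability) was chosen, among trials
#' with unequal expected values.
#'
#' @param trials A session table.
#' @return Percentage in `[0, 100]`, or `NA` if no unequal-EV trial exists.
#' @export
compute_accuracy <- function(trials) {
  ev_l <- trials$m_left * trials$p_left
  ev_r <- trials$m_right * trials$p_right
  unequal <- ev_l != ev_r
  if (!any(unequal)) {
    warning("no trials with unequal expected value")
    return(NA_real_)
  }
  correct <- (trials$value_choice == "right" & ev_r > ev_l) |
             (trials$value_choice == "left" & ev_l > ev_r)
  100 * sum(correct & unequal) / sum(unequal)
}

#' Assemble the per-participant decision-variable set
#'
#' Collects the scalars entering the E/I analysis: mean PLA, the cost
#' coefficient from the patch-stage RT regression, percent correct, the
#' fitted `alpha` and `gamma`, the value-difference coefficient from the
#' value-stage RT regression, the mean value-stage log RT (log-seconds; it
#' is z-scored across participants when entering the group GLM), and the
#' share of no-brainer trials (used as a covariate of no interest in
#' value-phase analyses).
#'
#' @param trials A session table.
#' @param fit A `value_fit` (or `NULL` to leave `alpha`/`gamma` `NA`).
#' @return A one-row `data.frame` of class `decision_variables`.
#' @export
compute_decision_variables <- function(trials, fit = NULL) {
  pla <- suppressWarnings(compute_patch_leaving_advantage(trials))
  d_patch <- build_design_matrix(trials, "patch_rt")
  b_patch <- fit_participant_regression(d_patch$y, d_patch$X, "linear")
  d_vrt <- build_design_matrix(trials, "value_rt")
  b_vrt <- fit_participant_regression(d_vrt$y, d_vrt$X, "linear")
  out <- data.frame(
    mean_pla = pla$mean_pla,
    cost_rt_beta = unname(b_patch[["cost"]]),
    pct_correct = compute_accuracy(trials),
    alpha = if (is.null(fit)) NA_real_ else fit$params$alpha,
    gamma = if (is.null(fit)) NA_real_ else fit$params$gamma,
    vdiff_rt_beta = unname(b_vrt[["ev_diff"]]),
    mean_logrt_value = mean(log(trials$rt_value)),
    nb_share = mean(trials$no_brainer != "none")
  )
  class(out) <- c("decision_variables", "data.frame")
  out
}

#' Robust slope via iteratively reweighted least squares (bisquare)
#'
#' Tukey bisquare weights with tuning constant 4.685 (95% Gaussian
#' efficiency), as used to confirm region-behaviour correlations against
#' influential points. Inference on the slope uses the robust standard
#' error with `n - 2` degrees of freedom.
#'
#' @param y,x Numeric vectors.
#' @return List with `slope`, `intercept`, `t`, `df`, `p`, `ci95`.
#' @export
robust_regression <- function(y, x) {
  stopifnot(length(y) == length(x), length(y) >= 4)
  if (stats::sd(x) == 0)
    stop("constant predictor in robust regression", call. = FALSE)
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  if (!fit$converged)
    stop("robust regression did not converge", call. = FALSE)
  s <- summary(fit)
  slope <- s$coefficients["x", "Value"]
  se <- s$coefficients["x", "Std. Error"]
  df <- length(y) - 2
  tval <- slope / se
  p <- 2 * stats::pt(-abs(tval), df)
  ci <- slope + c(-1, 1) * stats::qt(0.975, df) * se
  list(slope = slope, intercept = s$coefficients["(Intercept)", "Value"],
       t = tval, df = df, p = p, ci95 = ci)
}
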