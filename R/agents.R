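#' Parameters of a synthetic task agent
#'
#' An agent couples a stochastic stay/leave threshold on the patch-leaving
#' advantage (PLA) with a subjective-value softmax policy for the
#' value-guided stage and a log-linear response-time model. The leave policy
#' is a logistic threshold, `P(leave) = logistic((PLA - theta_leave) /
#' sigma_leave)` — a minimal monotone stochastic rule that makes the mean
#' PLA at leave trials a meaningful recoverable quantity. It is a generative
#' stand-in for behaviour, not a fitted process model.
#'
#' Default response-time coefficients point in the directions and at the
#' magnitudes typical of this task (slower on leave trials, after rewards
#' and after side changes; faster with practice and with larger value
#' differences); all are per z-unit of the corresponding design variable,
#' on the log-seconds scale.
#'
#' @param theta_leave PLA threshold (points) at which leaving becomes
#'   equiprobable.
#' @param sigma_leave Logistic noise scale (points) of the leave policy.
#' @param alpha,gamma Utility and probability-weighting curvature of the
#'   agent's subjective-value model (`SU` multiplicative family).
#' @param omega_mult Value-difference scale (softmax inverse temperature).
#' @param rt_patch_betas Named coefficients for the patch-stage RT model:
#'   `intercept, pvd_prev, switch, cost, trial, side_change, prev_reward`.
#' @param rt_value_betas Named coefficients for the value-stage RT model:
#'   `intercept, ev_diff, ev_sum, pvd, cost, prev_choice, patch_side,
#'   prev_reward, no_brainer, trial, switch`.
#' @param rt_noise_sd SD of the log-RT noise (log-seconds).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(theta_leave = 30, sigma_leave = 8,
                         alpha = 0.8, gamma = 0.9, omega_mult = 6.62,
                         rt_patch_betas = c(intercept = log(0.8),
                                            pvd_prev = 0, switch = 0.09,
                                            cost = 0.03, trial = -0.25,
                                            side_change = 0.05,
                                            prev_reward = 0.05),
                         rt_value_betas = c(intercept = log(1.2),
                                            ev_diff = -0.20, ev_sum = 0,
                                            pvd = -0.12, cost = 0,
                                            prev_choice = 0,
                                            patch_side = 0.02,
                                            prev_reward = 0,
                                            no_brainer = -0.32,
                                            trial = -0.21, switch = 0.05),
                         rt_noise_sd = 0.3) {
  stopifnot(sigma_leave > 0, rt_noise_sd > 0, alpha > 0, gamma > 0)
  structure(list(theta_leave = theta_leave, sigma_leave = sigma_leave,
                 alpha = alpha, gamma = gamma, omega_mult = omega_mult,
                 rt_patch_betas = rt_patch_betas,
                 rt_value_betas = rt_value_betas,
                 rt_noise_sd = rt_noise_sd),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat("Agent: theta_leave =", x$theta_leave, "(sigma =", x$sigma_leave,
      "), alpha =", x$alpha, ", gamma =", x$gamma,
      ", omega_mult =", x$omega_mult, "\n")
  invisible(x)
}

#' Stochastic stay/leave policy
#'
#' @param pla Patch-leaving advantage (points): previous-trial value of the
#'   alternative minus the current patch, minus the displayed cost.
#' @param agent An [agent_params()] object.
#' @return `"stay"` or `"leave"`.
#' @export
patch_policy <- function(pla, agent) {
  p_leave <- stats::plogis((pla - agent$theta_leave) / agent$sigma_leave)
  if (stats::runif(1) < p_leave) "leave" else "stay"
}

# default threshold/noise chosen so a default cohort reproduces the
# observed behavioural regime (about 20 leaves per 320-trial session at a
# mean patch-leaving advantage near 19 points)

# fixed generation-side magnitude scale: the full band of magnitudes the
# task can produce (10% to 90% of the value clamp interval)
generation_magnitude_range <- function(params = patch_dynamics_params()) {
  c(ceiling(0.1 * params$value_min), floor(0.9 * params$value_max))
}

#' Softmax value-choice policy
#'
#' Option values are computed under the agent's `SU` multiplicative model
#' (curvatures `alpha`, `gamma`, scale `omega_mult`) on magnitudes mapped to
#' the `[1, 10]` fitting range via the fixed task-wide magnitude band, and
#' the choice is drawn from the softmax probability.
#'
#' @param options An `option_pair`.
#' @param agent An [agent_params()] object.
#' @return `"left"` or `"right"`.
#' @export
value_policy <- function(options, agent) {
  spec <- value_model_spec("multiplicative", "SU",
                           fixed = list(omega_mult = agent$omega_mult),
                           n_starts = 1L)
  pars <- list(alpha = agent$alpha, gamma = agent$gamma,
               omega_mult = agent$omega_mult)
  r <- generation_magnitude_range()
  vl <- option_value(rescale_magnitudes(options$m_left, r), options$p_left,
                     pars, spec)
  vr <- option_value(rescale_magnitudes(options$m_right, r), options$p_right,
                     pars, spec)
  if (stats::runif(1) < choice_probability(vl, vr)) "right" else "left"
}

#' Generate log-normal response times for a session
#'
#' `log RT = intercept + sum(beta_k * z_k) + Normal(0, rt_noise_sd^2)`,
#' where the `z_k` are the same z-scored design variables the analysis
#' stage regresses response times on (see [build_design_matrix()]). Design
#' variables that are constant within the session contribute nothing.
#' First-trial regressors that reference the previous trial are taken as
#' zero after z-scoring.
#'
#' @param trials A session table (response-time columns may be `NA`).
#' @param stage `"patch"` or `"value"`.
#' @param agent An [agent_params()] object.
#' @return Numeric vector of response times in seconds, one per trial.
#' @export
generate_response_times <- function(trials, stage = c("patch", "value"),
                                    agent) {
  stage <- match.arg(stage)
  n <- nrow(trials)
  vars <- rt_design_variables(trials, stage)
  betas <- if (stage == "patch") agent$rt_patch_betas else agent$rt_value_betas
  lin <- rep(betas[["intercept"]], n)
  for (nm in names(vars)) {
    b <- betas[[nm]]
    if (is.null(b) || b == 0) next
    lin <- lin + b * zscore_or_zero(vars[[nm]])
  }
  exp(lin + stats::rnorm(n, 0, agent$rt_noise_sd))
}

# raw (un-z-scored) RT design variables; previous-trial references are 0 on
# the first trial
rt_design_variables <- function(trials, stage) {
  n <- nrow(trials)
  prev0 <- function(x) c(0, x[-n])
  if (stage == "patch") {
    list(
      pvd_prev = prev0(trials$val_alt - trials$val_cur),
      switch = as.numeric(trials$switch),
      cost = trials$cost,
      trial = trials$trial,
      side_change = as.numeric(trials$side_cur != prev0(trials$side_cur)),
      prev_reward = prev0(as.numeric(trials$reward > 0))
    )
  } else {
    ev_l <- trials$m_left * trials$p_left
    ev_r <- trials$m_right * trials$p_right
    list(
      ev_diff = abs(ev_r - ev_l),
      ev_sum = ev_r + ev_l,
      pvd = trials$val_alt - trials$val_cur,
      cost = trials$cost,
      prev_choice = prev0(as.numeric(trials$value_choice == "right")),
      patch_side = as.numeric(trials$side_cur == "right"),
      prev_reward = prev0(as.numeric(trials$reward > 0)),
      no_brainer = as.numeric(trials$no_brainer != "none"),
      trial = trials$trial,
      switch = as.numeric(trials$switch)
    )
  }
}

#' Specification of a synthetic cohort
#'
#' Describes a cohort of agents together with five-region neurochemistry:
#' per-region E/I means and SDs, and a set of planted cross-subject
#' correlations between regional E/I balance and agent parameters. Planted
#' targets may be agent parameters (`theta_leave`, `alpha`, `gamma`,
#' `cost_rt_beta`, `vdiff_rt_beta`) — which shape the agents themselves —
#' or any other label, in which case the correlated latent variable is
#' returned as a column of the cohort's `latents` table (useful for
#' calibration and power studies on the inference layer alone).
#'
#' @param n_participants Cohort size.
#' @param regions Region names (five MRS voxel sites).
#' @param ei_means,ei_sds Per-region E/I ratio mean and SD (glutamate/GABA
#'   after creatine and grey-matter normalization).
#' @param planted_effects Data frame with columns `region`, `target`, `r`.
#' @param agent_base An [agent_params()] object giving the cohort means of
#'   un-planted agent parameters.
#' @param agent_sds Named numeric vector of cross-subject SDs for
#'   `theta_leave`, `alpha`, `gamma`, `cost_rt_beta`, `vdiff_rt_beta`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 29L,
                        regions = c("dACC", "vmPFC", "dlPFC", "lM1", "rM1"),
                        ei_means = c(dACC = 4.5, vmPFC = 4.2, dlPFC = 4.0,
                                     lM1 = 3.8, rM1 = 3.8),
                        ei_sds = c(dACC = 0.55, vmPFC = 0.5, dlPFC = 0.5,
                                   lM1 = 0.45, rM1 = 0.45),
                        planted_effects = data.frame(
                          region = c("dACC", "vmPFC"),
                          target = c("theta_leave", "alpha"),
                          r = c(0.5, -0.46)),
                        agent_base = agent_params(),
                        agent_sds = c(theta_leave = 10, alpha = 0.2,
                                      gamma = 0.25, cost_rt_beta = 0.04,
                                      vdiff_rt_beta = 0.08)) {
  stopifnot(n_participants >= 2, length(regions) == length(ei_means),
            length(regions) == length(ei_sds))
  if (nrow(planted_effects) > 0) {
    stopifnot(all(planted_effects$region %in% regions),
              all(abs(planted_effects$r) < 1))
  }
  structure(list(n_participants = as.integer(n_participants),
                 regions = regions,
                 ei_means = stats::setNames(ei_means, regions),
                 ei_sds = stats::setNames(ei_sds, regions),
                 planted_effects = planted_effects,
                 agent_base = agent_base, agent_sds = agent_sds),
            class = "cohort_spec")
}

# latent correlation matrix over [regions ; planted targets]
cohort_latent_corr <- function(spec) {
  targets <- unique(spec$planted_effects$target)
  d <- length(spec$regions) + length(targets)
  nms <- c(spec$regions, targets)
  C <- diag(d)
  dimnames(C) <- list(nms, nms)
  for (i in seq_len(nrow(spec$planted_effects))) {
    pe <- spec$planted_effects[i, ]
    C[pe$region, pe$target] <- C[pe$target, pe$region] <- pe$r
  }
  C
}

#' Generate a synthetic cohort of agents with planted neurochemistry links
#'
#' Draws, per participant, a multivariate-normal latent vector over the five
#' regional E/I values and the planted targets, with the requested
#' correlation structure. Regional E/I is mapped to plausible absolute
#' GABA/glutamate/creatine concentrations and tissue fractions by fixing
#' creatine and tissue fractions near realistic constants and solving the
#' metabolite concentrations to reproduce the latent E/I after the full
#' normalization chain, so that the normalization arithmetic downstream is
#' exercised rather than bypassed. Quality metrics are drawn inside the
#' acceptance window so the synthetic cohort passes QC by construction.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A list with `agents` (list of [agent_params()]), `metabolites`
#'   (long data frame: `participant, region, GABA_abs, Glu_abs, Cr_abs,
#'   CRLB_GABA, CRLB_Glu, FWHM, SNR, GM_frac, WM_frac`), `latents`
#'   (data frame of the latent draws: planted targets on their natural
#'   scale plus the realized per-region E/I), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_participants
  C <- cohort_latent_corr(spec)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("planted correlation structure is not positive semi-definite",
         call. = FALSE)
  L <- chol(C + diag(1e-10, nrow(C)))
  Z <- matrix(stats::rnorm(n * nrow(C)), n) %*% L
  colnames(Z) <- colnames(C)

  regions <- spec$regions
  ei <- sweep(sweep(Z[, regions, drop = FALSE], 2, spec$ei_sds, "*"),
              2, spec$ei_means, "+")
  ei <- pmax(ei, 0.5)  # keep ratios physical

  targets <- setdiff(colnames(C), regions)
  base <- spec$agent_base
  agent_mean <- c(theta_leave = base$theta_leave, alpha = base$alpha,
                  gamma = base$gamma,
                  cost_rt_beta = unname(base$rt_patch_betas[["cost"]]),
                  vdiff_rt_beta = unname(base$rt_value_betas[["ev_diff"]]))
  draw_param <- function(nm) {
    z <- if (nm %in% targets) Z[, nm] else stats::rnorm(n)
    agent_mean[[nm]] + spec$agent_sds[[nm]] * z
  }
  theta <- draw_param("theta_leave")
  alpha <- pmax(draw_param("alpha"), 0.1)
  gamma <- pmax(draw_param("gamma"), 0.1)
  cost_b <- draw_param("cost_rt_beta")
  vdiff_b <- draw_param("vdiff_rt_beta")

  agents <- lapply(seq_len(n), function(i) {
    a <- base
    a$theta_leave <- theta[i]
    a$alpha <- alpha[i]
    a$gamma <- gamma[i]
    a$rt_patch_betas[["cost"]] <- cost_b[i]
    a$rt_value_betas[["ev_diff"]] <- vdiff_b[i]
    a
  })

  # invert the normalization chain: EI = Glu_norm / GABA_norm reduces to
  # Glu_abs / GABA_abs, but all intermediate quantities are produced so the
  # full arithmetic path is exercised
  nr <- length(regions)
  met <- do.call(rbind, lapply(seq_len(n), function(i) {
    gm <- stats::runif(nr, 0.55, 0.70)
    wm <- stats::runif(nr, 0.20, 0.30)
    cr <- stats::rnorm(nr, 8, 0.4)
    gaba_norm <- stats::rnorm(nr, 0.28, 0.02)   # creatine-normalized GABA
    cr_norm <- cr / (gm + wm)
    gaba_abs <- gaba_norm * cr_norm * gm
    glu_abs <- ei[i, ] * gaba_abs
    data.frame(participant = i, region = regions,
               GABA_abs = gaba_abs, Glu_abs = as.numeric(glu_abs),
               Cr_abs = cr,
               CRLB_GABA = stats::runif(nr, 5, 15),
               CRLB_Glu = stats::runif(nr, 3, 10),
               FWHM = stats::runif(nr, 8, 18),
               SNR = stats::runif(nr, 12, 35),
               GM_frac = gm, WM_frac = wm,
               stringsAsFactors = FALSE)
  }))
  rownames(met) <- NULL

  latents <- data.frame(participant = seq_len(n), theta_leave = theta,
                        alpha = alpha, gamma = gamma,
                        cost_rt_beta = cost_b, vdiff_rt_beta = vdiff_b)
  for (tg in setdiff(targets, names(agent_mean))) latents[[tg]] <- Z[, tg]
  for (rg in regions) latents[[paste0("ei_", rg)]] <- ei[, rg]

  list(agents = agents, metabolites = met, latents = latents, spec = spec)
}
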