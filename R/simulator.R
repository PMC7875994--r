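#' Parameters of the patch reward dynamics
#'
#' The two patches carry latent means that diffuse as a decaying Gaussian
#' random walk, `mu[t+1] = lambda * mu[t] + (1 - lambda) * kappa + eps`,
#' where the decay centre `kappa` is low for the currently occupied patch
#' (it depletes) and high for the alternative (it replenishes), and
#' `eps ~ Normal(0, mean_noise_sd^2)`. The values shown to the agent are
#' Gaussian draws around these means, clamped to `[value_min, value_max]`
#' and rounded to integer points. The latent mean recursion itself is never
#' clamped; only sampled values are, which keeps the fixed-point behaviour
#' of the recursion exact and testable.
#'
#' @param lambda_decay Decay rate in (0,1).
#' @param kappa_chosen Decay centre (points) of the occupied patch.
#' @param kappa_unchosen Decay centre (points) of the alternative patch.
#' @param mean_noise_sd SD (points) of the mean-diffusion noise.
#' @param value_variance Variance (points^2) of the value draw around the mean.
#' @param value_min,value_max Clamp interval (points) for sampled values.
#' @param initial_mean Starting mean (points) of both patches.
#' @param cost_set Set of possible travel costs (points).
#' @param n_trials Number of trials in a session.
#' @return An object of class `patch_dynamics_params`.
#' @examples
#' p <- patch_dynamics_params()
#' p$lambda_decay
#' @export
patch_dynamics_params <- function(lambda_decay = 0.96,
                                  kappa_chosen = 1,
                                  kappa_unchosen = 100,
                                  mean_noise_sd = 1.2,
                                  value_variance = 3.5,
                                  value_min = 10,
                                  value_max = 90,
                                  initial_mean = 50,
                                  cost_set = c(5, 10, 15, 20),
                                  n_trials = 320L) {
  p <- list(lambda_decay = lambda_decay, kappa_chosen = kappa_chosen,
            kappa_unchosen = kappa_unchosen, mean_noise_sd = mean_noise_sd,
            value_variance = value_variance, value_min = value_min,
            value_max = value_max, initial_mean = initial_mean,
            cost_set = cost_set, n_trials = as.integer(n_trials))
  validate_patch_params(p)
  structure(p, class = "patch_dynamics_params")
}

validate_patch_params <- function(p) {
  stopifnot(
    is.numeric(p$lambda_decay), p$lambda_decay > 0, p$lambda_decay < 1,
    p$mean_noise_sd >= 0, p$value_variance >= 0,
    p$value_min < p$value_max,
    all(p$cost_set > 0), length(p$cost_set) >= 1,
    p$n_trials >= 1
  )
  invisible(p)
}

#' @export
print.patch_dynamics_params <- function(x, ...) {
  cat("Patch dynamics: mu[t+1] =", x$lambda_decay, "* mu[t] + (1 -",
      x$lambda_decay, ") * kappa + eps\n")
  cat("  kappa (occupied / alternative):", x$kappa_chosen, "/",
      x$kappa_unchosen, "\n")
  cat("  noise SD:", x$mean_noise_sd, " value variance:", x$value_variance, "\n")
  cat("  values clamped to [", x$value_min, ",", x$value_max, "], costs {",
      paste(x$cost_set, collapse = ", "), "},", x$n_trials, "trials\n")
  invisible(x)
}

#' One step of the decaying Gaussian random walk on patch means
#'
#' Applies the mean recursion to both patches, with the low decay centre for
#' the currently occupied patch and the high one for the alternative. Noise
#' is drawn independently per patch. The recursion is not clamped.
#'
#' @param mu_current,mu_alternative Latent means (points).
#' @param params A [patch_dynamics_params()] object.
#' @return Named numeric vector `c(current = ..., alternative = ...)`.
#' @examples
#' p <- patch_dynamics_params(mean_noise_sd = 0)
#' update_patch_means(50, 50, p)  # 48.04, 52.0
#' @export
update_patch_means <- function(mu_current, mu_alternative, params) {
  validate_patch_params(params)
  if (!is.finite(mu_current) || !is.finite(mu_alternative))
    stop("non-finite patch mean", call. = FALSE)
  eps <- stats::rnorm(2, 0, params$mean_noise_sd)
  lam <- params$lambda_decay
  c(current = lam * mu_current + (1 - lam) * params$kappa_chosen + eps[1L],
    alternative = lam * mu_alternative + (1 - lam) * params$kappa_unchosen + eps[2L])
}

#' Sample displayed patch values around the latent means
#'
#' Values are Gaussian draws with variance `value_variance`, clamped into
#' `[value_min, value_max]` and rounded to integer points.
#'
#' @inheritParams update_patch_means
#' @return Named integer-valued vector `c(current = ..., alternative = ...)`.
#' @export
sample_patch_values <- function(mu_current, mu_alternative, params) {
  validate_patch_params(params)
  if (!is.finite(mu_current) || !is.finite(mu_alternative))
    stop("non-finite patch mean", call. = FALSE)
  v <- stats::rnorm(2, c(mu_current, mu_alternative),
                    sqrt(params$value_variance))
  v <- pmin(pmax(v, params$value_min), params$value_max)
  v <- round(v)
  c(current = v[1L], alternative = v[2L])
}

#' Travel cost for the current trial
#'
#' The cost stays constant across trials and is redrawn uniformly from the
#' cost set only after a leave decision (and on the first trial).
#'
#' @param previous_cost Cost (points) displayed on the previous trial, or
#'   `NA` on the first trial.
#' @param previous_was_leave Logical; did the previous trial end in a leave?
#' @param params A [patch_dynamics_params()] object.
#' @return A cost from `params$cost_set`.
#' @export
draw_cost <- function(previous_cost, previous_was_leave, params) {
  validate_patch_params(params)
  if (is.na(previous_cost)) previous_was_leave <- TRUE
  if (!previous_was_leave) {
    if (!previous_cost %in% params$cost_set)
      stop("previous cost not in cost set", call. = FALSE)
    return(previous_cost)
  }
  params$cost_set[sample.int(length(params$cost_set), 1L)]
}

#' Split the chosen patch value into a pair of risky options
#'
#' The patch value is allocated to two options at a random ratio such that
#' neither option receives less than 10% of the total and an exact 50/50
#' split is excluded. The left share is drawn uniformly from the integer set
#' `{ceiling(0.1 V), ..., floor(0.9 V)} \ {V/2}`. Each option independently
#' receives a reward probability from `{0.1, 0.2, ..., 0.9}`.
#'
#' @param patch_value Total points available (integer).
#' @return An object of class `option_pair`: fields `m_left`, `m_right`,
#'   `p_left`, `p_right`, `no_brainer` (`"left"`, `"right"` or `"none"`),
#'   `flipped`.
#' @export
generate_options <- function(patch_value) {
  stopifnot(is.finite(patch_value), patch_value == round(patch_value))
  lo <- ceiling(0.1 * patch_value)
  hi <- floor(0.9 * patch_value)
  if (hi < lo)
    stop("patch value ", patch_value,
         " too small for a split with both options >= 10% of the total",
         call. = FALSE)
  cand <- seq.int(lo, hi)
  if (patch_value %% 2 == 0) cand <- cand[cand != patch_value / 2]
  if (length(cand) == 0L)
    stop("patch value ", patch_value,
         " admits only a 50% split, which is excluded", call. = FALSE)
  m_left <- cand[sample.int(length(cand), 1L)]
  pset <- seq(0.1, 0.9, by = 0.1)
  p <- pset[sample.int(9L, 2L, replace = TRUE)]
  opt <- structure(list(m_left = m_left, m_right = patch_value - m_left,
                        p_left = p[1L], p_right = p[2L],
                        no_brainer = "none", flipped = FALSE),
                   class = "option_pair")
  opt$no_brainer <- detect_no_brainer(opt)
  opt
}

#' Detect a dominating ("no-brainer") option
#'
#' An option is a no-brainer when it strictly dominates the other on both
#' reward magnitude and reward probability. Ties on either attribute mean no
#' option dominates.
#'
#' @param options An `option_pair`.
#' @return `"left"`, `"right"`, or `"none"`.
#' @export
detect_no_brainer <- function(options) {
  if (options$m_left > options$m_right && options$p_left > options$p_right)
    return("left")
  if (options$m_right > options$m_left && options$p_right > options$p_left)
    return("right")
  "none"
}

#' Magnitude flip applied to no-brainer trials
#'
#' To control difficulty, the reward magnitudes of a dominated option pair
#' are swapped in 50% of no-brainer trials. The original experiment code
#' contained an error by which only no-brainers favouring the *left* option
#' were eligible for the flip, which made right-favouring no-brainers (and
#' higher right expected values) systematically more frequent. That
#' asymmetry is reproduced by default and can be switched off.
#'
#' @param options An `option_pair` with `no_brainer` evaluated.
#' @param replicate_side_bias_bug If `TRUE` (default) only left-favouring
#'   no-brainers are flip-eligible; if `FALSE`, both sides are.
#' @return The (possibly flipped) `option_pair`, with `no_brainer`
#'   re-evaluated and `flipped` set.
#' @export
apply_flip_rule <- function(options, replicate_side_bias_bug = TRUE) {
  nb <- options$no_brainer
  eligible <- if (replicate_side_bias_bug) nb == "left"
              else nb %in% c("left", "right")
  if (eligible && stats::runif(1) < 0.5) {
    m <- options$m_left
    options$m_left <- options$m_right
    options$m_right <- m
    options$flipped <- TRUE
    options$no_brainer <- detect_no_brainer(options)
  }
  options
}

#' Simulate one session of the two-stage task
#'
#' Runs the full trial loop: cost display, patch choice (stay/leave),
#' cost redraw after a leave, mean diffusion and value reveal, option
#' generation from the chosen patch's value, value-guided choice, and
#' independent Bernoulli outcomes for both options. Presentation sides are
#' randomized per trial. Response times for both stages are generated in a
#' post-pass from the session's z-scored design variables (see
#' [generate_response_times()]).
#'
#' @param agent An [agent_params()] object supplying the stay/leave and
#'   value-choice policies.
#' @param params A [patch_dynamics_params()] object.
#' @param seed Optional integer seed for the session.
#' @param replicate_side_bias_bug Passed to [apply_flip_rule()].
#' @return A `data.frame` with one row per trial and columns
#'   `trial, cost, mu_cur, mu_alt, val_cur, val_alt, side_cur, patch_choice,
#'   switch, m_left, m_right, p_left, p_right, no_brainer, flipped,
#'   value_choice, rew_left, rew_right, reward, rt_patch, rt_value`,
#'   carrying attribute `schema_version`.
#' @examples
#' s <- simulate_session(agent_params(), patch_dynamics_params(n_trials = 20),
#'                       seed = 1)
#' nrow(s)
#' @export
simulate_session <- function(agent, params = patch_dynamics_params(),
                             seed = NULL, replicate_side_bias_bug = TRUE) {
  stopifnot(inherits(agent, "agent_params"))
  validate_patch_params(params)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_trials

  trial <- seq_len(n)
  cost <- mu_cur <- mu_alt <- val_cur <- val_alt <- numeric(n)
  m_left <- m_right <- p_left <- p_right <- numeric(n)
  rew_left <- rew_right <- reward <- numeric(n)
  side_cur <- patch_choice <- no_brainer <- value_choice <- character(n)
  switch_tr <- flipped <- logical(n)

  mu_c <- params$initial_mean
  mu_a <- params$initial_mean
  prev_val_c <- params$initial_mean
  prev_val_a <- params$initial_mean
  prev_cost <- NA_real_
  prev_leave <- TRUE

  for (t in trial) {
    cost[t] <- draw_cost(prev_cost, prev_leave, params)
    pla <- (prev_val_a - prev_val_c) - cost[t]
    choice <- patch_policy(pla, agent)
    if (!choice %in% c("stay", "leave"))
      stop("agent returned an illegal patch action at trial ", t, call. = FALSE)
    patch_choice[t] <- choice
    switch_tr[t] <- choice == "leave"
    if (switch_tr[t]) {        # occupancy swaps before the mean update
      tmp <- mu_c; mu_c <- mu_a; mu_a <- tmp
    }
    mu <- update_patch_means(mu_c, mu_a, params)
    mu_c <- mu[["current"]]; mu_a <- mu[["alternative"]]
    v <- sample_patch_values(mu_c, mu_a, params)
    mu_cur[t] <- mu_c; mu_alt[t] <- mu_a
    val_cur[t] <- v[["current"]]; val_alt[t] <- v[["alternative"]]
    side_cur[t] <- c("left", "right")[sample.int(2L, 1L)]

    opt <- apply_flip_rule(generate_options(val_cur[t]),
                           replicate_side_bias_bug)
    m_left[t] <- opt$m_left; m_right[t] <- opt$m_right
    p_left[t] <- opt$p_left; p_right[t] <- opt$p_right
    no_brainer[t] <- opt$no_brainer; flipped[t] <- opt$flipped

    vc <- value_policy(opt, agent)
    if (!vc %in% c("left", "right"))
      stop("agent returned an illegal value action at trial ", t, call. = FALSE)
    value_choice[t] <- vc
    # outcomes are independent across options
    rl <- stats::runif(1) < opt$p_left
    rr <- stats::runif(1) < opt$p_right
    rew_left[t] <- if (rl) opt$m_left else 0
    rew_right[t] <- if (rr) opt$m_right else 0
    reward[t] <- if (vc == "left") rew_left[t] else rew_right[t]

    prev_val_c <- val_cur[t]; prev_val_a <- val_alt[t]
    prev_cost <- cost[t]; prev_leave <- switch_tr[t]
  }

  trials <- data.frame(
    trial = trial, cost = cost, mu_cur = mu_cur, mu_alt = mu_alt,
    val_cur = val_cur, val_alt = val_alt, side_cur = side_cur,
    patch_choice = patch_choice, switch = switch_tr,
    m_left = m_left, m_right = m_right, p_left = p_left, p_right = p_right,
    no_brainer = no_brainer, flipped = flipped, value_choice = value_choice,
    rew_left = rew_left, rew_right = rew_right, reward = reward,
    rt_patch = NA_real_, rt_value = NA_real_,
    stringsAsFactors = FALSE
  )
  trials$rt_patch <- generate_response_times(trials, "patch", agent)
  trials$rt_value <- generate_response_times(trials, "value", agent)
  attr(trials, "schema_version") <- trials_schema_version()
  trials
}
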