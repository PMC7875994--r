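#' Rescale reward magnitudes to the unit fitting range
#'
#' Before fitting, reward magnitudes are linearly mapped so that the
#' smallest observed magnitude becomes 1 and the largest becomes 10. The
#' default scope is per participant (each participant's own min/max define
#' the map); a fixed global range can be supplied instead so that agents
#' simulated on different sessions share a common magnitude scale.
#'
#' @param magnitudes Numeric vector of magnitudes (points).
#' @param range Optional length-2 vector giving the raw range to map from;
#'   defaults to `range(magnitudes)`.
#' @return Numeric vector in `[1, 10]`.
#' @examples
#' rescale_magnitudes(c(10, 50, 90))  # 1, 5.5, 10
#' @export
rescale_magnitudes <- function(magnitudes, range = NULL) {
  stopifnot(length(magnitudes) > 0, all(is.finite(magnitudes)))
  r <- range %||% range(magnitudes)
  if (diff(r) <= 0)
    stop("cannot rescale a constant magnitude vector", call. = FALSE)
  out <- 1 + 9 * (magnitudes - r[1L]) / (r[2L] - r[1L])
  pmin(pmax(out, 1), 10)
}

#' Probability weighting function
#'
#' `w(p) = p^gamma / (p^gamma + (1-p)^gamma)^(1/gamma)`. With `gamma = 1`
#' this is the identity; `gamma < 1` gives the classic inverse-S distortion
#' (overweighting small, underweighting large probabilities).
#'
#' @param p Probabilities in `[0, 1]`.
#' @param gamma Curvature parameter, `> 0`.
#' @return Weighted probabilities in `[0, 1]`.
#' @export
weight_probability <- function(p, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("gamma must be a positive scalar", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1))
  pg <- p^gamma
  pg / (pg + (1 - p)^gamma)^(1 / gamma)
}

#' Utility (subjective magnitude) function
#'
#' Power-law curvature over rescaled magnitudes: `u(m) = m^alpha`.
#'
#' @param m Non-negative magnitudes (on the rescaled `[1, 10]` range).
#' @param alpha Curvature exponent.
#' @return `m^alpha`.
#' @export
utility <- function(m, alpha) {
  stopifnot(all(m >= 0))
  m^alpha
}

#' Specification of a subjective-value choice model
#'
#' Three families combine subjective magnitude `u(m)` and weighted
#' probability `w(p)`:
#' * `multiplicative`: `V = omega_mult * u(m) * w(p)`
#' * `additive`: `V = omega_m * u(m) + omega_p * w(p)`
#' * `hybrid`: a convex mixture of the normalized additive and the
#'   multiplicative value, scaled by `omega_sum = omega_m + omega_p +
#'   omega_mult`.
#'
#' The distortion variant controls which curvature parameters are free:
#' `EV` fixes `alpha = gamma = 1` (objective values); `EU` frees `alpha`
#' only; `EVPW` frees `gamma` only; `SU` frees both. Additional parameters
#' may be fixed via `fixed` — the headline model of this package is the
#' `SU` multiplicative family with `omega_mult` fixed at 6.62, leaving
#' exactly `alpha` and `gamma` free.
#'
#' @param family `"multiplicative"`, `"additive"` or `"hybrid"`.
#' @param distortion `"SU"`, `"EU"`, `"EVPW"` or `"EV"`.
#' @param fixed Named list of parameters to fix (e.g.
#'   `list(omega_mult = 6.62)`).
#' @param bounds Named list of length-2 lower/upper bounds for free
#'   parameters; defaults: `alpha`, `gamma` in `[0.05, 5]`, weights in
#'   `[0, 50]`.
#' @param n_starts Number of random starting points for the multi-start fit.
#' @return An object of class `value_model_spec` with elements `family`,
#'   `distortion`, `free` (names), `fixed`, `bounds`, `n_starts`, `label`.
#' @export
value_model_spec <- function(family = c("multiplicative", "additive", "hybrid"),
                             distortion = c("SU", "EU", "EVPW", "EV"),
                             fixed = list(),
                             bounds = NULL,
                             n_starts = 1000L) {
  family <- match.arg(family)
  distortion <- match.arg(distortion)
  stopifnot(n_starts >= 1)

  pars <- switch(family,
                 multiplicative = "omega_mult",
                 additive = c("omega_m", "omega_p"),
                 hybrid = c("omega_m", "omega_p", "omega_mult"))
  pars <- c("alpha", "gamma", pars)

  fixed_all <- list()
  if (distortion %in% c("EV", "EVPW")) fixed_all$alpha <- 1
  if (distortion %in% c("EV", "EU")) fixed_all$gamma <- 1
  for (nm in names(fixed)) {
    if (!nm %in% pars)
      stop("fixed parameter '", nm, "' not in the ", family, " family",
           call. = FALSE)
    fixed_all[[nm]] <- fixed[[nm]]
  }
  free <- setdiff(pars, names(fixed_all))

  default_bounds <- list(alpha = c(0.05, 5), gamma = c(0.05, 5),
                         omega_m = c(0, 50), omega_p = c(0, 50),
                         omega_mult = c(0, 50))
  b <- default_bounds
  for (nm in names(bounds)) b[[nm]] <- bounds[[nm]]

  structure(list(family = family, distortion = distortion,
                 free = free, fixed = fixed_all,
                 bounds = b[free], n_starts = as.integer(n_starts),
                 label = paste0(distortion, "-", family,
                                if (length(fixed)) "-fixed" else "")),
            class = "value_model_spec")
}

#' @export
print.value_model_spec <- function(x, ...) {
  cat("Value model:", x$label, "\n")
  cat("  free:", if (length(x$free)) paste(x$free, collapse = ", ") else "none", "\n")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                          collapse = ", "), "\n")
  invisible(x)
}

full_params <- function(theta, spec) {
  p <- as.list(theta)
  names(p) <- spec$free
  c(p, spec$fixed)
}

#' Subjective value of an option under a model specification
#'
#' @param m Rescaled magnitudes (in `[1, 10]`).
#' @param p Reward probabilities.
#' @param params Named list/vector with the parameters the family needs
#'   (`alpha`, `gamma`, and the relevant `omega`s).
#' @param spec A [value_model_spec()].
#' @return Numeric vector of option values.
#' @export
option_value <- function(m, p, params, spec) {
  params <- as.list(params)
  u <- utility(m, params$alpha)
  w <- weight_probability(p, params$gamma)
  switch(spec$family,
    multiplicative = params$omega_mult * u * w,
    additive = params$omega_m * u + params$omega_p * w,
    hybrid = {
      om <- params$omega_m; op <- params$omega_p; ox <- params$omega_mult
      if (om + op == 0)
        stop("hybrid model undefined when omega_m + omega_p = 0",
             call. = FALSE)
      osum <- om + op + ox
      mix <- ox / osum
      osum * ((1 - mix) * ((om / (om + op)) * u + (op / (om + op)) * w) +
              mix * (u * w))
    })
}

#' Softmax choice probability for the right option
#'
#' Unit-temperature logistic on the value difference; the scale of the
#' `omega` parameters plays the role of an inverse temperature. Evaluated
#' overflow-safely via `plogis`.
#'
#' @param v_left,v_right Option values.
#' @return `P(choose right)`.
#' @export
choice_probability <- function(v_left, v_right) {
  stopifnot(all(is.finite(v_left)), all(is.finite(v_right)))
  stats::plogis(v_right - v_left)
}

# canonical fitting frame: rescaled magnitudes + probabilities + 0/1 choice
prepare_fit_data <- function(trials, rescale_range = NULL) {
  stopifnot(all(c("m_left", "m_right", "p_left", "p_right",
                  "value_choice") %in% names(trials)))
  if (nrow(trials) == 0L) stop("empty trial set", call. = FALSE)
  r <- rescale_range %||% range(c(trials$m_left, trials$m_right))
  data.frame(
    m_left = rescale_magnitudes(trials$m_left, r),
    m_right = rescale_magnitudes(trials$m_right, r),
    p_left = trials$p_left, p_right = trials$p_right,
    choice_right = as.numeric(trials$value_choice == "right")
  )
}

#' Negative log-likelihood of observed value choices
#'
#' `-sum(log P(observed choice))` under the softmax rule, with per-trial
#' probabilities floored at 1e-12 to keep the objective finite at extreme
#' parameter values.
#'
#' @param trials Data frame with columns `m_left`, `m_right` (rescaled),
#'   `p_left`, `p_right`, `choice_right` (0/1) — as produced internally from
#'   a session table — or a raw session table (then magnitudes are rescaled
#'   first).
#' @param params Named parameter list (see [option_value()]).
#' @param spec A [value_model_spec()].
#' @return The scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(trials, params, spec) {
  if (!"choice_right" %in% names(trials)) trials <- prepare_fit_data(trials)
  if (nrow(trials) == 0L) stop("empty trial set", call. = FALSE)
  vl <- option_value(trials$m_left, trials$p_left, params, spec)
  vr <- option_value(trials$m_right, trials$p_right, params, spec)
  pr <- choice_probability(vl, vr)
  pobs <- ifelse(trials$choice_right == 1, pr, 1 - pr)
  -sum(log(pmax(pobs, 1e-12)))
}

# fast likelihood closure used inside the optimizer: precomputes the data
# vectors once and avoids per-evaluation validation (the box bounds already
# guarantee legal curvature parameters)
make_nll_objective <- function(dat, spec) {
  ml <- dat$m_left; mr <- dat$m_right
  pl <- dat$p_left; pr <- dat$p_right
  right <- dat$choice_right == 1
  family <- spec$family
  free <- spec$free
  fixed <- spec$fixed
  function(theta) {
    p <- fixed
    p[free] <- theta
    wl <- { pg <- pl^p$gamma; pg / (pg + (1 - pl)^p$gamma)^(1 / p$gamma) }
    wr <- { pg <- pr^p$gamma; pg / (pg + (1 - pr)^p$gamma)^(1 / p$gamma) }
    ul <- ml^p$alpha; ur <- mr^p$alpha
    if (family == "multiplicative") {
      vl <- p$omega_mult * ul * wl; vr <- p$omega_mult * ur * wr
    } else if (family == "additive") {
      vl <- p$omega_m * ul + p$omega_p * wl
      vr <- p$omega_m * ur + p$omega_p * wr
    } else {
      om <- p$omega_m; op <- p$omega_p; ox <- p$omega_mult
      if (om + op <= 0) return(1e10)
      osum <- om + op + ox; mix <- ox / osum
      vl <- osum * ((1 - mix) * ((om * ul + op * wl) / (om + op)) +
                      mix * ul * wl)
      vr <- osum * ((1 - mix) * ((om * ur + op * wr) / (om + op)) +
                      mix * ur * wr)
    }
    pright <- stats::plogis(vr - vl)
    pobs <- ifelse(right, pright, 1 - pright)
    v <- -sum(log(pmax(pobs, 1e-12)))
    if (!is.finite(v)) 1e10 else v
  }
}

#' Fit a value model by constrained multi-start maximum likelihood
#'
#' Draws `spec$n_starts` starting points uniformly within the parameter
#' bounds and runs a constrained quasi-Newton (`L-BFGS-B`) minimisation of
#' the negative log-likelihood from each; the lowest-NLL solution wins.
#' Deterministic given `seed`.
#'
#' @param trials Session table (or prepared fitting frame).
#' @param spec A [value_model_spec()].
#' @param seed Integer seed for the start draws.
#' @param rescale_range Optional fixed magnitude range for rescaling.
#' @return An object of class `value_fit`: `params` (free + fixed), `nll`,
#'   `bic`, `k`, `n`, `per_start` (data frame of all starts), `convergence`,
#'   `spec`, `seed`.
#' @export
fit_value_model <- function(trials, spec, seed = 1L, rescale_range = NULL) {
  stopifnot(inherits(spec, "value_model_spec"))
  dat <- if ("choice_right" %in% names(trials)) trials
         else prepare_fit_data(trials, rescale_range)
  n <- nrow(dat)
  k <- length(spec$free)
  obj <- make_nll_objective(dat, spec)

  if (k == 0L) {
    nll <- obj(numeric(0))
    return(structure(list(params = spec$fixed, nll = nll,
                          bic = k * log(n) + 2 * nll, k = k, n = n,
                          per_start = data.frame(start = integer(0)),
                          convergence = 0L, spec = spec, seed = seed),
                     class = "value_fit"))
  }

  set.seed(seed)
  lower <- vapply(spec$bounds, `[`, numeric(1), 1L)
  upper <- vapply(spec$bounds, `[`, numeric(1), 2L)
  starts <- matrix(stats::runif(spec$n_starts * k, rep(lower, each = spec$n_starts),
                                rep(upper, each = spec$n_starts)),
                   nrow = spec$n_starts)
  res <- vector("list", spec$n_starts)
  for (i in seq_len(spec$n_starts)) {
    res[[i]] <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) list(par = starts[i, ], value = Inf,
                               convergence = 99L))
  }
  nlls <- vapply(res, function(r) r$value, numeric(1))
  conv <- vapply(res, function(r) r$convergence, numeric(1))
  if (all(!is.finite(nlls)))
    stop("all ", spec$n_starts, " starts failed to converge (",
         sum(conv == 99), " errored)", call. = FALSE)
  best <- which.min(nlls)
  theta <- res[[best]]$par
  names(theta) <- spec$free
  per_start <- data.frame(start = seq_len(spec$n_starts), nll = nlls,
                          convergence = conv)
  structure(list(params = c(as.list(theta), spec$fixed),
                 nll = nlls[best], bic = k * log(n) + 2 * nlls[best],
                 k = k, n = n, per_start = per_start,
                 convergence = conv[best], spec = spec, seed = seed),
            class = "value_fit")
}

#' @export
print.value_fit <- function(x, ...) {
  cat("Value model fit:", x$spec$label, "\n")
  cat("  NLL =", format(x$nll, digits = 6), " BIC =",
      format(x$bic, digits = 6), " (k =", x$k, ", n =", x$n, ")\n")
  cat("  params:", paste(names(x$params),
                         format(unlist(x$params), digits = 4),
                         sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Rank fitted models by BIC
#'
#' `BIC = k log(n) + 2 NLL`. Fits must come from the same trial set; ties
#' are broken toward the model with fewer free parameters.
#'
#' @param fits List of `value_fit` objects (optionally named).
#' @return List with `ranking` (data frame, ascending BIC) and `winner`
#'   (the winning fit).
#' @export
compare_models_bic <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "value_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop("fits computed on different trial counts: ",
         paste(unique(ns), collapse = ", "), call. = FALSE)
  labels <- names(fits) %||% vapply(fits, function(f) f$spec$label,
                                    character(1))
  if (is.null(names(fits))) names(fits) <- labels
  tab <- data.frame(model = labels,
                    k = vapply(fits, `[[`, numeric(1), "k"),
                    nll = vapply(fits, `[[`, numeric(1), "nll"),
                    bic = vapply(fits, `[[`, numeric(1), "bic"),
                    stringsAsFactors = FALSE)
  ord <- order(tab$bic, tab$k)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(ranking = tab, winner = fits[[ord[1L]]])
}

#' Parameter recovery for a value model
#'
#' For each of `n_sets` random true parameter vectors (uniform within the
#' spec's bounds), simulates choices on the supplied trial template under
#' the softmax rule, refits the model, and reports per-parameter Pearson
#' correlations between true and recovered values.
#'
#' @param spec A [value_model_spec()].
#' @param n_sets Number of true parameter sets.
#' @param trials_template Session table supplying the option sets.
#' @param seed Master seed; per-set streams are derived from it.
#' @param n_starts_fit Starts per refit (defaults to `spec$n_starts`).
#' @return List with `table` (true and recovered values per set) and
#'   `correlations` (named, one per free parameter).
#' @export
recover_parameters <- function(spec, n_sets, trials_template, seed = 1L,
                               n_starts_fit = NULL) {
  stopifnot(n_sets >= 1, length(spec$free) >= 1)
  dat <- prepare_fit_data(trials_template)
  fit_spec <- spec
  fit_spec$n_starts <- as.integer(n_starts_fit %||% spec$n_starts)
  lower <- vapply(spec$bounds, `[`, numeric(1), 1L)
  upper <- vapply(spec$bounds, `[`, numeric(1), 2L)
  k <- length(spec$free)

  out <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    set.seed(derive_seed(seed, i))
    theta <- stats::runif(k, lower, upper)
    names(theta) <- spec$free
    pars <- full_params(theta, spec)
    vl <- option_value(dat$m_left, dat$p_left, pars, spec)
    vr <- option_value(dat$m_right, dat$p_right, pars, spec)
    sim <- dat
    sim$choice_right <- as.numeric(stats::runif(nrow(dat)) <
                                     choice_probability(vl, vr))
    fit <- fit_value_model(sim, fit_spec, seed = derive_seed(seed, i + n_sets))
    rec <- unlist(fit$params[spec$free])
    row <- c(set = i, stats::setNames(theta, paste0("true_", spec$free)),
             stats::setNames(rec, paste0("recovered_", spec$free)))
    out[[i]] <- row
  }
  tab <- as.data.frame(do.call(rbind, out))
  cors <- vapply(spec$free, function(p)
    stats::cor(tab[[paste0("true_", p)]], tab[[paste0("recovered_", p)]]),
    numeric(1))
  list(table = tab, correlations = cors)
}
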