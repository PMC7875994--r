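#' Quality-control filter for voxel metabolite measurements
#'
#' A measurement is retained only if, for both GABA and glutamate, the
#' Cramér–Rao lower bound is below 20%, the linewidth (FWHM) below 25 Hz,
#' and the signal-to-noise ratio above 8. Participants with any excluded
#' region are dropped listwise from the link analyses.
#'
#' @param measurements Long metabolite table with columns `participant`,
#'   `region`, `GABA_abs`, `Glu_abs`, `Cr_abs`, `CRLB_GABA`, `CRLB_Glu`,
#'   `FWHM`, `SNR`, `GM_frac`, `WM_frac`.
#' @param crlb_max,fwhm_max,snr_min Quality thresholds.
#' @return List with `measurements` (the table plus `included` flag and
#'   `reason`), `excluded_participants`, and `included` (the rows of
#'   participants passing QC in all regions).
#' @export
qc_filter <- function(measurements, crlb_max = 20, fwhm_max = 25,
                      snr_min = 8) {
  req <- c("participant", "region", "CRLB_GABA", "CRLB_Glu", "FWHM", "SNR")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("missing quality fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(measurements[req]))
    stop("missing values in quality fields", call. = FALSE)
  reason <- character(nrow(measurements))
  reason[measurements$CRLB_GABA >= crlb_max |
           measurements$CRLB_Glu >= crlb_max] <- "CRLB"
  bad_fwhm <- measurements$FWHM >= fwhm_max
  reason[bad_fwhm] <- ifelse(reason[bad_fwhm] == "", "FWHM",
                             paste(reason[bad_fwhm], "FWHM", sep = "+"))
  bad_snr <- measurements$SNR <= snr_min
  reason[bad_snr] <- ifelse(reason[bad_snr] == "", "SNR",
                            paste(reason[bad_snr], "SNR", sep = "+"))
  measurements$included <- reason == ""
  measurements$reason <- reason
  excl <- unique(measurements$participant[!measurements$included])
  list(measurements = measurements,
       excluded_participants = excl,
       included = measurements[!measurements$participant %in% excl, ,
                               drop = FALSE])
}

#' Normalize metabolite concentrations by grey matter and creatine
#'
#' GABA and glutamate are assumed to reside predominantly in grey matter,
#' so their absolute concentrations are divided by the relative grey-matter
#' fraction of the voxel. Total creatine resides in grey and white matter
#' and is divided by the combined fraction. The reported concentrations are
#' the grey-matter-corrected values divided by the corrected creatine:
#' `GABA_norm = (GABA_abs / GM) / (Cr_abs / (GM + WM))`, likewise for
#' glutamate.
#'
#' @param measurements Long metabolite table (see [qc_filter()]).
#' @return The table with columns `GABA_norm` and `Glu_norm` appended.
#' @export
normalize_metabolites <- function(measurements) {
  m <- measurements
  if (any(m$GM_frac <= 0) || any(m$GM_frac + m$WM_frac <= 0))
    stop("non-positive tissue fractions", call. = FALSE)
  stopifnot(all(m$GM_frac >= 0 & m$GM_frac <= 1),
            all(m$WM_frac >= 0 & m$WM_frac <= 1),
            all(m$GM_frac + m$WM_frac <= 1 + 1e-9),
            all(m$GABA_abs > 0), all(m$Glu_abs > 0), all(m$Cr_abs > 0))
  cr_norm <- m$Cr_abs / (m$GM_frac + m$WM_frac)
  m$GABA_norm <- (m$GABA_abs / m$GM_frac) / cr_norm
  m$Glu_norm <- (m$Glu_abs / m$GM_frac) / cr_norm
  m
}

#' Excitation/inhibition balance
#'
#' The ratio of normalized glutamate to normalized GABA.
#'
#' @param gaba_norm,glu_norm Normalized concentrations, `> 0`.
#' @return `glu_norm / gaba_norm`.
#' @export
compute_ei <- function(gaba_norm, glu_norm) {
  if (any(gaba_norm <= 0)) stop("non-positive GABA", call. = FALSE)
  stopifnot(all(glu_norm > 0))
  glu_norm / gaba_norm
}

#' Reshape a normalized metabolite table to wide per-participant form
#'
#' @param measurements Output of [normalize_metabolites()].
#' @return List with `ei` (data frame `participant` + one E/I column per
#'   region) and `transmitters` (data frame `participant` +
#'   `<region>_GABA` / `<region>_Glu` columns).
#' @export
ei_profiles <- function(measurements) {
  m <- measurements
  m$EI <- compute_ei(m$GABA_norm, m$Glu_norm)
  parts <- sort(unique(m$participant))
  regions <- unique(m$region)
  cnt <- table(m$participant)
  if (any(cnt != length(regions)))
    stop("each participant needs exactly one measurement per region",
         call. = FALSE)
  grab <- function(col) {
    out <- data.frame(participant = parts)
    for (rg in regions) {
      sub <- m[m$region == rg, ]
      out[[rg]] <- sub[[col]][match(parts, sub$participant)]
    }
    out
  }
  ei <- grab("EI")
  gaba <- grab("GABA_norm"); glu <- grab("Glu_norm")
  tx <- data.frame(participant = parts)
  for (rg in regions) {
    tx[[paste0(rg, "_GABA")]] <- gaba[[rg]]
    tx[[paste0(rg, "_Glu")]] <- glu[[rg]]
  }
  list(ei = ei, transmitters = tx)
}

#' Five-region GLM of a decision variable on E/I balance
#'
#' Regresses the (z-scored) decision variable on the z-scored E/I balances
#' of all five regions simultaneously, plus a constant and any covariates
#' of no interest (for value-phase variables, the share of no-brainer
#' trials). Zero-variance columns are dropped with a warning; genuine
#' collinearity among the remaining columns is an error.
#'
#' @param dv Numeric vector, one value per participant.
#' @param ei_matrix Data frame or matrix of per-region E/I (columns named
#'   by region); a `participant` column, if present, is ignored.
#' @param covariates Optional data frame/matrix of additional z-scored
#'   covariates.
#' @return List with `table` (per-region `beta`, `t`, `p`, `ci_lo`,
#'   `ci_hi`), `fit` (the `lm` object), `regions`, `dropped`.
#' @export
ei_glm <- function(dv, ei_matrix, covariates = NULL) {
  X <- as.data.frame(ei_matrix)
  X$participant <- NULL
  stopifnot(length(dv) == nrow(X))
  n <- length(dv)
  keep <- vapply(X, function(col) stats::sd(col) > 0, logical(1))
  dropped <- names(X)[!keep]
  if (length(dropped))
    warning("dropping constant region column(s): ",
            paste(dropped, collapse = ", "))
  X <- X[keep]
  regions <- names(X)
  if (n <= length(regions) + 2L + NCOL(covariates %||% matrix(nrow = n, ncol = 0)))
    stop("too few participants for a ", length(regions),
         "-region GLM", call. = FALSE)
  dat <- data.frame(lapply(X, zscore))
  names(dat) <- regions
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    cv <- data.frame(lapply(cv, zscore))
    names(cv) <- paste0("cov_", names(cv))
    dat <- cbind(dat, cv)
  }
  dat$.dv <- zscore(dv, "dv")
  fit <- stats::lm(.dv ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  tab <- data.frame(region = regions,
                    beta = s[regions, "Estimate"],
                    t = s[regions, "t value"],
                    p = s[regions, "Pr(>|t|)"],
                    ci_lo = ci[regions, 1L], ci_hi = ci[regions, 2L],
                    row.names = NULL)
  list(table = tab, fit = fit, regions = regions, dropped = dropped)
}

residualize <- function(y, nuisance) {
  if (NCOL(nuisance) == 0L) return(y - mean(y))
  stats::resid(stats::lm(y ~ ., data = as.data.frame(nuisance)))
}

#' Gated partial correlation between a decision variable and one region's E/I
#'
#' Residualizes both the decision variable and the target region's E/I on
#' the other regions' E/I (plus a constant), then reports the Pearson
#' correlation between the residuals. Intended as the follow-up to a
#' significant region effect in [ei_glm()].
#'
#' @inheritParams ei_glm
#' @param target_region Column name of the target region.
#' @return List with `r`, `p`, `ci95`, `df`, and `residuals` (data frame
#'   `dv_resid`, `ei_resid` for plotting or robust refits).
#' @export
partial_correlation_region <- function(dv, ei_matrix, target_region) {
  X <- as.data.frame(ei_matrix)
  X$participant <- NULL
  stopifnot(target_region %in% names(X), length(dv) == nrow(X))
  nuis <- X[setdiff(names(X), target_region)]
  rd <- residualize(dv, nuis)
  rt <- residualize(X[[target_region]], nuis)
  ct <- stats::cor.test(rd, rt)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci95 = unname(ct$conf.int), df = unname(ct$parameter),
       residuals = data.frame(dv_resid = rd, ei_resid = rt))
}

#' Gated partial correlation for a single transmitter
#'
#' Asks whether a region-level E/I effect is carried by GABA or glutamate:
#' both the decision variable and the transmitter of interest in the target
#' region are residualized on the other transmitter in that region and on
#' both transmitters in the four other regions (nine nuisance columns plus
#' a constant), and the residuals are correlated.
#'
#' @param dv Numeric vector per participant.
#' @param transmitter_matrix Wide data frame with `<region>_GABA` and
#'   `<region>_Glu` columns (see [ei_profiles()]).
#' @param target_region Region name.
#' @param transmitter `"GABA"` or `"Glu"`.
#' @return List with `r`, `p`, `ci95`, `df`, `residuals`.
#' @export
partial_correlation_transmitter <- function(dv, transmitter_matrix,
                                            target_region,
                                            transmitter = c("GABA", "Glu")) {
  transmitter <- match.arg(transmitter)
  X <- as.data.frame(transmitter_matrix)
  X$participant <- NULL
  target_col <- paste0(target_region, "_", transmitter)
  stopifnot(target_col %in% names(X), length(dv) == nrow(X))
  nuis <- X[setdiff(names(X), target_col)]
  if (length(dv) <= ncol(nuis) + 3L)
    stop("too few participants for ", ncol(nuis),
         " nuisance regressors", call. = FALSE)
  rd <- residualize(dv, nuis)
  rt <- residualize(X[[target_col]], nuis)
  ct <- stats::cor.test(rd, rt)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci95 = unname(ct$conf.int), df = unname(ct$parameter),
       residuals = data.frame(dv_resid = rd, tx_resid = rt))
}

#' Contrast of two region coefficients from the E/I GLM
#'
#' Tests whether the relationship with the decision variable is stronger in
#' one region than another: a t-test of the linear contrast
#' `beta_a - beta_b` using the coefficient covariance of the fitted GLM.
#'
#' @inheritParams ei_glm
#' @param region_a,region_b Region column names.
#' @return List with `estimate`, `t`, `df`, `p`.
#' @export
region_coefficient_contrast <- function(dv, ei_matrix, region_a, region_b,
                                        covariates = NULL) {
  g <- ei_glm(dv, ei_matrix, covariates)
  stopifnot(region_a %in% g$regions, region_b %in% g$regions)
  b <- stats::coef(g$fit)
  V <- stats::vcov(g$fit)
  est <- b[[region_a]] - b[[region_b]]
  if (region_a == region_b) {
    return(list(estimate = 0, t = 0, df = g$fit$df.residual, p = 1))
  }
  se <- sqrt(V[region_a, region_a] + V[region_b, region_b] -
               2 * V[region_a, region_b])
  tval <- est / se
  df <- g$fit$df.residual
  list(estimate = est, t = tval, df = df,
       p = 2 * stats::pt(-abs(tval), df))
}

#' Run the gated hierarchy linking decision variables to regional E/I
#'
#' Implements the testing hierarchy: (1) only decision variables that are
#' of a priori interest — and, if behavioural-significance p-values are
#' supplied, that showed a significant behavioural effect — are tested;
#' (2) each is regressed on the five regional E/I balances simultaneously
#' (with the no-brainer share as a covariate of no interest for value-phase
#' variables); (3) if, and only if, a region is significant in that GLM,
#' follow-ups are computed for that region: the gated partial correlation,
#' a robust bisquare refit of the residual pairs, transmitter-level partial
#' correlations, and coefficient contrasts against the other regions;
#' (4) optionally, mediation-style re-entry of additional decision
#' variables into the design. No multiple-comparison correction across
#' regions is applied.
#'
#' @param dvs Data frame of decision variables (one row per participant),
#'   e.g. rows of [compute_decision_variables()] plus a `participant`
#'   column.
#' @param ei Wide E/I data frame (see [ei_profiles()]).
#' @param transmitters Wide transmitter data frame (see [ei_profiles()]);
#'   `NULL` skips transmitter follow-ups.
#' @param config List: `dv_names` (variables to test, default the seven
#'   canonical decision variables), `value_dvs` (which get the no-brainer
#'   covariate), `gate_alpha` (default 0.05), `behavioural_p` (optional
#'   named p-values for step 1), `mediation` (named list mapping a DV to
#'   covariate DVs to re-enter, default `pct_correct ~ alpha + gamma`).
#' @return An object of class `ei_link`: one element per decision variable
#'   with the GLM table, gated follow-ups per significant region, contrast
#'   results, any mediation refit, and `reason` strings for every non-test.
#' @export
run_testing_hierarchy <- function(dvs, ei, transmitters = NULL,
                                  config = list()) {
  cfg <- utils::modifyList(list(
    dv_names = c("mean_pla", "cost_rt_beta", "pct_correct", "alpha",
                 "gamma", "vdiff_rt_beta", "mean_logrt_value"),
    value_dvs = c("pct_correct", "alpha", "gamma", "vdiff_rt_beta",
                  "mean_logrt_value"),
    gate_alpha = 0.05,
    behavioural_p = NULL,
    mediation = list(pct_correct = c("alpha", "gamma"))
  ), config)

  ei_df <- as.data.frame(ei)
  if (!is.null(ei_df$participant) && !is.null(dvs$participant)) {
    common <- intersect(dvs$participant, ei_df$participant)
    dvs <- dvs[match(common, dvs$participant), , drop = FALSE]
    ei_df <- ei_df[match(common, ei_df$participant), , drop = FALSE]
    if (!is.null(transmitters)) {
      tx <- as.data.frame(transmitters)
      transmitters <- tx[match(common, tx$participant), , drop = FALSE]
    }
  }

  out <- list()
  for (dv_name in cfg$dv_names) {
    node <- list(dv = dv_name, tested = FALSE, reason = NULL)
    if (!dv_name %in% names(dvs)) {
      node$reason <- "decision variable not available"
      out[[dv_name]] <- node
      next
    }
    if (!is.null(cfg$behavioural_p) && dv_name %in% names(cfg$behavioural_p) &&
        cfg$behavioural_p[[dv_name]] >= cfg$gate_alpha) {
      node$reason <- "no significant behavioural effect (step-1 gate)"
      out[[dv_name]] <- node
      next
    }
    dv <- dvs[[dv_name]]
    if (anyNA(dv)) {
      node$reason <- "missing decision-variable values"
      out[[dv_name]] <- node
      next
    }
    covars <- NULL
    if (dv_name %in% cfg$value_dvs && "nb_share" %in% names(dvs))
      covars <- dvs["nb_share"]
    g <- ei_glm(dv, ei_df, covars)
    node$tested <- TRUE
    node$glm <- g$table
    sig <- g$table$region[g$table$p < cfg$gate_alpha]
    node$followups <- list()
    if (length(sig) == 0L) {
      node$reason <- "no region significant in the five-region GLM"
    } else {
      for (rg in sig) {
        fu <- list(region = rg)
        fu$partial <- partial_correlation_region(dv, ei_df, rg)
        fu$robust <- robust_regression(fu$partial$residuals$dv_resid,
                                       fu$partial$residuals$ei_resid)
        if (!is.null(transmitters)) {
          tx_try <- try({
            fu$gaba <- partial_correlation_transmitter(dv, transmitters, rg,
                                                       "GABA")
            fu$glu <- partial_correlation_transmitter(dv, transmitters, rg,
                                                      "Glu")
          }, silent = TRUE)
          if (inherits(tx_try, "try-error"))
            fu$transmitter_reason <- conditionMessage(attr(tx_try, "condition"))
        }
        others <- setdiff(g$regions, rg)
        fu$contrasts <- lapply(stats::setNames(others, others), function(o)
          region_coefficient_contrast(dv, ei_df, rg, o, covars))
        node$followups[[rg]] <- fu
      }
    }
    med <- cfg$mediation[[dv_name]]
    if (!is.null(med) && all(med %in% names(dvs)) &&
        !anyNA(dvs[med]) && length(sig) > 0L) {
      node$mediation <- ei_glm(dv, ei_df,
                               cbind(covars %||% NULL, dvs[med]))$table
    }
    out[[dv_name]] <- node
  }
  structure(out, class = "ei_link", gate_alpha = cfg$gate_alpha)
}

#' @export
print.ei_link <- function(x, ...) {
  cat("Gated E/I link analysis (alpha =", attr(x, "gate_alpha"), ")\n")
  for (node in x) {
    cat("-", node$dv, ": ")
    if (!node$tested) {
      cat("not tested (", node$reason, ")\n", sep = "")
    } else {
      sig <- names(node$followups)
      cat(if (length(sig)) paste("significant in", paste(sig, collapse = ", "))
          else "no significant region", "\n")
    }
  }
  invisible(x)
}
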