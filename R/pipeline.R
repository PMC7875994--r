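trials_schema_version <- function() "1.0"

trials_required_columns <- function() {
  c("trial", "cost", "mu_cur", "mu_alt", "val_cur", "val_alt", "side_cur",
    "patch_choice", "switch", "m_left", "m_right", "p_left", "p_right",
    "no_brainer", "flipped", "value_choice", "rew_left", "rew_right",
    "reward", "rt_patch", "rt_value")
}

#' Write a trial table to TSV
#'
#' UTF-8, tab-separated, header row, `.` decimal mark. The schema version
#' is recorded in a `# schema:` comment line.
#'
#' @param trials A session table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(trials_required_columns(), names(trials))
  if (length(miss))
    stop("trial table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# schema: trials/",
                    attr(trials, "schema_version") %||% trials_schema_version()),
             con)
  utils::write.table(trials, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a trial table from TSV
#'
#' Validates the canonical schema. A sidecar column mapping (named list or
#' YAML file, canonical name -> source name) allows ingest of externally
#' deposited tables with a different column layout; unknown extra columns
#' are preserved.
#'
#' @param path TSV file path.
#' @param mapping Optional named list/vector or path to a YAML file mapping
#'   canonical column names to the file's column names.
#' @return A session `data.frame` with attribute `schema_version`.
#' @export
read_trials <- function(path, mapping = NULL) {
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping))
      mapping <- yaml::read_yaml(mapping)
    mapping <- unlist(mapping)
    absent <- setdiff(unname(mapping), names(tab))
    if (length(absent))
      stop("mapped source column(s) not in file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    for (canonical in names(mapping))
      names(tab)[names(tab) == mapping[[canonical]]] <- canonical
  }
  miss <- setdiff(trials_required_columns(), names(tab))
  if (length(miss))
    stop("trial table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(tab$rt_patch <= 0, na.rm = TRUE) ||
      any(tab$rt_value <= 0, na.rm = TRUE))
    stop("implausible (non-positive) response times", call. = FALSE)
  tab$switch <- as.logical(tab$switch)
  tab$flipped <- as.logical(tab$flipped)
  attr(tab, "schema_version") <- trials_schema_version()
  tab
}

#' Session-level behavioural summary
#'
#' The headline descriptive statistics of a cohort of sessions: mean leave
#' count, mean PLA at leave trials, mean share of no-brainer trials, and
#' the cost-level repeated-measures ANOVA on median leave thresholds.
#'
#' @param sessions List of session tables.
#' @return List with `mean_leave_count`, `mean_pla`, `mean_nb_share_pct`,
#'   `anova` (see [rm_anova_linear_trend()]; `NULL` if fewer than 3
#'   participants have all cost levels), `n`.
#' @export
behavioural_summary <- function(sessions) {
  leave_counts <- vapply(sessions, function(s) sum(s$switch), numeric(1))
  plas <- vapply(sessions, function(s)
    suppressWarnings(compute_patch_leaving_advantage(s)$mean_pla), numeric(1))
  nb <- vapply(sessions, function(s) mean(s$no_brainer != "none"), numeric(1))
  med <- t(vapply(sessions, median_leave_vdiff_by_cost, numeric(4)))
  anova <- if (sum(stats::complete.cases(med)) >= 3)
    rm_anova_linear_trend(med) else NULL
  list(mean_leave_count = mean(leave_counts),
       mean_pla = mean(plas, na.rm = TRUE),
       mean_nb_share_pct = 100 * mean(nb),
       anova = anova, n = length(sessions))
}

#' Configuration for a full pipeline run
#'
#' A serialized configuration (plus the seed) is sufficient to reproduce
#' every output of the deterministic stages bit-for-bit.
#'
#' @param seed Master seed; all per-participant streams derive from it.
#' @param sim_params A [patch_dynamics_params()].
#' @param cohort A [cohort_spec()].
#' @param fit_starts Starting points per model fit.
#' @param replicate_side_bias_bug Passed to the simulator.
#' @param gate_alpha Significance gate of the link hierarchy.
#' @param out_dir Optional output directory for TSV/CSV/JSON artefacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       sim_params = patch_dynamics_params(),
                       cohort = cohort_spec(),
                       fit_starts = 50L,
                       replicate_side_bias_bug = TRUE,
                       gate_alpha = 0.05,
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), sim_params = sim_params,
                 cohort = cohort, fit_starts = as.integer(fit_starts),
                 replicate_side_bias_bug = replicate_side_bias_bug,
                 gate_alpha = gate_alpha, out_dir = out_dir,
                 schema_version = "1.0"),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Generates a cohort, simulates one session per agent, fits the headline
#' value model (`SU` multiplicative, `omega_mult` fixed at 6.62), assembles
#' the decision variables, normalizes the metabolite table, and runs the
#' gated E/I link hierarchy. With `out_dir` set, writes per-participant
#' trial TSVs, the decision-variable CSV, the metabolite CSV, and a JSON
#' report (with the config echoed) to disk.
#'
#' @param config A [run_config()].
#' @return List with `cohort`, `sessions`, `fits`, `dvs`, `summary`,
#'   `profiles`, `link`, and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$cohort, seed = derive_seed(config$seed, 1))
  n <- config$cohort$n_participants

  sessions <- lapply(seq_len(n), function(i)
    simulate_session(cohort$agents[[i]], config$sim_params,
                     seed = derive_seed(config$seed, 100 + i),
                     replicate_side_bias_bug = config$replicate_side_bias_bug))

  spec <- value_model_spec("multiplicative", "SU",
                           fixed = list(omega_mult = 6.62),
                           n_starts = config$fit_starts)
  fits <- lapply(seq_len(n), function(i)
    fit_value_model(sessions[[i]], spec,
                    seed = derive_seed(config$seed, 1000 + i)))

  dvs <- do.call(rbind, lapply(seq_len(n), function(i)
    compute_decision_variables(sessions[[i]], fits[[i]])))
  dvs <- cbind(participant = seq_len(n), dvs)

  qc <- qc_filter(cohort$metabolites)
  profiles <- ei_profiles(normalize_metabolites(qc$included))
  link <- run_testing_hierarchy(dvs, profiles$ei, profiles$transmitters,
                                list(gate_alpha = config$gate_alpha))
  res <- list(cohort = cohort, sessions = sessions, fits = fits, dvs = dvs,
              summary = behavioural_summary(sessions),
              profiles = profiles, link = link, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n))
      write_trials(sessions[[i]],
                   file.path(config$out_dir,
                             sprintf("trials_p%02d.tsv", i)))
    utils::write.csv(dvs, file.path(config$out_dir, "decision_variables.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$metabolites,
                     file.path(config$out_dir, "metabolites.csv"),
                     row.names = FALSE)
    report <- list(
      schema_version = config$schema_version,
      seed = config$seed,
      summary = res$summary[c("mean_leave_count", "mean_pla",
                              "mean_nb_share_pct", "n")],
      bic = data.frame(participant = seq_len(n),
                       bic = vapply(fits, `[[`, numeric(1), "bic"),
                       nll = vapply(fits, `[[`, numeric(1), "nll")),
      link = serialize_link(link)
    )
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

serialize_link <- function(link) {
  lapply(link, function(node) {
    out <- list(dv = node$dv, tested = node$tested)
    if (!is.null(node$reason)) out$reason <- node$reason
    if (!is.null(node$glm)) out$glm <- node$glm
    if (length(node$followups)) {
      out$followups <- lapply(node$followups, function(fu) {
        list(region = fu$region,
             partial = fu$partial[c("r", "p", "ci95", "df")],
             robust = fu$robust[c("slope", "t", "df", "p")],
             gaba = if (!is.null(fu$gaba)) fu$gaba[c("r", "p")],
             glu = if (!is.null(fu$glu)) fu$glu[c("r", "p")],
             contrasts = lapply(fu$contrasts, function(ct)
               ct[c("estimate", "t", "p")]))
      })
    }
    if (!is.null(node$mediation)) out$mediation <- node$mediation
    out
  })
}
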