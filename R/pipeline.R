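#' Validate and normalise a pipeline run configuration
#'
#' A run configuration names the data source (exactly one of `generator`, a
#' [generator_config()] argument list, or `input`, a session directory), the
#' analysis settings per stage, and the master `seed`. Defaults are filled
#' for every omitted setting; unknown keys are rejected so typos surface
#' before any compute. The `hmm` block must be present (it may be an empty
#' list to accept all defaults).
#'
#' @param config named list, or path to a JSON file holding one.
#' @return Normalised configuration list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  known <- c("generator", "input", "seed", "hmm", "pc", "filters",
             "metrics", "windows", "output_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  has_gen <- !is.null(config$generator)
  has_input <- !is.null(config$input)
  if (has_gen && has_input)
    stop("ambiguous source: supply either 'generator' or 'input', not both")
  if (!has_gen && !has_input)
    stop("no data source: supply 'generator' or 'input'")
  if (is.null(config$hmm))
    stop("config is missing the 'hmm' block (use an empty block for defaults)")

  fill <- function(block, defaults, name) {
    block <- as.list(block)
    bad <- setdiff(names(block), names(defaults))
    if (length(bad))
      stop("unknown key(s) in '", name, "': ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, block)
  }
  out <- list(
    generator = if (has_gen) as.list(config$generator) else NULL,
    input = config$input,
    seed = if (is.null(config$seed)) 1L else as.integer(config$seed),
    hmm = fill(config$hmm,
               list(S = 2L, S_range = NULL, folds = 4L, n_restarts = 10L,
                    tol_loglik = 1e-3, tol_params = 1e-5, max_iter = 500L),
               "hmm"),
    pc = fill(config$pc %||% list(),
              list(kernel_half_width_ms = 12, unit_kernel_mode = "literal",
                   leakage_min_separation_um = 150), "pc"),
    filters = fill(config$filters %||% list(),
                   list(min_rate_hz = 5, min_trials = 10L,
                        response_filter = FALSE), "filters"),
    metrics = fill(config$metrics %||% list(),
                   list(rate_match_tolerance = 0.02, attmi_window = "cue_to_dimming"),
                   "metrics"),
    windows = fill(config$windows %||% list(),
                   list(pc = "cue_to_dimming", hmm = "cue_to_dimming"),
                   "windows"),
    output_dir = config$output_dir %||% "popstate_run")
  if (out$metrics$rate_match_tolerance <= 0)
    stop("'metrics$rate_match_tolerance' must be positive")
  if (out$hmm$folds < 2) stop("'hmm$folds' must be at least 2")
  if (out$hmm$n_restarts < 1) stop("'hmm$n_restarts' must be at least 1")
  class(out) <- "run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent per-stage substreams derived from the master seed, all < 2^31
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + stage * 7919L) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Chains simulate (or load) -> filters -> HMM fit and Viterbi decoding per
#' attention condition -> population coupling -> per-unit metrics
#' (ON/OFF ratio, attMI, rate matching) -> pairwise noise correlations ->
#' cross-metric correlations, and writes every stage's table plus a run
#' manifest to `config$output_dir`. Deterministic given `config$seed`: each
#' stage draws from its own substream, so rerunning a single stage
#' reproduces its output.
#'
#' @param config a [validate_config()]-normalised configuration (raw lists
#'   and file paths are accepted and normalised first).
#' @param quiet suppress per-stage log lines.
#' @return List with `session`, `models`, `unit_metrics`, `pair_metrics`,
#'   `correlations`, `output_dir` (invisibly written tables).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  say <- function(...) if (!quiet) message("[popstate] ", sprintf(...))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$generator)) {
    gen_args <- config$generator
    gen_args$seed <- stage_seed(config$seed, 1L)
    gen <- generate_session(do.call(generator_config, gen_args))
    session <- gen$session
    say("simulate: %d trials, %d spike trains", nrow(session$trials),
        length(session$spike_trains))
  } else {
    session <- read_session(config$input)
    say("load: session '%s'", session$session_id)
  }

  su_ids <- vapply(Filter(function(tr) tr$kind == "single_unit",
                          session$spike_trains), `[[`, character(1), "unit_id")
  incl <- lapply(su_ids, function(id)
    inclusion_filter(session, id, min_rate_hz = config$filters$min_rate_hz,
                     min_trials = config$filters$min_trials))
  names(incl) <- su_ids
  keep <- su_ids[vapply(incl, `[[`, logical(1), "included")]
  if (config$filters$response_filter && length(keep)) {
    resp <- vapply(keep, function(id)
      response_filter(session, id)$included, logical(1))
    keep <- keep[resp]
  }
  say("filters: %d/%d single units included", length(keep), length(su_ids))
  if (!length(keep)) stop("stage 'filters': no unit passed the inclusion filters")

  hmm_window <- analysis_window(config$windows$hmm, session$monkey_profile)
  conditions <- c("attend_RF", "attend_away")
  models <- list(); trajectories <- list()
  set.seed(stage_seed(config$seed, 2L))
  for (cond in conditions) {
    counts <- hmm_count_trials(session, hmm_window, cond)
    fit <- multi_restart_fit(counts, config$hmm$S,
                             n_restarts = config$hmm$n_restarts,
                             tol_loglik = config$hmm$tol_loglik,
                             tol_params = config$hmm$tol_params,
                             max_iter = config$hmm$max_iter)
    models[[cond]] <- fit
    trajectories[[cond]] <- lapply(counts, viterbi, model = fit)
    say("fit-hmm [%s]: loglik %.1f, %d iterations", cond,
        fit$log_likelihood, fit$n_iterations)
  }

  pc_window <- analysis_window(config$windows$pc, session$monkey_profile)
  opts <- coupling_options(config$pc$kernel_half_width_ms,
                           config$pc$unit_kernel_mode,
                           config$pc$leakage_min_separation_um)
  pc <- list()
  for (cond in conditions)
    pc[[cond]] <- session_population_coupling(session, keep, pc_window,
                                              cond, opts)
  say("compute-pc: %d units x %d conditions", length(keep), length(conditions))

  attmi_window <- analysis_window(config$metrics$attmi_window,
                                  session$monkey_profile)
  rows <- list()
  for (cond in conditions) {
    trials <- session_trials(session, cond)
    ivs <- lapply(seq_len(nrow(trials)), function(i)
      resolve_window(hmm_window, trials[i, ]))
    for (id in keep) {
      unit <- get_unit(session, id)
      spikes_by_trial <- lapply(ivs, function(iv)
        unit$spike_times[unit$spike_times >= iv[1] & unit$spike_times < iv[2]])
      ratio <- on_off_ratio(spikes_by_trial, trajectories[[cond]], ivs)
      am <- unit_attmi(session, id, attmi_window)
      rm_rf <- unit_trial_rates(session, id, attmi_window, "attend_RF")
      rm_aw <- unit_trial_rates(session, id, attmi_window, "attend_away")
      rm <- rate_match(rm_rf, rm_aw,
                       tolerance = config$metrics$rate_match_tolerance,
                       floor_n = config$filters$min_trials)
      r <- pc[[cond]][[id]]
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id = id, condition = cond,
        C0 = r$C0, C_norm = r$C_norm, Z = r$Z,
        on_off_ratio = ratio$ratio, ratio_trials_used = ratio$n_used,
        attMI = am$attMI, rate_matched = rm$matched,
        stringsAsFactors = FALSE)
    }
  }
  unit_metrics <- do.call(rbind, rows)

  pair_metrics <- NULL
  if (length(keep) >= 2) {
    pair_metrics <- do.call(rbind, lapply(conditions, function(cond)
      session_noise_correlations(session, cond, keep,
                                 min_trials = config$filters$min_trials)))
  }

  correlations <- NULL
  if (length(keep) >= 3) {
    correlations <- tryCatch(
      metric_correlations(unit_metrics, group_by = "condition"),
      error = function(e) NULL)
  }

  fwrite_sorted <- function(df, file)
    data.table::fwrite(df, file.path(config$output_dir, file), sep = "\t")
  fwrite_sorted(unit_metrics, "unit_metrics.tsv")
  if (!is.null(pair_metrics)) fwrite_sorted(pair_metrics, "pair_metrics.tsv")
  if (!is.null(correlations)) fwrite_sorted(correlations, "correlations.tsv")
  jsonlite::write_json(
    lapply(models, function(m) list(S = m$S, lambda = m$lambda, P = m$P,
                                    pi0 = m$pi0,
                                    log_likelihood = m$log_likelihood)),
    file.path(config$output_dir, "hmm_models.json"), auto_unbox = TRUE,
    digits = NA)
  manifest <- list(package_version = as.character(utils::packageVersion("popstate")),
                   seed = config$seed,
                   config = unclass(config)[setdiff(names(config), "output_dir")],
                   n_units_in = length(su_ids), n_units_included = length(keep))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("report: wrote %s", config$output_dir)

  invisible(list(session = session, models = models,
                 unit_metrics = unit_metrics, pair_metrics = pair_metrics,
                 correlations = correlations, output_dir = config$output_dir))
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `popstate` CLI script
#' (`inst/cli/popstate`). Subcommands: `simulate` (write a synthetic session
#' directory), `run` (full pipeline from a JSON config), `fit-hmm`,
#' `compute-pc`, `metrics` (stage-wise runs on a session directory) and
#' `report` (print a run manifest).
#'
#' @param args character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
popstate_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: popstate <simulate|run|fit-hmm|compute-pc|metrics|report> ...",
    "  simulate   --out DIR [--seed N]",
    "  run        --config FILE.json [--out DIR]",
    "  fit-hmm    --session DIR --out DIR [--seed N] [--S N]",
    "  compute-pc --session DIR --out DIR [--leakage UM]",
    "  metrics    --session DIR --out DIR [--seed N]",
    "  report     --run DIR", sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1L] + 1L] else default
  }
  switch(cmd,
    simulate = {
      seed <- as.integer(opt("--seed", "1"))
      out <- opt("--out"); if (is.null(out)) stop("simulate needs --out")
      gen <- generate_session(generator_config(seed = seed))
      write_session(gen$session, out)
      message("wrote synthetic session to ", out)
    },
    run = {
      cfgfile <- opt("--config"); if (is.null(cfgfile)) stop("run needs --config")
      cfg <- validate_config(cfgfile)
      out <- opt("--out"); if (!is.null(out)) cfg$output_dir <- out
      run_pipeline(cfg)
    },
    `fit-hmm` = {
      ses <- read_session(opt("--session"))
      out <- opt("--out"); dir.create(out, showWarnings = FALSE, recursive = TRUE)
      set.seed(as.integer(opt("--seed", "1")))
      S <- as.integer(opt("--S", "2"))
      for (cond in c("attend_RF", "attend_away")) {
        counts <- hmm_count_trials(ses, condition = cond)
        fit <- multi_restart_fit(counts, S)
        jsonlite::write_json(list(S = fit$S, lambda = fit$lambda, P = fit$P,
                                  pi0 = fit$pi0,
                                  log_likelihood = fit$log_likelihood),
                             file.path(out, paste0("hmm_", cond, ".json")),
                             auto_unbox = TRUE, digits = NA)
        traj <- do.call(rbind, lapply(names(counts), function(tid) {
          v <- viterbi(counts[[tid]], fit)
          data.frame(trial_id = tid, bin_index = seq_along(v$states) - 1L,
                     phase = v$states,
                     label = if (is.null(v$labels)) NA_character_ else v$labels)
        }))
        data.table::fwrite(traj, file.path(out, paste0("states_", cond, ".tsv")),
                           sep = "\t")
      }
      message("wrote HMM fits to ", out)
    },
    `compute-pc` = {
      ses <- read_session(opt("--session"))
      out <- opt("--out"); dir.create(out, showWarnings = FALSE, recursive = TRUE)
      opts <- coupling_options(
        leakage_min_separation_um = as.numeric(opt("--leakage", "150")))
      res <- do.call(rbind, lapply(c("attend_RF", "attend_away"), function(cond)
        coupling_table(session_population_coupling(ses, condition = cond,
                                                   options = opts))))
      data.table::fwrite(res, file.path(out, "population_coupling.tsv"),
                         sep = "\t")
      message("wrote population coupling to ", out)
    },
    metrics = {
      cfg <- validate_config(list(input = opt("--session"),
                                  seed = as.integer(opt("--seed", "1")),
                                  hmm = list(),
                                  output_dir = opt("--out", "popstate_run")))
      run_pipeline(cfg)
    },
    report = {
      run <- opt("--run"); if (is.null(run)) stop("report needs --run")
      cat(readLines(file.path(run, "manifest.json")), sep = "\n")
    },
    { cat(usage, "\n"); return(invisible(1L)) })
  invisible(0L)
}
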