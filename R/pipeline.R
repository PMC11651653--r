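#' Default pipeline configuration
#'
#' Nested parameter blocks, one per stage, with the study-condition defaults.
#' The configuration is validated before any stage runs and a copy is written
#' alongside the run outputs.
#'
#' @param n_sessions Number of synthetic sessions to simulate.
#' @param n_neurons ROIs per session.
#' @param seed Global seed; stage seeds are derived from it.
#' @param groups Group label per session (recycled), e.g. `"non_lesioned"` /
#'   `"lesioned"`.
#' @param ... Overrides for individual blocks (`schedule`, `psych`, `synth`,
#'   `signals`, `modulation`, `clustering`, `decoding`); each is a list merged
#'   over the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_sessions = 2, n_neurons = 20, seed = 1,
                            groups = c("non_lesioned", "lesioned"), ...) {
  defaults <- list(
    n_sessions = n_sessions, n_neurons = n_neurons, seed = seed,
    groups = groups,
    schedule = list(iti_mean = 8, iti_sd = 2, iti_floor = 3, n_trials = 400,
                    catch_fraction = 0.1,
                    sound_levels = seq(35, 75, by = 5), response_window = 1.5),
    psych = list(midpoint = 56, slope = 0.3, lapse_rate = 0.02,
                 false_alarm_rate = 0.15, lick_latency_floor = 0.12),
    synth = list(noise_sd = 0.05, neuropil_gain = 0.7, frame_rate_hz = 28,
                 drift_amplitude = 0.05, drift_period_s = 300),
    signals = list(gaussian_sigma_s = 10, min_window_s = 60, max_window_s = 60,
                   L = 193),
    modulation = list(q = 0.05),
    clustering = list(n_components = 9,
                      n_neighbors_grid = seq(5, 50, by = 5),
                      n_clusters_grid = 2:15),
    decoding = list(n_draws = 25, dummy_repeats = 100, min_each = 15,
                    frame_stride = 1)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else defaults[[nm]] <- overrides[[nm]]
  }
  cfg <- defaults
  # validate before anything runs
  do.call(schedule_params, cfg$schedule)
  do.call(psych_model, cfg$psych)
  stop_if_not(cfg$n_sessions >= 1, "n_sessions must be >= 1")
  stop_if_not(cfg$synth$frame_rate_hz >= 27 && cfg$synth$frame_rate_hz <= 30,
              "frame_rate_hz must be in [27, 30]")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- lapply(raw, function(b) {
    if (is.list(b) && !is.null(names(b))) {
      lapply(b, function(v) if (is.list(v)) unlist(v) else v)
    } else if (is.list(b)) unlist(b) else b
  })
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline on synthetic sessions
#'
#' Stages, in dependency order: simulate sessions, condition the fluorescence
#' (neuropil correction, dF/F, slow-baseline removal, trial tensor), score
#' behaviour, per-neuron modulation statistics, pooled response-profile
#' clustering, per-session decoding, and group comparison of the decoding
#' timecourses. Each stage writes CSV outputs into `out_dir`; all output
#' hashes are collected in `manifest.csv` and the configuration is serialized
#' to `config.yaml`. A stage failure aborts with the stage name; earlier
#' outputs are preserved.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created).
#' @param stages Stages to run (default all, in order).
#' @return Invisibly, a list with the in-memory stage results and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "preprocess", "behavior",
                                    "modulate", "cluster", "decode",
                                    "compare")) {
  stop_if_not(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  state <- list(out_dir = out_dir)
  spars <- do.call(schedule_params, config$schedule)
  pm <- do.call(psych_model, config$psych)
  grp <- rep_len(config$groups, config$n_sessions)

  if ("simulate" %in% stages) state$sessions <- run_stage("simulate", function() {
    lapply(seq_len(config$n_sessions), function(s) {
      sd_s <- config$seed + 1000L * s
      sched <- sample_schedule(spars, seed = sd_s)
      licks <- sample_behavior(sched, pm, seed = sd_s + 1)
      syn <- synthesize_session(
        sched, licks, default_prototypes(), n_neurons = config$n_neurons,
        noise_sd = config$synth$noise_sd,
        neuropil_gain = config$synth$neuropil_gain,
        drift = list(amplitude = config$synth$drift_amplitude,
                     period_s = config$synth$drift_period_s),
        frame_rate_hz = config$synth$frame_rate_hz, seed = sd_s + 2)
      syn$session$group <- grp[s]
      bdir <- file.path(out_dir, sprintf("session_%02d", s))
      write_session_bundle(syn$session, syn$ground_truth, sched, licks, bdir)
      list(session = syn$session, ground_truth = syn$ground_truth,
           schedule = sched, licks = licks, id = s)
    })
  })

  if ("preprocess" %in% stages) state$tensors <- run_stage("preprocess", function() {
    lapply(state$sessions, function(ss) {
      corrected <- neuropil_correct(ss$session$F, ss$session$Fneu,
                                    r = config$synth$neuropil_gain)
      dff <- compute_dff(corrected, frame_rate = ss$session$frame_rate)
      dff <- remove_slow_baseline(dff,
                                  gaussian_sigma_s = config$signals$gaussian_sigma_s,
                                  min_window_s = config$signals$min_window_s,
                                  max_window_s = config$signals$max_window_s)
      suppressMessages(extract_trials(dff, ss$schedule))
    })
  })

  if ("behavior" %in% stages) state$behavior <- run_stage("behavior", function() {
    rows <- lapply(seq_along(state$sessions), function(s) {
      ss <- state$sessions[[s]]
      oc <- score_trials(ss$schedule, ss$licks)
      ps <- psychometric(oc)
      data.frame(session = s, group = grp[s], hit_rate = ps$hit_rate,
                 fa_rate = ps$fa_rate, dprime = ps$dprime,
                 bins_json = as.character(jsonlite::toJSON(ps$bins, digits = NA)))
    })
    tab <- do.call(rbind, rows)
    data.table::fwrite(tab, file.path(out_dir, "behavior_summary.csv"))
    tab
  })

  if ("modulate" %in% stages) state$modulation <- run_stage("modulate", function() {
    rows <- lapply(seq_along(state$sessions), function(s) {
      ss <- state$sessions[[s]]
      oc <- score_trials(ss$schedule, ss$licks)
      mod <- modulation_analysis(state$tensors[[s]], oc,
                                 seed = config$seed + 77L * s,
                                 q = config$modulation$q)
      cbind(session = s, mod)
    })
    tab <- do.call(rbind, rows)
    data.table::fwrite(tab, file.path(out_dir, "modulation.csv"))
    tab
  })

  if ("cluster" %in% stages) state$clustering <- run_stage("cluster", function() {
    avgs <- lapply(seq_along(state$sessions), function(s) {
      ss <- state$sessions[[s]]
      oc <- score_trials(ss$schedule, ss$licks)
      keep <- exclude_lick_contaminated_hits(oc, ss$licks)
      outcome_averages(state$tensors[[s]], oc, L = config$signals$L,
                       trial_subset = keep)
    })
    X <- build_features(avgs)
    pca <- pca_reduce(X, n_components = min(config$clustering$n_components,
                                            min(dim(X))))
    model <- hyperparameter_search(
      pca$scores,
      n_neighbors_grid = config$clustering$n_neighbors_grid,
      n_clusters_grid = config$clustering$n_clusters_grid,
      seed = config$seed)
    n_per <- vapply(avgs, function(a) nrow(a$hit), integer(1))
    session_of <- rep(seq_along(avgs), n_per)
    clusters <- data.frame(neuron = sequence(n_per), session = session_of,
                           group = grp[session_of], cluster = model$labels)
    data.table::fwrite(clusters, file.path(out_dir, "clusters.csv"))
    data.table::fwrite(model$grid, file.path(out_dir, "grid_search.csv"))
    comp <- composition_test(model$labels, grp[session_of] == "lesioned")
    data.table::fwrite(comp, file.path(out_dir, "composition.csv"))
    list(model = model, clusters = clusters, composition = comp, pca = pca)
  })

  if ("decode" %in% stages) state$decoding <- run_stage("decode", function() {
    res <- lapply(seq_along(state$sessions), function(s) {
      ss <- state$sessions[[s]]
      oc <- score_trials(ss$schedule, ss$licks)
      keep <- exclude_lick_contaminated_hits(oc, ss$licks)
      sel <- tryCatch(select_trials(oc, trial_subset = keep),
                      error = function(e) NULL)
      if (is.null(sel)) return(NULL)
      frames <- seq(1, dim(state$tensors[[s]]$values)[3],
                    by = config$decoding$frame_stride)
      tryCatch(
        decode_session(state$tensors[[s]], oc, seed = config$seed + 11L * s,
                       trial_idx = sel$trial_idx, frames = frames,
                       n_draws = config$decoding$n_draws,
                       dummy_repeats = config$decoding$dummy_repeats,
                       min_each = config$decoding$min_each),
        error = function(e) {
          message(sprintf("session %d excluded from decoding: %s", s,
                          conditionMessage(e)))
          NULL
        })
    })
    kept <- which(!vapply(res, is.null, logical(1)))
    stop_if_not(length(kept) >= 1, "no session passed the decoding gates")
    tab <- do.call(rbind, lapply(kept, function(s) {
      data.frame(session = s, group = grp[s],
                 frame_time_s = res[[s]]$frame_time,
                 trained = res[[s]]$trained, dummy = res[[s]]$dummy,
                 n_rois = res[[s]]$n_rois, n_hit = res[[s]]$n_hit,
                 n_miss = res[[s]]$n_miss)
    }))
    data.table::fwrite(tab, file.path(out_dir, "decoding.csv"))
    list(results = res, kept = kept, table = tab)
  })

  if ("compare" %in% stages) state$comparison <- run_stage("compare", function() {
    dec <- state$decoding
    if (length(dec$kept) < 5) {
      message("comparison skipped: fewer than 5 decoded sessions")
      return(NULL)
    }
    L0 <- min(vapply(dec$kept, function(s) length(dec$results[[s]]$trained),
                     integer(1)))
    trained <- do.call(rbind, lapply(dec$kept, function(s) {
      interpolate_timecourse(dec$results[[s]]$trained, L0)
    }))
    dummy <- vapply(dec$kept, function(s) dec$results[[s]]$dummy[1], numeric(1))
    ft <- interpolate_timecourse(dec$results[[dec$kept[1]]]$frame_time, L0)
    cmp <- compare_to_dummy(trained, dummy, frame_time = ft)
    cmp$comparison <- "trained_vs_dummy"
    data.table::fwrite(cmp, file.path(out_dir, "comparisons.csv"))
    cmp
  })

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.csv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir, files))))
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
  invisible(c(state, list(manifest = manifest)))
}

#' Summary tables for a completed run
#'
#' Reads a run directory and returns the three summary tables: the
#' psychometric/behaviour table, the cluster table with composition
#' proportions, and the decoding timecourse table (with significance rows
#' when the comparison stage ran).
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List `behavior`, `clusters`, `composition`, `decoding`,
#'   `comparisons` (NULL when absent but optional).
#' @export
report_run <- function(run_dir) {
  need <- c("behavior_summary.csv", "clusters.csv", "composition.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run; missing artifacts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) as.data.frame(data.table::fread(p)) else NULL
  }
  list(behavior = rd("behavior_summary.csv"),
       clusters = rd("clusters.csv"),
       composition = rd("composition.csv"),
       decoding = rd("decoding.csv"),
       comparisons = rd("comparisons.csv"))
}
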