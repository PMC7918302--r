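# End-to-end orchestration over a fixture/recording cohort: preprocess ->
# events -> sleep -> spindles -> spectral -> stats, with a JSON report.
# Every stage is isolated: a failing stage is recorded in the report (with
# its error message) and the remaining stages still run.

stage_try <- function(report, name, expr, log = message) {
  res <- tryCatch(expr, error = function(e) {
    log(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    list(error = conditionMessage(e))
  })
  report[[name]] <- res
  report
}

#' Run the full analysis pipeline on a cohort directory
#'
#' The directory layout is the one written by [write_fixture_cohort()]: a
#' `manifest.json` naming per-animal EDF and hypnogram files.  Animals with
#' a missing hypnogram are dropped from sleep-dependent stages with an
#' explicit log entry, never silently.
#'
#' @param cohort_dir Directory containing `manifest.json`.
#' @param out_path Optional path for the JSON report.
#' @param event_par [event_params()] for the detection stage.
#' @param spindle_par [spindle_params()].
#' @param scheme [band_scheme()].
#' @param fspec [filter_spec()].
#' @param n_clusters,seed Clustering controls.
#' @param quiet Suppress progress logging.
#' @return The report (a nested list); when `out_path` is given the JSON is
#'   written and its md5 recorded in `attr(report, "content_hash")`.
#' @export
run_pipeline <- function(cohort_dir, out_path = NULL,
                         event_par = event_params(),
                         spindle_par = spindle_params(),
                         scheme = band_scheme(), fspec = filter_spec(),
                         n_clusters = 9, seed = 1L, quiet = FALSE) {
  log <- if (quiet) function(...) invisible() else message
  manifest <- jsonlite::read_json(file.path(cohort_dir, "manifest.json"))
  animals <- manifest$animals
  log(sprintf("cohort: %d animals @ %s h, fs %s", length(animals),
              manifest$hours, manifest$fs))

  per <- list()
  for (a in animals) {
    id <- a$animal_id
    edf_path <- file.path(cohort_dir, a$edf)
    hyp_path <- file.path(cohort_dir, a$hypnogram)
    rec <- load_edf(edf_path, c(EEG_F = "frontal_eeg", EEG_P = "parietal_eeg",
                                EMG = "emg"))
    h <- if (file.exists(hyp_path))
      read_hypnogram_csv(hyp_path, manifest$epoch_len_s,
                         start_zeitgeber_h(rec))
    else {
      log(sprintf("animal %s: hypnogram missing; sleep stages skipped", id))
      NULL
    }
    eeg <- apply_zero_phase(get_channel(rec, "frontal_eeg"), rec$fs, fspec)
    per[[id]] <- list(id = id, arm = a$arm, fs = rec$fs, eeg = eeg, hyp = h,
                      hours = length(eeg) / rec$fs / 3600)
  }

  report <- list(config = list(n_clusters = n_clusters, seed = seed,
                               cohort_dir = basename(cohort_dir),
                               manifest_seed = manifest$seed))

  # ---- events ---------------------------------------------------------
  report <- stage_try(report, "events", {
    evs <- lapply(per, function(p) {
      ev <- detect_events(p$eeg, p$fs, event_par)
      ev <- classify_discrete_spikes(ev, p$fs, event_par)
      if (nrow(ev)) {
        ev$animal_id <- p$id
        ev$group <- p$arm
      }
      ev
    })
    all_ev <- do.call(rbind, evs[vapply(evs, nrow, 0L) > 0])
    spikes <- all_ev[all_ev$is_discrete_spike, , drop = FALSE]
    wf <- do.call(rbind, lapply(per, function(p) {
      s <- spikes[spikes$animal_id == p$id, , drop = FALSE]
      extract_waveforms(p$eeg, s, p$fs)
    }))
    ord <- order(match(spikes$animal_id, names(per)))  # waveform row order
    spikes <- spikes[ord, , drop = FALSE]
    model <- fit_cluster_model(wf, spikes$group, n_clusters = n_clusters,
                               seed = seed)
    spikes$cluster <- model$cluster
    hours <- vapply(per, function(p) p$hours, 0)
    rates <- summarize_event_rates(spikes, model, hours)
    rates$group <- vapply(per[rates$animal_id], function(p) p$arm, "")
    cmp_all <- compare_event_rates(rates, "events_per_hour")
    cmp_rel <- compare_event_rates(rates, "cci_related_events_per_hour")
    list(n_events = nrow(all_ev), n_spikes = nrow(spikes),
         cluster_ratio = model$cluster_ratio,
         rates = rates, welch_all_events = cmp_all,
         welch_cci_related = cmp_rel)
  }, log)

  scored <- per[!vapply(per, function(p) is.null(p$hyp), TRUE)]

  # ---- sleep architecture --------------------------------------------
  report <- stage_try(report, "sleep", {
    arch <- lapply(scored, function(p) {
      st <- score_times(p$hyp)
      bs <- bout_summary(p$hyp)
      list(animal_id = p$id, group = p$arm,
           minutes = as.list(st$minutes),
           sleep_efficiency_pct = unname(st$sleep_efficiency_pct),
           bouts = bs, binned_minutes = bin_states(p$hyp, 4))
    })
    eff <- vapply(arch, function(x) x$sleep_efficiency_pct, 0)
    grp <- vapply(arch, function(x) x$group, "")
    aov_eff <- if (length(unique(grp)) >= 2 && all(table(grp) >= 2))
      one_way_anova_holm(eff, grp) else NULL
    list(per_animal = arch, efficiency_anova = aov_eff)
  }, log)

  # ---- spindles -------------------------------------------------------
  report <- stage_try(report, "spindles", {
    sp <- lapply(scored, function(p) {
      env <- sigma_envelope(p$eeg, p$fs, spindle_par)
      s <- detect_spindles(env, p$hyp, p$fs, spindle_par)
      list(animal_id = p$id, group = p$arm,
           metrics = spindle_metrics(s, p$hyp),
           binned = bin_spindle_density(s, p$hyp, 6))
    })
    dens <- vapply(sp, function(x) x$metrics$density_per_min, 0)
    grp <- vapply(sp, function(x) x$group, "")
    mixed <- tryCatch({
      longd <- do.call(rbind, lapply(sp, function(x) {
        b <- x$binned
        data.frame(animal_id = x$animal_id, group = x$group, bin = b$bin,
                   value = b$density_per_min)
      }))
      mixed_anova(na.omit(longd))
    }, error = function(e) list(error = conditionMessage(e)))
    list(per_animal = sp, density = setNames(as.list(dens), names(sp)),
         density_mixed_anova = mixed)
  }, log)

  # ---- spectral -------------------------------------------------------
  report <- stage_try(report, "spectral", {
    prof <- lapply(scored, function(p) {
      spec <- epoch_spectra(p$eeg, p$fs, p$hyp, scheme)
      list(animal_id = p$id, group = p$arm,
           profile = nrem_delta_profile(spec, p$hyp, 4))
    })
    longd <- do.call(rbind, lapply(prof, function(x) {
      data.frame(animal_id = x$animal_id, group = x$group,
                 bin = x$profile$bin, value = x$profile$mean_n_delta)
    }))
    mixed <- tryCatch(mixed_anova(na.omit(longd)),
                      error = function(e) list(error = conditionMessage(e)))
    group_means <- tapply(longd$value, longd$group, mean, na.rm = TRUE)
    list(per_animal = prof, group_mean_n_delta = as.list(group_means),
         n_delta_mixed_anova = mixed)
  }, log)

  # ---- event-wake correlation ----------------------------------------
  report <- stage_try(report, "event_wake_correlation", {
    out <- list()
    for (p in scored) {
      ev <- detect_events(p$eeg, p$fs, event_par)
      hours_n <- floor(p$hours)
      if (hours_n < 3) next
      ev_h <- tabulate(floor(ev$onset_sample / p$fs / 3600) + 1, hours_n)
      zt <- epoch_zt(p$hyp)
      hour_idx <- floor((seq_along(p$hyp$states) - 1) *
                          p$hyp$epoch_len_s / 3600) + 1
      wake_h <- vapply(seq_len(hours_n), function(hh) {
        sum(p$hyp$states[hour_idx == hh] == "WAKE") * p$hyp$epoch_len_s / 60
      }, 0)
      out[[p$id]] <- hourly_event_wake_correlation(ev_h, wake_h)
    }
    out
  }, log)

  if (!is.null(out_path)) {
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE, force = TRUE)
    attr(report, "content_hash") <- unname(tools::md5sum(out_path))
  }
  report
}

#' Minimal command-line interface
#'
#' Subcommands: `synth --out DIR [--hours H] [--fs FS] [--seed S]
#' [--animals NC=2,sham=2,CCI=2]` and `run --cohort DIR [--out report.json]`.
#'
#' @param args Character vector of CLI arguments.
#' @return Exit status, invisibly.
#' @export
ptesleep_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: ptesleep <synth|run> [options]\n")
    return(invisible(1L))
  }
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i)) args[i + 1] else default
  }
  cmd <- args[1]
  if (cmd == "synth") {
    spec <- opt("animals", "NC=2,sham=2,CCI=2")
    kv <- strsplit(strsplit(spec, ",")[[1]], "=")
    n_animals <- setNames(as.integer(vapply(kv, `[`, "", 2)),
                          vapply(kv, `[`, "", 1))
    cfg <- cohort_config(n_animals = n_animals,
                         hours = as.numeric(opt("hours", "24")),
                         fs = as.numeric(opt("fs", "1024")),
                         seed = as.integer(opt("seed", "20260101")))
    write_fixture_cohort(cfg, opt("out", "fixtures"))
  } else if (cmd == "run") {
    run_pipeline(opt("cohort", "fixtures"),
                 out_path = opt("out", "report.json"))
  } else {
    cat("unknown subcommand: ", cmd, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}
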