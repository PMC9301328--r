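# End-to-end orchestration of the synthetic study: simulate, hyperalign,
# source-reconstruct, estimate TRFs, decode the envelope, build networks,
# scan densities, and evaluate condition separability, with stage-level
# caching and a reproducible report.

#' Build and validate a pipeline configuration
#'
#' Defaults reproduce the study conditions the analysis emulates: 21
#' subjects, 48 non-repeated trials (24 per condition) at 250 Hz, a
#' 122-channel montage, a 68-ROI parcellation, and a stimulus-locked SNR of
#' -15 dB (background brain activity plus sensor noise);
#' trial duration and dipole count are desk-scale (6 s, 500 sources).
#'
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @param n_subjects,n_trials_per_condition,fs,duration_s study dimensions.
#' @param n_channels,n_sources,n_roi,n_communities forward-model dimensions.
#' @param misalignment subject channel-mixing deviation bound.
#' @param snr_db stimulus-locked signal to total noise ratio in dB (see
#'   [simulate_study()]).
#' @param noise_mix fraction of noise variance carried by background source
#'   activity versus sensor noise (see [simulate_study()]).
#' @param condition_b,difference_window_ms see [make_ground_truth()].
#' @param alpha sLORETA regularization fraction.
#' @param mcca_ridge MCCA within-set ridge.
#' @param n_components MCCA truncation (`NULL` = the model default).
#' @param align_space averaging space of the hyperaligned pathway
#'   (`"component"`, the aligned average, or `"electrode"`; see
#'   [denoise_and_average()]).
#' @param encoder_lag_step_ms encoder TRF lag step (default the sampling
#'   step).
#' @param encoder_ridge encoder ridge relative to the mean diagonal of the
#'   lagged-envelope Gram matrix (default 0.1, the held-out prediction
#'   plateau; see the methods vignette).
#' @param decoder_lag_step_ms decoder lag step (default 40 ms; the 0-800 ms
#'   span is always kept).
#' @param ridge_grid,inner_folds decoder ridge selection, see
#'   [loo_crossval()].
#' @param t_grid,gamma,detect_runs,scan_runs community detection settings.
#' @param kmeans_reps,embed_method,perplexity separability settings.
#' @param windows_ms TRF window grid for [window_cluster()].
#' @param pathways subset of `c("single_trial", "naive_average",
#'   "hyperaligned")`.
#' @return validated config object of class `run_config`.
#' @export
study_config <- function(seed = 1, n_subjects = 21, n_trials_per_condition = 24,
                         fs = 250, duration_s = 6, n_channels = 122,
                         n_sources = 500, n_roi = 68, n_communities = 4,
                         misalignment = 1.2, snr_db = -15, noise_mix = 0.75,
                         condition_b = "redraw",
                         difference_window_ms = c(300, 450),
                         alpha = 0.05, mcca_ridge = 1e-6, n_components = NULL,
                         align_space = "component",
                         encoder_lag_step_ms = 1000 / fs,
                         encoder_ridge = 0.1,
                         decoder_lag_step_ms = 40,
                         ridge_grid = 10^c(-4, -2, 0, 2), inner_folds = 3,
                         t_grid = seq(0.01, 0.5, by = 0.01), gamma = 1,
                         detect_runs = 100, scan_runs = 50,
                         kmeans_reps = 1000, embed_method = "pca",
                         perplexity = 10,
                         windows_ms = list(c(0, 150), c(150, 300),
                                           c(300, 450), c(450, 600)),
                         pathways = c("single_trial", "naive_average",
                                      "hyperaligned")) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 1, n_trials_per_condition >= 2, fs > 0,
            duration_s > 0, n_channels >= 2, n_sources >= n_roi,
            n_roi >= n_communities, n_communities >= 2,
            misalignment >= 0, alpha > 0, gamma > 0,
            all(t_grid > 0 & t_grid <= 1))
  bad <- setdiff(pathways, c("single_trial", "naive_average", "hyperaligned"))
  if (length(bad)) stop_invalid("unknown pathway(s): %s", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: %d subjects x %d trials (%g s @ %g Hz), %d ch -> %d src -> %d ROI\n",
              x$n_subjects, 2 * x$n_trials_per_condition, x$duration_s, x$fs,
              x$n_channels, x$n_sources, x$n_roi))
  cat("  pathways:", paste(x$pathways, collapse = ", "),
      sprintf("| SNR %g dB, misalignment %.2f, seed %d\n",
              x$snr_db, x$misalignment, x$seed))
  invisible(x)
}

# stage-level .rds caching keyed by the relevant config fields; the key is
# stored inside the cache file and compared on load
cached_stage <- function(cache_dir, stage, key_fields, compute) {
  if (is.null(cache_dir)) return(compute())
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  key <- paste(deparse(key_fields), collapse = "")
  path <- file.path(cache_dir, paste0(stage, ".rds"))
  if (file.exists(path)) {
    cached <- readRDS(path)
    if (identical(cached$key, key)) return(cached$value)
  }
  value <- compute()
  saveRDS(list(key = key, value = value), path)
  value
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> hyperalign -> inverse -> TRF -> decode -> networks ->
#' density scan -> separability for the configured pathways and returns a
#' machine-readable report.  Stages are cached as `.rds` under `cache_dir`
#' (if given) keyed by the parameters they depend on, so re-runs with an
#' unchanged config are idempotent.
#'
#' @param config a [study_config()] object.
#' @param cache_dir optional directory for stage caches.
#' @param write_dir optional directory; when given, tabular outputs and the
#'   report JSON are written there with a content-hash manifest.
#' @param verbose print stage progress (default `TRUE`).
#' @return a `run_report` list; see the fields in the source and the methods
#'   vignette.
#' @export
run_pipeline <- function(config, cache_dir = NULL, write_dir = NULL,
                         verbose = TRUE) {
  if (!inherits(config, "run_config")) {
    stop_invalid("config must be a study_config() object")
  }
  cfg <- config
  if ("hyperaligned" %in% cfg$pathways && cfg$n_subjects < 2) {
    stop_invalid("the hyperaligned pathway needs at least 2 subjects (MCCA is a multi-set method)")
  }
  t_start <- Sys.time()
  say <- function(...) {
    if (verbose) {
      message(sprintf("[%6.1fs] ", as.numeric(difftime(Sys.time(), t_start,
                                                       units = "secs"))),
              sprintf(...))
    }
  }

  # ---- stage: synthesis -------------------------------------------------
  synth_key <- cfg[c("seed", "n_subjects", "n_trials_per_condition", "fs",
                     "duration_s", "n_channels", "n_sources", "n_roi",
                     "n_communities", "misalignment", "snr_db", "noise_mix",
                     "condition_b", "difference_window_ms")]
  say("stage synth: %d subjects x %d trials", cfg$n_subjects,
      2 * cfg$n_trials_per_condition)
  synth <- cached_stage(cache_dir, "synth", synth_key, function() {
    gt <- make_ground_truth(
      n_roi = cfg$n_roi, n_channels = cfg$n_channels,
      n_sources = cfg$n_sources, n_communities = cfg$n_communities,
      lag_grid_ms = seq(0, 800, by = 1000 / cfg$fs),
      misalignment = cfg$misalignment, n_subjects = cfg$n_subjects,
      condition_b = cfg$condition_b,
      difference_window_ms = cfg$difference_window_ms,
      seed = derive_seed(cfg$seed, "gt"))
    envelopes <- lapply(seq_len(2 * cfg$n_trials_per_condition), function(tr) {
      make_envelope(cfg$duration_s, cfg$fs,
                    seed = derive_seed(cfg$seed, paste0("env", tr)))
    })
    eeg <- simulate_study(gt, envelopes,
                          n_subjects = cfg$n_subjects,
                          n_trials_per_condition = cfg$n_trials_per_condition,
                          snr_db = cfg$snr_db, noise_mix = cfg$noise_mix,
                          seed = derive_seed(cfg$seed, "study"))
    list(gt = gt, envelopes = envelopes, eeg = eeg)
  })
  gt <- synth$gt; envelopes <- synth$envelopes; eeg <- synth$eeg
  n_trials <- 2 * cfg$n_trials_per_condition

  # ---- stage: hyperalignment -------------------------------------------
  model <- NULL
  if ("hyperaligned" %in% cfg$pathways) {
    say("stage align: MCCA over %d subjects", cfg$n_subjects)
    model <- cached_stage(cache_dir, "mcca", c(synth_key, cfg["mcca_ridge"]),
                          function() {
      fit_mcca_eeg(eeg, ridge = cfg$mcca_ridge)
    })
  }

  # ---- stage: source reconstruction + ROI series -----------------------
  inv <- make_inverse_operator(gt$leadfield, alpha = cfg$alpha)
  pathway_trial <- function(pathway, tr) {
    switch(pathway,
      single_trial = eeg$data[1, tr, , ],
      naive_average = naive_average(eeg, tr),
      hyperaligned = denoise_and_average(model, eeg, tr,
        n_components = cfg$n_components %||% model$default_k,
        space = cfg$align_space))
  }
  say("stage inverse: sLORETA + ROI aggregation for %d pathway(s)",
      length(cfg$pathways))
  roi_key <- c(synth_key, cfg[c("alpha", "mcca_ridge", "n_components",
                                "align_space", "pathways")])
  roi_by_pathway <- cached_stage(cache_dir, "roi", roi_key, function() {
    out <- list()
    for (pw in cfg$pathways) {
      out[[pw]] <- lapply(seq_len(n_trials), function(tr) {
        src <- apply_inverse(inv, pathway_trial(pw, tr))
        aggregate_roi(src, gt$parcellation, fs = cfg$fs)
      })
    }
    out
  })

  # ---- stage: per-trial encoder TRFs -----------------------------------
  enc_lags <- seq(0, 800, by = cfg$encoder_lag_step_ms)
  say("stage trf: per-trial encoders (%d lags)", length(enc_lags))
  trf_by_pathway <- cached_stage(cache_dir, "trf", c(roi_key,
                                 cfg[c("encoder_lag_step_ms", "encoder_ridge")]), function() {
    lapply(roi_by_pathway, function(roi_trials) {
      lapply(seq_len(n_trials), function(tr) {
        env <- envelopes[[tr]]$values
        ridge <- cfg$encoder_ridge * stats::var(env) * length(env)
        fit_encoder(envelopes[[tr]], roi_trials[[tr]], lags_ms = enc_lags,
                    ridge = ridge)$weights
      })
    })
  })

  # ---- stage: envelope decoding (condition A trials) -------------------
  dec_lags <- seq(0, 800, by = cfg$decoder_lag_step_ms)
  idx_a <- which(eeg$condition_labels == "A")
  say("stage decode: leave-one-out over %d trials x %d pathway(s)",
      length(idx_a), length(cfg$pathways))
  decode_key <- c(roi_key, cfg[c("decoder_lag_step_ms", "ridge_grid",
                                 "inner_folds")])
  decoding <- cached_stage(cache_dir, "decode", decode_key, function() {
    lapply(roi_by_pathway, function(roi_trials) {
      trials <- lapply(idx_a, function(tr) {
        list(envelope = envelopes[[tr]], roi = roi_trials[[tr]])
      })
      loo_crossval(trials, lags_ms = dec_lags, ridge_grid = cfg$ridge_grid,
                   fs = cfg$fs, inner_folds = cfg$inner_folds)
    })
  })

  invisible(gc(FALSE))

  # ---- stage: networks, density scan, scale selection ------------------
  say("stage network: per-trial and condition-level connectivity")
  net_key <- c(roi_key, cfg[c("encoder_lag_step_ms", "t_grid", "gamma",
                              "detect_runs", "scan_runs", "kmeans_reps",
                              "embed_method", "perplexity")])
  networks <- cached_stage(cache_dir, "network", net_key, function() {
    pw_nets <- lapply(trf_by_pathway, function(trfs) {
      lapply(trfs, trf_connectivity)
    })
    cond_nets <- lapply(c(A = "A", B = "B"), function(cond) {
      average_connectivity(pw_nets$hyperaligned[eeg$condition_labels == cond])
    })
    scans <- lapply(cond_nets, function(cn) {
      scan_densities(cn, t_grid = cfg$t_grid, gamma = cfg$gamma,
                     n_runs = cfg$scan_runs, seed = derive_seed(cfg$seed, "scan"))
    })
    # separability F1 per density from thresholded per-trial networks
    feats_full <- t(vapply(pw_nets$hyperaligned, vectorize_network,
                           numeric(edge_count(cfg$n_roi))))
    f1_curve <- vapply(seq_along(cfg$t_grid), function(k) {
      tk <- cfg$t_grid[k]
      feats <- t(vapply(pw_nets$hyperaligned, function(cn) {
        vectorize_network(threshold_density(cn, tk)$values)
      }, numeric(edge_count(cfg$n_roi))))
      emb <- embed_2d(feats, method = cfg$embed_method,
                      seed = derive_seed(cfg$seed, 2000 + k),
                      perplexity = cfg$perplexity)
      kmeans_f1(emb, eeg$condition_labels, n_reps = max(100, cfg$kmeans_reps %/% 10),
                seed = derive_seed(cfg$seed, 3000 + k))
    }, numeric(1))
    for (cond in names(scans)) scans[[cond]]$F1 <- f1_curve
    selected <- lapply(scans, select_scale)
    list(pw_nets = pw_nets[intersect(c("hyperaligned", "single_trial"),
                                     names(pw_nets))],
         cond_nets = cond_nets, scans = scans, f1_curve = f1_curve,
         selected = selected, feats_full = feats_full)
  })

  # ---- stage: separability + window analysis ---------------------------
  say("stage evaluate: condition separability and TRF windows")
  eval_key <- net_key
  evaluation <- cached_stage(cache_dir, "evaluate", eval_key, function() {
    f1_full <- vapply(names(networks$pw_nets), function(pw) {
      feats <- t(vapply(networks$pw_nets[[pw]], vectorize_network,
                        numeric(edge_count(cfg$n_roi))))
      emb <- embed_2d(feats, method = cfg$embed_method,
                      seed = derive_seed(cfg$seed, paste0("emb_", pw)),
                      perplexity = cfg$perplexity)
      kmeans_f1(emb, eeg$condition_labels, n_reps = cfg$kmeans_reps,
                seed = derive_seed(cfg$seed, paste0("km_", pw)))
    }, numeric(1))
    f1_windows <- if ("hyperaligned" %in% names(trf_by_pathway)) {
      window_cluster(trf_by_pathway$hyperaligned, eeg$condition_labels,
                     lags_ms = enc_lags, windows_ms = cfg$windows_ms,
                     method = cfg$embed_method,
                     seed = derive_seed(cfg$seed, "windows"),
                     perplexity = cfg$perplexity,
                     n_reps = cfg$kmeans_reps)
    } else NULL
    list(f1_full = f1_full, f1_windows = f1_windows)
  })

  invisible(gc(FALSE)) # free stage intermediates before assembling output

  report <- structure(list(
    config = unclass(cfg),
    decoding = decoding,
    mean_z = vapply(decoding, function(d) mean(d$z, na.rm = TRUE), numeric(1)),
    mcca = if (!is.null(model)) {
      list(eigenvalues = model$eigenvalues,
           canonical_correlations = model$canonical_correlations,
           default_k = model$default_k)
    } else NULL,
    networks = list(
      selected = lapply(networks$selected, function(s) {
        s[c("density", "vi", "f1", "Q")]
      }),
      partitions = lapply(networks$selected, function(s) s$partition),
      n_communities = vapply(networks$selected,
                             function(s) length(unique(s$partition)),
                             numeric(1)),
      Q_curves = lapply(networks$scans, function(s) s$Q_d),
      VI_curves = lapply(networks$scans, function(s) s$VI),
      f1_curve = networks$f1_curve,
      densities = cfg$t_grid),
    f1_full = evaluation$f1_full,
    f1_windows = evaluation$f1_windows,
    ground_truth_labels = gt$community_labels,
    provenance = list(package_version = as.character(utils::packageVersion("trfnet")),
                      r_version = paste(R.version$major, R.version$minor, sep = "."),
                      seed = cfg$seed)
  ), class = "run_report")

  if (!is.null(write_dir)) write_report(report, networks, eeg, write_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat("  mean Fisher z by pathway:",
      paste(sprintf("%s=%.3f", names(x$mean_z), x$mean_z), collapse = ", "), "\n")
  cat("  full-network separability F1:",
      paste(sprintf("%s=%.3f", names(x$f1_full), x$f1_full), collapse = ", "), "\n")
  for (cond in names(x$networks$selected)) {
    s <- x$networks$selected[[cond]]
    cat(sprintf("  condition %s: density %.2f, Q %.3f, %d communities\n",
                cond, s$density, s$Q, x$networks$n_communities[[cond]]))
  }
  invisible(x)
}

#' Compare envelope-prediction accuracy across pathways
#'
#' Mean Fisher z per pathway with seeded bootstrap confidence intervals over
#' trials, and the resulting ordering.
#'
#' @param report a [run_pipeline()] report (needs >= 2 pathways), or a named
#'   list of `prediction_result` data frames.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return data.frame with `pathway`, `mean_z`, `ci_lo`, `ci_hi`, sorted by
#'   `mean_z` descending, with the ordering string as attribute `ordering`.
#' @export
compare_pathways <- function(report, n_boot = 2000, conf = 0.95, seed = 1) {
  decoding <- if (inherits(report, "run_report")) report$decoding else report
  if (length(decoding) < 2) {
    stop_invalid("need at least 2 pathways to compare, got %d", length(decoding))
  }
  rows <- with_seed(seed, {
    lapply(names(decoding), function(pw) {
      z <- decoding[[pw]]$z
      z <- z[!is.na(z)]
      boots <- vapply(seq_len(n_boot), function(b) {
        mean(z[sample.int(length(z), replace = TRUE)])
      }, numeric(1))
      qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2))
      data.frame(pathway = pw, mean_z = mean(z), ci_lo = qs[1], ci_hi = qs[2],
                 row.names = NULL)
    })
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_z), ]
  rownames(out) <- NULL
  attr(out, "ordering") <- paste(out$pathway, collapse = " > ")
  out
}

#' Deterministic digest of a run report
#'
#' MD5 of the canonically serialized report, for bit-for-bit reproducibility
#' checks across re-runs with the same config.
#'
#' @param report a `run_report`.
#' @return hex digest string.
#' @export
report_digest <- function(report) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(report, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}
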