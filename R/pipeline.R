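#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults mirror the
#' study protocol: 14 channels at 128 Hz, alpha 8-12 Hz and beta 12-28 Hz,
#' 10 s stimuli with 5 s transitions, 12 stimuli per condition, stratified
#' 10-fold cross-validation. The configuration (and its hash) is echoed into
#' every serialized result for provenance.
#'
#' @param device A [device_profile()].
#' @param design A [design_config()].
#' @param truth An [affect_ground_truth()].
#' @param noise A [noise_spec()].
#' @param effect A [response_effect()].
#' @param filter_order Butterworth order (default 4).
#' @param window_s,hop_s,edge_s Band-power windowing (defaults 1, 0.25, 1 s).
#' @param abs_uv,z_thresh Artifact-rejection thresholds (100 uV, z 5).
#' @param norm_scope Normalization scope for [normalize_affect()].
#' @param folds,repeats Cross-validation settings (defaults 10, 1).
#' @param eeg_sessions Sessions for which EEG is synthesized and decoded
#'   (default `c(1, 5)`: first session and the follow-up assessment).
#' @param artifact_rate_per_min,artifact_uv Injected-artifact settings
#'   (default rate 0: clean recordings).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(device = device_profile(),
                            design = design_config(),
                            truth = affect_ground_truth(),
                            noise = noise_spec(),
                            effect = response_effect(),
                            filter_order = 4,
                            window_s = 1, hop_s = 0.25, edge_s = 1,
                            abs_uv = 100, z_thresh = 5,
                            norm_scope = "participant_session",
                            folds = 10, repeats = 1,
                            eeg_sessions = c(1L, 5L),
                            artifact_rate_per_min = 0,
                            artifact_uv = 300,
                            seed = 1) {
  stopifnot(
    inherits(device, "device_profile"), inherits(design, "design_config"),
    inherits(truth, "affect_ground_truth"), inherits(noise, "noise_spec"),
    inherits(effect, "response_effect")
  )
  if (folds < 2) {
    abort("`folds` must be at least 2.")
  }
  if (repeats < 1) {
    abort("`repeats` must be at least 1.")
  }
  structure(
    list(
      device = device, design = design, truth = truth, noise = noise,
      effect = effect, filter_order = filter_order,
      window_s = window_s, hop_s = hop_s, edge_s = edge_s,
      abs_uv = abs_uv, z_thresh = z_thresh, norm_scope = norm_scope,
      folds = folds, repeats = repeats,
      eeg_sessions = as.integer(eeg_sessions),
      artifact_rate_per_min = artifact_rate_per_min,
      artifact_uv = artifact_uv,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config[setdiff(names(config), "seed")]), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

# Per participant-session: synthesize EEG, preprocess, extract features.
process_session <- function(schedule, config, seed) {
  rec <- generate_recording(
    schedule,
    truth = config$truth, device = config$device,
    noise = config$noise, seed = seed
  )
  if (config$artifact_rate_per_min > 0) {
    rec <- inject_artifacts(
      rec, config$artifact_rate_per_min, config$artifact_uv,
      seed = derive_seed(seed, 1)
    )
  }
  alpha <- band_power(rec, "alpha", config$window_s, config$hop_s,
                      config$edge_s, config$filter_order)
  beta <- band_power(rec, "beta", config$window_s, config$hop_s,
                     config$edge_s, config$filter_order)
  both <- bind_band_power(alpha, beta)
  mask <- reject_artifact_windows(rec, both, config$abs_uv, config$z_thresh)
  affect <- compute_affect(both, mask = mask)
  feats <- epoch_affect(affect, schedule)
  list(
    features = feats,
    n_windows = nrow(affect),
    n_rejected = nrow(mask)
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates, deterministically under `config$seed`: (1) building
#' stimulus schedules for the whole roster, (2) simulating verbal responses
#' and computing the response statistics (within-session Wilcoxon per group,
#' across-session paired comparison per group), (3) synthesizing EEG for the
#' EEG subset of participants in the configured sessions, preprocessing,
#' affect feature extraction and normalization, (4) per-participant
#' four-class decoding (ANN and linear SVM, first vs follow-up session
#' compared fold-wise), and (5) EG arousal-valence centroids with quadrant
#' agreement. Results are returned and, when `out_dir` is given, written as
#' JSON/TSV files embedding the configuration hash and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list of class `result_bundle` with elements `responses`,
#'   `accuracy`, `stats`, `cv`, `comparisons`, `centroids`, `agreement`,
#'   `log`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  log_lines <- list()
  log_stage <- function(stage, participant, detail) {
    log_lines[[length(log_lines) + 1]] <<- tibble(
      stage = stage, participant = participant, detail = detail
    )
  }

  schedules <- build_study_schedules(config$design, seed = derive_seed(seed, 1))
  log_stage("schedules", "all", sprintf("%d participant-sessions", length(schedules)))

  responses <- simulate_verbal_responses(
    schedules, effect = config$effect, seed = derive_seed(seed, 2)
  )
  acc <- accuracy_table(responses)
  stats <- list(
    within_session = lapply(
      c(EG = "EG", CG = "CG"),
      function(g) within_session_test(acc, group = g)
    ),
    across_session = across_session_test(acc)
  )
  log_stage("responses", "all", sprintf("%d responses", nrow(responses)))

  roster <- study_roster(config$design)
  eeg_ids <- roster$participant_id[roster$has_eeg]
  features <- list()
  for (pid in eeg_ids) {
    for (ses in config$eeg_sessions) {
      key <- sprintf("%s_s%02d", pid, ses)
      sched <- schedules[[key]]
      if (is.null(sched)) next
      res <- process_session(
        sched, config,
        seed = derive_seed(seed, 100 + match(pid, roster$participant_id) * 10 + ses)
      )
      features[[key]] <- res$features
      log_stage(
        "features", key,
        sprintf("%d windows kept, %d rejected", nrow(res$features), res$n_rejected)
      )
    }
  }
  all_feats <- new_epoch_feature_set(bind_rows(features), "raw")
  norm_feats <- normalize_affect(all_feats, scope = config$norm_scope)

  cv <- list()
  comparisons <- list()
  for (pid in eeg_ids) {
    per_session <- lapply(config$eeg_sessions, function(ses) {
      sel <- filter(
        norm_feats,
        .data$participant_id == pid,
        .data$session_index == ses,
        .data$condition == "NM1"
      )
      sel <- new_epoch_feature_set(sel, "zscored")
      out <- tryCatch(
        list(
          ann = train_eval_ann(sel, config$folds, config$repeats,
                               seed = derive_seed(seed, 500 + ses)),
          svm = train_eval_linear_svm(sel, config$folds, config$repeats,
                                      seed = derive_seed(seed, 600 + ses))
        ),
        error = function(e) {
          log_stage("decode", sprintf("%s_s%02d", pid, ses),
                    paste("skipped:", conditionMessage(e)))
          NULL
        }
      )
      out
    })
    names(per_session) <- sprintf("s%02d", config$eeg_sessions)
    cv[[pid]] <- per_session
    ok <- !vapply(per_session, is.null, logical(1))
    if (length(config$eeg_sessions) == 2 && all(ok)) {
      comparisons[[pid]] <- compare_models(
        per_session[[2]]$ann, per_session[[1]]$ann
      )
    }
    if (any(ok)) {
      accs <- vapply(
        per_session[ok],
        function(s) s$ann$mean_accuracy, numeric(1)
      )
      log_stage("decode", pid,
                paste(sprintf("%s ann %.3f", names(accs), accs), collapse = "; "))
    }
  }

  centroids <- lapply(
    c(session1 = "session1", post_session4 = "post_session4"),
    function(tag) compute_centroids(norm_feats, session_tag = tag)
  )
  agreement <- lapply(centroids, quadrant_agreement)
  log_stage("centroids", "EG", sprintf(
    "quadrant agreement %d/4 (session1), %d/4 (post_session4)",
    attr(agreement$session1, "n_match"), attr(agreement$post_session4, "n_match")
  ))

  bundle <- structure(
    list(
      responses = responses,
      accuracy = acc,
      stats = stats,
      cv = cv,
      comparisons = comparisons,
      centroids = centroids,
      agreement = agreement,
      log = bind_rows(log_lines),
      config_hash = config_hash(config),
      seed = seed
    ),
    class = "result_bundle"
  )
  if (!is.null(out_dir)) {
    write_result_bundle(bundle, config, out_dir)
  }
  bundle
}

write_result_bundle <- function(bundle, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config_hash = bundle$config_hash, seed = bundle$seed)
  write_responses_tsv(bundle$responses, file.path(out_dir, "responses.tsv"))
  write.table(bundle$accuracy, file.path(out_dir, "accuracy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (pid in names(bundle$cv)) {
    per <- bundle$cv[[pid]]
    ser <- lapply(per, function(s) {
      if (is.null(s)) return(NULL)
      lapply(s, function(cvres) {
        list(
          classifier = cvres$classifier,
          fold_accuracy = cvres$fold_accuracy,
          mean_accuracy = cvres$mean_accuracy,
          confusion = as.data.frame.matrix(cvres$confusion),
          n_instances = cvres$n_instances,
          seed = cvres$seed
        )
      })
    })
    jsonlite::write_json(
      c(meta, list(participant = pid, results = ser)),
      file.path(out_dir, sprintf("cv_%s.json", pid)),
      auto_unbox = TRUE, digits = NA
    )
  }
  for (tag in names(bundle$centroids)) {
    write_centroids_tsv(
      bundle$centroids[[tag]],
      file.path(out_dir, sprintf("centroids_%s.tsv", tag))
    )
  }
  stats_ser <- list(
    within_session = lapply(bundle$stats$within_session,
                            function(t) as.list(tidy(t))),
    across_session = as.data.frame(bundle$stats$across_session)
  )
  jsonlite::write_json(
    c(meta, stats_ser), file.path(out_dir, "stats.json"),
    auto_unbox = TRUE, digits = NA
  )
  write.table(bundle$log, file.path(out_dir, "run_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle>\n")
  cat(sprintf("  responses: %d rows; accuracy cells: %d\n",
              nrow(x$responses), nrow(x$accuracy)))
  cat(sprintf("  decoded participants: %d\n", length(x$cv)))
  cat(sprintf("  centroid agreement: session1 %d/4, post_session4 %d/4\n",
              attr(x$agreement$session1, "n_match"),
              attr(x$agreement$post_session4, "n_match")))
  invisible(x)
}
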