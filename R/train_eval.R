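#' Experiment configuration for the three-stage pipeline
#'
#' Bundles the desk-scale study conditions: cohort geometry, the three-stage
#' training schedule (contrastive pre-training, supervised rPPG fine-tuning,
#' frozen-backbone end-to-end SpO2 training), and the ablation variant.
#' Reference full-scale learning rates are 0.001 / 0.0001 / 0.005 with
#' 300 / 200 / 50 epochs; the desk-scale epoch defaults keep the same
#' schedule shape at single-CPU cost.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param duration_s Recording length per subject in seconds.
#' @param rate Frame rate (fps).
#' @param frame_size Generated frame size in pixels.
#' @param roi_size Working ROI resolution fed to the backbone (multiple of 8).
#' @param width Backbone channel width multiplier (1 = full scale).
#' @param window_frames Analysis window length in frames.
#' @param epochs Length-3 integer vector: epochs for stages 1--3.
#' @param lrs Length-3 numeric vector: learning rates for stages 1--3
#'   (desk-scale overrides of the full-scale 0.001 / 0.0001 / 0.005
#'   schedule; short desk runs need a faster stage-3 rate to traverse the
#'   percent output scale).
#' @param head_batch Minibatch size for stage-3 head training.
#' @param batch_size Contrastive batch size.
#' @param hidden Head LSTM hidden size.
#' @param conv_channels Head convolution widths.
#' @param tuples_per_subject Contrastive windows drawn per subject (stage 1).
#' @param supervised_per_subject Labeled windows per subject (stage 2).
#' @param condition Test condition: `"stable"`, `"lighting"` or
#'   `"rotation"`.
#' @param variant Ablation variant: `"baseline"`, `"proposed-backbone"`,
#'   `"+contrastive"`, `"+mfam"` or `"full"`.
#' @param noise_sd Sensor noise level of the generator.
#' @param seed Master seed; all folds, initializations and shuffles derive
#'   from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 6, duration_s = 60, rate = 30,
                              frame_size = 64, roi_size = 16, width = 0.25,
                              window_frames = 60,
                              epochs = c(8, 8, 120),
                              lrs = c(0.001, 5e-4, 0.02),
                              batch_size = 4, head_batch = 16, hidden = 16,
                              conv_channels = c(8, 16),
                              tuples_per_subject = 2,
                              supervised_per_subject = 2,
                              condition = c("stable", "lighting", "rotation"),
                              variant = "full",
                              noise_sd = 0.003, seed = 1) {
  condition <- match.arg(condition)
  variants <- c("baseline", "proposed-backbone", "+contrastive", "+mfam", "full")
  if (!variant %in% variants) {
    stop_config(sprintf(
      "unknown variant '%s'; must be one of %s.", variant,
      paste(variants, collapse = ", ")
    ))
  }
  if (length(epochs) != 3 || length(lrs) != 3) {
    stop_config("`epochs` and `lrs` must have one entry per stage.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), duration_s = as.integer(duration_s),
      rate = rate, frame_size = as.integer(frame_size),
      roi_size = as.integer(roi_size), width = width,
      window_frames = as.integer(window_frames),
      epochs = as.integer(epochs), lrs = lrs,
      batch_size = as.integer(batch_size), head_batch = as.integer(head_batch),
      hidden = as.integer(hidden),
      conv_channels = as.integer(conv_channels),
      tuples_per_subject = as.integer(tuples_per_subject),
      supervised_per_subject = as.integer(supervised_per_subject),
      condition = condition, variant = variant,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

variant_flags <- function(variant) {
  list(
    contrastive = variant %in% c("+contrastive", "full"),
    mfam = variant %in% c("+mfam", "full"),
    bilstm = variant %in% c("proposed-backbone", "full")
  )
}

subject_scene <- function(cfg, i, seed_offset = 0) {
  scene_config(
    duration_s = cfg$duration_s, rate = cfg$rate, size = cfg$frame_size,
    hr_bpm = 62 + 4 * ((i - 1) %% 7),
    spo2_trace = make_spo2_trace(
      cfg$duration_s,
      kind = "dip",
      base = 99.5 - 0.4 * ((i - 1) %% 6),
      depth = 2.5 + 0.6 * ((i - 1) %% 5),
      t0 = cfg$duration_s * (0.3 + 0.08 * ((i - 1) %% 5)),
      width = cfg$duration_s / 8
    ),
    lighting_amp = if (cfg$condition == "lighting") 0.1 else 0,
    rotation_deg = if (cfg$condition == "rotation") 10 else 0,
    noise_sd = cfg$noise_sd,
    seed = cfg$seed * 1000L + seed_offset * 100L + i
  )
}

#' Generate and preprocess a synthetic cohort
#'
#' Renders one synthetic recording per subject (distinct heart rates, SpO2
#' dip trajectories and noise realizations), crops face and hand ROIs with
#' the generator-true boxes, rescales them to the working resolution, and
#' aligns the reference PPG and per-window SpO2 labels.
#'
#' @param cfg An [experiment_config()].
#' @param seed_offset Offset folded into per-subject seeds (used to draw
#'   independent test cohorts).
#' @return List of subject records: `id`, `face_roi`, `hand_roi`, `ppg`
#'   (aligned [waveform()]), `windows` (label tibble), `hr_bpm`.
#' @export
build_cohort <- function(cfg, seed_offset = 0) {
  lapply(seq_len(cfg$n_subjects), function(i) {
    sc <- subject_scene(cfg, i, seed_offset)
    smp <- generate_sample(sc)
    roi <- function(clip, box) {
      boxes <- detect_roi(clip, detector = "fixed", box = box)
      crop_resize(clip, boxes, out_size = cfg$roi_size)
    }
    face_roi <- roi(smp$face_clip, smp$face_box)
    hand_roi <- roi(smp$hand_clip, smp$hand_box)
    lab <- prepare_labels(smp$ppg, smp$spo2_trace, face_roi,
                          window_frames = cfg$window_frames)
    list(
      id = paste0("S", i), face_roi = face_roi, hand_roi = hand_roi,
      ppg = lab$ppg, windows = lab$windows, hr_bpm = sc$hr_bpm,
      spo2_trace = smp$spo2_trace
    )
  })
}

subject_window_clips <- function(subj, cfg) {
  lapply(seq_len(nrow(subj$windows)), function(k) {
    clip_window(subj$face_roi, subj$windows$start_frame[k], cfg$window_frames)
  })
}

#' Train the pipeline on a set of subjects under an ablation variant
#'
#' Runs the stages the variant calls for: contrastive pre-training and
#' supervised rPPG fine-tuning (variants with contrastive learning), then
#' frozen-backbone end-to-end SpO2 training of the head (all variants).
#'
#' @param subjects Subject records from [build_cohort()].
#' @param cfg An [experiment_config()].
#' @param variant Overrides `cfg$variant` if given.
#' @return A trained `spo2cam_model`.
#' @export
train_pipeline <- function(subjects, cfg, variant = NULL) {
  if (is.null(variant)) variant <- cfg$variant
  fl <- variant_flags(variant)
  est <- build_estimator(
    rppg_config(input_size = cfg$roi_size, width = cfg$width),
    seed = cfg$seed
  )
  wf <- cfg$window_frames
  if (fl$contrastive) {
    tuples <- list()
    labeled <- list()
    for (s in subjects) {
      tt <- n_frames(s$face_roi)
      n_take <- function(k) {
        starts <- unique(round(seq(1, tt - wf + 1, length.out = k)))
        starts
      }
      for (st in n_take(cfg$tuples_per_subject)) {
        tuples[[length(tuples) + 1]] <- make_contrastive_tuple(
          clip_window(s$face_roi, st, wf), clip_window(s$hand_roi, st, wf),
          seed = cfg$seed + length(tuples)
        )
      }
      for (st in n_take(cfg$supervised_per_subject)) {
        labeled[[length(labeled) + 1]] <- list(
          face = clip_window(s$face_roi, st, wf),
          ppg = waveform(s$ppg$samples[st:(st + wf - 1)], s$ppg$rate)
        )
      }
    }
    st1 <- train_stage1(
      est, tuples,
      stage_config(cfg$lrs[1], cfg$epochs[1], cfg$batch_size, cfg$seed)
    )
    st2 <- train_stage2(
      st1$est, labeled,
      stage_config(cfg$lrs[2], cfg$epochs[2], cfg$batch_size, cfg$seed)
    )
    est <- st2$est
  }
  model <- build_spo2_model(
    est,
    head_config(
      in_ch = if (fl$bilstm) 9L else 6L,
      conv_channels = if (fl$bilstm) cfg$conv_channels else integer(0),
      hidden = cfg$hidden, bidirectional = fl$bilstm
    ),
    use_mfam = fl$mfam, seed = cfg$seed
  )
  windows <- list()
  for (s in subjects) {
    clips <- subject_window_clips(s, cfg)
    for (k in seq_along(clips)) {
      windows[[length(windows) + 1]] <- list(
        clip = clips[[k]], spo2 = s$windows$spo2[k]
      )
    }
  }
  st3 <- train_stage3(
    model, windows, stage_config(cfg$lrs[3], cfg$epochs[3], cfg$head_batch, cfg$seed)
  )
  st3$model
}

evaluate_subject <- function(model, subj, cfg) {
  pred <- predict_spo2(model, subj$face_roi, cfg$window_frames)
  ref <- subj$windows$spo2
  err <- pred$spo2 - ref
  tibble::tibble(
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    # a degenerate (constant) prediction has no defined correlation
    pearson = if (stats::sd(pred$spo2) > 0 && stats::sd(ref) > 0) {
      stats::cor(pred$spo2, ref)
    } else {
      NA_real_
    }
  )
}

#' Leave-one-subject-out evaluation
#'
#' Each subject is held out exactly once: the remaining subjects train all
#' stages of the variant's pipeline, and the held-out subject's windows are
#' predicted. No held-out frames enter any training stage of their fold.
#' Reports per-subject MAE / RMSE / Pearson plus the MAE of the
#' predict-the-training-mean baseline, and aggregates across subjects as
#' median and interquartile range.
#'
#' @param subjects Subject records from [build_cohort()] (ids must be
#'   unique; at least 3 subjects).
#' @param cfg An [experiment_config()].
#' @param variant Overrides `cfg$variant`.
#' @return A tibble of class `spo2cam_eval` with one row per subject and a
#'   `summary` attribute (median/IQR of each metric).
#' @export
leave_one_out <- function(subjects, cfg, variant = NULL) {
  if (is.null(variant)) variant <- cfg$variant
  ids <- vapply(subjects, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_leakage("subject ids overlap across records.")
  if (length(subjects) < 3) stop_data("need at least 3 subjects.")
  rows <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    train_set <- subjects[-k]
    test_subj <- subjects[[k]]
    if (test_subj$id %in% vapply(train_set, `[[`, character(1), "id")) {
      stop_leakage("held-out subject appears in its own training fold.")
    }
    model <- train_pipeline(train_set, cfg, variant)
    m <- evaluate_subject(model, test_subj, cfg)
    train_mean <- mean(unlist(lapply(train_set, function(s) s$windows$spo2)))
    rows[[k]] <- tibble::tibble(
      subject = test_subj$id, variant = variant,
      mae = m$mae, rmse = m$rmse, pearson = m$pearson,
      mae_mean_pred = mean(abs(train_mean - test_subj$windows$spo2))
    )
  }
  rep <- do.call(rbind, rows)
  summ <- tibble::tibble(
    variant = variant,
    mae_median = stats::median(rep$mae), mae_iqr = stats::IQR(rep$mae),
    rmse_median = stats::median(rep$rmse), rmse_iqr = stats::IQR(rep$rmse),
    pearson_median = stats::median(rep$pearson, na.rm = TRUE),
    pearson_iqr = stats::IQR(rep$pearson, na.rm = TRUE),
    mae_mean_pred_median = stats::median(rep$mae_mean_pred)
  )
  attr(rep, "summary") <- summ
  class(rep) <- c("spo2cam_eval", class(rep))
  rep
}

#' Median/IQR summary of an evaluation report
#' @param report A `spo2cam_eval` tibble from [leave_one_out()].
#' @return A one-row tibble of medians and IQRs.
#' @export
eval_summary <- function(report) {
  s <- attr(report, "summary")
  if (is.null(s)) stop_state("`report` carries no summary attribute.")
  s
}

#' Run the ablation grid on identical folds
#'
#' Evaluates each variant with [leave_one_out()] on the same subjects, the
#' same folds and the same seeds, so differences are attributable to the
#' ablated component alone.
#'
#' @param subjects Subject records from [build_cohort()].
#' @param cfg An [experiment_config()].
#' @param variants Character vector of variants (default: all five).
#' @return A list with `reports` (per-variant `spo2cam_eval`) and `table`
#'   (one summary row per variant).
#' @export
run_ablation <- function(subjects, cfg,
                         variants = c("baseline", "proposed-backbone",
                                      "+contrastive", "+mfam", "full")) {
  known <- c("baseline", "proposed-backbone", "+contrastive", "+mfam", "full")
  bad <- setdiff(variants, known)
  if (length(bad)) stop_config(sprintf("unknown variant(s): %s", paste(bad, collapse = ", ")))
  reports <- lapply(variants, function(v) leave_one_out(subjects, cfg, v))
  names(reports) <- variants
  list(reports = reports, table = do.call(rbind, lapply(reports, eval_summary)))
}

#' Evaluate one trained model across recording conditions
#'
#' Trains the configured variant once on a stable-environment cohort, then
#' tests it on independently generated cohorts under the three conditions:
#' stable, lighting fluctuations, and face rotation.
#'
#' @param cfg An [experiment_config()].
#' @param conditions Conditions to test.
#' @return A tibble with one row per condition (mean over test subjects of
#'   MAE / RMSE / Pearson).
#' @export
condition_suite <- function(cfg, conditions = c("stable", "lighting", "rotation")) {
  train_cfg <- cfg
  train_cfg$condition <- "stable"
  train_subjects <- build_cohort(train_cfg)
  model <- train_pipeline(train_subjects, train_cfg)
  rows <- lapply(conditions, function(cond) {
    test_cfg <- cfg
    test_cfg$condition <- cond
    test_subjects <- build_cohort(test_cfg, seed_offset = 7)
    ms <- do.call(rbind, lapply(test_subjects, function(s) {
      evaluate_subject(model, s, test_cfg)
    }))
    tibble::tibble(
      condition = cond, mae = mean(ms$mae), rmse = mean(ms$rmse),
      pearson = mean(ms$pearson)
    )
  })
  do.call(rbind, rows)
}
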