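# End-to-end orchestration: preprocess -> coherence -> scores -> prediction,
# plus disk-based simulate/analyze runs with manifests.

#' Default artifact templates for stereotyped-component flagging
#'
#' Generic descriptors matched against ICA components: a frontal
#' low-frequency template for blinks (and eye movements) and a smooth
#' whole-array gradient with a ~1.2 Hz period for cardiac components.
#'
#' @param montage `fpcoh_montage`
#' @param cardiac_period_s expected cardiac period (default 1/1.2 s)
#' @return list of templates for [flag_stereotyped_artifacts()]
#' @export
default_artifact_templates <- function(montage, cardiac_period_s = 1 / 1.2) {
  list(
    list(reason = "blink", topography = frontal_topography(montage),
         max_centroid_hz = 6),
    list(reason = "cardiac", topography = cardiac_topography(montage),
         period_s = cardiac_period_s))
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed order: average re-reference, zero-phase 50 Hz low-pass, 1-s
#' epoching with detrend, amplitude-based epoch rejection, and (optionally)
#' Infomax ICA with automatic and template-based artifact-component
#' rejection followed by reconstruction. Every step is recorded in the
#' epoch set's provenance.
#'
#' @param rec `fpcoh_recording`
#' @param ica run the ICA stage (default TRUE)
#' @param ica_seed seed for the ICA fit (required when `ica = TRUE`)
#' @param n_components ICA components (default: data rank up to 64)
#' @param amp_limit_uV epoch peak-amplitude rejection limit (default 100)
#' @param tau_single,tau_muscle automatic-rule thresholds (defaults 0.8, 0.5)
#' @param templates stereotyped-artifact templates (default
#'   [default_artifact_templates()] on the recording's montage)
#' @return cleaned `fpcoh_epochs`
#' @export
preprocess_subject <- function(rec, ica = TRUE, ica_seed = NULL,
                               n_components = NULL, amp_limit_uV = 100,
                               tau_single = 0.8, tau_muscle = 0.5,
                               templates = NULL) {
  rec <- rereference_average(rec)
  rec <- lowpass_50(rec)
  ep <- epoch_and_detrend(rec)
  ep <- reject_epochs_amplitude(ep, amp_limit_uV)
  if (!ica) return(ep)
  if (is.null(ica_seed)) stop("ica_seed is required when ica = TRUE")
  if (is.null(n_components)) {
    # average reference removes one degree of freedom
    n_components <- min(dim(ep$epochs)[1] - 1L, 64L)
  }
  dec <- decompose_ica(ep, n_components = n_components, rng_seed = ica_seed)
  dec <- auto_flag_components(dec, tau_single = tau_single,
                              tau_muscle = tau_muscle)
  if (is.null(templates))
    templates <- default_artifact_templates(rec$montage)
  dec <- flag_stereotyped_artifacts(dec, templates)
  reconstruct_clean(dec, ep)
}

#' Analyze an in-memory synthetic cohort end to end
#'
#' Preprocesses every subject's recording, estimates the coherence table,
#' combines it with the tracking scores into subject records, and runs the
#' prediction, change and baseline analyses.
#'
#' @param cohort `fpcoh_cohort` generated with EEG
#' @param ica run the ICA stage (default FALSE: artifact-free cohorts do
#'   not need it)
#' @param bands band map (default [default_bands()])
#' @param lesion_excluded optional logical vector of per-subject exclusion
#'   flags (default none excluded)
#' @param ... passed to [preprocess_subject()]
#' @return list with `records`, `prediction`, `changes`, `baseline`,
#'   `coherence` (long data frame over subjects)
#' @export
analyze_cohort <- function(cohort, ica = FALSE, bands = default_bands(),
                           lesion_excluded = NULL, ...) {
  subs <- cohort$subjects
  if (is.null(subs[[1]]$recording))
    stop("cohort was generated without EEG; re-run generate_cohort(eeg=TRUE)")
  if (is.null(lesion_excluded)) lesion_excluded <- rep(FALSE, length(subs))
  records <- vector("list", length(subs))
  coh_rows <- list()
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    ep <- preprocess_subject(s$recording, ica = ica,
                             ica_seed = if (ica) s$truth$seed + 1L else NULL,
                             ...)
    tab <- coherence_table(ep, cohort$rois, bands)
    coh_rows[[i]] <- cbind(subject_id = s$id, tab)
    records[[i]] <- subject_record(s$id, tab,
                                   sr_pre = s$pre$sr, sr_post = s$post$sr,
                                   er_pre = s$pre$er, er_post = s$post$er,
                                   excluded_lesion = lesion_excluded[i])
  }
  list(records = records,
       prediction = run_prediction(records, cohort$rois, names(bands), "sr"),
       changes = change_tests(records),
       baseline = baseline_relation(records),
       coherence = do.call(rbind, coh_rows))
}

write_manifest <- function(dir, files, extra = list()) {
  hashes <- tools::md5sum(file.path(dir, files))
  manifest <- c(list(files = lapply(seq_along(files), function(i)
    list(path = files[i], md5 = unname(hashes[i])))), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a cohort and write its artifacts to disk
#'
#' Writes per-subject EEG (EDF and/or CSV), pre/post trace CSVs,
#' calibration JSONs, the ground-truth JSON, the montage and ROI
#' configuration, and a manifest with content hashes. Rerunning with the
#' same configuration reproduces identical content.
#'
#' @param config `fpcoh_simconfig`
#' @param out_dir output directory (created if missing)
#' @param eeg_format `"edf"`, `"csv"`, or `"none"`
#' @param ... passed to [generate_cohort()]
#' @return the cohort, invisibly
#' @export
run_simulate <- function(config, out_dir, eeg_format = c("edf", "csv", "none"),
                         ...) {
  eeg_format <- match.arg(eeg_format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output dir not writable: ", out_dir)
  cohort <- generate_cohort(config, eeg = eeg_format != "none", ...)
  files <- character()
  put <- function(f) files <<- c(files, f)
  write_montage_csv(cohort$montage, file.path(out_dir, "montage.csv"))
  put("montage.csv")
  write_roi_config(cohort$rois, file.path(out_dir, "rois.json"))
  put("rois.json")
  for (s in cohort$subjects) {
    if (eeg_format == "edf") {
      write_edf(s$recording, file.path(out_dir, paste0(s$id, "_eeg.edf")))
      put(paste0(s$id, "_eeg.edf"))
    } else if (eeg_format == "csv") {
      utils::write.csv(data.frame(lead_id = rownames(s$recording$data),
                                  s$recording$data, check.names = FALSE),
                       file.path(out_dir, paste0(s$id, "_eeg.csv")),
                       row.names = FALSE, quote = FALSE)
      put(paste0(s$id, "_eeg.csv"))
    }
    for (k in 1:3) {
      write_trace_csv(s$pre_traces[[k]],
                      file.path(out_dir, sprintf("%s_pre_run%d.csv", s$id, k)))
      put(sprintf("%s_pre_run%d.csv", s$id, k))
      write_trace_csv(s$post_traces[[k]],
                      file.path(out_dir, sprintf("%s_post_run%d.csv", s$id, k)))
      put(sprintf("%s_post_run%d.csv", s$id, k))
    }
    jsonlite::write_json(
      list(rounds = s$calibration$rounds, fit = s$calibration$fit,
           v_maxerr = s$calibration$v_maxerr, v_train = s$calibration$v_train),
      file.path(out_dir, paste0(s$id, "_calibration.json")),
      auto_unbox = TRUE, digits = NA)
    put(paste0(s$id, "_calibration.json"))
  }
  utils::write.csv(cohort$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  put("ground_truth.csv")
  jsonlite::write_json(cohort$truth, file.path(out_dir, "ground_truth.json"),
                       dataframe = "rows", digits = NA)
  put("ground_truth.json")
  write_manifest(out_dir, files,
                 extra = list(n_subjects = config$n_subjects,
                              fs_eeg = config$fs_eeg,
                              seed = config$rng_seed,
                              eeg_format = eeg_format))
  invisible(cohort)
}

#' Analyze a simulated cohort directory
#'
#' Loads the artifacts written by [run_simulate()], re-runs preprocessing
#' and coherence estimation, scores the traces, and writes coherence,
#' score and prediction CSVs plus a summary JSON covering the full and
#' lesion-excluded cohorts.
#'
#' @param in_dir directory produced by [run_simulate()]
#' @param out_dir report directory (default `file.path(in_dir, "report")`)
#' @param ica run the ICA stage (default FALSE)
#' @param ica_seed seed for ICA when enabled
#' @param lesion_excluded optional per-subject exclusion flags (recycled
#'   from a `lesion_flags.csv` with columns subject_id,excluded if present)
#' @return list as from [analyze_cohort()], invisibly
#' @export
run_analyze <- function(in_dir, out_dir = file.path(in_dir, "report"),
                        ica = FALSE, ica_seed = 1L, lesion_excluded = NULL) {
  man_path <- file.path(in_dir, "manifest.json")
  if (!file.exists(man_path)) stop("missing input: ", man_path)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  montage <- read_montage_csv(file.path(in_dir, "montage.csv"),
                              neighbor_factor = 1.001)
  rois <- load_roi_config(file.path(in_dir, "rois.json"), montage)
  truth <- utils::read.csv(file.path(in_dir, "ground_truth.csv"))
  flags_path <- file.path(in_dir, "lesion_flags.csv")
  if (is.null(lesion_excluded) && file.exists(flags_path)) {
    fl <- utils::read.csv(flags_path)
    lesion_excluded <- as.logical(fl$excluded[match(truth$subject,
                                                    fl$subject_id)])
  }
  if (is.null(lesion_excluded))
    lesion_excluded <- rep(FALSE, nrow(truth))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- vector("list", nrow(truth))
  coh_rows <- list()
  for (i in seq_len(nrow(truth))) {
    id <- truth$subject[i]
    edf <- file.path(in_dir, paste0(id, "_eeg.edf"))
    csv <- file.path(in_dir, paste0(id, "_eeg.csv"))
    if (file.exists(edf)) {
      e <- read_edf(edf)
      rec <- eeg_recording(e$data, e$fs, montage)
    } else if (file.exists(csv)) {
      df <- utils::read.csv(csv, check.names = FALSE)
      rec <- eeg_recording(as.matrix(df[, -1]), man$fs_eeg, montage)
    } else stop("missing EEG for subject ", id, ": ", edf, " or ", csv)
    ep <- preprocess_subject(rec, ica = ica,
                             ica_seed = if (ica) ica_seed + i else NULL)
    tab <- coherence_table(ep, rois)
    coh_rows[[i]] <- cbind(subject_id = id, tab)
    runs <- function(ph) lapply(1:3, function(k)
      read_trace_csv(file.path(in_dir, sprintf("%s_%s_run%d.csv", id, ph, k))))
    pre <- score_battery(runs("pre")); post <- score_battery(runs("post"))
    records[[i]] <- subject_record(id, tab, pre$sr, post$sr, pre$er, post$er,
                                   excluded_lesion = lesion_excluded[i])
  }
  res <- list(records = records,
              prediction = run_prediction(records, rois),
              changes = change_tests(records),
              baseline = baseline_relation(records),
              coherence = do.call(rbind, coh_rows))
  utils::write.csv(res$coherence, file.path(out_dir, "coherence.csv"),
                   row.names = FALSE)
  utils::write.csv(res$prediction, file.path(out_dir, "prediction.csv"),
                   row.names = FALSE)
  scores <- do.call(rbind, lapply(records, function(r)
    data.frame(subject_id = r$subject_id, sr_pre = r$sr_pre,
               sr_post = r$sr_post, er_pre = r$er_pre, er_post = r$er_post,
               pct_change_sr = r$pct_change_sr,
               pct_change_er = r$pct_change_er,
               excluded_lesion = r$excluded_lesion)))
  utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  prim <- res$prediction[1, ]
  jsonlite::write_json(
    list(n_subjects = nrow(truth),
         lesion_excluded_n = sum(lesion_excluded),
         lesion_flags_present = any(lesion_excluded),
         primary = as.list(prim),
         changes = res$changes),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
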