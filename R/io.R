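#' Write per-run event files
#'
#' One tab-separated events file per run with columns `onset`, `duration`,
#' `trial_type` (BIDS events layout).
#'
#' @param schedule A `trial_schedule`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default "run").
#' @return Invisibly, the written file paths.
#' @export
write_events_tsv <- function(schedule, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(unique(schedule$run), function(r) {
    s <- schedule[schedule$run == r, c("onset", "duration", "trial_type")]
    p <- file.path(dir, sprintf("%s-%02d_events.tsv", prefix, r))
    utils::write.table(s, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Read per-run event files into a schedule
#'
#' Reconstructs a `trial_schedule` from events files written by
#' [write_events_tsv()] (or any BIDS-style events TSV with the eight
#' paradigm trial types). Run indices are taken from file order.
#'
#' @param paths Character vector of events TSV paths, one per run.
#' @param lead_in,lead_out,trial_duration Schedule attributes not stored in
#'   the events files.
#' @return A `trial_schedule`.
#' @export
read_events_tsv <- function(paths, lead_in = 30, lead_out = 30,
                            trial_duration = 5.5) {
  runs <- lapply(seq_along(paths), function(k) {
    d <- utils::read.delim(paths[k], stringsAsFactors = FALSE)
    stopifnot(all(c("onset", "duration", "trial_type") %in% names(d)))
    data.frame(run = k, trial = seq_len(nrow(d)), onset = d$onset,
               duration = d$duration, trial_type = d$trial_type,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, runs)
  parts <- strsplit(out$trial_type, "_", fixed = TRUE)
  out$laterality <- vapply(parts, `[`, "", 1L)
  out$body_part <- vapply(parts, `[`, "", 2L)
  out$painful <- vapply(parts, `[`, "", 3L) == "pain"
  soa <- if (nrow(runs[[1]]) > 1) diff(runs[[1]]$onset[1:2]) else 5.5
  structure(out, class = c("trial_schedule", "data.frame"), soa = soa,
            lead_in = lead_in, lead_out = lead_out,
            trial_duration = trial_duration,
            stim_duration = out$duration[1],
            run_duration = lead_in + nrow(runs[[1]]) * soa + lead_out)
}

#' Write a skin-conductance trace with a JSON sidecar
#'
#' Two-column TSV (`time`, `conductance` in muS) plus a sidecar recording
#' the sampling rate, run index and event markers.
#'
#' @param trace An `scr_trace`.
#' @param path TSV path; the sidecar replaces the extension with `.json`.
#' @return Invisibly `path`.
#' @export
write_scr_tsv <- function(trace, path) {
  tt <- (seq_along(trace$samples) - 1) / trace$sampling_rate
  utils::write.table(data.frame(time = tt, conductance = trace$samples),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(sampling_rate = trace$sampling_rate,
                            run = trace$run, onsets = trace$onsets),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a skin-conductance trace written by [write_scr_tsv()]
#'
#' @param path TSV path (sidecar expected alongside).
#' @return An `scr_trace`.
#' @export
read_scr_tsv <- function(path) {
  d <- utils::read.delim(path)
  sc <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                            simplifyVector = TRUE)
  structure(list(samples = d$conductance, sampling_rate = sc$sampling_rate,
                 run = sc$run, onsets = sc$onsets),
            class = "scr_trace")
}

#' Write / read a region time-series table
#'
#' TSV with one column per region, one row per volume.
#'
#' @param bold Matrix volumes x regions.
#' @param path TSV path.
#' @return Invisibly `path`.
#' @export
write_roi_tsv <- function(bold, path) {
  utils::write.table(as.data.frame(bold), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_tsv
#' @return For `read_roi_tsv`, a numeric matrix.
#' @export
read_roi_tsv <- function(path) {
  as.matrix(utils::read.delim(path))
}

#' Write a model-evidence table
#'
#' Long-format TSV with columns `subject`, `model`, `F` (and optionally
#' `session`).
#'
#' @param evidence Subjects x models matrix of summed log evidence.
#' @param path TSV path.
#' @return Invisibly `path`.
#' @export
write_evidence_tsv <- function(evidence, path) {
  ev <- as.matrix(evidence)
  d <- data.frame(subject = rep(seq_len(nrow(ev)), ncol(ev)),
                  model = rep(seq_len(ncol(ev)), each = nrow(ev)),
                  F = as.vector(ev))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a model-evidence table written by [write_evidence_tsv()]
#'
#' @param path TSV path.
#' @return Subjects x models matrix.
#' @export
read_evidence_tsv <- function(path) {
  d <- utils::read.delim(path)
  ev <- matrix(NA_real_, max(d$subject), max(d$model))
  ev[cbind(d$subject, d$model)] <- d$F
  ev
}

#' Serialise a DCM fit to JSON
#'
#' Posterior means, covariance, free energy and convergence diagnostics.
#'
#' @param fit A `dcm_fit`.
#' @param path JSON path.
#' @return Invisibly `path`.
#' @export
write_dcm_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$spec$name, theta = as.list(fit$theta),
         Sigma = unname(fit$Sigma), F = fit$F,
         lambda = as.numeric(fit$lambda), converged = fit$converged,
         iterations = fit$iterations),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a group-dataset manifest
#'
#' JSON record of the cohort: per-subject id, group label and ground-truth
#' parameters, together with the effect specification and the generating
#' seed, sufficient to regenerate the dataset with [generate_group()].
#'
#' @param dataset A `group_dataset`.
#' @param path JSON path.
#' @return Invisibly `path`.
#' @export
write_group_manifest <- function(dataset, path) {
  subjects <- lapply(dataset$subjects, function(s) {
    list(id = s$id, group = s$group,
         dprime = s$truth$dprime, criterion = s$truth$criterion,
         scr_all = s$truth$scr_all, scr_pain = s$truth$scr_pain,
         b_diag = as.list(s$truth$b_diag),
         eq = s$truth$eq, tas20 = s$truth$tas20)
  })
  jsonlite::write_json(list(seed = dataset$seed,
                            effect_spec = unclass(dataset$effect_spec),
                            subjects = subjects),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a DCM specification as JSON
#'
#' @param spec A `dcm_spec`.
#' @param path JSON path.
#' @return Invisibly `path`; for `read_dcm_spec_json`, a `dcm_spec`.
#' @export
write_dcm_spec_json <- function(spec, path) {
  jsonlite::write_json(list(name = spec$name, b_self = spec$b_self,
                            b_extrinsic = spec$b_extrinsic),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dcm_spec_json
#' @export
read_dcm_spec_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  dcm_spec(j$name, j$b_self, j$b_extrinsic)
}
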