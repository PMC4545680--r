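#' Group-difference specification for the synthetic cohort
#'
#' Offsets added to the control-group population means for subjects in the
#' ASD group. Defaults emulate the reported direction and magnitude of the
#' study's effects: lower sensitivity (control hit/false-alarm means imply
#' d' near 3.0 versus 2.26), slightly more conservative criterion, reduced
#' overall skin-conductance responding with an enhanced pain-specific
#' component, greater pain-related disinhibition of the AIC
#' self-connection (-0.5 on the log scale), lower trait empathy and higher
#' alexithymia.
#'
#' @param dprime,criterion Behavioral offsets.
#' @param scr_all,scr_pain Skin-conductance amplitude offsets (muS).
#' @param b_aic_self Offset on the pain modulation of the AIC
#'   self-connection (log scale).
#' @param eq,tas20 Trait score offsets.
#' @return Named list of class `group_effects`.
#' @export
group_effects <- function(dprime = -0.77, criterion = 0.135,
                          scr_all = -0.4, scr_pain = 0.25,
                          b_aic_self = -0.5, eq = -24, tas20 = 18) {
  structure(list(dprime = dprime, criterion = criterion, scr_all = scr_all,
                 scr_pain = scr_pain, b_aic_self = b_aic_self, eq = eq,
                 tas20 = tas20),
            class = "group_effects")
}

#' Null group-difference specification
#'
#' All offsets zero: both groups are draws from one population, for
#' type-I-error checks.
#'
#' @return A `group_effects` with all zeros.
#' @export
null_effects <- function() {
  group_effects(dprime = 0, criterion = 0, scr_all = 0, scr_pain = 0,
                b_aic_self = 0, eq = 0, tas20 = 0)
}

# Control-group population means and between-subject standard deviations.
group_population <- function() {
  list(mean = list(dprime = 3.03, criterion = -0.04,
                   scr_all = 0.5, scr_pain = 0.05,
                   b_diag = c(AIC = -0.4, EBA = -0.4, LPFC = -0.4),
                   eq = 42, tas20 = 40),
       sd = list(dprime = 0.45, criterion = 0.15,
                 scr_all = 0.15, scr_pain = 0.1,
                 b_diag = 0.2, eq = 9, tas20 = 8))
}

#' Generate a two-group synthetic dataset with known ground truth
#'
#' Draws per-subject true parameters from the population model (control
#' means plus `effect_spec` offsets for ASD subjects, with between-subject
#' Gaussian variation), then builds each subject's schedule and the
#' requested measured components from those parameters, so behavior, skin
#' conductance and BOLD are mutually consistent within subject.
#'
#' @param n_per_group Subjects per group (>= 2; default 15, the per-group
#'   fMRI sample analysed in the study).
#' @param effect_spec A `group_effects` (default [group_effects()]).
#' @param seed Integer seed; fixes every draw.
#' @param components Character subset of `c("behavior", "scr", "bold")`
#'   naming the measured data to synthesise (ground-truth parameters are
#'   always returned; with `character(0)` only parameters and traits are
#'   drawn and no schedule is built).
#' @param n_runs Runs per subject (default 4).
#' @param model Generating model index (default 8).
#' @param snr BOLD signal-to-noise ratio (default 2).
#' @param scr_sampling_rate Hz for skin-conductance traces (default 100).
#' @param scr_noise_sd Skin-conductance noise, muS.
#' @return List of class `group_dataset`: `subjects` (each with `id`,
#'   `group`, `truth`, `schedule`, and the requested components),
#'   `effect_spec`, `population`, `seed`.
#' @export
generate_group <- function(n_per_group = 15,
                           effect_spec = group_effects(), seed = 1,
                           components = "behavior", n_runs = 4, model = 8,
                           snr = 2, scr_sampling_rate = 100,
                           scr_noise_sd = 0.02) {
  stopifnot(n_per_group >= 2)
  pop <- group_population()
  set.seed(seed)
  n_total <- 2L * n_per_group
  groups <- rep(c("HC", "ASD"), each = n_per_group)
  subject_seeds <- sample.int(.Machine$integer.max %/% 2L, 3L * n_total)
  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    asd <- groups[i] == "ASD"
    off <- function(nm) if (asd) effect_spec[[nm]] else 0
    set.seed(subject_seeds[i])
    truth <- list(
      dprime = max(0, pop$mean$dprime + off("dprime") +
                     stats::rnorm(1, 0, pop$sd$dprime)),
      criterion = pop$mean$criterion + off("criterion") +
        stats::rnorm(1, 0, pop$sd$criterion),
      scr_all = max(0.05, pop$mean$scr_all + off("scr_all") +
                      stats::rnorm(1, 0, pop$sd$scr_all)),
      scr_pain = pop$mean$scr_pain + off("scr_pain") +
        stats::rnorm(1, 0, pop$sd$scr_pain),
      b_diag = pop$mean$b_diag + c(off("b_aic_self"), 0, 0) +
        stats::rnorm(3, 0, pop$sd$b_diag),
      eq = pop$mean$eq + off("eq") + stats::rnorm(1, 0, pop$sd$eq),
      tas20 = pop$mean$tas20 + off("tas20") +
        stats::rnorm(1, 0, pop$sd$tas20),
      group_mean_b_aic = pop$mean$b_diag[["AIC"]] + off("b_aic_self"))
    params <- dcm_ground_truth(model = model,
                               b_aic_self = truth$b_diag[["AIC"]])
    diag(params$B)[2:3] <- truth$b_diag[2:3] *
      as.numeric(dcm_model_space()[[model]]$b_self)
    truth$dcm_params <- params
    schedule <- if (length(components)) {
      generate_schedule(n_runs = n_runs, seed = subject_seeds[n_total + i])
    }
    sub <- list(id = sprintf("sub-%02d", i), group = groups[i],
                truth = truth, schedule = schedule)
    if ("behavior" %in% components) {
      sub$behavior <- generate_behavior(schedule, truth$dprime,
                                        truth$criterion,
                                        seed = subject_seeds[2L * n_total + i])
    }
    if ("scr" %in% components) {
      sub$scr <- generate_scr(
        schedule,
        amplitudes = list(all = truth$scr_all, pain = truth$scr_pain,
                          trial_sd = 0.05),
        noise_sd = scr_noise_sd, sampling_rate = scr_sampling_rate,
        seed = subject_seeds[2L * n_total + i] + 1L)
    }
    if ("bold" %in% components) {
      sub$bold <- generate_bold(schedule, params, snr = snr,
                                seed = subject_seeds[2L * n_total + i] + 2L)
    }
    subjects[[i]] <- sub
  }
  structure(list(subjects = subjects, effect_spec = effect_spec,
                 population = pop, seed = seed),
            class = "group_dataset")
}

#' Extract one per-subject ground-truth measure from a group dataset
#'
#' @param dataset A `group_dataset`.
#' @param measure Name within each subject's `truth` (e.g. `"dprime"`), or
#'   `"b_aic_self"` for the AIC entry of `b_diag`.
#' @return Data.frame with `id`, `group`, `value`.
#' @export
group_truth_table <- function(dataset, measure) {
  vals <- vapply(dataset$subjects, function(s) {
    if (measure == "b_aic_self") s$truth$b_diag[["AIC"]]
    else as.numeric(s$truth[[measure]])
  }, numeric(1))
  data.frame(id = vapply(dataset$subjects, `[[`, "", "id"),
             group = vapply(dataset$subjects, `[[`, "", "group"),
             value = vals, stringsAsFactors = FALSE)
}
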