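#' Trial types of the empathy-for-pain paradigm
#'
#' The eight stimulus categories cross laterality (left/right), body part
#' (hand/foot) and pain (painful/nonpainful).
#'
#' @return Character vector of the 8 trial-type labels.
#' @export
trial_types <- function() {
  as.vector(outer(
    as.vector(outer(c("L", "R"), c("hand", "foot"), paste, sep = "_")),
    c("pain", "nopain"), paste, sep = "_"))
}

#' Generate counterbalanced trial schedules
#'
#' Builds per-run event schedules for the empathy-for-pain paradigm: 64 trials
#' per run (8 of each of the 8 types), a fixed stimulus-onset asynchrony, and
#' fixation pads at the start and end of the run. Transition counterbalancing
#' is achieved by walking a seeded Eulerian circuit on the complete directed
#' graph (with self-loops) over the 8 types, so that each ordered type pair
#' occurs at most once among the 63 within-run transitions.
#'
#' @param n_runs Number of runs (default 4).
#' @param seed Integer seed fixing the pseudo-randomised order.
#' @param soa Stimulus onset asynchrony in seconds (default 5.5).
#' @param trial_duration Trial duration in seconds (default 5.5: 2.5 s
#'   stimulus/response window followed by 3 s fixation).
#' @param stim_duration Stimulus presentation / response window in seconds
#'   (default 2.5).
#' @param lead_in,lead_out Fixation pads in seconds before the first and after
#'   the last trial (default 30 each), allowing skin-conductance and
#'   hemodynamic responses to return to baseline.
#' @return A data.frame of class `trial_schedule` with columns `run`, `trial`,
#'   `onset`, `duration`, `trial_type`, `laterality`, `body_part`, `painful`,
#'   and attributes `soa`, `lead_in`, `lead_out`, `stim_duration`,
#'   `run_duration`.
#' @export
generate_schedule <- function(n_runs = 4, seed = 1, soa = 5.5,
                              trial_duration = 5.5, stim_duration = 2.5,
                              lead_in = 30, lead_out = 30) {
  stopifnot(n_runs >= 1, soa > 0, lead_in >= 0, lead_out >= 0)
  types <- trial_types()
  set.seed(seed)
  runs <- lapply(seq_len(n_runs), function(r) {
    seq8 <- eulerian_type_sequence(8L)
    data.frame(
      run = r,
      trial = seq_len(64L),
      onset = lead_in + soa * (0:63),
      duration = stim_duration,
      trial_type = types[seq8],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, runs)
  parts <- strsplit(out$trial_type, "_", fixed = TRUE)
  out$laterality <- vapply(parts, `[`, "", 1L)
  out$body_part <- vapply(parts, `[`, "", 2L)
  out$painful <- vapply(parts, `[`, "", 3L) == "pain"
  structure(out,
            class = c("trial_schedule", "data.frame"),
            soa = soa, lead_in = lead_in, lead_out = lead_out,
            trial_duration = trial_duration, stim_duration = stim_duration,
            run_duration = lead_in + 64 * soa + lead_out)
}

# Sources of the 64 edges of a random Eulerian circuit on the complete
# directed graph with self-loops over k vertices: each vertex appears exactly
# k times and each ordered pair is used at most once (Hierholzer's algorithm,
# ties broken by the current RNG state).
eulerian_type_sequence <- function(k = 8L) {
  succ <- lapply(seq_len(k), function(v) sample.int(k))
  nleft <- rep(k, k)
  start <- sample.int(k, 1L)
  stack <- c(start)
  circuit <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    if (nleft[v] > 0L) {
      w <- succ[[v]][nleft[v]]
      nleft[v] <- nleft[v] - 1L
      stack <- c(stack, w)
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  circuit <- rev(circuit)   # closed walk of k^2 + 1 vertices
  circuit[seq_len(k * k)]   # sources of the k^2 edges
}

#' Check schedule invariants
#'
#' Verifies trial counts (64 per run, 8 per type), constant onset spacing and
#' the fixation pads. Called by downstream generators; errors on violation.
#'
#' @param schedule A `trial_schedule`.
#' @return Invisibly `TRUE`.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  soa <- attr(schedule, "soa")
  for (r in unique(schedule$run)) {
    s <- schedule[schedule$run == r, ]
    if (nrow(s) != 64L) stop("run ", r, ": expected 64 trials")
    if (any(table(s$trial_type) != 8L))
      stop("run ", r, ": expected 8 trials of each of the 8 types")
    if (max(abs(diff(s$onset) - soa)) > 1e-9)
      stop("run ", r, ": onsets must be spaced by the SOA")
    if (s$onset[1] < attr(schedule, "lead_in") - 1e-9)
      stop("run ", r, ": first onset inside the lead-in pad")
    run_end <- s$onset[64] + attr(schedule, "trial_duration")
    if (attr(schedule, "run_duration") - run_end <
        attr(schedule, "lead_out") - attr(schedule, "trial_duration") - 1e-9)
      stop("run ", r, ": insufficient lead-out pad")
  }
  invisible(TRUE)
}

#' Transition counts between trial types
#'
#' Tabulates successive type-to-type transitions within each run; used to
#' verify the counterbalancing of the pseudo-randomised design.
#'
#' @param schedule A `trial_schedule`.
#' @return 8 x 8 integer matrix of transition counts (from row to column).
#' @export
transition_counts <- function(schedule) {
  types <- trial_types()
  tab <- matrix(0L, 8, 8, dimnames = list(types, types))
  for (r in unique(schedule$run)) {
    s <- schedule$trial_type[schedule$run == r]
    for (i in seq_len(length(s) - 1L)) {
      tab[s[i], s[i + 1L]] <- tab[s[i], s[i + 1L]] + 1L
    }
  }
  tab
}
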