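## Synthetic 2IFC observer.
##
## The observer is a noisy-W comparator: each interval's pattern is encoded
## with independent Gaussian positional noise, optionally passed through a
## feature-based colour filter on cued trials, and scored with the
## holographic goodness W; the interval with the larger internal W is
## chosen. It is a minimal stand-in for human participants that reproduces
## the qualitative behavioural structure of the task (segregation benefit,
## cue benefit for colour-segregated symmetry, cue cost for nongrouped
## antisymmetry, chance performance when the attended colour carries no
## symmetry), not a mechanistic claim.

#' Observer parameters
#'
#' @param sigma_pos Positional encoding noise SD: degrees of polar angle
#'   for wedges, degrees of visual angle for dots. Must be >= 0.
#' @param attention_filter Probability in `[0, 1]` that, on a cued trial,
#'   symmetry matching is restricted to elements of the cued colour.
#' @param cue_utilization Factor in `[0, 1]` scaling `attention_filter`;
#'   captures age- and stimulus-specific differences in how much of the cue
#'   is exploited.
#' @param lapse_rate Probability of a uniformly random response.
#' @param match_tolerance Matching tolerance passed to [score_symmetry()];
#'   `NULL` uses the geometry default.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(sigma_pos = 2, attention_filter = 0.9,
                            cue_utilization = 1, lapse_rate = 0.02,
                            match_tolerance = NULL) {
  probs <- c(attention_filter, cue_utilization, lapse_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sigma_pos < 0) stop("`sigma_pos` must be >= 0", call. = FALSE)
  structure(
    list(sigma_pos = sigma_pos, attention_filter = attention_filter,
         cue_utilization = cue_utilization, lapse_rate = lapse_rate,
         match_tolerance = match_tolerance),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> sigma_pos = %.3g, filter = %.2g x %.2g, lapse = %.2g\n",
    x$sigma_pos, x$attention_filter, x$cue_utilization, x$lapse_rate))
  invisible(x)
}

#' Observer presets by age group and stimulus type
#'
#' Configuration presets emulating the qualitative age dissociation:
#' older observers carry larger positional encoding noise for both stimulus
#' types, exploit colour cues fully for wedge patterns (where cueing lets
#' them overcome their deficit) but hardly at all for dot patterns (where
#' cueing fails to help them). The presets are configuration for synthetic
#' data, not fitted estimates.
#'
#' @param age `"younger"` or `"older"`.
#' @param stimulus `"wedge"` or `"dot"`.
#' @return An [observer_params()].
#' @export
observer_preset <- function(age = c("younger", "older"),
                            stimulus = c("wedge", "dot")) {
  age <- match.arg(age)
  stimulus <- match.arg(stimulus)
  sigma <- if (stimulus == "wedge") 2.5 else 0.33
  if (age == "older") sigma <- sigma * 1.6
  cue_util <- if (age == "older" && stimulus == "dot") 0.15 else 1
  observer_params(sigma_pos = sigma, attention_filter = 0.9,
                  cue_utilization = cue_util, lapse_rate = 0.02)
}

## Structural colour-grouping check: a hemifield-pure two-colour layout is
## perceptually obvious, so the observer treats the colour cue as neutral
## and does not filter (attention is distributed over both colours).
is_colour_grouped <- function(pattern) {
  el <- pattern$elements
  hemi <- element_hemifield(pattern)
  lc <- unique(el$colour[hemi == "left"])
  rc <- unique(el$colour[hemi == "right"])
  length(lc) == 1 && length(rc) == 1 && lc != rc
}

#' Internal noisy goodness of a pattern
#'
#' Jitters every element position with independent zero-mean Gaussian noise
#' of SD `sigma_pos`, optionally applies the feature-based colour filter
#' (with probability `attention_filter * cue_utilization`, on cued trials
#' only, and never for colour-grouped patterns, where the cue is neutral),
#' and returns the holographic W of the resulting internal representation.
#' Uses the current RNG stream.
#'
#' @param pattern A `sym_pattern`.
#' @param params An [observer_params()].
#' @param cued Logical; whether the trial is colour-cued.
#' @param cue_colour Hue name; required when `cued`.
#' @param .filter_state Internal: preset attentional state (logical); used
#'   by [decide_2ifc()] to share one attentional draw across the two
#'   intervals of a trial. `NULL` draws it from the filter probability.
#' @return The internal evidence W (dimensionless).
#' @export
perceive_W <- function(pattern, params, cued = FALSE, cue_colour = NULL,
                       .filter_state = NULL) {
  stopifnot(inherits(params, "observer_params"))
  if (cued && is.null(cue_colour)) {
    stop("`cue_colour` is required on cued trials", call. = FALSE)
  }
  if (is.null(.filter_state)) {
    .filter_state <- stats::runif(1) <
      params$attention_filter * params$cue_utilization
  }
  p <- pattern
  if (cued && .filter_state && !is_colour_grouped(pattern)) {
    p <- subset_elements(p, colour = cue_colour)
  }
  el <- p$elements
  if (nrow(el) == 0) return(0)
  if (params$sigma_pos > 0) {
    if (stimulus_type(p$geometry) == "wedge") {
      el$theta <- (el$theta + stats::rnorm(nrow(el), 0, params$sigma_pos)) %% 360
    } else {
      el$x <- el$x + stats::rnorm(nrow(el), 0, params$sigma_pos)
      el$y <- el$y + stats::rnorm(nrow(el), 0, params$sigma_pos)
    }
    p$elements <- el
  }
  score_symmetry(p, tolerance = params$match_tolerance)$W
}

#' Decide a 2IFC trial
#'
#' With probability `lapse_rate` the response is uniformly random;
#' otherwise the observer computes the internal W of each interval and
#' chooses the larger, breaking exact ties uniformly at random.
#'
#' @param interval_a,interval_b `sym_pattern`s; exactly one must have
#'   `symmetric_flag = TRUE`.
#' @inheritParams perceive_W
#' @return A list with `choice` (`"first"`/`"second"`) and `correct`
#'   (logical).
#' @export
decide_2ifc <- function(interval_a, interval_b, params, cued = FALSE,
                        cue_colour = NULL) {
  flags <- c(interval_a$symmetric_flag, interval_b$symmetric_flag)
  if (sum(flags) != 1) {
    stop("exactly one interval must contain the symmetric pattern",
         call. = FALSE)
  }
  if (stats::runif(1) < params$lapse_rate) {
    choice <- sample(c("first", "second"), 1)
  } else {
    # the attentional state is a property of the trial, not the interval:
    # one draw decides whether the colour filter is engaged for both
    fs <- stats::runif(1) < params$attention_filter * params$cue_utilization
    wa <- perceive_W(interval_a, params, cued, cue_colour, .filter_state = fs)
    wb <- perceive_W(interval_b, params, cued, cue_colour, .filter_state = fs)
    choice <- if (wa > wb) "first" else if (wb > wa) "second" else
      sample(c("first", "second"), 1)
  }
  target <- if (flags[1]) "first" else "second"
  list(choice = choice, correct = choice == target)
}

#' Simulate one participant through an experiment design
#'
#' Runs every trial of the design: two fresh patterns are generated per
#' trial (the symmetric pattern and its foil), presented in random order,
#' and judged with [decide_2ifc()]. Practice trials are simulated first in
#' each block and repeated (up to `max_practice_attempts`) while accuracy
#' does not exceed the design's practice threshold; they are flagged
#' `practice = TRUE` so analyses can drop them. Per-trial RNG seeds are
#' derived from `seed` by counter, so the record is reproducible and
#' independent of evaluation order.
#'
#' @param design An [build_design()] object.
#' @param params An [observer_params()], or a named list with elements
#'   `wedge` and `dot` when the design mixes stimulus types.
#' @param participant Participant identifier stored in the records.
#' @param seed Integer seed for the participant's RNG stream.
#' @param max_practice_attempts Maximum repetitions of a practice run.
#' @return A data frame of trial records (one row per simulated trial,
#'   practice included and flagged).
#' @export
simulate_participant <- function(design, params, participant = "p01",
                                 seed = 1L, max_practice_attempts = 3L) {
  stopifnot(inherits(design, "experiment_design"))
  get_params <- function(stim) {
    if (inherits(params, "observer_params")) return(params)
    params[[stim]]
  }
  trials <- design$trials
  geoms <- design$geometries
  rec <- vector("list", 0L)
  counter <- 0L
  run_trial <- function(tr, practice) {
    counter <<- counter + 1L
    trial_seed <- derive_seed(seed, counter)
    geom <- geoms[[tr$geometry_id]]
    cond <- condition_label(tr$condition, tr$n_colours, tr$stimulus_type)
    foil <- condition_label(tr$foil_condition, tr$n_colours, tr$stimulus_type)
    target <- generate_pattern(geom, cond, cue_colour = design$cue_colour,
                               seed = derive_seed(trial_seed, 1L))
    foil_p <- generate_pattern(geom, foil, cue_colour = design$cue_colour,
                               seed = derive_seed(trial_seed, 2L))
    with_seed(trial_seed, {
      first_is_target <- stats::runif(1) < 0.5
      a <- if (first_is_target) target else foil_p
      b <- if (first_is_target) foil_p else target
      cued <- tr$attention == "cued"
      out <- decide_2ifc(a, b, get_params(tr$stimulus_type), cued,
                         if (cued) design$cue_colour else NULL)
      data.frame(
        participant = participant, experiment = design$experiment,
        block = tr$block_id, block_index = tr$block_index,
        stimulus_type = tr$stimulus_type, n_wedges = tr$n_wedges,
        n_colours = tr$n_colours, condition = tr$condition,
        attention = tr$attention, cue_colour = design$cue_colour,
        practice = practice,
        symmetric_interval = if (first_is_target) "first" else "second",
        response = out$choice, correct = out$correct,
        trial_seed = trial_seed, stringsAsFactors = FALSE)
    })
  }
  for (b in unique(trials$block_index)) {
    blk <- trials[trials$block_index == b, , drop = FALSE]
    prac <- blk[blk$practice, , drop = FALSE]
    main <- blk[!blk$practice, , drop = FALSE]
    if (nrow(prac) > 0) {
      for (attempt in seq_len(max_practice_attempts)) {
        runs <- lapply(seq_len(nrow(prac)),
                       function(i) run_trial(prac[i, ], practice = TRUE))
        rec <- c(rec, runs)
        acc <- mean(vapply(runs, function(r) r$correct, logical(1)))
        if (acc > design$practice_threshold) break
      }
    }
    rec <- c(rec, lapply(seq_len(nrow(main)),
                         function(i) run_trial(main[i, ], practice = FALSE)))
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of participants
#'
#' Builds one design per participant (block order counterbalanced by
#' participant index, half the participants cued to each colour when the
#' count is even) and simulates each with the observer preset for their age
#' group and the design's stimulus types.
#'
#' @param n_participants Number of participants.
#' @param experiment 1 or 2.
#' @param seed Master seed; participant seeds are derived from it.
#' @param age_groups Character vector recycled over participants
#'   (`"younger"`/`"older"`).
#' @param trials_per_condition Optional reduced trial count per condition
#'   (defaults to the full design: 40 in Experiment 1, 50 in Experiment 2).
#' @param include_practice Logical; simulate practice runs as well.
#' @return A data frame of trial records for all participants, with an
#'   `age_group` column.
#' @export
simulate_cohort <- function(n_participants, experiment = 1, seed = 1L,
                            age_groups = "younger",
                            trials_per_condition = NULL,
                            include_practice = FALSE) {
  ages <- rep_len(age_groups, n_participants)
  cues <- rep_len(c("red", "green"), n_participants)
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    des <- build_design(experiment, seed = derive_seed(seed, i),
                        cue_colour = cues[i],
                        trials_per_condition = trials_per_condition,
                        include_practice = include_practice,
                        counterbalance_index = i)
    prm <- list(wedge = observer_preset(ages[i], "wedge"),
                dot = observer_preset(ages[i], "dot"))
    rec <- simulate_participant(des, prm,
                                participant = sprintf("p%02d", i),
                                seed = derive_seed(seed, 10000L + i))
    rec$age_group <- ages[i]
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
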