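## Experiment designs.
##
## Experiment 1 (wedges only, younger adults): blocks cross {24, 36} wedges
## x {2, 3} colours, 120 main trials per block (40 per colour-symmetry
## condition: segregated, nonsegregated, antisymmetric), run first without
## and then with attention to colour; block order within each attention
## phase is randomized per participant. Wedges cover 50% of a 13.79 deg
## circle with a 3.10 deg blank centre; stimulus duration 500 ms.
##
## Experiment 2 (wedges vs dots, younger and older adults): blocks by
## stimulus type (16 wedges at 20% coverage of a 14.74 deg circle; 96
## Gaussian blobs over ~11 x 11 deg), 250 main trials per block (50 per
## condition: segregated, random segregated, nonsegregated, antisymmetric,
## colour-grouped antisymmetric), uncued then cued, block order
## counterbalanced; stimulus duration 1000 ms. Colour-grouped noise
## patterns serve as foils for the colour-grouped antisymmetric condition;
## all other conditions use plain random foils.

EXP1_CONDITIONS <- c("segregated", "nonsegregated", "antisymmetric")
EXP2_CONDITIONS <- c("segregated", "random_segregated", "nonsegregated",
                     "antisymmetric", "grouped_antisymmetric")

foil_for <- function(condition) {
  ifelse(condition == "grouped_antisymmetric", "grouped_random_foil",
         "random_foil")
}

#' Build the trial/block structure of an experiment
#'
#' Returns the complete, ordered trial list of one participant's session,
#' with block structure, practice trials, timing metadata, and the
#' practice/exclusion thresholds. Uncued blocks always precede cued blocks;
#' condition order within a block is randomized by `seed`.
#'
#' @param experiment 1 or 2.
#' @param seed Integer seed for block and trial-order randomization.
#' @param cue_colour The participant's attended colour (`"red"` or
#'   `"green"`); also the fixed signal colour of segregated patterns.
#' @param trials_per_condition Main trials per colour-symmetry condition
#'   per block; `NULL` for the full design (40 in Experiment 1, 50 in
#'   Experiment 2).
#' @param practice_trials Practice trials per block (16; 0 to disable).
#' @param include_practice Logical; include practice rows in the trial
#'   list.
#' @param counterbalance_index Participant index used to counterbalance the
#'   Experiment 2 block order (odd: wedges first; even: dots first).
#' @return An object of class `experiment_design`: list with `trials` (data
#'   frame), `geometries`, timing metadata, thresholds, `cue_colour` and
#'   `seed`.
#' @examples
#' d <- build_design(2, seed = 1)
#' table(d$trials$attention[!d$trials$practice])  # 500 uncued, 500 cued
#' @export
build_design <- function(experiment, seed = 1L, cue_colour = "red",
                         trials_per_condition = NULL, practice_trials = 16L,
                         include_practice = TRUE, counterbalance_index = 1L) {
  if (!experiment %in% c(1, 2)) stop("`experiment` must be 1 or 2",
                                     call. = FALSE)
  cue_colour <- match.arg(cue_colour, c("red", "green"))
  tpc <- if (is.null(trials_per_condition)) {
    if (experiment == 1) 40L else 50L
  } else as.integer(trials_per_condition)

  if (experiment == 1) {
    geoms <- list(w24 = wedge_geometry(24, 0.5, 13.79, 3.10),
                  w36 = wedge_geometry(36, 0.5, 13.79, 3.10))
    stim_blocks <- expand.grid(n_wedges = c(24L, 36L), n_colours = c(2L, 3L))
    stim_blocks$geometry_id <- ifelse(stim_blocks$n_wedges == 24, "w24", "w36")
    stim_blocks$stimulus_type <- "wedge"
    conditions <- EXP1_CONDITIONS
    stimulus_ms <- 500
  } else {
    geoms <- list(w16 = wedge_geometry(16, 0.2, 14.74, 3.10),
                  d96 = dot_geometry(96, 11, 0.41, 5))
    first <- if (counterbalance_index %% 2 == 1) c("wedge", "dot") else
      c("dot", "wedge")
    stim_blocks <- data.frame(
      n_wedges = ifelse(first == "wedge", 16L, NA_integer_),
      n_colours = 2L,
      geometry_id = ifelse(first == "wedge", "w16", "d96"),
      stimulus_type = first, stringsAsFactors = FALSE)
    conditions <- EXP2_CONDITIONS
    stimulus_ms <- 1000
  }

  trials <- with_seed(seed, {
    rows <- list()
    block_index <- 0L
    for (attention in c("uncued", "cued")) {
      order_idx <- if (experiment == 1) {
        sample.int(nrow(stim_blocks))  # random block order per phase
      } else {
        seq_len(nrow(stim_blocks))     # counterbalanced via stim_blocks
      }
      for (bi in order_idx) {
        block_index <- block_index + 1L
        sb <- stim_blocks[bi, ]
        block_id <- sprintf("%s_b%d_%s",
                            if (experiment == 1)
                              paste0("w", sb$n_wedges, "c", sb$n_colours)
                            else sb$stimulus_type,
                            block_index, attention)
        make_rows <- function(conds, practice) {
          data.frame(block_index = block_index, block_id = block_id,
                     attention = attention,
                     stimulus_type = sb$stimulus_type,
                     geometry_id = sb$geometry_id,
                     n_wedges = sb$n_wedges, n_colours = sb$n_colours,
                     condition = conds, foil_condition = foil_for(conds),
                     practice = practice, stringsAsFactors = FALSE)
        }
        if (include_practice && practice_trials > 0) {
          pr_conds <- sample(rep_len(conditions, practice_trials))
          rows[[length(rows) + 1L]] <- make_rows(pr_conds, TRUE)
        }
        main_conds <- sample(rep(conditions, each = tpc))
        rows[[length(rows) + 1L]] <- make_rows(main_conds, FALSE)
      }
    }
    do.call(rbind, rows)
  })
  trials$trial_index <- seq_len(nrow(trials))
  rownames(trials) <- NULL

  structure(
    list(experiment = as.integer(experiment), trials = trials,
         geometries = geoms, conditions = conditions,
         trials_per_condition = tpc,
         practice_trials = if (include_practice) as.integer(practice_trials)
                           else 0L,
         practice_threshold = 0.6, exclusion_threshold = 0.55,
         timing = list(fixation_ms = 700, isi_ms = 700,
                       stimulus_ms = stimulus_ms),
         fixation_cross_deg = c(width = 0.55, height = 5.52),
         cue_colour = cue_colour, seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  main <- x$trials[!x$trials$practice, ]
  cat(sprintf(
    "<experiment_design> Experiment %d: %d blocks, %d main trials (+%d practice), cue colour %s\n",
    x$experiment, length(unique(x$trials$block_index)), nrow(main),
    sum(x$trials$practice), x$cue_colour))
  invisible(x)
}

#' Cue-validity accounting of a cued Experiment 2 block
#'
#' Classifies the cued trials of an Experiment 2 design by whether the
#' colour cue directs attention toward the symmetry signal (valid: the
#' segregated condition, and half of the random-segregated trials in
#' expectation), is uninformative (neutral: the colour-grouped
#' antisymmetric condition, where symmetry spans both colours by
#' construction), or directs attention away from some or all of the signal
#' (invalid: nonsegregated, nongrouped antisymmetric, and the other half of
#' random-segregated trials). With the full design this gives 30% valid,
#' 20% neutral, 50% invalid.
#'
#' @param design An Experiment 2 [build_design()] with cued trials.
#' @return Named numeric vector of percentages (`valid`, `neutral`,
#'   `invalid`), summing to 100.
#' @export
cue_validity_breakdown <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  if (design$experiment != 2) {
    stop("cue-validity accounting is defined for Experiment 2 designs",
         call. = FALSE)
  }
  tr <- design$trials
  tr <- tr[!tr$practice & tr$attention == "cued", , drop = FALSE]
  if (nrow(tr) == 0) stop("design has no cued trials", call. = FALSE)
  valid <- sum(tr$condition == "segregated") +
    0.5 * sum(tr$condition == "random_segregated")
  neutral <- sum(tr$condition == "grouped_antisymmetric")
  invalid <- nrow(tr) - valid - neutral
  100 * c(valid = valid, neutral = neutral, invalid = invalid) / nrow(tr)
}

#' Exclude participants by overall accuracy
#'
#' Removes participants whose overall accuracy on main (non-practice)
#' trials falls strictly below `threshold`, mirroring the usual
#' poor-performance exclusion rule (a participant at exactly the threshold
#' is retained).
#'
#' @param trials Trial-record data frame with `participant`, `correct` and
#'   (optionally) `practice` columns.
#' @param threshold Exclusion threshold, a proportion in (0.5, 1).
#' @return A list with `trials` (records of retained participants) and
#'   `report` (data frame: participant, n_trials, accuracy, excluded).
#' @export
apply_exclusions <- function(trials, threshold = 0.55) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop("no trial records supplied", call. = FALSE)
  }
  if (threshold <= 0.5 || threshold >= 1) {
    stop("`threshold` must lie in (0.5, 1)", call. = FALSE)
  }
  main <- if ("practice" %in% names(trials)) trials[!trials$practice, ]
          else trials
  acc <- tapply(main$correct, main$participant, mean)
  report <- data.frame(participant = names(acc),
                       n_trials = as.integer(table(main$participant)[names(acc)]),
                       accuracy = as.numeric(acc),
                       excluded = as.numeric(acc) < threshold,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  keep <- report$participant[!report$excluded]
  list(trials = trials[trials$participant %in% keep, , drop = FALSE],
       report = report)
}
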