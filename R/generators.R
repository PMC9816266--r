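## Pattern generation.
##
## Placement is rejection sampling with explicit constraints:
##  * signal elements are sampled in the right hemifield (with a margin of
##    one wedge width / no extra margin for dots) and mirrored to the left,
##    so mirror pairs are exact by construction;
##  * no two wedges' angular extents overlap (centre distance >= one wedge
##    width); no two blob centres are closer than one blob diameter;
##  * a noise element is rejected whenever its mirrored position falls
##    within the matching tolerance of any other element, so noise carries
##    exactly 0% position symmetry at the tolerance used for scoring.
## Budgets: 10,000 proposals per element, then up to 100 restarts of the
## whole pattern, then an error naming the constraint that failed.

.PROPOSALS_PER_ELEMENT <- 10000L
.PATTERN_RESTARTS <- 100L

#' Default matching tolerance for a geometry
#'
#' Half a wedge width for wedge patterns, one blob diameter for dot
#' patterns. This is both the anti-accidental-symmetry tolerance used during
#' generation and the default tolerance of [score_symmetry()], so generated
#' foils score exactly W = 0.
#'
#' @param geometry A [wedge_geometry()] or [dot_geometry()].
#' @return Tolerance in degrees (polar angle for wedges, visual angle for
#'   dots).
#' @export
default_tolerance <- function(geometry) {
  if (inherits(geometry, "wedge_geometry")) geometry$wedge_width / 2
  else geometry$blob_diameter
}

#' Mean circumferential gap between wedges
#'
#' The average angular gap left between adjacent wedge elements,
#' `360 * (1 - coverage) / n_wedges`.
#'
#' @param geometry A [wedge_geometry()].
#' @return Gap in degrees of polar angle.
#' @examples
#' expected_mean_gap(wedge_geometry(24, 0.5))  # 7.5
#' expected_mean_gap(wedge_geometry(36, 0.5))  # 5
#' @export
expected_mean_gap <- function(geometry) {
  stopifnot(inherits(geometry, "wedge_geometry"))
  360 * (1 - geometry$coverage) / geometry$n_wedges
}

#' Average positional-tolerance window for n elements
#'
#' Under the idealization of n elements each occupying 1 degree at the
#' circumference, positional jitter is tolerated up to the average spacing
#' between elements, `360 / n_elements`.
#'
#' @param n_elements Positive element count.
#' @return Window in degrees.
#' @examples
#' tolerance_window(16)  # 22.5
#' tolerance_window(36)  # 10
#' @export
tolerance_window <- function(n_elements) {
  if (any(n_elements <= 0)) stop("`n_elements` must be positive", call. = FALSE)
  360 / n_elements
}

## Signal element count: half the elements for 2 colours; for 3 colours the
## largest even number not exceeding n/3 (8 of 24, 12 of 36).
signal_count <- function(n, n_colours) {
  if (n_colours == 2) return(n %/% 2L)
  s <- n %/% 3L
  if (s %% 2L == 1L) s <- s - 1L
  s
}

## ---- colour plans -------------------------------------------------------
## A colour plan is a list with:
##   pairs: data frame (colour_right, colour_left), one row per signal pair
##   noise: matrix [colour, hemifield] of noise element counts
## All sampling uses the current RNG stream.

plan_colours <- function(condition, n, cue_colour = NULL) {
  k <- condition$n_colours
  colours <- hue_names()[seq_len(k)]
  if (n %% (2L * k) != 0L) {
    stop("element count must be divisible by 2 * n_colours", call. = FALSE)
  }
  total_per_colour <- n %/% k
  cs <- condition$colour_symmetry
  n_signal <- if (is_foil_condition(cs)) 0L else signal_count(n, k)
  n_pairs <- n_signal %/% 2L
  n_noise <- n - n_signal

  pairs <- data.frame(colour_right = character(0), colour_left = character(0),
                      stringsAsFactors = FALSE)
  if (cs %in% c("segregated", "random_segregated")) {
    sig_col <- if (cs == "segregated" && !is.null(cue_colour)) {
      match.arg(cue_colour, colours)
    } else {
      sample(colours, 1)
    }
    pairs <- data.frame(colour_right = rep(sig_col, n_pairs),
                        colour_left = rep(sig_col, n_pairs),
                        stringsAsFactors = FALSE)
  } else if (cs == "nonsegregated") {
    per <- rep(n_pairs %/% k, k)
    extra <- n_pairs %% k
    if (extra > 0) {
      idx <- sample.int(k, extra)
      per[idx] <- per[idx] + 1L
    }
    cols <- sample(rep(colours, times = per))
    pairs <- data.frame(colour_right = cols, colour_left = cols,
                        stringsAsFactors = FALSE)
  } else if (cs == "antisymmetric") {
    combos <- utils::combn(colours, 2, simplify = FALSE)
    per <- rep(n_pairs %/% length(combos), length(combos))
    extra <- n_pairs %% length(combos)
    if (extra > 0) {
      idx <- sample.int(length(combos), extra)
      per[idx] <- per[idx] + 1L
    }
    pr <- character(0); pl <- character(0)
    for (j in seq_along(combos)) {
      m <- per[j]
      if (m == 0) next
      # balance orientations within each colour combination
      n_fwd <- m %/% 2L + sample(0:1, 1) * (m %% 2L)
      fwd <- sample(rep(c(TRUE, FALSE), c(n_fwd, m - n_fwd)))
      pr <- c(pr, ifelse(fwd, combos[[j]][1], combos[[j]][2]))
      pl <- c(pl, ifelse(fwd, combos[[j]][2], combos[[j]][1]))
    }
    ord <- sample.int(length(pr))
    pairs <- data.frame(colour_right = pr[ord], colour_left = pl[ord],
                        stringsAsFactors = FALSE)
  } else if (cs %in% c("grouped_antisymmetric", "grouped_random_foil")) {
    right_col <- sample(colours, 1)
    left_col <- setdiff(colours, right_col)
    if (cs == "grouped_antisymmetric") {
      pairs <- data.frame(colour_right = rep(right_col, n_pairs),
                          colour_left = rep(left_col, n_pairs),
                          stringsAsFactors = FALSE)
    }
    noise <- matrix(0L, k, 2, dimnames = list(colours, c("right", "left")))
    noise[right_col, "right"] <- n_noise %/% 2L
    noise[left_col, "left"] <- n_noise %/% 2L
    return(list(pairs = pairs, noise = noise))
  }

  ## Non-grouped conditions: solve the noise colour-by-hemifield counts so
  ## that every colour has total_per_colour elements overall and equally
  ## many in each hemifield.
  sig_right <- table(factor(pairs$colour_right, levels = colours))
  sig_left <- table(factor(pairs$colour_left, levels = colours))
  target_half <- total_per_colour / 2
  noise_right <- target_half - as.integer(sig_right)
  noise_left <- target_half - as.integer(sig_left)
  if (any(noise_right < 0) || any(noise_left < 0) ||
      any(c(noise_right, noise_left) %% 1 != 0)) {
    stop("no balanced noise colouring exists for this condition/geometry",
         call. = FALSE)
  }
  noise <- cbind(right = as.integer(noise_right),
                 left = as.integer(noise_left))
  rownames(noise) <- colours
  list(pairs = pairs, noise = noise)
}

## ---- wedge placement ----------------------------------------------------

place_wedges <- function(geometry, n_pairs, noise_counts) {
  w <- geometry$wedge_width
  tol <- w / 2
  margin <- w  # signal centres keep one full width clear of the axis
  placed <- numeric(0)

  propose_until <- function(lo, hi, ok) {
    for (i in seq_len(.PROPOSALS_PER_ELEMENT)) {
      th <- stats::runif(1, lo, hi)
      if (ok(th)) return(th)
    }
    NULL
  }

  ## signal pairs: sample in the right hemifield, mirror to the left
  for (p in seq_len(n_pairs)) {
    th <- propose_until(margin + w / 2, 180 - margin - w / 2, function(th) {
      length(placed) == 0 ||
        (min(circ_dist(th, placed)) >= w &&
           min(circ_dist(mirror_angle(th), placed)) >= w)
    })
    if (is.null(th)) return(list(fail = "signal wedge placement (non-overlap)"))
    placed <- c(placed, th, mirror_angle(th))
  }
  sig_right <- placed[seq_len(n_pairs) * 2 - 1]
  sig_left <- placed[seq_len(n_pairs) * 2]

  ## noise, per hemifield
  noise_theta <- list(right = numeric(0), left = numeric(0))
  for (hemi in c("right", "left")) {
    offs <- if (hemi == "right") 0 else 180
    for (i in seq_len(sum(noise_counts[, hemi]))) {
      th <- propose_until(offs + w / 2, offs + 180 - w / 2, function(th) {
        if (length(placed) > 0 && min(circ_dist(th, placed)) < w) return(FALSE)
        # anti-accidental symmetry: mirrored centre clear of everything
        length(placed) == 0 ||
          min(circ_dist(mirror_angle(th), placed)) > tol
      })
      if (is.null(th)) {
        return(list(fail = "noise wedge placement (non-overlap / 0% symmetry)"))
      }
      placed <- c(placed, th)
      noise_theta[[hemi]] <- c(noise_theta[[hemi]], th)
    }
  }
  list(sig_right = sig_right, sig_left = sig_left, noise = noise_theta)
}

## ---- dot placement ------------------------------------------------------

place_dots <- function(geometry, n_pairs, noise_counts) {
  d <- geometry$blob_diameter
  tol <- d
  half_fs <- geometry$field_size / 2
  px <- numeric(0); py <- numeric(0)

  too_close <- function(x, y, lim) {
    length(px) > 0 && min(sqrt((px - x)^2 + (py - y)^2)) < lim
  }
  propose <- function(hemi, check_mirror) {
    for (i in seq_len(.PROPOSALS_PER_ELEMENT)) {
      x <- stats::runif(1, d / 2, half_fs) * (if (hemi == "right") 1 else -1)
      y <- stats::runif(1, -half_fs, half_fs)
      if (too_close(x, y, d)) next
      if (check_mirror && length(px) > 0 &&
          min(sqrt((px + x)^2 + (py - y)^2)) <= tol) next
      return(c(x, y))
    }
    NULL
  }

  sig <- matrix(numeric(0), ncol = 2)
  for (p in seq_len(n_pairs)) {
    pt <- propose("right", check_mirror = FALSE)
    if (is.null(pt)) return(list(fail = "signal blob placement (non-overlap)"))
    # partner overlap with the opposite hemifield is impossible: |x1 + x2|
    # >= blob diameter whenever both |x| >= diameter / 2
    sig <- rbind(sig, pt)
    px <- c(px, pt[1], -pt[1]); py <- c(py, pt[2], pt[2])
  }

  noise_xy <- list(right = matrix(numeric(0), ncol = 2),
                   left = matrix(numeric(0), ncol = 2))
  for (hemi in c("right", "left")) {
    for (i in seq_len(sum(noise_counts[, hemi]))) {
      pt <- propose(hemi, check_mirror = TRUE)
      if (is.null(pt)) {
        return(list(fail = "noise blob placement (non-overlap / 0% symmetry)"))
      }
      noise_xy[[hemi]] <- rbind(noise_xy[[hemi]], pt)
      px <- c(px, pt[1]); py <- c(py, pt[2])
    }
  }
  list(sig = sig, noise = noise_xy)
}

## ---- generators ---------------------------------------------------------

#' Generate a colour-symmetric wedge pattern
#'
#' Constructs a wheel-shaped pattern of non-overlapping wedges for any
#' colour-symmetry condition. Symmetric conditions contain exactly-mirrored
#' signal pairs (half the elements for two colours; the largest even count
#' not exceeding a third of the elements for three colours) plus noise
#' elements whose mirror images stay clear of every other element, so the
#' noise carries 0% position symmetry at the scoring tolerance. Colour
#' totals are equal across colours, and each colour appears equally often in
#' the two hemifields (hemifield-pure for colour-grouped arrangements).
#'
#' @param geometry A [wedge_geometry()].
#' @param condition A [condition_label()] with `stimulus_type = "wedge"`.
#' @param cue_colour Optional hue name; for the `segregated` condition this
#'   fixes the signal colour (the experiment keeps it constant and equal to
#'   the attended colour). Ignored by other conditions.
#' @param seed Integer seed; identical inputs give identical patterns.
#' @return A `sym_pattern`.
#' @examples
#' p <- generate_wedge_pattern(wedge_geometry(24, 0.5),
#'                             condition_label("segregated", 2), seed = 1)
#' score_symmetry(p)$W  # 0.25
#' @export
generate_wedge_pattern <- function(geometry, condition, cue_colour = NULL,
                                   seed = 1L) {
  stopifnot(inherits(geometry, "wedge_geometry"))
  check_condition_geometry(condition, geometry, "wedge")
  with_seed(seed, {
    fail <- NULL
    for (attempt in seq_len(.PATTERN_RESTARTS)) {
      plan <- plan_colours(condition, geometry$n_wedges, cue_colour)
      pl <- place_wedges(geometry, nrow(plan$pairs), plan$noise)
      if (is.null(pl$fail)) {
        return(assemble_wedge(geometry, condition, plan, pl, seed))
      }
      fail <- pl$fail
    }
    stop(sprintf("wedge generation failed after %d restarts: %s",
                 .PATTERN_RESTARTS, fail), call. = FALSE)
  })
}

#' Generate a colour-symmetric dot pattern
#'
#' As [generate_wedge_pattern()], for fields of Gaussian blobs: signal dots
#' come in exactly-mirrored pairs about the vertical axis, no two blob
#' centres are closer than one blob diameter, no blob straddles the axis,
#' and no noise dot's mirror image falls within the matching tolerance of
#' any other element.
#'
#' @inheritParams generate_wedge_pattern
#' @param geometry A [dot_geometry()].
#' @param condition A [condition_label()] with `stimulus_type = "dot"`.
#' @return A `sym_pattern`.
#' @export
generate_dot_pattern <- function(geometry, condition, cue_colour = NULL,
                                 seed = 1L) {
  stopifnot(inherits(geometry, "dot_geometry"))
  check_condition_geometry(condition, geometry, "dot")
  with_seed(seed, {
    fail <- NULL
    for (attempt in seq_len(.PATTERN_RESTARTS)) {
      plan <- plan_colours(condition, geometry$n_dots, cue_colour)
      pl <- place_dots(geometry, nrow(plan$pairs), plan$noise)
      if (is.null(pl$fail)) {
        return(assemble_dot(geometry, condition, plan, pl, seed))
      }
      fail <- pl$fail
    }
    stop(sprintf("dot generation failed after %d restarts: %s",
                 .PATTERN_RESTARTS, fail), call. = FALSE)
  })
}

#' Generate the pattern for a condition, dispatching on geometry
#'
#' @inheritParams generate_wedge_pattern
#' @param geometry A [wedge_geometry()] or [dot_geometry()].
#' @return A `sym_pattern`.
#' @export
generate_pattern <- function(geometry, condition, cue_colour = NULL,
                             seed = 1L) {
  if (inherits(geometry, "wedge_geometry")) {
    generate_wedge_pattern(geometry, condition, cue_colour, seed)
  } else {
    generate_dot_pattern(geometry, condition, cue_colour, seed)
  }
}

check_condition_geometry <- function(condition, geometry, type) {
  stopifnot(inherits(condition, "condition_label"))
  if (condition$stimulus_type != type) {
    stop(sprintf("condition is for %s stimuli, geometry is %s",
                 condition$stimulus_type, type), call. = FALSE)
  }
  n <- n_elements(geometry)
  if (n %% (2L * condition$n_colours) != 0L) {
    stop("element count must be divisible by 2 * n_colours", call. = FALSE)
  }
}

assemble_wedge <- function(geometry, condition, plan, pl, seed) {
  n_pairs <- nrow(plan$pairs)
  w <- geometry$wedge_width
  rows <- list()
  if (n_pairs > 0) {
    rows[[1]] <- data.frame(
      role = "signal",
      colour = c(plan$pairs$colour_right, plan$pairs$colour_left),
      theta = c(pl$sig_right, pl$sig_left),
      width = w,
      pair = c(seq_len(n_pairs), seq_len(n_pairs)),
      stringsAsFactors = FALSE)
  }
  noise_cols <- c(rep(rownames(plan$noise), plan$noise[, "right"]),
                  rep(rownames(plan$noise), plan$noise[, "left"]))
  rows[[2]] <- data.frame(
    role = "noise", colour = noise_cols,
    theta = c(pl$noise$right, pl$noise$left), width = w, pair = NA_integer_,
    stringsAsFactors = FALSE)
  elements <- do.call(rbind, rows)
  rownames(elements) <- NULL
  pat <- new_pattern(elements, condition, geometry, seed,
                     symmetric_flag = n_pairs > 0)
  validate_pattern(pat)
  pat
}

assemble_dot <- function(geometry, condition, plan, pl, seed) {
  n_pairs <- nrow(plan$pairs)
  rows <- list()
  if (n_pairs > 0) {
    rows[[1]] <- data.frame(
      role = "signal",
      colour = c(plan$pairs$colour_right, plan$pairs$colour_left),
      x = c(pl$sig[, 1], -pl$sig[, 1]),
      y = c(pl$sig[, 2], pl$sig[, 2]),
      pair = c(seq_len(n_pairs), seq_len(n_pairs)),
      stringsAsFactors = FALSE)
  }
  noise_cols <- c(rep(rownames(plan$noise), plan$noise[, "right"]),
                  rep(rownames(plan$noise), plan$noise[, "left"]))
  noise_xy <- rbind(pl$noise$right, pl$noise$left)
  rows[[2]] <- data.frame(
    role = "noise", colour = noise_cols,
    x = noise_xy[, 1], y = noise_xy[, 2], pair = NA_integer_,
    stringsAsFactors = FALSE)
  elements <- do.call(rbind, rows)
  rownames(elements) <- NULL
  pat <- new_pattern(elements, condition, geometry, seed,
                     symmetric_flag = n_pairs > 0)
  validate_pattern(pat)
  pat
}

#' Keep only elements of a given role or colour
#'
#' Returns a copy of the pattern restricted to the selected elements; the
#' geometry and condition label are retained. Useful for scoring the
#' signal-only subset or emulating a perfect attentional filter.
#'
#' @param pattern A `sym_pattern`.
#' @param role Optional `"signal"` or `"noise"`.
#' @param colour Optional hue name.
#' @return A `sym_pattern` with the filtered element set (structural
#'   invariants of full patterns need not hold for subsets).
#' @export
subset_elements <- function(pattern, role = NULL, colour = NULL) {
  el <- pattern$elements
  keep <- rep(TRUE, nrow(el))
  if (!is.null(role)) keep <- keep & el$role == role
  if (!is.null(colour)) keep <- keep & el$colour %in% colour
  out <- pattern
  out$elements <- el[keep, , drop = FALSE]
  rownames(out$elements) <- NULL
  out
}

## ---- condition predicates ----------------------------------------------

#' Structural predicate for a colour-symmetry condition
#'
#' Decides from positions and colours alone (roles are ignored) whether a
#' pattern realizes the stated colour-symmetry arrangement: mirror pairs are
#' recovered with [score_symmetry()] at the default tolerance, and their
#' colour relations, the hemifield colour layout and the colour proportions
#' are checked against the condition's defining constraints.
#'
#' `segregated` and `random_segregated` patterns are structurally identical
#' (the latter differs only in how the signal colour is sampled across
#' trials), so `segregated` is checked against `signal_colour` when one is
#' supplied, while `random_segregated` accepts any monochrome signal.
#'
#' @param pattern A `sym_pattern`.
#' @param colour_symmetry One of [condition_names()].
#' @param signal_colour Optional designated signal colour for `segregated`.
#' @return Logical.
#' @export
condition_predicate <- function(pattern, colour_symmetry,
                                signal_colour = NULL) {
  colour_symmetry <- match.arg(colour_symmetry, condition_names())
  el <- pattern$elements
  n <- nrow(el)
  sc <- score_symmetry(pattern)
  hemi <- element_hemifield(pattern)
  pure <- length(unique(el$colour[hemi == "left"])) == 1 &&
    length(unique(el$colour[hemi == "right"])) == 1 &&
    el$colour[hemi == "left"][1] != el$colour[hemi == "right"][1]
  cols_balanced <- length(unique(as.integer(table(el$colour)))) == 1

  if (is_foil_condition(colour_symmetry)) {
    if (sc$E != 0) return(FALSE)
    if (colour_symmetry == "grouped_random_foil") return(pure)
    return(!pure && cols_balanced)
  }

  expected_pairs <- signal_count(n, length(unique(el$colour))) %/% 2L
  if (sc$E != expected_pairs || sc$E == 0) return(FALSE)
  pc1 <- el$colour[sc$matched_pairs[, 1]]
  pc2 <- el$colour[sc$matched_pairs[, 2]]
  paired <- c(sc$matched_pairs)

  switch(colour_symmetry,
    segregated = {
      mono <- length(unique(c(pc1, pc2))) == 1 && all(pc1 == pc2)
      col_ok <- is.null(signal_colour) || (mono && pc1[1] == signal_colour)
      mono && col_ok && !any(el$colour[-paired] == pc1[1]) && !pure
    },
    random_segregated = {
      mono <- length(unique(c(pc1, pc2))) == 1 && all(pc1 == pc2)
      mono && !any(el$colour[-paired] == pc1[1]) && !pure
    },
    nonsegregated = {
      all(pc1 == pc2) && length(unique(pc1)) > 1 && !pure
    },
    antisymmetric = all(pc1 != pc2) && !pure,
    grouped_antisymmetric = all(pc1 != pc2) && pure
  )
}
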