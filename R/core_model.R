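#' mirrorcue: colour symmetry stimuli, holographic goodness, and simulated
#' 2IFC symmetry-detection experiments
#'
#' The package covers the computational pipeline of a colour-symmetry
#' psychophysics study: constrained generation of wedge and random-dot
#' patterns under several colour-symmetry arrangements, scoring of any
#' pattern with the holographic model of regularity (perceptual goodness
#' W = E/N), a parametric two-interval forced-choice observer with
#' feature-based attention to colour, blocked experiment designs with
#' cue-validity accounting, and binomial mixed-model analysis of
#' single-trial accuracy with backward elimination and multiplicity-adjusted
#' contrasts.
#'
#' @keywords internal
"_PACKAGE"

## Angle convention used throughout: degrees of polar angle, 0 deg at
## 12 o'clock, clockwise positive. The mirror-symmetry axis is the vertical
## through the pattern centre, i.e. the 0/180 deg line. The "right"
## hemifield is theta in (0, 180), the "left" hemifield theta in (180, 360).
## Dot patterns use Cartesian degrees of visual angle with the origin at the
## pattern centre; mirroring maps (x, y) -> (-x, y).

#' Stimulus colour palette in CIE 1931 xyY
#'
#' Returns the four colour constants used by all stimuli: the unique hues
#' red, green and yellow (isoluminant at 49.887 cd/m\eqn{^2}) and the
#' mid-grey background (23 cd/m\eqn{^2}). Chromaticities are CIE 1931 (x, y);
#' `Y` is luminance in cd/m\eqn{^2}.
#'
#' @return A data frame with columns `name`, `x`, `y`, `Y` and one row per
#'   colour (`red`, `green`, `yellow`, `background`).
#' @examples
#' stim_palette()
#' @export
stim_palette <- function() {
  pal <- data.frame(
    name = c("red", "green", "yellow", "background"),
    x = c(0.3521, 0.2618, 0.3480, 0.2848),
    y = c(0.2966, 0.3612, 0.3640, 0.2932),
    Y = c(49.887, 49.887, 49.887, 23),
    stringsAsFactors = FALSE
  )
  rownames(pal) <- pal$name
  pal
}

#' Hue names available for stimulus elements
#' @return Character vector `c("red", "green", "yellow")`.
#' @export
hue_names <- function() c("red", "green", "yellow")

#' Colour-symmetry condition labels
#'
#' The seven recognised colour-symmetry arrangements: five symmetric-pattern
#' conditions (`segregated`, `random_segregated`, `nonsegregated`,
#' `antisymmetric`, `grouped_antisymmetric`) and the two foil classes
#' (`random_foil`, `grouped_random_foil`).
#'
#' @return Character vector of condition names.
#' @export
condition_names <- function() {
  c("segregated", "random_segregated", "nonsegregated", "antisymmetric",
    "grouped_antisymmetric", "random_foil", "grouped_random_foil")
}

#' Reflect a polar angle about the vertical symmetry axis
#'
#' Under the convention 0 deg = upward, clockwise positive, reflection about
#' the vertical axis is `(360 - theta) %% 360`. The map is an involution and
#' fixes only 0 and 180 deg.
#'
#' @param theta Numeric vector of angles in degrees, each in `[0, 360)`.
#' @return The reflected angles in `[0, 360)`.
#' @examples
#' mirror_angle(c(0, 90, 180))
#' @export
mirror_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop("`theta` must be finite numeric", call. = FALSE)
  }
  if (any(theta < 0 | theta >= 360)) {
    stop("`theta` must lie in [0, 360)", call. = FALSE)
  }
  (360 - theta) %% 360
}

#' Reflect dot coordinates about the vertical symmetry axis
#'
#' @param x,y Numeric vectors of Cartesian coordinates in degrees of visual
#'   angle, origin at the pattern centre.
#' @return A list with components `x` (negated) and `y` (unchanged).
#' @export
mirror_point <- function(x, y) list(x = -x, y = y)

## Circular distance between angles, in degrees (always in [0, 180]).
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Wedge-pattern geometry
#'
#' Geometry of a wheel-shaped wedge pattern: `n_wedges` annular sectors
#' jointly covering a fraction `coverage` of a circle of `outer_diameter`
#' degrees of visual angle, with a blank disc of `inner_diameter` at the
#' centre. The angular width of one wedge is derived as
#' `360 * coverage / n_wedges`.
#'
#' @param n_wedges Even integer >= 4; number of wedge elements.
#' @param coverage Fraction of the circle area occupied by wedges, in (0, 1).
#' @param outer_diameter Outer diameter in degrees of visual angle.
#' @param inner_diameter Blank-centre diameter in degrees of visual angle.
#' @return An object of class `wedge_geometry`.
#' @examples
#' wedge_geometry(24, 0.5)           # 24 wedges, each 7.5 deg wide
#' wedge_geometry(16, 0.2, 14.74)    # the sparser 16-wedge layout
#' @export
wedge_geometry <- function(n_wedges, coverage, outer_diameter = 13.79,
                           inner_diameter = 3.10) {
  stopifnot(is.numeric(n_wedges), length(n_wedges) == 1,
            is.numeric(coverage), length(coverage) == 1)
  n_wedges <- as.integer(n_wedges)
  if (n_wedges < 4 || n_wedges %% 2 != 0) {
    stop("`n_wedges` must be an even integer >= 4", call. = FALSE)
  }
  if (coverage <= 0 || coverage >= 1) {
    stop("`coverage` must be in (0, 1)", call. = FALSE)
  }
  if (inner_diameter >= outer_diameter) {
    stop("`inner_diameter` must be smaller than `outer_diameter`",
         call. = FALSE)
  }
  structure(
    list(n_wedges = n_wedges, coverage = coverage,
         outer_diameter = outer_diameter, inner_diameter = inner_diameter,
         wedge_width = 360 * coverage / n_wedges),
    class = c("wedge_geometry", "stim_geometry")
  )
}

#' Dot-pattern geometry
#'
#' Geometry of a random-dot pattern: `n_dots` Gaussian blobs of
#' `blob_diameter` degrees of visual angle spread over a square field of
#' side `field_size`. The rendered blob profile has standard deviation
#' `blob_diameter / blob_sd_factor`.
#'
#' @param n_dots Even integer; number of blobs.
#' @param field_size Side of the square field, degrees of visual angle.
#' @param blob_diameter Blob diameter, degrees of visual angle.
#' @param blob_sd_factor Ratio of diameter to the Gaussian profile SD.
#' @return An object of class `dot_geometry`.
#' @examples
#' dot_geometry()   # the default 96-blob, 11 x 11 deg field
#' @export
dot_geometry <- function(n_dots = 96, field_size = 11, blob_diameter = 0.41,
                         blob_sd_factor = 5) {
  n_dots <- as.integer(n_dots)
  if (n_dots < 2 || n_dots %% 2 != 0) {
    stop("`n_dots` must be an even integer >= 2", call. = FALSE)
  }
  if (blob_diameter >= field_size) {
    stop("`blob_diameter` must be smaller than `field_size`", call. = FALSE)
  }
  structure(
    list(n_dots = n_dots, field_size = field_size,
         blob_diameter = blob_diameter, blob_sd_factor = blob_sd_factor),
    class = c("dot_geometry", "stim_geometry")
  )
}

n_elements <- function(geometry) {
  if (inherits(geometry, "wedge_geometry")) geometry$n_wedges else geometry$n_dots
}

stimulus_type <- function(geometry) {
  if (inherits(geometry, "wedge_geometry")) "wedge" else "dot"
}

#' Condition label for a stimulus
#'
#' Bundles a colour-symmetry arrangement with the number of colours and the
#' stimulus type. Colour-grouped arrangements exist only for two-colour
#' stimuli (a hemifield-pure pattern needs exactly one colour per side).
#'
#' @param colour_symmetry One of [condition_names()].
#' @param n_colours 2 or 3.
#' @param stimulus_type `"wedge"` or `"dot"`.
#' @return An object of class `condition_label`.
#' @export
condition_label <- function(colour_symmetry, n_colours = 2,
                            stimulus_type = "wedge") {
  colour_symmetry <- match.arg(colour_symmetry, condition_names())
  stimulus_type <- match.arg(stimulus_type, c("wedge", "dot"))
  if (!n_colours %in% c(2, 3)) {
    stop("`n_colours` must be 2 or 3", call. = FALSE)
  }
  if (n_colours != 2 &&
      colour_symmetry %in% c("grouped_antisymmetric", "grouped_random_foil")) {
    stop("colour-grouped arrangements require exactly 2 colours",
         call. = FALSE)
  }
  structure(
    list(colour_symmetry = colour_symmetry, n_colours = as.integer(n_colours),
         stimulus_type = stimulus_type),
    class = "condition_label"
  )
}

is_foil_condition <- function(colour_symmetry) {
  colour_symmetry %in% c("random_foil", "grouped_random_foil")
}

is_grouped_condition <- function(colour_symmetry) {
  colour_symmetry %in% c("grouped_antisymmetric", "grouped_random_foil")
}

#' Construct a stimulus pattern object
#'
#' Low-level constructor; users normally obtain patterns from
#' [generate_wedge_pattern()] or [generate_dot_pattern()]. `elements` is a
#' data frame with columns `role` (`"signal"`/`"noise"`), `colour`, and
#' either `theta`/`width` (wedges, degrees) or `x`/`y` (dots, degrees of
#' visual angle); signal elements additionally carry `pair` (integer pair
#' id, `NA` for noise).
#'
#' @param elements Element data frame (see Details).
#' @param condition A [condition_label()].
#' @param geometry A [wedge_geometry()] or [dot_geometry()].
#' @param seed Integer RNG seed the pattern was generated from.
#' @param symmetric_flag Logical; `TRUE` when the pattern carries a symmetry
#'   signal (a target interval), `FALSE` for foils.
#' @return An object of class `sym_pattern`.
#' @export
new_pattern <- function(elements, condition, geometry, seed, symmetric_flag) {
  stopifnot(is.data.frame(elements), inherits(condition, "condition_label"),
            inherits(geometry, "stim_geometry"))
  structure(
    list(elements = elements, condition = condition, geometry = geometry,
         seed = as.integer(seed), symmetric_flag = isTRUE(symmetric_flag)),
    class = "sym_pattern"
  )
}

#' Hemifield of pattern elements
#'
#' Wedge elements are assigned by polar angle (right hemifield: theta in
#' (0, 180)); dots by the sign of `x` (right: x > 0). Elements exactly on
#' the axis would get `NA`; generators never place any there.
#'
#' @param pattern A `sym_pattern`.
#' @return Character vector (`"left"`/`"right"`), one entry per element.
#' @export
element_hemifield <- function(pattern) {
  el <- pattern$elements
  if (stimulus_type(pattern$geometry) == "wedge") {
    ifelse(el$theta > 0 & el$theta < 180, "right",
           ifelse(el$theta > 180, "left", NA_character_))
  } else {
    ifelse(el$x > 0, "right", ifelse(el$x < 0, "left", NA_character_))
  }
}

#' Validate a pattern against its structural invariants
#'
#' Checks element count, equal colour proportions, per-colour hemifield
#' balance (hemifield purity for colour-grouped arrangements), the
#' within-hemifield placement of every element, and pairwise non-overlap.
#'
#' @param pattern A `sym_pattern`.
#' @return Invisibly `TRUE`; otherwise an error naming the violated
#'   invariant.
#' @export
validate_pattern <- function(pattern) {
  el <- pattern$elements
  geom <- pattern$geometry
  cond <- pattern$condition
  if (nrow(el) != n_elements(geom)) {
    stop("element count does not match geometry", call. = FALSE)
  }
  cols <- table(el$colour)
  if (length(cols) != cond$n_colours || length(unique(as.integer(cols))) != 1) {
    stop("colours are not in equal proportion", call. = FALSE)
  }
  hemi <- element_hemifield(pattern)
  if (anyNA(hemi)) stop("element lies on the symmetry axis", call. = FALSE)
  if (sum(hemi == "left") != sum(hemi == "right")) {
    stop("hemifield element counts differ", call. = FALSE)
  }
  if (is_grouped_condition(cond$colour_symmetry)) {
    left_cols <- unique(el$colour[hemi == "left"])
    right_cols <- unique(el$colour[hemi == "right"])
    if (length(left_cols) != 1 || length(right_cols) != 1 ||
        left_cols == right_cols) {
      stop("colour-grouped pattern is not hemifield-pure", call. = FALSE)
    }
  } else {
    bal <- table(el$colour, hemi)
    if (any(bal[, "left"] != bal[, "right"])) {
      stop("per-colour hemifield balance violated", call. = FALSE)
    }
  }
  if (stimulus_type(geom) == "wedge") {
    half <- geom$wedge_width / 2
    lo <- el$theta - half
    hi <- el$theta + half
    in_right <- lo >= 0 & hi <= 180
    in_left <- lo >= 180 & hi <= 360
    if (!all(in_right | in_left)) {
      stop("wedge extent crosses the symmetry axis", call. = FALSE)
    }
    d <- abs(outer(el$theta, el$theta, "-")) %% 360
    d <- pmin(d, 360 - d)
    diag(d) <- Inf
    if (any(d < geom$wedge_width - 1e-9)) {
      stop("wedge extents overlap", call. = FALSE)
    }
  } else {
    if (any(abs(el$x) < geom$blob_diameter / 2 - 1e-12)) {
      stop("dot straddles the symmetry axis", call. = FALSE)
    }
    half_fs <- geom$field_size / 2
    if (any(abs(el$x) > half_fs | abs(el$y) > half_fs)) {
      stop("dot outside the field", call. = FALSE)
    }
    d <- as.matrix(stats::dist(cbind(el$x, el$y)))
    diag(d) <- Inf
    if (any(d < geom$blob_diameter - 1e-9)) {
      stop("blobs overlap", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.sym_pattern <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<sym_pattern> %s, %d elements, %d colours, %s (%s)\n",
              stimulus_type(g), n_elements(g), x$condition$n_colours,
              x$condition$colour_symmetry,
              if (x$symmetric_flag) "symmetric" else "foil"))
  cat(sprintf("  seed %d; roles: %s\n", x$seed,
              paste(sprintf("%s=%d", names(table(x$elements$role)),
                            as.integer(table(x$elements$role))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.wedge_geometry <- function(x, ...) {
  cat(sprintf(
    "<wedge_geometry> %d wedges, %.0f%% coverage, width %.3g deg, outer %.4g deg, inner %.4g deg\n",
    x$n_wedges, 100 * x$coverage, x$wedge_width, x$outer_diameter,
    x$inner_diameter))
  invisible(x)
}

#' @export
print.dot_geometry <- function(x, ...) {
  cat(sprintf(
    "<dot_geometry> %d blobs of %.3g deg over %.3g x %.3g deg\n",
    x$n_dots, x$blob_diameter, x$field_size, x$field_size))
  invisible(x)
}

#' @export
print.condition_label <- function(x, ...) {
  cat(sprintf("<condition> %s, %d colours, %s stimulus\n",
              x$colour_symmetry, x$n_colours, x$stimulus_type))
  invisible(x)
}

## Run `expr` with a temporary RNG state seeded from `seed`, restoring the
## caller's stream afterwards. Keeps pattern generation reproducible without
## clobbering simulation-level RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

## Derive a child seed from a parent seed and an index; stays below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483629) + 1L
}
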