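# Shared fixtures: standard geometries, Monte-Carlo trial runners over
# pre-generated pattern pools, and a brute-force matching oracle.

geom_w24 <- wedge_geometry(24, 0.5, 13.79, 3.10)
geom_w36 <- wedge_geometry(36, 0.5, 13.79, 3.10)
geom_w16 <- wedge_geometry(16, 0.2, 14.74, 3.10)
geom_d96 <- dot_geometry(96, 11, 0.41, 5)

foil_name <- function(condition) {
  if (condition == "grouped_antisymmetric") "grouped_random_foil" else "random_foil"
}

# Pool of (target, foil) pattern pairs for one condition; cycling a fixed
# pool keeps Monte-Carlo observer experiments cheap while still averaging
# over pattern realizations.
pattern_pool <- function(geometry, condition, n_colours = 2, pool = 50,
                         seed = 1L, cue_colour = "red") {
  st <- if (inherits(geometry, "wedge_geometry")) "wedge" else "dot"
  cl <- condition_label(condition, n_colours, st)
  fo <- condition_label(foil_name(condition), n_colours, st)
  list(
    target = lapply(seq_len(pool), function(i)
      generate_pattern(geometry, cl, cue_colour, seed = 1000L * seed + i)),
    foil = lapply(seq_len(pool), function(i)
      generate_pattern(geometry, fo, cue_colour, seed = 5000L * seed + i))
  )
}

# Monte-Carlo 2IFC accuracy over a pattern pool.
mc_accuracy <- function(pool, params, n_trials, cued = FALSE,
                        cue_colour = "red", seed = 1L) {
  np <- length(pool$target)
  set.seed(seed)
  mean(vapply(seq_len(n_trials), function(i) {
    j <- 1L + (i %% np)
    decide_2ifc(pool$target[[j]], pool$foil[[j]], params, cued,
                if (cued) cue_colour)$correct
  }, logical(1)))
}

# Brute-force maximum matching: enumerate all assignments of left elements
# to distinct right elements allowed by the adjacency matrix.
brute_force_max_matching <- function(adj) {
  nl <- nrow(adj)
  best <- 0L
  recurse <- function(u, used, size) {
    if (size + (nl - u + 1L) <= best) return()  # bound
    if (u > nl) {
      best <<- max(best, size)
      return()
    }
    recurse(u + 1L, used, size)  # leave u unmatched
    for (v in which(adj[u, ])) {
      if (!used[v]) {
        used[v] <- TRUE
        recurse(u + 1L, used, size + 1L)
        used[v] <- FALSE
      }
    }
  }
  if (nl > 0 && ncol(adj) > 0) recurse(1L, logical(ncol(adj)), 0L)
  best
}

# Brute-force E for a pattern: reimplements the pairing rule directly from
# element positions (independent of score_symmetry internals).
brute_force_E <- function(pattern, tolerance = NULL) {
  if (is.null(tolerance)) tolerance <- default_tolerance(pattern$geometry)
  el <- pattern$elements
  hemi <- element_hemifield(pattern)
  L <- which(hemi == "left")
  R <- which(hemi == "right")
  if (length(L) == 0 || length(R) == 0) return(0L)
  if (inherits(pattern$geometry, "wedge_geometry")) {
    d <- abs(outer((360 - el$theta[L]) %% 360, el$theta[R], "-")) %% 360
    d <- pmin(d, 360 - d)
  } else {
    d <- sqrt(outer(-el$x[L], el$x[R], "-")^2 + outer(el$y[L], el$y[R], "-")^2)
  }
  brute_force_max_matching(d <= tolerance)
}

# Simulated binomial single-trial accuracy data from known cell log-odds.
simulate_glmm_data <- function(n_participants, trials_per_cell, beta0 = 0.5,
                               effect_ab = 0, sd_participant = 0.3,
                               seed = 1L) {
  set.seed(seed)
  d <- expand.grid(participant = seq_len(n_participants),
                   A = c("a1", "a2"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  d <- d[rep(seq_len(nrow(d)), each = trials_per_cell), ]
  b0 <- rnorm(n_participants, beta0, sd_participant)
  eta <- b0[d$participant] +
    effect_ab * (d$A == "a2") * (d$B == "b2")
  d$correct <- rbinom(nrow(d), 1, plogis(eta))
  d$participant <- paste0("p", d$participant)
  rownames(d) <- NULL
  d
}
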