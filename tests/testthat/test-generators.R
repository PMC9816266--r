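test_that("generation is reproducible and seeds matter", {
  cond <- condition_label("segregated", 2)
  p1 <- generate_wedge_pattern(geom_w24, cond, "red", seed = 42)
  p2 <- generate_wedge_pattern(geom_w24, cond, "red", seed = 42)
  expect_identical(p1, p2)
  p3 <- generate_wedge_pattern(geom_w24, cond, "red", seed = 43)
  expect_false(identical(p1$elements, p3$elements))
  d1 <- generate_dot_pattern(geom_d96, condition_label("segregated", 2, "dot"),
                             seed = 7)
  d2 <- generate_dot_pattern(geom_d96, condition_label("segregated", 2, "dot"),
                             seed = 7)
  expect_identical(d1, d2)
  # generation does not disturb the caller's RNG stream
  set.seed(5); before <- .Random.seed
  invisible(generate_wedge_pattern(geom_w24, cond, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("wedge patterns realize the stated signal/noise/colour composition", {
  p <- generate_wedge_pattern(geom_w24, condition_label("segregated", 2),
                              "red", seed = 11)
  expect_equal(sum(p$elements$role == "signal"), 12)
  expect_equal(sum(p$elements$role == "noise"), 12)
  expect_equal(as.integer(table(p$elements$colour)), c(12, 12))
  expect_true(all(p$elements$colour[p$elements$role == "signal"] == "red"))

  p3 <- generate_wedge_pattern(geom_w24, condition_label("nonsegregated", 3),
                               seed = 12)
  expect_equal(sum(p3$elements$role == "signal"), 8)
  expect_equal(as.integer(table(p3$elements$colour)), c(8, 8, 8))

  p36 <- generate_wedge_pattern(geom_w36, condition_label("antisymmetric", 3),
                                seed = 13)
  expect_equal(sum(p36$elements$role == "signal"), 12)
  expect_equal(as.integer(table(p36$elements$colour)), c(12, 12, 12))

  pg <- generate_wedge_pattern(geom_w16,
                               condition_label("grouped_antisymmetric", 2),
                               seed = 14)
  hemi <- element_hemifield(pg)
  expect_length(unique(pg$elements$colour[hemi == "left"]), 1)
  expect_length(unique(pg$elements$colour[hemi == "right"]), 1)
  sig <- pg$elements[pg$elements$role == "signal", ]
  expect_equal(nrow(sig), 8)
  for (pr in unique(sig$pair)) {
    expect_length(unique(sig$colour[sig$pair == pr]), 2)  # mismatched
  }
})

test_that("signal pairs mirror exactly and noise carries no symmetry", {
  for (s in 1:5) {
    p <- generate_wedge_pattern(geom_w24, condition_label("antisymmetric", 2),
                                seed = 200 + s)
    sig <- p$elements[p$elements$role == "signal", ]
    for (pr in unique(sig$pair)) {
      th <- sig$theta[sig$pair == pr]
      expect_equal(mirror_angle(th[1]), th[2], tolerance = 1e-12)
    }
    # removing the signal leaves a zero-symmetry residue
    noise_only <- subset_elements(p, role = "noise")
    expect_equal(score_symmetry(noise_only)$E, 0)
  }
  for (s in 1:3) {
    pd <- generate_dot_pattern(geom_d96, condition_label("segregated", 2, "dot"),
                               seed = 300 + s)
    sig <- pd$elements[pd$elements$role == "signal", ]
    expect_equal(nrow(sig), 48)
    for (pr in unique(sig$pair)) {
      xy <- sig[sig$pair == pr, c("x", "y")]
      expect_equal(xy$x[1], -xy$x[2])
      expect_equal(xy$y[1], xy$y[2])
    }
    expect_equal(score_symmetry(subset_elements(pd, role = "noise"))$E, 0)
  }
})

test_that("mean circumferential gap matches closed form and measurement", {
  expect_equal(expected_mean_gap(wedge_geometry(36, 0.5)), 5)
  expect_equal(expected_mean_gap(geom_w24), 7.5)
  g16 <- wedge_geometry(16, 0.2, 14.74)
  expect_equal(expected_mean_gap(g16), 18)
  # cross-check against the measured mean gap of generated patterns
  gaps <- vapply(1:50, function(s) {
    p <- generate_wedge_pattern(g16, condition_label("random_foil", 2),
                                seed = 400 + s)
    th <- sort(p$elements$theta)
    mean(diff(c(th, th[1] + 360)) - g16$wedge_width)
  }, numeric(1))
  expect_equal(mean(gaps), 18, tolerance = 1e-9)  # exact: gaps sum to slack
})

test_that("tolerance window is the average spacing", {
  expect_equal(tolerance_window(16), 22.5)
  expect_equal(tolerance_window(24), 15)
  expect_equal(tolerance_window(36), 10)
  expect_equal(tolerance_window(360), 1)
  expect_error(tolerance_window(0), "positive")
})

test_that("condition predicates form a diagonal acceptance matrix", {
  classes <- c("segregated", "nonsegregated", "antisymmetric",
               "grouped_antisymmetric", "random_foil", "grouped_random_foil")
  for (s in 1:8) {
    for (ci in classes) {
      p <- generate_wedge_pattern(geom_w16, condition_label(ci, 2), "red",
                                  seed = 700 + 13 * s + match(ci, classes))
      for (cj in classes) {
        expect_identical(condition_predicate(p, cj, signal_colour = "red"),
                         ci == cj,
                         label = sprintf("%s pattern vs %s predicate", ci, cj))
      }
    }
  }
})

test_that("random-segregated signal colour varies uniformly across seeds", {
  cond <- condition_label("random_segregated", 2)
  cols <- vapply(1:60, function(s) {
    p <- generate_wedge_pattern(geom_w16, cond, cue_colour = "red",
                                seed = 900 + s)
    unique(p$elements$colour[p$elements$role == "signal"])
  }, character(1))
  expect_true(all(condition_predicate(
    generate_wedge_pattern(geom_w16, cond, seed = 901), "random_segregated")))
  # both colours occur; no tuning to the cue colour
  expect_gt(sum(cols == "green"), 10)
  expect_gt(sum(cols == "red"), 10)
})

test_that("invalid condition/geometry combinations fail loudly", {
  expect_error(generate_wedge_pattern(
    geom_w24, condition_label("segregated", 2, "dot")), "dot")
  expect_error(generate_dot_pattern(
    geom_d96, condition_label("segregated", 2, "wedge")), "wedge")
  # 16 wedges cannot balance 3 colours
  expect_error(generate_wedge_pattern(
    geom_w16, condition_label("nonsegregated", 3)), "divisible")
})
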