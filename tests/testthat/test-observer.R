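test_that("noise-free perception reduces to the holographic score", {
  p0 <- observer_params(sigma_pos = 0, lapse_rate = 0)
  seg <- generate_wedge_pattern(geom_w24, condition_label("segregated", 2),
                                "red", seed = 31)
  set.seed(1)
  expect_equal(perceive_W(seg, p0), 0.25)

  full <- observer_params(sigma_pos = 0, attention_filter = 1,
                          cue_utilization = 1, lapse_rate = 0)
  # cued full filter on segregated: only the (all-signal) cued colour remains
  expect_equal(perceive_W(seg, full, cued = TRUE, cue_colour = "red"), 0.5)
  # on nongrouped antisymmetric the attended colour carries no symmetry
  anti <- generate_wedge_pattern(geom_w24, condition_label("antisymmetric", 2),
                                 seed = 32)
  expect_equal(perceive_W(anti, full, cued = TRUE, cue_colour = "red"), 0)
  # colour-grouped patterns make the cue neutral: no filtering happens
  grp <- generate_wedge_pattern(geom_w16,
                                condition_label("grouped_antisymmetric", 2),
                                seed = 33)
  expect_equal(perceive_W(grp, full, cued = TRUE, cue_colour = "red"),
               score_symmetry(grp)$W)
  expect_error(perceive_W(seg, full, cued = TRUE), "cue_colour")
})

test_that("2IFC decisions are perfect without noise and random under lapse", {
  p0 <- observer_params(sigma_pos = 0, lapse_rate = 0)
  seg <- generate_wedge_pattern(geom_w24, condition_label("segregated", 2),
                                seed = 41)
  foil <- generate_wedge_pattern(geom_w24, condition_label("random_foil", 2),
                                 seed = 42)
  set.seed(2)
  expect_true(all(vapply(1:50, function(i)
    decide_2ifc(seg, foil, p0)$correct, logical(1))))
  expect_true(all(vapply(1:50, function(i)
    decide_2ifc(foil, seg, p0)$choice == "second", logical(1))))

  lapser <- observer_params(sigma_pos = 0, lapse_rate = 1)
  set.seed(3)
  acc <- mean(vapply(1:2000, function(i)
    decide_2ifc(seg, foil, lapser)$correct, logical(1)))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 2000))

  expect_error(decide_2ifc(seg, seg, p0), "exactly one")
  expect_error(decide_2ifc(foil, foil, p0), "exactly one")
})

test_that("accuracy decreases with positional noise", {
  pool <- pattern_pool(geom_w16, "segregated", pool = 40, seed = 3)
  sigmas <- c(0.5, 2, 4, 8)
  acc <- vapply(seq_along(sigmas), function(i) {
    mc_accuracy(pool, observer_params(sigma_pos = sigmas[i], lapse_rate = 0),
                n_trials = 1200, seed = 50 + i)
  }, numeric(1))
  expect_true(all(diff(acc) < 0))
  expect_gt(acc[1], 0.9)
})

test_that("simulated participants cover the design deterministically", {
  des <- build_design(2, seed = 6, trials_per_condition = 2,
                      include_practice = FALSE)
  prm <- list(wedge = observer_preset("younger", "wedge"),
              dot = observer_preset("younger", "dot"))
  rec <- simulate_participant(des, prm, participant = "s1", seed = 17)
  expect_equal(nrow(rec), 2 * 5 * 2 * 2)  # trials x conditions x stim x attention
  expect_identical(rec,
                   simulate_participant(des, prm, participant = "s1", seed = 17))
  expect_true(all(rec$correct == (rec$response == rec$symmetric_interval)))
  # full-scale design: 250 main trials per block, 50 per condition
  full <- build_design(2, seed = 6)
  main <- full$trials[!full$trials$practice, ]
  expect_equal(as.integer(table(main$block_index)), rep(250L, 4))
  expect_true(all(table(main$condition, main$block_index) == 50))

  # noise-free, lapse-free observer is perfect on segregated trials
  des1 <- build_design(1, seed = 8, trials_per_condition = 3,
                       include_practice = FALSE)
  rec1 <- simulate_participant(des1, observer_params(0, lapse_rate = 0),
                               seed = 19)
  expect_equal(mean(rec1$correct[rec1$condition == "segregated"]), 1)
})

test_that("practice blocks are flagged and repeated until the threshold", {
  des <- build_design(1, seed = 9, trials_per_condition = 1,
                      include_practice = TRUE, practice_trials = 4)
  good <- simulate_participant(des, observer_params(0, lapse_rate = 0),
                               seed = 23)
  expect_true(any(good$practice))
  # a perfect observer never repeats practice: 4 practice per block
  expect_equal(sum(good$practice), 4 * 8)
  lapser <- simulate_participant(des, observer_params(0, lapse_rate = 1),
                                 seed = 23, max_practice_attempts = 2)
  expect_gt(sum(lapser$practice), 4 * 8)  # some blocks repeated practice
})

test_that("cueing helps segregated, hurts nongrouped antisymmetric, spares the rest", {
  prm <- observer_preset("younger", "wedge")
  n <- 2500
  diffs <- vapply(c("segregated", "nonsegregated", "antisymmetric",
                    "grouped_antisymmetric"), function(cond) {
    pool <- pattern_pool(geom_w16, cond, pool = 40, seed = 11)
    mc_accuracy(pool, prm, n, cued = TRUE, seed = 61) -
      mc_accuracy(pool, prm, n, cued = FALSE, seed = 62)
  }, numeric(1))
  se2 <- sqrt(2 * 0.25 / n)  # SE of an accuracy difference, upper bound
  expect_gt(diffs["segregated"], 3 * se2)        # pronounced benefit
  expect_lt(diffs["antisymmetric"], -3 * se2)    # pronounced cost
  expect_lt(abs(diffs["grouped_antisymmetric"]), 3 * se2)  # neutral cue
  # any nonsegregated side effect stays small relative to the real effects
  expect_lt(abs(diffs["nonsegregated"]), diffs["segregated"])
  expect_lt(abs(diffs["nonsegregated"]), abs(diffs["antisymmetric"]))
})

test_that("cued full-filter antisymmetric performance sits at chance", {
  pool <- pattern_pool(geom_w16, "antisymmetric", pool = 40, seed = 13)
  n <- 3000
  # noiseless encoding: the attended colour carries zero symmetry in both
  # intervals, so every trial is an exact tie resolved by a coin flip
  exact <- observer_params(sigma_pos = 0, attention_filter = 1,
                           cue_utilization = 1, lapse_rate = 0)
  acc0 <- mc_accuracy(pool, exact, n, cued = TRUE, seed = 70)
  expect_lt(abs(acc0 - 0.5), 2 * sqrt(0.25 / n))
  # with encoding noise, accidental correspondences keep performance near
  # (not exactly at) chance, far below the uncued level
  noisy <- observer_params(sigma_pos = 2.5, attention_filter = 1,
                           cue_utilization = 1, lapse_rate = 0)
  acc <- mc_accuracy(pool, noisy, n, cued = TRUE, seed = 71)
  expect_lt(abs(acc - 0.5), 0.06)
  expect_lt(acc, mc_accuracy(pool, noisy, n, cued = FALSE, seed = 72) - 0.1)
})

test_that("no parameterization dips below the chance floor", {
  pool <- pattern_pool(geom_w16, "nonsegregated", pool = 30, seed = 15)
  hostile <- list(
    observer_params(sigma_pos = 50, lapse_rate = 0),
    observer_params(sigma_pos = 0, lapse_rate = 1),
    observer_params(sigma_pos = 10, attention_filter = 1,
                    cue_utilization = 1, lapse_rate = 0.5)
  )
  n <- 1500
  for (prm in hostile) {
    acc <- mc_accuracy(pool, prm, n, cued = TRUE, seed = 81)
    expect_gte(acc, 0.5 - 3 * sqrt(0.25 / n))
  }
})

test_that("age presets dissociate cue use between stimulus types", {
  old_w <- observer_preset("older", "wedge")
  old_d <- observer_preset("older", "dot")
  yng_w <- observer_preset("younger", "wedge")
  expect_gt(old_w$sigma_pos, yng_w$sigma_pos)
  expect_gt(old_w$cue_utilization, old_d$cue_utilization)
  # older observers gain from wedge cueing but not from dot cueing
  pw <- pattern_pool(geom_w16, "segregated", pool = 40, seed = 17)
  n <- 2000
  gain_w <- mc_accuracy(pw, old_w, n, cued = TRUE, seed = 91) -
    mc_accuracy(pw, old_w, n, cued = FALSE, seed = 92)
  pd <- pattern_pool(geom_d96, "segregated", pool = 30, seed = 18)
  gain_d <- mc_accuracy(pd, old_d, n, cued = TRUE, seed = 93) -
    mc_accuracy(pd, old_d, n, cued = FALSE, seed = 94)
  se2 <- sqrt(2 * 0.25 / n)
  expect_gt(gain_w, 3 * se2)
  expect_lt(abs(gain_d), gain_w / 2)
})
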