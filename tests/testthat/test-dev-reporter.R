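test_that("normalization is exact, idempotent and scale invariant", {
  flat <- normalize_course(make_course(rep(7, 13)))
  expect_equal(flat$normalized, rep(1 / 13, 13))
  one <- normalize_course(make_course(c(rep(0, 6), 5, rep(0, 6))))
  expect_equal(one$normalized[7], 1)
  expect_equal(sum(one$normalized), 1)
  a <- normalize_course(make_course(1:13))
  b <- normalize_course(make_course((1:13) * 1000))
  expect_equal(a$normalized, b$normalized)
  c2 <- make_course(1:13); c2$fluorescence <- a$normalized
  expect_equal(normalize_course(c2)$normalized, a$normalized)
  # per-replicate sums are exactly 1
  rc <- normalize_course(gen_reporter_course("mound", seed = 2))
  sums <- tapply(rc$normalized, rc$replicate_id, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-9)
})

test_that("an all-zero course is flagged dead, not normalized", {
  dead <- normalize_course(make_course(rep(0, 13)))
  expect_true(all(dead$dead))
  expect_true(all(is.na(dead$normalized)))
  expect_false(detect_profile(dead, 1.1)$has_profile)
})

test_that("profile detection follows the threshold arithmetic", {
  # uniform course: no point ever exceeds the mean
  flat <- normalize_course(make_course(rep(3, 13)))
  for (th in seq(1.1, 1.6, by = 0.1))
    expect_false(detect_profile(flat, th)$has_profile)
  # one point at 0.2 of the total: 0.2 >= 1.6/13 = 0.123
  pk <- make_peak_course(0.2 * 13)
  res <- detect_profile(pk, 1.6)
  expect_true(res$has_profile)
  expect_equal(res$peak_time_h, 12)
  expect_equal(res$peak_value, 0.2)
  expect_error(detect_profile(pk, 1.05), "threshold")
})

test_that("profile detection is monotone in the threshold", {
  set.seed(8)
  for (i in 1:20) {
    v <- rexp(13)
    nc <- normalize_course(make_course(v))
    det <- vapply(seq(1.1, 1.6, by = 0.1),
                  function(th) detect_profile(nc, th)$has_profile, logical(1))
    # once detection is lost at a threshold it stays lost at higher ones
    expect_true(all(diff(as.integer(det)) <= 0))
  }
})

test_that("threshold calibration returns the grid maximum that all controls pass", {
  strong <- lapply(1:3, function(s)
    normalize_course(gen_reporter_course("slug", seed = s, noise_cv = 0.02)))
  expect_equal(calibrate_threshold(strong), 1.6)
  # weakest control peak at 1.34/T calibrates to 1.3, and 1.4 fails
  ctrl <- list(make_peak_course(1.34), make_peak_course(1.55))
  expect_equal(calibrate_threshold(ctrl), 1.3)
  expect_false(all(vapply(ctrl, function(cc)
    detect_profile(cc, 1.4)$has_profile, logical(1))))
  # a flat control fails calibration outright
  expect_error(calibrate_threshold(list(make_peak_course(1.34),
                                        normalize_course(make_course(rep(1, 13))))),
               "calibration failed")
  expect_error(calibrate_threshold(list()), "empty control set")
})

test_that("treated identical to control is called normal", {
  ctrl <- normalize_course(gen_reporter_course("mound", seed = 4))
  res <- compare_development(ctrl, ctrl, threshold = 1.3, reporter = "mound")
  expect_equal(res$call, "normal")
})

test_that("a blocked downstream reporter is called absent", {
  ctrl <- normalize_course(gen_reporter_course("slug", seed = 5))
  th <- calibrate_threshold(list(ctrl))
  trt <- normalize_course(gen_reporter_course("slug", seed = 6,
                                              block_at_stage = "streaming"))
  res <- compare_development(ctrl, trt, th, reporter = "slug")
  expect_equal(res$call, "absent")
})

test_that("a control without a profile invalidates the assay", {
  flat <- normalize_course(make_course(rep(2, 13)))
  trt <- normalize_course(gen_reporter_course("slug", seed = 1))
  expect_error(compare_development(flat, trt, 1.2), "assay invalid")
})

test_that("planted delays are called delayed with significant timing", {
  hits <- vapply(1:40, function(s) {
    ctrl <- normalize_course(gen_reporter_course("mound", seed = s,
                                                 noise_cv = 0.03))
    trt <- normalize_course(gen_reporter_course("mound", seed = s + 1000,
                                                noise_cv = 0.03,
                                                delay_h = 4))
    res <- compare_development(ctrl, trt, 1.2, reporter = "mound")
    res$call == "delayed" && res$timing_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("attenuation is called when timing is unchanged", {
  ctrl <- normalize_course(gen_reporter_course("culminant", seed = 11,
                                               noise_cv = 0.02))
  trt <- normalize_course(gen_reporter_course("culminant", seed = 12,
                                              noise_cv = 0.02,
                                              attenuate_frac = 0.35))
  res <- compare_development(ctrl, trt, 1.1, reporter = "culminant")
  expect_true(res$call %in% c("attenuated", "absent"))
})

test_that("proportioning is computed only under a normal fruiting-body call", {
  sp <- normalize_course(make_course_reps(rbind(c(rep(1, 12), 4),
                                                c(rep(1, 12), 4))))
  st <- normalize_course(make_course_reps(rbind(c(rep(1, 12), 2),
                                                c(rep(1, 12), 2))))
  # treated identical to wild type: ratio 1
  res <- proportioning_score(sp, st, sp, st, "normal")
  expect_true(res$valid)
  expect_equal(res$ratio_vs_wildtype, 1)
  # treated prespore 24 h point carries twice the normalized signal: ratio 2
  sp2 <- normalize_course(make_course_reps(
    rbind(c(rep(0.6 / 12, 12), 0.4), c(rep(0.6 / 12, 12), 0.4))))
  spw <- normalize_course(make_course_reps(
    rbind(c(rep(0.8 / 12, 12), 0.2), c(rep(0.8 / 12, 12), 0.2))))
  res2 <- proportioning_score(sp2, st, spw, st, "normal")
  expect_true(res2$valid)
  expect_equal(res2$ratio_vs_wildtype, 2)
  # delayed fruiting body: no ratio emitted
  res3 <- proportioning_score(sp, st, sp, st, "delayed")
  expect_false(res3$valid)
  expect_true(is.na(res3$ratio_vs_wildtype))
})

test_that("agreement tallies match a brute-force per-cell comparison", {
  calls <- c("normal", "absent", "delayed", "advanced", "attenuated",
             "elevated")
  set.seed(31)
  q <- data.frame(compound = rep(sprintf("c%d", 1:10), each = 6),
                  reporter = rep(stage_order(), 10),
                  call = sample(calls, 60, replace = TRUE))
  v <- q; v$call <- sample(calls, 60, replace = TRUE)
  tal <- agreement_tally(q, v)
  # brute-force oracles
  pool2 <- function(x) ifelse(x %in% c("delayed", "advanced", "absent"),
                              "T", x)
  pool3 <- function(x) ifelse(x == "normal", "n", "d")
  expect_equal(tal$n_identical[tal$rule == "strict"], sum(q$call == v$call))
  expect_equal(tal$n_identical[tal$rule == "timing_pooled"],
               sum(pool2(q$call) == pool2(v$call)))
  expect_equal(tal$n_identical[tal$rule == "plus_strength"],
               sum(pool3(q$call) == pool3(v$call)))
  expect_equal(tal$n_total, rep(60, 3))
  # identical matrices agree fully under every rule
  tal2 <- agreement_tally(q, q)
  expect_equal(tal2$n_identical, rep(60, 3))
  # delayed-vs-absent counts as identical only once timing is pooled
  q1 <- data.frame(compound = "c", reporter = "slug", call = "delayed")
  v1 <- data.frame(compound = "c", reporter = "slug", call = "absent")
  t1 <- agreement_tally(q1, v1)
  expect_equal(t1$n_identical, c(0, 1, 1))
  expect_error(agreement_tally(q1, data.frame(compound = "d",
                                              reporter = "slug",
                                              call = "absent")), "keys")
})
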