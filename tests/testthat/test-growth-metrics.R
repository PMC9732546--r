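test_that("volume conversion follows both conventions and validates input", {
  expect_equal(volume_from_diameters(10, 6), 1800)
  expect_equal(volume_from_diameters(10, 6, "conventional"), 180)
  expect_equal(volume_from_diameters(2, 2), 8)
  # vectorized
  expect_equal(volume_from_diameters(c(10, 2), c(6, 2)), c(1800, 8))
  expect_error(volume_from_diameters(6, 10), class = "pdx_validation_error")
  expect_error(volume_from_diameters(5, 0), class = "pdx_validation_error")
  expect_error(volume_from_diameters(-3, -5), class = "pdx_validation_error")
})

test_that("RTV series normalizes to the day-1 baseline", {
  expect_equal(rtv_series(make_curve(c(100, 250, 400), c(1, 8, 15)))$rtv,
               c(1, 2.5, 4))
  expect_equal(rtv_series(make_curve(rep(120, 4)))$rtv, rep(1, 4))
  expect_equal(rtv_series(make_curve(c(80, 40)))$rtv, c(1, 0.5))
  # day-1 RTV is exactly 1 for arbitrary positive baselines
  for (v1 in c(0.3, 7, 123.456, 1e6))
    expect_identical(rtv_series(make_curve(c(v1, 2 * v1)))$rtv[1], 1)
  expect_error(growth_curve("m1", c(8, 15), c(1, 2)),
               class = "pdx_validation_error")  # no day-1 measurement
  expect_error(growth_curve("m1", c(1, 8, 8), c(1, 2, 3)),
               class = "pdx_validation_error")  # non-increasing days
})

test_that("median RTV uses the even-count mean-of-central-values convention", {
  arm <- make_arm("a", list(c(100, 100), c(100, 200), c(100, 900)))
  expect_equal(median_rtv(arm, 8), 2)
  arm2 <- make_arm("a", list(c(100, 100), c(100, 300)))
  expect_equal(median_rtv(arm2, 8), 2)
  expect_equal(median_rtv(make_arm("a", list(c(100, 200))), 8), 2)
  expect_error(median_rtv(arm, 99), class = "pdx_not_evaluable")
})

test_that("TGI series and optimal TGI follow 100 - 100*RTVt/RTVc", {
  days <- c(1, 8)
  treated <- make_arm("t", list(c(100, 150), c(100, 200), c(100, 250)), days)
  control <- make_arm("control", list(c(100, 400), c(100, 500), c(100, 600)), days)
  ser <- tgi_series(treated, control)
  expect_equal(ser$tgi_percent[ser$day == 8], 60)   # medians 2 vs 5
  expect_true(ser$meaningful[ser$day == 8])
  expect_equal(ser$tgi_percent[ser$day == 1], 0)
  expect_false(ser$meaningful[ser$day == 1])

  # identical arms: TGI identically zero
  same <- make_arm("control", list(c(100, 180, 320), c(90, 200, 410)))
  same_t <- make_arm("t", list(c(100, 180, 320), c(90, 200, 410)))
  expect_equal(tgi_series(same_t, same)$tgi_percent, c(0, 0, 0))

  # strong regression: treated median 0.5 vs control 4 -> 87.5%
  tr <- make_arm("t", list(c(100, 50), c(100, 50)), days)
  co <- make_arm("control", list(c(100, 400), c(100, 400)), days)
  expect_equal(tgi_series(tr, co)$tgi_percent[2], 87.5)

  # TGI invariant under common rescaling of all volumes
  sc <- 37.2
  tr2 <- make_arm("t", list(sc * c(100, 50), sc * c(100, 50)), days)
  co2 <- make_arm("control", list(sc * c(100, 400), sc * c(100, 400)), days)
  expect_equal(tgi_series(tr2, co2)$tgi_percent,
               tgi_series(tr, co)$tgi_percent)

  # optimal = max, ties to earliest day, and dominates the whole series
  t3 <- make_arm("t", list(c(100, 120, 180, 180), c(100, 120, 180, 180)))
  c3 <- make_arm("control", list(c(100, 200, 300, 300), c(100, 200, 300, 300)))
  ser3 <- tgi_series(t3, c3)
  opt3 <- optimal_tgi(t3, c3)
  expect_true(all(opt3$tgi_percent >= ser3$tgi_percent))
  expect_equal(opt3$day, 8)    # 40% first reached at day 8, tied later
  # treated grows faster than control: TGI negative after day 1 and the
  # optimal entry (day 1, TGI 0 by construction) is the series maximum
  t4 <- make_arm("t", list(c(100, 420), c(100, 420)), days)
  c4 <- make_arm("control", list(c(100, 400), c(100, 400)), days)
  ser4 <- tgi_series(t4, c4)
  expect_equal(ser4$tgi_percent[ser4$day == 8], -5)
  opt4 <- optimal_tgi(t4, c4)
  expect_equal(opt4$tgi_percent, max(ser4$tgi_percent))
  expect_false(opt4$meaningful)
  # same comparison on the post-baseline series alone: max of negatives
  t5 <- study_arm("t", lapply(t4$curves, function(g)
    growth_curve(g$mouse_id, c(1, 8, 15), c(100, 420, 1000), arm_label = "t")))
  c5 <- study_arm("control", lapply(c4$curves, function(g)
    growth_curve(g$mouse_id, c(1, 8, 15), c(100, 400, 880), arm_label = "control")))
  ser5 <- tgi_series(t5, c5)
  post <- ser5[ser5$day > 1, ]
  expect_true(all(post$tgi_percent < 0))
  expect_equal(max(post$tgi_percent), post$tgi_percent[1])  # least negative
  expect_error(tgi_series(make_arm("t", list(c(100, 150))), c4),
               class = "pdx_not_evaluable")  # min_n = 2 unmet
})

test_that("RTVV/ORR classification applies the strict -0.5 cut-off", {
  days <- c(1, 8)
  control <- make_arm("control", list(c(100, 400), c(100, 400), c(100, 400)), days)
  # mouse RTV 1.2 vs control median 4 -> rtvv 0.3, orr -0.7, responder
  m <- make_curve(c(100, 120), days, id = "t1", arm = "t")
  rec <- classify_response(m, control, 8)
  expect_equal(rec$rtvv, 0.3)
  expect_equal(rec$orr, -0.7)
  expect_true(rec$responder)
  expect_identical(rec$orr, rec$rtvv - 1)
  # mouse RTV equal to control median -> orr 0, non-responder
  rec2 <- classify_response(make_curve(c(100, 400), days, id = "t2", arm = "t"),
                            control, 8)
  expect_equal(rec2$orr, 0)
  expect_false(rec2$responder)
  # exact boundary rtvv = 0.5 -> orr = -0.5 -> NON-responder (strict <)
  rec3 <- classify_response(make_curve(c(100, 200), days, id = "t3", arm = "t"),
                            control, 8)
  expect_equal(rec3$orr, -0.5)
  expect_false(rec3$responder)
  # just inside: rtvv = 0.499 -> responder
  rec4 <- classify_response(make_curve(c(1000, 1996), days, id = "t4", arm = "t"),
                            control, 8)
  expect_equal(rec4$rtvv, 0.499)
  expect_true(rec4$responder)
  # monotonicity: lowering a responder's RTV keeps it a responder
  for (v in c(110, 80, 50, 20, 1)) {
    r <- classify_response(make_curve(c(100, v), days, id = "t", arm = "t"),
                           control, 8)
    expect_true(r$responder)
  }
  # mouse sacrificed before the evaluation day carries its last RTV, flagged
  early <- make_curve(c(100, 120), days, id = "t5", arm = "t",
                      status = "sacrificed")
  control3 <- make_arm("control",
                       list(c(100, 400, 800), c(100, 400, 800), c(100, 400, 800)))
  rec5 <- classify_response(early, control3, 15)
  expect_true(rec5$carried_forward)
  expect_equal(rec5$rtvv, 1.2 / 8)
})

test_that("ORR table counts responders and rounds percentages half-up", {
  days <- c(1, 8)
  control <- make_arm("control", list(c(100, 400), c(100, 400), c(100, 400)), days)
  # 3 responders of 16 -> 18.8% (half-up of 18.75)
  vols <- c(rep(120, 3), rep(390, 13))   # rtvv: 0.3 (x3), 0.975 (x13)
  arm16 <- make_arm("t", lapply(vols, function(v) c(100, v)), days)
  tab <- orr_table(list(arm16), control)
  expect_equal(tab$responders, 3)
  expect_equal(tab$n, 16)
  expect_equal(tab$responder_pct, 18.8)
  # 0 of 5 and 5 of 5
  none <- make_arm("n0", lapply(rep(390, 5), function(v) c(100, v)), days)
  all5 <- make_arm("n5", lapply(rep(110, 5), function(v) c(100, v)), days)
  tab2 <- orr_table(list(none, all5), control)
  expect_equal(tab2$responder_pct, c(0, 100))
  expect_equal(tab2$responders + tab2$non_responders, tab2$n)
  # 2x2 extraction is consistent with the counts
  m <- orr_matrix(tab2, "n0", "n5")
  expect_equal(unname(m), rbind(c(0L, 5L), c(5L, 0L)))
  expect_error(orr_table(list(), control), class = "pdx_validation_error")
})

test_that("orr = rtvv - 1 holds exactly across random studies", {
  study <- simulate_study(sim_config(seed = 11),
                          effects = c(control = 0, a = 0.3, b = 0.7))
  tab <- orr_table(study$arms[c("a", "b")], study$arms$control)
  resp <- attr(tab, "responses")
  expect_identical(resp$orr, resp$rtvv - 1)
  expect_identical(resp$responder, resp$orr < -0.5)
})
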