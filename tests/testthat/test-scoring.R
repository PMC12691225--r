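sc <- bundled_scale()

test_that("worked example: 16 of adjusted maximum 42 scores 38.1%", {
  r <- score_assessment(sixteen_of_42(sc), sc)
  expect_equal(r$total_points, 16)
  expect_equal(r$adjusted_max, 42)
  expect_equal(r$percent, 38.1)
  expect_equal(r$classification, "minimal-to-none")
})

test_that("zero and saturation cases score 0% and 100%", {
  it <- scale_items(sc)
  zero <- assessment("m", "2026-01-01 08:00",
                     points = setNames(rep(0, nrow(it)), it$item_id))
  rz <- score_assessment(zero, sc)
  expect_equal(rz$total_points, 0)
  expect_equal(rz$adjusted_max, 47)
  expect_equal(rz$percent, 0)

  maxed <- assessment("m", "2026-01-01 20:00",
                      points = setNames(it$max_points, it$item_id))
  rm_ <- score_assessment(maxed, sc)
  expect_equal(rm_$total_points, 47)
  expect_equal(rm_$percent, 100)
  expect_equal(rm_$classification, "analgesia-indicated")
})

test_that("percent rounding is half-up to one decimal", {
  expect_equal(round_half_up(100 * 16 / 42, 1), 38.1)  # 38.095...
  expect_equal(round_half_up(38.05, 1), 38.1)
  expect_equal(round_half_up(38.04, 1), 38.0)
  expect_equal(round_half_up(0.25, 1), 0.3)
})

test_that("classification threshold is strict above 40 by default", {
  expect_equal(classify(47), "analgesia-indicated")
  expect_equal(classify(28), "minimal-to-none")
  expect_equal(classify(40), "minimal-to-none")
  expect_equal(classify(40, boundary_policy = "treat"), "analgesia-indicated")
  expect_equal(classify(40.1), "analgesia-indicated")
  expect_error(classify(101), class = "score_validation_error")
  expect_error(classify(-1), class = "score_validation_error")
})

test_that("invalid responses are rejected", {
  expect_error(
    score_assessment(assessment("m", "2026-01-01 08:00",
                                points = c(tail_position = 3),
                                scale = sc, fill_zero = TRUE), sc),
    "tail_position", class = "assessment_validation_error")
  expect_error(
    score_assessment(assessment("m", "2026-01-01 08:00",
                                points = c(posture_weight = 1)), sc),
    class = "assessment_validation_error")  # missing items
  expect_error(
    assessment("m", "2026-01-01 08:00",
               points = c(posture_weight = 1, posture_weight = 2)),
    class = "assessment_validation_error")
  it <- scale_items(sc)
  expect_error(
    score_assessment(assessment("m", "2026-01-01 08:00",
                                skipped = it$item_id), sc),
    class = "degenerate_scale_error")
})

test_that("engine totals match an independent re-summation on random forms", {
  set.seed(42)
  for (i in 1:200) {
    rnd <- random_assessment(sc)
    r <- score_assessment(rnd$assessment, sc)
    expect_equal(r$total_points, sum(rnd$points))
    expect_equal(r$adjusted_max, scale_maximum(sc, rnd$skipped))
    expect_equal(r$percent,
                 round_half_up(100 * sum(rnd$points) / r$adjusted_max, 1))
    expect_equal(sum(r$per_part$points), r$total_points)
  }
})

test_that("exhaustive enumeration on the toy instrument matches brute force", {
  toy <- toy_scale()
  it <- scale_items(toy)
  grids <- expand.grid(it$allowed_points, stringsAsFactors = FALSE)
  for (row in seq_len(nrow(grids))) {
    pts <- setNames(as.numeric(grids[row, ]), it$item_id)
    r <- score_assessment(assessment("m", "2026-01-01 08:00", points = pts),
                          toy)
    expect_equal(r$total_points, sum(pts))
    expect_equal(r$adjusted_max, toy$total_max)
    expect_equal(r$percent, round_half_up(100 * sum(pts) / toy$total_max, 1))
  }
})

test_that("skipping more items never raises the adjusted maximum", {
  set.seed(7)
  it <- scale_items(sc)
  for (i in 1:25) {
    rnd <- random_assessment(sc, skip_prob = 0.2)
    r1 <- score_assessment(rnd$assessment, sc)
    # demote one scored zero-point item to skipped
    zeros <- names(rnd$points)[rnd$points == 0]
    if (!length(zeros)) next
    pts2 <- rnd$points[names(rnd$points) != zeros[1]]
    a2 <- assessment("m", "2026-01-01 08:00", points = pts2,
                     skipped = c(rnd$skipped, zeros[1]))
    r2 <- score_assessment(a2, sc)
    expect_lte(r2$adjusted_max, r1$adjusted_max)
    expect_gte(r2$percent, r1$percent)  # same total over a smaller maximum
  }
})

test_that("trajectories order by time and flag escalation", {
  it <- scale_items(sc)
  form_for <- function(percent, time) {
    # integer-point approximation: percent of 47 rounded to nearest half
    pts <- allocate <- marepain:::allocate_points(percent, sc)
    assessment("tr_mare", time, points = pts)
  }
  a1 <- form_for(12, "2026-01-01 08:00")
  a2 <- form_for(15, "2026-01-01 20:00")
  a3 <- form_for(47, "2026-01-02 08:00")
  tr <- build_trajectory(list(a3, a1, a2), sc)
  expect_true(tr$escalation_flag)
  expect_equal(nrow(tr$scores), 3L)
  expect_true(!is.unsorted(tr$scores$timestamp))
  expect_equal(tr$scores$delta[-1], diff(tr$scores$percent))

  d1 <- form_for(9, "2026-01-01 08:00")
  d2 <- form_for(8, "2026-01-01 20:00")
  expect_false(build_trajectory(list(d1, d2), sc)$escalation_flag)

  # order invariance
  set.seed(3)
  for (perm in 1:5) {
    shuffled <- sample(list(a1, a2, a3))
    expect_equal(build_trajectory(shuffled, sc), tr)
  }
  expect_error(build_trajectory(list(a1, a1), sc),
               class = "trajectory_validation_error")
  other <- assessment("other", "2026-01-03 08:00",
                      points = setNames(rep(0, nrow(it)), it$item_id))
  expect_error(build_trajectory(list(a1, other), sc),
               class = "trajectory_validation_error")
})
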