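straight_track <- function(step_um = 2, n = 13, interval = 15) {
  cell_track(1L, 0:(n - 1L), step_um * (0:(n - 1L)), rep(0, n),
             frame_interval_min = interval)
}

test_that("net displacement is the Euclidean distance between frames", {
  tr <- cell_track(1L, 0:2, c(0, 3, 10), c(0, 4, 10), frame_interval_min = 15)
  expect_equal(net_displacement(tr, 0, 1), 5)          # 3-4-5 triangle
  expect_equal(net_displacement(tr, 1, 1), 0)
  tr2 <- cell_track(1L, 0:2, c(0, 10, 10), c(0, 0, 10), frame_interval_min = 15)
  expect_equal(net_displacement(tr2, 0, 2), sqrt(200))
  expect_error(net_displacement(tr, 0, 7), "not in the trajectory")
})

test_that("annotation crosses at the first strict threshold exceedance", {
  # straight +x at 2 um per 15-min step: net 20 um at step 10
  a <- annotate_direction(straight_track(), 0)
  expect_equal(a$label, 0L)
  expect_equal(a$label_name, "upper_right")
  expect_equal(a$delta_t_min, 150)
  expect_equal(a$net_um, 20)

  # rule (ii): dx < 0, dy <= 0 is upper left
  tr <- cell_track(1L, 0:1, c(0, -5), c(0, -20), frame_interval_min = 15)
  expect_equal(annotate_direction(tr, 0)$label, 1L)

  # net exactly 18 um (scaled 3-4-5) is NOT a crossing; the scan continues
  tr <- cell_track(1L, 0:2, c(0, 10.8, 30), c(0, 14.4, 0),
                   frame_interval_min = 15)
  a <- annotate_direction(tr, 0)
  expect_equal(net_displacement(tr, 0, 1), 18)
  expect_equal(a$delta_t_min, 30)
  expect_equal(a$dx_um, 30)

  # a stationary cell never crosses and is excluded
  tr <- cell_track(1L, 0:9, rep(1, 10), rep(1, 10), frame_interval_min = 15)
  expect_null(annotate_direction(tr, 0))
})

test_that("quadrant rule partitions displacements with the y-down convention", {
  expect_equal(quadrant_label(3, -4), 0L)
  expect_equal(quadrant_label(-1, 0), 1L)   # dy = 0 counts as upper
  expect_equal(quadrant_label(-1, 2), 2L)
  expect_equal(quadrant_label(0, 1), 3L)    # dx = 0 counts as right
  expect_equal(direction_name(0:3),
               c("upper_right", "upper_left", "lower_left", "lower_right"))
})

test_that("resampling keeps every (eval/acquisition)-th point from the first", {
  tr3 <- cell_track(1L, 0:14, 0:14, rep(0, 15), frame_interval_min = 3)
  r <- resample_interval(tr3, 15)
  expect_equal(length(r), 3L)                  # every 5th of 15 points
  expect_equal(r$x_um, c(0, 5, 10))
  expect_equal(r$frame_interval_min, 15)

  tr15 <- straight_track(interval = 15)
  r15 <- resample_interval(tr15, 15)
  expect_equal(r15$x_um, tr15$x_um)            # identity

  tr5 <- cell_track(1L, 0:11, 0:11, rep(0, 12), frame_interval_min = 5)
  expect_equal(resample_interval(tr5, 15)$x_um, c(0, 3, 6, 9))  # every 3rd

  expect_error(resample_interval(tr5, 7), "integer multiple")
})

test_that("motility statistics follow v = sum(dd)/dt and k = dr/sum(dd)", {
  tr <- straight_track()
  expect_equal(average_speed(tr, 0), 20 / 150)
  expect_equal(directionality(tr, 0), 1)

  one <- cell_track(1L, 0:1, c(0, 20), c(0, 0), frame_interval_min = 15)
  expect_equal(average_speed(one, 0), 4 / 3)

  # zig-zag (10,0) then (0,10): crossing at the second step for a 12-um
  # threshold; v = 20/30, k = sqrt(200)/20
  zig <- cell_track(1L, 0:2, c(0, 10, 10), c(0, 0, 10), frame_interval_min = 15)
  expect_equal(average_speed(zig, 0, diameter_um = 12), 20 / 30)
  expect_equal(directionality(zig, 0, diameter_um = 12), sqrt(200) / 20)

  stat <- cell_track(1L, 0:3, rep(0, 4), rep(0, 4), frame_interval_min = 15)
  expect_error(average_speed(stat, 0), "excluded")
})

test_that("annotation agrees with the brute-force prefix-scan oracle", {
  set.seed(101)
  n_match <- 0L
  for (i in 1:200) {
    interval <- sample(c(3, 5, 15), 1)
    tr <- random_track(n_points = sample(6:40, 1),
                       frame_interval_min = interval,
                       step_scale = runif(1, 0.5, 4) * interval / 3)
    a <- annotate_direction(tr, 0, eval_interval_min = 15)
    o <- oracle_annotate(tr, 0, eval_interval_min = 15)
    if (is.null(a) && is.null(o)) { n_match <- n_match + 1L; next }
    expect_false(is.null(a) || is.null(o))
    expect_equal(a$label, o$label)
    expect_equal(a$delta_t_min, o$delta_t_min)
    expect_equal(c(a$dx_um, a$dy_um), c(o$dx, o$dy))
    n_match <- n_match + 1L
  }
  expect_equal(n_match, 200L)
})

test_that("labels are equivariant under reflections and rotation", {
  set.seed(77)
  maps <- list(hflip = c(1L, 0L, 3L, 2L), vflip = c(3L, 2L, 1L, 0L),
               rot180 = c(2L, 3L, 0L, 1L))
  n_checked <- 0L
  for (i in 1:60) {
    tr <- random_track(n_points = 15, step_scale = 8)
    a <- annotate_direction(tr, 0)
    if (is.null(a)) next
    for (tf in names(maps)) {
      at <- annotate_direction(transform_track(tr, tf), 0)
      expect_equal(at$label, maps[[tf]][a$label + 1L],
                   info = sprintf("transform %s, case %d", tf, i))
    }
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 30)
})

test_that("directionality never exceeds 1 and is 1 only for straight paths", {
  set.seed(5)
  for (i in 1:50) {
    tr <- random_track(n_points = 12, step_scale = 10)
    a <- annotate_direction(tr, 0)
    if (is.null(a)) next
    k <- directionality(tr, 0)
    expect_lte(k, 1 + 1e-12)
    expect_gt(k, 0)
  }
})

test_that("trajectory validation rejects malformed inputs", {
  expect_error(cell_track(1, c(0, 0, 1), 1:3, 1:3, 15), "strictly increasing")
  expect_error(cell_track(1, 0:1, 1:2, 1:2, -5), "positive")
  expect_error(annotate_direction(straight_track(), 99), "not in the trajectory")
})
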