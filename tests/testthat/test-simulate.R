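small_cfg <- function(...) {
  sim_config(n_cells = 4, n_frames = 5, image_size_px = 256, seed = 11, ...)
}

test_that("identical config and seed give bit-identical movie and tracks", {
  a <- generate_dataset(small_cfg())
  b <- generate_dataset(small_cfg())
  expect_identical(a$movie, b$movie)
  expect_identical(a$tracks, b$tracks)
  # and a different seed gives a different movie
  c <- generate_dataset(sim_config(n_cells = 4, n_frames = 5,
                                   image_size_px = 256, seed = 12))
  expect_false(identical(a$movie, c$movie))
})

test_that("a zero-speed cell stays put and is excluded downstream", {
  cfg <- sim_config(n_cells = 1, n_frames = 8, image_size_px = 256,
                    speed_mean = 0, speed_sd = 0, seed = 3)
  tr <- simulate_trajectory(cfg, cell_seed = 42)
  expect_equal(diff(range(tr$x_um)), 0)
  expect_equal(diff(range(tr$y_um)), 0)
  expect_null(annotate_direction(tr, 0))
})

test_that("a near-deterministic heading gives a straight path with k = 1", {
  cfg <- sim_config(n_cells = 1, n_frames = 12, image_size_px = 2048,
                    heading_concentration = 1e6, speed_sd = 0, seed = 5)
  tr <- simulate_trajectory(cfg, cell_seed = 8)
  expect_equal(directionality(tr, 0), 1, tolerance = 1e-6)
  # and the empirical speed recovers the configured speed
  expect_equal(average_speed(tr, 0), cfg$speed_mean, tolerance = 0.02)
})

test_that("kappa = 0 gives uniformly distributed turning angles", {
  cfg <- sim_config(n_cells = 1, n_frames = 10001, image_size_px = 4096,
                    heading_concentration = 0, speed_mean = 0.2,
                    speed_sd = 0, seed = 1)
  tr <- simulate_trajectory(cfg, cell_seed = 123)
  turn <- atan2(sin(diff(tr$headings)), cos(diff(tr$headings)))
  ks <- suppressWarnings(stats::ks.test(turn, "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("an empty scene is pure background with the configured noise", {
  cfg <- small_cfg(noise_sd = 0.015)
  set.seed(1)
  fr <- render_frame(data.frame(x_um = numeric(0), y_um = numeric(0),
                                heading = numeric(0)), cfg)
  expect_equal(mean(fr), 0.5, tolerance = 0.01)
  expect_lt(abs(stats::sd(fr) - 0.015), 0.002)
  # noiseless rendering is deterministic
  f1 <- render_frame(data.frame(x_um = 80, y_um = 80, heading = 1), cfg,
                     noise = FALSE)
  f2 <- render_frame(data.frame(x_um = 80, y_um = 80, heading = 1), cfg,
                     noise = FALSE)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0 & f1 <= 1))
})

test_that("the rendered cell is asymmetric along its heading", {
  cfg <- sim_config(n_cells = 1, n_frames = 2, image_size_px = 200, seed = 2)
  set.seed(42)
  ahead <- numeric(50); behind <- numeric(50)
  px <- cfg$pixel_size_um
  for (i in 1:50) {
    cx <- runif(1, 60, 70); cy <- runif(1, 60, 70)
    fr <- render_frame(data.frame(x_um = cx, y_um = cy, heading = 0), cfg)
    cc <- round(cx / px) + 1L
    win <- 35L   # half-plane strips around the centroid
    cols_ahead <- (cc + 1):(cc + win)
    cols_behind <- (cc - win):(cc - 1)
    rows <- (round(cy / px) + 1L - win):(round(cy / px) + 1L + win)
    ahead[i] <- mean(fr[rows, cols_ahead])
    behind[i] <- mean(fr[rows, cols_behind])
  }
  expect_lt(stats::t.test(ahead, behind, paired = TRUE)$p.value, 0.01)
})

test_that("generated labels are near-balanced for isotropic initial headings", {
  cfg <- sim_config(seed = 4)   # 200 cells
  set.seed(cfg$seed)
  trajs <- lapply(1:cfg$n_cells, function(i)
    simulate_trajectory(cfg, cell_seed = NULL, cell_id = i))
  ann <- do.call(rbind, lapply(trajs, function(tr) annotate_all(tr)))
  frac <- as.vector(table(factor(ann$label, levels = 0:3))) / nrow(ann)
  expect_true(all(frac >= 0.15 & frac <= 0.35))
})

test_that("one step beyond the diameter annotates at a single interval", {
  # two-frame movies: a cell is annotated exactly when its one realized
  # step (reflecting walls can shorten it) exceeds the 18-um diameter,
  # and then always at delta_t of one interval
  cfg <- sim_config(n_cells = 30, n_frames = 2, image_size_px = 512,
                    speed_mean = 2, speed_sd = 0, seed = 9)
  set.seed(cfg$seed)
  n_annotated <- 0L
  for (i in 1:cfg$n_cells) {
    tr <- simulate_trajectory(cfg, cell_seed = NULL, cell_id = i)
    a <- annotate_direction(tr, 0)
    if (net_displacement(tr, 0, 1) > 18) {
      expect_equal(a$delta_t_min, cfg$frame_interval_min)
      o <- oracle_annotate(tr, 0)
      expect_equal(a$label, o$label)
      n_annotated <- n_annotated + 1L
    } else {
      expect_null(a)
    }
  }
  # the 30-um step dwarfs the threshold, so annotation is the rule
  expect_gt(n_annotated, 25)
})

test_that("morphology at a frame points along the next displacement", {
  cfg <- sim_config(n_cells = 1, n_frames = 10, image_size_px = 1024, seed = 6)
  tr <- simulate_trajectory(cfg, cell_seed = 31)
  dx <- diff(tr$x_um); dy <- diff(tr$y_um)
  moved <- sqrt(dx^2 + dy^2) > 1e-9
  expect_equal(tr$headings[c(moved, FALSE)],
               atan2(dy[moved], dx[moved]))
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_trajectory(sim_config(n_frames = 1)), "n_frames")
  expect_error(sim_config(heading_concentration = -1), ">= 0")
  expect_error(sim_config(body_radius_um = 0), "positive")
  expect_error(sim_config(noise_sd = -0.1), "non-negative")
})

test_that("movie and tracks round-trip through TIFF and CSV", {
  ds <- generate_dataset(small_cfg())
  dir <- withr::local_tempdir()
  write_movie_tiff(ds$movie, file.path(dir, "movie.tif"))
  write_tracks(ds$tracks, file.path(dir, "tracks.csv"),
               pixel_size_um = ds$config$pixel_size_um,
               frame_interval_min = ds$config$frame_interval_min)
  movie2 <- read_movie_tiff(file.path(dir, "movie.tif"))
  expect_equal(dim(movie2), dim(ds$movie))
  expect_lt(max(abs(movie2 - ds$movie)), 1e-6)   # 32-bit float round-trip
  rt <- read_tracks(file.path(dir, "tracks.csv"))
  expect_equal(rt$frame_interval_min, 15)
  trajs <- tracks_to_trajectories(rt$tracks, rt$pixel_size_um,
                                  rt$frame_interval_min)
  expect_equal(length(trajs), 4L)
  expect_equal(trajs[[1]]$x_um, ds$trajectories[[1]]$x_um, tolerance = 1e-6)
})
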