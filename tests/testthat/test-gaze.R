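# build a minimal synthetic gaze stream with an identity-orientation
# head looking down at the plane z = 0 from (x, y, h)
down_stream <- function(targets, t, head = c(5, 5, 2)) {
  q <- c(1, 0, 0, 0)   # camera +z points along world +z: use -z gaze
  n <- length(t)
  out <- data.frame(t = t, hx = head[1], hy = head[2], hz = head[3],
                    qw = NA, qx = NA, qy = NA, qz = NA,
                    gx = NA, gy = NA, gz = NA, valid = TRUE)
  # orient the camera straight down: +z world -> camera frame via
  # a 180-degree rotation about x (so camera +z = world -z)
  qd <- c(0, 1, 0, 0)
  for (i in seq_len(n)) {
    wd <- c(targets[i, 1] - head[1], targets[i, 2] - head[2], -head[3])
    wd <- wd / sqrt(sum(wd^2))
    gd <- as.numeric(ipguidance:::quat_rotate(c(qd[1], -qd[2:4]), wd))
    out[i, c("qw", "qx", "qy", "qz")] <- qd
    out[i, c("gx", "gy", "gz")] <- gd
  }
  out
}

test_that("gaze rays register onto the flight plane and back", {
  expect_equal(gaze_to_world(c(0, 0, 2), c(1, 0, 0, 0), c(0, 0, -1), 0),
               c(0, 0, 0))
  # round trip over random poses
  set.seed(13)
  for (i in 1:30) {
    head <- c(runif(1, 0, 10), runif(1, -4, 0), runif(1, 1, 3))
    q <- ipguidance:::cam_quat(runif(1, -pi, pi), runif(1, 0.15, 1.2))
    w <- c(runif(1, 0, 10), runif(1, 0, 8), 0)
    wd <- (w - head); wd <- wd / sqrt(sum(wd^2))
    gd <- as.numeric(ipguidance:::quat_rotate(c(q[1], -q[2:4]), wd))
    back <- gaze_to_world(head, q, gd, 0)
    expect_lt(sqrt(sum((back - w)^2)), 1e-9)
  }
  # parallel ray misses
  expect_null(gaze_to_world(c(0, 0, 2), c(1, 0, 0, 0), c(1, 0, 0), 0))
  # ray pointing away misses
  expect_null(gaze_to_world(c(0, 0, 2), c(1, 0, 0, 0), c(0, 0, 1), 0))
})

test_that("pinhole projection maps axis and field edges correctly", {
  cam <- camera_intrinsics()   # 1280 x 960, 60 x 46 deg
  expect_equal(project_to_image(c(0, 0, 5), c(0, 0, 0), c(1, 0, 0, 0), cam),
               c(u = 640, v = 480))
  # horizontal half-field point lands on the image border
  edge <- project_to_image(c(tan(30 * pi / 180) * 5, 0, 5),
                           c(0, 0, 0), c(1, 0, 0, 0), cam)
  expect_lt(abs(edge[["u"]] - 1280), 1)
  # behind the camera
  expect_null(project_to_image(c(0, 0, -5), c(0, 0, 0), c(1, 0, 0, 0), cam))
  expect_error(project_to_image(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0, 0), cam),
               "center")
})

test_that("stationary gaze yields a fixation; a fast burst a saccade", {
  # 300 ms rest, a ~400 deg/s 50 ms sweep, 300 ms rest
  t <- seq(0, 0.65, by = 1 / 120)
  n <- length(t)
  tg <- matrix(NA, n, 2)
  a <- c(3, 5); b <- c(7, 5)     # ~21 degrees apart seen from (5,5,2)...
  pre <- t < 0.3
  sac <- t >= 0.3 & t < 0.35
  post <- t >= 0.35
  tg[pre, ] <- rep(a, each = sum(pre))
  u <- (t[sac] - 0.3) / 0.05
  tg[sac, ] <- cbind(a[1] + u * (b[1] - a[1]), a[2] + u * (b[2] - a[2]))
  tg[post, ] <- rep(b, each = sum(post))
  stream <- down_stream(tg, t)
  ev <- classify_gaze(stream, helo = NULL, plane_height = 0)
  fx <- ev[ev$kind == "fixation", ]
  expect_identical(nrow(fx), 2L)        # 300 ms is a valid fixation span
  sc <- ev[ev$kind == "saccade", ]
  expect_identical(nrow(sc), 1L)        # one admissible-velocity saccade
  expect_true(all(sc$t_end - sc$t_start >= 0.02))
  expect_true(all(sc$peak_speed > 150))
})

test_that("event spans tile the stream without overlap", {
  run <- fix_gaze_run()
  gz <- make_gaze(run, run$plan, seed = 4)
  ev <- classify_gaze(gz$stream, run, plane_height = 0)
  ev <- ev[order(ev$t_start), ]
  expect_true(all(abs(ev$t_start[-1] - ev$t_end[-nrow(ev)]) < 1e-9))
  expect_lt(ev$t_start[1], min(gz$stream$t) + 0.02)
  expect_gt(ev$t_end[nrow(ev)], max(gz$stream$t) - 0.02)
})

test_that("raising the saccade threshold never increases saccade count", {
  run <- fix_gaze_run()
  gz <- make_gaze(run, run$plan, seed = 6)
  counts <- vapply(c(100, 150, 250, 400), function(th) {
    ev <- classify_gaze(gz$stream, run, plane_height = 0,
                        saccade_speed = th)
    sum(ev$kind == "saccade")
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("classifier recovers planted schedules near-perfectly", {
  run <- fix_gaze_run()
  prec <- rec <- numeric(0)
  for (seed in 1:8) {
    gz <- make_gaze(run, run$plan, seed = seed)
    ev <- classify_gaze(gz$stream, run, plane_height = 0)
    det <- ev[ev$kind %in% c("fixation", "saccade", "smooth_pursuit"), ]
    rec <- c(rec, match_events(gz$events, det) / nrow(gz$events))
    prec <- c(prec, match_events(det, gz$events) / nrow(det))
  }
  expect_gte(min(rec), 0.95)
  expect_gte(min(prec), 0.95)
})

test_that("blink gaps split events and are excluded", {
  run <- fix_gaze_run()
  gz <- make_gaze(run, run$plan, seed = 2)
  s <- gz$stream
  blink <- s$t > 3 & s$t < 3.2
  s$valid[blink] <- FALSE
  ev <- classify_gaze(s, run, plane_height = 0)
  inv <- ev[ev$kind == "invalid", ]
  expect_gte(nrow(inv), 1)
  # no classified event spans the blink
  cl <- ev[ev$kind %in% c("fixation", "saccade", "smooth_pursuit"), ]
  expect_false(any(cl$t_start < 3.05 & cl$t_end > 3.15))
})

test_that("density maps conserve mass and peak at planted targets", {
  run <- fix_gaze_run()
  env <- fixture_world()
  gz <- make_gaze(run, run$plan, seed = 3)
  ev <- classify_gaze(gz$stream, run, plane_height = 0)
  dens_f <- gaze_density(ev, "fixation", env$bounds, resolution = 0.4)
  expect_equal(sum(dens_f$density), 1, tolerance = 1e-12)
  # fixation mass concentrates at planted subgoal targets
  peak <- which(dens_f$density == max(dens_f$density), arr.ind = TRUE)[1, ]
  pk <- c(dens_f$xs[peak[1]], dens_f$ys[peak[2]])
  targets <- run$plan$subgoals
  expect_lt(min(sqrt((targets[, 1] - pk[1])^2 + (targets[, 2] - pk[2])^2)),
            0.6)
  # pursuit mass lies along the vehicle path
  dens_p <- gaze_density(ev, "smooth_pursuit", env$bounds, resolution = 0.4)
  pk2 <- which(dens_p$density == max(dens_p$density), arr.ind = TRUE)[1, ]
  p2 <- c(dens_p$xs[pk2[1]], dens_p$ys[pk2[2]])
  s <- run$samples
  expect_lt(min(sqrt((s$s_x - p2[1])^2 + (s$s_y - p2[2])^2)), 0.6)
})

test_that("attention metrics capture the predicted gaze pattern", {
  run <- fix_gaze_run()
  gz <- make_gaze(run, run$plan, seed = 1)
  ev <- classify_gaze(gz$stream, run, plane_height = 0)
  rep <- attention_metrics(ev, run, run$plan)
  expect_gte(rep$pursuit_fraction, 0.8)
  expect_gte(rep$pursuit_vehicle_coincidence, 0.8)
  expect_equal(rep$fixation_subgoal_overlap, 1)
  n_planted <- sum(gz$events$kind == "saccade" & !is.na(gz$events$target_x))
  expect_identical(rep$anticipatory_saccade_count, as.integer(n_planted))
  expect_true(all(rep$lead_times > 0))
})

test_that("an all-pursuit stream scores pursuit fraction one", {
  run <- fix_gaze_run()
  # pursuit-only schedule: no anticipation lead
  s <- run$samples
  t <- seq(s$t[1], s$t[nrow(s)], by = 1 / 60)
  tg <- cbind(approx(s$t, s$s_x, xout = t)$y, approx(s$t, s$s_y, xout = t)$y)
  stream <- down_stream(tg, t, head = c(6, -2, 3))
  ev <- classify_gaze(stream, run, plane_height = 0)
  rep <- attention_metrics(ev, run, run$plan)
  expect_equal(rep$pursuit_fraction, 1)
  expect_identical(rep$anticipatory_saccade_count, 0L)
})
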