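# Seeded synthetic fixtures: worlds, trajectory ensembles, gaze streams.
#
# The generators emulate the guidance experiment: a set of start points
# (bundles of repeated runs) flying to a fixed goal around rectangular
# obstacles, and an operator gaze stream alternating smooth pursuit of
# the vehicle with anticipatory fixations at upcoming subgoal regions.
# Every generator takes an integer seed and is bitwise reproducible;
# worlds, ensembles, and gaze streams draw from independent sub-seeds so
# each artifact can be regenerated in isolation.

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# derive an independent sub-seed from a root seed and a stream name
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Random rectangular-obstacle world
#'
#' Places `n_obstacles` non-overlapping axis-aligned rectangles by
#' rejection sampling and a goal in free space with clearance from all
#' obstacles.
#'
#' @param seed integer seed.
#' @param n_obstacles number of rectangles.
#' @param bounds workspace `c(xmin, ymin, xmax, ymax)` (m).
#' @param size_range rectangle side-length range (m).
#' @param margin minimum separation between obstacles and to the goal (m).
#' @param max_tries rejection-sampling budget.
#' @return A [guidance_env()].
#' @export
make_world <- function(seed, n_obstacles = 2L, bounds = c(0, 0, 12, 8),
                       size_range = c(1, 2.5), margin = 0.8,
                       max_tries = 500L) {
  with_seed(sub_seed(seed, "world"), {
    obs <- list()
    tries <- 0L
    while (length(obs) < n_obstacles) {
      tries <- tries + 1L
      if (tries > max_tries) stop("obstacle placement failed")
      w <- stats::runif(1, size_range[1], size_range[2])
      h <- stats::runif(1, size_range[1], size_range[2])
      x0 <- stats::runif(1, bounds[1] + margin, bounds[3] - margin - w)
      y0 <- stats::runif(1, bounds[2] + margin, bounds[4] - margin - h)
      cand <- c(x0, y0, x0 + w, y0 + h)
      clash <- FALSE
      for (o in obs) {
        e <- c(min(o[, 1]), min(o[, 2]), max(o[, 1]), max(o[, 2]))
        if (cand[1] < e[3] + margin && cand[3] > e[1] - margin &&
            cand[2] < e[4] + margin && cand[4] > e[2] - margin) {
          clash <- TRUE; break
        }
      }
      if (!clash)
        obs[[length(obs) + 1L]] <- rect_obstacle(cand[1], cand[2],
                                                 cand[3], cand[4])
    }
    goal <- NULL
    for (i in seq_len(max_tries)) {
      g <- c(stats::runif(1, bounds[1] + margin, bounds[3] - margin),
             stats::runif(1, bounds[2] + margin, bounds[4] - margin))
      ok <- TRUE
      for (o in obs) {
        e <- c(min(o[, 1]), min(o[, 2]), max(o[, 1]), max(o[, 2]))
        if (g[1] > e[1] - margin && g[1] < e[3] + margin &&
            g[2] > e[2] - margin && g[2] < e[4] + margin) {
          ok <- FALSE; break
        }
      }
      if (ok) { goal <- g; break }
    }
    if (is.null(goal)) stop("goal placement failed")
    guidance_env(bounds, obs, goal_spec(goal))
  })
}

#' The standard obstacle-course fixture world
#'
#' A fixed single-wall world patterned after the guidance experiment's
#' task space: a vertical wall obstacle between the start side and the
#' goal, so that occluded starts are funneled around a wall corner while
#' unobstructed starts fly straight in.
#'
#' @return A [guidance_env()].
#' @export
fixture_world <- function() {
  guidance_env(c(0, 0, 12, 8),
               list(rect_obstacle(5.4, 0, 6.2, 5.8)),
               goal_spec(c(10.5, 5), pos_tol = 0.2, speed_tol = 0.12))
}

#' Start bundles for the standard fixture world
#'
#' Four bundles: two occluded by the wall (routed around its top corner
#' from approach courses more than 30 degrees apart) and two with
#' direct line of sight to the goal from well-separated directions.
#'
#' @return 4 x 2 matrix of start positions (m).
#' @export
fixture_starts <- function() {
  rbind(c(0.6, 2.6),
        c(4.6, 3.0),
        c(8.8, 7.2),
        c(8.8, 1.2))
}

#' Simulate a trajectory ensemble with planted ground truth
#'
#' For every start, plans a subgoal sequence with the wavefront planner
#' and simulates repeated runs with seeded per-run perturbations
#' (initial-course jitter plus small actuation jitter, so dynamics
#' invariants still hold on noisy runs). Unreachable starts are skipped
#' with a warning.
#'
#' @param env a [guidance_env()].
#' @param starts n x 2 matrix of start positions.
#' @param seed integer seed.
#' @param reps runs per start.
#' @param params a [guidance_params()].
#' @param ttg a `ttg` for planning; default uniform motion at cruise
#'   speed.
#' @param resolution planner grid resolution (m).
#' @param course_jitter_sd initial-course jitter (rad).
#' @param act_jitter_sd actuation jitter on `a_t`, `a_n` (m/s^2).
#' @param t_max per-run time budget (s).
#' @return list with `trajectories` (list of `trajectory`), `plans`
#'   (per start), `map` (the `ttg_map`), and `labels` (data.frame
#'   `traj, bundle, start_x, start_y`).
#' @export
make_ensemble <- function(env, starts = fixture_starts(), seed = 1L,
                          reps = 3L,
                          params = guidance_params(capture_radius = 0.2),
                          ttg = NULL, resolution = NULL,
                          course_jitter_sd = 0.1, act_jitter_sd = 0.03,
                          t_max = 90) {
  if (is.null(ttg)) ttg <- ttg_uniform(params$cruise_speed)
  map <- propagate_wavefront(env, ttg, resolution = resolution)
  starts <- as.matrix(starts)
  trajs <- list(); labels <- list(); plans <- list()
  with_seed(sub_seed(seed, "ensemble"), {
    for (b in seq_len(nrow(starts))) {
      st <- starts[b, ]
      plan <- tryCatch(subgoal_sequence(map, st), error = function(e) NULL)
      if (is.null(plan)) {
        warning(sprintf("start %d unreachable; skipped", b))
        next
      }
      plans[[length(plans) + 1L]] <- plan
      g0 <- plan$subgoals[1, ]
      course0 <- atan2(g0[2] - st[2], g0[1] - st[1])
      for (r in seq_len(reps)) {
        psi0 <- course0 + stats::rnorm(1, 0, course_jitter_sd)
        noise_t <- stats::rnorm(20000, 0, act_jitter_sd)
        noise_n <- stats::rnorm(20000, 0, act_jitter_sd)
        perturb <- if (act_jitter_sd > 0)
          function(i, u) u + c(noise_t[i], noise_n[i]) else NULL
        tr <- simulate_guidance(env, plan,
                                agent_state(0, st[1], st[2], 0, psi0),
                                params, t_max = t_max, perturb = perturb)
        attr(tr, "id") <- length(trajs) + 1L
        trajs[[length(trajs) + 1L]] <- tr
        labels[[length(labels) + 1L]] <-
          data.frame(traj = length(trajs), bundle = b,
                     start_x = st[1], start_y = st[2],
                     status = tr$status, collided = tr$collided)
      }
    }
  })
  list(trajectories = trajs,
       plans = plans,
       map = map,
       labels = if (length(labels)) do.call(rbind, labels) else
         data.frame(traj = integer(), bundle = integer()))
}

#' Planted ground truth for an ensemble
#'
#' Derives, from the planted plans, the convergence structure that IP
#' extraction should recover. A plan waypoint is a *convergence region*
#' when at least two distinct predecessors (different bundles' starts or
#' different upstream waypoints) lead into it; the goal always is one.
#' Waypoints passed by a single funneled stream (e.g. the second of two
#' consecutive corner waypoints) are not separable by any
#' convergence-based extraction and are folded into their downstream
#' leg. Every trajectory is then segmented at its convergence regions;
#' legs sharing (origin, target) carry the same planted label.
#'
#' @param ens result of [make_ensemble()].
#' @return list with `regions` (data.frame `x, y` of convergence
#'   regions, goal last) and `legs` (data.frame `traj, label, t0, t1`:
#'   planted leg time intervals).
#' @export
planted_truth <- function(ens) {
  key <- function(p) sprintf("%.3f_%.3f", p[1], p[2])
  # predecessor sets per waypoint
  preds <- list()
  pos <- list()
  for (ti in seq_along(ens$trajectories)) {
    tr <- ens$trajectories[[ti]]
    b <- ens$labels$bundle[ens$labels$traj == ti]
    sg <- tr$plan$subgoals
    prev <- sprintf("start%d", b)
    for (k in seq_len(nrow(sg))) {
      id <- key(sg[k, ])
      preds[[id]] <- union(preds[[id]], prev)
      pos[[id]] <- sg[k, ]
      prev <- id
    }
  }
  goal_id <- key(ens$map$env$goal$position)
  kept <- union(names(preds)[vapply(preds, length, 0L) >= 2L], goal_id)
  regions <- do.call(rbind, lapply(kept, function(id) pos[[id]]))
  regions <- data.frame(x = regions[, 1], y = regions[, 2],
                        is_goal = kept == goal_id)
  regions <- rbind(regions[!regions$is_goal, ], regions[regions$is_goal, ])
  # per-trajectory planted legs, cut at kept-region entry times
  legs <- list()
  for (ti in seq_along(ens$trajectories)) {
    tr <- ens$trajectories[[ti]]
    b <- ens$labels$bundle[ens$labels$traj == ti]
    s <- tr$samples
    sg <- tr$plan$subgoals
    ids <- apply(sg, 1, key)
    kept_idx <- which(ids %in% kept)
    prev <- sprintf("start%d", b)
    t_prev <- s$t[1]
    for (k in kept_idx) {
      # entry time: first sample within 0.5 m of the waypoint
      d <- sqrt((s$s_x - sg[k, 1])^2 + (s$s_y - sg[k, 2])^2)
      hit <- which(d <= 0.5 & s$t >= t_prev)
      t_ent <- if (length(hit)) s$t[hit[1]] else s$t[nrow(s)]
      legs[[length(legs) + 1L]] <- data.frame(
        traj = ti, label = paste(prev, ids[k], sep = "->"),
        t0 = t_prev, t1 = t_ent)
      prev <- ids[k]
      t_prev <- t_ent
    }
  }
  list(regions = regions, legs = do.call(rbind, legs))
}

#' Planted label of extracted segments
#'
#' Assigns each extracted candidate member the planted leg (from
#' [planted_truth()]) with the largest time overlap; used to score
#' extraction against ground truth (e.g. with [adjusted_rand()]).
#'
#' @param cands list of `candidate_ip` from [partition_by_subgoal()].
#' @param truth result of [planted_truth()].
#' @return data.frame `candidate, traj, planted` (one row per member).
#' @export
planted_labels_for <- function(cands, truth) {
  out <- list()
  for (ci in seq_along(cands)) {
    mi <- cands[[ci]]$member_index
    for (r in seq_len(nrow(mi))) {
      legs <- truth$legs[truth$legs$traj == mi$traj[r], ]
      ov <- pmax(0, pmin(legs$t1, mi$t_end[r]) - pmax(legs$t0, mi$t_start[r]))
      out[[length(out) + 1L]] <- data.frame(
        candidate = ci, traj = mi$traj[r],
        planted = legs$label[which.max(ov)])
    }
  }
  do.call(rbind, out)
}

#' Uniform-motion playback of a planned route
#'
#' Traverses the subgoal polyline of a plan at exactly constant speed
#' (kinematic playback, no controller): the idealized uniform-motion
#' condition under which the time-to-go of each leg is distance/speed.
#'
#' @param plan a [subgoal_plan()].
#' @param start length-2 start position (m).
#' @param speed constant speed (m/s).
#' @param dt sample interval (s).
#' @return A `trajectory` with constant `v` and piecewise-constant
#'   course.
#' @export
make_uniform_run <- function(plan, start, speed, dt = 0.05) {
  wp <- rbind(start, plan$subgoals)
  segs <- diff(wp)
  lens <- sqrt(rowSums(segs^2))
  courses <- atan2(segs[, 2], segs[, 1])
  t_cum <- c(0, cumsum(lens)) / speed
  t_grid <- seq(0, t_cum[length(t_cum)], by = dt)
  if (t_grid[length(t_grid)] < t_cum[length(t_cum)])
    t_grid <- c(t_grid, t_cum[length(t_cum)])
  leg <- pmin(findInterval(t_grid, t_cum, rightmost.closed = TRUE),
              length(lens))
  u <- (t_grid - t_cum[leg]) / (t_cum[leg + 1L] - t_cum[leg])
  pos <- wp[leg, , drop = FALSE] + segs[leg, , drop = FALSE] * u
  samples <- data.frame(t = t_grid, s_x = pos[, 1], s_y = pos[, 2],
                        v = speed, psi = courses[leg], a_t = 0, a_n = 0,
                        subgoal_idx = as.integer(leg))
  structure(list(samples = samples, status = "success", collided = FALSE,
                 plan = plan, params = NULL), class = "trajectory")
}

#' Scripted gaze stream with planted events
#'
#' Generates the model-predicted attention pattern for one flown
#' trajectory: smooth pursuit of the vehicle, interrupted ahead of each
#' subgoal switch by a saccade to the next subgoal, a fixation there,
#' and a saccade back to the vehicle. Saccade speeds are drawn within
#' 200-600 deg/s and durations within 20-200 ms (50-180 ms in practice;
#' shorter saccades are unresolvable at the sampling rate). Fixation
#' durations are drawn within 150-600 ms. The head yaw tracks the
#' vehicle bearing through a first-order low-pass; angular noise is
#' added to the gaze direction. Anticipation targets with less than
#' 12 deg of angular separation from the vehicle are skipped: durations
#' under 50 ms are unresolvable at the sampling rate, and stretching
#' the duration would push the speed below the saccadic range.
#'
#' @param traj a successful `trajectory`.
#' @param plan its [subgoal_plan()].
#' @param seed integer seed.
#' @param rate sampling rate (Hz).
#' @param head_pos operator head position (m), world frame.
#' @param plane_height flight-plane height (m).
#' @param noise_deg angular gaze noise SD (deg).
#' @param lead anticipation lead time before a subgoal switch (s).
#' @param fix_range fixation duration range (s).
#' @return list with `stream` (gaze sample data.frame: `t, hx, hy, hz,
#'   qw, qx, qy, qz, gx, gy, gz, valid`) and `events` (planted truth:
#'   `kind, t_start, t_end, target_x, target_y`).
#' @export
make_gaze <- function(traj, plan, seed = 1L, rate = 60,
                      head_pos = c(6, -2.5, 1.4), plane_height = 0,
                      noise_deg = 0.5, lead = 1.2,
                      fix_range = c(0.2, 0.5)) {
  stopifnot(traj$status == "success")
  s <- traj$samples
  with_seed(sub_seed(seed, "gaze"), {
    t_grid <- seq(s$t[1], s$t[nrow(s)], by = 1 / rate)
    veh <- cbind(stats::approx(s$t, s$s_x, xout = t_grid, rule = 2)$y,
                 stats::approx(s$t, s$s_y, xout = t_grid, rule = 2)$y)
    # subgoal switch times
    idx <- stats::approx(s$t, s$subgoal_idx, xout = t_grid,
                         method = "constant", rule = 2)$y
    n <- length(t_grid)
    # schedule: target point per sample, plus planted event list
    target <- veh
    kind <- rep("smooth_pursuit", n)
    events <- list()
    switches <- which(diff(s$subgoal_idx) > 0)
    sw_times <- s$t[switches + 1L]
    sw_to <- s$subgoal_idx[switches + 1L]
    dir_to <- function(p3) {
      v <- c(p3[1], p3[2], plane_height) - head_pos
      v / sqrt(sum(v^2))
    }
    ang_between <- function(a, b) acos(min(1, max(-1, sum(a * b))))
    cursor <- 1L
    for (si in seq_along(sw_times)) {
      g_next <- plan$subgoals[sw_to[si], ]
      t_anchor <- sw_times[si] - lead
      if (t_anchor <= t_grid[cursor] + 0.2) next
      i0 <- findInterval(t_anchor, t_grid)
      d_veh <- dir_to(veh[i0, ])
      d_sg <- dir_to(g_next)
      ang <- ang_between(d_veh, d_sg) * 180 / pi
      # below ~12 deg no admissible saccade exists: durations under
      # 50 ms are unresolvable at the sampling rate, and stretching the
      # duration would push the speed below the saccadic range
      if (ang < 12) next
      spd <- stats::runif(1, 220, 450)
      dur <- min(0.18, max(0.05, ang / spd))
      fix_dur <- stats::runif(1, fix_range[1], fix_range[2])
      t_sac1 <- c(t_grid[i0], t_grid[i0] + dur)
      t_fix <- c(t_sac1[2], t_sac1[2] + fix_dur)
      t_sac2 <- c(t_fix[2], t_fix[2] + dur)
      if (t_sac2[2] >= t_grid[n]) next
      in_sac1 <- t_grid >= t_sac1[1] & t_grid < t_sac1[2]
      in_fix <- t_grid >= t_fix[1] & t_grid < t_fix[2]
      in_sac2 <- t_grid >= t_sac2[1] & t_grid < t_sac2[2]
      if (!any(in_fix)) next
      # great-circle interpolation during saccades
      slerp <- function(a, b, u) {
        th <- ang_between(a, b)
        if (th < 1e-9) return(matrix(rep(a, length(u)), ncol = 3,
                                     byrow = TRUE))
        (outer(sin((1 - u) * th), a) + outer(sin(u * th), b)) / sin(th)
      }
      fix_pt <- c(g_next[1], g_next[2])
      target[in_fix, 1] <- fix_pt[1]
      target[in_fix, 2] <- fix_pt[2]
      kind[in_fix] <- "fixation"
      kind[in_sac1] <- "saccade"
      kind[in_sac2] <- "saccade"
      events[[length(events) + 1L]] <- data.frame(
        kind = c("saccade", "fixation", "saccade"),
        t_start = c(t_sac1[1], t_fix[1], t_sac2[1]),
        t_end = c(t_sac1[2], t_fix[2], t_sac2[2]),
        target_x = c(fix_pt[1], fix_pt[1], NA),
        target_y = c(fix_pt[2], fix_pt[2], NA),
        switch_time = sw_times[si])
      # mark saccade in-flight directions by slerp below
      for (ii in which(in_sac1)) {
        u <- (t_grid[ii] - t_sac1[1]) / dur
        d <- slerp(dir_to(veh[i0, ]), dir_to(fix_pt), u)
        target[ii, ] <- ray_plane(head_pos, d, plane_height)
      }
      i_back <- which(in_sac2)
      for (ii in i_back) {
        u <- (t_grid[ii] - t_sac2[1]) / dur
        d <- slerp(dir_to(fix_pt), dir_to(veh[min(n, max(i_back) + 1L), ]),
                   u)
        target[ii, ] <- ray_plane(head_pos, d, plane_height)
      }
      kind[in_sac1 | in_sac2] <- "saccade"
      cursor <- min(n, findInterval(t_sac2[2], t_grid) + 1L)
    }
    # pursuit runs between scheduled events
    r <- rle(kind)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] != "smooth_pursuit") next
      events[[length(events) + 1L]] <- data.frame(
        kind = "smooth_pursuit",
        t_start = t_grid[starts[k]], t_end = t_grid[ends[k]],
        target_x = NA, target_y = NA, switch_time = NA)
    }
    planted <- do.call(rbind, events)
    planted <- planted[order(planted$t_start), ]
    rownames(planted) <- NULL
    # head yaw low-passes the vehicle bearing; pitch points at the plane
    bearing <- atan2(veh[, 2] - head_pos[2], veh[, 1] - head_pos[1])
    yaw <- numeric(n)
    yaw[1] <- bearing[1]
    alpha <- 1 - exp(-(1 / rate) / 0.4)   # ~0.4 s head time constant
    for (i in 2:n)
      yaw[i] <- yaw[i - 1] + alpha * wrap_angle(bearing[i] - yaw[i - 1])
    stream <- data.frame(t = t_grid, hx = head_pos[1], hy = head_pos[2],
                         hz = head_pos[3], qw = NA_real_, qx = NA_real_,
                         qy = NA_real_, qz = NA_real_,
                         gx = NA_real_, gy = NA_real_, gz = NA_real_,
                         valid = TRUE)
    for (i in seq_len(n)) {
      # head orientation: camera +z along yaw direction, pitched down at
      # the mid-workspace point
      pitch <- atan2(head_pos[3] - plane_height,
                     sqrt(sum((veh[i, ] - head_pos[1:2])^2)))
      q <- cam_quat(yaw[i], pitch)
      stream[i, c("qw", "qx", "qy", "qz")] <- q
      wd <- c(target[i, 1], target[i, 2], plane_height) - head_pos
      wd <- wd / sqrt(sum(wd^2))
      wd <- perturb_dir(wd, noise_deg * pi / 180)
      gd <- as.numeric(quat_rotate(c(q[1], -q[2:4]), wd))
      stream[i, c("gx", "gy", "gz")] <- gd
    }
    list(stream = stream, events = planted)
  })
}

# intersection of the ray from p along unit d with plane z = h (xy only)
ray_plane <- function(p, d, h) {
  d <- as.numeric(d)
  tt <- (h - p[3]) / d[3]
  (p + tt * d)[1:2]
}

# quaternion with camera +z pointing at yaw (world xy) and down-pitch
cam_quat <- function(yaw, pitch) {
  # build rotation matrix with columns = camera axes in world frame:
  # z_cam: forward & down; x_cam: right (horizontal); y_cam: down-ish
  zc <- c(cos(yaw) * cos(pitch), sin(yaw) * cos(pitch), -sin(pitch))
  xc <- c(-sin(yaw), cos(yaw), 0) * -1    # right-hand: u to the right
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  R <- cbind(xc, yc, zc)
  rot_to_quat(R)
}

rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    S <- sqrt(tr + 1) * 2
    q <- c(S / 4, (R[3, 2] - R[2, 3]) / S, (R[1, 3] - R[3, 1]) / S,
           (R[2, 1] - R[1, 2]) / S)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    S <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / S, S / 4, (R[1, 2] + R[2, 1]) / S,
           (R[1, 3] + R[3, 1]) / S)
  } else if (R[2, 2] > R[3, 3]) {
    S <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / S, (R[1, 2] + R[2, 1]) / S, S / 4,
           (R[2, 3] + R[3, 2]) / S)
  } else {
    S <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / S, (R[1, 3] + R[3, 1]) / S,
           (R[2, 3] + R[3, 2]) / S, S / 4)
  }
  q / sqrt(sum(q^2))
}

# rotate a unit vector by a random small angle (sd radians)
perturb_dir <- function(d, sd) {
  if (sd <= 0) return(d)
  # orthonormal basis around d
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  ang <- stats::rnorm(1, 0, sd)
  phi <- stats::runif(1, 0, 2 * pi)
  axis_off <- cos(phi) * e1 + sin(phi) * e2
  out <- cos(ang) * d + sin(ang) * axis_off
  out / sqrt(sum(out^2))
}
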