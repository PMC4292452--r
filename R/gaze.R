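# Gaze registration, eye-movement classification, and attention metrics.
#
# Gaze streams carry a head pose (position + orientation quaternion in
# the world frame) and a unit gaze direction in the glasses frame. The
# gaze point in the world is the intersection of the gaze ray with a
# horizontal plane at the vehicle's flight height. Classification is
# velocity/duration thresholding on world-frame angular gaze speed:
# fast samples form saccades; stabilized intervals split into smooth
# pursuit (gaze tracks the moving vehicle) and fixation (gaze parked on
# a stationary point). World-frame velocities are classified because
# registration already compensates head motion.

quat_rotate <- function(q, v) {
  # rotate 3-vector(s) v (n x 3) by unit quaternion q = (w, x, y, z)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x * x + y * y)),
    3, 3, byrow = TRUE)
  v %*% t(R)
}

quat_from_yaw_pitch <- function(yaw, pitch) {
  # yaw about world z, then pitch about the rotated y axis
  cy <- cos(yaw / 2); sy <- sin(yaw / 2)
  cp <- cos(pitch / 2); sp <- sin(pitch / 2)
  # q = qz(yaw) * qy(pitch)
  c(cy * cp, -sy * sp, cy * sp, sy * cp)
}

#' Register a gaze sample into the world frame
#'
#' Rotates the glasses-frame gaze direction into the world frame and
#' intersects the ray from the head position with the horizontal plane
#' `z = plane_height` (the vehicle's flight plane). Rays parallel to or
#' pointing away from the plane miss.
#'
#' @param head_pos length-3 head position (m).
#' @param head_quat length-4 unit quaternion `(w, x, y, z)`.
#' @param gaze_dir length-3 unit gaze direction, glasses frame.
#' @param plane_height plane height (m).
#' @return length-3 world intersection point, or `NULL` on a miss.
#' @export
gaze_to_world <- function(head_pos, head_quat, gaze_dir, plane_height = 0) {
  wd <- as.numeric(quat_rotate(head_quat, gaze_dir))
  dz <- plane_height - head_pos[3]
  if (abs(wd[3]) < 1e-12) return(NULL)
  tt <- dz / wd[3]
  if (tt <= 0) return(NULL)
  head_pos + tt * wd
}

#' Scene-camera intrinsics
#'
#' Pinhole model from image size and field of view; principal point at
#' the image center. Defaults follow a 1280 x 960 scene camera with a
#' 60 x 46 degree field of view.
#'
#' @param width,height image size (px).
#' @param fov_h,fov_v field of view (deg).
#' @return list with focal lengths and principal point (class
#'   `camera_intrinsics`).
#' @export
camera_intrinsics <- function(width = 1280, height = 960,
                              fov_h = 60, fov_v = 46) {
  list(width = width, height = height,
       fx = (width / 2) / tan(fov_h * pi / 360),
       fy = (height / 2) / tan(fov_v * pi / 360),
       cx = width / 2, cy = height / 2)
}

#' Project a world point onto the scene-camera image plane
#'
#' Camera frame convention: +z optical axis (forward), +x right (image
#' u), +y down (image v); the glasses frame coincides with the camera
#' frame.
#'
#' @param p length-3 world point (m).
#' @param head_pos,head_quat glasses pose in the world frame.
#' @param cam a [camera_intrinsics()].
#' @return length-2 pixel `c(u, v)`, or `NULL` if behind the camera or
#'   outside the image.
#' @export
project_to_image <- function(p, head_pos, head_quat,
                             cam = camera_intrinsics()) {
  rel <- as.numeric(p) - as.numeric(head_pos)
  if (sqrt(sum(rel^2)) < 1e-12) stop("point coincides with the camera center")
  # world -> camera: inverse rotation
  qc <- c(head_quat[1], -head_quat[2:4])
  pc <- as.numeric(quat_rotate(qc, rel))
  if (pc[3] <= 0) return(NULL)
  u <- cam$cx + cam$fx * pc[1] / pc[3]
  v <- cam$cy + cam$fy * pc[2] / pc[3]
  if (u < 0 || u > cam$width || v < 0 || v > cam$height) return(NULL)
  c(u = u, v = v)
}

# 5-point running mean (edges: shorter symmetric windows)
smooth5 <- function(x) {
  n <- length(x)
  if (n < 5L) return(x)
  out <- as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2))
  out[1] <- mean(x[1:3]); out[2] <- mean(x[1:4])
  out[n - 1] <- mean(x[(n - 3):n]); out[n] <- mean(x[(n - 2):n])
  out
}

#' Classify a gaze stream into fixations, saccades, and smooth pursuits
#'
#' Angular gaze speed is computed from successive world-frame gaze
#' directions. Samples above `saccade_speed` seed saccade candidates,
#' extended over contiguous samples above half that threshold
#' (onset/offset hysteresis) and kept when their duration lies within
#' `saccade_dur` (which also rejects single-sample tracker spikes).
#' Stabilized intervals become smooth pursuit when the
#' gaze point tracks the vehicle (mean gaze-vehicle distance below
#' `pursuit_radius` and positively correlated motion), else fixation
#' when dispersion and duration qualify; leftovers are unclassified.
#' Invalid samples split events. Events tile the stream without
#' overlap.
#'
#' @param stream data.frame with columns `t, hx, hy, hz, qw, qx, qy, qz,
#'   gx, gy, gz, valid` (head pose, gaze direction, validity flag).
#' @param helo a `trajectory` (the tracked vehicle), or `NULL` (then no
#'   pursuit class is assigned).
#' @param plane_height gaze registration plane (m).
#' @param saccade_speed saccade velocity threshold (deg/s).
#' @param saccade_dur length-2 admissible saccade duration (s).
#' @param saccade_onset saccade onset/offset threshold (deg/s): a
#'   detected saccade extends over the contiguous run above it.
#' @param saccade_min_amp minimum net saccade amplitude (deg).
#' @param fix_min_dur minimum fixation duration (s).
#' @param fix_dispersion maximum fixation dispersion: RMS angular
#'   deviation of gaze directions about their mean (deg).
#' @param pursuit_angle angular radius of the foveal pursuit sector
#'   (deg): mean gaze-to-vehicle angular separation must stay inside it.
#' @param pursuit_lock foveal acquisition radius (deg): the median
#'   gaze-to-vehicle separation of a pursuit run must stay inside it.
#'   Pursuit implies the fovea is locked on the target; a stabilized
#'   interval merely *near* the vehicle (e.g. an anticipatory fixation
#'   at an upcoming subgoal the vehicle is approaching) is a fixation,
#'   and over sub-second windows gaze drift cannot separate the two.
#' @return data.frame of events: `kind` (factor: fixation, saccade,
#'   smooth_pursuit, unclassified), `t_start`, `t_end`, `wx`, `wy`
#'   (mean world gaze point), `dispersion` (m), `peak_speed` (deg/s).
#' @export
classify_gaze <- function(stream, helo = NULL, plane_height = 0,
                          saccade_speed = 150, saccade_dur = c(0.02, 0.2),
                          saccade_onset = 100, saccade_min_amp = 3,
                          fix_min_dur = 0.15, fix_dispersion = 1,
                          pursuit_angle = 15, pursuit_lock = 3) {
  s <- as.data.frame(stream)
  n <- nrow(s)
  stopifnot(n >= 3L)
  if (!is.null(helo)) {
    hs <- helo$samples
    t0 <- max(s$t[1], hs$t[1]); t1 <- min(s$t[n], hs$t[nrow(hs)])
    if (t1 <= t0) stop("gaze stream and trajectory do not overlap in time")
  }
  # world gaze directions and plane points
  W <- matrix(NA_real_, n, 3L)
  Pw <- matrix(NA_real_, n, 2L)
  dist_ray <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!s$valid[i]) next
    wd <- as.numeric(quat_rotate(c(s$qw[i], s$qx[i], s$qy[i], s$qz[i]),
                                 c(s$gx[i], s$gy[i], s$gz[i])))
    W[i, ] <- wd
    p <- gaze_to_world(c(s$hx[i], s$hy[i], s$hz[i]),
                       c(s$qw[i], s$qx[i], s$qy[i], s$qz[i]),
                       c(s$gx[i], s$gy[i], s$gz[i]), plane_height)
    if (!is.null(p)) {
      Pw[i, ] <- p[1:2]
      dist_ray[i] <- sqrt(sum((p - c(s$hx[i], s$hy[i], s$hz[i]))^2))
    }
  }
  ok <- s$valid & !is.na(Pw[, 1])
  # angular speed between consecutive valid samples (deg/s)
  speed <- rep(NA_real_, n)
  for (i in 2:n) {
    if (!ok[i] || !ok[i - 1L]) next
    dtau <- s$t[i] - s$t[i - 1L]
    if (dtau <= 0) next
    cosang <- sum(W[i, ] * W[i - 1L, ]) /
      (sqrt(sum(W[i, ]^2)) * sqrt(sum(W[i - 1L, ]^2)))
    speed[i] <- acos(min(1, max(-1, cosang))) / dtau * 180 / pi
  }
  speed[1] <- speed[2]
  filt <- ifelse(is.na(speed), Inf, speed)
  # two-threshold saccade detection: samples above the peak threshold
  # seed a saccade, which extends over the surrounding contiguous run
  # above the (fixed) onset threshold. Keeping the onset threshold
  # independent of `saccade_speed` makes the saccade count monotone in
  # the peak threshold. Single-sample artifacts (tracker dropout
  # spikes) are rejected downstream by the minimum saccade duration
  # and amplitude.
  core <- ok & filt > saccade_speed
  wing <- ok & filt > min(saccade_onset, saccade_speed)
  fast <- core
  r0 <- rle(wing)
  e0 <- cumsum(r0$lengths); s0 <- e0 - r0$lengths + 1L
  for (k in seq_along(r0$values)) {
    if (r0$values[k] && any(core[s0[k]:e0[k]])) fast[s0[k]:e0[k]] <- TRUE
  }
  lab <- ifelse(!ok, "invalid", ifelse(fast, "fast", "slow"))
  # run-length segmentation
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  dt_med <- stats::median(diff(s$t))
  events <- list()
  for (k in seq_along(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    t_start <- s$t[i0] - dt_med / 2
    t_end <- s$t[i1] + dt_med / 2
    dur <- t_end - t_start
    kind <- if (r$values[k] == "invalid") "invalid" else "unclassified"
    wx <- NA_real_; wy <- NA_real_; disp <- NA_real_; pk <- NA_real_
    if (r$values[k] == "fast") {
      pk <- max(filt[i0:i1][is.finite(filt[i0:i1])], -Inf)
      # net amplitude across the run (from the last sample before to
      # the first after): rejects registration-noise blips that cross
      # the velocity threshold without relocating the gaze
      ia <- max(1L, i0 - 1L); ib <- min(n, i1 + 1L)
      amp <- if (ok[ia] && ok[ib]) {
        acos(min(1, max(-1, sum(W[ia, ] * W[ib, ]) /
                          (sqrt(sum(W[ia, ]^2)) * sqrt(sum(W[ib, ]^2)))))) *
          180 / pi
      } else Inf
      if (dur >= saccade_dur[1] && dur <= saccade_dur[2] &&
          amp >= saccade_min_amp) kind <- "saccade"
      # landing point: noise-averaged over the first stabilized samples
      # after the run (in-flight samples undershoot the target, and a
      # single post-saccadic sample carries the full registration noise)
      land <- which(!is.na(Pw[, 1]) & seq_len(n) > i1)
      if (!length(land)) land <- which(!is.na(Pw[i0:i1, 1])) + i0 - 1L
      if (length(land)) {
        land <- land[seq_len(min(5L, length(land)))]
        wx <- mean(Pw[land, 1])
        wy <- mean(Pw[land, 2])
      }
    } else if (r$values[k] == "slow") {
      # trim one sample at each end: velocity-threshold boundaries can
      # leak a saccade-in-flight sample into the stabilized run
      j0 <- if (i1 - i0 >= 2L) i0 + 1L else i0
      j1 <- if (i1 - i0 >= 2L) i1 - 1L else i1
      keep <- (j0:j1)[!is.na(Pw[j0:j1, 1])]
      if (length(keep)) {
        pts <- Pw[keep, , drop = FALSE]
        ctr <- colMeans(pts)
        wx <- ctr[1]; wy <- ctr[2]
        disp <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
        pk <- max(filt[i0:i1][is.finite(filt[i0:i1])], 0)
        # angular dispersion of gaze directions about their mean (deg);
        # thresholds live in gaze-angle space: oblique ray/plane
        # incidence amplifies angular noise into large on-plane scatter
        D <- W[keep, , drop = FALSE]
        mdir <- colMeans(D)
        mdir <- mdir / sqrt(sum(mdir^2))
        devs <- acos(pmin(1, pmax(-1, D %*% mdir))) * 180 / pi
        ang_disp <- sqrt(mean(devs^2))
        pursuit <- FALSE
        if (!is.null(helo) && length(keep) >= 5L) {
          hp <- cbind(
            stats::approx(helo$samples$t, helo$samples$s_x,
                          xout = s$t[keep], rule = 2)$y,
            stats::approx(helo$samples$t, helo$samples$s_y,
                          xout = s$t[keep], rule = 2)$y)
          # angular separation between gaze and the head-vehicle ray
          hv <- cbind(hp[, 1] - s$hx[keep], hp[, 2] - s$hy[keep],
                      plane_height - s$hz[keep])
          hv <- hv / sqrt(rowSums(hv^2))
          sep <- acos(pmin(1, pmax(-1, rowSums(D * hv)))) * 180 / pi
          if (mean(sep) < pursuit_angle &&
              stats::median(sep) < pursuit_lock) {
            # the gaze must drift with the target: fit the angular
            # velocity of (noise-smoothed) gaze directions in the
            # tangent plane at the mean direction and require it to
            # match the vehicle's apparent angular velocity in both
            # magnitude and direction
            e1 <- if (abs(mdir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
            e1 <- e1 - sum(e1 * mdir) * mdir
            e1 <- e1 / sqrt(sum(e1^2))
            e2 <- c(mdir[2] * e1[3] - mdir[3] * e1[2],
                    mdir[3] * e1[1] - mdir[1] * e1[3],
                    mdir[1] * e1[2] - mdir[2] * e1[1])
            tt <- s$t[keep]
            slope2 <- function(M) {  # deg/s per tangent axis
              y <- cbind(M %*% e1, M %*% e2) * 180 / pi
              y <- apply(y, 2, smooth5)
              tc <- tt - mean(tt)
              c(sum(tc * y[, 1]), sum(tc * y[, 2])) / sum(tc^2)
            }
            sg_ <- slope2(D)
            sv_ <- slope2(hv)
            msg_ <- sqrt(sum(sg_^2)); msv_ <- sqrt(sum(sv_^2))
            pursuit <- msv_ > 1 && msg_ > 0.5 * msv_ &&
              sum(sg_ * sv_) / max(msg_ * msv_, 1e-12) > 0.5
          }
        }
        if (pursuit) {
          kind <- "smooth_pursuit"
        } else if (dur >= fix_min_dur && ang_disp <= fix_dispersion) {
          kind <- "fixation"
        }
      }
    }
    events[[k]] <- data.frame(kind = kind, t_start = t_start, t_end = t_end,
                              wx = wx, wy = wy, dispersion = disp,
                              peak_speed = pk)
  }
  ev <- do.call(rbind, events)
  ev$kind <- factor(ev$kind, levels = c("fixation", "saccade",
                                        "smooth_pursuit", "unclassified",
                                        "invalid"))
  attr(ev, "samples") <- data.frame(t = s$t, wx = Pw[, 1], wy = Pw[, 2],
                                    speed = filt,
                                    event = rep(seq_along(r$values),
                                                r$lengths))
  ev
}

#' Spatial density map of gaze events
#'
#' 2-D histogram (normalized to total mass 1) of the world gaze points
#' of all stream samples belonging to events of the requested kind.
#'
#' @param events result of [classify_gaze()] (with its `samples`
#'   attribute).
#' @param kind one of `"fixation"`, `"saccade"`, `"smooth_pursuit"`.
#' @param bounds length-4 `c(xmin, ymin, xmax, ymax)` (m).
#' @param resolution cell size (m).
#' @return list with `density` matrix (sums to 1), `xs`, `ys`.
#' @export
gaze_density <- function(events, kind, bounds, resolution = 0.25) {
  smp <- attr(events, "samples")
  if (is.null(smp)) stop("events carry no per-sample records")
  sel <- smp$event %in% which(events$kind == kind)
  pts <- smp[sel & !is.na(smp$wx), c("wx", "wy")]
  if (!nrow(pts)) stop(sprintf("no samples of kind '%s'", kind))
  xs <- seq(bounds[1], bounds[3], by = resolution)
  ys <- seq(bounds[2], bounds[4], by = resolution)
  ix <- pmin(length(xs) - 1L, pmax(1L, findInterval(pts$wx, xs)))
  iy <- pmin(length(ys) - 1L, pmax(1L, findInterval(pts$wy, ys)))
  D <- matrix(0, length(xs) - 1L, length(ys) - 1L)
  for (k in seq_along(ix)) D[ix[k], iy[k]] <- D[ix[k], iy[k]] + 1
  list(density = D / sum(D),
       xs = (xs[-1] + xs[-length(xs)]) / 2,
       ys = (ys[-1] + ys[-length(ys)]) / 2)
}

#' Attention metrics against the model's predicted gaze pattern
#'
#' Scores a classified gaze stream against the hierarchical model's
#' signature: pursuit of the vehicle most of the time, fixations at
#' subgoal regions, and anticipatory saccades landing near the next
#' subgoal while the vehicle still approaches the current one (lead
#' time = subgoal switch time minus saccade end).
#'
#' @param events result of [classify_gaze()].
#' @param helo the vehicle `trajectory` (with `subgoal_idx` samples).
#' @param plan the [subgoal_plan()] flown.
#' @param r_subgoal radius around a subgoal counting as "at" it (m).
#' @param r_coincide gaze-vehicle coincidence radius for pursuit (m).
#' @return list (class `attention_report`): `pursuit_fraction`,
#'   `pursuit_vehicle_coincidence`, `fixation_subgoal_overlap`,
#'   `anticipatory_saccade_count`, `mean_lead_time`, `lead_times`.
#' @export
attention_metrics <- function(events, helo, plan, r_subgoal = 0.6,
                              r_coincide = 0.6) {
  smp <- attr(events, "samples")
  hs <- helo$samples
  classified <- events$kind %in% c("fixation", "saccade", "smooth_pursuit")
  dur <- events$t_end - events$t_start
  pursuit_fraction <- if (any(classified))
    sum(dur[events$kind == "smooth_pursuit"]) / sum(dur[classified]) else 0
  # pursuit sample coincidence with the vehicle
  psel <- smp$event %in% which(events$kind == "smooth_pursuit") & !is.na(smp$wx)
  coincide <- NA_real_
  if (any(psel)) {
    hx <- stats::approx(hs$t, hs$s_x, xout = smp$t[psel], rule = 2)$y
    hy <- stats::approx(hs$t, hs$s_y, xout = smp$t[psel], rule = 2)$y
    coincide <- mean(sqrt((smp$wx[psel] - hx)^2 +
                          (smp$wy[psel] - hy)^2) <= r_coincide)
  }
  # fixation overlap with any subgoal
  fx <- events[events$kind == "fixation" & !is.na(events$wx), ]
  overlap <- NA_real_
  if (nrow(fx)) {
    dmin <- vapply(seq_len(nrow(fx)), function(i) {
      min(sqrt((plan$subgoals[, 1] - fx$wx[i])^2 +
               (plan$subgoals[, 2] - fx$wy[i])^2))
    }, 0)
    overlap <- mean(dmin <= r_subgoal)
  }
  # anticipatory saccades: land near subgoal k+1 while active subgoal is k
  sac <- events[events$kind == "saccade" & !is.na(events$wx), ]
  lead_times <- numeric()
  if (nrow(sac)) {
    for (i in seq_len(nrow(sac))) {
      k <- hs$subgoal_idx[findInterval(sac$t_end[i], hs$t,
                                       all.inside = TRUE)]
      if (k >= nrow(plan$subgoals)) next
      g_next <- plan$subgoals[k + 1L, ]
      if (sqrt((sac$wx[i] - g_next[1])^2 +
               (sac$wy[i] - g_next[2])^2) > r_subgoal) next
      sw <- hs$t[match(k + 1L, hs$subgoal_idx)]
      if (is.na(sw)) next
      lead_times <- c(lead_times, sw - sac$t_end[i])
    }
  }
  structure(list(
    pursuit_fraction = pursuit_fraction,
    pursuit_vehicle_coincidence = coincide,
    fixation_subgoal_overlap = overlap,
    anticipatory_saccade_count = length(lead_times),
    mean_lead_time = if (length(lead_times)) mean(lead_times) else NA_real_,
    lead_times = lead_times),
    class = "attention_report")
}

#' @export
print.attention_report <- function(x, ...) {
  cat("<attention_report>\n")
  cat(sprintf("  pursuit fraction            %.3f\n", x$pursuit_fraction))
  cat(sprintf("  pursuit-vehicle coincidence %.3f\n",
              x$pursuit_vehicle_coincidence))
  cat(sprintf("  fixation-subgoal overlap    %.3f\n",
              x$fixation_subgoal_overlap))
  cat(sprintf("  anticipatory saccades       %d (mean lead %.2f s)\n",
              x$anticipatory_saccade_count, x$mean_lead_time))
  invisible(x)
}
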