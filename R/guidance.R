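# Closed-loop hierarchical guidance simulator.
#
# Three nested levels, evaluated once per fixed time step:
#   planning   - a subgoal state machine over an ordered subgoal plan;
#   guidance   - tau-coupled gap closure producing a velocity reference
#                (speed + course) toward the active subgoal;
#   tracking   - saturated proportional feedback turning the reference
#                error into tangential / normal acceleration commands.
# The vehicle is a planar point-mass-with-heading model
#   s_x' = v cos(psi),  s_y' = v sin(psi),  v' = a_t,  psi' = a_n / v,
# integrated with fixed-step RK4 so trajectories are reproducible and
# alignable. The simulator itself is fully deterministic; all
# stochasticity lives in the fixture generators.

#' Agent state
#'
#' Planar vehicle state at a timestamp: position (m), speed (m/s, >= 0),
#' and course angle psi (rad, wrapped to (-pi, pi]).
#'
#' @param t time (s).
#' @param s_x,s_y position (m).
#' @param v speed (m/s), non-negative.
#' @param psi course angle (rad).
#' @return An object of class `agent_state` (named numeric vector).
#' @export
agent_state <- function(t = 0, s_x = 0, s_y = 0, v = 0, psi = 0) {
  stopifnot(v >= 0)
  structure(c(t = t, s_x = s_x, s_y = s_y, v = v, psi = wrap_angle(psi)),
            class = "agent_state")
}

#' Guidance parameters
#'
#' Tunables of the three-level controller.
#'
#' @param tau_dot constant tau-coupling rate k_tau (dimensionless,
#'   0 < k < 1): the terminal gap is closed holding d(tau)/dt = k, which
#'   drives speed to zero together with the gap.
#' @param cruise_speed commanded speed on non-terminal legs (m/s).
#' @param k_track_v,k_track_psi proportional tracking gains (1/s).
#' @param a_t_max,a_n_max tangential / normal acceleration limits (m/s^2).
#' @param dt integration step (s).
#' @param v_floor speed floor used in the turn-rate kinematics (m/s),
#'   avoids the turning singularity at rest.
#' @param capture_radius subgoal capture radius (m); `NULL` means
#'   2 x the goal position tolerance at simulation time.
#' @param brake_frac fraction of `a_t_max` commanded as terminal
#'   deceleration; sets the braking distance
#'   `d_brake = cruise^2 / (2 * brake_frac * a_t_max)`.
#' @return An object of class `guidance_params`.
#' @export
guidance_params <- function(tau_dot = 0.5, cruise_speed = 0.6,
                            k_track_v = 3, k_track_psi = 4,
                            a_t_max = 2, a_n_max = 2.5, dt = 0.02,
                            v_floor = 0.05, capture_radius = NULL,
                            brake_frac = 0.5) {
  stopifnot(tau_dot > 0, tau_dot < 1, cruise_speed > 0, dt > 0,
            k_track_v > 0, k_track_psi > 0, a_t_max > 0, a_n_max > 0,
            v_floor > 0, brake_frac > 0, brake_frac <= 1)
  structure(list(tau_dot = tau_dot, cruise_speed = cruise_speed,
                 k_track_v = k_track_v, k_track_psi = k_track_psi,
                 a_t_max = a_t_max, a_n_max = a_n_max, dt = dt,
                 v_floor = v_floor, capture_radius = capture_radius,
                 brake_frac = brake_frac),
            class = "guidance_params")
}

#' Subgoal plan
#'
#' Ordered subgoal positions ending at the goal position.
#'
#' @param subgoals n x 2 matrix of subgoal positions (m); the last row
#'   must equal the goal position of `terminal`.
#' @param terminal a [goal_spec()].
#' @return An object of class `subgoal_plan`.
#' @export
subgoal_plan <- function(subgoals, terminal) {
  subgoals <- matrix(as.numeric(as.matrix(subgoals)), ncol = 2L)
  stopifnot(nrow(subgoals) >= 1L, inherits(terminal, "goal_spec"))
  if (max(abs(subgoals[nrow(subgoals), ] - terminal$position)) > 1e-9)
    stop("last subgoal must equal the goal position")
  structure(list(subgoals = subgoals, terminal = terminal),
            class = "subgoal_plan")
}

#' One integration step of the vehicle dynamics
#'
#' Fixed-step 4th-order Runge-Kutta with the control held constant over
#' the step (zero-order hold). Speed is clipped at zero after the step.
#'
#' @param x an [agent_state()].
#' @param u length-2 control `c(a_t, a_n)` (m/s^2).
#' @param dt step (s), > 0.
#' @param v_floor speed floor in the turn-rate term (m/s).
#' @return The propagated [agent_state()].
#' @export
step_dynamics <- function(x, u, dt, v_floor = 0.05) {
  stopifnot(dt > 0)
  u <- unname(as.numeric(u))
  f <- function(s) {
    c(s[3] * cos(s[4]), s[3] * sin(s[4]), u[1], u[2] / max(s[3], v_floor))
  }
  y <- c(x[["s_x"]], x[["s_y"]], x[["v"]], x[["psi"]])
  k1 <- f(y)
  k2 <- f(y + dt / 2 * k1)
  k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  agent_state(x[["t"]] + dt, y[1], y[2], max(0, y[3]), wrap_angle(y[4]))
}

#' Braking distance of the constant-tau-dot terminal closure
#'
#' Distance at which the terminal deceleration profile departs from
#' cruise: `d_brake = cruise^2 / (2 * brake_frac * a_t_max)` (the
#' constant-deceleration distance at a commanded deceleration of
#' `brake_frac * a_t_max`).
#'
#' @param p a [guidance_params()].
#' @return braking distance (m).
#' @export
brake_distance <- function(p) {
  p$cruise_speed^2 / (2 * p$brake_frac * p$a_t_max)
}

#' Tau-coupled velocity reference
#'
#' The perceptual-guidance level: given the gap to the active subgoal it
#' emits a speed and course reference. The course reference points along
#' the gap. On intermediate legs the speed reference is the cruise
#' speed. On the terminal leg, once the gap falls below the braking
#' distance, the speed reference enforces constant-tau-dot closure:
#' with tau = gap / closure-rate held so that d(tau)/dt = k, the speed
#' follows `v(d) = cruise * (d / d_brake)^(1 - k)`, driving speed to 0
#' together with the gap.
#'
#' @param x an [agent_state()].
#' @param g_k length-2 active subgoal position (m).
#' @param p a [guidance_params()].
#' @param is_terminal is `g_k` the final goal?
#' @return list with `speed` (m/s) and `course` (rad).
#' @export
tau_guidance <- function(x, g_k, p, is_terminal = FALSE) {
  dx <- g_k[1] - x[["s_x"]]
  dy <- g_k[2] - x[["s_y"]]
  d <- sqrt(dx * dx + dy * dy)
  if (d == 0) return(list(speed = 0, course = x[["psi"]], a_ff = 0))
  course <- atan2(dy, dx)
  if (!is_terminal)
    return(list(speed = p$cruise_speed, course = course, a_ff = 0))
  db <- brake_distance(p)
  a_ff <- if (d < db) {
    # deceleration along the constant-tau-dot profile (dynamic inverse)
    -(1 - p$tau_dot) * p$cruise_speed^2 / db * (d / db)^(1 - 2 * p$tau_dot)
  } else 0
  list(speed = tau_speed_ref(d, p), course = course, a_ff = a_ff)
}

#' Terminal speed reference as a function of gap
#'
#' The 1-D constant-tau-dot law used by [tau_guidance()] on the final
#' leg; exposed so it can be integrated and checked against the analytic
#' gap solution `d(t) = d0 (1 - t/T)^(1/k)`, `T = d0 / (k v0)`.
#'
#' @param d gap (m), >= 0.
#' @param p a [guidance_params()].
#' @return speed reference (m/s).
#' @export
tau_speed_ref <- function(d, p) {
  db <- brake_distance(p)
  ifelse(d >= db, p$cruise_speed,
         p$cruise_speed * (pmax(d, 0) / db)^(1 - p$tau_dot))
}

#' Tracking-level control law
#'
#' Saturated proportional feedback on speed and course error with
#' optional acceleration feedforward from the guidance level:
#' `a_t = clip(k_v (v_ref - v) + a_ff)`,
#' `a_n = clip(k_psi wrap(psi_ref - psi) v)`.
#' Zero error (and zero feedforward) yields zero input.
#'
#' @param x an [agent_state()].
#' @param ref list with `speed` and `course` (from [tau_guidance()]).
#' @param p a [guidance_params()].
#' @return length-2 control `c(a_t, a_n)`.
#' @export
tracking_control <- function(x, ref, p) {
  a_t <- p$k_track_v * (ref$speed - x[["v"]]) + (ref$a_ff %||% 0)
  a_n <- p$k_track_psi * wrap_angle(ref$course - x[["psi"]]) *
    max(x[["v"]], p$v_floor)
  c(a_t = max(-p$a_t_max, min(p$a_t_max, a_t)),
    a_n = max(-p$a_n_max, min(p$a_n_max, a_n)))
}

#' Subgoal state machine
#'
#' Advances the active subgoal index when the vehicle enters the capture
#' radius of the active subgoal. The final subgoal uses the goal
#' tolerances instead. The index never decreases.
#'
#' @param x an [agent_state()].
#' @param plan a [subgoal_plan()].
#' @param idx current active index (1-based).
#' @param capture_radius capture radius (m) for non-terminal subgoals.
#' @return the (possibly advanced) active index.
#' @export
advance_subgoal <- function(x, plan, idx, capture_radius) {
  n <- nrow(plan$subgoals)
  if (idx >= n) return(n)
  g <- plan$subgoals[idx, ]
  d <- sqrt((x[["s_x"]] - g[1])^2 + (x[["s_y"]] - g[2])^2)
  if (d < capture_radius) idx + 1L else idx
}

#' Simulate the closed-loop guidance behavior
#'
#' Runs the three-level loop from `x0` until the goal tolerances are met
#' or `t_max` elapses. A sample entering an obstacle marks the
#' trajectory as collided (the run continues so the trace is complete).
#'
#' @param env a [guidance_env()].
#' @param plan a [subgoal_plan()] (last subgoal = goal position).
#' @param x0 initial [agent_state()], outside all obstacles.
#' @param p a [guidance_params()].
#' @param t_max time budget (s).
#' @param perturb optional function `(step_index, u) -> u` applied to the
#'   commanded control before saturation; used by fixture generators to
#'   inject actuation jitter. `NULL` for the deterministic loop.
#' @return An object of class `trajectory`: list with `samples` (a
#'   data.frame `t, s_x, s_y, v, psi, a_t, a_n, subgoal_idx`), `status`
#'   (`"success"`, `"timeout"`), `collided` flag, and the `plan`.
#' @examples
#' env <- guidance_env(c(0, 0, 12, 8), list(), goal_spec(c(10, 4)))
#' plan <- subgoal_plan(rbind(c(10, 4)), env$goal)
#' tr <- simulate_guidance(env, plan, agent_state(0, 1, 4, 0, 0),
#'                         guidance_params())
#' @export
simulate_guidance <- function(env, plan, x0, p = guidance_params(),
                              t_max = 120, perturb = NULL) {
  stopifnot(inherits(env, "guidance_env"), inherits(plan, "subgoal_plan"),
            inherits(x0, "agent_state"))
  if (point_in_obstacle(c(x0[["s_x"]], x0[["s_y"]]), env))
    stop("initial state lies inside an obstacle")
  capture <- if (is.null(p$capture_radius)) 2 * plan$terminal$pos_tol
             else p$capture_radius
  n_sub <- nrow(plan$subgoals)
  goal <- plan$terminal
  n_max <- ceiling(t_max / p$dt) + 1L
  S <- matrix(NA_real_, n_max, 8L)
  colnames(S) <- c("t", "s_x", "s_y", "v", "psi", "a_t", "a_n", "subgoal_idx")
  x <- x0
  idx <- 1L
  collided <- FALSE
  status <- "timeout"
  i <- 0L
  repeat {
    i <- i + 1L
    idx <- advance_subgoal(x, plan, idx, capture)
    gd <- sqrt((x[["s_x"]] - goal$position[1])^2 +
               (x[["s_y"]] - goal$position[2])^2)
    done <- (gd <= goal$pos_tol && x[["v"]] <= goal$speed_tol)
    if (point_in_obstacle(c(x[["s_x"]], x[["s_y"]]), env)) collided <- TRUE
    if (done || i >= n_max) {
      S[i, ] <- c(x, 0, 0, idx)
      if (done) status <- "success"
      break
    }
    ref <- tau_guidance(x, plan$subgoals[idx, ], p, idx == n_sub)
    u <- tracking_control(x, ref, p)
    if (!is.null(perturb)) {
      u <- perturb(i, u)
      u[1] <- max(-p$a_t_max, min(p$a_t_max, u[1]))
      u[2] <- max(-p$a_n_max, min(p$a_n_max, u[2]))
    }
    S[i, ] <- c(x, u, idx)
    x <- step_dynamics(x, u, p$dt, p$v_floor)
  }
  samples <- as.data.frame(S[seq_len(i), , drop = FALSE])
  samples$subgoal_idx <- as.integer(samples$subgoal_idx)
  structure(list(samples = samples, status = status, collided = collided,
                 plan = plan, params = p),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<trajectory> %d samples, %.2f s, status %s%s\n",
    nrow(s), s$t[nrow(s)] - s$t[1], x$status,
    if (x$collided) " (collided)" else ""))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, env = NULL, ...) {
  s <- x$samples
  if (!is.null(env)) {
    plot(env, ...)
  } else {
    graphics::plot(s$s_x, s$s_y, type = "n", asp = 1,
                   xlab = "x (m)", ylab = "y (m)", ...)
  }
  graphics::lines(s$s_x, s$s_y, col = 4)
  graphics::points(s$s_x[1], s$s_y[1], pch = 1)
  invisible(x)
}

#' Analytic constant-tau-dot gap solution
#'
#' Closed form of the 1-D gap under the constant-tau-dot law starting
#' from gap `d0` at closure speed `v0`:
#' `d(t) = d0 * (1 - t/T)^(1/k)` with `T = d0 / (k v0)`; 0 for `t >= T`.
#' Used as the oracle for the terminal-closure dynamics.
#'
#' @param t time(s) since closure start (s).
#' @param d0 initial gap (m).
#' @param v0 initial closure speed (m/s).
#' @param k tau-coupling rate.
#' @return gap value(s) (m).
#' @export
tau_gap_analytic <- function(t, d0, v0, k) {
  T_close <- d0 / (k * v0)
  d <- d0 * pmax(0, 1 - t / T_close)^(1 / k)
  d
}
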