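test_that("dynamics integrate straight, accelerating, and circular motion", {
  # uniform straight motion
  x <- agent_state(0, 0, 0, 1, 0)
  for (i in 1:50) x <- step_dynamics(x, c(0, 0), 0.02)
  expect_equal(unname(x[c("s_x", "s_y", "v", "psi")]), c(1, 0, 1, 0),
               tolerance = 1e-12)

  # constant tangential acceleration from rest: v = a t, s = a t^2 / 2
  x <- agent_state(0, 0, 0, 0, 0)
  for (i in 1:100) x <- step_dynamics(x, c(0.5, 0), 0.01)
  expect_equal(x[["v"]], 0.5, tolerance = 1e-9)
  expect_equal(x[["s_x"]], 0.25, tolerance = 1e-6)

  # constant normal acceleration: circle of radius v^2/a_n, closing on
  # itself after one period 2 pi v / a_n
  v <- 1; a_n <- 1
  x <- agent_state(0, 0, 0, v, 0)
  n <- round(2 * pi * v / a_n / 0.02)
  for (i in seq_len(n)) x <- step_dynamics(x, c(0, a_n), 0.02)
  expect_lt(sqrt(x[["s_x"]]^2 + x[["s_y"]]^2), 0.02)  # closes on start
  expect_equal(x[["v"]], v, tolerance = 1e-9)
})

test_that("speed is conserved under zero tangential input", {
  x <- agent_state(0, 0, 0, 0.8, 0.3)
  for (i in 1:200) {
    x2 <- step_dynamics(x, c(0, runif(1, -1, 1)), 0.02)
    expect_lt(abs(x2[["v"]] - x[["v"]]), 1e-9)
    x <- x2
  }
})

test_that("terminal closure follows the analytic constant-tau-dot law", {
  p <- guidance_params(cruise_speed = 1, tau_dot = 0.5)
  d0 <- brake_distance(p)
  v0 <- p$cruise_speed
  T_close <- d0 / (p$tau_dot * v0)
  # integrate the guidance law itself (RK4, fine step)
  dt <- 1e-4
  d <- d0
  t <- 0
  checkpoints <- dt * round(seq(0.05, 0.95, length.out = 20) *
                              T_close / dt)
  sim_at <- numeric(0)
  for (ck in checkpoints) {
    while (t < ck - dt / 2) {
      f <- function(x) -tau_speed_ref(max(x, 0), p)
      k1 <- f(d); k2 <- f(d + dt / 2 * k1)
      k3 <- f(d + dt / 2 * k2); k4 <- f(d + dt * k3)
      d <- d + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + dt
    }
    sim_at <- c(sim_at, d)
  }
  ana <- tau_gap_analytic(checkpoints, d0, v0, p$tau_dot)
  expect_lt(max(abs(sim_at - ana)), 1e-7)
})

test_that("tracking control is proportional, saturated, and zero at rest", {
  p <- guidance_params(k_track_v = 2, a_t_max = 5, a_n_max = 2)
  x <- agent_state(0, 0, 0, 1, 0)
  u0 <- tracking_control(x, list(speed = 1, course = 0, a_ff = 0), p)
  expect_equal(unname(u0), c(0, 0))
  u1 <- tracking_control(x, list(speed = 2, course = 0, a_ff = 0), p)
  expect_equal(u1[["a_t"]], 2)
  u2 <- tracking_control(x, list(speed = 1, course = pi, a_ff = 0),
                         guidance_params(k_track_psi = 100))
  expect_equal(abs(u2[["a_n"]]), guidance_params()$a_n_max)
})

test_that("subgoal index advances on capture and never decreases", {
  goal <- goal_spec(c(10, 0))
  plan <- subgoal_plan(rbind(c(5, 0), c(10, 0)), goal)
  far <- agent_state(0, 0, 0, 0.5, 0)
  expect_identical(advance_subgoal(far, plan, 1L, 0.4), 1L)
  near <- agent_state(0, 4.8, 0, 0.5, 0)
  expect_identical(advance_subgoal(near, plan, 1L, 0.4), 2L)

  # monotonicity over simulated runs with randomized starts
  env <- fixture_world()
  map <- fix_map()
  set.seed(21)
  for (i in 1:10) {
    st <- c(runif(1, 0.5, 4.5), runif(1, 0.5, 7.5))
    if (point_in_obstacle(st, env)) next
    plan <- tryCatch(subgoal_sequence(map, st), error = function(e) NULL)
    if (is.null(plan)) next
    tr <- simulate_guidance(env, plan,
                            agent_state(0, st[1], st[2], 0, 0),
                            guidance_params(capture_radius = 0.2))
    expect_true(all(diff(tr$samples$subgoal_idx) >= 0))
  }
})

test_that("free-space flight arrives near the nominal flight time", {
  env <- guidance_env(c(0, 0, 14, 8), list(), goal_spec(c(11, 4), 0.2, 0.1))
  p <- guidance_params(cruise_speed = 1)
  plan <- subgoal_plan(rbind(c(11, 4)), env$goal)
  tr <- simulate_guidance(env, plan, agent_state(0, 1, 4, 0, 0), p,
                          t_max = 40)
  expect_identical(tr$status, "success")
  t_arr <- max(tr$samples$t)
  expect_lt(abs(t_arr - 10) / 10, 0.15)   # terminal deceleration adds time
  # success contract
  n <- nrow(tr$samples)
  gap <- sqrt((tr$samples$s_x[n] - 11)^2 + (tr$samples$s_y[n] - 4)^2)
  expect_lte(gap, env$goal$pos_tol)
  expect_lte(tr$samples$v[n], env$goal$speed_tol)
})

test_that("a start already inside goal tolerances succeeds immediately", {
  env <- guidance_env(c(0, 0, 14, 8), list(), goal_spec(c(11, 4), 0.2, 0.1))
  plan <- subgoal_plan(rbind(c(11, 4)), env$goal)
  tr <- simulate_guidance(env, plan, agent_state(0, 11.05, 4, 0, 0),
                          guidance_params())
  expect_identical(tr$status, "success")
  expect_identical(nrow(tr$samples), 1L)
})

test_that("closed-loop gap to the active subgoal shrinks after transients", {
  env <- guidance_env(c(0, 0, 14, 8), list(), goal_spec(c(11, 4), 0.2, 0.1))
  plan <- subgoal_plan(rbind(c(6, 6), c(11, 4)), env$goal)
  tr <- simulate_guidance(env, plan, agent_state(0, 1, 1, 0, 0),
                          guidance_params())
  s <- tr$samples
  for (k in unique(s$subgoal_idx)) {
    leg <- s[s$subgoal_idx == k, ]
    g <- plan$subgoals[k, ]
    gap <- sqrt((leg$s_x - g[1])^2 + (leg$s_y - g[2])^2)
    tail80 <- gap[seq(ceiling(0.2 * length(gap)), length(gap))]
    expect_true(all(diff(tail80) <= 1e-9))
  }
})

test_that("simulation is bitwise deterministic", {
  env <- fixture_world()
  plan <- subgoal_plan(rbind(c(10.5, 5)), env$goal)
  a <- simulate_guidance(env, plan, agent_state(0, 8.8, 1.2, 0, 1),
                         guidance_params())
  b <- simulate_guidance(env, plan, agent_state(0, 8.8, 1.2, 0, 1),
                         guidance_params())
  expect_identical(a$samples, b$samples)
})

test_that("plans routed through corner subgoals avoid collisions", {
  ens <- fix_ensemble()
  expect_true(all(!ens$labels$collided))
  expect_true(all(ens$labels$status == "success"))
})
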