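straight_traj <- function(len = 10, v = 1, dt = 0.1, y = 0, x0 = 0,
                          psi = 0) {
  t <- seq(0, len / v, by = dt)
  data.frame(t = t, s_x = x0 + v * t * cos(psi), s_y = y + v * t * sin(psi),
             v = v, psi = psi, a_t = 0, a_n = 0, subgoal_idx = 1L)
}

test_that("arc-length resampling spaces points equally", {
  tr <- straight_traj(len = 10, v = 1)
  seg <- resample_arclength(tr, N = 11L)
  expect_equal(seg$states$s_x, 0:10, tolerance = 1e-9)
  expect_equal(seg$length, 10, tolerance = 1e-9)

  # endpoints only
  seg2 <- resample_arclength(tr, N = 2L)
  expect_equal(seg2$states$s_x, c(0, 10), tolerance = 1e-9)

  # path length preserved for a curved path
  t <- seq(0, 2 * pi, by = 0.01)
  curved <- data.frame(t = t, s_x = cos(t), s_y = sin(t), v = 1,
                       psi = t + pi / 2)
  seg3 <- resample_arclength(curved, N = 200L)
  d <- sqrt(diff(seg3$states$s_x)^2 + diff(seg3$states$s_y)^2)
  expect_lt(abs(sum(d) - 2 * pi) / (2 * pi), 0.001)
  # equal spacing
  expect_lt(diff(range(d)) / mean(d), 1e-3)

  expect_error(resample_arclength(straight_traj(len = 0.0)), "samples|zero")
})

test_that("planar Procrustes recovers planted rigid transforms", {
  set.seed(5)
  A <- cbind(cumsum(runif(50, 0.1, 0.5)), cumsum(rnorm(50, 0, 0.3)))
  out0 <- align_se2(A, A)
  expect_lt(abs(out0$transform$theta), 1e-12)
  expect_lt(out0$residual, 1e-12)

  tf <- se2(37 * pi / 180, c(3, -1))
  B <- se2_apply(tf, A)
  out <- align_se2(A, B)
  expect_lt(abs(out$transform$theta - tf$theta), 1e-9)
  expect_lt(out$residual, 1e-9)

  # symmetry of the residual
  expect_lt(abs(align_se2(A, B)$residual - align_se2(B, A)$residual), 1e-9)

  # degenerate: all points coincident
  P <- matrix(1, 10, 2)
  dg <- align_se2(P, P + 2)
  expect_identical(dg$transform$theta, 0)
  expect_lt(dg$residual, 1e-12)
})

test_that("noisy Procrustes residual sits at the noise scale", {
  set.seed(42)
  sigma <- 0.01   # RMS 2-D displacement per point
  A <- cbind(cumsum(runif(50, 0.1, 0.5)), cumsum(rnorm(50, 0, 0.3)))
  tf <- se2(1.1, c(-2, 0.5))
  resid <- replicate(300, {
    B <- se2_apply(tf, A) +
      matrix(rnorm(100, 0, sigma / sqrt(2)), ncol = 2)
    align_se2(A, B)$residual
  })
  expect_true(all(resid > 0.5 * sigma & resid < 1.5 * sigma))
})

test_that("parallel straight ensembles yield only the goal region", {
  env <- guidance_env(c(0, 0, 12, 8), list(), goal_spec(c(10, 4), 0.5))
  ens <- lapply(c(3.7, 3.9, 4.1, 4.3), function(y) {
    # parallel straight runs, all terminating inside the goal region
    t <- seq(0, 1, by = 0.005)
    data.frame(t = t * 9, s_x = 1 + t * 9, s_y = y, v = 1, psi = 0)
  })
  sg <- find_subgoals(ens, env)
  expect_identical(nrow(sg), 1L)
  expect_true(sg$is_goal[1])

  # duplicates change nothing (idempotence)
  sg2 <- find_subgoals(c(ens, ens), env)
  expect_identical(nrow(sg2), 1L)

  # single trajectory: only the goal region
  sg3 <- find_subgoals(ens[1], env)
  expect_identical(nrow(sg3), 1L)
})

test_that("a funneling corner is recovered as a subgoal region", {
  ens <- fix_ensemble()
  env <- fixture_world()
  sg <- find_subgoals(ens$trajectories, env)
  truth <- planted_truth(ens)
  expect_identical(nrow(sg), nrow(truth$regions))
  # corner region center lies within two map cells of the planted
  # corner waypoint, and near the occluding wall vertex
  corner <- sg[!sg$is_goal, ]
  planted <- truth$regions[!truth$regions$is_goal, ]
  expect_lt(sqrt((corner$x - planted$x)^2 + (corner$y - planted$y)^2),
            2 * fix_map()$resolution)
  expect_lt(sqrt((corner$x - 5.4)^2 + (corner$y - 5.8)^2),
            2 * fix_map()$resolution)
})

test_that("partition pieces tile each trajectory and recover bundles", {
  ens <- fix_ensemble()
  env <- fixture_world()
  sg <- find_subgoals(ens$trajectories, env)
  cands <- partition_by_subgoal(ens$trajectories, sg)

  # coverage: per trajectory, pieces tile the record without overlap
  idx <- do.call(rbind, lapply(cands, `[[`, "member_index"))
  for (ti in unique(idx$traj)) {
    segs <- idx[idx$traj == ti, ]
    segs <- segs[order(segs$t_start), ]
    s <- ens$trajectories[[ti]]$samples
    expect_equal(segs$t_start[1], s$t[1])
    expect_equal(segs$t_end[nrow(segs)], s$t[nrow(s)])
    if (nrow(segs) > 1)
      expect_true(all(diff(segs$t_start) > 0))
  }

  # four start bundles + the shared corner exit = five candidates
  expect_identical(length(cands), 5L)
  lab <- planted_labels_for(cands, planted_truth(ens))
  expect_equal(adjusted_rand(lab$candidate, lab$planted), 1)
})

test_that("single-subgoal worlds give one candidate", {
  env <- guidance_env(c(0, 0, 12, 8), list(), goal_spec(c(10, 4), 0.5))
  t <- seq(0, 9, by = 0.05)
  ens <- lapply(c(3.7, 3.9, 4.1, 4.3), function(y)
    data.frame(t = t, s_x = 1 + t, s_y = y, v = 1, psi = 0))
  sg <- find_subgoals(ens, env)
  cands <- partition_by_subgoal(ens, sg, course_split = pi)
  expect_identical(length(cands), 1L)
})

test_that("SE(2)-congruent candidates group; mirrored ones do not", {
  set.seed(9)
  base <- cbind(seq(0, 5, length.out = 50),
                sin(seq(0, 5, length.out = 50)) * 1.5)
  mk_cand <- function(P, label) {
    segs <- lapply(1:2, function(i)
      structure(list(states = data.frame(
        t = seq(0, 1, length.out = nrow(P)), s_x = P[, 1], s_y = P[, 2],
        v = 1, psi = 0), source_id = i, span = c(0, 1), length = 5),
        class = "ip_segment"))
    structure(list(members = segs, subgoal = data.frame(x = 0, y = 0),
                   approach_course = 0, label = label,
                   member_index = data.frame(traj = 1:2, t_start = 0,
                                             t_end = 1)),
              class = "candidate_ip")
  }
  copies <- lapply(1:4, function(i) {
    tf <- se2(runif(1, -pi, pi), runif(2, -5, 5))
    mk_cand(se2_apply(tf, base), sprintf("pi_%d", i - 1))
  })
  mirrored <- mk_cand(cbind(base[, 1], -base[, 2]), "pi_4")

  lib <- group_candidates(copies, threshold = 0.01)
  expect_identical(length(lib$ips), 1L)

  lib2 <- group_candidates(c(copies, list(mirrored)), threshold = 0.01)
  sizes <- sort(as.integer(table(lib2$classes)))
  expect_identical(sizes, c(1L, 4L))

  # zero threshold with noise: every candidate its own class
  noisy <- lapply(1:3, function(i)
    mk_cand(base + matrix(rnorm(100, 0, 0.01), ncol = 2),
            sprintf("pi_%d", i)))
  lib3 <- group_candidates(noisy, threshold = 0)
  expect_identical(length(lib3$ips), 3L)
})

test_that("grouping is invariant to input order and rigid motion", {
  ens <- fix_ensemble()
  env <- fixture_world()
  sg <- find_subgoals(ens$trajectories, env)
  cands <- partition_by_subgoal(ens$trajectories, sg)
  lib <- group_candidates(cands)
  perm <- rev(seq_along(cands))
  lib_r <- group_candidates(cands[perm])
  # same partition structure under reordering
  expect_identical(sort(as.integer(table(lib$classes))),
                   sort(as.integer(table(lib_r$classes))))

  # rigidly transforming every member leaves class sizes and residuals
  # unchanged
  tf <- se2(0.8, c(3, -2))
  cands_t <- lapply(cands, function(cd) {
    cd$members <- lapply(cd$members, function(m) {
      P <- se2_apply(tf, cbind(m$states$s_x, m$states$s_y))
      m$states$s_x <- P[, 1]; m$states$s_y <- P[, 2]
      m
    })
    cd
  })
  lib_t <- group_candidates(cands_t)
  expect_identical(lib$classes, lib_t$classes)
  expect_lt(max(abs(lib$residuals - lib_t$residuals)), 1e-6)
})
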