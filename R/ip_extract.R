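# Interaction-Pattern extraction from trajectory ensembles.
#
# Two equivalence relations drive the decomposition: subgoal equivalence
# (trajectory histories sharing identical futures from a common state —
# operationalized on finite noisy data as a merge-point criterion) and
# planar rigid-motion symmetry (segments that superimpose under an SE(2)
# element belong to the same pattern). Candidate IPs bundle the segments
# terminating at one subgoal region with a common approach course; the
# symmetry grouping then merges congruent candidates into the IP library.

#' Resample a trajectory span by arc length
#'
#' Returns `N` states equally spaced along the path, with speed and
#' course linearly interpolated (course via unwrapped angles). Equal
#' spatial spacing is what makes shape comparison by Procrustes
#' alignment meaningful.
#'
#' @param traj a `trajectory` (or a data.frame with `t, s_x, s_y, v, psi`).
#' @param span optional numeric length-2 time interval; default whole.
#' @param N number of output samples (>= 2).
#' @return An object of class `ip_segment`: list with `states` (a
#'   data.frame `t, s_x, s_y, v, psi`), `source_id`, `span`, `length`.
#' @export
resample_arclength <- function(traj, span = NULL, N = 50L) {
  s <- if (inherits(traj, "trajectory")) traj$samples else as.data.frame(traj)
  stopifnot(N >= 2L)
  if (!is.null(span)) {
    keep <- s$t >= span[1] - 1e-12 & s$t <= span[2] + 1e-12
    s <- s[keep, , drop = FALSE]
  }
  if (nrow(s) < 2L) stop("span covers fewer than 2 samples")
  dx <- diff(s$s_x); dy <- diff(s$s_y)
  seg <- sqrt(dx * dx + dy * dy)
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  if (L <= 0) stop("zero-length path cannot be resampled")
  # collapse duplicate arc positions for interpolation
  keep <- c(TRUE, diff(arc) > 0)
  arc_u <- arc[keep]
  at <- seq(0, L, length.out = N)
  interp <- function(y) stats::approx(arc_u, y[keep], xout = at,
                                      rule = 2)$y
  psi_un <- unwrap_angle(s$psi)
  states <- data.frame(
    t = interp(s$t),
    s_x = interp(s$s_x),
    s_y = interp(s$s_y),
    v = interp(s$v),
    psi = wrap_angle(interp(psi_un)))
  structure(list(states = states,
                 source_id = attr(traj, "id", exact = TRUE),
                 span = range(states$t), length = L),
            class = "ip_segment")
}

# cumulative unwrapping of a wrapped angle sequence
unwrap_angle <- function(a) {
  if (length(a) < 2L) return(a)
  a[1] + c(0, cumsum(wrap_angle(diff(a))))
}

#' Rigid SE(2) alignment of two equal-length segments (planar Procrustes)
#'
#' Closed-form rotation + translation (no scaling, no reflection)
#' minimizing the mean squared point distance from `a` to `b`; the
#' residual is the RMS distance after the transform. Degenerate inputs
#' (all points coincident) yield the identity rotation and centroid
#' translation.
#'
#' @param a,b `ip_segment` objects or n x 2 point matrices with equal n.
#' @return list with `transform` (an [se2()]) and `residual` (m).
#' @export
align_se2 <- function(a, b) {
  A <- segment_points(a); B <- segment_points(b)
  stopifnot(nrow(A) == nrow(B))
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sxx <- sum(Ac[, 1] * Bc[, 1] + Ac[, 2] * Bc[, 2])
  sxy <- sum(Ac[, 1] * Bc[, 2] - Ac[, 2] * Bc[, 1])
  theta <- if (sxx == 0 && sxy == 0) 0 else atan2(sxy, sxx)
  ct <- cos(theta); st <- sin(theta)
  t <- cb - c(ct * ca[1] - st * ca[2], st * ca[1] + ct * ca[2])
  tf <- se2(theta, t)
  resid <- sqrt(mean(rowSums((se2_apply(tf, A) - B)^2)))
  list(transform = tf, residual = resid)
}

segment_points <- function(x) {
  if (inherits(x, "ip_segment")) cbind(x$states$s_x, x$states$s_y)
  else as.matrix(x)
}

#' Discover subgoal regions from a trajectory ensemble
#'
#' Operationalizes subgoal equivalence: for every trajectory pair, the
#' earliest state after which the two paths coincide (within
#' `merge_dist`) for at least `merge_len` of arc length is a merge
#' state. Pairs that were never separated beforehand (duplicates,
#' repeated runs from one start) contribute nothing — their coincidence
#' is trivial, not a convergence event. Merge states are clustered
#' (complete linkage, cut at `cluster_radius`); clusters supported by at
#' least `min_support` merge events become subgoal regions. The goal is
#' always a region.
#'
#' @param ensemble list of `trajectory` objects (or sample data.frames).
#' @param env a [guidance_env()] (supplies the goal region).
#' @param merge_dist coincidence tolerance (m).
#' @param merge_len required coinciding arc length (m).
#' @param cluster_radius spatial clustering cutoff for merge states (m).
#' @param min_support minimum merge events per region.
#' @param spacing resampling step along paths for the pairwise test (m).
#' @return data.frame with columns `x`, `y`, `radius`, `support`,
#'   `is_goal`, one row per subgoal region (goal last).
#' @export
find_subgoals <- function(ensemble, env, merge_dist = 0.1, merge_len = 0.5,
                          cluster_radius = 0.5, min_support = 2L,
                          spacing = NULL) {
  if (is.null(spacing)) spacing <- merge_dist / 2
  paths <- lapply(ensemble, function(tr) {
    s <- if (inherits(tr, "trajectory")) tr$samples else as.data.frame(tr)
    resample_path(cbind(s$s_x, s$s_y), spacing)
  })
  merges <- list()
  n <- length(paths)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        m <- merge_state(paths[[i]], paths[[j]], merge_dist, merge_len,
                         spacing)
        if (!is.null(m)) merges[[length(merges) + 1L]] <- m
      }
    }
  }
  goal <- env$goal$position
  regions <- data.frame(x = goal[1], y = goal[2],
                        radius = max(cluster_radius, env$goal$pos_tol),
                        support = n, is_goal = TRUE)
  if (length(merges)) {
    M <- do.call(rbind, merges)
    # merge states near the goal belong to the goal region
    dg <- sqrt((M[, 1] - goal[1])^2 + (M[, 2] - goal[2])^2)
    M <- M[dg > cluster_radius, , drop = FALSE]
    if (nrow(M)) {
      cl <- if (nrow(M) == 1L) 1L else
        stats::cutree(stats::hclust(stats::dist(M), method = "complete"),
                      h = cluster_radius)
      for (k in sort(unique(cl))) {
        pts <- M[cl == k, , drop = FALSE]
        if (nrow(pts) < min_support) next
        ctr <- colMeans(pts)
        rad <- max(cluster_radius / 2,
                   max(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)))
        regions <- rbind(
          data.frame(x = ctr[1], y = ctr[2], radius = rad,
                     support = nrow(pts), is_goal = FALSE),
          regions)
      }
    }
  }
  rownames(regions) <- NULL
  regions
}

# resample a polyline to (approximately) uniform spacing
resample_path <- function(P, spacing) {
  seg <- sqrt(rowSums(diff(P)^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  if (L <= 0) return(P[1, , drop = FALSE])
  keep <- c(TRUE, diff(arc) > 0)
  at <- seq(0, L, by = spacing)
  if (at[length(at)] < L) at <- c(at, L)
  cbind(stats::approx(arc[keep], P[keep, 1], xout = at)$y,
        stats::approx(arc[keep], P[keep, 2], xout = at)$y)
}

# earliest merge state of path A onto path B, or NULL.
# Requires the pair to have been separated (> 2*merge_dist) before the
# merge; coincidence must persist for >= merge_len of arc length.
merge_state <- function(A, B, merge_dist, merge_len, spacing) {
  nA <- nrow(A)
  # min distance from each A sample to B's sample set
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  dmin <- sqrt(apply(d2, 1, min))
  run_need <- max(2L, ceiling(merge_len / spacing))
  close <- dmin <= merge_dist
  # earliest index where a run of `run_need` close samples starts and
  # coincidence persists to the end of A
  idx <- NA_integer_
  r <- rle(close)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= run_need && ends[k] == nA) {
      idx <- starts[k]
      break
    }
  }
  if (is.na(idx)) return(NULL)
  if (idx <= 1L) return(NULL)                       # never separated
  if (max(dmin[seq_len(idx - 1L)]) <= 2 * merge_dist) return(NULL)
  c(A[idx, 1], A[idx, 2])
}

#' Partition an ensemble into candidate Interaction Patterns
#'
#' Cuts every trajectory at its entries into subgoal regions; each
#' maximal inter-subgoal piece joins the candidate of its terminating
#' subgoal. Within one subgoal region, pieces are split into candidates
#' by approach course (complete-linkage clustering on angular distance,
#' cut at `course_split`). The pieces cover each trajectory without
#' overlap.
#'
#' @param ensemble list of `trajectory` objects.
#' @param subgoals data.frame from [find_subgoals()].
#' @param N resampling count per segment.
#' @param course_split angular cutoff (rad) separating approach bundles.
#' @param min_members candidates need at least this many segments.
#' @return list of candidates, class `candidate_ip`: each has `members`
#'   (list of `ip_segment`), `subgoal` (region row), `approach_course`,
#'   `label`, and `member_index` (data.frame `traj, t_start, t_end`).
#' @export
partition_by_subgoal <- function(ensemble, subgoals, N = 50L,
                                 course_split = pi / 6, min_members = 2L) {
  pieces <- list()
  for (ti in seq_along(ensemble)) {
    tr <- ensemble[[ti]]
    s <- if (inherits(tr, "trajectory")) tr$samples else as.data.frame(tr)
    cuts <- region_entries(s, subgoals)
    bounds <- c(1L, cuts$row + 1L)   # pieces tile the samples exactly once
    for (k in seq_len(nrow(cuts))) {
      i0 <- bounds[k]; i1 <- cuts$row[k]
      if (i1 - i0 < 2L) next
      piece <- s[i0:i1, , drop = FALSE]
      L <- sum(sqrt(diff(piece$s_x)^2 + diff(piece$s_y)^2))
      if (L <= 1e-9) next
      n2 <- nrow(piece)
      appr <- atan2(piece$s_y[n2] - piece$s_y[max(1L, n2 - 5L)],
                    piece$s_x[n2] - piece$s_x[max(1L, n2 - 5L)])
      pieces[[length(pieces) + 1L]] <- list(
        traj = ti, region = cuts$region[k], approach = appr,
        t_start = piece$t[1], t_end = piece$t[n2], data = piece)
    }
  }
  if (!length(pieces)) return(list())
  reg_ids <- vapply(pieces, `[[`, 0L, "region")
  out <- list()
  for (rg in sort(unique(reg_ids))) {
    ps <- pieces[reg_ids == rg]
    ang <- vapply(ps, `[[`, 0, "approach")
    cl <- cluster_angles(ang, course_split)
    for (g in sort(unique(cl))) {
      grp <- ps[cl == g]
      if (length(grp) < min_members) next
      members <- lapply(grp, function(p) {
        seg <- resample_arclength(p$data, N = N)
        seg$source_id <- p$traj
        seg
      })
      out[[length(out) + 1L]] <- structure(list(
        members = members,
        subgoal = subgoals[rg, ],
        approach_course = circ_mean(vapply(grp, `[[`, 0, "approach")),
        label = sprintf("pi_%d", length(out)),
        member_index = data.frame(
          traj = vapply(grp, `[[`, 0L, "traj"),
          t_start = vapply(grp, `[[`, 0, "t_start"),
          t_end = vapply(grp, `[[`, 0, "t_end"))),
        class = "candidate_ip")
    }
  }
  out
}

# first-entry rows of a trajectory into each subgoal region, in time order
region_entries <- function(s, subgoals) {
  rows <- integer(); regs <- integer()
  inside_prev <- rep(FALSE, nrow(subgoals))
  last_cut <- 1L
  for (i in seq_len(nrow(s))) {
    d <- sqrt((s$s_x[i] - subgoals$x)^2 + (s$s_y[i] - subgoals$y)^2)
    inside <- d <= subgoals$radius
    new_entry <- which(inside & !inside_prev)
    if (length(new_entry)) {
      rg <- new_entry[which.min(d[new_entry])]
      if (i - last_cut >= 2L) {
        rows <- c(rows, i); regs <- c(regs, rg)
        last_cut <- i
      }
    }
    inside_prev <- inside
  }
  if (!length(rows)) {
    # never entered a region: the whole record aims at the goal
    goal_rg <- which(subgoals$is_goal)[1]
    rows <- nrow(s); regs <- goal_rg
  } else if (rows[length(rows)] < nrow(s)) {
    # absorb the within-region tail into the final piece
    rows[length(rows)] <- nrow(s)
  }
  data.frame(row = rows, region = regs)
}

# complete-linkage clustering of angles under circular distance
cluster_angles <- function(a, cutoff) {
  n <- length(a)
  if (n == 1L) return(1L)
  D <- abs(wrap_angle(outer(a, a, "-")))
  stats::cutree(stats::hclust(stats::as.dist(D), method = "complete"),
                h = cutoff)
}

circ_mean <- function(a) atan2(mean(sin(a)), mean(cos(a)))

#' Group candidate IPs into an IP library by SE(2) congruence
#'
#' Each candidate's representative is the pointwise mean of its members
#' after alignment to the first member. Representatives are clustered by
#' complete linkage on pairwise [align_se2()] residuals and cut at
#' `threshold`; complete linkage guarantees the maximum within-class
#' residual stays below the cut. Reflection is not in SE(2), so mirrored
#' candidates stay in their own class. Ties are broken by candidate
#' label order (deterministic).
#'
#' @param cands list of `candidate_ip` from [partition_by_subgoal()].
#' @param threshold grouping residual cut (m); default 3 x the median
#'   within-candidate residual (scale-free w.r.t. noise level).
#' @return An object of class `ip_library`: list with `ips` (each a list
#'   of `candidate` indices, a `representative` point matrix, and
#'   per-member `transforms` into the representative frame), `classes`
#'   (integer class id per candidate), `residuals` (pairwise matrix),
#'   and `threshold`.
#' @export
group_candidates <- function(cands, threshold = NULL) {
  n <- length(cands)
  if (!n) stop("no candidates to group")
  reps <- vector("list", n)
  within <- numeric(n)
  for (i in seq_len(n)) {
    r <- candidate_representative(cands[[i]])
    reps[[i]] <- r$mean
    within[i] <- r$residual
  }
  if (is.null(threshold)) threshold <- 3 * stats::median(within)
  D <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        D[i, j] <- D[j, i] <- align_se2(reps[[i]], reps[[j]])$residual
      }
    }
  }
  classes <- if (n == 1L) 1L else
    stats::cutree(stats::hclust(stats::as.dist(D), method = "complete"),
                  h = threshold)
  ips <- lapply(sort(unique(classes)), function(k) {
    idx <- which(classes == k)
    ref <- reps[[idx[1]]]
    tfs <- lapply(idx, function(i) align_se2(reps[[i]], ref)$transform)
    list(candidates = idx, representative = ref, transforms = tfs)
  })
  structure(list(ips = ips, classes = classes, residuals = D,
                 threshold = threshold, within_residual = within,
                 labels = vapply(cands, `[[`, "", "label")),
            class = "ip_library")
}

# align members to the first member and average pointwise
candidate_representative <- function(cand) {
  pts <- lapply(cand$members, segment_points)
  ref <- pts[[1]]
  aligned <- lapply(pts, function(P) se2_apply(align_se2(P, ref)$transform, P))
  M <- Reduce(`+`, aligned) / length(aligned)
  resid <- sqrt(mean(vapply(aligned,
                            function(P) mean(rowSums((P - M)^2)), 0)))
  list(mean = M, residual = resid)
}

#' @export
print.ip_library <- function(x, ...) {
  sizes <- table(x$classes)
  cat(sprintf("<ip_library> %d candidate(s) in %d IP class(es); sizes: %s\n",
              length(x$classes), length(x$ips),
              paste(as.integer(sizes), collapse = ", ")))
  cat(sprintf("  grouping threshold %.4g m\n", x$threshold))
  invisible(x)
}
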