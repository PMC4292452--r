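# Planar environment representation and SE(2) rigid transforms.
#
# Conventions used throughout the package: world frame, meters, x east /
# y north, angles in radians measured CCW from +x; grids are cell-centered.
# Polygons are stored as counter-clockwise vertex matrices (n x 2, open
# ring: last vertex != first). Boundary points count as inside for
# collision queries (conservative), but a segment touching a vertex or
# edge tangentially is clear: wavefront paths hug obstacle corners.

#' Goal specification
#'
#' A goal state with position and terminal-speed tolerances. A trajectory
#' terminates successfully when it is within `pos_tol` of `position` with
#' speed below `speed_tol`.
#'
#' @param position numeric length-2, goal position (m).
#' @param pos_tol positive scalar, position tolerance (m).
#' @param speed_tol positive scalar, terminal speed tolerance (m/s).
#' @return An object of class `goal_spec`.
#' @export
goal_spec <- function(position, pos_tol = 0.2, speed_tol = 0.1) {
  position <- as.numeric(position)
  stopifnot(length(position) == 2L, is.finite(position),
            pos_tol > 0, speed_tol > 0)
  structure(list(position = position, pos_tol = pos_tol,
                 speed_tol = speed_tol), class = "goal_spec")
}

#' Planar guidance environment
#'
#' Axis-aligned workspace bounds, simple polygonal obstacles (CCW vertex
#' matrices), and a goal.
#'
#' @param bounds numeric length-4 `c(xmin, ymin, xmax, ymax)` (m).
#' @param obstacles list of n x 2 numeric matrices, one per polygon,
#'   vertices counter-clockwise, within bounds.
#' @param goal a [goal_spec()].
#' @return An object of class `guidance_env`.
#' @examples
#' env <- guidance_env(c(0, 0, 10, 8),
#'                     list(rect_obstacle(4, 3, 6, 5)),
#'                     goal_spec(c(9, 4)))
#' @export
guidance_env <- function(bounds, obstacles = list(), goal) {
  bounds <- as.numeric(bounds)
  stopifnot(length(bounds) == 4L, bounds[3] > bounds[1], bounds[4] > bounds[2],
            inherits(goal, "goal_spec"))
  obstacles <- lapply(obstacles, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    stopifnot(ncol(p) == 2L, nrow(p) >= 3L)
    if (polygon_area(p) < 0) p <- p[nrow(p):1, , drop = FALSE]  # enforce CCW
    if (!polygon_simple(p)) stop("obstacle polygon is self-intersecting")
    if (any(p[, 1] < bounds[1] | p[, 1] > bounds[3] |
            p[, 2] < bounds[2] | p[, 2] > bounds[4]))
      stop("obstacle outside workspace bounds")
    p
  })
  env <- structure(list(bounds = bounds, obstacles = obstacles, goal = goal),
                   class = "guidance_env")
  if (point_in_obstacle(goal$position, env))
    stop("goal position lies inside an obstacle")
  env
}

#' Axis-aligned rectangular obstacle
#'
#' @param xmin,ymin,xmax,ymax rectangle extent (m).
#' @return A 4 x 2 CCW vertex matrix.
#' @export
rect_obstacle <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' @export
print.guidance_env <- function(x, ...) {
  cat(sprintf("<guidance_env> bounds [%g, %g] x [%g, %g] m, %d obstacle(s)\n",
              x$bounds[1], x$bounds[3], x$bounds[2], x$bounds[4],
              length(x$obstacles)))
  cat(sprintf("  goal (%.2f, %.2f), pos tol %.2g m, speed tol %.2g m/s\n",
              x$goal$position[1], x$goal$position[2],
              x$goal$pos_tol, x$goal$speed_tol))
  invisible(x)
}

#' @export
plot.guidance_env <- function(x, add = FALSE, ...) {
  if (!add) {
    graphics::plot(NA, xlim = x$bounds[c(1, 3)], ylim = x$bounds[c(2, 4)],
                   asp = 1, xlab = "x (m)", ylab = "y (m)", ...)
  }
  for (p in x$obstacles)
    graphics::polygon(p[, 1], p[, 2], col = "grey70", border = "grey30")
  graphics::points(x$goal$position[1], x$goal$position[2], pch = 8, col = 2)
  invisible(x)
}

# signed area (> 0 for CCW rings)
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

# simple-polygon check: no two non-adjacent edges properly intersect
polygon_simple <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_properly_intersect(a[i, ], b[i, ], a[j, ], b[j, ]))
        return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

segments_properly_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(q1, q2, p1); d2 <- cross2(q1, q2, p2)
  d3 <- cross2(p1, p2, q1); d4 <- cross2(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Point-in-polygon classification
#'
#' Even-odd rule. Returns `"inside"`, `"boundary"`, or `"outside"`.
#' @param pt length-2 point.
#' @param poly n x 2 vertex matrix.
#' @param tol boundary tolerance (m).
#' @keywords internal
point_in_polygon <- function(pt, poly, tol = 1e-12) {
  n <- nrow(poly)
  x <- pt[1]; y <- pt[2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge test
    ex <- xj - xi; ey <- yj - yi
    len2 <- ex * ex + ey * ey
    if (len2 > 0) {
      t <- ((x - xi) * ex + (y - yi) * ey) / len2
      t <- min(1, max(0, t))
      dx <- x - (xi + t * ex); dy <- y - (yi + t * ey)
      if (dx * dx + dy * dy <= tol * tol) return("boundary")
    }
    if ((yi > y) != (yj > y)) {
      xint <- xi + (y - yi) / (yj - yi) * (xj - xi)
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  if (inside) "inside" else "outside"
}

#' Is a point inside (or on the boundary of) any obstacle?
#'
#' Boundary points count as inside: collision checks are conservative.
#' @param pt length-2 point.
#' @param env a [guidance_env()].
#' @param tol boundary tolerance (m).
#' @return logical scalar.
#' @export
point_in_obstacle <- function(pt, env, tol = 1e-9) {
  for (p in env$obstacles)
    if (point_in_polygon(pt, p, tol) != "outside") return(TRUE)
  FALSE
}

# strict-interior test (boundary excluded), used by segment_clear midpoints
point_strictly_inside <- function(pt, env, tol = 1e-9) {
  for (p in env$obstacles)
    if (point_in_polygon(pt, p, tol) == "inside") return(TRUE)
  FALSE
}

#' Segment clearance test
#'
#' `TRUE` iff the open segment from `p` to `q` intersects no obstacle
#' interior. Tangential contact (the segment grazing a vertex or running
#' along an edge) counts as clear; zero-length segments are clear by
#' definition. Symmetric in `p`, `q`.
#'
#' The test collects all intersection parameters of the segment with
#' obstacle edges and probes the strict interior at midpoints between
#' consecutive parameters, which is robust for corner-grazing paths.
#'
#' @param p,q length-2 endpoints (m).
#' @param env a [guidance_env()].
#' @return logical scalar.
#' @export
segment_clear <- function(p, q, env) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (all(p == q)) return(TRUE)
  ts <- c(0, 1)
  d <- q - p
  for (poly in env$obstacles) {
    n <- nrow(poly)
    j <- c(2:n, 1L)
    for (i in seq_len(n)) {
      a <- poly[i, ]; b <- poly[j[i], ]
      e <- b - a
      denom <- d[1] * e[2] - d[2] * e[1]
      if (abs(denom) > 1e-14) {
        t <- ((a[1] - p[1]) * e[2] - (a[2] - p[2]) * e[1]) / denom
        s <- ((a[1] - p[1]) * d[2] - (a[2] - p[2]) * d[1]) / denom
        if (t > -1e-12 && t < 1 + 1e-12 && s > -1e-12 && s < 1 + 1e-12)
          ts <- c(ts, min(1, max(0, t)))
      } else {
        # parallel: if collinear, the endpoints' projections bound overlap
        if (abs(cross2(a, b, p)) < 1e-12) {
          for (v in list(a, b)) {
            t <- sum((v - p) * d) / sum(d * d)
            if (t > 0 && t < 1) ts <- c(ts, t)
          }
        }
      }
    }
  }
  ts <- sort(unique(ts))
  mids <- (ts[-length(ts)] + ts[-1]) / 2
  for (t in mids) {
    m <- p + t * d
    if (point_strictly_inside(m, env)) return(FALSE)
  }
  TRUE
}

#' Occluding obstacle vertices seen from a point
#'
#' Returns obstacle vertices that are visible from `source` and locally
#' occluding: both incident edges lie on one side of the source-to-vertex
#' ray, so the vertex casts a visibility shadow. These are the wavefront
#' planner's candidate subgoal seeds. A neighbor collinear with the ray
#' counts as same-side (deterministic tie-break).
#'
#' @param env a [guidance_env()].
#' @param source length-2 viewpoint, outside all obstacles.
#' @return data.frame with columns `x`, `y`, `convex`, `obstacle`, `vertex`.
#' @export
occluding_vertices <- function(env, source) {
  source <- as.numeric(source)
  if (point_strictly_inside(source, env))
    stop("source lies inside an obstacle")
  out <- list()
  for (oi in seq_along(env$obstacles)) {
    poly <- env$obstacles[[oi]]
    n <- nrow(poly)
    for (vi in seq_len(n)) {
      v <- poly[vi, ]
      if (sum((v - source)^2) < 1e-18) next
      if (!segment_clear(source, v, env)) next
      prev <- poly[if (vi == 1L) n else vi - 1L, ]
      nxt  <- poly[if (vi == n) 1L else vi + 1L, ]
      s_prev <- cross2(source, v, prev)
      s_next <- cross2(source, v, nxt)
      # same side (collinear counts as same side on either sign)
      occl <- (s_prev >= 0 && s_next >= 0) || (s_prev <= 0 && s_next <= 0)
      if (!occl) next
      # convex corner of a CCW ring: left turn at v
      convex <- cross2(prev, v, nxt) > 0
      out[[length(out) + 1L]] <-
        data.frame(x = v[1], y = v[2], convex = convex,
                   obstacle = oi, vertex = vi)
    }
  }
  if (!length(out))
    return(data.frame(x = numeric(), y = numeric(), convex = logical(),
                      obstacle = integer(), vertex = integer()))
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# SE(2) rigid transforms

#' SE(2) rigid transform
#'
#' Rotation by `theta` (rad, CCW) followed by translation `t` (m). SE(2)
#' is the symmetry group of the planar vehicle: trajectories that
#' superimpose under an SE(2) element express the same guidance behavior.
#'
#' @param theta rotation angle (rad).
#' @param t numeric length-2 translation (m).
#' @return An object of class `se2`.
#' @export
se2 <- function(theta = 0, t = c(0, 0)) {
  stopifnot(is.finite(theta), length(t) == 2L, is.finite(t))
  structure(list(theta = wrap_angle(theta), t = as.numeric(t)), class = "se2")
}

#' @rdname se2
#' @export
se2_identity <- function() se2(0, c(0, 0))

#' @export
print.se2 <- function(x, ...) {
  cat(sprintf("<se2> theta = %.6g rad, t = (%.6g, %.6g)\n",
              x$theta, x$t[1], x$t[2]))
  invisible(x)
}

#' Apply an SE(2) transform to points
#'
#' @param tf an [se2()] transform.
#' @param pts n x 2 matrix (or length-2 vector) of points.
#' @return n x 2 matrix of transformed points.
#' @export
se2_apply <- function(tf, pts) {
  stopifnot(inherits(tf, "se2"))
  if (is.null(dim(pts))) pts <- matrix(as.numeric(pts), ncol = 2L)
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 2L, nrow(pts) >= 1L)
  ct <- cos(tf$theta); st <- sin(tf$theta)
  cbind(ct * pts[, 1] - st * pts[, 2] + tf$t[1],
        st * pts[, 1] + ct * pts[, 2] + tf$t[2])
}

#' Compose two SE(2) transforms
#'
#' `se2_compose(a, b)` is the transform applying `b` first, then `a`.
#' @param a,b [se2()] transforms.
#' @return An [se2()] transform.
#' @export
se2_compose <- function(a, b) {
  stopifnot(inherits(a, "se2"), inherits(b, "se2"))
  ct <- cos(a$theta); st <- sin(a$theta)
  se2(a$theta + b$theta,
      c(ct * b$t[1] - st * b$t[2] + a$t[1],
        st * b$t[1] + ct * b$t[2] + a$t[2]))
}

#' Invert an SE(2) transform
#' @param tf an [se2()] transform.
#' @return The inverse transform.
#' @export
se2_inverse <- function(tf) {
  stopifnot(inherits(tf, "se2"))
  ct <- cos(tf$theta); st <- sin(tf$theta)
  se2(-tf$theta, c(-(ct * tf$t[1] + st * tf$t[2]),
                   -(-st * tf$t[1] + ct * tf$t[2])))
}

#' Wrap an angle to (-pi, pi]
#' @param a angle(s) in radians.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
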