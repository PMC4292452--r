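# Time-to-go (TTG) learning.
#
# The behavior inside an Interaction Pattern is abstracted by a TTG
# function: the remaining time to subgoal arrival as a function of the
# state expressed in the subgoal-centered frame (rotated so the approach
# course is +x). Working in that frame makes the learned function
# SE(2)-invariant by construction, which is what lets the wavefront
# planner reuse it at every spawned subgoal. The fit is linear in
# parameters over a small feature basis, with features entering by
# forward stepwise selection under k-fold cross-validation.

#' Empirical time-to-go samples from a segment
#'
#' For each state along the segment the label is the remaining time to
#' segment end (0 at the end, strictly decreasing along the segment).
#' Features are computed in the subgoal-centered frame:
#' \describe{
#'   \item{d}{distance to the subgoal (m)}
#'   \item{beta}{bearing-to-subgoal error: angle between the current
#'     course and the bearing to the subgoal (rad, wrapped)}
#'   \item{v}{speed (m/s)}
#'   \item{kappa}{path curvature (1/m, finite differences)}
#'   \item{dpsi_togo}{total heading change remaining to segment end (rad)}
#' }
#'
#' @param seg an `ip_segment` (from [resample_arclength()]) or a
#'   data.frame with `t, s_x, s_y, v, psi`.
#' @param subgoal length-2 subgoal position; default the segment's last
#'   point.
#' @return data.frame of features plus the `ttg` label column (s).
#' @export
empirical_ttg <- function(seg, subgoal = NULL) {
  s <- if (inherits(seg, "ip_segment")) seg$states else as.data.frame(seg)
  n <- nrow(s)
  stopifnot(n >= 2L)
  if (is.null(subgoal)) subgoal <- c(s$s_x[n], s$s_y[n])
  dx <- subgoal[1] - s$s_x
  dy <- subgoal[2] - s$s_y
  d <- sqrt(dx * dx + dy * dy)
  bearing <- atan2(dy, dx)
  beta <- wrap_angle(bearing - s$psi)
  beta[d < 1e-9] <- 0
  psi_un <- unwrap_angle(s$psi)
  # curvature = dpsi/ds along the path
  ds <- sqrt(diff(s$s_x)^2 + diff(s$s_y)^2)
  kappa <- c(0, diff(psi_un) / pmax(ds, 1e-9))
  data.frame(d = d, beta = beta, v = s$v, kappa = kappa,
             dpsi_togo = psi_un[n] - psi_un,
             ttg = s$t[n] - s$t)
}

# feature basis: linear-in-parameters terms over the raw features.
ttg_basis <- function(X, terms = NULL) {
  full <- data.frame(
    d = X$d,
    beta = X$beta,
    abs_beta = abs(X$beta),
    v = X$v,
    kappa = X$kappa,
    d_abs_beta = X$d * abs(X$beta),
    beta2 = X$beta^2)
  if (!is.null(X$dpsi_togo)) full$abs_dpsi_togo <- abs(X$dpsi_togo)
  if (is.null(terms)) full else full[, terms, drop = FALSE]
}

#' Fit a time-to-go function by forward stepwise selection
#'
#' Builds TTG samples (if given segments) and fits a linear-in-parameters
#' model over the term basis `{d, beta, |beta|, v, kappa, d|beta|,
#' beta^2, |dpsi_togo|}`. Terms enter one at a time, each step adding the
#' term that minimizes k-fold cross-validated RMSE; selection stops when
#' the relative CV improvement drops below `stop_tol`. The final
#' coefficients are refit on all data. Folds are seeded, so a fixed seed
#' gives an identical selected set.
#'
#' @param samples data.frame from [empirical_ttg()] (or an rbind of
#'   several), containing the feature columns and a `ttg` label.
#' @param k_folds number of CV folds.
#' @param stop_tol relative CV-RMSE improvement below which selection
#'   stops.
#' @param max_terms cap on selected terms.
#' @param min_samples minimum rows required.
#' @param seed integer seed for the fold assignment.
#' @return An object of class `ttg`: coefficients, `selected_features`,
#'   `cv_rmse` (s), the training `domain` (max `d`, max `|beta|`), and
#'   fit diagnostics. Supports `print`, `summary`, `coef`, `predict`,
#'   and `plot` (level sets).
#' @examples
#' s <- data.frame(d = runif(200, 0, 10), beta = 0, v = 1, kappa = 0,
#'                 dpsi_togo = 0)
#' s$ttg <- s$d / s$v
#' f <- fit_ttg(s, seed = 1)
#' predict(f, data.frame(d = 2, beta = 0, v = 1, kappa = 0))
#' @export
fit_ttg <- function(samples, k_folds = 5L, stop_tol = 0.01,
                    max_terms = 5L, min_samples = 20L, seed = 1L) {
  samples <- as.data.frame(samples)
  stopifnot("ttg" %in% names(samples), nrow(samples) >= min_samples)
  y <- samples$ttg
  B <- ttg_basis(samples)
  n <- nrow(B)
  # drop constant / duplicated columns (rank safety)
  keepc <- vapply(B, function(col) stats::sd(col) > 1e-12, TRUE)
  B <- B[, keepc, drop = FALSE]
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  cv_rmse_for <- function(terms) {
    errs <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      Xtr <- as.matrix(cbind(1, B[tr, terms, drop = FALSE]))
      fit <- tryCatch(stats::lm.fit(Xtr, y[tr]), error = function(e) NULL)
      if (is.null(fit)) return(Inf)
      beta_hat <- fit$coefficients
      beta_hat[is.na(beta_hat)] <- 0
      Xte <- as.matrix(cbind(1, B[!tr, terms, drop = FALSE]))
      errs[f] <- sqrt(mean((Xte %*% beta_hat - y[!tr])^2))
    }
    mean(errs)
  }
  selected <- character()
  best_rmse <- cv_rmse_for(selected)   # intercept-only baseline
  repeat {
    if (length(selected) >= min(max_terms, ncol(B))) break
    cand <- setdiff(names(B), selected)
    rmses <- vapply(cand, function(tm) cv_rmse_for(c(selected, tm)), 0)
    bi <- which.min(rmses)
    if (!is.finite(rmses[bi])) break
    rel_impr <- (best_rmse - rmses[bi]) / max(best_rmse, 1e-12)
    if (rel_impr < stop_tol) break
    selected <- c(selected, cand[bi])
    best_rmse <- rmses[bi]
  }
  X <- as.matrix(cbind(`(intercept)` = 1, B[, selected, drop = FALSE]))
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    warning("rank-deficient design; dropping aliased term(s)")
    drop_t <- setdiff(names(coefs)[is.na(coefs)], "(intercept)")
    selected <- setdiff(selected, drop_t)
    X <- as.matrix(cbind(`(intercept)` = 1, B[, selected, drop = FALSE]))
    fit <- stats::lm.fit(X, y)
    coefs <- fit$coefficients
  }
  names(coefs)[1] <- "(intercept)"
  structure(list(
    coefficients = coefs,
    selected_features = selected,
    cv_rmse = best_rmse,
    domain = list(d_max = max(samples$d),
                  beta_max = max(abs(samples$beta))),
    n_samples = n,
    sigma = sqrt(mean(fit$residuals^2)),
    kind = "fitted"),
    class = "ttg")
}

#' Uniform-motion time-to-go function
#'
#' The closed-form TTG at constant speed: `ttg = d / speed`, with an
#' unbounded domain. Useful as the planner's baseline abstraction and in
#' oracle comparisons.
#'
#' @param speed constant speed (m/s).
#' @return An object of class `ttg`.
#' @export
ttg_uniform <- function(speed) {
  stopifnot(speed > 0)
  structure(list(
    coefficients = c(`(intercept)` = 0, d = 1 / speed),
    selected_features = "d",
    cv_rmse = 0,
    domain = list(d_max = Inf, beta_max = pi),
    n_samples = 0L, sigma = 0, kind = "uniform"),
    class = "ttg")
}

#' Evaluate a time-to-go function
#'
#' Predictions are clamped at zero and are exactly zero at zero gap.
#' States outside the training domain are still evaluated but flagged in
#' the `"extrapolated"` attribute.
#'
#' @param object a `ttg` fit.
#' @param newdata data.frame with at least `d`; missing feature columns
#'   default to 0 (`v` to its training-free default 0).
#' @param ... unused.
#' @return numeric vector of non-negative times (s), with attribute
#'   `extrapolated` (logical vector).
#' @export
predict.ttg <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  for (nm in c("d", "beta", "v", "kappa", "dpsi_togo"))
    if (is.null(newdata[[nm]])) newdata[[nm]] <- 0
  B <- ttg_basis(newdata, object$selected_features)
  X <- as.matrix(cbind(1, B))
  out <- as.numeric(X %*% object$coefficients)
  out <- pmax(0, out)
  out[newdata$d <= 1e-12] <- 0
  attr(out, "extrapolated") <-
    newdata$d > object$domain$d_max |
    abs(newdata$beta) > object$domain$beta_max
  out
}

#' @export
coef.ttg <- function(object, ...) object$coefficients

#' @export
print.ttg <- function(x, ...) {
  cat(sprintf("<ttg> %s; terms: %s\n", x$kind,
              if (length(x$selected_features))
                paste(x$selected_features, collapse = " + ")
              else "(intercept only)"))
  cat(sprintf("  cv RMSE %.4g s over %d samples; domain d <= %.3g m, |beta| <= %.3g rad\n",
              x$cv_rmse, x$n_samples, x$domain$d_max, x$domain$beta_max))
  invisible(x)
}

#' @export
summary.ttg <- function(object, ...) {
  print(object)
  cat("  coefficients:\n")
  print(object$coefficients)
  invisible(object)
}

#' Level sets of a learned TTG function in the subgoal frame
#'
#' Draws iso-TTG contours over the (x, y) subgoal-centered plane,
#' evaluating the fit with the course pointed at the subgoal plus the
#' local bearing error implied by the position. The dashed boundary
#' marks the training domain.
#'
#' @param x a `ttg` fit.
#' @param v speed at which to evaluate (m/s).
#' @param r_max plot radius (m); default the domain's `d_max` (or 10).
#' @param n grid resolution.
#' @param ... passed to [graphics::contour()].
#' @export
plot.ttg <- function(x, v = 1, r_max = NULL, n = 101L, ...) {
  if (is.null(r_max))
    r_max <- if (is.finite(x$domain$d_max)) x$domain$d_max else 10
  xs <- seq(-r_max, 0.2 * r_max, length.out = n)
  ys <- seq(-0.6 * r_max, 0.6 * r_max, length.out = n)
  g <- expand.grid(px = xs, py = ys)
  d <- sqrt(g$px^2 + g$py^2)
  # course assumed along +x (the approach course); bearing error follows
  beta <- wrap_angle(atan2(-g$py, -g$px) - 0)
  z <- predict(x, data.frame(d = d, beta = beta, v = v, kappa = 0))
  graphics::contour(xs, ys, matrix(z, n, n), asp = 1,
                    xlab = "x (subgoal frame, m)", ylab = "y (m)", ...)
  graphics::points(0, 0, pch = 8, col = 2)
  if (is.finite(x$domain$d_max)) {
    th <- seq(0, 2 * pi, length.out = 181)
    graphics::lines(x$domain$d_max * cos(th), x$domain$d_max * sin(th),
                    lty = 2, col = "grey40")
  }
  invisible(x)
}
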