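# Readers/writers for the package's file dialects and the subcommand CLI.
#
# Dialects: trajectory CSV (t,s_x,s_y,v,psi,a_t,a_n,subgoal_idx; header
# mandatory; one run per file), environment JSON/YAML, gaze CSV, TTG
# function JSON, TTG map as value/parent CSV grids + subgoal JSON.

#' Write / read a trajectory CSV
#'
#' Columns `t, s_x, s_y, v, psi, a_t, a_n, subgoal_idx`; numeric
#' columns are serialized at 12 significant digits so a write/read round
#' trip is lossless at 1e-9.
#'
#' @param traj a `trajectory`.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  s <- traj$samples
  for (nm in c("t", "s_x", "s_y", "v", "psi", "a_t", "a_n"))
    s[[nm]] <- signif(s[[nm]], 12)
  utils::write.csv(s, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory()` returns a `trajectory` (status fields
#'   unknown, set to `"loaded"`).
#' @export
read_trajectory <- function(path) {
  s <- utils::read.csv(path)
  need <- c("t", "s_x", "s_y", "v", "psi", "a_t", "a_n", "subgoal_idx")
  missing <- setdiff(need, names(s))
  if (length(missing))
    stop(sprintf("trajectory CSV lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  if (nrow(s)) {
    bad <- which(diff(s$t) <= 0)
    if (length(bad))
      stop(sprintf("non-monotone time at row %d of %s", bad[1] + 1L, path))
    if (!all(is.finite(as.matrix(s[need[1:7]]))))
      stop(sprintf("non-finite values in %s", path))
  }
  structure(list(samples = s, status = "loaded", collided = NA,
                 plan = NULL, params = NULL), class = "trajectory")
}

#' Read all trajectory CSVs in a directory
#' @param dir directory containing `*.csv` trajectory files.
#' @return list of `trajectory` objects (possibly empty, with a warning).
#' @export
read_trajectories <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) {
    warning("no trajectory CSV files found")
    return(list())
  }
  out <- lapply(files, read_trajectory)
  for (i in seq_along(out)) attr(out[[i]], "id") <- i
  out
}

#' Write / read an environment as JSON (or YAML)
#'
#' Schema: `{bounds:[xmin,ymin,xmax,ymax], obstacles:[[[x,y],...],...],
#' goal:{position:[x,y], pos_tol, speed_tol}}`.
#'
#' @param env a [guidance_env()].
#' @param path file path; `.yaml`/`.yml` selects YAML.
#' @export
write_environment <- function(env, path) {
  obj <- list(bounds = env$bounds,
              obstacles = lapply(env$obstacles, function(p)
                lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))),
              goal = list(position = env$goal$position,
                          pos_tol = env$goal$pos_tol,
                          speed_tol = env$goal$speed_tol))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  obj$bounds <- unlist(obj$bounds)
  obj$goal <- lapply(obj$goal, unlist)
  obstacles <- lapply(obj$obstacles, function(p) {
    if (is.matrix(p)) p else do.call(rbind, lapply(p, unlist))
  })
  guidance_env(as.numeric(obj$bounds), obstacles,
               goal_spec(as.numeric(obj$goal$position),
                         obj$goal$pos_tol, obj$goal$speed_tol))
}

#' Write / read a TTG function as JSON
#' @param ttg a `ttg`.
#' @param path file path.
#' @export
write_ttg <- function(ttg, path) {
  jsonlite::write_json(list(
    coefficients = as.list(ttg$coefficients),
    selected_features = ttg$selected_features,
    cv_rmse = ttg$cv_rmse, domain = ttg$domain,
    n_samples = ttg$n_samples, sigma = ttg$sigma, kind = ttg$kind),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ttg
#' @export
read_ttg <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    coefficients = unlist(obj$coefficients),
    selected_features = as.character(obj$selected_features),
    cv_rmse = obj$cv_rmse,
    domain = list(d_max = as.numeric(obj$domain$d_max),
                  beta_max = as.numeric(obj$domain$beta_max)),
    n_samples = obj$n_samples, sigma = obj$sigma, kind = obj$kind),
    class = "ttg")
}

#' Write a gaze stream CSV
#' @param stream gaze sample data.frame (see [make_gaze()]).
#' @param path file path.
#' @export
write_gaze <- function(stream, path) {
  s <- stream
  for (nm in setdiff(names(s), "valid")) s[[nm]] <- signif(s[[nm]], 12)
  utils::write.csv(s, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  s <- utils::read.csv(path)
  need <- c("t", "hx", "hy", "hz", "qw", "qx", "qy", "qz",
            "gx", "gy", "gz", "valid")
  missing <- setdiff(need, names(s))
  if (length(missing))
    stop(sprintf("gaze CSV lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  s
}

#' Write a TTG map (values + parent grids as CSV, subgoals as JSON)
#' @param map a `ttg_map`.
#' @param dir output directory (created if needed).
#' @export
write_ttg_map <- function(map, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(map$values, file.path(dir, "values.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(map$parent, file.path(dir, "parent.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(subgoals = map$subgoals, xs = map$xs,
                            ys = map$ys, resolution = map$resolution),
                       file.path(dir, "map.json"), digits = NA,
                       dataframe = "columns")
  invisible(dir)
}

# -------------------------------------------------------------------------
# adjusted Rand index between two labelings (closed form over the
# pair-count contingency table); cross-checked against mclust in tests
#' Adjusted Rand index
#' @param a,b two label vectors of equal length.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# -------------------------------------------------------------------------
# CLI

cli_usage <- function() {
  paste(
    "usage: ipguidance <subcommand> [options]",
    "",
    "subcommands:",
    "  make-fixtures    --seed S --out DIR [--reps N]",
    "  simulate         --env FILE --start 'x,y' --out FILE [--seed S]",
    "  extract-ip       --env FILE --traj DIR --out DIR",
    "  learn-ttg        --traj DIR --out FILE [--seed S]",
    "  plan             --env FILE --ttg FILE --out DIR [--resolution R]",
    "  classify-gaze    --gaze FILE --traj FILE --out FILE",
    "  attention-report --gaze FILE --traj FILE --env FILE --out FILE",
    sep = "\n")
}

cli_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(argv) && !grepl("^--", argv[i + 1L])) {
        opts[[key]] <- argv[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      opts$.positional <- c(opts$.positional, a)
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package's functions; the
#' `inst/cli/ipguidance` Rscript forwards `commandArgs()` here. Returns
#' (rather than calls `quit()` with) the exit status so it is testable
#' in-process: 0 on success, 1 on processing errors, 2 on usage errors.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
ip_cli <- function(argv = character()) {
  if (!length(argv) || argv[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(if (!length(argv)) 2L else 0L))
  }
  cmd <- argv[1]
  opts <- cli_args(argv[-1])
  if (isTRUE(opts$help)) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  seed <- as.integer(opts$seed %||% 1L)
  res <- tryCatch({
    switch(cmd,
      "make-fixtures" = cli_make_fixtures(opts, seed),
      "simulate" = cli_simulate(opts, seed),
      "extract-ip" = cli_extract(opts),
      "learn-ttg" = cli_learn_ttg(opts, seed),
      "plan" = cli_plan(opts),
      "classify-gaze" = cli_classify(opts),
      "attention-report" = cli_attention(opts),
      {
        message("unknown subcommand: ", cmd, "\n", cli_usage())
        return(invisible(2L))
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_need <- function(opts, keys) {
  miss <- keys[!keys %in% names(opts)]
  if (length(miss))
    stop(sprintf("missing option(s): %s",
                 paste(paste0("--", miss), collapse = ", ")))
}

cli_make_fixtures <- function(opts, seed) {
  cli_need(opts, "out")
  out <- opts$out
  dir.create(file.path(out, "trajectories"), recursive = TRUE,
             showWarnings = FALSE)
  env <- fixture_world()
  write_environment(env, file.path(out, "env.json"))
  ens <- make_ensemble(env, seed = seed,
                       reps = as.integer(opts$reps %||% 3L))
  for (i in seq_along(ens$trajectories))
    write_trajectory(ens$trajectories[[i]],
                     file.path(out, "trajectories",
                               sprintf("run_%03d.csv", i)))
  utils::write.csv(ens$labels, file.path(out, "labels.csv"),
                   row.names = FALSE)
  # gaze stream for the first successful run
  ok <- which(vapply(ens$trajectories, function(tr)
    tr$status == "success", TRUE))
  if (length(ok)) {
    tr <- ens$trajectories[[ok[1]]]
    gz <- make_gaze(tr, tr$plan, seed = seed)
    write_gaze(gz$stream, file.path(out, "gaze.csv"))
    utils::write.csv(gz$events, file.path(out, "gaze_events_truth.csv"),
                     row.names = FALSE)
    write_trajectory(tr, file.path(out, "gaze_run.csv"))
    jsonlite::write_json(list(subgoals = tr$plan$subgoals),
                         file.path(out, "gaze_plan.json"), digits = NA)
  }
  message(sprintf("fixtures written to %s (%d trajectories)",
                  out, length(ens$trajectories)))
}

cli_simulate <- function(opts, seed) {
  cli_need(opts, c("env", "start", "out"))
  env <- read_environment(opts$env)
  st <- as.numeric(strsplit(opts$start, ",")[[1]])
  map <- propagate_wavefront(env, ttg_uniform(guidance_params()$cruise_speed))
  plan <- subgoal_sequence(map, st)
  course0 <- atan2(plan$subgoals[1, 2] - st[2], plan$subgoals[1, 1] - st[1])
  tr <- simulate_guidance(env, plan, agent_state(0, st[1], st[2], 0, course0))
  write_trajectory(tr, opts$out)
  message(sprintf("simulated %s run (%.1f s) -> %s",
                  tr$status, max(tr$samples$t), opts$out))
}

cli_extract <- function(opts) {
  cli_need(opts, c("env", "traj", "out"))
  env <- read_environment(opts$env)
  trajs <- read_trajectories(opts$traj)
  sg <- find_subgoals(trajs, env)
  cands <- partition_by_subgoal(trajs, sg)
  lib <- group_candidates(cands)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sg, file.path(opts$out, "subgoals.csv"),
                   row.names = FALSE)
  utils::write.csv(lib$residuals, file.path(opts$out, "residuals.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    classes = lib$classes, labels = lib$labels, threshold = lib$threshold,
    candidates = lapply(cands, function(cd) list(
      label = cd$label,
      subgoal = c(cd$subgoal$x, cd$subgoal$y),
      approach_course = cd$approach_course,
      members = cd$member_index))),
    file.path(opts$out, "ip_library.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  message(sprintf("%d subgoal region(s), %d candidate(s), %d IP class(es)",
                  nrow(sg), length(cands), length(lib$ips)))
}

cli_learn_ttg <- function(opts, seed) {
  cli_need(opts, c("traj", "out"))
  trajs <- read_trajectories(opts$traj)
  if (!length(trajs)) stop("no trajectories to learn from")
  samples <- do.call(rbind, lapply(trajs, function(tr)
    empirical_ttg(resample_arclength(tr, N = 80L))))
  fit <- fit_ttg(samples, seed = seed)
  write_ttg(fit, opts$out)
  message(sprintf("ttg fit: %s (cv RMSE %.3g s) -> %s",
                  paste(fit$selected_features, collapse = " + "),
                  fit$cv_rmse, opts$out))
}

cli_plan <- function(opts) {
  cli_need(opts, c("env", "ttg", "out"))
  env <- read_environment(opts$env)
  ttg <- read_ttg(opts$ttg)
  res <- if (is.null(opts$resolution)) NULL else as.numeric(opts$resolution)
  map <- propagate_wavefront(env, ttg, resolution = res)
  write_ttg_map(map, opts$out)
  if (isTRUE(opts$plot)) {
    grDevices::png(file.path(opts$out, "ttg_map.png"), 900, 600)
    plot(map)
    grDevices::dev.off()
  }
  message(sprintf("map %d x %d, %d subgoal(s) -> %s",
                  nrow(map$values), ncol(map$values), nrow(map$subgoals),
                  opts$out))
}

cli_classify <- function(opts) {
  cli_need(opts, c("gaze", "traj", "out"))
  stream <- read_gaze(opts$gaze)
  helo <- read_trajectory(opts$traj)
  ev <- classify_gaze(stream, helo)
  out <- ev
  attr(out, "samples") <- NULL
  utils::write.csv(out, opts$out, row.names = FALSE)
  message(sprintf("%d events (%d fixation, %d saccade, %d pursuit) -> %s",
                  nrow(ev), sum(ev$kind == "fixation"),
                  sum(ev$kind == "saccade"),
                  sum(ev$kind == "smooth_pursuit"), opts$out))
}

cli_attention <- function(opts) {
  cli_need(opts, c("gaze", "traj", "env", "out"))
  stream <- read_gaze(opts$gaze)
  helo <- read_trajectory(opts$traj)
  env <- read_environment(opts$env)
  ev <- classify_gaze(stream, helo)
  plan_file <- opts$plan %||% file.path(dirname(opts$gaze), "gaze_plan.json")
  plan <- if (file.exists(plan_file)) {
    sg <- jsonlite::read_json(plan_file, simplifyVector = TRUE)$subgoals
    subgoal_plan(sg, env$goal)
  } else {
    subgoal_plan(rbind(env$goal$position), env$goal)
  }
  rep <- attention_metrics(ev, helo, plan)
  jsonlite::write_json(unclass(rep)[c("pursuit_fraction",
                                      "pursuit_vehicle_coincidence",
                                      "fixation_subgoal_overlap",
                                      "anticipatory_saccade_count",
                                      "mean_lead_time")],
                       opts$out, auto_unbox = TRUE, digits = NA)
  print(rep)
}
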