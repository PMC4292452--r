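# Shared, lazily-built fixtures (expensive artifacts built once per run).

.fix_cache <- new.env(parent = emptyenv())

fix_get <- function(name, build) {
  if (!exists(name, envir = .fix_cache)) {
    assign(name, build(), envir = .fix_cache)
  }
  get(name, envir = .fix_cache)
}

fix_env <- function() fixture_world()

fix_ensemble <- function(seed = 3L, reps = 2L) {
  fix_get(sprintf("ens_%d_%d", seed, reps),
          function() make_ensemble(fixture_world(), seed = seed, reps = reps))
}

fix_map <- function() {
  fix_get("map", function()
    propagate_wavefront(fixture_world(), ttg_uniform(0.6)))
}

fix_gaze_run <- function() {
  fix_get("gaze_run", function() {
    ens <- fix_ensemble()
    # the first occluded-bundle run: three legs, two subgoal switches
    ens$trajectories[[1]]
  })
}

# event-level match count: same kind and >50% overlap of the shorter
# of the two spans (robust to boundary jitter on brief saccades)
match_events <- function(ref, other) {
  tp <- 0L
  dur_o <- other$t_end - other$t_start
  for (i in seq_len(nrow(ref))) {
    ov <- pmin(other$t_end, ref$t_end[i]) - pmax(other$t_start, ref$t_start[i])
    hit <- as.character(other$kind) == as.character(ref$kind[i]) &
      ov > 0.5 * pmin(ref$t_end[i] - ref$t_start[i], dur_o)
    if (any(hit)) tp <- tp + 1L
  }
  tp
}

digest_file <- function(path) unname(tools::md5sum(path))

# one-rectangle world used across wavefront tests
one_rect_world <- function() {
  guidance_env(c(0, 0, 12, 8),
               list(rect_obstacle(5, 3, 7, 5)),
               goal_spec(c(10, 4)))
}
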