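# Shared synthetic scenes, built once per test run and cached.

.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .scene_cache))
    assign(key, force(expr), envir = .scene_cache)
  get(key, envir = .scene_cache)
}

walk_scene <- function() cached("walk36",
  make_scene(list(list(bp_walk(), 36)), image_size = c(96, 224),
             n_traj = 80, seed = 2))

pause_scene <- function() cached("pause20",
  make_scene(list(list(bp_pause(), 20)), image_size = c(96, 160),
             n_traj = 60, seed = 3))

walk_pause_sit_scene <- function() cached("wps",
  make_scene(list(list(bp_walk(), 30), list(bp_pause(), 8),
                  list(bp_sit(), 25)),
             image_size = c(96, 224), n_traj = 80, seed = 4))

walk_run_scene <- function() cached("wr",
  make_scene(list(list(bp_walk(period = 12), 48),
                  list(bp_run(period = 6), 48)),
             image_size = c(96, 320), seed = 4))

walk_pots <- function() cached("walk36_pots", extract_pots(walk_scene()))

# a small scene (<= 30 trajectories would violate make_scene's density
# floor, so build a 50-trajectory scene and keep the first 24 trajectories)
tiny_shot <- function() cached("tiny", {
  s <- make_scene(list(list(bp_walk(), 16)), image_size = c(96, 180),
                  n_traj = 50, seed = 9)
  s$trajectories <- s$trajectories[1:24]
  s$parts <- s$parts[1:24]
  s
})

# deterministic synthetic trajectory for low-level descriptor tests
line_traj <- function(id, start, origin, velocity, frames) {
  k <- 0:(frames - 1)
  list(id = id, start = as.integer(start),
       points = cbind(origin[1] + velocity[1] * k,
                      origin[2] + velocity[2] * k))
}
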