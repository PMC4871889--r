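# Shared fixtures built in code.  Kept small so the full suite stays fast;
# the heavier scaled-down study analogues live in test-acceptance.R.

# light registration settings for small test grids
light_config <- function(metric = "ncc") {
  registration_config(levels = 3, max_iters_per_level = c(60, 60, 30),
                      metric = metric)
}

# memoised small phantom (64^2) used across tests
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom(64)
    cache
  }
})

# random smooth displacement field on a grid
random_smooth_field <- function(grid, amplitude_vox, sigma_vox, seed) {
  chronoatlas:::random_velocity_field(as_grid_geometry(grid),
                                      amplitude_vox, sigma_vox, seed)
}

# brute-force per-voxel vote counting; independent of majority_vote()
counting_oracle <- function(maps) {
  stack <- vapply(maps, function(m) as.vector(m$data),
                  integer(length(maps[[1]]$data)))
  win <- apply(stack, 1, function(v) {
    tab <- table(v)
    best <- max(tab)
    min(as.integer(names(tab)[tab == best]))
  })
  label_map(array(as.integer(win), dim = dim(maps[[1]]$data)),
            maps[[1]]$spacing, maps[[1]]$origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

grid_pts <- function(x) chronoatlas:::grid_world_coords(as_grid_geometry(x))
interior_of <- function(x) chronoatlas:::interior_mask(dim(x$data))
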