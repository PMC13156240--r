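# Shared fixture builders.  Everything is generated in code; no binary data.

flat_grid <- function(n = 8, value = 5, cs = 60) {
  grid_create(matrix(value, n, n), cs)
}

# inclined plane: z rises `per_cell` meters per cell going east
plane_grid <- function(nr = 10, nc = 10, per_cell = 1, cs = 60) {
  grid_create(outer(rep(0, nr), seq_len(nc) - 1, function(a, b) b) * per_cell +
                matrix(0, nr, nc), cs)
}

lone_mask <- function(n = 9, at = c(5, 5), cs = 60) {
  m <- matrix(FALSE, n, n)
  m[at[1], at[2]] <- TRUE
  mask_create(m, cell_size = cs)
}

# brute-force nearest-member distance (independent oracle for the EDT)
brute_distance <- function(mask) {
  mem <- which(mask$member, arr.ind = TRUE)
  cs <- mask$cell_size
  out <- matrix(NA_real_, nrow(mask$member), ncol(mask$member))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    out[i, j] <- min(sqrt((mem[, 1] - i)^2 + (mem[, 2] - j)^2)) * cs
  }
  out
}

# V-shaped valley running north-south at column `vcol`
v_valley_dem <- function(n = 21, vcol = 11, slope = 5, cs = 60) {
  z <- outer(rep(1, n), abs(seq_len(n) - vcol)) * slope
  grid_create(z, cs)
}

# lazily built, cached synthetic worlds shared across test files
.world_cache <- new.env(parent = emptyenv())
get_test_world <- function(size = 130, seed = 42) {
  key <- paste0("w", size, "_", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- generate_world(world_config(size = size, seed = seed))
  .world_cache[[key]]
}
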