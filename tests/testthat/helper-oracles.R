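# Independent brute-force oracles used to cross-check the implementation.

# Benjamini-Hochberg by the step-up definition: adjusted p_(i) is the
# smallest p_(j) * m / j over j >= i (ordered ascending), capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  scaled <- p[ord] * m / seq_len(m)
  adj[ord] <- pmin(rev(cummin(rev(scaled))), 1)
  adj
}

# 3D connected components by explicit flood fill over a logical mask.
# Returns an integer label array (0 = background).
flood_fill_components <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  labels <- array(0L, dim = dims)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  }
  lab <- 0L
  for (i in which(mask)) {
    if (labels[i] != 0L) next
    lab <- lab + 1L
    queue <- i
    labels[i] <- lab
    while (length(queue) > 0L) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(v, dims)
      for (k in seq_len(nrow(offs))) {
        z <- co[1] + offs$dz[k]; y <- co[2] + offs$dy[k]; x <- co[3] + offs$dx[k]
        if (z < 1 || z > dims[1] || y < 1 || y > dims[2] ||
            x < 1 || x > dims[3]) next
        j <- (x - 1L) * dims[1] * dims[2] + (y - 1L) * dims[1] + z
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- lab
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

# Two-sided permutation test for a difference in means.
perm_test_p <- function(a, b, B = 20000, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(B)) {
    idx <- sample.int(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

# Render an isolated Gaussian focus into a stack (independent of the
# generator's own rendering path).
plant_focus <- function(stack, z0, y0, x0, amp = 150, sd_xy = 1.2, sd_z = 0.8) {
  dims <- dim(stack)
  for (z in seq_len(dims[1])) for (y in seq_len(dims[2])) for (x in seq_len(dims[3])) {
    d2 <- (z - z0)^2 / sd_z^2 + (y - y0)^2 / sd_xy^2 + (x - x0)^2 / sd_xy^2
    if (d2 < 25) stack[z, y, x] <- stack[z, y, x] + amp * exp(-0.5 * d2)
  }
  stack
}

# Small straight-tube image config shared across tests (fast to generate).
small_image_config <- function(marker = NULL, ...) {
  args <- utils::modifyList(
    list(n_cd = 10L, nucleus_spacing = 14, tube_radius = 16,
         nucleus_radius = 5, z_slices = 4L, curve_amp = 0, camera_sd = 1),
    list(...))
  do.call(image_config, c(list(marker = marker), args))
}

small_marker <- function(noise_sd = 0) {
  profile_config("toy",
                 breakpoints = data.frame(cd = c(1, 3, 10),
                                          level = c(120, 120, 30)),
                 noise_sd = noise_sd, background_level = 15, max_cd = 10L)
}
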