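# Independent oracles used across the suite. These deliberately avoid the
# package's own solver/transform code paths.

# Brute-force Euclidean distance (cell units) from every cell to the
# nearest TRUE cell: O(N * W) direct minimum.
brute_force_distance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  tgt <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  if (nrow(tgt) == 0) return(out)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    out[i, j] <- sqrt(min((tgt[, 1] - i)^2 + (tgt[, 2] - j)^2))
  }
  out
}

# Dense multiresolution grid search for the bounded unmixing objective
# min sum((A %*% T^4 - y)^2) over t_min <= T_k <= t_max, for p <= 3
# classes. Evaluates the exact sum-of-squares via its quadratic form.
# Final grid step 0.005 K, below the 0.01 K target resolution.
grid_search_window <- function(A, y, t_min, t_max) {
  p <- ncol(A)
  G <- crossprod(A)
  b <- crossprod(A, y)
  c0 <- sum(y^2)
  sse <- function(Tm) {            # Tm: n_pts x p matrix of temperatures
    X <- Tm^4
    c0 - 2 * X %*% b + rowSums((X %*% G) * X)
  }
  centers <- rep((t_min + t_max) / 2, p)
  half <- (t_max - t_min) / 2
  step <- 1
  repeat {
    axes <- lapply(seq_len(p), function(k) {
      g <- seq(centers[k] - half, centers[k] + half, by = step)
      pmin(pmax(g, t_min), t_max)
    })
    Tm <- as.matrix(do.call(expand.grid, axes))
    best <- which.min(sse(Tm))
    centers <- Tm[best, ]
    if (step <= 0.005) break
    half <- step * 1.5
    step <- step / 10
  }
  as.numeric(centers)
}

# A small solvable window: n pixels, fractions over `active` classes
# (others zero), composed from known truth temps with unit-free noise.
make_window <- function(n = 25, active = c(1, 6), truth = c(295, 310),
                        emis = default_emissivities(), noise = 0,
                        seed = 1) {
  set.seed(seed)
  fr <- matrix(0, n, 8)
  raw <- matrix(runif(n * length(active), 0.05, 1), n)
  raw <- raw / rowSums(raw)
  fr[, active] <- raw
  tk4 <- rep(0, 8)
  tk4[active] <- truth^4
  eps_px <- as.vector(fr %*% emis)
  rad <- as.vector(fr %*% (emis * tk4))
  lst <- (rad / eps_px)^0.25 + rnorm(n, 0, noise)
  list(lst = lst, emis = eps_px, fr = fr)
}

# Default small scene shared by several tests (cached per session).
small_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_scene(scene_config(grid_rows = 40, grid_cols = 40,
                                            seed = 42))
    cache
  }
})
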