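# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's minimum-image/graph code paths.

# Shortest displacement q - p over the 9 periodic images (2D).
brute_min_image <- function(p, q, L) {
  best <- NULL
  for (ix in -1:1) for (iy in -1:1) {
    d <- (q + c(ix * L[1], iy * L[2])) - p
    if (is.null(best) || sum(d^2) < sum(best^2)) best <- d
  }
  best
}

# Brute-force contact matrix via the 9-image distances.
brute_contact_matrix <- function(x, y, L, cutoff) {
  n <- length(x)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- brute_min_image(c(x[i], y[i]), c(x[j], y[j]), L)
    m[i, j] <- sqrt(sum(d^2)) < cutoff
  }
  m
}

# Connected components by boolean transitive closure (matrix powers).
brute_components <- function(m) {
  n <- nrow(m)
  reach <- m | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      k <- k + 1L
      comp[reach[i, ]] <- k
    }
  }
  comp
}

# Direct double-loop MSD over all origin/lag pairs (lateral).
brute_msd <- function(X, Y, lag) {
  nf <- ncol(X)
  acc <- 0
  cnt <- 0
  for (o in seq_len(nf - lag)) {
    acc <- acc + sum((X[, o + lag] - X[, o])^2 + (Y[, o + lag] - Y[, o])^2)
    cnt <- cnt + nrow(X)
  }
  acc / cnt
}

# Build a receptor-only trajectory from explicit coordinates.
receptor_frame <- function(coords, box, species = NULL, n_frames = 1L,
                           dt = 0.1) {
  make_layout("custom", coords = coords, box = box, species = species,
              n_frames = n_frames, dt = dt)
}

# Small free-diffusion config: no attractions and no excluded volume, so
# the walks are exactly Brownian.
free_config <- function(D, n, box_len = 200, dt = 1e-2, n_steps = 100,
                        species = "SDPC", Dr = 0) {
  sim_config(tibble::tibble(species = species, count = n, D = D, Dr = Dr,
                            radius = if (Dr > 0) 1.8 else 0.4),
             box_spec(c(box_len, box_len)),
             dt = dt, n_steps = n_steps, stride = 1L, init_min_sep = 0,
             k_rep = 0)
}

uniform_gas_traj <- function(n_target = 400, n_frames = 10, box_len = 30,
                             seed = 7, target = "DPPC") {
  set.seed(seed)
  np <- n_target + 1
  df <- tibble::tibble(
    frame = rep(seq_len(n_frames) - 1L, each = np),
    time = rep((seq_len(n_frames) - 1) * 0.1, each = np),
    id = rep(seq_len(np) - 1L, n_frames),
    species = rep(c("A2A", rep(target, n_target)), n_frames),
    x = runif(np * n_frames, 0, box_len),
    y = runif(np * n_frames, 0, box_len),
    theta = NA_real_
  )
  as_trajectory(df, box_spec(c(box_len, box_len)))
}
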