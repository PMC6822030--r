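# Independent oracles, written as direct transcriptions of the formulas with
# plain loops; deliberately not sharing code with the package internals.

# Poisson point-process SCR negative log-likelihood by full enumeration
brute_negloglik <- function(p0, sigma, D, traps, enc, ss) {
  act <- traps$activity
  y <- enc$y
  n <- dim(y)[1]
  G <- ss$n_pixels
  a <- ss$pixel_area
  J <- length(traps$x)
  K <- ncol(act)
  pmat <- matrix(0, G, J)
  for (g in seq_len(G)) {
    for (j in seq_len(J)) {
      d <- sqrt((ss$x[g] - traps$x[j])^2 + (ss$y[g] - traps$y[j])^2)
      pmat[g, j] <- p0 * exp(-d^2 / (2 * sigma^2))
    }
  }
  pdot <- numeric(G)
  for (g in seq_len(G)) {
    prod0 <- 1
    for (j in seq_len(J)) for (k in seq_len(K))
      if (act[j, k] == 1) prod0 <- prod0 * (1 - pmat[g, j])
    pdot[g] <- 1 - prod0
  }
  ll <- 0
  for (i in seq_len(n)) {
    Li <- 0
    for (g in seq_len(G)) {
      pr <- 1
      for (j in seq_len(J)) for (k in seq_len(K)) {
        if (act[j, k] == 1) {
          pr <- pr * if (y[i, j, k] == 1) pmat[g, j] else 1 - pmat[g, j]
        }
      }
      Li <- Li + D * a * pr
    }
    ll <- ll + log(Li)
  }
  -ll + sum(D * a * pdot) + lgamma(n + 1)
}

# area of the convex hull of (x, y) dilated by w, via an explicit
# Minkowski-sum polygon with arcs discretized into many segments (shoelace)
dilated_hull_area <- function(x, y, w, arc_n = 20000) {
  h <- grDevices::chull(x, y)
  px <- x[h]; py <- y[h]
  m <- length(h)
  if (m == 1 || all(px == px[1] & py == py[1])) {
    th <- seq(0, 2 * pi, length.out = arc_n + 1)[-1]
    ox <- px[1] + w * cos(th); oy <- py[1] + w * sin(th)
  } else if (m == 2) {
    # stadium around the segment
    dx <- px[2] - px[1]; dy <- py[2] - py[1]
    a0 <- atan2(dy, dx)
    th1 <- seq(a0 + pi / 2, a0 + 3 * pi / 2, length.out = arc_n)
    th2 <- seq(a0 - pi / 2, a0 + pi / 2, length.out = arc_n)
    ox <- c(px[1] + w * cos(th1), px[2] + w * cos(th2))
    oy <- c(py[1] + w * sin(th1), py[2] + w * sin(th2))
  } else {
    # chull returns clockwise order; make counter-clockwise
    i2 <- c(2:m, 1)
    if (sum(px * py[i2] - px[i2] * py) < 0) { px <- rev(px); py <- rev(py) }
    ox <- oy <- numeric(0)
    for (v in seq_len(m)) {
      prev <- if (v == 1) m else v - 1
      nxt <- if (v == m) 1 else v + 1
      a_in <- atan2(py[v] - py[prev], px[v] - px[prev])
      a_out <- atan2(py[nxt] - py[v], px[nxt] - px[v])
      n1 <- a_in - pi / 2   # outward normal of incoming edge (ccw polygon)
      n2 <- a_out - pi / 2
      while (n2 < n1) n2 <- n2 + 2 * pi
      th <- seq(n1, n2, length.out = max(2, ceiling(arc_n * (n2 - n1) / (2 * pi))))
      ox <- c(ox, px[v] + w * cos(th))
      oy <- c(oy, py[v] + w * sin(th))
    }
  }
  nn <- length(ox)
  i2 <- c(2:nn, 1)
  abs(sum(ox * oy[i2] - ox[i2] * oy)) / 2
}

# M0 profile log-likelihood for a grid search over N
m0_profile_oracle <- function(N, freq) {
  S <- sum(seq_len(freq$K) * freq$f)
  p <- S / (N * freq$K)
  lgamma(N + 1) - lgamma(N - freq$n + 1) + S * log(p) + (N * freq$K - S) * log(1 - p)
}

# random tiny SCR instance within the enumeration bounds
random_tiny_instance <- function(seed) {
  set.seed(seed)
  G <- sample(1:4, 1); J <- sample(1:3, 1); K <- sample(1:3, 1)
  ss <- state_space(runif(G, 0, 5000), runif(G, 0, 5000), resolution = 1000)
  act <- matrix(rbinom(J * K, 1, 0.8), J, K)
  for (j in seq_len(J)) if (sum(act[j, ]) == 0) act[j, sample(K, 1)] <- 1L
  traps <- trap_array(paste0("T", seq_len(J)), runif(J, 0, 5000),
                      runif(J, 0, 5000), act)
  n <- sample(0:3, 1)
  y <- array(0L, c(n, J, K))
  if (n > 0) {
    for (i in seq_len(n)) {
      repeat {
        yi <- matrix(rbinom(J * K, 1, 0.4), J, K) * act
        if (sum(yi) > 0) break
      }
      y[i, , ] <- yi
    }
  }
  enc <- encounter_data(y, traps)
  list(traps = traps, enc = enc, ss = ss,
       p0 = runif(1, 0.05, 0.8), sigma = runif(1, 500, 4000),
       D = exp(runif(1, log(1e-8), log(1e-5))))
}

# small, fast synthetic session for end-to-end tests
small_sim_session <- function(seed = 7, p0 = 0.4, sigma = 3000, N = 15,
                              n_occasions = 8, label = "sim") {
  traps <- make_checkerboard_traps(5, 6, cell = 2700, n_occasions = n_occasions)
  ss <- build_state_space(traps, buffer = 7500, resolution = 1500)
  sim <- simulate_scr(traps, ss, p0 = p0, sigma = sigma, N = N,
                      session_id = label, seed = seed)
  list(sim = sim, ss = ss)
}
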