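#' Checkerboard camera-trap design
#'
#' Lays a grid of `n_cells_x` by `n_cells_y` square cells of side `cell` and
#' places one camera site at the center of every second cell (checkerboard by
#' `(row + col + phase)` parity), the systematic one-cell-in-two design used
#' in lynx camera-trap surveys so that every potential home range holds at
#' least one site.
#'
#' @param n_cells_x,n_cells_y number of design cells per axis (`>= 1`).
#' @param cell cell side in meters (default 2700).
#' @param origin coordinates of the lower-left corner of the design.
#' @param phase 0 or 1, selecting which cell color of the checkerboard holds
#'   the sites.
#' @param n_occasions number of (fully active) capture occasions.
#' @return A [trap_array()] with `cell_size` metadata set.
#' @export
make_checkerboard_traps <- function(n_cells_x, n_cells_y, cell = 2700,
                                    origin = c(0, 0), phase = 0,
                                    n_occasions = 1) {
  if (cell <= 0) abort_validation("cell size must be positive")
  if (n_cells_x < 1 || n_cells_y < 1)
    abort_validation("need at least one cell per axis")
  if (!phase %in% c(0, 1)) abort_validation("phase must be 0 or 1")
  g <- expand.grid(col = seq_len(n_cells_x) - 1L, row = seq_len(n_cells_y) - 1L)
  keep <- (g$col + g$row + phase) %% 2 == 0
  g <- g[keep, , drop = FALSE]
  trap_array(site_id = sprintf("S%03d", seq_len(nrow(g))),
             x = origin[1] + (g$col + 0.5) * cell,
             y = origin[2] + (g$row + 0.5) * cell,
             activity = matrix(1L, nrow(g), n_occasions),
             cell_size = cell)
}

#' Simulate a spatial capture-recapture survey
#'
#' Draws activity centers over the state-space and Bernoulli detections on
#' active site-occasions from the half-normal model
#' `p = p0 * exp(-d^2/(2 sigma^2))`. By default the number of individuals is
#' `N ~ Poisson(density * area(state-space))`, matching the Poisson
#' point-process likelihood fitted by [fit_scr()]; a fixed `N` can be given
#' instead for recovery experiments. Centers are drawn by sampling a pixel
#' uniformly and jittering uniformly within it, which matches the estimator's
#' discretization without lattice artifacts. Individuals never detected are
#' recorded in the returned truth but omitted from the encounter data, as in
#' a real survey.
#'
#' @param traps a [trap_array()]; its activity mask defines the occasions.
#' @param statespace a [state_space()] enclosing the traps.
#' @param p0 baseline detection probability.
#' @param sigma movement scale, meters.
#' @param density expected activity centers per m2 (used unless `N` given).
#' @param N fixed number of individuals (overrides `density`).
#' @param n_occasions optional occasion count; if the trap array carries a
#'   single all-active occasion it is expanded to this many.
#' @param centers optional fixed matrix of activity centers (columns x, y),
#'   overriding both `density` and `N`.
#' @param dropout per-site-occasion probability of camera failure (activity
#'   thinning), default 0.
#' @param session_id label for the simulated session.
#' @param seed optional integer seed for reproducibility.
#' @return list with `encounters` (an [encounter_data()]), `traps` (the trap
#'   array actually used, with any thinned activity), and `truth` (class
#'   `sim_truth`: `N_true`, `centers`, `p0_true`, `sigma_true`, `detected`,
#'   `seed`).
#' @export
simulate_scr <- function(traps, statespace, p0, sigma, density = NULL,
                         N = NULL, n_occasions = NULL, centers = NULL,
                         dropout = 0, session_id = "sim", seed = NULL) {
  if (p0 < 0 || p0 > 1) abort_validation("p0 must be in [0, 1]")
  if (sigma <= 0) abort_validation("sigma must be > 0")
  if (dropout < 0 || dropout >= 1) abort_validation("dropout must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  act <- traps$activity
  if (!is.null(n_occasions) && n_occasions != ncol(act)) {
    if (ncol(act) == 1L && all(act == 1L)) {
      act <- matrix(1L, nrow(act), n_occasions)
    } else {
      abort_validation("n_occasions conflicts with the trap activity mask")
    }
  }
  if (dropout > 0) {
    thin <- matrix(stats::rbinom(length(act), 1L, 1 - dropout),
                   nrow(act), ncol(act))
    act2 <- act * thin
    # keep every site estimable: re-activate one occasion if thinned to zero
    dead <- which(rowSums(act2) == 0)
    for (j in dead) act2[j, which(act[j, ] == 1L)[1]] <- 1L
    act <- act2
  }
  traps <- trap_array(traps$site_id, traps$x, traps$y, act, traps$cell_size)
  A <- state_space_area(statespace)
  if (is.null(centers)) {
    if (is.null(N)) {
      if (is.null(density)) abort_validation("give density, N, or centers")
      N <- stats::rpois(1, density * A)
    }
    pix <- sample.int(statespace$n_pixels, N, replace = TRUE)
    half <- statespace$resolution / 2
    centers <- cbind(
      x = statespace$x[pix] + stats::runif(N, -half, half),
      y = statespace$y[pix] + stats::runif(N, -half, half))
  } else {
    centers <- as.matrix(centers)
    colnames(centers) <- c("x", "y")
    N <- nrow(centers)
  }
  J <- length(traps$site_id); K <- ncol(act)
  y <- array(0L, c(N, J, K))
  if (N > 0) {
    d2 <- outer(centers[, 1], traps$x, "-")^2 + outer(centers[, 2], traps$y, "-")^2
    p <- p0 * exp(-d2 / (2 * sigma^2))          # N x J
    for (k in seq_len(K)) {
      on <- which(act[, k] == 1L)
      if (!length(on)) next
      y[, on, k] <- stats::rbinom(N * length(on), 1L, p[, on, drop = FALSE])
    }
  }
  detected <- which(apply(y, 1, sum) > 0)
  yd <- y[detected, , , drop = FALSE]
  if (length(detected))
    dimnames(yd)[[1]] <- sprintf("ind%03d", detected)
  enc <- encounter_data(yd, traps, session_id = session_id)
  truth <- structure(list(N_true = N, centers = centers, p0_true = p0,
                          sigma_true = sigma, detected = detected,
                          seed = seed),
                     class = "sim_truth")
  list(encounters = enc, traps = traps, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: N = %d (%d detected), p0 = %.3f, sigma = %.0f m\n",
              x$N_true, length(x$detected), x$p0_true, x$sigma_true))
  invisible(x)
}

#' Assign sex labels to detected individuals
#'
#' Draws iid labels F/M/U with probabilities `p_female`, `p_male` and
#' `1 - p_female - p_male`, emulating surveys where sex can be confirmed from
#' photographs for only a minority of individuals.
#'
#' @param enc an [encounter_data()].
#' @param p_female,p_male probabilities, with `p_female + p_male <= 1`.
#' @param seed optional integer seed.
#' @return The encounter data with new `sex` labels.
#' @export
assign_sex <- function(enc, p_female, p_male, seed = NULL) {
  if (p_female < 0 || p_male < 0 || p_female + p_male > 1)
    abort_validation("need p_female, p_male >= 0 and p_female + p_male <= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(enc$individuals)
  enc$sex <- sample(c("F", "M", "U"), n, replace = TRUE,
                    prob = c(p_female, p_male, 1 - p_female - p_male))
  enc
}

#' Write a simulated session to disk
#'
#' Emits the same CSV dialects read by [read_traps()] and
#' [read_encounters()], plus a JSON sidecar holding the simulation truth.
#'
#' @param dir output directory (created if needed).
#' @param traps a [trap_array()].
#' @param encounters an [encounter_data()].
#' @param truth optional `sim_truth` object.
#' @param label basename for the three files.
#' @return Invisibly, the paths written.
#' @export
write_session <- function(dir, traps, encounters, truth = NULL, label = "session") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(traps = file.path(dir, paste0(label, "_traps.csv")),
             encounters = file.path(dir, paste0(label, "_encounters.csv")))
  write_traps(traps, paths["traps"])
  write_encounters(encounters, paths["encounters"])
  if (!is.null(truth)) {
    paths["truth"] <- file.path(dir, paste0(label, "_truth.json"))
    jsonlite::write_json(
      list(N_true = truth$N_true, p0_true = truth$p0_true,
           sigma_true = truth$sigma_true,
           centers = as.data.frame(truth$centers),
           detected = truth$detected, seed = truth$seed),
      paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
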