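#' Mean maximum distance moved (MMDM)
#'
#' For every individual detected at two or more distinct sites, the maximum
#' pairwise Euclidean distance between its capture sites; MMDM is the mean of
#' those per-individual maxima. Individuals seen at a single site carry no
#' movement information and are excluded. Duplicate detections and the
#' occasion structure do not affect the result.
#'
#' @param enc an [encounter_data()].
#' @param traps the matching [trap_array()].
#' @return MMDM in meters, with attribute `n_used` (individuals contributing).
#'   `NA` with a warning when no individual was detected at more than one
#'   site.
#' @export
mmdm <- function(enc, traps) {
  m <- individual_max_moves(enc, traps)
  if (!length(m)) {
    warning("no individual detected at more than one site; MMDM undefined")
    return(structure(NA_real_, n_used = 0L))
  }
  structure(mean(m), n_used = length(m))
}

# per-individual maximum distance between distinct capture sites
individual_max_moves <- function(enc, traps) {
  n <- dim(enc$y)[1]
  if (n == 0) return(numeric(0))
  seen <- apply(enc$y, c(1, 2), max)     # n x J site indicator
  out <- numeric(0)
  for (i in seq_len(n)) {
    j <- which(seen[i, ] == 1L)
    if (length(j) < 2) next
    d <- sqrt(outer(traps$x[j], traps$x[j], "-")^2 +
              outer(traps$y[j], traps$y[j], "-")^2)
    out <- c(out, max(d))
  }
  out
}

#' Effective trapping area from a buffered trap polygon
#'
#' Dilates the convex hull of the trap locations by `buffer_w`. For a convex
#' polygon the Minkowski-sum area has the closed form
#' `A + P * w + pi * w^2` (hull area, perimeter and buffer width); degenerate
#' hulls reduce to a disc (single point, `pi w^2`) or a stadium (collinear
#' sites, `2 L w + pi w^2`). `method = "disc_union"` instead computes the
#' area of the union of discs of radius `w` around the sites by fine-grid
#' quadrature, for sensitivity analysis (approximate, not used by default).
#'
#' @param traps a [trap_array()] (or a 2-column coordinate matrix).
#' @param buffer_w buffer width in meters, `>= 0`.
#' @param method `"convex_hull"` (closed form, default) or `"disc_union"`.
#' @param grid_n quadrature points per axis for `"disc_union"`.
#' @return Object of class `eta_result`: `buffer_w`, `hull_area`,
#'   `hull_perimeter` (m), `eta_area` (m2), `method`.
#' @export
effective_trapping_area <- function(traps, buffer_w,
                                    method = c("convex_hull", "disc_union"),
                                    grid_n = 600) {
  method <- match.arg(method)
  if (buffer_w < 0) abort_validation("buffer width must be >= 0")
  if (inherits(traps, "trap_array")) {
    x <- traps$x; y <- traps$y
  } else {
    traps <- as.matrix(traps); x <- traps[, 1]; y <- traps[, 2]
  }
  if (!length(x)) abort_validation("need at least one trap")
  w <- buffer_w
  if (method == "disc_union") {
    gx <- seq(min(x) - w, max(x) + w, length.out = grid_n)
    gy <- seq(min(y) - w, max(y) + w, length.out = grid_n)
    cell <- diff(gx[1:2]) * diff(gy[1:2])
    inside <- matrix(FALSE, grid_n, grid_n)
    for (j in seq_along(x)) {
      d2 <- outer((gx - x[j])^2, (gy - y[j])^2, "+")
      inside <- inside | (d2 <= w^2)
    }
    eta <- sum(inside) * cell
    return(structure(list(buffer_w = w, hull_area = NA_real_,
                          hull_perimeter = NA_real_, eta_area = eta,
                          method = method),
                     class = "eta_result"))
  }
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  m <- length(hull)
  if (m >= 3) {
    i2 <- c(2:m, 1)
    area <- abs(sum(hx * hy[i2] - hx[i2] * hy)) / 2
    perim <- sum(sqrt((hx[i2] - hx)^2 + (hy[i2] - hy)^2))
  } else area <- 0
  if (m < 3 || area == 0) {
    # degenerate hull: a point or a segment of collinear sites
    L <- max(sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2))
    if (L == 0) {
      area <- 0; perim <- 0; eta <- pi * w^2
    } else {
      area <- 0; perim <- 2 * L; eta <- 2 * L * w + pi * w^2
    }
  } else {
    eta <- area + perim * w + pi * w^2
  }
  structure(list(buffer_w = w, hull_area = area, hull_perimeter = perim,
                 eta_area = eta, method = method),
            class = "eta_result")
}

#' @export
print.eta_result <- function(x, ...) {
  cat(sprintf("Effective trapping area (%s): %.2f km2 (hull %.2f km2, perimeter %.1f km, buffer %.0f m)\n",
              x$method, x$eta_area / 1e6, x$hull_area / 1e6,
              x$hull_perimeter / 1e3, x$buffer_w))
  invisible(x)
}

#' MMDM-buffered effective trapping area for a session
#'
#' Computes the session MMDM and the effective trapping area with the full
#' (`half = FALSE`) or half (`half = TRUE`, HMMDM) MMDM as buffer width.
#'
#' @param enc an [encounter_data()].
#' @param traps the matching [trap_array()].
#' @param half use HMMDM (MMDM/2) as the buffer width.
#' @return An `eta_result` with `mmdm` and `n_individuals_used` added.
#' @export
eta_from_mmdm <- function(enc, traps, half = FALSE) {
  m <- mmdm(enc, traps)
  if (is.na(m))
    abort("MMDM undefined: no individual detected at more than one site",
          "scrdens_mmdm_undefined")
  w <- if (half) as.numeric(m) / 2 else as.numeric(m)
  eta <- effective_trapping_area(traps, w)
  eta$mmdm <- as.numeric(m)
  eta$n_individuals_used <- attr(m, "n_used")
  eta
}

#' Convert a nonspatial abundance estimate to density
#'
#' Density per 100 km2 as `100 * N / ETA(km2)`, treating the effective
#' trapping area as fixed, so `SE(D) = 100 * SE(N) / ETA(km2)`.
#'
#' @param N abundance estimate.
#' @param se_N its standard error.
#' @param eta an `eta_result`, or the effective trapping area in m2.
#' @return list with `density` and `se` (individuals per 100 km2).
#' @export
nonspatial_density <- function(N, se_N, eta) {
  area_m2 <- if (inherits(eta, "eta_result")) eta$eta_area else as.numeric(eta)
  if (!is.finite(area_m2) || area_m2 <= 0)
    abort_validation("effective trapping area must be positive")
  list(density = 1e8 * N / area_m2, se = 1e8 * se_N / area_m2)
}
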