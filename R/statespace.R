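#' Construct a state-space from explicit pixel centers
#'
#' Low-level constructor; most users should call [build_state_space()].
#'
#' @param x,y numeric pixel-center coordinates in meters (equal length).
#' @param resolution pixel side in meters; pixel area is `resolution^2`.
#' @param buffer buffer width used to build the grid (metadata).
#' @return An object of class `state_space`.
#' @export
state_space <- function(x, y, resolution, buffer = NA_real_) {
  stopifnot(length(x) == length(y), length(x) >= 1, resolution > 0)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 resolution = as.numeric(resolution),
                 pixel_area = as.numeric(resolution)^2,
                 buffer = as.numeric(buffer),
                 n_pixels = length(x)),
            class = "state_space")
}

#' Discretize the region of candidate activity centers
#'
#' Buffers the bounding box of the outermost trap locations by `buffer` on
#' every side and covers it with a regular grid of square pixels of side
#' `resolution`. Pixel centers start at `min - buffer + resolution/2` on each
#' axis and the per-axis pixel count is `ceiling(span / resolution)`, so the
#' grid never undershoots the buffered box. The buffer should be at least
#' about twice the movement scale `sigma` so that the state-space plausibly
#' contains all activity centers of detectable individuals.
#'
#' @param traps a [trap_array()].
#' @param buffer buffer width in meters (default 15000).
#' @param resolution pixel side in meters (default 1500, i.e. 2.25 km2 pixels).
#' @return A [state_space()].
#' @export
build_state_space <- function(traps, buffer = 15000, resolution = 1500) {
  if (!inherits(traps, "trap_array") || length(traps$site_id) < 1)
    abort_validation("build_state_space needs a non-empty trap_array")
  if (buffer <= 0 || resolution <= 0)
    abort_validation("buffer and resolution must be positive")
  axis_centers <- function(v) {
    lo <- min(v) - buffer
    span <- diff(range(v)) + 2 * buffer
    n <- max(1L, as.integer(ceiling(span / resolution - 1e-9)))
    lo + resolution / 2 + resolution * (seq_len(n) - 1L)
  }
  cx <- axis_centers(traps$x)
  cy <- axis_centers(traps$y)
  g <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  ss <- state_space(g$x, g$y, resolution, buffer)
  ss$nx <- length(cx); ss$ny <- length(cy)
  ss
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("State-space: %d pixels of %.0f m (%.2f km2 each), total %.0f km2\n",
              x$n_pixels, x$resolution, x$pixel_area / 1e6,
              x$n_pixels * x$pixel_area / 1e6))
  invisible(x)
}

state_space_area <- function(ss) ss$n_pixels * ss$pixel_area

#' Half-normal detection function
#'
#' Per-occasion detection probability of an individual at a trap a distance
#' `d` from its activity center: `p(d) = p0 * exp(-d^2 / (2 * sigma^2))`.
#' `p0` is the detection probability when the trap sits exactly at the
#' activity center and `sigma` (meters) is the spatial scale of movement.
#'
#' @param d distance(s) in meters, `d >= 0`.
#' @param p0 baseline detection probability in `[0, 1]`.
#' @param sigma movement scale in meters, `> 0`.
#' @return Detection probabilities in `[0, p0]`.
#' @export
half_normal_p <- function(d, p0, sigma) {
  if (any(d < 0)) abort_validation("d must be >= 0")
  if (p0 < 0 || p0 > 1) abort_validation("p0 must be in [0, 1]")
  if (sigma <= 0) abort_validation("sigma must be > 0")
  p0 * exp(-d^2 / (2 * sigma^2))
}

# squared-distance matrix pixels x traps
dist2_matrix <- function(ss, traps) {
  outer(ss$x, traps$x, "-")^2 + outer(ss$y, traps$y, "-")^2
}
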