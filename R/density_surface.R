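#' Pixel density surface of a fitted SCR model
#'
#' Expected number of activity centers per state-space pixel given the data
#' and the fitted parameters: the sum over detected individuals of the
#' posterior probability that their center lies in the pixel, plus the
#' expected number of undetected centers `D * a * (1 - pdot(s))`. At the
#' maximum-likelihood estimates the surface sums over pixels to the estimated
#' abundance `N = D * A(S)`.
#'
#' @param fit an [fit_scr()] result.
#' @param session session index or label (default 1).
#' @return Object of class `density_surface`: a data frame with pixel centers
#'   `x`, `y` (m) and `density` (expected individuals per pixel), with the
#'   grid dimensions, resolution and fitted abundance as attributes.
#' @export
density_surface <- function(fit, session = 1) {
  stopifnot(inherits(fit, "scr_fit"))
  if (is.character(session)) session <- match(session, fit$sessions$labels)
  if (is.na(session) || session < 1 || session > length(fit$sessions$sessions))
    abort_validation("unknown session")
  s <- fit$sessions$sessions[[session]]
  ss <- fit$statespaces[[session]]
  g <- as.integer(fit$sharing)[session]
  pc <- precompute_session(s$traps, s$encounters, ss)
  p0 <- stats::plogis(fit$params$p0_logit[g])
  sigma <- exp(fit$params$log_sigma[g])
  D <- exp(fit$params$log_density[session])
  logp <- log(p0) - pc$d2 / (2 * sigma^2)
  P <- pmin(exp(logp), 1 - 1e-12)
  log1mp <- log1p(-P)
  log_p0dot <- drop(log1mp %*% pc$Kj)
  dens <- D * pc$a * exp(log_p0dot)       # expected undetected centers per pixel
  if (pc$n > 0) {
    V <- logp %*% t(pc$Y) + log1mp %*% t(pc$KmY)
    post <- exp(sweep(V, 2, col_logsumexp(V), "-"))  # G x n, columns sum to 1
    dens <- dens + rowSums(post)
  }
  out <- data.frame(x = ss$x, y = ss$y, density = dens)
  structure(out, class = c("density_surface", "data.frame"),
            nx = ss$nx, ny = ss$ny, resolution = ss$resolution,
            N = fit$per_session$N[session],
            session = fit$sessions$labels[session])
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("Density surface '%s': %d pixels, sum %.4f individuals (max %.4f per pixel)\n",
              attr(x, "session"), nrow(x), sum(x$density), max(x$density)))
  invisible(x)
}

#' @export
plot.density_surface <- function(x, ...) {
  nx <- attr(x, "nx"); ny <- attr(x, "ny")
  z <- matrix(x$density, nx, ny)
  graphics::image(sort(unique(x$x)), sort(unique(x$y)), z,
                  xlab = "x (m)", ylab = "y (m)", useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE), ...)
  invisible(x)
}

#' @export
plot.scr_fit <- function(x, session = 1, ...) {
  plot(density_surface(x, session), ...)
}

#' Write a density surface as an ESRI ASCII grid
#'
#' @param surf a [density_surface()].
#' @param path output `.asc` path.
#' @return Invisibly, `path`.
#' @export
write_density_asc <- function(surf, path) {
  nx <- attr(surf, "nx"); ny <- attr(surf, "ny")
  res <- attr(surf, "resolution")
  z <- matrix(surf$density, nx, ny)      # column g = y level, row = x level
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", nx),
               sprintf("nrows %d", ny),
               sprintf("xllcorner %.6f", min(surf$x) - res / 2),
               sprintf("yllcorner %.6f", min(surf$y) - res / 2),
               sprintf("cellsize %.6f", res),
               "NODATA_value -9999"), con)
  # ASCII grids run top row first
  for (r in ny:1) writeLines(paste(formatC(z[, r], format = "g", digits = 10),
                                   collapse = " "), con)
  invisible(path)
}

#' Write a density surface as long-format CSV
#'
#' Columns `x,y,density` in the input coordinate system.
#'
#' @param surf a [density_surface()].
#' @param path output `.csv` path.
#' @export
write_density_csv <- function(surf, path) {
  utils::write.csv(as.data.frame(surf), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
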