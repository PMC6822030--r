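#' Capture-frequency summary of an encounter history
#'
#' Drops the spatial information: an individual counts as detected in
#' occasion `k` if it was photographed at any site during that occasion. The
#' result tallies `f[c]`, the number of individuals detected in exactly `c`
#' of the `K` occasions — the sufficient statistics of the closed-population
#' models M0 and Mh.
#'
#' @param enc an [encounter_data()].
#' @return Object of class `capture_freq` with elements `K`, `n` and `f`
#'   (length `K`).
#' @export
capture_frequencies <- function(enc) {
  stopifnot(inherits(enc, "encounter_data"))
  K <- dim(enc$y)[3]
  n <- dim(enc$y)[1]
  if (n > 0) {
    det_occ <- apply(enc$y, c(1, 3), max)            # n x K occasion indicator
    counts <- rowSums(det_occ)
    f <- tabulate(counts, nbins = K)
  } else f <- integer(K)
  structure(list(K = K, n = n, f = as.integer(f)), class = "capture_freq")
}

#' @export
print.capture_freq <- function(x, ...) {
  cat(sprintf("Capture frequencies: n = %d individuals, K = %d occasions\n", x$n, x$K))
  nz <- which(x$f > 0)
  if (length(nz))
    cat(paste(sprintf("  f%d = %d", nz, x$f[nz]), collapse = "\n"), "\n")
  invisible(x)
}

m0_loglik <- function(N, p, freq) {
  S <- sum(seq_len(freq$K) * freq$f)      # total occasion-detections
  n <- freq$n; K <- freq$K
  lgamma(N + 1) - lgamma(N - n + 1) +
    S * log(p) + (N * K - S) * log1p(-p)
}

#' Closed-population model M0 (constant detection probability)
#'
#' Maximizes the M0 likelihood, in which all individuals share one
#' per-occasion detection probability `p`, over `(N, p)` with `N` treated as
#' continuous (`N >= n`). `p` is profiled analytically (`p_hat = S / (N K)`
#' with `S` the total number of occasion-detections) and `N` found by 1-d
#' optimization of the profile likelihood. Standard errors come from the
#' inverse observed information at the maximum. If no individual was detected
#' more than once the likelihood increases without bound in `N`; the fit is
#' then flagged as a boundary solution.
#'
#' @param freq a [capture_frequencies()] result.
#' @return Object of class `m0_fit`: `N` (continuous MLE), `N_rounded`, `p`,
#'   `se_N`, `se_p`, `loglik`, `boundary` flag.
#' @export
fit_m0 <- function(freq) {
  stopifnot(inherits(freq, "capture_freq"))
  if (freq$n < 1) abort_validation("need at least one detected individual")
  if (freq$K < 2) abort_validation("need at least two occasions")
  n <- freq$n; K <- freq$K
  S <- sum(seq_len(K) * freq$f)
  profile <- function(N) m0_loglik(N, min(S / (N * K), 1 - 1e-12), freq)
  if (S <= n) {
    # every individual seen exactly once: N-hat unbounded
    warning("all individuals detected once; M0 abundance is a boundary solution")
    return(structure(list(N = Inf, N_rounded = NA_integer_, p = NA_real_,
                          se_N = NA_real_, se_p = NA_real_,
                          loglik = NA_real_, boundary = TRUE, n = n, K = K),
                     class = "m0_fit"))
  }
  hi <- n
  while (profile(hi * 2) > profile(hi) && hi < 1e8) hi <- hi * 2
  opt <- stats::optimize(profile, c(n, hi * 2), maximum = TRUE, tol = 1e-8)
  Nhat <- opt$maximum
  boundary <- Nhat > 1e7
  phat <- S / (Nhat * K)
  H <- suppressWarnings(
    num_hessian(function(par) -m0_loglik(par[1], par[2], freq), c(Nhat, phat),
                h = c(1e-3 * (Nhat + 1), min(1e-6, (1 - phat) / 2 + 1e-12))))
  vc <- if (all(is.finite(H))) try(solve(H), silent = TRUE) else NULL
  if (is.null(vc) || inherits(vc, "try-error") ||
      !all(is.finite(diag(vc))) || any(diag(vc) < 0)) {
    se <- c(NA_real_, NA_real_)
  } else se <- sqrt(diag(vc))
  structure(list(N = Nhat, N_rounded = as.integer(round(Nhat)), p = phat,
                 se_N = se[1], se_p = se[2], loglik = opt$objective,
                 boundary = boundary, n = n, K = K),
            class = "m0_fit")
}

#' @export
print.m0_fit <- function(x, ...) {
  cat(sprintf("M0: N-hat = %.2f (SE %.2f), p-hat = %.4f (SE %.4f), n = %d, K = %d%s\n",
              x$N, x$se_N, x$p, x$se_p, x$n, x$K,
              if (isTRUE(x$boundary)) " [boundary]" else ""))
  invisible(x)
}

#' Chao lower-bound estimator for model Mh
#'
#' Heterogeneous-detection abundance via Chao's moment estimator built from
#' singletons and doubletons: `N = n + f1^2 / (2 f2)`, with the
#' bias-corrected form `N = n + f1 (f1 - 1) / (2 (f2 + 1))` when `f2 = 0`.
#' The variance uses Chao's asymptotic formulas. With no singletons the
#' estimate is `n` itself.
#'
#' @param freq a [capture_frequencies()] result.
#' @return Object of class `mh_fit`: `N`, `N_rounded`, `se_N`, `f1`, `f2`.
#' @export
fit_mh_chao <- function(freq) {
  stopifnot(inherits(freq, "capture_freq"))
  if (freq$n < 1) abort_validation("need at least one detected individual")
  n <- freq$n
  f1 <- if (freq$K >= 1) freq$f[1] else 0L
  f2 <- if (freq$K >= 2) freq$f[2] else 0L
  if (f1 == 0) {
    N <- n; v <- 0
  } else if (f2 > 0) {
    r <- f1 / f2
    N <- n + f1^2 / (2 * f2)
    v <- f2 * (r^4 / 4 + r^3 + r^2 / 2)
  } else {
    N <- n + f1 * (f1 - 1) / 2
    v <- f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * N)
  }
  structure(list(N = N, N_rounded = as.integer(round(N)), se_N = sqrt(v),
                 f1 = f1, f2 = f2, n = n, K = freq$K),
            class = "mh_fit")
}

#' @export
print.mh_fit <- function(x, ...) {
  cat(sprintf("Mh (Chao lower bound): N-hat = %.2f (SE %.2f), n = %d, f1 = %d, f2 = %d\n",
              x$N, x$se_N, x$n, x$f1, x$f2))
  invisible(x)
}
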