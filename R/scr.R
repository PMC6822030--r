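# Maximum-likelihood SCR on a discretized state-space.
#
# Poisson point-process likelihood per session, homogeneous density D over
# the state-space S of pixels g with area a:
#   -log L = -sum_i log( sum_g D a P(y_i | s_g) ) + sum_g D a pdot(s_g) + log(n!)
# where P(y_i|s) is the product of Bernoulli terms over active site-occasions
# with p_j(s) = p0 exp(-d_j(s)^2 / (2 sigma^2)), and pdot(s) is the
# probability of at least one detection for a center at s. Detection
# probability is constant across occasions, so each individual enters through
# its per-site occasion-detection counts.

precompute_session <- function(traps, enc, ss) {
  y <- enc$y
  n <- dim(y)[1]
  Kj <- rowSums(traps$activity)                 # active occasions per site
  Y <- if (n) apply(y, c(1, 2), sum) else matrix(0L, 0, length(traps$site_id))
  Y <- matrix(as.numeric(Y), n, length(traps$site_id))
  list(d2 = dist2_matrix(ss, traps), Kj = as.numeric(Kj),
       Y = Y, KmY = sweep(-Y, 2, Kj, "+"),
       n = n, G = ss$n_pixels, a = ss$pixel_area)
}

# negative log-likelihood of one session given natural-scale-free parameters
negloglik_session <- function(p0_logit, log_sigma, log_density, pc) {
  p0 <- stats::plogis(p0_logit)
  sigma <- exp(log_sigma)
  logp <- log(p0) - pc$d2 / (2 * sigma^2)       # G x J
  P <- pmin(exp(logp), 1 - 1e-12)
  log1mp <- log1p(-P)
  log_p0dot <- drop(log1mp %*% pc$Kj)           # log Pr(no detection | s_g)
  Da <- exp(log_density) * pc$a
  expo <- Da * sum(1 - exp(log_p0dot))
  if (pc$n == 0) return(expo)
  V <- logp %*% t(pc$Y) + log1mp %*% t(pc$KmY)  # G x n: log P(y_i | s_g)
  sum_i <- sum(log(Da) + col_logsumexp(V))
  -sum_i + expo + lgamma(pc$n + 1)
}

unpack_params <- function(theta, ng, S) {
  list(p0_logit = theta[seq_len(ng)],
       log_sigma = theta[ng + seq_len(ng)],
       log_density = theta[2 * ng + seq_len(S)])
}

#' Joint negative log-likelihood of a multi-session SCR model
#'
#' Sum over sessions of the Poisson point-process SCR likelihood with the
#' half-normal detection function, marginalizing each individual's activity
#' center over the state-space pixels in log space (no underflow for valid
#' inputs). Detection parameters are shared within sharing groups; density is
#' per session.
#'
#' @param params list with numeric vectors `p0_logit` and `log_sigma` (one
#'   entry per sharing group) and `log_density` (log individuals per m2, one
#'   entry per session).
#' @param sessions a [session_set()] (or coercible list of sessions).
#' @param statespaces a [state_space()] or list of them, one per session.
#' @return The negative log-likelihood (finite for finite parameters).
#' @export
scr_negloglik <- function(params, sessions, statespaces) {
  sessions <- session_set(sessions)
  S <- length(sessions$sessions)
  if (inherits(statespaces, "state_space")) statespaces <- list(statespaces)
  if (length(statespaces) == 1L) statespaces <- rep(statespaces, S)
  if (any(!is.finite(c(params$p0_logit, params$log_sigma, params$log_density))))
    abort_validation("parameters must be finite")
  grp <- as.integer(sessions$sharing)
  total <- 0
  for (s in seq_len(S)) {
    pc <- precompute_session(sessions$sessions[[s]]$traps,
                             sessions$sessions[[s]]$encounters,
                             statespaces[[s]])
    total <- total + negloglik_session(params$p0_logit[grp[s]],
                                       params$log_sigma[grp[s]],
                                       params$log_density[s], pc)
  }
  total
}

# method-of-moments starting values: sigma0 = MMDM/2, p0 = 0.1, D0 = n/A
scr_start <- function(sessions, statespaces) {
  maxima <- numeric(0)
  for (s in sessions$sessions) {
    m <- individual_max_moves(s$encounters, s$traps)
    maxima <- c(maxima, m)
  }
  if (length(maxima) && mean(maxima) > 0) {
    sigma0 <- mean(maxima) / 2
  } else {
    # fall back on the trap spacing when no individual moved between sites
    tr <- sessions$sessions[[1]]$traps
    if (length(tr$x) > 1) {
      dm <- sqrt(outer(tr$x, tr$x, "-")^2 + outer(tr$y, tr$y, "-")^2)
      diag(dm) <- Inf
      sigma0 <- stats::median(apply(dm, 1, min))
    } else sigma0 <- statespaces[[1]]$resolution * 2
  }
  S <- length(sessions$sessions)
  logD0 <- vapply(seq_len(S), function(s) {
    n <- max(1L, dim(sessions$sessions[[s]]$encounters$y)[1])
    log(n / state_space_area(statespaces[[s]]))
  }, numeric(1))
  list(p0_logit = stats::qlogis(0.1), log_sigma = log(sigma0), log_density = logD0)
}

#' Fit a spatial capture-recapture model
#'
#' Maximizes the Poisson point-process SCR likelihood with half-normal
#' detection over unconstrained parameters (`logit p0`, `log sigma` per
#' sharing group; `log density` per session) by quasi-Newton (BFGS)
#' multi-start optimization. Starting values come from a method-of-moments
#' initializer (`sigma0` = half the mean maximum distance moved, `p0` = 0.1,
#' `D0` = detected individuals / state-space area), with additional starts at
#' fixed offsets from it. The variance matrix is the inverse observed
#' information from a finite-difference Hessian; per-session expected
#' abundance over the state-space is `N = D * A(S)` with delta-method
#' standard errors.
#'
#' @param sessions a [session_set()], or a single session given as a list
#'   with `traps` and `encounters`.
#' @param sharing optional sharing vector passed to [session_set()] when
#'   `sessions` is a plain list.
#' @param buffer state-space buffer in meters (default 15000).
#' @param resolution state-space pixel side in meters (default 1500).
#' @param statespaces optional list of pre-built [state_space()] objects
#'   (overrides `buffer`/`resolution`).
#' @param n_starts number of optimizer starts (default 3).
#' @param control passed to [stats::optim()].
#' @return Object of class `scr_fit`: estimates, `vcov`, `logLik`,
#'   per-session abundance/density with SEs, convergence diagnostics.
#' @seealso [density_surface()], [summary.scr_fit()], [simulate.scr_fit()]
#' @export
fit_scr <- function(sessions, sharing = NULL, buffer = 15000, resolution = 1500,
                    statespaces = NULL, n_starts = 3, control = list()) {
  if (!inherits(sessions, "session_set")) {
    if (!is.null(sessions$traps)) sessions <- list(sessions)
    sessions <- session_set(sessions, sharing)
  }
  S <- length(sessions$sessions)
  ng <- nlevels(sessions$sharing)
  grp <- as.integer(sessions$sharing)
  for (g in seq_len(ng)) {
    if (sum(vapply(which(grp == g),
                   function(s) dim(sessions$sessions[[s]]$encounters$y)[1],
                   integer(1))) == 0)
      abort_validation(sprintf("sharing group %s has no detected individual",
                               levels(sessions$sharing)[g]))
  }
  if (is.null(statespaces)) {
    statespaces <- lapply(sessions$sessions, function(s)
      build_state_space(s$traps, buffer = buffer, resolution = resolution))
  } else {
    if (inherits(statespaces, "state_space")) statespaces <- list(statespaces)
    if (length(statespaces) == 1L) statespaces <- rep(statespaces, S)
  }
  pcs <- lapply(seq_len(S), function(s)
    precompute_session(sessions$sessions[[s]]$traps,
                       sessions$sessions[[s]]$encounters, statespaces[[s]]))
  ns <- vapply(pcs, function(pc) pc$n, numeric(1))
  # full joint negative log-likelihood over (p0_logit, log_sigma, log_density)
  nll <- function(theta) {
    if (any(!is.finite(theta))) return(1e12)
    p <- unpack_params(theta, ng, S)
    v <- 0
    for (s in seq_len(S))
      v <- v + negloglik_session(p$p0_logit[grp[s]], p$log_sigma[grp[s]],
                                 p$log_density[s], pcs[[s]])
    if (!is.finite(v)) 1e12 else v
  }
  # density profiles out analytically in the Poisson form: given the detection
  # parameters, the per-session MLE is D = n / (a * sum_g pdot(s_g)), so the
  # optimizer only searches the detection scale
  profile_logD <- function(det) {
    vapply(seq_len(S), function(s) {
      pc <- pcs[[s]]
      if (pc$n == 0) return(-Inf)
      p0 <- stats::plogis(det[grp[s]]); sigma <- exp(det[ng + grp[s]])
      logp <- log(p0) - pc$d2 / (2 * sigma^2)
      log1mp <- log1p(-pmin(exp(logp), 1 - 1e-12))
      Esum <- pc$a * sum(1 - exp(drop(log1mp %*% pc$Kj)))
      log(pc$n) - log(Esum)
    }, numeric(1))
  }
  nll_profile <- function(det) {
    if (any(!is.finite(det))) return(1e12)
    v <- nll(c(det, pmax(profile_logD(det), -744)))
    if (!is.finite(v)) 1e12 else v
  }
  st <- scr_start(sessions, statespaces)
  # deterministic multi-start offsets around the moment initializer
  offsets <- list(c(0, 0), c(0.6, -0.4), c(-0.6, 0.4), c(1.2, 0.6), c(-1.2, -0.6))
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
  best <- NULL
  for (i in seq_len(min(n_starts, length(offsets)))) {
    off <- offsets[[i]]
    start <- c(rep(st$p0_logit + off[1], ng), rep(st$log_sigma + off[2], ng))
    opt <- try(stats::optim(start, nll_profile, method = "BFGS", control = ctrl),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) abort("all optimizer starts failed", "scrdens_numerical_error")
  theta <- c(best$par, profile_logD(best$par))
  keep <- c(rep(TRUE, 2 * ng), ns > 0)    # drop -Inf densities of empty sessions
  H <- num_hessian(function(th) { full <- theta; full[keep] <- th; nll(full) },
                   theta[keep])
  grad_norm <- {
    h <- 1e-6 * (abs(theta[keep]) + 1)
    g <- vapply(seq_len(sum(keep)), function(i) {
      e <- numeric(sum(keep)); e[i] <- h[i]
      thp <- theta; thp[keep] <- theta[keep] + e
      thm <- theta; thm[keep] <- theta[keep] - e
      (nll(thp) - nll(thm)) / (2 * h[i])
    }, numeric(1))
    sqrt(sum(g^2))
  }
  converged <- best$convergence == 0
  if (!converged)
    warning("optimizer did not report convergence (code ", best$convergence, ")")
  vc_red <- try(solve(H), silent = TRUE)
  vc <- matrix(NA_real_, length(theta), length(theta))
  if (inherits(vc_red, "try-error") || !all(is.finite(vc_red)) ||
      any(diag(vc_red) < 0)) {
    warning("observed information is singular; standard errors unavailable")
  } else {
    vc_red <- (vc_red + t(vc_red)) / 2
    vc[keep, keep] <- vc_red
  }
  p <- unpack_params(theta, ng, S)
  se <- suppressWarnings(sqrt(diag(vc)))
  pse <- unpack_params(se, ng, S)
  A <- vapply(statespaces, state_space_area, numeric(1))
  D <- exp(p$log_density)               # per m2
  Nhat <- D * A
  se_N <- Nhat * pse$log_density        # delta method on log scale
  D100 <- D * 1e8                       # per 100 km2
  se_D100 <- D100 * pse$log_density
  sigma_hat <- exp(p$log_sigma)
  for (s in seq_len(S)) {
    if (is.finite(sigma_hat[grp[s]]) && is.finite(statespaces[[s]]$buffer) &&
        statespaces[[s]]$buffer < 2 * sigma_hat[grp[s]])
      warning(sprintf("session %s: buffer (%.0f m) < 2 sigma-hat (%.0f m)",
                      sessions$labels[s], statespaces[[s]]$buffer,
                      2 * sigma_hat[grp[s]]))
  }
  names(theta) <- c(paste0("p0_logit.", levels(sessions$sharing)),
                    paste0("log_sigma.", levels(sessions$sharing)),
                    paste0("log_density.", sessions$labels))
  dimnames(vc) <- list(names(theta), names(theta))
  per_session <- data.frame(
    session = sessions$labels,
    group = as.character(sessions$sharing),
    n = vapply(pcs, function(pc) pc$n, numeric(1)),
    detections = vapply(sessions$sessions,
                        function(s) sum(s$encounters$y), numeric(1)),
    area_km2 = A / 1e6,
    N = Nhat, se_N = se_N,
    D_per_100km2 = D100, se_D = se_D100,
    row.names = NULL)
  structure(list(
    coefficients = theta, vcov = vc, logLik = -best$value,
    params = p, se = pse, sessions = sessions, statespaces = statespaces,
    per_session = per_session, sharing = sessions$sharing,
    converged = converged, grad_norm = grad_norm,
    n_params = length(theta)),
    class = "scr_fit")
}

#' @export
print.scr_fit <- function(x, ...) {
  cat("Spatial capture-recapture fit (half-normal detection, ML)\n")
  cat(sprintf("  log-likelihood: %.4f  (%d parameters, converged: %s)\n",
              x$logLik, x$n_params, x$converged))
  ng <- length(x$params$p0_logit)
  for (g in seq_len(ng))
    cat(sprintf("  group %s: p0 = %.4f (logit %.3f), sigma = %.0f m (log %.3f)\n",
                levels(x$sharing)[g], stats::plogis(x$params$p0_logit[g]),
                x$params$p0_logit[g], exp(x$params$log_sigma[g]),
                x$params$log_sigma[g]))
  print(x$per_session[, c("session", "n", "N", "se_N", "D_per_100km2", "se_D")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.scr_fit <- function(object, ...) object$coefficients

#' @export
vcov.scr_fit <- function(object, ...) object$vcov

#' @export
logLik.scr_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_params, class = "logLik")
}

#' Summarize an SCR fit
#'
#' Detection and movement estimates per sharing group and abundance/density
#' per session (density in individuals per 100 km2), with standard errors.
#'
#' @param object an [fit_scr()] result.
#' @param ... unused.
#' @export
summary.scr_fit <- function(object, ...) {
  ng <- length(object$params$p0_logit)
  detection <- data.frame(
    group = levels(object$sharing),
    p0_logit = object$params$p0_logit, se_p0_logit = object$se$p0_logit,
    log_sigma = object$params$log_sigma, se_log_sigma = object$se$log_sigma,
    p0 = stats::plogis(object$params$p0_logit),
    sigma_m = exp(object$params$log_sigma),
    row.names = NULL)
  structure(list(detection = detection, per_session = object$per_session,
                 logLik = object$logLik, converged = object$converged,
                 grad_norm = object$grad_norm),
            class = "summary.scr_fit")
}

#' @export
print.summary.scr_fit <- function(x, ...) {
  cat("Detection / movement (per sharing group):\n")
  print(x$detection, digits = 4, row.names = FALSE)
  cat("\nAbundance / density (per session):\n")
  print(x$per_session, digits = 4, row.names = FALSE)
  cat(sprintf("\nlog-likelihood %.4f; gradient norm %.2e; converged: %s\n",
              x$logLik, x$grad_norm, x$converged))
  invisible(x)
}

#' Predict from an SCR fit
#'
#' `type = "density"` returns the pixel density surface of a session (see
#' [density_surface()]); `type = "detection"` evaluates the fitted
#' half-normal detection curve at distances `d`.
#'
#' @param object an `scr_fit`.
#' @param type `"density"` or `"detection"`.
#' @param session session index or label for `type = "density"`.
#' @param d distances (m) for `type = "detection"`.
#' @param group sharing-group index for `type = "detection"`.
#' @param ... unused.
#' @export
predict.scr_fit <- function(object, type = c("density", "detection"),
                            session = 1, d = NULL, group = 1, ...) {
  type <- match.arg(type)
  if (type == "density") return(density_surface(object, session))
  if (is.null(d)) d <- seq(0, 4 * exp(object$params$log_sigma[group]), length.out = 200)
  data.frame(d = d, p = half_normal_p(d, stats::plogis(object$params$p0_logit[group]),
                                      exp(object$params$log_sigma[group])))
}

#' Simulate encounter data from a fitted SCR model
#'
#' Parametric-bootstrap replicates: for each session, draws
#' `N ~ Poisson(D_hat * A)` activity centers and half-normal Bernoulli
#' detections at the fitted parameter values.
#'
#' @param object an `scr_fit`.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of length `nsim`; each element is a list (one per session) of
#'   [simulate_scr()] results.
#' @export
simulate.scr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  grp <- as.integer(object$sharing)
  lapply(seq_len(nsim), function(r) {
    lapply(seq_along(object$sessions$sessions), function(s) {
      simulate_scr(object$sessions$sessions[[s]]$traps, object$statespaces[[s]],
                   p0 = stats::plogis(object$params$p0_logit[grp[s]]),
                   sigma = exp(object$params$log_sigma[grp[s]]),
                   density = exp(object$params$log_density[s]),
                   session_id = object$sessions$labels[s])
    })
  })
}

#' Marginal likelihood of one encounter history
#'
#' Probability of an individual's site-by-occasion history with its activity
#' center marginalized uniformly over the state-space pixels:
#' `(1/G) * sum_g prod_{j,k active} p_j(s_g)^y (1-p_j(s_g))^(1-y)`, computed
#' in log space.
#'
#' @param y_i binary site x occasion matrix, consistent with the activity
#'   mask of `traps`.
#' @param traps a [trap_array()].
#' @param ss a [state_space()].
#' @param p0,sigma half-normal detection parameters.
#' @return The marginal probability (a single number in `[0, 1]`).
#' @export
marginal_individual_lik <- function(y_i, traps, ss, p0, sigma) {
  y_i <- as.matrix(y_i)
  if (!all(y_i %in% c(0, 1)) || any(y_i == 1 & traps$activity == 0))
    abort_validation("y_i must be binary and zero on inactive site-occasions")
  if (p0 < 0 || p0 > 1 || sigma <= 0)
    abort_validation("need p0 in [0, 1] and sigma > 0")
  if (p0 == 0) {
    # degenerate: nothing can ever be detected
    return(if (sum(y_i) == 0) 1 else 0)
  }
  Yj <- rowSums(y_i)                      # occasion-detections per site
  Kj <- rowSums(traps$activity)           # active occasions per site
  d2 <- dist2_matrix(ss, traps)
  logp <- log(p0) - d2 / (2 * sigma^2)
  P <- pmin(exp(logp), 1 - 1e-12)
  log1mp <- log1p(-P)
  v <- drop(logp %*% Yj + log1mp %*% (Kj - Yj))
  exp(logsumexp(v) - log(ss$n_pixels))
}
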