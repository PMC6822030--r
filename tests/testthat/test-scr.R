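test_that("marginal individual likelihood averages over pixels", {
  # two pixels with detection probabilities 0.2 and 0.4, one trap, one occasion
  sigma <- 1000
  dstar <- sigma * sqrt(2 * log(2))        # half-maximum distance
  ss <- state_space(c(0, dstar), c(0, 0), resolution = 1000)
  traps <- trap_array("T1", dstar, 0, matrix(1L, 1, 1))
  y1 <- matrix(1L, 1, 1)
  expect_equal(marginal_individual_lik(y1, traps, ss, 0.4, sigma), 0.3,
               tolerance = 1e-12)
  # single pixel: plain product of Bernoulli terms at that pixel
  ss1 <- state_space(0, 0, resolution = 1000)
  traps2 <- trap_array("T1", 3000, 0, matrix(1L, 1, 2))
  p <- half_normal_p(3000, 0.5, sigma)
  y2 <- matrix(c(1L, 0L), 1, 2)
  expect_equal(marginal_individual_lik(y2, traps2, ss1, 0.5, sigma),
               p * (1 - p), tolerance = 1e-12)
  # p0 = 0: an all-zero history is certain
  y0 <- matrix(0L, 1, 2)
  expect_equal(marginal_individual_lik(y0, traps2, ss1, 0, sigma), 1)
})

test_that("negative log-likelihood equals brute-force enumeration on tiny instances", {
  for (seed in 1:40) {
    inst <- random_tiny_instance(seed)
    sess <- list(list(traps = inst$traps, encounters = inst$enc))
    params <- list(p0_logit = qlogis(inst$p0), log_sigma = log(inst$sigma),
                   log_density = log(inst$D))
    got <- scr_negloglik(params, sess, inst$ss)
    want <- brute_negloglik(inst$p0, inst$sigma, inst$D, inst$traps, inst$enc, inst$ss)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under translation of the coordinate system", {
  inst <- random_tiny_instance(5)
  params <- list(p0_logit = qlogis(inst$p0), log_sigma = log(inst$sigma),
                 log_density = log(inst$D))
  v1 <- scr_negloglik(params, list(list(traps = inst$traps, encounters = inst$enc)),
                      inst$ss)
  tr2 <- trap_array(inst$traps$site_id, inst$traps$x + 1e4, inst$traps$y - 1e4,
                    inst$traps$activity)
  enc2 <- inst$enc
  ss2 <- state_space(inst$ss$x + 1e4, inst$ss$y - 1e4, inst$ss$resolution)
  v2 <- scr_negloglik(params, list(list(traps = tr2, encounters = enc2)), ss2)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("on a detection-free session the likelihood is exactly the exposure term", {
  traps <- make_checkerboard_traps(3, 3, n_occasions = 4)
  ss <- build_state_space(traps, buffer = 5000, resolution = 2500)
  enc0 <- encounter_data(array(0L, c(0, length(traps$site_id), 4)), traps)
  sess <- list(list(traps = traps, encounters = enc0))
  D <- 1e-7
  p <- list(p0_logit = qlogis(0.2), log_sigma = log(3000), log_density = log(D))
  p2 <- list(p0_logit = qlogis(0.2), log_sigma = log(3000), log_density = log(2 * D))
  v1 <- scr_negloglik(p, sess, ss)
  v2 <- scr_negloglik(p2, sess, ss)
  # doubling D adds the exposure term once more
  expect_equal(v2 - v1, v1, tolerance = 1e-9)
  # and the exposure term is sum_g D a pdot(s_g), computed directly
  pdot <- vapply(seq_len(ss$n_pixels), function(g) {
    d <- sqrt((ss$x[g] - traps$x)^2 + (ss$y[g] - traps$y)^2)
    1 - prod((1 - half_normal_p(d, 0.2, 3000))^rowSums(traps$activity))
  }, numeric(1))
  expect_equal(v1, D * ss$pixel_area * sum(pdot), tolerance = 1e-9)
})

test_that("sharing two identical sessions equals fitting the doubled session", {
  s <- small_sim_session(seed = 21)
  sim <- s$sim
  two <- session_set(list(list(traps = sim$traps, encounters = sim$encounters),
                          list(traps = sim$traps, encounters = sim$encounters)),
                     sharing = c(1, 1))
  fit2 <- suppressWarnings(fit_scr(two, statespaces = s$ss, n_starts = 1))
  ydoub <- array(0L, c(2 * dim(sim$encounters$y)[1], dim(sim$encounters$y)[2],
                       dim(sim$encounters$y)[3]))
  ydoub[seq_len(dim(sim$encounters$y)[1]), , ] <- sim$encounters$y
  ydoub[dim(sim$encounters$y)[1] + seq_len(dim(sim$encounters$y)[1]), , ] <- sim$encounters$y
  encd <- encounter_data(ydoub, sim$traps)
  fitd <- suppressWarnings(fit_scr(list(traps = sim$traps, encounters = encd),
                                   statespaces = s$ss, n_starts = 1))
  expect_equal(fit2$params$p0_logit, fitd$params$p0_logit, tolerance = 1e-3)
  expect_equal(fit2$params$log_sigma, fitd$params$log_sigma, tolerance = 1e-3)
  # both sessions of the shared fit get the same density; the doubled session twice that
  expect_equal(fit2$params$log_density[1], fit2$params$log_density[2], tolerance = 1e-3)
  expect_equal(exp(fitd$params$log_density), 2 * exp(fit2$params$log_density[1]),
               tolerance = 2e-3)
})

test_that("degenerate single-pixel model matches a grid-search MLE", {
  # one trap on the only pixel: distance 0, so only p0 and Lambda = D a matter
  ss <- state_space(0, 0, resolution = 1000)
  traps <- trap_array("T1", 0, 0, matrix(1L, 1, 5))
  y <- array(0L, c(3, 1, 5))
  y[1, 1, ] <- c(1L, 1L, 0L, 0L, 0L)
  y[2, 1, ] <- c(1L, 0L, 1L, 1L, 0L)
  y[3, 1, ] <- c(0L, 0L, 0L, 0L, 1L)
  enc <- encounter_data(y, traps)
  fit <- suppressWarnings(fit_scr(list(traps = traps, encounters = enc),
                                  statespaces = ss, n_starts = 2))
  # independent oracle: grid over (p0, Lambda) of the same degenerate model
  nll <- function(p0, lam) {
    pdet <- 1 - (1 - p0)^5
    li <- vapply(1:3, function(i) {
      k <- sum(y[i, 1, ])
      lam * p0^k * (1 - p0)^(5 - k)
    }, numeric(1))
    -sum(log(li)) + lam * pdet + lgamma(4)
  }
  grid <- expand.grid(p0 = seq(0.01, 0.8, by = 0.002),
                      lam = seq(3, 15, by = 0.02))
  vals <- mapply(nll, grid$p0, grid$lam)
  best <- grid[which.min(vals), ]
  expect_equal(plogis(fit$params$p0_logit), best$p0, tolerance = 0.01)
  expect_equal(exp(fit$params$log_density) * ss$pixel_area, best$lam,
               tolerance = 0.05)
})

test_that("fitting requires detected individuals and reports convergence diagnostics", {
  traps <- make_checkerboard_traps(3, 3, n_occasions = 4)
  ss <- build_state_space(traps, buffer = 5000, resolution = 2500)
  enc0 <- encounter_data(array(0L, c(0, length(traps$site_id), 4)), traps)
  expect_error(fit_scr(list(traps = traps, encounters = enc0), statespaces = ss),
               class = "scrdens_validation_error")
  s <- small_sim_session(seed = 33)
  fit <- suppressWarnings(fit_scr(list(traps = s$sim$traps, encounters = s$sim$encounters),
                                  statespaces = s$ss, n_starts = 1))
  expect_true(is.finite(fit$grad_norm))
  expect_true(fit$converged)
  expect_true(isSymmetric(fit$vcov))
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  expect_equal(fit$per_session$N,
               fit$per_session$D_per_100km2 / 100 * fit$per_session$area_km2)
})

test_that("print, summary, coef, vcov, logLik, predict and simulate methods work", {
  s <- small_sim_session(seed = 2)
  fit <- suppressWarnings(fit_scr(list(traps = s$sim$traps, encounters = s$sim$encounters),
                                  statespaces = s$ss, n_starts = 1))
  expect_output(print(fit), "Spatial capture-recapture")
  expect_output(print(summary(fit)), "Detection / movement")
  expect_length(coef(fit), 3)
  expect_equal(dim(vcov(fit)), c(3, 3))
  expect_s3_class(logLik(fit), "logLik")
  pd <- predict(fit, type = "detection", d = c(0, 1000))
  expect_equal(pd$p[1], plogis(fit$params$p0_logit))
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]][[1]]$encounters, "encounter_data")
})

test_that("density surfaces conserve abundance and respect information limits", {
  s <- small_sim_session(seed = 14)
  fit <- suppressWarnings(fit_scr(list(traps = s$sim$traps, encounters = s$sim$encounters),
                                  statespaces = s$ss, n_starts = 1))
  surf <- density_surface(fit)
  expect_equal(sum(surf$density), fit$per_session$N[1], tolerance = 1e-6)
  expect_true(all(surf$density >= 0))

  # p0 -> 0 with no detections: flat surface at D a everywhere
  traps <- s$sim$traps
  enc0 <- encounter_data(array(0L, c(0, length(traps$site_id), ncol(traps$activity))), traps)
  fake <- fit
  fake$sessions <- session_set(list(list(traps = traps, encounters = enc0)))
  fake$params$p0_logit <- qlogis(1e-10)
  surf0 <- density_surface(fake)
  Da <- exp(fake$params$log_density[1]) * s$ss$pixel_area
  expect_equal(surf0$density, rep(Da, s$ss$n_pixels), tolerance = 1e-6)

  # posterior concentration: many detections at one site, small sigma
  j0 <- 8
  K <- ncol(traps$activity)
  y1 <- array(0L, c(1, length(traps$site_id), K))
  y1[1, j0, ] <- 1L
  enc1 <- encounter_data(y1, traps)
  fake2 <- fit
  fake2$sessions <- session_set(list(list(traps = traps, encounters = enc1)))
  fake2$params$log_sigma <- log(400)
  surf2 <- density_surface(fake2)
  g_best <- which.max(surf2$density)
  expect_lt(sqrt((surf2$x[g_best] - traps$x[j0])^2 +
                 (surf2$y[g_best] - traps$y[j0])^2),
            s$ss$resolution)  # the argmax pixel holds the site
})

test_that("abundance scales with state-space area at fixed density; density is buffer-stable", {
  s <- small_sim_session(seed = 40, sigma = 2500, p0 = 0.5, N = 25)
  sim <- s$sim
  fit1 <- suppressWarnings(fit_scr(list(traps = sim$traps, encounters = sim$encounters),
                                   buffer = 7500, resolution = 1500, n_starts = 1))
  fit2 <- suppressWarnings(fit_scr(list(traps = sim$traps, encounters = sim$encounters),
                                   buffer = 12000, resolution = 1500, n_starts = 1))
  A1 <- fit1$per_session$area_km2
  A2 <- fit2$per_session$area_km2
  expect_gt(A2, A1)
  # same density applied to a larger state-space means more expected centers
  expect_gt(fit1$per_session$D_per_100km2[1] / 100 * A2, fit1$per_session$N[1])
  # enlarging the buffer beyond ~2 sigma moves density by less than one SE
  expect_lt(abs(fit2$per_session$D_per_100km2[1] - fit1$per_session$D_per_100km2[1]),
            fit1$per_session$se_D[1])
})
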