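# a cheap analytical forward map for estimator checks: Q(lambda) = gamma1^2
toy_problem <- function(statistic = 1L) {
  calibration_problem(statistic = statistic,
                      forward = function(lambda, seed) lambda[[1L]]^2)
}

test_that("the forward map is reproducible and validates its domain", {
  prob <- calibration_problem(statistic = 1, R = 1, steps = 3,
                              grid = hex_grid(12, 12),
                              bd = bd_spec(M = 5))
  q1 <- forward_map(c(0.7, 1 / 3), prob, seed = 5)
  q2 <- forward_map(c(0.7, 1 / 3), prob, seed = 5)
  expect_identical(q1, q2)
  expect_error(forward_map(c(0.2, 1 / 3), prob), "outside")
  expect_error(forward_map(c(0.7, 0.9), prob), "outside")
})

test_that("forward variance shrinks like 1/R", {
  # CLT scaling of the replicate average, on a fast small problem
  grid <- hex_grid(10, 10)
  base <- calibration_problem(statistic = 1, R = 1, steps = 3, grid = grid,
                              bd = bd_spec(M = 3))
  lam <- c(0.7, 1 / 3)
  vars <- sapply(c(1L, 4L), function(R) {
    p <- base; p$R <- R
    var(vapply(1:40, function(s) forward_map(lam, p, seed = s), numeric(1)))
  })
  # quadrupling R should cut the variance by roughly 4 (allow 2x slack)
  expect_lt(vars[2], vars[1] / 2)
})

test_that("the affected-cell statistic grows with the survival baseline phi", {
  grid <- hex_grid(15, 15)
  prob <- calibration_problem(statistic = 1, R = 4, steps = 8, grid = grid,
                              bd = bd_spec(M = 5))
  lo <- forward_map(c(0.7, 0.18), prob, seed = 2)
  hi <- forward_map(c(0.7, 0.70), prob, seed = 2)
  expect_gt(hi, lo)
})

test_that("synthetic observations concentrate for a point-mass generator", {
  prob <- toy_problem()
  obs <- synthetic_observations(prob, n = 30, reps = 2,
                                mean = c(0.7, 1 / 3), sd = 1e-9, seed = 4)
  expect_length(obs$data, 30L)
  expect_lt(diff(range(obs$data)), 1e-6)
  expect_equal(mean(obs$data), 0.49, tolerance = 1e-4)
  # draws respect the domain box
  expect_true(all(obs$lambda[, 1] >= 0.4 & obs$lambda[, 1] <= 1))
})

test_that("consistent-Bayes identity: matching densities give uniform weights", {
  prob <- toy_problem()
  # use the prior-pushforward sample itself as the observed data: both
  # kernel estimates then coincide and every weight ratio is exactly 1
  set.seed(6)
  post0 <- sip_posterior(prob, observations = stats::runif(200, 0.16, 1),
                         n_prior = 200, seed = 6)
  obs <- structure(list(data = post0$Q, generator = "synthetic"),
                   class = "observation_set")
  post <- sip_posterior(prob, obs, n_prior = 200, seed = 6)
  expect_equal(max(post$weights), min(post$weights), tolerance = 1e-12)
  expect_equal(sum(post$weights), 1, tolerance = 1e-12)
})

test_that("the posterior pushforward matches the observed-data density", {
  # pushforward-consistency on the 1-D toy map Q = gamma1^2: reweighted
  # forward values should be distributed like the observations
  prob <- toy_problem()
  set.seed(7)
  lam_true <- cbind(stats::runif(4000, 0.55, 0.85), 0.3)
  obs <- structure(list(data = lam_true[, 1]^2, generator = "synthetic"),
                   class = "observation_set")
  post <- sip_posterior(prob, obs, n_prior = 2000, seed = 7)
  # weighted resample of Q from the posterior
  idx <- sample(length(post$Q), 4000, replace = TRUE, prob = post$weights)
  qs <- post$Q[idx]
  # ties from resampling are expected; only the statistic matters here
  ks <- suppressWarnings(stats::ks.test(qs, obs$data))
  expect_lt(ks$statistic, 0.08)
})

test_that("posterior weights are a distribution supported on the domain", {
  prob <- toy_problem()
  set.seed(8)
  obs <- structure(list(data = runif(100, 0.2, 0.9), generator = "s"),
                   class = "observation_set")
  post <- sip_posterior(prob, obs, n_prior = 300, seed = 8)
  expect_true(all(post$weights >= 0))
  expect_equal(sum(post$weights), 1)
  expect_true(all(post$samples[, 1] >= 0.4 & post$samples[, 1] <= 1))
  expect_true(all(post$samples[, 2] >= 1 / 6))
})

test_that("observations outside the reachable range are dropped with a warning", {
  prob <- toy_problem()
  obs <- structure(list(data = c(0.5, 25), generator = "s"),
                   class = "observation_set")
  expect_warning(post <- sip_posterior(prob, obs, n_prior = 200, seed = 9),
                 "dropped")
  expect_error(sip_posterior(prob, structure(list(data = 1e6, generator = "s"),
                                             class = "observation_set"),
                             n_prior = 100, seed = 9),
               "support mismatch")
})

test_that("posterior summaries handle uniform and degenerate weights", {
  prob <- toy_problem()
  post <- list(samples = cbind(gamma1 = runif(500, 0.4, 1),
                               phi = runif(500, 1 / 6, 0.7)),
               weights = rep(1 / 500, 500), problem = prob)
  class(post) <- "sip_posterior"
  ps <- posterior_summaries(post)
  # flat marginals up to estimator noise
  dens <- ps$marginals$gamma1$y
  expect_lt(max(dens), 2.6 * (1 / 0.6))
  expect_equal(sum(ps$joint$z > 0) > 100, TRUE)
  # weights concentrated on one sample: mean equals that sample
  w2 <- rep(0, 500); w2[17] <- 1
  post2 <- post; post2$weights <- w2
  ps2 <- posterior_summaries(post2)
  expect_equal(unname(ps2$mean), unname(post$samples[17, ]))
  post3 <- post; post3$weights <- rep(0, 500)
  expect_error(posterior_summaries(post3), "degenerate")
})

test_that("image conversion thresholds, quantizes and clamps as specified", {
  # all-black image converts to an all-zero field
  black <- matrix(0, 40, 40)
  expect_true(all(image_to_density(black, noise = FALSE) == 0))
  # uniform grey level 230: retained at 230/256
  grey <- matrix(230 / 255, 40, 40)
  d <- image_to_density(grey, noise = FALSE)
  expect_true(all(d == 230 / 256))
  # noisy conversion stays in [0, 1]; isolated zeros stay zero
  img <- matrix(0, 32, 32)
  img[10:14, 10:14] <- 220 / 255
  dn <- image_to_density(img, noise = TRUE, seed = 3)
  expect_true(all(dn >= 0 & dn <= 1))
  base <- image_to_density(img, noise = FALSE)
  st <- hexsca:::hex_neighbor_stats(base)
  far <- base == 0 & st$na == 0L
  expect_true(all(dn[far] == 0))
  expect_error(image_to_density(img, target = c(64, 64)), "exceed")
})

test_that("the synthetic survey image round-trips through the conversion", {
  g <- hex_grid(32, 32)
  img <- make_fixture("synthetic-survey-image", g, seed = 5)
  path <- tempfile(fileext = ".png")
  make_fixture("synthetic-survey-image", g, seed = 5, path = path)
  d_mat <- image_to_density(img, noise = FALSE)
  d_png <- image_to_density(path, noise = FALSE)
  expect_equal(d_png, d_mat)
  # planted blob recovered exactly above the threshold
  planted <- floor(img * 255 + 0.5) / 256
  planted[planted < 0.8] <- 0
  expect_equal(d_mat, planted)
  expect_gt(sum(d_mat > 0), 0)
})
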