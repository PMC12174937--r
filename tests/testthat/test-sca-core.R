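test_that("inclusion probability follows the weight/difference law", {
  # isolated affected cell: half of its density
  for (p in seq(0.1, 1, by = 0.1))
    expect_equal(inclusion_probability(1, p), p / 2)
  expect_equal(inclusion_probability(0, 0.9), 0)
  # general form with emphasis exponents
  expect_equal(inclusion_probability(3, 0.6, alpha = 2, beta = 2),
               ((9 / 10) * 0.6)^2)
  expect_equal(inclusion_probability(3, 0.6, alpha = 2, beta = 2), 0.2916)
  expect_error(inclusion_probability(1, 0.5, alpha = 0), "positive")
  expect_error(inclusion_probability(1, 0.5, beta = -1), "positive")
})

test_that("survival probability is the shifted arctangent, within [0, 1]", {
  expect_equal(survival_probability(0, 1 / 3, 1 / 3), 1 / 3)
  expect_equal(survival_probability(1, 1 / 3, 1 / 3),
               1 / 3 + (1 / 3) * (pi / 4))
  expect_error(survival_probability(0.5, 0.9, 0.5), "exceeds 1")
  # monotone nondecreasing in the density
  x <- seq(0, 1, length.out = 50)
  expect_true(all(diff(survival_probability(x, 0.2, 0.3, xi = 2)) >= 0))
})

test_that("probabilities stay in [0, 1] over randomized parameters", {
  set.seed(3)
  for (rep in 1:200) {
    w <- sample(0:6, 1); d <- runif(1)
    a <- runif(1, 0.1, 3); b <- runif(1, 0.1, 3)
    p <- inclusion_probability(w, d, a, b)
    expect_gte(p, 0); expect_lte(p, 1)
    xi <- runif(1, 0.1, 4); rho <- runif(1, 0, 0.99 / atan(xi))
    phi <- runif(1, 0, 1 - rho * atan(xi))
    ps <- survival_probability(runif(1), phi, rho, xi)
    expect_gte(ps, 0); expect_lte(ps, 1)
  }
})

test_that("partition and pool follow the mean-density rule", {
  # the printed single-cell example: one affected cell among five included
  pp <- partition_and_pool(c(1, 0, 0, 0, 0), gamma1 = 0.8)
  expect_equal(pp$mean_density, 0.2)
  expect_equal(sum(pp$contributors), 1L)
  expect_equal(pp$pool, 4 * 0.8 * 1 / 5)
  # ties at the mean contribute zero and the pool vanishes
  pp2 <- partition_and_pool(rep(0.4, 6), gamma1 = 0.8)
  expect_true(all(pp2$contributors))
  expect_equal(pp2$pool, 0)
  # hand-evaluated mixed case
  pp3 <- partition_and_pool(c(0.9, 0.3, 0, 0), gamma1 = 0.8)
  expect_equal(pp3$mean_density, 0.3)
  expect_equal(pp3$contributors, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(pp3$pool, 0.8 * (0.6 + 0))
  expect_error(partition_and_pool(numeric(0), 0.8), "no cells")
})

test_that("the forced-draw single-cell update reproduces the printed state exactly", {
  we <- worked_example()
  ms <- macro_step(we$field, we$params, we$grid, seed = 1, t = 0,
                   draws = we$draws)
  want <- matrix(0, 5, 5)
  want[2, 2] <- 1 - 0.64 + 0.1024       # 1 - 4 g1/5 + 4 g1 g2 / 25
  want[1, 1] <- 0.1024; want[2, 1] <- 0.1024; want[2, 3] <- 0.1024
  want[3, 2] <- 0
  expect_identical(dim(ms$field), dim(want))
  expect_equal(ms$field, want, tolerance = 1e-15)
  oc <- ms$outcomes[[1]]
  expect_equal(oc$H, 1L); expect_equal(oc$K, 4L)
  expect_equal(oc$mean_density, 0.2)
  expect_equal(oc$pool, 0.64)
})

test_that("the forced-draw update equals the printed transition matrix times the state", {
  we <- worked_example()
  ms <- macro_step(we$field, we$params, we$grid, seed = 1, draws = we$draws)
  g1 <- 0.8; g2 <- 0.8
  cells <- list(c(1, 1), c(1, 2), c(1, 3), c(2, 1), c(2, 2), c(2, 3), c(3, 2))
  A <- diag(7)
  s <- 4 * g1 * g2 / 25
  A[1, 5] <- s                      # (1,1) receives
  A[4, 5] <- s                      # (2,1) receives
  A[5, 5] <- 1 - 4 * g1 / 5 + s     # contributor keeps + receives
  A[6, 5] <- s                      # (2,3) receives
  A[7, ] <- 0                       # (3,2) zeroed
  state <- vapply(cells, function(c_) we$field[c_[1], c_[2]], numeric(1))
  got <- vapply(cells, function(c_) ms$field[c_[1], c_[2]], numeric(1))
  expect_equal(got, as.numeric(A %*% state), tolerance = 1e-15)
})

test_that("degenerate parameter limits behave as the update algebra dictates", {
  we <- worked_example()
  # gamma1 = 0: nothing to disperse, only a failed survival can zero a cell
  p0 <- sca_params(gamma1 = 0, gamma2 = 0.8)
  ms <- macro_step(we$field, p0, we$grid, seed = 1, draws = we$draws)
  want <- we$field  # all densities zero except the affected cell; pool 0
  expect_equal(ms$field, want)
  # gamma2 = 1, all survival draws succeed, no boundary contact: conservation
  g <- hex_grid(7, 7)
  f <- matrix(0, 7, 7); f[4, 4] <- 0.9; f[4, 5] <- 0.2
  p1 <- sca_params(gamma1 = 0.8, gamma2 = 1)
  sur <- matrix(1, 7, 7)
  set.seed(5)
  ms2 <- macro_step(f, p1, g, seed = 5,
                    draws = list(inclusion = matrix(1, 7, 7),
                                 survival = sur))
  expect_equal(sum(ms2$field), sum(f), tolerance = 1e-12)
})

test_that("the per-neighbourhood mass ledger balances to machine precision", {
  set.seed(8)
  g <- hex_grid(7, 7)
  for (rep in 1:200) {
    cells <- random_affected_set(g)
    f <- matrix(0, 7, 7); f[cells] <- runif(nrow(cells))
    pars <- sca_params(gamma1 = runif(1), gamma2 = runif(1),
                       phi = 0.2, rho = runif(1, 0, 0.8))
    ms <- macro_step(f, pars, g, seed = rep, t = rep)
    delta <- sum(ms$field) - sum(f)
    terms <- sum(vapply(ms$outcomes, function(o)
      o$lost_in_transit + o$zeroed_mass + o$absorbed_mass, numeric(1)))
    expect_lt(abs(delta + terms), 1e-12)
    expect_true(all(ms$field >= 0 & ms$field <= 1))
  }
})

test_that("H + K equals the number of included cells and the pool is nonnegative", {
  set.seed(9)
  g <- hex_grid(8, 8)
  for (rep in 1:50) {
    cells <- random_affected_set(g)
    f <- matrix(0, 8, 8); f[cells] <- runif(nrow(cells))
    ms <- macro_step(f, sca_params(), g, seed = rep)
    for (o in ms$outcomes) {
      if (is.null(o$included)) next
      # included counts real cells; H + K also counts auxiliary recipients
      expect_gte(o$H + o$K, nrow(o$included))
      expect_gte(o$pool, 0)
    }
  }
})

test_that("neighbourhoods disperse independently (block-diagonal update)", {
  g <- hex_grid(9, 9)
  a <- c(5, 2); b <- c(5, 7)
  expect_gt(hex_distance(a, b), 3L)
  f_both <- matrix(0, 9, 9)
  f_both[a[1], a[2]] <- 0.8; f_both[b[1], b[2]] <- 0.6
  f_a <- matrix(0, 9, 9); f_a[a[1], a[2]] <- 0.8
  f_b <- matrix(0, 9, 9); f_b[b[1], b[2]] <- 0.6
  for (seed in c(1, 7, 23)) {
    joint <- macro_step(f_both, sca_params(), g, seed = seed, t = 3)$field
    alone_a <- macro_step(f_a, sca_params(), g, seed = seed, t = 3)$field
    alone_b <- macro_step(f_b, sca_params(), g, seed = seed, t = 3)$field
    expect_equal(joint, alone_a + alone_b, tolerance = 1e-15)
  }
})

test_that("an empty field passes through unchanged", {
  g <- hex_grid(6, 6)
  f <- matrix(0, 6, 6)
  ms <- macro_step(f, sca_params(), g, seed = 1)
  expect_equal(ms$field, f)
  expect_length(ms$outcomes, 0L)
})

test_that("barrier cells are never colonized", {
  g <- hex_grid(15, 15)
  mask <- make_fixture("bridge-mask", g) > 0
  f <- matrix(0, 15, 15); f[8, 4] <- 0.8
  params <- sca_params()
  bd <- bd_spec()
  field <- f
  for (t in 1:60) {
    field <- couple_microscale(field, bd, t - 1, seed = 42)
    field <- macro_step(field, params, g, seed = 42, t = t,
                        barrier = mask)$field
    expect_true(all(field[mask] == 0))
  }
  # density nevertheless crosses through the corridor eventually
  expect_gt(sum(field[, 9:15]), 0)
})

test_that("boundary contact sends mass to auxiliary cells, which absorb it", {
  g <- hex_grid(4, 4)
  f <- matrix(0, 4, 4); f[1, 1] <- 1
  absorbed <- 0
  for (seed in 1:40) {
    ms <- macro_step(f, sca_params(), g, seed = seed)
    absorbed <- absorbed + sum(vapply(ms$outcomes, `[[`, numeric(1),
                                      "absorbed_mass"))
  }
  expect_gt(absorbed, 0)
})

test_that("inclusion sampling is reproducible and hits its Bernoulli rate", {
  g <- hex_grid(5, 5)
  f <- matrix(0, 5, 5); f[3, 3] <- 0.8
  nb <- find_interaction_neighbourhoods(f, g)[[1]]
  w <- inclusion_weights(nb, f, g)
  s1 <- sample_inclusion(nb, w, sca_params(), seed = 99)
  s2 <- sample_inclusion(nb, w, sca_params(), seed = 99)
  expect_identical(s1$included, s2$included)
  # empirical inclusion frequency of the affected cell (p_I = 0.4)
  set.seed(101)
  n <- 1e5
  hits <- sum(runif(n) < inclusion_probability(1, 0.8))
  p <- 0.4
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("retention keeps a fraction of a failed recipient's density", {
  we <- worked_example()
  pr <- sca_params(gamma1 = 0.8, gamma2 = 0.8, retention = 0.5)
  ms <- macro_step(we$field, pr, we$grid, seed = 1, draws = we$draws)
  expect_equal(ms$field[3, 2], 0.5 * 0.1024, tolerance = 1e-15)
})
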