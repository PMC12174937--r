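#' Define a stochastic-inverse-problem calibration
#'
#' Sets up the calibration of the dispersal parameters `(gamma1, phi)` over
#' a box domain, holding the remaining parameters fixed (`gamma2` and `rho`
#' are fixed because their effect on the dispersal statistics is nearly
#' indistinguishable from `phi`'s, which makes them jointly
#' unidentifiable).  The forward map is the expected value of one of the
#' four observables of [calibration_statistics()], estimated by averaging
#' over `R` replicate multiscale runs of `steps` macro steps from a
#' standard initial pattern (a single cell of density 0.5 at the centre of
#' the grid).
#'
#' @param statistic which observable (1-4) the forward map returns.
#' @param lambda_lower,lambda_upper bounds of the box domain for
#'   `(gamma1, phi)`.
#' @param fixed an [sca_params()] providing the non-calibrated parameters.
#' @param bd a [bd_spec()] for the microscale model.
#' @param steps macro steps per run.
#' @param R replicate runs averaged per forward evaluation.
#' @param grid a [hex_grid()].
#' @param init initial density matrix (default: standard single cell).
#' @param forward optional function `(lambda, seed) -> numeric` replacing
#'   the simulation-based forward map (used for analytical toys and
#'   estimator checks).
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(statistic = 1L,
                                lambda_lower = c(gamma1 = 0.4, phi = 1 / 6),
                                lambda_upper = NULL,
                                fixed = sca_params(gamma2 = 0.8, rho = 1 / 3),
                                bd = bd_spec(b = 1, d = 0.2, C = 100,
                                             N = 100, M = 20),
                                steps = 30L, R = 2L,
                                grid = hex_grid(30, 30), init = NULL,
                                forward = NULL) {
  rho <- if (is.function(fixed$rho)) fixed$rho(0) else fixed$rho
  xi <- if (is.function(fixed$xi)) fixed$xi(0) else fixed$xi
  if (is.null(lambda_upper)) {
    # largest feasible phi given the survival-probability constraint
    lambda_upper <- c(gamma1 = 1.0, phi = 1 - max(rho) * atan(max(xi)))
  }
  stopifnot(statistic %in% 1:4, length(lambda_lower) == 2L,
            length(lambda_upper) == 2L, all(lambda_lower < lambda_upper),
            R >= 1L)
  if (lambda_upper[["phi"]] + max(rho) * atan(max(xi)) > 1 + 1e-12)
    stop("phi upper bound violates phi + rho * atan(xi) <= 1")
  if (is.null(init)) {
    init <- matrix(0, grid$m, grid$n)
    init[ceiling(grid$m / 2), ceiling(grid$n / 2)] <- 0.5
  }
  structure(list(statistic = as.integer(statistic),
                 lambda_lower = lambda_lower, lambda_upper = lambda_upper,
                 fixed = fixed, bd = bd, steps = as.integer(steps),
                 R = as.integer(R), grid = grid, init = init,
                 forward = forward),
            class = "calibration_problem")
}

in_domain <- function(lambda, problem) {
  all(lambda >= problem$lambda_lower - 1e-12) &&
    all(lambda <= problem$lambda_upper + 1e-12)
}

#' Forward map of the calibration problem
#'
#' Expected observable at a parameter point: the chosen statistic averaged
#' over `R` independent multiscale runs, each seeded deterministically from
#' `seed`.
#'
#' @param lambda numeric `c(gamma1, phi)` inside the domain.
#' @param problem a [calibration_problem()].
#' @param seed integer seed.
#' @return The estimated expected statistic (scalar).
#' @export
forward_map <- function(lambda, problem, seed = 1L) {
  if (!in_domain(lambda, problem))
    stop("lambda outside the calibration domain")
  if (!is.null(problem$forward))
    return(problem$forward(lambda, seed))
  p <- problem$fixed
  params <- sca_params(gamma1 = lambda[[1L]], gamma2 = p$gamma2,
                       phi = lambda[[2L]], rho = p$rho,
                       alpha = p$alpha, beta = p$beta, xi = p$xi,
                       retention = p$retention, ps_at = p$ps_at)
  vals <- vapply(seq_len(problem$R), function(r) {
    run <- simulate_dispersion(problem$init, params, problem$bd,
                               steps = problem$steps,
                               seed = derive_seed(seed, 0L, r),
                               grid = problem$grid)
    calibration_statistics(run$snapshots, problem$grid,
                           which = problem$statistic)
  }, numeric(1))
  mean(vals)
}

# draw from N(mean, sd^2 I) truncated to the domain box, by rejection
rtrunc_norm_box <- function(n, mean, sd, lower, upper) {
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  while (got < n) {
    cand <- cbind(stats::rnorm(n, mean[1L], sd), stats::rnorm(n, mean[2L], sd))
    ok <- cand[, 1L] >= lower[1L] & cand[, 1L] <= upper[1L] &
      cand[, 2L] >= lower[2L] & cand[, 2L] <= upper[2L]
    take <- min(sum(ok), n - got)
    if (take > 0L) {
      out[got + seq_len(take), ] <- cand[which(ok)[seq_len(take)], ]
      got <- got + take
    }
  }
  out
}

#' Generate synthetic observations from a data-generating distribution
#'
#' Draws `n` parameter samples from a normal data-generating distribution
#' (truncated to the calibration domain), runs the forward map with `reps`
#' replicate runs per sample, and returns the observed statistics.
#'
#' @param problem a [calibration_problem()].
#' @param n number of observations.
#' @param reps replicate runs averaged per observation.
#' @param mean,sd data-generating normal: mean `(gamma1, phi)` and common
#'   standard deviation.
#' @param seed integer seed.
#' @return A list of class `observation_set`: `data` (numeric vector),
#'   `lambda` (the generating parameter draws), `generator`.
#' @export
synthetic_observations <- function(problem, n = 100L, reps = 10L,
                                   mean = c(0.7, 1 / 3), sd = 0.05,
                                   seed = 1L) {
  set.seed(derive_seed(seed, 0L, 1L))
  lam <- rtrunc_norm_box(n, mean, sd, problem$lambda_lower,
                         problem$lambda_upper)
  sub <- problem
  sub$R <- as.integer(reps)
  q <- vapply(seq_len(n), function(k)
    forward_map(lam[k, ], sub, seed = derive_seed(seed, 1L, k)),
    numeric(1))
  structure(list(data = q, lambda = lam, generator = "synthetic"),
            class = "observation_set")
}

#' Generate noisy observations of a single true parameter value
#'
#' Classic noisy-observation model for data-poor settings: the forward map
#' is evaluated once at `lambda_true` and `n` observations are formed by
#' adding iid `N(0, sigma^2)` noise.
#'
#' @param problem a [calibration_problem()].
#' @param lambda_true the true parameter value.
#' @param n number of noisy observations.
#' @param sigma observation noise standard deviation.
#' @param reps replicate runs for the forward evaluation.
#' @param seed integer seed.
#' @return An `observation_set` with `generator = "noisy"`.
#' @export
noisy_observations <- function(problem, lambda_true, n = 100L, sigma = 0.1,
                               reps = 10L, seed = 1L) {
  sub <- problem
  sub$R <- as.integer(reps)
  q0 <- forward_map(lambda_true, sub, seed = derive_seed(seed, 2L, 0L))
  set.seed(derive_seed(seed, 2L, 1L))
  structure(list(data = q0 + stats::rnorm(n, 0, sigma),
                 lambda = matrix(lambda_true, n, 2L, byrow = TRUE),
                 generator = "noisy"),
            class = "observation_set")
}

#' Consistent-Bayes posterior of the stochastic inverse problem
#'
#' Solves the calibration problem with the uniform-ansatz prior: `n_prior`
#' parameter samples are drawn uniformly on the domain, the forward map is
#' evaluated at each, and every sample is weighted by the ratio of the
#' observed-data density to the prior-pushforward density at its forward
#' value (both Gaussian kernel estimates with Silverman bandwidth).  The
#' posterior's pushforward through the forward map then matches the
#' observed-data distribution; when the two densities coincide, the
#' posterior equals the prior (all weights equal).
#'
#' Observations at which the pushforward density is (numerically) zero are
#' outside the reachable observable range; they are dropped with a warning.
#'
#' @param problem a [calibration_problem()].
#' @param observations an `observation_set` (or a bare numeric vector).
#' @param n_prior number of uniform prior samples (>= 100 recommended).
#' @param seed integer seed.
#' @return An object of class `sip_posterior`: `samples` (n x 2 matrix of
#'   `(gamma1, phi)`), normalized `weights`, the forward values `Q`, and
#'   the problem.
#' @export
sip_posterior <- function(problem, observations, n_prior = 200L, seed = 1L) {
  obs <- if (inherits(observations, "observation_set")) observations$data
         else as.numeric(observations)
  if (length(obs) < 1L) stop("need at least one observation")
  set.seed(derive_seed(seed, 3L, 0L))
  lo <- problem$lambda_lower; up <- problem$lambda_upper
  lam <- cbind(stats::runif(n_prior, lo[1L], up[1L]),
               stats::runif(n_prior, lo[2L], up[2L]))
  colnames(lam) <- c("gamma1", "phi")
  Q <- vapply(seq_len(n_prior), function(k)
    forward_map(lam[k, ], problem, seed = derive_seed(seed, 4L, k)),
    numeric(1))
  push <- stats::density(Q, bw = "nrd0")
  eval_kde <- function(kde, x) {
    y <- stats::approx(kde$x, kde$y, x, rule = 1L)$y
    y[is.na(y)] <- 0   # outside the evaluation range the density is ~0
    y
  }
  push_at <- function(x) eval_kde(push, x)
  # flag observations outside the reachable range of the pushforward
  reach <- push_at(obs) > 1e-12 * max(push$y)
  if (!any(reach))
    stop("pushforward density is zero at every observation: ",
         "support mismatch between data and model")
  if (any(!reach)) {
    warning(sum(!reach), " observation(s) outside the pushforward support",
            " were dropped")
    obs <- obs[reach]
  }
  fobs <- stats::density(obs, bw = if (length(obs) >= 2L) "nrd0"
                                   else stats::bw.nrd0(Q))
  obs_at <- function(x) eval_kde(fobs, x)
  w <- obs_at(Q) / push_at(Q)
  w[!is.finite(w)] <- 0
  if (sum(w) <= 0) stop("all posterior weights are zero")
  structure(list(samples = lam, weights = w / sum(w), Q = Q,
                 problem = problem, observations = obs),
            class = "sip_posterior")
}

#' @export
print.sip_posterior <- function(x, ...) {
  ess <- 1 / sum(x$weights^2)
  pm <- posterior_summaries(x)$mean
  cat(sprintf("<sip_posterior> %d weighted samples (ESS %.1f)\n",
              nrow(x$samples), ess))
  cat(sprintf("  posterior mean: gamma1 = %.3f, phi = %.3f\n",
              pm[[1L]], pm[[2L]]))
  invisible(x)
}

#' Summaries of a calibration posterior
#'
#' Weighted kernel marginal densities for each parameter, a gridded joint
#' density (weighted 2-D histogram over the domain), and the weighted
#' posterior mean.
#'
#' @param posterior a [sip_posterior()].
#' @param grid_n resolution of the joint-density grid.
#' @return A list with `marginals` (list of `density` objects named
#'   `gamma1`, `phi`), `joint` (list `x`, `y`, `z`), and `mean`.
#' @export
posterior_summaries <- function(posterior, grid_n = 40L) {
  w <- posterior$weights
  if (sum(w) <= 0) stop("degenerate posterior: all weights zero")
  lam <- posterior$samples
  lo <- posterior$problem$lambda_lower
  up <- posterior$problem$lambda_upper
  marg <- lapply(1:2, function(k)
    stats::density(lam[, k], weights = w, bw = stats::bw.nrd0(lam[, k]),
                   from = lo[k], to = up[k]))
  names(marg) <- colnames(lam)
  bx <- seq(lo[1L], up[1L], length.out = grid_n + 1L)
  by <- seq(lo[2L], up[2L], length.out = grid_n + 1L)
  ix <- pmin(findInterval(lam[, 1L], bx, rightmost.closed = TRUE), grid_n)
  iy <- pmin(findInterval(lam[, 2L], by, rightmost.closed = TRUE), grid_n)
  z <- matrix(0, grid_n, grid_n)
  for (k in seq_along(w)) z[ix[k], iy[k]] <- z[ix[k], iy[k]] + w[k]
  cell_area <- diff(bx)[1L] * diff(by)[1L]
  list(marginals = marg,
       joint = list(x = (bx[-1L] + bx[-length(bx)]) / 2,
                    y = (by[-1L] + by[-length(by)]) / 2,
                    z = z / cell_area),
       mean = c(gamma1 = sum(w * lam[, 1L]), phi = sum(w * lam[, 2L])))
}

#' Convert a grayscale image to a density field
#'
#' Reproduces the survey-map conversion pipeline: the image is read (PNG
#' path, or a numeric matrix in `[0, 1]`), reduced to grey with 256 levels,
#' resampled to the target grid by nearest neighbour, divided by 256 to
#' give densities, thresholded (entries below `threshold` are zeroed), and
#' optionally degraded with two noise layers — `N(0, sd_nonzero^2)` added
#' to non-zero cells and `N(0, sd_adjacent^2)` added to zero cells that are
#' hex-adjacent to at least one non-zero cell — before clamping to
#' `[0, 1]`.
#'
#' @param image path of a PNG file, or a numeric matrix in `[0, 1]`.
#' @param target target grid dimensions `c(rows, cols)`.
#' @param threshold densities below this are zeroed (default 0.8).
#' @param sd_nonzero,sd_adjacent standard deviations of the two noise
#'   layers.
#' @param noise logical; `FALSE` gives the noiseless conversion.
#' @param seed integer seed for the noise draws.
#' @return A density matrix on the target grid.
#' @export
image_to_density <- function(image, target = c(32L, 32L), threshold = 0.8,
                             sd_nonzero = 0.2, sd_adjacent = 0.6,
                             noise = TRUE, seed = 1L) {
  if (is.character(image)) {
    img <- png::readPNG(image)
  } else {
    img <- image
  }
  if (length(dim(img)) == 3L) {
    # luminance of an RGB(A) image
    img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  }
  if (any(img < 0) || any(img > 1)) stop("image values must lie in [0, 1]")
  if (target[1L] > nrow(img) || target[2L] > ncol(img))
    stop("target dimensions exceed the image dimensions")
  grey <- floor(img * 255 + 0.5)   # 256 shades
  ri <- ceiling(seq_len(target[1L]) * nrow(grey) / target[1L])
  rj <- ceiling(seq_len(target[2L]) * ncol(grey) / target[2L])
  dens <- grey[ri, rj, drop = FALSE] / 256
  dens[dens < threshold] <- 0
  if (noise) {
    set.seed(seed)
    nz <- dens > 0
    st <- hex_neighbor_stats(dens)
    adj <- !nz & st$na > 0L
    dens[nz] <- dens[nz] + stats::rnorm(sum(nz), 0, sd_nonzero)
    dens[adj] <- dens[adj] + stats::rnorm(sum(adj), 0, sd_adjacent)
    dens <- pmin(pmax(dens, 0), 1)
  }
  dens
}
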