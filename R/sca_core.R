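#' Inclusion probability
#'
#' Probability that a cell takes part in this step's dispersal, as a function
#' of its inclusion weight `w` (number of adjacent affected cells, plus one
#' if the cell itself is affected) and the maximum density difference `d`
#' with its six neighbours:
#' `p_I = ((w^alpha / (1 + w^alpha)) * d)^beta`.
#' With `alpha = beta = 1` this is `w / (1 + w) * d`; an isolated affected
#' cell (`w = 1`, `d = pi`) is included with probability half its density.
#'
#' @param w non-negative integer (vectorised).
#' @param d density difference in `[0, 1]` (vectorised).
#' @param alpha,beta positive emphasis exponents.
#' @return Probabilities in `[0, 1]`.
#' @export
inclusion_probability <- function(w, d, alpha = 1, beta = 1) {
  if (any(alpha <= 0) || any(beta <= 0))
    stop("alpha and beta must be strictly positive")
  if (any(w < 0)) stop("w must be non-negative")
  if (any(d < -1e-12) || any(d > 1 + 1e-12)) stop("d must lie in [0, 1]")
  wa <- w^alpha
  (wa / (1 + wa) * d)^beta
}

#' Colonization survival probability
#'
#' Probability that density dispersed into a cell colonizes successfully:
#' `p_S = phi + rho * atan(xi * pi)`, nondecreasing in the cell density
#' `pi`.  The parameter constraint `phi + rho * atan(xi) <= 1` (checked
#' here) keeps the value a probability for all densities in `[0, 1]`.
#'
#' @param pi_density cell density in `[0, 1]` (vectorised).
#' @param phi baseline survival probability.
#' @param rho weight of the density-dependent term.
#' @param xi arctangent shape parameter.
#' @return Probabilities in `[0, 1]`.
#' @export
survival_probability <- function(pi_density, phi, rho, xi = 1) {
  if (any(phi < 0) || any(rho < 0) || any(xi <= 0))
    stop("need phi >= 0, rho >= 0, xi > 0")
  if (any(phi + rho * atan(xi) > 1 + 1e-12))
    stop("survival probability exceeds 1: need phi + rho * atan(xi) <= 1")
  phi + rho * atan(xi * pi_density)
}

#' Partition included cells and compute the dispersal pool
#'
#' Included cells whose density is at least the mean density of all included
#' cells are the *contributing* cells; each donates `gamma1 * (pi - mean)`
#' to the pool.  Ties at the mean contribute zero but still receive a share.
#'
#' @param densities densities of the included cells (non-empty).
#' @param gamma1 dispersed fraction, scalar or one value per cell.
#' @return A list with `mean_density`, logical `contributors`, and `pool`.
#' @export
partition_and_pool <- function(densities, gamma1) {
  if (length(densities) == 0L)
    stop("no cells included in dispersion")
  pi_bar <- mean(densities)
  contrib <- densities >= pi_bar
  g1 <- if (length(gamma1) > 1L) gamma1[contrib] else gamma1
  pool <- sum(g1 * (densities[contrib] - pi_bar))
  list(mean_density = pi_bar, contributors = contrib, pool = pool)
}

#' Sample inclusion draws for a neighbourhood
#'
#' One Bernoulli draw per cell of the interaction neighbourhood (affected
#' and halo, in canonical order: real cells by column-major index, then
#' auxiliary cells), with probabilities from [inclusion_probability()].
#'
#' @param nbhd one element of [find_interaction_neighbourhoods()].
#' @param weights the data frame from [inclusion_weights()].
#' @param params an [sca_params()] (only `alpha`, `beta` are used; scalars).
#' @param seed optional integer seed for reproducibility.
#' @return `weights` with extra columns `p_I` and `included` (0/1).
#' @export
sample_inclusion <- function(nbhd, weights, params = sca_params(),
                             seed = NULL) {
  alpha <- if (is.function(params$alpha)) params$alpha(0) else params$alpha
  beta <- if (is.function(params$beta)) params$beta(0) else params$beta
  stopifnot(length(alpha) == 1L, length(beta) == 1L)
  ord <- order(weights$aux, weights$j, weights$i)
  weights <- weights[ord, ]
  weights$p_I <- inclusion_probability(weights$w, weights$d, alpha, beta)
  if (!is.null(seed)) set.seed(seed)
  weights$included <- as.integer(stats::runif(nrow(weights)) < weights$p_I)
  weights
}

# mix a (seed, t, id) triple into one 32-bit seed; all arithmetic stays
# below 2^53 so doubles are exact
derive_seed <- function(seed, t, id) {
  as.integer(((seed %% 1e6) * 1000003 + (t %% 1e6) * 9973 + id * 7919) %%
               2147483647)
}

# Parameter value for an auxiliary cell: mean over its real neighbours.
aux_param <- function(mat, i, j, grid) {
  off <- hex_offsets_r(j)
  ni <- i + off[, 1L]; nj <- j + off[, 2L]
  ok <- ni >= 1L & ni <= grid$m & nj >= 1L & nj <= grid$n
  if (!any(ok)) return(mean(mat))
  mean(mat[cbind(ni[ok], nj[ok])])
}

# Core per-neighbourhood dispersal kernel.  `pr` is the resolved parameter
# list (matrices); `pI_mat` the grid of inclusion probabilities; `draws`
# optionally forces the Bernoulli outcomes (matrices over the real grid).
# Assumes the RNG state has been prepared by the caller.
process_neighbourhood <- function(nbhd, field, grid, pr, pI_mat,
                                  draws = NULL) {
  real <- rbind(nbhd$affected,
                nbhd$halo[nbhd$halo[, "aux"] == 0L, c("i", "j"), drop = FALSE])
  ord <- order(cell_linear_index(real, grid))
  real <- real[ord, , drop = FALSE]
  aux <- nbhd$halo[nbhd$halo[, "aux"] == 1L, c("i", "j"), drop = FALSE]
  n_real <- nrow(real); n_aux <- nrow(aux)

  dens <- c(field[real], rep(0, n_aux))
  pI <- pI_mat[real]
  g2 <- pr$gamma2[real]
  g1 <- pr$gamma1[real]
  phi <- pr$phi[real]; rho <- pr$rho[real]; xi <- pr$xi[real]
  if (n_aux > 0L) {
    for (k in seq_len(n_aux)) {
      i <- aux[k, 1L]; j <- aux[k, 2L]
      w <- 0L; dmx <- 0
      off <- hex_offsets_r(j)
      ni <- i + off[, 1L]; nj <- j + off[, 2L]
      ok <- ni >= 1L & ni <= grid$m & nj >= 1L & nj <= grid$n
      if (any(ok)) {
        nb <- field[cbind(ni[ok], nj[ok])]
        w <- sum(nb > 0)
        dmx <- max(c(nb, 0))
      }
      a <- aux_param(pr$alpha, i, j, grid)
      b <- aux_param(pr$beta, i, j, grid)
      pI <- c(pI, inclusion_probability(w, dmx, a, b))
      g1 <- c(g1, aux_param(pr$gamma1, i, j, grid))
      g2 <- c(g2, aux_param(pr$gamma2, i, j, grid))
      phi <- c(phi, 0); rho <- c(rho, 0); xi <- c(xi, 1)
    }
  }
  is_aux <- c(rep(FALSE, n_real), rep(TRUE, n_aux))

  if (is.null(draws)) {
    u <- stats::runif(n_real + n_aux)
    incl <- u < pI
  } else {
    incl <- c(draws$inclusion[real] == 1, rep(FALSE, n_aux))
  }

  no_change <- list(
    updates = NULL, id = nbhd$id,
    included = NULL, H = 0L, K = 0L,
    mean_density = NA_real_, pool = 0,
    zeroed = NULL, zeroed_mass = 0, absorbed_mass = 0, lost_in_transit = 0
  )
  if (!any(incl)) return(no_change)

  pp <- partition_and_pool(dens[incl], g1[incl])
  pi_bar <- pp$mean_density
  pool <- pp$pool
  contrib <- logical(n_real + n_aux)
  contrib[incl] <- pp$contributors
  H <- sum(contrib)
  K <- sum(incl) - H
  unit_share <- pool / (H + K)      # pre-survival share per included cell
  share <- g2 * unit_share          # what actually arrives

  new <- dens
  # contributing cells donate and receive
  ci <- which(contrib & !is_aux)
  new[ci] <- dens[ci] - g1[ci] * (dens[ci] - pi_bar) + share[ci]
  # non-contributing real recipients face the colonization draw
  ki <- which(incl & !contrib & !is_aux)
  zeroed_cells <- NULL; zeroed_mass <- 0
  if (length(ki) > 0L) {
    at <- if (pr$ps_at == "prospective") dens[ki] + share[ki] else dens[ki]
    pS <- phi[ki] + rho[ki] * atan(xi[ki] * at)
    if (is.null(draws)) {
      bs <- stats::runif(length(ki)) < pS
    } else {
      bs <- draws$survival[real[ki, , drop = FALSE]] == 1
    }
    prospective <- dens[ki] + share[ki]
    new[ki] <- ifelse(bs, prospective, pr$retention * prospective)
    if (any(!bs)) {
      fail <- ki[!bs]
      zeroed_cells <- real[fail, , drop = FALSE]
      zeroed_mass <- sum((1 - pr$retention) * (dens[fail] + share[fail]))
    }
  }
  # auxiliary recipients absorb their arriving share (no survival draw);
  # any auxiliary "contributor" (possible only when pi_bar = 0) absorbs 0
  ai <- which(incl & is_aux)
  absorbed <- if (length(ai) > 0L) sum(share[ai]) else 0
  lost <- sum((1 - g2[incl]) * unit_share)

  upd_cells <- real
  upd_vals <- new[seq_len(n_real)]
  inc_real <- real[incl[seq_len(n_real)], , drop = FALSE]
  list(
    updates = list(cells = upd_cells, values = upd_vals),
    id = nbhd$id,
    included = inc_real, H = H, K = K,
    mean_density = pi_bar, pool = pool,
    zeroed = zeroed_cells, zeroed_mass = zeroed_mass,
    absorbed_mass = absorbed, lost_in_transit = lost
  )
}

#' Apply one dispersal update to a single interaction neighbourhood
#'
#' Executes the dispersal bookkeeping for one neighbourhood: partition of
#' the included cells into contributors and non-contributors, pooling of the
#' donated density, uniform redistribution of the surviving fraction
#' `gamma2` of the pool, colonization-survival draws for non-contributing
#' recipients (failure removes the cell's density, up to the retention
#' factor), and absorption of shares sent to auxiliary cells.
#'
#' @param nbhd one element of [find_interaction_neighbourhoods()].
#' @param draws either `NULL` (sample from the current RNG state) or a list
#'   with 0/1 matrices `inclusion` and `survival` over the real grid,
#'   forcing the Bernoulli outcomes (used for worked examples and tests).
#' @param params an [sca_params()].
#' @param field the density matrix the neighbourhood was found on.
#' @param grid a [hex_grid()].
#' @param t macro time (for time-varying parameters).
#' @return A list: `next_field` (updated matrix) plus the step outcome
#'   (`included`, `H`, `K`, `mean_density`, `pool`, `zeroed`,
#'   `zeroed_mass`, `absorbed_mass`, `lost_in_transit`).
#' @export
apply_dispersion <- function(nbhd, draws = NULL, params = sca_params(),
                             field, grid, t = 0L) {
  pr <- resolve_params(params, t, grid)
  st <- hex_neighbor_stats(field)
  w <- st$na + (field > 0)
  pI_mat <- inclusion_probability(w, st$dmax, pr$alpha, pr$beta)
  out <- process_neighbourhood(nbhd, field, grid, pr, pI_mat, draws)
  nf <- field
  if (!is.null(out$updates))
    nf[out$updates$cells] <- out$updates$values
  check_bounds(nf)
  c(list(next_field = nf), out[setdiff(names(out), "updates")])
}

check_bounds <- function(field) {
  if (any(field < -1e-12) || any(field > 1 + 1e-12))
    stop("density left [0, 1]; the update algebra guarantees boundedness ",
         "only for neighbourhood-homogeneous gamma1")
  invisible(field)
}

#' One macroscale dispersal step
#'
#' Advances the whole density field by one macro time step: interaction
#' neighbourhoods are identified, and each is dispersed independently with
#' its own RNG substream derived from `(seed, t, neighbourhood id)` — so the
#' outcome in a neighbourhood is identical whether or not other
#' neighbourhoods are present (block-diagonal structure of the update).
#'
#' @param field numeric `m` x `n` density matrix in `[0, 1]`.
#' @param params an [sca_params()].
#' @param grid a [hex_grid()].
#' @param seed integer seed; if `NULL` the current RNG state is used (the
#'   per-neighbourhood independence contract then no longer holds
#'   bit-for-bit).
#' @param t macro time of the step (used for schedules and seeding).
#' @param barrier optional logical matrix; `TRUE` cells never participate in
#'   dispersal and never receive density.
#' @param draws optional forced Bernoulli outcomes, as in
#'   [apply_dispersion()].
#' @return A list with `field` (the next state) and `outcomes` (one entry
#'   per neighbourhood, see [apply_dispersion()]).
#' @export
macro_step <- function(field, params = sca_params(), grid = NULL,
                       seed = NULL, t = 0L, barrier = NULL, draws = NULL) {
  if (is.null(grid)) grid <- hex_grid(nrow(field), ncol(field))
  stopifnot(nrow(field) == grid$m, ncol(field) == grid$n)
  if (any(field < 0) || any(field > 1)) stop("densities must lie in [0, 1]")
  if (!is.null(barrier) && any(field[barrier] > 0))
    stop("barrier cells must have zero density")
  pr <- resolve_params(params, t, grid)
  nbhds <- find_interaction_neighbourhoods(field, grid, barrier)
  if (length(nbhds) == 0L)
    return(list(field = field, outcomes = list()))
  st <- hex_neighbor_stats(field)
  w <- st$na + (field > 0)
  pI_mat <- inclusion_probability(w, st$dmax, pr$alpha, pr$beta)
  if (!is.null(barrier)) pI_mat[barrier] <- 0
  nf <- field
  outcomes <- vector("list", length(nbhds))
  for (k in seq_along(nbhds)) {
    nb <- nbhds[[k]]
    if (!is.null(seed)) set.seed(derive_seed(seed, t, nb$id))
    out <- process_neighbourhood(nb, field, grid, pr, pI_mat, draws)
    if (!is.null(out$updates))
      nf[out$updates$cells] <- out$updates$values
    outcomes[[k]] <- out[setdiff(names(out), "updates")]
  }
  check_bounds(nf)
  list(field = nf, outcomes = outcomes)
}
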