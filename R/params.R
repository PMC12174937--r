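#' Dispersal-rule parameters
#'
#' Bundles the parameters of the macroscale dispersal rules.  Each parameter
#' may be a scalar, an `m` x `n` matrix (per-cell fields, e.g. for wind or
#' terrain effects), or a function of macro time `t` returning either.
#'
#' * `gamma1` in `[0, 1]`: fraction of the above-mean density that a
#'   contributing cell donates to the dispersal pool.
#' * `gamma2` in `[0, 1]`: dispersal survival rate; the fraction of a
#'   dispersed share that reaches its destination (1 - `gamma2` is lost in
#'   transit).
#' * `phi` (>= 0): baseline colonization survival probability.
#' * `rho` (>= 0): weight of the density-dependent survival term
#'   `rho * atan(xi * pi)`; the constraint `phi + rho * atan(xi) <= 1` keeps
#'   the survival probability a probability for all densities.
#' * `alpha`, `beta` (> 0): emphasis exponents of the generalized inclusion
#'   probability `((w^alpha / (1 + w^alpha)) * d)^beta`.
#' * `xi` (> 0): shape of the arctangent in the survival probability.
#' * `retention` in `[0, 1)`: fraction of the prospective density kept by a
#'   recipient whose colonization draw fails; 0 (default) zeroes the cell.
#' * `ps_at`: density at which the survival probability is evaluated for a
#'   recipient — `"prospective"` (current density plus incoming share; the
#'   default, which reproduces the printed single-cell worked update) or
#'   `"current"` (the pre-update density).
#'
#' @param gamma1,gamma2,phi,rho,alpha,beta,xi scalars, matrices, or
#'   functions of `t` (see above).
#' @param retention scalar in `[0, 1)`.
#' @param ps_at `"prospective"` or `"current"`.
#' @return An object of class `sca_params`.
#' @examples
#' sca_params()                        # the base setting of the model
#' sca_params(phi = 0.2, rho = 1/6)
#' @export
sca_params <- function(gamma1 = 0.8, gamma2 = 0.8, phi = 1 / 3, rho = 1 / 3,
                       alpha = 1, beta = 1, xi = 1,
                       retention = 0, ps_at = c("prospective", "current")) {
  ps_at <- match.arg(ps_at)
  p <- list(gamma1 = gamma1, gamma2 = gamma2, phi = phi, rho = rho,
            alpha = alpha, beta = beta, xi = xi,
            retention = retention, ps_at = ps_at)
  validate_sca_params(p)
  structure(p, class = "sca_params")
}

validate_sca_params <- function(p) {
  chk <- function(x, name, lo, hi = Inf, open_lo = FALSE) {
    if (is.function(x)) return(invisible())
    v <- as.numeric(x)
    bad <- if (open_lo) any(v <= lo | v > hi) else any(v < lo | v > hi)
    if (any(is.na(v)) || bad)
      stop(sprintf("parameter '%s' must lie in %s%g, %g]", name,
                   if (open_lo) "(" else "[", lo, hi))
  }
  chk(p$gamma1, "gamma1", 0, 1)
  chk(p$gamma2, "gamma2", 0, 1)
  chk(p$phi, "phi", 0, 1)
  chk(p$rho, "rho", 0)
  chk(p$alpha, "alpha", 0, open_lo = TRUE)
  chk(p$beta, "beta", 0, open_lo = TRUE)
  chk(p$xi, "xi", 0, open_lo = TRUE)
  chk(p$retention, "retention", 0, 1)
  if (!is.function(p$phi) && !is.function(p$rho) && !is.function(p$xi)) {
    s <- as.numeric(p$phi) + as.numeric(p$rho) * atan(as.numeric(p$xi))
    if (any(s > 1 + 1e-12))
      stop("survival probability exceeds 1: need phi + rho * atan(xi) <= 1")
  }
  invisible()
}

#' @export
print.sca_params <- function(x, ...) {
  fmt <- function(v) {
    if (is.function(v)) "<function of t>"
    else if (is.matrix(v)) sprintf("<%d x %d field>", nrow(v), ncol(v))
    else format(v, digits = 4)
  }
  cat("<sca_params>\n")
  for (nm in c("gamma1", "gamma2", "phi", "rho", "alpha", "beta", "xi"))
    cat(sprintf("  %-7s %s\n", nm, fmt(x[[nm]])))
  cat(sprintf("  retention %g, survival evaluated at %s density\n",
              x$retention, x$ps_at))
  invisible(x)
}

# Evaluate one parameter at macro time t and return a full m x n matrix.
resolve_param <- function(v, t, grid) {
  if (is.function(v)) v <- v(t)
  if (is.matrix(v)) {
    stopifnot(nrow(v) == grid$m, ncol(v) == grid$n)
    v
  } else {
    matrix(v, grid$m, grid$n)
  }
}

resolve_params <- function(params, t, grid) {
  out <- lapply(params[c("gamma1", "gamma2", "phi", "rho",
                         "alpha", "beta", "xi")],
                resolve_param, t = t, grid = grid)
  s <- out$phi + out$rho * atan(out$xi)
  if (any(s > 1 + 1e-12))
    stop("survival probability exceeds 1 at t = ", t,
         ": need phi + rho * atan(xi) <= 1 in every cell")
  out$retention <- params$retention
  out$ps_at <- params$ps_at
  out
}
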