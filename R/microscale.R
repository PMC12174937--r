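#' Birth-death microscale specification
#'
#' Discrete-time stochastic birth-death process on each cell, with logistic
#' births `b_n = n b (1 - n/C)` and linear deaths `d_n = d n`, simulated
#' with per-micro-step transition probabilities `b_n / N` and `d_n / N`
#' (micro step `dtau = 1/N`; one macro step spans unit time).  Optional
#' schedules modulate the rate coefficients multiplicatively as a function
#' of macro time, e.g. an annual cycle.
#'
#' @param b,d non-negative birth and death rate coefficients.
#' @param C positive integer carrying capacity.
#' @param N positive integer micro steps per macro step.
#' @param M positive integer replicate simulations per cell.
#' @param birth_schedule,death_schedule `NULL` or a function of macro time
#'   `t` returning a non-negative multiplicative factor; see
#'   [bd_schedule()] for the built-ins.
#' @return An object of class `bd_spec`.
#' @examples
#' bd_spec()                                    # b = 1, d = 0.2, C = N = 100
#' bd_spec(birth_schedule = bd_schedule("sinusoidal", period = 20))
#' @export
bd_spec <- function(b = 1, d = 0.2, C = 100, N = 100, M = 20,
                    birth_schedule = NULL, death_schedule = NULL) {
  C <- as.integer(C); N <- as.integer(N); M <- as.integer(M)
  stopifnot(b >= 0, d >= 0, C >= 1L, N >= 1L, M >= 1L)
  spec <- structure(list(b = b, d = d, C = C, N = N, M = M,
                         birth_schedule = birth_schedule,
                         death_schedule = death_schedule),
                    class = "bd_spec")
  if (is.null(birth_schedule) && is.null(death_schedule))
    validate_bd_probs(spec, 1, 1)
  spec
}

# max over n of (b_n + d_n) / N must be <= 1 for valid probabilities;
# b_n peaks at n = C/2 with value b C / 4, d_n at n = C with value d C.
validate_bd_probs <- function(spec, bmod, dmod) {
  pmax_ <- (spec$b * bmod * spec$C / 4 + spec$d * dmod * spec$C) / spec$N
  if (pmax_ > 1)
    stop(sprintf(
      "invalid birth-death configuration: max (b_n + d_n)/N = %.3f > 1; ",
      pmax_), "increase N or decrease the rates")
  invisible()
}

#' @export
print.bd_spec <- function(x, ...) {
  cat(sprintf(
    "<bd_spec> b = %g, d = %g, C = %d, N = %d micro steps, M = %d replicates\n",
    x$b, x$d, x$C, x$N, x$M))
  if (!is.null(x$birth_schedule)) cat("  birth schedule: set\n")
  if (!is.null(x$death_schedule)) cat("  death schedule: set\n")
  invisible(x)
}

#' Built-in rate schedules
#'
#' Multiplicative modulations of the birth/death coefficients as functions
#' of macro time `t`:
#' * `"sinusoidal"`: `1 + sin(2 pi t / period)` — an annual cycle when
#'   `period` macro steps make up one year; the birth rate vanishes at the
#'   trough.
#' * `"endemic"`: a `period`-step year in which births exceed deaths only
#'   during a short summer window; returns a list of two functions
#'   (`birth`, `death`).
#' * `"epidemic"`: births dominate deaths all year (hot-year regime);
#'   returns a list of two functions.
#'
#' The endemic/epidemic shapes are stylized step-function approximations of
#' an annual temperature-driven cycle.
#'
#' @param name `"sinusoidal"`, `"endemic"` or `"epidemic"`.
#' @param period length of the cycle in macro steps (default 20).
#' @return A function of `t` (sinusoidal) or a list with elements `birth`
#'   and `death` (endemic/epidemic).
#' @export
bd_schedule <- function(name = c("sinusoidal", "endemic", "epidemic"),
                        period = 20) {
  name <- match.arg(name)
  switch(name,
    sinusoidal = function(t) 1 + sin(2 * pi * t / period),
    endemic = list(
      # births high only in a 4-step summer window; deaths high in winter
      birth = function(t) ifelse((t %% period) %in% 8:11, 2, 0.1),
      death = function(t) ifelse((t %% period) %in% 8:11, 1, 3)
    ),
    epidemic = list(
      birth = function(t) ifelse((t %% period) %in% 8:11, 2, 1.2),
      death = function(t) 0.5 + 0 * t
    )
  )
}

bd_modulation <- function(spec, t) {
  bmod <- if (is.null(spec$birth_schedule)) 1 else spec$birth_schedule(t)
  dmod <- if (is.null(spec$death_schedule)) 1 else spec$death_schedule(t)
  if (bmod < 0 || dmod < 0) stop("rate modulations must be non-negative")
  c(bmod = bmod, dmod = dmod)
}

#' Birth and death rates at a population size
#'
#' Logistic birth rate `b_n = n b (1 - n/C)` and linear death rate
#' `d_n = d n`, including any schedule modulation at macro time `t`.  State
#' 0 is absorbing (`b_0 = d_0 = 0`) and the logistic factor vanishes at
#' `n = C`.
#'
#' @param n population size(s) in `0..C`.
#' @param t macro time (for schedules).
#' @param spec a [bd_spec()].
#' @return A list with vectors `b_n` and `d_n`.
#' @export
bd_rates <- function(n, t = 0, spec = bd_spec()) {
  if (any(n < 0) || any(n > spec$C)) stop("n must lie in 0..C")
  mod <- bd_modulation(spec, t)
  list(b_n = n * spec$b * (1 - n / spec$C) * mod[["bmod"]],
       d_n = spec$d * n * mod[["dmod"]])
}

#' One micro step of the birth-death chain
#'
#' Moves each population up by one with probability `b_n / N`, down by one
#' with probability `d_n / N`, otherwise stays.  Vectorised over `n`.
#'
#' @param n current population size(s) in `0..C`.
#' @param t macro time (for schedules).
#' @param spec a [bd_spec()].
#' @return Updated population size(s).
#' @export
bd_step <- function(n, t = 0, spec = bd_spec()) {
  r <- bd_rates(n, t, spec)
  mod <- bd_modulation(spec, t)
  validate_bd_probs(spec, mod[["bmod"]], mod[["dmod"]])
  pb <- r$b_n / spec$N
  pd <- r$d_n / spec$N
  u <- stats::runif(length(n))
  n + (u < pb) - (u >= pb & u < pb + pd)
}

#' Simulate full microscale trajectories
#'
#' Runs `M` independent birth-death chains for `N` micro steps from a common
#' initial size and returns the whole trajectories (used for diagnostics
#' and the replicate-mean tests; the coupling path uses the final values
#' only).
#'
#' @param n0 initial population size.
#' @param spec a [bd_spec()].
#' @param t macro time (schedules are held at `t` for the whole macro step).
#' @param M number of replicate chains (defaults to `spec$M`).
#' @return An `M` x `(N + 1)` integer matrix of population sizes.
#' @export
bd_trajectories <- function(n0, spec = bd_spec(), t = 0, M = spec$M) {
  mod <- bd_modulation(spec, t)
  validate_bd_probs(spec, mod[["bmod"]], mod[["dmod"]])
  out <- matrix(0L, M, spec$N + 1L)
  out[, 1L] <- as.integer(n0)
  n <- rep(as.integer(n0), M)
  r_all <- bd_rates(0:spec$C, t, spec)
  pb <- r_all$b_n / spec$N
  pd <- r_all$d_n / spec$N
  for (s in seq_len(spec$N)) {
    u <- stats::runif(M)
    n <- n + (u < pb[n + 1L]) - (u >= pb[n + 1L] & u < pb[n + 1L] + pd[n + 1L])
    out[, s + 1L] <- n
  }
  out
}

#' Couple the microscale model into the macroscale density field
#'
#' For every cell with positive density, starts `M` birth-death chains at
#' `round(pi * C)` (ties to even), evolves each for `N` micro steps (one
#' unit of macro time) with schedules held at macro time `t`, and replaces
#' the cell density by the replicate mean of the final counts divided by
#' `C`.  Empty cells stay empty (no immigration at the microscale).
#'
#' @param field numeric `m` x `n` density matrix.
#' @param spec a [bd_spec()].
#' @param t macro time.
#' @param seed optional integer; the draw stream is reproducible per
#'   `(seed, t, field)`.
#' @return The updated density matrix.
#' @export
couple_microscale <- function(field, spec = bd_spec(), t = 0, seed = NULL) {
  mod <- bd_modulation(spec, t)
  validate_bd_probs(spec, mod[["bmod"]], mod[["dmod"]])
  cells <- which(field > 0)
  if (length(cells) == 0L) return(field)
  if (!is.null(seed)) set.seed(derive_seed(seed, t, 0L))
  x0 <- as.integer(round(field[cells] * spec$C))
  init <- rep(x0, each = spec$M)
  fin <- bd_simulate_cpp(init, spec$b, spec$d, spec$C, spec$N,
                         mod[["bmod"]], mod[["dmod"]])
  means <- colMeans(matrix(fin, nrow = spec$M))
  field[cells] <- means / spec$C
  field
}
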