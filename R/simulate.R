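#' Run the coupled multiscale simulation
#'
#' Alternates the microscale birth-death update and the macroscale dispersal
#' step: at each macro time `t = 1..steps`, the birth-death process runs for
#' one unit of time on the state at `t - 1` (replicate-averaged per cell),
#' then one dispersal step advances the field to `t`.  With `bd = NULL` the
#' pure dispersal automaton is simulated.
#'
#' @param init numeric `m` x `n` initial density matrix in `[0, 1]`.
#' @param params an [sca_params()].
#' @param bd a [bd_spec()], or `NULL` for no microscale dynamics.
#' @param steps number of macro steps.
#' @param seed integer seed; all randomness derives from it.
#' @param grid a [hex_grid()] (defaults to the dimensions of `init`).
#' @param barrier optional logical matrix of unavailable cells.
#' @return An object of class `sca_run`: list with `snapshots` (density
#'   matrices at times `0..steps`), `log` (per-step data frame with
#'   neighbourhood count, affected count and the mass-ledger terms),
#'   `params`, `bd`, `seed`, `grid`.
#' @examples
#' g <- hex_grid(15, 15)
#' init <- matrix(0, 15, 15); init[8, 8] <- 0.5
#' run <- simulate_dispersion(init, sca_params(), bd = NULL,
#'                            steps = 5, seed = 1, grid = g)
#' sapply(run$snapshots, function(f) sum(f > 0))
#' @export
simulate_dispersion <- function(init, params = sca_params(), bd = bd_spec(),
                                steps = 30L, seed = 1L, grid = NULL,
                                barrier = NULL) {
  if (is.null(grid)) grid <- hex_grid(nrow(init), ncol(init))
  stopifnot(nrow(init) == grid$m, ncol(init) == grid$n)
  if (any(init < 0) || any(init > 1)) stop("densities must lie in [0, 1]")
  field <- init
  snapshots <- vector("list", steps + 1L)
  snapshots[[1L]] <- field
  log_rows <- vector("list", steps)
  for (t in seq_len(steps)) {
    if (!is.null(bd))
      field <- couple_microscale(field, bd, t = t - 1L, seed = seed)
    ms <- macro_step(field, params, grid, seed = seed, t = t,
                     barrier = barrier)
    oc <- ms$outcomes
    sum_of <- function(nm) sum(vapply(oc, `[[`, numeric(1), nm))
    log_rows[[t]] <- data.frame(
      time = t,
      n_nbhd = length(oc),
      n_affected = sum(ms$field > 0),
      pool = sum_of("pool"),
      lost_in_transit = sum_of("lost_in_transit"),
      zeroed_mass = sum_of("zeroed_mass"),
      absorbed_mass = sum_of("absorbed_mass"),
      total_density = sum(ms$field)
    )
    field <- ms$field
    snapshots[[t + 1L]] <- field
  }
  structure(list(snapshots = snapshots,
                 log = if (steps > 0L) do.call(rbind, log_rows) else NULL,
                 params = params, bd = bd, seed = seed, grid = grid),
            class = "sca_run")
}

#' @export
print.sca_run <- function(x, ...) {
  T_ <- length(x$snapshots) - 1L
  last <- x$snapshots[[T_ + 1L]]
  cat(sprintf("<sca_run> %d macro steps on a %d x %d grid (seed %d)\n",
              T_, x$grid$m, x$grid$n, x$seed))
  cat(sprintf("  final state: %d affected cells, total density %.3f\n",
              sum(last > 0), sum(last)))
  invisible(x)
}

#' Write and read density fields as delimited text
#'
#' Plain tab-delimited `m` x `n` matrices, full precision, no headers, so
#' that write-then-read round-trips exactly.
#'
#' @param field numeric matrix.
#' @param path file path.
#' @return `read_density` returns a numeric matrix.
#' @export
write_density <- function(field, path) {
  utils::write.table(format(field, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Run a simulation from a configuration and write its outputs
#'
#' The configuration is a nested list (or the path of a YAML file holding
#' one) with entries `grid` (`m`, `n`), `params` (arguments of
#' [sca_params()]), `bd` (arguments of [bd_spec()], or `NULL`), `steps`,
#' `seed`, `init` (a fixture name understood by [make_fixture()], or the
#' path of a density matrix), optional `barrier` (path of a 0/1 matrix) and
#' `snapshots` (times to write; default all).  Outputs under `out_dir`:
#' `snapshot_t<t>.tsv`, `stats.tsv` (per-time pattern summaries), `log.tsv`
#' (mass ledger), and `manifest.yaml` (the full configuration).  Identical
#' manifests produce byte-identical outputs.
#'
#' @param config list or path of a YAML config file.
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing and just return the run.
#' @return The [simulate_dispersion()] run object, invisibly.
#' @export
run_simulation <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$grid) || is.null(cfg$steps) || is.null(cfg$seed))
    stop("config must provide grid, steps and seed")
  grid <- hex_grid(cfg$grid$m, cfg$grid$n)
  params <- do.call(sca_params, as.list(cfg$params %||% list()))
  bd <- if (is.null(cfg$bd)) NULL else do.call(bd_spec, as.list(cfg$bd))
  init <- resolve_init(cfg$init %||% "single-cell", grid)
  barrier <- if (!is.null(cfg$barrier)) read_density(cfg$barrier) > 0 else NULL
  run <- simulate_dispersion(init, params, bd, steps = cfg$steps,
                             seed = cfg$seed, grid = grid, barrier = barrier)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    snaps <- cfg$snapshots %||% (seq_along(run$snapshots) - 1L)
    for (t in snaps)
      write_density(run$snapshots[[t + 1L]],
                    file.path(out_dir, sprintf("snapshot_t%03d.tsv", t)))
    sm <- do.call(rbind, lapply(seq_along(run$snapshots), function(s)
      pattern_summary(run$snapshots[[s]], grid, time = s - 1L)))
    utils::write.table(sm, file.path(out_dir, "stats.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(run$log))
      utils::write.table(run$log, file.path(out_dir, "log.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    yaml::write_yaml(cfg, file.path(out_dir, "manifest.yaml"))
  }
  invisible(run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_init <- function(init, grid) {
  if (is.matrix(init)) return(init)
  if (file.exists(init)) return(read_density(init))
  make_fixture(init, grid = grid)
}

#' Built-in fixtures for simulations and tests
#'
#' Deterministic or seeded constructions of initial fields, masks,
#' parameter rasters and a synthetic survey image:
#' * `"single-cell"`: density 0.5 in the central cell.
#' * `"two-neighbourhoods"`: two cells of density 0.5 more than three hex
#'   steps apart.
#' * `"random-blob"`: seeded random densities in a hex disk around the
#'   centre.
#' * `"bridge-mask"`: logical barrier (as 0/1) splitting the domain in two
#'   except for a two-row corridor.
#' * `"wind-field"`: a `beta` exponent raster that favours inclusion
#'   downwind (`beta < 1`) and disfavours it upwind, linear along the wind
#'   direction.
#' * `"synthetic-survey-image"`: a grayscale matrix in `[0, 1]` (optionally
#'   written as 8-bit PNG) with an elliptical high-intensity blob whose
#'   grey levels are multiples of 1/255 at or above the conversion
#'   threshold, so a noiseless [image_to_density()] recovers the planted
#'   field exactly.
#'
#' @param name fixture name (see above).
#' @param grid a [hex_grid()] (image fixture uses its dimensions in
#'   pixels).
#' @param seed integer seed for the random fixtures.
#' @param path optional file path; the fixture is written there (PNG for
#'   the image, tab-delimited text otherwise).
#' @param wind_strength slope of the wind `beta` raster.
#' @return The fixture as a matrix (invisibly the path if written).
#' @export
make_fixture <- function(name, grid = hex_grid(30, 30), seed = 1L,
                         path = NULL, wind_strength = 0.5) {
  m <- grid$m; n <- grid$n
  ctr <- c(ceiling(m / 2), ceiling(n / 2))
  fx <- switch(name,
    "single-cell" = {
      f <- matrix(0, m, n); f[ctr[1L], ctr[2L]] <- 0.5; f
    },
    "two-neighbourhoods" = {
      f <- matrix(0, m, n)
      a <- c(ctr[1L], max(1L, ctr[2L] - 3L))
      b <- c(ctr[1L], min(n, ctr[2L] + 3L))
      if (hex_distance(a, b) <= 3L) stop("grid too small for two blobs")
      f[a[1L], a[2L]] <- 0.5; f[b[1L], b[2L]] <- 0.5; f
    },
    "random-blob" = {
      set.seed(seed)
      f <- matrix(0, m, n)
      all_cells <- cbind(i = rep(seq_len(m), n),
                         j = rep(seq_len(n), each = m))
      d <- hex_distance_many(ctr, all_cells)
      inside <- d <= max(2L, min(m, n) %/% 6L)
      f[all_cells[inside, , drop = FALSE]] <-
        stats::runif(sum(inside), 0.2, 1)
      f
    },
    "bridge-mask" = {
      mask <- matrix(0, m, n)
      wall <- ctr[2L]
      mask[, wall] <- 1
      gap <- ctr[1L] + c(0L, 1L)
      mask[gap, wall] <- 0
      mask
    },
    "wind-field" = {
      # wind blowing in +x (west -> east): beta < 1 east of the centre
      xy <- centroid_xy(cbind(i = rep(seq_len(m), n),
                              j = rep(seq_len(n), each = m)), grid)
      u <- (xy[, "x"] - mean(range(xy[, "x"]))) / diff(range(xy[, "x"])) * 2
      matrix(pmin(pmax(1 - wind_strength * u, 0.3), 1.7), m, n)
    },
    "synthetic-survey-image" = {
      img <- matrix(50 / 255, m, n)
      ii <- matrix(rep(seq_len(m), n), m, n)
      jj <- matrix(rep(seq_len(n), each = m), m, n)
      inside <- ((ii - ctr[1L]) / (m / 5))^2 + ((jj - ctr[2L]) / (n / 4))^2 <= 1
      set.seed(seed)
      levels <- sample(205:255, sum(inside), replace = TRUE)
      img[inside] <- levels / 255
      img
    },
    stop("unknown fixture name: ", name)
  )
  if (!is.null(path)) {
    if (name == "synthetic-survey-image") {
      png::writePNG(fx, path)
    } else {
      write_density(fx, path)
    }
    return(invisible(path))
  }
  fx
}
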