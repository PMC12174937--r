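#' Cells with positive density
#'
#' @param field numeric density matrix.
#' @return Integer matrix with columns `i`, `j` (column-major order).
#' @export
affected_cells <- function(field) {
  idx <- which(field > 0, arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[order(idx[, "j"], idx[, "i"]), , drop = FALSE]
}

#' Boundary edges of an affected pattern
#'
#' Counts, over all affected cells, the hexagon edges whose opposite cell is
#' not affected; the exterior of the domain counts as not affected.  Equals
#' `6 * N_a - 2 * (number of internal adjacencies)`.
#'
#' @param affected integer matrix of cells (columns `i`, `j`), non-empty.
#' @param grid a [hex_grid()].
#' @return Integer edge count.
#' @export
boundary_edge_count <- function(affected, grid) {
  if (is.null(affected) || nrow(affected) == 0L)
    stop("the affected set is empty")
  keys <- paste(affected[, 1L], affected[, 2L])
  edges <- 0L
  for (k in seq_len(nrow(affected))) {
    nb <- moore_neighbors(unname(affected[k, 1:2]), grid)
    nb_keys <- paste(nb[, "i"], nb[, "j"])
    edges <- edges + sum(!(nb_keys %in% keys))
  }
  edges
}

#' Pattern complexity
#'
#' Boundary complexity of an affected pattern, by either of two equivalent
#' definitions: the number of boundary edges divided by the number of
#' affected cells (`method = "edges"`), or
#' `(6 N_a - sum(n_a)) / N_a` where `n_a` counts each affected cell's
#' affected neighbours (`method = "adjacency"`).  Smooth compact patterns
#' score low; ragged boundaries score high; a single cell scores 6.
#'
#' @param affected integer matrix of cells (columns `i`, `j`), non-empty.
#' @param grid a [hex_grid()].
#' @param method `"edges"` or `"adjacency"`.
#' @return Complexity (edges per affected cell).
#' @export
pattern_complexity <- function(affected, grid,
                               method = c("edges", "adjacency")) {
  method <- match.arg(method)
  if (is.null(affected) || nrow(affected) == 0L)
    stop("the affected set is empty")
  n_a <- nrow(affected)
  if (method == "edges") {
    boundary_edge_count(affected, grid) / n_a
  } else {
    keys <- paste(affected[, 1L], affected[, 2L])
    na_sum <- 0L
    for (k in seq_len(n_a)) {
      nb <- moore_neighbors(unname(affected[k, 1:2]), grid)
      na_sum <- na_sum + sum(paste(nb[, "i"], nb[, "j"]) %in% keys)
    }
    (6 * n_a - na_sum) / n_a
  }
}

#' Equal-area radius and centre of mass of a pattern
#'
#' The radius of the circle whose area equals the affected area (unit cell
#' area, so `r = sqrt(N_a / pi)`) and the density-weighted centre of mass
#' of the affected cells' centroids.
#'
#' @param field numeric density matrix.
#' @param grid a [hex_grid()].
#' @param affected optional affected-cell matrix (defaults to
#'   `affected_cells(field)`).
#' @return A list with `radius`, `centre` (x, y), and `n_affected`.
#' @export
equal_area_radius_and_com <- function(field, grid,
                                      affected = affected_cells(field)) {
  if (nrow(affected) == 0L) stop("the affected set is empty")
  dens <- field[affected[, 1:2, drop = FALSE]]
  if (sum(dens) <= 0) stop("all affected densities are zero")
  xy <- centroid_xy(affected, grid)
  com <- colSums(xy * dens) / sum(dens)
  list(radius = sqrt(nrow(affected) / pi), centre = com,
       n_affected = nrow(affected))
}

#' Summary statistics of one pattern snapshot
#'
#' @param field numeric density matrix.
#' @param grid a [hex_grid()].
#' @param time the macro time of the snapshot.
#' @return A one-row data frame: `time`, `n_affected`, `boundary_edges`,
#'   `complexity`, `radius`, `com_x`, `com_y`, `mean_density` (over
#'   affected cells).
#' @export
pattern_summary <- function(field, grid, time = NA_integer_) {
  aff <- affected_cells(field)
  if (nrow(aff) == 0L)
    return(data.frame(time = time, n_affected = 0L, boundary_edges = NA,
                      complexity = NA, radius = NA, com_x = NA, com_y = NA,
                      mean_density = NA))
  # fast path: internal adjacencies from the neighbour-stat kernel
  st <- hex_neighbor_stats(field)
  mask <- field > 0
  be <- 6L * nrow(aff) - sum(st$na[mask])
  rc <- equal_area_radius_and_com(field, grid, aff)
  data.frame(time = time, n_affected = nrow(aff), boundary_edges = be,
             complexity = be / nrow(aff), radius = rc$radius,
             com_x = rc$centre[[1L]], com_y = rc$centre[[2L]],
             mean_density = mean(field[aff[, 1:2, drop = FALSE]]))
}

#' Per-neighbourhood radius and dispersion-rate series
#'
#' Tracks interaction neighbourhoods across a sequence of snapshots by
#' maximal overlap of their affected sets, computes the equal-area radius of
#' each at each time, and differences consecutive radii to obtain the
#' dispersion rate.  When neighbourhoods merge, the merged neighbourhood
#' continues the series of the larger parent; a neighbourhood that vanishes
#' ends its series.
#'
#' @param snapshots list of density matrices (consecutive times).
#' @param grid a [hex_grid()].
#' @param times optional numeric times (default `0, 1, ...`).
#' @return A data frame with columns `time`, `nbhd`, `n_affected`,
#'   `radius`, `rate` (`NA` at each series' first time).
#' @export
dispersion_rate_series <- function(snapshots, grid, times = NULL) {
  stopifnot(length(snapshots) >= 2L)
  if (is.null(times)) times <- seq_along(snapshots) - 1L
  rows <- list()
  prev_sets <- list()   # persistent id -> linear-index set
  prev_radius <- numeric()
  next_id <- 0L
  for (s in seq_along(snapshots)) {
    nbhds <- find_interaction_neighbourhoods(snapshots[[s]], grid)
    cur_sets <- list(); cur_radius <- numeric()
    for (nb in nbhds) {
      cells <- cell_linear_index(nb$affected, grid)
      # match to the previous neighbourhood with the largest overlap
      best <- NA_character_; best_n <- 0L
      for (pid in names(prev_sets)) {
        ov <- length(intersect(cells, prev_sets[[pid]]))
        ov_size <- length(prev_sets[[pid]])
        if (ov > best_n || (ov == best_n && ov > 0L && !is.na(best) &&
                            ov_size > length(prev_sets[[best]]))) {
          best <- pid; best_n <- ov
        }
      }
      if (best_n > 0L && !(best %in% names(cur_sets))) {
        id <- best
      } else {
        next_id <- next_id + 1L
        id <- as.character(next_id)
      }
      cur_sets[[id]] <- cells
      r <- sqrt(length(cells) / pi)
      cur_radius[[id]] <- r
      rate <- if (id %in% names(prev_radius)) r - prev_radius[[id]] else NA
      rows[[length(rows) + 1L]] <- data.frame(
        time = times[s], nbhd = as.integer(id),
        n_affected = length(cells), radius = r, rate = rate)
    }
    prev_sets <- cur_sets
    prev_radius <- unlist(cur_radius)
    if (is.null(prev_radius)) prev_radius <- numeric()
  }
  do.call(rbind, rows)
}

#' Calibration summary statistics of a run
#'
#' The four observables used for parameter calibration, computed from the
#' whole-grid affected pattern of each snapshot:
#' 1. time-average number of affected cells;
#' 2. time-average of the mean density over affected cells;
#' 3. time-average boundary complexity (edges definition);
#' 4. slope of the least-squares line of `log(complexity)` against time.
#'
#' @param snapshots list of density matrices.
#' @param grid a [hex_grid()].
#' @param which integer subset of `1:4`.
#' @return Named numeric vector (subset of `n_affected`, `mean_density`,
#'   `complexity`, `complexity_slope`).
#' @export
calibration_statistics <- function(snapshots, grid, which = 1:4) {
  sm <- do.call(rbind, lapply(seq_along(snapshots), function(s)
    pattern_summary(snapshots[[s]], grid, time = s - 1L)))
  ok <- sm$n_affected > 0L
  if (!any(ok)) stop("run contains no affected cells at any time")
  out <- c(
    n_affected = mean(sm$n_affected),
    mean_density = mean(sm$mean_density[ok]),
    complexity = mean(sm$complexity[ok]),
    complexity_slope = {
      d <- sm[ok & sm$complexity > 0, ]
      if (nrow(d) >= 2L)
        unname(stats::coef(stats::lm(log(complexity) ~ time, data = d))[2L])
      else NA_real_
    }
  )
  out[which]
}
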