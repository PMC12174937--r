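#' Hexagonal grid specification
#'
#' Defines an `m` x `n` partition of the plane into flat-top hexagonal cells,
#' indexed by 1-based `(i, j)` with `i` the row and `j` the column.  Even
#' columns are shifted up by half a cell height, so every interior cell has
#' exactly six neighbours and the centroid spacing between any two adjacent
#' cells is one unit.  Cells with indices outside `1..m` x `1..n` are
#' *auxiliary* cells: they sit one (or more) steps outside the boundary,
#' carry density zero, and are used to implement absorbing boundaries.
#'
#' @param m,n positive integers: number of rows and columns.
#' @return An object of class `hex_grid` with elements `m` and `n`.
#' @examples
#' g <- hex_grid(5, 5)
#' moore_neighbors(c(2, 2), g)
#' @export
hex_grid <- function(m, n) {
  m <- as.integer(m); n <- as.integer(n)
  stopifnot(length(m) == 1L, length(n) == 1L, m >= 1L, n >= 1L)
  structure(list(m = m, n = n), class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d x %d flat-top hexagonal cells (%d total)\n",
              x$m, x$n, x$m * x$n))
  invisible(x)
}

# Row/column offsets of the six neighbours, in the cyclic order
# N, NE, SE, S, SW, NW (consecutive entries are mutually adjacent).
# `j` is the 1-based column index of the centre cell.
hex_offsets_r <- function(j) {
  if (j %% 2L == 0L) {
    cbind(di = c(-1L, -1L, 0L, 1L, 0L, -1L),
          dj = c(0L, 1L, 1L, 0L, -1L, -1L))
  } else {
    cbind(di = c(-1L, 0L, 1L, 1L, 1L, 0L),
          dj = c(0L, 1L, 1L, 0L, -1L, -1L))
  }
}

is_real_cell <- function(cell, grid) {
  cell[1L] >= 1L && cell[1L] <= grid$m && cell[2L] >= 1L && cell[2L] <= grid$n
}

#' Moore neighbourhood of a hexagonal cell
#'
#' Returns the six cells adjacent to `cell`, in a fixed cyclic order
#' (N, NE, SE, S, SW, NW); consecutive entries of the result are themselves
#' mutually adjacent.  Positions that fall outside the grid are returned as
#' auxiliary cells and flagged in the `aux` column.
#'
#' @param cell integer vector `c(i, j)` (1-based row, column) of a real cell.
#' @param grid a [hex_grid()].
#' @return A 6 x 3 integer matrix with columns `i`, `j`, `aux` (0/1).
#' @export
moore_neighbors <- function(cell, grid) {
  cell <- as.integer(cell)
  if (!is_real_cell(cell, grid))
    stop("cell (", cell[1L], ", ", cell[2L], ") is outside the grid")
  off <- hex_offsets_r(cell[2L])
  i <- cell[1L] + off[, "di"]
  j <- cell[2L] + off[, "dj"]
  aux <- as.integer(i < 1L | i > grid$m | j < 1L | j > grid$n)
  cbind(i = i, j = j, aux = aux)
}

# Offset -> cube coordinates (x, y, z with x + y + z = 0) for the flat-top,
# even-columns-shifted-up layout.  Accepts vectors.
offset_to_cube <- function(i, j) {
  q <- j - 1L
  r <- i - 1L
  x <- q
  z <- r - (q + (q %% 2L)) %/% 2L
  cbind(x = x, y = -x - z, z = z)
}

#' Hexagonal lattice distance
#'
#' Length of the shortest adjacency path between two cells, computed via
#' cube coordinates.  A metric on the (infinite extension of the) lattice.
#'
#' @param a,b integer vectors `c(i, j)`; auxiliary indices are allowed.
#' @param grid a [hex_grid()] (used only for interface symmetry).
#' @return A non-negative integer.
#' @export
hex_distance <- function(a, b, grid = NULL) {
  ca <- offset_to_cube(a[1L], a[2L])
  cb <- offset_to_cube(b[1L], b[2L])
  as.integer(sum(abs(ca - cb)) / 2L)
}

# Vectorised pairwise-free variant used internally: distances from one cell
# to many cells given as a matrix with columns i, j.
hex_distance_many <- function(cell, cells) {
  ca <- offset_to_cube(cell[1L], cell[2L])
  cb <- offset_to_cube(cells[, 1L], cells[, 2L])
  diffs <- abs(cb - matrix(as.vector(ca), nrow(cb), 3L, byrow = TRUE))
  as.integer(rowSums(diffs) %/% 2L)
}

#' Planar centroid of a hexagonal cell
#'
#' Centroid coordinates with unit distance between the centroids of any two
#' adjacent cells.  The x axis runs along columns, the y axis along rows
#' (increasing downwards); even columns are shifted up by half a unit.
#'
#' @param cell integer vector `c(i, j)`, or a matrix with columns `i`, `j`.
#' @param grid a [hex_grid()] (used only for interface symmetry).
#' @return A numeric vector `c(x, y)`, or a two-column matrix.
#' @export
centroid_xy <- function(cell, grid = NULL) {
  if (is.matrix(cell)) {
    i <- cell[, 1L]; j <- cell[, 2L]
    cbind(x = sqrt(3) / 2 * (j - 1), y = (i - 1) - 0.5 * ((j - 1) %% 2))
  } else {
    i <- cell[1L]; j <- cell[2L]
    c(x = sqrt(3) / 2 * (j - 1), y = (i - 1) - 0.5 * ((j - 1) %% 2))
  }
}

# linear index of real cells (column-major, matching R matrices)
cell_linear_index <- function(cells, grid) {
  (cells[, 2L] - 1L) * grid$m + cells[, 1L]
}
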