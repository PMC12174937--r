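#' Find interaction neighbourhoods of a density field
#'
#' Affected cells (density strictly greater than 0) belong to the same
#' interaction neighbourhood when they are connected under the transitive
#' closure of "hex distance at most 3", i.e. separated by at most two
#' unaffected cells along a shortest path.  Each neighbourhood also carries
#' its *halo*: the unaffected immediate neighbours of its affected members,
#' including auxiliary (off-grid) cells.
#'
#' Internally the grouping is computed as the hex-adjacency connected
#' components of the affected mask dilated by one step: two radius-1 disks
#' around affected cells contain adjacent cells exactly when the two centres
#' are at hex distance 3 or less, so the component structure of the dilated
#' mask reproduces the distance rule exactly.  The mask is padded by two
#' columns/rows on each side so that connections routed through off-grid
#' positions are honoured (the metric is defined on the infinite lattice).
#'
#' @param field numeric `m` x `n` matrix with entries in `[0, 1]`.
#' @param grid a [hex_grid()] matching `dim(field)`.
#' @param barrier optional logical matrix; `TRUE` cells are unavailable and
#'   are treated as permanently unaffected.
#' @return A list of neighbourhoods; each is a list with elements
#'   `affected` (matrix of cells `i`,`j`), `halo` (matrix with columns
#'   `i`,`j`,`aux`), and `id` (the smallest column-major linear index among
#'   the affected cells, stable under the presence of other neighbourhoods).
#'   A zero field yields an empty list.
#' @export
find_interaction_neighbourhoods <- function(field, grid, barrier = NULL) {
  stopifnot(nrow(field) == grid$m, ncol(field) == grid$n)
  affected <- field > 0
  if (!is.null(barrier)) affected <- affected & !barrier
  if (!any(affected)) return(list())
  lab <- label_affected(affected, grid)
  groups <- split_components(affected, lab, grid)
  groups
}

# Label affected *and* halo cells by neighbourhood.  Pads by 2 (even pad
# preserves column parity) so off-grid routes and auxiliary halo cells are
# labelled too.  Returns list(lab = padded label matrix, pad = 2L).
label_affected <- function(affected, grid) {
  pad <- 2L
  m <- grid$m + 2L * pad
  n <- grid$n + 2L * pad
  big <- matrix(FALSE, m, n)
  big[pad + seq_len(grid$m), pad + seq_len(grid$n)] <- affected
  # dilate by one hex step
  dil <- big
  idx <- which(big, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    off <- hex_offsets_r(idx[k, 2L])   # parity preserved by even pad
    dil[cbind(idx[k, 1L] + off[, 1L], idx[k, 2L] + off[, 2L])] <- TRUE
  }
  lab <- hex_label_components(dil)
  list(lab = lab, pad = pad)
}

split_components <- function(affected, labelling, grid) {
  pad <- labelling$pad
  lab <- labelling$lab
  core <- lab[pad + seq_len(grid$m), pad + seq_len(grid$n)]
  comp_ids <- sort(unique(core[affected]))
  out <- vector("list", length(comp_ids))
  for (k in seq_along(comp_ids)) {
    cid <- comp_ids[k]
    mem <- which(lab == cid, arr.ind = TRUE)
    i <- mem[, 1L] - pad
    j <- mem[, 2L] - pad
    real <- i >= 1L & i <= grid$m & j >= 1L & j <= grid$n
    aff <- logical(length(i))
    aff[real] <- affected[cbind(i[real], j[real])]
    aff_cells <- cbind(i = i[aff], j = j[aff])
    halo <- cbind(i = i[!aff], j = j[!aff], aux = as.integer(!real[!aff]))
    ord <- order(aff_cells[, "j"], aff_cells[, "i"])
    aff_cells <- aff_cells[ord, , drop = FALSE]
    ord_h <- order(halo[, "aux"], halo[, "j"], halo[, "i"])
    halo <- halo[ord_h, , drop = FALSE]
    out[[k]] <- list(
      affected = aff_cells,
      halo = halo,
      id = min(cell_linear_index(aff_cells, grid))
    )
  }
  # order neighbourhoods by id for determinism
  out[order(vapply(out, `[[`, integer(1), "id"))]
}

#' Inclusion weights and maximum density differences
#'
#' For each cell of an interaction neighbourhood (affected and halo,
#' including auxiliary cells) computes the inclusion weight `w` — the number
#' of adjacent affected cells, plus one for affected cells themselves — and
#' `d`, the maximum absolute density difference with its six neighbours
#' (auxiliary and off-grid neighbours carry density 0).
#'
#' @param nbhd one element of [find_interaction_neighbourhoods()].
#' @param field the density matrix the neighbourhood was found on.
#' @param grid a [hex_grid()].
#' @return A data frame with columns `i`, `j`, `aux`, `affected`, `w`, `d`.
#' @export
inclusion_weights <- function(nbhd, field, grid) {
  cells <- rbind(
    cbind(nbhd$affected, aux = 0L),
    nbhd$halo
  )
  affected_set <- nbhd$affected
  aff_idx <- cell_linear_index(affected_set, grid)
  dens_at <- function(i, j) {
    if (i >= 1L && i <= grid$m && j >= 1L && j <= grid$n) field[i, j] else 0
  }
  n <- nrow(cells)
  w <- integer(n); d <- numeric(n); aff <- logical(n)
  for (k in seq_len(n)) {
    i <- cells[k, "i"]; j <- cells[k, "j"]
    off <- hex_offsets_r(j)
    ni <- i + off[, 1L]; nj <- j + off[, 2L]
    nd <- mapply(dens_at, ni, nj)
    me <- dens_at(i, j)
    n_aff <- sum(nd > 0)
    aff[k] <- me > 0
    w[k] <- n_aff + as.integer(aff[k])
    d[k] <- max(abs(me - nd))
  }
  data.frame(i = cells[, "i"], j = cells[, "j"], aux = cells[, "aux"],
             affected = aff, w = w, d = d)
}
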