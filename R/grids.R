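# A spot_grid is a dense lattice over the array-coordinate bounding box of one
# sample. values[i, j] corresponds to array position
# (row_offset + i - 1, col_offset + j - 1); unoccupied positions are NA.

new_spot_grid <- function(values, row_offset, col_offset) {
  stopifnot(is.matrix(values))
  structure(
    list(values = values,
         row_offset = as.integer(row_offset),
         col_offset = as.integer(col_offset)),
    class = "spot_grid"
  )
}

#' @export
print.spot_grid <- function(x, ...) {
  cat(sprintf("<spot_grid> %d x %d lattice, offsets (%d, %d), %d occupied cells\n",
              nrow(x$values), ncol(x$values), x$row_offset, x$col_offset,
              sum(!is.na(x$values))))
  invisible(x)
}

#' @export
dim.spot_grid <- function(x) dim(x$values)

same_frame <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    a$row_offset == b$row_offset && a$col_offset == b$col_offset
}

# Array coordinates of every lattice cell, in column-major order of `values`.
grid_coords <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  list(row = rep.int(seq_len(nr), nc) + grid$row_offset - 1L,
       col = rep(seq_len(nc), each = nr) + grid$col_offset - 1L)
}

check_integer_coords <- function(row, col) {
  bad <- !is.finite(row) | !is.finite(col) | row != round(row) | col != round(col)
  if (any(bad)) {
    stop("array coordinates must be integers; offending rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
}

#' Build tumor/parenchyma occupancy lattices for one sample
#'
#' Converts the spot table of a single sample into three aligned lattices over
#' the bounding box of the observed array coordinates: a tumor indicator grid
#' (1 on tumor spots, 0 on parenchyma spots), its complement, and a barcode
#' grid used to map lattice cells back to spots. Lattice positions not covered
#' by any spot are `NA` in all three grids.
#'
#' @param spots data frame with columns `barcode`, `array_row`, `array_col`
#'   and `tissue_class` (1 = tumor, 0 = parenchyma) for one sample.
#' @return list with elements `tumor`, `parenchyma` (numeric `spot_grid`s) and
#'   `barcodes` (character `spot_grid`).
#' @export
build_label_grids <- function(spots) {
  stopifnot(is.data.frame(spots))
  need <- c("barcode", "array_row", "array_col", "tissue_class")
  miss <- setdiff(need, names(spots))
  if (length(miss)) stop("spot table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(spots) == 0L) stop("spot table is empty", call. = FALSE)
  check_integer_coords(spots$array_row, spots$array_col)
  if (!all(spots$tissue_class %in% c(0, 1))) {
    stop("tissue_class must be 0 (parenchyma) or 1 (tumor)", call. = FALSE)
  }
  key <- paste(spots$array_row, spots$array_col)
  if (anyDuplicated(key)) {
    dups <- spots$barcode[key %in% key[duplicated(key)]]
    stop("duplicate array coordinates for barcodes: ",
         paste(unique(dups), collapse = ", "), call. = FALSE)
  }
  row_off <- min(spots$array_row); col_off <- min(spots$array_col)
  nr <- max(spots$array_row) - row_off + 1L
  nc <- max(spots$array_col) - col_off + 1L
  i <- spots$array_row - row_off + 1L
  j <- spots$array_col - col_off + 1L
  idx <- cbind(i, j)

  tum <- matrix(NA_real_, nr, nc)
  tum[idx] <- as.numeric(spots$tissue_class)
  par <- matrix(NA_real_, nr, nc)
  par[idx] <- 1 - as.numeric(spots$tissue_class)
  bc <- matrix(NA_character_, nr, nc)
  bc[idx] <- as.character(spots$barcode)

  list(tumor      = new_spot_grid(tum, row_off, col_off),
       parenchyma = new_spot_grid(par, row_off, col_off),
       barcodes   = new_spot_grid(bc, row_off, col_off))
}

#' Missing-aware square moving average on a lattice
#'
#' Each cell becomes the arithmetic mean of the non-missing cells inside the
#' square window of side `2 * delta + 1` centered on it (the Chebyshev ball of
#' radius `delta`). With `edge_policy = "clip"` the window is clipped at the
#' lattice borders and the mean is taken over the in-bounds cells; with
#' `edge_policy = "missing"` every cell within `delta` of a border becomes
#' missing. A cell whose window contains no observed value is missing.
#'
#' @param grid numeric `spot_grid` (or plain matrix).
#' @param delta integer window half-width, `>= 1`.
#' @param edge_policy `"clip"` (default) or `"missing"`.
#' @return `spot_grid` of window means.
#' @export
moving_average <- function(grid, delta, edge_policy = c("clip", "missing")) {
  edge_policy <- match.arg(edge_policy)
  if (is.matrix(grid)) grid <- new_spot_grid(grid, 1L, 1L)
  stopifnot(inherits(grid, "spot_grid"))
  if (length(delta) != 1L || !is.finite(delta) || delta != round(delta) || delta < 1) {
    stop("delta must be a single integer >= 1", call. = FALSE)
  }
  v <- grid$values
  if (length(v) == 0L) stop("empty grid", call. = FALSE)
  delta <- as.integer(delta)
  nr <- nrow(v); nc <- ncol(v)
  obs <- !is.na(v)
  vz <- v
  vz[!obs] <- 0
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (dr in -delta:delta) {
    ti <- max(1L, 1L - dr):min(nr, nr - dr)
    if (ti[1L] > ti[length(ti)]) next
    si <- ti + dr
    for (dc in -delta:delta) {
      tj <- max(1L, 1L - dc):min(nc, nc - dc)
      if (tj[1L] > tj[length(tj)]) next
      sj <- tj + dc
      acc[ti, tj] <- acc[ti, tj] + vz[si, sj]
      cnt[ti, tj] <- cnt[ti, tj] + obs[si, sj]
    }
  }
  res <- acc / cnt
  res[cnt == 0L] <- NA_real_
  if (edge_policy == "missing") {
    edge <- rep(TRUE, 0)
    if (nr > 2L * delta && nc > 2L * delta) {
      keep_r <- (delta + 1L):(nr - delta)
      keep_c <- (delta + 1L):(nc - delta)
      mask <- matrix(TRUE, nr, nc)
      mask[keep_r, keep_c] <- FALSE
      res[mask] <- NA_real_
    } else {
      res[] <- NA_real_
    }
  }
  new_spot_grid(res, grid$row_offset, grid$col_offset)
}

#' Weighted composite boundary-distance score
#'
#' Combines two moving averages of a binary tissue-indicator lattice into a
#' single boundary-distance score, then restricts it to one tissue
#' compartment: `score = w_small * MA(indicator, delta_small) +
#' w_large * MA(indicator, delta_large)`, multiplied elementwise by `mask`.
#' With the tumor indicator, tumor weights (2, 1) and the tumor mask, interior
#' tumor spots approach the maximum score 3; with the parenchyma indicator,
#' weights (2, 0.1) and the parenchyma mask the maximum is 2.1. Masked-out
#' occupied cells are exactly 0; unoccupied cells stay missing.
#'
#' @param indicator binary `spot_grid` (1 inside the compartment of interest).
#' @param mask binary `spot_grid` selecting the compartment whose spots keep
#'   their score (usually equal to `indicator`).
#' @param weights numeric length-2, `(w_small, w_large)`.
#' @param deltas integer length-2, `(delta_small, delta_large)`.
#' @return `spot_grid` of composite scores.
#' @export
composite_score <- function(indicator, mask, weights = c(2, 1), deltas = c(2L, 3L)) {
  stopifnot(inherits(indicator, "spot_grid"), inherits(mask, "spot_grid"))
  if (!same_frame(indicator, mask)) {
    stop("indicator and mask grids do not share shape and offsets", call. = FALSE)
  }
  stopifnot(length(weights) == 2L, length(deltas) == 2L)
  ma_s <- moving_average(indicator, deltas[[1L]])
  ma_l <- moving_average(indicator, deltas[[2L]])
  vals <- (weights[[1L]] * ma_s$values + weights[[2L]] * ma_l$values) * mask$values
  new_spot_grid(vals, indicator$row_offset, indicator$col_offset)
}
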