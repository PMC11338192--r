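#' Zonation parameters
#'
#' Bundles every tunable of the zonation: the two window half-widths, the
#' compositing weights for the tumor and parenchyma scores, the score cuts
#' that separate consecutive zones on each side of the boundary, and the
#' ordered zone names. The defaults give 8 zones about one spot layer thick
#' (~100 um on a standard Visium array): tumor cuts (2.96, 2.7, 2.3) on the
#' 0-3 tumor score and parenchyma cuts (2.095, 1.91, 1.7) on the 0-2.1
#' parenchyma score. Supplying `k` tumor cuts and `m` parenchyma cuts yields
#' `k + m + 2` zones, so finer zonations are possible with more cuts and
#' matching names.
#'
#' @param delta_small,delta_large integer window half-widths (defaults 2, 3).
#' @param tumor_weights,parenchyma_weights numeric length-2 compositing
#'   weights `(w_small, w_large)`; defaults `(2, 1)` and `(2, 0.1)`.
#' @param tumor_cuts,parenchyma_cuts strictly decreasing positive score cuts.
#' @param zone_names ordered labels, inner tumor first; length must equal
#'   `length(tumor_cuts) + length(parenchyma_cuts) + 2`.
#' @return object of class `zonation_params`.
#' @export
zonation_params <- function(delta_small = 2L,
                            delta_large = 3L,
                            tumor_weights = c(2, 1),
                            parenchyma_weights = c(2, 0.1),
                            tumor_cuts = c(2.96, 2.7, 2.3),
                            parenchyma_cuts = c(2.095, 1.91, 1.7),
                            zone_names = paste0("Zone_", LETTERS[1:8])) {
  if (delta_small < 1 || delta_large < 1) stop("deltas must be >= 1", call. = FALSE)
  if (any(diff(tumor_cuts) >= 0) || any(tumor_cuts <= 0)) {
    stop("tumor_cuts must be strictly decreasing and positive", call. = FALSE)
  }
  if (any(diff(parenchyma_cuts) >= 0) || any(parenchyma_cuts <= 0)) {
    stop("parenchyma_cuts must be strictly decreasing and positive", call. = FALSE)
  }
  n_zones <- length(tumor_cuts) + length(parenchyma_cuts) + 2L
  if (length(zone_names) != n_zones) {
    stop(sprintf("expected %d zone names for %d tumor and %d parenchyma cuts, got %d",
                 n_zones, length(tumor_cuts), length(parenchyma_cuts),
                 length(zone_names)), call. = FALSE)
  }
  if (anyDuplicated(zone_names)) stop("zone names must be unique", call. = FALSE)
  structure(
    list(delta_small = as.integer(delta_small),
         delta_large = as.integer(delta_large),
         tumor_weights = as.numeric(tumor_weights),
         parenchyma_weights = as.numeric(parenchyma_weights),
         tumor_cuts = as.numeric(tumor_cuts),
         parenchyma_cuts = as.numeric(parenchyma_cuts),
         zone_names = as.character(zone_names)),
    class = "zonation_params"
  )
}

#' @export
print.zonation_params <- function(x, ...) {
  cat("<zonation_params>\n",
      sprintf("  deltas: %d, %d\n", x$delta_small, x$delta_large),
      sprintf("  tumor weights (%s) cuts (%s)\n",
              paste(x$tumor_weights, collapse = ", "),
              paste(x$tumor_cuts, collapse = ", ")),
      sprintf("  parenchyma weights (%s) cuts (%s)\n",
              paste(x$parenchyma_weights, collapse = ", "),
              paste(x$parenchyma_cuts, collapse = ", ")),
      sprintf("  zones: %s\n", paste(x$zone_names, collapse = " > ")), sep = "")
  invisible(x)
}

# Ordinal on the tumor side: -(1 + #cuts below s) for s > 0, 0 on parenchyma.
# With the default cuts: s > M1 -> -4, (M2, M1] -> -3, (M3, M2] -> -2,
# (0, M3] -> -1. Half-open intervals (lo, hi] throughout.
tumor_ordinal <- function(s, cuts) {
  below <- Reduce(`+`, lapply(cuts, function(ct) as.integer(s > ct)))
  ifelse(s > 0, -(1L + below), 0L)
}

# Ordinal on the parenchyma side: #cuts below s for s > 0 ((0, L3] -> 0,
# (L3, L2] -> 1, (L2, L1] -> 2, > L1 -> 3), 0 on tumor.
parenchyma_ordinal <- function(s, cuts) {
  below <- Reduce(`+`, lapply(cuts, function(ct) as.integer(s > ct)))
  ifelse(s > 0, below, 0L)
}

#' Assign compartmental zones from composite scores
#'
#' Thresholds the tumor and parenchyma composite scores into ordinal zone
#' indices and maps them to zone labels. On the tumor side higher scores mean
#' deeper inside the tumor (most negative ordinal, first zone name); on the
#' parenchyma side higher scores mean further from the boundary (largest
#' ordinal, last zone name). Because each occupied cell carries a positive
#' score on exactly one side, the summed ordinal spans
#' `-(k_tumor + 1) .. k_parenchyma` and indexes the zone names in order.
#'
#' @param tumor_score,parenchyma_score `spot_grid`s from [composite_score()].
#' @param barcodes character `spot_grid` from [build_label_grids()].
#' @param params [zonation_params()].
#' @return list with `zones` (character `spot_grid`) and `table`, a data frame
#'   with one row per occupied cell: `barcode`, `zone`, `row`, `col` (array
#'   coordinates), ordered by row then column.
#' @export
assign_zones <- function(tumor_score, parenchyma_score, barcodes, params = zonation_params()) {
  stopifnot(inherits(tumor_score, "spot_grid"),
            inherits(parenchyma_score, "spot_grid"),
            inherits(barcodes, "spot_grid"),
            inherits(params, "zonation_params"))
  if (!same_frame(tumor_score, parenchyma_score) || !same_frame(tumor_score, barcodes)) {
    stop("score and barcode grids do not share shape and offsets", call. = FALSE)
  }
  ts <- tumor_score$values
  ps <- parenchyma_score$values
  occ <- !is.na(ts) & !is.na(ps)
  if (!identical(is.na(ts), is.na(ps))) {
    stop("tumor and parenchyma scores disagree on which cells are occupied", call. = FALSE)
  }
  if (any(occ & (ts < 0 | ps < 0))) stop("negative composite scores", call. = FALSE)
  if (any(occ & ts > 0 & ps > 0)) {
    stop("mask violation: some occupied cells carry positive scores on both sides",
         call. = FALSE)
  }
  k_t <- length(params$tumor_cuts)
  combined <- tumor_ordinal(ts, params$tumor_cuts) +
    parenchyma_ordinal(ps, params$parenchyma_cuts)
  idx <- combined + k_t + 2L
  if (any(occ & (idx < 1L | idx > length(params$zone_names)))) {
    stop("combined ordinal outside the configured zone range", call. = FALSE)
  }
  zones <- matrix(NA_character_, nrow(ts), ncol(ts))
  zones[occ] <- params$zone_names[idx[occ]]

  coords <- grid_coords(tumor_score)
  keep <- which(occ)
  tab <- data.frame(barcode = as.vector(barcodes$values)[keep],
                    zone = zones[keep],
                    row = coords$row[keep],
                    col = coords$col[keep],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$row, tab$col), , drop = FALSE]
  rownames(tab) <- NULL
  list(zones = new_spot_grid(zones, tumor_score$row_offset, tumor_score$col_offset),
       table = tab)
}

#' Zonate one sample
#'
#' Runs the full per-sample pipeline: occupancy lattices, moving-average
#' composites for both compartments, and zone assignment.
#'
#' @param spots spot table for a single sample (see [build_label_grids()]).
#' @param params [zonation_params()].
#' @return list with `table` (zone assignment table), `zones`, `tumor_score`,
#'   `parenchyma_score` (all `spot_grid`s) and `grids` (the label grids).
#' @export
zonate_sample <- function(spots, params = zonation_params()) {
  grids <- build_label_grids(spots)
  deltas <- c(params$delta_small, params$delta_large)
  ts <- composite_score(grids$tumor, grids$tumor,
                        weights = params$tumor_weights, deltas = deltas)
  ps <- composite_score(grids$parenchyma, grids$parenchyma,
                        weights = params$parenchyma_weights, deltas = deltas)
  az <- assign_zones(ts, ps, grids$barcodes, params)
  list(table = az$table, zones = az$zones,
       tumor_score = ts, parenchyma_score = ps, grids = grids)
}

#' Attach zone labels to a multi-sample spot table
#'
#' Joins per-sample zone assignment tables back onto the spot table by
#' `(sample_id, barcode)` key; row order of either input is irrelevant. Every
#' in-tissue spot must be matched; an unmatched barcode is an error, never a
#' silent default zone.
#'
#' @param spots spot table with `barcode` and `sample_id` columns (and
#'   optionally `in_tissue`; spots with `in_tissue == 0` are left `NA`).
#' @param tables named list of zone assignment tables, one per sample.
#' @return `spots` with a `zone` column added.
#' @export
annotate_spots_with_zones <- function(spots, tables) {
  stopifnot(is.data.frame(spots), is.list(tables))
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("`tables` must be a named list keyed by sample_id", call. = FALSE)
  }
  zone <- rep(NA_character_, nrow(spots))
  eligible <- if ("in_tissue" %in% names(spots)) spots$in_tissue != 0 else rep(TRUE, nrow(spots))
  for (sample in unique(spots$sample_id[eligible])) {
    sel <- which(eligible & spots$sample_id == sample)
    tab <- tables[[sample]]
    if (is.null(tab)) stop("no zone table for sample ", sample, call. = FALSE)
    hit <- match(spots$barcode[sel], tab$barcode)
    if (anyNA(hit)) {
      missing_bc <- spots$barcode[sel][is.na(hit)]
      stop(sprintf("sample %s: barcodes absent from its zone table: %s",
                   sample, paste(utils::head(missing_bc, 5L), collapse = ", ")),
           call. = FALSE)
    }
    zone[sel] <- tab$zone[hit]
  }
  spots$zone <- zone
  spots
}

#' Zonate a multi-sample spot table
#'
#' Splits the spot table by sample, zonates each sample independently (windows
#' never cross samples), and joins the zone labels back by barcode. Spots with
#' `in_tissue == 0` are excluded from the lattices and left unzoned.
#'
#' @param spots spot table with columns `barcode`, `sample_id`, `array_row`,
#'   `array_col`, `tissue_class` and optionally `in_tissue`.
#' @param params [zonation_params()].
#' @return list with `spots` (annotated table), `tables` (named list of
#'   per-sample zone assignment tables) and `results` (full per-sample output
#'   of [zonate_sample()]).
#' @export
zonate <- function(spots, params = zonation_params()) {
  stopifnot(is.data.frame(spots))
  if (!"sample_id" %in% names(spots)) spots$sample_id <- "sample"
  eligible <- if ("in_tissue" %in% names(spots)) spots$in_tissue != 0 else rep(TRUE, nrow(spots))
  samples <- unique(spots$sample_id[eligible])
  if (length(samples) == 0L) stop("no in-tissue spots to zonate", call. = FALSE)
  results <- lapply(samples, function(s) {
    zonate_sample(spots[eligible & spots$sample_id == s, , drop = FALSE], params)
  })
  names(results) <- samples
  tables <- lapply(results, `[[`, "table")
  annotated <- annotate_spots_with_zones(spots, tables)
  list(spots = annotated, tables = tables, results = results)
}
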