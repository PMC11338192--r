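# Readers/writers for the Space Ranger-adjacent formats the pipeline touches,
# plus QC and log-normalization.

V1_POSITION_COLS <- c("barcode", "in_tissue", "array_row", "array_col",
                      "pixel_row", "pixel_col")

#' Read a Space Ranger tissue-positions file
#'
#' Auto-detects the two dialects: the headerless 6-column v1 layout
#' (`barcode,in_tissue,array_row,array_col,pixel_row,pixel_col`) and the
#' headered v2 layout (`barcode,in_tissue,array_row,array_col,
#' pxl_row_in_fullres,pxl_col_in_fullres`). Gzip input is transparent.
#'
#' @param path CSV path.
#' @return data frame with columns `barcode`, `in_tissue`, `array_row`,
#'   `array_col`, `pixel_row`, `pixel_col`.
#' @export
read_tissue_positions <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, fixed = TRUE)
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) != 6L) {
    stop(sprintf("expected 6 columns in tissue positions file, found %d: %s",
                 ncol(df), path), call. = FALSE)
  }
  names(df) <- V1_POSITION_COLS
  check_integer_coords(df$array_row, df$array_col)
  df$in_tissue <- as.integer(df$in_tissue)
  df$array_row <- as.integer(df$array_row)
  df$array_col <- as.integer(df$array_col)
  df
}

#' Parse Visium HD bin barcodes into array coordinates
#'
#' HD barcodes encode the bin position as `<prefix><col>_<row>[-suffix]`
#' (e.g. `s_016um_00042_00007-1` is column 42, row 7). The first numeric
#' field is the column and the second the row; a trailing `-<n>` suffix is
#' stripped.
#'
#' @param barcode character vector of barcodes.
#' @param prefix bin-size prefix, e.g. `"s_016um_"`; adjust for other bin
#'   sizes (`"s_008um_"`, `"s_002um_"`).
#' @return data frame with `array_row` and `array_col`.
#' @export
parse_hd_barcode <- function(barcode, prefix = "s_016um_") {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", prefix)
  pat <- paste0("^", esc, "([0-9]+)_([0-9]+)(-[0-9]+)?$")
  m <- regmatches(barcode, regexec(pat, barcode))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) {
    stop("barcodes do not match HD pattern <prefix><digits>_<digits>[-n]: ",
         paste(utils::head(barcode[bad], 5L), collapse = ", "), call. = FALSE)
  }
  data.frame(array_row = as.integer(vapply(m, `[`, "", 3L)),
             array_col = as.integer(vapply(m, `[`, "", 2L)))
}

#' Emit Visium HD bin barcodes from array coordinates
#'
#' Inverse of [parse_hd_barcode()]: formats `(row, col)` as
#' `<prefix><col, 5 digits>_<row, 5 digits><suffix>`.
#'
#' @param array_row,array_col integer coordinates.
#' @param prefix bin-size prefix.
#' @param suffix trailing suffix, default `"-1"`.
#' @export
emit_hd_barcode <- function(array_row, array_col, prefix = "s_016um_", suffix = "-1") {
  sprintf("%s%05d_%05d%s", prefix, as.integer(array_col), as.integer(array_row), suffix)
}

find_one <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a 10x-style MatrixMarket counts triplet
#'
#' Loads `matrix.mtx[.gz]`, `features.tsv[.gz]` (or `genes.tsv`) and
#' `barcodes.tsv[.gz]` from a directory into a sparse genes-by-spots matrix.
#' Orientation is normalized so rows are genes; duplicate gene symbols get
#' deterministic suffixes `.1`, `.2`, ... in file order.
#'
#' @param dir directory containing the triplet.
#' @return `dgCMatrix` with gene symbols as rownames, barcodes as colnames.
#' @export
read_counts_mtx <- function(dir) {
  mtx <- find_one(dir, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- find_one(dir, c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
  bc <- find_one(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(mtx) || is.null(feat) || is.null(bc)) {
    stop("directory lacks matrix.mtx / features.tsv / barcodes.tsv: ", dir, call. = FALSE)
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- utils::read.delim(feat, header = FALSE, stringsAsFactors = FALSE)
  symbols <- if (ncol(features) >= 2L) features[[2L]] else features[[1L]]
  barcodes <- readLines(bc)
  if (length(symbols) == 0L || length(barcodes) == 0L || length(m) == 0L) {
    stop("empty counts matrix in ", dir, call. = FALSE)
  }
  if (nrow(m) == length(symbols) && ncol(m) == length(barcodes)) {
    # genes x spots already
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(symbols)) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf("matrix is %d x %d but there are %d features and %d barcodes",
                 nrow(m), ncol(m), length(symbols), length(barcodes)), call. = FALSE)
  }
  rownames(m) <- make.unique(as.character(symbols), sep = ".")
  colnames(m) <- barcodes
  m
}

#' Percent of counts in a gene set
#'
#' Per-spot percentage of total counts carried by genes whose symbol matches
#' an anchored pattern (a `^` is prepended when absent, so `"mt-"` matches
#' `mt-Co1` but not `Tmt-x`).
#'
#' @param counts genes-by-spots matrix.
#' @param pattern gene-symbol regular expression, anchored at the start.
#' @return named numeric vector, one percentage per spot.
#' @export
percent_feature_set <- function(counts, pattern) {
  if (!startsWith(pattern, "^")) pattern <- paste0("^", pattern)
  hit <- grepl(pattern, rownames(counts))
  tot <- Matrix::colSums(counts)
  sub <- Matrix::colSums(counts[hit, , drop = FALSE])
  pct <- 100 * sub / tot
  if (any(tot == 0)) {
    warning("spots with zero total counts get 0%: ",
            paste(utils::head(colnames(counts)[tot == 0], 5L), collapse = ", "))
    pct[tot == 0] <- 0
  }
  pct
}

#' QC parameters
#'
#' @param min_features minimum detected genes per spot (default 500).
#' @param max_pct_mito maximum mitochondrial-count percentage (default 20).
#' @param mito_pattern anchored symbol pattern for mitochondrial genes.
#' @param hb_pattern anchored symbol pattern for hemoglobin genes.
#' @param inclusive if `TRUE`, thresholds are inclusive (`>=` / `<=`); the
#'   default follows strict inequalities.
#' @export
qc_params <- function(min_features = 500L, max_pct_mito = 20,
                      mito_pattern = "mt-", hb_pattern = "Hb.*-",
                      inclusive = FALSE) {
  stopifnot(min_features >= 0, max_pct_mito >= 0, max_pct_mito <= 100)
  structure(list(min_features = as.integer(min_features),
                 max_pct_mito = as.numeric(max_pct_mito),
                 mito_pattern = mito_pattern,
                 hb_pattern = hb_pattern,
                 inclusive = isTRUE(inclusive)),
            class = "qc_params")
}

#' Filter spots on QC metrics
#'
#' Keeps spots with detected-gene count strictly above `min_features` and
#' mitochondrial percentage strictly below `max_pct_mito` (inclusive
#' comparisons with `inclusive = TRUE`).
#'
#' @param counts genes-by-spots matrix.
#' @param params [qc_params()].
#' @return list with `keep` (barcodes retained) and `report`, a data frame of
#'   per-spot metrics, kept flag and removal reason.
#' @export
qc_filter <- function(counts, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  n_feature <- Matrix::colSums(counts > 0)
  pct_mito <- percent_feature_set(counts, params$mito_pattern)
  if (params$inclusive) {
    ok_feat <- n_feature >= params$min_features
    ok_mito <- pct_mito <= params$max_pct_mito
  } else {
    ok_feat <- n_feature > params$min_features
    ok_mito <- pct_mito < params$max_pct_mito
  }
  kept <- ok_feat & ok_mito
  reason <- rep("", length(kept))
  reason[!ok_feat] <- "low_n_features"
  reason[!ok_mito] <- ifelse(nzchar(reason[!ok_mito]),
                             paste(reason[!ok_mito], "high_pct_mito", sep = ";"),
                             "high_pct_mito")
  report <- data.frame(barcode = colnames(counts),
                       n_features = as.integer(n_feature),
                       percent_mito = as.numeric(pct_mito),
                       kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  if (!any(kept)) {
    stop("QC removed every spot; review min_features/max_pct_mito thresholds",
         call. = FALSE)
  }
  list(keep = colnames(counts)[kept], report = report)
}

#' Library-size log-normalization
#'
#' `value = ln(1 + scale * count / spot_total)`, the standard log-normalized
#' expression used for downstream scoring. Zero counts stay exactly 0.
#'
#' @param counts nonnegative genes-by-spots matrix.
#' @param scale size factor, default `1e4`.
#' @return sparse matrix of log-normalized values, same dimnames.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  m <- methods::as(counts, "CsparseMatrix")
  tot <- Matrix::colSums(m)
  if (any(tot == 0)) {
    stop("spots with zero total counts cannot be normalized (QC-filter first): ",
         paste(utils::head(colnames(m)[tot == 0], 5L), collapse = ", "), call. = FALSE)
  }
  if (any(m@x < 0)) stop("negative counts", call. = FALSE)
  per_col <- rep.int(tot, diff(m@p))
  m@x <- log1p(m@x / per_col * scale)
  m
}

#' Read gene signatures from a YAML file
#'
#' The file maps signature names to gene-symbol lists.
#'
#' @param path YAML path.
#' @return named list of character vectors.
#' @export
read_signatures <- function(path) {
  sigs <- yaml::read_yaml(path)
  if (!is.list(sigs) || is.null(names(sigs)) || any(!nzchar(names(sigs)))) {
    stop("signature file must map names to gene lists: ", path, call. = FALSE)
  }
  lapply(sigs, as.character)
}

#' Write pipeline outputs
#'
#' Writes the annotated per-spot metadata as a gzip CSV, one zone CSV per
#' sample (`barcode,sample,row,col,zone`), and any summary tables as plain
#' CSVs. Rows are ordered by sample then barcode, so identical inputs give
#' byte-identical files.
#'
#' @param spots annotated spot table (with `zone` column).
#' @param tables named list of per-sample zone assignment tables.
#' @param out_dir output directory, created if needed.
#' @param summaries optional named list of data frames.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(spots, tables, out_dir, summaries = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character(0)

  md <- spots[order(spots$sample_id, spots$barcode), , drop = FALSE]
  md_path <- file.path(out_dir, "spot_metadata.csv.gz")
  con <- gzfile(md_path, "w")
  utils::write.csv(md, con, row.names = FALSE)
  close(con)
  paths <- c(paths, md_path)

  for (sample in names(tables)) {
    tab <- tables[[sample]]
    if (nrow(tab) == 0L) warning("sample ", sample, " has no zoned spots")
    out <- data.frame(barcode = tab$barcode,
                      sample = rep(sample, nrow(tab)),
                      row = tab$row, col = tab$col, zone = tab$zone,
                      stringsAsFactors = FALSE)
    out <- out[order(out$barcode), , drop = FALSE]
    p <- file.path(out_dir, paste0("zones_", sample, ".csv"))
    utils::write.csv(out, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(summaries)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(summaries[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
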