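# Synthetic Visium-like datasets with known geometry and expression
# structure, so the whole zonation pipeline can be exercised end to end
# without external downloads.

#' Simulation specification
#'
#' Describes a synthetic spatial dataset: lattice extent and layout, the
#' tumor region geometry, label noise, the sample/group design, the gene
#' programs, and the count model. The defaults emulate a standard Visium
#' capture area: hex-packed lattice (spots where row + col is even) of
#' 78 x 128 array positions (~5,000 spots), 100 um pitch, a disk-shaped
#' metastatic region, and eight samples split across the Ctrl / nonRes /
#' parRes treatment groups. Counts are negative binomial around
#' spot-specific lognormal library sizes, with tumor/parenchyma marker
#' programs, mitochondrial genes at a target fraction of the library, and
#' boundary-distance gradient genes.
#'
#' @param n_rows,n_cols lattice extent in array coordinates (0-based rows
#'   `0..n_rows-1`).
#' @param layout `"hex"` (spots where `row + col` is even, as on a Visium
#'   array) or `"full"` (every position occupied).
#' @param pitch_um center-to-center spot distance in micrometers.
#' @param region tumor geometry: `list(type = "half_plane", axis, cut)`
#'   (tumor where the coordinate is `<= cut`), `list(type = "disk", center,
#'   radius)`, or `list(type = "multi_disk", centers, radii)`. Default: a
#'   disk centered on the lattice with radius a third of its smaller extent.
#' @param label_flip_prob probability of flipping each spot's tissue label
#'   (label-level noise; must be `< 0.5`).
#' @param samples named character vector mapping sample ids to group labels.
#' @param tumor_markers,parenchyma_markers,gradient_genes,n_background gene
#'   program layout; mitochondrial genes are fixed `mt-` symbols.
#' @param marker_fold fold-change of marker genes inside their tissue.
#' @param gradient_log2_range log2 expression span of gradient genes from the
#'   deepest tumor to the most distant parenchyma.
#' @param mito_fraction target fraction of the library on `mt-` genes.
#' @param mean_library,library_sdlog lognormal library-size model
#'   (mean counts per spot and sdlog).
#' @param dispersion negative-binomial size parameter.
#' @param seed integer master seed; the same spec and seed give byte-identical
#'   datasets.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_rows = 78L, n_cols = 128L,
                            layout = c("hex", "full"),
                            pitch_um = 100,
                            region = NULL,
                            label_flip_prob = 0,
                            samples = c(Sample3 = "Ctrl", Sample4 = "nonRes",
                                        Sample7 = "Ctrl", Sample10 = "parRes",
                                        Sample11 = "parRes", Sample14 = "nonRes",
                                        Sample19 = "Ctrl", Sample22 = "parRes"),
                            tumor_markers = c("Epcam", "Cdh1", "Cldn7",
                                              "Krt8", "Krt18", "Spp1"),
                            parenchyma_markers = c("Alb", "Fabp1", "Apob",
                                                   "Car3", "Ttr"),
                            gradient_genes = paste0("Grad", 1:4),
                            n_background = 180L,
                            marker_fold = 8,
                            gradient_log2_range = 2,
                            mito_fraction = 0.1,
                            mean_library = 1e4,
                            library_sdlog = 0.35,
                            dispersion = 2,
                            seed = 1L) {
  layout <- match.arg(layout)
  if (is.null(region)) {
    # a metastatic nodule centered on the capture area, ~1/3 of its extent
    region <- list(type = "disk",
                   center = c(floor(n_rows / 2), floor(n_cols / 2)),
                   radius = floor(min(n_rows, n_cols) / 3))
  }
  if (label_flip_prob < 0 || label_flip_prob >= 0.5) {
    stop("label_flip_prob must be in [0, 0.5)", call. = FALSE)
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be a named vector: sample_id -> group", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         layout = layout, pitch_um = pitch_um, region = region,
         label_flip_prob = label_flip_prob, samples = samples,
         tumor_markers = tumor_markers,
         parenchyma_markers = parenchyma_markers,
         gradient_genes = gradient_genes,
         n_background = as.integer(n_background),
         marker_fold = marker_fold,
         gradient_log2_range = gradient_log2_range,
         mito_fraction = mito_fraction,
         mean_library = mean_library, library_sdlog = library_sdlog,
         dispersion = dispersion, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

MITO_GENES <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Atp8", "Atp6",
                              "Co3", "Nd3", "Nd4", "Cytb"))

region_membership <- function(region, row, col, n_rows, n_cols) {
  inside_lattice <- function(r, c) {
    r >= 0 && r <= n_rows - 1L && c >= 0 && c <= n_cols - 1L
  }
  switch(region$type,
    half_plane = {
      axis <- if (is.null(region$axis)) "col" else region$axis
      if (region$cut < 0 ||
          region$cut > (if (axis == "col") n_cols - 1L else n_rows - 1L)) {
        stop("half-plane cut outside the lattice", call. = FALSE)
      }
      if (axis == "col") col <= region$cut else row <= region$cut
    },
    disk = {
      if (!inside_lattice(region$center[[1L]], region$center[[2L]])) {
        stop("disk center outside the lattice", call. = FALSE)
      }
      (row - region$center[[1L]])^2 + (col - region$center[[2L]])^2 <=
        region$radius^2
    },
    multi_disk = {
      hit <- rep(FALSE, length(row))
      for (i in seq_along(region$radii)) {
        ctr <- region$centers[[i]]
        if (!inside_lattice(ctr[[1L]], ctr[[2L]])) {
          stop("disk center outside the lattice", call. = FALSE)
        }
        hit <- hit | (row - ctr[[1L]])^2 + (col - ctr[[2L]])^2 <=
          region$radii[[i]]^2
      }
      hit
    },
    stop("unknown region type: ", region$type, call. = FALSE)
  )
}

# Signed Chebyshev distance from each spot to the nearest spot of the
# opposite class: negative inside the tumor, positive in the parenchyma.
signed_boundary_distance <- function(row, col, tumor) {
  d <- rep(NA_real_, length(row))
  if (!any(tumor) || all(tumor)) return(d)
  for (side in c(TRUE, FALSE)) {
    from <- which(tumor == side)
    to <- which(tumor != side)
    best <- rep(Inf, length(from))
    for (j in to) {
      best <- pmin(best, pmax(abs(row[from] - row[j]), abs(col[from] - col[j])))
    }
    d[from] <- if (side) -best else best
  }
  d
}

#' Generate a labeled spot lattice for one sample
#'
#' Places spots on the configured lattice, marks the tumor region, applies
#' optional label-flip noise, and records the true signed Chebyshev distance
#' to the tissue boundary as ground truth (`NA` when only one tissue is
#' present).
#'
#' @param spec [simulation_spec()].
#' @param sample_id,group identity of the sample.
#' @param seed seed for the label noise; defaults to `spec$seed`.
#' @return spot table with columns `barcode`, `array_row`, `array_col`,
#'   `sample_id`, `group`, `tissue_class`, `true_class`, `boundary_dist`,
#'   `in_tissue`.
#' @export
make_labeled_lattice <- function(spec, sample_id = names(spec$samples)[[1L]],
                                 group = spec$samples[[1L]], seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  pos <- expand.grid(array_row = 0:(spec$n_rows - 1L),
                     array_col = 0:(spec$n_cols - 1L))
  if (spec$layout == "hex") {
    pos <- pos[(pos$array_row + pos$array_col) %% 2L == 0L, , drop = FALSE]
  }
  pos <- pos[order(pos$array_row, pos$array_col), , drop = FALSE]
  member <- region_membership(spec$region, pos$array_row, pos$array_col,
                              spec$n_rows, spec$n_cols)
  tissue <- as.integer(member)
  if (spec$label_flip_prob > 0) {
    flip <- with_seed(seed, stats::runif(nrow(pos)) < spec$label_flip_prob)
    tissue <- ifelse(flip, 1L - tissue, tissue)
  }
  data.frame(
    barcode = sprintf("BC%03d_%03d-1", pos$array_row, pos$array_col),
    array_row = pos$array_row,
    array_col = pos$array_col,
    sample_id = sample_id,
    group = group,
    tissue_class = tissue,
    true_class = as.integer(member),
    boundary_dist = signed_boundary_distance(pos$array_row, pos$array_col,
                                             member),
    in_tissue = 1L,
    stringsAsFactors = FALSE)
}

#' Simulate a counts matrix for labeled spots
#'
#' Negative-binomial counts around spot-specific lognormal library sizes.
#' Marker genes are multiplied by `marker_fold` inside their tissue,
#' mitochondrial (`mt-`) genes take a fixed `mito_fraction` of the expected
#' library, and gradient genes span `gradient_log2_range` log2 units linearly
#' in the true boundary distance (increasing from inner tumor to distant
#' parenchyma). Fully determined by `seed`.
#'
#' @param spots output of [make_labeled_lattice()].
#' @param spec [simulation_spec()].
#' @param seed seed for the count draw; defaults to `spec$seed`.
#' @return sparse genes-by-spots `dgCMatrix` of counts.
#' @export
simulate_counts <- function(spots, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  background <- sprintf("Gene%04d", seq_len(spec$n_background))
  genes <- c(spec$tumor_markers, spec$parenchyma_markers,
             spec$gradient_genes, MITO_GENES, background)
  n_spots <- nrow(spots)

  with_seed(seed, {
    base <- stats::rgamma(length(genes), shape = 0.8, rate = 1) + 1e-3
    names(base) <- genes
    w <- matrix(base, nrow = length(genes), ncol = n_spots,
                dimnames = list(genes, spots$barcode))

    tum <- spots$tissue_class == 1L
    w[spec$tumor_markers, tum] <- w[spec$tumor_markers, tum] * spec$marker_fold
    w[spec$parenchyma_markers, !tum] <-
      w[spec$parenchyma_markers, !tum] * spec$marker_fold

    d <- spots$boundary_dist
    if (all(is.na(d))) d <- rep(0, n_spots)
    span <- max(abs(d), na.rm = TRUE)
    if (span > 0) {
      frac <- (d + span) / (2 * span)  # 0 deepest tumor .. 1 farthest liver
      grad_fold <- 2^(spec$gradient_log2_range * frac)
      w[spec$gradient_genes, ] <-
        w[spec$gradient_genes, , drop = FALSE] *
        rep(grad_fold, each = length(spec$gradient_genes))
    }

    mito <- rownames(w) %in% MITO_GENES
    col_other <- colSums(w[!mito, , drop = FALSE])
    col_mito <- colSums(w[mito, , drop = FALSE])
    w[!mito, ] <- sweep(w[!mito, , drop = FALSE], 2,
                        (1 - spec$mito_fraction) / col_other, `*`)
    w[mito, ] <- sweep(w[mito, , drop = FALSE], 2,
                       spec$mito_fraction / col_mito, `*`)

    lib <- stats::rlnorm(n_spots,
                         meanlog = log(spec$mean_library) -
                           spec$library_sdlog^2 / 2,
                         sdlog = spec$library_sdlog)
    mu <- sweep(w, 2, lib, `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = spec$dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    Matrix::Matrix(counts, sparse = TRUE)
  })
}

#' Simulate a full multi-sample dataset
#'
#' Runs [make_labeled_lattice()] and [simulate_counts()] for every sample in
#' the spec, with per-sample seeds derived from the master seed.
#'
#' @param spec [simulation_spec()].
#' @return list with `spots` (all samples stacked) and `counts` (named list
#'   of per-sample matrices).
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  sample_ids <- names(spec$samples)
  per <- lapply(seq_along(sample_ids), function(i) {
    s <- (spec$seed + 7919L * i) %% .Machine$integer.max
    spots <- make_labeled_lattice(spec, sample_ids[[i]], spec$samples[[i]],
                                  seed = s)
    list(spots = spots, counts = simulate_counts(spots, spec, seed = s + 1L))
  })
  names(per) <- sample_ids
  list(spots = do.call(rbind, lapply(per, `[[`, "spots")),
       counts = lapply(per, `[[`, "counts"))
}

#' Write a simulated dataset to disk
#'
#' Emits, per sample, a headered tissue-positions CSV and a MatrixMarket
#' counts triplet (`counts_<sample>/matrix.mtx` + `features.tsv` +
#' `barcodes.tsv`), plus one merged label CSV
#' (`labels.csv`: `barcode,sample,group,ift`) and a JSON manifest recording
#' the spec and seed. With `hd = TRUE` all barcodes are rewritten in the
#' Visium HD style `s_<bin>um_<col>_<row>-1`.
#'
#' @param spots stacked spot table from [simulate_dataset()].
#' @param counts named list of per-sample counts matrices.
#' @param out_dir output directory.
#' @param hd emit HD-style barcodes.
#' @param bin_um HD bin size in micrometers (default 16).
#' @param spec optional [simulation_spec()] recorded in the manifest.
#' @return invisibly, `out_dir`.
#' @export
emit_dataset <- function(spots, counts, out_dir, hd = FALSE, bin_um = 16L,
                         spec = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  spots <- spots[order(spots$sample_id, spots$array_row, spots$array_col), ,
                 drop = FALSE]
  if (hd) {
    prefix <- sprintf("s_%03dum_", as.integer(bin_um))
    new_bc <- emit_hd_barcode(spots$array_row, spots$array_col, prefix = prefix)
    remap <- stats::setNames(new_bc, paste(spots$sample_id, spots$barcode))
    for (s in names(counts)) {
      key <- paste(s, colnames(counts[[s]]))
      colnames(counts[[s]]) <- unname(remap[key])
    }
    spots$barcode <- new_bc
  }
  for (s in unique(spots$sample_id)) {
    sub <- spots[spots$sample_id == s, , drop = FALSE]
    pos <- data.frame(barcode = sub$barcode,
                      in_tissue = sub$in_tissue,
                      array_row = sub$array_row,
                      array_col = sub$array_col,
                      pxl_row_in_fullres = sub$array_row * 100L,
                      pxl_col_in_fullres = sub$array_col * 100L)
    utils::write.csv(pos, file.path(out_dir, paste0(s, "_tissue_positions.csv")),
                     row.names = FALSE, quote = FALSE)
    cdir <- file.path(out_dir, paste0("counts_", s))
    dir.create(cdir, showWarnings = FALSE)
    m <- counts[[s]]
    if (is.null(m)) stop("no counts for sample ", s, call. = FALSE)
    Matrix::writeMM(m, file.path(cdir, "matrix.mtx"))
    writeLines(paste(rownames(m), rownames(m), "Gene Expression", sep = "\t"),
               file.path(cdir, "features.tsv"))
    writeLines(colnames(m), file.path(cdir, "barcodes.tsv"))
  }
  labels <- data.frame(barcode = spots$barcode, sample = spots$sample_id,
                       group = spots$group, ift = spots$tissue_class)
  utils::write.csv(labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(generator = "spotzoner", hd = hd, bin_um = as.integer(bin_um))
  if (!is.null(spec)) manifest$spec <- unclass(spec)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
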