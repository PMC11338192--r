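# Shared fixtures and independent oracles, built in code at test time.

# Fully occupied rectangular spot table; tissue_class from a predicate on
# (row, col), default all tumor.
full_spot_table <- function(n_rows, n_cols, tumor_when = function(r, c) TRUE,
                            sample_id = "s1", group = "Ctrl",
                            row0 = 1L, col0 = 1L) {
  pos <- expand.grid(array_row = row0:(row0 + n_rows - 1L),
                     array_col = col0:(col0 + n_cols - 1L))
  data.frame(barcode = sprintf("BC%03d_%03d", pos$array_row, pos$array_col),
             array_row = pos$array_row,
             array_col = pos$array_col,
             sample_id = sample_id,
             group = group,
             tissue_class = as.integer(tumor_when(pos$array_row, pos$array_col)),
             in_tissue = 1L,
             stringsAsFactors = FALSE)
}

# Straight vertical boundary: tumor occupies the first `tumor_cols` columns.
boundary_spot_table <- function(n = 40L, tumor_cols = 20L, ...) {
  full_spot_table(n, n, tumor_when = function(r, c) c <= tumor_cols, ...)
}

# Literal double-loop moving-average oracle (ignores NA; all-NA window -> NA).
ma_brute <- function(v, delta) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- v[max(1, i - delta):min(nr, i + delta),
                max(1, j - delta):min(nc, j + delta)]
      vals <- vals[!is.na(vals)]
      if (length(vals)) out[i, j] <- mean(vals)
    }
  }
  out
}

# Random lattice with missing cells, values in {0,1} or uniform.
random_grid <- function(nr, nc, p_missing = 0.3, binary = TRUE) {
  v <- if (binary) sample(0:1, nr * nc, replace = TRUE)
       else stats::runif(nr * nc)
  v[stats::runif(nr * nc) < p_missing] <- NA
  matrix(as.numeric(v), nr, nc)
}

# Script-style sequential in-place threshold overwrites (the oracle for the
# interval-based zone assignment).
sequential_zone_oracle <- function(ts, ps, params = zonation_params()) {
  M <- params$tumor_cuts; L <- params$parenchyma_cuts
  m <- ts
  m[!is.na(ts) & ts > M[1]] <- -4
  m[!is.na(ts) & ts <= M[1] & ts > M[2]] <- -3
  m[!is.na(ts) & ts <= M[2] & ts > M[3]] <- -2
  m[!is.na(ts) & ts <= M[3] & ts > 0] <- -1
  l <- ps
  l[!is.na(ps) & ps <= L[3] & ps > 0] <- 0
  l[!is.na(ps) & ps <= L[2] & ps > L[3]] <- 1
  l[!is.na(ps) & ps <= L[1] & ps > L[2]] <- 2
  l[!is.na(ps) & ps > L[1]] <- 3
  comb <- m + l
  out <- matrix(NA_character_, nrow(ts), ncol(ts))
  for (k in -4:3) out[!is.na(comb) & comb == k] <- params$zone_names[k + 5L]
  out
}

# Zone ordinal 1..8 (Zone_A = 1) for monotonicity checks.
zone_ordinal <- function(zone, params = zonation_params()) {
  match(zone, params$zone_names)
}

# Tiny deterministic counts fixture: genes x spots dense matrix.
toy_counts <- function() {
  m <- matrix(c(10, 90, 0,
                5, 45, 50,
                0, 80, 20,
                1, 9, 0), nrow = 4, byrow = TRUE,
              dimnames = list(c("mt-Co1", "Alb", "Epcam", "Hbb-bs"),
                              c("sp1", "sp2", "sp3")))
  Matrix::Matrix(m, sparse = TRUE)
}

# Small simulation spec for fast end-to-end runs.
small_spec <- function(...) {
  simulation_spec(n_rows = 16L, n_cols = 24L, layout = "full",
                  region = list(type = "half_plane", axis = "col", cut = 11),
                  samples = c(sampleA = "Ctrl", sampleB = "parRes"),
                  n_background = 40L, seed = 42L, ...)
}

# Small dense expression fixture with planted structure: 2 groups x 2 zones.
profile_fixture <- function(n_per_cell = 6, seed = 99) {
  withr::with_seed(seed, {
    cells <- expand.grid(group = c("Ctrl", "parRes"),
                         zone = c("Zone_B", "Zone_F"),
                         stringsAsFactors = FALSE)
    spots <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ]
    spots$barcode <- sprintf("sp%02d", seq_len(nrow(spots)))
    spots$sample_id <- "s1"
    genes <- c("Epcam", "Alb", "Flat", sprintf("g%02d", 1:20))
    counts <- matrix(stats::rpois(length(genes) * nrow(spots), 20),
                     nrow = length(genes),
                     dimnames = list(genes, spots$barcode))
    counts["Epcam", spots$zone == "Zone_B"] <- 200   # tumor-side marker
    counts["Alb", spots$zone == "Zone_F"] <- 200     # parenchyma-side marker
    counts["Flat", ] <- 30
    norm <- log_normalize(Matrix::Matrix(counts, sparse = TRUE))
    list(spots = spots, norm = norm)
  })
}
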