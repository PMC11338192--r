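# Downstream statistics on zoned spots: signature-based tissue labeling,
# module scores, one-vs-rest rank-sum differential expression, and per-zone
# median summaries.

#' Label spots as tumor or parenchyma from marker signatures
#'
#' Assigns `tissue_class = 1` to spots whose mean log-normalized expression of
#' the tumor signature exceeds that of the parenchyma signature, and 0
#' otherwise; exact ties go to 0 with a warning. This automates the manual
#' cluster annotation step when per-spot labels are not supplied.
#'
#' @param norm log-normalized genes-by-spots matrix.
#' @param tumor_sig,parenchyma_sig character vectors of gene symbols; each
#'   must intersect the measured gene universe.
#' @return integer vector of 0/1 labels, named by barcode.
#' @export
label_spots_by_signature <- function(norm,
                                     tumor_sig = c("Epcam", "Cdh1", "Cldn7", "Actb",
                                                   "S100a6", "Tmsb10", "Timp1", "Bgn",
                                                   "Col3a1", "Saa3", "Spp1"),
                                     parenchyma_sig = c("Alb", "Fabp1", "Apob", "Car3")) {
  ts <- intersect(tumor_sig, rownames(norm))
  ps <- intersect(parenchyma_sig, rownames(norm))
  if (length(ts) == 0L) stop("tumor signature has no genes in the matrix", call. = FALSE)
  if (length(ps) == 0L) stop("parenchyma signature has no genes in the matrix", call. = FALSE)
  mt <- Matrix::colMeans(norm[ts, , drop = FALSE])
  mp <- Matrix::colMeans(norm[ps, , drop = FALSE])
  if (any(mt == mp)) {
    warning(sum(mt == mp), " spot(s) tie between signatures; labeled parenchyma (0)")
  }
  out <- as.integer(mt > mp)
  names(out) <- colnames(norm)
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Gene-signature module score
#'
#' Per-spot signature score computed as the mean expression of the signature
#' genes minus the mean expression of expression-matched control genes: all
#' genes are ranked by average expression across spots and split into `nbin`
#' equal-frequency bins; each signature gene contributes `nctrl` control genes
#' drawn from its own bin (with replacement when the bin is smaller than
#' `nctrl`). The draw is governed entirely by `seed`.
#'
#' @param norm log-normalized genes-by-spots matrix.
#' @param genes signature gene symbols.
#' @param nbin number of expression bins (default 24).
#' @param nctrl control genes drawn per signature gene (default 100).
#' @param seed integer seed for the control draw (required).
#' @return numeric score per spot, named by barcode.
#' @export
module_score <- function(norm, genes, nbin = 24L, nctrl = 100L, seed) {
  if (missing(seed)) stop("module_score requires an explicit seed", call. = FALSE)
  genes <- intersect(genes, rownames(norm))
  if (length(genes) == 0L) stop("signature has no genes in the matrix", call. = FALSE)
  n_genes <- nrow(norm)
  if (nbin < 1L || nbin > n_genes) {
    stop("nbin must be between 1 and the number of genes", call. = FALSE)
  }
  avg <- Matrix::rowMeans(norm)
  # equal-frequency bins; ties and the control draw are resolved in
  # gene-name order so the score is invariant to matrix row order
  ord <- order(avg, rownames(norm))
  rk <- integer(n_genes)
  rk[ord] <- seq_len(n_genes)
  bin <- cut(rk, breaks = nbin, labels = FALSE)
  names(bin) <- rownames(norm)
  ctrl <- with_seed(seed, {
    unlist(lapply(genes, function(g) {
      pool <- sort(names(bin)[bin == bin[[g]]])
      sample(pool, size = nctrl, replace = length(pool) < nctrl)
    }), use.names = FALSE)
  })
  sig_mean <- Matrix::colMeans(norm[genes, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[match(ctrl, rownames(norm)), , drop = FALSE])
  out <- as.numeric(sig_mean - ctrl_mean)
  names(out) <- colnames(norm)
  out
}

#' Combined treatment-group / zone label
#'
#' Concatenates group and zone as `<group>_<zone>` (e.g. `parRes_Zone_B`),
#' the unit at which one-vs-rest differential expression is run. Splitting the
#' label on the first underscore recovers the two keys.
#'
#' @param spots spot table with `group` and `zone` columns.
#' @return character vector of labels.
#' @export
zone_group_key <- function(spots) {
  stopifnot(all(c("group", "zone") %in% names(spots)))
  if (anyNA(spots$zone)) stop("spots without a zone assignment", call. = FALSE)
  paste(spots$group, spots$zone, sep = "_")
}

split_zone_group_key <- function(key) {
  group <- sub("_.*$", "", key)
  zone <- sub("^[^_]*_", "", key)
  data.frame(group = group, zone = zone, stringsAsFactors = FALSE)
}

# Exact two-sided rank-sum p-value by enumeration of all assignments of the
# observed (possibly tied) ranks to the in-group; p = 2 * min(P(W <= w),
# P(W >= w)) capped at 1.
exact_ranksum_p <- function(ranks, in_group) {
  m <- sum(in_group)
  w_obs <- sum(ranks[in_group])
  combos <- utils::combn(length(ranks), m)
  w_all <- colSums(matrix(ranks[combos], nrow = m))
  tol <- 1e-9
  p <- 2 * min(mean(w_all <= w_obs + tol), mean(w_all >= w_obs - tol))
  min(p, 1)
}

# Tie-corrected normal-approximation two-sided rank-sum p-value.
approx_ranksum_p <- function(ranks, in_group) {
  n_tot <- length(ranks)
  m <- sum(in_group)
  n <- n_tot - m
  w <- sum(ranks[in_group])
  mu <- m * (n_tot + 1) / 2
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- m * n / 12 * ((n_tot + 1) - tie_term / (n_tot * (n_tot - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

ranksum_p <- function(ranks, in_group, exact_max = 8L) {
  m <- sum(in_group)
  n <- length(ranks) - m
  if (m == 0L || n == 0L) stop("both groups need at least one spot", call. = FALSE)
  if (m <= exact_max && n <= exact_max) exact_ranksum_p(ranks, in_group)
  else approx_ranksum_p(ranks, in_group)
}

#' One-vs-rest Wilcoxon differential expression
#'
#' For every label and every gene, tests the spots carrying the label against
#' all remaining spots with a two-sided Wilcoxon rank-sum test (midranks with
#' tie-corrected normal approximation; exact enumeration when both sides have
#' at most 8 spots). Fold changes follow the log-normalized convention
#' `avg_log2FC = log2((mean(expm1(x)) + 1) / (mean(expm1(y)) + 1))`, and
#' `pct_in`/`pct_out` are the percentages of spots with nonzero expression.
#' p-values are Benjamini-Hochberg adjusted within each label.
#'
#' @param norm log-normalized genes-by-spots matrix.
#' @param labels character vector of per-spot labels (e.g. from
#'   [zone_group_key()]), aligned with the columns of `norm`.
#' @return data frame with columns `gene`, `label`, `avg_log2FC`, `p_value`,
#'   `p_adjusted`, `pct_in`, `pct_out`.
#' @export
wilcoxon_one_vs_rest <- function(norm, labels) {
  if (length(labels) != ncol(norm)) {
    stop("labels must align with the columns of the matrix", call. = FALSE)
  }
  labs <- sort(unique(labels))
  dense <- as.matrix(norm)
  n_genes <- nrow(dense)
  ranks <- t(apply(dense, 1L, rank))  # midranks, per gene across all spots

  out <- vector("list", length(labs))
  for (k in seq_along(labs)) {
    in_group <- labels == labs[[k]]
    if (!any(in_group)) stop("label with zero spots: ", labs[[k]], call. = FALSE)
    x <- dense[, in_group, drop = FALSE]
    y <- dense[, !in_group, drop = FALSE]
    p <- vapply(seq_len(n_genes), function(g) ranksum_p(ranks[g, ], in_group), 0)
    lfc <- log2((rowMeans(expm1(x)) + 1) / (rowMeans(expm1(y)) + 1))
    out[[k]] <- data.frame(
      gene = rownames(dense),
      label = labs[[k]],
      avg_log2FC = as.numeric(lfc),
      p_value = p,
      p_adjusted = stats::p.adjust(p, method = "BH"),
      pct_in = 100 * rowMeans(x > 0),
      pct_out = 100 * rowMeans(y > 0),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a differential-expression table
#'
#' Tab-separated layout with the conventional column names
#' `p_val, avg_log2FC, pct.1, pct.2, p_val_adj, GeneID, Cluster`
#' (percentages as fractions in `pct.1`/`pct.2`).
#'
#' @param de result of [wilcoxon_one_vs_rest()].
#' @param path output file.
#' @export
write_de_table <- function(de, path) {
  out <- data.frame(p_val = de$p_value,
                    avg_log2FC = de$avg_log2FC,
                    pct.1 = round(de$pct_in / 100, 3),
                    pct.2 = round(de$pct_out / 100, 3),
                    p_val_adj = de$p_adjusted,
                    GeneID = de$gene,
                    Cluster = de$label,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Per-zone fold-change summary for selected genes
#'
#' Converts `avg_log2FC` to linear fold change (`FC = 2^avg_log2FC`),
#' summarizes the median FC per gene and zone-group label, attaches each
#' gene's minimum across the table, and splits the label back into group and
#' zone columns.
#'
#' @param de result of [wilcoxon_one_vs_rest()].
#' @param genes genes of interest; absent genes are dropped with a warning.
#' @return data frame with columns `name`, `zone`, `group`, `median`,
#'   `minimum`.
#' @export
gene_fc_summary <- function(de, genes) {
  present <- genes %in% de$gene
  if (!all(present)) {
    warning("genes absent from the DE table, omitted: ",
            paste(genes[!present], collapse = ", "))
  }
  genes <- genes[present]
  if (length(genes) == 0L) stop("no requested genes in the DE table", call. = FALSE)
  sub <- de[de$gene %in% genes, , drop = FALSE]
  sub$fc <- 2^sub$avg_log2FC
  agg <- stats::aggregate(fc ~ gene + label, data = sub, FUN = stats::median)
  mins <- stats::aggregate(fc ~ gene, data = agg, FUN = min)
  names(mins)[2L] <- "minimum"
  agg <- merge(agg, mins, by = "gene")
  keys <- split_zone_group_key(agg$label)
  out <- data.frame(name = agg$gene, zone = keys$zone, group = keys$group,
                    median = agg$fc, minimum = agg$minimum,
                    stringsAsFactors = FALSE)
  out <- out[order(out$name, out$zone, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-zone median module-score summary
#'
#' Median module score per (signature, zone, group) cell, with each
#' signature's minimum across all cells attached. Empty cells are omitted.
#'
#' @param scores data frame or matrix of per-spot scores, one column per
#'   signature, rows aligned with `spots`.
#' @param spots spot table with `zone` and `group` columns.
#' @return data frame with columns `name`, `zone`, `group`, `median`,
#'   `minimum`.
#' @export
signature_median_summary <- function(scores, spots) {
  scores <- as.data.frame(scores)
  stopifnot(nrow(scores) == nrow(spots),
            all(c("zone", "group") %in% names(spots)))
  long <- do.call(rbind, lapply(names(scores), function(nm) {
    data.frame(name = nm, zone = spots$zone, group = spots$group,
               value = scores[[nm]], stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(value ~ name + zone + group, data = long,
                          FUN = stats::median)
  mins <- stats::aggregate(value ~ name, data = agg, FUN = min)
  names(mins)[2L] <- "minimum"
  agg <- merge(agg, mins, by = "name")
  out <- data.frame(name = agg$name, zone = agg$zone, group = agg$group,
                    median = agg$value, minimum = agg$minimum,
                    stringsAsFactors = FALSE)
  out <- out[order(out$name, out$zone, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
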