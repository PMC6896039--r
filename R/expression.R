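# Expression-matrix processing (RPKM, heatmap normalisation, hierarchical
# clustering), the two-fold cold-response candidate filter, and 2^-ddCt
# relative quantification of qPCR Ct tables.

#' RPKM from raw counts
#'
#' RPKM = count x 1e9 / (gene length x column total): reads per kilobase
#' of transcript per million mapped reads.
#'
#' @param counts Non-negative count matrix (genes x samples) with gene
#'   rownames.
#' @param lengths Named numeric vector of transcript lengths in bp.
#' @return An RPKM matrix of the same shape.
#' @export
compute_rpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0L) {
    stop("missing gene length(s): ", paste(missing, collapse = ", "))
  }
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("zero column total: cannot compute RPKM")
  sweep(sweep(counts, 2L, totals, `/`), 1L, len, `/`) * 1e9
}

#' Heatmap normalisation of RPKM values
#'
#' Applies `log10(scale x RPKM + 1)` (default scale 25): RPKM expanded 25
#' times, then log10-transformed with a unit pseudocount so absent genes
#' (RPKM 0) map exactly to 0.
#'
#' @param rpkm Non-negative RPKM matrix (or vector).
#' @param scale Expansion factor (default 25).
#' @param pseudocount Added inside the log (default 1; set to 0 with a
#'   `floor` to reproduce a pure `log10(25x)` transform).
#' @param floor Value assigned where `scale * rpkm + pseudocount <= 0`.
#' @return Transformed values, same shape.
#' @export
heat_normalize <- function(rpkm, scale = 25, pseudocount = 1, floor = 0) {
  if (any(rpkm < 0)) stop("negative expression value")
  x <- scale * rpkm + pseudocount
  out <- ifelse(x > 0, log10(x), floor)
  out
}

#' Two-fold up/down candidate filter
#'
#' Fold change is computed as `(after + p) / (before + p)` with
#' pseudocount `p` (default 1) on RPKM values. Genes with FC >= threshold
#' are up candidates; genes with FC <= 1/threshold are down candidates.
#'
#' @param before,after Matched named vectors of expression (e.g. RPKM
#'   before/after freezing).
#' @param threshold Fold-change threshold (default 2).
#' @param pseudocount Added to both sides (default 1).
#' @return A list with `up`, `down` (character vectors of gene names) and
#'   `fold_change` (named vector).
#' @export
fold_change_candidates <- function(before, after, threshold = 2,
                                   pseudocount = 1) {
  stopifnot(length(before) == length(after))
  if (is.null(names(before))) names(before) <- paste0("g", seq_along(before))
  fc <- (after + pseudocount) / (before + pseudocount)
  names(fc) <- names(before)
  list(up = names(fc)[fc >= threshold],
       down = names(fc)[fc <= 1 / threshold],
       fold_change = fc)
}

#' Hierarchically cluster genes by expression profile
#'
#' Agglomerative clustering (Euclidean distance, average linkage) cut to
#' `k` clusters; deterministic given the input order.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param k Number of clusters (default 6).
#' @return Named integer vector: gene -> cluster label.
#' @export
hcluster_genes <- function(matrix, k = 6L) {
  matrix <- as.matrix(matrix)
  if (k > nrow(matrix)) stop("k exceeds the number of genes")
  hc <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = "average")
  stats::cutree(hc, k = k)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per gene and sample, dCt = mean Ct(gene) - mean Ct(reference); ddCt =
#' dCt(sample) - dCt(calibrator); RQ = 2^-ddCt. Replicate standard
#' deviations are propagated into the dCt
#' (`sd = sqrt(sd_gene^2 + sd_ref^2)`) and reported as an RQ range.
#'
#' @param ct Data.frame with columns `gene`, `sample`, `replicate`, `ct`.
#' @param reference_gene Name of the internal control gene (e.g. `Actin`).
#' @param calibrator_sample Name of the calibrator sample (e.g. the 0 h
#'   time point).
#' @return A data.frame with `gene`, `sample`, `dct`, `ddct`, `rq`,
#'   `rq_low`, `rq_high` (RQ at ddct +/- 1 sd).
#' @export
relative_expression <- function(ct, reference_gene, calibrator_sample) {
  required <- c("gene", "sample", "replicate", "ct")
  stopifnot(all(required %in% names(ct)))
  samples <- unique(ct$sample)
  if (!calibrator_sample %in% samples) {
    stop("calibrator sample '", calibrator_sample, "' not in table")
  }
  for (s in samples) {
    if (!any(ct$gene == reference_gene & ct$sample == s)) {
      stop("reference gene '", reference_gene, "' missing in sample '",
           s, "'")
    }
  }
  agg_mean <- stats::aggregate(ct ~ gene + sample, data = ct, FUN = mean)
  agg_sd <- stats::aggregate(ct ~ gene + sample, data = ct,
                             FUN = function(x) {
                               if (length(x) > 1L) stats::sd(x) else 0
                             })
  key <- function(g, s) paste(g, s, sep = "\r")
  mean_ct <- stats::setNames(agg_mean$ct, key(agg_mean$gene, agg_mean$sample))
  sd_ct <- stats::setNames(agg_sd$ct, key(agg_sd$gene, agg_sd$sample))
  genes <- setdiff(unique(ct$gene), reference_gene)
  rows <- list()
  for (g in genes) {
    dct <- mean_ct[key(g, samples)] - mean_ct[key(reference_gene, samples)]
    sdv <- sqrt(sd_ct[key(g, samples)]^2 + sd_ct[key(reference_gene, samples)]^2)
    ddct <- dct - dct[[which(samples == calibrator_sample)]]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, sample = samples,
      dct = unname(dct), ddct = unname(ddct),
      rq = 2^(-unname(ddct)),
      rq_low = 2^(-(unname(ddct) + unname(sdv))),
      rq_high = 2^(-(unname(ddct) - unname(sdv))),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
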