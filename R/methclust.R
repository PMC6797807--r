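#' Construct a probes-by-samples beta-value matrix
#'
#' Container for methylation array beta-values (fraction methylated, in
#' `[0, 1]`) with probe genomic coordinates, sorted by position within each
#' chromosome.
#'
#' @param beta Numeric matrix, probes x samples, values in `[0, 1]`, with
#'   rownames (probe ids) and colnames (sample ids).
#' @param chrom,pos Probe coordinates, one per row of `beta` (1-based).
#' @return A `beta_matrix`: list with `beta`, `probes` (data frame
#'   `probe_id, chrom, pos`) and `sample_ids`. Probes are reordered to be
#'   coordinate-sorted within chromosome.
#' @export
beta_matrix <- function(beta, chrom, pos) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)),
            length(chrom) == nrow(beta), length(pos) == nrow(beta))
  if (anyNA(beta)) stop2("beta values must be complete (impute before loading)")
  if (any(beta < 0 | beta > 1)) stop2("beta values must lie in [0, 1]")
  ord <- order(as.character(chrom), as.integer(pos))
  beta <- beta[ord, , drop = FALSE]
  probes <- data.frame(probe_id = rownames(beta),
                       chrom = as.character(chrom)[ord],
                       pos = as.integer(pos)[ord])
  if (anyDuplicated(probes[c("chrom", "pos")]))
    stop2("probe coordinates must be strictly increasing within chromosome")
  structure(list(beta = beta, probes = probes, sample_ids = colnames(beta)),
            class = "beta_matrix")
}

#' Read a beta matrix TSV (probe_id, chrom, pos, then one column per sample)
#'
#' @param path TSV path.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop2("beta TSV must start with columns probe_id, chrom, pos")
  m <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  rownames(m) <- df$probe_id
  beta_matrix(m, df$chrom, df$pos)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("Beta-value matrix:", nrow(x$beta), "probes x", ncol(x$beta),
      "samples on", length(unique(x$probes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Select the most variably methylated probes
#'
#' Ranks probes by their standard deviation across samples (denominator
#' n - 1) and keeps the top `n` — the standard device for letting a
#' methylation heatmap or clustering see the loci that differ between
#' tumors. Ties at the cutoff are broken by probe id order.
#'
#' @param bm A [beta_matrix()].
#' @param n Number of probes to keep (default 500).
#' @return A `beta_matrix` restricted to the selected probes (original
#'   coordinate order preserved).
#' @export
select_variable_probes <- function(bm, n = 500) {
  stopifnot(inherits(bm, "beta_matrix"))
  if (n > nrow(bm$beta))
    stop2("n (", n, ") exceeds the number of probes (", nrow(bm$beta), ")")
  sds <- apply(bm$beta, 1, sd)
  ord <- order(-sds, bm$probes$probe_id)
  keep <- sort(ord[seq_len(n)])
  beta_matrix(bm$beta[keep, , drop = FALSE],
              bm$probes$chrom[keep], bm$probes$pos[keep])
}

#' Hierarchically cluster samples on their methylation profiles
#'
#' Builds the Euclidean distance matrix between samples over the (usually
#' pre-selected) probes and applies agglomerative clustering with complete
#' linkage; cluster labels come from cutting the tree into `k` groups.
#'
#' @param bm A [beta_matrix()], typically from [select_variable_probes()].
#' @param k Number of clusters (default 2).
#' @return List with `labels` (named integer vector per sample, values in
#'   `1:k`) and `tree` (the `hclust` object).
#' @export
cluster_samples <- function(bm, k = 2) {
  stopifnot(inherits(bm, "beta_matrix"))
  if (k > ncol(bm$beta))
    stop2("k (", k, ") exceeds the number of samples (", ncol(bm$beta), ")")
  tree <- hclust(dist(t(bm$beta), method = "euclidean"), method = "complete")
  list(labels = cutree(tree, k = k), tree = tree)
}

#' Per-probe Welch tests between two sample groups
#'
#' Runs a two-sample Welch t-test on every probe's beta-values between the
#' designated group and the rest, reporting the unadjusted p-value and the
#' beta difference (designated group mean minus other group mean, so
#' negative values mean hypomethylation in the designated group). Probes
#' with zero variance in both groups are reported with `p = 1` and a
#' `zero_variance` flag instead of failing, so array-wide scans never
#' abort. A Benjamini-Hochberg adjusted column is added when
#' `adjust = TRUE` (off by default; the region caller uses raw p-values).
#'
#' @param bm A [beta_matrix()].
#' @param labels Named vector assigning each sample of `bm` to a group.
#' @param group1 The designated group's label value (e.g. the
#'   mutant-genotype cluster); all other labels form group 2.
#' @param adjust Add a `p_adj` Benjamini-Hochberg column (default FALSE).
#' @return Data frame: `probe_id, chrom, pos, delta_beta, t, p,
#'   zero_variance` (and `p_adj` when requested).
#' @export
test_probes <- function(bm, labels, group1, adjust = FALSE) {
  stopifnot(inherits(bm, "beta_matrix"))
  if (is.null(names(labels))) {
    if (length(labels) != ncol(bm$beta))
      stop2("labels must cover every sample")
    names(labels) <- bm$sample_ids
  }
  if (!all(bm$sample_ids %in% names(labels)))
    stop2("unlabeled samples: ",
          paste(setdiff(bm$sample_ids, names(labels)), collapse = ", "))
  g1 <- bm$sample_ids[labels[bm$sample_ids] == group1]
  g2 <- setdiff(bm$sample_ids, g1)
  if (length(g1) < 2 || length(g2) < 2)
    stop2("both groups need at least 2 samples (got ", length(g1), " and ",
          length(g2), ")")
  x1 <- bm$beta[, g1, drop = FALSE]
  x2 <- bm$beta[, g2, drop = FALSE]
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  zv <- se2 == 0
  p[zv] <- 1; tstat[zv] <- 0
  out <- data.frame(probe_id = bm$probes$probe_id, chrom = bm$probes$chrom,
                    pos = bm$probes$pos, delta_beta = m1 - m2, t = tstat,
                    p = p, zero_variance = zv, row.names = NULL)
  if (adjust) out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Call contiguous differentially methylated regions
#'
#' A probe is significant when its Welch p-value is below `p_threshold` and
#' its beta difference is at least `delta_min` in magnitude. Maximal runs
#' of consecutive significant probes on one chromosome sharing the sign of
#' the difference, with inter-probe gaps of at most `max_gap` bases and at
#' least `min_probes` probes, are reported as DMRs. Direction is `hypo`
#' when the designated group is the less methylated (negative
#' `delta_beta`).
#'
#' @inheritParams test_probes
#' @param p_threshold Probe significance cutoff on the raw p-value
#'   (default 0.05).
#' @param delta_min Minimum absolute beta difference (default 0.2).
#' @param min_probes Minimum probes per region (default 3).
#' @param max_gap Maximum distance in bases between consecutive probes of
#'   one region (default 1000).
#' @return Data frame of regions: `chrom, start, end` (positions of the
#'   first and last probe, 1-based inclusive), `probe_count, direction,
#'   mean_delta_beta, min_p`. Zero rows when nothing is significant.
#' @examples
#' sim <- simulate_methylation(n_probes = 2000, n_dmrs = 3, seed = 1)
#' dmrs <- find_dmrs(sim$beta, sim$labels, group1 = "mutant")
#' nrow(dmrs)
#' @export
find_dmrs <- function(bm, labels, group1, p_threshold = 0.05,
                      delta_min = 0.2, min_probes = 3, max_gap = 1000,
                      adjust = FALSE) {
  tests <- test_probes(bm, labels, group1, adjust = adjust)
  pcol <- if (adjust) tests$p_adj else tests$p
  sig <- pcol < p_threshold & abs(tests$delta_beta) >= delta_min
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), probe_count = integer(),
                      direction = character(), mean_delta_beta = numeric(),
                      min_p = numeric())
  if (!any(sig)) return(empty)
  out <- list()
  for (ch in unique(tests$chrom)) {
    ti <- tests[tests$chrom == ch, , drop = FALSE]
    si <- sig[tests$chrom == ch]
    # break runs at non-significant probes, sign changes, or large gaps
    run_break <- !si |
      c(TRUE, diff(sign(ti$delta_beta)) != 0) |
      c(TRUE, diff(ti$pos) > max_gap)
    run_id <- cumsum(run_break)
    run_id[!si] <- NA
    for (r in unique(run_id[!is.na(run_id)])) {
      rows <- ti[which(run_id == r), , drop = FALSE]
      if (nrow(rows) < min_probes) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = rows$pos[1], end = rows$pos[nrow(rows)],
        probe_count = nrow(rows),
        direction = if (rows$delta_beta[1] < 0) "hypo" else "hyper",
        mean_delta_beta = mean(rows$delta_beta),
        min_p = min(rows$p))
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Write DMRs as a BED file
#'
#' BED uses 0-based, end-exclusive coordinates, so `start - 1` and `end`
#' delimit the region spanned by its first and last probe.
#'
#' @param dmrs Data frame from [find_dmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                    end = dmrs$end,
                    name = sprintf("dmr_%d", seq_len(nrow(dmrs))),
                    probe_count = dmrs$probe_count,
                    direction = dmrs$direction)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @importFrom stats p.adjust
NULL
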