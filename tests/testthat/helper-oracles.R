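# Independent oracles and small fixture builders used across the suite.

# Exhaustive 2-signature NNLS oracle: minimizes ||c - e1 s1 - e2 s2||_2 over
# the integer grid e1, e2 in 0..emax (step 1 mutation), via the quadratic
# expansion so the full grid stays cheap.
grid_nnls_oracle <- function(counts, s1, s2, emax = NULL) {
  if (is.null(emax)) emax <- ceiling(1.5 * sum(counts))
  e <- 0:emax
  g11 <- sum(s1 * s1); g22 <- sum(s2 * s2); g12 <- sum(s1 * s2)
  b1 <- sum(s1 * counts); b2 <- sum(s2 * counts)
  # rss(e1,e2) = ||c||^2 - 2(e1 b1 + e2 b2) + e1^2 g11 + 2 e1 e2 g12 + e2^2 g22
  rss <- outer(e^2 * g11 - 2 * e * b1, e^2 * g22 - 2 * e * b2, `+`) +
    2 * g12 * outer(e, e)
  ij <- arrayInd(which.min(rss), dim(rss))
  list(e1 = e[ij[1]], e2 = e[ij[2]],
       rss = min(rss) + sum(counts^2))
}

# Brute-force per-probe standard deviations (the sd-sort oracle).
sd_sort_oracle <- function(beta, n) {
  sds <- apply(beta, 1, stats::sd)
  names(sort(sds, decreasing = TRUE))[seq_len(n)]
}

# Set-intersection trunk oracle.
trunk_oracle <- function(key_sets) Reduce(intersect, key_sets)

# Adjusted Rand index between two label vectors.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  if (max(si, sj) == exp_idx) return(1)
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Write a toy FASTA file and return its path.
toy_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

test_sigs <- function() ccs_signatures()
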