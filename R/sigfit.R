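#' Cosine similarity between two 96-channel profiles
#'
#' Scale-invariant similarity used to confirm the presence of a mutational
#' process when a sample's burden is dominated by one signature (e.g. an
#' ultraviolet-driven carcinoma against the UV signature).
#'
#' @param profile_a,profile_b Non-negative numeric vectors of equal length
#'   with positive norm (raw counts or probabilities; scale is irrelevant).
#' @return Similarity in `[0, 1]`.
#' @examples
#' sigs <- ccs_signatures()
#' cosine_similarity(sigs[, "Signature.7"], sigs[, "Signature.7"])
#' @export
cosine_similarity <- function(profile_a, profile_b) {
  a <- as.numeric(profile_a); b <- as.numeric(profile_b)
  stopifnot(length(a) == length(b))
  if (any(a < 0) || any(b < 0))
    stop2("profiles must be non-negative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop2("undefined similarity: zero-norm profile")
  sum(a * b) / (na * nb)
}

.check_catalog_signatures <- function(catalog, signatures) {
  stopifnot(inherits(catalog, "catalog96"))
  if (!inherits(signatures, "signature_matrix"))
    signatures <- as_signature_matrix(signatures)
  if (!identical(names(catalog), rownames(signatures)))
    stop2("catalog channel labels do not match the signature matrix")
  if (attr(catalog, "total") <= 0)
    stop2("empty catalog: cannot fit signatures to zero mutations")
  signatures
}

#' Fit signature exposures to a catalog by non-negative least squares
#'
#' Estimates, for one sample, the number of mutations attributable to each
#' reference signature: exposures `e >= 0` minimizing
#' `|| counts - P e ||_2` where `P` is the 96 x K signature matrix. The fit
#' is on raw counts, so exposures are mutation attributions, and is
#' deterministic (Lawson-Hanson NNLS).
#'
#' @param catalog A [build_catalog()] result with positive total.
#' @param signatures A `signature_matrix` (see [read_signatures()]).
#' @return An `exposure_fit`: list with `sample_id`, `exposures` (named, in
#'   mutations), `exposure_fractions` (exposures / catalog total),
#'   `reconstructed` (96-vector `P e`), `residual_norm` (L2 distance between
#'   counts and reconstruction), `catalog_total`.
#' @examples
#' sigs <- ccs_signatures()
#' cat7 <- simulate_catalog(c(Signature.7 = 1), 1000, sigs, seed = 1)$catalog
#' fit_exposures(cat7, sigs[, c("Signature.1", "Signature.7")])
#' @export
fit_exposures <- function(catalog, signatures) {
  signatures <- .check_catalog_signatures(catalog, signatures)
  counts <- as.numeric(catalog)
  sol <- pracma::lsqnonneg(unclass(signatures), counts)
  e <- setNames(sol$x, colnames(signatures))
  recon <- as.numeric(unclass(signatures) %*% e)
  structure(list(
    sample_id = attr(catalog, "sample_id"),
    exposures = e,
    exposure_fractions = e / attr(catalog, "total"),
    reconstructed = setNames(recon, names(catalog)),
    residual_norm = sqrt(sum((counts - recon)^2)),
    catalog_total = attr(catalog, "total")
  ), class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("Signature exposure fit for '", x$sample_id, "' (",
      x$catalog_total, " substitutions)\n", sep = "")
  nz <- x$exposures[x$exposures > 0.5]
  ord <- order(nz, decreasing = TRUE)
  for (i in ord)
    cat(sprintf("  %-14s %8.1f  (%.1f%%)\n", names(nz)[i], nz[i],
                100 * nz[i] / x$catalog_total))
  cat(sprintf("  residual L2 norm: %.2f\n", x$residual_norm))
  invisible(x)
}

#' @export
coef.exposure_fit <- function(object, ...) object$exposures

#' @export
fitted.exposure_fit <- function(object, ...) object$reconstructed

#' Bootstrap exceedance probabilities for signature exposures
#'
#' Quantifies confidence that each signature contributes at least a
#' `threshold` fraction of a sample's mutations. Each replicate resamples
#' the sample's mutations with replacement — equivalently, draws a
#' multinomial catalog of the same size from the observed channel
#' frequencies — and refits exposures; the exceedance probability of a
#' signature is the fraction of replicates in which its fitted exposure
#' fraction is at least `threshold`.
#'
#' @inheritParams fit_exposures
#' @param threshold Exposure fraction of interest (default 0.05: five
#'   percent of the sample's mutations).
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; identical seeds give identical results.
#' @return A `sig_bootstrap`: list with `sample_id`, `threshold`, `n_boot`,
#'   `seed`, `exceedance_prob` (named, per signature), `mean_fraction`
#'   (mean bootstrap exposure fraction, used for rank tie-breaks), and
#'   `fractions` (`n_boot` x K matrix of replicate exposure fractions).
#' @export
bootstrap_confidence <- function(catalog, signatures, threshold = 0.05,
                                 n_boot = 1000, seed = NULL) {
  signatures <- .check_catalog_signatures(catalog, signatures)
  if (n_boot < 1) stop2("n_boot must be >= 1")
  total <- attr(catalog, "total")
  if (total < 50)
    warning("catalog has fewer than 50 mutations; bootstrap confidence is unstable")
  p <- as.numeric(catalog) / total
  S <- unclass(signatures)
  frac <- with_seed(seed, {
    reps <- rmultinom(n_boot, total, p)
    t(apply(reps, 2, function(cts) pracma::lsqnonneg(S, as.numeric(cts))$x / total))
  })
  if (n_boot == 1L) frac <- matrix(frac, nrow = 1L)
  colnames(frac) <- colnames(signatures)
  structure(list(
    sample_id = attr(catalog, "sample_id"),
    threshold = threshold, n_boot = as.integer(n_boot), seed = seed,
    exceedance_prob = colMeans(frac >= threshold),
    mean_fraction = colMeans(frac),
    fractions = frac
  ), class = "sig_bootstrap")
}

#' @export
print.sig_bootstrap <- function(x, ...) {
  cat("Bootstrap signature confidence for '", x$sample_id, "' (",
      x$n_boot, " replicates, threshold ", x$threshold, ")\n", sep = "")
  p <- sort(x$exceedance_prob, decreasing = TRUE)
  show <- p[p > 0 | seq_along(p) <= 3]
  for (i in seq_along(show))
    cat(sprintf("  %-14s P(fraction >= %.2f) = %.3f\n",
                names(show)[i], x$threshold, show[i]))
  invisible(x)
}

.rank_signatures <- function(boot) {
  # exceedance desc, then mean bootstrap fraction desc, then id asc
  ids <- names(boot$exceedance_prob)
  ord <- order(-boot$exceedance_prob, -boot$mean_fraction, ids)
  ids[ord]
}

#' Fit mutational signatures with bootstrap selection
#'
#' The full per-sample fitting procedure: fit all candidate signatures to
#' the sample's 96-channel catalog, compute bootstrap exceedance
#' probabilities that each signature accounts for at least `threshold` of
#' the mutations, rank signatures by that confidence (ties broken by mean
#' bootstrap exposure fraction, then signature identifier), keep the top
#' `k`, and refit on the selected subset. With `select = FALSE` only the
#' full-set fit and bootstrap are returned.
#'
#' @inheritParams bootstrap_confidence
#' @param k Number of signatures to retain for the final fit (default 3).
#' @param select Logical; if `FALSE`, skip selection and refitting.
#' @return An object of class `sigfit` with components `full_fit`
#'   (`exposure_fit` on all K signatures), `bootstrap` (`sig_bootstrap`),
#'   `selected` (character, the retained signatures in rank order), `fit`
#'   (`exposure_fit` on the selected subset; the full fit when
#'   `select = FALSE`), plus `catalog`, `signatures` and the call. Methods:
#'   `print`, `summary`, `coef`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' sigs <- ccs_signatures()
#' cat1 <- simulate_catalog(c(Signature.1 = 0.6, Signature.5 = 0.4), 800,
#'                          sigs, seed = 42)$catalog
#' f <- fit_signatures(cat1, sigs, k = 3, n_boot = 100, seed = 7)
#' coef(f)
#' @export
fit_signatures <- function(catalog, signatures, k = 3, threshold = 0.05,
                           n_boot = 1000, seed = NULL, select = TRUE) {
  signatures <- .check_catalog_signatures(catalog, signatures)
  K <- ncol(signatures)
  if (select && (k < 1 || k > K))
    stop2("k must be between 1 and the number of signatures (", K, ")")
  full_fit <- fit_exposures(catalog, signatures)
  boot <- bootstrap_confidence(catalog, signatures, threshold = threshold,
                               n_boot = n_boot, seed = seed)
  if (select) {
    selected <- .rank_signatures(boot)[seq_len(k)]
    fit <- fit_exposures(catalog, signatures[, selected, drop = FALSE])
  } else {
    selected <- colnames(signatures)
    fit <- full_fit
  }
  structure(list(
    full_fit = full_fit, bootstrap = boot, selected = selected, fit = fit,
    catalog = catalog, signatures = signatures,
    threshold = threshold, k = if (select) k else K, seed = seed,
    call = match.call()
  ), class = "sigfit")
}

#' @export
print.sigfit <- function(x, ...) {
  cat("Mutational signature fit: sample '", attr(x$catalog, "sample_id"),
      "', ", attr(x$catalog, "total"), " substitutions\n", sep = "")
  cat("  selected (by bootstrap exceedance, threshold ", x$threshold, "): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  print(x$fit)
  invisible(x)
}

#' @export
summary.sigfit <- function(object, ...) {
  df <- data.frame(
    signature = names(object$full_fit$exposures),
    exposure_full = unname(object$full_fit$exposures),
    exceedance_prob = unname(object$bootstrap$exceedance_prob),
    mean_boot_fraction = unname(object$bootstrap$mean_fraction),
    selected = names(object$full_fit$exposures) %in% object$selected,
    exposure_final = NA_real_, fraction_final = NA_real_
  )
  i <- match(object$selected, df$signature)
  df$exposure_final[i] <- unname(object$fit$exposures[object$selected])
  df$fraction_final[i] <- unname(object$fit$exposure_fractions[object$selected])
  df <- df[order(-df$exceedance_prob, -df$mean_boot_fraction, df$signature), ]
  rownames(df) <- NULL
  structure(list(table = df, sample_id = object$fit$sample_id,
                 residual_norm = object$fit$residual_norm,
                 cosine = cosine_similarity(as.numeric(object$catalog),
                                            object$fit$reconstructed)),
            class = "summary.sigfit")
}

#' @export
print.summary.sigfit <- function(x, ...) {
  cat("Sample '", x$sample_id, "': final-fit residual ",
      sprintf("%.2f", x$residual_norm), ", cosine(catalog, reconstruction) ",
      sprintf("%.4f", x$cosine), "\n", sep = "")
  print(head(x$table, 10), digits = 3)
  invisible(x)
}

#' @export
coef.sigfit <- function(object, ...) object$fit$exposures

#' @export
fitted.sigfit <- function(object, ...) object$fit$reconstructed

#' @export
residuals.sigfit <- function(object, ...) {
  as.numeric(object$catalog) - object$fit$reconstructed
}

#' @export
plot.sigfit <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(par(op))
  cls <- rep(c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"), each = 16)
  cols <- c(`C>A` = "#03BCEE", `C>G` = "#010101", `C>T` = "#E32926",
            `T>A` = "#CAC9C9", `T>C` = "#A1CE63", `T>G` = "#EBC6C4")[cls]
  barplot(as.numeric(x$catalog), col = cols, border = NA,
          main = paste0("Observed catalog (", attr(x$catalog, "total"), ")"),
          ylab = "mutations", ...)
  barplot(x$fit$reconstructed, col = cols, border = NA,
          main = paste("Reconstruction:", paste(x$selected, collapse = " + ")),
          ylab = "mutations", ...)
  invisible(x)
}

#' @importFrom stats simulate
#' @export
simulate.sigfit <- function(object, nsim = 1, seed = NULL, ...) {
  # multinomial catalogs drawn from the fitted reconstruction
  p <- object$fit$reconstructed
  p <- p / sum(p)
  total <- attr(object$catalog, "total")
  with_seed(seed, {
    reps <- rmultinom(nsim, total, p)
    lapply(seq_len(nsim), function(i) {
      structure(as.integer(reps[, i]), names = sbs_channels(),
                class = "catalog96",
                sample_id = paste0(object$fit$sample_id, "_sim", i),
                total = total, n_excluded = 0L)
    })
  })
}

#' @importFrom graphics barplot par
NULL
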