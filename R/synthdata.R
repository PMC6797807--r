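#' Simulate a 96-channel catalog from a signature mixture
#'
#' Draws `n_mutations` substitutions from the multinomial whose channel
#' probabilities are the exposure-weighted mixture of signature columns —
#' the generative model under which the exposure fit is consistent.
#'
#' @param exposure_fractions Named non-negative vector of signature
#'   fractions summing to 1 (names must be columns of `signatures`).
#' @param n_mutations Number of substitutions to draw (>= 1).
#' @param signatures A `signature_matrix`.
#' @param seed Integer seed; the same seed regenerates the same catalog.
#' @param sample_id Label for the catalog.
#' @return List with `catalog` (a `catalog96`) and `truth` (scenario,
#'   parameters and the planted exposure fractions).
#' @examples
#' sigs <- ccs_signatures()
#' sim <- simulate_catalog(c(Signature.7 = 1), 1287, sigs, seed = 7)
#' cosine_similarity(sim$catalog, sigs[, "Signature.7"])
#' @export
simulate_catalog <- function(exposure_fractions, n_mutations, signatures,
                             seed = NULL, sample_id = "sim") {
  stopifnot(inherits(signatures, "signature_matrix"))
  f <- exposure_fractions
  if (is.null(names(f)) || !all(names(f) %in% colnames(signatures)))
    stop2("exposure_fractions must be named by signatures present in the matrix")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop2("exposure fractions must be non-negative and sum to 1")
  if (n_mutations < 1) stop2("n_mutations must be >= 1")
  p <- as.numeric(unclass(signatures)[, names(f), drop = FALSE] %*% f)
  counts <- with_seed(seed, as.integer(rmultinom(1, n_mutations, p)))
  catalog <- structure(counts, names = sbs_channels(), class = "catalog96",
                       sample_id = sample_id, total = sum(counts),
                       n_excluded = 0L)
  list(catalog = catalog,
       truth = list(scenario = "catalog", seed = seed,
                    parameters = list(n_mutations = n_mutations),
                    planted = list(exposure_fractions = as.list(f))))
}

# draw (ref, alt, context5, context3) rows for channels sampled from a mixture
.draw_channel_records <- function(n, fractions, signatures) {
  p <- as.numeric(unclass(signatures)[, names(fractions), drop = FALSE] %*%
                    fractions)
  idx <- sample.int(96L, n, replace = TRUE, prob = p)
  lab <- sbs_channels()[idx]
  data.frame(ref = substr(lab, 3, 3), alt = substr(lab, 5, 5),
             context5 = substr(lab, 1, 1), context3 = substr(lab, 7, 7))
}

#' Simulate a multi-tumor patient with trunk and private mutations
#'
#' Emulates a patient whose tumors (e.g. several pulmonary cylindromas)
#' descend from one ancestral clone: a planted trunk mutation set carried
#' by every tumor plus per-tumor private sets, each drawn from its own
#' signature mixture. Genomic positions are sampled without replacement
#' from a toy genome (24 contigs of 10 Mb by default) so keys never
#' collide; trinucleotide contexts are drawn from the mixtures directly,
#' so the mutation tables feed [build_catalog()] without a reference
#' FASTA.
#'
#' @param n_samples Number of tumors (default 3).
#' @param trunk_n Size of the shared mutation set (default 1848).
#' @param private_ns Integer vector of private-set sizes, one per tumor.
#' @param trunk_exposures,private_exposures Named fraction vectors for the
#'   trunk and private signature mixtures (defaults: UV-dominated trunk
#'   `Signature.7` 0.7 / `Signature.5` 0.3; private `Signature.5` 0.7 /
#'   `Signature.1` 0.3).
#' @param signatures A `signature_matrix`.
#' @param seed Integer seed.
#' @param contigs,contig_len Toy genome shape.
#' @return List with `mutations` (named list of per-sample data frames
#'   with `sample, chrom, pos, ref, alt, context5, context3`) and `truth`
#'   (planted trunk/private key sets and mixtures).
#' @export
simulate_patient_phylogeny <- function(n_samples = 3, trunk_n = 1848,
                                       private_ns = c(500, 700, 900),
                                       trunk_exposures = c(Signature.7 = 0.7,
                                                           Signature.5 = 0.3),
                                       private_exposures = c(Signature.5 = 0.7,
                                                             Signature.1 = 0.3),
                                       signatures = ccs_signatures(),
                                       seed = NULL,
                                       contigs = 24, contig_len = 1e7) {
  stopifnot(trunk_n >= 0, length(private_ns) == n_samples, n_samples >= 2)
  n_total <- trunk_n + sum(private_ns)
  if (n_total > contigs * contig_len)
    stop2("requested mutations exceed distinct positions in the toy genome")
  with_seed(seed, {
    # distinct genomic slots across all groups, then split
    slot <- sample(contigs * contig_len, n_total, replace = FALSE)
    chrom <- paste0("chr", (slot - 1) %/% contig_len + 1)
    pos <- as.integer((slot - 1) %% contig_len + 1)
    off <- 0L
    mk_group <- function(k, exposures) {
      i <- off + seq_len(k)
      off <<- off + k
      cbind(data.frame(chrom = chrom[i], pos = pos[i]),
            .draw_channel_records(k, exposures, signatures))
    }
    trunk <- mk_group(trunk_n, trunk_exposures)
    privates <- lapply(private_ns, mk_group, exposures = private_exposures)
    samples <- paste0("tumor", seq_len(n_samples))
    mutations <- lapply(seq_len(n_samples), function(i) {
      df <- rbind(trunk, privates[[i]])
      cbind(data.frame(sample = samples[i]), df)
    })
    names(mutations) <- samples
    list(mutations = mutations,
         truth = list(scenario = "phylogeny", seed = seed,
                      parameters = list(n_samples = n_samples,
                                        trunk_n = trunk_n,
                                        private_ns = private_ns),
                      planted = list(
                        trunk_keys = mutation_keys(trunk),
                        private_keys = lapply(privates, mutation_keys),
                        trunk_exposures = as.list(trunk_exposures),
                        private_exposures = as.list(private_exposures))))
  })
}

#' Simulate targeted deep-sequencing variant calls for planted clones
#'
#' Emulates a deep-sequencing panel (average depth around 500x) over a set
#' of planted mutant clones: each variant's depth is Poisson, alt-read
#' count binomial at the clone's true allele fraction, and the reported
#' VAF is exactly alt/depth. Calls with at least `min_alt` supporting
#' reads get `filter = "PASS"`, `qual = 100`; others get a fail flag and a
#' low quality, exercising the strict-filter path.
#'
#' @param clones Data frame with `chrom, pos, ref, alt, gene, consequence,
#'   true_vaf` (one row per planted clone variant; `true_vaf` in (0, 1)).
#' @param depth_mean Mean sequencing depth (default 500).
#' @param seed Integer seed.
#' @param tumor_id Label for the call set.
#' @param min_alt Alt-read support needed for a PASS call (default 5).
#' @return List with `calls` (VariantCall-style data frame with observed
#'   `vaf`, `depth`, `alt_reads`, `qual`, `filter`) and `truth`.
#' @export
simulate_deep_seq_vafs <- function(clones, depth_mean = 500, seed = NULL,
                                   tumor_id = "tumor", min_alt = 5) {
  stopifnot(is.data.frame(clones), depth_mean >= 1)
  if (nrow(clones) == 0L) {
    calls <- data.frame(tumor_id = character(), chrom = character(),
                        pos = integer(), ref = character(), alt = character(),
                        gene = character(), consequence = character(),
                        depth = integer(), alt_reads = integer(),
                        vaf = numeric(), qual = numeric(), filter = character())
    return(list(calls = calls,
                truth = list(scenario = "deepseq", seed = seed,
                             parameters = list(depth_mean = depth_mean),
                             planted = list(clones = clones))))
  }
  if (any(clones$true_vaf <= 0 | clones$true_vaf >= 1))
    stop2("true_vaf must lie strictly in (0, 1)")
  with_seed(seed, {
    depth <- rpois(nrow(clones), depth_mean)
    depth[depth == 0] <- 1L
    alt_reads <- rbinom(nrow(clones), depth, clones$true_vaf)
    calls <- data.frame(tumor_id = tumor_id, chrom = clones$chrom,
                        pos = clones$pos, ref = clones$ref, alt = clones$alt,
                        gene = clones$gene, consequence = clones$consequence,
                        depth = depth, alt_reads = alt_reads,
                        vaf = alt_reads / depth,
                        qual = ifelse(alt_reads >= min_alt, 100, 30),
                        filter = ifelse(alt_reads >= min_alt, "PASS", "LOWSUPPORT"))
    list(calls = calls,
         truth = list(scenario = "deepseq", seed = seed,
                      parameters = list(depth_mean = depth_mean,
                                        min_alt = min_alt),
                      planted = list(clones = clones)))
  })
}

#' Simulate a two-cluster beta matrix with planted hypomethylated regions
#'
#' Generates a probes-by-samples beta matrix for two sample groups (a
#' mutant-like designated group and a wild-type-like group) with
#' `n_dmrs` planted regions of `dmr_probes` consecutive probes in which
#' the designated group's mean beta is shifted down by `delta_beta`.
#' Background betas follow a bimodal array-like mixture; planted-region
#' probes start from the methylated component so the hypomethylation shift
#' survives truncation to `[0, 1]`. Probes are evenly spaced; planted
#' regions are separated by enough background probes that the distance
#' between two regions always exceeds `gap_guard` bases, keeping them
#' distinct for a region caller with `max_gap <= gap_guard`.
#'
#' @param n_group1,n_group2 Samples in the designated (mutant-like) and
#'   other group (defaults 5 and 3).
#' @param n_probes Total probes (default 20000).
#' @param n_dmrs Number of planted regions (default 10).
#' @param dmr_probes Probes per planted region (default 3).
#' @param delta_beta Planted beta decrease in the designated group
#'   (default 0.4).
#' @param noise_sd Per-sample Gaussian noise on beta (default 0.05).
#' @param probe_spacing Distance in bases between consecutive probes
#'   (default 300).
#' @param gap_guard Minimum genomic separation between planted regions in
#'   bases (default 1000, matching [find_dmrs()]'s default `max_gap`).
#' @param seed Integer seed.
#' @return List with `beta` (a [beta_matrix()]), `labels` (named group
#'   vector: `"mutant"` / `"wildtype"`), and `truth` (planted region
#'   intervals, probe indices, and parameters).
#' @export
simulate_methylation <- function(n_group1 = 5, n_group2 = 3,
                                 n_probes = 20000, n_dmrs = 10,
                                 dmr_probes = 3, delta_beta = 0.4,
                                 noise_sd = 0.05, probe_spacing = 300,
                                 gap_guard = 1000, seed = NULL) {
  guard_probes <- ceiling(gap_guard / probe_spacing) + 1L
  need <- n_dmrs * (dmr_probes + guard_probes) + guard_probes
  if (need > n_probes)
    stop2("n_probes too small to place ", n_dmrs,
          " non-overlapping regions separated by more than ", gap_guard,
          " bases (need >= ", need, ")")
  with_seed(seed, {
    n_samp <- n_group1 + n_group2
    samples <- c(paste0("mut", seq_len(n_group1)),
                 paste0("wt", seq_len(n_group2)))
    labels <- setNames(rep(c("mutant", "wildtype"), c(n_group1, n_group2)),
                       samples)
    pos <- as.integer(seq_len(n_probes)) * as.integer(probe_spacing)
    # place region starts by distributing the spare probes randomly
    spare <- n_probes - need
    extra <- if (n_dmrs > 0) {
      cuts <- sort(sample.int(spare + n_dmrs, n_dmrs))
      diff(c(0L, cuts)) - 1L                      # n_dmrs gaps summing <= spare
    } else integer(0)
    starts <- integer(n_dmrs)
    cursor <- guard_probes
    for (i in seq_len(n_dmrs)) {
      cursor <- cursor + extra[i]
      starts[i] <- cursor + 1L
      cursor <- cursor + dmr_probes + guard_probes
    }
    in_dmr <- logical(n_probes)
    for (i in seq_len(n_dmrs))
      in_dmr[starts[i]:(starts[i] + dmr_probes - 1L)] <- TRUE
    # bimodal background; planted probes start methylated
    lowcomp <- runif(n_probes) < 0.5
    base <- ifelse(lowcomp, rbeta(n_probes, 2, 10), rbeta(n_probes, 10, 2))
    base[in_dmr] <- rbeta(sum(in_dmr), 10, 2)
    mean_mat <- matrix(base, n_probes, n_samp)
    mean_mat[in_dmr, seq_len(n_group1)] <-
      mean_mat[in_dmr, seq_len(n_group1)] - delta_beta
    beta <- mean_mat + matrix(rnorm(n_probes * n_samp, 0, noise_sd),
                              n_probes, n_samp)
    beta <- pmin(pmax(beta, 0), 1)
    dimnames(beta) <- list(sprintf("cg%07d", seq_len(n_probes)), samples)
    bm <- beta_matrix(beta, rep("chr1", n_probes), pos)
    regions <- if (n_dmrs > 0) data.frame(
      chrom = "chr1",
      start = pos[starts],
      end = pos[starts + dmr_probes - 1L],
      first_probe = starts, probe_count = dmr_probes) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 first_probe = integer(), probe_count = integer())
    list(beta = bm, labels = labels,
         truth = list(scenario = "methylation", seed = seed,
                      parameters = list(n_group1 = n_group1,
                                        n_group2 = n_group2,
                                        n_probes = n_probes, n_dmrs = n_dmrs,
                                        dmr_probes = dmr_probes,
                                        delta_beta = delta_beta,
                                        noise_sd = noise_sd,
                                        probe_spacing = probe_spacing,
                                        gap_guard = gap_guard),
                      planted = list(regions = regions,
                                     labels = as.list(labels))))
  })
}

#' Serialize a generator's planted truth as JSON
#'
#' Every simulator returns a `truth` list recording its scenario,
#' parameters, seed and planted ground truth; writing it next to the data
#' lets downstream tests read expectations from the file rather than from
#' constants.
#'
#' @param truth A `truth` list from any `simulate_*` function.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
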