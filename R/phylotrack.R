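#' Mutation identity keys
#'
#' A mutation's identity across samples of one patient is the tuple
#' (chrom, pos, ref, alt); allele fraction and quality play no role in
#' presence calls.
#'
#' @param mutations Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector of keys `"chrom:pos:ref:alt"`.
#' @export
mutation_keys <- function(mutations) {
  paste(as.character(mutations$chrom), as.integer(mutations$pos),
        toupper(as.character(mutations$ref)),
        toupper(as.character(mutations$alt)), sep = ":")
}

#' Partition a patient's mutations by tumor presence pattern
#'
#' Groups the union of mutation keys across all tumors of one patient by
#' the exact subset of tumors that carry each mutation. The group whose
#' pattern covers every tumor is the trunk — the shared ancestral mutation
#' set that establishes a common origin for geographically separated
#' lesions (e.g. multiple pulmonary cylindromas seeded from one skin
#' tumor).
#'
#' @param per_sample_keys Named list (>= 2 entries) mapping sample id to a
#'   character vector of mutation keys (see [mutation_keys()]); duplicates
#'   within a sample are ignored.
#' @param patient_id Optional patient label.
#' @return A `presence_partition`: list with `patient_id`, `sample_ids`,
#'   `groups` (named list of key vectors; names are presence bitmasks such
#'   as `"110"`, one character per sample in `sample_ids` order), `trunk`
#'   (keys present in all samples), and `summary` (data frame of pattern,
#'   samples, size).
#' @examples
#' p <- partition_mutations(list(a = c("1:1:C:A", "1:2:C:T"),
#'                               b = c("1:1:C:A")))
#' p$trunk
#' @export
partition_mutations <- function(per_sample_keys, patient_id = "patient") {
  stopifnot(is.list(per_sample_keys))
  if (length(per_sample_keys) < 2L)
    stop2("presence partition undefined for fewer than 2 samples")
  if (is.null(names(per_sample_keys)) || any(names(per_sample_keys) == ""))
    stop2("per_sample_keys must be a named list of samples")
  samples <- names(per_sample_keys)
  sets <- lapply(per_sample_keys, function(k) unique(as.character(k)))
  all_keys <- unique(unlist(sets, use.names = FALSE))
  if (length(all_keys) == 0L) {
    groups <- list()
  } else {
    inc <- vapply(sets, function(s) all_keys %in% s, logical(length(all_keys)))
    if (length(all_keys) == 1L) inc <- matrix(inc, nrow = 1L)
    pattern <- apply(inc, 1, function(r) paste(as.integer(r), collapse = ""))
    groups <- split(all_keys, pattern)
  }
  trunk_pat <- paste(rep("1", length(samples)), collapse = "")
  smry <- data.frame(
    pattern = names(groups),
    samples = vapply(names(groups), function(p) {
      paste(samples[strsplit(p, "")[[1]] == "1"], collapse = ",")
    }, ""),
    size = vapply(groups, length, 0L),
    row.names = NULL
  )
  if (nrow(smry)) smry <- smry[order(-nchar(gsub("0", "", smry$pattern)),
                                     -smry$size), , drop = FALSE]
  rownames(smry) <- NULL
  structure(list(patient_id = patient_id, sample_ids = samples,
                 groups = groups,
                 trunk = groups[[trunk_pat]] %||% character(0),
                 summary = smry),
            class = "presence_partition")
}

#' @export
print.presence_partition <- function(x, ...) {
  cat("Presence partition for patient '", x$patient_id, "' (",
      length(x$sample_ids), " tumors: ",
      paste(x$sample_ids, collapse = ", "), ")\n", sep = "")
  cat("  trunk (shared by all):", length(x$trunk), "mutations\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Star-with-trunk topology as a Newick string
#'
#' Writes the patient's tumors as a star tree hanging off a single trunk
#' edge, with edge lengths equal to mutation counts: the trunk edge carries
#' the shared mutation count and each tip its private count. Internal
#' branch patterns (mutations shared by a strict subset of tumors) are not
#' representable on this topology and are ignored here; they remain
#' available in the partition's groups.
#'
#' @param partition A `presence_partition`.
#' @return A single Newick string, terminated by `;`.
#' @export
phylo_newick <- function(partition) {
  stopifnot(inherits(partition, "presence_partition"))
  s <- partition$sample_ids
  priv <- vapply(seq_along(s), function(i) {
    pat <- paste(as.integer(seq_along(s) == i), collapse = "")
    length(partition$groups[[pat]] %||% character(0))
  }, 0L)
  tips <- paste0(s, ":", priv, collapse = ",")
  paste0("(", tips, "):", length(partition$trunk), ";")
}

#' Attribute mutational signatures to trunk and branch mutation groups
#'
#' For each presence-pattern group of a partition, builds a 96-channel
#' catalog from the group's mutations and runs the bootstrap signature fit
#' ([fit_signatures()]). A signature is called present in a branch when its
#' bootstrap exceedance probability reaches `confidence`; the UV signature
#' appearing in the trunk of pulmonary lesions is the package's motivating
#' origin-tracking call.
#'
#' @param partition A `presence_partition`.
#' @param mutations Data frame covering every key in the partition, with
#'   `chrom, pos, ref, alt, context5, context3` (one row per key suffices;
#'   duplicate keys across samples are collapsed).
#' @param signatures A `signature_matrix`.
#' @param k,threshold,n_boot,seed Passed to [fit_signatures()].
#' @param confidence Exceedance probability required to call a signature
#'   present (default 0.95).
#' @param min_size Groups smaller than this are still fitted but flagged
#'   `low_confidence` (default 50).
#' @return Data-frame-like list of class `branch_attribution_set`: one
#'   element per non-empty group with `pattern`, `size`, `low_confidence`,
#'   `fit` (a `sigfit`), and `present_signatures`. An empty trunk produces
#'   a warning and no trunk element.
#' @export
attribute_branch_signatures <- function(partition, mutations, signatures,
                                        k = 3, threshold = 0.05,
                                        n_boot = 200, seed = NULL,
                                        confidence = 0.95, min_size = 50) {
  stopifnot(inherits(partition, "presence_partition"))
  keys <- mutation_keys(mutations)
  first <- !duplicated(keys)
  mut <- mutations[first, , drop = FALSE]
  keys <- keys[first]
  trunk_pat <- paste(rep("1", length(partition$sample_ids)), collapse = "")
  if (length(partition$trunk) == 0L)
    warning("empty trunk: no trunk attribution emitted")
  out <- list()
  pats <- names(partition$groups)
  for (j in seq_along(pats)) {
    grp <- partition$groups[[j]]
    if (length(grp) == 0L) next
    idx <- match(grp, keys)
    if (anyNA(idx))
      stop2("mutation table is missing ", sum(is.na(idx)),
            " key(s) of pattern ", pats[j])
    cat_j <- build_catalog(mut[idx, , drop = FALSE],
                           sample_id = paste0(partition$patient_id, ":", pats[j]))
    fit <- fit_signatures(cat_j, signatures, k = k, threshold = threshold,
                          n_boot = n_boot, seed = seed)
    out[[pats[j]]] <- list(
      pattern = pats[j],
      is_trunk = identical(pats[j], trunk_pat),
      size = length(grp),
      low_confidence = length(grp) < min_size,
      fit = fit,
      present_signatures =
        names(which(fit$bootstrap$exceedance_prob >= confidence))
    )
  }
  structure(out, class = "branch_attribution_set")
}

#' @export
print.branch_attribution_set <- function(x, ...) {
  cat("Branch signature attribution (", length(x), " groups)\n", sep = "")
  for (b in x) {
    cat(sprintf("  %s%s  n=%d%s  present: %s\n", b$pattern,
                if (b$is_trunk) " (trunk)" else "", b$size,
                if (b$low_confidence) " [low confidence]" else "",
                if (length(b$present_signatures))
                  paste(b$present_signatures, collapse = ", ") else "-"))
  }
  invisible(x)
}
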