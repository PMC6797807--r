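#' Filter targeted deep-sequencing variant calls
#'
#' Strict mode keeps calls with `filter == "PASS"` and `qual >= 100`, the
#' inclusion rule for deep-sequencing panels where the caller caps quality
#' at 100. Relaxed mode — used when microdissected regions are profiled and
#' calls are confirmed by inspecting aligned reads — keeps every
#' non-synonymous call and marks it for review.
#'
#' @param calls Data frame of variant calls with at least `filter` and
#'   `qual` columns (strict mode) or a `consequence` column (relaxed mode).
#' @param mode `"strict"` or `"relaxed"`.
#' @return The retained rows. Strict mode attaches a `rejections` attribute
#'   (data frame of row index and reason). Relaxed mode adds a logical
#'   `review` column set to `TRUE`.
#' @examples
#' calls <- data.frame(filter = c("PASS", "PASS"), qual = c(100, 99),
#'                     consequence = "missense")
#' filter_variants(calls, "strict")
#' @export
filter_variants <- function(calls, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(calls))
  if (mode == "strict") {
    reason <- rep(NA_character_, nrow(calls))
    has_filter <- "filter" %in% names(calls)
    has_qual <- "qual" %in% names(calls)
    if (!has_filter || !has_qual)
      stop2("strict filtering requires 'filter' and 'qual' columns")
    reason[is.na(calls$filter) | is.na(calls$qual)] <- "missing filter/qual"
    miss <- !is.na(reason)
    reason[!miss & calls$filter != "PASS"] <- "filter not PASS"
    reason[!miss & calls$filter == "PASS" & calls$qual < 100] <- "qual below 100"
    keep <- is.na(reason)
    out <- calls[keep, , drop = FALSE]
    attr(out, "rejections") <- data.frame(row = which(!keep),
                                          reason = reason[!keep])
    return(out)
  }
  if (!"consequence" %in% names(calls))
    stop2("relaxed filtering requires a 'consequence' column")
  keep <- !is.na(calls$consequence) & calls$consequence != "synonymous"
  out <- calls[keep, , drop = FALSE]
  if (nrow(out)) out$review <- TRUE
  out
}

#' Enumerate co-occurring mutant clones in one tumor and gene
#'
#' Each distinct qualifying variant (unique chrom/pos/ref/alt with allele
#' fraction at or above `vaf_min`) is counted as one mutant clone; a tumor
#' carrying two or more distinct variants in the same gene harbours
#' co-occurring clones — the intratumoral heterogeneity readout. Identical
#' variants observed in different sections of the same tumor are
#' deduplicated by variant key.
#'
#' @param calls Filtered variant calls for one tumor and gene: data frame
#'   with `chrom, pos, ref, alt, vaf` (a `gene`/`tumor_id` column, if
#'   present, must be constant).
#' @param vaf_min Minimum allele fraction for a variant to count as a
#'   clone (default 0.05, the lower end of driver VAFs seen on deep
#'   sequencing).
#' @return A `clone_report`: list with `tumor_id`, `gene`, `variants`
#'   (deduplicated qualifying rows), `clone_count` and `heterogeneous`
#'   (`clone_count >= 2`).
#' @export
enumerate_clones <- function(calls, vaf_min = 0.05) {
  stopifnot(is.data.frame(calls))
  tumor_id <- if ("tumor_id" %in% names(calls) && nrow(calls))
    unique(as.character(calls$tumor_id)) else "tumor"
  gene <- if ("gene" %in% names(calls) && nrow(calls))
    unique(as.character(calls$gene)) else NA_character_
  if (length(tumor_id) > 1L || length(gene) > 1L)
    stop2("enumerate_clones expects calls from a single tumor and gene")
  if (nrow(calls)) {
    qual <- calls[!is.na(calls$vaf) & calls$vaf >= vaf_min, , drop = FALSE]
    qual <- qual[!duplicated(mutation_keys(qual)), , drop = FALSE]
  } else qual <- calls
  structure(list(tumor_id = tumor_id, gene = gene, variants = qual,
                 clone_count = nrow(qual), heterogeneous = nrow(qual) >= 2L),
            class = "clone_report")
}

#' @export
print.clone_report <- function(x, ...) {
  cat("Tumor '", x$tumor_id, "', gene ", x$gene, ": ", x$clone_count,
      " mutant clone(s)", if (x$heterogeneous) " - heterogeneous", "\n",
      sep = "")
  if (x$clone_count)
    print(x$variants[, intersect(c("chrom", "pos", "ref", "alt", "vaf"),
                                 names(x$variants))], row.names = FALSE)
  invisible(x)
}

#' Classify a variant as a putative driver mutation
#'
#' Applies the cancer-gene-census style rule: inactivating mutations
#' (nonsense, frameshift, essential splice) in tumor suppressors are
#' drivers; missense mutations in tumor suppressors are drivers only when
#' recurrent; any mutation in a dominant oncogene is a driver only when
#' recurrent (hotspots such as AKT1 E17K); synonymous changes are never
#' drivers. Recurrence is supplied as a count from an external frequency
#' table.
#'
#' @param consequence One of `missense`, `nonsense`, `frameshift`,
#'   `essential_splice`, `synonymous`, `other` (vectorized).
#' @param gene_role `"tumor_suppressor"` or `"oncogene"`; anything else
#'   yields `"uncertain"`.
#' @param recurrence_count Times the identical change is reported in a
#'   reference mutation-frequency table.
#' @param recurrence_min Count at which a mutation is deemed recurrent
#'   (default 3).
#' @return Character vector in `c("driver", "non_driver", "uncertain")`.
#' @examples
#' classify_driver("nonsense", "tumor_suppressor", 0)
#' classify_driver("missense", "oncogene", 50)
#' @export
classify_driver <- function(consequence, gene_role, recurrence_count,
                            recurrence_min = 3) {
  n <- max(length(consequence), length(gene_role), length(recurrence_count))
  consequence <- rep_len(as.character(consequence), n)
  gene_role <- rep_len(as.character(gene_role), n)
  recurrence_count <- rep_len(as.numeric(recurrence_count), n)
  inact <- c("nonsense", "frameshift", "essential_splice")
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (consequence[i] == "synonymous") "non_driver"
    else if (identical(gene_role[i], "tumor_suppressor")) {
      if (consequence[i] %in% inact) "driver"
      else if (consequence[i] == "missense") {
        if (recurrence_count[i] >= recurrence_min) "driver" else "uncertain"
      } else "uncertain"
    } else if (identical(gene_role[i], "oncogene")) {
      if (recurrence_count[i] >= recurrence_min) "driver" else "non_driver"
    } else "uncertain"
  }
  out
}

#' Call biallelic loss of a tumor suppressor
#'
#' Determines how the wild-type allele of a germline-mutated tumor
#' suppressor was lost in a tumor: by loss of heterozygosity (any
#' allele-specific copy-number state covering the gene with minor allele
#' count 0, including copy-neutral LOH such as major 2 / minor 0), or by a
#' second somatic hit (a qualifying somatic driver-class mutation in the
#' gene on top of the germline allele), or neither.
#'
#' @param gene_interval List or one-row data frame with `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param germline_hit Logical: does the patient carry a germline mutation
#'   in the gene?
#' @param somatic_hits Data frame of filtered somatic calls in the gene
#'   (may have zero rows); rows with `consequence` in nonsense/frameshift/
#'   essential_splice/missense qualify as second hits.
#' @param segments Data frame of allele-specific copy-number segments:
#'   `chrom, start, end, major, minor` (1-based inclusive, `major >=
#'   minor`). Order is irrelevant; a covering segment split into pieces
#'   with identical allele counts behaves like the unsplit segment.
#' @return A `biallelic_call`: list with `mechanism` (`"LOH"`,
#'   `"second_somatic_hit"` or `"none"`) and `evidence` text. Segments that
#'   span the gene with discordant minor alleles give an ambiguous-LOH
#'   evidence note rather than an error.
#' @examples
#' seg <- data.frame(chrom = "16", start = 1, end = 9e7, major = 2, minor = 0)
#' gi <- list(chrom = "16", start = 50775961, end = 50835846)
#' assess_biallelic_loss(gi, TRUE, data.frame(), seg)$mechanism
#' @export
assess_biallelic_loss <- function(gene_interval, germline_hit, somatic_hits,
                                  segments) {
  gi <- as.list(gene_interval)
  stopifnot(!is.null(gi$chrom), !is.null(gi$start), !is.null(gi$end))
  segs <- segments[as.character(segments$chrom) == as.character(gi$chrom) &
                     segments$end >= gi$start & segments$start <= gi$end,
                   , drop = FALSE]
  segs <- segs[order(segs$start), , drop = FALSE]
  loh <- FALSE; ambiguous <- FALSE
  if (nrow(segs)) {
    # does the union of overlapping segments tile the whole interval?
    covered <- nrow(segs) > 0 && segs$start[1] <= gi$start &&
      segs$end[nrow(segs)] >= gi$end &&
      (nrow(segs) == 1 || all(segs$start[-1] <= segs$end[-nrow(segs)] + 1))
    if (covered) {
      if (all(segs$minor == 0)) loh <- TRUE
      else if (any(segs$minor == 0)) ambiguous <- TRUE
    } else if (any(segs$minor == 0)) ambiguous <- TRUE
  }
  if (loh) {
    cn <- unique(paste0(segs$major, "+", segs$minor))
    return(structure(list(mechanism = "LOH",
                          evidence = paste0("minor allele 0 across gene (states ",
                                            paste(cn, collapse = ", "), ")")),
                     class = "biallelic_call"))
  }
  qual_cons <- c("nonsense", "frameshift", "essential_splice", "missense")
  second <- is.data.frame(somatic_hits) && nrow(somatic_hits) > 0 &&
    any(somatic_hits$consequence %in% qual_cons)
  if (isTRUE(germline_hit) && second) {
    ev <- "germline allele plus qualifying somatic mutation"
    if (ambiguous) ev <- paste0(ev, "; ambiguous LOH: discordant minor alleles across segments")
    return(structure(list(mechanism = "second_somatic_hit", evidence = ev),
                     class = "biallelic_call"))
  }
  ev <- "no covering minor-allele-0 segment and no qualifying second hit"
  if (ambiguous) ev <- paste0("ambiguous LOH: discordant minor alleles across segments; ", ev)
  structure(list(mechanism = "none", evidence = ev), class = "biallelic_call")
}

#' @export
print.biallelic_call <- function(x, ...) {
  cat("Biallelic loss call:", x$mechanism, "\n  evidence:", x$evidence, "\n")
  invisible(x)
}
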