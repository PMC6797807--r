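#' The fixed 96-channel substitution catalog convention
#'
#' Somatic single-base substitutions are classified into 96 channels: six
#' pyrimidine-referenced substitution classes (C>A, C>G, C>T, T>A, T>C, T>G)
#' times 16 trinucleotide contexts (5' base, then 3' base, each A, C, G, T in
#' alphabetical order). The ordering is class-major, then 5' base, then 3'
#' base, matching the layout used by version-2 reference signature tables, so
#' `sbs_channels()[1]` is `"A[C>A]A"` and `sbs_channels()[96]` is
#' `"T[T>G]T"`.
#'
#' @return Character vector of the 96 channel labels, in canonical order.
#' @examples
#' head(sbs_channels())
#' @export
sbs_channels <- function() {
  bases <- c("A", "C", "G", "T")
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(96)
  i <- 0L
  for (cl in classes) {
    ref <- substr(cl, 1, 1)
    alt <- substr(cl, 3, 3)
    for (f5 in bases) for (f3 in bases) {
      i <- i + 1L
      out[i] <- paste0(f5, "[", ref, ">", alt, "]", f3)
    }
  }
  out
}

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify substitutions into the 96-channel convention
#'
#' Maps each substitution, given its reference and alternate allele and the
#' immediate 5' and 3' flanking bases, to its channel index. Purine-reference
#' mutations (ref A or G) are reverse-complemented first so the reference is
#' always a pyrimidine; a mutation and its opposite-strand representation
#' therefore always land on the same channel.
#'
#' @param ref,alt Reference and alternate bases (single characters, A/C/G/T);
#'   vectors are recycled to a common length.
#' @param context5,context3 Bases immediately 5' and 3' of `ref` on the same
#'   strand as `ref`.
#' @return Integer vector of channel indices in `1:96`, following the
#'   ordering of [sbs_channels()]. Use `sbs_channels()[classify_sbs(...)]`
#'   for labels.
#' @examples
#' classify_sbs("C", "A", "A", "A")            # 1, A[C>A]A
#' classify_sbs("G", "T", "G", "T")            # reverse complement of A[C>A]C
#' sbs_channels()[classify_sbs("T", "G", "T", "T")]
#' @export
classify_sbs <- function(ref, alt, context5, context3) {
  n <- max(length(ref), length(alt), length(context5), length(context3))
  ref <- toupper(rep_len(as.character(ref), n))
  alt <- toupper(rep_len(as.character(alt), n))
  f5 <- toupper(rep_len(as.character(context5), n))
  f3 <- toupper(rep_len(as.character(context3), n))
  ok <- ref %in% .BASES & alt %in% .BASES & f5 %in% .BASES & f3 %in% .BASES
  if (!all(ok))
    stop2("invalid base: all of ref, alt, context5, context3 must be A/C/G/T")
  if (any(ref == alt))
    stop2("invalid substitution: ref must differ from alt")
  # strand-normalize purine references
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    new5 <- ifelse(pur, unname(.COMP[f3]), f5)
    new3 <- ifelse(pur, unname(.COMP[f5]), f3)
    alt <- ifelse(pur, unname(.COMP[alt]), alt)
    ref <- ifelse(pur, unname(.COMP[ref]), ref)
    f5 <- new5
    f3 <- new3
  }
  cls <- match(paste0(ref, ">", alt), c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  (cls - 1L) * 16L + (match(f5, .BASES) - 1L) * 4L + match(f3, .BASES)
}

#' Build a 96-channel substitution catalog for one sample
#'
#' Counts a sample's somatic single-base substitutions into the 96 channels
#' of [sbs_channels()]. Records that are not simple A/C/G/T substitutions
#' (indels, MNVs, non-ACGT contexts) are excluded and counted in the
#' `n_excluded` attribute; signature analysis is substitution-only.
#'
#' @param mutations A data frame with columns `ref`, `alt`, `context5`,
#'   `context3` (and optionally `sample`/`sample_id`, `chrom`, `pos`), e.g.
#'   from [read_mutations()] or [simulate_patient_phylogeny()].
#' @param sample_id Sample label stored on the catalog. Defaults to the
#'   (single) value of the `sample` column when present, else `"sample"`.
#' @return An object of class `catalog96`: a named integer vector of length
#'   96 with attributes `sample_id`, `total` (number of records retained) and
#'   `n_excluded`. An empty input yields an all-zero catalog with a warning.
#' @examples
#' m <- data.frame(ref = "C", alt = "A", context5 = "A", context3 = "A")
#' build_catalog(m[rep(1, 3), ], "toy")
#' @export
build_catalog <- function(mutations, sample_id = NULL) {
  stopifnot(is.data.frame(mutations))
  if (is.null(sample_id)) {
    sc <- mutations[["sample"]] %||% mutations[["sample_id"]]
    sample_id <- if (!is.null(sc) && length(unique(sc)) == 1L)
      as.character(unique(sc)) else "sample"
  }
  counts <- integer(96)
  n_excluded <- 0L
  if (nrow(mutations) == 0L) {
    warning("empty mutation list: returning all-zero catalog")
  } else {
    need <- c("ref", "alt", "context5", "context3")
    miss <- setdiff(need, names(mutations))
    if (length(miss))
      stop2("mutations lack required column(s): ", paste(miss, collapse = ", "))
    ref <- toupper(as.character(mutations$ref))
    alt <- toupper(as.character(mutations$alt))
    f5 <- toupper(as.character(mutations$context5))
    f3 <- toupper(as.character(mutations$context3))
    keep <- nchar(ref) == 1L & nchar(alt) == 1L &
      ref %in% .BASES & alt %in% .BASES & ref != alt &
      f5 %in% .BASES & f3 %in% .BASES
    keep[is.na(keep)] <- FALSE
    n_excluded <- sum(!keep)
    if (any(keep)) {
      idx <- classify_sbs(ref[keep], alt[keep], f5[keep], f3[keep])
      counts <- tabulate(idx, nbins = 96L)
    }
  }
  structure(as.integer(counts), names = sbs_channels(), class = "catalog96",
            sample_id = sample_id, total = sum(counts),
            n_excluded = n_excluded)
}

#' @export
print.catalog96 <- function(x, ...) {
  cat("96-channel substitution catalog for sample '",
      attr(x, "sample_id"), "'\n", sep = "")
  cat("  total substitutions:", attr(x, "total"),
      " (excluded:", attr(x, "n_excluded"), ")\n")
  nz <- x[x > 0]
  top <- sort(nz, decreasing = TRUE)
  cat("  top channels:",
      paste0(names(head(top, 5)), "=", head(top, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Fetch the trinucleotide context at a genomic position from a FASTA file
#'
#' Reads the bases at `pos - 1`, `pos` and `pos + 1` (1-based) on the named
#' sequence of a FASTA file. The caller is expected to verify that the middle
#' base matches the mutation record's reference allele; [annotate_contexts()]
#' does this for a whole table.
#'
#' @param chrom Sequence name as it appears in the FASTA headers.
#' @param pos 1-based position; must satisfy `2 <= pos <= length - 1`.
#' @param fasta_source Path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @return Named character vector `c(context5 = , ref = , context3 = )`,
#'   uppercase.
#' @export
fetch_context <- function(chrom, pos, fasta_source) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop2("fetch_context requires the Biostrings package")
  seqs <- if (inherits(fasta_source, "DNAStringSet")) fasta_source
          else Biostrings::readDNAStringSet(fasta_source)
  # FASTA headers may carry descriptions after the name
  nm <- sub("\\s.*$", "", names(seqs))
  i <- match(as.character(chrom), nm)
  if (is.na(i)) stop2("sequence '", chrom, "' not found in FASTA")
  len <- Biostrings::width(seqs[i])
  pos <- as.integer(pos)
  if (pos - 1L < 1L || pos + 1L > len)
    stop2("position ", pos, " out of range on '", chrom,
          "' (need flanking bases within 1..", len, ")")
  tri <- toupper(as.character(Biostrings::subseq(seqs[[i]], pos - 1L, pos + 1L)))
  c(context5 = substr(tri, 1, 1), ref = substr(tri, 2, 2),
    context3 = substr(tri, 3, 3))
}

#' Annotate a mutation table with trinucleotide contexts from a FASTA
#'
#' Looks up `context5`/`context3` for every record and drops (with a report)
#' records whose FASTA base disagrees with the stated reference allele.
#'
#' @param mutations Data frame with `chrom`, `pos`, `ref` columns.
#' @param fasta_source Path to a FASTA file or a `DNAStringSet`.
#' @return The input with `context5`/`context3` columns filled; records
#'   failing the reference match are removed and reported via a warning with
#'   attribute `n_ref_mismatch`.
#' @export
annotate_contexts <- function(mutations, fasta_source) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop2("annotate_contexts requires the Biostrings package")
  seqs <- if (inherits(fasta_source, "DNAStringSet")) fasta_source
          else Biostrings::readDNAStringSet(fasta_source)
  n <- nrow(mutations)
  f5 <- f3 <- rb <- character(n)
  for (i in seq_len(n)) {
    ctx <- fetch_context(mutations$chrom[i], mutations$pos[i], seqs)
    f5[i] <- ctx[["context5"]]; rb[i] <- ctx[["ref"]]; f3[i] <- ctx[["context3"]]
  }
  ok <- rb == toupper(as.character(mutations$ref))
  if (any(!ok))
    warning(sum(!ok), " record(s) dropped: reference allele does not match FASTA")
  out <- mutations[ok, , drop = FALSE]
  out$context5 <- f5[ok]
  out$context3 <- f3[ok]
  attr(out, "n_ref_mismatch") <- sum(!ok)
  out
}
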