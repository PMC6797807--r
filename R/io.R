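#' Read somatic mutation lists from TSV or VCF
#'
#' Accepts either a tab-delimited table with header columns
#' `sample, chrom, pos, ref, alt` (optionally `context5, context3, vaf,
#' qual, filter`) or a VCF 4.x file, from which only CHROM, POS, REF, ALT
#' and, when present, QUAL/FILTER are consumed.
#'
#' @param path File path; files ending in `.vcf` are parsed as VCF.
#' @param sample_id Sample label to assign when the file carries none
#'   (VCF input, or TSV without a `sample` column).
#' @return Data frame with columns `sample, chrom, pos, ref, alt` plus any
#'   optional columns present. Positions are 1-based integers.
#' @export
read_mutations <- function(path, sample_id = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop2("reading VCF input requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT)
    df$qual <- suppressWarnings(as.numeric(fix$QUAL))
    df$filter <- fix$FILTER
    df$sample <- sample_id %||%
      sub("\\.vcf(\\.gz)?$", "", basename(path), ignore.case = TRUE)
    return(df[, c("sample", setdiff(names(df), "sample"))])
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop2("mutation TSV lacks column(s): ", paste(miss, collapse = ", "))
  if (!"sample" %in% names(df)) df$sample <- sample_id %||% "sample"
  df$pos <- as.integer(df$pos)
  df
}

#' Write a set of catalogs as a channels-by-samples TSV
#'
#' @param catalogs A single `catalog96` or a list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catalogs <- function(catalogs, path) {
  if (inherits(catalogs, "catalog96")) catalogs <- list(catalogs)
  mat <- sapply(catalogs, as.integer)
  colnames(mat) <- vapply(catalogs, attr, "", "sample_id")
  df <- data.frame(channel = sbs_channels(), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a channels-by-samples catalog TSV written by [write_catalogs()]
#'
#' @param path Input file.
#' @return Named list of `catalog96` objects, one per sample column.
#' @export
read_catalogs <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(df[[1]], sbs_channels()))
    stop2("catalog file does not follow the 96-channel label convention")
  out <- lapply(names(df)[-1], function(s) {
    structure(as.integer(df[[s]]), names = sbs_channels(),
              class = "catalog96", sample_id = s, total = sum(df[[s]]),
              n_excluded = NA_integer_)
  })
  names(out) <- names(df)[-1]
  out
}

#' Read a reference signature matrix (96 channels x K signatures)
#'
#' The file is a TSV whose first column holds channel labels in the
#' `"A[C>A]A"` style and whose remaining columns are signatures. Labels must
#' cover the canonical 96 channels; rows are reordered to [sbs_channels()]
#' order, and each column must sum to 1 within 1e-6.
#'
#' @param path TSV path.
#' @return A `signature_matrix`: numeric 96 x K matrix with channel labels
#'   as rownames and signature identifiers as colnames.
#' @seealso [ccs_signatures()] for the bundled matrix.
#' @export
read_signatures <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- df[[1]]
  if (!setequal(labs, sbs_channels()))
    stop2("signature file channel labels do not match the 96-channel convention")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labs
  m <- m[sbs_channels(), , drop = FALSE]
  as_signature_matrix(m)
}

#' Validate and class a 96 x K signature matrix
#'
#' @param m Numeric matrix, 96 rows labelled with the canonical channel
#'   labels, one column per signature.
#' @return The matrix with class `signature_matrix`.
#' @export
as_signature_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 96L, ncol(m) >= 1L)
  if (!identical(rownames(m), sbs_channels()))
    stop2("rownames must equal sbs_channels() in order")
  if (any(m < 0)) stop2("signature probabilities must be non-negative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    stop2("each signature column must sum to 1 (tolerance 1e-6)")
  class(m) <- c("signature_matrix", class(m))
  m
}

#' The bundled 30-signature reference matrix (synthetic)
#'
#' Loads the signature matrix shipped with the package:
#' `signatures_96x30_synthetic.tsv`, a synthetic stand-in laid out like the
#' version-2 COSMIC signature table (96 labelled channels, columns
#' `Signature.1` ... `Signature.30`). Signature.1 carries the CpG-deamination
#' profile (C>T at NpCpG), Signature.7 the ultraviolet profile (C>T at
#' dipyrimidines) and Signature.5 a near-flat profile; the remaining columns
#' are sparse distributions. It is not the COSMIC release and must not be
#' used to interpret real tumors; supply your own matrix via
#' [read_signatures()] for real analyses.
#'
#' @return A `signature_matrix` (96 x 30).
#' @examples
#' sigs <- ccs_signatures()
#' colnames(sigs)[1:3]
#' @export
ccs_signatures <- function() {
  path <- system.file("extdata", "signatures_96x30_synthetic.tsv",
                      package = "ccstools", mustWork = TRUE)
  read_signatures(path)
}
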