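#' Construct a genotype dataset
#'
#' A \code{genotype_dataset} bundles a variant table, a sample table and a
#' hard-call dosage matrix. Dosages count copies of \code{allele1} (the A1
#' allele of the \code{.bim} convention), so values are 0, 1, 2 or \code{NA}
#' for a missing call. The call matrix is stored variant-major (rows are
#' variants, columns are samples), matching the SNP-major layout of PLINK-1
#' \code{.bed} files.
#'
#' @param variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos} (1-based bp), \code{allele1}, \code{allele2}. Alleles must be
#'   single characters in \code{A,C,G,T} and differ within a variant.
#' @param samples data.frame with columns \code{fid}, \code{iid} and
#'   optionally \code{sex} (1 male, 2 female, 0 unknown) and \code{cohort}.
#'   The working sample id is the \code{fid}/\code{iid} concatenation, which
#'   keeps ids unique when cohorts are merged.
#' @param calls integer matrix, \code{nrow(variants)} by \code{nrow(samples)},
#'   entries in \code{0:2} or \code{NA}.
#' @return An object of class \code{genotype_dataset}.
#' @export
genotype_dataset <- function(variants, samples, calls) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need_v <- c("id", "chrom", "pos", "allele1", "allele2")
  if (!all(need_v %in% names(variants)))
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  if (!all(c("fid", "iid") %in% names(samples)))
    stop("samples must have columns fid, iid")
  if (is.null(samples$sex)) samples$sex <- 0L
  if (is.null(samples$cohort)) samples$cohort <- "cohort1"
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(variants) || ncol(calls) != nrow(samples))
    stop("calls must be nrow(variants) x nrow(samples)")
  if (anyDuplicated(variants$id))
    stop("duplicate variant ids")
  sid <- paste(samples$fid, samples$iid, sep = "_")
  if (anyDuplicated(sid))
    stop("duplicate sample ids (fid_iid)")
  bad <- variants$allele1 == variants$allele2
  if (any(bad))
    stop("allele1 == allele2 for variant(s): ",
         paste(utils::head(variants$id[bad]), collapse = ", "))
  if (any(variants$pos < 1))
    stop("positions must be >= 1")
  if (any(!is.na(calls))) {
    rng <- range(calls, na.rm = TRUE)
    if (rng[1] < 0L || rng[2] > 2L)
      stop("calls must be 0, 1, 2 or NA")
  }
  rownames(calls) <- variants$id
  colnames(calls) <- sid
  structure(
    list(variants = variants, samples = samples, calls = calls),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$variants), "variants x",
      nrow(x$samples), "samples\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  cat("  cohorts:", paste(unique(x$samples$cohort), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Sample identifiers of a genotype dataset
#'
#' @param d A \code{genotype_dataset}.
#' @return Character vector of \code{fid_iid} ids, in column order.
#' @export
sample_ids <- function(d) colnames(d$calls)

#' Allele-1 frequencies from non-missing calls
#'
#' @param d A \code{genotype_dataset}.
#' @return Numeric vector, one frequency per variant (\code{NaN} where every
#'   call is missing).
#' @export
allele_freq <- function(d) {
  rowMeans(d$calls, na.rm = TRUE) / 2
}

#' Subset a genotype dataset
#'
#' @param d A \code{genotype_dataset}.
#' @param variants Optional index/logical/character vector of variants to keep.
#' @param samples Optional index/logical/character vector of samples to keep
#'   (character values are matched against \code{fid_iid} ids).
#' @return A \code{genotype_dataset} with the requested rows/columns.
#' @export
subset_genotypes <- function(d, variants = NULL, samples = NULL) {
  vi <- seq_len(nrow(d$variants))
  si <- seq_len(nrow(d$samples))
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, d$variants$id) else vi[variants]
    if (anyNA(vi)) stop("unknown variant id in subset")
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, sample_ids(d)) else si[samples]
    if (anyNA(si)) stop("unknown sample id in subset")
  }
  genotype_dataset(d$variants[vi, , drop = FALSE],
                   d$samples[si, , drop = FALSE],
                   d$calls[vi, si, drop = FALSE])
}

#' Read a delimited phenotype/covariate table
#'
#' Reads a whitespace- or tab-delimited table with a header row and returns a
#' data.frame keyed by a sample-id column.
#'
#' @param path File path.
#' @param id_col Name of the sample id column (default \code{"sample_id"}).
#' @return data.frame with the id column first.
#' @export
read_phenotype_table <- function(path, id_col = "sample_id") {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!id_col %in% names(tab))
    stop("phenotype table lacks id column '", id_col, "'")
  tab[, c(id_col, setdiff(names(tab), id_col)), drop = FALSE]
}

#' Write a phenotype/covariate table
#'
#' @param tab data.frame to write.
#' @param path Output path; tab-separated with header, no quotes.
#' @return Invisibly, \code{path}.
#' @export
write_phenotype_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
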