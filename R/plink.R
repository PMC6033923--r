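# PLINK-1 binary trio codec.
#
# .bed layout (SNP-major): 3 magic bytes 0x6c 0x1b 0x01, then one row of
# ceiling(n_samples / 4) bytes per variant. Two bits per genotype, sample
# order within a byte runs from the lowest-order bit pair upwards:
#   00 homozygous allele1 (dosage 2)   01 missing
#   10 heterozygous       (dosage 1)   11 homozygous allele2 (dosage 0)

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# byte value (0..255) -> 4 dosages; built once at load time
.bed_decode_table <- local({
  two_bit <- c(2L, NA_integer_, 1L, 0L)      # indexed by bit pair value + 1
  m <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255) {
    v <- b
    for (k in 1:4) {
      m[b + 1L, k] <- two_bit[v %% 4L + 1L]
      v <- v %/% 4L
    }
  }
  m
})

.dosage_to_code <- function(x) {
  # dosage (0,1,2,NA) -> two-bit code value
  code <- integer(length(x))
  code[is.na(x)] <- 1L
  code[!is.na(x) & x == 2L] <- 0L
  code[!is.na(x) & x == 1L] <- 2L
  code[!is.na(x) & x == 0L] <- 3L
  code
}

#' Read a PLINK-1 binary fileset
#'
#' Reads \code{prefix.bed}, \code{prefix.bim} and \code{prefix.fam} into a
#' \code{\link{genotype_dataset}}. Only SNP-major .bed files are supported
#' (the only mode modern tools write). Missing genotypes are preserved as
#' \code{NA}; dosage counts the A1 allele of the \code{.bim} file.
#'
#' @param prefix Path prefix of the fileset (no extension).
#' @return A \code{genotype_dataset}.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing file: ", f)

  bim_tab <- utils::read.table(bim, stringsAsFactors = FALSE,
                               col.names = c("chrom", "id", "cm", "pos",
                                             "allele1", "allele2"),
                               colClasses = c("character", "character",
                                              "numeric", "integer",
                                              "character", "character"))
  fam_tab <- utils::read.table(fam, stringsAsFactors = FALSE,
                               col.names = c("fid", "iid", "pat", "mat",
                                             "sex", "pheno"))
  m <- nrow(bim_tab)
  n <- nrow(fam_tab)
  bytes_per_variant <- ceiling(n / 4)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || !identical(raw[1:3], .bed_magic))
    stop("not a PLINK-1 SNP-major .bed file (bad magic bytes): ", bed)
  payload <- raw[-(1:3)]
  expected <- bytes_per_variant * m
  if (length(payload) != expected)
    stop(".bed payload length ", length(payload), " != expected ", expected,
         " (= ceiling(n/4) * m); truncated or mismatched fileset")

  calls <- matrix(NA_integer_, nrow = m, ncol = n)
  if (m > 0 && n > 0) {
    byte_mat <- matrix(as.integer(payload), nrow = bytes_per_variant, ncol = m)
    # decode all bytes to 4 genotypes each, then trim padding
    dec <- .bed_decode_table[byte_mat + 1L, , drop = FALSE]  # (bytes*m) x 4
    # dec rows iterate over byte_mat column-major: bytes within variant fastest
    geno <- matrix(t(dec), nrow = 4L * bytes_per_variant, ncol = m)
    calls <- t(geno[seq_len(n), , drop = FALSE])
  }

  variants <- data.frame(id = bim_tab$id, chrom = bim_tab$chrom,
                         pos = bim_tab$pos, allele1 = bim_tab$allele1,
                         allele2 = bim_tab$allele2,
                         stringsAsFactors = FALSE)
  samples <- data.frame(fid = as.character(fam_tab$fid),
                        iid = as.character(fam_tab$iid),
                        sex = fam_tab$sex, pheno = fam_tab$pheno,
                        stringsAsFactors = FALSE)
  genotype_dataset(variants, samples, calls)
}

#' Write a PLINK-1 binary fileset
#'
#' Inverse of \code{\link{read_plink}}: \code{read_plink(write_plink(d, p))}
#' reproduces \code{d}'s variants, samples and calls in order.
#'
#' @param d A \code{genotype_dataset}.
#' @param prefix Output path prefix.
#' @return Invisibly, \code{prefix}.
#' @export
write_plink <- function(d, prefix) {
  stopifnot(inherits(d, "genotype_dataset"))
  m <- nrow(d$variants)
  n <- nrow(d$samples)
  bytes_per_variant <- ceiling(n / 4)

  bim <- data.frame(chrom = d$variants$chrom, id = d$variants$id,
                    cm = rep(0, m), pos = d$variants$pos,
                    a1 = d$variants$allele1, a2 = d$variants$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sex <- if (is.null(d$samples$sex)) rep(0L, n) else d$samples$sex
  pheno <- if (is.null(d$samples$pheno)) rep(-9L, n) else d$samples$pheno
  fam <- data.frame(fid = d$samples$fid, iid = d$samples$iid,
                    pat = 0L, mat = 0L, sex = sex, pheno = pheno)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  if (m > 0 && bytes_per_variant > 0) {
    # pad sample dimension to a multiple of 4 with dosage-0 (code 3 is
    # conventional padding is 0 bits; PLINK pads with zero bits = code 0?
    # PLINK pads with zeroes, decoded as hom-A1 but ignored on read)
    pad <- 4L * bytes_per_variant - n
    codes <- .dosage_to_code(as.vector(t(d$calls)))          # sample-fastest
    code_mat <- matrix(codes, nrow = n, ncol = m)
    if (pad > 0)
      code_mat <- rbind(code_mat, matrix(0L, nrow = pad, ncol = m))
    i1 <- seq(1, 4L * bytes_per_variant, by = 4)
    bytes <- code_mat[i1, , drop = FALSE] +
      4L * code_mat[i1 + 1L, , drop = FALSE] +
      16L * code_mat[i1 + 2L, , drop = FALSE] +
      64L * code_mat[i1 + 3L, , drop = FALSE]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}
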