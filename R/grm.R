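# Genomic relationship matrix and ancestry principal components.

#' Compute the genomic relationship matrix
#'
#' Standard allele-frequency-standardised estimator of pairwise additive
#' relatedness: for samples j and k,
#' \deqn{G_{jk} = \frac{1}{m_{jk}} \sum_i
#'   \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)}}
#' where the sum runs over variants non-missing in both samples and
#' \eqn{m_{jk}} is the count of such variants (pairwise-complete handling,
#' which keeps the diagonal unbiased under missingness). Monomorphic
#' variants carry no relatedness information and are skipped with a warning.
#'
#' @param d A \code{genotype_dataset}.
#' @param freqs Optional vector of allele1 frequencies to standardise with
#'   (one per variant). By default frequencies are estimated in-sample; a
#'   supplied vector lets two merged cohorts share one scaling.
#' @return Object of class \code{grm}: \code{values} (n x n symmetric),
#'   \code{n_snps} (per-pair non-missing variant counts),
#'   \code{sample_ids}.
#' @export
compute_grm <- function(d, freqs = NULL) {
  stopifnot(inherits(d, "genotype_dataset"))
  x <- d$calls                                   # variants x samples
  p <- if (is.null(freqs)) rowMeans(x, na.rm = TRUE) / 2 else freqs
  if (length(p) != nrow(x)) stop("freqs length must equal variant count")
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic variants")
  if (any(!poly))
    warning(sum(!poly), " monomorphic variant(s) skipped in GRM")
  x <- x[poly, , drop = FALSE]
  p <- p[poly]

  w <- (x - 2 * p) / sqrt(2 * p * (1 - p))       # standardised dosage
  obs <- !is.na(w)
  w[!obs] <- 0
  num <- crossprod(w)                            # sum over shared variants
  m_jk <- crossprod(obs * 1L)
  if (any(diag(m_jk) == 0))
    stop("sample(s) with zero usable genotypes: ",
         paste(utils::head(colnames(x)[diag(m_jk) == 0]), collapse = ", "))
  values <- num / pmax(m_jk, 1L)
  values[m_jk == 0] <- 0
  structure(list(values = values, n_snps = m_jk,
                 sample_ids = colnames(d$calls)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat("grm:", n, "samples,", max(x$n_snps), "variants\n")
  cat(sprintf("  mean diagonal %.4f; off-diagonal range [%.4f, %.4f]\n",
              mean(diag(x$values)),
              if (length(off)) min(off) else NA_real_,
              if (length(off)) max(off) else NA_real_))
  invisible(x)
}

#' Subset a GRM by sample id or index
#'
#' @param grm A \code{grm}.
#' @param ids Character ids or indices to keep, in the requested order.
#' @return A \code{grm} over the requested samples.
#' @export
subset_grm <- function(grm, ids) {
  i <- if (is.character(ids)) match(ids, grm$sample_ids) else ids
  if (anyNA(i)) stop("unknown sample id in GRM subset")
  structure(list(values = grm$values[i, i, drop = FALSE],
                 n_snps = grm$n_snps[i, i, drop = FALSE],
                 sample_ids = grm$sample_ids[i]),
            class = "grm")
}

#' Principal components of a GRM
#'
#' Eigen-decomposes the double-centred relationship matrix (the conventional
#' source of ancestry PCs) and returns the top-k score matrix, each column
#' scaled by the square root of its eigenvalue. Sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param grm A \code{grm}.
#' @param k Number of components (default 20, capped at n).
#' @return list of class \code{grm_pca}: \code{scores} (n x k, rownames =
#'   sample ids), \code{eigenvalues} (non-increasing).
#' @export
grm_pca <- function(grm, k = 20) {
  G <- grm$values
  n <- nrow(G)
  if (k > n) stop("k must not exceed the sample count")
  Gc <- sweep(G, 1, rowMeans(G))
  Gc <- sweep(Gc, 2, colMeans(Gc))
  eig <- eigen(Gc, symmetric = TRUE)
  val <- eig$values[seq_len(k)]
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(vec[, j]))
    if (vec[lead, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- sweep(vec, 2, sqrt(pmax(val, 0)), `*`)
  rownames(scores) <- grm$sample_ids
  structure(list(scores = scores, eigenvalues = val), class = "grm_pca")
}

#' Write a GRM in the three-file lower-triangle convention
#'
#' Serialises \code{prefix.grm.bin} (single-precision packed lower triangle,
#' diagonal included), \code{prefix.grm.N.bin} (per-pair variant counts) and
#' \code{prefix.grm.id} (tab-separated family/individual ids), the layout
#' standard REML tools exchange.
#'
#' @param grm A \code{grm}.
#' @param prefix Output path prefix.
#' @return Invisibly, \code{prefix}.
#' @export
write_grm <- function(grm, prefix) {
  n <- nrow(grm$values)
  lt <- which(lower.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  ord <- order(lt[, 1], lt[, 2])               # row-major over the triangle
  vals <- grm$values[lt[ord, , drop = FALSE]]
  cnts <- grm$n_snps[lt[ord, , drop = FALSE]]
  writeBin(as.numeric(vals), paste0(prefix, ".grm.bin"), size = 4)
  writeBin(as.numeric(cnts), paste0(prefix, ".grm.N.bin"), size = 4)
  # split fid from iid at the FIRST underscore only (iids may contain more)
  has_us <- grepl("_", grm$sample_ids)
  ids <- cbind(ifelse(has_us, sub("_.*$", "", grm$sample_ids),
                      grm$sample_ids),
               ifelse(has_us, sub("^[^_]*_", "", grm$sample_ids),
                      grm$sample_ids))
  utils::write.table(ids, paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a three-file lower-triangle GRM
#'
#' @param prefix Path prefix written by \code{\link{write_grm}} (or a
#'   compatible tool).
#' @return A \code{grm}.
#' @export
read_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)
  n <- nrow(ids)
  n_lt <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = n_lt, size = 4)
  cnts <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = n_lt, size = 4)
  V <- matrix(0, n, n)
  idx <- cbind(rep(seq_len(n), times = seq_len(n)),
               unlist(lapply(seq_len(n), seq_len)))
  V[idx] <- vals
  V[idx[, c(2, 1)]] <- vals
  Nm <- matrix(0, n, n)
  Nm[idx] <- cnts
  Nm[idx[, c(2, 1)]] <- cnts
  sid <- paste(ids[, 1], ids[, 2], sep = "_")
  dimnames(V) <- dimnames(Nm) <- list(sid, sid)
  structure(list(values = V, n_snps = Nm, sample_ids = sid), class = "grm")
}
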