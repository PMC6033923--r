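# The U-shape analysis: a fixed quadratic transform maps age at first birth
# (AFB) to a relative-risk-scale response, which is then regressed on a
# polygenic score with covariates. The default transform coefficients are
# the published registry-derived polynomial relating maternal age to
# offspring psychotic-disorder risk; they are treated as given constants.

.ushape_default_coef <- c(c0 = 2.7214, c1 = -0.1105, c2 = 0.0018)

#' Quadratic response transform of age at first birth
#'
#' Evaluates \eqn{z = c_0 + c_1 X + c_2 X^2} at the supplied ages. With the
#' default coefficients the curve is U-shaped: decreasing up to
#' \eqn{-c_1 / (2 c_2) \approx 30.69} years and increasing after, encoding
#' elevated offspring risk at both early and late maternal ages.
#'
#' @param afb Ages at first birth in years (all \code{>= 0}).
#' @param coefficients Named or positional numeric length-3 vector
#'   \code{(c0, c1, c2)}.
#' @return Numeric vector of transformed values.
#' @export
response_transform <- function(afb, coefficients = .ushape_default_coef) {
  if (any(afb < 0, na.rm = TRUE)) stop("age at first birth must be >= 0")
  stopifnot(length(coefficients) == 3)
  coefficients <- unname(coefficients)
  coefficients[1] + coefficients[2] * afb + coefficients[3] * afb^2
}

#' Regress the response transform on a polygenic score
#'
#' Multiple linear regression of \code{z} on the PRS plus covariates, on
#' complete cases (listwise deletion, counts logged). The reported
#' \code{r_squared} is the incremental R-squared of the PRS term
#' (\eqn{R^2_{full} - R^2_{covariates}}), since with many covariates the
#' PRS contribution is only interpretable as an increment; the full-model
#' R-squared is also returned. The p-value is the two-sided t-test on the
#' PRS coefficient.
#'
#' @param z Response values (e.g. from \code{\link{response_transform}}).
#' @param prs Polygenic score, one value per sample.
#' @param covariates Optional matrix/data.frame; factors are one-hot encoded
#'   with a reference level, collinear columns dropped with a warning.
#' @param standardize_prs Z-score the PRS before fitting (default TRUE;
#'   affects the coefficient scale, not the p-value).
#' @return list of class \code{response_regression}: \code{beta_prs},
#'   \code{se}, \code{p}, \code{r_squared} (incremental),
#'   \code{r_squared_full}, \code{n}, \code{n_dropped}.
#' @export
regress_response_on_prs <- function(z, prs, covariates = NULL,
                                    standardize_prs = TRUE) {
  stopifnot(length(z) == length(prs))
  C <- if (is.null(covariates)) NULL else .design_matrix(as.data.frame(covariates))
  keep <- !is.na(z) & !is.na(prs)
  if (!is.null(C)) keep <- keep & rowSums(is.na(C)) == 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " incomplete record(s) dropped")
  z <- z[keep]; prs <- prs[keep]
  if (!is.null(C)) C <- C[keep, , drop = FALSE]
  if (standardize_prs) prs <- (prs - mean(prs)) / stats::sd(prs)

  X0 <- cbind(intercept = rep(1, length(z)), C)
  X0 <- .drop_collinear(X0)
  X1 <- .drop_collinear(cbind(X0, prs = prs))
  if (!"prs" %in% colnames(X1))
    stop("PRS is collinear with the covariates; effect not estimable")
  fit1 <- stats::lm.fit(X1, z)
  fit0 <- stats::lm.fit(X0, z)
  rss1 <- sum(fit1$residuals^2)
  rss0 <- sum(fit0$residuals^2)
  tss <- sum((z - mean(z))^2)
  df <- length(z) - ncol(X1)
  if (df <= 0) stop("more parameters than observations")
  sigma2 <- rss1 / df
  XtXi <- chol2inv(chol(crossprod(X1)))
  j <- match("prs", colnames(X1))
  beta <- unname(fit1$coefficients[j])
  se <- sqrt(sigma2 * XtXi[j, j])
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  structure(list(
    beta_prs = unname(beta), se = se, p = p,
    r_squared = if (tss > 0) (rss0 - rss1) / tss else 0,
    r_squared_full = if (tss > 0) 1 - rss1 / tss else 0,
    n = length(z), n_dropped = n_dropped, df = df
  ), class = "response_regression")
}

#' @export
print.response_regression <- function(x, ...) {
  cat(sprintf(
    "PRS -> response regression: beta %.4g (SE %.3g), p = %.3g\n",
    x$beta_prs, x$se, x$p))
  cat(sprintf("  incremental R^2 %.3g (full-model %.3g), n = %d\n",
              x$r_squared, x$r_squared_full, x$n))
  invisible(x)
}

#' Stratify women into younger/older AFB groups
#'
#' @param afb Ages at first birth.
#' @param cutpoint Years; the default 26 is the integer cohort mean used in
#'   the stratified analyses. \code{"mean"} recomputes the sample mean
#'   (rounded to the nearest integer) instead.
#' @return factor with levels \code{younger} (\code{afb < cutpoint}) and
#'   \code{older} (\code{afb >= cutpoint}).
#' @export
stratify_by_afb <- function(afb, cutpoint = 26) {
  if (identical(cutpoint, "mean")) cutpoint <- round(mean(afb, na.rm = TRUE))
  g <- factor(ifelse(afb < cutpoint, "younger", "older"),
              levels = c("younger", "older"))
  if (any(table(g) == 0))
    warning("empty AFB stratum at cutpoint ", cutpoint)
  g
}

.afb_breaks <- c(0, 20, 25, 30, 35, Inf)
.afb_labels <- c("<20", "20-<25", "25-<30", "30-<35", ">=35")

#' Mean polygenic score by AFB bin
#'
#' Summarises a (standardised) PRS within the conventional five AFB bins.
#'
#' @param prs Polygenic score values.
#' @param afb Ages at first birth (same length).
#' @return data.frame: \code{bin}, \code{mean_prs}, \code{se} (sd/sqrt(n);
#'   \code{NA} for bins with fewer than 2 members), \code{n}.
#' @export
bin_prs_by_afb <- function(prs, afb) {
  stopifnot(length(prs) == length(afb))
  bin <- cut(afb, breaks = .afb_breaks, labels = .afb_labels, right = FALSE)
  out <- lapply(.afb_labels, function(lb) {
    v <- prs[!is.na(bin) & bin == lb]
    data.frame(bin = lb, mean_prs = if (length(v)) mean(v) else NA_real_,
               se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare mean PRS between two AFB bins
#'
#' Two-sided Welch (unequal-variance) two-sample t-test on the raw PRS
#' values of two groups.
#'
#' @param prs_a,prs_b Numeric PRS values of the two groups (each n >= 2).
#' @return p-value.
#' @export
compare_bins <- function(prs_a, prs_b) {
  if (length(prs_a) < 2 || length(prs_b) < 2)
    stop("both groups need at least 2 members")
  if (stats::sd(prs_a) == 0 && stats::sd(prs_b) == 0)
    stop("degenerate variance in both groups")
  stats::t.test(prs_a, prs_b)$p.value
}

#' Sensitivity re-fit with additional covariates
#'
#' Re-runs \code{\link{regress_response_on_prs}} with lifestyle /
#' socioeconomic covariates (education, income, smoking, alcohol status in
#' the motivating analysis) appended to the design; incomplete records are
#' dropped and counted, since such covariates typically shrink the sample.
#'
#' @param z,prs,covariates As \code{\link{regress_response_on_prs}}.
#' @param extra Matrix/data.frame of additional adjustment covariates.
#' @return A \code{response_regression}.
#' @export
sensitivity_adjust <- function(z, prs, covariates = NULL, extra) {
  E <- as.data.frame(extra)
  all_missing <- vapply(E, function(c) all(is.na(c)), logical(1))
  if (any(all_missing))
    stop("extra covariate(s) entirely missing: ",
         paste(names(E)[all_missing], collapse = ", "))
  C <- if (is.null(covariates)) E else cbind(as.data.frame(covariates), E)
  regress_response_on_prs(z, prs, C)
}
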