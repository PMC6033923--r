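# Genomic BLUP: predicted genetic values for samples in the GRM, including
# those with no phenotype (the profile of a disease score in an independent
# cohort is the leading use).

#' Predict genetic values (GBLUP) from a REML fit
#'
#' For a single-trait fit with observed records \eqn{y} on samples
#' \eqn{o} and any target samples \eqn{\tau} in the GRM,
#' \deqn{\hat u_\tau = \sigma_g^2 G_{\tau o} V_o^{-1} (y - X \hat b),
#'   \qquad V_o = \sigma_g^2 G_{oo} + \sigma_e^2 I,}
#' with \eqn{\hat b} the generalised least-squares fixed effects. The
#' prediction error variance reported per target ignores fixed-effect
#' uncertainty (the standard large-n proxy).
#'
#' @param object A single-trait \code{greml} fit.
#' @param grm The \code{grm} used in fitting (supplies relationships of
#'   targets to the observed samples).
#' @param targets Character ids (or indices into the GRM) to predict;
#'   default all GRM samples, phenotyped or not.
#' @param trait Trait index to predict from (default 1).
#' @param ... Unused.
#' @return data.frame of class \code{blup_solution}: \code{id}, \code{u}
#'   (predicted genetic value), \code{pev} (prediction error variance),
#'   \code{reliability}.
#' @export
predict.greml <- function(object, grm, targets = NULL, trait = 1, ...) {
  stopifnot(inherits(grm, "grm"))
  lay <- object$layout
  kg <- lay$idx_gvar[trait]
  ke <- lay$idx_evar[trait]
  sg2 <- object$theta[kg]
  se2 <- object$theta[ke]
  blk <- object$blocks[[trait]]
  obs <- match(blk$ids, grm$sample_ids)
  if (anyNA(obs)) stop("fit and GRM sample ids disagree")
  if (is.null(targets)) targets <- grm$sample_ids
  tgt <- if (is.character(targets)) match(targets, grm$sample_ids) else targets
  if (anyNA(tgt)) stop("unknown target sample id")

  Goo <- grm$values[obs, obs, drop = FALSE]
  Gto <- grm$values[tgt, obs, drop = FALSE]
  Gtt <- diag(grm$values)[tgt]

  if (object$boundary[kg] || sg2 <= 0) {
    warning("genetic variance at zero; all predictions are 0")
    return(structure(data.frame(id = grm$sample_ids[tgt], u = 0, pev = 0,
                                reliability = 0),
                     class = c("blup_solution", "data.frame")))
  }
  V <- sg2 * Goo
  diag(V) <- diag(V) + se2
  ch <- chol(V)
  Vi <- chol2inv(ch)
  X <- blk$X
  XtViX <- crossprod(X, Vi %*% X)
  b <- solve(XtViX, crossprod(X, Vi %*% blk$y))
  resid <- blk$y - drop(X %*% b)
  Vir <- drop(Vi %*% resid)
  u <- sg2 * drop(Gto %*% Vir)
  # PEV_i = sg2*G_ii - sg2^2 * g_i' V^-1 g_i
  ViGt <- Vi %*% t(Gto)
  quad <- colSums(t(Gto) * ViGt)
  pev <- pmax(sg2 * Gtt - sg2^2 * quad, 0)
  rel <- ifelse(sg2 * Gtt > 0, 1 - pev / (sg2 * Gtt), 0)
  structure(data.frame(id = grm$sample_ids[tgt], u = u, pev = pev,
                       reliability = rel, stringsAsFactors = FALSE),
            class = c("blup_solution", "data.frame"))
}
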