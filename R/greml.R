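# Multi-trait genomic REML (average-information algorithm with EM warm-up).
#
# The model is the linear mixed model per trait t
#     y_t = X_t b_t + g_t + e_t,    g ~ N(0, Sigma_g (x) G),  e_t ~ N(0, I se2_t)
# where traits are recorded on sample sets that may be disjoint (the design
# used when one cohort carries the disease phenotype and another the
# quantitative trait). With disjoint samples residual covariances are
# structurally zero, so the parameters are the per-trait genetic variances,
# the pairwise genetic covariances, and the per-trait residual variances.

#' Bundle a phenotype with its covariates
#'
#' @param trait Character trait label.
#' @param ids Sample ids (must appear in the GRM used for fitting).
#' @param y Numeric phenotype (0/1 for a case-control trait analysed on the
#'   observed scale, continuous otherwise).
#' @param X Optional covariate matrix (an intercept is added if absent);
#'   collinear columns are dropped with a warning.
#' @return list of class \code{phenotype_block}.
#' @export
phenotype_block <- function(trait, ids, y, X = NULL) {
  stopifnot(length(ids) == length(y))
  if (is.null(X)) X <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(c) all(c == c[1]))))
    X <- cbind(intercept = 1, X)
  stopifnot(nrow(X) == length(y))
  keep <- !is.na(y) & rowSums(is.na(X)) == 0
  if (any(!keep))
    message(sum(!keep), " record(s) with missing phenotype/covariates dropped")
  X <- X[keep, , drop = FALSE]
  X <- .drop_collinear(X)
  structure(list(trait = trait, ids = as.character(ids)[keep],
                 y = as.numeric(y)[keep], X = X),
            class = "phenotype_block")
}

.drop_collinear <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping collinear covariate column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  X
}

#' Residualise a phenotype on covariates
#'
#' Ordinary least-squares residuals of \code{y} on \code{X} (intercept added
#' if absent), the usual pre-adjustment before variance-component analysis.
#' Residuals have mean exactly zero.
#'
#' @param y Numeric response.
#' @param X Covariate matrix or data.frame; factors are expanded to
#'   treatment-coded dummies.
#' @return Numeric vector of residuals.
#' @export
residualize <- function(y, X = NULL) {
  if (is.null(X)) return(y - mean(y))
  X <- .design_matrix(X)
  if (!any(apply(X, 2, function(c) all(c == c[1])))) X <- cbind(1, X)
  X <- .drop_collinear(X)
  stats::lm.fit(X, y)$residuals
}

.design_matrix <- function(X) {
  if (is.data.frame(X))
    X <- stats::model.matrix(~ . - 1, data = X)
  as.matrix(X)
}

# ---- parameter bookkeeping -------------------------------------------------

.vc_layout <- function(n_traits) {
  pairs <- if (n_traits > 1) utils::combn(n_traits, 2) else
    matrix(integer(), 2, 0)
  list(
    n_traits = n_traits,
    n_gvar = n_traits,
    pairs = pairs,
    k = 2L * n_traits + ncol(pairs),
    idx_gvar = seq_len(n_traits),
    idx_gcov = n_traits + seq_len(ncol(pairs)),
    idx_evar = n_traits + ncol(pairs) + seq_len(n_traits)
  )
}

.vc_names <- function(layout, traits) {
  c(paste0("Vg(", traits, ")"),
    if (ncol(layout$pairs))
      paste0("Cg(", traits[layout$pairs[1, ]], ",",
             traits[layout$pairs[2, ]], ")"),
    paste0("Ve(", traits, ")"))
}

# ---- fitting ---------------------------------------------------------------

#' Fit single- or multi-trait genomic REML
#'
#' Restricted maximum-likelihood estimation of genetic and residual
#' (co)variances from a genomic relationship matrix, by average-information
#' updates after a few EM warm-up iterations. Out-of-bounds proposals are
#' handled by step halving and by clamping variances at a small positive
#' boundary (1e-6 of the phenotypic variance, flagged in the result). The
#' sampling covariance of the estimates is the inverse average-information
#' matrix at the optimum.
#'
#' @param grm A \code{\link{compute_grm}} result covering every phenotyped
#'   sample.
#' @param blocks A \code{\link{phenotype_block}} or list of up to three
#'   blocks; sample sets may be disjoint (residual covariances are then
#'   structurally zero and are not estimated).
#' @param tol Convergence tolerance on the maximum relative parameter change
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 100); non-convergence is an error
#'   carrying the trajectory.
#' @param n_em Number of EM warm-up iterations (default 3).
#' @param verbose Print the likelihood trajectory.
#' @return Object of class \code{greml} with components \code{theta} (named
#'   estimates), \code{ase} (inverse-AI sampling covariance), \code{grad}
#'   (score at the optimum), \code{logLik}, \code{trajectory},
#'   \code{boundary} (logical flags), plus the data layout needed by
#'   \code{predict}.
#' @export
fit_greml <- function(grm, blocks, tol = 1e-6, max_iter = 100L, n_em = 3L,
                      verbose = FALSE) {
  stopifnot(inherits(grm, "grm"))
  if (inherits(blocks, "phenotype_block")) blocks <- list(blocks)
  T_ <- length(blocks)
  if (T_ < 1 || T_ > 3) stop("1 to 3 phenotype blocks supported")

  idx <- lapply(blocks, function(b) {
    i <- match(b$ids, grm$sample_ids)
    if (anyNA(i)) stop("phenotyped sample(s) absent from GRM in trait ",
                       b$trait)
    i
  })
  n_t <- vapply(idx, length, integer(1))
  offs <- cumsum(c(0L, n_t))
  rows <- lapply(seq_len(T_), function(t) offs[t] + seq_len(n_t[t]))
  n <- sum(n_t)
  y <- unlist(lapply(blocks, `[[`, "y"))
  X <- matrix(0, n, sum(vapply(blocks, function(b) ncol(b$X), integer(1))))
  cstart <- 0L
  for (t in seq_len(T_)) {
    X[rows[[t]], cstart + seq_len(ncol(blocks[[t]]$X))] <- blocks[[t]]$X
    cstart <- cstart + ncol(blocks[[t]]$X)
  }
  # genetic sub-blocks of the GRM, upper-triangle including diagonal
  Gb <- vector("list", T_ * T_)
  dim(Gb) <- c(T_, T_)
  for (t in seq_len(T_)) for (s in t:T_)
    Gb[[t, s]] <- grm$values[idx[[t]], idx[[s]], drop = FALSE]

  lay <- .vc_layout(T_)
  traits <- vapply(blocks, `[[`, character(1), "trait")
  vp <- vapply(seq_len(T_), function(t)
    stats::var(stats::lm.fit(blocks[[t]]$X, blocks[[t]]$y)$residuals),
    numeric(1))
  floor_v <- 1e-6 * vp
  theta <- numeric(lay$k)
  theta[lay$idx_gvar] <- 0.5 * vp
  theta[lay$idx_evar] <- 0.5 * vp
  names(theta) <- .vc_names(lay, traits)

  assemble_V <- function(th) {
    V <- matrix(0, n, n)
    for (t in seq_len(T_)) {
      V[rows[[t]], rows[[t]]] <- th[lay$idx_gvar[t]] * Gb[[t, t]]
      dtt <- rows[[t]]
      V[cbind(dtt, dtt)] <- V[cbind(dtt, dtt)] + th[lay$idx_evar[t]]
    }
    for (q in seq_len(ncol(lay$pairs))) {
      t <- lay$pairs[1, q]; s <- lay$pairs[2, q]
      blk <- th[lay$idx_gcov[q]] * Gb[[t, s]]
      V[rows[[t]], rows[[s]]] <- blk
      V[rows[[s]], rows[[t]]] <- t(blk)
    }
    V
  }

  # multiply V_k (the derivative of V wrt component k) into a vector
  mult_Vk <- function(k, v) {
    out <- numeric(n)
    if (k %in% lay$idx_gvar) {
      t <- match(k, lay$idx_gvar)
      out[rows[[t]]] <- Gb[[t, t]] %*% v[rows[[t]]]
    } else if (k %in% lay$idx_gcov) {
      q <- match(k, lay$idx_gcov)
      t <- lay$pairs[1, q]; s <- lay$pairs[2, q]
      out[rows[[t]]] <- Gb[[t, s]] %*% v[rows[[s]]]
      out[rows[[s]]] <- crossprod(Gb[[t, s]], v[rows[[t]]])
    } else {
      t <- match(k, lay$idx_evar)
      out[rows[[t]]] <- v[rows[[t]]]
    }
    out
  }

  trace_PVk <- function(P, k) {
    if (k %in% lay$idx_gvar) {
      t <- match(k, lay$idx_gvar)
      sum(P[rows[[t]], rows[[t]]] * Gb[[t, t]])
    } else if (k %in% lay$idx_gcov) {
      q <- match(k, lay$idx_gcov)
      t <- lay$pairs[1, q]; s <- lay$pairs[2, q]
      2 * sum(P[rows[[t]], rows[[s]]] * Gb[[t, s]])
    } else {
      t <- match(k, lay$idx_evar)
      sum(diag(P)[rows[[t]]])
    }
  }

  reml_eval <- function(th) {
    V <- assemble_V(th)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      # near-singular proposal: ridge and retry once
      ch <- tryCatch(chol(V + diag(1e-6 * mean(diag(V)), n)),
                     error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      warning("covariance matrix not positive definite; ridge added")
    }
    logdetV <- 2 * sum(log(diag(ch)))
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chX <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chX)) return(NULL)
    logdetX <- 2 * sum(log(diag(chX)))
    W <- chol2inv(chX)                        # (X'V^-1X)^-1
    P <- Vi - ViX %*% W %*% t(ViX)
    Py <- drop(P %*% y)
    ll <- -0.5 * (logdetV + logdetX + sum(y * Py))
    U <- vapply(seq_len(lay$k), function(k) mult_Vk(k, Py), numeric(n))
    yPVPy <- drop(crossprod(Py, U))
    trv <- vapply(seq_len(lay$k), function(k) trace_PVk(P, k), numeric(1))
    grad <- -0.5 * (trv - yPVPy)
    PU <- P %*% U
    AI <- 0.5 * crossprod(U, PU)
    list(ll = ll, grad = grad, AI = AI, yPVPy = yPVPy, trv = trv,
         Vi = Vi, W = W, ViX = ViX, Py = Py, b = drop(W %*% crossprod(X, Vi %*% y)))
  }

  constrain <- function(th) {
    th[lay$idx_gvar] <- pmax(th[lay$idx_gvar], floor_v)
    th[lay$idx_evar] <- pmax(th[lay$idx_evar], floor_v)
    at_floor <- th[lay$idx_gvar] <= floor_v * (1 + 1e-9)
    for (q in seq_len(ncol(lay$pairs))) {
      t <- lay$pairs[1, q]; s <- lay$pairs[2, q]
      if (at_floor[t] || at_floor[s]) {
        # a boundary trait has no estimable genetic covariance
        th[lay$idx_gcov[q]] <- 0
      } else {
        # loose cap only (raw rg may exceed |1|, as in unconstrained REML
        # tools, so boundary tests of rg = 1 are not biased); positive
        # definiteness of V is enforced by the Cholesky guard instead
        lim <- 1.5 * sqrt(th[lay$idx_gvar[t]] * th[lay$idx_gvar[s]])
        th[lay$idx_gcov[q]] <- max(min(th[lay$idx_gcov[q]], lim), -lim)
      }
    }
    th
  }

  ev <- reml_eval(theta)
  if (is.null(ev)) stop("initial covariance matrix is singular")
  traj <- data.frame(iter = 0L, logLik = ev$ll, t(theta))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (iter <= n_em) {
      delta <- numeric(lay$k)
      for (t in seq_len(T_)) {
        kg <- lay$idx_gvar[t]; ke <- lay$idx_evar[t]
        delta[kg] <- theta[kg]^2 * (ev$yPVPy[kg] - ev$trv[kg]) / n_t[t]
        delta[ke] <- theta[ke]^2 * (ev$yPVPy[ke] - ev$trv[ke]) / n_t[t]
      }
      # EM leaves covariances at their current value during warm-up
    } else {
      # active set: components held at the zero boundary with the score
      # still pushing downwards are fixed and removed from the AI system,
      # which otherwise damps the steps of the free components
      at_floor <- logical(lay$k)
      at_floor[lay$idx_gvar] <- theta[lay$idx_gvar] <= floor_v * (1 + 1e-9)
      at_floor[lay$idx_evar] <- theta[lay$idx_evar] <= floor_v * (1 + 1e-9)
      pinned <- at_floor & ev$grad < 0
      for (q in seq_len(ncol(lay$pairs)))
        if (pinned[lay$idx_gvar[lay$pairs[1, q]]] ||
            pinned[lay$idx_gvar[lay$pairs[2, q]]])
          pinned[lay$idx_gcov[q]] <- TRUE
      free <- which(!pinned)
      delta <- numeric(lay$k)
      A <- ev$AI[free, free, drop = FALSE]
      A <- A + diag(1e-9 * mean(diag(A)), length(free))
      delta[free] <- tryCatch(solve(A, ev$grad[free]),
                              error = function(e) ev$grad[free] /
                                pmax(diag(ev$AI)[free], 1e-8))
    }
    # bound each proposed move so a near-singular AI matrix cannot fling
    # the parameters out of the admissible region entirely
    cap <- 10 * pmax(abs(theta), 0.1 * mean(vp))
    delta <- pmin(pmax(delta, -cap), cap)
    step <- 1
    stalled <- FALSE
    repeat {
      theta_new <- constrain(theta + step * delta)
      ev_new <- suppressWarnings(reml_eval(theta_new))
      # a step is only ever accepted if it does not lose likelihood
      # (beyond round-off); an exhausted line search means the current
      # point cannot be improved along this direction
      if (!is.null(ev_new) && ev_new$ll >= ev$ll - 1e-4) break
      step <- step / 2
      if (step < 1 / 4096) { stalled <- TRUE; break }
    }
    if (stalled) {
      # fall back to a damped EM move on the variances (uphill for small
      # enough damping), covariances shrunk toward zero
      delta_em <- numeric(lay$k)
      for (t in seq_len(T_)) {
        kg <- lay$idx_gvar[t]; ke <- lay$idx_evar[t]
        delta_em[kg] <- theta[kg]^2 * (ev$yPVPy[kg] - ev$trv[kg]) / n_t[t]
        delta_em[ke] <- theta[ke]^2 * (ev$yPVPy[ke] - ev$trv[ke]) / n_t[t]
      }
      delta_em[lay$idx_gcov] <- -0.05 * theta[lay$idx_gcov]
      theta_new <- constrain(theta + 0.5 * delta_em)
      ev_new <- suppressWarnings(reml_eval(theta_new))
      if (is.null(ev_new) || ev_new$ll < ev$ll - 1e-4) {
        # no admissible uphill move exists: the likelihood is maximised
        # (possibly at a constraint boundary); stop here
        converged <- TRUE
        break
      }
    }
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-8))
    theta <- theta_new
    ev <- ev_new
    traj <- rbind(traj, data.frame(iter = iter, logLik = ev$ll, t(theta)))
    if (verbose)
      message(sprintf("iter %3d logL %.6f max rel change %.2e",
                      iter, ev$ll, rel))
    # primary criterion: relative parameter change; secondary: a flat
    # restricted likelihood with parameters moving below sqrt(tol)
    # (components pinned at the boundary otherwise stall the strict test)
    dll <- abs(ev$ll - traj$logLik[nrow(traj) - 1])
    if (iter > n_em &&
        (rel < tol || (dll < max(tol, 1e-8) && rel < sqrt(tol)))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    err <- simpleError("REML did not converge")
    err$trajectory <- traj
    stop(err)
  }

  boundary <- logical(lay$k)
  boundary[lay$idx_gvar] <- theta[lay$idx_gvar] <= floor_v * (1 + 1e-9)
  boundary[lay$idx_evar] <- theta[lay$idx_evar] <= floor_v * (1 + 1e-9)
  ase <- tryCatch(solve(ev$AI), error = function(e) {
    warning("AI matrix singular at optimum; SEs unavailable")
    matrix(NA_real_, lay$k, lay$k)
  })
  dimnames(ase) <- list(names(theta), names(theta))

  structure(list(
    theta = theta, ase = ase, grad = ev$grad, AI = ev$AI,
    logLik = ev$ll, trajectory = traj, boundary = boundary,
    converged = converged, layout = lay, traits = traits,
    fixed = ev$b, n_records = n_t, tol = tol,
    blocks = blocks, grm_ids = grm$sample_ids, idx = idx,
    phen_var = vp
  ), class = "greml")
}

#' @export
print.greml <- function(x, ...) {
  cat("Genomic REML fit (", length(x$traits), " trait",
      if (length(x$traits) > 1) "s", "): ",
      paste(x$traits, collapse = ", "), "\n", sep = "")
  se <- sqrt(diag(x$ase))
  out <- data.frame(estimate = x$theta, SE = se)
  print(round(out, 4))
  cat(sprintf("logLik %.3f after %d iterations\n", x$logLik,
              max(x$trajectory$iter)))
  invisible(x)
}

#' @export
coef.greml <- function(object, ...) object$theta

#' @export
vcov.greml <- function(object, ...) object$ase

#' @export
logLik.greml <- function(object, ...) {
  structure(object$logLik, df = object$layout$k, class = "logLik")
}

#' @export
summary.greml <- function(object, ...) {
  lay <- object$layout
  se <- sqrt(diag(object$ase))
  h2 <- h2_estimates(object)
  rg <- NULL
  if (lay$n_traits > 1) {
    rg <- do.call(rbind, lapply(seq_len(ncol(lay$pairs)), function(q) {
      g <- genetic_correlation(object, lay$pairs[1, q], lay$pairs[2, q])
      data.frame(traits = paste(g$traits, collapse = ":"),
                 rg = g$rg, se = g$se)
    }))
  }
  structure(list(components = data.frame(estimate = object$theta, SE = se),
                 h2 = h2, rg = rg, logLik = object$logLik,
                 traits = object$traits),
            class = "summary.greml")
}

#' @export
print.summary.greml <- function(x, ...) {
  cat("Variance components:\n")
  print(round(x$components, 4))
  cat("\nSNP-heritability (observed scale):\n")
  print(transform(x$h2, h2 = round(h2, 4), se = round(se, 4)),
        row.names = FALSE)
  if (!is.null(x$rg)) {
    cat("\nGenetic correlations:\n")
    print(transform(x$rg, rg = round(rg, 4), se = round(se, 4)))
  }
  invisible(x)
}

#' Heritability estimates from a REML fit
#'
#' Observed-scale SNP-heritability per trait, \eqn{h^2 = Vg / (Vg + Ve)},
#' with delta-method standard errors from the AI sampling covariance.
#'
#' @param fit A \code{greml} object.
#' @return data.frame with columns \code{trait}, \code{h2}, \code{se}.
#' @export
h2_estimates <- function(fit) {
  lay <- fit$layout
  out <- lapply(seq_len(lay$n_traits), function(t) {
    kg <- lay$idx_gvar[t]; ke <- lay$idx_evar[t]
    vg <- fit$theta[kg]; ve <- fit$theta[ke]
    vp <- vg + ve
    grad <- numeric(lay$k)
    grad[kg] <- ve / vp^2
    grad[ke] <- -vg / vp^2
    se <- sqrt(drop(t(grad) %*% fit$ase %*% grad))
    data.frame(trait = fit$traits[t], h2 = vg / vp, se = se)
  })
  do.call(rbind, out)
}

#' Genetic correlation between two fitted traits
#'
#' \eqn{r_g = C_g(t_1, t_2) / \sqrt{V_g(t_1) V_g(t_2)}} with a delta-method
#' standard error that uses the full sampling covariance of the three
#' components (not an independence approximation). The raw estimate is kept
#' in the result; \code{rg} itself is projected onto [-1, 1].
#'
#' @param fit A \code{greml} fit of two or more traits.
#' @param t1,t2 Trait indices or labels.
#' @return list of class \code{genetic_correlation}: \code{rg}, \code{se},
#'   \code{raw}, \code{traits}.
#' @export
genetic_correlation <- function(fit, t1 = 1, t2 = 2) {
  lay <- fit$layout
  if (lay$n_traits < 2) stop("fit has fewer than two traits")
  if (is.character(t1)) t1 <- match(t1, fit$traits)
  if (is.character(t2)) t2 <- match(t2, fit$traits)
  lo <- min(t1, t2); hi <- max(t1, t2)
  q <- which(lay$pairs[1, ] == lo & lay$pairs[2, ] == hi)
  kg1 <- lay$idx_gvar[lo]; kg2 <- lay$idx_gvar[hi]; kc <- lay$idx_gcov[q]
  v1 <- fit$theta[kg1]; v2 <- fit$theta[kg2]; cg <- fit$theta[kc]
  if (v1 <= 0 || v2 <= 0 || any(fit$boundary[c(kg1, kg2)]))
    stop("genetic correlation undefined: a genetic variance is at zero")
  raw <- cg / sqrt(v1 * v2)
  grad <- numeric(lay$k)
  grad[kc] <- 1 / sqrt(v1 * v2)
  grad[kg1] <- -0.5 * cg / (v1^1.5 * sqrt(v2))
  grad[kg2] <- -0.5 * cg / (v2^1.5 * sqrt(v1))
  se <- sqrt(drop(t(grad) %*% fit$ase %*% grad))
  structure(list(rg = max(min(raw, 1), -1), se = se, raw = raw,
                 traits = fit$traits[c(lo, hi)]),
            class = "genetic_correlation")
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf("rg(%s, %s) = %.4f (SE %.4f)\n", x$traits[1], x$traits[2],
              x$rg, x$se))
  invisible(x)
}

#' Wald test for an estimate against a null value
#'
#' Compares \code{(estimate - null_value) / se} to the standard normal.
#'
#' @param estimate,se Point estimate and its standard error (\code{se > 0}).
#' @param null_value Null-hypothesis value (default 0).
#' @param tail \code{"two"} (default), \code{"upper"} or \code{"lower"}.
#' @return p-value.
#' @export
wald_test <- function(estimate, se, null_value = 0, tail = c("two", "upper",
                                                             "lower")) {
  tail <- match.arg(tail)
  if (!is.finite(se) || se <= 0) stop("se must be positive")
  z <- (estimate - null_value) / se
  switch(tail,
         two = 2 * stats::pnorm(-abs(z)),
         upper = stats::pnorm(z, lower.tail = FALSE),
         lower = stats::pnorm(z))
}

#' Transform observed-scale heritability to the liability scale
#'
#' Standard threshold-model transformation for an ascertained case-control
#' sample: \deqn{h^2_{lia} = h^2_{obs} \frac{K^2 (1-K)^2}{P(1-P)\,
#' \varphi(\Phi^{-1}(1-K))^2}} with population prevalence K and sample case
#' fraction P.
#'
#' @param h2_obs Observed-scale (0/1 regression) heritability.
#' @param K Population prevalence, in (0, 1).
#' @param P Sample case proportion, in (0, 1).
#' @return Liability-scale heritability.
#' @export
observed_to_liability_h2 <- function(h2_obs, K, P) {
  if (K <= 0 || K >= 1 || P <= 0 || P >= 1)
    stop("K and P must lie strictly between 0 and 1")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  h2_obs * K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
}
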