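# Direct (non-iterative) BayesC: recover per-SNP effective information from
# SNP-BLUP prediction error variances, form likelihood ratios and posterior
# QTL probabilities, convert them to SNP-specific variance weights, and solve
# the weighted component-space mixed-model equations.
#
# The single-SNP model behind the likelihood ratio is
#   y = 1 mu + b_j x_j + eps,   Var(eps) = R sigma_e2,
# where R = I + G_{-j}/sigma_e2 absorbs all other SNPs. R is never formed:
# the method reaches x_j' R^-1 x_j only through the SNP-BLUP PEV, assuming R
# is approximately independent of j.

.PP_FLOOR <- 1e-6
.COMPONENT_CAP <- 10000L

#' Effective information per SNP
#'
#' Inverts the single-SNP PEV identity
#' `PEV(b_j) = (x_j'R^-1 x_j + lambda_b)^{-1} sigma_e2` for the effective
#' number of records `c_j = x_j'R^-1 x_j` contributing to SNP j, using the
#' SNP-BLUP variance ratio because the PEV comes from the SNP-BLUP fit.
#'
#' @param pev per-SNP prediction error variances (all > 0).
#' @param lambda_b SNP-BLUP variance ratio.
#' @param sigma_e2 residual variance.
#' @return `c_j = sigma_e2 / pev_j - lambda_b`, clamped at 0 from below.
#' @export
effective_info <- function(pev, lambda_b, sigma_e2) {
  if (any(pev <= 0)) stop("PEV must be strictly positive")
  pmax(sigma_e2 / pev - lambda_b, 0)
}

#' Recover the single-SNP right-hand side
#'
#' The SNP-BLUP normal equation for SNP j reads
#' `(c_j + lambda_b) b_hat_j = x_j'R^-1(y - 1 mu)`; combining the effective
#' information and the SNP-BLUP estimate therefore returns the right-hand
#' side `rhs_j = (c_j + lambda_b) * b_hat_j` without ever forming R.
#'
#' @param c_j effective information from [effective_info()].
#' @param lambda_b SNP-BLUP variance ratio.
#' @param b_hat SNP-BLUP effect estimates.
#' @return per-SNP right-hand sides.
#' @export
rhs_from_blup <- function(c_j, lambda_b, b_hat) {
  (c_j + lambda_b) * b_hat
}

#' Log-likelihood ratio of a non-zero versus zero SNP effect
#'
#' `LLR_j = 0.5 * [log(lambda) - log(lambda + c_j)
#'                + (rhs_j^2 / sigma_e2) / (c_j + lambda)]`,
#' the difference of the two multivariate-normal log-likelihoods under
#' `b_j ~ N(0, sigma2)` and `b_j = 0`, with `lambda = sigma_e2 / sigma2`
#' the slab variance ratio.
#'
#' @param c_j effective information (>= 0).
#' @param rhs recovered right-hand sides.
#' @param lambda slab variance ratio `sigma_e2 / sigma2`.
#' @param sigma_e2 residual variance.
#' @return per-SNP log-likelihood ratios.
#' @export
log_likelihood_ratio <- function(c_j, rhs, lambda, sigma_e2) {
  stopifnot(lambda > 0, all(c_j >= 0))
  0.5 * (log(lambda) - log(lambda + c_j) + (rhs^2 / sigma_e2) / (c_j + lambda))
}

#' Posterior probability of a non-zero SNP effect
#'
#' Adds the prior log-odds to the likelihood ratio,
#' `LPPR_j = LLR_j + log(pi) - log(1 - pi)`, and maps through the logistic
#' function `PP_j = 1 / (1 + exp(-LPPR_j))` (computed with [plogis()], which
#' is stable for |LPPR| far beyond 700).
#'
#' @param llr log-likelihood ratios.
#' @param pi prior probability of a non-zero effect, in (0, 1).
#' @return list with `lppr` and `pp`.
#' @export
posterior_probability <- function(llr, pi) {
  if (pi <= 0 || pi >= 1) stop("pi must be strictly inside (0, 1)")
  lppr <- llr + log(pi) - log1p(-pi)
  list(lppr = lppr, pp = plogis(lppr))
}

#' Scaled per-SNP variance weights
#'
#' `D_j = PP_j * sigma2`, rescaled to `D~_j = D_j * k / sum(D_j)` so the
#' total prior SNP variance (`trace(D~) * sigma_b2 = k * sigma_b2`) matches
#' the SNP-BLUP analysis. Posterior probabilities are floored at `1e-6`
#' first so that the weighted system stays invertible.
#'
#' @param pp posterior probabilities.
#' @param sigma2 slab variance (cancels in the scaling but kept for the
#'   definition of `D_j`).
#' @return vector `d_tilde` with `sum(d_tilde) == length(pp)`.
#' @export
snp_variance_weights <- function(pp, sigma2 = 1) {
  pp <- pmin(pmax(pp, .PP_FLOOR), 1 - 1e-12)
  d <- pp * sigma2
  d * length(d) / sum(d)
}

#' Solve the weighted component-space mixed-model equations
#'
#' Solves `[S^2 + (V'DV)^{-1} lambda_b] s_c = S U'(y - 1 mu)` where
#' `D = diag(d_tilde)`. `W = V'DV` is accumulated blockwise over
#' chromosomes and factorized once (Cholesky, with a diagonal jitter of
#' `1e-10 * mean(diag(W))` applied only on failure and reported); the
#' factorization is returned so the back-transform can reuse it.
#'
#' @param msvd a `merged_svd` with at most 10,000 components.
#' @param y phenotypes (uncentered).
#' @param d_tilde per-SNP variance weights, all > 0.
#' @param lambda_b SNP-BLUP variance ratio.
#' @param mu overall mean; default [estimate_mu()].
#' @return list with `s_c` (component effects) and `w_inv` (`(V'DV)^{-1}`).
#' @export
solve_bayesc_components <- function(msvd, y, d_tilde, lambda_b,
                                    mu = estimate_mu(y)) {
  stopifnot(inherits(msvd, "merged_svd"))
  if (msvd$m > .COMPONENT_CAP) {
    stop("number of components (", msvd$m, ") exceeds the cap of ",
         .COMPONENT_CAP, "; truncate the per-chromosome SVDs harder")
  }
  if (length(d_tilde) != msvd$k) stop("d_tilde length does not match SNP count")
  if (any(d_tilde <= 0)) stop("d_tilde must be strictly positive")
  W <- msvd_weighted_gram(msvd, d_tilde)
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-10 * mean(diag(W))
    message("solve_bayesc_components: V'DV factorization failed, ",
            "retrying with diagonal jitter ", signif(jit, 3),
            " (consider a larger PP floor)")
    ch <- tryCatch(chol(W + diag(jit, nrow(W))), error = function(e) {
      stop("V'DV is numerically singular even after jitter; ",
           "increase the posterior-probability floor")
    })
  }
  w_inv <- chol2inv(ch)
  rhs <- msvd$d * as.numeric(crossprod(msvd$u, y - mu))
  M <- w_inv * lambda_b
  diag(M) <- diag(M) + msvd$d^2
  list(s_c = as.numeric(solve(M, rhs)), w_inv = w_inv)
}

#' Back-transform weighted component effects to BayesC SNP effects
#'
#' `b_c = D V (V'DV)^{-1} s_c`, the conditional-expectation back-transform
#' that reduces to `b = V s` at uniform weights and full-rank V.
#'
#' @param msvd a `merged_svd`.
#' @param d_tilde per-SNP variance weights.
#' @param s_c weighted component effects.
#' @param w_inv `(V'DV)^{-1}` as returned by [solve_bayesc_components()];
#'   recomputed when omitted.
#' @return vector of k BayesC SNP effects.
#' @export
bayesc_snp_effects <- function(msvd, d_tilde, s_c, w_inv = NULL) {
  stopifnot(inherits(msvd, "merged_svd"), length(s_c) == msvd$m)
  if (is.null(w_inv)) {
    W <- msvd_weighted_gram(msvd, d_tilde)
    w_inv <- chol2inv(chol(W))
  }
  d_tilde * msvd_vmult(msvd, as.numeric(w_inv %*% s_c))
}

#' Genomic estimated breeding values from SNP effects
#'
#' `gebv = X_target b`, where `X_target` must be standardized with the
#' reference-population allele frequencies so that effect estimates
#' transfer to descendant generations.
#'
#' @param effects k SNP effects.
#' @param x_target a [standardize()]d genotype object (or bare matrix).
#' @param snp_ids optional SNP ids the effects belong to; when both sides
#'   carry ids a mismatch is an error listing the missing SNPs.
#' @return per-individual breeding values.
#' @export
predict_gebv <- function(effects, x_target, snp_ids = NULL) {
  X <- if (inherits(x_target, "std_geno")) x_target$X else as.matrix(x_target)
  if (ncol(X) != length(effects)) {
    stop("effect vector length (", length(effects),
         ") does not match target SNP count (", ncol(X), ")")
  }
  if (!is.null(snp_ids) && inherits(x_target, "std_geno")) {
    missing_ids <- setdiff(snp_ids, x_target$map$id)
    if (length(missing_ids) > 0L) {
      stop("target genotypes lack ", length(missing_ids), " SNP(s): ",
           paste(head(missing_ids, 5L), collapse = ", "),
           if (length(missing_ids) > 5L) ", ..." else "")
    }
    if (!identical(snp_ids, x_target$map$id)) {
      stop("target SNP order differs from the effect SNP order")
    }
  }
  as.numeric(X %*% effects)
}

#' Direct BayesC fit
#'
#' Runs the full non-iterative chain: SNP-BLUP PEV -> effective
#' information -> recovered right-hand sides -> log-likelihood ratios ->
#' posterior probabilities -> scaled variance weights -> weighted
#' component solve -> BayesC SNP effects and training breeding values
#' (`U S s_c`).
#'
#' @param msvd a [svd_genotypes()] result.
#' @param y phenotypes.
#' @param cfg a [variance_config()].
#' @param blup optional precomputed [snp_blup()] fit on the same data.
#' @return object of class `bayesc_fit`: `mu`, `s_c`, `b_c`, `gebv_train`,
#'   and per-SNP `info` data.frame (`c_j`, `rhs`, `llr`, `lppr`, `pp`,
#'   `d_tilde`), plus `sum_pp`.
#' @export
bayesc_direct <- function(msvd, y, cfg, blup = NULL) {
  stopifnot(inherits(msvd, "merged_svd"), inherits(cfg, "variance_config"))
  if (is.null(blup)) blup <- snp_blup(msvd, y, cfg)
  c_j <- effective_info(blup$pev, cfg$lambda_b, cfg$sigma_e2)
  rhs <- rhs_from_blup(c_j, cfg$lambda_b, blup$b_hat)
  llr <- log_likelihood_ratio(c_j, rhs, cfg$lambda, cfg$sigma_e2)
  post <- posterior_probability(llr, cfg$pi)
  d_tilde <- snp_variance_weights(post$pp, cfg$sigma2)
  sol <- solve_bayesc_components(msvd, y, d_tilde, cfg$lambda_b, mu = blup$mu)
  b_c <- bayesc_snp_effects(msvd, d_tilde, sol$s_c, sol$w_inv)
  fit <- list(mu = blup$mu, s_c = sol$s_c, b_c = b_c,
              gebv_train = as.numeric(msvd$u %*% (msvd$d * sol$s_c)),
              info = data.frame(c_j = c_j, rhs = rhs, llr = llr,
                                lppr = post$lppr, pp = post$pp,
                                d_tilde = d_tilde),
              sum_pp = sum(post$pp), blup = blup, config = cfg)
  class(fit) <- "bayesc_fit"
  fit
}

#' @export
print.bayesc_fit <- function(x, ...) {
  cat(sprintf(
    "direct BayesC fit: %d SNPs, sum(PP) = %.2f, max(PP) = %.3f\n",
    length(x$b_c), x$sum_pp, max(x$info$pp)
  ))
  invisible(x)
}
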