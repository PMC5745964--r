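# SNP-BLUP in SVD component space: diagonal mixed-model equations,
# back-transform to SNP effects, and per-SNP prediction error variances.

#' Variance and prior configuration
#'
#' Collects the variance components shared by all fits. The per-SNP
#' SNP-BLUP variance is `sigma_b2 = sigma_g2 / k` and its ratio
#' `lambda_b = sigma_e2 / sigma_b2`. The BayesC slab variance `sigma2` is
#' approximately the largest variance a single SNP effect is expected to
#' have; by default each large-effect SNP is assumed to explain a fraction
#' `slab_fraction = 0.001` of the additive genetic variance
#' (`sigma2 = 0.001 * sigma_g2`). The alternative `"pi_consistent"` mode
#' instead solves `k * pi * sigma2 = sigma_g2`, so that the total genetic
#' variance assumed by the mixture matches `sigma_g2`.
#'
#' All variances are treated as known: none are re-estimated from data.
#'
#' @param k number of SNPs in the panel.
#' @param sigma_g2 additive genetic variance.
#' @param h2 narrow-sense heritability; used to derive `sigma_e2` as
#'   `sigma_g2 * (1 - h2) / h2` when `sigma_e2` is not given.
#' @param sigma_e2 residual variance (overrides `h2`).
#' @param pi prior probability that a SNP effect is non-zero.
#' @param sigma2 slab variance of a non-zero effect (overrides the mode).
#' @param slab_mode `"fixed_slab"` or `"pi_consistent"`, see above.
#' @param slab_fraction fraction of `sigma_g2` a large-effect SNP explains
#'   under `"fixed_slab"`.
#' @return object of class `variance_config` with fields `sigma_g2`,
#'   `sigma_e2`, `sigma_b2`, `lambda_b`, `pi`, `sigma2`, `lambda`, `k`.
#' @export
variance_config <- function(k, sigma_g2 = 1, h2 = NULL, sigma_e2 = NULL,
                            pi = 0.01, sigma2 = NULL,
                            slab_mode = c("fixed_slab", "pi_consistent"),
                            slab_fraction = 0.001) {
  slab_mode <- match.arg(slab_mode)
  if (is.null(sigma_e2)) {
    if (is.null(h2)) stop("supply either h2 or sigma_e2")
    if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
    sigma_e2 <- sigma_g2 * (1 - h2) / h2
  }
  if (sigma_g2 <= 0 || sigma_e2 <= 0) stop("variances must be positive")
  if (pi <= 0 || pi > 1) stop("pi must be in (0, 1]")
  if (is.null(sigma2)) {
    sigma2 <- switch(slab_mode,
      fixed_slab = slab_fraction * sigma_g2,
      pi_consistent = sigma_g2 / (k * pi)
    )
  }
  if (sigma2 <= 0) stop("sigma2 must be positive")
  sigma_b2 <- sigma_g2 / k
  cfg <- list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
              sigma_b2 = sigma_b2, lambda_b = sigma_e2 / sigma_b2,
              pi = pi, sigma2 = sigma2, lambda = sigma_e2 / sigma2,
              k = k, slab_mode = slab_mode)
  class(cfg) <- "variance_config"
  cfg
}

#' Estimate the overall mean
#'
#' Because standardized genotype columns sum to zero, the mean equation of
#' the mixed-model equations decouples and `mu_hat = mean(y)`.
#'
#' @param y phenotype vector.
#' @return scalar mean.
#' @export
estimate_mu <- function(y) {
  if (length(y) == 0L) stop("empty phenotype vector")
  mean(y)
}

#' Solve the component-space mixed-model equations
#'
#' The coefficient matrix `S^2 + I lambda_b` is diagonal, so
#' `s_hat_i = S_i (U'(y - mu))_i / (S_i^2 + lambda_b)` element-wise.
#'
#' @param msvd a [svd_genotypes()] / [merge_chromosome_svds()] result.
#' @param y phenotypes (uncentered).
#' @param lambda_b variance ratio `sigma_e2 / sigma_b2`.
#' @param mu overall mean; default [estimate_mu()].
#' @return vector of component effects `s_hat`.
#' @export
solve_components <- function(msvd, y, lambda_b, mu = estimate_mu(y)) {
  stopifnot(inherits(msvd, "merged_svd"), lambda_b > 0)
  uty <- as.numeric(crossprod(msvd$u, y - mu))
  msvd$d * uty / (msvd$d^2 + lambda_b)
}

#' Back-transform component effects to SNP effects
#'
#' `b_hat = V s_hat`, streamed over per-chromosome V blocks. The result is
#' invariant to the per-component sign ambiguity of the SVD because a sign
#' flip of a U column is always matched by the flip of the same V column.
#'
#' @param msvd a `merged_svd`.
#' @param s_hat component effects.
#' @return vector of k SNP effects.
#' @export
snp_effects <- function(msvd, s_hat) {
  stopifnot(inherits(msvd, "merged_svd"), length(s_hat) == msvd$m)
  msvd_vmult(msvd, s_hat)
}

#' Per-SNP prediction error variance
#'
#' Computes `pev_j = V_j. (S^2 + I lambda_b)^{-1} V_j.' sigma_e2`, which
#' accounts for the simultaneous estimation of all SNP effects, plus the
#' no-information remainder `sigma_b2 * (1 - ||V_j.||^2)` for loading that
#' the retained components do not carry. With an economy SVD of a k > N
#' matrix the V row norms are below 1 even at full rank, and the remainder
#' term is exactly what makes the result equal the diagonal of the dense
#' MME inverse `(X'X / sigma_e2 + I / sigma_b2)^{-1}`. It also guarantees
#' `0 < pev_j <= sigma_b2`, so SNPs orthogonal to all retained components
#' report the prior variance rather than a spurious zero.
#'
#' @param msvd a `merged_svd`.
#' @param lambda_b variance ratio `sigma_e2 / sigma_b2`.
#' @param sigma_e2 residual variance.
#' @return vector of k prediction error variances.
#' @export
snp_pev <- function(msvd, lambda_b, sigma_e2) {
  stopifnot(inherits(msvd, "merged_svd"), lambda_b > 0, sigma_e2 > 0)
  sigma_b2 <- sigma_e2 / lambda_b
  w <- 1 / (msvd$d^2 + lambda_b)
  pev <- numeric(msvd$k)
  row_ss <- numeric(msvd$k)
  for (bl in msvd$blocks) {
    v2 <- bl$v^2
    pev[bl$rows] <- pev[bl$rows] +
      sigma_e2 * as.numeric(v2 %*% w[bl$cols])
    row_ss[bl$rows] <- row_ss[bl$rows] + rowSums(v2)
  }
  pev + sigma_b2 * pmax(0, 1 - row_ss)
}

#' Fit SNP-BLUP through the SVD factorization
#'
#' @param msvd a [svd_genotypes()] result.
#' @param y phenotypes aligned to the rows of U.
#' @param cfg a [variance_config()].
#' @return object of class `blup_fit`: `mu`, `s_hat`, `b_hat`, `pev`,
#'   `gebv_train` (= `U S s_hat`), `row_ss`, and the ratios used.
#' @export
snp_blup <- function(msvd, y, cfg) {
  stopifnot(inherits(msvd, "merged_svd"), inherits(cfg, "variance_config"))
  if (length(y) != nrow(msvd$u)) stop("phenotype length does not match N")
  mu <- estimate_mu(y)
  s_hat <- solve_components(msvd, y, cfg$lambda_b, mu = mu)
  fit <- list(mu = mu,
              s_hat = s_hat,
              b_hat = snp_effects(msvd, s_hat),
              pev = snp_pev(msvd, cfg$lambda_b, cfg$sigma_e2),
              gebv_train = as.numeric(msvd$u %*% (msvd$d * s_hat)),
              row_ss = msvd_row_ss(msvd),
              lambda_b = cfg$lambda_b, sigma_e2 = cfg$sigma_e2,
              sigma_b2 = cfg$sigma_b2)
  class(fit) <- "blup_fit"
  fit
}

#' @export
print.blup_fit <- function(x, ...) {
  cat(sprintf("snp_blup fit: %d SNP effects, mu_hat = %.4g, mean PEV = %.4g\n",
              length(x$b_hat), x$mu, mean(x$pev)))
  invisible(x)
}
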