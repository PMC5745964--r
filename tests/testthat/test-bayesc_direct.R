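test_that("effective information inverts the PEV identity", {
  sigma_e2 <- 1.5; lambda_b <- 400
  sigma_b2 <- sigma_e2 / lambda_b
  expect_equal(effective_info(sigma_b2, lambda_b, sigma_e2), 0)
  expect_equal(effective_info(sigma_e2 / (100 + lambda_b), lambda_b, sigma_e2), 100)
  expect_error(effective_info(c(0.1, 0), lambda_b, sigma_e2))
})

test_that("right-hand-side recovery matches the normal-equation arithmetic", {
  expect_equal(rhs_from_blup(50, 10, 0), 0)
  expect_equal(rhs_from_blup(100, 400, 0.01), 5)
})

test_that("effective info and rhs equal the explicit dense-R oracle", {
  # R_j = I + X_{-j} X_{-j}' sigma_b2 / sigma_e2 formed per SNP; the
  # PEV-based recovery is the exact block inversion of the joint system,
  # so agreement is far inside the approximate 5% the shared-R view allows
  set.seed(601)
  fx <- std_fixture(40, 60)
  X <- fx$xs$X; N <- nrow(X); k <- ncol(X)
  vc <- variance_config(k = k, sigma_g2 = 1, h2 = 0.5, pi = 0.1,
                        slab_mode = "pi_consistent")
  y <- as.numeric(X %*% rnorm(k, 0, sqrt(vc$sigma_b2))) + rnorm(N)
  yc <- y - mean(y)
  fit <- snp_blup(fx$msvd, y, vc)
  c_j <- effective_info(fit$pev, vc$lambda_b, vc$sigma_e2)
  rhs <- rhs_from_blup(c_j, vc$lambda_b, fit$b_hat)
  for (j in c(1, 5, 17, 33, k)) {
    Rinv <- solve(diag(N) + tcrossprod(X[, -j]) * vc$sigma_b2 / vc$sigma_e2)
    c_dense <- drop(t(X[, j]) %*% Rinv %*% X[, j])
    rhs_dense <- drop(t(X[, j]) %*% Rinv %*% yc)
    expect_equal(c_j[j], c_dense, tolerance = 1e-6)
    expect_equal(rhs[j], rhs_dense, tolerance = 1e-6)
  }
})

test_that("the likelihood ratio equals the dense multivariate-normal difference", {
  # single-SNP dataset: the background term vanishes (R = I), so the
  # pipeline LLR must equal the difference of the two exact log-densities
  set.seed(602)
  N <- 200
  g <- genotype_matrix(matrix(rbinom(N, 2, 0.3), N, 1),
                       data.frame(chrom = "c1", pos = 1, id = "s1"))
  xs <- standardize(g)
  y <- 1 + 0.3 * xs$X[, 1] + rnorm(N)
  sigma_e2 <- 1; sigma2 <- 0.05
  vc <- variance_config(k = 1, sigma_g2 = 0.01, sigma_e2 = sigma_e2,
                        pi = 0.01, sigma2 = sigma2)
  msvd <- svd_genotypes(xs, frac = 1)
  fit <- snp_blup(msvd, y, vc)
  c_j <- effective_info(fit$pev, vc$lambda_b, sigma_e2)
  rhs <- rhs_from_blup(c_j, vc$lambda_b, fit$b_hat)
  llr <- log_likelihood_ratio(c_j, rhs, vc$lambda, sigma_e2)

  yc <- y - mean(y)
  xcol <- xs$X[, 1]
  l0 <- dmvnorm_log0(yc, diag(sigma_e2, N))
  l1 <- dmvnorm_log0(yc, diag(sigma_e2, N) + tcrossprod(xcol) * sigma2)
  expect_equal(llr[1], l1 - l0, tolerance = 1e-6)
})

test_that("likelihood-ratio limits behave as the mixture demands", {
  # no data, models indistinguishable
  expect_equal(log_likelihood_ratio(0, 0, lambda = 10, sigma_e2 = 1), 0)
  # slab collapse: lambda -> Inf drives LLR to 0 monotonically
  lams <- 10^(2:9)
  llrs <- log_likelihood_ratio(rep(50, length(lams)), rep(3, length(lams)),
                               lams, 1)
  expect_true(all(diff(abs(llrs)) < 0))
  expect_lt(abs(llrs[length(llrs)]), 1e-6)
})

test_that("posterior probabilities combine evidence and prior exactly", {
  expect_equal(posterior_probability(0, 0.5)$pp, 0.5)
  # zero evidence returns the prior
  expect_equal(posterior_probability(0, 0.01)$pp, 0.01)
  # llr = -log(pi/(1-pi)) = log(99) = 4.59512 brings pp back to 0.5
  expect_equal(posterior_probability(log(99), 0.01)$pp, 0.5)
  expect_equal(posterior_probability(4.59512, 0.01)$pp, 0.5, tolerance = 1e-5)
  # numerically stable far beyond +-700
  expect_equal(posterior_probability(800, 0.01)$pp, 1)
  expect_equal(posterior_probability(-800, 0.01)$pp, 0)
  expect_error(posterior_probability(0, 1))

  # strictly increasing in llr at fixed pi and in pi at fixed llr
  pps <- posterior_probability(seq(-5, 5, by = 0.5), 0.1)$pp
  expect_true(all(diff(pps) > 0))
  pps2 <- vapply(c(0.01, 0.05, 0.2, 0.5, 0.9),
                 function(p) posterior_probability(1.3, p)$pp, 1)
  expect_true(all(diff(pps2) > 0))
})

test_that("variance weights are proportional to PP and conserve the total", {
  expect_equal(snp_variance_weights(rep(0.3, 7)), rep(1, 7))
  expect_equal(snp_variance_weights(c(0.9, 0.1)), c(1.8, 0.2))
  set.seed(603)
  pp <- runif(500)
  d <- snp_variance_weights(pp, sigma2 = 0.02)
  expect_equal(sum(d), 500, tolerance = 1e-12)
  expect_equal(d / d[1], pp / pp[1], tolerance = 1e-10)
  # flooring keeps zero-PP SNPs strictly positive
  d0 <- snp_variance_weights(c(0, 1, 1))
  expect_true(all(d0 > 0))
})

test_that("uniform weights reduce the weighted solver to SNP-BLUP", {
  set.seed(604)
  fx <- std_fixture(30, 70)
  y <- rnorm(30, 5)
  lam <- 12
  s_hat <- solve_components(fx$msvd, y, lam)
  sol <- solve_bayesc_components(fx$msvd, y, rep(1, fx$msvd$k), lam)
  expect_equal(sol$s_c, s_hat, tolerance = 1e-10)
  b_c <- bayesc_snp_effects(fx$msvd, rep(1, fx$msvd$k), sol$s_c, sol$w_inv)
  expect_equal(b_c, snp_effects(fx$msvd, s_hat), tolerance = 1e-10)
  # centered phenotypes give a null solution
  expect_equal(solve_bayesc_components(fx$msvd, rep(2, 30),
                                       rep(1, fx$msvd$k), lam)$s_c,
               rep(0, fx$msvd$m))
  expect_equal(bayesc_snp_effects(fx$msvd, rep(1, fx$msvd$k),
                                  rep(0, fx$msvd$m)),
               rep(0, fx$msvd$k))
})

test_that("weighted solve and back-transform match the dense weighted ridge", {
  set.seed(605)
  fx <- std_fixture(25, 55)
  X <- fx$xs$X; k <- ncol(X)
  y <- rnorm(25, 1)
  yc <- y - mean(y)
  lam <- 9
  d_tilde <- snp_variance_weights(runif(k, 0.01, 0.99))
  sol <- solve_bayesc_components(fx$msvd, y, d_tilde, lam)
  b_c <- bayesc_snp_effects(fx$msvd, d_tilde, sol$s_c, sol$w_inv)
  b_dense <- solve(crossprod(X) + diag(lam / d_tilde), crossprod(X, yc))
  expect_equal(b_c, as.numeric(b_dense), tolerance = 1e-6)
  # component view of the same solution: s = V' b
  expect_equal(sol$s_c,
               as.numeric(crossprod(dense_V(fx$msvd), b_dense)),
               tolerance = 1e-6)
})

test_that("predict_gebv transfers effects and validates SNP sets", {
  set.seed(606)
  fx <- std_fixture(15, 30)
  expect_equal(predict_gebv(rep(0, fx$msvd$k), fx$xs), rep(0, 15))
  vc <- variance_config(k = fx$msvd$k, sigma_g2 = 1, h2 = 0.5)
  y <- rnorm(15)
  fit <- snp_blup(fx$msvd, y, vc)
  expect_equal(predict_gebv(fit$b_hat, fx$xs), fit$gebv_train,
               tolerance = 1e-8)
  expect_error(predict_gebv(fit$b_hat[-1], fx$xs), "does not match")
  expect_error(predict_gebv(fit$b_hat, fx$xs,
                            snp_ids = c(fx$xs$map$id[-1], "absent")),
               "absent")
})

test_that("a near-one prior with the SNP-BLUP slab reproduces SNP-BLUP", {
  set.seed(607)
  fx <- std_fixture(30, 60)
  y <- rnorm(30, 2)
  vc <- variance_config(k = fx$msvd$k, sigma_g2 = 1, h2 = 0.5,
                        pi = 1 - 1e-15, sigma2 = 1 / fx$msvd$k)
  blup <- snp_blup(fx$msvd, y, vc)
  bc <- bayesc_direct(fx$msvd, y, vc, blup = blup)
  expect_equal(bc$info$d_tilde, rep(1, fx$msvd$k), tolerance = 1e-9)
  expect_equal(bc$s_c, blup$s_hat, tolerance = 1e-6)
  expect_equal(bc$b_c, blup$b_hat, tolerance = 1e-6)
})

test_that("a planted large-effect QTL earns a top-ranked posterior probability", {
  set.seed(608)
  fx <- std_fixture(300, 80)
  k <- fx$msvd$k
  qtl <- 17
  y <- 0.8 * fx$xs$X[, qtl] + rnorm(300, 0, sqrt(0.5))
  vc <- variance_config(k = k, sigma_g2 = 0.6, sigma_e2 = 0.5, pi = 1 / k,
                        slab_mode = "pi_consistent")
  fit <- bayesc_direct(fx$msvd, y, vc)
  expect_gt(fit$info$pp[qtl], median(fit$info$pp))
  expect_equal(which.max(fit$info$pp), qtl)
})
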