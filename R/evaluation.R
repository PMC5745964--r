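# Accuracy and bias profiles over descendant generations, the full
# simulate -> SVD -> fit -> forward-predict study driver, and a plain
# hold-out tuner for the mixture prior.

#' Prediction accuracy
#'
#' Pearson correlation between true and estimated breeding values.
#'
#' @param tbv true breeding values.
#' @param gebv estimated breeding values.
#' @return correlation, or `NA` when either vector is constant.
#' @export
accuracy <- function(tbv, gebv) {
  if (length(tbv) != length(gebv)) stop("tbv and gebv lengths differ")
  if (length(tbv) < 3L) stop("need at least 3 individuals")
  if (sd(tbv) == 0 || sd(gebv) == 0) return(NA_real_)
  cor(tbv, gebv)
}

#' Prediction bias
#'
#' Regression coefficient of TBV on GEBV; 1 means unbiased, values below 1
#' mean the spread of the estimated breeding values is too large (GEBV
#' need shrinking).
#'
#' @inheritParams accuracy
#' @return OLS slope of `tbv ~ gebv`, or `NA` for constant `gebv`.
#' @export
bias <- function(tbv, gebv) {
  if (length(tbv) != length(gebv)) stop("tbv and gebv lengths differ")
  if (length(tbv) < 3L) stop("need at least 3 individuals")
  if (var(gebv) == 0) return(NA_real_)
  cov(tbv, gebv) / var(gebv)
}

.config_fingerprint <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full evaluation study
#'
#' Per replicate: simulate a study, decompose the reference genotypes,
#' estimate SNP effects in generation 0 with each requested method, and
#' predict breeding values for generations 1..n_forward_gen, scoring
#' accuracy (correlation of TBV with GEBV) and bias (regression of TBV on
#' GEBV) per generation. Unless overridden, `pi` is set to the true
#' QTL fraction (number of QTL / number of panel SNPs) and the slab
#' variance follows the `pi`-consistent convention
#' `k * pi * sigma2 = sigma_g2`, with all variances assumed known.
#'
#' @param cfg a [sim_config()].
#' @param methods subset of `"snp_blup"`, `"bayesc_svd"`, `"bayesc_mcmc"`.
#' @param replicates number of independent replicates.
#' @param seed base seed; replicate r uses `seed + r - 1`.
#' @param pi,sigma2,slab_mode prior overrides passed to [variance_config()].
#' @param svd_frac per-chromosome explained-variance retention.
#' @param merge_mode `"hierarchical"` or `"block_diagonal"`.
#' @param mcmc_iter,mcmc_burnin Gibbs sweeps for the MCMC arm.
#' @param out_dir optional directory for `profiles.tsv`,
#'   `pp_manhattan.tsv` and `run_manifest.json`.
#' @return object of class `study_result`: `profiles` (data.frame with
#'   replicate, method, generation, n, accuracy, bias), `sum_pp`
#'   (per replicate and method), `snp_tables` (per-SNP PP of the last
#'   replicate, for Manhattan-style output), `manifest`.
#' @export
run_study <- function(cfg, methods = c("snp_blup", "bayesc_svd", "bayesc_mcmc"),
                      replicates = cfg$n_replicates, seed = 1,
                      pi = NULL, sigma2 = NULL, slab_mode = "pi_consistent",
                      svd_frac = 0.95, merge_mode = "hierarchical",
                      mcmc_iter = 2000L, mcmc_burnin = 500L,
                      out_dir = NULL) {
  methods <- match.arg(methods, c("snp_blup", "bayesc_svd", "bayesc_mcmc"),
                       several.ok = TRUE)
  profiles <- list()
  sum_pp <- list()
  snp_tables <- NULL
  timings <- list()
  for (r in seq_len(replicates)) {
    set.seed(seed + r - 1)
    t0 <- Sys.time()
    study <- simulate_study(cfg)
    t1 <- Sys.time()
    k <- ncol(study$X$X)
    pi_r <- if (is.null(pi)) length(study$qtl$idx) / k else pi
    vc <- variance_config(k = k, sigma_g2 = 1, sigma_e2 = study$sigma_e2,
                          pi = pi_r, sigma2 = sigma2, slab_mode = slab_mode)
    msvd <- svd_genotypes(study$X, frac = svd_frac, mode = merge_mode)
    t2 <- Sys.time()
    effects <- list()
    pp_tab <- data.frame(snp_id = study$genotypes$map$id,
                         chrom = study$genotypes$map$chrom,
                         pos = study$genotypes$map$pos)
    blup <- NULL
    if (any(c("snp_blup", "bayesc_svd") %in% methods)) {
      blup <- snp_blup(msvd, study$phenotypes$y, vc)
    }
    if ("snp_blup" %in% methods) effects$snp_blup <- blup$b_hat
    if ("bayesc_svd" %in% methods) {
      fit <- bayesc_direct(msvd, study$phenotypes$y, vc, blup = blup)
      effects$bayesc_svd <- fit$b_c
      sum_pp[[length(sum_pp) + 1L]] <-
        data.frame(replicate = r, method = "bayesc_svd", sum_pp = fit$sum_pp)
      pp_tab$pp_svd <- fit$info$pp
    }
    if ("bayesc_mcmc" %in% methods) {
      mc <- gibbs_bayesc(study$X, study$phenotypes$y, pi = pi_r,
                         sigma2 = vc$sigma2, sigma_e2 = vc$sigma_e2,
                         n_iter = mcmc_iter, burn_in = mcmc_burnin)
      effects$bayesc_mcmc <- mc$b_bar
      sum_pp[[length(sum_pp) + 1L]] <-
        data.frame(replicate = r, method = "bayesc_mcmc", sum_pp = mc$sum_pp)
      pp_tab$pp_mcmc <- mc$pp_mcmc
    }
    t3 <- Sys.time()
    for (gen in seq_along(study$generations)) {
      gd <- study$generations[[gen]]
      Xg <- standardize(gd$genotypes, freq = study$genotypes$freq)
      for (m in names(effects)) {
        gebv <- predict_gebv(effects[[m]], Xg)
        profiles[[length(profiles) + 1L]] <- data.frame(
          replicate = r, method = m, generation = gen,
          n = length(gebv),
          accuracy = accuracy(gd$tbv, gebv),
          bias = bias(gd$tbv, gebv)
        )
      }
    }
    snp_tables <- pp_tab
    timings[[r]] <- c(simulate = as.numeric(t1 - t0, units = "secs"),
                      svd = as.numeric(t2 - t1, units = "secs"),
                      fit = as.numeric(t3 - t2, units = "secs"))
  }
  profiles <- do.call(rbind, profiles)
  sum_pp <- if (length(sum_pp) > 0L) do.call(rbind, sum_pp) else NULL
  manifest <- list(
    config = unclass(cfg), config_hash = .config_fingerprint(unclass(cfg)),
    seed = seed, replicates = replicates, methods = methods,
    dims = list(n_ref = cfg$n_ref, k_panel = if (exists("k")) k else NA),
    timings_sec = timings
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(profiles, file.path(out_dir, "profiles.tsv"), sep = "\t")
    data.table::fwrite(snp_tables, file.path(out_dir, "pp_manhattan.tsv"),
                       sep = "\t")
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out <- list(profiles = profiles, sum_pp = sum_pp,
              snp_tables = snp_tables, manifest = manifest)
  class(out) <- "study_result"
  out
}

#' @export
print.study_result <- function(x, ...) {
  agg <- aggregate(accuracy ~ method + generation, x$profiles, mean)
  cat("study_result: mean accuracy by generation\n")
  print(utils::head(agg[order(agg$method, agg$generation), ], 40L),
        row.names = FALSE)
  invisible(x)
}

#' Hold-out tuning of the mixture prior
#'
#' Random individual-level folds; within each fold the SVD of the training
#' genotypes is computed once and reused across the whole (`pi`, `sigma2`)
#' grid — the expensive factorization does not depend on the prior.
#' Validation accuracy is the correlation between held-out phenotypes and
#' their predicted breeding values.
#'
#' @param xs a [standardize()]d genotype object (reference population).
#' @param y phenotypes.
#' @param pi_grid candidate values of `pi`.
#' @param sigma2_grid candidate slab variances; `NULL` derives `sigma2`
#'   from each `pi` by the `pi`-consistent rule.
#' @param folds number of random folds (>= 2).
#' @param sigma_g2,sigma_e2 assumed variance components.
#' @param svd_frac,merge_mode SVD options, see [svd_genotypes()].
#' @return list with `grid` (data.frame of pi, sigma2, mean and per-fold
#'   validation accuracy) and `best` (row with the highest mean accuracy).
#' @export
holdout_tune <- function(xs, y, pi_grid, sigma2_grid = NULL, folds = 2L,
                         sigma_g2 = 1, sigma_e2 = 1,
                         svd_frac = 0.95, merge_mode = "hierarchical") {
  stopifnot(inherits(xs, "std_geno"))
  folds <- as.integer(folds)
  if (folds < 2L) stop("need at least 2 folds")
  n <- nrow(xs$X)
  if (folds > n / 2) stop("degenerate folds: too few individuals per fold")
  k <- ncol(xs$X)
  grid <- if (is.null(sigma2_grid)) {
    data.frame(pi = pi_grid, sigma2 = sigma_g2 / (k * pi_grid))
  } else {
    expand.grid(pi = pi_grid, sigma2 = sigma2_grid)
  }
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  acc <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    val <- which(fold_id == f)
    tr <- which(fold_id != f)
    xs_tr <- xs
    xs_tr$X <- xs$X[tr, , drop = FALSE]
    msvd <- svd_genotypes(xs_tr, frac = svd_frac, mode = merge_mode)
    for (gidx in seq_len(nrow(grid))) {
      vc <- variance_config(k = k, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                            pi = grid$pi[gidx], sigma2 = grid$sigma2[gidx])
      fit <- bayesc_direct(msvd, y[tr], vc)
      pred <- as.numeric(xs$X[val, , drop = FALSE] %*% fit$b_c)
      acc[gidx, f] <- accuracy(y[val], pred)
    }
  }
  grid$mean_accuracy <- rowMeans(acc)
  grid <- cbind(grid, `colnames<-`(acc, paste0("fold", seq_len(folds))))
  list(grid = grid, best = grid[which.max(grid$mean_accuracy), , drop = FALSE])
}
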