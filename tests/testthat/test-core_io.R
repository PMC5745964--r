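test_that("VCF ingestion counts ALT alleles, skips multi-allelic records, imputes missing", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", "b", sep = "\t"),
    paste("chr01", "100", "v1", "A", "T", ".", ".", ".", "GT", "0/0", "0/1", sep = "\t"),
    paste("chr01", "200", "v2", "A", "T,G", ".", ".", ".", "GT", "0/1", "1/1", sep = "\t"),
    paste("chr01", "300", "v3", "C", "G", ".", ".", ".", "GT", "1/1", "./.", sep = "\t")
  ), vcf)
  g <- suppressMessages(read_genotypes(vcf, format = "vcf"))
  # multi-allelic v2 dropped; v1 counts 0,1 so p = 0.25
  expect_equal(ncol(g$counts), 2L)
  expect_equal(g$map$id, c("v1", "v3"))
  expect_equal(unname(g$counts[, 1]), c(0, 1))
  expect_equal(g$freq[[1]], 0.25)
  # ./. imputed to the column mean dosage (= 2 here), keeping X'1 = 0
  expect_equal(unname(g$counts[, 2]), c(2, 2))
})

test_that("simulator-emitted VCF round-trips to identical counts", {
  set.seed(301)
  g <- sim_binomial_geno(12, 30)
  path <- tempfile(fileext = ".vcf")
  write_vcf(g, path)
  g2 <- read_genotypes(path, format = "vcf")
  expect_equal(unname(g2$counts), unname(g$counts))
  expect_equal(g2$map$pos, g$map$pos)
  expect_equal(g2$freq, g$freq)
})

test_that("matrix format round-trips bit-exactly and rejects ragged input", {
  set.seed(302)
  g <- sim_binomial_geno(10, 25)
  mpath <- tempfile(); spath <- tempfile()
  write_genotype_matrix(g, mpath, spath)
  g2 <- read_genotypes(mpath, format = "matrix", map_path = spath)
  expect_identical(unname(g2$counts), unname(g$counts))
  expect_equal(g2$map$id, g$map$id)

  ragged <- tempfile()
  writeLines(c("0 1 2", "1 2"), ragged)
  expect_error(read_genotypes(ragged, format = "matrix", map_path = spath))
})

test_that("MAF filter keeps exactly the strictly-eligible columns", {
  # frequencies 0.005, 0.05, 0.995 from explicit allele counts (N = 100)
  cnt <- matrix(0, 100, 3)
  cnt[1, 1] <- 1            # p = 0.005
  cnt[1:10, 2] <- 1         # p = 0.05
  cnt[, 3] <- 2; cnt[1, 3] <- 1  # p = 0.995
  g <- genotype_matrix(cnt, data.frame(chrom = "c1", pos = 1:3, id = paste0("s", 1:3)))
  expect_equal(g$freq, c(0.005, 0.05, 0.995), ignore_attr = TRUE)
  kept <- filter_maf(g, 0.01)
  expect_equal(kept$map$id, "s2")
  # threshold 0 keeps everything polymorphic
  expect_equal(ncol(filter_maf(g, 0)$counts), 3L)
  expect_error(filter_maf(g, 0.6))

  # random fixture: kept set equals a brute-force per-column scan
  set.seed(303)
  gr <- sim_binomial_geno(50, 200, p_range = c(0.005, 0.995))
  p <- colMeans(gr$counts) / 2
  brute <- which(pmin(p, 1 - p) > 0.1)
  expect_equal(filter_maf(gr, 0.1)$map$id, gr$map$id[brute])
})

test_that("standardization applies the three frequency codes and centers columns", {
  # p = 0.5: codes are -sqrt(2)/1, 0, +sqrt(2)/1 scaled by 1/sqrt(0.5) = +-1.41421356, 0
  cnt <- matrix(c(0, 1, 1, 2), 4, 1)
  g <- genotype_matrix(cnt, data.frame(chrom = "c1", pos = 1, id = "s1"))
  xs <- standardize(g)
  expect_equal(sort(unique(xs$X[, 1])), c(-1.41421356, 0, 1.41421356),
               tolerance = 1e-8)

  set.seed(304)
  gr <- filter_maf(sim_binomial_geno(50, 200), 0.01)
  xr <- standardize(gr)
  expect_lt(max(abs(colMeans(xr$X))), 1e-10)
  # element-wise oracle: code(g) = (g - 2p)/sqrt(2p(1-p))
  p <- gr$freq
  oracle <- sweep(sweep(gr$counts, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(unname(xr$X), unname(oracle), tolerance = 1e-12)
  # each column takes at most 3 distinct values
  expect_true(all(apply(xr$X, 2, function(col) length(unique(col))) <= 3))

  g0 <- genotype_matrix(matrix(0, 5, 1),
                        data.frame(chrom = "c1", pos = 1, id = "s1"))
  expect_error(standardize(g0), "monomorphic")
})

test_that("SNP report and GEBV tables round-trip", {
  map <- data.frame(chrom = "c1", pos = 1:3, id = paste0("s", 1:3))
  vals <- list(freq = c(0.1, 0.2, 0.3), b = c(1.234567890123, -2e-8, 0),
               pev = c(1e-4, 2e-4, 3e-4), llr = c(-1.5, 0, 4.2),
               pp = c(0.01, 0.5, 0.99), d = c(0.5, 1, 1.5))
  path <- tempfile()
  write_snp_report(map, vals$freq, vals$b, vals$pev, vals$llr, vals$pp,
                   vals$d, path = path)
  rep <- read_snp_report(path)
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$b_hat, vals$b, tolerance = 1e-12)
  expect_equal(rep$pev, vals$pev, tolerance = 1e-12)
  expect_error(write_snp_report(map, vals$freq, vals$b[1:2], vals$pev,
                                path = tempfile()))

  # empty effect set -> header-only file
  p2 <- tempfile()
  write_snp_report(map[0, ], numeric(0), numeric(0), numeric(0), path = p2)
  expect_equal(nrow(read_snp_report(p2)), 0L)

  gpath <- tempfile()
  write_gebv(c("a", "b"), 1L, c(0.5, -0.5), gpath)
  gb <- read_snp_report(gpath)
  expect_equal(gb$gebv, c(0.5, -0.5))
  expect_error(write_gebv(c("a", "b"), 1L, 1:3, tempfile()))
})

test_that("standardize after MAF filtering never yields non-finite values", {
  set.seed(305)
  for (i in 1:5) {
    g <- filter_maf(sim_binomial_geno(30, 80, p_range = c(0.02, 0.98)), 0.01)
    expect_true(all(is.finite(standardize(g)$X)))
  }
})
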