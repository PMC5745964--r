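# Economy SVD of the genotype matrix: per-chromosome decomposition,
# truncation by explained variance, hierarchical merge into a genome-wide
# factorization, and the block-diagonal shortcut for weak family structure.
#
# A MergedSVD never materializes the k x m matrix V as one dense block:
# V is kept as a list of per-chromosome blocks (rows = SNPs of that
# chromosome, cols = the retained components), which is also the contract
# consumers use to stream V row-blocks.

#' Economy SVD of one chromosome's standardized genotypes
#'
#' Components with (numerically) zero singular values are dropped, so the
#' factors satisfy `U'U = I`, `V'V = I` and `U S V'` reconstructs the input
#' at full retained rank.
#'
#' @param X_c N x k_c numeric matrix (standardized genotypes of one
#'   chromosome or chromosome segment).
#' @param chrom chromosome label carried into downstream maps.
#' @return object of class `chrom_svd`: list with `chrom`, `u` (N x m_c),
#'   `d` (singular values, descending), `v` (k_c x m_c), `k` (= k_c),
#'   `total_ss` (sum of all squared singular values), `var_explained`.
#' @export
economy_svd <- function(X_c, chrom = "1") {
  X_c <- as.matrix(X_c)
  if (anyNA(X_c) || any(!is.finite(X_c))) stop("non-finite values in genotype matrix")
  if (ncol(X_c) == 0L || all(X_c == 0)) {
    out <- list(chrom = as.character(chrom),
                u = matrix(0, nrow(X_c), 0L), d = numeric(0),
                v = matrix(0, ncol(X_c), 0L), k = ncol(X_c),
                total_ss = 0, var_explained = 1)
    class(out) <- "chrom_svd"
    return(out)
  }
  sv <- svd(X_c)
  tol <- max(dim(X_c)) * .Machine$double.eps * sv$d[1L]
  m <- sum(sv$d > tol)
  out <- list(chrom = as.character(chrom),
              u = sv$u[, seq_len(m), drop = FALSE],
              d = sv$d[seq_len(m)],
              v = sv$v[, seq_len(m), drop = FALSE],
              k = ncol(X_c),
              total_ss = sum(sv$d^2),
              var_explained = if (sum(sv$d^2) > 0) sum(sv$d[seq_len(m)]^2) / sum(sv$d^2) else 1)
  class(out) <- "chrom_svd"
  out
}

#' Truncate a chromosome SVD by explained variance
#'
#' Keeps the smallest leading set of components whose cumulative squared
#' singular values reach at least `frac` of the total
#' (`Trace(S_retained^2) >= frac * Trace(S^2)`), optionally further capped
#' at `max_components`.
#'
#' @param sv a [economy_svd()] result.
#' @param frac fraction of total variance to retain, in (0, 1].
#' @param max_components absolute cap on the number of components.
#' @return truncated `chrom_svd` with `var_explained` updated.
#' @export
truncate_svd <- function(sv, frac = 0.95, max_components = Inf) {
  stopifnot(inherits(sv, "chrom_svd"))
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  if (length(sv$d) == 0L) return(sv)
  ss <- sv$d^2
  cum <- cumsum(ss) / sum(ss)
  m <- which(cum >= frac - 1e-15)[1L]
  m <- min(m, max_components, length(sv$d))
  sv$u <- sv$u[, seq_len(m), drop = FALSE]
  sv$v <- sv$v[, seq_len(m), drop = FALSE]
  sv$d <- sv$d[seq_len(m)]
  sv$var_explained <- sum(ss[seq_len(m)]) / sv$total_ss
  sv
}

#' Merge per-chromosome SVDs into a genome-wide factorization
#'
#' Hierarchical mode re-decomposes the horizontal concatenation of the
#' per-chromosome `U_c S_c` score matrices, `T = [U_1 S_1 ... U_l S_l]`,
#' as `T = U0 S0 V0'`, and assembles the genome-wide V blockwise as
#' `V_c %*% V0[rows of chromosome c, ]`. Block-diagonal mode simply
#' concatenates the factors without re-orthogonalization, which is
#' adequate when family structure is weak; use [orthogonality_check()]
#' on the resulting U to judge that approximation.
#'
#' @param parts list of [economy_svd()] (possibly truncated) results
#'   sharing the same N.
#' @param mode `"hierarchical"` or `"block_diagonal"`.
#' @param merged_frac optional second truncation of the merged spectrum
#'   (hierarchical mode only); default 1 keeps all merged components.
#' @return object of class `merged_svd`: list with `u` (N x m), `d` (m),
#'   `blocks` (per chromosome: `chrom`, `rows` global SNP indices, `cols`
#'   component indices, `v` the V row-block), `m`, `k`, `merged` flag.
#' @export
merge_chromosome_svds <- function(parts, mode = c("hierarchical", "block_diagonal"),
                                  merged_frac = 1) {
  mode <- match.arg(mode)
  stopifnot(length(parts) >= 1L, all(vapply(parts, inherits, TRUE, "chrom_svd")))
  ns <- vapply(parts, function(p) nrow(p$u), 1L)
  if (length(unique(ns)) != 1L) stop("chromosome SVDs disagree on N")
  parts <- parts[order(vapply(parts, function(p) p$chrom, ""))] # map order
  ks <- vapply(parts, function(p) p$k, 1L)
  ms <- vapply(parts, function(p) length(p$d), 1L)
  row_off <- c(0L, cumsum(ks))
  col_off <- c(0L, cumsum(ms))
  if (mode == "block_diagonal") {
    blocks <- vector("list", length(parts))
    for (i in seq_along(parts)) {
      blocks[[i]] <- list(chrom = parts[[i]]$chrom,
                          rows = row_off[i] + seq_len(ks[i]),
                          cols = col_off[i] + seq_len(ms[i]),
                          v = parts[[i]]$v)
    }
    out <- list(u = do.call(cbind, lapply(parts, `[[`, "u")),
                d = unlist(lapply(parts, `[[`, "d")),
                blocks = blocks, m = sum(ms), k = sum(ks), merged = FALSE)
    class(out) <- "merged_svd"
    return(out)
  }
  scores <- do.call(cbind, lapply(parts, function(p) {
    p$u * rep(p$d, each = nrow(p$u))
  }))
  sv0 <- economy_svd(scores, chrom = "merged")
  if (merged_frac < 1) sv0 <- truncate_svd(sv0, frac = merged_frac)
  m <- length(sv0$d)
  blocks <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    v0_rows <- sv0$v[col_off[i] + seq_len(ms[i]), , drop = FALSE]
    blocks[[i]] <- list(chrom = parts[[i]]$chrom,
                        rows = row_off[i] + seq_len(ks[i]),
                        cols = seq_len(m),
                        v = parts[[i]]$v %*% v0_rows)
  }
  out <- list(u = sv0$u, d = sv0$d, blocks = blocks,
              m = m, k = sum(ks), merged = TRUE)
  class(out) <- "merged_svd"
  out
}

#' @export
print.merged_svd <- function(x, ...) {
  cat(sprintf("merged_svd: %d SNPs x %d components (%s merge), N = %d\n",
              x$k, x$m, if (x$merged) "hierarchical" else "block-diagonal",
              nrow(x$u)))
  invisible(x)
}

#' Genome-wide SVD of standardized genotypes
#'
#' Convenience wrapper: splits the standardized genotype matrix by
#' chromosome (segments can be encoded as pseudo-chromosomes in the map),
#' runs [economy_svd()] and [truncate_svd()] per chromosome, and merges
#' with [merge_chromosome_svds()].
#'
#' @param xs a [standardize()]d genotype object.
#' @param frac per-chromosome explained-variance retention; default 0.95.
#' @param max_components per-chromosome absolute cap.
#' @param mode merge mode, see [merge_chromosome_svds()].
#' @param merged_frac second truncation of the merged spectrum; default off.
#' @return a `merged_svd` carrying the SNP map as attribute `map`.
#' @export
svd_genotypes <- function(xs, frac = 0.95, max_components = Inf,
                          mode = "hierarchical", merged_frac = 1) {
  stopifnot(inherits(xs, "std_geno"))
  chroms <- unique(xs$map$chrom)
  parts <- lapply(chroms, function(ch) {
    cols <- which(xs$map$chrom == ch)
    truncate_svd(economy_svd(xs$X[, cols, drop = FALSE], chrom = ch),
                 frac = frac, max_components = max_components)
  })
  out <- merge_chromosome_svds(parts, mode = mode, merged_frac = merged_frac)
  attr(out, "map") <- xs$map
  out
}

#' Maximum off-diagonal entry of U'U
#'
#' Diagnostic for the block-diagonal merge shortcut: values near zero mean
#' the per-chromosome components are nearly orthogonal and the shortcut is
#' safe.
#'
#' @param U numeric matrix.
#' @return `max |(U'U)_{ij}|` over `i != j` (0 for a single column).
#' @export
orthogonality_check <- function(U) {
  U <- as.matrix(U)
  if (anyNA(U) || any(!is.finite(U))) stop("non-finite values in U")
  if (ncol(U) < 2L) return(0)
  G <- crossprod(U)
  diag(G) <- 0
  max(abs(G))
}

# ---- internal blockwise V operations -------------------------------------

# b = V s, streamed per chromosome block
msvd_vmult <- function(msvd, s) {
  b <- numeric(msvd$k)
  for (bl in msvd$blocks) {
    b[bl$rows] <- as.numeric(bl$v %*% s[bl$cols])
  }
  b
}

# s = V' b
msvd_vtmult <- function(msvd, b) {
  s <- numeric(msvd$m)
  for (bl in msvd$blocks) {
    s[bl$cols] <- s[bl$cols] + as.numeric(crossprod(bl$v, b[bl$rows]))
  }
  s
}

# W = V' diag(w) V, accumulated blockwise (m x m)
msvd_weighted_gram <- function(msvd, w) {
  W <- matrix(0, msvd$m, msvd$m)
  for (bl in msvd$blocks) {
    W[bl$cols, bl$cols] <- W[bl$cols, bl$cols] +
      crossprod(bl$v, w[bl$rows] * bl$v)
  }
  W
}

# ||V_j.||^2 per SNP
msvd_row_ss <- function(msvd) {
  rs <- numeric(msvd$k)
  for (bl in msvd$blocks) {
    rs[bl$rows] <- rs[bl$rows] + rowSums(bl$v^2)
  }
  rs
}
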