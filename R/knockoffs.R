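#' Cluster tightly linked variants
#'
#' Groups variants into tight-LD clusters using single-linkage hierarchical
#' clustering with distance `1 - |r|`, cut at height 0.25, so that variants
#' from two different clusters never have `|r| > 0.75`. Tight clusters are
#' treated as one discovery unit during knockoff generation: cluster
#' co-members are excluded from each other's conditioning sets and their
#' residuals are permuted jointly, which prevents knockoffs from collapsing
#' onto near-copies of the originals in regions of strong LD.
#'
#' Clustering is performed within chromosome; variants on different
#' chromosomes are never clustered together.
#'
#' @param panel A [genotype_panel()].
#' @return Integer vector of cluster ids, one per variant.
#' @export
ld_clusters <- function(panel) {
  v <- panel$variants
  cl <- integer(n_variants(panel))
  offset <- 0L
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    r <- if (length(idx) > 1L) safe_cor(panel$dosages[, idx, drop = FALSE]) else NULL
    k <- clusters_from_r(r, length(idx))
    cl[idx] <- offset + k
    offset <- offset + max(k)
  }
  cl
}

clusters_from_r <- function(r, p) {
  if (p == 1L) return(1L)
  hc <- stats::hclust(stats::as.dist(1 - abs(r)), method = "single")
  stats::cutree(hc, h = 0.25)
}

# column-centered BLAS correlation with zero-variance guard:
# constant columns get r = 0
safe_cor <- function(x, y = NULL) {
  n <- nrow(x)
  xc <- x - rep(colMeans(x), each = n)
  sx <- sqrt(colSums(xc^2))
  sx0 <- sx == 0
  sx[sx0] <- Inf
  if (is.null(y)) {
    r <- crossprod(xc) / tcrossprod(sx)
    diag(r) <- 1
  } else {
    y <- as.matrix(y)
    yc <- y - rep(colMeans(y), each = n)
    sy <- sqrt(colSums(yc^2))
    sy[sy == 0] <- Inf
    r <- crossprod(xc, yc) / tcrossprod(sx, sy)
  }
  r[is.na(r)] <- 0
  r
}

#' Select the conditioning neighborhood of a variant
#'
#' The sequential conditional model for variant `j` conditions on its
#' K-nearest neighbors in LD: the up-to-`K` variants within +/-100 kb of
#' `j`'s position (same chromosome) with `|r| > 0.05`, ranked by decreasing
#' `|r|`, excluding variants in `j`'s own tight-LD cluster. The cap is
#' `K = floor(n^(1/3))`, which keeps the per-variant regression
#' well-conditioned as the sample size grows. Ties in `|r|` are broken by
#' smaller genomic distance, then by lower variant index.
#'
#' @param panel A [genotype_panel()].
#' @param clusters Cluster ids from [ld_clusters()].
#' @param j Target variant index.
#' @param r Optional precomputed correlation matrix over the panel's
#'   variants (used internally to avoid recomputation).
#' @param window_bp Conditioning window half-width in bp.
#' @return Integer vector of neighbor indices (possibly empty).
#' @export
select_neighbors <- function(panel, clusters, j, r = NULL, window_bp = 1e5) {
  v <- panel$variants
  k_cap <- neighbor_cap(n_samples(panel))
  cand <- which(
    v$chrom == v$chrom[j] &
      abs(v$pos - v$pos[j]) <= window_bp &
      seq_len(nrow(v)) != j &
      clusters != clusters[j]
  )
  if (!length(cand)) return(integer(0))
  rj <- if (is.null(r)) {
    drop(safe_cor(panel$dosages[, cand, drop = FALSE],
                  panel$dosages[, j, drop = FALSE]))
  } else {
    r[cand, j]
  }
  keep <- abs(rj) > 0.05
  cand <- cand[keep]
  if (!length(cand)) return(integer(0))
  rj <- rj[keep]
  ord <- order(-abs(rj), abs(v$pos[cand] - v$pos[j]), cand)
  cand[ord][seq_len(min(k_cap, length(cand)))]
}

neighbor_cap <- function(n) as.integer(floor(n^(1/3) + 1e-8))

#' Least-squares conditional mean of a variant
#'
#' Fits the linear conditional model of `G_j` on its original-genotype
#' neighbors and the already-generated knockoff copies of those neighbors
#' (per-copy coefficients), by minimizing squared loss. Rank-deficient
#' designs are handled by the minimum-norm convention of the pivoted QR
#' solver (redundant columns dropped). An empty design reduces to the
#' intercept-only fit: the fitted value is the column mean.
#'
#' @param panel A [genotype_panel()].
#' @param knockoffs List of `M` knockoff matrices generated so far (columns
#'   not yet generated may hold anything; only `generated` columns are used).
#' @param neighbors Integer vector of neighbor indices.
#' @param j Target variant index.
#' @param generated Logical vector marking columns already generated.
#' @return List with `fitted` and `residual` n-vectors and `coef`.
#' @export
fit_conditional_mean <- function(panel, knockoffs, neighbors, j,
                                 generated = rep(FALSE, n_variants(panel))) {
  g <- panel$dosages[, j]
  design <- conditional_design(panel, knockoffs, neighbors, generated,
                               n_samples(panel))
  if (is.null(design)) {
    fitted <- rep(mean(g), length(g))
    return(list(fitted = fitted, residual = g - fitted,
                coef = stats::setNames(mean(g), "(Intercept)")))
  }
  X <- cbind(`(Intercept)` = 1, design)
  # normal equations with Cholesky; tiny ridge when (near-)rank-deficient
  XtX <- crossprod(X)
  Xtg <- crossprod(X, g)
  co <- tryCatch(drop(chol2inv(chol(XtX)) %*% Xtg), error = function(e) NULL)
  if (is.null(co) || anyNA(co)) {
    co <- drop(solve(XtX + 1e-6 * diag(ncol(X)), Xtg))
  }
  fitted <- drop(X %*% co)
  list(fitted = fitted, residual = g - fitted,
       coef = stats::setNames(co, colnames(X)))
}

# Assemble the conditioning design: original neighbors plus all M knockoff
# copies of neighbors already generated. With neighbors capped at K the
# total design width is at most K * (M + 1) by construction.
conditional_design <- function(panel, knockoffs, neighbors, generated, n) {
  if (!length(neighbors)) return(NULL)
  done <- neighbors[generated[neighbors]]
  if (!length(done) || !length(knockoffs)) {
    return(panel$dosages[, neighbors, drop = FALSE])
  }
  kn_cols <- if (is.list(knockoffs[[1]])) {
    # generator-internal representation: per-copy lists of column vectors
    unlist(lapply(knockoffs, function(cp) cp[done]), recursive = FALSE)
  } else {
    lapply(knockoffs, function(cp) cp[, done, drop = FALSE])
  }
  do.call(cbind, c(list(panel$dosages[, neighbors, drop = FALSE]), kn_cols))
}

#' Generate multiple knockoff copies of a genotype panel
#'
#' Produces `M` synthetic dosage matrices exchangeable with the original
#' panel via a sequential conditional model. Variants are processed in
#' genomic-position order; each tight-LD cluster is generated jointly when
#' its first member is reached. For each cluster member the conditional mean
#' given its LD neighbors (excluding cluster co-members) and the previously
#' generated knockoff columns is fitted by least squares; then `M`
#' independent permutations of individuals are drawn and the same
#' permutation (per copy) is applied jointly to all cluster members'
#' residual vectors, preserving within-cluster residual correlation. The
#' knockoff dosage is fitted value plus permuted residual, kept continuous
#' and never clipped to `[0, 2]`.
#'
#' @param panel A [genotype_panel()].
#' @param M Number of knockoff copies (default 5).
#' @param seed Integer seed; the same seed reproduces the knockoff set
#'   bit for bit.
#' @param clusters Optional precomputed cluster ids from [ld_clusters()].
#' @return An object of class `knockoff_set`: list with `copies` (list of
#'   `M` matrices), `M` and `seed`.
#' @export
generate_knockoffs <- function(panel, M = 5, seed = 1, clusters = NULL) {
  stopifnot(M >= 1, n_variants(panel) >= 1)
  set.seed(as.integer(seed))
  n <- n_samples(panel)
  p <- n_variants(panel)
  v <- panel$variants

  # columns accumulate in per-copy lists (assembled into matrices at the
  # end) so earlier copies can be read during later fits without
  # triggering copy-on-write of whole matrices
  kcols <- replicate(M, vector("list", p), simplify = FALSE)
  generated <- rep(FALSE, p)

  cl_offset <- 0L
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    r_chr <- if (length(idx) > 1L) {
      safe_cor(panel$dosages[, idx, drop = FALSE])
    } else {
      matrix(1, 1, 1)
    }
    if (is.null(clusters)) {
      # reuse the per-chromosome correlation block for clustering
      cl_chr <- clusters_from_r(if (length(idx) > 1L) r_chr else NULL,
                                length(idx))
      clusters_chr <- integer(p)
      clusters_chr[idx] <- cl_offset + cl_chr
      cl_offset <- cl_offset + max(cl_chr)
    } else {
      clusters_chr <- clusters
    }
    lookup <- integer(p)
    lookup[idx] <- seq_along(idx)
    for (j in idx) {
      if (generated[j]) next
      members <- idx[clusters_chr[idx] == clusters_chr[j] & !generated[idx]]
      fits <- lapply(members, function(jj) {
        nb_local <- select_neighbors_local(v, clusters_chr, jj, idx, r_chr,
                                           lookup, n)
        fit_conditional_mean(panel, kcols, nb_local, jj, generated)
      })
      for (m in seq_len(M)) {
        perm <- sample.int(n)
        for (i in seq_along(members)) {
          kcols[[m]][[members[i]]] <-
            fits[[i]]$fitted + fits[[i]]$residual[perm]
        }
      }
      generated[members] <- TRUE
    }
  }
  copies <- lapply(kcols, function(cl) {
    m <- do.call(cbind, cl)
    dimnames(m) <- dimnames(panel$dosages)
    m
  })
  structure(list(copies = copies, M = M, seed = seed), class = "knockoff_set")
}

# neighbor selection against a per-chromosome correlation block
select_neighbors_local <- function(v, clusters, j, idx, r_chr, lookup, n) {
  cand <- idx[abs(v$pos[idx] - v$pos[j]) <= 1e5 &
                idx != j & clusters[idx] != clusters[j]]
  if (!length(cand)) return(integer(0))
  rj <- r_chr[lookup[cand], lookup[j]]
  keep <- abs(rj) > 0.05
  cand <- cand[keep]
  if (!length(cand)) return(integer(0))
  rj <- rj[keep]
  ord <- order(-abs(rj), abs(v$pos[cand] - v$pos[j]), cand)
  cand[ord][seq_len(min(neighbor_cap(n), length(cand)))]
}

#' @export
print.knockoff_set <- function(x, ...) {
  cat(sprintf("<knockoff_set> M = %d copies of %d x %d dosages (seed %d)\n",
              x$M, nrow(x$copies[[1]]), ncol(x$copies[[1]]), x$seed))
  invisible(x)
}
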