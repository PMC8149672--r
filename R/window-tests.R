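#' Ensemble p-value for one window
#'
#' Computes the window importance score used by the screen: for 1 bp
#' windows, the single-variant score test (saddlepoint-corrected for binary
#' traits); for multi-bp windows, the Cauchy combination of an ensemble of
#' tests computed on the window's variants:
#'
#' * burden and dispersion (SKAT) tests on common + low-frequency variants
#'   with Beta(1, 25) MAF weights;
#' * burden and SKAT on rare variants (MAF <= 0.01, MAC >= 5) with
#'   Beta(1, 25) weights;
#' * burden and SKAT on rare variants re-weighted by each supplied
#'   functional-annotation score (min-max scaled to `[0, 1]` per window and
#'   multiplied with the Beta weight);
#' * an unweighted burden of ultra-rare variants (MAC < 5);
#' * single-variant score tests for every variant in the window.
#'
#' Components whose variant set is empty (or degenerate) are omitted, not
#' entered as p = 1. Exactly the same code path is used whether `dosages`
#' is the original panel matrix or a knockoff copy; variant categories and
#' weights always come from the original panel's variant table so original
#' and knockoff windows contain matched variant sets.
#'
#' @param null A [fit_null_model()] object.
#' @param dosages Dosage matrix (original or one knockoff copy).
#' @param window One row of a [tile_windows()] tibble.
#' @param variants The panel's variant tibble ([variant_info()]).
#' @param annotations Optional tibble with `variant_id` plus numeric score
#'   columns.
#' @param use_spa Apply the saddlepoint tail in 1 bp windows (binomial).
#' @param details Return the per-component p-values instead of the
#'   combined value.
#' @return Combined p-value, or (with `details = TRUE`) a tibble of
#'   components `test_id`, `p`.
#' @export
window_pvalue <- function(null, dosages, window, variants,
                          annotations = NULL, use_spa = TRUE,
                          details = FALSE) {
  ann <- annotation_matrix(annotations, variants)
  ctx <- build_scan_ctx(null, dosages, variants, ann,
                        use_spa && null$family == "binomial")
  comps <- window_components(ctx, window$members[[1]],
                             window$size_class[[1]], named = TRUE)
  if (details) {
    return(tibble::tibble(
      test_id = names(comps) %||% character(),
      p = unname(unlist(comps)) %||% numeric()
    ))
  }
  if (!length(comps)) return(NA_real_)
  cauchy_combine(unlist(comps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# match annotation scores to panel variants; returns p x K numeric matrix
# or NULL
annotation_matrix <- function(annotations, variants) {
  if (is.null(annotations)) return(NULL)
  annotations <- as.data.frame(annotations)
  stopifnot("variant_id" %in% names(annotations))
  score_cols <- setdiff(names(annotations), "variant_id")
  if (!length(score_cols)) return(NULL)
  m <- match(variants$variant_id, annotations$variant_id)
  out <- as.matrix(annotations[m, score_cols, drop = FALSE])
  rownames(out) <- variants$variant_id
  out
}

# Precompute, once per dosage matrix, everything the per-window ensemble
# needs: per-column score statistics U_j = g_j' res, covariate projections
# B = X'Wg_j, score variances V_j, and the sqrt(W)-scaled dosages used for
# the window cross-products.
build_scan_ctx <- function(null, dosages, variants, ann, use_spa) {
  U <- drop(crossprod(dosages, null$residuals))
  if (null$family == "gaussian") {
    # constant variance weights: scale cross-products instead of copying
    # the dosage matrix twice
    s2 <- null$w[1]
    sG <- dosages
    e_scale <- s2
    B <- s2 * crossprod(null$X, dosages)
    V <- pmax(s2 * colSums(dosages * dosages) -
                colSums(B * (null$A %*% B)), 0)
  } else {
    sG <- sqrt(null$w) * dosages
    e_scale <- 1
    B <- crossprod(null$X, null$w * dosages)
    V <- pmax(colSums(sG * sG) - colSums(B * (null$A %*% B)), 0)
  }
  p_sv <- rep(NA_real_, length(U))
  ok <- V > 1e-12
  p_sv[ok] <- pmax(stats::pchisq(U[ok]^2 / V[ok], df = 1,
                                 lower.tail = FALSE), 1e-300)
  if (use_spa) {
    # saddlepoint tail for every single-variant score test of a binary
    # trait; only columns beyond the switch threshold differ from the
    # normal tail, so the correction is computed just for those
    needs <- which(ok & U^2 / V >= 4)
    for (j in needs) {
      p_sv[j] <- saddlepoint_pvalue(U[j], dosages[, j], null)
    }
  }
  list(
    null = null, dosages = dosages, sG = sG, e_scale = e_scale,
    U = U, B = B, V = V, p_sv = p_sv,
    category = as.character(variants$category),
    maf = as.numeric(variants$maf),
    variant_id = as.character(variants$variant_id),
    ann = ann, use_spa = use_spa
  )
}

# The per-window ensemble; returns a numeric vector of component p-values
# (named only when `named = TRUE`, the slow introspection path).
window_components <- function(ctx, members, size_class, named = FALSE) {
  null <- ctx$null
  if (size_class == "1bp") {
    j <- members[1]
    if (ctx$V[j] <= 1e-12) return(numeric(0))
    return(c(sv = ctx$p_sv[j]))
  }

  cat_m <- ctx$category[members]
  Um <- ctx$U[members]
  comps <- numeric(0)

  # covariate-projected cross-product over the window, computed lazily
  # (only once some component has >= 2 variants) and shared by all
  # burden/SKAT components
  E_full <- NULL
  get_E <- function() {
    if (is.null(E_full)) {
      sGs <- ctx$sG[, members, drop = FALSE]
      Bs <- ctx$B[, members, drop = FALSE]
      E_full <<- ctx$e_scale * crossprod(sGs) - crossprod(Bs, null$A %*% Bs)
    }
    E_full
  }

  grp_test <- function(idx, wts, id, skat = TRUE) {
    if (length(idx) == 1L) {
      # exact 1-df reduction: weighted burden and the quadratic form both
      # collapse to the single-variant score test
      pv <- ctx$p_sv[members[idx]]
      if (is.na(pv) || wts[1] == 0) return(numeric(0))
      out <- rep(pv, if (skat) 2L else 1L)
      if (named) {
        names(out) <- paste0(c("burden_", "skat_")[seq_along(out)], id)
      }
      return(out)
    }
    E <- get_E()[idx, idx, drop = FALSE]
    Vb <- drop(crossprod(wts, E %*% wts))
    Ub <- sum(wts * Um[idx])
    out <- numeric(0)
    if (Vb > 1e-12) {
      pb <- if (ctx$use_spa && Ub^2 / Vb >= 4) {
        # the burden is itself a near-lattice dosage sum for rare carriers,
        # so binary traits get the same saddlepoint tail as single variants
        b <- drop(ctx$dosages[, members[idx], drop = FALSE] %*% wts)
        saddlepoint_pvalue(Ub, b, null)
      } else {
        max(stats::pchisq(Ub^2 / Vb, df = 1, lower.tail = FALSE), 1e-300)
      }
      out <- if (named) c(out, stats::setNames(pb, paste0("burden_", id))) else c(out, pb)
    }
    if (skat) {
      K <- E * tcrossprod(wts)
      lambda <- if (nrow(K) == 2L) {
        # closed-form symmetric 2x2 eigenvalues
        tr <- K[1] + K[4]
        d <- sqrt(max((K[1] - K[4])^2 + 4 * K[2]^2, 0))
        c(tr + d, tr - d) / 2
      } else {
        eigen(K, symmetric = TRUE, only.values = TRUE)$values
      }
      lambda <- lambda[lambda > 1e-10 * max(lambda, 0)]
      if (length(lambda)) {
        ps <- pchisqmix(sum((wts * Um[idx])^2), lambda)
        out <- if (named) c(out, stats::setNames(ps, paste0("skat_", id))) else c(out, ps)
      }
    }
    out
  }

  cl <- which(cat_m %in% c("common", "low_frequency"))
  if (length(cl)) {
    comps <- c(comps, grp_test(cl, beta_maf_weights(ctx$maf[members[cl]]),
                               "common_lf"))
  }

  ra <- which(cat_m == "rare")
  if (length(ra)) {
    wbeta <- beta_maf_weights(ctx$maf[members[ra]])
    comps <- c(comps, grp_test(ra, wbeta, "rare"))
    if (!is.null(ctx$ann)) {
      for (k in seq_len(ncol(ctx$ann))) {
        sc <- ctx$ann[members[ra], k]
        sc[is.na(sc)] <- 0
        rng <- range(sc)
        scaled <- if (rng[2] > rng[1]) {
          (sc - rng[1]) / (rng[2] - rng[1])
        } else {
          rep(1, length(sc))
        }
        wts <- scaled * wbeta
        if (any(wts > 0)) {
          comps <- c(comps, grp_test(ra, wts,
                                     paste0("ann_", colnames(ctx$ann)[k])))
        }
      }
    }
  }

  # unweighted carrier burden is the informative ultra-rare component; the
  # corresponding quadratic form is near-degenerate at MAC < 5 and omitted
  ur <- which(cat_m == "ultra_rare")
  if (length(ur)) {
    comps <- c(comps, grp_test(ur, rep(1, length(ur)), "ultrarare",
                               skat = FALSE))
  }

  keep <- !is.na(ctx$p_sv[members])
  if (any(keep)) {
    sv <- ctx$p_sv[members][keep]
    if (named) names(sv) <- paste0("sv_", ctx$variant_id[members][keep])
    comps <- c(comps, sv)
  }
  comps
}

# ACAT without the argument validation of the exported function; inputs are
# p-values this package just computed.
acat_fast <- function(p) {
  p <- pmin(p, 1 - 1e-15)
  tiny <- p < 1e-15
  t_j <- numeric(length(p))
  t_j[tiny] <- 1 / (p[tiny] * pi)
  t_j[!tiny] <- tanpi(0.5 - p[!tiny])
  T_stat <- mean(t_j)
  pv <- if (T_stat > 1e15) 1 / (T_stat * pi) else 0.5 - atan(T_stat) / pi
  max(min(pv, 1), 1e-300)
}

# Batch engine: p-values for every window on one dosage matrix.
scan_pvalues <- function(null, dosages, windows, variants, ann = NULL,
                         use_spa = TRUE) {
  ctx <- build_scan_ctx(null, dosages, variants, ann,
                        use_spa && null$family == "binomial")
  members <- windows$members
  size_class <- windows$size_class
  vapply(seq_along(members), function(i) {
    comps <- window_components(ctx, members[[i]], size_class[[i]])
    if (!length(comps)) NA_real_ else acat_fast(comps)
  }, numeric(1))
}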