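#' Keep one representative variant per tight-LD cluster
#'
#' Applies the 0.75 tight-LD clustering and keeps a single randomly chosen
#' member of each cluster. Used by the single-region simulation design so
#' that empirical FDR is well defined (no two retained variants are near
#' copies of one another).
#'
#' @param panel A [genotype_panel()].
#' @return A `genotype_panel` of cluster representatives.
#' @export
ld_representatives <- function(panel) {
  cl <- ld_clusters(panel)
  keep <- vapply(split(seq_along(cl), cl), function(ix) {
    if (length(ix) == 1L) ix else sample_from(ix, 1)
  }, integer(1))
  panel_subset(panel, sort(keep))
}

#' Subset a panel to a set of variant columns
#'
#' @param panel A [genotype_panel()].
#' @param idx Variant column indices (or a logical vector).
#' @return A `genotype_panel`.
#' @export
panel_subset <- function(panel, idx) {
  genotype_panel(panel$dosages[, idx, drop = FALSE], panel$variants[idx, ])
}

combine_panels <- function(panels) {
  genotype_panel(
    do.call(cbind, lapply(panels, `[[`, "dosages")),
    dplyr::bind_rows(lapply(panels, `[[`, "variants"))
  )
}

#' Conventional association-test comparator
#'
#' The same window ensemble p-values as the knockoff screen, thresholded
#' the conventional ways: Bonferroni at `0.05 / #windows` (FWER control)
#' and Benjamini-Hochberg at the target FDR. Used by the simulation
#' designs to reproduce the comparisons against standard association
#' testing.
#'
#' @param p Vector of per-window p-values (original cohort).
#' @param q Target FDR for the BH rule.
#' @param alpha Family-wise error level for the Bonferroni rule.
#' @return Tibble with logical columns `bonferroni` and `bh`.
#' @export
conventional_selection <- function(p, q = 0.1, alpha = 0.05) {
  tibble::tibble(
    bonferroni = p < alpha / length(p),
    bh = stats::p.adjust(p, "BH") <= q
  )
}

# Re-apply the knockoff filter at a different target FDR from a tidy scan
# table (needs columns W, kappa, tau).
rethreshold <- function(windows, M, q, method = c("multiple", "single")) {
  method <- match.arg(method)
  if (method == "single") threshold_single(windows$W, q)$selected
  else threshold_multiple(windows, M, q)$selected
}

# long, tightly correlated LD blocks emulating a strong-LD region like the
# APOE neighborhood, used by the prioritization and shadow designs
tight_ld_panel <- function(n, p, seed) {
  simulate_genotypes(n, p, block_range = c(10, 24),
                     rho_range = c(0.9, 0.995), seed = seed)
}

causal_truth <- function(causal) {
  tibble::tibble(chrom = causal$chrom, start = causal$pos, end = causal$pos)
}

#' Run a simulation design
#'
#' Reproduces the package's simulation experiments: single-region power and
#' FDR, genome-wide multi-locus locus discovery, causal-variant
#' prioritization, the shadow-effect comparison, population stratification
#' and knockoff-stability. Problem sizes are arguments so the designs can
#' be run at reduced scale; the defaults are the scaled-down study
#' conditions described in the package vignette.
#'
#' @param design One of `"single_region"`, `"genome_wide"`,
#'   `"prioritization"`, `"shadow"`, `"stratification"`, `"stability"`.
#' @param reps Number of replicates.
#' @param seed Integer seed driving all randomness.
#' @param ... Design-specific knobs passed through (see the individual
#'   `design_*` functions).
#' @return A list with elements `per_rep` (tibble) and `summary` (tibble).
#' @export
run_design <- function(design = c("single_region", "genome_wide",
                                  "prioritization", "shadow",
                                  "stratification", "stability"),
                       reps = 10, seed = 1, ...) {
  design <- match.arg(design)
  fn <- switch(design,
    single_region = design_single_region,
    genome_wide = design_genome_wide,
    prioritization = design_prioritization,
    shadow = design_shadow,
    stratification = design_stratification,
    stability = design_stability
  )
  fn(reps = reps, seed = seed, ...)
}

#' Single-region power and FDR design
#'
#' Per replicate: simulate an LD-block panel over a 200 kb region, keep one
#' representative per 0.75 tight-LD cluster, retain `p` variants, set 0.5%
#' of them causal within a 10 kb signal window (common- or rare-variant
#' focus with genetic-variance targets 0.05 and 0.1 respectively), simulate
#' the trait, run the `M`-knockoff screen and evaluate window-level power
#' and FDP (a window is causal if it contains a causal variant) at each
#' target FDR in `qs`. Optionally also evaluates the single-knockoff filter
#' on the first knockoff copy for the power comparison.
#'
#' @param reps,seed Replicates and master seed.
#' @param n,p Individuals and retained variants per replicate.
#' @param focus Causal-variant scenarios to run: any of `"common"`,
#'   `"rare"`. The genotype panel and knockoff set of a replicate are
#'   shared across scenarios (knockoffs do not depend on the phenotype).
#' @param family Trait family.
#' @param qs Target FDR grid.
#' @param M Number of knockoffs.
#' @param compare_single Also evaluate the single-knockoff filter on the
#'   first knockoff copy.
#' @return List with `per_rep` and `summary` tibbles.
#' @export
design_single_region <- function(reps = 10, seed = 1, n = 5000, p = 300,
                                 focus = "common",
                                 family = "gaussian",
                                 qs = c(0.05, 0.1, 0.2), M = 5,
                                 compare_single = FALSE) {
  set.seed(as.integer(seed))
  seeds <- sample.int(2^28, reps)
  rows <- vector("list", 0L)
  for (r in seq_len(reps)) {
    raw <- simulate_genotypes(n, round(p * 1.6), seed = seeds[r])
    reps_panel <- ld_representatives(raw)
    if (n_variants(reps_panel) > p) {
      reps_panel <- panel_subset(
        reps_panel, sort(sample.int(n_variants(reps_panel), p))
      )
    }
    kn <- generate_knockoffs(reps_panel, M = M, seed = seeds[r] + 1)
    for (fc in focus) {
      cfg <- sim_config(
        causal_fraction = 0.005, signal_window_bp = 10000,
        effect = "variance",
        variance_target = if (fc == "common") 0.05 else 0.1,
        family = family, focus = fc
      )
      sim <- simulate_phenotype(reps_panel, cfg)
      scan <- ks_scan(reps_panel, sim$pheno, "y", "x1", family = family,
                      fdr = qs[1], seed = seeds[r] + 1, knockoffs = kn)
      tw <- tidy(scan)
      truth <- causal_truth(sim$causal)
      single <- if (compare_single) feature_stats(tw$p, tw$p_knockoff_1)
      for (q in qs) {
        tw$selected <- rethreshold(tw, M, q)
        ev <- evaluate_selection(tw, truth, buffers = integer(0))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          rep = r, focus = fc, q = q, method = paste0("M", M),
          power = ev$power, fdp = ev$fdp, n_selected = sum(tw$selected)
        )
        if (compare_single) {
          tw$selected <- threshold_single(single$W, q)$selected
          ev1 <- evaluate_selection(tw, truth, buffers = integer(0))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            rep = r, focus = fc, q = q, method = "M1",
            power = ev1$power, fdp = ev1$fdp, n_selected = sum(tw$selected)
          )
        }
      }
    }
  }
  per_rep <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$focus, .data$q, .data$method),
    power = mean(.data$power, na.rm = TRUE), fdr = mean(.data$fdp),
    fdr_se = stats::sd(.data$fdp) / sqrt(dplyr::n()), .groups = "drop"
  )
  list(per_rep = per_rep, summary = summary)
}

#' Genome-wide multi-locus design
#'
#' Simulates independent 200 kb loci on separate chromosomes
#' (`n_causal` causal + `n_noise` noise), places a 10 kb causal window in
#' each causal locus with 10% of its variants causal and per-locus genetic
#' variance 1, simulates a quantitative trait, scans the whole panel and
#' evaluates locus-level power (fraction of causal loci hit) and FDP at
#' distance buffers around the causal windows.
#'
#' @inheritParams design_single_region
#' @param n_causal,n_noise Numbers of causal and noise loci.
#' @param variants_per_locus Variants simulated per locus.
#' @param q Target FDR.
#' @param buffers Distance buffers (bp) for locus-level FDP.
#' @export
design_genome_wide <- function(reps = 5, seed = 1, n = 3000,
                               n_causal = 10, n_noise = 50,
                               variants_per_locus = 24, q = 0.1, M = 5,
                               family = "gaussian",
                               buffers = c(50000, 75000, 100000)) {
  set.seed(as.integer(seed))
  seeds <- sample.int(2^28, reps)
  n_loci <- n_causal + n_noise
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    panels <- lapply(seq_len(n_loci), function(k) {
      simulate_genotypes(n, variants_per_locus,
                         chrom = sprintf("locus%03d", k),
                         seed = seeds[r] + k)
    })
    panel <- combine_panels(panels)
    set.seed(seeds[r])
    causal_loci <- sort(sample.int(n_loci, n_causal))
    v <- panel$variants
    eta <- rep(0, n)
    sws <- vector("list", n_causal)
    for (i in seq_along(causal_loci)) {
      chr <- sprintf("locus%03d", causal_loci[i])
      vloc <- v[v$chrom == chr, ]
      # causal variants are drawn from MAF > 0.01 sites: at this scale a
      # causal window holds only a couple of causal variants, and
      # concentrating a per-locus variance of 1 on a rare site would give
      # a single carrier an outcome shift of ~15 residual SDs, creating
      # chance-carrier-sharing associations across loci that no local-LD
      # knockoff can silence
      elig <- vloc$maf > 0.01
      sw <- place_signal_window(vloc, elig, 10000, 1)
      in_win <- which(v$chrom == chr & v$maf > 0.01 &
                        v$pos >= sw$start & v$pos <= sw$end)
      s <- max(1L, round(0.1 * length(in_win)))
      cidx <- sort(sample_from(in_win, s))
      G <- panel$dosages[, cidx, drop = FALSE]
      m <- v$maf[cidx]
      shape <- 1 / sqrt(2 * m * (1 - m))
      vg <- apply(G, 2, stats::var)
      a <- sqrt(1 / sum(shape^2 * vg))
      eta <- eta + drop(G %*% (a * shape))
      sws[[i]] <- sw
    }
    signal_windows <- dplyr::bind_rows(sws)
    x1 <- stats::rnorm(n)
    y <- x1 + eta + stats::rnorm(n, sd = sqrt(3))
    scan <- ks_scan(panel, tibble::tibble(y = y, x1 = x1), "y", "x1",
                    family = family, M = M, fdr = q, seed = seeds[r] + 1)
    tw <- tidy(scan)
    sel <- tw[tw$selected, ]
    hit <- vapply(seq_len(nrow(signal_windows)), function(i) {
      any(sel$chrom == signal_windows$chrom[i])
    }, logical(1))
    out <- tibble::tibble(rep = r, q = q,
                          power = mean(hit),
                          n_selected = nrow(sel))
    for (b in buffers) {
      out[[paste0("fdp_", format(b, scientific = FALSE))]] <-
        if (nrow(sel)) mean(!overlaps_any(sel, signal_windows, b)) else 0
    }
    rows[[r]] <- out
  }
  per_rep <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise_at(
    dplyr::group_by(per_rep, .data$q),
    dplyr::vars(-"rep"), mean
  )
  list(per_rep = per_rep, summary = summary)
}

#' Causal-variant prioritization design
#'
#' Binary trait with 0.25% causal variants in a 5 kb window and effects
#' `1.4 |log10 MAF|`; compares the knockoff screen against conventional
#' Bonferroni selection on the fraction of selected windows overlapping the
#' causal window and the maximum distance from a selected window to it.
#'
#' @inheritParams design_single_region
#' @param q Target FDR.
#' @export
design_prioritization <- function(reps = 5, seed = 1, n = 3000, p = 300,
                                  q = 0.1, M = 5) {
  set.seed(as.integer(seed))
  seeds <- sample.int(2^28, reps)
  cfg <- sim_config(causal_fraction = 0.0025, signal_window_bp = 5000,
                    effect = "log_maf", a = 1.4, family = "binomial",
                    focus = "all")
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    panel <- tight_ld_panel(n, p, seeds[r])
    sim <- simulate_phenotype(panel, cfg)
    scan <- ks_scan(panel, sim$pheno, "y", "x1", family = "binomial",
                    M = M, fdr = q, seed = seeds[r] + 1)
    tw <- tidy(scan)
    conv <- conventional_selection(tw$p, q = q)
    sw <- sim$signal_window
    dist_to <- function(sel) {
      if (!nrow(sel)) return(NA_real_)
      max(pmax(0, pmax(sw$start - sel$end, sel$start - sw$end)))
    }
    frac_overlap <- function(sel) {
      if (!nrow(sel)) return(NA_real_)
      mean(overlaps_any(sel, sw, 0))
    }
    ks_sel <- tw[tw$selected, ]
    bf_sel <- tw[conv$bonferroni, ]
    rows[[r]] <- tibble::tibble(
      rep = r,
      ks_overlap = frac_overlap(ks_sel), ks_maxdist = dist_to(ks_sel),
      conv_overlap = frac_overlap(bf_sel), conv_maxdist = dist_to(bf_sel),
      ks_n = nrow(ks_sel), conv_n = nrow(bf_sel)
    )
  }
  per_rep <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise_all(per_rep[-1], mean, na.rm = TRUE)
  list(per_rep = per_rep, summary = summary)
}

#' Shadow-effect design
#'
#' Causal variants are common (MAF > 0.01) but the screen is applied to
#' rare variants only, so every detection is a false positive induced by LD
#' with the common causal variants. Counts false positives for the
#' knockoff screen and for the conventional Bonferroni comparator on the
#' identical rare-variant window p-values.
#'
#' @inheritParams design_prioritization
#' @export
design_shadow <- function(reps = 5, seed = 1, n = 3000, p = 300,
                          q = 0.1, M = 5) {
  set.seed(as.integer(seed))
  seeds <- sample.int(2^28, reps)
  cfg <- sim_config(causal_fraction = 0.0025, signal_window_bp = 5000,
                    effect = "log_maf", a = 1.4, family = "binomial",
                    focus = "common")
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    panel <- tight_ld_panel(n, p, seeds[r])
    sim <- simulate_phenotype(panel, cfg)
    rare <- which(panel$variants$maf < 0.01)
    if (length(rare) < 5) next
    rare_panel <- panel_subset(panel, rare)
    # knockoffs are generated from the full panel so the rare knockoffs
    # keep their LD with the (excluded) common causal variants -- this is
    # what lets the filter recognize the shadow as a proxy association
    kn_full <- generate_knockoffs(panel, M = M, seed = seeds[r] + 1)
    kn_rare <- structure(
      list(copies = lapply(kn_full$copies, function(cp) {
        cp[, rare, drop = FALSE]
      }), M = M, seed = kn_full$seed),
      class = "knockoff_set"
    )
    scan <- ks_scan(rare_panel, sim$pheno, "y", "x1", family = "binomial",
                    M = M, fdr = q, seed = seeds[r] + 1,
                    knockoffs = kn_rare)
    tw <- tidy(scan)
    conv <- conventional_selection(tw$p, q = q)
    rows[[r]] <- tibble::tibble(
      rep = r, ks_fp = sum(tw$selected), conv_fp = sum(conv$bonferroni),
      bh_fp = sum(conv$bh)
    )
  }
  per_rep <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise_all(per_rep[-1], mean)
  list(per_rep = per_rep, summary = summary)
}

# latent-block panel with group-shifted allele frequencies
# (Balding-Nichols Beta drift around a shared base spectrum)
simulate_stratified_genotypes <- function(n_per_group, p, fst = 0.05,
                                          seed = 1, chrom = "chr1") {
  set.seed(as.integer(seed))
  base <- simulate_genotypes(sum(n_per_group), p, seed = seed, chrom = chrom)
  p <- ncol(base$dosages)  # monomorphic draws were dropped
  f <- pmax(colMeans(base$dosages) / 2, 1 / (2 * sum(n_per_group)))
  pos <- base$variants$pos
  groups <- rep(seq_along(n_per_group), n_per_group)
  dos <- matrix(0L, sum(n_per_group), p)
  rstart <- 0L
  for (g in seq_along(n_per_group)) {
    ng <- n_per_group[g]
    shape1 <- f * (1 - fst) / fst
    shape2 <- (1 - f) * (1 - fst) / fst
    fg <- stats::rbeta(p, shape1, shape2)
    fg <- pmin(pmax(fg, 1e-5), 0.999)
    thresh <- stats::qnorm(1 - fg)
    block <- 8L
    for (h in 1:2) {
      j0 <- 0L
      while (j0 < p) {
        len <- min(block, p - j0)
        z <- matrix(stats::rnorm(ng * len), ng, len)
        if (len > 1) for (k in 2:len) z[, k] <- 0.7 * z[, k - 1] + sqrt(1 - 0.49) * z[, k]
        idx <- j0 + seq_len(len)
        dos[rstart + seq_len(ng), idx] <- dos[rstart + seq_len(ng), idx] +
          (z > rep(thresh[idx], each = ng))
        j0 <- j0 + len
      }
    }
    rstart <- rstart + ng
  }
  list(
    panel = genotype_panel(dos, data.frame(
      variant_id = sprintf("%s_v%04d", chrom, seq_len(p)),
      chrom = chrom, pos = pos
    )),
    groups = groups
  )
}

#' Population-stratification design
#'
#' Three subpopulations with drifted allele frequencies; the trait mean (or
#' prevalence) depends on the subpopulation but on no genetic variant, so
#' every detection is a stratification false positive. Compares the
#' knockoff screen and the conventional Bonferroni comparator, unadjusted
#' and adjusted for the leading principal components of the dosage matrix.
#' With `mode = "rare_driven"`, background loci carrying rare causal
#' variants (scaled effect `gamma`) create the prevalence differences
#' instead of a direct group shift, and the null target region is
#' evaluated.
#'
#' @inheritParams design_prioritization
#' @param family Trait family.
#' @param mode `"mean_shift"` or `"rare_driven"`.
#' @param gamma Stratification magnitude for `"rare_driven"`.
#' @param n_pcs Principal components used in the adjusted analyses.
#' @param n_background Background causal loci for `"rare_driven"`.
#' @export
design_stratification <- function(reps = 5, seed = 1, n = 1500, p = 150,
                                  q = 0.1, M = 5,
                                  family = "gaussian",
                                  mode = c("mean_shift", "rare_driven"),
                                  gamma = 0.5, n_pcs = 10,
                                  n_background = 20) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  seeds <- sample.int(2^28, reps)
  npg <- rep(n %/% 3, 3)
  npg[1] <- n - sum(npg[2:3])
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    sg <- simulate_stratified_genotypes(npg, p, seed = seeds[r])
    panel <- sg$panel
    z <- sg$groups - 1
    nn <- sum(npg)
    x1 <- stats::rnorm(nn)
    if (mode == "mean_shift") {
      eta_strat <- z
    } else {
      eta_strat <- rep(0, nn)
      for (k in seq_len(n_background)) {
        bg <- simulate_stratified_genotypes(npg, 20, seed = seeds[r] + 1000 + k,
                                            chrom = sprintf("bg%03d", k))
        vb <- bg$panel$variants
        rare <- which(vb$maf < 0.01 & vb$mac > 10)
        if (length(rare) < 1) next
        cidx <- rare[seq_len(max(1L, round(0.1 * length(rare))))]
        G <- bg$panel$dosages[, cidx, drop = FALSE]
        m <- vb$maf[cidx]
        shape <- 1 / sqrt(2 * m * (1 - m))
        vg <- apply(G, 2, stats::var)
        a <- sqrt(0.01 / sum(shape^2 * vg))
        eta_strat <- eta_strat + gamma * drop(G %*% (a * shape))
      }
    }
    if (family == "gaussian") {
      y <- x1 + eta_strat + stats::rnorm(nn, sd = sqrt(3))
    } else {
      b0 <- stats::uniroot(function(b) mean(stats::plogis(b + x1 + eta_strat)) - 0.1,
                           c(-50, 50))$root
      y <- stats::rbinom(nn, 1, stats::plogis(b0 + x1 + eta_strat))
    }
    # ancestry PCs are computed from a separate background panel, standing
    # in for genome-wide PCA (principal components of one small test region
    # are far too noisy to capture ancestry)
    bg_pca <- simulate_stratified_genotypes(npg, 800, seed = seeds[r] + 5000,
                                            chrom = "bgPC")
    pcs <- stats::prcomp(bg_pca$panel$dosages, center = TRUE,
                         scale. = FALSE)$x[, seq_len(n_pcs), drop = FALSE]
    ph <- tibble::tibble(y = y, x1 = x1)
    ph_pc <- dplyr::bind_cols(ph, tibble::as_tibble(pcs))
    kn <- generate_knockoffs(panel, M = M, seed = seeds[r] + 1)
    scan_u <- ks_scan(panel, ph, "y", "x1", family = family, M = M,
                      fdr = q, seed = seeds[r] + 1, knockoffs = kn)
    scan_a <- ks_scan(panel, ph_pc, "y", c("x1", colnames(pcs)),
                      family = family, M = M, fdr = q,
                      seed = seeds[r] + 1, knockoffs = kn)
    conv_u <- conventional_selection(tidy(scan_u)$p, q = q)
    conv_a <- conventional_selection(tidy(scan_a)$p, q = q)
    rows[[r]] <- tibble::tibble(
      rep = r,
      ks_unadj = sum(tidy(scan_u)$selected) > 0,
      ks_adj = sum(tidy(scan_a)$selected) > 0,
      conv_unadj = sum(conv_u$bonferroni) > 0,
      conv_adj = sum(conv_a$bonferroni) > 0
    )
  }
  per_rep <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise_all(per_rep[-1], mean)
  list(per_rep = per_rep, summary = summary)
}

#' Knockoff-stability design
#'
#' Fixes one dataset (binary trait, 1.25% causal variants in a 5 kb window,
#' effects `0.7 |log10 MAF|`), generates a pool of knockoffs once, and
#' repeatedly draws `M` of them. Compares the median-based gap statistic
#' with the max-based variant on the variance of `tau` across redraws and
#' on how often the causal windows are re-selected.
#'
#' @inheritParams design_prioritization
#' @param pool Size of the knockoff pool.
#' @export
design_stability <- function(reps = 20, seed = 1, n = 2000, p = 200,
                             q = 0.1, M = 5, pool = 15) {
  set.seed(as.integer(seed))
  panel <- simulate_genotypes(n, p, seed = seed)
  cfg <- sim_config(causal_fraction = 0.0125, signal_window_bp = 5000,
                    effect = "log_maf", a = 0.7, family = "binomial",
                    focus = "all")
  sim <- simulate_phenotype(panel, cfg)
  null <- fit_null_model(sim$pheno, "y", "x1", "binomial")
  windows <- tile_windows(panel)
  kn <- generate_knockoffs(panel, M = pool, seed = seed + 1)
  p0 <- scan_pvalues(null, panel$dosages, windows, panel$variants,
                     use_spa = TRUE)
  pk <- vapply(kn$copies, function(cp) {
    scan_pvalues(null, cp, windows, panel$variants, use_spa = TRUE)
  }, numeric(nrow(windows)))
  ok <- !is.na(p0) & !apply(pk, 1, anyNA)
  windows <- windows[ok, ]; p0 <- p0[ok]; pk <- pk[ok, , drop = FALSE]
  truth <- causal_truth(sim$causal)
  causal_win <- overlaps_any(windows, truth, 0)

  tau_med <- tau_max <- matrix(NA_real_, nrow(windows), reps)
  sel_med <- sel_max <- matrix(FALSE, nrow(windows), reps)
  for (r in seq_len(reps)) {
    draw <- sample.int(pool, M)
    st_med <- feature_stats(p0, pk[, draw, drop = FALSE], statistic = "median")
    st_max <- feature_stats(p0, pk[, draw, drop = FALSE], statistic = "max")
    tau_med[, r] <- ifelse(st_med$kappa == 0, st_med$tau, -st_med$tau)
    tau_max[, r] <- ifelse(st_max$kappa == 0, st_max$tau, -st_max$tau)
    sel_med[, r] <- threshold_multiple(st_med, M, q)$selected
    sel_max[, r] <- threshold_multiple(st_max, M, q)$selected
  }
  var_med <- apply(tau_med, 1, stats::var)
  var_max <- apply(tau_max, 1, stats::var)
  per_window <- tibble::tibble(
    chrom = windows$chrom, start = windows$start, end = windows$end,
    size_class = windows$size_class, causal = causal_win,
    var_tau_median = var_med, var_tau_max = var_max,
    resel_median = rowMeans(sel_med), resel_max = rowMeans(sel_max)
  )
  summary <- tibble::tibble(
    frac_windows_median_stabler = mean(var_med < var_max, na.rm = TRUE),
    frac_signal_median_stabler =
      mean(var_med[causal_win] < var_max[causal_win], na.rm = TRUE),
    resel_causal_median = mean(rowMeans(sel_med)[causal_win]),
    resel_causal_max = mean(rowMeans(sel_max)[causal_win])
  )
  list(per_rep = per_window, summary = summary)
}
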