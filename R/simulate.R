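#' Simulate an LD-block-structured genotype panel
#'
#' Generates unphased dosages by thresholding a latent block-AR(1) Gaussian
#' copula at per-variant target allele frequencies and summing two
#' independent haplotypes. Variants are organized into LD blocks of random
#' length; within a block the latent correlation decays geometrically, so
#' nearby variants are correlated (occasionally tightly, `|r| > 0.75`)
#' while variants in different blocks are independent. The target MAF
#' spectrum is a mixture over frequency classes placing substantial mass on
#' rare (MAF < 0.01) and ultra-rare (MAC < 5) variants, emulating the site
#' frequency spectrum of sequencing panels; under the default mixture the
#' realized spectrum carries at least ~20% rare and ~5% ultra-rare
#' variants.
#'
#' @param n Number of individuals.
#' @param p Number of variants.
#' @param region_length Region span in bp (positions drawn uniformly).
#' @param block_range Range of LD-block lengths (variants per block).
#' @param rho_range Range of within-block latent AR(1) correlations.
#' @param spectrum Named mixture weights over frequency classes
#'   (`common`, `low_frequency`, `rare`, `ultra_rare`), normalized
#'   internally.
#' @param chrom Chromosome label.
#' @param pos_offset Position of the region start minus 1.
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A [genotype_panel()].
#' @export
simulate_genotypes <- function(n, p, region_length = 2e5,
                               block_range = c(4, 14),
                               rho_range = c(0.4, 0.98),
                               spectrum = c(common = 0.35,
                                            low_frequency = 0.15,
                                            rare = 0.30,
                                            ultra_rare = 0.20),
                               chrom = "chr1", pos_offset = 0L,
                               seed = 1) {
  set.seed(as.integer(seed))
  spectrum <- spectrum / sum(spectrum)
  cls <- sample(names(spectrum), p, replace = TRUE, prob = spectrum)
  # rare class: MAC >= 5 needs f >= 5/(2n); cap below the 0.01 boundary so
  # the class stays nonempty at small n
  f_rare_min <- min(max(5 / (2 * n), 1e-4), 0.009)
  f <- numeric(p)
  f[cls == "common"] <- stats::runif(sum(cls == "common"), 0.05, 0.5)
  f[cls == "low_frequency"] <- stats::runif(sum(cls == "low_frequency"), 0.01, 0.05)
  f[cls == "rare"] <- exp(stats::runif(sum(cls == "rare"),
                                       log(f_rare_min), log(0.01)))
  f[cls == "ultra_rare"] <- sample(1:4, sum(cls == "ultra_rare"),
                                   replace = TRUE) / (2 * n)

  # LD blocks with AR(1) latent correlation, shared by both haplotypes
  blocks <- integer(0)
  while (sum(blocks) < p) {
    blocks <- c(blocks, sample(block_range[1]:block_range[2], 1))
  }
  blocks[length(blocks)] <- blocks[length(blocks)] - (sum(blocks) - p)
  blocks <- blocks[blocks > 0]
  rho <- stats::runif(length(blocks), rho_range[1], rho_range[2])

  thresh <- stats::qnorm(1 - f)
  dos <- matrix(0L, n, p)
  for (h in 1:2) {
    j0 <- 0L
    for (b in seq_along(blocks)) {
      len <- blocks[b]
      z <- matrix(stats::rnorm(n * len), n, len)
      if (len > 1) {
        for (k in 2:len) {
          z[, k] <- rho[b] * z[, k - 1] + sqrt(1 - rho[b]^2) * z[, k]
        }
      }
      idx <- j0 + seq_len(len)
      dos[, idx] <- dos[, idx] + (z > rep(thresh[idx], each = n))
      j0 <- j0 + len
    }
  }

  pos <- sort(sample.int(region_length, p))
  genotype_panel(dos, data.frame(
    variant_id = sprintf("%s_v%04d", chrom, seq_len(p)),
    chrom = chrom, pos = pos + pos_offset
  ))
}

#' Phenotype-generation configuration
#'
#' Bundles the simulation recipe for [simulate_phenotype()]: which variants
#' may be causal, how many, where, the effect-size law and its
#' calibration, and the trait family.
#'
#' Two effect laws are supported. `"variance"` sets
#' `beta_j = a / sqrt(2 m_j (1 - m_j))` and calibrates `a` so the genetic
#' variance `sum_j beta_j^2 var(g_j)` equals `variance_target` exactly on
#' the realized genotypes. `"log_maf"` sets `beta_j = a |log10 m_j|` with
#' `a` given directly.
#'
#' @param causal_fraction Fraction of the panel's variants set causal
#'   (rounded, at least 1).
#' @param signal_window_bp Length of the causal window the causal variants
#'   are drawn from.
#' @param effect `"variance"` or `"log_maf"`.
#' @param variance_target Genetic-variance target for the `"variance"` law.
#' @param a Coefficient for the `"log_maf"` law.
#' @param family Trait family.
#' @param prevalence Target case fraction for binary traits.
#' @param focus Which variants are eligible to be causal: `"all"`,
#'   `"common"` (MAF > 0.01) or `"rare"` (MAF < 0.01).
#' @param eps_var Variance of the residual noise for quantitative traits.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(causal_fraction = 0.005, signal_window_bp = 10000,
                       effect = c("variance", "log_maf"),
                       variance_target = 0.05, a = 1.4,
                       family = c("gaussian", "binomial"),
                       prevalence = 0.1,
                       focus = c("all", "common", "rare"),
                       eps_var = 3) {
  structure(list(
    causal_fraction = causal_fraction,
    signal_window_bp = signal_window_bp,
    effect = match.arg(effect),
    variance_target = variance_target,
    a = a,
    family = match.arg(family),
    prevalence = prevalence,
    focus = match.arg(focus),
    eps_var = eps_var
  ), class = "sim_config")
}

#' Simulate a phenotype on a genotype panel
#'
#' Places a causal window of the configured length uniformly within the
#' panel span (retrying until it holds enough eligible variants), draws the
#' causal variants, computes effect sizes per the configured law, and
#' simulates the trait:
#' quantitative `Y = X1 + sum beta_j g_j + eps` with `X1 ~ N(0, 1)` and
#' `eps ~ N(0, eps_var)`; binary
#' `logit(mu) = beta0 + X1 + sum beta_j g_j` with the intercept solved
#' numerically so the expected prevalence hits the target. With
#' `causal_fraction = 0` no causal window is drawn (global-null and
#' stratification designs).
#'
#' @param panel A [genotype_panel()].
#' @param config A [sim_config()].
#' @return List with `pheno` (tibble: `y`, `x1`), `causal` (tibble of
#'   causal variants), `signal_window` (one-row tibble or NULL), `beta`,
#'   `genetic_variance` (realized `sum beta^2 var(g)`) and `beta0`
#'   (binary traits).
#' @export
simulate_phenotype <- function(panel, config) {
  n <- n_samples(panel)
  v <- panel$variants
  eligible <- switch(config$focus,
    all = rep(TRUE, nrow(v)),
    common = v$maf > 0.01,
    rare = v$maf < 0.01
  )
  x1 <- stats::rnorm(n)
  eta_g <- rep(0, n)
  causal <- v[0, ]
  beta <- numeric(0)
  sw <- NULL
  gvar <- 0

  s <- max(1L, round(config$causal_fraction * nrow(v)))
  if (config$causal_fraction > 0) {
    sw <- place_signal_window(v, eligible, config$signal_window_bp, s)
    in_win <- which(eligible & v$chrom == sw$chrom &
                      v$pos >= sw$start & v$pos <= sw$end)
    cidx <- sort(sample_from(in_win, s))
    G <- panel$dosages[, cidx, drop = FALSE]
    m <- v$maf[cidx]
    vg <- apply(G, 2, stats::var)
    beta <- if (config$effect == "variance") {
      shape <- 1 / sqrt(2 * m * (1 - m))
      a <- sqrt(config$variance_target / sum(shape^2 * vg))
      a * shape
    } else {
      config$a * abs(log10(m))
    }
    eta_g <- drop(G %*% beta)
    gvar <- sum(beta^2 * vg)
    causal <- v[cidx, ]
  }

  if (config$family == "gaussian") {
    y <- x1 + eta_g + stats::rnorm(n, sd = sqrt(config$eps_var))
    beta0 <- NA_real_
  } else {
    eta <- x1 + eta_g
    beta0 <- stats::uniroot(
      function(b0) mean(stats::plogis(b0 + eta)) - config$prevalence,
      lower = -50, upper = 50, tol = 1e-10
    )$root
    y <- stats::rbinom(n, 1, stats::plogis(beta0 + eta))
  }
  list(
    pheno = tibble::tibble(y = y, x1 = x1),
    causal = causal,
    signal_window = sw,
    beta = beta,
    genetic_variance = gvar,
    beta0 = beta0
  )
}

# sample k elements from an index vector; never falls into sample()'s
# scalar-x behavior
sample_from <- function(x, k) x[sample.int(length(x), k)]

place_signal_window <- function(v, eligible, width, s, max_tries = 200) {
  span <- range(v$pos)
  chrom <- v$chrom[1]
  for (i in seq_len(max_tries)) {
    start <- sample_from(seq(span[1], max(span[1], span[2] - width)), 1)
    hits <- sum(eligible & v$chrom == chrom &
                  v$pos >= start & v$pos <= start + width - 1)
    if (hits >= s) {
      return(tibble::tibble(chrom = chrom, start = start,
                            end = start + width - 1L))
    }
  }
  stop("could not place a signal window with ", s,
       " eligible variants", call. = FALSE)
}
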