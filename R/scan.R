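#' Genome-wide knockoff screen
#'
#' Runs the full screening pipeline on a genotype panel: tile overlapping
#' candidate windows of every requested size, generate `M` knockoff copies
#' of the panel, compute the ensemble p-value of every window on the
#' original and on each knockoff copy (identical code path, only the dosage
#' matrix differs), contrast them into feature statistics, and apply the
#' multiple-knockoff filter at the target FDR. All window size classes are
#' pooled into one genome-wide filter pass. The run is deterministic given
#' `seed`.
#'
#' @param panel A [genotype_panel()].
#' @param pheno Data frame with the outcome and covariate columns, rows
#'   aligned with the panel's individuals.
#' @param outcome Name of the outcome column in `pheno`.
#' @param covariates Covariate column names in `pheno`.
#' @param family `"gaussian"` or `"binomial"`.
#' @param sizes Window sizes in bp.
#' @param M Number of knockoffs.
#' @param fdr Target FDR `q`.
#' @param seed Integer seed for the knockoff sampling.
#' @param annotations Optional per-variant annotation score tibble
#'   (`variant_id` + numeric columns).
#' @param use_spa Saddlepoint correction for 1 bp windows of binary traits.
#' @param knockoffs Optional precomputed [generate_knockoffs()] set (its
#'   `M` overrides the `M` argument).
#' @param verbose Log per-chromosome progress to stderr.
#' @return An object of class `ks_scan`; see [tidy.ks_scan()],
#'   [glance.ks_scan()], [autoplot.ks_scan()].
#' @export
ks_scan <- function(panel, pheno, outcome, covariates = character(),
                    family = c("gaussian", "binomial"),
                    sizes = c(1, 1000, 5000, 10000), M = 5, fdr = 0.1,
                    seed = 1, annotations = NULL, use_spa = TRUE,
                    knockoffs = NULL, verbose = FALSE) {
  family <- match.arg(family)
  if (nrow(pheno) != n_samples(panel)) {
    stop("phenotype rows (", nrow(pheno), ") do not match panel individuals (",
         n_samples(panel), ")", call. = FALSE)
  }
  null <- fit_null_model(pheno, outcome, covariates, family)
  windows <- tile_windows(panel, sizes)
  if (!nrow(windows)) stop("empty window set", call. = FALSE)
  if (is.null(knockoffs)) {
    knockoffs <- generate_knockoffs(panel, M = M, seed = seed)
  }
  M <- knockoffs$M
  ann <- annotation_matrix(annotations, panel$variants)
  spa <- use_spa && family == "binomial"

  if (verbose) {
    message("scanning ", nrow(windows), " windows on ",
            length(unique(windows$chrom)), " chromosome(s)")
  }
  p0 <- scan_pvalues(null, panel$dosages, windows, panel$variants, ann, spa)
  pk <- matrix(NA_real_, nrow(windows), M)
  for (m in seq_len(M)) {
    if (verbose) message("scanning knockoff copy ", m, "/", M)
    pk[, m] <- scan_pvalues(null, knockoffs$copies[[m]], windows,
                            panel$variants, ann, spa)
  }

  testable <- !is.na(p0) & !apply(pk, 1, anyNA)
  windows <- windows[testable, ]
  p0 <- p0[testable]
  pk <- pk[testable, , drop = FALSE]

  stats <- feature_stats(p0, pk)
  thr <- threshold_multiple(stats, M, fdr)
  qv <- knockoff_qvalues(stats, M)

  res <- dplyr::bind_cols(
    windows[, c("chrom", "start", "end", "size_class", "n_variants")],
    tibble::tibble(p = p0), stats_pk_cols(pk), stats,
    tibble::tibble(qvalue = qv, selected = thr$selected)
  )
  res$members <- windows$members
  structure(
    list(windows = res, tau_hat = thr$tau_hat, M = M, fdr = fdr,
         family = family, seed = seed, n = n_samples(panel),
         p_variants = n_variants(panel)),
    class = "ks_scan"
  )
}

stats_pk_cols <- function(pk) {
  colnames(pk) <- paste0("p_knockoff_", seq_len(ncol(pk)))
  tibble::as_tibble(pk)
}

#' @export
print.ks_scan <- function(x, ...) {
  cat(sprintf(
    "<ks_scan> %d windows, M = %d knockoffs, target FDR %.2g\n",
    nrow(x$windows), x$M, x$fdr
  ))
  cat(sprintf("threshold tau_hat = %s; %d window(s) selected\n",
              format(x$tau_hat, digits = 4), sum(x$windows$selected)))
  invisible(x)
}

#' Tidy a knockoff scan
#'
#' One row per window: coordinates, size class, original and knockoff
#' p-values, feature statistics `W`, `kappa`, `tau`, the knockoff Q-value,
#' and the selection flag at the run's target FDR.
#'
#' @param x A [ks_scan()] object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ks_scan
#' @export
tidy.ks_scan <- function(x, ...) {
  dplyr::select(x$windows, -"members")
}

#' Summarize a knockoff scan
#'
#' @param x A [ks_scan()] object.
#' @param ... Unused.
#' @return One-row tibble: windows tested and selected (overall and per
#'   size class), the data dimensions and the filter threshold.
#' @method glance ks_scan
#' @export
glance.ks_scan <- function(x, ...) {
  sel <- x$windows[x$windows$selected, ]
  by_size <- table(factor(sel$size_class,
                          levels = unique(x$windows$size_class)))
  tibble::tibble(
    n_windows = nrow(x$windows),
    n_selected = nrow(sel),
    !!!stats::setNames(as.list(as.integer(by_size)),
                       paste0("selected_", names(by_size))),
    n_individuals = x$n,
    n_variants = x$p_variants,
    M = x$M,
    target_fdr = x$fdr,
    tau_hat = x$tau_hat
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style plot of a knockoff scan
#'
#' Plots the feature statistic `W` of every window against its midpoint
#' position, faceted by chromosome, with the selection threshold drawn and
#' selected windows highlighted.
#'
#' @param object A [ks_scan()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ks_scan
#' @export
autoplot.ks_scan <- function(object, ...) {
  d <- tidy(object)
  d$mid <- (d$start + d$end) / 2
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$W,
                                        colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "feature statistic W",
                  colour = "selected") +
    ggplot2::theme_minimal()
  if (is.finite(object$tau_hat)) {
    gg <- gg + ggplot2::geom_hline(yintercept = object$tau_hat,
                                   linetype = "dashed")
  }
  gg
}

#' Write scan outputs
#'
#' Writes the full per-window table and the selected-window table as TSVs,
#' plus a small JSON run-metadata file (seed, configuration, counts).
#'
#' @param scan A [ks_scan()] object.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_scan <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  full <- tidy(scan)
  utils::write.table(full, file.path(dir, "windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(full[full$selected, ], file.path(dir, "selected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = scan$seed, M = scan$M, target_fdr = scan$fdr,
         family = scan$family, n_windows = nrow(full),
         n_selected = sum(full$selected),
         tau_hat = if (is.finite(scan$tau_hat)) scan$tau_hat else NULL,
         package_version = as.character(utils::packageVersion("kscreen"))),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Evaluate a selection against simulation truth
#'
#' Window-level power is the fraction of causal windows detected;
#' window-level FDP is the fraction of detected windows that are not
#' causal; locus-level FDP at a buffer is the fraction of detected windows
#' lying entirely outside every causal window extended by the buffer. FDP
#' on an empty selection is 0 by convention.
#'
#' @param selection Window tibble with a logical `selected` column (e.g.
#'   from [tidy.ks_scan()]).
#' @param causal_windows Tibble of causal windows (`chrom`, `start`, `end`).
#' @param buffers Buffer widths (bp) for locus-level FDP.
#' @return One-row tibble: `power`, `fdp`, and one `fdp_<buffer>` column
#'   per buffer.
#' @export
evaluate_selection <- function(selection, causal_windows,
                               buffers = c(50000, 75000, 100000)) {
  sel <- selection[selection$selected, , drop = FALSE]
  causal_flag <- overlaps_any(selection, causal_windows, 0)
  power <- if (any(causal_flag)) {
    sum(causal_flag & selection$selected) / sum(causal_flag)
  } else {
    NA_real_
  }
  fdp <- if (nrow(sel)) mean(!overlaps_any(sel, causal_windows, 0)) else 0
  out <- tibble::tibble(power = power, fdp = fdp)
  for (b in buffers) {
    out[[paste0("fdp_", format(b, scientific = FALSE))]] <-
      if (nrow(sel)) mean(!overlaps_any(sel, causal_windows, b)) else 0
  }
  out
}

overlaps_any <- function(windows, causal, buffer) {
  vapply(seq_len(nrow(windows)), function(i) {
    any(causal$chrom == windows$chrom[i] &
          causal$start - buffer <= windows$end[i] &
          causal$end + buffer >= windows$start[i])
  }, logical(1))
}
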