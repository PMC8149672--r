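#' Construct a genotype panel
#'
#' A genotype panel bundles an `n x p` dosage matrix (counts of the minor
#' allele, or imputed dosages, nominally in `[0, 2]`) with a per-variant
#' table carrying genomic coordinates and allele-frequency summaries.
#' Variants are sorted by chromosome and position; monomorphic variants
#' (minor allele count 0) are dropped; missing dosages are imputed to the
#' column mean (twice the allele frequency), which preserves the MAF.
#'
#' @param dosages Numeric matrix, individuals in rows and variants in
#'   columns. `NA` entries are mean-imputed.
#' @param variants Data frame with one row per column of `dosages` and
#'   columns `variant_id`, `chrom`, `pos` (1-based base-pair position).
#' @return An object of class `genotype_panel`: a list with the dosage
#'   matrix and a tibble of variant metadata (`variant_id`, `chrom`, `pos`,
#'   `maf`, `mac`, `category`).
#' @seealso [read_genotypes()], [tile_windows()], [generate_knockoffs()]
#' @export
genotype_panel <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  variants <- tibble::as_tibble(variants)
  stopifnot(
    ncol(dosages) == nrow(variants),
    all(c("variant_id", "chrom", "pos") %in% names(variants))
  )
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)

  ord <- order(variants$chrom, variants$pos)
  dosages <- dosages[, ord, drop = FALSE]
  variants <- variants[ord, c("variant_id", "chrom", "pos")]

  # mean imputation of missing genotypes
  if (anyNA(dosages)) {
    mu <- colMeans(dosages, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(dosages))
    dosages[idx] <- mu[(idx - 1L) %/% nrow(dosages) + 1L]
  }

  n <- nrow(dosages)
  f <- colMeans(dosages) / 2
  maf <- pmin(f, 1 - f)
  mac <- as.integer(round(n * 2 * maf))

  keep <- mac > 0L
  if (!any(keep)) stop("no polymorphic variants in panel", call. = FALSE)
  dosages <- dosages[, keep, drop = FALSE]
  variants <- variants[keep, ]
  maf <- maf[keep]
  mac <- mac[keep]

  variants$maf <- unname(maf)
  variants$mac <- unname(mac)
  variants$category <- variant_category(maf, mac)
  colnames(dosages) <- variants$variant_id

  structure(
    list(dosages = dosages, variants = variants),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d individuals x %d variants\n",
    nrow(x$dosages), ncol(x$dosages)
  ))
  print(dplyr::count(x$variants, .data$category))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

n_variants <- function(panel) ncol(panel$dosages)
n_samples <- function(panel) nrow(panel$dosages)

#' Classify variants by allele frequency
#'
#' Assigns each variant to exactly one frequency category: `common`
#' (MAF > 0.05), `low_frequency` (0.01 < MAF <= 0.05), `rare`
#' (MAF <= 0.01 and MAC >= 5) or `ultra_rare` (MAC < 5, regardless of MAF).
#' The ultra-rare rule takes precedence: a minor allele observed fewer than
#' five times carries too little information for frequency-based testing
#' whatever its nominal frequency.
#'
#' @param maf Numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @param mac Integer vector of minor allele counts.
#' @return Character vector of category labels.
#' @export
variant_category <- function(maf, mac) {
  stopifnot(length(maf) == length(mac))
  out <- rep("rare", length(maf))
  out[maf > 0.01] <- "low_frequency"
  out[maf > 0.05] <- "common"
  out[mac < 5] <- "ultra_rare"
  out
}

#' Read genotypes from a VCF or a dosage matrix
#'
#' Reads either a VCF file (`GT` genotypes, or `DS` dosages when present)
#' or a pair of plain-text tables (a samples-by-variants dosage matrix and a
#' variant table with `variant_id`, `chrom`, `pos`) and returns a
#' [genotype_panel()]. Multi-allelic VCF records are skipped. Coordinates
#' are 1-based inclusive, matching VCF `POS`.
#'
#' @param path Path to a VCF (`.vcf` / `.vcf.gz`) or to a dosage TSV.
#' @param variant_table Path to the variant TSV when `path` is a dosage
#'   matrix; ignored for VCF input.
#' @param region Optional `"chrom:start-end"` string restricting the loaded
#'   variants.
#' @return A `genotype_panel`.
#' @export
read_genotypes <- function(path, variant_table = NULL, region = NULL) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    panel <- read_vcf_panel(path)
  } else {
    if (is.null(variant_table)) {
      stop("dosage-matrix input requires `variant_table`", call. = FALSE)
    }
    dos <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    var <- utils::read.table(variant_table, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    panel <- genotype_panel(as.matrix(dos), var)
  }
  if (!is.null(region)) panel <- subset_region(panel, region)
  panel
}

read_vcf_panel <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- if (is.null(dim(fix))) matrix(fix, nrow = 1, dimnames = list(NULL, names(fix))) else fix
  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "."
  fmt <- unique(unlist(strsplit(vcf@gt[, 1], ":")))
  if ("DS" %in% fmt) {
    dos <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- apply(gt, c(1, 2), gt_to_dosage)
  }
  dos <- t(dos[biallelic, , drop = FALSE])
  ids <- fix[biallelic, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[biallelic, "CHROM"], ":", fix[biallelic, "POS"])[blank]
  genotype_panel(dos, data.frame(
    variant_id = ids,
    chrom = fix[biallelic, "CHROM"],
    pos = as.integer(fix[biallelic, "POS"]),
    stringsAsFactors = FALSE
  ))
}

gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  sum(as.integer(strsplit(gt, "[/|]")[[1]]))
}

subset_region <- function(panel, region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("malformed region: ", region, call. = FALSE)
  keep <- panel$variants$chrom == m[2] &
    panel$variants$pos >= as.integer(m[3]) &
    panel$variants$pos <= as.integer(m[4])
  if (!any(keep)) stop("no variants in region ", region, call. = FALSE)
  genotype_panel(panel$dosages[, keep, drop = FALSE], panel$variants[keep, ])
}

#' @rdname genotype_panel
#' @param panel A `genotype_panel`.
#' @export
variant_info <- function(panel) panel$variants
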