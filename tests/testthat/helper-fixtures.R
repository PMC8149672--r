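# fixtures built in code; nothing on disk except the tiny VCF written by
# its own test

# panel with prescribed dosage columns (rows = individuals)
toy_panel <- function(dosages, pos = NULL, chrom = "chr1") {
  dosages <- as.matrix(dosages)
  if (is.null(pos)) pos <- seq_len(ncol(dosages)) * 100L
  genotype_panel(dosages, data.frame(
    variant_id = paste0("v", seq_len(ncol(dosages))),
    chrom = chrom, pos = pos
  ))
}

# latent-Gaussian pair of dosage columns with target correlation
correlated_dosages <- function(n, r, maf = 0.3) {
  z1 <- rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  z3 <- rnorm(n); z4 <- r * z3 + sqrt(1 - r^2) * rnorm(n)
  th <- qnorm(1 - maf)
  cbind((z1 > th) + (z3 > th), (z2 > th) + (z4 > th))
}

write_toy_vcf <- function(path, gts, pos = NULL, chrom = "1") {
  # gts: matrix of "0/0"-style strings, variants x samples
  nv <- nrow(gts); ns <- ncol(gts)
  if (is.null(pos)) pos <- seq_len(nv) * 50L
  con <- file(path, "w")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", seq_len(ns))), collapse = "\t")
  ), con)
  for (i in seq_len(nv)) {
    writeLines(paste(c(chrom, pos[i], paste0("var", i), "A", "G", ".",
                       "PASS", ".", "GT", gts[i, ]), collapse = "\t"), con)
  }
  close(con)
  path
}

# standard small null dataset for association tests
null_dataset <- function(n = 400, seed = 1) {
  set.seed(seed)
  list(
    pheno = tibble::tibble(y = rnorm(n), x1 = rnorm(n)),
    g = rbinom(n, 2, 0.3)
  )
}
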