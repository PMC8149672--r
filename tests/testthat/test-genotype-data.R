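test_that("VCF loading drops monomorphic sites and computes MAF/MAC by counting", {
  gts <- rbind(
    c("0/1", "0/1", "0/1", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0"),
    rep("0/0", 10),                       # monomorphic, must be dropped
    c("1/1", "0/1", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "./.")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, gts)
  panel <- read_genotypes(path)
  expect_equal(n_variants <- ncol(panel$dosages), 2)
  v <- variant_info(panel)
  expect_false("var2" %in% v$variant_id)
  expect_equal(v$maf[v$variant_id == "var1"], 0.15)
  expect_equal(v$mac[v$variant_id == "var1"], 3L)
  # missing genotype mean-imputed: var3 has 3 alt alleles over 9 typed
  expect_equal(panel$dosages[10, "var3"], 3 / 9)
})

test_that("dosage-matrix round trip preserves dosages", {
  set.seed(4)
  dos <- matrix(rbinom(50, 2, 0.4), 10, 5,
                dimnames = list(paste0("s", 1:10), paste0("v", 1:5)))
  var <- data.frame(variant_id = paste0("v", 1:5), chrom = "chr2",
                    pos = c(10L, 20L, 30L, 40L, 50L))
  dpath <- withr::local_tempfile(fileext = ".tsv")
  vpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(dos, dpath, sep = "\t", quote = FALSE, col.names = NA)
  write.table(var, vpath, sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- read_genotypes(dpath, variant_table = vpath)
  expect_equal(unname(panel$dosages), unname(dos))
  expect_error(read_genotypes(dpath), "variant_table")
})

test_that("region restriction filters by coordinates and errors when empty", {
  panel <- toy_panel(matrix(rbinom(40, 2, 0.4), 10, 4),
                     pos = c(100L, 200L, 300L, 400L))
  sub <- kscreen:::subset_region(panel, "chr1:150-350")
  expect_equal(variant_info(sub)$pos, c(200L, 300L))
  expect_error(kscreen:::subset_region(panel, "chr1:900-999"), "no variants")
  expect_error(kscreen:::subset_region(panel, "garbage"), "malformed")
})

test_that("variant categories partition the MAF/MAC grid exhaustively", {
  expect_equal(variant_category(0.06, 120), "common")
  expect_equal(variant_category(0.005, 12), "rare")
  expect_equal(variant_category(0.03, 4), "ultra_rare")  # MAC rules over MAF
  # boundary conventions: MAF = 0.05 low-frequency, MAF = 0.01 rare
  expect_equal(variant_category(0.05, 100), "low_frequency")
  expect_equal(variant_category(0.01, 20), "rare")
  grid <- expand.grid(maf = c(1e-4, 0.005, 0.01, 0.02, 0.05, 0.2, 0.5),
                      mac = c(1L, 4L, 5L, 50L, 500L))
  cats <- variant_category(grid$maf, grid$mac)
  expect_true(all(cats %in% c("common", "low_frequency", "rare",
                              "ultra_rare")))
  expect_equal(cats[grid$mac < 5], rep("ultra_rare", sum(grid$mac < 5)))
})

test_that("tiling matches the hand-enumerated half-overlap grid", {
  dos <- matrix(rbinom(60, 2, 0.4), 20, 3)
  panel <- toy_panel(dos, pos = c(100L, 600L, 1400L))
  w <- tile_windows(panel, sizes = 1000)
  expect_equal(w$start, c(1L, 501L, 1001L))
  expect_equal(w$end, c(1000L, 1500L, 2000L))
  expect_equal(w$members, list(1:2, 2:3, 3L))
})

test_that("1bp windows exist only for common and low-frequency variants", {
  set.seed(7)
  n <- 300
  dos <- cbind(rbinom(n, 2, 0.3),                    # common
               c(rep(1, 3), rep(0, n - 3)),          # ultra-rare
               c(rep(1, 6), rep(0, n - 6)))          # rare (MAF = 0.01)
  panel <- toy_panel(dos, pos = c(50L, 150L, 250L))
  w <- tile_windows(panel, sizes = c(1, 1000))
  w1 <- w[w$size_class == "1bp", ]
  expect_equal(nrow(w1), 1)
  expect_equal(w1$start, 50L)
  rare_only <- panel_subset(panel, 2:3)
  w2 <- tile_windows(rare_only, sizes = c(1, 1000))
  expect_false("1bp" %in% w2$size_class)
})

test_that("every variant is covered by each multi-bp size class and overlaps share exactly the half-window variants", {
  panel <- simulate_genotypes(150, 60, seed = 42)
  w <- tile_windows(panel)
  for (sc in c("1kb", "5kb", "10kb")) {
    ws <- w[w$size_class == sc, ]
    covered <- sort(unique(unlist(ws$members)))
    expect_equal(covered, seq_len(ncol(panel$dosages)))
    # consecutive same-size windows share exactly the overlap-half variants
    ord <- order(ws$start)
    pos <- variant_info(panel)$pos
    for (i in seq_len(nrow(ws) - 1)) {
      a <- ws[ord[i], ]; b <- ws[ord[i + 1], ]
      if (b$start > a$end) next
      shared <- intersect(a$members[[1]], b$members[[1]])
      in_overlap <- a$members[[1]][pos[a$members[[1]]] >= b$start &
                                     pos[a$members[[1]]] <= a$end]
      expect_equal(sort(shared), sort(in_overlap))
    }
  }
  expect_setequal(unique(w$size_class), c("1bp", "1kb", "5kb", "10kb"))
})

test_that("window BED export is 0-based half-open on disk", {
  panel <- toy_panel(matrix(rbinom(40, 2, 0.4), 10, 4),
                     pos = c(100L, 600L, 900L, 1400L))
  w <- tile_windows(panel, sizes = 1000)
  path <- withr::local_tempfile(fileext = ".bed")
  write_windows_bed(w, path)
  bed <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(bed$start, w$start - 1L)
  expect_equal(bed$end, w$end)
})
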