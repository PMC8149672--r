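#' Tile a panel into overlapping candidate windows
#'
#' Screens are run over candidate windows of several fixed physical sizes
#' (by default 1 bp, 1 kb, 5 kb and 10 kb), with consecutive windows of the
#' same size overlapping by exactly half the window length. For a size
#' `s > 1` the window start grid is anchored at the largest multiple of
#' `s/2` at or below the first variant position on the chromosome, so window
#' membership does not depend on where the loaded region happens to begin
#' mid-grid. Windows containing no variants are omitted. Size-1 windows are
#' single-variant windows and are emitted only at common and low-frequency
#' variant positions, where a single-variant test is informative.
#'
#' Coordinates are 1-based inclusive. Adjacent same-size windows that happen
#' to contain identical variant sets are retained, not deduplicated, so the
#' selection filter's accounting runs over the full tiling.
#'
#' @param panel A [genotype_panel()].
#' @param sizes Integer vector of window lengths in bp.
#' @param single_bp_categories Variant categories that receive 1 bp windows.
#' @return A tibble with columns `chrom`, `start`, `end`, `size_class` and a
#'   list-column `members` of variant indices (column indices into the
#'   panel's dosage matrix).
#' @export
tile_windows <- function(panel, sizes = c(1, 1000, 5000, 10000),
                         single_bp_categories = c("common", "low_frequency")) {
  stopifnot(length(sizes) >= 1, n_variants(panel) >= 1)
  v <- panel$variants
  out <- vector("list", 0L)
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    pos <- v$pos[idx]
    for (s in sort(unique(as.integer(sizes)))) {
      if (s <= 1L) {
        sel <- idx[v$category[idx] %in% single_bp_categories]
        if (length(sel)) {
          out[[length(out) + 1L]] <- tibble::tibble(
            chrom = chr, start = v$pos[sel], end = v$pos[sel],
            size_class = "1bp", members = as.list(sel)
          )
        }
        next
      }
      half <- s %/% 2L
      # anchor one half-step below a variant sitting exactly on the grid so
      # the (start, start+s] convention still covers it
      origin <- ((min(pos) - 1L) %/% half) * half
      starts <- seq.int(origin, max(pos), by = half)
      # window [start+1, start+s] in 1-based inclusive coordinates, so that
      # the grid anchored at a multiple of s/2 yields e.g. [1, s], [s/2+1, ...]
      wins <- lapply(starts, function(st) idx[pos > st & pos <= st + s])
      keep <- lengths(wins) > 0L
      if (any(keep)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = chr, start = starts[keep] + 1L, end = starts[keep] + s,
          size_class = size_class_label(s), members = wins[keep]
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$n_variants <- lengths(res$members)
  dplyr::arrange(res, .data$chrom, .data$start, .data$end)
}

size_class_label <- function(s) {
  if (s == 1L) "1bp" else if (s %% 1000L == 0L) paste0(s %/% 1000L, "kb") else paste0(s, "bp")
}

#' Write windows as a BED-like TSV
#'
#' On-disk coordinates follow BED conventions (0-based half-open); in-memory
#' window tables are 1-based inclusive.
#'
#' @param windows A window tibble from [tile_windows()].
#' @param path Output file path.
#' @export
write_windows_bed <- function(windows, path) {
  utils::write.table(
    data.frame(chrom = windows$chrom, start = windows$start - 1L,
               end = windows$end, size_class = windows$size_class,
               n_variants = lengths(windows$members)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
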