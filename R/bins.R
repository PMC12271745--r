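#' Build a bin table for one or more chromosomes
#'
#' A bin table tiles each chromosome with fixed-width windows (the matrix
#' row/column unit and the network node). Coordinates are 0-based, half-open;
#' the last bin of a chromosome may be shorter than `resolution`.
#'
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param resolution bin width in bp (default 40 kb, the working resolution of
#'   the pipeline).
#' @return a `BinTable`: a data.frame with columns `chrom`, `start`, `end`,
#'   `bin_id` (0-based, per chromosome, consecutive in coordinate order) and
#'   `midpoint`, with the resolution stored as an attribute.
#' @export
bin_table <- function(chrom_sizes, resolution = 40000L) {
  cn_assert(length(chrom_sizes) >= 1 && !is.null(names(chrom_sizes)),
            "chrom_sizes must be a named vector of lengths")
  cn_assert(resolution >= 1, "resolution must be positive")
  out <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    len <- as.numeric(chrom_sizes[[ch]])
    cn_assert(len > 0, "chromosome length must be positive")
    starts <- seq(0, len - 1, by = resolution)
    ends <- pmin(starts + resolution, len)
    data.frame(
      chrom = ch, start = starts, end = ends,
      bin_id = seq_along(starts) - 1L,
      midpoint = (starts + ends) / 2,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "resolution") <- as.integer(resolution)
  class(out) <- c("BinTable", "data.frame")
  out
}

#' Locate the bin containing a genomic position
#'
#' @param bins a `BinTable`.
#' @param chrom chromosome name (recycled against `pos`).
#' @param pos 0-based position(s) in bp.
#' @return integer vector of per-chromosome `bin_id`s; positions outside the
#'   tiled extent raise an error (every covered position maps to exactly one
#'   bin).
#' @export
bin_for_position <- function(bins, chrom, pos) {
  res <- attr(bins, "resolution")
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  vapply(seq_len(n), function(i) {
    sub <- bins[bins$chrom == chrom[i], , drop = FALSE]
    cn_assert(nrow(sub) > 0, paste0("chromosome not in bin table: ", chrom[i]))
    cn_assert(pos[i] >= 0 && pos[i] < max(sub$end),
              paste0("position outside chromosome extent: ", pos[i]))
    id <- as.integer(pos[i] %/% res)
    # guard against a short terminal bin
    cn_assert(id <= max(sub$bin_id), "position outside chromosome extent")
    id
  }, integer(1))
}

# internal: BinTable restricted to one chromosome, validated
bins_for_chrom <- function(bins, chrom) {
  sub <- bins[bins$chrom == chrom, , drop = FALSE]
  cn_assert(nrow(sub) > 0, paste0("chromosome not in bin table: ", chrom))
  attr(sub, "resolution") <- attr(bins, "resolution")
  class(sub) <- c("BinTable", "data.frame")
  sub
}

# internal: GRanges view of a BinTable (0-based half-open -> 1-based closed)
bins_as_granges <- function(bins) {
  GenomicRanges::GRanges(
    seqnames = bins$chrom,
    ranges = IRanges::IRanges(start = bins$start + 1, end = bins$end)
  )
}
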