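#' Construct an intrachromosomal contact map
#'
#' Sparse upper-triangular storage of a symmetric chromatin-contact matrix for
#' one chromosome. Marginals are full-matrix row sums (each off-diagonal entry
#' contributes to both endpoints, a diagonal entry once to its own row), so the
#' total equals half the sum of marginals plus half the diagonal mass.
#'
#' @param chrom chromosome name.
#' @param entries data.frame with columns `bin_i`, `bin_j` (0-based local bin
#'   ids) and `count`; pairs given lower-triangular are flipped, duplicates
#'   summed.
#' @param n_bins number of bins on the chromosome.
#' @param resolution bin width in bp.
#' @param bias optional per-bin multiplicative visibility biases (length
#'   `n_bins`).
#' @return a `ContactMap` object.
#' @export
contact_map <- function(chrom, entries, n_bins, resolution = 40000L, bias = NULL) {
  cn_assert(all(c("bin_i", "bin_j", "count") %in% names(entries)),
            "entries must have bin_i, bin_j, count", "chromanet_format_error")
  cn_assert(all(entries$count >= 0), "negative contact count",
            "chromanet_format_error")
  cn_assert(all(entries$bin_i >= 0 & entries$bin_i < n_bins &
                entries$bin_j >= 0 & entries$bin_j < n_bins),
            "bin id outside chromosome", "chromanet_format_error")
  i <- pmin(entries$bin_i, entries$bin_j)
  j <- pmax(entries$bin_i, entries$bin_j)
  key <- i * n_bins + j
  if (anyDuplicated(key)) {
    cnt <- tapply(entries$count, key, sum)
    key <- as.numeric(names(cnt))
    i <- key %/% n_bins
    j <- key %% n_bins
    count <- as.numeric(cnt)
  } else {
    count <- entries$count
  }
  ord <- order(i, j)
  entries <- data.frame(bin_i = as.integer(i[ord]), bin_j = as.integer(j[ord]),
                        count = count[ord])
  marg <- numeric(n_bins)
  off <- entries$bin_i != entries$bin_j
  m1 <- tapply(entries$count[off], entries$bin_i[off], sum)
  m2 <- tapply(entries$count[off], entries$bin_j[off], sum)
  md <- tapply(entries$count[!off], entries$bin_i[!off], sum)
  add <- function(m, v) { idx <- as.integer(names(v)) + 1L; m[idx] <- m[idx] + v; m }
  marg <- add(marg, m1); marg <- add(marg, m2); marg <- add(marg, md)
  if (!is.null(bias)) {
    cn_assert(length(bias) == n_bins, "bias vector length mismatch")
  }
  structure(
    list(chrom = chrom, entries = entries, n_bins = as.integer(n_bins),
         resolution = as.integer(resolution), marginals = marg,
         total = sum(as.numeric(entries$count)), bias = bias),
    class = "ContactMap"
  )
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap: %s | %d bins @ %d bp | %d nonzero pairs | total %s\n",
              x$chrom, x$n_bins, x$resolution, nrow(x$entries),
              format(x$total, big.mark = ",")))
  invisible(x)
}

# internal: dense symmetric matrix view (desk-scale only)
contact_map_dense <- function(map) {
  m <- matrix(0, map$n_bins, map$n_bins)
  idx <- cbind(map$entries$bin_i + 1L, map$entries$bin_j + 1L)
  m[idx] <- map$entries$count
  m[idx[, c(2, 1), drop = FALSE]] <- map$entries$count
  m
}

# internal: ContactMap from a dense symmetric matrix
contact_map_from_dense <- function(chrom, m, resolution, bias = NULL) {
  up <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  contact_map(chrom,
              data.frame(bin_i = up[, 1] - 1L, bin_j = up[, 2] - 1L,
                         count = m[up]),
              n_bins = nrow(m), resolution = resolution, bias = bias)
}

#' Read a HiC-Pro raw matrix for one chromosome
#'
#' HiC-Pro emits a bins BED file carrying global bin ids and a
#' whitespace-separated triplet file `id_i id_j count`. Global ids are remapped
#' to per-chromosome 0-based ids at read time; only intrachromosomal triplets
#' of the requested chromosome are kept. Diagonal entries are read as given
#' (they are removed later by the self-interaction filter, not here).
#'
#' @param bed_path path to the bins BED (chrom, start, end, global id).
#' @param matrix_path path to the triplet matrix file.
#' @param chrom chromosome to extract.
#' @return a [contact_map()] with computed marginals and total.
#' @export
read_hicpro_matrix <- function(bed_path, matrix_path, chrom) {
  bed <- utils::read.table(bed_path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  cn_assert(ncol(bed) >= 4, "bins BED needs chrom,start,end,id",
            "chromanet_format_error")
  names(bed)[1:4] <- c("chrom", "start", "end", "id")
  cn_assert(!anyDuplicated(bed$id), "duplicate bin ids in BED",
            "chromanet_format_error")
  trip <- utils::read.table(matrix_path, header = FALSE, sep = "",
                            stringsAsFactors = FALSE)
  cn_assert(ncol(trip) >= 3, "matrix file needs 3 columns",
            "chromanet_format_error")
  names(trip)[1:3] <- c("i", "j", "count")
  cn_assert(is.numeric(trip$count) && all(trip$count > 0),
            "triplet counts must be positive numbers", "chromanet_format_error")
  cn_assert(all(trip$i %in% bed$id) && all(trip$j %in% bed$id),
            "triplet references a bin id absent from the BED",
            "chromanet_format_error")
  sub <- bed[bed$chrom == chrom, , drop = FALSE]
  cn_assert(nrow(sub) > 0, paste0("chromosome has no bins: ", chrom),
            "chromanet_empty_map_error")
  sub <- sub[order(sub$start), , drop = FALSE]
  local <- stats::setNames(seq_len(nrow(sub)) - 1L, sub$id)
  widths <- sub$end - sub$start
  resolution <- as.integer(max(widths))
  keep <- trip$i %in% sub$id & trip$j %in% sub$id
  trip <- trip[keep, , drop = FALSE]  # interchromosomal triplets ignored
  entries <- data.frame(
    bin_i = unname(local[as.character(trip$i)]),
    bin_j = unname(local[as.character(trip$j)]),
    count = trip$count
  )
  map <- contact_map(chrom, entries, n_bins = nrow(sub), resolution = resolution)
  attr(map, "global_ids") <- sub$id
  map
}

#' Write a contact map in the HiC-Pro matrix dialect
#'
#' @param map a `ContactMap`.
#' @param bed_path,matrix_path output paths for the bins BED and triplet file.
#' @param id_offset first global bin id (HiC-Pro ids are usually 1-based).
#' @return invisibly, the two paths.
#' @export
write_hicpro_matrix <- function(map, bed_path, matrix_path, id_offset = 1L) {
  starts <- (seq_len(map$n_bins) - 1L) * map$resolution
  bed <- data.frame(chrom = map$chrom, start = starts,
                    end = starts + map$resolution,
                    id = seq_len(map$n_bins) - 1L + id_offset)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  trip <- data.frame(i = map$entries$bin_i + id_offset,
                     j = map$entries$bin_j + id_offset,
                     count = map$entries$count)
  utils::write.table(trip, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(bed_path, matrix_path))
}
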