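#' Read a BED interval file as a labelled region set
#'
#' @param path BED file (0-based half-open, 3+ columns); `track`/`browser`/`#`
#'   lines are skipped.
#' @param label region label, e.g. `"blacklist"` or `"centromere"`.
#' @return a `RegionSet`: data.frame with `chrom`, `start`, `end`, `label`.
#' @export
read_regions_bed <- function(path, label = "other") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(region_set(character(), numeric(), numeric(), label))
  fields <- strsplit(lines, "\\s+")
  cn_assert(all(lengths(fields) >= 3), "BED line with fewer than 3 columns",
            "chromanet_format_error")
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  cn_assert(!anyNA(start) && !anyNA(end), "non-numeric BED coordinates",
            "chromanet_format_error")
  cn_assert(all(start < end), "BED interval with start >= end",
            "chromanet_format_error")
  region_set(chrom, start, end, label)
}

#' Construct a region set
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param label one label recycled over intervals, or a vector.
#' @return a `RegionSet` data.frame.
#' @export
region_set <- function(chrom, start, end, label = "other") {
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end),
                    label = rep_len(as.character(label), length(chrom)),
                    stringsAsFactors = FALSE)
  cn_assert(all(out$start < out$end) || nrow(out) == 0,
            "interval with start >= end", "chromanet_format_error")
  class(out) <- c("RegionSet", "data.frame")
  out
}

# internal: GRanges view of a RegionSet
regions_as_granges <- function(regions) {
  if (nrow(regions) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end)
  )
}

#' Read a tabular gene annotation
#'
#' Expects a header line with columns `gene_id`, `symbol`, `chrom`, `strand`,
#' `start`, `end`, `biotype` (tab-separated). The TSS is `start` on the `+`
#' strand and `end` on the `-` strand. Biotypes are collapsed to
#' `coding`/`ncRNA` (case-insensitive match on protein_coding/coding vs
#' lncRNA/ncRNA/miRNA/snoRNA/snRNA/rRNA); other biotypes are dropped and the
#' dropped count reported via a message and an attribute.
#'
#' @param path annotation file path.
#' @return data.frame of gene records with columns `gene_id`, `symbol`,
#'   `chrom`, `strand`, `tss`, `biotype`; attribute `n_dropped`.
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "symbol", "chrom", "strand", "start", "end", "biotype")
  cn_assert(all(need %in% names(tab)),
            paste0("annotation missing columns: ",
                   paste(setdiff(need, names(tab)), collapse = ", ")),
            "chromanet_format_error")
  cn_assert(all(tab$strand %in% c("+", "-")), "unknown strand symbol",
            "chromanet_format_error")
  bt <- tolower(tab$biotype)
  coding <- bt %in% c("protein_coding", "coding")
  ncrna <- bt %in% c("ncrna", "lncrna", "lincrna", "mirna", "snorna",
                     "snrna", "rrna", "misc_rna", "antisense")
  keep <- coding | ncrna
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("read_gene_annotation: dropped %d genes with out-of-scope biotypes",
                    n_dropped))
  }
  out <- data.frame(
    gene_id = tab$gene_id[keep], symbol = tab$symbol[keep],
    chrom = tab$chrom[keep], strand = tab$strand[keep],
    tss = ifelse(tab$strand[keep] == "+", tab$start[keep], tab$end[keep]),
    biotype = ifelse(coding[keep], "coding", "ncRNA"),
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a gene annotation table readable by [read_gene_annotation()]
#' @param genes data.frame with the annotation columns (`tss` is expanded back
#'   to `start`/`end` if absent).
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  if (!("start" %in% names(genes))) {
    genes$start <- ifelse(genes$strand == "+", genes$tss, pmax(genes$tss - 1000, 0))
    genes$end <- ifelse(genes$strand == "+", genes$tss + 1000, genes$tss)
  }
  utils::write.table(
    genes[, c("gene_id", "symbol", "chrom", "strand", "start", "end", "biotype")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

edge_table_columns <- c("chrom", "bin_i", "bin_j", "count", "distance_bp",
                        "omega", "pvalue", "qvalue", "zscore", "edge_type")

# internal: canonical empty edge table
empty_edge_table <- function() {
  out <- data.frame(chrom = character(), bin_i = integer(), bin_j = integer(),
                    count = numeric(), distance_bp = numeric(), omega = numeric(),
                    pvalue = numeric(), qvalue = numeric(), zscore = numeric(),
                    edge_type = character(), stringsAsFactors = FALSE)
  out
}

#' Write / read a significant-interaction edge table (TSV)
#'
#' Round-trips losslessly to 12 significant digits; rows are sorted by
#' `(bin_i, bin_j)`.
#'
#' @param edges edge table data.frame with the canonical columns (`chrom`,
#'   `bin_i`, `bin_j`, `count`, `distance_bp`, `omega`, `pvalue`, `qvalue`,
#'   `zscore`, `edge_type`; missing optional statistics may be `NA`).
#' @param path file path.
#' @return `read_edge_table` returns the edge table; `write_edge_table`
#'   returns the path invisibly.
#' @export
write_edge_table <- function(edges, path) {
  miss <- setdiff(edge_table_columns, names(edges))
  for (m in miss) edges[[m]] <- NA
  edges <- edges[, edge_table_columns, drop = FALSE]
  edges <- edges[order(edges$bin_i, edges$bin_j), , drop = FALSE]
  num <- vapply(edges, is.numeric, TRUE)
  edges[num] <- lapply(edges[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.12g", x))
  })
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = c(chrom = "character"))
  miss <- setdiff(edge_table_columns, names(tab))
  cn_assert(length(miss) == 0,
            paste0("edge table missing columns: ", paste(miss, collapse = ", ")),
            "chromanet_format_error")
  tab <- tab[, edge_table_columns, drop = FALSE]
  tab[order(tab$bin_i, tab$bin_j), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: per line, set name, description, then member genes,
#'   tab-separated.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(f) {
    cn_assert(length(f) >= 3, "GMT line with fewer than 3 fields",
              "chromanet_format_error")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}

#' Write / read a gene-by-sample count matrix with a condition header
#'
#' TSV with a first comment line `#condition<TAB>...` giving each sample's
#' condition label, then a header of sample names and one row per gene.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids).
#' @param condition character vector of per-sample condition labels.
#' @param path file path.
#' @export
write_counts_matrix <- function(counts, condition, path) {
  cn_assert(length(condition) == ncol(counts), "condition length mismatch")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#condition", condition), collapse = "\t"), con)
  writeLines(paste(c("gene_id", colnames(counts)), collapse = "\t"), con)
  utils::write.table(data.frame(gene_id = rownames(counts), counts,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_matrix
#' @return `read_counts_matrix` returns a list with `counts` (matrix) and
#'   `condition`.
#' @export
read_counts_matrix <- function(path) {
  first <- readLines(path, n = 1)
  cn_assert(startsWith(first, "#condition"), "missing #condition header line",
            "chromanet_format_error")
  condition <- strsplit(first, "\t")[[1]][-1]
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                           stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  list(counts = counts, condition = condition)
}
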