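#' Read and write per-site count tables
#'
#' Tab-separated count tables with columns chrom, pos, strand, context,
#' count_modified, count_total (plus optional sample/assay columns).
#' `read_count_tsv()` also accepts the cytosine-report dialect produced by
#' common bisulfite pipelines (chrom, pos(1-based), strand,
#' count_methylated, count_unmethylated, context, trinucleotide) via
#' `dialect = "cytosine_report"`; positions are converted to 0-based and the
#' total is the methylated + unmethylated sum.
#'
#' @param path File path.
#' @param dialect `"markswitch"` (default) or `"cytosine_report"`.
#' @return A tibble of counts.
#' @export
read_count_tsv <- function(path, dialect = c("markswitch", "cytosine_report")) {
  dialect <- arg_match(dialect)
  if (dialect == "markswitch") {
    out <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    return(as_tibble(out))
  }
  raw <- utils::read.table(
    path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
    col.names = c("chrom", "pos", "strand", "count_methylated",
                  "count_unmethylated", "context", "trinucleotide")
  )
  tibble(
    chrom = raw$chrom, pos = raw$pos - 1L, strand = raw$strand,
    context = raw$context,
    count_modified = raw$count_methylated,
    count_total = raw$count_methylated + raw$count_unmethylated
  )
}

#' @rdname read_count_tsv
#' @param counts Count tibble to write.
#' @export
write_count_tsv <- function(counts, path) {
  utils::write.table(as_tibble(counts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write interval tibbles as BED
#'
#' BED files are 0-based half-open.  BED4 carries a name column; BED5 adds a
#' score.  Extra columns beyond the fifth are ignored on read.
#'
#' @param path File path.
#' @return A tibble with chrom, start, end and, when present, name and
#'   score.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(raw)[seq_len(min(5, ncol(raw)))] <-
    c("chrom", "start", "end", "name", "score")[seq_len(min(5, ncol(raw)))]
  out <- as_tibble(raw[, seq_len(min(5, ncol(raw))), drop = FALSE])
  if (any(out$end < out$start)) abort("Malformed BED: end < start.")
  arrange(out, .data$chrom, .data$start)
}

#' @rdname read_bed
#' @param intervals Interval tibble with chrom, start, end and optional
#'   name/score columns (aliases `feature`, `state`, `gene_id` are used as
#'   the BED name when `name` is absent).
#' @export
write_bed <- function(intervals, path) {
  tbl <- as_tibble(intervals)
  name_col <- intersect(c("name", "feature", "state", "gene_id", "peak_id"),
                        names(tbl))[1]
  cols <- list(tbl$chrom, tbl$start, tbl$end)
  if (!is.na(name_col)) {
    cols <- c(cols, list(tbl[[name_col]]))
    if ("score" %in% names(tbl)) cols <- c(cols, list(tbl$score))
  }
  names(cols) <- paste0("V", seq_along(cols))
  utils::write.table(do.call(data.frame, cols), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
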