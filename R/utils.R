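# Internal helpers shared across modules.

# Canonical mark keys.  "5mC" denotes the BS-derived composite (5mC+5hmC reads
# as C); "5hmC" the TAB signal; "5fC_5caC" the MAB signal.
.marks <- c("5mC", "5hmC", "5fC_5caC")

# Accepted aliases -> canonical key.
normalize_mark <- function(mark) {
  map <- c(
    "5mC" = "5mC", "5mC_plus_5hmC" = "5mC", "5mc" = "5mC",
    "5hmC" = "5hmC", "5hmc" = "5hmC",
    "5fC_5caC" = "5fC_5caC", "5fC5caC" = "5fC_5caC", "5fc_5cac" = "5fC_5caC",
    "5fC" = "5fC_5caC"
  )
  out <- unname(map[mark])
  if (anyNA(out)) {
    abort(paste0(
      "Unknown mark(s): ", paste(unique(mark[is.na(out)]), collapse = ", "),
      ". Expected one of ", paste(.marks, collapse = ", "), " (or aliases)."
    ))
  }
  out
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

check_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(paste0("`", name, "` must be numeric and non-missing."))
  }
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!all(lo_ok & hi_ok)) {
    abort(paste0("`", name, "` must lie in the ", if (allow_zero) "[" else "(",
                 "0, 1", if (allow_one) "]" else ")", " interval."))
  }
  invisible(x)
}

# Standardise a per-site count table: accepts count_modified/count_total or
# k/n column naming, checks 0 <= k <= n, and reports the first offending row.
normalize_counts <- function(counts, arg = "counts") {
  counts <- as_tibble(counts)
  if ("count_modified" %in% names(counts) && !"k" %in% names(counts)) {
    counts <- rename(counts, k = "count_modified")
  }
  if ("count_total" %in% names(counts) && !"n" %in% names(counts)) {
    counts <- rename(counts, n = "count_total")
  }
  required <- c("k", "n")
  missing <- setdiff(required, names(counts))
  if (length(missing)) {
    abort(paste0("`", arg, "` lacks required column(s): ",
                 paste(missing, collapse = ", "),
                 " (count_modified/count_total also accepted)."))
  }
  bad <- which(counts$k < 0 | counts$n < 0 | counts$k > counts$n)
  if (length(bad)) {
    row <- counts[bad[1L], ]
    loc <- if (all(c("chrom", "pos") %in% names(row))) {
      paste0(" at ", row$chrom, ":", row$pos)
    } else {
      paste0(" in row ", bad[1L])
    }
    abort(paste0("Malformed counts", loc, ": k = ", row$k, ", n = ", row$n,
                 " violates 0 <= k <= n."))
  }
  counts
}

# Site identity used for joins throughout: strand-specific genomic key.
site_keys <- function(tbl) intersect(c("chrom", "pos", "strand"), names(tbl))

# Convert a 0-based half-open interval tibble (chrom, start, end) to GRanges.
intervals_to_granges <- function(tbl, arg = "intervals") {
  tbl <- as_tibble(tbl)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(tbl))) {
    abort(paste0("`", arg, "` must have columns chrom, start, end."))
  }
  if (any(tbl$start < 0)) abort(paste0("`", arg, "` has negative start."))
  if (any(tbl$end < tbl$start)) {
    abort(paste0("`", arg, "` has end < start (intervals are 0-based half-open)."))
  }
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
  )
}

# Convert per-site positions (0-based) to width-1 GRanges.
sites_to_granges <- function(tbl, arg = "sites") {
  tbl <- as_tibble(tbl)
  if (!all(c("chrom", "pos") %in% names(tbl))) {
    abort(paste0("`", arg, "` must have columns chrom, pos."))
  }
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$pos + 1L, width = 1L)
  )
}

# findOverlaps with harmonized seqlevels, so disjoint chromosome sets
# compare silently (they simply never overlap).
find_overlaps_q <- function(query, subject, ...) {
  lv <- union(GenomeInfoDb::seqlevels(query), GenomeInfoDb::seqlevels(subject))
  GenomeInfoDb::seqlevels(query) <- lv
  GenomeInfoDb::seqlevels(subject) <- lv
  GenomicRanges::findOverlaps(query, subject, ...)
}

# Signed direction call for a delta against a positive cutoff.
delta_direction <- function(delta, cutoff) {
  dplyr::case_when(
    delta > cutoff ~ "+",
    delta < -cutoff ~ "-",
    TRUE ~ "0"
  )
}
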