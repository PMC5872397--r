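#' Classify the dinucleotide context of a cytosine, strand-specifically
#'
#' Determines the CpN context of a position from the reference sequence.  On
#' the plus strand the base at `pos` must be `C` and the context is read from
#' the following base (`A` gives CpA, `C` CpC, `T` CpT, `G` CpG).  On the
#' minus strand the base at `pos` must be `G` (a cytosine on the reverse
#' complement) and the context is the complement of the preceding plus-strand
#' base.  Positions that are not a cytosine on the requested strand, or whose
#' neighbouring base is `N` or out of range, return `NA` (unclassifiable).
#'
#' @param ref_seq Reference sequence for one chromosome: a single character
#'   string of A/C/G/T/N (a `Biostrings` sequence is accepted and converted).
#' @param pos Integer vector of 0-based positions.
#' @param strand Character vector of `"+"`/`"-"`, recycled to `length(pos)`.
#' @return Character vector of contexts (`"CpG"`, `"CpA"`, `"CpC"`, `"CpT"`)
#'   or `NA`.
#' @examples
#' classify_context("ACATG", pos = 1, strand = "+")   # CpA
#' classify_context("ACATG", pos = 4, strand = "-")   # T precedes G: CpA
#' @export
classify_context <- function(ref_seq, pos, strand) {
  if (!is.character(ref_seq)) ref_seq <- as.character(ref_seq)
  stopifnot(length(ref_seq) == 1L)
  ref_seq <- toupper(ref_seq)
  len <- nchar(ref_seq)
  strand <- rep_len(strand, length(pos))
  base_at <- function(i) {
    out <- rep(NA_character_, length(i))
    ok <- i >= 0 & i < len
    if (any(ok)) {
      out[ok] <- substring(ref_seq, i[ok] + 1L, i[ok] + 1L)
    }
    out
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  here <- base_at(pos)
  out <- rep(NA_character_, length(pos))
  plus <- strand == "+"
  nxt <- base_at(pos + 1L)
  ok_p <- plus & !is.na(here) & here == "C" & nxt %in% c("A", "C", "G", "T")
  out[ok_p] <- paste0("Cp", nxt[ok_p])
  prv <- base_at(pos - 1L)
  prv_c <- unname(comp[prv])
  ok_m <- !plus & !is.na(here) & here == "G" &
    !is.na(prv_c) & prv_c %in% c("A", "C", "G", "T")
  out[ok_m] <- paste0("Cp", prv_c[ok_m])
  out
}

#' Strand-specific non-CpG methylation profile
#'
#' Summarises non-CpG (CpA/CpC/CpT) methylation per sample and, when a group
#' mapping is supplied, calls differential non-CpG sites between two groups.
#' A site is highly modified when `m > high_cut` (strict, default 0.4; no
#' medium tier for non-CpG).  Differential calls compare unweighted group
#' means per strand-specific site: hyper when `delta > diff_cut`, hypo when
#' `delta < -diff_cut`.  Two conventional cutoffs apply: 0.2 for comparisons
#' between cell classes and 0.1 for changes across differentiation
#' (`comparison` selects the default; `diff_cut` overrides).
#'
#' @param tables Long site table with chrom, pos, strand, context, sample, m
#'   (CpG rows are dropped with a message if present).
#' @param groups Optional tibble (sample, group) with exactly two groups; the
#'   first level (alphabetical, or factor order) is the reference.
#' @param high_cut High-modification threshold.  Default 0.4.
#' @param comparison `"cell_type"` (cutoff 0.2) or `"differentiation"`
#'   (cutoff 0.1).
#' @param diff_cut Optional explicit differential cutoff overriding
#'   `comparison`.
#' @return A list of class `noncpg_profile`: `site_counts` (sites per context
#'   per sample), `high_counts` (highly modified sites per context per
#'   sample), and when `groups` is given, `differential` (per-site deltas and
#'   calls) and `diff_counts` (hyper/hypo counts per context).
#' @export
noncpg_profile <- function(tables, groups = NULL, high_cut = 0.4,
                           comparison = c("cell_type", "differentiation"),
                           diff_cut = NULL) {
  comparison <- arg_match(comparison)
  cut <- diff_cut %||% switch(comparison, cell_type = 0.2,
                              differentiation = 0.1)
  tbl <- as_tibble(tables)
  need <- c("chrom", "pos", "strand", "context", "sample", "m")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(paste0("`tables` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(tbl$context == "CpG")) {
    inform("Dropping CpG rows from the non-CpG profile.")
    tbl <- filter(tbl, .data$context != "CpG")
  }
  bad <- setdiff(unique(tbl$context), c("CpA", "CpC", "CpT"))
  if (length(bad)) {
    abort(paste0("Unknown non-CpG context(s): ", paste(bad, collapse = ", ")))
  }
  ctx_levels <- c("CpA", "CpC", "CpT")
  tbl <- mutate(tbl, context = factor(.data$context, levels = ctx_levels))
  site_counts <- count(tbl, .data$sample, .data$context, .drop = FALSE,
                       name = "n_sites")
  high_counts <- tbl %>%
    filter(.data$m > high_cut) %>%
    count(.data$sample, .data$context, .drop = FALSE, name = "n_high")
  out <- list(site_counts = site_counts, high_counts = high_counts,
              high_cut = high_cut, diff_cut = cut)
  if (!is.null(groups)) {
    groups <- as_tibble(groups)
    lv <- if (is.factor(groups$group)) levels(groups$group) else
      sort(unique(groups$group))
    if (length(lv) != 2) abort("`groups` must define exactly 2 groups.")
    g <- inner_join(tbl, groups, by = "sample")
    means <- g %>%
      group_by(.data$chrom, .data$pos, .data$strand, .data$context,
               .data$group) %>%
      summarise(m = mean(.data$m), .groups = "drop") %>%
      pivot_wider(names_from = "group", values_from = "m") %>%
      filter(!is.na(.data[[lv[1]]]), !is.na(.data[[lv[2]]]))
    differential <- means %>%
      mutate(delta = .data[[lv[2]]] - .data[[lv[1]]],
             call = dplyr::case_when(
               .data$delta > cut ~ "hyper",
               .data$delta < -cut ~ "hypo",
               TRUE ~ "no_change"
             ))
    out$differential <- differential
    out$diff_counts <- differential %>%
      filter(.data$call != "no_change") %>%
      count(.data$context, .data$call, .drop = FALSE, name = "n_sites")
    out$groups <- lv
  }
  structure(out, class = "noncpg_profile")
}

#' @export
print.noncpg_profile <- function(x, ...) {
  cat("<noncpg_profile> high cutoff ", x$high_cut, sep = "")
  if (!is.null(x$differential)) {
    cat("; differential ", x$groups[2], " vs ", x$groups[1],
        " at cutoff ", x$diff_cut, sep = "")
  }
  cat("\n")
  print(as.data.frame(x$site_counts))
  invisible(x)
}
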