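#' Fraction of each interval covered by a peak set
#'
#' For every interval in `a`, computes the number of its bases covered by the
#' union of the intervals in `bset`, divided by the interval's length.  Using
#' the union means abutting or overlapping peaks are never double-counted:
#' an interval fully tiled by two adjacent peaks has fraction 1.
#'
#' @param a Interval tibble (chrom, start, end), 0-based half-open.
#' @param bset Interval tibble to cover against.
#' @return The tibble `a` with an `overlap_fraction` column in [0, 1].
#' @examples
#' a <- tibble::tibble(chrom = "chrS1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chrS1", start = c(100, 150),
#'                     end = c(150, 400))
#' overlap_fraction(a, b)
#' @export
overlap_fraction <- function(a, bset) {
  a <- as_tibble(a)
  if (any(a$end <= a$start)) {
    abort("Zero- or negative-length interval in `a`; overlap fraction undefined.")
  }
  ga <- intervals_to_granges(a, "a")
  if (nrow(as_tibble(bset)) == 0) {
    return(mutate(a, overlap_fraction = 0))
  }
  gb <- GenomicRanges::reduce(intervals_to_granges(bset, "bset"))
  hits <- find_overlaps_q(ga, gb)
  covered <- numeric(nrow(a))
  if (length(hits)) {
    inter <- GenomicRanges::pintersect(ga[S4Vectors::queryHits(hits)],
                                       gb[S4Vectors::subjectHits(hits)])
    w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(w))] <- as.numeric(w)
  }
  mutate(a, overlap_fraction = covered / (a$end - a$start))
}

#' Stratify peaks into tissue-specific and shared
#'
#' Applies the peak quality filter (`fdr < fdr_max` and `score >= score_min`,
#' the FDR strict and the score inclusive) to every tissue's peaks, then
#' labels each focal-tissue peak: it is `shared` with another tissue when at
#' least `min_fraction` of the peak is covered by the union of that tissue's
#' filtered peaks, and `specific` when no other tissue reaches that
#' fraction.  The overlap criterion is evaluated on the focal peak only (not
#' reciprocally), against the union of the other tissue's peaks.
#'
#' @param peaks Tibble of peaks across tissues: tissue, chrom, start, end,
#'   fdr, score (plus any identifier columns, which pass through).
#' @param focal_tissue Tissue whose peaks are labelled.
#' @param min_fraction Sharing threshold on the covered fraction.
#'   Default 0.6.
#' @param fdr_max,score_min Quality filter. Defaults 0.01 and 30.
#' @return The focal tissue's filtered peaks with `overlap_best` (largest
#'   covered fraction against any other tissue), `label`
#'   (`"specific"`/`"shared"`) and `shared_with` (comma-separated tissues).
#' @examples
#' pk <- tibble::tibble(
#'   tissue = c("brain", "liver"), chrom = "chrS1",
#'   start = c(0, 5000), end = c(1000, 6000), fdr = 0.001, score = 50)
#' stratify_tissue_specific(pk, "brain")
#' @export
stratify_tissue_specific <- function(peaks, focal_tissue, min_fraction = 0.6,
                                     fdr_max = 0.01, score_min = 30) {
  peaks <- as_tibble(peaks)
  need <- c("tissue", "chrom", "start", "end", "fdr", "score")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) {
    abort(paste0("`peaks` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!focal_tissue %in% peaks$tissue) {
    abort(paste0("Focal tissue `", focal_tissue, "` absent from `peaks`."))
  }
  if (length(unique(peaks$tissue)) < 2) {
    abort("Need peaks from at least 2 tissues.")
  }
  filtered <- filter(peaks, .data$fdr < fdr_max, .data$score >= score_min)
  focal <- filter(filtered, .data$tissue == focal_tissue)
  if (nrow(focal) == 0) {
    return(mutate(focal, overlap_best = numeric(), label = character(),
                  shared_with = character()))
  }
  others <- setdiff(unique(filtered$tissue), focal_tissue)
  fracs <- sapply(others, function(tis) {
    overlap_fraction(focal,
                     filter(filtered, .data$tissue == tis))$overlap_fraction
  })
  fracs <- matrix(fracs, nrow = nrow(focal),
                  dimnames = list(NULL, others))
  shared_with <- apply(fracs, 1, function(fr) {
    paste(others[fr >= min_fraction], collapse = ",")
  })
  focal %>%
    mutate(
      overlap_best = if (length(others)) apply(fracs, 1, max) else 0,
      label = if_else(.data$overlap_best >= min_fraction, "shared",
                      "specific"),
      shared_with = shared_with
    )
}

#' Chromatin-state co-localization of switch codes
#'
#' Maps each coded site into the (non-overlapping) chromatin-state
#' segmentation and computes, for every state and switch code,
#' `enrichment(s, c) = (sites of c in s / sites of c) / (sites in s / all
#' sites)`.  Sites falling outside every segment are collected in an
#' `unassigned` state row.  Codes present in the input's factor levels but
#' absent from the data give `NA` enrichment.
#'
#' @param codes Tibble from [switch_codes()] (site keys + `code`; `code` may
#'   be a factor to force empty classes into the output).
#' @param segmentation Interval tibble with chrom, start, end, state.
#' @return A tibble: state, code, n_sites, n_code, n_state, enrichment.
#' @export
state_colocalization <- function(codes, segmentation) {
  codes <- as_tibble(codes)
  seg <- as_tibble(segmentation)
  if (!"state" %in% names(seg)) abort("`segmentation` needs a `state` column.")
  gseg <- intervals_to_granges(seg, "segmentation")
  ov <- GenomicRanges::countOverlaps(gseg, gseg)
  if (any(ov > 1)) abort("`segmentation` intervals overlap.")
  hits <- find_overlaps_q(sites_to_granges(codes), gseg)
  state <- rep("unassigned", nrow(codes))
  state[S4Vectors::queryHits(hits)] <- seg$state[S4Vectors::subjectHits(hits)]
  scored <- mutate(codes, state = state)
  code_levels <- if (is.factor(codes$code)) levels(codes$code) else
    sort(unique(as.character(codes$code)))
  n_total <- nrow(scored)
  per_state <- count(scored, .data$state, name = "n_state")
  per_code <- count(scored, code = as.character(.data$code), name = "n_code")
  expand_grid(state = unique(state), code = code_levels) %>%
    left_join(count(mutate(scored, code = as.character(.data$code)),
                    .data$state, .data$code, name = "n_sites"),
              by = c("state", "code")) %>%
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L)) %>%
    left_join(per_state, by = "state") %>%
    left_join(per_code, by = "code") %>%
    mutate(enrichment = dplyr::case_when(
      is.na(.data$n_code) | .data$n_code == 0 ~ NA_real_,
      TRUE ~ (.data$n_sites / .data$n_code) / (.data$n_state / n_total)
    )) %>%
    arrange(.data$state, .data$code)
}

#' Assign genes to regions by TSS distance
#'
#' A gene is assigned to a region when the minimum distance between the
#' region and the gene's transcription start site is at most `window_bp`
#' (distance 0 when the TSS lies inside the region).  Many-to-many
#' assignments are allowed.  This symmetric fixed-window rule is a
#' deliberately simple stand-in for regulatory-domain tools; typical windows
#' are 50 kb (permissive) or 10 kb (proximal).
#'
#' @param regions Interval tibble (chrom, start, end + optional id columns).
#' @param genes Tibble with gene_id, chrom, tss, strand.
#' @param window_bp Maximum region-TSS distance in bp.
#' @return A tibble of region-gene pairs with `distance`.
#' @export
assign_genes <- function(regions, genes, window_bp = 50000) {
  if (window_bp < 0) abort("`window_bp` must be non-negative.")
  regions <- as_tibble(regions)
  genes <- as_tibble(genes)
  if (!nrow(regions) || !nrow(genes)) {
    return(bind_cols(regions[0, ], genes[0, c("gene_id", "tss", "strand")],
                     tibble(distance = numeric())))
  }
  gr <- intervals_to_granges(regions, "regions")
  gt <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$tss + 1L, width = 1L))
  hits <- find_overlaps_q(gr, gt, maxgap = window_bp)
  if (!length(hits)) {
    return(bind_cols(regions[0, ], genes[0, c("gene_id", "tss", "strand")],
                     tibble(distance = numeric())))
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  tss <- genes$tss[si]
  start <- regions$start[qi]
  end <- regions$end[qi]
  distance <- dplyr::case_when(
    tss >= start & tss < end ~ 0,
    tss < start ~ start - tss,
    TRUE ~ tss - (end - 1)
  )
  keep <- distance <= window_bp
  out <- bind_cols(
    regions[qi[keep], ],
    genes[si[keep], c("gene_id", "tss", "strand")],
    tibble(distance = distance[keep])
  )
  arrange(out, .data$chrom, .data$start, .data$distance)
}

#' Classify per-gene expression change between two groups
#'
#' Computes `log2FC = log2((mean_B + pc) / (mean_A + pc))` per gene and
#' classifies it as `up` / `down` / `unchanged` against a fold-change cutoff
#' and an FDR gate.  Q-values are taken from `qvalues` when supplied (e.g.
#' from an external differential-expression run); otherwise, when both groups
#' have at least 2 replicates, a Welch t-test with Benjamini-Hochberg
#' correction is used.  With fewer replicates and no supplied q-values,
#' classification falls back to fold change alone (q is `NA`).
#'
#' @param expr_a,expr_b Expression tibbles (gene column + one numeric column
#'   per sample) over a shared gene universe.
#' @param log2fc_cutoff Absolute log2 fold-change cutoff.  Default 1.
#' @param fdr_cutoff Q-value cutoff.  Default 0.05.
#' @param pseudocount Added to group means before the ratio.  Default 1.
#' @param qvalues Optional tibble (gene, q_value) of externally computed
#'   q-values.
#' @return A tibble: gene, mean_a, mean_b, log2fc, q_value, change.
#' @export
classify_expression_change <- function(expr_a, expr_b, log2fc_cutoff = 1,
                                       fdr_cutoff = 0.05, pseudocount = 1,
                                       qvalues = NULL) {
  expr_a <- as_tibble(expr_a)
  expr_b <- as_tibble(expr_b)
  if (!"gene" %in% names(expr_a) || !"gene" %in% names(expr_b)) {
    abort("Expression tables need a `gene` column.")
  }
  va <- as.matrix(expr_a[setdiff(names(expr_a), "gene")])
  vb <- as.matrix(expr_b[setdiff(names(expr_b), "gene")])
  if (ncol(va) < 1 || ncol(vb) < 1) abort("Each group needs >= 1 sample.")
  shared <- intersect(expr_a$gene, expr_b$gene)
  if (!length(shared)) abort("No shared genes between groups.")
  ia <- match(shared, expr_a$gene)
  ib <- match(shared, expr_b$gene)
  mean_a <- rowMeans(va)[ia]
  mean_b <- rowMeans(vb)[ib]
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  q <- if (!is.null(qvalues)) {
    qv <- as_tibble(qvalues)
    qv$q_value[match(shared, qv$gene)]
  } else if (ncol(va) >= 2 && ncol(vb) >= 2) {
    p <- vapply(seq_along(shared), function(i) {
      xa <- va[ia[i], ]
      xb <- vb[ib[i], ]
      if (sd(xa) == 0 && sd(xb) == 0) {
        if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
      } else {
        tryCatch(t.test(xb, xa)$p.value, error = function(e) NA_real_)
      }
    }, numeric(1))
    p.adjust(p, method = "BH")
  } else {
    rep(NA_real_, length(shared))
  }
  q_pass <- is.na(q) | q < fdr_cutoff
  tibble(
    gene = shared, mean_a = mean_a, mean_b = mean_b, log2fc = log2fc,
    q_value = q,
    change = dplyr::case_when(
      log2fc > log2fc_cutoff & q_pass ~ "up",
      log2fc < -log2fc_cutoff & q_pass ~ "down",
      TRUE ~ "unchanged"
    )
  )
}
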