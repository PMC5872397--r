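# Independent brute-force oracles used across test files.  These deliberately
# avoid the package's vectorised/interval machinery: per-base loops and raw
# pmf sums only.

# Fraction of [a_start, a_end) covered by the union of b intervals, counted
# base by base.
bf_overlap_fraction <- function(a_start, a_end, b_start, b_end) {
  bases <- a_start:(a_end - 1L)
  covered <- vapply(bases, function(p) {
    any(p >= b_start & p < b_end)
  }, logical(1))
  mean(covered)
}

# Upper-tail binomial probability P(X >= k) by pmf summation.
bf_binom_upper <- function(k, n, p, inclusive = TRUE) {
  from <- if (inclusive) k else k + 1L
  if (from > n) return(0)
  sum(dbinom(from:n, n, p))
}

# Direct ratio-of-proportions enrichment for one (feature, direction) cell.
bf_enrichment <- function(event_features, event_dirs, universe_features,
                          feature, direction) {
  ev_dir <- event_features[event_dirs == direction]
  if (length(ev_dir) == 0) return(NA_real_)
  n_f_univ <- sum(universe_features == feature)
  if (n_f_univ == 0) return(NA_real_)
  (sum(ev_dir == feature) / length(ev_dir)) /
    (n_f_univ / length(universe_features))
}

# Per-quadrant F1 of predicted vs planted labels.
f1_score <- function(truth_labels, pred_labels, positive) {
  tp <- sum(truth_labels == positive & pred_labels == positive)
  fp <- sum(truth_labels != positive & pred_labels == positive)
  fn <- sum(truth_labels == positive & pred_labels != positive)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

# Reverse complement of an A/C/G/T/N string.
bf_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# Small random interval tibble on one chromosome.
random_intervals <- function(n, genome_len = 500, max_width = 60) {
  start <- sample.int(genome_len - max_width, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  tibble::tibble(chrom = "chrS1", start = start, end = start + width)
}
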