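#' Score per-site modification levels from bisulfite counts
#'
#' Computes the modification level at each site as the ratio of modified-state
#' reads to total reads, `m = k/n`, and applies the per-mark coverage filter.
#' The filter is strict: a site is retained only when `n > min_coverage`, so
#' with the conventional `min_coverage = 10` a site at exactly 10x is dropped.
#'
#' @param counts Data frame of per-site counts with columns `chrom`, `pos`,
#'   `strand`, and `k`/`n` (aliases `count_modified`/`count_total` accepted).
#'   Extra columns (`context`, `sample`, `assay`) pass through.
#' @param mark Mark label recorded in the output: one of `"5mC"` (BS composite
#'   of 5mC+5hmC), `"5hmC"` (TAB) or `"5fC_5caC"` (MAB); aliases such as
#'   `"5mC_plus_5hmC"` are accepted.
#' @param min_coverage Coverage floor; rows with `n <= min_coverage` are
#'   dropped.  Default 10.
#'
#' @return A tibble (the site mark table) with the input columns plus `mark`
#'   and `m`, in the input row order.
#' @examples
#' counts <- tibble::tibble(chrom = "chrS1", pos = c(100, 120, 140),
#'                          strand = "+", k = c(7, 13, 0), n = c(10, 20, 25))
#' score_sites(counts, mark = "5mC", min_coverage = 10)
#' @seealso [call_5fc_5cac()] for the MAB-specific binomial caller,
#'   [estimate_efficiency()] for spike-in calibration.
#' @export
score_sites <- function(counts, mark, min_coverage = 10) {
  stopifnot(is.numeric(min_coverage), length(min_coverage) == 1L,
            min_coverage >= 0)
  counts <- normalize_counts(counts)
  mark <- normalize_mark(mark)
  counts %>%
    filter(.data$n > min_coverage) %>%
    mutate(mark = mark, m = .data$k / .data$n)
}

#' Estimate assay conversion efficiency from spike-in controls
#'
#' Pools read observations over all spike-in positions of one control and
#' estimates the chemistry's efficiency as the fraction of observations
#' consistent with successful conversion, with a normal-approximation 95\%
#' confidence interval.  The direction of "success" depends on the control
#' and the assay:
#' \itemize{
#'   \item unmethylated lambda under MAB: success = read as C
#'     (M.SssI methylation efficiency; its complement is the false-T failure
#'     rate used by [call_5fc_5cac()]);
#'   \item unmethylated lambda under BS or TAB: success = read as T
#'     (bisulfite conversion efficiency);
#'   \item 5mC control under TAB: success = read as T (Tet1 oxidation /
#'     conversion efficiency);
#'   \item 5hmC control under TAB: success = read as C (glucosylation
#'     protection efficiency);
#'   \item 5mC or 5hmC control under BS: success = read as C.
#' }
#' Counts follow the package-wide convention that `k` is the number of reads
#' in the assay's modified state (C for BS/TAB, T for MAB).
#'
#' @param spikein_counts Data frame of spike-in counts with `k`/`n` columns
#'   (or `count_modified`/`count_total`); an `assay` column is used when
#'   `assay` is not supplied.
#' @param control_kind One of `"lambda_unmethylated"`, `"5mC_control"`,
#'   `"5hmC_control"`.  If missing and the table has a `control_kind` column
#'   with a single value, that value is used.
#' @param assay One of `"BS"`, `"TAB"`, `"MAB"`.
#' @param conf_level Confidence level for the interval.  Default 0.95.
#'
#' @return An object of class `efficiency_estimate` with fields `control_kind`,
#'   `assay`, `E` (efficiency), `epsilon` (failure rate, `1 - E`), `n_obs`,
#'   `ci95`.  [tidy()] and [glance()] methods are provided.
#' @examples
#' spike <- tibble::tibble(k = 38, n = 1000)  # lambda read as T under MAB
#' estimate_efficiency(spike, "lambda_unmethylated", assay = "MAB")
#' @export
estimate_efficiency <- function(spikein_counts,
                                control_kind = c("lambda_unmethylated",
                                                 "5mC_control", "5hmC_control"),
                                assay = NULL, conf_level = 0.95) {
  counts <- normalize_counts(spikein_counts, arg = "spikein_counts")
  if (missing(control_kind) && "control_kind" %in% names(counts)) {
    ck <- unique(counts$control_kind)
    if (length(ck) != 1L) {
      abort("`spikein_counts` mixes control kinds; pass `control_kind`.")
    }
    control_kind <- ck
  }
  control_kind <- arg_match(control_kind)
  if (is.null(assay)) {
    if (!"assay" %in% names(counts)) {
      abort("Supply `assay` or include an `assay` column.")
    }
    assay <- unique(counts$assay)
    if (length(assay) != 1L) {
      abort("`spikein_counts` mixes assays; pass `assay`.")
    }
  }
  assay <- arg_match(assay, values = c("BS", "TAB", "MAB"))
  if ("control_kind" %in% names(counts)) {
    counts <- filter(counts, .data$control_kind == !!control_kind)
  }
  n_obs <- sum(counts$n)
  if (n_obs == 0) abort("Zero total spike-in observations.")
  k_mod <- sum(counts$k)  # reads in the assay's modified state

  # success = modified-state reads?  (else success = n - k)
  success_is_modified <- switch(
    assay,
    BS = control_kind != "lambda_unmethylated",  # modified state is C
    TAB = control_kind == "5hmC_control",        # protection success reads C
    MAB = FALSE                                  # modified state T = failure/5fC
  )
  succ <- if (success_is_modified) k_mod else n_obs - k_mod
  E <- succ / n_obs
  se <- sqrt(E * (1 - E) / n_obs)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(E + c(-1, 1) * z * se, 0), 1)
  structure(
    list(control_kind = control_kind, assay = assay, E = E, epsilon = 1 - E,
         n_obs = n_obs, ci95 = ci, conf_level = conf_level),
    class = "efficiency_estimate"
  )
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat("<efficiency_estimate>\n")
  cat("  control: ", x$control_kind, "  assay: ", x$assay, "\n", sep = "")
  cat(sprintf("  E = %.4f (%.2f%%), failure rate = %.4f\n",
              x$E, 100 * x$E, x$epsilon))
  cat(sprintf("  %d observations; %g%% CI [%.4f, %.4f]\n",
              x$n_obs, 100 * x$conf_level, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @rdname estimate_efficiency
#' @param x An `efficiency_estimate`.
#' @param ... Unused.
#' @method tidy efficiency_estimate
#' @export
tidy.efficiency_estimate <- function(x, ...) {
  tibble(
    control_kind = x$control_kind, assay = x$assay,
    estimate = x$E, failure_rate = x$epsilon,
    conf.low = x$ci95[1], conf.high = x$ci95[2], n_obs = x$n_obs
  )
}

#' @rdname estimate_efficiency
#' @method glance efficiency_estimate
#' @export
glance.efficiency_estimate <- function(x, ...) {
  tibble(estimate = x$E, n_obs = x$n_obs, conf_level = x$conf_level)
}

#' Binomial caller for 5fC/5caC from MAB counts
#'
#' In MAB sequencing, unmodified CpGs are enzymatically methylated by M.SssI
#' before bisulfite conversion, so a read reports T only when the site carries
#' 5fC/5caC or when M.SssI failed (rate `fail_rate`).  For each site the
#' caller computes an upper-tail binomial p-value for the observed T count
#' against the failure background, `P(X >= k)` with
#' `X ~ Binomial(n, fail_rate)` (the inclusive tail; set
#' `tail = "exclusive"` for `P(X > k)`).  A site is called positive when it
#' has at least `min_coverage` reads and `p_value < alpha`.
#'
#' @param mab_table Site mark table (or raw count table) for the MAB assay;
#'   `k` is the T-read count.
#' @param fail_rate M.SssI failure rate in (0, 1), typically estimated from an
#'   unmethylated lambda spike-in via [estimate_efficiency()] (`epsilon`).
#' @param min_coverage Minimum coverage for a call (inclusive).  Default 20.
#' @param alpha P-value threshold for a call.  Default 0.1.
#' @param tail `"inclusive"` (default) for `P(X >= k)` or `"exclusive"` for
#'   `P(X > k)`.
#' @param adjust If `TRUE`, add Benjamini-Hochberg `q_value` and gate calls on
#'   it instead of the raw p-value.  Off by default: the conventional screen
#'   uses the raw `P < 0.1`.
#'
#' @return The input tibble with columns `m`, `p_value` (and `q_value` when
#'   `adjust`) and logical `called`.
#' @examples
#' mab <- tibble::tibble(chrom = "chrS1", pos = c(10, 20), strand = "+",
#'                       k = c(0, 4), n = c(30, 20))
#' call_5fc_5cac(mab, fail_rate = 0.038)
#' @export
call_5fc_5cac <- function(mab_table, fail_rate, min_coverage = 20, alpha = 0.1,
                          tail = c("inclusive", "exclusive"), adjust = FALSE) {
  tail <- arg_match(tail)
  check_fraction(fail_rate, "fail_rate", allow_zero = FALSE, allow_one = FALSE)
  tbl <- normalize_counts(mab_table, arg = "mab_table")
  k <- tbl$k
  n <- tbl$n
  p <- if (tail == "inclusive") {
    pbinom(k - 1, n, fail_rate, lower.tail = FALSE)  # P(X >= k)
  } else {
    pbinom(k, n, fail_rate, lower.tail = FALSE)      # P(X > k)
  }
  tbl <- mutate(tbl, mark = "5fC_5caC", m = k / n, p_value = p)
  if (adjust) {
    tbl <- mutate(tbl, q_value = p.adjust(.data$p_value, method = "BH"),
                  called = .data$n >= min_coverage & .data$q_value < alpha)
  } else {
    tbl <- mutate(tbl, called = .data$n >= min_coverage & .data$p_value < alpha)
  }
  tbl
}

#' Derived pure-5mC levels by 5hmC subtraction
#'
#' BS measures the 5mC+5hmC composite and TAB measures 5hmC alone, so a
#' derived pure-5mC level can be formed as the difference, clipped at zero.
#' This is an optional convenience: the primary analyses keep the assays
#' separate because sampling noise makes the per-site difference unstable at
#' modest coverage.
#'
#' @param bs_table,tab_table Site mark tables for BS and TAB from the same
#'   sample; joined on chrom/pos/strand (and sample when present).
#' @return A tibble with `m_bs`, `m_tab` and `m_5mC_pure = max(m_bs - m_tab, 0)`
#'   over the shared sites.
#' @export
subtract_5hmc <- function(bs_table, tab_table) {
  keys <- intersect(site_keys(bs_table),
                    c(site_keys(tab_table),
                      intersect("sample", names(tab_table))))
  keys <- union(keys, intersect("sample", intersect(names(bs_table),
                                                    names(tab_table))))
  a <- select(as_tibble(bs_table), all_of(keys), m_bs = "m")
  b <- select(as_tibble(tab_table), all_of(keys), m_tab = "m")
  inner_join(a, b, by = keys) %>%
    mutate(m_5mC_pure = pmax(.data$m_bs - .data$m_tab, 0))
}
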