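#' Co-expression screen against a driver gene
#'
#' For every gene in the matrix, tests the Pearson correlation of its
#' expression with the driver gene across samples, and applies a dynamic
#' range gate: a gene passes when the correlation p-value (two-sided, from
#' the t transform) is below `p_cut` and the log2 fold change between its
#' highest- and lowest-expressing sample exceeds `range_cut`.  A pseudocount
#' keeps the range defined at zero expression.  Constant genes, whose
#' correlation is undefined, are reported with `status = "skipped"` rather
#' than failed.
#'
#' @param expr Expression tibble: `gene` column plus one numeric column per
#'   sample (at least 4 samples).
#' @param driver Name of the driver gene (e.g. a TET family member).
#' @param p_cut Correlation p-value gate.  Default 0.05.
#' @param range_cut Gate on log2(max/min) expression across samples.
#'   Default 0.5.
#' @param pseudocount Added to expression before the max/min ratio.
#'   Default 0.1.
#' @return A tibble per non-driver gene: r, p_value, range_stat, status
#'   (`"tested"`/`"skipped"`), direction (`"positive"`/`"negative"`), passed.
#' @examples
#' xs <- generate_expression_survival(expression_config(n_genes = 30), seed = 1)
#' dplyr::filter(tet_coexpression(xs$expr, "TET2"), passed)
#' @export
tet_coexpression <- function(expr, driver, p_cut = 0.05, range_cut = 0.5,
                             pseudocount = 0.1) {
  expr <- as_tibble(expr)
  if (!"gene" %in% names(expr)) abort("`expr` needs a `gene` column.")
  sample_cols <- setdiff(names(expr), "gene")
  if (length(sample_cols) < 4) abort("Need at least 4 samples.")
  if (!driver %in% expr$gene) {
    abort(paste0("Driver gene `", driver, "` not in the matrix."))
  }
  x <- as.numeric(expr[match(driver, expr$gene), sample_cols])
  if (sd(x) == 0) abort("Driver gene has zero variance.")
  others <- filter(expr, .data$gene != driver)
  res <- purrr::map(seq_len(nrow(others)), function(i) {
    y <- as.numeric(others[i, sample_cols])
    range_stat <- log2((max(y) + pseudocount) / (min(y) + pseudocount))
    if (sd(y) == 0) {
      return(tibble(gene = others$gene[i], r = NA_real_, p_value = NA_real_,
                    range_stat = range_stat, status = "skipped"))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(gene = others$gene[i], r = unname(ct$estimate),
           p_value = ct$p.value, range_stat = range_stat, status = "tested")
  }) %>% list_rbind()
  res %>%
    mutate(
      direction = dplyr::case_when(
        is.na(.data$r) ~ NA_character_,
        .data$r >= 0 ~ "positive",
        TRUE ~ "negative"
      ),
      passed = .data$status == "tested" & .data$p_value < p_cut &
        .data$range_stat > range_cut
    )
}

#' Correlate promoter modification with driver expression
#'
#' Screens region-level (promoter) modification for association with a
#' driver gene's expression across the same samples.  A promoter-mark pair
#' passes when the Pearson correlation p-value is below `p_cut` (default
#' 0.01) and the modification spans a dynamic range of at least `range_min`
#' (default 0.1) between its maximum and minimum sample.
#'
#' @param driver_expr Tibble (sample, expr) or named numeric vector of driver
#'   expression per sample.
#' @param promoter_marks Long region-level table with columns region (or
#'   gene_id/region_id), mark, sample, m — e.g. from [aggregate_regions()].
#' @param p_cut Correlation p-value gate.  Default 0.01.
#' @param range_min Gate on max - min modification.  Default 0.1.
#' @return A tibble keyed by (region, mark): r, p_value, range_stat, status,
#'   direction, passed.
#' @export
promoter_mark_correlation <- function(driver_expr, promoter_marks,
                                      p_cut = 0.01, range_min = 0.1) {
  if (is.numeric(driver_expr) && !is.null(names(driver_expr))) {
    driver_expr <- tibble(sample = names(driver_expr),
                          expr = unname(driver_expr))
  }
  driver_expr <- as_tibble(driver_expr)
  marks_tbl <- as_tibble(promoter_marks)
  id_col <- intersect(c("region", "region_id", "gene_id", "name"),
                      names(marks_tbl))[1]
  if (is.na(id_col)) abort("`promoter_marks` needs a region identifier column.")
  if (!all(c("mark", "sample", "m") %in% names(marks_tbl))) {
    abort("`promoter_marks` needs mark, sample and m columns.")
  }
  res <- marks_tbl %>%
    rename(region = all_of(id_col)) %>%
    inner_join(driver_expr, by = "sample") %>%
    group_by(.data$region, .data$mark) %>%
    summarise(
      n = n(),
      range_stat = max(.data$m) - min(.data$m),
      r = if (n() >= 3 && sd(.data$m) > 0 && sd(.data$expr) > 0) {
        cor(.data$expr, .data$m)
      } else {
        NA_real_
      },
      p_value = if (n() >= 3 && sd(.data$m) > 0 && sd(.data$expr) > 0) {
        cor.test(.data$expr, .data$m)$p.value
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  res %>%
    mutate(
      status = if_else(is.na(.data$r), "skipped", "tested"),
      direction = dplyr::case_when(
        is.na(.data$r) ~ NA_character_,
        .data$r >= 0 ~ "positive",
        TRUE ~ "negative"
      ),
      passed = .data$status == "tested" & .data$p_value < p_cut &
        .data$range_stat >= range_min
    )
}

#' Median-split log-rank survival screen for one gene
#'
#' Splits patients at the median of the gene's expression and compares the
#' survival curves of the above- and below-median halves with the standard
#' log-rank test.  The gene is flagged prognostic when the log-rank p-value
#' is below `p_cut` and the gene is expressed (value above
#' `expressed_threshold`) in more than `min_expressed_fraction` of patients.
#'
#' @param expr Tibble (sample, expr) or named numeric vector of the gene's
#'   expression per patient.
#' @param surv Survival tibble with sample, time (`time` or `time_months`)
#'   and event indicator (`event` or `event01`).
#' @param p_cut P-value gate.  Default 0.05.
#' @param min_expressed_fraction Expression-prevalence gate.  Default 0.5.
#' @param expressed_threshold A patient counts as expressing the gene when
#'   its value exceeds this.  Default 0.
#' @return A one-row tibble: statistic (log-rank chi-square), p_value,
#'   n_high, n_low, expressed_fraction, passed.  Degenerate inputs (no
#'   events, or fewer than 2 patients in a half) give `NA` statistic and
#'   `passed = FALSE`.
#' @examples
#' xs <- generate_expression_survival(expression_config(), seed = 1)
#' gene_expr <- tibble::tibble(
#'   sample = names(xs$patient_expr)[-1],
#'   expr = as.numeric(xs$patient_expr[1, -1]))
#' logrank_median_split(gene_expr, xs$survival)
#' @export
logrank_median_split <- function(expr, surv, p_cut = 0.05,
                                 min_expressed_fraction = 0.5,
                                 expressed_threshold = 0) {
  if (is.numeric(expr) && !is.null(names(expr))) {
    expr <- tibble(sample = names(expr), expr = unname(expr))
  }
  expr <- as_tibble(expr)
  surv <- as_tibble(surv)
  if ("time_months" %in% names(surv) && !"time" %in% names(surv)) {
    surv <- rename(surv, time = "time_months")
  }
  if ("event01" %in% names(surv) && !"event" %in% names(surv)) {
    surv <- rename(surv, event = "event01")
  }
  dat <- inner_join(expr, surv, by = "sample")
  if (nrow(dat) < 4) abort("Need at least 4 patients with expression and survival.")
  dat$high <- dat$expr > median(dat$expr)
  n_high <- sum(dat$high)
  n_low <- sum(!dat$high)
  expressed_fraction <- mean(dat$expr > expressed_threshold)
  stat <- p <- NA_real_
  if (n_high >= 2 && n_low >= 2 && sum(dat$event) > 0) {
    fit <- tryCatch(
      survival::survdiff(survival::Surv(time, event) ~ high, data = dat),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      stat <- fit$chisq
      p <- pchisq(fit$chisq, df = 1, lower.tail = FALSE)
    }
  }
  tibble(
    statistic = stat, p_value = p, n_high = n_high, n_low = n_low,
    expressed_fraction = expressed_fraction,
    passed = !is.na(p) & p < p_cut &
      expressed_fraction > min_expressed_fraction
  )
}

#' Log-rank screen over a gene-by-patient expression matrix
#'
#' Applies [logrank_median_split()] to every gene of a patient expression
#' matrix.
#'
#' @param patient_expr Tibble: `gene` column plus one column per patient.
#' @param surv Survival tibble as in [logrank_median_split()].
#' @param ... Passed to [logrank_median_split()].
#' @return A tibble with one row per gene.
#' @export
logrank_screen <- function(patient_expr, surv, ...) {
  patient_expr <- as_tibble(patient_expr)
  if (!"gene" %in% names(patient_expr)) {
    abort("`patient_expr` needs a `gene` column.")
  }
  cols <- setdiff(names(patient_expr), "gene")
  purrr::map(seq_len(nrow(patient_expr)), function(i) {
    e <- tibble(sample = cols, expr = as.numeric(patient_expr[i, cols]))
    logrank_median_split(e, surv, ...) %>%
      mutate(gene = patient_expr$gene[i], .before = 1)
  }) %>% list_rbind()
}
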