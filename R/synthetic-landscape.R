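#' Configuration for the synthetic regulatory landscape
#'
#' @param tissues Tissue labels; the first is the focal tissue by convention.
#' @param peaks_per_tissue Peaks per tissue passing the quality filters.
#' @param shared_fraction Fraction of each tissue's peaks planted as shared:
#'   identical coordinates copied into every tissue (overlap fraction 1).
#'   The remaining peaks are planted tissue-specific with zero overlap
#'   against any other tissue's peaks.
#' @param peak_width Peak width in bp.
#' @param fail_fraction Extra peaks (as a fraction of `peaks_per_tissue`)
#'   planted to fail the FDR/score quality filter.
#' @param n_chrom,chrom_length Synthetic genome shape.
#' @param n_states Number of chromatin-state labels in the segmentation.
#' @param segment_mean_width Mean chromatin-state segment width in bp.
#' @param n_genes Number of genes in the annotation.
#' @param promoter_width Strand-aware promoter window upstream of the TSS
#'   (TSS1500 convention by default).
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(tissues = c("brain", "liver", "lung"),
                             peaks_per_tissue = 100,
                             shared_fraction = 0.3,
                             peak_width = 1000,
                             fail_fraction = 0,
                             n_chrom = 2,
                             chrom_length = 1e6,
                             n_states = 16,
                             segment_mean_width = 2000,
                             n_genes = 100,
                             promoter_width = 1500) {
  check_fraction(shared_fraction, "shared_fraction")
  check_fraction(fail_fraction, "fail_fraction")
  if (length(tissues) < 2) abort("Need at least 2 tissues.")
  structure(
    list(tissues = tissues, peaks_per_tissue = peaks_per_tissue,
         shared_fraction = shared_fraction, peak_width = peak_width,
         fail_fraction = fail_fraction, n_chrom = n_chrom,
         chrom_length = chrom_length, n_states = n_states,
         segment_mean_width = segment_mean_width, n_genes = n_genes,
         promoter_width = promoter_width),
    class = "landscape_config"
  )
}

#' Generate a synthetic regulatory landscape with planted labels
#'
#' Produces per-tissue peak sets with planted shared/tissue-specific labels,
#' a non-overlapping chromatin-state segmentation, a gene annotation with
#' strand-aware promoter windows, and a genomic-feature tiling.  All
#' intervals are 0-based half-open on the synthetic `chrS*` genome.  Shared
#' peaks are byte-identical across tissues; specific peaks are placed in
#' disjoint genomic slots, so the planted labels are exactly what an overlap
#' stratifier at any threshold in (0, 1] must recover.
#'
#' @param config A [landscape_config()].
#' @param seed Integer seed.
#' @return A list of class `regulatory_landscape` with tibbles `peaks`
#'   (tissue, peak_id, chrom, start, end, fdr, score, planted), `states`
#'   (chrom, start, end, state), `genes` (gene_id, chrom, tss, strand),
#'   `promoters`, and `features`.
#' @examples
#' land <- generate_regulatory_landscape(landscape_config(), seed = 1)
#' dplyr::count(land$peaks, tissue, planted)
#' @export
generate_regulatory_landscape <- function(config, seed) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(seed, {
    chroms <- paste0("chrS", seq_len(config$n_chrom))
    w <- config$peak_width
    gap <- max(100, round(w / 5))
    slot_w <- w + gap
    slots_per_chrom <- floor(config$chrom_length / slot_w)
    capacity <- config$n_chrom * slots_per_chrom
    n_shared <- round(config$shared_fraction * config$peaks_per_tissue)
    n_spec <- config$peaks_per_tissue - n_shared
    n_fail <- round(config$fail_fraction * config$peaks_per_tissue)
    needed <- n_shared + length(config$tissues) * (n_spec + n_fail)
    if (needed > capacity) {
      abort(paste0("Peak layout unsatisfiable: need ", needed,
                   " disjoint slots but the genome holds ", capacity, "."))
    }
    slot_ids <- sample.int(capacity, needed)
    slot_interval <- function(id) {
      chrom_i <- (id - 1L) %/% slots_per_chrom + 1L
      off <- ((id - 1L) %% slots_per_chrom) * slot_w
      start <- off + sample.int(gap, 1L) - 1L
      tibble(chrom = chroms[chrom_i], start = start, end = start + w)
    }
    take <- function(k) {
      ids <- slot_ids[seq_len(k)]
      slot_ids <<- slot_ids[-seq_len(k)]
      list_rbind(purrr::map(ids, slot_interval))
    }

    shared <- if (n_shared > 0) take(n_shared) else NULL
    peaks <- list()
    for (tis in config$tissues) {
      parts <- list()
      if (!is.null(shared)) {
        parts$shared <- mutate(shared, planted = "shared")
      }
      if (n_spec > 0) {
        parts$spec <- mutate(take(n_spec), planted = "specific")
      }
      if (n_fail > 0) {
        parts$fail <- mutate(take(n_fail), planted = "fail_filter")
      }
      tp <- list_rbind(parts) %>%
        mutate(tissue = tis,
               fdr = if_else(.data$planted == "fail_filter",
                             runif(dplyr::n(), 0.011, 0.05),
                             runif(dplyr::n(), 0, 0.009)),
               score = if_else(.data$planted == "fail_filter",
                               runif(dplyr::n(), 5, 29),
                               runif(dplyr::n(), 30, 120))) %>%
        arrange(.data$chrom, .data$start) %>%
        mutate(peak_id = paste0(tis, "_pk", sprintf("%04d", row_number())))
      peaks[[tis]] <- tp
    }
    peaks <- list_rbind(peaks) %>%
      select("tissue", "peak_id", "chrom", "start", "end", "fdr", "score",
             "planted")

    # Chromatin-state tiling: contiguous, non-overlapping, genome-covering.
    states <- list_rbind(purrr::map(chroms, function(cc) {
      widths <- integer()
      total <- 0
      while (total < config$chrom_length) {
        wd <- max(200L, stats::rgeom(1, 1 / config$segment_mean_width) + 1L)
        widths <- c(widths, wd)
        total <- total + wd
      }
      ends <- pmin(cumsum(widths), config$chrom_length)
      starts <- c(0L, utils::head(ends, -1L))
      keep <- starts < ends
      tibble(chrom = cc, start = starts[keep], end = ends[keep],
             state = paste0("state_", sample.int(config$n_states,
                                                 sum(keep), replace = TRUE)))
    }))

    genes <- tibble(
      gene_id = sprintf("G%04d", seq_len(config$n_genes)),
      chrom = sample(chroms, config$n_genes, replace = TRUE),
      tss = sample.int(config$chrom_length - 2L * config$promoter_width,
                       config$n_genes) + config$promoter_width,
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
    ) %>% arrange(.data$chrom, .data$tss)

    promoters <- genes %>%
      mutate(
        start = if_else(.data$strand == "+",
                        pmax(.data$tss - config$promoter_width, 0),
                        .data$tss + 1L),
        end = if_else(.data$strand == "+",
                      .data$tss,
                      pmin(.data$tss + 1L + config$promoter_width,
                           config$chrom_length))
      ) %>%
      select("gene_id", "chrom", "start", "end", "strand")

    feature_names <- c("promoter", "gene_body", "cgi", "shore", "shelf",
                       "open_sea", "intergenic")
    features <- list_rbind(purrr::map(chroms, function(cc) {
      bounds <- seq(0L, config$chrom_length, by = 5000L)
      if (utils::tail(bounds, 1L) < config$chrom_length) {
        bounds <- c(bounds, config$chrom_length)
      }
      tibble(chrom = cc, start = utils::head(bounds, -1L),
             end = utils::tail(bounds, -1L),
             feature = sample(feature_names, length(bounds) - 1L,
                              replace = TRUE))
    }))

    structure(
      list(peaks = peaks, states = states, genes = genes,
           promoters = promoters, features = features, config = config,
           seed = seed),
      class = "regulatory_landscape"
    )
  })
}

#' @export
print.regulatory_landscape <- function(x, ...) {
  cat("<regulatory_landscape> ", length(unique(x$peaks$tissue)), " tissues, ",
      nrow(x$peaks), " peaks, ", nrow(x$states), " state segments, ",
      nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Configuration for synthetic expression and survival data
#'
#' @param n_samples Cell-line samples in the expression matrix (the screen's
#'   working scale is around 14: a dozen tumour-derived lines plus normals).
#' @param n_genes Total genes.
#' @param driver Driver gene name (a TET stand-in).
#' @param n_coexpr_pos,n_coexpr_neg Planted positively/negatively co-expressed
#'   gene counts.
#' @param target_r Target Pearson correlation of planted genes with the
#'   driver.
#' @param n_patients Patients in the survival cohort.
#' @param hazard_ratio Hazard ratio of above- vs below-median expression of
#'   the prognostic gene.
#' @param event_rate Expected fraction of patients with an observed event.
#' @param median_survival Median survival (months) of the below-median group.
#' @param n_null_patient_genes Extra patient-cohort genes unrelated to
#'   survival, for null calibration.
#' @return A list of class `expression_config`.
#' @export
expression_config <- function(n_samples = 14, n_genes = 200,
                              driver = "TET2",
                              n_coexpr_pos = 20, n_coexpr_neg = 20,
                              target_r = 0.8,
                              n_patients = 150, hazard_ratio = 2,
                              event_rate = 0.7, median_survival = 12,
                              n_null_patient_genes = 5) {
  if (n_samples < 3) abort("`n_samples` must be at least 3.")
  if (abs(target_r) > 1) abort("`target_r` must lie in [-1, 1].")
  check_fraction(event_rate, "event_rate", allow_zero = FALSE)
  if (hazard_ratio <= 0) abort("`hazard_ratio` must be positive.")
  structure(
    list(n_samples = n_samples, n_genes = n_genes, driver = driver,
         n_coexpr_pos = n_coexpr_pos, n_coexpr_neg = n_coexpr_neg,
         target_r = target_r, n_patients = n_patients,
         hazard_ratio = hazard_ratio, event_rate = event_rate,
         median_survival = median_survival,
         n_null_patient_genes = n_null_patient_genes),
    class = "expression_config"
  )
}

#' Generate expression and survival data with planted structure
#'
#' Builds (i) a cell-line expression matrix in which planted gene sets are
#' correlated with a driver gene at a target Pearson r (latent-Gaussian
#' construction: planted gene i uses `r z_driver + sqrt(1-r^2) e_i` on the
#' latent scale, so `target_r = 1` gives exact affine copies), and (ii) a
#' patient survival cohort whose times are exponential with a configured
#' hazard ratio between above- and below-median expression of the prognostic
#' gene, censored to the configured event rate.
#'
#' @param config An [expression_config()].
#' @param seed Integer seed.
#' @return A list of class `expression_truth`: `expr` (tibble, gene column +
#'   one column per sample), `survival` (tibble sample/time_months/event01),
#'   `patient_expr` (genes x patients, prognostic gene first), and `truth`
#'   (driver, coexpr_pos, coexpr_neg, prognostic gene).
#' @examples
#' xs <- generate_expression_survival(expression_config(n_genes = 50), seed = 1)
#' head(xs$expr)
#' @export
generate_expression_survival <- function(config, seed) {
  stopifnot(inherits(config, "expression_config"))
  with_seed(seed, {
    ns <- config$n_samples
    samples <- sprintf("S%02d", seq_len(ns))
    r <- config$target_r
    n_planted <- config$n_coexpr_pos + config$n_coexpr_neg
    if (n_planted + 1 > config$n_genes) {
      abort("`n_genes` too small for the planted co-expressed sets.")
    }
    z_driver <- rnorm(ns)
    gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
    pos_ids <- gene_ids[seq_len(config$n_coexpr_pos)]
    neg_ids <- gene_ids[config$n_coexpr_pos + seq_len(config$n_coexpr_neg)]
    latent <- function(sign_r) {
      if (abs(r) == 1) sign_r * z_driver
      else sign_r * r * z_driver + sqrt(1 - r^2) * rnorm(ns)
    }
    expr_rows <- purrr::map(gene_ids, function(g) {
      z <- if (g %in% pos_ids) latent(1)
      else if (g %in% neg_ids) latent(-1)
      else rnorm(ns)
      mu <- runif(1, 20, 100)
      pmax(mu + 0.15 * mu * z, 0)
    })
    driver_expr <- pmax(50 + 10 * z_driver, 0)
    expr <- as_tibble(setNames(
      as.data.frame(do.call(rbind, c(list(driver_expr), expr_rows))),
      samples
    ))
    expr <- bind_cols(tibble(gene = c(config$driver, gene_ids)), expr)

    # Patient cohort: exponential survival with a median-split hazard ratio
    # on the prognostic gene; independent censoring tuned to the event rate.
    np <- config$n_patients
    patients <- sprintf("P%03d", seq_len(np))
    prog_gene <- config$driver
    pe <- rnorm(np, 50, 10)
    null_genes <- if (config$n_null_patient_genes > 0) {
      matrix(rnorm(np * config$n_null_patient_genes, 50, 10),
             nrow = config$n_null_patient_genes)
    } else {
      NULL
    }
    high <- pe > median(pe)
    rate_low <- log(2) / config$median_survival
    rate <- if_else(high, rate_low * config$hazard_ratio, rate_low)
    er <- config$event_rate
    t_event <- rexp(np, rate)
    t_cens <- if (er >= 1) rep(Inf, np) else rexp(np, rate * (1 - er) / er)
    surv <- tibble(
      sample = patients,
      time_months = pmin(t_event, t_cens),
      event01 = as.integer(t_event <= t_cens)
    )
    pmat <- rbind(pe, null_genes)
    patient_expr <- bind_cols(
      tibble(gene = c(prog_gene,
                      if (config$n_null_patient_genes > 0)
                        sprintf("NULL%02d", seq_len(config$n_null_patient_genes)))),
      as_tibble(setNames(as.data.frame(pmat), patients))
    )
    structure(
      list(expr = expr, survival = surv, patient_expr = patient_expr,
           truth = list(driver = config$driver, coexpr_pos = pos_ids,
                        coexpr_neg = neg_ids, prognostic = prog_gene),
           config = config, seed = seed),
      class = "expression_truth"
    )
  })
}

#' @export
print.expression_truth <- function(x, ...) {
  cat("<expression_truth> ", nrow(x$expr), " genes x ",
      ncol(x$expr) - 1L, " samples; ", nrow(x$survival),
      " patients in the survival cohort\n", sep = "")
  invisible(x)
}
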