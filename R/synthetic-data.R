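#' Simulation configuration for ground-truthed modification landscapes
#'
#' Builds the configuration consumed by [generate_truth()].  The generator
#' emulates the study design the downstream pipeline assumes: two cell classes
#' (reference neural-stem-like and glioma-stem-like by default), per-site true
#' levels of the three cytosine marks with 5mC + 5hmC + 5fC/5caC <= 1
#' (mutually exclusive chemical states of one cytosine), a configurable set of
#' planted switching events between the classes, and small between-class
#' drift at all other sites that stays strictly below the differential
#' cutoffs.
#'
#' @param n_sites Number of cytosine sites.
#' @param n_chrom,chrom_length Synthetic genome shape; chromosomes are named
#'   `chrS1..chrSn` to avoid implying real coordinates.
#' @param context_probs Named probabilities over `CpG`, `CpA`, `CpC`, `CpT`
#'   contexts.  The default keeps non-CpG contexts at roughly the 3:1.1:1
#'   CpA:CpC:CpT abundance seen in reduced-representation data.
#' @param level_shapes List of `c(shape1, shape2)` Beta parameters for the
#'   reference-class level of each mark.
#' @param switch_spec Tibble with columns `fraction`, `d_5mC`, `d_5hmC`,
#'   `d_5fC_5caC`: each row plants that fraction of sites with the given true
#'   between-class deltas (class B minus class A).
#' @param jitter_sd SD of between-class drift at non-switching sites;
#'   truncated at 80\% of each mark's site cutoff so drift never crosses a
#'   differential threshold.
#' @param preset Cutoff preset (or name) defining the quadrant rule used for
#'   the planted switch labels.
#' @param cell_types Length-2 character vector, reference class first.
#' @param feature_probs Named probabilities for the per-site genomic-feature
#'   annotation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 2000,
                       n_chrom = 2,
                       chrom_length = 1e6,
                       context_probs = c(CpG = 0.70, CpA = 0.18,
                                         CpC = 0.066, CpT = 0.054),
                       level_shapes = list(
                         "5mC" = c(1.2, 0.8),
                         "5hmC" = c(1.5, 14),
                         "5fC_5caC" = c(1, 40)
                       ),
                       switch_spec = NULL,
                       jitter_sd = 0.01,
                       preset = "default",
                       cell_types = c("NSC", "GSC"),
                       feature_probs = c(promoter = 0.10, gene_body = 0.30,
                                         cgi = 0.08, shore = 0.08,
                                         shelf = 0.06, open_sea = 0.18,
                                         intergenic = 0.20)) {
  check_fraction(context_probs, "context_probs")
  check_fraction(feature_probs, "feature_probs")
  if (is.null(switch_spec)) {
    switch_spec <- tibble(fraction = numeric(), d_5mC = numeric(),
                          d_5hmC = numeric(), d_5fC_5caC = numeric())
  }
  switch_spec <- as_tibble(switch_spec)
  need <- c("fraction", "d_5mC", "d_5hmC", "d_5fC_5caC")
  miss <- setdiff(need, names(switch_spec))
  if (length(miss)) {
    abort(paste0("`switch_spec` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  check_fraction(switch_spec$fraction, "switch_spec$fraction")
  if (sum(switch_spec$fraction) > 1) {
    abort("Planted switch fractions sum to more than 1.")
  }
  if (any(abs(c(switch_spec$d_5mC, switch_spec$d_5hmC,
                switch_spec$d_5fC_5caC)) > 1)) {
    abort("Planted deltas must lie in [-1, 1].")
  }
  if (length(cell_types) != 2L) abort("`cell_types` must have length 2.")
  structure(
    list(n_sites = n_sites, n_chrom = n_chrom, chrom_length = chrom_length,
         context_probs = context_probs, level_shapes = level_shapes,
         switch_spec = switch_spec, jitter_sd = jitter_sd,
         preset = as_cutoff_preset(preset), cell_types = cell_types,
         feature_probs = feature_probs),
    class = "sim_config"
  )
}

#' Generate a ground-truth modification landscape
#'
#' Draws per-site true levels of 5mC, 5hmC and 5fC/5caC for the two cell
#' classes of a [sim_config()], plants the configured switching events, and
#' records the resulting per-mark directions and pairwise quadrant labels.
#' The planted labels are exactly the labels the quadrant rule of the
#' config's cutoff preset assigns to the true level deltas, so any classifier
#' run on noiseless data must reproduce them.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seed and config give identical output.
#' @return An object of class `mark_truth`: a list with tibbles `sites`
#'   (site_id, chrom, pos, strand, context, feature, planted, switch_class),
#'   `levels` (site_id, cell_type, mark, level), `directions` (site_id, mark,
#'   delta, direction), `pair_labels` (site_id, pair, label), plus the config.
#' @examples
#' spec <- tibble::tibble(fraction = 0.1, d_5mC = -0.4, d_5hmC = -0.1,
#'                        d_5fC_5caC = 0)
#' truth <- generate_truth(sim_config(n_sites = 500, switch_spec = spec),
#'                         seed = 1)
#' dplyr::count(truth$pair_labels, pair, label)
#' @export
generate_truth <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- config$n_sites
    if (n < 1) abort("`n_sites` must be positive.")
    chroms <- paste0("chrS", seq_len(config$n_chrom))
    chrom <- sample(chroms, n, replace = TRUE)
    pos <- integer(n)
    for (cc in chroms) {
      idx <- which(chrom == cc)
      pos[idx] <- sort(sample.int(config$chrom_length - 2L, length(idx)))
    }
    sites <- tibble(
      site_id = sprintf("s%06d", seq_len(n)),
      chrom = chrom, pos = pos,
      strand = sample(c("+", "-"), n, replace = TRUE),
      context = sample(names(config$context_probs), n, replace = TRUE,
                       prob = config$context_probs),
      feature = sample(names(config$feature_probs), n, replace = TRUE,
                       prob = config$feature_probs)
    ) %>% arrange(.data$chrom, .data$pos)
    sites$site_id <- sprintf("s%06d", seq_len(n))

    # Reference-class levels, rescaled into the simplex when they overflow.
    A <- sapply(.marks, function(mk) {
      sh <- config$level_shapes[[mk]]
      rbeta(n, sh[1], sh[2])
    })
    over <- rowSums(A) > 0.995
    A[over, ] <- A[over, ] * 0.995 / rowSums(A[over, , drop = FALSE])

    # Plant switches: draw feasible reference levels so that level + delta
    # stays inside [0.001, 0.999] per mark and the simplex for both classes.
    spec <- config$switch_spec
    planted_class <- rep(NA_integer_, n)
    n_planted <- round(spec$fraction * n)
    avail <- seq_len(n)
    margin <- 0.02
    B <- A
    for (i in seq_along(n_planted)) {
      if (n_planted[i] == 0) next
      if (n_planted[i] > length(avail)) abort("Switch fractions exceed site count.")
      take <- sample(avail, n_planted[i])
      avail <- setdiff(avail, take)
      planted_class[take] <- i
      d <- c("5mC" = spec$d_5mC[i], "5hmC" = spec$d_5hmC[i],
             "5fC_5caC" = spec$d_5fC_5caC[i])
      for (s in take) {
        ok <- FALSE
        for (try in 1:200) {
          a <- A[s, ]
          for (mk in .marks) {
            if (d[mk] < 0) {
              lo <- -d[mk] + margin
              a[mk] <- runif(1, lo, min(0.97, lo + 0.35))
            } else if (d[mk] > 0) {
              hi <- 1 - d[mk] - margin
              a[mk] <- runif(1, min(0.005, hi), min(0.35, hi))
            } else {
              sh <- config$level_shapes[[mk]]
              a[mk] <- rbeta(1, sh[1], sh[2])
            }
          }
          if (sum(a) <= 0.98 && sum(a + d) <= 0.98 && all(a + d >= 0.001)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) abort("Could not satisfy switch deltas within the level simplex.")
        A[s, ] <- a
        B[s, ] <- a + d
      }
    }

    # Non-switching sites drift by truncated noise strictly below the cutoffs.
    cuts <- config$preset$delta_site[.marks]
    free <- which(is.na(planted_class))
    for (mk in .marks) {
      eps <- rnorm(length(free), 0, config$jitter_sd)
      lim <- 0.8 * cuts[mk]
      eps <- pmin(pmax(eps, -lim), lim)
      B[free, mk] <- pmin(pmax(A[free, mk] + eps, 0), 1)
    }
    overB <- free[rowSums(B[free, , drop = FALSE]) > 1]
    B[overB, ] <- A[overB, ]  # degenerate overflow: no drift

    levels <- bind_rows(
      tibble(site_id = rep(sites$site_id, 3),
             cell_type = config$cell_types[1],
             mark = rep(.marks, each = n), level = as.vector(A)),
      tibble(site_id = rep(sites$site_id, 3),
             cell_type = config$cell_types[2],
             mark = rep(.marks, each = n), level = as.vector(B))
    )

    delta_mat <- B - A
    dir_mat <- vapply(.marks, function(mk) {
      delta_direction(delta_mat[, mk], cuts[mk])
    }, character(n))
    directions <- tibble(
      site_id = rep(sites$site_id, 3),
      mark = rep(.marks, each = n),
      delta = as.vector(delta_mat),
      direction = as.vector(dir_mat)
    )
    dirw <- pivot_wider(directions, id_cols = "site_id", names_from = "mark",
                        values_from = "direction")
    pair_labels <- bind_rows(
      tibble(site_id = dirw$site_id, pair = "5mC-5hmC",
             label = paste(dirw$`5mC`, dirw$`5hmC`, sep = "/")),
      tibble(site_id = dirw$site_id, pair = "5hmC-5fC_5caC",
             label = paste(dirw$`5hmC`, dirw$`5fC_5caC`, sep = "/")),
      tibble(site_id = dirw$site_id, pair = "5mC-5fC_5caC",
             label = paste(dirw$`5mC`, dirw$`5fC_5caC`, sep = "/"))
    )

    sites$planted <- !is.na(planted_class)
    sites$switch_class <- planted_class
    structure(
      list(sites = sites, levels = levels, directions = directions,
           pair_labels = pair_labels, cell_types = config$cell_types,
           config = config, seed = seed),
      class = "mark_truth"
    )
  })
}

#' @export
print.mark_truth <- function(x, ...) {
  cat("<mark_truth> ", nrow(x$sites), " sites, cell types ",
      paste(x$cell_types, collapse = " vs "), ", ",
      sum(x$sites$planted), " planted switching sites\n", sep = "")
  invisible(x)
}

#' Assay chemistry configuration
#'
#' Describes one bisulfite chemistry and its coverage model for
#' [simulate_assay_counts()].  Efficiencies default to the values measured by
#' the calibration spike-ins this workflow assumes: Tet1 oxidation 97.04\%,
#' 5hmC protection ~100\%, M.SssI methylation 96.20\%.  The bisulfite
#' conversion efficiency defaults to 1 because those spike-in efficiencies
#' are end-to-end read-level measurements that already absorb conversion
#' error.  Coverage is negative binomial (overdispersed, as in
#' reduced-representation libraries); set `coverage_dispersion = Inf` for
#' Poisson.
#'
#' @param assay `"BS"`, `"TAB"` or `"MAB"`.
#' @param bisulfite_conversion_eff Probability an unprotected cytosine
#'   converts to T.
#' @param tet1_oxidation_eff TAB: probability Tet1 oxidizes an unprotected
#'   5mC/5hmC so it reads T.
#' @param hmC_protection_eff TAB: probability a 5hmC is glucosyl-protected.
#' @param mssi_methylation_eff MAB: probability M.SssI methylates an
#'   unmodified CpG (its complement is the false-T failure rate).
#' @param coverage_mean,coverage_dispersion Negative-binomial mean and size.
#' @param seed Optional default seed for simulations using this config.
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(assay = c("BS", "TAB", "MAB"),
                         bisulfite_conversion_eff = 1,
                         tet1_oxidation_eff = 0.9704,
                         hmC_protection_eff = 1,
                         mssi_methylation_eff = 0.962,
                         coverage_mean = 50,
                         coverage_dispersion = 5,
                         seed = NULL) {
  assay <- arg_match(assay)
  check_fraction(bisulfite_conversion_eff, "bisulfite_conversion_eff")
  check_fraction(tet1_oxidation_eff, "tet1_oxidation_eff")
  check_fraction(hmC_protection_eff, "hmC_protection_eff")
  check_fraction(mssi_methylation_eff, "mssi_methylation_eff")
  if (coverage_mean <= 0) abort("`coverage_mean` must be positive.")
  structure(
    list(assay = assay,
         bisulfite_conversion_eff = bisulfite_conversion_eff,
         tet1_oxidation_eff = tet1_oxidation_eff,
         hmC_protection_eff = hmC_protection_eff,
         mssi_methylation_eff = mssi_methylation_eff,
         coverage_mean = coverage_mean,
         coverage_dispersion = coverage_dispersion,
         seed = seed),
    class = "assay_config"
  )
}

# Probability a read reports the assay's modified state, given true levels.
# m, h, f are the per-site true fractions of 5mC, 5hmC, 5fC/5caC.
assay_read_prob <- function(m, h, f, cfg) {
  bc <- cfg$bisulfite_conversion_eff
  u <- pmax(1 - m - h - f, 0)
  switch(
    cfg$assay,
    # BS: 5mC and 5hmC resist conversion and read C; unmodified and 5fC/5caC
    # convert (with efficiency bc).
    BS = m + h + (u + f) * (1 - bc),
    # TAB: protected 5hmC reads C; unprotected 5hmC and 5mC read C only when
    # Tet1 oxidation fails; everything else converts.
    TAB = {
      ox <- cfg$tet1_oxidation_eff
      prot <- cfg$hmC_protection_eff
      h * (prot + (1 - prot) * (1 - ox)) + m * (1 - ox) + (u + f) * (1 - bc)
    },
    # MAB: modified state is T; true 5fC/5caC converts, and unmodified sites
    # leak to T when M.SssI methylation fails.
    MAB = {
      me <- cfg$mssi_methylation_eff
      bc * (f + u * (1 - me))
    }
  )
}

#' Simulate per-site assay counts from a truth set
#'
#' Draws site coverage from the config's count distribution, then draws the
#' modified-state read count from a binomial whose success probability
#' composes the site's true mark levels with the assay chemistry: BS reports
#' 5mC+5hmC as unconverted C, TAB reports protected 5hmC as C with
#' oxidation/protection-failure leakage, MAB reports 5fC/5caC as T with
#' false-T leakage at the M.SssI failure rate.
#'
#' @param truth A [generate_truth()] result.
#' @param cell_type One of the truth set's cell types.
#' @param assay_cfg An [assay_config()].
#' @param sample_name Sample label stored in the output; default the cell type.
#' @param level_jitter_sd Optional per-line biological drift: Gaussian noise
#'   of this SD added to the true levels (then clipped to [0,1]) before read
#'   sampling, emulating line-to-line variation within a cell class.
#' @param seed Seed; defaults to the config's seed.
#' @return A tibble with columns chrom, pos, strand, context, sample, assay,
#'   count_modified, count_total.
#' @examples
#' truth <- generate_truth(sim_config(n_sites = 100), seed = 1)
#' simulate_assay_counts(truth, "NSC", assay_config("BS", seed = 2))
#' @export
simulate_assay_counts <- function(truth, cell_type, assay_cfg,
                                  sample_name = cell_type,
                                  level_jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(truth, "mark_truth"), inherits(assay_cfg, "assay_config"))
  if (!cell_type %in% truth$cell_types) {
    abort(paste0("Unknown cell type `", cell_type, "`; truth has: ",
                 paste(truth$cell_types, collapse = ", ")))
  }
  if (nrow(truth$sites) == 0) abort("Truth set has no sites.")
  seed <- seed %||% assay_cfg$seed
  with_seed(seed, {
    lv <- truth$levels %>%
      filter(.data$cell_type == !!cell_type) %>%
      pivot_wider(id_cols = "site_id", names_from = "mark",
                  values_from = "level")
    lv <- lv[match(truth$sites$site_id, lv$site_id), ]
    m <- lv$`5mC`; h <- lv$`5hmC`; f <- lv$`5fC_5caC`
    if (level_jitter_sd > 0) {
      jitter1 <- function(x) pmin(pmax(x + rnorm(length(x), 0, level_jitter_sd), 0), 1)
      m <- jitter1(m); h <- jitter1(h); f <- jitter1(f)
      s <- m + h + f
      over <- s > 1
      m[over] <- m[over] / s[over]; h[over] <- h[over] / s[over]
      f[over] <- f[over] / s[over]
    }
    p <- pmin(pmax(assay_read_prob(m, h, f, assay_cfg), 0), 1)
    ns <- nrow(truth$sites)
    n <- if (is.infinite(assay_cfg$coverage_dispersion)) {
      rpois(ns, assay_cfg$coverage_mean)
    } else {
      rnbinom(ns, size = assay_cfg$coverage_dispersion,
              mu = assay_cfg$coverage_mean)
    }
    k <- rbinom(ns, n, p)
    tibble(
      chrom = truth$sites$chrom, pos = truth$sites$pos,
      strand = truth$sites$strand, context = truth$sites$context,
      sample = sample_name, assay = assay_cfg$assay,
      count_modified = k, count_total = n
    )
  })
}

#' Simulate spike-in control counts
#'
#' Generates read observations for control molecules of known modification
#' state under one assay chemistry: fully unmodified lambda phage DNA, a
#' fully 5mC control, and a fully 5hmC control.  `n_obs` total reads per
#' control are spread over `n_sites` positions.  Counts use the package
#' convention that `count_modified` is the assay's modified state (C reads
#' for BS/TAB, T reads for MAB).
#'
#' @param assay_cfg An [assay_config()].
#' @param n_obs Total read observations per control.
#' @param control_kinds Controls to simulate.
#' @param n_sites Spike-in positions per control.
#' @param seed Seed; defaults to the config's seed.
#' @return A tibble with columns control_kind, chrom, pos, assay,
#'   count_modified, count_total.
#' @examples
#' spike <- simulate_spikein_counts(assay_config("MAB", seed = 1),
#'                                  n_obs = 20000)
#' estimate_efficiency(spike, "lambda_unmethylated")
#' @export
simulate_spikein_counts <- function(assay_cfg, n_obs = 200000,
                                    control_kinds = c("lambda_unmethylated",
                                                      "5mC_control",
                                                      "5hmC_control"),
                                    n_sites = 200, seed = NULL) {
  stopifnot(inherits(assay_cfg, "assay_config"))
  seed <- seed %||% assay_cfg$seed
  bc <- assay_cfg$bisulfite_conversion_eff
  ox <- assay_cfg$tet1_oxidation_eff
  prot <- assay_cfg$hmC_protection_eff
  me <- assay_cfg$mssi_methylation_eff
  p_mod <- function(kind) {
    switch(
      assay_cfg$assay,
      BS = switch(kind, lambda_unmethylated = 1 - bc, `5mC_control` = 1,
                  `5hmC_control` = 1),
      TAB = switch(kind, lambda_unmethylated = 1 - bc,
                   `5mC_control` = 1 - ox,
                   `5hmC_control` = prot + (1 - prot) * (1 - ox)),
      MAB = switch(kind, lambda_unmethylated = bc * (1 - me),
                   `5mC_control` = 0, `5hmC_control` = 0)
    )
  }
  chrom_of <- c(lambda_unmethylated = "lambda",
                `5mC_control` = "ctrl_5mC", `5hmC_control` = "ctrl_5hmC")
  with_seed(seed, {
    purrr::map(control_kinds, function(kind) {
      n <- as.vector(stats::rmultinom(1, n_obs, rep(1 / n_sites, n_sites)))
      k <- rbinom(n_sites, n, p_mod(kind))
      tibble(control_kind = kind, chrom = unname(chrom_of[kind]),
             pos = seq_len(n_sites) - 1L, assay = assay_cfg$assay,
             count_modified = k, count_total = n)
    }) %>% list_rbind()
  })
}

#' Simulate one assay run: genomic sites plus spike-in controls
#'
#' Convenience wrapper combining [simulate_assay_counts()] and
#' [simulate_spikein_counts()].
#'
#' @inheritParams simulate_assay_counts
#' @param spikein_obs Total spike-in observations per control.
#' @param seed Seed; the site and spike-in draws use `seed` and `seed + 1`.
#' @return A list with tibbles `sites` and `spikein`.
#' @export
simulate_assay_run <- function(truth, cell_type, assay_cfg,
                               sample_name = cell_type, spikein_obs = 200000,
                               level_jitter_sd = 0, seed = NULL) {
  seed <- seed %||% assay_cfg$seed
  list(
    sites = simulate_assay_counts(truth, cell_type, assay_cfg,
                                  sample_name = sample_name,
                                  level_jitter_sd = level_jitter_sd,
                                  seed = seed),
    spikein = simulate_spikein_counts(assay_cfg, n_obs = spikein_obs,
                                      seed = if (is.null(seed)) NULL else seed + 1L)
  )
}

#' Simulate a multi-line cohort across assays
#'
#' Generates count tables for several cell lines per cell class and one or
#' more assay chemistries, with per-line biological drift on the true levels.
#'
#' @param truth A [generate_truth()] result.
#' @param n_lines Named integer vector: lines per cell type,
#'   e.g. `c(NSC = 3, GSC = 12)`.
#' @param assay_cfgs List of [assay_config()] objects (one per chemistry).
#' @param level_jitter_sd Per-line drift SD passed to
#'   [simulate_assay_counts()].
#' @param seed Base seed; each line-assay draw uses an offset of it.
#' @return One long tibble of counts with `sample`, `cell_type`, `assay`
#'   columns.
#' @export
simulate_cohort <- function(truth, n_lines = c(NSC = 3, GSC = 12),
                            assay_cfgs = list(assay_config("BS"),
                                              assay_config("TAB"),
                                              assay_config("MAB")),
                            level_jitter_sd = 0.02, seed = 1) {
  stopifnot(inherits(truth, "mark_truth"))
  if (is.null(names(n_lines)) || !all(names(n_lines) %in% truth$cell_types)) {
    abort("`n_lines` must be named by the truth set's cell types.")
  }
  lines <- purrr::imap(n_lines, function(k, ct) {
    tibble(cell_type = ct, sample = paste0(ct, seq_len(k)))
  }) %>% list_rbind()
  out <- vector("list", nrow(lines) * length(assay_cfgs))
  idx <- 1L
  for (i in seq_len(nrow(lines))) {
    for (j in seq_along(assay_cfgs)) {
      out[[idx]] <- simulate_assay_counts(
        truth, lines$cell_type[i], assay_cfgs[[j]],
        sample_name = lines$sample[i],
        level_jitter_sd = level_jitter_sd,
        seed = seed + 1000L * i + j
      ) %>% mutate(cell_type = lines$cell_type[i])
      idx <- idx + 1L
    }
  }
  list_rbind(out)
}
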