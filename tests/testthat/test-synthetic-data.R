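both_loss_spec <- tibble::tibble(fraction = 0.1, d_5mC = -0.4,
                                 d_5hmC = -0.1, d_5fC_5caC = 0)

test_that("generators are deterministic given seed and config", {
  cfg <- sim_config(n_sites = 300, switch_spec = both_loss_spec)
  t1 <- generate_truth(cfg, seed = 5)
  t2 <- generate_truth(cfg, seed = 5)
  expect_identical(t1$sites, t2$sites)
  expect_identical(t1$levels, t2$levels)
  expect_identical(t1$pair_labels, t2$pair_labels)
  expect_false(identical(t1$levels, generate_truth(cfg, seed = 6)$levels))

  acfg <- assay_config("BS")
  expect_identical(simulate_assay_counts(t1, "GSC", acfg, seed = 9),
                   simulate_assay_counts(t1, "GSC", acfg, seed = 9))
  expect_identical(simulate_spikein_counts(acfg, n_obs = 2000, seed = 9),
                   simulate_spikein_counts(acfg, n_obs = 2000, seed = 9))

  lcfg <- landscape_config(peaks_per_tissue = 30)
  expect_identical(generate_regulatory_landscape(lcfg, seed = 3)$peaks,
                   generate_regulatory_landscape(lcfg, seed = 3)$peaks)

  ecfg <- expression_config(n_genes = 50)
  expect_identical(generate_expression_survival(ecfg, seed = 3)$expr,
                   generate_expression_survival(ecfg, seed = 3)$expr)
})

test_that("true levels respect the cytosine-state simplex", {
  truth <- generate_truth(sim_config(n_sites = 500,
                                     switch_spec = both_loss_spec), seed = 2)
  expect_true(all(truth$levels$level >= 0 & truth$levels$level <= 1))
  sums <- truth$levels %>%
    dplyr::group_by(site_id, cell_type) %>%
    dplyr::summarise(s = sum(level), .groups = "drop")
  expect_true(all(sums$s <= 1 + 1e-12))
})

test_that("planted quadrant labels match labels re-derived by the classifier", {
  spec <- tibble::tibble(
    fraction = c(0.1, 0.05),
    d_5mC = c(-0.4, -0.35), d_5hmC = c(-0.1, 0), d_5fC_5caC = c(0, 0.08)
  )
  truth <- generate_truth(sim_config(n_sites = 600, switch_spec = spec),
                          seed = 4)
  # Re-derive the 5mC/5hmC pair labels by running classify_switch_pairs on
  # the true (noiseless) deltas.
  wide <- truth$levels %>%
    tidyr::pivot_wider(names_from = "cell_type", values_from = "level")
  keyed <- dplyr::left_join(wide, truth$sites, by = "site_id")
  mk_delta <- function(mk) {
    keyed %>%
      dplyr::filter(mark == mk) %>%
      dplyr::transmute(chrom, pos, strand, site_id, mark = mk,
                       m_a = NSC, m_b = GSC, delta = GSC - NSC,
                       direction = dplyr::case_when(
                         delta > cutoff_preset("default")$delta_site[mk] ~ "+",
                         delta < -cutoff_preset("default")$delta_site[mk] ~ "-",
                         TRUE ~ "0"
                       ))
  }
  quads <- classify_switch_pairs(mk_delta("5mC"), mk_delta("5hmC"))
  rederived <- quads$sites %>%
    dplyr::left_join(dplyr::select(mk_delta("5mC"), chrom, pos, strand,
                                   site_id),
                     by = c("chrom", "pos", "strand"))
  planted <- truth$pair_labels %>% dplyr::filter(pair == "5mC-5hmC")
  cmp <- dplyr::inner_join(
    dplyr::select(rederived, site_id, quadrant),
    planted, by = "site_id"
  )
  expect_equal(nrow(cmp), 600)
  expect_equal(cmp$quadrant, cmp$label)
  # The first planted class is exactly the both-loss quadrant.
  class1 <- truth$sites$site_id[which(truth$sites$switch_class == 1)]
  expect_setequal(
    cmp$site_id[cmp$label == "-/-"],
    class1
  )
  expect_equal(length(class1), 60)
})

test_that("a config with no planted switches yields only no-change labels", {
  truth <- generate_truth(sim_config(n_sites = 200), seed = 3)
  expect_true(all(truth$pair_labels$label == "0/0"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(switch_spec = tibble::tibble(
    fraction = 1.4, d_5mC = 0.3, d_5hmC = 0, d_5fC_5caC = 0
  )), "fraction")
  expect_error(sim_config(context_probs = c(CpG = -0.1, CpA = 1.1)), "0, 1")
  truth <- generate_truth(sim_config(n_sites = 50), seed = 1)
  expect_error(simulate_assay_counts(truth, "HELA", assay_config("BS")),
               "Unknown cell type")
})

test_that("MAB with a perfect enzyme and no true 5fC/5caC never reads T", {
  cfg <- sim_config(n_sites = 300,
                    level_shapes = list("5mC" = c(2, 2), "5hmC" = c(1, 10),
                                        "5fC_5caC" = c(1, 1)))
  truth <- generate_truth(cfg, seed = 8)
  # Force true 5fC/5caC to zero everywhere.
  truth$levels$level[truth$levels$mark == "5fC_5caC"] <- 0
  mab <- assay_config("MAB", mssi_methylation_eff = 1)
  counts <- simulate_assay_counts(truth, "NSC", mab, seed = 2)
  expect_true(all(counts$count_modified == 0))
})

test_that("with perfect chemistry observed ratios converge to the composite truth", {
  truth <- generate_truth(sim_config(n_sites = 150), seed = 10)
  wide <- truth$levels %>%
    dplyr::filter(cell_type == "NSC") %>%
    tidyr::pivot_wider(names_from = "mark", values_from = "level") %>%
    dplyr::left_join(truth$sites, by = "site_id") %>%
    dplyr::arrange(chrom, pos)
  perfect <- function(assay) {
    assay_config(assay, tet1_oxidation_eff = 1, hmC_protection_eff = 1,
                 mssi_methylation_eff = 1, coverage_mean = 5000,
                 coverage_dispersion = Inf)
  }
  bs <- simulate_assay_counts(truth, "NSC", perfect("BS"), seed = 3)
  tab <- simulate_assay_counts(truth, "NSC", perfect("TAB"), seed = 4)
  mab <- simulate_assay_counts(truth, "NSC", perfect("MAB"), seed = 5)
  expect_lt(max(abs(bs$count_modified / bs$count_total -
                      (wide$`5mC` + wide$`5hmC`))), 0.03)
  expect_lt(max(abs(tab$count_modified / tab$count_total - wide$`5hmC`)),
            0.03)
  expect_lt(max(abs(mab$count_modified / mab$count_total -
                      wide$`5fC_5caC`)), 0.03)
})

test_that("spike-ins reproduce the configured chemistry efficiencies", {
  lam <- simulate_spikein_counts(assay_config("MAB"), n_obs = 50000,
                                 control_kinds = "lambda_unmethylated",
                                 seed = 21)
  frac_C <- 1 - sum(lam$count_modified) / sum(lam$count_total)
  expect_equal(frac_C, 0.962, tolerance = 0.01)

  tab5mc <- simulate_spikein_counts(assay_config("TAB"), n_obs = 50000,
                                    control_kinds = "5mC_control", seed = 22)
  frac_T <- 1 - sum(tab5mc$count_modified) / sum(tab5mc$count_total)
  expect_equal(frac_T, 0.9704, tolerance = 0.01)

  # Full protection: the 5hmC control reads all C under TAB.
  tab5hmc <- simulate_spikein_counts(assay_config("TAB"), n_obs = 5000,
                                     control_kinds = "5hmC_control",
                                     seed = 23)
  expect_equal(sum(tab5hmc$count_modified), sum(tab5hmc$count_total))
})

test_that("landscape planting matches downstream stratification", {
  # shared_fraction 0: every peak is tissue-specific.
  land0 <- generate_regulatory_landscape(
    landscape_config(peaks_per_tissue = 40, shared_fraction = 0), seed = 6)
  lab0 <- stratify_tissue_specific(land0$peaks, "brain")
  expect_true(all(lab0$label == "specific"))

  # Identical peak files in two tissues: nothing is specific.
  land1 <- generate_regulatory_landscape(
    landscape_config(tissues = c("a", "b"), peaks_per_tissue = 30,
                     shared_fraction = 1), seed = 7)
  lab1 <- stratify_tissue_specific(land1$peaks, "a")
  expect_true(all(lab1$label == "shared"))

  # Planted labels agree with the stratifier at the default threshold.
  land <- generate_regulatory_landscape(
    landscape_config(peaks_per_tissue = 50, shared_fraction = 0.3), seed = 8)
  lab <- stratify_tissue_specific(land$peaks, "brain")
  expect_equal(lab$label == "specific", lab$planted == "specific")

  # Unsatisfiable density errors out.
  expect_error(
    generate_regulatory_landscape(
      landscape_config(peaks_per_tissue = 10000, chrom_length = 1e5,
                       n_chrom = 1), seed = 1),
    "unsatisfiable"
  )
})

test_that("planted co-expression hits the target correlation", {
  # Exact affine copies at target_r = 1.
  exact <- generate_expression_survival(
    expression_config(n_genes = 30, n_coexpr_pos = 5, n_coexpr_neg = 0,
                      target_r = 1), seed = 2)
  driver <- as.numeric(exact$expr[exact$expr$gene == "TET2", -1])
  for (g in exact$truth$coexpr_pos) {
    y <- as.numeric(exact$expr[exact$expr$gene == g, -1])
    expect_equal(cor(driver, y), 1, tolerance = 1e-12)
  }

  # Mean recovered correlation near the target at large n.
  rs <- vapply(1:100, function(i) {
    xs <- generate_expression_survival(
      expression_config(n_samples = 150, n_genes = 12, n_coexpr_pos = 3,
                        n_coexpr_neg = 0, target_r = 0.8), seed = 300 + i)
    drv <- as.numeric(xs$expr[xs$expr$gene == "TET2", -1])
    mean(vapply(xs$truth$coexpr_pos, function(g) {
      cor(drv, as.numeric(xs$expr[xs$expr$gene == g, -1]))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(mean(rs), 0.8, tolerance = 0.05)

  expect_error(expression_config(n_samples = 2), "at least 3")
})

test_that("a null survival gene is flagged at about the nominal rate", {
  flags <- vapply(1:150, function(i) {
    xs <- generate_expression_survival(
      expression_config(n_samples = 3, n_genes = 2, n_coexpr_pos = 0,
                        n_coexpr_neg = 0, n_patients = 60, hazard_ratio = 2,
                        n_null_patient_genes = 1), seed = 5000 + i)
    nulls <- xs$patient_expr[xs$patient_expr$gene == "NULL01", ]
    e <- tibble::tibble(sample = names(nulls)[-1],
                        expr = as.numeric(nulls[1, -1]))
    logrank_median_split(e, xs$survival)$p_value < 0.05
  }, logical(1))
  # Monte-Carlo check of the type-I rate (0.05 nominal, 150 replicates).
  expect_lte(mean(flags), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 150))
})
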