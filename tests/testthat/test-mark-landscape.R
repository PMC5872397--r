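make_delta <- function(pos, delta, mark, cutoff) {
  tibble::tibble(
    chrom = "chrS1", pos = pos, strand = "+", mark = mark, delta = delta,
    direction = dplyr::case_when(delta > cutoff ~ "+",
                                 delta < -cutoff ~ "-", TRUE ~ "0")
  )
}

test_that("tier boundaries follow the high/low cutoffs with boundaries medium", {
  tbl <- tibble::tibble(
    sample = "NSC1",
    mark = c("5mC", "5mC", "5hmC", "5fC_5caC", "5fC_5caC"),
    m = c(0.65, 0.2, 0.05, 0.09, 0.21)
  )
  tiers <- tier_sites(tbl)$tier
  expect_equal(tiers, c("high", "medium", "medium", "low", "high"))
})

test_that("tier proportions sum to one within each sample-mark stratum", {
  withr::with_seed(3, {
    tbl <- tibble::tibble(
      sample = rep(c("a", "b"), each = 60),
      mark = rep(c("5mC", "5hmC", "5fC_5caC"), 40),
      m = runif(120)
    )
    props <- tier_proportions(tier_sites(tbl))
    sums <- props %>%
      dplyr::group_by(sample, mark) %>%
      dplyr::summarise(s = sum(proportion), .groups = "drop")
    expect_equal(sums$s, rep(1, nrow(sums)))
  })
})

test_that("differential calls apply the per-mark site cutoffs", {
  a <- tibble::tibble(chrom = "chrS1", pos = 1:2, strand = "+", mark = "5mC",
                      m = c(0.50, 0.50))
  b <- tibble::tibble(chrom = "chrS1", pos = 1:2, strand = "+", mark = "5mC",
                      m = c(0.25, 0.45))
  d <- differential_sites(a, b)
  expect_equal(d$delta, c(-0.25, -0.05))
  expect_equal(d$direction, c("-", "0"))

  h_a <- dplyr::mutate(a, mark = "5hmC", m = c(0.10, 0.10))
  h_b <- dplyr::mutate(b, mark = "5hmC", m = c(0.14, 0.16))
  dh <- differential_sites(h_a, h_b)
  expect_equal(dh$direction, c("0", "+"))  # 0.04 below, 0.06 above 0.05

  expect_true(all(differential_sites(a, a)$direction == "0"))
})

test_that("group levels average per-sample ratios, with pooled counts optional", {
  a <- tibble::tibble(chrom = "chrS1", pos = 1, strand = "+", mark = "5mC",
                      sample = c("s1", "s2"), k = c(1, 30), n = c(10, 40),
                      m = c(0.1, 0.75))
  b <- dplyr::mutate(a, m = c(0.9, 0.9), k = c(9, 36), n = c(10, 40))
  mean_mode <- differential_sites(a, b)
  expect_equal(mean_mode$m_a, mean(c(0.1, 0.75)))
  pooled <- differential_sites(a, b, method = "pooled")
  expect_equal(pooled$m_a, 31 / 50)
})

test_that("region aggregation is an unweighted site mean with a floor", {
  tbl <- tibble::tibble(
    chrom = "chrS1", pos = c(10, 20, 30, 200), strand = "+",
    sample = "s1", mark = "5mC", m = c(0.2, 0.4, 0.6, 0.9)
  )
  regions <- tibble::tibble(chrom = "chrS1", start = c(0, 100, 300),
                            end = c(50, 150, 400),
                            region_id = c("r1", "r2", "r3"))
  agg <- aggregate_regions(tbl, regions, min_sites = 1)
  expect_equal(agg$m[agg$region_id == "r1"], 0.4)
  expect_false("r2" %in% agg$region_id)  # zero covered sites: dropped
  expect_false("r3" %in% agg$region_id)
})

test_that("region aggregation matches a brute-force per-site re-aggregation", {
  withr::with_seed(9, {
    tbl <- tibble::tibble(
      chrom = "chrS1", pos = sort(sample.int(1000, 200)), strand = "+",
      sample = "s1", mark = "5mC", m = runif(200)
    )
    regions <- random_intervals(20, genome_len = 1000, max_width = 120) %>%
      dplyr::mutate(region_id = paste0("r", dplyr::row_number()))
    agg <- aggregate_regions(tbl, regions, min_sites = 1)
    for (i in seq_len(nrow(regions))) {
      inside <- tbl$m[tbl$pos >= regions$start[i] & tbl$pos < regions$end[i]]
      if (length(inside) == 0) {
        expect_false(regions$region_id[i] %in% agg$region_id)
      } else {
        expect_equal(agg$m[agg$region_id == regions$region_id[i]],
                     mean(inside))
      }
    }
  })
})

test_that("switch quadrants classify direction pairs under the strict preset", {
  cut5mc <- cutoff_preset("strict")$delta_site["5mC"]
  expect_equal(unname(cut5mc), 0.25)
  dx <- make_delta(1:3, c(-0.30, -0.30, 0), "5mC", cut5mc)
  dy <- make_delta(1:3, c(-0.10, 0.06, 0), "5fC_5caC", 0.05)
  q <- classify_switch_pairs(dx, dy)
  expect_equal(q$sites$quadrant, c("-/-", "-/+", "0/0"))
  expect_equal(sum(q$counts$n), q$n_shared)
  expect_equal(nrow(q$counts), 9)

  # All-zero deltas land every site in the centre cell.
  d0x <- make_delta(1:4, rep(0, 4), "5mC", 0.25)
  d0y <- make_delta(1:4, rep(0, 4), "5hmC", 0.05)
  q0 <- classify_switch_pairs(d0x, d0y)
  expect_equal(q0$counts$n[q0$counts$quadrant == "0/0"], 4L)

  expect_error(classify_switch_pairs(dx, make_delta(2:4, c(0, 0, 0),
                                                    "5hmC", 0.05)),
               "universes")
})

test_that("quadrant counts always sum to the shared-site count", {
  withr::with_seed(12, {
    for (i in 1:5) {
      n <- sample(50:200, 1)
      dx <- make_delta(1:n, runif(n, -0.5, 0.5), "5mC", 0.25)
      dy <- make_delta(1:n, runif(n, -0.2, 0.2), "5hmC", 0.05)
      q <- classify_switch_pairs(dx, dy)
      expect_equal(sum(q$counts$n), n)
    }
  })
})

test_that("swapping groups negates deltas and transposes the quadrant matrix", {
  withr::with_seed(13, {
    n <- 120
    a <- tibble::tibble(chrom = "chrS1", pos = 1:n, strand = "+",
                        mark = "5mC", m = runif(n))
    b <- dplyr::mutate(a, m = pmin(pmax(m + runif(n, -0.5, 0.5), 0), 1))
    ah <- dplyr::mutate(a, mark = "5hmC", m = runif(n, 0, 0.3))
    bh <- dplyr::mutate(ah, m = pmin(pmax(m + runif(n, -0.15, 0.15), 0), 1))
    fwd <- classify_switch_pairs(differential_sites(a, b, "strict"),
                                 differential_sites(ah, bh, "strict"))
    rev <- classify_switch_pairs(differential_sites(b, a, "strict"),
                                 differential_sites(bh, ah, "strict"))
    expect_equal(differential_sites(a, b, "strict")$delta,
                 -differential_sites(b, a, "strict")$delta)
    flip <- c("-" = "+", "0" = "0", "+" = "-")
    fwd_counts <- fwd$counts %>%
      dplyr::mutate(dir_x = flip[as.character(dir_x)],
                    dir_y = flip[as.character(dir_y)]) %>%
      dplyr::arrange(dir_x, dir_y)
    rev_counts <- dplyr::arrange(rev$counts, as.character(dir_x),
                                 as.character(dir_y))
    expect_equal(fwd_counts$n,
                 rev_counts$n[match(paste(fwd_counts$dir_x, fwd_counts$dir_y),
                                    paste(rev_counts$dir_x, rev_counts$dir_y))])
  })
})

test_that("three-mark switch codes concatenate directions and count correctly", {
  dm <- make_delta(1:3, c(-0.3, 0, 0.3), "5mC", 0.2)
  dh <- make_delta(1:3, c(0, 0, 0.06), "5hmC", 0.05)
  df <- make_delta(1:3, c(0.06, 0, 0), "5fC_5caC", 0.05)
  codes <- switch_codes(dm, dh, df)
  expect_equal(codes$code[1], "5mC-/5hmC0/5fC5caC+")
  expect_equal(codes$code[2], "5mC0/5hmC0/5fC5caC0")
  freq <- code_frequencies(codes)
  expect_equal(sum(freq$n), 3)
  # Counting oracle: plain table() on the pasted directions.
  oracle <- table(paste0("5mC", dm$direction, "/5hmC", dh$direction,
                         "/5fC5caC", df$direction))
  expect_equal(sort(freq$n), sort(unname(as.integer(oracle))))
})

test_that("feature enrichment is a ratio of proportions with guards", {
  # Events distributed exactly like the universe: enrichment 1 everywhere.
  universe <- tibble::tibble(feature = rep(c("cgi", "shore", "open_sea"),
                                           times = c(20, 30, 50)))
  events <- tibble::tibble(
    feature = rep(c("cgi", "shore", "open_sea"), times = c(2, 3, 5)),
    direction = "+"
  )
  enr <- feature_enrichment(events, universe)
  expect_equal(enr$enrichment[enr$direction == "+"], rep(1, 3))
  # No hypo events: that direction is NA, not zero.
  expect_true(all(is.na(enr$enrichment[enr$direction == "-"])))

  # Direct ratio: 10 of 100 events in a feature with universe share 5%.
  u2 <- tibble::tibble(feature = rep(c("f", "other"), times = c(5, 95)))
  e2 <- tibble::tibble(feature = rep(c("f", "other"), times = c(10, 90)),
                       direction = "-")
  enr2 <- feature_enrichment(e2, u2)
  expect_equal(enr2$enrichment[enr2$feature == "f" & enr2$direction == "-"],
               2.0)
  expect_equal(
    enr2$signed_enrichment[enr2$feature == "f" & enr2$direction == "-"],
    -2.0)
})

test_that("feature enrichment agrees with the direct-count oracle and nulls to 1", {
  withr::with_seed(21, {
    feats <- c("promoter", "cgi", "gene_body", "open_sea")
    means <- numeric(30)
    for (rep_i in 1:30) {
      universe <- tibble::tibble(
        feature = sample(feats, 400, replace = TRUE, prob = c(1, 2, 3, 4)))
      idx <- sample.int(400, 80)
      events <- tibble::tibble(feature = universe$feature[idx],
                               direction = sample(c("+", "-"), 80,
                                                  replace = TRUE))
      enr <- feature_enrichment(events, universe)
      for (j in sample(nrow(enr), 4)) {
        expect_equal(
          enr$enrichment[j],
          bf_enrichment(events$feature, events$direction, universe$feature,
                        enr$feature[j], enr$direction[j])
        )
      }
      means[rep_i] <- mean(enr$enrichment, na.rm = TRUE)
    }
    # Resampling events from the universe: mean enrichment near 1.
    expect_equal(mean(means), 1, tolerance = 0.1)
  })
})

test_that("top-variable selection and the sample tree recover structure", {
  # Two identical samples merge first.
  tbl <- tibble::tibble(
    chrom = "chrS1", pos = rep(1:20, 3), strand = "+",
    sample = rep(c("a", "b", "c"), each = 20),
    m = c(seq(0, 1, length.out = 20), seq(0, 1, length.out = 20),
          runif(20))
  )
  wide <- select_top_variable(tbl, k = 20)
  tree <- build_epitree(wide)
  expect_equal(sort(tree$hclust$labels[-tree$hclust$merge[1, ]]),
               c("a", "b"))
  expect_match(tree$newick, "^\\(")

  expect_warning(select_top_variable(tbl, k = 100), "complete-case")

  # Planted two-class design: the 2-cut of the tree matches cell types.
  truth <- generate_truth(sim_config(
    n_sites = 300,
    switch_spec = tibble::tibble(fraction = 0.3, d_5mC = -0.4,
                                 d_5hmC = 0, d_5fC_5caC = 0)
  ), seed = 31)
  counts <- simulate_cohort(truth, n_lines = c(NSC = 3, GSC = 4),
                            assay_cfgs = list(assay_config("BS")),
                            level_jitter_sd = 0.02, seed = 32)
  scored <- score_sites(counts, "5mC", min_coverage = 10)
  top <- select_top_variable(scored, k = 150)
  grp <- tidy(build_epitree(top), k = 2)
  planted <- sub("[0-9]+$", "", grp$sample)
  expect_true(all(table(planted, grp$group) %in%
                    c(0, table(planted))))
})
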