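#' Classify sites into modification tiers
#'
#' Assigns each site to the `low` / `medium` / `high` tier by comparing its
#' level `m` with the per-mark tier cutoffs: `high` iff `m > tier_high`,
#' `low` iff `m < tier_low`, otherwise `medium` (values equal to a boundary
#' fall in `medium`).
#'
#' @param table Site mark table (from [score_sites()]) with `mark` and `m`.
#' @param preset Cutoff preset or preset name; see [cutoff_preset()].
#' @return The input tibble with a `tier` column.
#' @examples
#' tbl <- tibble::tibble(mark = "5mC", m = c(0.65, 0.4, 0.1),
#'                       sample = "NSC1")
#' tier_sites(tbl)
#' @seealso [tier_proportions()]
#' @export
tier_sites <- function(table, preset = "default") {
  preset <- as_cutoff_preset(preset)
  table <- as_tibble(table)
  if (!all(c("mark", "m") %in% names(table))) {
    abort("`table` must have `mark` and `m` columns (see score_sites()).")
  }
  mk <- normalize_mark(table$mark)
  hi <- preset$tier_high[mk]
  lo <- preset$tier_low[mk]
  mutate(table, tier = dplyr::case_when(
    .data$m > hi ~ "high",
    .data$m < lo ~ "low",
    TRUE ~ "medium"
  ))
}

#' Per-sample tier proportions
#'
#' Summarises a tiered site table into the proportion of low, medium and
#' highly modified sites per sample and mark.  Proportions sum to 1 within
#' each sample-mark stratum.
#'
#' @param tiered Output of [tier_sites()].
#' @return A tibble with sample, mark, tier, n, proportion.
#' @export
tier_proportions <- function(tiered) {
  tiered <- as_tibble(tiered)
  if (!"tier" %in% names(tiered)) abort("Run tier_sites() first.")
  keys <- intersect(c("sample", "mark"), names(tiered))
  tiered %>%
    mutate(tier = factor(.data$tier, levels = c("low", "medium", "high"))) %>%
    count(across(all_of(keys)), .data$tier, .drop = FALSE) %>%
    group_by(across(all_of(keys))) %>%
    mutate(proportion = .data$n / sum(.data$n)) %>%
    ungroup()
}

# Per-site group level: unweighted mean of per-sample ratios (default), or
# pooled counts sum(k)/sum(n).
group_site_levels <- function(table, method) {
  keys <- site_keys(table)
  extra <- intersect(c("context", "mark"), names(table))
  g <- group_by(as_tibble(table), across(all_of(c(keys, extra))))
  if (method == "mean") {
    summarise(g, m = mean(.data$m), n_samples = n(), .groups = "drop")
  } else {
    summarise(g, m = sum(.data$k) / sum(.data$n), n_samples = n(),
              .groups = "drop")
  }
}

#' Differential modification calls between two groups
#'
#' Computes the per-site group-level change `delta = m_B - m_A` for one mark
#' and classifies its direction against the preset's cutoff for the chosen
#' scope: `"+"` (gain) iff `delta > cutoff`, `"-"` (loss) iff
#' `delta < -cutoff`, else `"0"`.  Group levels are unweighted means of
#' per-sample ratios by default (`method = "pooled"` uses summed counts).
#' Sites absent from either group are excluded; their counts are attached as
#' attributes `n_only_a` / `n_only_b`.
#'
#' @param table_a,table_b Site mark tables for groups A (reference) and B,
#'   one mark each.
#' @param preset Cutoff preset or name.
#' @param scope `"site"` (single-site cutoffs) or `"region"` (region-average
#'   cutoffs, for tables produced by [aggregate_regions()]).
#' @param method `"mean"` or `"pooled"` group-level summary.
#' @return A tibble of delta calls: site keys, mark, m_a, m_b, delta,
#'   direction.
#' @examples
#' a <- tibble::tibble(chrom = "chrS1", pos = 1:2, strand = "+",
#'                     mark = "5mC", m = c(0.5, 0.5), k = c(5, 5), n = 10)
#' b <- dplyr::mutate(a, m = c(0.25, 0.48), k = round(m * n))
#' differential_sites(a, b)
#' @export
differential_sites <- function(table_a, table_b, preset = "default",
                               scope = c("site", "region"),
                               method = c("mean", "pooled")) {
  scope <- arg_match(scope)
  method <- arg_match(method)
  preset <- as_cutoff_preset(preset)
  a <- group_site_levels(table_a, method)
  b <- group_site_levels(table_b, method)
  mk <- unique(normalize_mark(c(a$mark, b$mark)))
  if (length(mk) != 1L) abort("Tables must contain a single common mark.")
  keys <- intersect(site_keys(a), site_keys(b))
  if (!length(keys)) abort("Tables share no site key columns.")
  shared <- inner_join(
    select(a, all_of(keys), any_of("context"), m_a = "m"),
    select(b, all_of(keys), m_b = "m"),
    by = keys
  )
  if (nrow(shared) == 0) abort("No shared sites between the two groups.")
  cutoff <- if (scope == "site") preset$delta_site[mk] else preset$delta_region[mk]
  out <- shared %>%
    mutate(mark = mk, delta = .data$m_b - .data$m_a,
           direction = delta_direction(.data$delta, cutoff))
  attr(out, "n_only_a") <- nrow(a) - nrow(shared)
  attr(out, "n_only_b") <- nrow(b) - nrow(shared)
  attr(out, "cutoff") <- unname(cutoff)
  out
}

#' Aggregate site levels over regions
#'
#' Computes the unweighted mean of site-level modification over each region
#' (0-based half-open intervals), per sample and mark.  Regions covered by
#' fewer than `min_sites` sites are dropped.
#'
#' @param table Site mark table with chrom/pos and `m`.
#' @param regions Interval tibble with chrom, start, end and a region
#'   identifier column (`region_id`, `gene_id` or `name`; one is created from
#'   coordinates if absent).
#' @param min_sites Minimum covered sites per region.  Default 1.
#' @return A tibble: region identifier, (sample, mark if present), mean `m`,
#'   `n_sites`.
#' @export
aggregate_regions <- function(table, regions, min_sites = 1) {
  table <- as_tibble(table)
  regions <- as_tibble(regions)
  id_col <- intersect(c("region_id", "gene_id", "name"), names(regions))[1]
  if (is.na(id_col)) {
    regions$region_id <- paste0(regions$chrom, ":", regions$start, "-",
                                regions$end)
    id_col <- "region_id"
  }
  gr_sites <- sites_to_granges(table, "table")
  gr_regions <- intervals_to_granges(regions, "regions")
  hits <- find_overlaps_q(gr_sites, gr_regions)
  if (length(hits) == 0) {
    return(tibble(!!id_col := character(), m = numeric(),
                  n_sites = integer()))
  }
  mapped <- table[S4Vectors::queryHits(hits), ]
  mapped[[id_col]] <- regions[[id_col]][S4Vectors::subjectHits(hits)]
  keys <- c(id_col, intersect(c("sample", "mark"), names(mapped)))
  mapped %>%
    group_by(across(all_of(keys))) %>%
    summarise(m = mean(.data$m), n_sites = n(), .groups = "drop") %>%
    filter(.data$n_sites >= min_sites)
}

#' Pairwise switching quadrants between two marks
#'
#' Joins two delta-call tables over the same site universe and assigns each
#' site to one of the nine quadrants formed by the direction pair, e.g.
#' `-/-` (joint loss), `-/+` (loss of the first mark with gain of the
#' second).  The 3x3 quadrant counts always sum to the number of shared
#' sites.
#'
#' @param delta_x,delta_y Delta-call tibbles from [differential_sites()] for
#'   the two marks, indexed by the same site universe.
#' @return An object of class `switch_quadrants`: list with `sites` (per-site
#'   labels), `counts` (complete 3x3 tibble with `n`), and the mark pair.
#' @examples
#' a <- tibble::tibble(chrom = "c", pos = 1:3, strand = "+",
#'                     mark = "5mC", direction = c("-", "0", "-"),
#'                     delta = c(-0.3, 0, -0.26))
#' b <- tibble::tibble(chrom = "c", pos = 1:3, strand = "+",
#'                     mark = "5hmC", direction = c("-", "0", "+"),
#'                     delta = c(-0.1, 0, 0.06))
#' classify_switch_pairs(a, b)$counts
#' @export
classify_switch_pairs <- function(delta_x, delta_y) {
  delta_x <- as_tibble(delta_x)
  delta_y <- as_tibble(delta_y)
  keys <- intersect(site_keys(delta_x), site_keys(delta_y))
  if (!length(keys)) abort("Delta tables share no site key columns.")
  kx <- do.call(paste, delta_x[keys])
  ky <- do.call(paste, delta_y[keys])
  if (!setequal(kx, ky)) {
    abort("Site universes differ between the two delta tables.")
  }
  mark_x <- if ("mark" %in% names(delta_x)) {
    unique(normalize_mark(delta_x$mark))
  } else {
    "x"
  }
  mark_y <- if ("mark" %in% names(delta_y)) {
    unique(normalize_mark(delta_y$mark))
  } else {
    "y"
  }
  joined <- inner_join(
    select(delta_x, all_of(keys), dir_x = "direction", delta_x = "delta"),
    select(delta_y, all_of(keys), dir_y = "direction", delta_y = "delta"),
    by = keys
  )
  dirs <- c("-", "0", "+")
  sites <- joined %>%
    mutate(dir_x = factor(.data$dir_x, levels = dirs),
           dir_y = factor(.data$dir_y, levels = dirs),
           quadrant = paste(.data$dir_x, .data$dir_y, sep = "/"))
  counts <- sites %>%
    count(.data$dir_x, .data$dir_y, .drop = FALSE) %>%
    mutate(quadrant = paste(.data$dir_x, .data$dir_y, sep = "/"))
  structure(
    list(sites = sites, counts = counts, marks = c(mark_x, mark_y),
         n_shared = nrow(sites)),
    class = "switch_quadrants"
  )
}

#' @export
print.switch_quadrants <- function(x, ...) {
  cat("<switch_quadrants> ", x$marks[1], " vs ", x$marks[2], ", ",
      x$n_shared, " shared sites\n", sep = "")
  m <- pivot_wider(x$counts, id_cols = "dir_x", names_from = "dir_y",
                   values_from = "n")
  print(as.data.frame(m))
  invisible(x)
}

#' @rdname classify_switch_pairs
#' @param x A `switch_quadrants` object.
#' @param ... Unused.
#' @method tidy switch_quadrants
#' @export
tidy.switch_quadrants <- function(x, ...) {
  mutate(x$counts, mark_x = x$marks[1], mark_y = x$marks[2])
}

#' @rdname classify_switch_pairs
#' @method glance switch_quadrants
#' @export
glance.switch_quadrants <- function(x, ...) {
  top <- x$counts %>%
    filter(.data$quadrant != "0/0") %>%
    arrange(dplyr::desc(.data$n)) %>%
    slice_head(n = 1)
  tibble(n_shared = x$n_shared,
         n_no_change = x$counts$n[x$counts$quadrant == "0/0"],
         top_switch_quadrant = top$quadrant, top_switch_n = top$n)
}

#' Three-mark switch codes
#'
#' Combines delta calls for 5mC, 5hmC and 5fC/5caC over a shared site
#' universe into one of the 27 switch codes, written
#' `5mC<d>/5hmC<d>/5fC5caC<d>` with `d` in `-`, `0`, `+` (e.g.
#' `5mC-/5hmC0/5fC5caC+` for loss of 5mC with gain of 5fC/5caC).
#'
#' @param delta_5mC,delta_5hmC,delta_5fC Delta-call tibbles from
#'   [differential_sites()].
#' @return A tibble with the site keys, per-mark directions and `code`.
#' @seealso [code_frequencies()]
#' @export
switch_codes <- function(delta_5mC, delta_5hmC, delta_5fC) {
  tabs <- list(delta_5mC, delta_5hmC, delta_5fC)
  keys <- Reduce(intersect, lapply(tabs, site_keys))
  if (!length(keys)) abort("Delta tables share no site key columns.")
  ks <- lapply(tabs, function(t) do.call(paste, as_tibble(t)[keys]))
  if (!setequal(ks[[1]], ks[[2]]) || !setequal(ks[[1]], ks[[3]])) {
    abort("Site universes differ across the three delta tables.")
  }
  out <- inner_join(
    select(as_tibble(delta_5mC), all_of(keys), dir_5mC = "direction"),
    select(as_tibble(delta_5hmC), all_of(keys), dir_5hmC = "direction"),
    by = keys
  ) %>%
    inner_join(select(as_tibble(delta_5fC), all_of(keys),
                      dir_5fC_5caC = "direction"),
               by = keys) %>%
    mutate(code = paste0("5mC", .data$dir_5mC, "/5hmC", .data$dir_5hmC,
                         "/5fC5caC", .data$dir_5fC_5caC))
  out
}

#' Switch-code frequency table
#'
#' @param codes Output of [switch_codes()].
#' @return A tibble of code counts; `sum(n)` equals the site count.
#' @export
code_frequencies <- function(codes) {
  count(as_tibble(codes), .data$code, sort = TRUE)
}

#' Feature enrichment of differential events
#'
#' Compares where differential events fall across genomic features against
#' the background of all covered sites:
#' `e(f, dir) = (events of dir in f / events of dir) / (universe sites in f /
#' universe sites)`, so `e = 1` means the events of that direction distribute
#' over feature `f` like the covered-site universe.  A `signed_enrichment`
#' column carries hyper (`+`) events positive and hypo (`-`) events negative
#' for plotting.  Features with no universe sites give `NA` (undefined), as
#' does a direction with zero events.
#'
#' @param events Tibble of differential sites with a `direction` column
#'   (`"+"`/`"-"`; `"0"` rows are ignored) and either a `feature` column or
#'   chrom/pos keys resolvable against `annotation`.
#' @param universe Tibble of all covered sites (same feature resolution).
#' @param annotation Optional interval tibble (chrom, start, end, feature)
#'   used to assign features to both `events` and `universe` when they lack a
#'   `feature` column; sites overlapping several feature intervals count in
#'   each.
#' @return A tibble: feature, direction, n_events, n_universe, enrichment,
#'   signed_enrichment.
#' @export
feature_enrichment <- function(events, universe, annotation = NULL) {
  assign_features <- function(tbl) {
    tbl <- as_tibble(tbl)
    if ("feature" %in% names(tbl)) return(tbl)
    if (is.null(annotation)) {
      abort("Supply `annotation` or pre-annotated `feature` columns.")
    }
    ann <- as_tibble(annotation)
    hits <- find_overlaps_q(sites_to_granges(tbl),
                                        intervals_to_granges(ann, "annotation"))
    out <- tbl[S4Vectors::queryHits(hits), ]
    out$feature <- ann$feature[S4Vectors::subjectHits(hits)]
    out
  }
  ev <- assign_features(events) %>% filter(.data$direction %in% c("+", "-"))
  un <- assign_features(universe)
  feats <- sort(unique(un$feature))
  n_universe_total <- nrow(un)
  base <- count(un, .data$feature, name = "n_universe")
  grid <- expand_grid(feature = feats, direction = c("+", "-"))
  ev_counts <- count(ev, .data$feature, .data$direction, name = "n_events")
  totals <- count(ev, .data$direction, name = "n_events_total")
  grid %>%
    left_join(base, by = "feature") %>%
    left_join(ev_counts, by = c("feature", "direction")) %>%
    left_join(totals, by = "direction") %>%
    mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      enrichment = dplyr::case_when(
        is.na(.data$n_events_total) | .data$n_events_total == 0 ~ NA_real_,
        .data$n_universe == 0 | is.na(.data$n_universe) ~ NA_real_,
        TRUE ~ (.data$n_events / .data$n_events_total) /
          (.data$n_universe / n_universe_total)
      ),
      signed_enrichment = .data$enrichment *
        if_else(.data$direction == "+", 1, -1)
    ) %>%
    select("feature", "direction", "n_events", "n_universe", "enrichment",
           "signed_enrichment")
}

#' Select the most variably modified sites across samples
#'
#' Restricts to sites covered in every sample (complete cases), ranks them by
#' cross-sample variance of `m`, and keeps the top `k`; ties break by genomic
#' order.  If fewer than `k` complete-case sites exist, all are used with a
#' warning.
#'
#' @param table Long site mark table with sample and `m` columns.
#' @param k Number of sites to keep (the full-scale convention is 150,000;
#'   scale to your site universe).
#' @return A wide tibble: site keys plus one `m` column per sample, top-`k`
#'   rows.
#' @seealso [build_epitree()]
#' @export
select_top_variable <- function(table, k) {
  table <- as_tibble(table)
  keys <- site_keys(table)
  wide <- pivot_wider(table, id_cols = all_of(keys), names_from = "sample",
                      values_from = "m")
  wide <- wide[complete.cases(wide), ]
  if (ncol(wide) - length(keys) < 3) abort("Need at least 3 samples.")
  if (nrow(wide) < k) {
    warn(paste0("Only ", nrow(wide), " complete-case sites available; ",
                "using all of them."))
    k <- nrow(wide)
  }
  vals <- as.matrix(wide[setdiff(names(wide), keys)])
  wide$`.var` <- apply(vals, 1, var)
  wide %>%
    arrange(dplyr::desc(.data$.var), .data$chrom, .data$pos) %>%
    slice_head(n = k) %>%
    arrange(.data$chrom, .data$pos) %>%
    select(-".var")
}

#' Build an epigenetic sample tree from a site-by-sample matrix
#'
#' Hierarchically clusters samples on their modification profiles (Euclidean
#' distance, average linkage by default) and returns the dendrogram as a
#' phylogenetic-style tree with a newick serialisation.
#'
#' @param wide Wide tibble from [select_top_variable()] (site keys + one
#'   column per sample), or a numeric matrix with samples as columns.
#' @param distance Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An object of class `epitree`: list with the `hclust` fit, the
#'   `ape::phylo` tree, and its `newick` string.
#' @export
build_epitree <- function(wide, distance = "euclidean", linkage = "average") {
  if (is_tibble(wide) || is.data.frame(wide)) {
    keys <- site_keys(wide)
    mat <- as.matrix(as_tibble(wide)[setdiff(names(wide), keys)])
  } else {
    mat <- as.matrix(wide)
  }
  if (ncol(mat) < 3) abort("Need at least 3 samples to build a tree.")
  d <- dist(t(mat), method = distance)
  hc <- hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(
    list(hclust = hc, phylo = phy,
         newick = ape::write.tree(phy)),
    class = "epitree"
  )
}

#' @export
print.epitree <- function(x, ...) {
  cat("<epitree> ", length(x$phylo$tip.label), " samples; linkage ",
      x$hclust$method, "\n", sep = "")
  cat(x$newick, "\n")
  invisible(x)
}

#' @rdname build_epitree
#' @param x An `epitree`.
#' @param k Number of groups for the membership column of `tidy()`.
#' @param ... Unused.
#' @method tidy epitree
#' @export
tidy.epitree <- function(x, k = 2, ...) {
  grp <- cutree(x$hclust, k = k)
  tibble(sample = names(grp), group = unname(grp))
}

#' @rdname build_epitree
#' @method glance epitree
#' @export
glance.epitree <- function(x, ...) {
  tibble(n_samples = length(x$phylo$tip.label),
         linkage = x$hclust$method,
         height = max(x$hclust$height))
}
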