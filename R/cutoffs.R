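#' Cutoff presets for tiering and differential calling
#'
#' A cutoff preset bundles the thresholds used throughout the pipeline:
#' per-mark tier boundaries (highly/lowly modified sites), per-mark
#' differential cutoffs for single-site comparisons, and per-mark cutoffs for
#' region-average comparisons.  Marks are keyed `5mC` (the BS composite
#' signal), `5hmC` (TAB) and `5fC_5caC` (MAB).
#'
#' Shipped presets:
#' \describe{
#'   \item{`"default"`}{Tier cutoffs high/low of 0.6/0.2 (5mC), 0.15/0.05
#'     (5hmC), 0.2/0.1 (5fC/5caC); site deltas 0.2/0.05/0.05; region-average
#'     deltas 0.15/0.02/0.02.}
#'   \item{`"strict"`}{As `"default"` but with the stricter 0.25 site delta
#'     for 5mC (0.25/0.05/0.05), used for switching-quadrant scatter analyses.}
#'   \item{`"promoter-expression"`}{Site and region deltas of 0.1/0.025/0.025,
#'     used when relating average promoter modification change to expression
#'     change.}
#' }
#'
#' @param name Preset name, or `NULL` to build a custom preset from the other
#'   arguments.
#' @param tier_high,tier_low Named numeric vectors over the three marks giving
#'   the high/low tier boundaries.
#' @param delta_site,delta_region Named numeric vectors over the three marks
#'   giving the differential cutoffs at site and region scope.
#'
#' @return An object of class `cutoff_preset`: a list with elements `name`,
#'   `tier_high`, `tier_low`, `delta_site`, `delta_region`.
#' @examples
#' cutoff_preset("default")
#' cutoff_preset("strict")$delta_site
#' @export
cutoff_preset <- function(name = c("default", "strict", "promoter-expression"),
                          tier_high = NULL, tier_low = NULL,
                          delta_site = NULL, delta_region = NULL) {
  th <- c("5mC" = 0.6, "5hmC" = 0.15, "5fC_5caC" = 0.2)
  tl <- c("5mC" = 0.2, "5hmC" = 0.05, "5fC_5caC" = 0.1)
  dr <- c("5mC" = 0.15, "5hmC" = 0.02, "5fC_5caC" = 0.02)
  if (is.null(name)) {
    preset <- list(name = "custom", tier_high = th, tier_low = tl,
                   delta_site = c("5mC" = 0.2, "5hmC" = 0.05, "5fC_5caC" = 0.05),
                   delta_region = dr)
  } else {
    name <- arg_match(name)
    preset <- switch(
      name,
      "default" = list(
        name = name, tier_high = th, tier_low = tl,
        delta_site = c("5mC" = 0.2, "5hmC" = 0.05, "5fC_5caC" = 0.05),
        delta_region = dr
      ),
      "strict" = list(
        name = name, tier_high = th, tier_low = tl,
        delta_site = c("5mC" = 0.25, "5hmC" = 0.05, "5fC_5caC" = 0.05),
        delta_region = dr
      ),
      "promoter-expression" = list(
        name = name, tier_high = th, tier_low = tl,
        delta_site = c("5mC" = 0.1, "5hmC" = 0.025, "5fC_5caC" = 0.025),
        delta_region = c("5mC" = 0.1, "5hmC" = 0.025, "5fC_5caC" = 0.025)
      )
    )
  }
  for (field in c("tier_high", "tier_low", "delta_site", "delta_region")) {
    override <- switch(field, tier_high = tier_high, tier_low = tier_low,
                       delta_site = delta_site, delta_region = delta_region)
    if (!is.null(override)) {
      names(override) <- normalize_mark(names(override))
      preset[[field]][names(override)] <- override
      preset$name <- "custom"
    }
  }
  ok <- preset$tier_low >= 0 & preset$tier_low < preset$tier_high &
    preset$tier_high <= 1
  if (!all(ok)) abort("Tier cutoffs must satisfy 0 <= low < high <= 1.")
  if (any(preset$delta_site <= 0) || any(preset$delta_region <= 0)) {
    abort("Differential cutoffs must be positive.")
  }
  structure(preset, class = "cutoff_preset")
}

#' @export
print.cutoff_preset <- function(x, ...) {
  cat("<cutoff_preset: ", x$name, ">\n", sep = "")
  m <- rbind(tier_high = x$tier_high, tier_low = x$tier_low,
             delta_site = x$delta_site, delta_region = x$delta_region)
  print(m)
  invisible(x)
}

# Resolve either a preset object or a preset name.
as_cutoff_preset <- function(preset) {
  if (inherits(preset, "cutoff_preset")) return(preset)
  if (is.character(preset) && length(preset) == 1L) return(cutoff_preset(preset))
  abort("`preset` must be a cutoff_preset object or a preset name.")
}
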