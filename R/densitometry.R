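# Western-blot densitometry: per-lane phospho/total ERK ratios, scaling to
# the normothermic control group, and the 2 x 2 distension-by-temperature
# analysis. Band quantification from gel images is out of scope; input is a
# lane-intensity table.

#' Phospho/total ERK ratio per lane
#'
#' @param lanes data.frame with positive intensity columns `perk1`, `perk2`,
#'   `erk1`, `erk2` (arbitrary densitometry units).
#' @param isoform 1 or 2 (ERK1 at 44 kDa, ERK2 at 42 kDa).
#' @return numeric vector `perk_k / erk_k`; invariant to per-lane exposure
#'   scaling.
#' @export
perk_ratio <- function(lanes, isoform = 2) {
  stopifnot(isoform %in% c(1, 2))
  pk <- lanes[[paste0("perk", isoform)]]
  ek <- lanes[[paste0("erk", isoform)]]
  if (is.null(pk) || is.null(ek)) stop("lane table lacks intensity columns")
  if (any(pk <= 0) || any(ek <= 0)) stop("band intensities must be positive")
  pk / ek
}

#' Normalize ratios to the 37.5 C control group
#'
#' Divides every lane's phospho/total ratio by the mean ratio of the
#' normothermic (37.5 C) undistended control group, so that group's
#' normalized mean is exactly 1.
#'
#' @param lanes lane table with `temp_C` and `condition`
#'   (`"control"`/`"distended"`) columns plus band intensities.
#' @return the table with added columns `ratio_perk1`, `ratio_perk2`,
#'   `norm_perk1`, `norm_perk2`.
#' @export
normalize_to_control <- function(lanes) {
  stopifnot(all(c("temp_C", "condition") %in% names(lanes)))
  ref <- lanes$temp_C == 37.5 & lanes$condition == "control"
  if (!any(ref)) stop("no 37.5 C control lanes to normalize to")
  out <- as.data.frame(lanes)
  for (iso in 1:2) {
    r <- perk_ratio(lanes, iso)
    ref_mean <- mean(r[ref])
    if (!is.finite(ref_mean) || ref_mean <= 0)
      stop("37.5 C control group has non-positive mean ratio")
    out[[paste0("ratio_perk", iso)]] <- r
    out[[paste0("norm_perk", iso)]] <- r / ref_mean
  }
  out
}

#' Full blot analysis for the 2 x 2 pERK design
#'
#' Normalizes ratios to the 37.5 C control group, then runs the balanced
#' two-way ANOVA (distension condition x temperature) with
#' distended-vs-control Bonferroni post-tests within each temperature,
#' separately for pERK2 and pERK1.
#'
#' @param lanes lane table (see [simulate_blot_lanes()] for the layout);
#'   needs all four condition-by-temperature cells with >= 2 lanes each.
#' @param alpha significance level (default 0.05).
#' @return list with `normalized` (the augmented table), `perk2` and
#'   `perk1` (`ubd_report` objects).
#' @export
blot_analysis <- function(lanes, alpha = 0.05) {
  norm <- normalize_to_control(lanes)
  cells <- table(norm$condition, norm$temp_C)
  if (any(dim(cells) != c(2, 2)) || any(cells < 2))
    stop("blot analysis requires the full 2 x 2 design with >= 2 lanes per cell")
  rep2 <- analyze_design(norm, "fig5_blot", alpha = alpha)
  norm1 <- norm
  norm1$norm_perk2 <- norm1$norm_perk1
  rep1 <- analyze_design(norm1, "fig5_blot", alpha = alpha)
  list(normalized = norm, perk2 = rep2, perk1 = rep1)
}
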