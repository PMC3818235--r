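# Replicated end-to-end simulation studies: each replicate runs the full
# simulate -> score -> analyze pipeline on a fresh seeded cohort. Studies
# default to 25 Hz sampling: the rectified-AUC coefficient of variation
# scales as 1/sqrt(samples per window) and is already ~3% there, so the
# pass/fail structure of the studies is insensitive to the rate while
# traces stay small.

#' Run one full pipeline replicate
#'
#' Simulates a cohort for a design, scores every animal's session, and runs
#' the design's ANOVA + Bonferroni analysis.
#'
#' @param design design name (see [build_protocol()]).
#' @param params [sim_params()]; its `seed` is replaced by `seed` and its
#'   `sampling_rate` by `sampling_rate` when given.
#' @param seed replicate seed (integer); default keeps `params$seed`.
#' @param alpha significance level.
#' @param sampling_rate optional Hz override for the simulated traces.
#' @param overrides protocol overrides.
#' @return list with `report` (`ubd_report`), `table`, `records`.
#' @export
run_vmr_replicate <- function(design, params = sim_params(), seed = NULL,
                              alpha = 0.05, sampling_rate = NULL,
                              overrides = list()) {
  if (!is.null(seed)) params$seed <- as.integer(seed)
  if (!is.null(sampling_rate)) params$sampling_rate <- sampling_rate
  cohort <- simulate_cohort(design, params, overrides)
  scored <- score_cohort(cohort)
  report <- analyze_design(scored$table, design, alpha = alpha)
  list(report = report, table = scored$table, records = scored$records)
}

#' Replicated power/type-I study of the VMR pipeline
#'
#' Repeats [run_vmr_replicate()] `n_reps` times with seeds derived from
#' `seed` and extracts per-replicate decision indicators.
#'
#' @inheritParams run_vmr_replicate
#' @param n_reps number of replicates.
#' @param seed master seed for the study.
#' @return data.frame, one row per replicate. Two-way designs report
#'   `p_A` (set or temperature) and `p_B` (pressure) plus
#'   `top_contrast` (stratum/levels of the smallest adjusted post-test p);
#'   one-way designs report `p_group` and the cohort means of the first and
#'   last sets (`mean_first_set`, `mean_last_set`).
#' @export
vmr_power_study <- function(design, n_reps, params = sim_params(), seed = 1,
                            alpha = 0.05, sampling_rate = 25,
                            overrides = list()) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, 1000L + r)
    res <- run_vmr_replicate(design, params, seed = rep_seed, alpha = alpha,
                             sampling_rate = sampling_rate,
                             overrides = overrides)
    tt <- res$report$anova$terms
    post <- res$report$posttests
    top <- which.min(post$p_adjusted)
    top_lab <- paste0(post$stratum[top], ":", post$level_1[top], "-",
                      post$level_2[top])
    if (res$report$anova$kind == "two_way") {
      rows[[r]] <- data.frame(
        rep = r, seed = rep_seed,
        p_A = tt$p[tt$term == "A"], p_B = tt$p[tt$term == "B"],
        top_contrast = top_lab)
    } else {
      tab <- res$table
      first <- min(tab$set_index); last <- max(tab$set_index)
      rows[[r]] <- data.frame(
        rep = r, seed = rep_seed,
        p_group = tt$p[tt$term == "group"],
        mean_first_set = mean(tab$mean_vmr[tab$set_index == first]),
        mean_last_set = mean(tab$mean_vmr[tab$set_index == last]),
        top_contrast = top_lab)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replicated study of the blot pipeline
#'
#' Repeats simulate-lanes -> [blot_analysis()] and records, per replicate,
#' the distension main-effect p for pERK2 and pERK1 and which
#' within-temperature contrasts were flagged.
#'
#' @param n_reps number of replicates.
#' @param params [blot_sim_params()].
#' @param seed master seed.
#' @param alpha significance level.
#' @return data.frame with columns `p_distension_perk2`,
#'   `p_distension_perk1`, `flag_37`, `flag_33` (within-temperature
#'   distended-vs-control flags for pERK2), `n_flags_perk1`, and
#'   `control_norm_mean` (normalized 37.5 C control mean, 1 by
#'   construction).
#' @export
blot_power_study <- function(n_reps, params = blot_sim_params(), seed = 1,
                             alpha = 0.05) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    params$seed <- derive_seed(seed, 2000L + r)
    lanes <- simulate_blot_lanes(params)
    res <- blot_analysis(lanes, alpha = alpha)
    p2 <- res$perk2$anova$terms
    p1 <- res$perk1$anova$terms
    post2 <- res$perk2$posttests
    flag_of <- function(temp) {
      i <- post2$stratum == sprintf("%.1fC", temp)
      any(post2$significant[i])
    }
    norm <- res$normalized
    ctrl <- norm$temp_C == 37.5 & norm$condition == "control"
    rows[[r]] <- data.frame(
      rep = r,
      p_distension_perk2 = p2$p[p2$term == "A"],
      p_distension_perk1 = p1$p[p1$term == "A"],
      flag_37 = flag_of(37.5), flag_33 = flag_of(33.5),
      n_flags_perk1 = sum(res$perk1$posttests$significant),
      control_norm_mean = mean(norm$norm_perk2[ctrl]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
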