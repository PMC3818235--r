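# Per-design dispatch: which ANOVA and which Bonferroni family each figure
# design uses.

#' Analyze a scored VMR table (or blot table) per study design
#'
#' Dispatches to the analysis used for each design:
#' \describe{
#'   \item{`fig2_short` / `fig2_long`}{two-way ANOVA, set x pressure, on
#'     triplicate-averaged normalized VMRs (animals as replicates);
#'     Bonferroni family: all set pairs within each pressure.}
#'   \item{`fig3_temp`}{two-way ANOVA, temperature x pressure; all
#'     temperature pairs within each pressure.}
#'   \item{`fig4_ramp` / `fig4_const`}{one-way ANOVA across the nine
#'     temperature-labelled sets; each set versus the first 37.5 C set.}
#'   \item{`fig5_blot`}{two-way ANOVA, condition x temperature, on
#'     control-normalized pERK2/ERK2 ratios; distended-vs-control within
#'     each temperature (use [blot_analysis()] to go from raw lanes).}
#' }
#' Animals cross sets in the VMR designs, but set/temperature are analyzed
#' as plain fixed effects (no repeated-measures term), matching the printed
#' analysis style; the report notes this limitation.
#'
#' @param table a pooled table from [score_cohort()] (columns `animal`,
#'   `set_index`, `pressure_mmHg`, `temp_C`, `mean_vmr`) or, for
#'   `fig5_blot`, a normalized blot table (columns `temp_C`, `condition`,
#'   `norm_perk2`).
#' @param design design name (see [build_protocol()]).
#' @param alpha significance level (default 0.05).
#' @return object of class `ubd_report`: list with `design`, `anova`,
#'   `posttests`, `flags` (significant comparisons), `alpha`, `notes`.
#' @export
analyze_design <- function(table, design, alpha = 0.05) {
  if (!design %in% UBD_DESIGNS) stop("unknown design: ", design)
  need <- function(cols) {
    miss <- setdiff(cols, names(table))
    if (length(miss))
      stop("table does not match design '", design, "': missing columns ",
           paste(miss, collapse = ", "))
  }
  notes <- paste("Fixed-effects ANOVA on a balanced layout; repeated",
                 "measures across sets within animal are not modeled.")
  if (design %in% c("fig2_short", "fig2_long")) {
    need(c("mean_vmr", "set_index", "pressure_mmHg"))
    fit <- two_way_anova(table$mean_vmr,
                         a = paste0("set", table$set_index),
                         b = paste0(table$pressure_mmHg, "mmHg"))
    post <- bonferroni_posttest(fit, pairs = "all", alpha = alpha)
    terms <- c(A = "set", B = "pressure")
  } else if (design == "fig3_temp") {
    need(c("mean_vmr", "temp_C", "pressure_mmHg"))
    fit <- two_way_anova(table$mean_vmr,
                         a = sprintf("%.1fC", table$temp_C),
                         b = paste0(table$pressure_mmHg, "mmHg"))
    post <- bonferroni_posttest(fit, pairs = "all", alpha = alpha)
    terms <- c(A = "temperature", B = "pressure")
  } else if (design %in% c("fig4_ramp", "fig4_const")) {
    need(c("mean_vmr", "set_index", "temp_C"))
    if (length(unique(table$set_index)) != 9)
      stop("table does not match design '", design, "': expected nine sets")
    lab <- sprintf("set%d_%.1fC", table$set_index, table$temp_C)
    lab <- factor(lab, levels = unique(lab[order(table$set_index)]))
    fit <- one_way_anova(table$mean_vmr, lab)
    post <- bonferroni_posttest(fit, pairs = "vs_first", alpha = alpha)
    terms <- c(group = "set (temperature)")
  } else { # fig5_blot
    need(c("norm_perk2", "condition", "temp_C"))
    fit <- two_way_anova(table$norm_perk2,
                         a = table$condition,
                         b = sprintf("%.1fC", table$temp_C))
    post <- bonferroni_posttest(fit, pairs = "all", alpha = alpha)
    terms <- c(A = "distension", B = "temperature")
  }
  flags <- as.data.frame(post)[post$significant, , drop = FALSE]
  structure(list(design = design, anova = fit, term_labels = terms,
                 posttests = post, flags = flags, alpha = alpha,
                 notes = notes),
            class = "ubd_report")
}

#' @export
print.ubd_report <- function(x, ...) {
  cat("== UBD analysis report: design ", x$design, " ==\n", sep = "")
  cat("note: ", x$notes, "\n", sep = "")
  tt <- x$anova$terms
  lab <- x$term_labels
  tt$term <- ifelse(tt$term %in% names(lab), lab[tt$term], tt$term)
  tt$p <- format_p(tt$p)
  print(tt, row.names = FALSE, digits = 5)
  cat("\n")
  print(x$posttests)
  if (nrow(x$flags) == 0) cat("no significant post-test contrasts at alpha = ",
                              x$alpha, "\n", sep = "")
  invisible(x)
}

#' Convert a report to plain lists for JSON serialization
#' @param report a `ubd_report`.
#' @return nested list mirroring the report.
#' @export
report_to_list <- function(report) {
  tt <- report$anova$terms
  lab <- report$term_labels
  tt$term <- ifelse(tt$term %in% names(lab), lab[tt$term], tt$term)
  tt$p_label <- format_p(tt$p)
  post <- as.data.frame(report$posttests)
  post$p_label <- format_p(post$p_adjusted)
  list(design = report$design, alpha = report$alpha, notes = report$notes,
       anova = tt, posttests = post,
       flagged = as.data.frame(report$flags))
}
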