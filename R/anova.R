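# Fixed-effects ANOVA for balanced layouts, written out as the classical
# mean-decomposition (no model-matrix machinery), plus Bonferroni
# post-tests in the convention of the commercial stats packages common in
# this field: all pairs of the primary factor within each stratum of the
# second factor, raw p multiplied by the family size. Unbalanced layouts
# are rejected outright: the designs this package analyzes are balanced,
# and unbalanced sums-of-squares conventions would add ambiguity the data
# cannot resolve.

P_FLOOR <- 1e-15

format_p <- function(p) {
  ifelse(p <= P_FLOOR, sprintf("< %g", P_FLOOR), sprintf("%.4g", p))
}

new_anova_result <- function(terms, grand_mean, data, kind) {
  structure(list(terms = terms, grand_mean = grand_mean,
                 data = data, kind = kind),
            class = "ubd_anova")
}

#' @export
print.ubd_anova <- function(x, ...) {
  cat(if (x$kind == "one_way") "One-way" else "Two-way",
      "fixed-effects ANOVA (balanced)\n")
  tab <- x$terms
  tab$p <- format_p(tab$p)
  print(tab, row.names = FALSE, digits = 5)
  invisible(x)
}

#' One-way fixed-effects ANOVA
#'
#' Classical between/within decomposition computed from group means;
#' p-value from the F distribution. Requires at least two groups with at
#' least two observations each.
#'
#' @param values numeric response.
#' @param group grouping factor (coerced).
#' @return `ubd_anova` object; `$terms` holds SS, df, MS, F and p for the
#'   group term and the within (error) term. p-values below 1e-15 are
#'   floored at that limit (reported as "< 1e-15" when printed).
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  stopifnot(length(values) == length(group), all(is.finite(values)))
  ns <- tabulate(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(ns < 2)) stop("every group needs at least 2 observations")
  grand <- mean(values)
  gm <- tapply(values, group, mean)
  ss_b <- sum(ns * (gm - grand)^2)
  ss_w <- sum((values - gm[as.integer(group)])^2)
  df_b <- nlevels(group) - 1
  df_w <- length(values) - nlevels(group)
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  if (ms_w <= 0 && ss_b > 0) {
    warning("zero within-group variance with unequal means; ",
            "p reported at the representable floor")
    f <- Inf; p <- P_FLOOR
  } else {
    f <- ms_b / ms_w
    p <- max(pf(f, df_b, df_w, lower.tail = FALSE), P_FLOOR)
  }
  terms <- data.frame(
    term = c("group", "within"),
    df = c(df_b, df_w), ss = c(ss_b, ss_w), ms = c(ms_b, ms_w),
    F = c(f, NA), p = c(p, NA))
  new_anova_result(terms, grand,
                   data.frame(y = values, a = group), "one_way")
}

#' Two-way fixed-effects ANOVA (balanced, with interaction)
#'
#' Sums of squares for factors A, B, their interaction and error via cell
#' and marginal means, for a complete balanced layout with at least two
#' replicates per cell. F statistics are tested against the error mean
#' square. Unbalanced or incomplete layouts are rejected.
#'
#' @param values numeric response.
#' @param a,b crossing factors (coerced).
#' @return `ubd_anova` object with terms `A`, `B`, `A:B`, `error`.
#' @export
two_way_anova <- function(values, a, b) {
  a <- factor(a); b <- factor(b)
  stopifnot(length(values) == length(a), length(values) == length(b),
            all(is.finite(values)))
  I <- nlevels(a); J <- nlevels(b)
  if (I < 2 || J < 2) stop("both factors need at least 2 levels")
  counts <- table(a, b)
  if (any(counts == 0)) stop("incomplete layout: empty cells")
  if (length(unique(as.vector(counts))) != 1)
    stop("unbalanced layout: this ANOVA requires equal replicates per cell")
  n <- counts[1, 1]
  if (n < 2) stop("need >= 2 replicates per cell for the interaction term")
  grand <- mean(values)
  am <- tapply(values, a, mean)
  bm <- tapply(values, b, mean)
  cm <- tapply(values, list(a, b), mean)
  ss_a <- J * n * sum((am - grand)^2)
  ss_b <- I * n * sum((bm - grand)^2)
  ss_ab <- n * sum((cm - outer(am, rep(1, J)) - outer(rep(1, I), bm) + grand)^2)
  ss_e <- sum((values - cm[cbind(as.integer(a), as.integer(b))])^2)
  df <- c(I - 1, J - 1, (I - 1) * (J - 1), I * J * (n - 1))
  ss <- c(ss_a, ss_b, ss_ab, ss_e)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(pmax(pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), P_FLOOR), NA)
  terms <- data.frame(term = c("A", "B", "A:B", "error"),
                      df = df, ss = ss, ms = ms, F = f, p = p)
  new_anova_result(terms, grand,
                   data.frame(y = values, a = a, b = b), "two_way")
}

ms_error <- function(anova) {
  tt <- anova$terms
  er <- if (anova$kind == "one_way") "within" else "error"
  list(ms = tt$ms[tt$term == er], df = tt$df[tt$term == er])
}

#' Bonferroni post-tests on a balanced ANOVA
#'
#' Pairwise comparisons of the primary factor, within each stratum of the
#' second factor for two-way fits, using the pooled error mean square:
#' `t = |mean1 - mean2| / sqrt(MS_error * 2 / n_cell)` with the error
#' degrees of freedom. Adjusted p = `min(1, m * raw p)` where m is the
#' number of comparisons in the whole family (pairs x strata).
#'
#' @param anova a [one_way_anova()] or [two_way_anova()] result.
#' @param pairs `"all"` for all level pairs of the primary factor, or
#'   `"vs_first"` to compare every level against the first (control) level.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return object of class `ubd_posttest`: data.frame of comparisons with
#'   `stratum`, `level_1`, `level_2`, `mean_diff`, `t`, `df`, `p_raw`,
#'   `p_adjusted`, `significant`; attribute `m` is the family size.
#' @export
bonferroni_posttest <- function(anova, pairs = c("all", "vs_first"),
                                alpha = 0.05) {
  stopifnot(inherits(anova, "ubd_anova"))
  pairs <- match.arg(pairs)
  dat <- anova$data
  err <- ms_error(anova)
  lev <- levels(dat$a)
  pair_idx <- if (pairs == "all") utils::combn(seq_along(lev), 2)
              else rbind(1L, seq_along(lev)[-1])
  if (ncol(pair_idx) == 0) stop("empty comparison family")
  strata <- if (anova$kind == "two_way") levels(dat$b) else "(all)"
  rows <- list()
  for (s in strata) {
    sub <- if (anova$kind == "two_way") dat[dat$b == s, ] else dat
    gm <- tapply(sub$y, sub$a, mean)
    nc <- tabulate(factor(sub$a, levels = lev))
    for (k in seq_len(ncol(pair_idx))) {
      i <- pair_idx[1, k]; j <- pair_idx[2, k]
      diff <- gm[[lev[i]]] - gm[[lev[j]]]
      se <- sqrt(err$ms * (1 / nc[i] + 1 / nc[j]))
      t <- abs(diff) / se
      p <- 2 * pt(-t, err$df)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, level_1 = lev[i], level_2 = lev[j],
        mean_diff = diff, t = t, df = err$df, p_raw = p)
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adjusted <- pmin(1, m * out$p_raw)
  out$p_raw <- pmax(out$p_raw, P_FLOOR)
  out$p_adjusted <- pmax(out$p_adjusted, P_FLOOR)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  structure(out, m = m, alpha = alpha,
            class = c("ubd_posttest", "data.frame"))
}

#' @export
print.ubd_posttest <- function(x, ...) {
  cat("Bonferroni post-tests (family m = ", attr(x, "m"),
      ", alpha = ", attr(x, "alpha"), ")\n", sep = "")
  y <- as.data.frame(x)
  y$p_raw <- format_p(y$p_raw)
  y$p_adjusted <- format_p(y$p_adjusted)
  print(y, row.names = FALSE, digits = 4)
  invisible(x)
}
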