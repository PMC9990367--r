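## Nonparametric group comparisons on per-slice readouts.

#' Create a group sample
#'
#' @param name Group name.
#' @param values Numeric per-slice readouts (finite, n >= 1).
#' @param mouse Optional mouse ids parallel to `values` (for mouse-level
#'   aggregation).
#' @return A `group_sample` object.
#' @export
group_sample <- function(name, values, mouse = NULL) {
  if (!is.character(name) || length(name) != 1L) stopf("'name' must be a string")
  if (!is.numeric(values) || length(values) < 1L || any(!is.finite(values)))
    stopf("group '%s' must have at least one finite value", name)
  if (!is.null(mouse) && length(mouse) != length(values))
    stopf("'mouse' must be parallel to 'values'")
  structure(list(name = name, values = as.numeric(values), mouse = mouse),
            class = "group_sample")
}

as_group_sample <- function(x, name = "group") {
  if (inherits(x, "group_sample")) x else group_sample(name, x)
}

comparison_result <- function(method, statistic, p, n, note = "",
                              adjusted_p = NA_real_, groups = NULL) {
  structure(list(method = method, statistic = statistic,
                 p = p, adjusted_p = adjusted_p, n = n, note = note,
                 groups = groups),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> %s = %.4g, p = %.4g%s (%s; n = %s)\n",
              x$method, names(x$statistic)[1], x$statistic[1], x$p,
              if (!is.na(x$adjusted_p)) sprintf(", adj. p = %.4g", x$adjusted_p) else "",
              x$note, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Significance stars matching the figure convention
#'
#' `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001, `****` p <= 0.0001,
#' `ns` otherwise.
#'
#' @param p P value(s).
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum comparison. The reported statistic is
#' `U = min(U_a, U_b)`. The p value is exact by enumeration when both groups
#' have n <= 8 and there are no ties, otherwise the normal approximation
#' with tie and continuity correction is used (the computation is delegated
#' to [stats::wilcox.test()], which implements both paths).
#'
#' @param a,b [group_sample()] objects or numeric vectors.
#' @return A `comparison_result`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_u <- function(a, b) {
  a <- as_group_sample(a, "a"); b <- as_group_sample(b, "b")
  na <- length(a$values); nb <- length(b$values)
  ties <- anyDuplicated(c(a$values, b$values)) > 0
  exact <- na <= 8 && nb <= 8 && !ties
  if (identical(a$values, b$values) ||
      (length(unique(c(a$values, b$values))) == 1L)) {
    ## degenerate all-tied case: no evidence against the null
    return(comparison_result("mann_whitney_u", c(U = na * nb / 2), p = 1,
                             n = c(na, nb), note = "all tied",
                             groups = c(a$name, b$name)))
  }
  wt <- suppressWarnings(
    wilcox.test(a$values, b$values, exact = exact, correct = TRUE))
  u_a <- unname(wt$statistic)
  u <- min(u_a, na * nb - u_a)
  comparison_result("mann_whitney_u", c(U = u), p = min(wt$p.value, 1),
                    n = c(na, nb),
                    note = if (exact) "exact enumeration" else
                      "normal approximation, tie/continuity corrected",
                    groups = c(a$name, b$name))
}

#' Kruskal-Wallis test across three or more groups
#'
#' Tie-corrected H statistic referred to the chi-square distribution with
#' k - 1 degrees of freedom (delegated to [stats::kruskal.test()]). For two
#' groups use [mann_whitney_u()].
#'
#' @param groups List of [group_sample()] objects (>= 3, each n >= 2).
#' @return A `comparison_result`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(seq_along(groups), function(i)
    as_group_sample(groups[[i]], paste0("group", i)))
  if (length(groups) < 3L)
    stopf("kruskal_wallis needs >= 3 groups; use mann_whitney_u for two")
  ns <- vapply(groups, function(g) length(g$values), integer(1))
  if (any(ns < 2L)) stopf("every group needs n >= 2")
  vals <- unlist(lapply(groups, `[[`, "values"))
  fac <- factor(rep(vapply(groups, `[[`, character(1), "name"), ns))
  if (length(unique(vals)) == 1L)
    return(comparison_result("kruskal_wallis", c(H = 0), p = 1, n = ns,
                             note = "all tied",
                             groups = levels(fac)))
  kt <- kruskal.test(vals, fac)
  comparison_result("kruskal_wallis", c(H = unname(kt$statistic)),
                    p = kt$p.value, n = ns,
                    note = sprintf("chi-square, df = %d", unname(kt$parameter)),
                    groups = levels(fac))
}

#' Many-to-one post hoc comparisons against a reference group
#'
#' After a Kruskal-Wallis test, each group is compared against the reference
#' with Dunn-style z statistics on the pooled ranks (tie-corrected pooled
#' variance), Bonferroni-adjusted over the k - 1 comparisons. A parametric
#' Dunnett alternative (`method = "dunnett"`, via the multcomp package) is
#' offered because the two procedures are often conflated in figure legends;
#' the rank-based path is the default for internal consistency with the
#' omnibus test.
#'
#' @param groups List of [group_sample()] objects (>= 3).
#' @param reference Name of the reference group.
#' @param method `"dunn"` (rank-based, default) or `"dunnett"` (parametric).
#' @return List of `comparison_result`, one per non-reference group.
#' @export
posthoc_vs_reference <- function(groups, reference,
                                 method = c("dunn", "dunnett")) {
  method <- match.arg(method)
  groups <- lapply(seq_along(groups), function(i)
    as_group_sample(groups[[i]], paste0("group", i)))
  nms <- vapply(groups, `[[`, character(1), "name")
  if (!reference %in% nms) stopf("reference group '%s' not present", reference)
  if (length(groups) < 3L) stopf("post hoc requires >= 3 groups")
  others <- which(nms != reference)
  ref <- which(nms == reference)[1]
  k <- length(others)

  if (method == "dunnett") {
    if (!requireNamespace("multcomp", quietly = TRUE))
      stopf("method 'dunnett' requires the multcomp package")
    vals <- unlist(lapply(groups, `[[`, "values"))
    fac <- stats::relevel(factor(rep(nms, vapply(groups, function(g)
      length(g$values), integer(1)))), ref = reference)
    fit <- stats::aov(vals ~ fac)
    gh <- multcomp::glht(fit, linfct = multcomp::mcp(fac = "Dunnett"))
    sm <- summary(gh)
    res <- lapply(seq_len(k), function(i) {
      other_nm <- sub(" - .*$", "", names(sm$test$coefficients)[i])
      comparison_result("dunnett", c(t = unname(sm$test$tstat[i])),
                        p = unname(sm$test$pvalues[i]),
                        adjusted_p = unname(sm$test$pvalues[i]),
                        n = c(length(groups[[ref]]$values),
                              length(groups[[which(nms == other_nm)[1]]]$values)),
                        note = "parametric Dunnett (single-step adjusted)",
                        groups = c(reference, other_nm))
    })
    return(res)
  }

  vals <- unlist(lapply(groups, `[[`, "values"))
  ns <- vapply(groups, function(g) length(g$values), integer(1))
  gid <- rep(seq_along(groups), ns)
  rk <- rank(vals)
  N <- length(vals)
  tie_tab <- table(vals)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  var_term <- N * (N + 1) / 12 - tie_corr
  mean_rank <- tapply(rk, gid, mean)

  raw <- vapply(others, function(i) {
    z <- (mean_rank[[as.character(i)]] - mean_rank[[as.character(ref)]]) /
      sqrt(var_term * (1 / ns[i] + 1 / ns[ref]))
    c(z = z, p = 2 * pnorm(-abs(z)))
  }, numeric(2))
  adj <- pmin(raw["p", ] * k, 1)

  lapply(seq_len(k), function(i) {
    comparison_result("dunn", c(z = raw["z", i]), p = raw["p", i],
                      adjusted_p = adj[i], n = c(ns[ref], ns[others[i]]),
                      note = sprintf("rank-based many-to-one, Bonferroni over %d", k),
                      groups = c(reference, nms[others[i]]))
  })
}

#' Summarize a per-trace results table and run the group comparisons
#'
#' Produces per-group descriptive statistics (n slices, n mice, median, mean,
#' SD) for each readout and the matching comparison: Mann-Whitney for two
#' groups, Kruskal-Wallis plus many-to-one post hoc for three or more.
#' QC-flagged traces are excluded from the statistics (but counted) unless
#' `use_flagged = TRUE`. With `unit = "mouse"` the per-mouse median is the
#' observational unit instead of the slice.
#'
#' @param results data.frame with columns `group`, `mouse`, `slice`, the
#'   readout columns, and optionally `flags` (empty string = pass).
#' @param readouts Character vector of readout column names.
#' @param reference Reference group for post hoc comparisons (defaults to
#'   the first group).
#' @param unit `"slice"` (default) or `"mouse"`.
#' @param use_flagged Include QC-flagged traces?
#' @param posthoc Passed to [posthoc_vs_reference()].
#' @return List with `summary` and `comparisons` data.frames.
#' @export
summarize_cohort <- function(results, readouts, reference = NULL,
                             unit = c("slice", "mouse"), use_flagged = FALSE,
                             posthoc = c("dunn", "dunnett")) {
  unit <- match.arg(unit)
  posthoc <- match.arg(posthoc)
  if (!is.data.frame(results) || !all(c("group", "mouse") %in% names(results)))
    stopf("'results' must have group and mouse columns")
  missing_cols <- setdiff(readouts, names(results))
  if (length(missing_cols))
    stopf("unknown readout column(s): %s", paste(missing_cols, collapse = ", "))
  groups_all <- unique(results$group)
  if (!is.null(reference) && !reference %in% groups_all)
    stopf("unknown reference group '%s'", reference)
  reference <- reference %||% groups_all[1]

  flagged <- if ("flags" %in% names(results) && !use_flagged)
    !is.na(results$flags) & nzchar(results$flags) else rep(FALSE, nrow(results))

  summary_rows <- list(); comp_rows <- list()
  for (ro in readouts) {
    ok <- !flagged & is.finite(results[[ro]])
    samples <- list()
    for (g in groups_all) {
      gi <- results$group == g
      vals <- results[[ro]][gi & ok]
      mice <- results$mouse[gi & ok]
      if (unit == "mouse" && length(vals)) {
        vals <- as.numeric(tapply(vals, mice, median))
        mice <- unique(mice)
      }
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        readout = ro, group = g,
        n = length(vals), n_mice = length(unique(results$mouse[gi & ok])),
        n_excluded = sum(gi & !ok),
        median = if (length(vals)) median(vals) else NA_real_,
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) sd(vals) else NA_real_,
        stringsAsFactors = FALSE)
      if (length(vals)) samples[[g]] <- group_sample(g, vals)
    }
    eligible <- names(samples)
    if (length(eligible) < 2L) {
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        readout = ro, group_a = NA, group_b = NA, method = "none",
        statistic = NA_real_, p = NA_real_, adjusted_p = NA_real_,
        stars = NA, note = "no eligible traces", stringsAsFactors = FALSE)
    } else if (length(eligible) == 2L) {
      cr <- mann_whitney_u(samples[[1]], samples[[2]])
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        readout = ro, group_a = eligible[1], group_b = eligible[2],
        method = cr$method, statistic = unname(cr$statistic[1]), p = cr$p,
        adjusted_p = NA_real_, stars = as.character(p_stars(cr$p)),
        note = cr$note, stringsAsFactors = FALSE)
    } else {
      kw <- kruskal_wallis(unname(samples))
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        readout = ro, group_a = "all", group_b = "all",
        method = kw$method, statistic = unname(kw$statistic[1]), p = kw$p,
        adjusted_p = NA_real_, stars = as.character(p_stars(kw$p)),
        note = kw$note, stringsAsFactors = FALSE)
      ph <- posthoc_vs_reference(unname(samples), reference, method = posthoc)
      for (cr in ph)
        comp_rows[[length(comp_rows) + 1L]] <- data.frame(
          readout = ro, group_a = cr$groups[1], group_b = cr$groups[2],
          method = cr$method, statistic = unname(cr$statistic[1]), p = cr$p,
          adjusted_p = cr$adjusted_p,
          stars = as.character(p_stars(cr$adjusted_p)),
          note = cr$note, stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, summary_rows),
       comparisons = do.call(rbind, comp_rows))
}
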