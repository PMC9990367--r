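# Nonparametric comparisons: exactness, oracles, invariances.

test_that("Mann-Whitney U and exact p match enumeration on the textbook case", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p, 0.1)
  expect_match(res$note, "exact")
})

test_that("Mann-Whitney exact path agrees with the permutation oracle", {
  set.seed(31)
  for (na in 2:5) for (nb in 2:5) {
    vals <- sample(seq_len(50), na + nb)   # distinct values
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    res <- mann_whitney_u(a, b)
    expect_equal(res$p, perm_mw_p(a, b), tolerance = 1e-12,
                 label = sprintf("layout %d/%d", na, nb))
  }
})

test_that("Mann-Whitney approximation stays near the exact p for small n", {
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(8, 0.6)
    exact_p <- perm_mw_p(a, b)
    approx_p <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})

test_that("Mann-Whitney degenerate and invalid inputs", {
  expect_equal(mann_whitney_u(rep(5, 4), rep(5, 4))$p, 1)
  expect_error(mann_whitney_u(1, numeric(0)), "at least one")
  # permutation invariance within groups
  a <- c(3, 9, 1, 7); b <- c(2, 8, 5)
  expect_equal(mann_whitney_u(a, b)$p,
               mann_whitney_u(rev(a), sample(b))$p)
})

test_that("Kruskal-Wallis matches the rank-formula oracle and handles edge cases", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(g)
  expect_equal(unname(res$statistic), kw_bruteforce(g), tolerance = 1e-12)
  set.seed(8)
  g2 <- list(rnorm(6), rnorm(5, 1), rnorm(7, 2), rnorm(4))
  expect_equal(unname(kruskal_wallis(g2)$statistic), kw_bruteforce(g2),
               tolerance = 1e-12)
  ident <- list(rep(2, 3), rep(2, 3), rep(2, 3))
  res3 <- kruskal_wallis(ident)
  expect_equal(unname(res3$statistic), 0)
  expect_equal(res3$p, 1)
  expect_error(kruskal_wallis(list(c(1, 2), c(3, 4))), "3 groups")
  expect_error(kruskal_wallis(list(c(1, 2), c(3, 4), 5)), "n >= 2")
})

test_that("many-to-one post hoc is calibrated on identical groups and needs a reference", {
  ident <- lapply(1:3, function(i) group_sample(paste0("g", i), rep(c(1, 2), 4)))
  ph <- posthoc_vs_reference(ident, "g1")
  expect_true(all(vapply(ph, `[[`, numeric(1), "adjusted_p") == 1))
  expect_error(posthoc_vs_reference(ident, "nope"), "not present")
  expect_error(posthoc_vs_reference(ident[1:2], "g1"), ">= 3")
  # adjusted p never below raw p
  set.seed(21)
  gs <- lapply(1:4, function(i) group_sample(paste0("g", i), rnorm(8, i / 2)))
  ph2 <- posthoc_vs_reference(gs, "g1")
  for (cr in ph2) expect_gte(cr$adjusted_p, cr$p)
})

test_that("parametric Dunnett alternative runs when multcomp is present", {
  skip_if_not_installed("multcomp")
  set.seed(4)
  gs <- list(group_sample("ref", rnorm(10)),
             group_sample("up", rnorm(10, 2)),
             group_sample("same", rnorm(10)))
  ph <- posthoc_vs_reference(gs, "ref", method = "dunnett")
  names(ph) <- vapply(ph, function(x) x$groups[2], character(1))
  expect_lt(ph[["up"]]$adjusted_p, 0.05)
  expect_gt(ph[["same"]]$adjusted_p, 0.05)
})

test_that("summarize_cohort counts, compares, and honours QC flags", {
  tab <- data.frame(
    group = rep(c("ctrl", "ko"), each = 3),
    mouse = c(1, 1, 2, 1, 2, 2), slice = c(1, 2, 1, 1, 1, 2),
    slope = c(1.0, 1.2, 1.1, 2.0, 2.2, 2.1),
    flags = "", stringsAsFactors = FALSE)
  out <- summarize_cohort(tab, "slope")
  expect_equal(nrow(out$summary), 2)
  expect_equal(nrow(out$comparisons), 1)
  expect_identical(out$comparisons$method, "mann_whitney_u")
  # flagged traces are excluded but counted
  tab2 <- tab; tab2$flags[4:6] <- "low_r2"
  out2 <- summarize_cohort(tab2, "slope")
  expect_equal(out2$summary$n_excluded[out2$summary$group == "ko"], 3)
  expect_match(out2$comparisons$note, "no eligible")
  # unknown reference group rejected
  expect_error(summarize_cohort(tab, "slope", reference = "zz"), "unknown")
  # three groups route through Kruskal-Wallis + post hoc
  tab3 <- rbind(tab, within(tab, group <- "third"))
  tab3$slope <- tab3$slope + seq_len(nrow(tab3)) * 0.01
  out3 <- summarize_cohort(tab3, "slope", reference = "ctrl")
  expect_true("kruskal_wallis" %in% out3$comparisons$method)
  expect_equal(sum(out3$comparisons$method == "dunn"), 2)
})
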