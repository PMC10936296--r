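# Statistical machinery: nonparametric tests, corrections, MANOVA, report.

test_that("Shapiro-Wilk gates on sample size and flags heavy skew", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  set.seed(71)
  skewed <- exp(stats::rnorm(50, 0, 1.5))
  hits <- sum(replicate(20, shapiro_wilk(exp(stats::rnorm(50, 0, 1.5)))$p_value < 0.05))
  expect_gte(hits, 18)  # skewed samples rejected with high probability
  expect_s3_class(shapiro_wilk(skewed), "exo_test_result")
})

test_that("Kruskal-Wallis reproduces the hand-ranked H and its chi-square p", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, stats::pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r$p_value, 0.0273, tolerance = 1e-3)
  # identical constants: H = 0, p = 1
  flat <- kruskal_wallis(list(rep(2, 4), rep(2, 5)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # two groups: H equals the squared MW normal deviate (no ties)
  set.seed(72)
  a <- stats::rnorm(9); b <- stats::rnorm(7)
  h <- kruskal_wallis(list(a, b))$statistic
  u <- sum(outer(a, b, ">"))
  z <- (u - length(a) * length(b) / 2) /
    sqrt(length(a) * length(b) * (length(a) + length(b) + 1) / 12)
  expect_equal(h, z^2, tolerance = 1e-10)
  # invariant under strictly monotone transforms
  expect_equal(kruskal_wallis(list(exp(a), exp(b)))$statistic, h, tolerance = 1e-10)
})

test_that("Mann-Whitney exact p equals full enumeration; symmetric; ties handled", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_true(r$exact)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(mw_enum_p(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  # every tie-free pair with n <= 5 matches the enumeration oracle
  set.seed(73)
  for (n1 in 1:5) {
    for (n2 in n1:5) {
      a <- stats::rnorm(n1); b <- stats::rnorm(n2)
      expect_equal(mann_whitney(a, b)$p_value, mw_enum_p(a, b),
                   tolerance = 1e-12,
                   label = sprintf("exact MW p (n1=%d, n2=%d)", n1, n2))
      expect_equal(mann_whitney(a, b)$p_value, mann_whitney(b, a)$p_value,
                   tolerance = 1e-12)
    }
  }
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_false(same$exact)
  expect_equal(same$p_value, 1)
})

test_that("Bonferroni correction is capped, monotone and never below raw", {
  pairs <- data.frame(group_a = letters[1:3], group_b = letters[4:6],
                      statistic = 0, p_raw = c(0.01, 0, 0.2))
  out <- bonferroni(pairs)
  expect_equal(out$p_corrected, c(0.03, 0, 0.6))
  expect_true(all(out$p_corrected >= out$p_raw))
  m21 <- data.frame(group_a = "a", group_b = "b", statistic = 0,
                    p_raw = rep(0.01, 21))
  expect_equal(bonferroni(m21)$p_corrected[1], 0.21)
  big <- data.frame(group_a = "a", group_b = "b", statistic = 0,
                    p_raw = rep(0.2, 10))
  expect_equal(bonferroni(big)$p_corrected[1], 1)
  # monotone in the number of comparisons
  expect_lte(bonferroni(m21[1:3, ])$p_corrected[1], bonferroni(m21)$p_corrected[1])
})

test_that("pairwise Mann-Whitney covers all unordered pairs", {
  set.seed(74)
  g <- rep(c("A", "B", "C", "D"), each = 6)
  v <- stats::rnorm(24) + 3 * (g == "D")
  tab <- pairwise_mann_whitney(v, g)
  expect_equal(nrow(tab), choose(4, 2))
  expect_true(all(tab$p_corrected >= tab$p_raw))
  d_rows <- tab[tab$group_a == "D" | tab$group_b == "D", ]
  expect_true(mean(d_rows$significant) > 0.5)
})

test_that("MANOVA collapses to the two-sample t-test for one response", {
  set.seed(75)
  g <- rep(c("A", "B"), each = 12)
  y <- stats::rnorm(24) + 0.8 * (g == "B")
  mv <- manova_oneway(matrix(y, ncol = 1), g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(mv$wilks$F_approx, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(mv$wilks$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(mv$followups$p_value[1], tt$p.value, tolerance = 1e-10)
})

test_that("MANOVA flags an injected single-channel shift and errors on singularity", {
  set.seed(76)
  g <- rep(c("A", "B", "C"), each = 15)
  y <- matrix(stats::rnorm(45 * 3), 45, 3,
              dimnames = list(NULL, c("r1", "r2", "r3")))
  y[g == "C", 2] <- y[g == "C", 2] + 3  # >= 3 pooled SD shift
  mv <- manova_oneway(y, g)
  expect_true(mv$wilks$significant)
  expect_true(mv$followups$significant[mv$followups$response == "r2"])
  expect_false(mv$followups$p_value[1] < 1e-4)  # null channel not wildly significant
  # more responses than residual df -> explicit singularity advice
  g2 <- rep(c("A", "B"), each = 3)
  y2 <- matrix(stats::rnorm(6 * 8), 6, 8)
  expect_error(manova_oneway(y2, g2), "singular")
})

test_that("Tukey HSD separates shifted groups and degrades gracefully", {
  set.seed(77)
  g <- rep(c("A", "B", "C"), each = 10)
  v <- stats::rnorm(30) + 5 * (g == "C")
  tk <- tukey_hsd(v, g)
  expect_equal(nrow(tk), 3)
  ab <- tk[(tk$group_a == "A" & tk$group_b == "B"), ]
  expect_false(ab$significant)
  expect_true(all(tk$significant[tk$group_a == "C" | tk$group_b == "C"]))
  # degenerate zero-variance case
  expect_warning(dg <- tukey_hsd(rep(c(1, 1, 2), each = 3),
                                 rep(c("A", "B", "C"), each = 3)),
                 "zero within-group variance")
  expect_equal(dg$p_adj[dg$group_a == "A" & dg$group_b == "B"], 1)
  expect_equal(dg$p_adj[dg$group_a == "A" & dg$group_b == "C"], 0)
})

test_that("the study report implements the full analysis plan", {
  cfg <- tiny_config(seed = 78)
  ds <- generate_study(cfg)
  oc <- process_study(ds)
  rep <- run_study_stats(oc, ds$discomfort)
  expect_s3_class(rep, "stats_report")
  # exclusion matches the generated phenotype assignment
  expect_setequal(rep$excluded,
                  ds$participants$pid[ds$participants$phenotype == "cocontractor"])
  # force tests exclude NoExo and cover both outcomes and phases
  expect_setequal(names(rep$forces),
                  c("peak_FS_N.lift", "peak_FW_N.lift",
                    "peak_FS_N.lower", "peak_FW_N.lower"))
  f <- rep$forces[["peak_FS_N.lift"]]
  expect_false("NoExo" %in% names(f$group_means))
  expect_s3_class(f$kruskal, "exo_test_result")
  if (f$kruskal$significant) {
    expect_equal(nrow(f$pairwise), choose(6, 2))
  }
  # discomfort segments retained and tested
  expect_true(all(c("LB", "LS", "RS") %in% rep$discomfort$retained))
  expect_error(run_study_stats(oc[, 1:3]), "missing columns")
})
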