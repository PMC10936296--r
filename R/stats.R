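# Study statistics: normality screening, nonparametric omnibus and pairwise
# tests with Bonferroni correction, MANOVA with per-muscle follow-ups, and
# the co-contractor exclusion rule.  Thin, schema-stable fronts over the
# base-R tests so the whole study report has one shape.

test_result <- function(test, statistic, df = NULL, p_value, alpha = 0.05, extra = list()) {
  structure(c(list(test = test, statistic = unname(statistic), df = df,
                   p_value = unname(p_value), alpha = alpha,
                   significant = unname(p_value) < alpha), extra),
            class = "exo_test_result")
}

#' @export
print.exo_test_result <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else sprintf(" (df %s)", paste(round(x$df, 2), collapse = ", "))
  cat(sprintf("%s: statistic %.4g%s, p = %.4g%s\n", x$test, x$statistic, dfs,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Gatekeeper for choosing nonparametric tests; requires 3 <= n <= 5000.
#'
#' @param x numeric sample.
#' @param alpha significance level.
#' @return An `exo_test_result` with the W statistic.
#' @export
shapiro_wilk <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  res <- stats::shapiro.test(x)
  test_result("Shapiro-Wilk", res$statistic, p_value = res$p.value, alpha = alpha)
}

#' Kruskal-Wallis rank-sum test
#'
#' Omnibus nonparametric comparison of `k >= 2` groups, with mid-rank tie
#' correction and a chi-square reference on `k - 1` df.  All observations
#' identical gives H = 0, p = 1.
#'
#' @param values numeric observations, or a list of group samples.
#' @param groups group labels (ignored when `values` is a list).
#' @param alpha significance level.
#' @return An `exo_test_result` with the H statistic.
#' @export
kruskal_wallis <- function(values, groups = NULL, alpha = 0.05) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(unique(values)) == 1L) {
    return(test_result("Kruskal-Wallis", c(H = 0), df = nlevels(groups) - 1L,
                       p_value = 1, alpha = alpha))
  }
  res <- stats::kruskal.test(values, groups)
  test_result("Kruskal-Wallis", c(H = unname(res$statistic)),
              df = unname(res$parameter), p_value = res$p.value, alpha = alpha)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact two-sided p by full enumeration of the U null distribution when
#' `min(n) <= exact_threshold` and the pooled sample has no ties; otherwise
#' the normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param a,b numeric samples.
#' @param exact_threshold largest `min(n)` for which the exact p is used.
#' @param alpha significance level.
#' @return An `exo_test_result` with the U statistic (`a` over `b`) and an
#'   `exact` flag.
#' @export
mann_whitney <- function(a, b, exact_threshold = 8, alpha = 0.05) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && min(length(a), length(b)) <= exact_threshold
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  test_result("Mann-Whitney", c(U = unname(res$statistic)),
              p_value = min(res$p.value, 1), alpha = alpha,
              extra = list(exact = exact))
}

#' Bonferroni-corrected pairwise table
#'
#' `corrected_p = min(1, m * raw_p)` with `m` the number of comparisons.
#'
#' @param pairs data frame with columns `group_a`, `group_b`, `statistic`,
#'   `p_raw` (e.g. assembled from [mann_whitney()] calls).
#' @param alpha significance level.
#' @return The table with `p_corrected` and `significant` columns.
#' @export
bonferroni <- function(pairs, alpha = 0.05) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1L, "p_raw" %in% names(pairs))
  pairs$p_corrected <- pmin(1, pairs$p_raw * nrow(pairs))
  pairs$significant <- pairs$p_corrected < alpha
  pairs
}

#' All pairwise Mann-Whitney comparisons with Bonferroni correction
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param exact_threshold passed to [mann_whitney()].
#' @param alpha significance level.
#' @return Pairwise table (see [bonferroni()]), one row per unordered pair.
#' @export
pairwise_mann_whitney <- function(values, groups, exact_threshold = 8, alpha = 0.05) {
  groups <- factor(groups)
  lv <- levels(groups)
  if (length(lv) < 2) stop("need at least 2 groups")
  cmb <- utils::combn(lv, 2)
  rows <- apply(cmb, 2L, function(pr) {
    mw <- mann_whitney(values[groups == pr[1L]], values[groups == pr[2L]],
                       exact_threshold, alpha)
    data.frame(group_a = pr[1L], group_b = pr[2L], statistic = mw$statistic,
               p_raw = mw$p_value, stringsAsFactors = FALSE)
  })
  bonferroni(do.call(rbind, rows), alpha)
}

#' One-way MANOVA (Wilks' lambda) with per-response follow-up ANOVAs
#'
#' Tests a multivariate response (the 8 nRMS channels) against a grouping
#' factor using Wilks' lambda and its standard F transform, then runs a
#' one-way ANOVA per response column.
#'
#' @param responses numeric matrix (observations x responses).
#' @param groups group labels, length `nrow(responses)`.
#' @param alpha significance level.
#' @return List of class `exo_manova`: `wilks` (an `exo_test_result` with
#'   lambda, the F approximation and its df) and `followups` (data frame of
#'   per-response F tests).
#' @export
manova_oneway <- function(responses, groups, alpha = 0.05) {
  responses <- as.matrix(responses)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (nrow(responses) != length(groups)) stop("responses/groups length mismatch")
  if (ncol(responses) == 1L) {
    # univariate edge case: Wilks reduces to the one-way ANOVA F
    y <- responses[, 1L]
    a <- stats::anova(stats::aov(y ~ groups))
    ss_h <- a[["Sum Sq"]][1L]; ss_e <- a[["Sum Sq"]][2L]
    wilks <- test_result(
      "MANOVA (Wilks)", c(lambda = ss_e / (ss_e + ss_h)),
      df = c(num = a$Df[1L], den = a$Df[2L]),
      p_value = a[["Pr(>F)"]][1L], alpha = alpha,
      extra = list(F_approx = a[["F value"]][1L])
    )
    followups <- data.frame(response = colnames(responses)[1L] %||% "V1",
                            F_value = a[["F value"]][1L], df1 = a$Df[1L],
                            df2 = a$Df[2L], p_value = a[["Pr(>F)"]][1L],
                            stringsAsFactors = FALSE)
    followups$significant <- followups$p_value < alpha
    return(structure(list(wilks = wilks, followups = followups),
                     class = "exo_manova"))
  }
  fit <- stats::manova(responses ~ groups)
  sm <- tryCatch(summary(fit, test = "Wilks"),
                 error = function(e) {
                   stop("pooled within-group covariance is singular; reduce the ",
                        "response dimension or pool groups (", conditionMessage(e), ")")
                 })
  st <- sm$stats
  wilks <- test_result(
    "MANOVA (Wilks)", c(lambda = st[1L, "Wilks"]),
    df = c(num = st[1L, "num Df"], den = st[1L, "den Df"]),
    p_value = st[1L, "Pr(>F)"], alpha = alpha,
    extra = list(F_approx = st[1L, "approx F"])
  )
  followups <- do.call(rbind, lapply(seq_len(ncol(responses)), function(j) {
    a <- stats::anova(stats::aov(responses[, j] ~ groups))
    data.frame(response = colnames(responses)[j] %||% paste0("V", j),
               F_value = a[["F value"]][1L], df1 = a$Df[1L], df2 = a$Df[2L],
               p_value = a[["Pr(>F)"]][1L], stringsAsFactors = FALSE)
  }))
  followups$significant <- followups$p_value < alpha
  structure(list(wilks = wilks, followups = followups), class = "exo_manova")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.exo_manova <- function(x, ...) {
  print(x$wilks)
  cat("follow-up ANOVAs:\n")
  print(x$followups, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range test on all group pairs with pooled within-group
#' variance.  Zero within-group variance is degenerate: the function warns
#' and reports p = 0 for pairs with unequal means, p = 1 otherwise.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param alpha significance level.
#' @return Data frame `group_a`, `group_b`, `diff`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  mse <- suppressWarnings(stats::anova(stats::aov(values ~ groups))[["Mean Sq"]][2L])
  if (mse <= 1e-12 * max(stats::var(values), .Machine$double.xmin)) {
    warning("zero within-group variance; reporting degenerate p-values")
    mns <- tapply(values, groups, mean)
    cmb <- utils::combn(levels(groups), 2)
    out <- data.frame(group_a = cmb[1L, ], group_b = cmb[2L, ],
                      diff = mns[cmb[2L, ]] - mns[cmb[1L, ]],
                      stringsAsFactors = FALSE)
    out$p_adj <- ifelse(out$diff == 0, 1, 0)
  } else {
    tk <- stats::TukeyHSD(stats::aov(values ~ groups))$groups
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    out <- data.frame(group_a = vapply(nm, `[`, "", 2L),
                      group_b = vapply(nm, `[`, "", 1L),
                      diff = tk[, "diff"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE)
  }
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Run the full study statistics
#'
#' Implements the study's analysis plan on a processed outcomes table:
#' \enumerate{
#'   \item Repetitions are averaged per participant x condition x phase
#'     (avoids pseudo-replication).
#'   \item Device-to-body forces (`peak_FS_N`, `peak_FW_N`; exosuit
#'     configurations only) and retained discomfort segments: Shapiro-Wilk
#'     normality screen, Kruskal-Wallis omnibus across configurations, and
#'     -- where the omnibus is significant -- Mann-Whitney pairwise
#'     comparisons with Bonferroni correction.
#'   \item EMG nRMS: participants classified as co-contractors by
#'     [phenotype_classify()] are excluded, then per phase a one-way MANOVA
#'     (Wilks) over the 8 channels across all conditions with per-channel
#'     follow-up ANOVAs and Tukey HSD pairwise tests.
#' }
#'
#' @param outcomes outcomes table from [process_study()].
#' @param discomfort long-format discomfort reports (see
#'   [filter_segments()]); optional.
#' @param alpha significance level for every test.
#' @param exclude_cocontractors apply the EMG exclusion rule.
#' @param exact_threshold passed to [mann_whitney()].
#' @return List of class `stats_report` with elements `phenotypes`,
#'   `excluded`, `forces`, `discomfort`, `emg` and `alpha`.
#' @export
run_study_stats <- function(outcomes, discomfort = NULL, alpha = 0.05,
                            exclude_cocontractors = TRUE, exact_threshold = 8) {
  need <- c("pid", "condition", "repetition", "phase", "peak_FS_N", "peak_FW_N")
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) stop("outcomes table missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(outcomes$condition)) < 2) stop("need at least 2 conditions")
  nrms_cols <- grep("^nRMS_.*_pct$", names(outcomes), value = TRUE)

  phen <- phenotype_classify(outcomes)
  excluded <- phen$pid[phen$phenotype == "cocontractor"]

  # repetition averaging
  num_cols <- c("peak_FS_N", "peak_FW_N", nrms_cols)
  avg <- stats::aggregate(outcomes[num_cols],
                          outcomes[c("pid", "condition", "phase")], mean)

  # --- forces: exo configurations only (NoExo has no device force)
  exo <- avg[avg$condition != "NoExo", , drop = FALSE]
  forces <- list()
  for (phase in unique(exo$phase)) {
    d <- exo[exo$phase == phase, , drop = FALSE]
    for (outc in c("peak_FS_N", "peak_FW_N")) {
      kw <- kruskal_wallis(d[[outc]], d$condition, alpha)
      entry <- list(
        shapiro = shapiro_wilk(d[[outc]], alpha),
        kruskal = kw,
        group_means = sort(tapply(d[[outc]], d$condition, mean)),
        pairwise = if (kw$significant) {
          pairwise_mann_whitney(d[[outc]], d$condition, exact_threshold, alpha)
        }
      )
      forces[[paste(outc, phase, sep = ".")]] <- entry
    }
  }

  # --- discomfort: retained segments, single combined lift+lower score
  disc <- NULL
  if (!is.null(discomfort) && nrow(discomfort)) {
    retained <- filter_segments(discomfort)
    disc <- list(retained = retained,
                 summary = summarize_discomfort(discomfort, retained),
                 tests = list())
    for (seg in retained) {
      d <- discomfort[discomfort$reported & discomfort$segment == seg, , drop = FALSE]
      d <- stats::aggregate(vas ~ pid + condition, d, mean)
      if (length(unique(d$condition)) < 2) next
      kw <- kruskal_wallis(d$vas, d$condition, alpha)
      disc$tests[[seg]] <- list(
        kruskal = kw,
        pairwise = if (kw$significant) {
          pairwise_mann_whitney(d$vas, d$condition, exact_threshold, alpha)
        }
      )
    }
  }

  # --- EMG: exclusion rule, then MANOVA + Tukey per phase
  emg <- NULL
  if (length(nrms_cols)) {
    keep <- if (exclude_cocontractors) !(avg$pid %in% excluded) else rep(TRUE, nrow(avg))
    emg_avg <- avg[keep, , drop = FALSE]
    emg <- list()
    for (phase in unique(emg_avg$phase)) {
      d <- emg_avg[emg_avg$phase == phase, , drop = FALSE]
      mv <- tryCatch(manova_oneway(as.matrix(d[nrms_cols]), d$condition, alpha),
                     error = function(e) conditionMessage(e))
      if (is.character(mv)) {
        emg[[phase]] <- list(error = mv)
        next
      }
      tukey <- lapply(stats::setNames(nrms_cols, nrms_cols), function(cn) {
        tukey_hsd(d[[cn]], d$condition, alpha)
      })
      emg[[phase]] <- list(manova = mv, tukey = tukey)
    }
  }

  structure(list(phenotypes = phen, excluded = excluded, forces = forces,
                 discomfort = disc, emg = emg, alpha = alpha),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report> alpha =", x$alpha, "\n")
  cat(sprintf("  excluded (co-contractors): %s\n",
              if (length(x$excluded)) paste(x$excluded, collapse = ", ") else "none"))
  for (nm in names(x$forces)) {
    f <- x$forces[[nm]]
    cat(sprintf("  %s: H = %.3f, p = %.4g%s\n", nm, f$kruskal$statistic,
                f$kruskal$p_value, if (f$kruskal$significant) " *" else ""))
  }
  if (!is.null(x$discomfort)) {
    cat("  retained discomfort segments:",
        paste(x$discomfort$retained, collapse = ", "), "\n")
  }
  if (!is.null(x$emg)) {
    for (phase in names(x$emg)) {
      if (!is.null(x$emg[[phase]]$error)) {
        cat(sprintf("  EMG %s: not testable (%s)\n", phase, x$emg[[phase]]$error))
        next
      }
      w <- x$emg[[phase]]$manova$wilks
      cat(sprintf("  EMG %s: Wilks lambda = %.4f, p = %.4g%s\n", phase,
                  w$statistic, w$p_value, if (w$significant) " *" else ""))
    }
  }
  invisible(x)
}
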