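# constructed group data forcing each branch of the decision cascade;
# groups are standardised to exact sample mean/sd so the variance gate is
# forced by construction, not by luck of the draw
cascade_data <- function(branch, n = 15, k = 4) {
  withr::with_seed(51, {
    g <- rep(LETTERS[1:k], each = n)
    # one standardised normal vector, reused affinely per group: groups
    # with equal scale then have *identical* absolute deviations, so the
    # Levene gate outcome is forced by construction
    z <- as.vector(scale(rnorm(n)))
    norm_group <- function(s, mu = 10) z * s + mu
    x <- switch(branch,
      normal_equal = unlist(lapply(seq_len(k),
                                   function(i) norm_group(1, 10 + 0.1 * i))),
      normal_unequal = unlist(lapply(c(0.2, 0.2, 0.2, 4), norm_group)),
      nonnormal = c(unlist(lapply(rep(1, k - 1), norm_group)),
                    exp(rnorm(n, 0, 1.5)) + 8),
      nonnormal_unequal = c(unlist(lapply(rep(0.2, k - 1), norm_group)),
                            exp(rnorm(n, 0, 2)) + 8))
    list(x = x, g = g)
  })
}

test_that("the cascade selects the omnibus/post-hoc pair for every gate
           combination", {
  d <- cascade_data("normal_equal")
  p <- plan_comparison(d$x, d$g)
  expect_true(p$normality_ok); expect_true(p$variance_ok)
  expect_equal(p$omnibus, "ONEWAY_ANOVA")
  expect_equal(p$posthoc, "TUKEY_HSD")

  d <- cascade_data("normal_unequal")
  p <- plan_comparison(d$x, d$g)
  expect_true(p$normality_ok); expect_false(p$variance_ok)
  expect_equal(p$omnibus, "WELCH_ANOVA")
  expect_equal(p$posthoc, "GAMES_HOWELL")

  for (branch in c("nonnormal", "nonnormal_unequal")) {
    d <- cascade_data(branch)
    p <- plan_comparison(d$x, d$g)
    expect_false(p$normality_ok)
    expect_equal(p$omnibus, "KRUSKAL_WALLIS")
    expect_equal(p$posthoc, "BONFERRONI_PAIRWISE")
  }
})

test_that("gate decisions agree with direct Shapiro-Wilk and Levene tests", {
  d <- cascade_data("normal_unequal")
  p <- plan_comparison(d$x, d$g, alpha = 0.05)
  for (g in unique(d$g)) {
    expect_equal(p$shapiro$shapiro_p[p$shapiro$group == g],
                 shapiro.test(d$x[d$g == g])$p.value, tolerance = 1e-12)
  }
  lev <- car::leveneTest(d$x ~ factor(d$g), center = mean)
  expect_equal(p$levene_p, lev[["Pr(>F)"]][1], tolerance = 1e-12)
})

test_that("near-ceiling skewed efficiency-like data takes the non-normal
           branch", {
  withr::with_seed(52, {
    # conversion efficiencies bunched against 100% with a left tail
    x <- pmin(100, 100 - rexp(60, rate = 2))
    g <- rep(paste0("kit", 1:4), each = 15)
    p <- plan_comparison(x, g)
    expect_equal(p$omnibus, "KRUSKAL_WALLIS")
  })
})

test_that("undersized or single groups are rejected naming the kit", {
  expect_error(plan_comparison(rnorm(10), rep("A", 10)), ">= 2 groups")
  expect_error(plan_comparison(c(rnorm(5), 1, 2), c(rep("A", 5), "B", "B")),
               "B")
})

test_that("identical groups yield maximal p-values and no significant pairs", {
  x <- rep(7, 20); g <- rep(c("A", "B"), each = 10)
  r <- run_comparison(x, g)
  expect_equal(r$omnibus_p, 1)
  expect_true(all(r$pairwise$tier == "ns"))
})

test_that("a strongly shifted group is significant against every other at
           the smallest tier", {
  withr::with_seed(53, {
    n <- 12
    x <- c(rnorm(3 * n, 0, 1), rnorm(n, 10, 1))  # 10 pooled SDs away
    g <- rep(c("A", "B", "C", "D"), each = n)
    r <- run_comparison(x, g)
    expect_lt(r$omnibus_p, 0.001)
    vs_d <- r$pairwise[r$pairwise$group1 == "D" | r$pairwise$group2 == "D", ]
    expect_equal(nrow(vs_d), 3)
    expect_true(all(vs_d$tier == "***"))
  })
})

test_that("Bonferroni adjustment is min(1, m*p) and never below the raw p", {
  withr::with_seed(54, {
    x <- rnorm(30); g <- rep(c("A", "B", "C"), each = 10)
    plan <- plan_comparison(c(x, exp(rnorm(10, 0, 2))),
                            c(g, rep("D", 10)))
    expect_equal(plan$omnibus, "KRUSKAL_WALLIS")
    xx <- c(x, exp(rnorm(10, 0, 2))); gg <- c(g, rep("D", 10))
    r <- run_comparison(xx, gg, plan = plan)
    raw <- suppressWarnings(
      pairwise.wilcox.test(xx, factor(gg), p.adjust.method = "none",
                           exact = FALSE))$p.value
    adj <- r$pairwise
    for (i in seq_len(nrow(adj))) {
      p_raw <- raw[adj$group2[i], adj$group1[i]]
      expect_equal(adj$p[i], min(1, 6 * p_raw), tolerance = 1e-9)
      expect_gte(adj$p[i], p_raw)
    }
  })
})

test_that("Games-Howell reduces to the Welch t-test for two groups and is
           permutation invariant", {
  withr::with_seed(55, {
    x <- c(rnorm(10, 0, 1), rnorm(14, 1.2, 3))
    g <- rep(c("A", "B"), c(10, 14))
    gh <- games_howell(x, g)
    tt <- t.test(x[g == "A"], x[g == "B"], var.equal = FALSE)
    # with k = 2 the studentized range is sqrt(2)|t| with the same df
    expect_equal(gh$statistic, sqrt(2) * abs(unname(tt$statistic)),
                 tolerance = 1e-9)
    expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-9)
    expect_equal(gh$p, tt$p.value, tolerance = 1e-9)

    # group relabelling/order must not change any p-value
    x3 <- c(x, rnorm(12, 0.5, 2)); g3 <- c(g, rep("C", 12))
    perm <- sample(length(x3))
    a <- games_howell(x3, g3)
    b <- games_howell(x3[perm], g3[perm])
    key <- function(d) d[order(d$group1, d$group2), c("group1", "group2", "p")]
    expect_equal(key(a), key(b), tolerance = 1e-12)
  })
})

test_that("compare_kits runs the full cascade per metric on a results table", {
  withr::with_seed(56, {
    res <- tibble::tibble(
      kit = rep(c("K1", "K2", "K3"), each = 8),
      conversion_efficiency = pmin(100, 100 - rexp(24, 1)),
      degradation_level = rlnorm(24, log(1.4), 0.2),
      recovery = rnorm(24, rep(c(50, 45, 20), each = 8), 5))
    cmp <- compare_kits(res)
    expect_named(cmp, c("conversion_efficiency", "degradation_level",
                        "recovery"))
    expect_s3_class(cmp$recovery, "comparison_result")
    # K3 recovery sits 5+ SDs below the others
    vs3 <- cmp$recovery$pairwise
    vs3 <- vs3[vs3$group1 == "K3" | vs3$group2 == "K3", ]
    expect_true(all(vs3$p < 0.05))
    expect_error(compare_kits(res[res$kit == "K1", ]), ">= 2 kits")
  })
})
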