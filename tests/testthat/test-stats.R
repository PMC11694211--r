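test_that("normality gate routes clean normal data to RM-ANOVA", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    choose_test(matrix(rnorm(64), 16, 4)) == "rm_anova"
  }, logical(1))
  # all four independent columns must pass Shapiro-Wilk at alpha = 0.05, so
  # the parametric branch is taken with probability 0.95^4 = 0.8145
  expect_lt(abs(mean(hits) - 0.95^4), 0.10)
})

test_that("normality gate routes skewed or degenerate data to Friedman", {
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    tab <- matrix(rnorm(64), 16, 4)
    tab[, 2] <- exp(tab[, 2] * 1.5)   # log-normal column
    choose_test(tab) == "friedman"
  }, logical(1))
  expect_gt(mean(hits), 0.5)

  tab <- matrix(rnorm(64), 16, 4)
  tab[, 3] <- 2
  expect_identical(choose_test(tab), "friedman")
  expect_error(choose_test(matrix(rnorm(8), 2, 4)), "at least 3")
})

# brute-force sums-of-squares oracle, written with explicit loops
.ss_oracle <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  ss_cond <- 0
  for (j in seq_len(k)) ss_cond <- ss_cond + n * (mean(tab[, j]) - grand)^2
  ss_subj <- 0
  for (i in seq_len(n)) ss_subj <- ss_subj + k * (mean(tab[i, ]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (tab[i, j] - grand)^2
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  list(f = f, eta = ss_cond / (ss_cond + ss_err),
       p = pf(f, k - 1, (k - 1) * (n - 1), lower.tail = FALSE))
}

test_that("rm_anova equals explicit sums-of-squares arithmetic", {
  for (s in 1:100) {
    set.seed(s)
    tab <- matrix(rnorm(20, sd = runif(1, 0.5, 3)), 5, 4)
    got <- rm_anova(tab)
    want <- .ss_oracle(tab)
    expect_equal(got$statistic, want$f, tolerance = 1e-10)
    expect_equal(got$effect_size, want$eta, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("rm_anova agrees with the aov error-stratum fit", {
  for (s in 1:25) {
    set.seed(s)
    tab <- matrix(rnorm(24), 6, 4)
    got <- rm_anova(tab)
    d <- data.frame(y = as.vector(tab),
                    subj = factor(rep(1:6, 4)),
                    cond = factor(rep(1:4, each = 6)))
    fit <- summary(stats::aov(y ~ cond + Error(subj/cond), data = d))
    strat <- fit[["Error: subj:cond"]][[1]]
    expect_equal(got$statistic, strat["cond", "F value"], tolerance = 1e-8)
    expect_equal(got$p_value, strat["cond", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("rm_anova handles degenerate tables as specified", {
  same <- matrix(rep(rnorm(6), 4), 6, 4)   # identical columns
  got <- rm_anova(same)
  expect_equal(got$statistic, 0)
  expect_equal(got$effect_size, 0)
  expect_equal(got$p_value, 1)

  # condition effect with no subject-by-condition variability
  tab <- outer(rnorm(5), c(0, 1, 0, 2), "+")
  expect_error(rm_anova(tab), "degenerate")

  # within-subject invariance: per-subject offsets leave F unchanged
  set.seed(1)
  tab2 <- matrix(rnorm(20), 5, 4)
  shifted <- tab2 + rnorm(5) * 10
  expect_equal(rm_anova(tab2)$statistic, rm_anova(shifted)$statistic,
               tolerance = 1e-9)
})

test_that("friedman statistic matches hand-ranked arithmetic and friedman.test", {
  tab <- rbind(c(1, 2, 3), c(1, 2, 3), c(2, 1, 3))
  # row ranks (1,2,3),(1,2,3),(2,1,3): column rank sums 4,5,9
  hand <- 12 / (3 * 3 * 4) * sum((c(4, 5, 9) - 3 * 4 / 2)^2)
  got <- friedman_test(tab)
  expect_equal(got$statistic, hand, tolerance = 1e-12)
  expect_equal(got$effect_size, hand / (3 * 2), tolerance = 1e-12)

  expect_equal(friedman_test(matrix(rep(1:4, 4), 4, 4, byrow = TRUE))$statistic,
               friedman_test(matrix(rep(4:1, 4), 4, 4, byrow = TRUE))$statistic)
  expect_equal(friedman_test(matrix(5, 4, 4))$statistic, 0)

  for (s in 1:20) {
    set.seed(s)
    tab <- matrix(round(rnorm(32), 1), 8, 4)  # rounding induces ties
    got <- friedman_test(tab)
    ref <- stats::friedman.test(tab)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("post hocs cover all six pairs with Bonferroni adjustment", {
  set.seed(2)
  tab <- matrix(rnorm(40), 10, 4,
                dimnames = list(NULL, snatch_conditions()))
  ph <- posthoc(tab, "rm_anova")
  expect_identical(nrow(ph), 6L)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 6))
  expect_true(all(ph$p_adj <= 1))

  tab[, 2] <- tab[, 1]                      # identical pair
  phw <- posthoc(tab, "friedman")
  expect_equal(phw$p_raw[phw$pair == "RL vs bCI"], 1)
})

test_that("a planted shift is flagged by the post hocs", {
  flagged <- vapply(1:30, function(s) {
    set.seed(s)
    tab <- matrix(rnorm(64), 16, 4,
                  dimnames = list(NULL, snatch_conditions()))
    tab[, 4] <- tab[, 4] + 2               # d = 2 shift in DL
    ph <- posthoc(tab, "rm_anova")
    dl <- grepl("DL", ph$pair)
    all(ph$p_adj[dl] < 0.05)
  }, logical(1))
  expect_gte(mean(flagged), 0.8)
})

test_that("analyze_variable gates the post hocs on omnibus significance", {
  set.seed(3)
  null_tab <- matrix(rnorm(40), 10, 4)
  r0 <- analyze_variable(null_tab + 100)   # null: almost surely ns
  if (r0$p_value >= 0.05) expect_null(r0$posthoc)
  eff <- matrix(rnorm(40), 10, 4); eff[, 1] <- eff[, 1] + 5
  r1 <- analyze_variable(eff)
  expect_lt(r1$p_value, 0.05)
  expect_identical(nrow(r1$posthoc), 6L)
})

test_that("the full battery keeps its type-I error under the global null", {
  rejections <- vapply(1:2000, function(s) {
    set.seed(100000 + s)
    tab <- matrix(rnorm(64), 16, 4)
    analyze_variable(tab)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("variable_table aggregates by the chosen unit of analysis", {
  feats <- expand.grid(subject_id = sprintf("S%02d", 1:5),
                       condition = snatch_conditions(), trial_index = 1:3,
                       stringsAsFactors = FALSE)
  set.seed(4)
  feats$V_max <- rnorm(nrow(feats), 3.15, 0.3)
  tab_s <- variable_table(feats, "V_max", "subject_mean")
  expect_identical(dim(tab_s), c(5L, 4L))
  m <- with(feats, mean(V_max[subject_id == "S01" & condition == "DL"]))
  expect_equal(tab_s["S01", "DL"], m)
  tab_t <- variable_table(feats, "V_max", "trial")
  expect_identical(dim(tab_t), c(15L, 4L))
  expect_error(variable_table(feats, "nope"), "no column")
})

test_that("snatch_study assembles a full per-variable summary", {
  set.seed(8)
  feats <- expand.grid(subject_id = sprintf("S%02d", 1:8),
                       condition = snatch_conditions(), trial_index = 1:3,
                       stringsAsFactors = FALSE)
  feats$V_max <- rnorm(nrow(feats), 3.15, 0.3)
  feats$X1 <- rnorm(nrow(feats), -0.3, 3)
  feats$X2 <- rnorm(nrow(feats), -16, 3)
  feats$X3_DxT <- rnorm(nrow(feats), 9, 3)
  st <- snatch_study(feats, variables = c("V_max", "X1"))
  expect_s3_class(st, "snatch_study")
  expect_identical(st$table$variable, c("V_max", "X1"))
  expect_true(all(st$table$p_value >= 0 & st$table$p_value <= 1))
  expect_identical(nrow(st$adherence), 4L)
  expect_output(print(st), "V_max")
  expect_identical(as.data.frame(st), st$table)
})
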