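# One-way random-effects ICC and the reliability analyses built on it.

test_that("ICC: hand-worked ANOVA decompositions", {
  # identical sessions with between-subject spread: perfect reliability
  r <- icc(cbind(1:3, 1:3))
  expect_equal(r$icc, 1)
  expect_equal(r$ms_within, 0)
  # shifted sessions: MS_b = 2, MS_w = 0.5, ICC = 0.6
  r <- icc(cbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(r$ms_between, 2)
  expect_equal(r$ms_within, 0.5)
  expect_equal(r$icc, 0.6)
  expect_false(r$clamped)
  # equal subject means: raw ICC < 0, clamped to zero
  r <- icc(cbind(c(1, 2), c(2, 1)))
  expect_equal(r$icc, 0)
  expect_true(r$clamped)
  expect_lt(r$raw, 0)
})

test_that("ICC handles degenerate and invalid tables", {
  r <- icc(matrix(5, 3, 2))
  expect_true(is.na(r$icc))
  expect_error(icc(matrix(1:4, 1)), "2 subjects")
  expect_error(icc(cbind(c(1, NA), c(2, 3))), "complete")
})

test_that("ICC agrees with aov() on random tables", {
  set.seed(40)
  for (rep in 1:5) {
    tab <- matrix(rnorm(20 * 3), 20, 3)
    fit <- summary(aov(y ~ Error(subj),
                       data = data.frame(y = as.vector(tab),
                                         subj = factor(rep(1:20, 3)))))
    ms_b <- fit[[1]][[1]]["Residuals", "Mean Sq"]
    ms_w <- fit[[2]][[1]]["Residuals", "Mean Sq"]
    r <- icc(tab)
    expect_equal(r$ms_between, ms_b, tolerance = 1e-10)
    expect_equal(r$ms_within, ms_w, tolerance = 1e-10)
  }
})

test_that("ICC estimator recovers planted variance ratios", {
  set.seed(41)
  for (rho in c(0.2, 0.5, 0.8)) {
    est <- replicate(100, {
      subj <- rnorm(1000, 0, sqrt(rho))
      icc(subj + matrix(rnorm(2000, 0, sqrt(1 - rho)), 1000, 2))$icc
    })
    expect_lt(abs(mean(est) - rho), 0.02)
  }
})

test_that("ICC is invariant under a common positive affine transform", {
  set.seed(42)
  tab <- matrix(rnorm(30), 15, 2) + rnorm(15)
  expect_equal(icc(3.2 * tab - 7)$icc, icc(tab)$icc, tolerance = 1e-10)
})

test_that("grades partition [0,1] with the stated boundaries", {
  expect_equal(icc_grade(c(0, 0.2499, 0.25, 0.399, 0.4, 0.599, 0.6,
                           0.749, 0.75, 1)),
               c("poor", "poor", "low", "low", "fair", "fair", "good",
                 "good", "excellent", "excellent"))
  expect_error(icc_grade(1.1), "0, 1")
  expect_error(icc_grade(-0.2), "0, 1")
  # no gaps: every value on a fine grid gets exactly one grade
  expect_false(anyNA(icc_grade(seq(0, 1, by = 1e-3))))
})

make_cms <- function(n_sub, n_ch, icc_target, seed, noise = 0.1) {
  set.seed(seed)
  base <- array(0, c(n_sub, 2, n_ch, n_ch))
  for (i in seq_len(n_sub)) {
    subj <- matrix(rnorm(n_ch^2, 0, sqrt(icc_target)), n_ch)
    subj <- (subj + t(subj)) / 2
    for (s in 1:2) {
      sess <- matrix(rnorm(n_ch^2, 0, sqrt(1 - icc_target)), n_ch)
      m <- subj + (sess + t(sess)) / 2
      diag(m) <- 1
      base[i, s, , ] <- m
    }
  }
  base
}

test_that("edge reliability returns one result per unique connection", {
  cms <- make_cms(8, 10, 0.6, seed = 43)
  er <- edge_reliability(cms)
  expect_equal(nrow(er$edges), 45)
  expect_true(all(er$edges$icc >= 0 & er$edges$icc <= 1))
  expect_equal(sum(er$summary$grade_counts), 45)
  expect_equal(sum(er$summary$grade_fractions), 1)
})

test_that("edge reliability recovers planted levels monotonically", {
  means <- sapply(c(0.2, 0.5, 0.8), function(rho)
    edge_reliability(make_cms(200, 8, rho, seed = 44))$summary$mean)
  expect_equal(means, c(0.2, 0.5, 0.8), tolerance = 0.05)
  expect_true(all(diff(means) > 0))
})

test_that("identical sessions give edge ICC 1 everywhere", {
  cms <- make_cms(6, 6, 0.5, seed = 45)
  cms[, 2, , ] <- cms[, 1, , ]
  er <- edge_reliability(cms)
  expect_true(all(er$edges$icc == 1))
  expect_true(all(er$edges$grade == "excellent"))
})

make_curves <- function(n_sub, grid, f_subject, f_noise, metric = "Cp",
                        seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_sub)) {
    off <- f_subject(i)
    for (s in 1:2) {
      rows[[length(rows) + 1]] <-
        data.frame(subject = i, session = s, metric = metric,
                   node = NA_integer_, sparsity = grid,
                   value = off + grid + f_noise())
    }
  }
  do.call(rbind, rows)
}

test_that("metric reliability: identical sessions give ICC 1; AUC-ICC is compositional", {
  grid <- sparsity_grid(0.1, 0.9, 0.1)
  curves <- make_curves(6, grid, function(i) i / 2, function() 0)
  mr <- metric_reliability(curves)
  expect_true(all(mr$profile$icc == 1))
  expect_equal(mr$auc$auc_icc, 1)
  # compositional identity: AUC-ICC equals icc() of the per-subject AUCs
  aucs <- sapply(1:2, function(s) sapply(1:6, function(i) {
    v <- curves$value[curves$subject == i & curves$session == s]
    as.numeric(curve_auc(v, grid))
  }))
  expect_equal(mr$auc$auc_icc, icc(aucs)$icc)
})

test_that("planted reliable vs unreliable metrics separate in AUC-ICC", {
  grid <- sparsity_grid(0.1, 0.9, 0.1)
  reliable <- make_curves(12, grid, function(i) i, function() rnorm(1, 0, 0.05),
                          metric = "hi", seed = 46)
  flat <- make_curves(12, grid, function(i) 0, function() rnorm(1, 0, 1),
                      metric = "lo", seed = 47)
  mr <- metric_reliability(rbind(reliable, flat))
  hi <- mr$auc$auc_icc[mr$auc$metric == "hi"]
  lo <- mr$auc$auc_icc[mr$auc$metric == "lo"]
  expect_gt(hi, 0.9)
  expect_lt(lo, 0.2)
})

test_that("sparsity points missing for any subject are dropped from profiles", {
  grid <- c(0.2, 0.4, 0.6)
  curves <- make_curves(5, grid, function(i) i, function() 0)
  curves$value[curves$subject == 3 & curves$sparsity == 0.4] <- NA
  mr <- metric_reliability(curves)
  expect_equal(sort(unique(mr$profile$sparsity)), c(0.2, 0.6))
})

test_that("session similarity: identical, independent and table shape", {
  cms <- make_cms(5, 12, 0.5, seed = 48)
  cms[, 2, , ] <- cms[, 1, , ]
  ss <- session_similarity(cms)
  expect_equal(nrow(ss), 6)
  expect_equal(ss$subject[6], "group")
  expect_true(all(abs(ss$r - 1) < 1e-12))
  # independent sessions on many edges: near-zero similarity
  set.seed(49)
  big <- make_cms(3, 46, 0.0, seed = 49)
  ss2 <- session_similarity(big)
  expect_true(all(abs(ss2$r[1:3]) < 0.1))
})

test_that("strength-reliability correlation detects a planted monotone map", {
  set.seed(50)
  strength <- runif(200, -0.2, 0.8)
  iccs <- pmin(1, pmax(0, 0.3 + 0.5 * strength + rnorm(200, 0, 0.02)))
  sr <- strength_reliability_correlation(iccs, strength)
  expect_gt(sr$r, 0.95)
  expect_lt(sr$p, 1e-10)
  # strength-independent reliability: near-zero correlation
  sr0 <- strength_reliability_correlation(runif(1000), runif(1000))
  expect_lt(abs(sr0$r), 0.1)
  expect_error(strength_reliability_correlation(rep(0.5, 5), runif(5)),
               "degenerate")
})

test_that("paired session tests: identity, closed form, and metric grid", {
  aucs <- expand.grid(subject = 1:5, session = 1:2,
                      metric = c("Cp", "Lp"))
  aucs$value <- aucs$subject * 1.0
  st <- session_difference_tests(aucs)
  expect_equal(st$t, c(0, 0))
  expect_equal(st$p, c(1, 1))
  # hand-worked differences {1,2,3}: t = 2 / (1/sqrt(3)) = 3.4641
  aucs2 <- data.frame(subject = rep(1:3, 2), session = rep(1:2, each = 3),
                      metric = "Cp",
                      value = c(2, 3, 4, 1, 1, 1))
  st2 <- session_difference_tests(aucs2)
  expect_equal(st2$t, 2 * sqrt(3), tolerance = 1e-4)
  expect_equal(st2$t, 3.4641, tolerance = 1e-4)
  # agrees with t.test
  tt <- t.test(c(2, 3, 4), c(1, 1, 1), paired = TRUE)
  expect_equal(st2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(st2$p, tt$p.value, tolerance = 1e-12)
})

test_that("repeated-measures ANOVA: null, planted effect, and post-hoc output", {
  # all cells identical: F = 0, p = 1
  tab <- expand.grid(unit = 1:10, metric = c("a", "b", "c"),
                     signal = c("x", "y", "z"))
  tab$value <- 0.5
  an <- reliability_anova(tab)
  expect_equal(an$effects$F, c(0, 0, 0))
  expect_equal(an$effects$p, c(1, 1, 1))
  expect_true(all(c("factor", "level_1", "level_2", "t", "p") %in%
                    names(an$posthoc)))
  # planted metric effect is detected with high power
  set.seed(51)
  hits <- 0
  for (rep in 1:40) {
    tab$value <- 0.6 + rnorm(nrow(tab), 0, 0.1)
    tab$value[tab$metric == "c"] <- tab$value[tab$metric == "c"] - 0.3
    an <- reliability_anova(tab)
    if (an$effects$p[an$effects$effect == "metric"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
  expect_error(reliability_anova(tab[-1, ]), "incomplete")
})

test_that("repeated-measures ANOVA matches aov() error strata", {
  set.seed(52)
  tab <- expand.grid(unit = 1:12, metric = c("a", "b", "c"),
                     signal = c("x", "y"))
  tab$value <- rnorm(nrow(tab)) +
    0.3 * (tab$metric == "b") + 0.2 * (tab$signal == "y")
  an <- reliability_anova(tab)
  fit <- summary(aov(value ~ metric * signal +
                       Error(factor(unit) / (metric * signal)), data = tab))
  f_metric <- fit[["Error: factor(unit):metric"]][[1]]["metric", "F value"]
  f_signal <- fit[["Error: factor(unit):signal"]][[1]]["signal", "F value"]
  expect_equal(an$effects$F[an$effects$effect == "metric"], f_metric,
               tolerance = 1e-8)
  expect_equal(an$effects$F[an$effects$effect == "signal"], f_signal,
               tolerance = 1e-8)
})
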