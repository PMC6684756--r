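test_that("Mann-Whitney AUC handles ties and directions exactly", {
  # brute force over the 4 pairs: 1 + 0.5 + 1 + 1 over 4
  expect_equal(mann_whitney_auc(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
  expect_equal(mann_whitney_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_error(mann_whitney_auc(1:4, rep(1, 4)), "both outcome classes")
  # complement identity: auc(higher) + auc(lower) = 1, any data
  set.seed(2)
  for (rep in 1:10) {
    s <- sample(1:8, 30, TRUE)   # plenty of ties
    l <- rbinom(30, 1, 0.4); if (length(unique(l)) < 2) next
    expect_equal(mann_whitney_auc(s, l, "higher") +
                   mann_whitney_auc(s, l, "lower"), 1)
    # and equals explicit pair enumeration
    pos <- s[l == 1]; neg <- s[l == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(mann_whitney_auc(s, l), mean(cmp))
  }
})

test_that("LPO-CV with a training-independent scorer equals Mann-Whitney", {
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(20:60, 1)
    co <- toy_cohort(md = rnorm(n), gradx = rlnorm(n),
                     label = rbinom(n, 1, 0.3))
    if (length(unique(co$label)) < 2) next
    lpo <- lpo_cv_auc(co, score_fun = function(train, test) test$md_gy)
    expect_equal(lpo$auc, mann_whitney_auc(co$md_gy, co$label),
                 tolerance = 1e-12)
    expect_equal(lpo$n_pairs, sum(co$label) * sum(1 - co$label))
  }
})

test_that("a monotone-separable feature gives LPO-CV AUC of 1", {
  co <- toy_cohort(md = c(sort(rnorm(12, 10, 1)), sort(rnorm(6, 25, 1))),
                   label = rep(c(0, 1), c(12, 6)))
  lpo <- lpo_cv_auc(co, "md", ridge_lambda = 0.05)
  expect_equal(lpo$auc, 1.0)
})

test_that("label permutation drives the LPO-CV AUC to chance", {
  set.seed(33)
  n <- 60
  co <- toy_cohort(md = rnorm(n), label = rep(c(1, 0), c(12, 48)))
  aucs <- replicate(10, {
    co$label <- sample(co$label)
    lpo_cv_auc(co, "md", ridge_lambda = 0.05)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("Kendall concordance counts pairs exactly", {
  expect_equal(kendall_concordance(1:5, 1:5)$tau, 1)
  expect_equal(kendall_concordance(1:5, 1:5)$concordance_prob, 1)
  # 2 concordant, 1 discordant of 3 pairs
  expect_equal(kendall_concordance(c(1, 2, 3), c(2, 1, 3))$tau, 1 / 3)
  expect_error(kendall_concordance(1:3, 1:4), "equal length")
  # tau-a equals R's Kendall correlation on tie-free data
  set.seed(6)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  expect_equal(kendall_concordance(x, y)$tau,
               cor(x, y, method = "kendall"), tolerance = 1e-12)
  # tau-a with ties: zero numerator contribution, full denominator
  expect_equal(kendall_concordance(c(1, 1, 2), c(1, 2, 3))$tau, 2 / 3)
  expect_equal(kendall_concordance(c(1, 1, 2), c(1, 2, 3),
                                   method = "tau-b")$tau,
               cor(c(1, 1, 2), c(1, 2, 3), method = "kendall"))
})

test_that("median split halves the cohort and reports flipped AUC", {
  # even n, all-distinct feature values: equal strata
  set.seed(12)
  n <- 40
  co <- toy_cohort(md = rnorm(n, 19, 6), gradx = rlnorm(n, 0.24, 0.6),
                   label = rbinom(n, 1, 0.3))
  sp <- stratify_by_median(co, "gradx")
  expect_equal(sp$low$n, 20); expect_equal(sp$high$n, 20)
  expect_equal(sp$median, median(co$gradx_gy_per_mm))
  for (s in list(sp$low, sp$high))
    if (!is.na(s$auc)) expect_equal(s$auc + s$auc_flipped, 1)

  # ties go to the low stratum
  co2 <- toy_cohort(md = rnorm(6), gradx = c(1, 1, 1, 1, 2, 3),
                    label = c(0, 1, 0, 1, 0, 1))
  sp2 <- stratify_by_median(co2, "gradx")
  expect_equal(sp2$low$n, 4)

  # a stratum with one class gives NA AUC with a warning
  co3 <- toy_cohort(md = rnorm(8), gradx = c(1:4, 11:14),
                    label = c(0, 0, 0, 0, 0, 1, 1, 0))
  expect_warning(sp3 <- stratify_by_median(co3, "gradx"), "undefined")
  expect_true(is.na(sp3$low$auc))
})

test_that("opposite MD effects by stratum produce mirrored AUCs", {
  set.seed(44)
  n <- 200
  gradx <- c(rlnorm(n / 2, -0.5, 0.2), rlnorm(n / 2, 1, 0.2))
  md <- rnorm(n, 19, 6)
  lowg <- gradx <= median(gradx)
  p <- ifelse(lowg, plogis(-1 + 1.5 * scale(md)[, 1]),
              plogis(-1 - 1.5 * scale(md)[, 1]))
  co <- toy_cohort(md = md, gradx = gradx, label = rbinom(n, 1, p))
  sp <- stratify_by_median(co, "gradx")
  expect_gt(sp$low$auc, 0.5)
  expect_lt(sp$high$auc, 0.5)
  expect_gt(sp$high$auc_flipped, 0.5)
})
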