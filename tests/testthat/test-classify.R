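test_that("ROC on separated and random data behaves as expected", {
  r <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$chosen_sens, 1)
  expect_equal(r$chosen_spec, 1)
  expect_gte(r$chosen_threshold, 3)
  expect_lt(r$chosen_threshold, 10)

  # labels independent of scores: AUC ~ 0.5 in expectation
  set.seed(19)
  aucs <- replicate(200, {
    roc_curve(stats::runif(40), sample(rep(c(0, 1), 20)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)

  expect_error(roc_curve(1:5, rep(1, 5)), "both classes")
})

test_that("AUC equals the brute-force pairwise concordance count, ties included", {
  set.seed(23)
  for (rep in 1:20) {
    n <- 30L
    scores <- sample(1:10, n, replace = TRUE)  # heavy ties
    labels <- sample(c(rep(1, 12), rep(0, 18)))
    expect_equal(roc_curve(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC and the Youden cut-off are invariant under monotone transforms", {
  set.seed(29)
  scores <- stats::rnorm(50)
  labels <- stats::rbinom(50, 1, stats::plogis(2 * scores))
  if (sum(labels) %in% c(0, 50)) skip("degenerate draw")
  r1 <- roc_curve(scores, labels)
  r2 <- roc_curve(exp(scores), labels)
  expect_equal(r2$auc, r1$auc, tolerance = 1e-12)
  expect_equal(r2$chosen_threshold, exp(r1$chosen_threshold), tolerance = 1e-12)
  r3 <- roc_curve(-scores, labels)
  expect_equal(r3$auc, 1 - r1$auc, tolerance = 1e-12)
})

test_that("ROC AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  scores <- stats::rnorm(60)
  labels <- stats::rbinom(60, 1, stats::plogis(scores))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_curve(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("the published rule set has the eight printed thresholds", {
  rules <- published_rules()
  expect_equal(nrow(rules), 8L)
  get <- function(p, s) rules$threshold[rules$parameter == p & rules$statistic == s]
  expect_equal(get("area", "median"), 48.2)
  expect_equal(get("perimeter", "median"), 25.2)
  expect_equal(get("min_feret", "median"), 6.8)
  expect_equal(get("max_feret", "median"), 9.1)
  expect_equal(get("area", "iqr"), 19.4)
  expect_equal(get("perimeter", "iqr"), 5.3)
  expect_equal(get("min_feret", "iqr"), 1.5)
  expect_equal(get("max_feret", "iqr"), 2.2)
  expect_true(all(rules$direction == "greater"))
})

.summary_row <- function(median_area = 50, iqr_area = 20,
                         median_max_feret = 10, iqr_max_feret = 3) {
  tibble::tibble(
    case_id = "x", variant_label = "pILC", n_nuclei = 100L,
    median_area = median_area, q1_area = NA_real_, q3_area = NA_real_,
    iqr_area = iqr_area,
    median_perimeter = 26, q1_perimeter = NA_real_, q3_perimeter = NA_real_,
    iqr_perimeter = 6,
    median_min_feret = 7, q1_min_feret = NA_real_, q3_min_feret = NA_real_,
    iqr_min_feret = 2,
    median_max_feret = median_max_feret, q1_max_feret = NA_real_,
    q3_max_feret = NA_real_, iqr_max_feret = iqr_max_feret
  )
}

test_that("rule application uses strict thresholds and the stated combinations", {
  rules <- published_rules()
  area_rules <- rules[rules$parameter == "area", ]

  # published per-case values: median 82.5 / IQR 45.4 passes both area rules
  res5 <- apply_rules(.summary_row(82.5, 45.4), area_rules, "all_of")
  expect_true(all(res5$flags$flag))
  expect_true(res5$call)

  # median 47 / IQR 37.1 fails the median rule, passes the IQR rule
  res2 <- apply_rules(.summary_row(47, 37.1), area_rules, "any_of")
  expect_equal(res2$flags$flag[res2$flags$statistic == "median"], FALSE)
  expect_equal(res2$flags$flag[res2$flags$statistic == "iqr"], TRUE)
  expect_true(res2$call)
  expect_false(apply_rules(.summary_row(47, 37.1), area_rules, "all_of")$call)

  # a summary exactly at a threshold does not fire (strict inequality)
  at <- apply_rules(.summary_row(48.2, 19.4), area_rules, "any_of")
  expect_false(any(at$flags$flag))

  # single_parameter uses the max-feret median + IQR pair
  sp_hit <- apply_rules(.summary_row(median_max_feret = 9.5, iqr_max_feret = 2.5),
                        rules, "single_parameter")
  expect_true(sp_hit$call)
  sp_miss <- apply_rules(.summary_row(median_max_feret = 9.5, iqr_max_feret = 2.0),
                         rules, "single_parameter")
  expect_false(sp_miss$call)

  # vote_k counts flags; missing parameter is an error
  expect_true(apply_rules(.summary_row(82.5, 45.4), rules, "vote_k", k = 4)$call)
  expect_error(apply_rules(.summary_row()[, 1:5], area_rules), "lacks")
})

test_that("rule flags are monotone in the summary statistics", {
  rules <- published_rules()
  set.seed(43)
  for (rep in 1:20) {
    s <- .summary_row(stats::runif(1, 30, 70), stats::runif(1, 10, 30),
                      stats::runif(1, 7, 11), stats::runif(1, 1, 4))
    f1 <- apply_rules(s, rules, "any_of")$flags$flag
    bigger <- s
    for (nm in grep("^(median|iqr)_", names(s), value = TRUE)) {
      bigger[[nm]] <- s[[nm]] + stats::runif(1, 0, 5)
    }
    f2 <- apply_rules(bigger, rules, "any_of")$flags$flag
    expect_true(all(f2 >= f1))
  }
})

test_that("logistic fit reproduces the 2x2 closed form", {
  # cells a=10 (x=1,y=1), b=5 (x=0,y=1), c=4 (x=1,y=0), d=20 (x=0,y=0)
  x <- c(rep(1, 10), rep(0, 5), rep(1, 4), rep(0, 20))
  y <- c(rep(1, 15), rep(0, 24))
  fit <- fit_logistic(data.frame(exposure = x), y)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_equal(fit$coefficients$odds_ratio, 10 * 20 / (5 * 4),
               tolerance = 1e-6)
  expect_true(fit$coefficients$ci_lower <= fit$coefficients$odds_ratio)
  expect_true(fit$coefficients$odds_ratio <= fit$coefficients$ci_upper)
})

test_that("logistic fit is well calibrated under the null and recovers known coefficients", {
  set.seed(47)
  rejections <- replicate(100, {
    x <- stats::rnorm(500)
    y <- stats::rbinom(500, 1, 0.4)  # independent of x
    fit_logistic(data.frame(x = x), y)$coefficients$p_value < 0.05
  })
  expect_gte(mean(!rejections), 0.9)

  # parameter recovery within 2 SE at n = 400
  b0 <- -0.5; b1 <- 1.2; b2 <- -0.8
  x1 <- stats::rnorm(400); x2 <- stats::rnorm(400)
  y <- stats::rbinom(400, 1, stats::plogis(b0 + b1 * x1 + b2 * x2))
  fit <- fit_logistic(data.frame(x1 = x1, x2 = x2), y)
  est <- fit$coefficients
  expect_lt(abs(est$estimate[est$term == "x1"] - b1),
            2 * est$std_error[est$term == "x1"])
  expect_lt(abs(est$estimate[est$term == "x2"] - b2),
            2 * est$std_error[est$term == "x2"])
})

test_that("degenerate logistic designs are reported, not silently returned", {
  expect_error(fit_logistic(data.frame(x = rep(1, 10)), rep(c(0, 1), 5)),
               "constant")
  expect_error(fit_logistic(data.frame(x = rnorm(10)), rep(1, 10)), "class")
  # complete separation is flagged with a warning
  x <- c(1:10, 21:30)
  y <- rep(c(0, 1), each = 10)
  expect_warning(fit <- fit_logistic(data.frame(x = x), y), "separation")
  expect_true(fit$separation)
})
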