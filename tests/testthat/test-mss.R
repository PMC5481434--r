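test_that("candidate thresholds are midpoints of sorted unique values", {
  expect_equal(candidate_thresholds(c(1, 2, 3)), c(1.5, 2.5))
  expect_equal(candidate_thresholds(c(5, 5, 9)), 7.0)
  set.seed(41)
  v <- rnorm(20)
  expect_length(candidate_thresholds(v), 19)
  expect_true(all(diff(candidate_thresholds(v)) > 0))
  expect_length(candidate_thresholds(rnorm(500)), 50)   # grid cap
  expect_error(candidate_thresholds(rep(4, 5)), "distinct")
})

test_that("binarization is strict and monotone in the threshold", {
  expect_equal(binarize(10, 7)[1, 1], 1L)
  expect_equal(binarize(7, 7)[1, 1], 0L)
  set.seed(42)
  x <- matrix(rnorm(30), 10, 3)
  t1 <- c(0, 0, 0); t2 <- c(0.5, 0.2, 1)
  expect_true(all(binarize(x, t2) <= binarize(x, t1)))
})

test_that("majority state rule: counts, ties, unobserved states", {
  states <- matrix(c(rep(1, 10), rep(1, 10), rep(1, 10)), 10, 3)
  labels <- c(rep("case", 9), "control")
  rule <- fit_state_rule(states, labels,
                         markers = c("a", "b", "c"))
  expect_equal(rule$case_states, 7L)            # (1,1,1) majority case
  expect_equal(rule$state_table$class[8], "case")
  expect_true(all(rule$state_table$class[1:7] == "control"))  # unobserved

  tie <- fit_state_rule(matrix(1, 4, 1), c("case", "case", "control",
                                           "control"), markers = "m")
  expect_length(tie$case_states, 0)             # tie -> control
})

test_that("the canonical three-marker rule family is representable", {
  # case when dual below threshold, or all three markers above; thresholds 5
  set.seed(43)
  n <- 60
  dat <- data.frame(ca199_only = runif(n, 0, 10),
                    stra_only = runif(n, 0, 10),
                    dual = runif(n, 0, 10))
  truth_case <- dat$dual < 5 | (dat$ca199_only > 5 & dat$stra_only > 5)
  st <- binarize(dat, c(5, 5, 5))
  rule <- fit_state_rule(st, ifelse(truth_case, "case", "control"),
                         thresholds = c(5, 5, 5))
  # case states: dual bit (4) unset -> 0..3; plus all-above state 7
  expect_setequal(rule$case_states, c(0L, 1L, 2L, 3L, 7L))
  ct <- compact_state_table(rule)
  expect_equal(nrow(ct), 2)
  expect_true(any(ct$dual == "0" & ct$ca199_only == "X" &
                    ct$stra_only == "X"))
  # the second implicant is the all-high family: (1,1,1) or the
  # equivalent (1,1,X) given the low-dual row already covers (1,1,0)
  expect_true(any(ct$ca199_only == "1" & ct$stra_only == "1" &
                    ct$dual %in% c("1", "X")))
  # implicant cover equals the case-state set exactly
  covered <- unique(unlist(lapply(seq_len(nrow(ct)), function(i) {
    bits <- as.character(ct[i, rule$markers])
    states <- 0L
    for (j in seq_along(bits)) {
      add <- switch(bits[j], "0" = 0L, "1" = 2L^(j - 1), c(0L, 2L^(j - 1)))
      states <- as.integer(outer(states, add, "+"))
    }
    states
  })))
  expect_setequal(covered, rule$case_states)

  # classification follows the rule table
  pred <- classify(rule, data.frame(ca199_only = c(0, 9, 9),
                                    stra_only = c(9, 9, 2),
                                    dual = c(2, 9, 9)))
  expect_equal(as.character(pred), c("case", "case", "control"))
  expect_error(classify(rule, data.frame(dual = 1)), "missing marker")
})

test_that("panel performance fractions from confusion counts", {
  perf <- panel_performance(27, 3, 3, 12)
  expect_equal(perf$sensitivity, 0.90)
  expect_equal(perf$specificity, 0.80)
  expect_equal(perf$accuracy, 39 / 45)

  set.seed(44)
  x <- data.frame(m = c(rnorm(10, 0), rnorm(10, 6)))
  y <- rep(c("control", "case"), each = 10)
  rule <- panel_rule("m", 3, 1L)
  pf <- evaluate_panel(rule, x, y)
  expect_equal(pf$sensitivity, 1)
  expect_equal(pf$specificity, 1)

  # constant-case rule: everything called case
  allcase <- panel_rule("m", 3, c(0L, 1L))
  pfa <- evaluate_panel(allcase, x, y)
  expect_equal(pfa$sensitivity, 1)
  expect_equal(pfa$specificity, 0)
})

test_that("search matches a brute-force oracle for 1-marker panels", {
  set.seed(45)
  for (rep in 1:5) {
    n <- 12
    dat <- data.frame(m = round(rnorm(n, 5, 2), 1))
    y <- sample(c("case", "control"), n, replace = TRUE,
                prob = c(0.6, 0.4))
    if (length(unique(dat$m)) < 2 || min(table(factor(y,
        c("case", "control")))) < 2) next
    got <- search_panels(dat, y, min_sens = 0.7, min_spec = 0.7,
                         max_markers = 1)
    # oracle: every midpoint threshold, majority labeling per side
    oracle <- list()
    for (thr in candidate_thresholds(dat$m)) {
      above <- dat$m > thr
      cs <- integer(0)
      for (s in 0:1) {
        idx <- above == (s == 1)
        if (sum(y[idx] == "case") > sum(y[idx] == "control"))
          cs <- c(cs, s)
      }
      pred_case <- as.integer(above) %in% cs
      tp <- sum(pred_case & y == "case")
      tn <- sum(!pred_case & y == "control")
      sens <- tp / sum(y == "case"); spec <- tn / sum(y == "control")
      if (sens >= 0.7 - 1e-12 && spec >= 0.7 - 1e-12)
        oracle[[length(oracle) + 1]] <-
          c(thr = thr, mask = sum(2^cs[cs >= 0]) * (length(cs) > 0),
            tp = tp, tn = tn)
    }
    expect_equal(nrow(got), length(oracle))
    if (length(oracle)) {
      om <- do.call(rbind, oracle)
      om <- om[order(om[, "thr"]), , drop = FALSE]
      gm <- got[order(got$t1), ]
      expect_equal(gm$t1, unname(om[, "thr"]))
      expect_equal(gm$tp, unname(om[, "tp"]))
      expect_equal(gm$tn, unname(om[, "tn"]))
      mask_oracle <- vapply(seq_len(nrow(om)), function(i) {
        cs <- om[i, "mask"]
        as.integer(cs)
      }, 0L)
      expect_equal(gm$case_mask, unname(mask_oracle))
    }
  }
})

test_that("search matches an R reimplementation for 2-marker panels", {
  set.seed(46)
  n <- 10
  dat <- data.frame(a = round(rnorm(n), 1), b = round(rnorm(n), 1))
  y <- rep(c("case", "control"), 5)
  got <- search_panels(dat, y, min_sens = 0.6, min_spec = 0.6,
                       max_markers = 2)
  got2 <- got[!is.na(got$marker2), ]
  count <- 0
  for (ta in candidate_thresholds(dat$a))
    for (tb in candidate_thresholds(dat$b)) {
      st <- binarize(dat, c(ta, tb))
      rule <- fit_state_rule(st, y, thresholds = c(ta, tb))
      pf <- evaluate_panel(rule, dat, y)
      if (pf$sensitivity >= 0.6 - 1e-12 && pf$specificity >= 0.6 - 1e-12)
        count <- count + 1
    }
  expect_equal(nrow(got2), count)
})

test_that("majority labeling dominates single-threshold rules in training", {
  set.seed(47)
  for (rep in 1:10) {
    n <- 30
    dat <- data.frame(a = rnorm(n), b = rnorm(n))
    y <- sample(c("case", "control"), n, TRUE)
    ta <- sample(candidate_thresholds(dat$a), 1)
    tb <- sample(candidate_thresholds(dat$b), 1)
    st <- binarize(dat, c(ta, tb))
    rule <- fit_state_rule(st, y, thresholds = c(ta, tb))
    acc_rule <- evaluate_panel(rule, dat, y)$accuracy
    # any single-marker single-threshold rule on the same thresholds
    for (side in list(c("a", ta), c("b", tb))) {
      above <- dat[[side[1]]] > as.numeric(side[2])
      acc_simple <- max(mean((y == "case") == above),
                        mean((y == "case") == !above))
      expect_gte(acc_rule, acc_simple - 1e-12)
    }
  }
})

test_that("perfectly separable marker yields a qualifying 1-marker panel", {
  dat <- data.frame(good = c(1:5, 11:15), other = rnorm(10))
  y <- rep(c("control", "case"), each = 5)
  got <- search_panels(dat, y)
  one <- got[got$marker1 == "good" & is.na(got$marker2), ]
  expect_gte(nrow(one), 1)
  expect_true(any(one$accuracy == 1))
})

test_that("cross-validation is seed-reproducible with consistent arithmetic", {
  set.seed(48)
  ct <- generate_cohort(cohort_spec(seed = 48))
  dat <- ct[, c("ca199_only", "stra_only", "dual")]
  cv1 <- cross_validate(dat, ct$class_label, k = 5, rounds = 2,
                        seed = 9, case_label = "short",
                        max_candidates = 15)
  cv2 <- cross_validate(dat, ct$class_label, k = 5, rounds = 2,
                        seed = 9, case_label = "short",
                        max_candidates = 15)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_equal(cv1$round_medians,
               apply(cv1$accuracy, 1, median, na.rm = TRUE),
               ignore_attr = TRUE)
  expect_equal(cv1$overall, mean(cv1$round_medians, na.rm = TRUE))
  expect_error(cross_validate(dat, ct$class_label, k = 100,
                              case_label = "short"),
               "k greater")
})

test_that("cv_report preserves absent splits and computes medians", {
  acc <- rbind(c(NA, 80, 60, NA), c(NA, NA, NA, NA))
  rep <- cv_report(acc)
  expect_equal(unname(rep$round_medians), c(70, NA))
  expect_equal(rep$overall, 70)
})

test_that("random-label null is reproducible and finds few panels", {
  ct <- generate_cohort(cohort_spec(seed = 50))
  dat <- ct[, c("ca199_only", "stra_only", "dual")]
  n1 <- random_label_null(dat, k = 5, rounds = 1, seed = 4,
                          max_candidates = 15)
  n2 <- random_label_null(dat, k = 5, rounds = 1, seed = 4,
                          max_candidates = 15)
  expect_identical(n1$accuracy, n2$accuracy)
  expect_identical(n1$n_panels, n2$n_panels)
})

test_that("planted-rule cohorts are recovered by the search", {
  tr <- generate_cohort(cohort_spec(n_patients = 200, seed = 51))
  ps <- search_panels(tr[, c("ca199_only", "stra_only", "dual")],
                      tr$class_label, case_label = "short")
  expect_gt(nrow(ps), 0)
  rule <- panel_rule_from_row(ps, 1)
  te <- generate_cohort(cohort_spec(n_patients = 500, seed = 151))
  pred <- classify(rule, te)
  agree <- mean((pred == "case") == (te$class_label == "short"))
  expect_gte(agree, 0.95)
})
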