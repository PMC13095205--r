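test_that("macro metrics follow the per-class definitions", {
  # perfect predictions
  y <- factor(c("a", "a", "b", "b"))
  expect_equal(as.numeric(macro_metrics(y, y)), c(1, 1, 1))

  # confusion [[8,2],[3,7]]: per-class precision 8/11 and 7/9
  true <- factor(rep(c("a", "b"), each = 10))
  pred <- factor(c(rep("a", 8), rep("b", 2), rep("a", 3), rep("b", 7)))
  m <- macro_metrics(true, pred)
  expect_equal(unname(m["precision"]), mean(c(8 / 11, 7 / 9)), tolerance = 1e-12)
  expect_equal(unname(m["recall"]), mean(c(8 / 10, 7 / 10)), tolerance = 1e-12)

  # predicting one class in a balanced two-class set: macro recall 0.5,
  # and the never-predicted class contributes precision 0
  pred0 <- factor(rep("a", 20), levels = c("a", "b"))
  m0 <- macro_metrics(true, pred0)
  expect_equal(unname(m0["recall"]), 0.5)
  expect_equal(unname(m0["precision"]), 0.25)

  expect_error(macro_metrics(true, pred0[1:3]), "equal length")
})

test_that("macro metrics agree with a confusion-matrix oracle on random fixtures", {
  set.seed(17)
  for (rep in 1:5) {
    classes <- letters[1:sample(2:4, 1)]
    true <- factor(sample(classes, 40, replace = TRUE), levels = classes)
    pred <- factor(sample(classes, 40, replace = TRUE), levels = classes)
    expect_equal(as.numeric(macro_metrics(true, pred, levels = classes)),
                 as.numeric(oracle_macro(true, pred, classes)),
                 tolerance = 1e-12)
  }
})

test_that("Kaplan-Meier curves are the product-limit estimate", {
  # all censored: survival stays at 1
  t1 <- data.frame(time = c(2, 4, 6), event = 0, group = "low")
  km1 <- kaplan_meier(t1)
  expect_true(all(km1$survival == 1))

  # three events at 1,2,3: steps 2/3, 1/3, 0
  t2 <- data.frame(time = 1:3, event = 1, group = "high")
  km2 <- kaplan_meier(t2)
  expect_equal(km2$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  # one event at t=5 among four patients: S(5) = 0.75
  t3 <- data.frame(time = c(5, 7, 8, 9), event = c(1, 0, 0, 0), group = "g")
  km3 <- kaplan_meier(t3)
  expect_equal(km3$survival[km3$time == 5], 0.75)

  expect_error(kaplan_meier(data.frame(time = c(-1, 2), event = 1,
                                       group = "g")), "positive")
})

test_that("Kaplan-Meier matches the risk-set oracle and is non-increasing", {
  set.seed(23)
  for (rep in 1:3) {
    n <- 12
    tab <- data.frame(time = sample(1:8, n, replace = TRUE) + 0.5,
                      event = rbinom(n, 1, 0.7), group = "g")
    km <- kaplan_meier(tab)
    orc <- oracle_km(tab$time, tab$event)
    got <- km$survival[match(orc$time, km$time)]
    expect_equal(got, orc$survival, tolerance = 1e-12)
    expect_true(all(diff(km$survival) <= 1e-12))
  }
})

test_that("the log-rank statistic matches event-time enumeration", {
  # textbook toy: group A events at 1,2,3; group B events at 4,5,6
  tab <- data.frame(time = 1:6, event = 1,
                    group = rep(c("high", "low"), each = 3))
  res <- logrank_test(tab)
  expect_equal(res$chi2,
               oracle_logrank(tab$time, tab$event, tab$group == "high"),
               tolerance = 1e-8)
  expect_gte(res$chi2, 0)
  expect_equal(sum(res$observed), 6)

  # identical event patterns in both groups: no difference
  tab2 <- data.frame(time = rep(c(1, 2, 3), 2), event = rep(c(1, 1, 0), 2),
                     group = rep(c("high", "low"), each = 3))
  res2 <- logrank_test(tab2)
  expect_equal(res2$chi2, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1, tolerance = 1e-12)

  # invariant to swapping group labels
  tab3 <- tab
  tab3$group <- rep(c("low", "high"), each = 3)
  expect_equal(logrank_test(tab3)$chi2, res$chi2, tolerance = 1e-12)

  # mixed censoring fixture against the oracle
  set.seed(4)
  tab4 <- data.frame(time = sample(1:10, 14, replace = TRUE),
                     event = rbinom(14, 1, 0.6),
                     group = rep(c("high", "low"), 7))
  expect_equal(logrank_test(tab4)$chi2,
               oracle_logrank(tab4$time, tab4$event, tab4$group == "high"),
               tolerance = 1e-8)

  expect_error(logrank_test(data.frame(time = 1:3, event = 1, group = "g")),
               "two")
})

test_that("concordance index counts comparable pairs exactly", {
  # risk anti-ordered with time, all events: perfect concordance
  expect_equal(concordance_index(5:1, 1:5, rep(1, 5)), 1.0)
  # risk equal to time: fully discordant
  expect_equal(concordance_index(1:5, 1:5, rep(1, 5)), 0.0)

  # mixed-censoring fixture against the exhaustive pair loop
  risk <- c(2.1, 0.3, 1.7, 1.7, -0.5, 0.9)
  time <- c(1, 5, 2, 3, 8, 4)
  event <- c(1, 0, 1, 1, 0, 1)
  expect_equal(concordance_index(risk, time, event),
               oracle_cindex(risk, time, event), tolerance = 1e-12)

  # complement property without risk ties
  set.seed(6)
  r <- rnorm(10); tt <- sample(1:50, 10); ev <- rbinom(10, 1, 0.7)
  expect_equal(concordance_index(r, tt, ev) + concordance_index(-r, tt, ev),
               1, tolerance = 1e-12)

  # agreement with the survival package on a tie-free fixture
  sc <- survival::concordance(survival::Surv(tt, ev) ~ r, reverse = TRUE)
  expect_equal(concordance_index(r, tt, ev), unname(sc$concordance),
               tolerance = 1e-12)

  expect_error(concordance_index(1:3, c(2, 2, 2), c(0, 0, 0)), "comparable")
})

test_that("risk groups split at the median with ties going low", {
  ids <- sprintf("P%02d", 1:7)
  emb <- matrix(rnorm(14), 7, 2, dimnames = list(ids, NULL))
  scores <- c(5, 1, 3, 3, 2, 4, 3)   # median 3; ties -> low
  tab <- assign_risk_groups(emb, times = 1:7, events = rep(1, 7),
                            scores = scores)
  expect_equal(tab$group, ifelse(scores > 3, "high", "low"))
  expect_equal(sum(tab$group == "high"), 2)
  expect_error(assign_risk_groups(emb, 1:7, rep(1, 7), scores = rep(2, 7)),
               "constant")
})

test_that("the ridge risk head recovers a strong survival signal", {
  set.seed(12)
  n <- 80
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(sprintf("P%02d", 1:n), NULL))
  lp <- 1.5 * x[, 1] - 1.0 * x[, 2]
  time <- rexp(n, rate = 0.05 * exp(lp))
  event <- rbinom(n, 1, 0.8)
  res <- evaluate_survival(x, time, event, seed = 3)
  expect_gt(res$c_index, 0.6)
  expect_lt(res$logrank$p_value, 0.05)
  expect_equal(nrow(res$table), n)
  # groups are near-balanced by the median split
  expect_lte(abs(sum(res$table$group == "high") -
                 sum(res$table$group == "low")), 1)
})
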