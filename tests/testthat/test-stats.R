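test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  tab <- handCohort()
  a <- rmAnova(tab, 1L)
  # frozen from the independent from-scratch decomposition of the fixture
  expect_equal(a$F, 36)
  expect_equal(a$p, 0.0027700831, tolerance = 1e-8)
  expect_equal(a$df1, 2)
  expect_equal(a$df2, 4)
  expect_false(a$degenerate)
})

test_that("repeated-measures ANOVA agrees with aov on random cohorts", {
  set.seed(7)
  for (rep_ in 1:3) {
    tab <- syntheticCohort(means = c(50, 40, 60) + rnorm(3, 0, 5),
                           nSubjects = 8, noise = 8, seed = rep_)
    a <- rmAnova(tab, 1L)
    d <- data.frame(y = tab$pct_colder,
                    tp = factor(tab$timepoint, timepointLevels()),
                    s = factor(tab$subject))
    fit <- summary(stats::aov(y ~ tp + Error(s/tp), data = d))
    ref <- fit[["Error: s:tp"]][[1]]
    expect_equal(a$F, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(a$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("zero within-subject variance is flagged as degenerate with p = 1", {
  tab <- expand.grid(subject = c("a", "b", "c"),
                     timepoint = timepointLevels(),
                     stringsAsFactors = FALSE)
  tab$session <- 1L
  tab$pct_colder <- 42          # identical everywhere
  a <- rmAnova(tab, 1L)
  expect_true(a$degenerate)
  expect_equal(a$p, 1)
})

test_that("incomplete timepoint grids are rejected with the missing cells", {
  tab <- handCohort()
  tab <- tab[!(tab$subject == "s2" & tab$timepoint == "post_drug"), ]
  expect_error(rmAnova(tab, 1L), "s2/post_drug")
  expect_error(rmAnova(handCohort(), 99L), "no data")
  one <- handCohort()[handCohort()$subject == "s1", ]
  expect_error(rmAnova(one, 1L), ">= 2 subjects")
})

test_that("Tukey timepoint family matches emmeans on an aov fit", {
  library(emmeans)
  tab <- syntheticCohort(means = c(45, 30, 55), nSubjects = 7, noise = 6,
                         seed = 3)
  tk <- tukeyPairwise(tab, 1L, family = "timepoint")
  d <- data.frame(y = tab$pct_colder,
                  tp = factor(tab$timepoint, timepointLevels()),
                  s = factor(tab$subject))
  # embed the data in the call so emmeans can re-fit inside the test scope
  fit <- eval(bquote(stats::aov(y ~ tp + Error(s/tp), data = .(d))))
  em <- suppressMessages(
    summary(pairs(emmeans(fit, "tp"), adjust = "tukey")))
  expect_equal(tk$pAdj, em$p.value, tolerance = 1e-6)
  expect_equal(-tk$estimate, em$estimate, tolerance = 1e-10)
})

test_that("Tukey adjustment never falls below the unadjusted p", {
  tab <- syntheticCohort(means = c(50, 44, 58), nSubjects = 6, noise = 5,
                         seed = 11)
  tk <- tukeyPairwise(tab, 1L, family = "timepoint")
  m <- ThermoTrack:::.cohortWide(tab, 1L)
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  mse <- (sum((m - g)^2) - k * sum((rowMeans(m) - g)^2) -
            n * sum((colMeans(m) - g)^2)) / ((n - 1) * (k - 1))
  for (i in seq_len(nrow(tk))) {
    tstat <- abs(tk$estimate[i]) / sqrt(2 * mse / n)
    pUnadj <- 2 * stats::pt(-tstat, (n - 1) * (k - 1))
    expect_gte(tk$pAdj[i] + 1e-12, pUnadj)
  }
  # the most separated pair owns the smallest adjusted p
  expect_equal(which.min(tk$pAdj), 3L)   # pre_drug vs post_drug (44 vs 58)
})

test_that("identical timepoints give an adjusted p of 1", {
  tab <- syntheticCohort(means = c(50, 50, 70), nSubjects = 6, noise = 0,
                         seed = 1)
  # add subject-level scatter shared across timepoints so MSE > 0
  off <- rep(rnorm(6, 0, 3), times = 3)
  tab$pct_colder <- tab$pct_colder + off
  tk <- tukeyPairwise(tab, 1L, family = "timepoint")
  p12 <- tk$pAdj[tk$lhs == "before_oxa" & tk$rhs == "pre_drug"]
  expect_equal(p12, 1, tolerance = 1e-9)
})

test_that("plate family equals the paired comparison of the two plates", {
  tab <- handCohort()
  pl <- tukeyPairwise(tab, 1L, family = "plate")
  expect_equal(nrow(pl), 3L)
  for (tp in timepointLevels()) {
    x <- tab$pct_colder[tab$timepoint == tp]
    ref <- stats::t.test(x, mu = 50)
    row <- pl[pl$timepoint == tp, ]
    expect_equal(row$pAdj, ref$p.value, tolerance = 1e-10)
    expect_equal(row$meanPctColder, mean(x))
  }
})

test_that("star labels use strict thresholds and step monotonically", {
  expect_equal(stars(c(0.2, 0.03, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
  # boundaries are strict
  expect_equal(stars(c(0.05, 0.01, 0.001, 0.0001)),
               c("ns", "*", "**", "***"))
  expect_equal(hashes(0.004), "##")
  expect_error(stars(1.2), "\\[0, 1\\]")
  expect_error(stars(-0.1), "\\[0, 1\\]")
  # non-increasing step function of p
  p <- sort(runif(50))
  lv <- nchar(sub("ns", "", stars(p)))
  expect_true(all(diff(lv) <= 0))
})

test_that("preference calls combine direction and significance", {
  # strong warm preference: mean pct_colder 20, tiny scatter
  warm <- syntheticCohort(means = c(20, 20, 20), nSubjects = 6, noise = 2,
                          seed = 5)
  cw <- callPreference(warm, 1L, "pre_drug")
  expect_equal(direction(cw), "warmer")
  expect_lt(pAdj(cw), 0.001)
  # exactly 50 percent is "none" regardless of p
  tab50 <- expand.grid(subject = sprintf("s%d", 1:4),
                       timepoint = timepointLevels(),
                       stringsAsFactors = FALSE)
  tab50$session <- 1L
  tab50$pct_colder <- 50
  c50 <- callPreference(tab50, 1L, "pre_drug")
  expect_equal(direction(c50), "none")
  # non-significant scatter around 55 is "none"
  vague <- syntheticCohort(means = c(55, 55, 55), nSubjects = 4, noise = 25,
                           seed = 8)
  vague$pct_colder <- pmin(100, pmax(0, vague$pct_colder))
  cv <- callPreference(vague, 1L, "pre_drug")
  if (pAdj(cv) >= 0.05) expect_equal(direction(cv), "none")
})

test_that("drug-effect classification is total over the direction grid", {
  dirs <- c("warmer", "colder", "none")
  grid <- expand.grid(pre = dirs, post = dirs, stringsAsFactors = FALSE)
  cats <- vapply(seq_len(nrow(grid)), function(i) {
    category(callDrugEffect(prefCall(grid$pre[i]), prefCall(grid$post[i])))
  }, character(1))
  expect_equal(cats, c("maintained", "reversed", "no_baseline",
                       "reversed", "maintained", "no_baseline",
                       "lost", "lost", "no_baseline"))
  # every pair maps to exactly one category
  expect_true(all(cats %in% c("maintained", "lost", "reversed",
                              "no_baseline")))
  expect_error(
    callDrugEffect(prefCall("warmer", sessionId = 1L),
                   prefCall("none", sessionId = 2L)),
    "different sessions")
})

test_that("cohort validation reports offending rows", {
  tab <- handCohort()
  bad <- tab; bad$pct_colder[4] <- 140
  expect_error(validateCohortTable(bad), "row\\(s\\): 4")
  dup <- rbind(tab, tab[2, ])
  expect_error(validateCohortTable(dup), "duplicate")
  expect_error(validateCohortTable(data.frame()), "empty")
  expect_error(
    validateCohortTable(tab[, setdiff(names(tab), "pct_colder")]),
    "pct_colder")
  inc <- tab[-1, ]
  expect_error(validateCohortTable(inc), "missing cell")
  expect_silent(validateCohortTable(inc, allowIncomplete = TRUE))
})

test_that("timepoint ANOVA is calibrated when no treatment effect exists", {
  # identity effects: the three timepoints are exchangeable, so the
  # RM-ANOVA should reject at about its nominal level
  nullAgent <- AgentParams(preferenceGain = 0)
  ps <- unlist(lapply(1:150, function(s) {
    tab <- cohortTable(simulateCohort(10, standardProtocol(),
                                      agent = nullAgent, seed = s + 500L))
    vapply(1:9, function(sid) rmAnova(tab, sid)$p, numeric(1))
  }))
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.025)
  expect_lte(rate, 0.085)
})

test_that("cohort analysis recovers a drug-like pattern end to end", {
  sc <- simulateCohort(8, standardProtocol(durationS = 120),
                       effects = duloxetineProfile(), seed = 17)
  an <- analyzeCohort(cohortTable(sc))
  expect_equal(nrow(an), 9L)
  expect_equal(an$category[2], "reversed")
  expect_true(all(an$category[3:4] == "maintained"))
  expect_equal(an$dir_pre[1], "warmer")
  # report lines mention the analgesia sessions
  rep_ <- summaryReport(an)
  expect_match(rep_[length(rep_)], "lost or reversed")
  calls <- attr(an, "calls")
  expect_s4_class(calls[["2"]], "DrugEffectCall")
})
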