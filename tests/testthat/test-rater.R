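study_table <- function(overlap = 1)
  reconstruct_study_table(29, c(observer1 = 14, observer2 = 15), 11,
                          overlap = overlap)

test_that("confusion counts follow the cross-tabulation definitions", {
  tab <- study_table()
  cc <- confusion(tab$values[, "observer1"], tab$values[, "contrast"])
  expect_equal(cc$TP, 11); expect_equal(cc$FP, 3)
  expect_equal(cc$FN, 0); expect_equal(cc$TN, 15)
  ident <- c("positive", "positive", "negative", "negative", "negative")
  cc2 <- confusion(ident, ident)
  expect_equal(unlist(cc2[c("TP", "FP", "FN", "TN")]),
               c(TP = 2, FP = 0, FN = 0, TN = 3))
  cc3 <- confusion(rep("nondiagnostic", 4),
                   rep(c("positive", "negative"), 2))
  expect_equal(unlist(cc3[c("TP", "FP", "FN", "TN")]),
               c(TP = 0, FP = 0, FN = 0, TN = 0))
  expect_equal(cc3$n_excluded, 4)
  expect_error(confusion("positive", c("positive", "negative")),
               "equal length")
  expect_error(confusion("maybe", "positive"), "positive")
})

test_that("diagnostic metrics hold as exact fractions and percentages", {
  m <- diagnostic_metrics(lvtdm:::confusion_counts(11, 3, 0, 15))
  expect_equal(unname(m$percent),
               c(100, 83, 79, 100, 90))  # Se Sp PPV NPV Acc
  expect_equal(unname(m$value["specificity"]), 15 / 18)
  # rational identities
  expect_equal(m$value["sensitivity"] * (11 + 0), c(sensitivity = 11))
  expect_equal(m$value["accuracy"] * 29, c(accuracy = 26))
  perfect <- diagnostic_metrics(lvtdm:::confusion_counts(5, 0, 0, 5))
  expect_true(all(perfect$percent == 100))
  deg <- diagnostic_metrics(lvtdm:::confusion_counts(0, 0, 3, 7))
  expect_equal(unname(deg$percent["sensitivity"]), 0)
  expect_true(is.na(deg$value["ppv"]))
  expect_equal(deg$undefined, "ppv")
})

test_that("single-operating-point AUC is (Se + Sp) / 2", {
  expect_equal(round(binary_auc(lvtdm:::confusion_counts(11, 3, 0, 15)), 3),
               0.917)
  expect_equal(round(binary_auc(lvtdm:::confusion_counts(11, 4, 0, 14)), 3),
               0.889)
  expect_equal(binary_auc(lvtdm:::confusion_counts(4, 0, 0, 6)), 1)
  # constant positive rater: Se = 1, Sp = 0 -> chance area
  expect_equal(binary_auc(lvtdm:::confusion_counts(4, 6, 0, 0)), 0.5)
  # undefined specificity (no reference negatives at all)
  expect_true(is.na(binary_auc(lvtdm:::confusion_counts(4, 0, 1, 0))))
})

test_that("chi-square upper tail matches its closed form at df = 2", {
  expect_equal(chi2_upper_tail(0, 2), 1)
  expect_equal(chi2_upper_tail(6, 2), exp(-3))
  expect_equal(chi2_upper_tail(4.333, 2), exp(-4.333 / 2))
  expect_equal(round(chi2_upper_tail(13 / 3, 2), 3), 0.115)
  expect_error(chi2_upper_tail(-1, 2), "non-negative")
})

test_that("tie-corrected statistic reduces to the classic one without ties", {
  m <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(1, 3, 2))
  fr <- friedman_test(m)
  expect_equal(fr$tie_correction, 1)
  # cross-check against the reference implementation (valid with no ties)
  ref <- stats::friedman.test(m)
  expect_equal(fr$chi_square, unname(ref$statistic))
  expect_equal(fr$p_value, unname(ref$p.value))
})

test_that("fully tied tables are flagged as degenerate", {
  m <- matrix(1, 5, 3)
  fr <- friedman_test(m)
  expect_true(fr$degenerate)
  expect_equal(fr$chi_square, 0)
  expect_equal(fr$p_value, 1)
})

test_that("mean ranks always sum to k(k+1)/2", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:5, 1); n <- sample(2:20, 1)
    m <- matrix(sample(0:2, n * k, replace = TRUE), n, k)
    if (friedman_test(m)$degenerate) next
    expect_equal(sum(friedman_test(m)$mean_ranks), k * (k + 1) / 2)
  }
})

test_that("statistic agrees with the brute-force oracle on random tables", {
  set.seed(19)
  for (i in 1:60) {
    k <- sample(2:4, 1); n <- sample(2:30, 1)
    m <- matrix(sample(0:2, n * k, replace = TRUE), n, k)
    o <- friedman_oracle(m)
    fr <- friedman_test(m)
    expect_equal(fr$chi_square, o$chi, tolerance = 1e-12)
    expect_equal(unname(fr$rank_sums), o$Rj, tolerance = 1e-12)
    expect_equal(fr$degenerate, o$degenerate)
  }
})

test_that("study-table reconstruction reproduces the published statistics", {
  fr <- friedman_test(study_table(overlap = 1))
  expect_equal(round(fr$chi_square, 3), 4.333)
  expect_equal(fr$df, 2)
  expect_equal(round(fr$p_value, 3), 0.115)
  expect_equal(round(unname(fr$mean_ranks), 2), c(2.03, 2.09, 1.88))
  # the overlap between the two observers' false positives is identified
  # uniquely by the statistic
  chis <- sapply(0:3, function(a)
    friedman_test(study_table(overlap = a))$chi_square)
  expect_equal(which(abs(chis - 4.333) < 5e-4), 2L)  # a = 1
})

test_that("rank sums are invariant to the false-positive overlap", {
  for (a in 0:3) {
    fr <- friedman_test(study_table(overlap = a))
    expect_equal(unname(fr$rank_sums), c(59, 60.5, 54.5))
  }
})

test_that("inconsistent margins are rejected", {
  expect_error(reconstruct_study_table(29, c(10, 15), 11),
               "no-false-negative")
  expect_error(reconstruct_study_table(29, c(14, 15), 11, overlap = 5),
               "overlap")
  expect_error(reconstruct_study_table(10, c(14, 15), 11),
               "exceed")
})

test_that("rating tables validate entries and read from CSV", {
  expect_error(rating_table(matrix(c("positive", "bogus"), 1)),
               "row 1, column 2")
  path <- study_fixture_path()
  tab <- read_rating_table(path)
  expect_equal(dim(tab$values), c(29, 3))
  expect_equal(tab$rater_names, c("observer1", "observer2", "contrast"))
  expect_equal(sum(tab$values[, "contrast"] == "positive"), 11)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("observer1,contrast", "positive,positive", "oops,negative"),
             bad)
  expect_error(read_rating_table(bad), "row 2")
})

test_that("nondiagnostic rows are dropped listwise from the Friedman test", {
  vals <- rbind(c("positive", "positive", "positive"),
                c("nondiagnostic", "negative", "negative"),
                c("positive", "negative", "negative"),
                c("negative", "negative", "positive"))
  tab <- rating_table(vals)
  fr <- friedman_test(tab)
  expect_equal(fr$n, 3)
})
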