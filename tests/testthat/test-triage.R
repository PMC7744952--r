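test_that("triage labels normalise onto the five ordered levels", {
  lv <- normalize_triage(c("risk", "Sick", "Cold State", "Cold case",
                           "Normal", "Urgent"))
  expect_s3_class(lv, "ordered")
  expect_equal(as.character(lv),
               c("Risk", "Sick", "Cold State", "Cold State", "Normal",
                 "Urgent"))
  expect_true(normalize_triage("Normal") < normalize_triage("risk"))
  expect_error(normalize_triage("bogus"), "Unknown triage label")
})

test_that("both printed symptom bit-orders are produced", {
  g6 <- symptom_grid("rest_fastest")
  expect_equal(nrow(g6), 16)
  expect_equal(unname(unlist(g6[1, ])), rep(FALSE, 4))
  expect_equal(unname(unlist(g6[2, ])), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(unname(unlist(g6[16, ])), rep(TRUE, 4))
  g5 <- symptom_grid("chest_fastest")
  expect_equal(unname(unlist(g5[2, ])), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(unlist(g5[3, ])), c(FALSE, TRUE, FALSE, FALSE))
  expect_error(symptom_grid("rowwise"), "rest_fastest|arg")
})

test_that("enumeration crosses each vital block with all 16 symptom rows", {
  empty <- enumerate_combinations(tibble::tibble(spo2 = integer(),
                                                 bp_high = integer(),
                                                 bp_low = integer()))
  expect_equal(nrow(empty), 0)
  two <- enumerate_combinations(tibble::tibble(spo2 = c(97, 92),
                                               bp_high = 23, bp_low = 12))
  expect_equal(nrow(two), 32)
  expect_equal(sum(two$spo2 == 97), 16)
  expect_error(enumerate_combinations(tibble::tibble(spo2 = 97)), "bp_high")
})

test_that("the packaged fixtures have the printed row counts", {
  expect_equal(nrow(triage_fixture("table6")), 580)
  expect_equal(nrow(triage_fixture("table5")), 143)
})

test_that("fixture loading maps printed cells onto tidy columns", {
  fx <- triage_fixture("table6")
  expect_equal(fx$spo2[1], 97L)
  expect_equal(fx$bp_high[1], 23L)
  expect_false(fx$chest_pain[1])
  expect_equal(fx$peaks[1], "67")
  expect_equal(as.character(fx$triage[1]), "Sick")
  expect_equal(unique(fx$ecg_class[145:288]), "arrhythmia_wide")
  # enumeration table: printed BP columns are swapped relative to table6
  f5 <- triage_fixture("table5")
  expect_equal(f5$bp_high[1], 23L)
  expect_equal(f5$bp_low[1], 12L)
})

test_that("check_consistency finds exactly the duplicated-key disagreements", {
  fx <- triage_fixture("table6")
  one <- check_consistency(fx[1, ])
  expect_equal(nrow(one), 0)
  # constructed conflict: identical vectors, differing labels
  dup <- fx[c(1, 1), ]
  dup$triage <- normalize_triage(c("Sick", "Urgent"))
  confl <- check_consistency(dup)
  expect_equal(nrow(confl), 1)
  expect_equal(confl$n, 2L)
  # brute-force duplicate-grouping oracle over the whole fixture
  key <- do.call(paste, c(fx[c("spo2", "bp_high", "bp_low", "chest_pain",
                               "short_breath", "palpitation", "at_rest",
                               "peaks", "qrs_width", "pp", "st")], sep = "|"))
  oracle <- Filter(function(ix) length(unique(fx$triage[ix])) > 1,
                   split(seq_len(580), key))
  got <- check_consistency(fx)
  expect_equal(nrow(got), length(oracle))
  expect_setequal(unlist(got$rows), fx$p_no[unlist(oracle)])
  # the packaged table has a single conflicting pair
  expect_equal(sort(unlist(got$rows)), c(510L, 551L))
})

test_that("the induced rule list reproduces every non-conflicting row", {
  fx <- triage_fixture("table6")
  model <- induce_decision_model(fx)
  pred <- classify(fx, model)
  confl_rows <- unlist(check_consistency(fx)$rows)
  keep <- !fx$p_no %in% confl_rows
  expect_true(all(as.character(pred$triage[keep]) ==
                    as.character(fx$triage[keep])))
  expect_false(any(pred$extrapolated))
  g <- glance(model)
  expect_equal(g$n_train, 580L)
  expect_equal(g$n_conflict_groups, 1L)
  expect_equal(nrow(tidy(model)), g$n_rules)
})

test_that("a one-row table induces a constant model", {
  fx <- triage_fixture("table6")
  m <- induce_decision_model(fx[7, ])
  expect_equal(nrow(m$rules), 1)
  expect_equal(as.character(classify(fx[7, ], m)$triage),
               as.character(fx$triage[7]))
})

test_that("strict conflict handling refuses inconsistent tables", {
  fx <- triage_fixture("table6")
  expect_error(induce_decision_model(fx, conflicts = "strict"),
               "conflict")
  expect_silent(induce_decision_model(fx[1:100, ], conflicts = "strict"))
})

test_that("printed rows classify to their printed labels", {
  model <- induce_decision_model()
  # sleep-apnea block, SpO2 97, BP 23/12, no symptoms -> Sick
  r1 <- feature_row(97L, 23L, 12L, FALSE, FALSE, FALSE, FALSE,
                    "67", "0.06", st = "true")
  expect_equal(as.character(classify(r1, model)$triage), "Sick")
  # same vitals, all four symptoms -> Risk (printed "risk")
  r16 <- feature_row(97L, 23L, 12L, TRUE, TRUE, TRUE, TRUE,
                     "67", "0.06", st = "true")
  expect_equal(as.character(classify(r16, model)$triage), "Risk")
  # normal ECG, SpO2 97, BP 12/8, only at rest -> Normal
  r515 <- feature_row(97L, 12L, 8L, FALSE, FALSE, FALSE, TRUE,
                      "normal", "", st = "")
  expect_equal(as.character(classify(r515, model)$triage), "Normal")
})

test_that("classify is total: unseen vectors fall back to the nearest rule", {
  model <- induce_decision_model()
  unseen <- feature_row(85L, 23L, 12L, TRUE, TRUE, TRUE, TRUE,
                        "67", "0.06", st = "true")
  out <- classify(unseen, model)
  expect_true(out$extrapolated)
  expect_equal(as.character(out$triage), "Risk")  # nearest printed block
  expect_error(classify(unseen[, -1], model), "spo2")
})

test_that("classification is a pure function of the feature vector", {
  model <- induce_decision_model()
  fx <- triage_fixture("table6")
  a <- classify(fx[c(5, 5, 200), ], model)
  expect_identical(a$triage[1], a$triage[2])
  b <- classify(fx[c(5, 5, 200), ], model)
  expect_identical(a$triage, b$triage)
})

test_that("an independent decision tree also fits the de-conflicted rules", {
  skip_if_not_installed("rpart")
  rules <- tidy(induce_decision_model())
  dat <- rules
  dat$triage <- factor(as.character(dat$triage))
  for (cc in c("peaks", "qrs_width", "pp", "st")) dat[[cc]] <- factor(dat[[cc]])
  fit <- rpart::rpart(
    triage ~ spo2 + bp_high + bp_low + chest_pain + short_breath +
      palpitation + at_rest + peaks + qrs_width + st,
    data = dat, method = "class",
    control = rpart::rpart.control(minsplit = 2, minbucket = 1, cp = -1,
                                   xval = 0, maxdepth = 30)
  )
  pred <- predict(fit, dat, type = "class")
  # a fully grown tree reproduces the vast majority of the rule list; the
  # rule list itself is the exact-fit model
  expect_gt(mean(as.character(pred) == as.character(dat$triage)), 0.95)
})

test_that("no single symptom flip lowers the triage level in the fixture", {
  av <- audit_monotonicity()
  expect_s3_class(av, "tbl_df")
  expect_equal(nrow(av), 0)
})
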