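table1_counts <- c(2036, 5368, 12312, 27612, 14990, 10, 1, 63, 8, 9)

test_that("single-cell expected counts match the published model", {
  expect_identical(expected_false_count(7.5e6, 0.72, 0.65, 0.00058)$count,
                   2036)
  expect_identical(expected_false_count(2e6, 0.28, 0.25, 0.000055)$count,
                   8)  # 7.7 rounds up
  expect_identical(expected_false_count(7.5e6, 0.28, 0.65, 0.000007)$count,
                   10) # 9.555 rounds up
  expect_identical(expected_false_count(5e5, 0, 0.2, 0.2)$count, 0)
  expect_error(expected_false_count(-1, 0.5, 0.5, 0.001), "non-negative")
  expect_error(expected_false_count(10, 1.5, 0.5, 0.001), "exceed 1")
})

test_that("the published 15-marker caseload model reproduces every cell", {
  tab <- project(caseload_preset("table1_identifiler"))
  expect_equal(nrow(tab), 10)
  expect_identical(as.integer(tab$expected_count), as.integer(table1_counts))
  expect_identical(as.integer(attr(tab, "total_rounded_rows")), 62409L)
  expect_gt(attr(tab, "grand_total"), 60000)
  expect_gt(attr(tab, "total_unrounded"), 60000)
  # related rows are false negatives, unrelated rows false positives
  expect_identical(tab$arm, rep(c("related", "unrelated"), each = 5))
})

test_that("projections are linear in the total caseload", {
  model <- caseload_preset("table1_identifiler")
  base <- project(model)
  model$total_cases <- 2 * model$total_cases
  doubled <- project(model)
  expect_equal(doubled$unrounded, 2 * base$unrounded)
})

test_that("zero rates project zero counts", {
  model <- caseload_preset("table1_identifiler")
  model$rates$fn_rate <- 0
  model$rates$fp_rate <- 0
  tab <- project(model)
  expect_true(all(tab$expected_count == 0))
  expect_identical(attr(tab, "grand_total"), 0)
})

test_that("missing rates for a lab-mix cell are an error", {
  model <- caseload_preset("table1_identifiler")
  model$rates <- model$rates[model$rates$threshold != 1000, ]
  expect_error(project(model), "threshold 1000")
  expect_error(project(caseload_model(10, 0.5, c(trio = 1),
                                      list(trio = c("100" = 1)))),
               "no rates")
})

test_that("model construction validates its proportions", {
  expect_error(caseload_model(10, 1.2, c(trio = 1),
                              list(trio = c("100" = 1))),
               "related_fraction")
  expect_error(caseload_model(10, 0.5, c(trio = 0.6, full_sib = 0.3),
                              list()),
               "sum to 1")
  expect_error(caseload_model(10, 0.5, c(uncle = 1), list()), "unknown")
  expect_error(caseload_model(10, 0.5, c(trio = 1),
                              list(trio = c("100" = 0.7, "1000" = 0.5))),
               "more than 1")
})

test_that("simulation-fed projection equals the manual projection", {
  fs <- toy_panel2()
  pol100 <- decision_policy("binary", 2)
  rates <- rbind(
    exact_rates_bruteforce("parent_child", fs, pol100),
    exact_rates_bruteforce("full_sib", fs, pol100)
  )
  model <- caseload_model(
    total_cases = 1e6, related_fraction = 0.7,
    casetype_mix = c(parent_child = 0.6, full_sib = 0.4),
    lab_threshold_mix = list(parent_child = c("2" = 1),
                             full_sib = c("2" = 0.5))
  )
  via_sim <- project_from_simulation(model, rates)
  model$rates <- data.frame(case_type = rates$relationship,
                            threshold = rates$t_incl,
                            fn_rate = rates$fn_rate,
                            fp_rate = rates$fp_rate)
  manual <- project(model)
  expect_equal(as.data.frame(via_sim), as.data.frame(manual))
})

test_that("the enumerated 1-locus duo scenario projects 750 of 1000", {
  fs <- toy_panel1(c(0.5, 0.5))
  rates <- exact_rates_bruteforce("parent_child", fs,
                                  decision_policy("binary", 1.5))
  model <- caseload_model(1000, 1, c(parent_child = 1),
                          list(parent_child = c("1.5" = 1)))
  tab <- project_from_simulation(model, rates)
  expect_identical(tab$expected_count[tab$arm == "related"], 750)
})

test_that("an empty mix projects an empty table with total 0", {
  model <- caseload_model(1e6, 0.72, stats::setNames(numeric(0),
                                                     character(0)),
                          list())
  tab <- project_from_simulation(model,
                                 data.frame(relationship = character(),
                                            t_incl = numeric(),
                                            fn_rate = numeric(),
                                            fp_rate = numeric()))
  expect_equal(nrow(tab), 0)
  expect_identical(attr(tab, "grand_total"), 0)
})

test_that("coverage gaps in simulated rates are reported", {
  model <- caseload_preset("table1_identifiler")
  expect_error(
    project_from_simulation(model,
                            data.frame(relationship = "trio", t_incl = 100,
                                       fn_rate = 0, fp_rate = 0)),
    "threshold 1000")
})

test_that("caseload model configurations round-trip through JSON and YAML", {
  model <- caseload_preset("table1_identifiler")
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_caseload_model(model, path)
    back <- read_caseload_model(path)
    expect_equal(back$total_cases, model$total_cases)
    expect_equal(back$casetype_mix, model$casetype_mix)
    expect_equal(back$lab_threshold_mix, model$lab_threshold_mix)
    expect_equal(project(back)$expected_count,
                 project(model)$expected_count)
  }
})

test_that("projection CSV output carries the documented columns", {
  tab <- project(caseload_preset("table1_identifiler"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_false_counts(tab, path)
  df <- read.csv(path)
  expect_true(all(c("case_type", "arm", "threshold", "lab_fraction",
                    "false_rate", "expected_count") %in% names(df)))
  expect_identical(as.integer(df$expected_count),
                   as.integer(table1_counts))
})
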