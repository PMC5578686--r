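# scenario-level behaviour of the gating model under the frozen study
# conditions; the heavy per-model comparisons against the published
# table live in test-acceptance.R

test_that("full-strength locks hold while strongly reduced locks open", {
  locked <- c(1, 2, 6)
  open <- c(3, 4, 5, 8, 9, 10)
  pf_locked <- vapply(locked, function(id) get_scenario(id)$pore_final, 0)
  pf_open <- vapply(open, function(id) get_scenario(id)$pore_final, 0)
  expect_true(all(pf_locked < 14))
  expect_true(all(pf_open >= 25))
  # every locked scenario is flagged not-opened and carries no stress metrics
  for (id in locked) {
    r <- get_scenario(id)
    expect_false(r$opened)
    expect_true(is.na(r$threshold_MPa))
    expect_true(is.na(r$open_state_MPa))
  }
})

test_that("threshold stress never falls below the open-state stress", {
  for (id in c(3, 4, 5, 8, 9, 10)) {
    r <- get_scenario(id)
    expect_true(r$opened)
    expect_gte(r$threshold_MPa, r$open_state_MPa)
  }
})

test_that("the G26 deletion opens the pore wider than the V16 deletion", {
  expect_gte(get_scenario(9)$pore_final, get_scenario(8)$pore_final)
})

test_that("scenario runs are deterministic (bit-for-bit)", {
  a <- run_scenario(1, defaults = test_defaults(), increments = 6)
  b <- run_scenario(1, defaults = test_defaults(), increments = 6)
  expect_identical(a$pore_final, b$pore_final)
  expect_identical(a$helix_max_MPa, b$helix_max_MPa)
})

test_that("feasibility verdicts compare stresses with yield capacities", {
  d <- test_defaults()
  zero <- list(helix_max_MPa = c(N = 0, TM1 = 0, TM2 = 0, C = 0))
  expect_true(all(feasibility_check(zero, d$helices) ==
                    "within elastic limit"))
  over <- list(helix_max_MPa = c(N = 1e5, TM1 = 0, TM2 = 0, C = 0))
  v <- feasibility_check(over, d$helices)
  expect_identical(unname(v[["N"]]), "exceeds elastic limit")
  expect_error(feasibility_check(zero, d$helices["TM1"]),
               "missing yield data")
})

test_that("tabulate renders dashes for unopened scenarios and round-trips", {
  empty <- tabulate_results(list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("model", "pore_A", "threshold_MPa") %in% names(empty)))

  res <- lapply(c(1, 3), get_scenario)
  tab <- tabulate_results(res)
  expect_identical(nrow(tab), 2L)
  expect_true(is.na(tab$threshold_MPa[1]))  # model 1 locked: "-"
  expect_false(is.na(tab$threshold_MPa[2])) # model 3 opened: number

  tp <- tempfile()
  cfg <- list(seed = 1L, note = "test")
  write_report(res, cfg, tp)
  back <- read_report_table(tp)
  expect_equal(back$pore_A, round(tab$pore_A, 2), tolerance = 1e-9)
  expect_true(is.na(back$threshold_MPa[1]))
  expect_equal(back$threshold_MPa[2], tab$threshold_MPa[2], tolerance = 0.1)
  js <- jsonlite::read_json(paste0(tp, ".json"))
  expect_identical(length(js$scenarios), 2L)
  expect_identical(js$scenarios[[1]]$model, 1L)
})

test_that("identical inputs produce byte-identical reports", {
  res <- list(get_scenario(1))
  t1 <- tempfile(); t2 <- tempfile()
  write_report(res, list(seed = 7L), t1)
  write_report(res, list(seed = 7L), t2)
  expect_identical(readLines(paste0(t1, ".json")),
                   readLines(paste0(t2, ".json")))
  expect_identical(readLines(paste0(t1, ".tsv")),
                   readLines(paste0(t2, ".tsv")))
})
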