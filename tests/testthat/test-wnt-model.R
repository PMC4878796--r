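test_that("the wildtype network has the canonical size and marking", {
  net <- build_wnt_net()
  expect_identical(length(net$places), 18L)
  expect_identical(length(net$transitions), 11L)
  expect_identical(nrow(net$arcs), 41L)
  expect_identical(nrow(validate_net(net)), 0L)
  m <- net$marking
  expect_true(all(m[c("FZD", "LRP", "DVL", "AXIN", "APC", "CK1", "GSK3")] == 5L))
  expect_identical(m[["WNT"]], 0L)
  expect_true(all(m[c("TCF/LEF", "CTNNB1_gene", "AXIN2_gene")] == 1L))
  complexes <- c("WNT/FZD/LRP", "WNT/FZD/LRP/DVL", "signalosome", "DC",
                 "DC-CTNNB1", "TCF/LEF-CTNNB1", "CTNNB1_protein")
  expect_true(all(m[complexes] == 0L))
})

test_that("scenario knobs are range-checked", {
  expect_error(wnt_scenario(wnt = 6), "between 0 and 5")
  expect_error(wnt_scenario(gsk3 = -1), "between 0 and 5")
  expect_error(wnt_scenario(axin2_feedback = 0.2), "0, 0.15")
  expect_error(wnt_scenario(apc_weight = 0.3), "one of")
})

test_that("APC mutant mode adds four component-return arcs", {
  net <- build_wnt_net(wnt_scenario(apc_weight = 0.05))
  expect_identical(nrow(net$arcs), 45L)
  ret <- outputs_of(net, "t5")
  expect_identical(ret$weight[ret$place == "DC"], 0.05)
  for (p in c("AXIN", "APC", "CK1", "GSK3")) {
    expect_identical(ret$weight[ret$place == p], 0.95)
  }
  expect_identical(nrow(validate_net(net)), 0L)
  # null mutation: DC production weight 0 is declared deliberate
  net0 <- build_wnt_net(wnt_scenario(apc_weight = 0))
  expect_identical(nrow(validate_net(net0)), 0L)
})

test_that("total beta-catenin sums the three bound and free pools", {
  expect_identical(total_beta_catenin(c("CTNNB1_protein" = 0,
                                        "DC-CTNNB1" = 0,
                                        "TCF/LEF-CTNNB1" = 0)), 0)
  expect_identical(total_beta_catenin(c("CTNNB1_protein" = 2,
                                        "DC-CTNNB1" = 1,
                                        "TCF/LEF-CTNNB1" = 1)), 4)
  expect_identical(
    total_beta_catenin(tibble::tibble(
      place = c("CTNNB1_protein", "DC-CTNNB1", "TCF/LEF-CTNNB1"),
      tokens = c(3L, 0L, 1L))), 4L)
  expect_error(total_beta_catenin(c("CTNNB1_protein" = 1)), "lacks place")
})

test_that("with GSK3 = 0 total beta-catenin equals the step number", {
  net <- build_wnt_net(wnt_scenario(gsk3 = 0))
  tr <- simulate_net(net, steps = 60, seed = 4)
  tb <- apply(tr$markings, 1, total_beta_catenin)
  expect_equal(tb, 0:60, ignore_attr = TRUE)
})

test_that("structural mass balances hold along a stimulated trace", {
  net <- build_wnt_net(wnt_scenario(wnt = 5, axin2_feedback = 0.15))
  tr <- simulate_net(net, steps = 80, seed = 6)
  mk <- tr$markings
  # receptor components are conserved across their containing complexes
  fzd <- mk[, "FZD"] + mk[, "WNT/FZD/LRP"] + mk[, "WNT/FZD/LRP/DVL"] +
    mk[, "signalosome"]
  expect_true(all(fzd == 5L))
  lrp <- mk[, "LRP"] + mk[, "WNT/FZD/LRP"] + mk[, "WNT/FZD/LRP/DVL"] +
    mk[, "signalosome"]
  expect_true(all(lrp == 5L))
  dvl <- mk[, "DVL"] + mk[, "WNT/FZD/LRP/DVL"] + mk[, "signalosome"]
  expect_true(all(dvl == 5L))
  # AXIN pool grows only by the cumulative feedback transfers
  fb_in <- cumsum(tr$transfers[, "t11 -> AXIN"])
  axin <- mk[, "AXIN"] + mk[, "signalosome"] + mk[, "DC"] + mk[, "DC-CTNNB1"]
  expect_identical(axin[-1], 5L + fb_in)
  # TCF/LEF is catalytic, gene places are never consumed
  expect_true(all(mk[, "TCF/LEF"] == 1L))
  expect_true(all(mk[, "CTNNB1_gene"] == 1L))
  expect_true(all(mk[, "AXIN2_gene"] == 1L))
  # beta-catenin bookkeeping: produced by t9 (1/step), removed by t7/t8
  tb <- apply(mk, 1, total_beta_catenin)
  produced <- cumsum(tr$firings[, "t9"])
  degraded <- cumsum(tr$firings[, "t7"] + tr$firings[, "t8"])
  expect_equal(tb[-1], produced - degraded, ignore_attr = TRUE)
})

test_that("scenario files round-trip through YAML and JSON", {
  sc <- wnt_scenario(wnt = 4, gsk3 = 2, axin2_feedback = 0.1,
                     apc_weight = 0.2, steps = 50, replicates = 10, seed = 9)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(sc), yml)
  expect_identical(read_scenario(yml), sc)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(sc), jsn, auto_unbox = TRUE)
  expect_identical(read_scenario(jsn), sc)
  bad <- tempfile(fileext = ".json")
  writeLines('{"wnt": 1, "bogus": 2}', bad)
  expect_error(read_scenario(bad), "unknown scenario field")
})
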