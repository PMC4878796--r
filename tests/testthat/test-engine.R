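test_that("enabling follows the ceiling(weight) threshold rule", {
  net3 <- chain_net(tokens = 3, w_in = 3)
  expect_true(transition_enabled(net3, transition = "t"))
  net2 <- chain_net(tokens = 2, w_in = 3)
  expect_false(transition_enabled(net2, transition = "t"))
  # a fractional input arc needs one waiting token
  netf <- chain_net(tokens = 1, w_in = 0.1, w_out = 0.1)
  expect_true(transition_enabled(netf, transition = "t"))
  netf0 <- chain_net(tokens = 0, w_in = 0.1, w_out = 0.1)
  expect_false(transition_enabled(netf0, transition = "t"))
  # reservations count against availability
  expect_false(transition_enabled(net3, transition = "t",
                                  reserved = c(src = 1L)))
  expect_error(transition_enabled(net3, transition = "zz"), "unknown")
})

test_that("a lone weight-1 transition fires once per available token", {
  set.seed(1)
  firing <- sample_step_firing(chain_net(4))
  expect_identical(firing[["t"]], 4L)
})

test_that("maximal-step firing needs 3 tokens but consumes only 1 (t10)", {
  net <- build_wnt_net()
  m <- net$marking
  m["CTNNB1_protein"] <- 3L
  set.seed(42)
  firing <- sample_step_firing(net, marking = m)
  # 3 tokens enable exactly one t10 firing; a second would need 3 unreserved
  expect_identical(firing[["t10"]], 1L)
  res <- apply_firing(net, marking = m, firing = firing)
  expect_gte(res$marking[["CTNNB1_protein"]], 2L)
})

test_that("uniform conflict resolution picks each competitor ~50%", {
  net <- conflict_net(1)
  set.seed(7)
  wins <- replicate(10000, {
    f <- sample_step_firing(net)
    expect_identical(sum(f), 1L)  # 1 token: exactly one fires
    f[["ta"]]
  })
  # binomial 95% band around 0.5 at n = 10000 is +-1%; assert a 2% band
  expect_gt(mean(wins), 0.48)
  expect_lt(mean(wins), 0.52)
})

test_that("the gene-expression pattern reproduces gene and protein tokens", {
  net <- petri_net(
    tibble::tibble(source = c("gene", "t", "t"),
                   target = c("t", "gene", "protein"),
                   weight = 1),
    places = c("gene", "protein"), transitions = "t",
    marking = c(gene = 1L)
  )
  res <- apply_firing(net, firing = c(t = 1L))
  expect_identical(res$marking[["gene"]], 1L)
  expect_identical(res$marking[["protein"]], 1L)
})

test_that("fractional credits transfer on the exact periodic schedule", {
  # w = 0.1: transfers at steps 10, 20, ..., one token each
  tr <- simulate_net(chain_net(100, 0.1, 0.1), steps = 100, seed = 3)
  snk <- tr$markings[, "snk"]
  expect_identical(which(diff(snk) > 0), seq(10L, 100L, by = 10L))
  expect_identical(snk[101], 10L)
  # w = 0.15: three transfers per 20-step window, at offsets 7, 14, 20
  tr15 <- simulate_net(chain_net(100, 0.15, 0.15), steps = 40, seed = 3)
  expect_identical(which(diff(tr15$markings[, "snk"]) > 0),
                   c(7L, 14L, 20L, 27L, 34L, 40L))
  # w = 0.05: once per 20 steps
  tr05 <- simulate_net(chain_net(100, 0.05, 0.05), steps = 60, seed = 3)
  expect_identical(which(diff(tr05$markings[, "snk"]) > 0),
                   c(20L, 40L, 60L))
})

test_that("credit only accrues while the transition is enabled", {
  # source empty: no credit, no transfer, ever
  tr <- simulate_net(chain_net(0, 0.1, 0.1), steps = 50, seed = 1)
  expect_true(all(tr$markings[, "snk"] == 0L))
  expect_true(all(tr$firings == 0L))
})

test_that("simulate_net is a pure function of (net, steps, seed)", {
  net <- build_wnt_net(wnt_scenario(wnt = 4))
  a <- simulate_net(net, steps = 30, seed = 11)
  b <- simulate_net(net, steps = 30, seed = 11)
  expect_identical(a$markings, b$markings)
  expect_identical(a$firings, b$firings)
  c <- simulate_net(net, steps = 30, seed = 12)
  expect_false(identical(a$markings, c$markings))
  expect_error(simulate_net(net, steps = 0, seed = 1), "positive")
})

test_that("a net with no transitions never changes its marking", {
  net <- petri_net(NULL, places = c("a", "b"), transitions = character(),
                   marking = c(a = 2L, b = 1L))
  tr <- simulate_net(net, steps = 5, seed = 1)
  expect_true(all(tr$markings[, "a"] == 2L))
  expect_true(all(tr$markings[, "b"] == 1L))
})

test_that("ensembles of a conflict-free net have zero spread", {
  ens <- run_ensemble(chain_net(10), steps = 10, replicates = 5, seed = 1)
  expect_true(all(ens$sd == 0))
  # one replicate: SD reported as 0 with a warning
  expect_warning(
    e1 <- run_ensemble(chain_net(10), steps = 5, replicates = 1, seed = 1),
    "single replicate"
  )
  expect_true(all(e1$sd == 0))
  expect_error(run_ensemble(chain_net(10), 5, replicates = 0, seed = 1),
               "positive")
})

test_that("trace tidiers return long tibbles with consistent totals", {
  net <- build_wnt_net(wnt_scenario(gsk3 = 0))
  tr <- simulate_net(net, steps = 10, seed = 2)
  td <- tidy(tr)
  expect_identical(nrow(td), 11L * 18L)
  expect_identical(sort(unique(td$place)), sort(net$places))
  fg <- firings_of(tr)
  expect_identical(nrow(fg), 10L * 11L)
  # t9 fires every step in every scenario
  expect_true(all(fg$count[fg$transition == "t9"] == 1L))
  g <- glance(tr)
  expect_identical(g$steps, 10L)
  expect_identical(g$n_places, 18L)
})
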