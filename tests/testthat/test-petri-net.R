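test_that("weights parse into exact reduced rationals", {
  w <- parse_weight(c(1, 3, 0.1, 0.15, 0.05, 0.2, 0))
  expect_identical(w$num, c(1L, 3L, 1L, 3L, 1L, 1L, 0L))
  expect_identical(w$den, c(1L, 1L, 10L, 20L, 20L, 5L, 1L))
  w2 <- parse_weight(c("0.15", "3/20", "2"))
  expect_identical(w2$num, c(3L, 3L, 2L))
  expect_identical(w2$den, c(20L, 20L, 1L))
  expect_error(parse_weight("abc"), "cannot parse")
  expect_error(parse_weight(1 / 3), "1/10000")
  # round trip through the decimal label
  lab <- weight_label(w$num, w$den)
  w3 <- parse_weight(lab)
  expect_identical(w3$num, w$num)
  expect_identical(w3$den, w$den)
})

test_that("a valid chain validates cleanly and the report is idempotent", {
  net <- chain_net(4)
  expect_identical(nrow(validate_net(net)), 0L)
  expect_identical(validate_net(net), validate_net(net))
})

test_that("validate_net reports each violated invariant without raising", {
  # place -> place arc
  bad <- petri_net(
    tibble::tibble(source = "a", target = "b", weight = 1),
    places = c("a", "b"), transitions = "t"
  )
  expect_identical(validate_net(bad)$rule, "bipartiteness")

  # dangling endpoint, duplicate arc, zero and negative weights, bad marking
  bad2 <- petri_net(
    tibble::tibble(source = c("a", "a", "t", "t", "ghost"),
                   target = c("t", "t", "a", "b", "t"),
                   weight = c(1, 1, 0, -2, 1)),
    places = c("a", "b"), transitions = "t",
    marking = c(a = -1L)
  )
  rules <- validate_net(bad2)$rule
  expect_setequal(
    unique(rules),
    c("duplicate-arc", "zero-weight", "negative-weight",
      "dangling-endpoint", "marking-negative")
  )

  # shared place/transition name
  bad3 <- petri_net(
    tibble::tibble(source = "x", target = "x", weight = 1),
    places = "x", transitions = "x"
  )
  expect_true("disjoint-names" %in% validate_net(bad3)$rule)
})

test_that("zero weight is legal only for arcs declared zero_ok", {
  arcs <- tibble::tibble(source = c("a", "t"), target = c("t", "b"),
                         weight = c(1, 0))
  flagged <- petri_net(arcs, places = c("a", "b"), transitions = "t")
  expect_true("zero-weight" %in% validate_net(flagged)$rule)
  allowed <- petri_net(arcs, places = c("a", "b"), transitions = "t",
                       zero_ok = "t -> b")
  expect_identical(nrow(validate_net(allowed)), 0L)
})

test_that("inputs_of and outputs_of partition incident arcs exactly", {
  net <- build_wnt_net()
  # gene-expression pattern on t9: gene is input and also read-arc output
  expect_identical(inputs_of(net, "t9")$place, "CTNNB1_gene")
  expect_identical(inputs_of(net, "t9")$num, 1L)
  expect_setequal(outputs_of(net, "t9")$place,
                  c("CTNNB1_gene", "CTNNB1_protein"))
  # t10 needs 3 beta-catenin tokens, returns 2
  t10_in <- inputs_of(net, "t10")
  expect_identical(t10_in$weight[t10_in$place == "CTNNB1_protein"], 3)
  t10_out <- outputs_of(net, "t10")
  expect_identical(t10_out$weight[t10_out$place == "CTNNB1_protein"], 2)
  # per direction the incident sets are disjoint and jointly cover the arcs
  for (t in net$transitions) {
    inn <- inputs_of(net, t)
    out <- outputs_of(net, t)
    expect_false(any(duplicated(inn$place)))
    expect_false(any(duplicated(out$place)))
    incident <- sum(net$arcs$source == t | net$arcs$target == t)
    expect_identical(nrow(inn) + nrow(out), incident)
  }
  expect_error(inputs_of(net, "t99"), "unknown transition")
})

test_that("a transition with no arcs yields two empty sets", {
  net <- petri_net(
    tibble::tibble(source = "a", target = "t1", weight = 1),
    places = "a", transitions = c("t1", "lonely")
  )
  expect_identical(nrow(inputs_of(net, "lonely")), 0L)
  expect_identical(nrow(outputs_of(net, "lonely")), 0L)
})

test_that("initial marking defaults to zero and round-trips as a tibble", {
  net <- chain_net(4)
  m <- initial_marking(net)
  expect_identical(m$tokens[m$place == "src"], 4L)
  expect_identical(m$tokens[m$place == "snk"], 0L)
})
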