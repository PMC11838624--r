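test_that("threshold rule reproduces the worked one-bit optimum and cost limits", {
  b <- bundle_fixture()
  expect_equal(strategy_label(optimal_strategy(1, b)), "n=1:01")

  # free intervention: intervene on every history
  cheap <- model_bundle(system_model(0.1, 0.3), detector_model(0.2, 0.8),
                        cost_model(K = 1e-9, S = c(0, 0, 0)), strict = FALSE)
  expect_true(all(unclass(optimal_strategy(2, cheap)) == 1L))
  # intervention as costly as the abnormality: never intervene
  dear <- model_bundle(system_model(0.1, 0.3), detector_model(0.2, 0.8),
                       cost_model(K = 1 - 1e-9, S = c(0, 0, 0)), strict = FALSE)
  expect_true(all(unclass(optimal_strategy(2, dear)) == 0L))
})

test_that("threshold rule matches exhaustive enumeration", {
  b <- bundle_fixture(S = c(0, 0.01, 0.02))
  expect_identical(unclass(brute_force_optimal(1, b)),
                   unclass(optimal_strategy(1, b)))
  expect_identical(unclass(brute_force_optimal(2, b)),
                   unclass(optimal_strategy(2, b)))
  # high K suppresses all intervention
  highK <- bundle_fixture(S = c(0, 0.01, 0.02))
  highK$costs$K <- 0.9
  expect_true(all(unclass(brute_force_optimal(2, highK)) == 0L))

  expect_error(brute_force_optimal(5, b), "refused")

  set.seed(808)
  for (i in 1:30) {
    bb <- random_strict_bundle(max_depth = 3)
    for (n in 1:3) {
      expect_identical(unclass(brute_force_optimal(n, bb)),
                       unclass(optimal_strategy(n, bb)))
    }
  }
})

test_that("loss of the optimum never increases with depth at equal cost", {
  set.seed(909)
  for (i in 1:10) {
    bb <- random_strict_bundle(max_depth = 4)
    bb$costs$S[] <- 0  # equal (zero) surveillance cost at every depth
    losses <- vapply(1:4, function(n) {
      expected_loss(optimal_strategy(n, bb), bb)$value
    }, numeric(1))
    expect_true(all(diff(losses) <= 1e-12))
  }
})

test_that("protocol selection reproduces the three-way one-bit comparison", {
  b <- bundle_fixture()
  choice <- select_protocol(1, b)
  expect_equal(strategy_label(choice$chosen), "n=1:01")
  expect_equal(choice$loss$value, 0.20)
  expect_identical(nrow(choice$ranking), 3L)
  expect_setequal(choice$ranking$label, c("never", "always", "n=1:01"))
  expect_equal(choice$ranking$loss, sort(choice$ranking$loss))

  # prohibitive surveillance cost: fall back to the no-surveillance rule
  dear <- bundle_fixture(S = c(0, 10))
  expect_equal(strategy_label(select_protocol(1, dear)$chosen), "never")  # a1 < K

  # K above every 1-bit posterior: never intervene even with cheap data
  hiK <- bundle_fixture()
  post_max <- max(posterior_abnormal("0", hiK), posterior_abnormal("1", hiK))
  hiK$costs$K <- min(post_max + 0.05, 0.99)
  expect_equal(strategy_label(select_protocol(1, hiK)$chosen), "never")

  expect_error(select_protocol(3, b), "depth n")
})

test_that("two-bit selection lands in the five-strategy family", {
  # the candidate set the analysis reduces to: never, always, last-bit,
  # both-bits-1, at-least-one-bit-1 (plus, per the open question, any
  # other theta-optimal 2-bit table -- log, don't fail, if one appears)
  family <- c("never", "always", "n=1:01", "n=2:0001", "n=2:0111",
              "n=2:0000", "n=2:1111", "n=2:0101")
  set.seed(1010)
  outside <- character(0)
  for (i in 1:100) {
    b <- random_strict_bundle(max_depth = 2)
    lab <- strategy_label(select_protocol(2, b)$chosen)
    if (!lab %in% family) outside <- c(outside, lab)
  }
  if (length(outside) > 0) {
    message("2-bit winners outside the canonical family: ",
            paste(unique(outside), collapse = ", "))
  }
  expect_length(outside, 0)
})

test_that("phase diagram partitions the (K, S1) plane into the three regions", {
  b <- bundle_fixture()
  grid <- phase_diagram(phase_axis("K", 0.01, 0.99, 41),
                        phase_axis("S1", 0, 0.3, 31),
                        b, max_n = 1)
  labs <- unique(as.vector(grid$labels))
  expect_setequal(labs, c("never", "always", "n=1:01"))

  # S1 = 0 row boundary: always wins iff K < a1 = 0.25 (surveillance ties
  # resolve to the cheaper depth when the bit adds nothing)
  a1 <- 0.25
  col0 <- grid$labels[, 1]
  Ks <- grid$axis1$values
  expect_true(all(col0[Ks > a1] != "always"))
  # surveillance never wins once S1 exceeds both baselines' losses
  high <- grid$axis2$values > pmax(a1, max(Ks))
  expect_true(all(grid$labels[, high] %in% c("never", "always")))

  # monotone shrinkage: along increasing S1 at fixed K, once surveillance
  # stops winning it never wins again
  for (i in seq_along(Ks)) {
    surv <- as.integer(grid$labels[i, ] == "n=1:01")
    expect_true(all(diff(surv) <= 0))
  }
})

test_that("every phase-grid cell re-validates through select_protocol", {
  b <- bundle_fixture()
  grid <- phase_diagram(phase_axis("K", 0.05, 0.95, 13),
                        phase_axis("S1", 0, 0.25, 11),
                        b, max_n = 1)
  set.seed(1111)
  cells <- cbind(sample(13, 40, replace = TRUE), sample(11, 40, replace = TRUE))
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]
    bb <- model_bundle(
      b$system, b$detector,
      cost_model(K = grid$axis1$values[i], S = c(0, grid$axis2$values[j])),
      strict = FALSE
    )
    expect_identical(grid$labels[i, j],
                     strategy_label(select_protocol(1, bb)$chosen))
  }
  # degenerate 1x1 grid equals a single selection
  g1 <- phase_diagram(phase_axis("K", 0.4, 0.4, 1), phase_axis("S1", 0.01, 0.01, 1),
                      b, max_n = 1)
  expect_identical(as.vector(g1$labels), "n=1:01")

  expect_error(phase_diagram(phase_axis("K", 0.1, 0.9, 5),
                             phase_axis("K", 0.1, 0.9, 5), b, 1),
               "different parameters")
  expect_error(phase_axis("K", 1, 0, 5), "invalid axis range")
  expect_error(phase_axis("bogus", 0, 1, 5), "unknown axis parameter")
})

test_that("selection tie rules prefer smaller depth and fewer interventions", {
  # with S1 = 0 and an uninformative detector (lenient), every 1-bit
  # strategy ties a depth-0 baseline; the depth-0 one must be chosen
  flat <- model_bundle(system_model(0.1, 0.3), detector_model(0.5, 0.5),
                       cost_model(K = 0.4, S = c(0, 0)), strict = FALSE)
  choice <- select_protocol(1, flat)
  expect_equal(strategy_depth(choice$chosen), 0L)
  expect_equal(strategy_label(choice$chosen), "never")  # a1 = 0.25 < K
})
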