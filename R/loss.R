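#' Expected cost per unit time with no surveillance
#'
#' The two depth-0 baselines: always intervening costs `K` per step;
#' never intervening costs `a1` per step (the stationary abnormal
#' fraction). Comparing the two gives the no-surveillance rule: always
#' intervene if `a1 > K`, never otherwise.
#'
#' @param action 1 = always intervene, 0 = never intervene.
#' @param bundle A [model_bundle()].
#' @return A `loss_value` (see [expected_loss()]).
#' @export
loss_no_surveillance <- function(action, bundle) {
  stopifnot(inherits(bundle, "model_bundle"), action %in% c(0, 1))
  expected_loss(strategy(0, action), bundle)
}

#' Exact expected cost per unit time of a strategy
#'
#' The steady-state loss of running depth-`n` surveillance with decision
#' table `Y` is
#' `L_n(Y) = a1 + S_n - sum over histories b with Y(b) = 1 of Delta(b)`:
#' start from the never-intervene cost `a1`, pay the surveillance cost,
#' and bank the (signed) saving `Delta(b)` for every history on which the
#' table intervenes. This is exact, not a simulation estimate; the
#' simulator in this package is its empirical oracle.
#'
#' @param strat A [strategy()].
#' @param bundle A [model_bundle()] whose cost model has an `S` entry for
#'   the strategy's depth.
#' @return An object of class `loss_value`: list with `value` (the loss,
#'   in units of the abnormality cost), `strategy`, and `S_n` (the depth
#'   cost used).
#' @examples
#' b <- model_bundle(system_model(0.1, 0.3), detector_model(0.2, 0.8),
#'                   cost_model(K = 0.4, S = c(0, 0.01)))
#' expected_loss(strategy(1, c(0, 1)), b)$value  # 0.20
#' @export
expected_loss <- function(strat, bundle) {
  stopifnot(is_strategy(strat), inherits(bundle, "model_bundle"))
  n <- strategy_depth(strat)
  S_n <- surveillance_cost(bundle$costs, n)
  a1 <- stationary_abnormal_prob(bundle$system)
  value <- a1 + S_n
  if (n == 0) {
    # empty history: Delta of the (only) history is a1 - K by the sum rule
    if (strat[[1]] == 1L) value <- value - (a1 - bundle$costs$K)
  } else {
    on_hists <- names(strat)[unclass(strat) == 1L]
    for (h in on_hists) value <- value - delta_stat(h, bundle)
  }
  structure(list(value = value, strategy = strat, S_n = S_n),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("<loss_value> %s: expected cost/step = %.6g (S_n = %g)\n",
              strategy_label(x$strategy), x$value, x$S_n))
  invisible(x)
}

#' @export
as.numeric.loss_value <- function(x, ...) x$value
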