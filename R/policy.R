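#' Optimal strategy at a fixed surveillance depth
#'
#' The loss `L_n` is linear in the decision table with per-history
#' coefficients `-Delta(b)`, so it is minimized term by term: intervene on
#' history `b` exactly when `Delta(b) > 0` (Heaviside rule). An exact tie
#' `Delta(b) = 0` resolves to action 0 — both actions cost the same and
#' the package prefers the minimal-action table.
#'
#' @param n Surveillance depth, `n >= 1`.
#' @param bundle A [model_bundle()].
#' @return The loss-minimizing depth-`n` [strategy()].
#' @examples
#' b <- model_bundle(system_model(0.1, 0.3), detector_model(0.2, 0.8),
#'                   cost_model(K = 0.4, S = c(0, 0.01)))
#' strategy_label(optimal_strategy(1, b))  # "n=1:01"
#' @export
optimal_strategy <- function(n, bundle) {
  stopifnot(inherits(bundle, "model_bundle"), n >= 1)
  strategy(n, as.integer(delta_vec(n, bundle) > 0))
}

#' Exhaustive-search optimal strategy (test oracle)
#'
#' Evaluates [expected_loss()] arithmetic for every one of the
#' `2^(2^n)` depth-`n` decision tables and returns the argmin. Exists to
#' independently confirm [optimal_strategy()]; refuse-by-design above
#' `n = 4` (65,536 tables).
#'
#' Ties in loss resolve exactly as elsewhere in the package: fewer
#' interventions first, then the lexicographically smallest action string.
#'
#' @inheritParams optimal_strategy
#' @return The loss-minimizing depth-`n` [strategy()].
#' @export
brute_force_optimal <- function(n, bundle) {
  stopifnot(inherits(bundle, "model_bundle"), n >= 1)
  if (n > 4) {
    stop(sprintf("brute force enumeration refused for n = %d (2^(2^%d) strategies); max n = 4",
                 n, n), call. = FALSE)
  }
  hists <- all_histories(n)
  m <- length(hists)
  d <- vapply(hists, delta_stat, numeric(1), bundle = bundle)
  a1 <- stationary_abnormal_prob(bundle$system)
  base <- a1 + surveillance_cost(bundle$costs, n)
  masks <- 0:(2^m - 1)
  # action matrix: column j = action on hists[j]; history j maps to bit
  # (m - j) so that the integer order of masks is the lexicographic order
  # of action strings
  M <- vapply(seq_len(m), function(j) bitwAnd(masks, bitwShiftL(1L, m - j)) > 0,
              logical(length(masks)))
  losses <- base - as.vector(M %*% d)
  ones <- rowSums(M)
  # masks ascend lexicographically, so which.min of (loss, ones) order works
  best <- order(losses, ones)[1]
  strategy(n, as.integer(M[best, ]))
}

# Delta statistics for every length-n history at once, in lexicographic
# history order. Same forward recursion as delta_stat, vectorized across
# all histories: extending every history by one bit doubles the row count,
# with child rows 2k-1 (bit 0) and 2k (bit 1) preserving lexicographic
# order. O(2^n) total.
delta_vec <- function(n, bundle) {
  sys <- bundle$system; det <- bundle$detector
  a1 <- stationary_abnormal_prob(sys)
  # columns: unnormalized joint with final state normal / abnormal
  alpha <- rbind(c((1 - a1) * det$p00, a1 * det$p10),
                 c((1 - a1) * det$p01, a1 * det$p11))
  if (n > 1) {
    for (i in 2:n) {
      m0 <- alpha[, 1] * sys$q00 + alpha[, 2] * sys$q10
      m1 <- alpha[, 1] * sys$q01 + alpha[, 2] * sys$q11
      alpha <- matrix(0, nrow = 2 * nrow(alpha), ncol = 2)
      odd <- seq(1, nrow(alpha), by = 2)
      alpha[odd, 1] <- m0 * det$p00; alpha[odd, 2] <- m1 * det$p10
      alpha[odd + 1, 1] <- m0 * det$p01; alpha[odd + 1, 2] <- m1 * det$p11
    }
  }
  K <- bundle$costs$K
  (1 - K) * alpha[, 2] - K * alpha[, 1]
}

# Loss-equality tie tolerance. Candidate losses that are equal in exact
# arithmetic (e.g. the all-ones table vs always-intervene at S_n = 0) can
# differ by ~1e-16 in floating point; ordering on rounded losses restores
# the intended tie rules. 1e-10 is far below any meaningful cost
# difference and far above accumulated rounding error.
round_loss <- function(x) round(x, 10)

# Candidate strategies and exact losses for depths 0..max_n: the two
# no-surveillance baselines plus the per-depth Heaviside optimum, ordered
# by (loss, depth, interventions, label). Shared by select_protocol and
# the phase-diagram classifier so both apply identical arithmetic and tie
# rules. Kept lean: phase diagrams call this tens of thousands of times.
protocol_candidates <- function(bundle, max_n) {
  a1 <- stationary_abnormal_prob(bundle$system)
  K <- bundle$costs$K
  label <- c("never", "always")
  loss <- c(a1, K)
  depth <- c(0L, 0L)
  ones <- c(0, 1)
  if (max_n >= 1) {
    for (n in seq_len(max_n)) {
      S_n <- surveillance_cost(bundle$costs, n)  # errors if S[n] missing
      d <- delta_vec(n, bundle)
      on <- d > 0
      label <- c(label, sprintf("n=%d:%s", n,
                                paste(as.integer(on), collapse = "")))
      loss <- c(loss, a1 + S_n - sum(d[on]))
      depth <- c(depth, as.integer(n))
      ones <- c(ones, sum(on))
    }
  }
  ord <- order(round_loss(loss), depth, ones, label)
  list(label = label[ord], n = depth[ord],
       S_n = unname(bundle$costs$S[depth[ord] + 1L]), loss = loss[ord])
}

#' Select the best protocol across surveillance depths
#'
#' Compares never-intervene, always-intervene, and the optimal depth-`n`
#' strategy for each `n = 1..max_n`, and returns the candidate with the
#' lowest exact expected cost per unit time. At `max_n = 1` this is the
#' three-way comparison `L0(0)` vs `L0(1)` vs `L1(0,1)`-type; at
#' `max_n = 2` it reproduces the five-way comparison over
#' \{never, always, best 1-bit, best 2-bit\}.
#'
#' Exact loss ties resolve to the smaller depth, then the table with fewer
#' interventions, then the lexicographically smallest action string:
#' cheaper and simpler protocols win ties.
#'
#' @param max_n Largest surveillance depth to consider (`>= 0`).
#' @param bundle A [model_bundle()] with `S` entries up to `max_n`.
#' @return An object of class `protocol_choice`: list with `chosen` (a
#'   [strategy()]), `loss` (its `loss_value`), and `ranking` (data frame
#'   of all candidates in ascending loss order, columns `label`, `n`,
#'   `S_n`, `loss`).
#' @examples
#' b <- model_bundle(system_model(0.1, 0.3), detector_model(0.2, 0.8),
#'                   cost_model(K = 0.4, S = c(0, 0.01)))
#' select_protocol(1, b)
#' @export
select_protocol <- function(max_n, bundle) {
  stopifnot(inherits(bundle, "model_bundle"), max_n >= 0)
  cand <- protocol_candidates(bundle, max_n)
  strategies <- lapply(cand$label, parse_strategy)
  losses <- Map(function(s, l, S_n) {
    structure(list(value = l, strategy = s, S_n = S_n), class = "loss_value")
  }, strategies, cand$loss, cand$S_n)
  ranking <- structure(
    list(label = cand$label, n = cand$n, S_n = cand$S_n, loss = cand$loss),
    class = "data.frame", row.names = seq_along(cand$label)
  )
  structure(
    list(chosen = strategies[[1]],
         loss = losses[[1]],
         ranking = ranking,
         alternatives = Map(list, strategy = strategies, loss = losses)),
    class = "protocol_choice"
  )
}

#' @export
print.protocol_choice <- function(x, ...) {
  cat("<protocol_choice>\n")
  cat(sprintf("  chosen: %s  (expected cost/step = %.6g)\n",
              strategy_label(x$chosen), x$loss$value))
  cat("  ranking:\n")
  df <- x$ranking
  rownames(df) <- NULL
  print(df, row.names = FALSE)
  invisible(x)
}

#' Axis specification for a phase diagram
#'
#' @param param Parameter swept along the axis: `"K"`, `"S1"`, `"S2"`, ...
#'   or one of `"q01"`, `"q10"`, `"p01"`, `"p11"`.
#' @param from,to Inclusive range endpoints.
#' @param steps Number of grid points (`>= 1`).
#' @return An object of class `phase_axis`.
#' @export
phase_axis <- function(param, from, to, steps) {
  ok <- grepl("^S[0-9]+$", param) || param %in% c("K", "q01", "q10", "p01", "p11")
  if (!ok) stop(sprintf("unknown axis parameter '%s'", param), call. = FALSE)
  if (!is.finite(from) || !is.finite(to) || from > to || steps < 1) {
    stop("invalid axis range", call. = FALSE)
  }
  structure(list(param = param,
                 values = if (steps == 1) from else seq(from, to, length.out = steps)),
            class = "phase_axis")
}

# Rebuild a bundle with one named parameter overridden. Leniently
# validated: phase-diagram axes legitimately sweep K (and others) across
# the full [0, 1] range, outside the strict regime.
override_param <- function(bundle, param, value) {
  sys <- bundle$system; det <- bundle$detector; cst <- bundle$costs
  q01 <- sys$q01; q10 <- sys$q10; p01 <- det$p01; p11 <- det$p11
  K <- cst$K; S <- unname(cst$S)
  if (grepl("^S[0-9]+$", param)) {
    depth <- as.integer(sub("^S", "", param))
    if (depth == 0 && value != 0) stop("S0 must stay 0", call. = FALSE)
    if (length(S) < depth + 1) S <- c(S, rep(0, depth + 1 - length(S)))
    S[depth + 1] <- value
  } else {
    assign(param, value)
  }
  if (any(c(q01, q10, p01, p11) < 0) || any(c(q01, q10, p01, p11) > 1) ||
      (q01 == 0 && q10 == 0) || value < 0) {
    stop(sprintf("axis value %g for %s leaves the model invalid", value, param),
         call. = FALSE)
  }
  structure(
    list(system = structure(list(q01 = q01, q10 = q10,
                                 q00 = 1 - q01, q11 = 1 - q10),
                            class = "system_model"),
         detector = structure(list(p01 = p01, p11 = p11,
                                   p00 = 1 - p01, p10 = 1 - p11),
                              class = "detector_model"),
         costs = structure(list(K = K, S = stats::setNames(S, as.character(seq_along(S) - 1L))),
                           class = "cost_model"),
         strict = FALSE),
    class = "model_bundle"
  )
}

#' Phase diagram: winning protocol across a 2-D parameter sweep
#'
#' Classifies every point of a rectangular grid by the label of the
#' minimum-loss protocol there ([select_protocol()] semantics, identical
#' tie rules, pointwise exact arithmetic — no analytic boundary tracing).
#' With `max_n = 1` and axes `(K, S1)` this reproduces the three-region
#' structure: never intervene at high K, always intervene at low K, and a
#' bounded surveillance triangle in between that vanishes once `S1` is
#' large enough.
#'
#' @param axis1,axis2 [phase_axis()] specifications (axis1 varies along
#'   rows of the result, axis2 along columns).
#' @param bundle A [model_bundle()] supplying every parameter not on an
#'   axis.
#' @param max_n Largest surveillance depth considered at each cell.
#' @return An object of class `phase_grid`: list with `labels` (character
#'   matrix, `length(axis1$values)` x `length(axis2$values)`), `axis1`,
#'   `axis2`, `max_n`.
#' @export
phase_diagram <- function(axis1, axis2, bundle, max_n) {
  stopifnot(inherits(axis1, "phase_axis"), inherits(axis2, "phase_axis"),
            inherits(bundle, "model_bundle"))
  if (axis1$param == axis2$param) {
    stop("the two axes must sweep different parameters", call. = FALSE)
  }
  v1 <- axis1$values; v2 <- axis2$values
  labels <- matrix(NA_character_, nrow = length(v1), ncol = length(v2))
  for (j in seq_along(v2)) {
    bj <- override_param(bundle, axis2$param, v2[j])
    for (i in seq_along(v1)) {
      bij <- override_param(bj, axis1$param, v1[i])
      labels[i, j] <- protocol_candidates(bij, max_n)$label[1]
    }
  }
  structure(list(labels = labels, axis1 = axis1, axis2 = axis2,
                 max_n = max_n),
            class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf("<phase_grid> %d x %d over %s x %s (max_n = %d)\n",
              nrow(x$labels), ncol(x$labels),
              x$axis1$param, x$axis2$param, x$max_n))
  tab <- sort(table(x$labels), decreasing = TRUE)
  for (lab in names(tab)) {
    cat(sprintf("  %-12s %6d cells (%.1f%%)\n", lab, tab[[lab]],
                100 * tab[[lab]] / length(x$labels)))
  }
  invisible(x)
}
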