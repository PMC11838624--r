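#' Two-state hidden system model
#'
#' The monitored system is a discrete-time Markov chain on \{normal = 0,
#' abnormal = 1\}. Only the two switching probabilities are stored; the
#' staying probabilities `q00 = 1 - q01` and `q11 = 1 - q10` are always
#' derived so that each row of the transition matrix sums to one exactly.
#'
#' @param q01 Probability of switching normal -> abnormal in one step.
#' @param q10 Probability of switching abnormal -> normal in one step.
#'
#' @return An object of class `system_model` with elements `q01`, `q10`,
#'   `q00`, `q11`.
#' @examples
#' sys <- system_model(q01 = 0.1, q10 = 0.3)
#' stationary_abnormal_prob(sys)  # 0.25
#' @export
system_model <- function(q01, q10) {
  check_prob(q01, "q01")
  check_prob(q10, "q10")
  if (q01 == 0 && q10 == 0) {
    stop("q01 = q10 = 0: stationary distribution is not unique", call. = FALSE)
  }
  structure(
    list(q01 = q01, q10 = q10, q00 = 1 - q01, q11 = 1 - q10),
    class = "system_model"
  )
}

#' Binary detector (emission) model
#'
#' At each time step the detector reports one bit, drawn Bernoulli
#' conditionally on the same-time hidden state: `P(1 | normal) = p01` and
#' `P(1 | abnormal) = p11`. Complements `p00`, `p10` are derived, never
#' stored, so normalization is exact.
#'
#' @param p01 Probability of observing 1 while the system is normal
#'   (type I error rate of the raw bit).
#' @param p11 Probability of observing 1 while the system is abnormal
#'   (sensitivity of the raw bit).
#'
#' @return An object of class `detector_model` with elements `p01`, `p11`,
#'   `p00`, `p10`.
#' @export
detector_model <- function(p01, p11) {
  check_prob(p01, "p01", open = FALSE)
  check_prob(p11, "p11", open = FALSE)
  structure(
    list(p01 = p01, p11 = p11, p00 = 1 - p01, p10 = 1 - p11),
    class = "detector_model"
  )
}

#' Normalized cost model
#'
#' All costs are dimensionless, measured relative to the cost `c` of one
#' time step spent abnormal without intervention. `K = k/c` is the
#' per-intervention cost and `S[n] = s_n/c` the per-step cost of running
#' surveillance at depth `n`. Raw costs `k`, `c`, `s` may be supplied
#' instead and are divided through immediately.
#'
#' @param K Normalized intervention cost, `k/c`. Either `K` or both `k`
#'   and `c` must be given.
#' @param S Numeric vector of normalized surveillance costs for depths
#'   `0, 1, 2, ...` (first element is depth 0 and must be 0). Defaults to
#'   `0`, i.e. only depth-0 (no surveillance) protocols are costed.
#' @param k,c,s Optional raw costs; `K = k/c`, `S = s/c`.
#'
#' @return An object of class `cost_model` with elements `K` and `S`
#'   (named `"0"`, `"1"`, ...).
#' @export
cost_model <- function(K = NULL, S = 0, k = NULL, c = NULL, s = NULL) {
  if (is.null(K)) {
    if (is.null(k) || is.null(c)) {
      stop("supply K, or both k and c", call. = FALSE)
    }
    if (c <= 0) stop("c must be positive", call. = FALSE)
    K <- k / c
    if (!is.null(s)) S <- s / c
  }
  if (!is.numeric(K) || length(K) != 1 || !is.finite(K) || K < 0) {
    stop("K must be a single finite nonnegative number", call. = FALSE)
  }
  if (!is.numeric(S) || length(S) < 1 || any(!is.finite(S)) || any(S < 0)) {
    stop("S must be a nonempty vector of finite nonnegative numbers",
         call. = FALSE)
  }
  if (S[1] != 0) {
    stop("S[0] (depth-0 surveillance cost) must be 0", call. = FALSE)
  }
  if (length(S) > 1 && any(diff(S) < 0)) {
    warning("surveillance cost S decreases with depth n somewhere; ",
            "permitted, but unusual", call. = FALSE)
  }
  names(S) <- as.character(seq_along(S) - 1L)
  structure(list(K = K, S = S), class = "cost_model")
}

#' Surveillance cost for a given depth
#'
#' @param costs A [cost_model()].
#' @param n Surveillance depth (number of bits in the decision window).
#' @return `S[n]` as a single number.
#' @export
surveillance_cost <- function(costs, n) {
  stopifnot(inherits(costs, "cost_model"))
  idx <- n + 1L
  if (n < 0 || idx > length(costs$S)) {
    stop(sprintf("no surveillance cost configured for depth n = %d (S has entries for n = 0..%d)",
                 n, length(costs$S) - 1L), call. = FALSE)
  }
  unname(costs$S[idx])
}

#' Bundle of system, detector and cost models
#'
#' Aggregates the three parameter groups and validates them jointly. With
#' `strict = TRUE` (default) the modeled regime's assumptions are enforced:
#' the detector is informative (`p11 > p01`), the chain is persistent
#' (`q01 < 1/2`, `q10 < 1/2`) and intervention is worthwhile (`0 < K < 1`).
#' With `strict = FALSE` only range and normalization constraints are
#' enforced; every formula in the package remains algebraically valid there.
#'
#' @param system A [system_model()].
#' @param detector A [detector_model()].
#' @param costs A [cost_model()].
#' @param strict Enforce the strict modeling assumptions (default `TRUE`).
#'
#' @return An object of class `model_bundle`.
#' @examples
#' b <- model_bundle(
#'   system_model(0.1, 0.3),
#'   detector_model(p01 = 0.2, p11 = 0.8),
#'   cost_model(K = 0.4, S = c(0, 0.01))
#' )
#' @export
model_bundle <- function(system, detector, costs, strict = TRUE) {
  stopifnot(inherits(system, "system_model"),
            inherits(detector, "detector_model"),
            inherits(costs, "cost_model"))
  bundle <- structure(
    list(system = system, detector = detector, costs = costs,
         strict = isTRUE(strict)),
    class = "model_bundle"
  )
  viol <- validate_bundle(bundle, strict = strict)
  if (length(viol) > 0) {
    stop("invalid model bundle:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  bundle
}

#' Validate a model bundle
#'
#' Reporting counterpart of the constructor checks: returns a character
#' vector of violated constraints (empty when valid) instead of erroring.
#'
#' @param bundle A `model_bundle` (or a bare list with the same fields).
#' @param strict If `TRUE`, also report violations of the strict modeling
#'   assumptions `p11 > p01`, `q00 > q01`, `q11 > q10` and `0 < K < 1`.
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_bundle <- function(bundle, strict = TRUE) {
  sys <- bundle$system; det <- bundle$detector; cst <- bundle$costs
  v <- character(0)
  rng <- function(x, nm, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi)
      sprintf("%s must be in [%g, %g]", nm, lo, hi)
  }
  v <- c(v, rng(sys$q01, "q01"), rng(sys$q10, "q10"),
         rng(det$p01, "p01"), rng(det$p11, "p11"))
  if (sys$q01 == 0 && sys$q10 == 0) {
    v <- c(v, "q01 = q10 = 0: stationary distribution undefined")
  }
  if (cst$K < 0) v <- c(v, "K must be nonnegative")
  if (any(cst$S < 0)) v <- c(v, "all S[n] must be nonnegative")
  if (cst$S[1] != 0) v <- c(v, "S[0] must be 0")
  if (isTRUE(strict)) {
    if (!(det$p11 > det$p01)) v <- c(v, "p11 > p01 (informative detector)")
    if (!(sys$q00 > sys$q01)) v <- c(v, "q00 > q01 (i.e. q01 < 1/2)")
    if (!(sys$q11 > sys$q10)) v <- c(v, "q11 > q10 (i.e. q10 < 1/2)")
    if (!(cst$K > 0 && cst$K < 1)) v <- c(v, "K < 1 (intervention cheaper than abnormality, K = k/c with k < c) and K > 0")
  }
  v
}

#' Stationary probability of the abnormal state
#'
#' The chain's unique stationary distribution puts mass
#' `a1 = q01 / (q01 + q10)` on the abnormal state. This is the prior
#' probability of abnormality at any time, absent observations.
#'
#' @param system A [system_model()].
#' @return `a1`, a single probability. The normal-state mass is `1 - a1`.
#' @export
stationary_abnormal_prob <- function(system) {
  stopifnot(inherits(system, "system_model"))
  system$q01 / (system$q01 + system$q10)
}

#' One-step propagation of the abnormality probability
#'
#' Applies the recurrence `a1(t) = a1(t-1) (1 - q10) + (1 - a1(t-1)) q01`.
#' Its unique fixed point is [stationary_abnormal_prob()]; iteration
#' converges geometrically at rate `|1 - q01 - q10|`.
#'
#' @param a1_t Current probability of being abnormal (vectorized).
#' @param system A [system_model()].
#' @return Next-step probability of being abnormal, same length as `a1_t`.
#' @export
propagate_prior <- function(a1_t, system) {
  stopifnot(inherits(system, "system_model"))
  if (any(!is.finite(a1_t)) || any(a1_t < 0) || any(a1_t > 1)) {
    stop("a1_t must be a probability in [0, 1]", call. = FALSE)
  }
  a1_t * (1 - system$q10) + (1 - a1_t) * system$q01
}

# range check for a single probability; open = TRUE excludes the endpoints
check_prob <- function(x, nm, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    stop(sprintf("%s must be a single probability in %s", nm,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.model_bundle <- function(x, ...) {
  a1 <- stationary_abnormal_prob(x$system)
  cat("<model_bundle>\n")
  cat(sprintf("  system:   q01 = %g, q10 = %g  (stationary a1 = %g)\n",
              x$system$q01, x$system$q10, a1))
  cat(sprintf("  detector: p01 = %g, p11 = %g\n",
              x$detector$p01, x$detector$p11))
  cat(sprintf("  costs:    K = %g, S = [%s]\n",
              x$costs$K, paste(format(x$costs$S), collapse = ", ")))
  cat(sprintf("  strict:   %s\n", x$strict))
  invisible(x)
}
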