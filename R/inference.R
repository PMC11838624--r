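#' @keywords internal
# Coerce a history argument (bit string "011" or numeric vector c(0,1,1),
# oldest observation first) to an integer bit vector. Empty histories are
# rejected: the decision statistics are defined for n >= 1.
as_history <- function(history) {
  if (is.character(history)) {
    stopifnot(length(history) == 1)
    if (!nzchar(history)) {
      stop("history must contain at least one bit", call. = FALSE)
    }
    if (!grepl("^[01]+$", history)) {
      stop(sprintf("history string '%s' must be bits", history),
           call. = FALSE)
    }
    history <- as.integer(strsplit(history, "")[[1]])
  }
  history <- as.integer(history)
  if (length(history) == 0) {
    stop("history must contain at least one bit", call. = FALSE)
  }
  if (any(is.na(history)) || !all(history %in% c(0L, 1L))) {
    stop("history bits must be 0 or 1", call. = FALSE)
  }
  history
}

# Forward filter: unnormalized joint P(history, final hidden state).
# Returns c(normal, abnormal). Linear in n — the literal hidden-path sum
# is exponential and survives only as a test oracle.
forward_joint <- function(bits, bundle) {
  sys <- bundle$system; det <- bundle$detector
  a1 <- stationary_abnormal_prob(sys)
  # emission probability of bit b from each hidden state
  emit <- function(b) {
    if (b == 1L) c(det$p01, det$p11) else c(det$p00, det$p10)
  }
  alpha <- c(1 - a1, a1) * emit(bits[1])
  if (length(bits) > 1) {
    for (i in 2:length(bits)) {
      e <- emit(bits[i])
      alpha <- c(alpha[1] * sys$q00 + alpha[2] * sys$q10,
                 alpha[1] * sys$q01 + alpha[2] * sys$q11) * e
    }
  }
  names(alpha) <- c("normal", "abnormal")
  alpha
}

#' Joint probability of an observation history and the final hidden state
#'
#' Under the stationary chain, the probability of observing the length-`n`
#' bit sequence `history` (oldest first) with the hidden state equal to
#' `final_state` at the time of the last bit. Computed by forward
#' filtering in O(n).
#'
#' @param history Bit string (e.g. `"011"`) or 0/1 vector, oldest
#'   observation first, most recent last.
#' @param final_state `"normal"`/`"abnormal"` (or 0/1).
#' @param bundle A [model_bundle()].
#' @return A single probability.
#' @examples
#' b <- model_bundle(system_model(0.1, 0.3), detector_model(0.2, 0.8),
#'                   cost_model(K = 0.4))
#' joint_prob("1", "abnormal", b)  # a1 * p11 = 0.2
#' @export
joint_prob <- function(history, final_state, bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  bits <- as_history(history)
  alpha <- forward_joint(bits, bundle)
  state <- if (is.character(final_state)) {
    match.arg(final_state, c("normal", "abnormal"))
  } else {
    if (!final_state %in% c(0, 1)) stop("final_state must be 0/1 or normal/abnormal")
    c("normal", "abnormal")[final_state + 1]
  }
  unname(alpha[state])
}

#' Posterior probability of the abnormal state given a history
#'
#' Bayes' rule on the joint table: the probability that the system is
#' abnormal at the time of the most recent observation, given the last
#' `n` bits.
#'
#' @inheritParams joint_prob
#' @return A single probability.
#' @export
posterior_abnormal <- function(history, bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  alpha <- forward_joint(as_history(history), bundle)
  tot <- sum(alpha)
  if (tot <= 0) {
    stop("history has probability 0 under this model (degenerate detector); ",
         "posterior undefined", call. = FALSE)
  }
  unname(alpha["abnormal"] / tot)
}

#' Delta decision statistic for an observation history
#'
#' `Delta(b)` is the expected cost per unit time of NOT intervening minus
#' that of intervening, given that the current window reads `b`:
#' `Delta(b) = (1 - K) P(b, abnormal) - K P(b, normal)`. Its sign
#' determines the optimal action for that history, and it satisfies
#' `Delta(b) = P(b) (posterior(b) - K)`: thresholding Delta at 0 is the
#' same rule as thresholding the posterior at K.
#'
#' @inheritParams joint_prob
#' @return A single signed number (units of the abnormality cost).
#' @examples
#' b <- model_bundle(system_model(0.1, 0.3), detector_model(0.2, 0.8),
#'                   cost_model(K = 0.4))
#' delta_stat("0", b)  # -0.21
#' delta_stat("1", b)  #  0.06
#' @export
delta_stat <- function(history, bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  alpha <- forward_joint(as_history(history), bundle)
  K <- bundle$costs$K
  unname((1 - K) * alpha["abnormal"] - K * alpha["normal"])
}

#' Per-history joint, posterior and Delta table for a whole depth
#'
#' Tabulates every length-`n` history with its joint probabilities, the
#' posterior probability of abnormality, and the Delta statistic. The
#' grand total of the two joint columns is exactly 1, and the Delta
#' column sums to `a1 - K`.
#'
#' @param n Window length, `n >= 1`.
#' @param bundle A [model_bundle()].
#' @return A data frame with columns `history`, `joint_normal`,
#'   `joint_abnormal`, `posterior`, `delta` (one row per history, in
#'   lexicographic order). Zero-probability histories get `posterior = NA`
#'   and `delta = 0`.
#' @export
delta_table <- function(n, bundle) {
  stopifnot(inherits(bundle, "model_bundle"), n >= 1)
  hists <- all_histories(n)
  K <- bundle$costs$K
  rows <- lapply(hists, function(h) {
    alpha <- forward_joint(as_history(h), bundle)
    tot <- sum(alpha)
    data.frame(
      history = h,
      joint_normal = unname(alpha["normal"]),
      joint_abnormal = unname(alpha["abnormal"]),
      posterior = if (tot > 0) unname(alpha["abnormal"]) / tot else NA_real_,
      delta = if (tot > 0) {
        unname((1 - K) * alpha["abnormal"] - K * alpha["normal"])
      } else 0
    )
  })
  do.call(rbind, rows)
}
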