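#' Simulate the hidden chain and its binary observations
#'
#' Draws the initial hidden state from the stationary distribution (so
#' the steady-state prior holds exactly from step 1, with no burn-in),
#' then advances the two-state chain with the transition probabilities
#' and emits one detector bit per step, Bernoulli-conditionally on the
#' same-time state. One integer seed drives both sequences; identical
#' `(bundle, T, seed)` give bit-identical runs.
#'
#' @param T Number of time steps (`>= 1`).
#' @param bundle A [model_bundle()].
#' @param seed Integer seed.
#' @param init Optional forced initial state (0/1) instead of a
#'   stationary draw; used for degenerate frozen-chain checks.
#' @return List with integer vectors `states` and `observations`, each of
#'   length `T` (0 = normal, 1 = abnormal).
#' @export
simulate_chain <- function(T, bundle, seed, init = NULL) {
  stopifnot(inherits(bundle, "model_bundle"), T >= 1)
  sys <- bundle$system; det <- bundle$detector
  a1 <- stationary_abnormal_prob(sys)
  withr::with_seed(as.integer(seed), {
    u0 <- stats::runif(1)
    u_state <- stats::runif(T)
    u_obs <- stats::runif(T)
    states <- integer(T)
    states[1] <- if (is.null(init)) as.integer(u0 < a1) else as.integer(init)
    if (T > 1) {
      q01 <- sys$q01; q11 <- sys$q11
      for (t in 2:T) {
        states[t] <- if (states[t - 1] == 1L) {
          as.integer(u_state[t] < q11)
        } else {
          as.integer(u_state[t] < q01)
        }
      }
    }
    observations <- ifelse(states == 1L, u_obs < det$p11, u_obs < det$p01)
    list(states = states, observations = as.integer(observations))
  })
}

#' Apply a decision table to an observation stream
#'
#' The action at step `t >= n` is the table entry for the window
#' `observations[t-n+1 .. t]` (oldest bit first). Steps with an
#' incomplete window (`t < n`) take action 0 and are excluded from cost
#' scoring. A pure function of each window: bits outside it never affect
#' the action.
#'
#' @param observations Integer 0/1 vector.
#' @param strat A [strategy()].
#' @return Integer 0/1 action vector of the same length, with attribute
#'   `scored_from` = first scored step (`max(n, 1)`).
#' @export
apply_strategy <- function(observations, strat) {
  stopifnot(is_strategy(strat), all(observations %in% c(0L, 1L)))
  n <- strategy_depth(strat)
  T <- length(observations)
  actions <- integer(T)
  if (n == 0) {
    actions[] <- strat[[1]]
  } else if (T >= n) {
    # window -> lexicographic table index, computed incrementally
    pow <- 2L^((n - 1):0)
    idx <- sum(observations[1:n] * pow) + 1L
    actions[n] <- strat[[idx]]
    if (T > n) {
      for (t in (n + 1):T) {
        idx <- (idx - 1L - observations[t - n] * pow[1]) * 2L +
          observations[t] + 1L
        actions[t] <- strat[[idx]]
      }
    }
  }
  attr(actions, "scored_from") <- max(n, 1L)
  actions
}

#' Full surveillance-and-intervention simulation run
#'
#' Simulates the chain, applies the strategy to the observation stream,
#' and records per-step costs: `K` when intervening, 1 when abnormal
#' without intervention, 0 otherwise, plus the surveillance cost `S_n`
#' on every scored step. Steps before the first complete window are
#' unscored (action 0, no surveillance cost).
#'
#' @param bundle A [model_bundle()].
#' @param strat A [strategy()].
#' @param T Number of steps.
#' @param seed Integer seed.
#' @return An object of class `simulation_run`: list with `T`, `seed`,
#'   `n`, `states`, `observations`, `actions`, `costs`, `scored_from`.
#' @export
simulate_run <- function(bundle, strat, T, seed) {
  stopifnot(inherits(bundle, "model_bundle"), is_strategy(strat))
  n <- strategy_depth(strat)
  S_n <- surveillance_cost(bundle$costs, n)
  chain <- simulate_chain(T, bundle, seed)
  actions <- apply_strategy(chain$observations, strat)
  scored_from <- attr(actions, "scored_from")
  K <- bundle$costs$K
  base <- ifelse(actions == 1L, K, ifelse(chain$states == 1L, 1, 0))
  costs <- base
  if (T >= scored_from) {
    costs[scored_from:T] <- costs[scored_from:T] + S_n
  }
  structure(
    list(T = T, seed = as.integer(seed), n = n,
         states = chain$states, observations = chain$observations,
         actions = as.integer(actions), costs = costs,
         scored_from = scored_from),
    class = "simulation_run"
  )
}

#' Empirical mean cost per step of a simulation run
#'
#' Monte-Carlo estimator of the exact expected loss: the mean per-step
#' cost over scored steps (surveillance cost included), with a naive
#' i.i.d. standard error. The chain is serially correlated, so the naive
#' standard error is optimistic; comparisons against [expected_loss()]
#' should use a generous band (5 naive standard errors in this package's
#' own tests).
#'
#' @param run A [simulate_run()] result.
#' @return List with `mean`, `stderr`, `n_scored`.
#' @export
empirical_cost <- function(run) {
  stopifnot(inherits(run, "simulation_run"))
  if (run$T < run$scored_from) {
    stop("no scored steps: run shorter than the strategy window",
         call. = FALSE)
  }
  x <- run$costs[run$scored_from:run$T]
  m <- length(x)
  list(mean = mean(x),
       stderr = if (m > 1) stats::sd(x) / sqrt(m) else NA_real_,
       n_scored = m)
}

#' Write / read a simulation run as CSV
#'
#' Columns `t,state,obs,action,cost` with `t` 1-indexed; `state` is
#' omitted when `include_state = FALSE` (emulating that the true state is
#' hidden in real deployments). The reader restores a `simulation_run`
#' (with `states = NULL` if the column is absent); a write-read round
#' trip is lossless for the stored sequences.
#'
#' @param run A [simulate_run()] result.
#' @param path Output file path.
#' @param include_state Write the hidden-state column (default `TRUE`).
#' @return `write_run` returns `path` invisibly; `read_run` returns a
#'   `simulation_run`.
#' @export
write_run <- function(run, path, include_state = TRUE) {
  stopifnot(inherits(run, "simulation_run"))
  df <- data.frame(t = seq_len(run$T), state = run$states,
                   obs = run$observations, action = run$actions,
                   cost = run$costs)
  if (!include_state) df$state <- NULL
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) {
      stop(sprintf("failed to write run to '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  invisible(path)
}

#' @rdname write_run
#' @param n Strategy depth the run was scored under (stored in the file's
#'   unscored prefix implicitly; must be supplied on read).
#' @param seed Seed to record on the restored object (optional).
#' @export
read_run <- function(path, n = 0, seed = NA_integer_) {
  df <- tryCatch(
    utils::read.csv(path),
    error = function(e) {
      stop(sprintf("failed to read run from '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  required <- c("t", "obs", "action", "cost")
  if (!all(required %in% names(df))) {
    stop(sprintf("run file '%s' must have columns %s", path,
                 paste(required, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(T = nrow(df), seed = seed, n = n,
         states = if ("state" %in% names(df)) as.integer(df$state) else NULL,
         observations = as.integer(df$obs),
         actions = as.integer(df$action),
         costs = df$cost,
         scored_from = max(n, 1L)),
    class = "simulation_run"
  )
}

#' @export
print.simulation_run <- function(x, ...) {
  cat(sprintf("<simulation_run> T = %d, seed = %s, strategy depth n = %d\n",
              x$T, x$seed, x$n))
  if (!is.null(x$states)) {
    cat(sprintf("  abnormal fraction: %.4f\n", mean(x$states)))
  } else {
    cat("  hidden states not available\n")
  }
  ec <- empirical_cost(x)
  cat(sprintf("  empirical cost/step: %.6g (se %.2g, %d scored steps)\n",
              ec$mean, ec$stderr, ec$n_scored))
  invisible(x)
}
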