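# Independent oracles and randomized-model generators shared across tests.
# Everything here is deliberately naive: the oracles enumerate hidden paths
# or strategies explicitly and never reuse the package's forward recursion.

# Joint P(history bits, final hidden state) by explicit enumeration of all
# 2^n hidden-state paths (exponential; fine for the n <= 8 used in tests).
brute_joint <- function(bits, bundle, final_state) {
  sys <- bundle$system; det <- bundle$detector
  a1 <- sys$q01 / (sys$q01 + sys$q10)
  a <- c(1 - a1, a1)
  p <- matrix(c(det$p00, det$p01, det$p10, det$p11), nrow = 2, byrow = TRUE)
  q <- matrix(c(sys$q00, sys$q01, sys$q10, sys$q11), nrow = 2, byrow = TRUE)
  n <- length(bits)
  paths <- as.matrix(expand.grid(rep(list(0:1), n)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    if (path[n] != final_state) next
    w <- a[path[1] + 1] * p[path[1] + 1, bits[1] + 1]
    if (n > 1) {
      for (i in 2:n) {
        w <- w * q[path[i - 1] + 1, path[i] + 1] * p[path[i] + 1, bits[i] + 1]
      }
    }
    total <- total + w
  }
  total
}

brute_delta <- function(bits, bundle) {
  K <- bundle$costs$K
  (1 - K) * brute_joint(bits, bundle, 1) - K * brute_joint(bits, bundle, 0)
}

# Expected loss recomputed from the brute-force joints (independent of
# delta_stat / expected_loss internals).
brute_loss <- function(strat, bundle) {
  n <- strategy_depth(strat)
  a1 <- bundle$system$q01 / (bundle$system$q01 + bundle$system$q10)
  S_n <- unname(bundle$costs$S[n + 1])
  val <- a1 + S_n
  if (n == 0) {
    if (strat[[1]] == 1) val <- val - (a1 - bundle$costs$K)
    return(val)
  }
  for (h in names(strat)[unclass(strat) == 1]) {
    bits <- as.integer(strsplit(h, "")[[1]])
    val <- val - brute_delta(bits, bundle)
  }
  val
}

# A random parameter set satisfying every strict assumption, with S
# defined for depths 0..max_depth. chance_bounded = TRUE additionally
# imposes p01 < 1/2 < p11 (detector at least as good as chance in each
# state) -- the regime in which the one-bit dominance L1(0,1) <= L1(1,0)
# is a theorem; see the dominance tests for a counterexample outside it.
random_strict_bundle <- function(max_depth = 3, S_scale = 0.05,
                                 chance_bounded = FALSE) {
  q01 <- runif(1, 0.02, 0.48)
  q10 <- runif(1, 0.02, 0.48)
  if (chance_bounded) {
    p01 <- runif(1, 0.01, 0.49)
    p11 <- runif(1, 0.51, 0.99)
  } else {
    p01 <- runif(1, 0.01, 0.6)
    p11 <- runif(1, p01 + 0.05, 0.99)
  }
  K <- runif(1, 0.05, 0.95)
  S <- c(0, sort(runif(max_depth, 0, S_scale)))
  model_bundle(system_model(q01, q10), detector_model(p01, p11),
               cost_model(K = K, S = S))
}

random_strategy <- function(n) {
  strategy(n, sample(0:1, 2^n, replace = TRUE))
}

bundle_fixture <- function(S = c(0, 0.01)) {
  model_bundle(system_model(0.1, 0.3), detector_model(p01 = 0.2, p11 = 0.8),
               cost_model(K = 0.4, S = S))
}

# Number of 4-connected components per label in a label matrix (flood fill).
label_components <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  seen <- matrix(FALSE, nr, nc)
  comp <- integer(0)
  for (start in which(!seen)) {
    if (seen[start]) next
    lab <- labels[start]
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cell - 1) %% nr + 1
      j <- (cell - 1) %/% nr + 1
      for (d in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (d[1] < 1 || d[1] > nr || d[2] < 1 || d[2] > nc) next
        nb <- (d[2] - 1) * nr + d[1]
        if (!seen[nb] && labels[nb] == lab) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    comp[lab] <- (if (is.na(comp[lab])) 0L else comp[lab]) + 1L
  }
  comp
}
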