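# Independent oracles used to cross-check the implementation on tiny
# instances. Deliberately brute-force and kept free of any package
# internals beyond basic matrix access.

# Exhaustive path enumeration: occupancy after `cycles` steps computed
# by summing the probability of every individual state path, never by
# matrix multiplication.
enum_occupancy <- function(matrices, init, cycles) {
  if (is.matrix(matrices)) matrices <- rep(list(matrices), cycles)
  S <- length(init)
  acc <- numeric(S)
  names(acc) <- names(init)
  recurse <- function(state, prob, depth) {
    if (prob == 0) return()
    if (depth == cycles) {
      acc[state] <<- acc[state] + prob
      return()
    }
    M <- matrices[[depth + 1]]
    for (ns in seq_len(S)) recurse(ns, prob * M[state, ns], depth + 1)
  }
  for (s in seq_len(S)) recurse(s, init[s], 0)
  acc
}

# Empirical percentile check for a fitted sampling distribution:
# simulate and compare the 2.5/97.5 percentiles against targets.
simulated_percentiles <- function(dist, n = 1e5, seed = 42) {
  set.seed(seed)
  x <- sample_dist(dist, n)
  stats::quantile(x, c(0.025, 0.975), names = FALSE)
}

# A tiny three-state book-independent transition matrix builder used to
# cross-check build_transition_matrix on the background-mortality-only
# reduction.
hand_mortality_matrix <- function(states, q) {
  M <- diag(length(states))
  dimnames(M) <- list(states, states)
  for (s in setdiff(states, "dead")) {
    M[s, s] <- 1 - q
    M[s, "dead"] <- q
  }
  M
}

# Random valid transition matrix over the package state space with an
# absorbing dead row; used for property tests.
random_transition_matrix <- function(states = htn_states()) {
  S <- length(states)
  M <- matrix(0, S, S, dimnames = list(states, states))
  for (i in seq_len(S - 1)) {
    w <- stats::rexp(S)
    M[i, ] <- w / sum(w)
  }
  M[S, S] <- 1
  M
}

# Small parameter book for fast end-to-end runs: two strata, short
# horizon.
small_book <- function(cycles = 10) {
  p <- default_parameters()
  p$strata <- p$strata[p$strata$age_low == 40, ]
  p$strata$age_low <- 30
  p$strata$age_high <- 100
  p$strata$population <- c(500, 500)
  for (s in c("male", "female")) {
    p$epi$background_mortality[[s]] <-
      c("30-100" = unname(p$epi$background_mortality[[s]]["40-65"]))
    p$risks$p10_chd[[s]] <- c("30-100" = unname(p$risks$p10_chd[[s]]["40-65"]))
    p$risks$p10_stroke[[s]] <-
      c("30-100" = unname(p$risks$p10_stroke[[s]]["40-65"]))
  }
  p$model$cycles <- cycles
  validate_parameters(p)
  p
}
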