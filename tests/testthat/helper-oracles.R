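# Independent oracles used across the suite.  These deliberately avoid the
# package's own formulas: the Moran oracle enumerates individual-level
# events, the path oracles work by brute-force enumeration or direct matrix
# powers.

# Moran one-step probabilities by enumerating (parent, victim) pairs over
# the individual population: N - i individuals of type A with fitness s,
# i of type B with fitness 1; parent chosen fitness-proportionally, victim
# uniformly.
moran_probs_enum <- function(N, s, i) {
  types <- c(rep("A", N - i), rep("B", i))
  w <- ifelse(types == "A", s, 1)
  if (sum(w) == 0) return(list(up = 0, down = 0, stay = 1))
  up <- down <- 0
  for (parent in seq_len(N)) for (victim in seq_len(N)) {
    pr <- w[parent] / sum(w) * (1 / N)
    if (types[parent] == "B" && types[victim] == "A") up <- up + pr
    if (types[parent] == "A" && types[victim] == "B") down <- down + pr
  }
  list(up = up, down = down, stay = 1 - up - down)
}

# All length-`nsteps` paths from `i0` with positive probability under P,
# as a list of integer state vectors plus their probabilities.
enum_paths <- function(P, i0, nsteps) {
  N <- nrow(P) - 1L
  paths <- list(list(states = i0, prob = 1))
  for (t in seq_len(nsteps)) {
    nxt <- list()
    for (pp in paths) {
      i <- pp$states[length(pp$states)]
      for (j in 0:N) {
        p <- P[i + 1L, j + 1L]
        if (p > 0)
          nxt[[length(nxt) + 1L]] <- list(states = c(pp$states, j),
                                          prob = pp$prob * p)
      }
    }
    paths <- nxt
  }
  paths
}

path_key <- function(states) paste(states, collapse = ",")

# Exact conditional path law: enumerate all paths of length TF from i0,
# keep those ending at k, renormalize.  Returns named probability vector
# keyed by the full path.
enum_bridge_law <- function(P, i0, k, TF) {
  paths <- enum_paths(P, i0, TF)
  keep <- Filter(function(pp) pp$states[length(pp$states)] == k, paths)
  tot <- sum(vapply(keep, `[[`, numeric(1), "prob"))
  pr <- vapply(keep, `[[`, numeric(1), "prob") / tot
  names(pr) <- vapply(keep, function(pp) path_key(pp$states), character(1))
  pr
}

# Vectorized forward simulation of many unconditioned chains at once:
# returns an (n x (nsteps + 1)) matrix of states.
sim_many_paths <- function(P, i0, nsteps, n) {
  N <- nrow(P) - 1L
  cum <- t(apply(P, 1, cumsum))
  states <- matrix(0L, n, nsteps + 1L)
  states[, 1L] <- i0
  for (t in seq_len(nsteps)) {
    cur <- states[, t]
    u <- stats::runif(n)
    nxt <- integer(n)
    for (v in unique(cur)) {
      idx <- cur == v
      nxt[idx] <- findInterval(u[idx], cum[v + 1L, ], left.open = TRUE)
    }
    states[, t + 1L] <- nxt
  }
  states
}

# Bare trajectory constructor for hand-built fixtures.
new_trajectory_for_test <- function(states, family, N)
  selbridge:::new_trajectory(states, family, N)

# Gambler's-ruin closed form for the Moran chain (down/up ratio = s).
moran_fixation_closed_form <- function(N, s, i) {
  if (s == 1) i / N else (1 - s^i) / (1 - s^N)
}
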