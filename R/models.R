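#' Specify a population-genetic Markov chain
#'
#' A model specification bundles the chain family, the number of alleles
#' `N` and the selection coefficient `s`.  The state of either chain is the
#' count of `B` alleles, an integer in `0..N`, with absorbing boundaries at
#' `0` (loss of `B`) and `N` (fixation of `B`).
#'
#' Under the Moran model the population consists of `N` haploid individuals
#' and `s` is the fitness ratio of type `A` over type `B` (`W_A / W_B`).
#' Under the Wright-Fisher model the population consists of `N / 2` diploid
#' individuals (`N` alleles at one autosomal locus), `s = W_AA / W_BB`, and
#' the heterozygote is codominant: `W_AB / W_BB = (1 + s) / 2`.  In both
#' cases `s = 1` is neutrality, `s > 1` favors `A`, and `0 <= s < 1` favors
#' `B`.  Only fitness ratios matter, so fitnesses are normalized internally
#' (Moran: `W_B = 1`, `W_A = s`; Wright-Fisher: `W_BB = 1`,
#' `W_AB = (1 + s) / 2`, `W_AA = s`).
#'
#' @param family `"moran"` or `"wright_fisher"` (partial matching allowed).
#' @param N Number of alleles; a positive even integer, `N >= 2`.
#' @param s Selection coefficient; a non-negative real.  `s = 0` is
#'   admitted (type `A` never reproduces).
#' @return An object of class `"model_spec"`: a list with elements
#'   `family`, `N`, `s`.
#' @examples
#' model_spec("moran", N = 54, s = 2)
#' @export
model_spec <- function(family = c("moran", "wright_fisher"), N, s) {
  family <- match.arg(family)
  if (length(N) != 1L || !is.finite(N) || N < 2 || N != round(N) ||
      N %% 2 != 0)
    stop("'N' must be a single even integer >= 2")
  if (length(s) != 1L || !is.finite(s) || s < 0)
    stop("'s' must be a single non-negative number")
  structure(list(family = family, N = as.integer(N), s = as.numeric(s)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> family=%s N=%d s=%g\n", x$family, x$N, x$s))
  invisible(x)
}

#' Moran one-step probabilities
#'
#' For the Moran birth-death chain, the probability that the `B`-allele
#' count moves up by one, down by one, or stays, given the current count
#' `i`.  One individual reproduces with probability proportional to its
#' fitness and the copy replaces a uniformly chosen individual, so with
#' `W_B = 1` and `W_A = s`:
#'
#' \deqn{P_i = \frac{i}{(N-i)s + i} \cdot \frac{N-i}{N}, \qquad
#'       Q_i = \frac{(N-i)s}{(N-i)s + i} \cdot \frac{i}{N}, \qquad
#'       R_i = 1 - P_i - Q_i.}
#'
#' The ratio `P_i / Q_i = 1 / s`, so `B` is favored (`P_i > Q_i`) exactly
#' when `s < 1`, and the neutral chain (`s = 1`) is a symmetric lazy walk.
#'
#' @param N Number of alleles (even integer).
#' @param s Selection coefficient, `s >= 0`.
#' @param i Current `B` count(s), in `0..N`; vectorized.
#' @return A list with numeric components `up`, `down`, `stay`, each the
#'   length of `i`.
#' @examples
#' moran_step_probs(54, s = 1, i = 27)  # c(.25, .25, .5)
#' @export
moran_step_probs <- function(N, s, i) {
  if (any(i < 0 | i > N | i != round(i))) stop("'i' must be integers in 0..N")
  if (s < 0) stop("'s' must be non-negative")
  denom <- (N - i) * s + i
  # boundaries: denom = 0 only if i = 0 and s = 0; both moves are 0 there
  up <- ifelse(denom > 0, i / denom * (N - i) / N, 0)
  down <- ifelse(denom > 0, (N - i) * s / denom * i / N, 0)
  list(up = up, down = down, stay = 1 - up - down)
}

#' Wright-Fisher gamete-pool frequency of allele B
#'
#' Deterministic selection step of the diploid Wright-Fisher model with
#' codominance.  With adult `B`-allele frequency `p_B = i / N` the gamete
#' pool carries `B` at frequency
#' \deqn{p'_B = p_B \, (p_B W_{BB} + p_A W_{AB}) / \bar W,}
#' where `\bar W = p_A^2 W_AA + 2 p_A p_B W_AB + p_B^2 W_BB` is the mean
#' fitness of the adult population and the fitnesses are `W_BB = 1`,
#' `W_AB = (1 + s) / 2`, `W_AA = s`.
#'
#' @inheritParams moran_step_probs
#' @return Numeric vector of gamete-pool `B` frequencies in `[0, 1]`.
#' @export
wf_gamete_freq <- function(N, s, i) {
  if (any(i < 0 | i > N | i != round(i))) stop("'i' must be integers in 0..N")
  if (s < 0) stop("'s' must be non-negative")
  pB <- i / N
  pA <- 1 - pB
  w_ab <- (1 + s) / 2
  wbar <- pA^2 * s + 2 * pA * pB * w_ab + pB^2
  out <- ifelse(wbar > 0, pB * (pB + pA * w_ab) / wbar, 0)
  # boundaries are exact regardless of fitnesses
  out[i == 0] <- 0
  out[i == N] <- 1
  out
}

#' Build the one-step transition matrix
#'
#' Constructs the `(N + 1) x (N + 1)` row-stochastic transition matrix of
#' the chain over `B`-allele counts `0..N`.  Rows `0` and `N` are
#' absorbing.  The Moran matrix is tridiagonal with off-diagonals from
#' [moran_step_probs()]; each Wright-Fisher row `i` is the
#' `Binomial(N, p'_B(i))` probability mass function with `p'_B` from
#' [wf_gamete_freq()].
#'
#' @param spec A [model_spec()].
#' @return A numeric matrix with attributes `family`, `N`, `s` and class
#'   `"transition_matrix"`.  Row/column names are the states `0..N`.
#' @examples
#' P <- transition_matrix(model_spec("moran", 4, 1))
#' P["2", ]  # c(0, .25, .5, .25, 0)
#' @export
transition_matrix <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  N <- spec$N
  states <- 0:N
  P <- matrix(0, N + 1L, N + 1L, dimnames = list(states, states))
  if (spec$family == "moran") {
    pr <- moran_step_probs(N, spec$s, states)
    for (i in seq_len(N - 1L)) {       # transient states 1..N-1
      P[i + 1L, i]      <- pr$down[i + 1L]
      P[i + 1L, i + 1L] <- pr$stay[i + 1L]
      P[i + 1L, i + 2L] <- pr$up[i + 1L]
    }
  } else {
    pb <- wf_gamete_freq(N, spec$s, states)
    for (i in seq_len(N - 1L))
      P[i + 1L, ] <- stats::dbinom(states, N, pb[i + 1L])
  }
  P[1L, 1L] <- 1
  P[N + 1L, N + 1L] <- 1
  structure(P, family = spec$family, N = N, s = spec$s,
            class = c("transition_matrix", "matrix"))
}
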