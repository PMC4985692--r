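#' Log hitting profile of a target state
#'
#' Backward recursion for the probability of occupying state `k` after
#' exactly `m` further steps, `h_m(i) = (P^m)_{ik}`, for all states `i`
#' and all remaining times `m = 0..m_max` at once.  The recursion
#' `h_m = P h_{m-1}` starts from the indicator of `k` and is renormalized
#' by its maximum at every step, accumulating the log scale, so the
#' returned values are exact log probabilities free of underflow even for
#' horizons of many hundreds of steps.
#'
#' @param P A transition matrix from [transition_matrix()] (any square
#'   row-stochastic matrix works).
#' @param k Target state in `0..N`.
#' @param m_max Largest remaining time needed (`>= 0`).
#' @return An `(N + 1) x (m_max + 1)` matrix whose column `m + 1` holds
#'   `log (P^m)_{.k}`; entries are `-Inf` where `k` is unreachable in `m`
#'   steps.
#' @export
hitting_logprofile <- function(P, k, m_max) {
  N <- nrow(P) - 1L
  if (k < 0 || k > N) stop("'k' must be in 0..N")
  if (m_max < 0) stop("'m_max' must be >= 0")
  H <- matrix(-Inf, N + 1L, m_max + 1L)
  v <- numeric(N + 1L)
  v[k + 1L] <- 1
  H[k + 1L, 1L] <- 0
  logscale <- 0
  if (m_max >= 1L) for (m in seq_len(m_max)) {
    v <- as.vector(P %*% v)
    cm <- max(v)
    if (cm <= 0) break       # k unreachable from everywhere at this horizon
    v <- v / cm
    logscale <- logscale + log(cm)
    H[, m + 1L] <- ifelse(v > 0, log(v) + logscale, -Inf)
  }
  H
}

#' Finite-horizon endpoint-conditioned transition row
#'
#' The Doob h-transform of row `i` of `P` given that the chain occupies
#' state `k` exactly `m` steps from now:
#' \deqn{P_{ij|k}(m) = P_{ij} \, \frac{(P^{m-1})_{jk}}{(P^m)_{ik}}.}
#' The normalization is automatic (`sum_j P_{ij} h_{m-1}(j) = h_m(i)`),
#' so the returned row sums to one whenever the bridge is feasible.  At
#' `m = 1` the row is the indicator of `j = k` (the last step is forced).
#'
#' @inheritParams hitting_logprofile
#' @param i Current state in `0..N`.
#' @param m Remaining number of steps, `m >= 1`.
#' @param logH Optional precomputed [hitting_logprofile()] for `(P, k)`
#'   with at least `m + 1` columns; avoids recomputing the recursion when
#'   many rows share a horizon.
#' @return Numeric probability vector over states `0..N`.
#' @export
conditional_transition_row <- function(P, i, k, m, logH = NULL) {
  N <- nrow(P) - 1L
  if (i < 0 || i > N) stop("'i' must be in 0..N")
  if (m < 1) stop("'m' must be >= 1")
  if (is.null(logH)) logH <- hitting_logprofile(P, k, m)
  hi <- logH[i + 1L, m + 1L]
  if (!is.finite(hi))
    stop(sprintf("infeasible bridge: state %d cannot reach %d in %d steps",
                 i, k, m))
  row <- P[i + 1L, ] * exp(logH[, m] - hi)
  row
}

#' Absorption probabilities of the two boundaries
#'
#' Probability `u_{ik}` of eventual absorption in boundary `k` (0 or `N`)
#' from every starting state `i`, obtained from the first-step linear
#' system `(I - Q) u = P[transient, k]` on the transient block
#' `Q = P[1..N-1, 1..N-1]`.
#'
#' For a tridiagonal (birth-death) chain such as the Moran model the
#' system has the classical ladder solution
#' `u_{iN} = sum_{j<i} pi_j / sum_{j<N} pi_j` with
#' `pi_j = prod_{l<=j} Q_l / P_l`; this form is evaluated in log space
#' (log-sum-exp), which keeps absorption probabilities as small as
#' `1e-300` accurate to relative precision where the dense solve would
#' drown them in round-off.  For the Moran chain the down/up ratio is
#' constant (`Q_i / P_i = s`), so these reduce to the gambler's-ruin form
#' `u_{iN} = (1 - s^i) / (1 - s^N)` (and `i / N` at `s = 1`), which the
#' test suite uses as an independent oracle.  Dense chains fall back to
#' the linear solve, with negative round-off (below the solver's absolute
#' precision) clamped to zero.
#'
#' @inheritParams hitting_logprofile
#' @param k Absorbing boundary, `0` or `N`.
#' @return Numeric vector `u_{.k}` over states `0..N`.
#' @export
absorption_probs <- function(P, k) {
  N <- nrow(P) - 1L
  if (!(k %in% c(0L, N))) stop("'k' must be an absorbing state (0 or N)")
  tr <- 2:N                     # matrix indices of transient states 1..N-1
  if (is_tridiagonal(P)) {
    # log pi_j, j = 0..N-1, with pi_0 = 1 and pi_j = prod_{l<=j} Q_l / P_l
    down <- P[cbind(tr, tr - 1L)]
    up <- P[cbind(tr, tr + 1L)]
    lpi <- c(0, cumsum(log(down) - log(up)))
    u <- numeric(N + 1L)
    if (k == N) {
      lS <- cumlogsumexp(lpi)               # lS[i] = log sum_{j<i} pi_j
      u[2:(N + 1L)] <- exp(lS - lS[N])
    } else {
      lT <- rev(cumlogsumexp(rev(lpi)))     # lT[i+1] = log sum_{j>=i} pi_j
      u[1:N] <- exp(lT - cumlogsumexp(lpi)[N])
    }
  } else {
    # dense chains: u_{.k} = lim_m (P^m)_{.k}, computed as a rescaled
    # monotone power iteration so that components spanning many orders of
    # magnitude stay relatively accurate (a direct linear solve drowns
    # probabilities below ~1e-16 x scale in round-off)
    v <- as.numeric(0:N == k)
    logscale <- 0
    old <- rep(-Inf, N + 1L)
    for (m in seq_len(200000L)) {
      v <- as.vector(P %*% v)
      cm <- max(v)
      v <- v / cm
      logscale <- logscale + log(cm)
      cur <- ifelse(v > 0, log(v) + logscale, -Inf)
      live <- is.finite(cur) & is.finite(old)
      if (m > N + 1L && all(is.finite(cur) == is.finite(old)) &&
          (!any(live) || max(cur[live] - old[live]) < 1e-13)) break
      old <- cur
    }
    u <- exp(cur)
  }
  u[(N - k) + 1L] <- 0                     # the opposite boundary
  u[k + 1L] <- 1
  u
}

is_tridiagonal <- function(P) all(P[abs(row(P) - col(P)) > 1L] == 0)

# log(cumsum(exp(x))) evaluated stably; element i is log sum_{j<=i} exp(x_j)
cumlogsumexp <- function(x) {
  out <- numeric(length(x))
  acc <- -Inf
  for (ix in seq_along(x)) {
    m <- max(acc, x[ix])
    acc <- if (is.finite(m)) m + log(exp(acc - m) + exp(x[ix] - m)) else -Inf
    out[ix] <- acc
  }
  out
}

#' Perron eigenpair of the transient submatrix
#'
#' Leading eigenvalue `lambda_0` and positive right eigenvector `w_0` of
#' the submatrix of `P` over the transient states `1..N-1`.  This is the
#' "largest non-trivial eigenvalue" governing quasi-stationary
#' conditioning: the trivial eigenvalue 1 belongs to the absorbing
#' boundaries, while the transient block is irreducible (for `s > 0`) so
#' its Perron root lies in `(0, 1)` with a strictly positive eigenvector.
#' If the dense eigendecomposition returns a complex or sign-indefinite
#' leading pair, the function falls back to power iteration (tolerance
#' 1e-12) and warns.
#'
#' @inheritParams hitting_logprofile
#' @return A list with `lambda0` (scalar) and `w0` (positive vector over
#'   states `1..N-1`, normalized to unit maximum).
#' @export
spectral_data <- function(P) {
  N <- nrow(P) - 1L
  Q <- P[2:N, 2:N, drop = FALSE]
  ev <- eigen(Q)
  lead <- which.max(Mod(ev$values))
  lambda0 <- ev$values[lead]
  w0 <- ev$vectors[, lead]
  ok <- abs(Im(lambda0)) < 1e-10 && all(abs(Im(w0)) < 1e-8)
  if (ok) {
    lambda0 <- Re(lambda0)
    w0 <- Re(w0)
    if (max(w0) < 0) w0 <- -w0
    ok <- all(w0 > 0)
  }
  if (!ok) {                     # power-iteration fallback
    warning("leading eigenpair not cleanly real/positive; using power iteration")
    w0 <- rep(1, N - 1L)
    lambda0 <- NA_real_
    for (it in 1:100000) {
      v <- as.vector(Q %*% w0)
      lam <- max(v)
      v <- v / lam
      if (max(abs(v - w0)) < 1e-12) { w0 <- v; lambda0 <- lam; break }
      w0 <- v
      lambda0 <- lam
    }
  }
  if (!(lambda0 > 0 && lambda0 < 1))
    stop("leading transient eigenvalue outside (0, 1)")
  list(lambda0 = lambda0, w0 = w0 / max(w0))
}

#' Asymptotic h-transform factor between two transient states
#'
#' In the limit of a distant conditioning time, conditioning on occupying
#' any transient state gives the time-independent factor
#' \deqn{\phi_{ij} = \frac{w_0(j)}{\lambda_0\, w_0(i)},}
#' where `(lambda_0, w_0)` is the Perron eigenpair of the transient block
#' ([spectral_data()]).  The factor does not depend on which transient
#' endpoint is conditioned on.
#'
#' @inheritParams hitting_logprofile
#' @param i,j Transient states in `1..N-1`.
#' @param sd Optional precomputed [spectral_data()].
#' @return Positive scalar `phi`.
#' @export
spectral_phi <- function(P, i, j, sd = NULL) {
  N <- nrow(P) - 1L
  if (any(c(i, j) < 1) || any(c(i, j) > N - 1L))
    stop("'i' and 'j' must be transient states in 1..N-1")
  if (is.null(sd)) sd <- spectral_data(P)
  sd$w0[j] / (sd$lambda0 * sd$w0[i])
}

#' Asymptotic endpoint-conditioned transition row
#'
#' Time-homogeneous conditioned row in the limit of a distant final
#' observation.  For a transient endpoint `k` (0 < k < N) the row is the
#' quasi-stationary transform `P_{ij} w_0(j) / (lambda_0 w_0(i))`
#' supported on transient `j`; for an absorbing endpoint it is the
#' absorption-conditioned transform `P_{ij} u_{jk} / u_{ik}`.
#'
#' @inheritParams hitting_logprofile
#' @param i Current state.
#' @param k Final (present-time) state being conditioned on.
#' @param sd,u Optional precomputed [spectral_data()] / [absorption_probs()]
#'   to amortize across many rows.
#' @return Numeric probability vector over states `0..N`.
#' @export
asymptotic_conditional_row <- function(P, i, k, sd = NULL, u = NULL) {
  N <- nrow(P) - 1L
  row <- numeric(N + 1L)
  if (k %in% c(0L, N)) {
    if (is.null(u)) u <- absorption_probs(P, k)
    if (u[i + 1L] <= 0)
      stop(sprintf("infeasible conditioning: absorption in %d impossible from %d",
                   k, i))
    row <- P[i + 1L, ] * u / u[i + 1L]
  } else {
    if (i < 1 || i > N - 1L)
      stop("conditioning on a transient endpoint requires a transient state")
    if (is.null(sd)) sd <- spectral_data(P)
    tr <- 2:N
    row[tr] <- P[i + 1L, tr] * sd$w0 / (sd$lambda0 * sd$w0[i])
  }
  row
}

#' Full asymptotic conditioned kernel
#'
#' Convenience wrapper building the whole `(N + 1) x (N + 1)`
#' time-homogeneous conditioned transition matrix for endpoint `k`
#' (rows at states incompatible with `k` are left as `NA`).
#'
#' @inheritParams asymptotic_conditional_row
#' @return Matrix of conditioned rows.
#' @keywords internal
asymptotic_conditional_kernel <- function(P, k) {
  N <- nrow(P) - 1L
  K <- matrix(NA_real_, N + 1L, N + 1L, dimnames = dimnames(P))
  if (k %in% c(0L, N)) {
    u <- absorption_probs(P, k)
    for (i in 0:N) if (u[i + 1L] > 0)
      K[i + 1L, ] <- asymptotic_conditional_row(P, i, k, u = u)
  } else {
    sd <- spectral_data(P)
    for (i in 1:(N - 1L))
      K[i + 1L, ] <- asymptotic_conditional_row(P, i, k, sd = sd)
  }
  K
}
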