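## Per-s caching -------------------------------------------------------------
## The hitting recursion and the asymptotic eigen/absorption solves depend
## only on (family, N, s, k, horizon), not on the trajectory, so an ensemble
## of fits over a shared s-grid reuses them.  A cache is a plain environment.

#' Create a likelihood-evaluation cache
#'
#' An environment reused across [loglik_conditional()], [maximize()] and
#' [run_case()] calls so that transition matrices, hitting recursions and
#' eigen/absorption solves are computed once per `s` value rather than
#' once per trajectory.
#'
#' @return An empty environment.
#' @export
new_cache <- function() new.env(parent = emptyenv())

cache_get <- function(cache, key, compute) {
  if (is.null(cache)) return(compute())
  if (!is.null(cache[[key]])) return(cache[[key]])
  cache[[key]] <- compute()
  cache[[key]]
}

get_matrix <- function(family, N, s, cache = NULL) {
  key <- sprintf("P|%s|%d|%.17g", family, N, s)
  cache_get(cache, key, function() transition_matrix(model_spec(family, N, s)))
}

## Per-step (i, j) log transition probabilities without building the full
## matrix; used by the unconditioned likelihood where only visited pairs
## matter.
step_logprobs <- function(family, N, s, i, j) {
  out <- numeric(length(i))
  absb <- i == 0L | i == N
  out[absb] <- ifelse(j[absb] == i[absb], 0, -Inf)
  tr <- !absb
  if (any(tr)) {
    if (family == "moran") {
      pr <- moran_step_probs(N, s, i[tr])
      d <- j[tr] - i[tr]
      p <- ifelse(d == 1L, pr$up, ifelse(d == -1L, pr$down,
                  ifelse(d == 0L, pr$stay, 0)))
      out[tr] <- ifelse(p > 0, log(p), -Inf)
    } else {
      pb <- wf_gamete_freq(N, s, i[tr])
      out[tr] <- stats::dbinom(j[tr], N, pb, log = TRUE)
    }
  }
  out
}

#' Unconditioned log-likelihood of a trajectory
#'
#' The classical likelihood built from the raw transition probabilities,
#' `log L(s) = sum_{i,j} n({i,j}) log P_ij(s)`, over the `T` consecutive
#' transitions of the record.  The gap transition to the final
#' observation never enters.  This is the appropriate likelihood when the
#' data are an ensemble of free-running trajectories; for a single
#' historical record see [loglik_conditional()].
#'
#' @param traj A `"trajectory"`.
#' @param s Candidate selection coefficient (scalar).
#' @param family,N Model family and allele number; default from the
#'   trajectory's own metadata.
#' @return Scalar log-likelihood; `-Inf` if any observed transition has
#'   zero probability under `s`.
#' @export
loglik_unconditional <- function(traj, s, family = traj$family, N = traj$N) {
  if (s < 0) return(-Inf)
  enc <- encode_transitions(traj)
  if (nrow(enc$counts) == 0L) return(0)
  lp <- step_logprobs(family, N, s, enc$counts$i, enc$counts$j)
  sum(enc$counts$n * lp)
}

#' Endpoint-conditioned log-likelihood of a trajectory
#'
#' The conditional likelihood `L_c(s)`: the product over the consecutive
#' transitions of the endpoint-conditioned (Doob h-transform) transition
#' probabilities `P_{ij|k}(s)`.  For finite-horizon records (cases I/II)
#' each step at time `t` uses the time-dependent factor with remaining
#' time `m = T_F - t`; for asymptotic records (cases III/IV) the
#' time-homogeneous quasi-stationary or absorption-conditioned factors
#' apply.  By construction `log L_c(s) = log L(s) + log Phi(s)` with
#' `Phi` the product of the per-step h-transform factors
#' (see [phi_functional()]).
#'
#' @inheritParams loglik_unconditional
#' @param k Conditioning endpoint; defaults to the trajectory's recorded
#'   final state.
#' @param horizon `"finite"` or `"asymptotic"`; default from the record.
#' @param cache Optional [new_cache()] environment.
#' @return Scalar log-likelihood; `-Inf` when the conditioning is
#'   infeasible at this `s` or a step has zero conditioned probability.
#' @export
loglik_conditional <- function(traj, s, family = traj$family, N = traj$N,
                               k = traj$final_state, horizon = traj$horizon,
                               cache = NULL) {
  if (is.na(k)) stop("trajectory carries no final observation to condition on")
  if (is.na(horizon)) stop("trajectory carries no horizon information")
  if (s < 0) return(-Inf)
  st <- traj$states
  T_len <- length(st) - 1L
  if (T_len == 0L) return(0)
  i <- st[-length(st)]
  j <- st[-1L]
  base <- step_logprobs(family, N, s, i, j)
  if (horizon == "finite") {
    TF <- traj$T_F
    logH <- cache_get(cache, sprintf("H|%s|%d|%.17g|%d|%d", family, N, s, k, TF),
                      function() hitting_logprofile(get_matrix(family, N, s, cache),
                                                    k, TF))
    m <- TF - (seq_len(T_len) - 1L)            # remaining time at each step
    lphi <- logH[cbind(j + 1L, m - 1L + 1L)] - logH[cbind(i + 1L, m + 1L)]
  } else if (k %in% c(0L, N)) {
    u <- cache_get(cache, sprintf("u|%s|%d|%.17g|%d", family, N, s, k),
                   function() absorption_probs(get_matrix(family, N, s, cache), k))
    lu <- ifelse(u > 0, log(u), -Inf)
    lphi <- lu[j + 1L] - lu[i + 1L]
  } else {
    sd <- cache_get(cache, sprintf("sd|%s|%d|%.17g", family, N, s),
                    function() spectral_data(get_matrix(family, N, s, cache)))
    if (any(i < 1L | i > N - 1L | j < 1L | j > N - 1L)) return(-Inf)
    lw <- log(sd$w0)
    lphi <- lw[j] - lw[i] - log(sd$lambda0)
  }
  tot <- base + lphi
  if (any(is.nan(tot))) return(-Inf)           # -Inf - (-Inf) guards
  sum(tot)
}

#' The h-transform functional Phi(s) of a trajectory
#'
#' Product of the per-step conditioning factors `phi_{ij|k}` along the
#' trajectory, returned on the log scale.  Satisfies the identity
#' `L_c(s) = Phi(s) L(s)` exactly.
#'
#' @inheritParams loglik_conditional
#' @return Scalar `log Phi(s)`.
#' @export
phi_functional <- function(traj, s, family = traj$family, N = traj$N,
                           k = traj$final_state, horizon = traj$horizon,
                           cache = NULL) {
  loglik_conditional(traj, s, family, N, k, horizon, cache) -
    loglik_unconditional(traj, s, family, N)
}

#' Log-likelihood curve over a grid of s values
#'
#' @inheritParams loglik_conditional
#' @param s_grid Numeric vector of candidate `s` values.
#' @param kind `"conditional"`, `"unconditional"` or `"ratio"`
#'   (`log R(s) = log L_c(s) - log L(s)`).
#' @return A data frame with columns `s`, `loglik`, `kind`.
#' @export
loglik_curve <- function(traj, s_grid,
                         kind = c("conditional", "unconditional", "ratio"),
                         cache = NULL) {
  kind <- match.arg(kind)
  f <- curve_fn(traj, kind, cache)
  data.frame(s = s_grid, loglik = vapply(s_grid, f, numeric(1)), kind = kind)
}

curve_fn <- function(traj, kind, cache = NULL) {
  switch(kind,
    unconditional = function(s) loglik_unconditional(traj, s),
    conditional = function(s) loglik_conditional(traj, s, cache = cache),
    ratio = function(s) {
      lc <- loglik_conditional(traj, s, cache = cache)
      lu <- loglik_unconditional(traj, s)
      r <- lc - lu
      if (is.nan(r)) -Inf else r
    })
}

#' Likelihood-ratio curve R(s) = L_c(s) / L(s)
#'
#' Pointwise ratio of the conditional to the unconditioned likelihood,
#' equal to `Phi(s)`; offered as an exploratory alternative estimator
#' whose maximum isolates the information carried by the conditioning.
#'
#' @inheritParams loglik_curve
#' @return A data frame with columns `s`, `loglik` (log `R`), `kind`.
#' @export
likelihood_ratio_curve <- function(traj, s_grid, cache = NULL) {
  loglik_curve(traj, s_grid, kind = "ratio", cache = cache)
}

golden_max <- function(f, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- f(x2) }
    else { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- f(x1) }
  }
  if (f1 >= f2) list(x = x1, f = f1) else list(x = x2, f = f2)
}

#' Maximum-likelihood estimate of the selection coefficient
#'
#' Maximizes a likelihood kind over `s` by evaluating a log-spaced grid
#' and refining the best grid point with golden-section search on the
#' log-`s` scale.  Because the conditional likelihood can be bimodal
#' (one mode governed by `L(s)`, one by `Phi(s)`), the global maximum is
#' reported, the grid-local maxima are retained, and a multimodality flag
#' is set when more than one exists.
#'
#' @inheritParams loglik_curve
#' @param kind Likelihood kind to maximize.
#' @param s_min,s_max Search interval, `0 < s_min < s_max`.
#' @param n_grid Number of log-spaced grid points.
#' @param tol Relative tolerance of the refinement.
#' @return An object of class `"mle_result"`: list with `s_hat`,
#'   `loglik`, `kind`, `boundary` (maximum at a search bound),
#'   `multimodal`, `failed` (flat, uninformative curve), `local_max_s`
#'   (grid-local maxima), and the evaluated `curve`.
#' @export
maximize <- function(traj, kind = c("conditional", "unconditional", "ratio"),
                     s_min = 0.05, s_max = 20, n_grid = 200L, tol = 1e-5,
                     cache = NULL) {
  kind <- match.arg(kind)
  if (s_min <= 0 || s_max <= s_min) stop("need 0 < s_min < s_max")
  s_grid <- exp(seq(log(s_min), log(s_max), length.out = n_grid))
  f <- curve_fn(traj, kind, cache)
  y <- vapply(s_grid, f, numeric(1))
  curve <- data.frame(s = s_grid, loglik = y, kind = kind)
  finite <- is.finite(y)
  if (!any(finite))
    stop("estimation failure: likelihood is zero over the whole search grid")
  res <- list(kind = kind, curve = curve, failed = FALSE, boundary = FALSE,
              multimodal = FALSE, local_max_s = numeric(0))
  if (diff(range(y[finite])) < 1e-12) {        # flat: no information about s
    res$failed <- TRUE
    res$s_hat <- NA_real_
    res$loglik <- y[which(finite)[1L]]
    return(structure(res, class = "mle_result"))
  }
  yy <- ifelse(finite, y, -Inf)
  n <- length(yy)
  is_lmax <- vapply(seq_len(n), function(ix) {
    if (!is.finite(yy[ix])) return(FALSE)
    left <- if (ix == 1L) -Inf else yy[ix - 1L]
    right <- if (ix == n) -Inf else yy[ix + 1L]
    yy[ix] >= left && yy[ix] >= right && (yy[ix] > left || yy[ix] > right)
  }, logical(1))
  res$local_max_s <- s_grid[is_lmax]
  res$multimodal <- sum(is_lmax) > 1L
  best <- which.max(yy)
  res$boundary <- best == 1L || best == n
  lo <- log(s_grid[max(1L, best - 1L)])
  hi <- log(s_grid[min(n, best + 1L)])
  if (hi > lo) {
    opt <- golden_max(function(ls) f(exp(ls)), lo, hi, tol = tol)
    if (opt$f >= yy[best]) {
      res$s_hat <- exp(opt$x); res$loglik <- opt$f
    } else {
      res$s_hat <- s_grid[best]; res$loglik <- yy[best]
    }
  } else {
    res$s_hat <- s_grid[best]; res$loglik <- yy[best]
  }
  structure(res, class = "mle_result")
}

#' @export
print.mle_result <- function(x, ...) {
  cat(sprintf("<mle_result> kind=%s s_hat=%s loglik=%s%s%s%s\n",
              x$kind,
              if (is.na(x$s_hat)) "NA" else format(x$s_hat, digits = 6),
              format(x$loglik, digits = 6),
              if (x$boundary) " [boundary]" else "",
              if (x$multimodal) " [multimodal]" else "",
              if (x$failed) " [failed]" else ""))
  invisible(x)
}
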