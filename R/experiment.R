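#' Configuration of a four-case recovery experiment
#'
#' Bundles every knob of the parameter-recovery study: model family and
#' size, generating selection coefficient, trajectory geometry, per-case
#' endpoints, ensemble size, seed, and the search interval of the
#' maximizer.  Defaults follow the canonical study design: `N = 54`
#' alleles, initial count `N_B(0) = 27`, generating `s = 2`, ensembles of
#' 100 trajectories, intermediate endpoint `k = 40` for cases I/III and
#' fixation (`k = N`) for cases II/IV; `T = 500` consecutive generations
#' for the slow Moran chain and `T = 100` for the fast Wright-Fisher
#' chain, whose cases II/IV use the near-fixation variant `k = N - 1`.
#'
#' @param family `"moran"` or `"wright_fisher"`.
#' @param N Number of alleles.
#' @param s_true Generating selection coefficient.
#' @param n_b0 Initial `B` count.
#' @param T_len Consecutive trajectory length; default 500 (Moran) or
#'   100 (Wright-Fisher).
#' @param k_intermediate Endpoint for cases I/III.
#' @param near_fixation If `TRUE`, cases II/IV condition on `k = N - 1`
#'   instead of `k = N`; default `TRUE` for Wright-Fisher.
#' @param n_traj Ensemble size per case.
#' @param seed Root seed; trajectory `idx` uses stream `seed + idx`.
#' @param s_min,s_max,n_grid,tol Passed to [maximize()].
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(family = c("moran", "wright_fisher"), N = 54L,
                              s_true = 2, n_b0 = 27L, T_len = NULL,
                              k_intermediate = 40L,
                              near_fixation = NULL,
                              n_traj = 100L, seed = 1L,
                              s_min = 0.05, s_max = 20, n_grid = 200L,
                              tol = 1e-5) {
  family <- match.arg(family)
  if (is.null(T_len)) T_len <- if (family == "moran") 500L else 100L
  if (is.null(near_fixation)) near_fixation <- family == "wright_fisher"
  structure(list(family = family, N = as.integer(N), s_true = s_true,
                 n_b0 = as.integer(n_b0), T_len = as.integer(T_len),
                 k_intermediate = as.integer(k_intermediate),
                 near_fixation = isTRUE(near_fixation),
                 n_traj = as.integer(n_traj), seed = as.integer(seed),
                 s_min = s_min, s_max = s_max, n_grid = as.integer(n_grid),
                 tol = tol),
            class = "experiment_config")
}

case_spec_from_config <- function(config, case) {
  k <- if (case %in% c("I", "III")) config$k_intermediate
       else if (config$near_fixation) config$N - 1L else config$N
  case_spec(case, N = config$N, n_b0 = config$n_b0, T_len = config$T_len, k = k)
}

#' Mode and 95% confidence interval of an estimate ensemble
#'
#' Summarizes a collection of per-trajectory maximizers: the mode is the
#' argmax of a Gaussian kernel density estimate computed on `log(s)`
#' (Silverman bandwidth), respecting the multiplicative scale of a
#' fitness ratio; the interval is the empirical 2.5%/97.5% quantile
#' range of the estimates themselves.
#'
#' @param estimates Numeric vector of positive estimates.
#' @return A list with `mode`, `ci_low`, `ci_high`, `n`.
#' @export
ensemble_mode_ci <- function(estimates) {
  estimates <- estimates[is.finite(estimates) & estimates > 0]
  if (length(estimates) == 0L) stop("no finite estimates to summarize")
  ci <- unname(stats::quantile(estimates, c(0.025, 0.975)))
  if (length(estimates) == 1L || stats::sd(log(estimates)) == 0) {
    return(list(mode = estimates[1L], ci_low = ci[1L], ci_high = ci[2L],
                n = length(estimates)))
  }
  d <- stats::density(log(estimates), bw = "nrd0", n = 1024L)
  list(mode = exp(d$x[which.max(d$y)]), ci_low = ci[1L], ci_high = ci[2L],
       n = length(estimates))
}

#' Run one case of the recovery study
#'
#' Simulates `n_traj` endpoint-conditioned trajectories for the given
#' case, maximizes the requested likelihood kinds on each, and summarizes
#' the resulting maximizers with [ensemble_mode_ci()].  Per-trajectory
#' failures (flat or all-zero likelihoods) are counted and excluded from
#' the summary, as are boundary maxima, which would otherwise pile
#' degenerate mass at the search bounds.
#'
#' @param config An [experiment_config()].
#' @param case `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param kinds Character vector of likelihood kinds to fit.
#' @param verbose Print one progress line per trajectory block.
#' @return A list with `summary` (one row per kind: mode, CI, counts) and
#'   `table` (one row per trajectory x kind with `s_hat` and flags).
#' @export
run_case <- function(config, case, kinds = c("conditional", "unconditional"),
                     verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cs <- case_spec_from_config(config, case)
  spec <- model_spec(config$family, config$N, config$s_true)
  cache <- new_cache()
  rows <- vector("list", config$n_traj * length(kinds))
  r <- 0L
  for (idx in seq_len(config$n_traj)) {
    traj <- simulate_conditioned(spec, cs, seed = config$seed + idx)
    for (kind in kinds) {
      fit <- tryCatch(
        maximize(traj, kind, s_min = config$s_min, s_max = config$s_max,
                 n_grid = config$n_grid, tol = config$tol, cache = cache),
        error = function(e) NULL)
      r <- r + 1L
      rows[[r]] <- data.frame(
        trajectory_id = idx, case = case, kind = kind,
        s_hat = if (is.null(fit)) NA_real_ else fit$s_hat,
        loglik = if (is.null(fit)) NA_real_ else fit$loglik,
        boundary_flag = if (is.null(fit)) FALSE else fit$boundary,
        multimodal_flag = if (is.null(fit)) FALSE else fit$multimodal,
        failed_flag = is.null(fit) || fit$failed)
    }
    if (verbose && idx %% 20L == 0L)
      message(sprintf("case %s: %d/%d trajectories fitted", case, idx,
                      config$n_traj))
  }
  table <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(kinds, function(kind) {
    sub <- table[table$kind == kind, ]
    usable <- sub$s_hat[!sub$failed_flag & !sub$boundary_flag &
                          is.finite(sub$s_hat)]
    mc <- if (length(usable)) ensemble_mode_ci(usable)
          else list(mode = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n = 0L)
    data.frame(case = case, kind = kind, mode = mc$mode, ci_low = mc$ci_low,
               ci_high = mc$ci_high, n_used = mc$n,
               n_boundary = sum(sub$boundary_flag, na.rm = TRUE),
               n_failed = sum(sub$failed_flag))
  }))
  list(summary = summary, table = table)
}

#' Reproduce a full four-case recovery figure
#'
#' Runs all four cases with both likelihood kinds under one root seed,
#' returning the stacked summary and per-trajectory tables.  `"fig2"`
#' uses the Moran defaults (`T = 500`), `"fig3"` the Wright-Fisher
#' defaults (`T = 100`, near-fixation endpoints for cases II/IV).  When
#' `out_dir` is given, tab-separated `summary.tsv` and `estimates.tsv`
#' are written there, plus (if ggplot2 is installed) a box-plot figure
#' of the per-case estimate distributions.
#'
#' @param which `"fig2"` (Moran) or `"fig3"` (Wright-Fisher).
#' @param n_traj,seed Override ensemble size and root seed.
#' @param out_dir Optional output directory.
#' @param ... Further overrides passed to [experiment_config()].
#' @param verbose Progress messages.
#' @return A list with `summary`, `table` and the `config` used.
#' @export
reproduce_figure <- function(which = c("fig2", "fig3"), n_traj = 100L,
                             seed = 1L, out_dir = NULL, ...,
                             verbose = FALSE) {
  which <- match.arg(which)
  family <- if (which == "fig2") "moran" else "wright_fisher"
  config <- experiment_config(family = family, n_traj = n_traj, seed = seed, ...)
  cases <- c("I", "II", "III", "IV")
  runs <- lapply(cases, function(cc) run_case(config, cc, verbose = verbose))
  summary <- do.call(rbind, lapply(runs, `[[`, "summary"))
  table <- do.call(rbind, lapply(runs, `[[`, "table"))
  rownames(summary) <- rownames(table) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(table, file.path(out_dir, "estimates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      ok <- table[!table$failed_flag & is.finite(table$s_hat), ]
      p <- ggplot2::ggplot(ok, ggplot2::aes(x = case, y = s_hat, fill = kind)) +
        ggplot2::geom_boxplot(outlier.size = 0.6) +
        ggplot2::geom_hline(yintercept = config$s_true, linetype = "dashed") +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "case", y = "maximum-likelihood s",
                      title = sprintf("%s recovery (%s model)", which, family)) +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(out_dir, paste0(which, "_recovery.pdf")), p,
                      width = 7, height = 4.5)
    }
  }
  list(summary = summary, table = table, config = config)
}
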