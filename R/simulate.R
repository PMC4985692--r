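#' Describe one of the four observation cases
#'
#' A single historical record consists of an initial count `N_B(0)`, `T`
#' strictly consecutive measurements, and one final measurement at
#' generation `T_F`.  Four limiting cases are distinguished by when the
#' final measurement falls and what it shows:
#'
#' * case I  — `T_F = T + 1`, final count at an intermediate frequency;
#' * case II — `T_F = T + 1`, allele `B` fixed at the final measurement;
#' * case III — `T_F >> T` (treated as the asymptotic limit), final count
#'   intermediate; the data between `T` and `T_F` are missing;
#' * case IV — `T_F >> T`, allele `B` fixed at present time.
#'
#' Cases I/II condition the chain on a finite horizon; cases III/IV use
#' the time-homogeneous asymptotic transform (quasi-stationary for a
#' transient endpoint, absorption-conditioned for a fixed one).
#'
#' @param case `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param N Number of alleles.
#' @param n_b0 Initial `B` count.
#' @param T_len Number of consecutive intermediate measurements.
#' @param k Final-count value `N_B(T_F)`.  Defaults: `N` for cases II/IV
#'   (fixation); must be supplied and transient for cases I/III.  Cases
#'   II/IV also accept `k = N - 1` (the near-fixation variant used for
#'   fast chains).
#' @return An object of class `"case_spec"`.
#' @export
case_spec <- function(case = c("I", "II", "III", "IV"), N, n_b0, T_len, k = NULL) {
  case <- match.arg(case)
  horizon <- if (case %in% c("I", "II")) "finite" else "asymptotic"
  if (is.null(k)) {
    if (case %in% c("II", "IV")) k <- N
    else stop("cases I/III need an explicit intermediate final count 'k'")
  }
  if (case %in% c("I", "III") && (k <= 0 || k >= N))
    stop("cases I/III require a transient final count (0 < k < N)")
  if (case %in% c("II", "IV") && !(k %in% c(N, N - 1L)))
    stop("cases II/IV require k = N (fixation) or k = N - 1 (near fixation)")
  if (n_b0 < 0 || n_b0 > N) stop("'n_b0' must be in 0..N")
  if (T_len < 0) stop("'T_len' must be >= 0")
  structure(list(case = case, N = as.integer(N), n_b0 = as.integer(n_b0),
                 T_len = as.integer(T_len), k = as.integer(k),
                 horizon = horizon,
                 T_F = if (horizon == "finite") as.integer(T_len + 1L) else NA_integer_),
            class = "case_spec")
}

new_trajectory <- function(states, family, N, case = NA_character_,
                           horizon = NA_character_, T_F = NA_integer_,
                           final_state = NA_integer_, seed = NA_integer_) {
  structure(list(states = as.integer(states), family = family, N = as.integer(N),
                 T_len = length(states) - 1L, case = case, horizon = horizon,
                 T_F = T_F, final_state = final_state, seed = seed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s N=%d T=%d case=%s final=(%s, %s)\n",
              x$family, x$N, x$T_len, x$case,
              if (is.na(x$T_F)) "present" else x$T_F,
              if (is.na(x$final_state)) "-" else x$final_state))
  invisible(x)
}

sample_state <- function(prob) sample.int(length(prob), 1L, prob = prob) - 1L

#' Simulate an unconditioned trajectory
#'
#' Forward simulation of the raw (unconditioned) chain from the one-step
#' transition matrix.  Useful as an oracle for the bridge machinery and
#' for users whose data genuinely come from a free-running ensemble
#' (experimental evolution).
#'
#' @param spec A [model_spec()].
#' @param n_b0 Initial `B` count.
#' @param T_len Number of steps to simulate.
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @return A `"trajectory"` object with `T_len + 1` states and no final
#'   conditioning record.
#' @export
simulate_unconditioned <- function(spec, n_b0, T_len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- transition_matrix(spec)
  states <- integer(T_len + 1L)
  states[1L] <- n_b0
  if (T_len > 0) for (t in seq_len(T_len)) {
    i <- states[t]
    if (i == 0L || i == spec$N) states[t + 1L] <- i
    else states[t + 1L] <- sample_state(P[i + 1L, ])
  }
  new_trajectory(states, spec$family, spec$N,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Simulate an endpoint-conditioned trajectory
#'
#' Draws a trajectory from the h-transformed chain for one of the four
#' observation cases.  For finite horizons (cases I/II) each step at time
#' `t` is drawn from the time-dependent conditioned row with remaining
#' time `m = T_F - t`, so the path hits `N_B(T_F) = k` exactly; the
#' hitting recursion is computed once per call.  For asymptotic horizons
#' (cases III/IV) steps are drawn from the time-homogeneous transformed
#' kernel and the final record is the pair `("present", k)`.
#'
#' @param spec A [model_spec()].
#' @param cs A [case_spec()].
#' @param seed Optional integer seed.
#' @return A `"trajectory"` with `cs$T_len + 1` recorded states plus the
#'   final observation (`T_F`, `k`).
#' @export
simulate_conditioned <- function(spec, cs, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(cs, "case_spec"))
  if (spec$N != cs$N) stop("model and case disagree on N")
  if (!is.null(seed)) set.seed(seed)
  P <- transition_matrix(spec)
  N <- spec$N
  states <- integer(cs$T_len + 1L)
  states[1L] <- cs$n_b0
  if (cs$horizon == "finite") {
    TF <- cs$T_F
    logH <- hitting_logprofile(P, cs$k, TF)
    if (!is.finite(logH[cs$n_b0 + 1L, TF + 1L]))
      stop(sprintf("infeasible bridge: cannot reach %d from %d in %d steps",
                   cs$k, cs$n_b0, TF))
    if (cs$T_len > 0) for (t in seq_len(cs$T_len)) {
      m <- TF - (t - 1L)      # remaining steps before this transition
      row <- conditional_transition_row(P, states[t], cs$k, m, logH = logH)
      states[t + 1L] <- sample_state(row)
    }
    new_trajectory(states, spec$family, N, case = cs$case, horizon = "finite",
                   T_F = TF, final_state = cs$k,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  } else {
    K <- asymptotic_conditional_kernel(P, cs$k)
    if (anyNA(K[cs$n_b0 + 1L, ]))
      stop("infeasible conditioning from the initial state")
    if (cs$T_len > 0) for (t in seq_len(cs$T_len)) {
      i <- states[t]
      if (i == cs$k && cs$k %in% c(0L, N)) states[t + 1L] <- i  # absorbed
      else states[t + 1L] <- sample_state(K[i + 1L, ])
    }
    new_trajectory(states, spec$family, N, case = cs$case, horizon = "asymptotic",
                   T_F = NA_integer_, final_state = cs$k,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  }
}

#' Count observed transitions
#'
#' Encodes a trajectory by its transition counts `n({i, j})`: the number
#' of consecutive steps moving from count `i` to count `j`.  Exactly one
#' `(i, j)` pair is recorded per consecutive step, so the counts sum to
#' `T`.  The gap transition from the last consecutive state to the final
#' observation is never included in the counts; it enters inference only
#' through the conditioning.
#'
#' @param traj A `"trajectory"`.
#' @return A list with `counts` (data frame `i`, `j`, `n`) and `T_len`.
#' @export
encode_transitions <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  st <- traj$states
  if (length(st) < 2L) return(list(counts = data.frame(i = integer(), j = integer(),
                                                       n = integer()),
                                   T_len = 0L))
  if (traj$family == "moran" && any(abs(diff(st)) > 1L))
    stop("non-consecutive states in the consecutive block of a Moran record")
  key <- paste(st[-length(st)], st[-1L])
  tab <- table(key)
  ij <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  counts <- data.frame(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]),
                       n = as.integer(tab))
  counts <- counts[order(counts$i, counts$j), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, T_len = length(st) - 1L)
}

#' Write / read a trajectory as tab-separated text
#'
#' Plain-text interchange format: `#`-prefixed `key=value` header lines
#' recording `family`, `N`, `case` and `seed`, then two tab-separated
#' columns `generation` and `n_B` with one row per measurement.  The
#' consecutive block occupies generations `0..T`; the final observation
#' is a last row whose generation is `T + 1` (finite horizon) or the
#' literal token `present` (asymptotic horizon).
#'
#' @param traj A `"trajectory"`.
#' @param path File path to write to.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the reconstructed `"trajectory"`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(family = traj$family, N = traj$N, case = traj$case, seed = traj$seed)
  for (nm in names(hdr)) writeLines(sprintf("# %s=%s", nm, hdr[[nm]]), con)
  writeLines("generation\tn_B", con)
  writeLines(sprintf("%d\t%d", seq_along(traj$states) - 1L, traj$states), con)
  if (!is.na(traj$final_state)) {
    gen <- if (is.na(traj$T_F)) "present" else as.character(traj$T_F)
    writeLines(sprintf("%s\t%d", gen, traj$final_state), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (hl in hdr_lines) {
    kv <- strsplit(sub("^#\\s*", "", hl), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[kv[1L]]] <- kv[2L]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)][-1L]            # drop column header
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  gens <- parts[, 1L]
  vals <- as.integer(parts[, 2L])
  is_present <- gens == "present"
  N <- as.integer(meta$N)
  case <- if (is.null(meta$case) || meta$case == "NA") NA_character_ else meta$case
  seed <- if (is.null(meta$seed) || meta$seed == "NA") NA_integer_ else as.integer(meta$seed)
  if (any(is_present)) {
    final_state <- vals[is_present]
    states <- vals[!is_present]
    new_trajectory(states, meta$family, N, case = case, horizon = "asymptotic",
                   T_F = NA_integer_, final_state = final_state, seed = seed)
  } else {
    gens <- as.integer(gens)
    T_len <- length(vals) - 2L
    if (T_len >= 0L && gens[length(gens)] == T_len + 1L &&
        !is.na(case) && case %in% c("I", "II")) {
      new_trajectory(vals[-length(vals)], meta$family, N, case = case,
                     horizon = "finite", T_F = gens[length(gens)],
                     final_state = vals[length(vals)], seed = seed)
    } else {
      new_trajectory(vals, meta$family, N, case = case, seed = seed)
    }
  }
}
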