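# Rank-sum testing as the paper's analyses used it: two-sided Mann-Whitney U
# at alpha = 0.05, no multiplicity correction, groups summarized as
# mean +/- SEM.

.rhinoct_env <- new.env(parent = emptyenv())

# Cached index combinations for the exact null (choose(n+m, n) splits).
.combn_cache <- function(N, n) {
  key <- paste(N, n, sep = "_")
  if (is.null(.rhinoct_env[[key]]))
    .rhinoct_env[[key]] <- utils::combn(N, n)
  .rhinoct_env[[key]]
}

#' Mann-Whitney U test (exact small-sample null, midranks for ties)
#'
#' Computes the U statistic of sample `x` using midranks, then a two-sided
#' p-value. For `n + m <= exact_limit` the permutation null is enumerated
#' over all `choose(n+m, n)` splits of the observed (possibly tied) midrank
#' vector; otherwise the normal approximation with tie-corrected variance
#' and a 0.5 continuity correction is used. The two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y Non-empty numeric samples.
#' @param alpha Significance threshold (default 0.05).
#' @param exact_limit Largest `n + m` for which the exact null is enumerated.
#' @return A `mw_test` list: `U` (for `x`), `p_value`, `method`
#'   (`"exact"` or `"normal_approx_tie_corrected"`), `alpha`,
#'   `significant` (`p_value < alpha`), `n`, `m`.
#' @export
mann_whitney_u <- function(x, y, alpha = 0.05, exact_limit = 16L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(c(x, y))))
    stop("samples must be finite", call. = FALSE)
  n <- length(x); m <- length(y)
  N <- n + m
  r <- rank(c(x, y))  # midranks
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (N <= exact_limit) {
    idx <- .combn_cache(N, n)
    Us <- colSums(matrix(r[idx], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    p_lo <- mean(Us <= U + eps)
    p_hi <- mean(Us >= U - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- n * m / 2
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      if (abs(U - mu) <= 0.5) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx_tie_corrected"
  }
  structure(list(U = U, p_value = p, method = method, alpha = alpha,
                 significant = p < alpha, n = n, m = m),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d, m = %d), p = %.4g [%s]%s\n",
              x$U, x$n, x$m, x$p_value, x$method,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Summarize a group as mean and standard error of the mean
#'
#' SEM is the sample standard deviation (n - 1 denominator) divided by
#' sqrt(n). For n = 1 the SEM is undefined; it is reported as 0 with
#' `sem_defined = FALSE`.
#'
#' @param values Non-empty numeric vector.
#' @param label Optional group label.
#' @return A `group_summary` list: `label`, `n`, `mean`, `sem`,
#'   `sem_defined`.
#' @export
summarize_group <- function(values, label = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)))
    stop("values must be a non-empty finite vector", call. = FALSE)
  n <- length(values)
  sem_defined <- n > 1L
  sem <- if (sem_defined) stats::sd(values) / sqrt(n) else 0
  structure(list(label = label, n = n, mean = mean(values), sem = sem,
                 sem_defined = sem_defined),
            class = "group_summary")
}

#' Empirical type-I error rate of the exact Mann-Whitney test
#'
#' Draws `reps` pairs of same-distribution Gaussian samples and reports the
#' fraction rejected at `alpha`. A calibration check: the rate should sit
#' just below `alpha` (the exact test is conservative on discrete nulls).
#'
#' @param n,m Group sizes.
#' @param reps Number of replicates.
#' @param alpha Significance threshold.
#' @param seed RNG seed.
#' @return The empirical rejection rate.
#' @export
estimate_type1_error <- function(n = 6L, m = 6L, reps = 2000L, alpha = 0.05,
                                 seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rej <- logical(reps)
  for (i in seq_len(reps))
    rej[i] <- mann_whitney_u(stats::rnorm(n), stats::rnorm(m),
                             alpha = alpha)$significant
  mean(rej)
}
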