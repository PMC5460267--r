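#' Estimate the null proportion pi0 with bootstrap lambda selection
#'
#' Implements the q-value null-proportion estimator with the bootstrap
#' method for choosing the tuning parameter lambda: for each grid value,
#' `pi0(lambda) = #\{p > lambda\} / (m * (1 - lambda))`; bootstrap resamples
#' of the p-values (with replacement) estimate the mean squared error of
#' each `pi0(lambda)` around the plug-in minimum over the grid, and the
#' lambda with the smallest estimated MSE is selected. The estimate is
#' clipped to (0, 1].
#'
#' @param p_raw non-empty vector of p-values in (0, 1].
#' @param lambda_grid grid of lambda values within `[0, 0.95]`.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed for the bootstrap resampling.
#' @return list with `pi0_hat`, `lambda_selected`, `pi0_grid` (the pi0
#'   estimate at every grid value), `n_boot`, `seed`.
#' @export
estimate_pi0 <- function(p_raw, lambda_grid = seq(0, 0.95, by = 0.05),
                         n_boot = 100L, seed = 1L) {
  if (length(p_raw) == 0L) {
    prscan_abort("p_raw must be non-empty", "prscan_validation_error")
  }
  if (any(!is.finite(p_raw)) || any(p_raw <= 0) || any(p_raw > 1)) {
    prscan_abort("p-values must lie in (0, 1]", "prscan_validation_error")
  }
  if (any(lambda_grid < 0) || any(lambda_grid > 0.95)) {
    prscan_abort("lambda_grid must lie within [0, 0.95]",
                 "prscan_config_error")
  }
  lambda_grid <- sort(unique(lambda_grid))
  m <- length(p_raw)
  pi0_of <- function(p, lam) {
    pmin(1, pmax(sum(p > lam) / (m * (1 - lam)), 0))
  }
  pi0_grid <- vapply(lambda_grid, function(l) pi0_of(p_raw, l), numeric(1))
  min_pi0 <- min(pi0_grid)
  boot_pi0 <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pb <- p_raw[sample.int(m, m, replace = TRUE)]
      vapply(lambda_grid, function(l) pi0_of(pb, l), numeric(1))
    }, numeric(length(lambda_grid)))
  })
  boot_pi0 <- matrix(boot_pi0, nrow = length(lambda_grid))
  mse <- rowMeans((boot_pi0 - min_pi0)^2)
  sel <- which.min(mse)   # ties: smallest lambda (which.min takes the first)
  pi0_hat <- min(1, max(pi0_grid[sel], 1 / m))   # clip into (0, 1]
  list(pi0_hat = pi0_hat, lambda_selected = lambda_grid[sel],
       pi0_grid = setNames(pi0_grid, lambda_grid), n_boot = n_boot,
       seed = seed)
}

#' Step-up FDR correction with a pi0 factor and an uncorrected-p floor
#'
#' Computes q-values by the monotone step-up rule on the sorted p-values,
#' `q_(i) = min_{j >= i} pi0_hat * m * p_(j) / j`, and then floors them at
#' the uncorrected p-values (`q_i = max(q_i, p_i)`), so correction never
#' lowers a p-value — the relevant case when pi0_hat < 1 and the raw
#' p-values are already small. With `pi0_hat = 1` this is the classic
#' step-up procedure.
#'
#' @param p_raw p-values in (0, 1].
#' @param pi0_hat estimated null proportion in (0, 1].
#' @return An `fdr_result`: `p_raw`, `q` (aligned to input order),
#'   `pi0_hat`, plus `lambda_selected`/`n_boot`/`seed` when filled in by
#'   [fdr_adjust()].
#' @export
fdr_correct <- function(p_raw, pi0_hat = 1) {
  if (length(p_raw) == 0L) {
    prscan_abort("p_raw must be non-empty", "prscan_validation_error")
  }
  if (!is.numeric(pi0_hat) || length(pi0_hat) != 1L || pi0_hat <= 0 ||
      pi0_hat > 1) {
    prscan_abort("pi0_hat must be a single value in (0, 1]",
                 "prscan_validation_error")
  }
  m <- length(p_raw)
  ord <- order(p_raw)
  p_sorted <- p_raw[ord]
  q_sorted <- pi0_hat * m * p_sorted / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))     # enforce step-up monotonicity
  q_sorted <- pmin(q_sorted, 1)
  q_sorted <- pmax(q_sorted, p_sorted)       # the uncorrected-p floor
  q <- numeric(m)
  q[ord] <- q_sorted
  structure(list(p_raw = p_raw, q = q, pi0_hat = pi0_hat,
                 lambda_selected = NA_real_, n_boot = NA_integer_,
                 seed = NA_integer_),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> m = %d tests, pi0_hat = %.3f%s; %d with q < 0.05\n",
              length(x$p_raw), x$pi0_hat,
              if (is.na(x$lambda_selected)) "" else
                sprintf(" (lambda = %.2f)", x$lambda_selected),
              sum(x$q < 0.05)))
  invisible(x)
}

#' FDR-adjust a family of p-values
#'
#' Front end combining [estimate_pi0()] and [fdr_correct()]. With fewer than
#' `min_m_pi0` tests the pi0 estimate is too unstable to trust, so the
#' conservative `pi0_hat = 1` is used (with a message) unless
#' `force_pi0_estimation = TRUE`. A Benjamini–Yekutieli alternative, valid
#' under arbitrary dependence between the p-values, is available as
#' `method = "BY"` (delegated to [stats::p.adjust()], then floored for
#' consistency of the reported invariant).
#'
#' @param p_raw p-values in (0, 1].
#' @param method `"bootstrap-qvalue"` (default) or `"BY"`.
#' @param lambda_grid,n_boot,seed passed to [estimate_pi0()].
#' @param min_m_pi0 minimum family size for pi0 estimation (default 30).
#' @param force_pi0_estimation estimate pi0 even for small families.
#' @return An `fdr_result`.
#' @export
fdr_adjust <- function(p_raw, method = c("bootstrap-qvalue", "BY"),
                       lambda_grid = seq(0, 0.95, by = 0.05),
                       n_boot = 100L, seed = 1L, min_m_pi0 = 30L,
                       force_pi0_estimation = FALSE) {
  method <- match.arg(method)
  if (method == "BY") {
    q <- pmax(p.adjust(p_raw, method = "BY"), p_raw)
    return(structure(list(p_raw = p_raw, q = q, pi0_hat = 1,
                          lambda_selected = NA_real_, n_boot = NA_integer_,
                          seed = NA_integer_),
                     class = "fdr_result"))
  }
  m <- length(p_raw)
  if (m < min_m_pi0 && !force_pi0_estimation) {
    message(sprintf(
      "family of %d tests is below %d: using conservative pi0_hat = 1",
      m, min_m_pi0))
    return(fdr_correct(p_raw, pi0_hat = 1))
  }
  est <- estimate_pi0(p_raw, lambda_grid, n_boot, seed)
  out <- fdr_correct(p_raw, pi0_hat = est$pi0_hat)
  out$lambda_selected <- est$lambda_selected
  out$n_boot <- est$n_boot
  out$seed <- est$seed
  out
}

#' Significance stars for FDR-corrected p-values
#'
#' Annotates each test with the stars of the smallest level its q-value
#' beats: with the default levels, `q < 0.01` gets `"**"`, `q < 0.05` gets
#' `"*"`, anything else the empty string.
#'
#' @param fdr an `fdr_result` or a numeric vector of q-values.
#' @param levels named character vector mapping level thresholds (as names)
#'   to annotations.
#' @return character vector of annotations aligned with the input.
#' @export
star_significance <- function(fdr, levels = c("0.05" = "*", "0.01" = "**")) {
  q <- if (inherits(fdr, "fdr_result")) fdr$q else as.numeric(fdr)
  cuts <- sort(as.numeric(names(levels)))   # ascending: most stringent first
  stars <- levels[as.character(cuts)]
  out <- rep("", length(q))
  for (i in seq_along(cuts)) {
    hit <- q < cuts[i] & out == ""
    out[hit] <- stars[i]
  }
  out
}
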