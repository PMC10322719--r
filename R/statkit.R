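# Estimation statistics: bootstrap mean differences (Gardner-Altman style)
# and the behavioural stress-index composite.

#' Bootstrap mean difference between two groups
#'
#' Resamples each group with replacement and forms the bootstrap
#' distribution of the mean difference `mean(a) - mean(b)`; the percentile
#' interval at `conf` gives the CI. The permutation p-value is the
#' proportion of shuffled-group comparisons whose mean difference is at
#' least as extreme as the observed one (two-sided).
#'
#' @param a,b numeric samples (n >= 3 each).
#' @param n_boot bootstrap resamples.
#' @param n_perm group-shuffle comparisons for the p-value.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return object of class `effect_estimate`: `difference`, `ci` (length
#'   2), `p`, `boot` (the bootstrap distribution), `n` (per group),
#'   `conf`, `seed`.
#' @export
bootstrap_mean_difference <- function(a, b, n_boot = 5000, n_perm = n_boot,
                                      conf = 0.95, seed = 1) {
  if (!length(a) || !length(b)) stop("empty sample")
  if (length(a) < 3 || length(b) < 3)
    warning("fewer than 3 observations per group")
  with_seed(seed, {
    na <- length(a); nb <- length(b)
    boot_a <- colMeans(matrix(sample(a, na * n_boot, replace = TRUE), na))
    boot_b <- colMeans(matrix(sample(b, nb * n_boot, replace = TRUE), nb))
    boot <- boot_a - boot_b
    alpha <- (1 - conf) / 2
    ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE)
    pool <- c(a, b)
    perm <- vapply(seq_len(n_perm), function(i) {
      s <- sample(pool)
      mean(s[seq_len(na)]) - mean(s[-seq_len(na)])
    }, numeric(1))
    obs <- mean(a) - mean(b)
    p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
    structure(list(difference = obs, ci = ci, p = p,
                   boot = boot, n = c(na, nb), conf = conf, seed = seed),
              class = "effect_estimate")
  })
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("mean difference %.4g [%g%% CI %.4g, %.4g], P = %.4g (n = %d, %d)\n",
              x$difference, 100 * x$conf, x$ci[1], x$ci[2], x$p,
              x$n[1], x$n[2]))
  invisible(x)
}

#' Behavioural stress index
#'
#' Combines marble burying, looming-evoked aversive time and forced-swim
#' immobility into one per-animal score: the (weighted) mean of the three
#' component z-scores relative to a reference cohort. Higher values mean a
#' stronger stress phenotype. The equal-weight z-composite is this
#' package's operationalisation; weights and the reference cohort are
#' configurable.
#'
#' @param components data.frame with columns `marble`, `looming`,
#'   `immobility` (one row per animal).
#' @param reference data.frame with the same columns: the cohort defining
#'   the normalisation (defaults to `components` itself).
#' @param weights positive component weights, recycled and normalised.
#' @return numeric stress index per animal, with the component z-scores as
#'   attribute `z`.
#' @export
stress_index <- function(components, reference = components,
                         weights = c(1, 1, 1)) {
  need <- c("marble", "looming", "immobility")
  if (!all(need %in% names(components)))
    stop("not evaluable: missing component(s) ",
         paste(setdiff(need, names(components)), collapse = ", "))
  if (anyNA(components[need])) stop("not evaluable: missing component values")
  stopifnot(all(weights > 0))
  w <- rep_len(weights, 3); w <- w / sum(w)
  z <- vapply(seq_along(need), function(j) {
    r <- reference[[need[j]]]
    (components[[need[j]]] - mean(r)) / sd(r)
  }, numeric(nrow(components)))
  z <- matrix(z, nrow = nrow(components))
  colnames(z) <- need
  structure(drop(z %*% w), z = z)
}
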