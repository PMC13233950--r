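## Repeatability (intraclass correlation) of replicated population
## measurements, e.g. ASR measured in several populations of the same
## species.

#' Repeatability (ICC) from replicated within-species measurements
#'
#' Fits a one-way random-intercept Gaussian model by REML
#' (`value ~ 1 + (1 | group)`) and returns
#' `r = sigma2_between / (sigma2_between + sigma2_within)` with a
#' parametric-bootstrap confidence interval (simulate from the fitted
#' model, refit, recompute r).
#'
#' @param values Numeric vector of measurements.
#' @param group Grouping labels (species).
#' @param n_boot Number of parametric bootstrap resamples (default 200).
#' @param seed Integer RNG seed for the bootstrap.
#' @param ci_level Confidence level (default 0.95).
#' @return List of class `repeatability_result`: `r`, `ci95`, `n_groups`,
#'   `n_obs`, `sigma2_between`, `sigma2_within`, `boot` (the bootstrap
#'   replicates).
#' @export
repeatability <- function(values, group, n_boot = 200L, seed = 1L,
                          ci_level = 0.95) {
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- factor(as.character(group[ok]))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (!any(table(group) >= 2)) stop("all groups are singletons; within-group variance undefined")
  dat <- data.frame(value = values, group = group)
  fit <- suppressMessages(lme4::lmer(value ~ 1 + (1 | group), data = dat, REML = TRUE))
  r_of <- function(f) {
    vc <- as.data.frame(lme4::VarCorr(f))
    vb <- vc$vcov[vc$grp == "group"]
    vw <- vc$vcov[vc$grp == "Residual"]
    vb / (vb + vw)
  }
  r <- r_of(fit)
  boot <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    set.seed(seed)
    sims <- stats::simulate(fit, nsim = n_boot)
    for (b in seq_len(n_boot)) {
      fb <- tryCatch(suppressMessages(suppressWarnings(
        lme4::refit(fit, newresp = sims[[b]]))), error = function(e) NULL)
      if (!is.null(fb)) boot[b] <- r_of(fb)
    }
  }
  a <- (1 - ci_level) / 2
  ci <- if (all(is.na(boot))) c(NA_real_, NA_real_) else
    unname(quantile(boot, c(a, 1 - a), na.rm = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(r = r, ci95 = ci,
                 n_groups = nlevels(group), n_obs = length(values),
                 sigma2_between = vc$vcov[vc$grp == "group"],
                 sigma2_within = vc$vcov[vc$grp == "Residual"],
                 boot = boot),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Repeatability r = %.3f (95%% CI %.3f-%.3f), %d groups, %d observations\n",
              x$r, x$ci95[1], x$ci95[2], x$n_groups, x$n_obs))
  invisible(x)
}
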