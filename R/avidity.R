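# Functional avidity: four-parameter log-logistic (4PL) dose-response fitting
# and EC50 comparison between T-cell compartments.

# mean response at concentration x (log10 scale), increasing in x for hill > 0
fourpl <- function(lx, lower, upper, hill, log10_ec50) {
  lower + (upper - lower) / (1 + 10^(hill * (log10_ec50 - lx)))
}

#' Fit a four-parameter logistic dose-response curve and estimate the EC50
#'
#' The EC50 — the peptide concentration evoking a half-maximal response —
#' is estimated by least squares on a 4PL curve in log10 concentration:
#' a coarse grid over EC50 and Hill slope (with asymptotes profiled out
#' linearly) picks a starting point, which Levenberg-Marquardt refinement
#' then polishes. Confidence intervals come from seeded residual-resampling
#' bootstrap (percentile method). Concentration units are carried as an
#' opaque tag: EC50 is reported in the input's unit and no unit conversion
#' is attempted.
#'
#' A series whose response range is below `min_response_fraction` of its
#' maximum response carries too weak a dose effect to constrain an EC50 and
#' is flagged unreliable instead of fitted. An EC50 landing outside the
#' spanned concentration range is flagged extrapolated.
#'
#' @param series tibble with columns `concentration` (positive) and
#'   `response` (non-negative); an optional `unit` column is carried into
#'   the result. At least 4 distinct concentrations are required.
#' @param n_bootstrap bootstrap resamples for the percentile CI
#'   (default 1000; 0 disables).
#' @param seed integer seed for the bootstrap.
#' @param pin_lower optionally fix the lower asymptote (e.g. 0).
#' @param min_response_fraction reliability floor on the dose effect
#'   (default 0.2).
#' @return An object of class `ec50_fit`; see [tidy.ec50_fit()],
#'   [glance.ec50_fit()], [autoplot.ec50_fit()].
#' @export
fit_ec50 <- function(series, n_bootstrap = 1000, seed = NULL,
                     pin_lower = NULL, min_response_fraction = 0.2) {
  stopifnot(all(series$concentration > 0))
  if (n_distinct(series$concentration) < 4) {
    abort("at least 4 distinct concentrations are required to fit an EC50")
  }
  unit <- if ("unit" %in% names(series)) unique(series$unit)[1] else NA_character_
  lx <- log10(series$concentration)
  y <- series$response

  dose_means <- tapply(y, lx, mean)
  rng <- max(dose_means) - min(dose_means)
  reliable <- max(y) > 0 && rng >= min_response_fraction * max(y)
  base <- list(data = as_tibble(series), unit = unit,
               n_bootstrap = n_bootstrap, seed = seed)
  if (!reliable) {
    return(structure(c(base, list(
      estimate = tibble(ec50 = NA_real_, log10_ec50 = NA_real_,
                        hill_slope = NA_real_, lower = NA_real_,
                        upper = NA_real_),
      ci = c(NA_real_, NA_real_), sigma = NA_real_,
      converged = FALSE, reliable = FALSE, extrapolated = NA)),
      class = "ec50_fit"))
  }

  start <- ec50_grid_start(lx, y, pin_lower)
  fit <- refine_4pl(lx, y, start, pin_lower)
  est <- fit$par
  ec50 <- 10^est[["log10_ec50"]]
  extrapolated <- ec50 < min(series$concentration) ||
    ec50 > max(series$concentration)

  ci <- c(NA_real_, NA_real_)
  if (fit$converged && n_bootstrap > 0) {
    boots <- bootstrap_ec50(lx, y, est, pin_lower, n_bootstrap, seed)
    if (sum(!is.na(boots)) >= 2) {
      ci <- unname(quantile(boots, c(0.025, 0.975), na.rm = TRUE))
    }
  }

  structure(c(base, list(
    estimate = tibble(ec50 = ec50, log10_ec50 = est[["log10_ec50"]],
                      hill_slope = est[["hill"]], lower = est[["lower"]],
                      upper = est[["upper"]]),
    ci = ci, sigma = fit$sigma,
    converged = fit$converged, reliable = TRUE,
    extrapolated = extrapolated)),
    class = "ec50_fit")
}

# coarse grid over (log10 EC50, hill); asymptotes solved by least squares
ec50_grid_start <- function(lx, y, pin_lower) {
  les <- seq(min(lx) - 1, max(lx) + 1, length.out = 30)
  hills <- c(0.25, 0.5, 1, 2, 4)
  best <- NULL
  for (le in les) {
    for (h in hills) {
      f <- 1 / (1 + 10^(h * (le - lx)))
      if (is.null(pin_lower)) {
        cf <- tryCatch(coef(lm(y ~ f)), error = function(e) NULL)
        if (is.null(cf) || any(is.na(cf))) next
        lower <- cf[[1]]; span <- cf[[2]]
      } else {
        lower <- pin_lower
        span <- sum(f * (y - lower)) / sum(f^2)
      }
      if (span <= 0) next
      sse <- sum((y - (lower + span * f))^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(sse = sse, par = c(log10_ec50 = le, hill = h,
                                        lower = lower, upper = lower + span))
      }
    }
  }
  if (is.null(best)) {
    best <- list(par = c(log10_ec50 = mean(lx), hill = 1,
                         lower = min(y), upper = max(y)))
  }
  best$par
}

refine_4pl <- function(lx, y, start, pin_lower) {
  # Levenberg-Marquardt on the residual function directly (nls.lm); the
  # formula interface's numeric derivatives are fragile on noise-free data
  if (is.null(pin_lower)) {
    p0 <- start[c("log10_ec50", "hill", "lower", "upper")]
    fn <- function(p) y - fourpl(lx, p[[3]], p[[4]], p[[2]], p[[1]])
    lo <- c(-Inf, 1e-3, -Inf, -Inf)
  } else {
    p0 <- start[c("log10_ec50", "hill", "upper")]
    fn <- function(p) y - fourpl(lx, pin_lower, p[[3]], p[[2]], p[[1]])
    lo <- c(-Inf, 1e-3, -Inf)
  }
  res <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = fn, lower = lo,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  start_sse <- sum(fn(p0)^2)
  if (!is.null(res) && res$info %in% 1:3 && sum(res$fvec^2) <= start_sse) {
    par <- res$par
    if (!is.null(pin_lower)) par <- c(par, lower = pin_lower)
    par <- par[c("log10_ec50", "hill", "lower", "upper")]
    npar <- length(p0)
    return(list(par = par,
                sigma = sqrt(sum(res$fvec^2) / max(1, length(y) - npar)),
                converged = TRUE))
  }
  # refinement failed: fall back to the grid optimum, flagged unconverged
  par <- start
  if (!is.null(pin_lower) && !"lower" %in% names(par)) {
    par <- c(par, lower = pin_lower)
  }
  list(par = par[c("log10_ec50", "hill", "lower", "upper")],
       sigma = sqrt(start_sse / max(1, length(y))), converged = FALSE)
}

bootstrap_ec50 <- function(lx, y, est, pin_lower, n_bootstrap, seed) {
  mu <- fourpl(lx, est[["lower"]], est[["upper"]], est[["hill"]],
               est[["log10_ec50"]])
  r <- y - mu
  run <- function() {
    purrr::map_dbl(seq_len(n_bootstrap), function(i) {
      yb <- mu + sample(r, length(r), replace = TRUE)
      fb <- refine_4pl(lx, yb, est, pin_lower)
      if (fb$converged) 10^fb$par[["log10_ec50"]] else NA_real_
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.ec50_fit <- function(x, ...) {
  cat("4PL dose-response fit\n")
  if (!x$reliable) {
    cat("  unreliable: dose effect too weak to estimate an EC50\n")
    return(invisible(x))
  }
  cat(sprintf("  EC50: %.4g %s  (95%% CI %.4g-%.4g, %d bootstrap)\n",
              x$estimate$ec50, ifelse(is.na(x$unit), "", x$unit),
              x$ci[1], x$ci[2], x$n_bootstrap))
  cat(sprintf("  hill slope %.3g, asymptotes %.3g / %.3g, converged: %s%s\n",
              x$estimate$hill_slope, x$estimate$lower, x$estimate$upper,
              x$converged,
              if (isTRUE(x$extrapolated)) " (EC50 extrapolated)" else ""))
  invisible(x)
}

#' Tidy an EC50 fit
#' @param x an `ec50_fit`.
#' @param ... unused.
#' @return One row per parameter with `term`, `estimate`, and for the EC50
#'   the bootstrap `conf.low`/`conf.high`.
#' @method tidy ec50_fit
#' @export
tidy.ec50_fit <- function(x, ...) {
  tibble(
    term = c("ec50", "hill_slope", "lower", "upper"),
    estimate = c(x$estimate$ec50, x$estimate$hill_slope,
                 x$estimate$lower, x$estimate$upper),
    conf.low = c(x$ci[1], NA, NA, NA),
    conf.high = c(x$ci[2], NA, NA, NA)
  )
}

#' @rdname tidy.ec50_fit
#' @method glance ec50_fit
#' @export
glance.ec50_fit <- function(x, ...) {
  dplyr::bind_cols(x$estimate,
                   tibble(sigma = x$sigma, converged = x$converged,
                          reliable = x$reliable,
                          extrapolated = x$extrapolated,
                          nobs = nrow(x$data)))
}

#' Plot an EC50 dose-response fit
#' @param object an `ec50_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ec50_fit
#' @export
autoplot.ec50_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0("concentration",
                             ifelse(is.na(object$unit), "",
                                    paste0(" (", object$unit, ")"))),
                  y = "response")
  if (object$reliable && object$converged) {
    grid <- tibble(concentration = 10^seq(log10(min(object$data$concentration)),
                                          log10(max(object$data$concentration)),
                                          length.out = 200))
    grid$response <- fourpl(log10(grid$concentration), object$estimate$lower,
                            object$estimate$upper, object$estimate$hill_slope,
                            object$estimate$log10_ec50)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick") +
      ggplot2::geom_vline(xintercept = object$estimate$ec50,
                          linetype = "dashed", colour = "grey40")
  }
  p
}

#' Compare functional avidity (EC50) between two groups of clones
#'
#' Tests log10(EC50) between two labeled groups with a two-tailed t-test,
#' falling back to the Mann-Whitney (Wilcoxon rank-sum) test when a
#' Shapiro-Wilk normality pre-check fails in either group. Reports the
#' median EC50 per group and their ratio; a lower EC50 means higher
#' functional avidity.
#'
#' @param estimates tibble with one row per clone.
#' @param ec50_col,group_col column names (strings) holding the EC50 and
#'   the group label; the group column must have exactly two levels with at
#'   least two clones each.
#' @param normality_alpha significance level of the pre-check (default 0.05).
#' @return A one-row tibble: group labels, per-group medians, `median_ratio`
#'   (first group / second group), `method`, `statistic`, `p_value`.
#' @export
compare_avidity <- function(estimates, ec50_col = "ec50", group_col = "group",
                            normality_alpha = 0.05) {
  g <- factor(estimates[[group_col]])
  if (nlevels(g) != 2) abort("`compare_avidity()` needs exactly two groups")
  x <- log10(estimates[[ec50_col]])
  xs <- split(x, g)
  sizes <- lengths(xs)
  if (any(sizes < 2)) {
    abort(paste0("each group needs >= 2 estimates; got ",
                 paste(sizes, collapse = " and ")))
  }
  normal <- all(purrr::map_lgl(xs, function(v) {
    if (length(v) < 3 || sd(v) == 0) return(TRUE) # too small to reject
    shapiro.test(v)$p.value > normality_alpha
  }))
  if (normal) {
    ht <- t.test(xs[[1]], xs[[2]])
    method <- "t-test (log10 EC50)"
  } else {
    ht <- suppressWarnings(wilcox.test(xs[[1]], xs[[2]]))
    method <- "Mann-Whitney"
  }
  med <- purrr::map_dbl(split(estimates[[ec50_col]], g), median)
  tibble(group1 = levels(g)[1], group2 = levels(g)[2],
         n1 = sizes[[1]], n2 = sizes[[2]],
         median1 = med[[1]], median2 = med[[2]],
         median_ratio = med[[1]] / med[[2]],
         method = method, statistic = unname(ht$statistic),
         p_value = ht$p.value)
}
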