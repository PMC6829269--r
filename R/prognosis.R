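#' Tav bin edges for survival stratification
#'
#' The published stratification uses a strict lowest bin (Tav < 0.125) and a
#' strict highest bin (Tav > 2); the intermediate edge (default 0.5) is not
#' published and is configurable. With edges `e1 < ... < ek` the bins are
#' `(-Inf, e1)`, `[e1, e2)`, ..., `[e(k-1), ek]`, `(ek, Inf)`: a value
#' exactly equal to the top edge falls in the bin below the top.
#'
#' @param edges Strictly increasing numeric vector, default
#'   `c(0.125, 0.5, 2)`.
#' @return A list of class `tav_binning` with `edges` and derived `labels`.
#' @export
tav_bins <- function(edges = c(0.125, 0.5, 2)) {
  if (length(edges) < 1 || is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing")
  k <- length(edges)
  if (k == 1) {
    labels <- c(paste0("<=", edges), paste0(">", edges))
  } else {
    mid <- if (k > 2)
      sprintf("[%g,%g)", edges[seq_len(k - 2)], edges[seq_len(k - 2) + 1])
    else character(0)
    labels <- c(paste0("<", edges[1]), mid,
                sprintf("[%g,%g]", edges[k - 1], edges[k]),
                paste0(">", edges[k]))
  }
  structure(list(edges = edges, labels = labels), class = "tav_binning")
}

#' Assign Tav values to survival-stratification bins
#'
#' @param tavs Numeric Tav values.
#' @param binning A [tav_bins()] object (or numeric edges).
#' @return Ordered factor of bin labels, lowest infiltration first.
#' @export
bin_by_tav <- function(tavs, binning = tav_bins()) {
  if (is.numeric(binning)) binning <- tav_bins(binning)
  e <- binning$edges
  idx <- findInterval(tavs, e) + 1L       # [e_i, e_{i+1}) bins
  idx[tavs == e[length(e)]] <- length(e)  # top edge belongs below the top bin
  factor(binning$labels[idx], levels = binning$labels, ordered = TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the step function of
#' survival probability over time.
#'
#' @param time Positive follow-up times.
#' @param event Logical/0-1 event indicator (TRUE = death observed).
#' @return A `km_fit`: data.frame-backed list with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`, queryable with [km_survival()].
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("no survival records")
  if (any(time <= 0)) stop("all times must be positive")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv,
                 n = length(time), events = sum(as.integer(event))),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier fit at given times
#'
#' @param fit A [km_estimate()] result.
#' @param times Times at which to evaluate S(t); S(t) = 1 before the first
#'   observed time.
#' @return Numeric survival probabilities.
#' @export
km_survival <- function(fit, times) {
  stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)(times)
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d, final S = %.4f\n",
              x$n, x$events, if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' @export
plot.km_fit <- function(x, xlab = "Time", ylab = "Survival probability",
                        ylim = c(0, 1), type = "s", ...) {
  plot(c(0, x$time), c(1, x$surv), type = type, xlab = xlab, ylab = ylab,
       ylim = ylim, ...)
  invisible(x)
}

#' Log-rank (Mantel-Cox) test between survival groups
#'
#' Standard Mantel-Cox statistic via [survival::survdiff()], returning the
#' observed and expected event counts per group alongside the chi-square
#' statistic.
#'
#' @param time Positive follow-up times.
#' @param event Logical/0-1 event indicator.
#' @param group Group labels (>= 2 groups).
#' @return A list of class `logrank_test`: `chi2`, `df`, `p`, `observed`,
#'   `expected` (both named by group).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) stop("at least two groups are required")
  event <- as.integer(event)
  if (sum(event) < 1) stop("log-rank test requires at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  obs <- as.vector(sd$obs); exp <- as.vector(sd$exp)
  names(obs) <- names(exp) <- levels(group)
  v <- if (is.matrix(sd$var)) sd$var[1, 1] else sd$var
  structure(list(chi2 = unname(sd$chisq), df = nlevels(group) - 1L,
                 p = stats::pchisq(sd$chisq, nlevels(group) - 1L,
                                   lower.tail = FALSE),
                 observed = obs, expected = exp, var1 = v),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox) test: chi2 = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = round(x$expected, 3), row.names = NULL))
  invisible(x)
}

#' Hazard ratio by the log-rank method
#'
#' The default (`"oe_ratio"`) is the log-rank-method hazard ratio as
#' popularized by common survival-analysis software:
#' `HR = (O_A/E_A) / (O_B/E_B)` from the observed and expected event counts
#' of the Mantel-Cox test, with the O-E approximation to the CI:
#' `exp(log HR +/- z * sqrt(1/E_A + 1/E_B))`. The Mantel-Haenszel variant
#' (`HR = exp((O_A - E_A)/V)`, CI `exp((O_A - E_A)/V +/- z/sqrt(V))`) is
#' available via `method`. Both are approximations that attenuate for hazard
#' ratios far from 1; see the package vignette. The first group level is the
#' numerator.
#'
#' @inheritParams logrank_test
#' @param group Two-level group labels; the first level is the numerator.
#' @param conf_level Confidence level, default 0.95.
#' @param method `"oe_ratio"` (default) or `"mantel_haenszel"`.
#' @return List with `hr`, `ci_lower`, `ci_upper`, `observed`, `expected`.
#' @export
hazard_ratio_logrank <- function(time, event, group, conf_level = 0.95,
                                 method = c("oe_ratio", "mantel_haenszel")) {
  method <- match.arg(method)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("exactly two groups are required")
  lr <- logrank_test(time, event, group)
  O <- lr$observed; E <- lr$expected
  if (any(E == 0)) stop("expected event count of zero in group: ",
                        paste(names(E)[E == 0], collapse = ", "))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "oe_ratio") {
    hr <- (O[1] / E[1]) / (O[2] / E[2])
    half <- z * sqrt(1 / E[1] + 1 / E[2])
  } else {
    hr <- exp((O[1] - E[1]) / lr$var1)
    half <- z / sqrt(lr$var1)
  }
  structure(list(hr = unname(hr),
                 ci_lower = unname(exp(log(hr) - half)),
                 ci_upper = unname(exp(log(hr) + half)),
                 conf_level = conf_level, method = method,
                 observed = O, expected = E, logrank = lr),
            class = "logrank_hr")
}

#' @export
print.logrank_hr <- function(x, ...) {
  cat(sprintf("Log-rank hazard ratio (%s vs %s): HR = %.3g (%.0f%% CI %.3g-%.3g)\n",
              names(x$observed)[1], names(x$observed)[2], x$hr,
              100 * x$conf_level, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Survival stratification of patients by Tav bin
#'
#' Bins patients by Tav, fits a Kaplan-Meier curve per bin, tests the curves
#' with the log-rank Mantel-Cox test and reports the lowest-versus-highest
#' bin hazard ratio by the log-rank method (the published presentation of
#' the neuroblastoma analysis).
#'
#' @param records data.frame with columns `time`, `event`, `tav`.
#' @param binning A [tav_bins()] object or numeric edges.
#' @return List of class `tav_stratification`: `bins` (per-patient factor),
#'   `km` (named list of [km_estimate()] fits), `logrank`, `hr_low_vs_high`
#'   (NULL when either extreme bin is empty or event-free).
#' @export
stratify_survival_by_tav <- function(records, binning = tav_bins()) {
  need <- c("time", "event", "tav")
  miss <- setdiff(need, colnames(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  bins <- bin_by_tav(records$tav, binning)
  used <- droplevels(bins)
  km <- lapply(split(records, used), function(d) km_estimate(d$time, d$event))
  lr <- logrank_test(records$time, records$event, used)
  lv <- levels(used)
  lo <- records[used == lv[1], ]; hi <- records[used == lv[length(lv)], ]
  hr <- NULL
  if (nrow(lo) && nrow(hi) && sum(lo$event) + sum(hi$event) > 0) {
    both <- rbind(lo, hi)
    g <- factor(c(rep(lv[1], nrow(lo)), rep(lv[length(lv)], nrow(hi))),
                levels = c(lv[1], lv[length(lv)]))
    hr <- tryCatch(hazard_ratio_logrank(both$time, both$event, g),
                   error = function(e) NULL)
  }
  structure(list(bins = bins, km = km, logrank = lr, hr_low_vs_high = hr),
            class = "tav_stratification")
}

#' @export
print.tav_stratification <- function(x, ...) {
  cat("Survival stratification by Tav bin\n")
  print(table(x$bins))
  print(x$logrank)
  if (!is.null(x$hr_low_vs_high)) print(x$hr_low_vs_high)
  invisible(x)
}
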