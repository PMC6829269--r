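#' Thresholds of the checkpoint-expression response rules
#'
#' The published three-parameter rule for anti-PD-1 response: (1) both
#' ligand/receptor ratios PD-L1/PD-1 and PD-L2/PD-1 strictly between 0.5 and
#' 10 (signature-1; signature-2 and -3 use only PD-L1/PD-1), (2) Tav-RNAseq
#' strictly greater than 1 (the tumor is T-cell infiltrated), (3) PD-1 /
#' Tav-RNAseq strictly greater than 0.5 (the infiltrating T cells are
#' exhausted enough to express PD-1). All inequalities are strict.
#'
#' @param ratio_low,ratio_high Open-interval bounds on the ligand/receptor
#'   ratios, defaults 0.5 and 10.
#' @param tav_min Minimum Tav-RNAseq, default 1.
#' @param pd1_over_tav_min Minimum PD-1/Tav-RNAseq ratio, default 0.5.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(ratio_low = 0.5, ratio_high = 10,
                        tav_min = 1, pd1_over_tav_min = 0.5) {
  if (ratio_low >= ratio_high) stop("ratio_low must be smaller than ratio_high")
  if (ratio_low <= 0 || tav_min <= 0 || pd1_over_tav_min <= 0)
    stop("all rule thresholds must be positive")
  structure(list(ratio_low = ratio_low, ratio_high = ratio_high,
                 tav_min = tav_min, pd1_over_tav_min = pd1_over_tav_min),
            class = "rule_config")
}

#' Tav from RNA-seq expression
#'
#' Mean over the signature genes of `log2(FPKM + 1)`. Receptor/ligand ratios
#' of the response rules stay on the linear FPKM scale; only Tav uses the
#' log transform (configurable via `offset`).
#'
#' @param fpkm Named non-negative linear FPKM vector (one sample) or genes x
#'   samples matrix.
#' @param signature A [gene_signature()] or character vector.
#' @param offset Added before the log2 transform, default 1.
#' @return Numeric Tav-RNAseq per sample (attribute `platform = "RNAseq"`).
#' @export
compute_tav_rnaseq <- function(fpkm, signature, offset = 1) {
  m <- as_sample_matrix(fpkm)
  if (any(m < 0)) stop("FPKM values must be non-negative")
  genes <- sig_overlap(signature, rownames(m), "the FPKM values")
  out <- colMeans(log2(m[genes, , drop = FALSE] + offset))
  if (!is.matrix(fpkm)) out <- unname(out)
  structure(out, platform = "RNAseq")
}

check_checkpoint <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(vals[[nm]] < 0, na.rm = TRUE))
      stop("negative ", nm, " expression")
}

good_bad <- function(good) factor(ifelse(good, "good", "bad"),
                                  levels = c("good", "bad"))

ratio_in_window <- function(num, pd1, rules) {
  ifelse(pd1 > 0,
         num / pd1 > rules$ratio_low & num / pd1 < rules$ratio_high,
         FALSE)
}

warn_pd1_zero <- function(pd1) {
  if (any(pd1 == 0))
    warning(sum(pd1 == 0),
            " profile(s) with PD-1 = 0 called 'bad' (ligand/receptor ratio undefined)")
}

#' Signature-1 call: both ligand/receptor ratios in window
#'
#' `good` when both PD-L1/PD-1 and PD-L2/PD-1 lie strictly within
#' `(ratio_low, ratio_high)`. PD-1 = 0 yields `bad` with a warning (the
#' ratio is undefined). Calls are invariant to a common rescaling of the
#' three checkpoint values.
#'
#' @param pd1,pdl1,pdl2 Non-negative linear expression (FPKM-like) of PDCD1,
#'   CD274 and PDCD1LG2.
#' @param rules A [rule_config()].
#' @return Factor `good`/`bad` per profile.
#' @export
signature1_call <- function(pd1, pdl1, pdl2, rules = rule_config()) {
  check_checkpoint(pd1 = pd1, pdl1 = pdl1, pdl2 = pdl2)
  warn_pd1_zero(pd1)
  good_bad(ratio_in_window(pdl1, pd1, rules) & ratio_in_window(pdl2, pd1, rules))
}

#' Signature-2 call: PD-L1/PD-1 ratio plus infiltration
#'
#' `good` when PD-L1/PD-1 lies strictly within `(ratio_low, ratio_high)` and
#' Tav-RNAseq is strictly greater than `tav_min`.
#'
#' @inheritParams signature1_call
#' @param tav_rnaseq Tav-RNAseq score (see [compute_tav_rnaseq()]).
#' @return Factor `good`/`bad` per profile.
#' @export
signature2_call <- function(pd1, pdl1, tav_rnaseq, rules = rule_config()) {
  check_checkpoint(pd1 = pd1, pdl1 = pdl1)
  warn_pd1_zero(pd1)
  good_bad(ratio_in_window(pdl1, pd1, rules) & tav_rnaseq > rules$tav_min)
}

#' Signature-3 call: the full three-parameter rule
#'
#' `good` when the signature-2 criteria hold and additionally
#' PD-1/Tav-RNAseq is strictly greater than `pd1_over_tav_min`. A profile
#' with `tav_rnaseq <= 0` and positive PD-1 is called `bad` with a warning
#' (the third ratio is undefined). Signature-3 `good` implies signature-2
#' `good` by construction.
#'
#' @inheritParams signature2_call
#' @return Factor `good`/`bad` per profile.
#' @export
signature3_call <- function(pd1, pdl1, tav_rnaseq, rules = rule_config()) {
  s2 <- signature2_call(pd1, pdl1, tav_rnaseq, rules) == "good"
  undef <- tav_rnaseq <= 0 & pd1 > 0
  if (any(undef))
    warning(sum(undef),
            " profile(s) with Tav-RNAseq <= 0 called 'bad' (PD-1/Tav ratio undefined)")
  third <- ifelse(tav_rnaseq > 0, pd1 / tav_rnaseq > rules$pd1_over_tav_min, FALSE)
  good_bad(s2 & third)
}

#' Overall response rate per call group
#'
#' `ORR = 100 * (#CR + #PR) / n` within each group of calls. Empty groups
#' are reported as `NA`.
#'
#' @param calls Factor/character of group calls (e.g. `good`/`bad`).
#' @param responses Factor/character of clinical responses among `CR`, `PR`,
#'   `PD`.
#' @return List with `orr` (named numeric, percent), `n` and `responders`
#'   per group.
#' @export
overall_response_rate <- function(calls, responses) {
  if (length(calls) != length(responses))
    stop("calls and responses must have equal length")
  bad <- setdiff(unique(as.character(responses)), c("CR", "PR", "PD"))
  if (length(bad)) stop("unknown response value(s): ", paste(bad, collapse = ", "))
  calls <- as.factor(calls)
  resp <- as.character(responses)
  groups <- levels(calls)
  n <- vapply(groups, function(g) sum(calls == g), integer(1))
  responders <- vapply(groups, function(g)
    sum(calls == g & resp %in% c("CR", "PR")), integer(1))
  orr <- ifelse(n > 0, 100 * responders / n, NA_real_)
  names(orr) <- groups
  list(orr = orr, n = n, responders = responders)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square without continuity correction by default (the Yates
#' correction is available via `correct = TRUE`). Any zero row or column
#' margin is an error.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param correct Apply the Yates continuity correction, default FALSE.
#' @return List with `chi2`, `df` and `p`.
#' @export
contingency_chi2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  ct <- stats::chisq.test(table, correct = correct)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Classify checkpoint profiles and summarize response
#'
#' Applies one of the three response rules to a profile table and reports
#' per-group overall response rates, the good-versus-bad contingency
#' chi-square on responders/non-responders, and (when survival columns are
#' present) the log-rank comparison and death hazard ratio.
#'
#' @param profiles data.frame with columns `pd1`, `pdl1`, `pdl2` (linear
#'   FPKM), `tav_rnaseq`, `response` (CR/PR/PD) and optionally `time`,
#'   `event`.
#' @param rule `"signature1"`, `"signature2"` or `"signature3"` (default).
#' @param rules A [rule_config()].
#' @return List of class `response_prediction`: `calls`, `orr`, `chi2`
#'   (NULL when a margin is empty), `hr_good_vs_bad` (NULL without survival
#'   data).
#' @export
predict_response <- function(profiles,
                             rule = c("signature3", "signature2", "signature1"),
                             rules = rule_config()) {
  rule <- match.arg(rule)
  calls <- switch(rule,
    signature1 = signature1_call(profiles$pd1, profiles$pdl1, profiles$pdl2, rules),
    signature2 = signature2_call(profiles$pd1, profiles$pdl1, profiles$tav_rnaseq, rules),
    signature3 = signature3_call(profiles$pd1, profiles$pdl1, profiles$tav_rnaseq, rules))
  orr <- overall_response_rate(calls, profiles$response)
  responder <- profiles$response %in% c("CR", "PR")
  tab <- table(calls, factor(responder, levels = c(TRUE, FALSE)))
  chi2 <- tryCatch(contingency_chi2(tab), error = function(e) NULL)
  hr <- NULL
  if (all(c("time", "event") %in% colnames(profiles)) && sum(profiles$event) > 0)
    hr <- tryCatch(
      hazard_ratio_logrank(profiles$time, profiles$event,
                           factor(calls, levels = c("bad", "good"))),
      error = function(e) NULL)
  structure(list(rule = rule, calls = calls, orr = orr, table = tab,
                 chi2 = chi2, hr_bad_vs_good = hr),
            class = "response_prediction")
}

#' @export
print.response_prediction <- function(x, ...) {
  cat(sprintf("Checkpoint response prediction (%s)\n", x$rule))
  cat(sprintf("  ORR: good %.1f%% (n=%d), bad %.1f%% (n=%d)\n",
              x$orr$orr["good"], x$orr$n["good"],
              x$orr$orr["bad"], x$orr$n["bad"]))
  if (!is.null(x$chi2))
    cat(sprintf("  contingency chi-square = %.3g, p = %.3g\n",
                x$chi2$chi2, x$chi2$p))
  if (!is.null(x$hr_bad_vs_good))
    cat(sprintf("  death HR (bad vs good) = %.3g (95%% CI %.3g-%.3g)\n",
                x$hr_bad_vs_good$hr, x$hr_bad_vs_good$ci_lower,
                x$hr_bad_vs_good$ci_upper))
  invisible(x)
}
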