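sig_overlap <- function(signature, available, what) {
  genes <- as_genes(signature)
  present <- genes[genes %in% available]
  if (!length(present))
    stop("no signature genes present in ", what)
  present
}

as_sample_matrix <- function(values) {
  if (is.matrix(values)) values
  else matrix(values, ncol = 1, dimnames = list(names(values), "sample"))
}

#' Ts%: signature signal as a percentage of purified T cells
#'
#' The T-cell infiltration score percentage. Per-gene log2 differences to the
#' purified-T-cell reference are averaged in log space and converted back:
#' `Ts% = 100 * 2^mean(x(g,s) - t_ref(g))`, so a sample identical to the
#' reference scores exactly 100 and a uniform 5-log2 deficit scores
#' `100 * 2^-5 = 3.125`. Under the cell-fraction mixture model of bulk tissue,
#' Ts% of a tissue with T-cell fraction f and negligible parenchymal
#' background approximates `100 * f`.
#'
#' @param values Named log2 vector (one sample) or genes x samples matrix.
#' @param signature A [gene_signature()] or character vector.
#' @param t_ref Named log2 T-cell reference profile.
#' @return Numeric Ts% per sample.
#' @export
ts_percent <- function(values, signature, t_ref) {
  m <- as_sample_matrix(values)
  genes <- sig_overlap(signature, intersect(rownames(m), names(t_ref)),
                       "both sample and t_ref")
  d <- m[genes, , drop = FALSE] - t_ref[genes]
  out <- 100 * 2^colMeans(d)
  if (is.matrix(values)) out else unname(out)
}

#' Tav: mean log2 expression of the signature genes
#'
#' The T-cell infiltration absolute value: the arithmetic mean of the log2
#' expression of the signature genes in a sample. Tav is platform-specific
#' (an Affymetrix Tav-array cannot be compared to a Tav-RNAseq), so the
#' result carries a `platform` attribute.
#'
#' @inheritParams ts_percent
#' @param platform Platform label, e.g. `"array"` or `"RNAseq"`.
#' @return Numeric Tav per sample with attribute `platform`.
#' @export
tav <- function(values, signature, platform = "array") {
  m <- as_sample_matrix(values)
  genes <- sig_overlap(signature, rownames(m), "the sample values")
  out <- colMeans(m[genes, , drop = FALSE])
  if (!is.matrix(values)) out <- unname(out)
  structure(out, platform = platform)
}

#' Ts-l2: log2 infiltration difference versus matched healthy tissue
#'
#' Mean over the signature genes of the tumor-minus-healthy-tissue log2
#' difference. Values within ±0.32 log2 (80-125% of the healthy-tissue
#' signal) indicate infiltration similar to the matched healthy tissue.
#' When both sides use the same T-cell reference,
#' `Ts-l2 = log2(Ts%_tumor / Ts%_HT)`.
#'
#' @param tumor_values Named log2 vector or genes x samples matrix.
#' @param ht_gene_means Named log2 vector of per-gene means over matched
#'   healthy-tissue samples.
#' @inheritParams ts_percent
#' @return Numeric Ts-l2 per sample.
#' @export
ts_l2 <- function(tumor_values, ht_gene_means, signature) {
  if (missing(ht_gene_means) || is.null(ht_gene_means))
    stop("a healthy-tissue reference profile is required for Ts-l2")
  m <- as_sample_matrix(tumor_values)
  genes <- sig_overlap(signature, intersect(rownames(m), names(ht_gene_means)),
                       "both tumor and healthy-tissue reference")
  out <- colMeans(m[genes, , drop = FALSE] - ht_gene_means[genes])
  if (is.matrix(tumor_values)) out else unname(out)
}

#' Band configuration for Ts% classification
#'
#' The `similar` band is the published 80-125% window around the
#' healthy-tissue reference Ts% (default 3.0, giving the 2.4-3.7 window).
#' The outer cut points (`moderate_high_frac`, `extremely_low_frac`) are not
#' published; the defaults (2.5x and 0.4x the reference) are package choices
#' and configurable.
#'
#' @param reference_ts Reference Ts% (mean healthy-tissue Ts%), default 3.0.
#' @param similar_low_frac,similar_high_frac Bounds of the similar band as
#'   fractions of the reference, defaults 0.8 and 1.25.
#' @param moderate_high_frac Upper bound of the moderate band, default 2.5.
#' @param extremely_low_frac Lower bound of the very-low band, default 0.4.
#' @return A list of class `band_config`.
#' @export
band_config <- function(reference_ts = 3.0,
                        similar_low_frac = 0.8, similar_high_frac = 1.25,
                        moderate_high_frac = 2.5, extremely_low_frac = 0.4) {
  if (!(extremely_low_frac < similar_low_frac &&
        similar_low_frac < similar_high_frac &&
        similar_high_frac < moderate_high_frac))
    stop("band fractions must satisfy extremely_low < similar_low < similar_high < moderate_high")
  structure(list(reference_ts = reference_ts,
                 similar_low_frac = similar_low_frac,
                 similar_high_frac = similar_high_frac,
                 moderate_high_frac = moderate_high_frac,
                 extremely_low_frac = extremely_low_frac),
            class = "band_config")
}

BAND_LEVELS <- c("extremely_low", "very_low", "similar", "moderate", "high")

#' Classify Ts% into infiltration bands
#'
#' `similar` spans `[0.8, 1.25] * reference` (closed); `moderate` is
#' `(1.25, moderate_high_frac] * reference`; `high` lies above; `very_low` is
#' `[extremely_low_frac, 0.8) * reference`; `extremely_low` below.
#'
#' @param ts_percent Positive Ts% values.
#' @param config A [band_config()].
#' @return Factor with levels extremely_low < very_low < similar < moderate
#'   < high.
#' @export
classify_band <- function(ts_percent, config = band_config()) {
  if (any(ts_percent <= 0)) stop("Ts% must be positive")
  r <- config$reference_ts
  eps <- 1e-9 * max(1, r)   # edge values land in their documented band
  band <- ifelse(ts_percent < r * config$extremely_low_frac - eps, "extremely_low",
          ifelse(ts_percent < r * config$similar_low_frac - eps, "very_low",
          ifelse(ts_percent <= r * config$similar_high_frac + eps, "similar",
          ifelse(ts_percent <= r * config$moderate_high_frac + eps, "moderate",
                 "high"))))
  factor(band, levels = BAND_LEVELS, ordered = TRUE)
}

#' Per-specimen infiltration call against healthy-tissue Tav
#'
#' A tumor specimen is called T-cell infiltrated when its Tav exceeds the
#' mean plus one sample standard deviation (n-1 denominator) of the Tav of
#' the matched healthy-tissue specimens; the inequality is strict.
#'
#' @param tumor_tav Tav of the tumor specimen(s).
#' @param ht_specimen_tavs Tav of at least two matched healthy-tissue
#'   specimens (same platform).
#' @return Logical per tumor specimen.
#' @export
call_infiltrated <- function(tumor_tav, ht_specimen_tavs) {
  if (length(ht_specimen_tavs) < 2)
    stop("at least two healthy-tissue specimens are required")
  thr <- mean(ht_specimen_tavs) + sd(ht_specimen_tavs)
  as.vector(tumor_tav > thr)
}

#' Adapt a signature to the genes measured by a platform
#'
#' Intersects the signature with the platform's gene list, preserving order.
#' When genes are lost the adapted signature is renamed by appending the
#' surviving gene count (e.g. an 8-gene survivor of `signature-H` becomes
#' `signature-H8`). Fewer than `min_genes` survivors is an error.
#'
#' @param signature A [gene_signature()].
#' @param platform_genes Character vector of genes measured by the platform.
#' @param min_genes Minimum surviving genes, default 8.
#' @return The adapted [gene_signature()].
#' @export
adapt_signature <- function(signature, platform_genes, min_genes = 8) {
  if (!length(platform_genes)) stop("platform gene list is empty")
  genes <- as_genes(signature)
  kept <- genes[genes %in% platform_genes]
  lost <- setdiff(genes, kept)
  if (length(kept) < min_genes)
    stop("only ", length(kept), " signature gene(s) on the platform (min ",
         min_genes, "); missing: ", paste(lost, collapse = ", "))
  name <- if (inherits(signature, "gene_signature")) signature$name else "signature"
  if (!length(lost)) return(
    gene_signature(name, kept, provenance = "all genes present on platform"))
  warning(length(lost), " signature gene(s) absent from platform dropped: ",
          paste(lost, collapse = ", "))
  gene_signature(paste0(name, length(kept)), kept,
                 provenance = paste0("platform adaptation of '", name,
                                     "'; dropped: ", paste(lost, collapse = ", ")))
}

#' Quartile concordance between two specimen rankings
#'
#' Specimens are ranked in descending score order (ties broken by the
#' original specimen order, so ranking is stable); the top and bottom
#' ceiling(n/4) specimens form Q1 and Q4. Reported is the percentage of the
#' reference's Q1 (Q4) specimens that are also in the other score's Q1 (Q4).
#'
#' @param scores_ref,scores_other Named numeric vectors over the same
#'   specimen set (n >= 4).
#' @return List with `q1_overlap_pct`, `q4_overlap_pct` and `q_size`.
#' @export
quartile_concordance <- function(scores_ref, scores_other) {
  ids <- names(scores_ref)
  if (is.null(ids) || is.null(names(scores_other)))
    stop("scores must be named by specimen id")
  if (!setequal(ids, names(scores_other)) ||
      length(ids) != length(scores_other))
    stop("specimen sets of the two score vectors differ")
  n <- length(ids)
  if (n < 4) stop("at least 4 specimens are required")
  scores_other <- scores_other[ids]
  q <- ceiling(n / 4)
  rank_ids <- function(s) ids[order(-s, seq_along(s))]
  ref_rank <- rank_ids(scores_ref)
  oth_rank <- rank_ids(scores_other)
  q1_ref <- ref_rank[seq_len(q)]; q4_ref <- ref_rank[(n - q + 1):n]
  q1_oth <- oth_rank[seq_len(q)]; q4_oth <- oth_rank[(n - q + 1):n]
  list(q1_overlap_pct = 100 * length(intersect(q1_ref, q1_oth)) / q,
       q4_overlap_pct = 100 * length(intersect(q4_ref, q4_oth)) / q,
       q_size = q)
}

#' Score every sample of a matrix for T-cell infiltration
#'
#' Convenience wrapper computing Ts%, Tav, band and (when a healthy-tissue
#' reference is supplied) Ts-l2 and the per-specimen infiltration call for
#' every column of an expression matrix.
#'
#' @param x Log2 expression matrix (genes x samples).
#' @param signature A [gene_signature()].
#' @param t_ref Named T-cell reference profile (log2).
#' @param ht_gene_means Optional named per-gene healthy-tissue means for
#'   Ts-l2.
#' @param ht_specimen_tavs Optional Tav values of individual healthy-tissue
#'   specimens for the infiltration call.
#' @param band A [band_config()].
#' @param platform Platform label for Tav.
#' @return A data.frame of class `infiltration_scores` with columns
#'   `sample_id`, `ts_percent`, `tav`, `band` and optionally `ts_l2`,
#'   `infiltrated`.
#' @export
score_infiltration <- function(x, signature, t_ref,
                               ht_gene_means = NULL, ht_specimen_tavs = NULL,
                               band = band_config(), platform = "array") {
  assert_log2(x)
  out <- data.frame(sample_id = colnames(x),
                    ts_percent = unname(ts_percent(x, signature, t_ref)),
                    tav = as.numeric(tav(x, signature, platform)),
                    stringsAsFactors = FALSE)
  out$band <- classify_band(out$ts_percent, band)
  if (!is.null(ht_gene_means))
    out$ts_l2 <- unname(ts_l2(x, ht_gene_means, signature))
  if (!is.null(ht_specimen_tavs))
    out$infiltrated <- call_infiltrated(out$tav, ht_specimen_tavs)
  attr(out, "platform") <- platform
  class(out) <- c("infiltration_scores", "data.frame")
  out
}

#' @export
print.infiltration_scores <- function(x, ...) {
  cat(sprintf("T-cell infiltration scores (%d samples, Tav-%s)\n",
              nrow(x), attr(x, "platform")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
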