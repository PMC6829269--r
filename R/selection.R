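#' Configuration for the six-round signature selection
#'
#' Thresholds and modes of the six-round procedure that reduces a candidate
#' gene list to a T-cell-restricted signature. The defaults are the published
#' ones: genes must be over-expressed by T cells by at least 3.32 log2
#' (ten-fold) versus every non-T immune subset (round 1) and versus the mean
#' of the non-lymphoid tissue means (round 2); the max-minus-min tissue range
#' must lie within 2.5-8.5 log2 (round 3); tissue-wise deviations from the
#' cohort mean profile greater than 3.32 log2 flag constitutive parenchymal
#' expression (rounds 4 and 5, the second pass recomputing the cohort mean
#' from survivors); and over-expression failures in cell lines from at least
#' two distinct parenchymal sources, or any immune-derived line, exclude a
#' gene (round 6).
#'
#' @param log2_min_overexpr Minimum log2 over-expression of T cells versus
#'   immune subsets, tissues and cell lines (rounds 1, 2, 6). Default 3.32
#'   (ten-fold).
#' @param range_min,range_max Inclusive bounds on the max-minus-min tissue
#'   range (round 3), defaults 2.5 and 8.5 log2.
#' @param deviation_threshold One-sided upper threshold on the tissue-wise
#'   deviation from the cohort mean profile (rounds 4-5), default 3.32 log2.
#' @param outlier_passes Number of deviation passes, default 2 (rounds 4 and
#'   5 as published).
#' @param cellline_min_parenchymal_sources Distinct parenchymal sources among
#'   violating cell lines needed to exclude a gene in round 6, default 2.
#' @param immune_compare_mode Round 1: `"per_group"` (the margin must clear
#'   every immune subset, default) or `"pooled"` (margin versus the unweighted
#'   mean of subset means).
#' @param tissue_compare_mode Round 2: `"mean_of_tissue_means"` (default) or
#'   `"per_tissue"` (margin must clear every single tissue).
#' @param signature_name Name given to the surviving signature.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(log2_min_overexpr = 3.32,
                             range_min = 2.5,
                             range_max = 8.5,
                             deviation_threshold = 3.32,
                             outlier_passes = 2L,
                             cellline_min_parenchymal_sources = 2L,
                             immune_compare_mode = c("per_group", "pooled"),
                             tissue_compare_mode = c("mean_of_tissue_means", "per_tissue"),
                             signature_name = "signature") {
  immune_compare_mode <- match.arg(immune_compare_mode)
  tissue_compare_mode <- match.arg(tissue_compare_mode)
  if (range_min >= range_max) stop("range_min must be smaller than range_max")
  if (log2_min_overexpr <= 0 || deviation_threshold <= 0 ||
      range_min <= 0 || range_max <= 0)
    stop("all thresholds must be positive")
  if (outlier_passes < 1) stop("outlier_passes must be >= 1")
  structure(list(log2_min_overexpr = log2_min_overexpr,
                 range_min = range_min, range_max = range_max,
                 deviation_threshold = deviation_threshold,
                 outlier_passes = as.integer(outlier_passes),
                 cellline_min_parenchymal_sources = as.integer(cellline_min_parenchymal_sources),
                 immune_compare_mode = immune_compare_mode,
                 tissue_compare_mode = tissue_compare_mode,
                 signature_name = signature_name),
            class = "selection_config")
}

partition <- function(diagnostics) {
  list(kept = diagnostics$gene[diagnostics$decision == "kept"],
       excluded = diagnostics$gene[diagnostics$decision == "excluded"],
       diagnostics = diagnostics)
}

#' Round 1: over-expression versus non-T immune subsets
#'
#' A gene is excluded when T cells over-express it by less than
#' `log2_min_overexpr` versus any immune subset (`per_group` mode) or versus
#' the unweighted mean of subset means (`pooled`). A margin exactly equal to
#' the threshold is kept ("less than" excludes).
#'
#' @param gm A `group_mean_table` (see [group_means()]) with `t_ref` and at
#'   least one `IMMUNE_NON_T` group.
#' @param config A [selection_config()].
#' @param genes Genes to evaluate; defaults to all genes in `gm`.
#' @return List with `kept`, `excluded` and a `diagnostics` data.frame (the
#'   limiting margin per gene).
#' @export
round1_immune_filter <- function(gm, config = selection_config(),
                                 genes = rownames(gm$means)) {
  if (is.null(gm$t_ref)) stop("t_ref missing: no T_CELL samples in the table")
  imm <- group_means_of_class(gm, "IMMUNE_NON_T")
  if (!ncol(imm)) stop("no IMMUNE_NON_T groups in the table")
  imm <- imm[genes, , drop = FALSE]
  t_ref <- gm$t_ref[genes]
  margins <- t_ref - imm  # per-gene, per-subset log2 margin
  margin <- if (config$immune_compare_mode == "per_group")
    apply(margins, 1, min) else t_ref - rowMeans(imm)
  diagnostics <- data.frame(
    round = 1L, gene = genes, margin = unname(margin),
    decision = ifelse(margin < config$log2_min_overexpr, "excluded", "kept"),
    stringsAsFactors = FALSE)
  partition(diagnostics)
}

#' Round 2: over-expression versus non-lymphoid tissues
#'
#' Default mode compares `t_ref` with the unweighted mean of per-tissue mean
#' expression; `per_tissue` mode requires the margin to clear every tissue.
#' Margins below `log2_min_overexpr` exclude; equality keeps.
#'
#' @inheritParams round1_immune_filter
#' @return As [round1_immune_filter()].
#' @export
round2_tissue_filter <- function(gm, config = selection_config(),
                                 genes = rownames(gm$means)) {
  if (is.null(gm$t_ref)) stop("t_ref missing: no T_CELL samples in the table")
  tis <- group_means_of_class(gm, "TISSUE")
  if (ncol(tis) < 2) stop("round 2 requires at least two TISSUE groups")
  tis <- tis[genes, , drop = FALSE]
  t_ref <- gm$t_ref[genes]
  margin <- if (config$tissue_compare_mode == "mean_of_tissue_means")
    t_ref - rowMeans(tis) else apply(t_ref - tis, 1, min)
  diagnostics <- data.frame(
    round = 2L, gene = genes, margin = unname(margin),
    decision = ifelse(margin < config$log2_min_overexpr, "excluded", "kept"),
    stringsAsFactors = FALSE)
  partition(diagnostics)
}

#' Round 3: tissue expression range filter
#'
#' The difference between the maximum and minimum per-tissue mean expression
#' of a gene must lie within `[range_min, range_max]` (bounds inclusive):
#' a too-small range means the gene does not track the varying T-cell content
#' of tissues, a too-large one that some parenchyma expresses it
#' constitutively.
#'
#' @inheritParams round1_immune_filter
#' @return As [round1_immune_filter()]; diagnostics carry the range.
#' @export
round3_range_filter <- function(gm, config = selection_config(),
                                genes = rownames(gm$means)) {
  tis <- group_means_of_class(gm, "TISSUE")
  if (ncol(tis) < 2) stop("round 3 requires at least two TISSUE groups")
  tis <- tis[genes, , drop = FALSE]
  rng <- apply(tis, 1, max) - apply(tis, 1, min)
  diagnostics <- data.frame(
    round = 3L, gene = genes, range = unname(rng),
    decision = ifelse(rng >= config$range_min & rng <= config$range_max,
                      "kept", "excluded"),
    stringsAsFactors = FALSE)
  partition(diagnostics)
}

#' Rounds 4-5: tissue-wise outlier deviation filter
#'
#' For every entering gene g and tissue t the tissue-minus-T-cell difference
#' nl/Tc(g,t) = mean(g,t) - t_ref(g) is computed; its mean over the entering
#' genes, M_nl/Tc(t), is the cohort profile of that pass. A gene whose
#' deviation nl/Tc(g,t) - M_nl/Tc(t) exceeds `deviation_threshold` in any
#' tissue (one-sided, above) is flagged as constitutively expressed by that
#' tissue's parenchyma and excluded. Exclusions within a pass are
#' simultaneous; each further pass recomputes M_nl/Tc from the survivors,
#' which is what distinguishes round 5 from round 4. The per-gene standard
#' deviation of the deviations across tissues is reported as a homogeneity
#' diagnostic.
#'
#' @inheritParams round1_immune_filter
#' @param genes Genes entering the first pass.
#' @param passes Number of passes (default from `config`).
#' @return List with `kept`, `excluded`, `diagnostics` (one row per gene and
#'   pass: max deviation, SD of deviations, decision) and `pass_excluded`, the
#'   genes excluded at each pass.
#' @export
round45_outlier_filter <- function(gm, config = selection_config(),
                                   genes = rownames(gm$means),
                                   passes = config$outlier_passes) {
  if (is.null(gm$t_ref)) stop("t_ref missing: no T_CELL samples in the table")
  tis <- group_means_of_class(gm, "TISSUE")
  if (ncol(tis) < 2) stop("rounds 4-5 require at least two TISSUE groups")
  entering <- genes
  diagnostics <- NULL
  pass_excluded <- vector("list", passes)
  for (p in seq_len(passes)) {
    if (length(entering) < 2) {
      warning("outlier pass ", p, " skipped: fewer than 2 genes entering")
      break
    }
    nl <- tis[entering, , drop = FALSE] - gm$t_ref[entering]
    M <- colMeans(nl)                      # cohort profile, frozen at pass entry
    dev <- sweep(nl, 2, M)
    max_dev <- apply(dev, 1, max)
    sd_dev <- apply(dev, 1, sd)
    out <- max_dev > config$deviation_threshold
    diagnostics <- rbind(diagnostics, data.frame(
      round = if (p == 1L) 4L else 5L, pass = p, gene = entering,
      max_deviation = unname(max_dev), sd_deviation = unname(sd_dev),
      decision = ifelse(out, "excluded", "kept"), stringsAsFactors = FALSE))
    pass_excluded[[p]] <- entering[out]
    entering <- entering[!out]
  }
  list(kept = entering, excluded = setdiff(genes, entering),
       diagnostics = diagnostics, pass_excluded = pass_excluded)
}

cellline_means <- function(x, annotation) {
  annotation <- validate_annotation(annotation)
  ann <- annotation[annotation$class == "CELL_LINE", ]
  ann <- ann[ann$sample_id %in% colnames(x), ]
  if (!nrow(ann)) return(NULL)
  lines <- unique(ann$group)
  means <- vapply(lines, function(l)
    rowMeans(x[, ann$sample_id[ann$group == l], drop = FALSE]),
    numeric(nrow(x)))
  dimnames(means) <- list(rownames(x), lines)
  src <- vapply(lines, function(l) {
    s <- unique(ann$source_lineage[ann$group == l])
    if (length(s) > 1)
      stop("cell line '", l, "' has conflicting source_lineage values")
    s
  }, character(1))
  list(means = means, source = src)
}

#' Round 6: cell-line over-expression filter
#'
#' A cell line violates for a gene when T cells over-express the gene by less
#' than `log2_min_overexpr` versus that line's mean. A gene is excluded when
#' the violating lines span at least `cellline_min_parenchymal_sources`
#' distinct parenchymal source lineages, or when any violating line is
#' immune-derived (`source_lineage == "immune"`). Violations are evaluated
#' per individual cell line, not per lineage aggregate.
#'
#' @param line_means List with `means` (genes x lines) and `source` (named
#'   character, parenchymal source or `"immune"` per line), as produced
#'   internally from a matrix + annotation.
#' @param t_ref Named T-cell reference profile.
#' @inheritParams round1_immune_filter
#' @return As [round1_immune_filter()]; diagnostics list the violating lines
#'   and distinct sources per gene.
#' @export
round6_cellline_filter <- function(line_means, t_ref,
                                   config = selection_config(),
                                   genes = rownames(line_means$means)) {
  lm <- line_means$means[genes, , drop = FALSE]
  src <- line_means$source
  viol <- (t_ref[genes] - lm) < config$log2_min_overexpr
  rows <- lapply(genes, function(g) {
    v <- colnames(lm)[viol[g, ]]
    v_src <- src[v]
    n_par <- length(unique(v_src[v_src != "immune"]))
    immune_hit <- any(v_src == "immune")
    data.frame(round = 6L, gene = g,
               violating_lines = paste(v, collapse = ","),
               n_parenchymal_sources = n_par, immune_line = immune_hit,
               decision = if (n_par >= config$cellline_min_parenchymal_sources ||
                              immune_hit) "excluded" else "kept",
               stringsAsFactors = FALSE)
  })
  partition(do.call(rbind, rows))
}

#' Run the six-round T-cell-restricted gene selection
#'
#' Applies the six rounds in order to a candidate gene list: (1)
#' over-expression versus every non-T immune subset, (2) over-expression
#' versus non-lymphoid tissues, (3) tissue range within bounds, (4-5) two
#' passes of the tissue-wise outlier deviation test, (6) the cell-line
#' filter. Rounds whose sample class is absent from the annotation are
#' skipped with a warning. Candidates missing from the matrix are dropped
#' with a warning.
#'
#' @param x Log2 expression matrix (genes x samples).
#' @param annotation Sample annotation (see [read_sample_annotation()]).
#' @param candidates A [gene_signature()] or character vector of candidate
#'   genes.
#' @param config A [selection_config()].
#' @param pooling T-cell reference pooling passed to [group_means()].
#' @return A `selection_report`: list with the surviving `signature`,
#'   `excluded_counts` (named by round), `rounds` (per-round diagnostics),
#'   `config`, `candidates` and `n_candidates`.
#' @export
run_selection <- function(x, annotation, candidates,
                          config = selection_config(),
                          pooling = c("pooled_samples", "mean_of_subgroup_means")) {
  pooling <- match.arg(pooling)
  cand <- as_genes(candidates)
  missing <- setdiff(cand, rownames(x))
  if (length(missing)) {
    warning("candidate gene(s) absent from matrix dropped: ",
            paste(missing, collapse = ", "))
    cand <- setdiff(cand, missing)
  }
  if (!length(cand)) stop("no candidate genes present in the matrix")
  annotation <- validate_annotation(annotation)
  gm <- group_means(x, annotation, pooling = pooling)
  if (is.null(gm$t_ref)) stop("selection requires T_CELL samples")
  classes <- unique(gm$group_class)
  n_tissues <- sum(gm$group_class == "TISSUE")

  current <- cand
  rounds <- list()
  excluded_counts <- stats::setNames(integer(6), paste0("round", 1:6))

  if ("IMMUNE_NON_T" %in% classes && length(current)) {
    r1 <- round1_immune_filter(gm, config, current)
    rounds$round1 <- r1$diagnostics
    excluded_counts["round1"] <- length(r1$excluded)
    current <- r1$kept
  } else warning("round 1 skipped: no IMMUNE_NON_T samples")

  if (n_tissues >= 2 && length(current)) {
    r2 <- round2_tissue_filter(gm, config, current)
    rounds$round2 <- r2$diagnostics
    excluded_counts["round2"] <- length(r2$excluded)
    current <- r2$kept

    if (length(current)) {
      r3 <- round3_range_filter(gm, config, current)
      rounds$round3 <- r3$diagnostics
      excluded_counts["round3"] <- length(r3$excluded)
      current <- r3$kept
    }

    if (length(current)) {
      r45 <- round45_outlier_filter(gm, config, current)
      rounds$round4 <- r45$diagnostics[r45$diagnostics$pass == 1, ]
      if (config$outlier_passes >= 2)
        rounds$round5 <- r45$diagnostics[r45$diagnostics$pass > 1, ]
      np <- length(r45$pass_excluded)
      excluded_counts["round4"] <- length(r45$pass_excluded[[1]])
      if (np >= 2)
        excluded_counts["round5"] <- length(unlist(r45$pass_excluded[-1]))
      current <- r45$kept
    }
  } else if (n_tissues < 2) warning("rounds 2-5 skipped: fewer than two TISSUE groups")

  if ("CELL_LINE" %in% classes && length(current)) {
    lm <- cellline_means(x, annotation)
    r6 <- round6_cellline_filter(lm, gm$t_ref, config, current)
    rounds$round6 <- r6$diagnostics
    excluded_counts["round6"] <- length(r6$excluded)
    current <- r6$kept
  } else if (!"CELL_LINE" %in% classes) warning("round 6 skipped: no CELL_LINE samples")

  if (!length(current))
    warning("no genes survived the selection; returning an empty signature")
  signature <- if (length(current))
    gene_signature(config$signature_name, current,
                   provenance = "six-round T-cell-restriction selection")
  else structure(list(name = config$signature_name, genes = character(0),
                      provenance = "six-round T-cell-restriction selection"),
                 class = "gene_signature")

  structure(list(signature = signature, excluded_counts = excluded_counts,
                 rounds = rounds, config = config, candidates = cand,
                 n_candidates = length(cand)),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Six-round T-cell-restricted gene selection\n"))
  cat(sprintf("  candidates: %d   survivors: %d\n",
              x$n_candidates, length(x$signature$genes)))
  cat("  excluded per round: ",
      paste(sprintf("%s=%d", sub("round", "r", names(x$excluded_counts)),
                    x$excluded_counts), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.selection_report <- function(object, ...) {
  print(object)
  cat("\nSurviving signature:\n")
  print(object$signature)
  invisible(object)
}
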