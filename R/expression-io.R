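#' Construct an expression matrix
#'
#' An expression matrix is a plain numeric matrix (genes in rows, samples in
#' columns) carrying a `scale_tag` attribute that records whether values are
#' log2 intensities or linear-scale measurements. All selection and scoring
#' functions require the log2 scale.
#'
#' @param values Numeric matrix with unique, non-empty row names (gene
#'   symbols) and column names (sample identifiers).
#' @param scale_tag `"log2"` (default) or `"linear"`.
#' @return A numeric matrix of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale_tag = c("log2", "linear")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("`values` must have gene row names and sample column names")
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 genes[bad[1]], samples[bad[2]]))
  }
  structure(values, scale_tag = scale_tag,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale_tag")))
  invisible(x)
}

scale_tag <- function(x) {
  tag <- attr(x, "scale_tag")
  if (is.null(tag)) "log2" else tag
}

assert_log2 <- function(x, what = "matrix") {
  if (scale_tag(x) != "log2")
    stop(what, " must be on the log2 scale (scale_tag = 'log2')")
  invisible(x)
}

file_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix from delimited text
#'
#' Reads a TSV (or CSV, detected from the extension) with gene symbols in the
#' first column and sample identifiers in the header row. Transposed files
#' (samples in rows) are handled via `orientation`.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param scale_tag Declared scale of the values, default `"log2"`.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows", "samples_in_rows"),
                                   scale_tag = c("log2", "linear")) {
  orientation <- match.arg(orientation)
  scale_tag <- match.arg(scale_tag)
  df <- utils::read.delim(path, sep = file_sep(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expected an id column plus at least one value column: ", path)
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate row identifiers in ", path, ": ", paste(dup, collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw), dimnames = dimnames(raw)))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 raw[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(raw)[bad[1, 2]], path))
  }
  rownames(num) <- ids
  if (orientation == "samples_in_rows") num <- t(num)
  expr_matrix(num, scale_tag = scale_tag)
}

#' Write an expression matrix to delimited text
#'
#' @param x Expression matrix (genes x samples).
#' @param path Output path; `.csv` extension selects comma separation.
#' @param id_column Name of the first (gene id) column in the header.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, id_column = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = file_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Expects a TSV/CSV with columns `sample_id`, `class`, `group` and optionally
#' `source_lineage`. `class` must be one of `T_CELL`, `IMMUNE_NON_T`,
#' `TISSUE`, `CELL_LINE`, `TUMOR`. Cell-line rows must carry a non-empty
#' `source_lineage` (a parenchymal source such as `"lung"`, or `"immune"`).
#'
#' @param path Path to the annotation file.
#' @return A validated `data.frame`.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.delim(path, sep = file_sep(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotation(df)
}

#' @rdname read_sample_annotation
#' @param annotation A data.frame to validate in place.
#' @export
validate_annotation <- function(annotation) {
  need <- c("sample_id", "class", "group")
  miss <- setdiff(need, colnames(annotation))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (!"source_lineage" %in% colnames(annotation))
    annotation$source_lineage <- NA_character_
  dup <- unique(annotation$sample_id[duplicated(annotation$sample_id)])
  if (length(dup))
    stop("duplicate sample_id in annotation: ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(annotation$class), SAMPLE_CLASSES)
  if (length(bad))
    stop("unknown sample class(es): ", paste(bad, collapse = ", "),
         " (expected ", paste(SAMPLE_CLASSES, collapse = "/"), ")")
  cl <- annotation$class == "CELL_LINE"
  if (any(cl & (is.na(annotation$source_lineage) | !nzchar(annotation$source_lineage))))
    stop("CELL_LINE samples must carry a non-empty source_lineage")
  annotation
}

#' Shift a log2 matrix so its trimmed mean hits a target
#'
#' Between-dataset normalization: the mean of all values in the matrix is
#' computed after discarding the lowest and highest `trim_fraction` of values
#' (`floor(trim_fraction * N)` values at each tail), and a single additive
#' log2 shift is applied so this trimmed mean equals `target`. An additive
#' shift in log2 space is a multiplicative rescale in linear space and leaves
#' all downstream log2 differences invariant; a linear-space variant is
#' available via `space = "linear"`.
#'
#' @param x Log2-scale expression matrix.
#' @param target Target trimmed mean (log2).
#' @param trim_fraction Fraction trimmed at each tail, default 0.05.
#' @param space `"log2"` (additive shift, default) or `"linear"`
#'   (multiplicative rescale of `2^x` so the trimmed mean of the re-logged
#'   values matches `target` up to Jensen effects; provided for comparison).
#' @return The shifted matrix, attributes preserved.
#' @export
trimmed_mean_normalize <- function(x, target, trim_fraction = 0.05,
                                   space = c("log2", "linear")) {
  space <- match.arg(space)
  assert_log2(x)
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)")
  tm <- trimmed_mean(as.numeric(x), trim_fraction)
  if (space == "log2") {
    out <- x + (target - tm)
  } else {
    lin <- 2^x * (2^target / 2^tm)
    out <- x
    out[] <- log2(lin)
  }
  out
}

trimmed_mean <- function(v, trim_fraction) {
  n <- length(v)
  k <- floor(trim_fraction * n)
  if (n - 2 * k < 1)
    stop("trimming leaves fewer than one value (n = ", n, ", k = ", k, " per tail)")
  s <- sort(v)
  mean(s[(k + 1):(n - k)])
}

#' Per-group mean expression and the T-cell reference profile
#'
#' Computes, for every gene, the mean log2 expression within each annotated
#' group, plus the T-cell reference profile `t_ref` used throughout selection
#' and scoring. With `pooling = "pooled_samples"` (default) `t_ref` averages
#' over all `T_CELL` samples; `"mean_of_subgroup_means"` takes the unweighted
#' mean of per-T-subset means, which protects against unbalanced subset sizes.
#'
#' @param x Log2 expression matrix.
#' @param annotation Sample annotation (see [read_sample_annotation()]).
#' @param pooling How to pool T-cell subsets into `t_ref`.
#' @return A `group_mean_table`: list with `means` (genes x groups),
#'   `group_class` (named character), `n_samples` (named integer) and `t_ref`
#'   (named numeric, present when T_CELL samples exist).
#' @export
group_means <- function(x, annotation,
                        pooling = c("pooled_samples", "mean_of_subgroup_means")) {
  pooling <- match.arg(pooling)
  assert_log2(x)
  annotation <- validate_annotation(annotation)
  samples <- colnames(x)
  miss <- setdiff(samples, annotation$sample_id)
  if (length(miss))
    stop("unannotated sample(s): ", paste(miss, collapse = ", "))
  ann <- annotation[match(samples, annotation$sample_id), ]
  groups <- unique(ann$group)
  means <- do.call(cbind, lapply(groups, function(g) {
    idx <- which(ann$group == g)
    if (!length(idx)) stop("group with zero samples: ", g)
    rowMeans(x[, idx, drop = FALSE])
  }))
  dimnames(means) <- list(rownames(x), groups)
  group_class <- vapply(groups, function(g) ann$class[ann$group == g][1], character(1))
  n_samples <- vapply(groups, function(g) sum(ann$group == g), integer(1))
  t_groups <- groups[group_class == "T_CELL"]
  t_ref <- NULL
  if (length(t_groups)) {
    if (pooling == "pooled_samples") {
      idx <- which(ann$class == "T_CELL")
      t_ref <- rowMeans(x[, idx, drop = FALSE])
    } else {
      t_ref <- rowMeans(means[, t_groups, drop = FALSE])
    }
  }
  structure(list(means = means, group_class = group_class,
                 n_samples = n_samples, t_ref = t_ref, pooling = pooling),
            class = "group_mean_table")
}

#' @export
print.group_mean_table <- function(x, ...) {
  cat(sprintf("<group_mean_table> %d genes, %d groups (%s)\n",
              nrow(x$means), ncol(x$means),
              paste(sprintf("%s:%d", names(table(x$group_class)),
                            as.integer(table(x$group_class))), collapse = " ")))
  if (!is.null(x$t_ref)) cat("  t_ref present (", x$pooling, ")\n", sep = "")
  invisible(x)
}

group_means_of_class <- function(gm, class) {
  gm$means[, names(gm$group_class)[gm$group_class == class], drop = FALSE]
}
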