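#' Construct a gene signature
#'
#' @param name Signature name.
#' @param genes Character vector of unique gene symbols (order is preserved).
#' @param provenance Free-text origin of the signature.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, provenance = "") {
  if (!length(genes)) stop("a gene signature must contain at least one gene")
  genes <- as.character(genes)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate genes in signature '", name, "': ", paste(dup, collapse = ", "))
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s (%d genes)\n  %s\n", x$name,
              length(x$genes), paste(x$genes, collapse = ", ")))
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$genes)

as_genes <- function(signature) {
  if (inherits(signature, "gene_signature")) signature$genes
  else as.character(signature)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' gene symbols. Duplicate genes within a line are collapsed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_signature()] objects.
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields in ", path)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) collapsed in GMT set '", fields[1], "' (line ", i, ")")
      genes <- unique(genes)
    }
    gene_signature(fields[1], genes, provenance = fields[2])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene signatures to a GMT file
#'
#' @param signatures A `gene_signature` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    desc <- if (nzchar(s$provenance)) s$provenance else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' The 15-gene T-cell-restricted signature (signature-H)
#'
#' Returns the published 15-gene T-cell-restricted signature shipped with the
#' package: CD2, CD247, CD28, CD3D, CD3G, CD6, GPR171, GZMK, ICOS, ITK,
#' KLRB1, PYHIN1, TIGIT, TRAT1, TRBC1.
#'
#' @return A [gene_signature()] of 15 genes named `"signature-H"`.
#' @export
signature_h <- function() {
  path <- system.file("extdata", "signature_H.gmt", package = "tcelsig",
                      mustWork = TRUE)
  read_gene_sets_gmt(path)[["signature-H"]]
}
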