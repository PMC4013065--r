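#' Per-time-point principal component analysis
#'
#' PCA of the descriptor table restricted to one imaging date, with every
#' descriptor centred and scaled to unit variance (so the decomposition is
#' of the correlation structure and is invariant to affine rescaling of
#' any input column). Zero-variance columns are dropped with a warning.
#'
#' @param table a descriptor table.
#' @param das imaging date to analyse; `NULL` pools all rows.
#' @param subset optional character vector of descriptor names to restrict
#'   the analysis to, e.g. [perez_perez_descriptors()] for comparison with
#'   single-time-point in-vitro studies.
#' @param descriptors candidate columns; defaults to the canonical 20.
#' @return an object of class `pca_result`: list with `loadings`
#'   (descriptor x component), `percent` (percent variance per component,
#'   summing to 100), `scores`, `sdev` and the analysed descriptor names.
#' @export
pca_per_timepoint <- function(table, das = NULL, subset = NULL,
                              descriptors = descriptor_names()) {
  d <- if (is.null(das)) table else table[table$das == das, , drop = FALSE]
  cols <- intersect(descriptors, names(d))
  if (!is.null(subset)) {
    unknown <- setdiff(subset, cols)
    if (length(unknown)) stop("subset descriptors not in table: ",
                              paste(unknown, collapse = ", "))
    cols <- intersect(cols, subset)
  }
  if (length(cols) < 2L) stop("need at least 2 descriptors for PCA")
  x <- d[, cols, drop = FALSE]
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2L) stop("need at least 2 observations for PCA")
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(names(sds)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) < 2L) stop("need at least 2 descriptors for PCA")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation, percent = pct,
                 scores = pc$x, sdev = pc$sdev,
                 descriptors = colnames(x), das = das, n = nrow(x)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d obs x %d descriptors%s\n", x$n,
              length(x$descriptors),
              if (is.null(x$das)) "" else sprintf(" at %g DAS", x$das)))
  k <- min(5L, length(x$percent))
  cat("percent variance:",
      paste(sprintf("PC%d %.2f%%", seq_len(k), x$percent[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Descriptors comparable with the Perez-Perez in-vitro study
#'
#' Seven descriptors of this pipeline with counterparts in the earlier
#' single-time-point rosette study (rosette area and perimeter, rosette
#' compactness, maximum Feret diameter, and fitted-outline size proxies
#' mapped to the convex-hull and enclosing-circle metrics). The published
#' correspondence table is not distributed with this package, so the
#' hull-based mappings are this package's own stand-ins; see the methods
#' vignette.
#'
#' @return character vector of 7 descriptor names.
#' @export
perez_perez_descriptors <- function() {
  c("area", "circumference", "compactness", "maxdiam",
    "mincirclediam", "conhullcirc", "conhullarea")
}
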