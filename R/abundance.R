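#' Sample-by-protein abundance matrix
#'
#' Thin container used throughout the pipeline: a numeric matrix (samples in
#' rows, proteins in columns, `NA` = missing) tagged with the layer it
#' carries: `"raw"` (positive linear scale), `"log2"`, or `"residual"`
#' (adjusted for systematic effects, per-protein mean ~ 0).
#'
#' @param values Numeric matrix with sample ids as rownames and protein ids
#'   as colnames.
#' @param layer One of `"raw"`, `"log2"`, `"residual"`.
#' @return Object of class `"abundance_matrix"`.
#' @export
abundance_matrix <- function(values, layer = c("raw", "log2", "residual")) {
  layer <- match.arg(layer)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (layer == "raw" && any(values[!is.na(values)] <= 0))
    stop("abundance_matrix: raw layer must be strictly positive where observed")
  structure(list(values = values, layer = layer), class = "abundance_matrix")
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' @export
as.matrix.abundance_matrix <- function(x, ...) x$values

#' @export
print.abundance_matrix <- function(x, ...) {
  v <- x$values
  cat("Abundance matrix [", x$layer, "]: ", nrow(v), " samples x ", ncol(v),
      " proteins; ", round(100 * mean(is.na(v)), 1), "% missing\n", sep = "")
  invisible(x)
}

#' Convert a raw-layer matrix to log2
#' @param x An `"abundance_matrix"` with layer `"raw"`.
#' @return An `"abundance_matrix"` with layer `"log2"`.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$layer != "raw") stop("log2_transform: expected the raw layer")
  abundance_matrix(log2(x$values), "log2")
}
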