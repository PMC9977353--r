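#' Read a gene-set library in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are dropped with a warning.
#'
#' @param path Path to the `.gmt` file.
#' @param source_label Library label (e.g. `"GO-BP"`, `"REACTOME"`).
#' @return Object of class `"gene_set_library"`: a named list of character
#'   vectors with attributes `description` and `source`.
#' @export
read_gmt <- function(path, source_label = NA_character_) {
  if (!file.exists(path)) stop("read_gmt: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || !nzchar(f[1]))
      stop("read_gmt: malformed line ", i,
           " (need name, description and at least one member)")
    nms[i] <- f[1]
    desc[i] <- f[2]
    mem <- f[-(1:2)]
    mem <- mem[nzchar(mem)]
    if (anyDuplicated(mem)) {
      warning("read_gmt: duplicate member(s) dropped in set '", f[1], "'")
      mem <- unique(mem)
    }
    if (!length(mem)) stop("read_gmt: malformed line ", i, " (empty set)")
    sets[[i]] <- mem
  }
  if (anyDuplicated(nms)) stop("read_gmt: duplicate set names")
  names(sets) <- nms
  structure(sets, description = stats::setNames(desc, nms),
            source = source_label, class = "gene_set_library")
}

#' Write a gene-set library in GMT format
#' @param library A `"gene_set_library"` (or named list of id vectors).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(library, path) {
  desc <- attr(library, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(library)),
                                             names(library))
  lines <- vapply(names(library), function(nm)
    paste(c(nm, desc[[nm]], library[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat("Gene-set library", if (!is.na(attr(x, "source")))
    paste0("(", attr(x, "source"), ")") else "", ":", length(x), "sets,",
    "median size", stats::median(lengths(x)), "\n")
  invisible(x)
}
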