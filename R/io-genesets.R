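#' Read a GMT gene-set collection
#'
#' Standard GMT: each line is `name<TAB>description<TAB>member1<TAB>...`.
#' Member lists are deduplicated and treated as unordered sets.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one per set); the
#'   `description` attribute carries the per-set description strings.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- structure(list(), descriptions = character(0))
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L], " has fewer than 3 fields",
         call. = FALSE)
  nm <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicated gene-set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[`, character(1), 2L), nm)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions;
#'   defaults to the set names.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list (one identifier per line)
#'
#' Used for ChIP target lists; blank lines and duplicates are dropped.
#' @param path File path.
#' @return Character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
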