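#' Position weight matrices
#'
#' A PWM is stored as a list with elements `id` (motif identifier), `counts`
#' (4 x width numeric matrix, rows A, C, G, T; real values allowed), and
#' `probs` (column-stochastic matrix after adding a pseudocount of 0.25 to
#' every cell). `new_pwm()` is the validated constructor used by the parsers
#' and the simulator.
#'
#' @param id Motif identifier.
#' @param counts 4 x width matrix of (possibly real-valued) base counts,
#'   rows in A, C, G, T order.
#' @param pseudocount Added to every cell before normalization.
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(id, counts, pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop("PWM '", id, "': counts must have 4 rows (A,C,G,T)", call. = FALSE)
  if (ncol(counts) < 1L)
    stop("PWM '", id, "': width must be >= 1", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("PWM '", id, "': counts must be finite and non-negative",
         call. = FALSE)
  rownames(counts) <- c("A", "C", "G", "T")
  colnames(counts) <- NULL
  p <- counts + pseudocount
  p <- sweep(p, 2L, colSums(p), "/")
  structure(list(id = id, counts = counts, probs = p,
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "width", ncol(x$counts), "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Width of a PWM
#' @param pwm A `pwm` object.
#' @return Integer motif width.
#' @export
pwm_width <- function(pwm) ncol(pwm$counts)

#' Consensus sequence of a PWM (most probable base per position)
#' @param pwm A `pwm` object.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$probs)[apply(pwm$probs, 2L, which.max)], collapse = "")
}

#' Read PWMs from a TRANSFAC-dialect or JASPAR PFM file
#'
#' TRANSFAC blocks consist of `AC`/`ID` header lines, a `P0` (or `PO`)
#' column-header line with A C G T, numbered position rows, and a `//`
#' terminator; the terminator may be absent before EOF and counts may be
#' real-valued (public matrix dumps vary). JASPAR files (`>` header followed
#' by four `A [ ... ]` style rows) are detected by sniffing and converted to
#' the same representation.
#'
#' @param path Path to the matrix file.
#' @return A list of [new_pwm()] objects, named by motif identifier.
#' @export
read_transfac <- function(path) {
  lines <- readLines(path)
  nonblank <- lines[nzchar(trimws(lines))]
  if (!length(nonblank)) return(list())
  if (startsWith(trimws(nonblank[[1L]]), ">"))
    return(parse_jaspar(lines))
  parse_transfac(lines)
}

parse_transfac <- function(lines) {
  pwms <- list()
  id <- NULL
  rows <- list()
  flush <- function() {
    if (is.null(id) && !length(rows)) return()
    if (!length(rows))
      stop("TRANSFAC block '", id, "' has no position rows", call. = FALSE)
    counts <- t(do.call(rbind, rows))
    pwms[[length(pwms) + 1L]] <<- new_pwm(id, counts)
    id <<- NULL
    rows <<- list()
  }
  for (raw in lines) {
    ln <- trimws(raw)
    if (!nzchar(ln)) next
    if (ln == "//") { flush(); next }
    tok <- strsplit(ln, "[ \t]+")[[1L]]
    tag <- toupper(tok[1L])
    if (tag %in% c("AC", "ID", "NA")) {
      # first identifier wins; ID overrides AC when both present
      if (is.null(id) || tag == "ID") id <- paste(tok[-1L], collapse = "_")
      next
    }
    if (tag %in% c("P0", "PO")) next
    if (grepl("^[0-9]+$", tok[1L])) {
      vals <- suppressWarnings(as.numeric(tok[-1L]))
      # tolerate a trailing consensus letter column
      if (length(vals) >= 4L && is.na(vals[length(vals)]))
        vals <- vals[-length(vals)]
      if (length(vals) != 4L || anyNA(vals))
        stop("PWM '", if (is.null(id)) "?" else id, "' position row ",
             tok[1L], " does not have 4 numeric fields", call. = FALSE)
      rows[[length(rows) + 1L]] <- vals
    }
    # other TRANSFAC tags (XX, BF, CC, ...) are ignored
  }
  flush()
  stats::setNames(pwms, vapply(pwms, `[[`, character(1), "id"))
}

parse_jaspar <- function(lines) {
  pwms <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (!startsWith(ln, ">"))
      stop("malformed JASPAR file near line ", i, call. = FALSE)
    id <- strsplit(sub("^>", "", ln), "[ \t]+")[[1L]][1L]
    rows <- matrix(NA_real_, 4L, 0L)
    taken <- 0L
    vals4 <- vector("list", 4L)
    j <- i + 1L
    while (j <= n && taken < 4L) {
      rl <- trimws(lines[[j]])
      if (nzchar(rl)) {
        rl <- gsub("^[ACGTacgt][ \t]*", "", rl)
        rl <- gsub("[][]", " ", rl)
        vals <- suppressWarnings(as.numeric(strsplit(trimws(rl), "[ \t]+")[[1L]]))
        if (anyNA(vals))
          stop("PWM '", id, "': non-numeric JASPAR count row ", j,
               call. = FALSE)
        taken <- taken + 1L
        vals4[[taken]] <- vals
      }
      j <- j + 1L
    }
    if (taken < 4L)
      stop("PWM '", id, "': expected 4 count rows", call. = FALSE)
    w <- unique(vapply(vals4, length, integer(1)))
    if (length(w) != 1L)
      stop("PWM '", id, "': ragged JASPAR count rows", call. = FALSE)
    counts <- do.call(rbind, vals4)
    pwms[[length(pwms) + 1L]] <- new_pwm(id, counts)
    i <- j
  }
  stats::setNames(pwms, vapply(pwms, `[[`, character(1), "id"))
}

#' Write PWMs in TRANSFAC format
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(pwms, path) {
  out <- character(0)
  for (p in pwms) {
    out <- c(out,
             paste("AC", p$id),
             "XX",
             paste("ID", p$id),
             "P0\tA\tC\tG\tT",
             vapply(seq_len(ncol(p$counts)), function(j) {
               paste(c(sprintf("%02d", j),
                       format(p$counts[, j], trim = TRUE)), collapse = "\t")
             }, character(1)),
             "//")
  }
  writeLines(out, path)
  invisible(path)
}
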