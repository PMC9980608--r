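#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats rnorm rpois rbinom runif cor cor.test wilcox.test
#'   median cmdscale var setNames quantile
#' @importFrom utils read.delim write.table head tail
NULL

QUALITY_TIERS <- c("complete", "high", "medium", "low", "not_determined")
DATASETS <- c("MG", "MV", "MT")
SITES <- c("PC", "DC", "STL")
SOURCES <- c("metavirome", "metagenome", "both")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tab-separated table
#'
#' Reads the TSV dialect used throughout the package: tab-separated, UTF-8,
#' `#`-prefixed comment lines allowed, header row required.
#'
#' @param path File path.
#' @param ... Passed to [utils::read.delim()].
#' @return A data.frame.
#' @export
read_bio_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("NA", ""), ...)
}

#' Write a tab-separated table
#'
#' Writes reals with 15 significant digits so a write/read round trip
#' reproduces integers bit-identically and reals to at least 12 significant
#' digits.
#'
#' @param x A data.frame.
#' @param path File path.
#' @param comment Optional character vector of comment lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_bio_tsv <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  is_real <- vapply(x, function(col) is.double(col) && !all(col == round(col), na.rm = TRUE),
                    logical(1))
  x[is_real] <- lapply(x[is_real], function(col) formatC(col, digits = 15, format = "g"))
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"))
  invisible(path)
}

## Coordinate conventions: files carry 1-based inclusive (GFF3) coordinates;
## internal interval arithmetic is 0-based half-open. Conversion lives here
## and nowhere else.

#' Convert 1-based inclusive coordinates to 0-based half-open
#' @param start,end 1-based inclusive integer coordinates.
#' @return A list with `start0` and `end0` (0-based half-open).
#' @export
to_zero_based <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start0 = start - 1L, end0 = end)
}

#' Convert 0-based half-open coordinates to 1-based inclusive
#' @param start0,end0 0-based half-open integer coordinates.
#' @return A list with `start` and `end` (1-based inclusive).
#' @export
to_one_based <- function(start0, end0) {
  stopifnot(all(start0 >= 0), all(end0 > start0))
  list(start = start0 + 1L, end = end0)
}

## Merge overlapping 1-based inclusive intervals; returns matrix cols start,end
merge_intervals <- function(start, end) {
  if (length(start) == 0) return(cbind(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}
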