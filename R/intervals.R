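#' Genomic intervals
#'
#' Intervals are plain `data.table`s with columns `chrom`, `start`, `end`
#' and `strand`, using the BED convention throughout: 0-based, half-open
#' `[start, end)`. The only 1-based surface in the package is the
#' methylation-table file dialect (see [read_methylation_table()]).
#'
#' @param chrom character chromosome names
#' @param start 0-based inclusive start
#' @param end exclusive end
#' @param strand one of `"+"`, `"-"`, `"."` (recycled)
#' @param ... further columns (e.g. `name`, `score`) carried along
#' @return a `data.table` of class `gintervals`
#' @export
#' @examples
#' gintervals("chr1", 100, 200, "+")
gintervals <- function(chrom, start, end, strand = ".", ...) {
  n <- max(length(chrom), length(start), length(end), length(strand))
  if (length(chrom) == 0L || length(start) == 0L) n <- 0L
  x <- data.table(chrom = rep_len(as.character(chrom), n),
                  start = rep_len(as.integer(start), n),
                  end = rep_len(as.integer(end), n),
                  strand = rep_len(as.character(strand), n), ...)
  validate_intervals(x)
  class(x) <- c("gintervals", class(x))
  x
}

validate_intervals <- function(x) {
  if (!all(c("chrom", "start", "end") %in% names(x)))
    data_error("intervals need chrom/start/end columns")
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    data_error("interval with empty chrom")
  bad <- which(!(x$start >= 0L & x$start < x$end))
  if (length(bad))
    data_error(sprintf("invalid interval at row %d: [%s, %s) on %s",
                       bad[1], x$start[bad[1]], x$end[bad[1]], x$chrom[bad[1]]))
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    data_error("strand must be one of +, -, .")
  invisible(x)
}

#' Read a BED3/BED6 file as intervals
#'
#' @param path file path
#' @return `gintervals` with `name`/`score` preserved when present
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) config_error(sprintf("missing input: %s", path))
  if (file.size(path) == 0L)
    return(gintervals(character(), integer(), integer()))
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- fread(path, sep = "\t", header = FALSE, fill = TRUE,
             colClasses = list(character = 1))
  setnames(x, cols[seq_len(min(ncol(x), 6L))])
  if (!"strand" %in% names(x)) x[, `:=`(strand = ".")]
  x[is.na(strand) | !strand %in% c("+", "-"), strand := "."]
  x[, `:=`(start = as.integer(start), end = as.integer(end))]
  validate_intervals(x)
  class(x) <- c("gintervals", class(x))
  x[]
}

#' Write intervals as BED
#'
#' Emits BED3 when neither name, score nor strand carries information,
#' BED6 otherwise. Round-trips losslessly through [read_bed()].
#'
#' @param intervals a `gintervals` (or compatible data.frame)
#' @param path output file
#' @export
write_bed <- function(intervals, path) {
  x <- as.data.table(intervals)
  validate_intervals(x)
  bed6 <- nrow(x) > 0L &&
    (("strand" %in% names(x) && any(x$strand != ".")) ||
     any(c("name", "score") %in% names(x)))
  out <- if (bed6) {
    data.table(x$chrom, x$start, x$end,
               x$name %||% ".", x$score %||% 0L, x$strand %||% ".")
  } else {
    data.table(x$chrom, x$start, x$end)
  }
  tryCatch(
    fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE),
    error = function(e) data_error(sprintf("cannot write %s: %s", path,
                                           conditionMessage(e))))
  invisible(path)
}

#' Overlap pairs between two interval sets
#'
#' Half-open semantics: `[a,b)` overlaps `[c,d)` iff `a < d` and `c < b`.
#' Backed by a sorted interval index (IRanges); an exhaustive all-pairs
#' comparison serves as the independent oracle in the test suite.
#'
#' @param query,subject interval tables (chrom/start/end)
#' @return `data.table` with columns `query`, `subject` (row indices)
#' @export
interval_overlap <- function(query, subject) {
  q <- as.data.table(query); s <- as.data.table(subject)
  if (nrow(q) == 0L || nrow(s) == 0L)
    return(data.table(query = integer(), subject = integer()))
  res <- vector("list", 0L)
  for (ch in intersect(unique(q$chrom), unique(s$chrom))) {
    qi <- which(q$chrom == ch); si <- which(s$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(q$start[qi] + 1L, q$end[qi]),
      IRanges::IRanges(s$start[si] + 1L, s$end[si]))
    res[[length(res) + 1L]] <- data.table(
      query = qi[S4Vectors::queryHits(hits)],
      subject = si[S4Vectors::subjectHits(hits)])
  }
  out <- rbindlist(res)
  if (nrow(out)) setorder(out, query, subject)
  out
}

#' Does each query interval overlap any subject interval?
#'
#' @inheritParams interval_overlap
#' @return logical vector along `query` rows
#' @export
overlaps_any <- function(query, subject) {
  hits <- interval_overlap(query, subject)
  out <- rep(FALSE, nrow(as.data.table(query)))
  out[unique(hits$query)] <- TRUE
  out
}
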