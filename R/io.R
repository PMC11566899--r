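#' Read a per-sample CpG methylation count table
#'
#' The on-disk dialect is a 5-column TSV: `chrom`, `pos` (1-based position
#' of the cytosine), `strand`, `meth` (methylated read count), `total`
#' (total read count) -- the least common denominator of allc / CX-report
#' style outputs. Positions are shifted to the internal 0-based convention
#' on read. The `collapsed` dialect expects one row per CpG site at the
#' forward-strand C; the `stranded` dialect returns per-strand records
#' untouched (collapse them with [collapse_strands()]).
#'
#' @param path TSV file (optionally with a header line)
#' @param dialect `"collapsed"` or `"stranded"`
#' @return `data.table` with columns chrom, pos (0-based), strand, meth,
#'   total, sorted by (chrom, pos)
#' @export
read_methylation_table <- function(path, dialect = c("collapsed", "stranded")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) config_error(sprintf("missing input: %s", path))
  empty <- data.table(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      total = integer())
  if (file.size(path) == 0L) return(empty)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty)
  has_header <- grepl("^chrom\t", lines[1])
  body <- if (has_header) lines[-1] else lines
  if (!length(body)) return(empty)
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5L)) {
    ln <- which(nf != 5L)[1] + has_header
    data_error(sprintf("malformed methylation table row at line %d of %s",
                       ln, path))
  }
  m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  pos1 <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.integer(m[, 4]))
  total <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(pos1) | is.na(meth) | is.na(total) |
                 !m[, 3] %in% c("+", "-", "."))
  if (length(bad))
    data_error(sprintf("malformed methylation table row at line %d of %s",
                       bad[1] + has_header, path))
  over <- which(meth > total)
  if (length(over))
    data_error(sprintf("meth > total at line %d of %s (%d > %d)",
                       over[1] + has_header, path, meth[over[1]],
                       total[over[1]]))
  if (any(meth < 0L) || any(pos1 < 1L))
    data_error(sprintf("negative count or position in %s", path))
  x <- data.table(chrom = m[, 1], pos = pos1 - 1L, strand = m[, 3],
                  meth = meth, total = total)
  if (dialect == "collapsed" && anyDuplicated(x, by = c("chrom", "pos")))
    data_error(sprintf("duplicate collapsed CpG position in %s", path))
  setorder(x, chrom, pos)
  x[]
}

#' Write a methylation count table (inverse of [read_methylation_table()])
#' @param records table with chrom, pos (0-based), strand, meth, total
#' @param path output TSV
#' @export
write_methylation_table <- function(records, path) {
  x <- as.data.table(records)
  out <- data.table(x$chrom, x$pos + 1L, x$strand %||% "+", x$meth, x$total)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and restricted to the alphabet {A,C,G,T,N}.
#'
#' @param path FASTA file
#' @return named character vector, one element per record
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) config_error(sprintf("missing input: %s", path))
  ss <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      # the parser silently drops invalid letters; surface them instead
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        data_error(sprintf("non-IUPAC character in FASTA file %s", path))
      invokeRestart("muffleWarning")
    })
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    data_error(sprintf("non-ACGTN character in FASTA record %s",
                       names(seqs)[bad][1]))
  seqs
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 70L)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with header: sample_id, breed, sex (M/F), neutered (TRUE/FALSE),
#' age_years, condition.
#'
#' @param path TSV file
#' @return `data.table`, one row per sample
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) config_error(sprintf("missing input: %s", path))
  x <- fread(path, sep = "\t", header = TRUE,
             colClasses = list(character = "sample_id"))
  need <- c("sample_id", "breed", "sex", "neutered", "age_years", "condition")
  miss <- setdiff(need, names(x))
  if (length(miss))
    data_error(sprintf("metadata missing columns: %s",
                       paste(miss, collapse = ", ")))
  if (!all(x$sex %in% c("M", "F"))) data_error("sex must be M or F")
  if (any(!is.finite(x$age_years)) || any(x$age_years <= 0))
    data_error("age_years must be positive")
  if (anyDuplicated(x$sample_id)) data_error("duplicate sample_id")
  x
}

#' Read SNP positions from a BED or 2-column TSV (chrom, 0-based pos)
#' @param path file
#' @return `data.table` with chrom, pos
#' @export
read_snp_positions <- function(path) {
  if (!file.exists(path)) config_error(sprintf("missing input: %s", path))
  if (file.size(path) == 0L)
    return(data.table(chrom = character(), pos = integer()))
  x <- fread(path, sep = "\t", header = FALSE,
             colClasses = list(character = 1))
  if (ncol(x) >= 3L && all(!is.na(suppressWarnings(as.integer(x[[3]]))))) {
    out <- data.table(chrom = x[[1]], pos = as.integer(x[[2]]))   # BED
  } else {
    out <- data.table(chrom = x[[1]], pos = as.integer(x[[2]]))
  }
  if (any(is.na(out$pos)) || any(out$pos < 0L))
    data_error(sprintf("bad SNP position in %s", path))
  unique(setorder(out, chrom, pos))[]
}
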