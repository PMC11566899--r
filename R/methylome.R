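#' CpG site-by-sample count matrix
#'
#' The central container: strand-collapsed CpG sites in rows, samples in
#' columns, with congruent integer matrices of methylated and total read
#' counts. A missing (site, sample) cell -- no data in that sample's file
#' -- is `NA` in both matrices, never encoded as zero counts.
#'
#' @param sites `data.table` with chrom, pos (0-based forward-strand C)
#' @param meth,total integer matrices, sites x samples
#' @param samples character vector of sample ids (column order)
#' @return object of class `cpg_matrix`
#' @export
cpg_matrix <- function(sites, meth, total, samples) {
  if (nrow(meth) != nrow(sites) || !identical(dim(meth), dim(total)))
    data_error("meth/total/sites shapes are not congruent")
  if (ncol(meth) != length(samples)) data_error("sample count mismatch")
  if (anyDuplicated(samples)) data_error("duplicate sample_id")
  na_ok <- is.na(meth) == is.na(total)
  if (!all(na_ok)) data_error("meth/total missingness differs")
  if (any(meth > total, na.rm = TRUE)) data_error("meth > total")
  colnames(meth) <- colnames(total) <- samples
  structure(list(sites = as.data.table(sites)[, .(chrom, pos)],
                 meth = meth, total = total, samples = samples),
            class = "cpg_matrix")
}

#' @export
print.cpg_matrix <- function(x, ...) {
  cat(sprintf("cpg_matrix: %d sites x %d samples (%d missing cells)\n",
              nrow(x$meth), length(x$samples), sum(is.na(x$meth))))
  invisible(x)
}

#' @export
dim.cpg_matrix <- function(x) dim(x$meth)

#' Collapse per-strand CpG records to forward-strand sites
#'
#' A CpG site is the pair (forward C at pos p, reverse C at pos p+1); the
#' collapsed record sits at p with counts summed over the pair. A site
#' covered on only one strand keeps that strand's counts.
#'
#' @param records per-strand table for one sample: chrom, pos (0-based),
#'   strand in {+,-}, meth, total
#' @return collapsed table: chrom, pos, strand "+", meth, total
#' @export
collapse_strands <- function(records) {
  x <- as.data.table(records)
  if (nrow(x) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      total = integer()))
  if (!all(x$strand %in% c("+", "-")))
    data_error("stranded records must have strand + or -")
  if (anyDuplicated(x, by = c("chrom", "pos", "strand"))) {
    d <- x[duplicated(x, by = c("chrom", "pos", "strand"))][1]
    data_error(sprintf("duplicate %s-strand record at %s:%d",
                       d$strand, d$chrom, d$pos))
  }
  x[, site := ifelse(strand == "+", pos, pos - 1L)]
  if (any(x$site < 0L)) data_error("reverse-strand record at position 0")
  out <- x[, .(strand = "+", meth = sum(meth), total = sum(total)),
           by = .(chrom, pos = site)]
  setorder(out, chrom, pos)
  setnames(out, c("chrom", "pos", "strand", "meth", "total"))
  out[]
}

#' Assemble per-sample collapsed tables into a [cpg_matrix]
#'
#' Sites are the union over samples, sorted by (chrom, pos); cells absent
#' from a sample's table are missing (`NA`).
#'
#' @param tables named list of collapsed tables (names = sample ids), or
#'   an unnamed list plus `sample_ids`
#' @param sample_ids sample identifiers (default `names(tables)`)
#' @return a [cpg_matrix]
#' @export
build_matrix <- function(tables, sample_ids = names(tables)) {
  if (length(tables) < 1L) config_error("need at least one sample")
  if (is.null(sample_ids) || anyDuplicated(sample_ids))
    data_error("sample ids must be present and unique")
  all_sites <- unique(rbindlist(
    lapply(tables, function(t) as.data.table(t)[, .(chrom, pos)])))
  setorder(all_sites, chrom, pos)
  n <- nrow(all_sites); m <- length(tables)
  meth <- matrix(NA_integer_, n, m)
  total <- matrix(NA_integer_, n, m)
  key <- paste(all_sites$chrom, all_sites$pos)
  for (j in seq_len(m)) {
    t <- as.data.table(tables[[j]])
    i <- match(paste(t$chrom, t$pos), key)
    meth[i, j] <- as.integer(t$meth)
    total[i, j] <- as.integer(t$total)
  }
  cpg_matrix(all_sites, meth, total, sample_ids)
}

#' Depth and presence quality filters
#'
#' A site is retained iff every sample has data and the total read count
#' lies in the closed interval `[min_depth, max_depth]` in every sample
#' (the printed rules "< 10 reads" and "more than 500 reads" are strict
#' removals outside that interval).
#'
#' @param matrix a [cpg_matrix]
#' @param min_depth,max_depth closed depth bounds (defaults 10, 500)
#' @param require_all require data in every sample (default TRUE)
#' @return filtered [cpg_matrix]; attribute `filter_stats` reports sites
#'   removed by missingness, low depth and high depth
#' @export
apply_quality_filters <- function(matrix, min_depth = 10L, max_depth = 500L,
                                  require_all = TRUE) {
  if (min_depth > max_depth) config_error("min_depth > max_depth")
  tot <- matrix$total
  miss <- rowSums(is.na(tot)) > 0L
  low <- rowSums(tot < min_depth, na.rm = TRUE) > 0L
  high <- rowSums(tot > max_depth, na.rm = TRUE) > 0L
  drop <- low | high
  if (require_all) drop <- drop | miss
  keep <- which(!drop)
  out <- cpg_matrix(matrix$sites[keep], matrix$meth[keep, , drop = FALSE],
                    tot[keep, , drop = FALSE], matrix$samples)
  attr(out, "filter_stats") <- c(n_input = nrow(tot),
                                 n_missing = sum(miss),
                                 n_low_depth = sum(low),
                                 n_high_depth = sum(high),
                                 n_retained = length(keep))
  out
}

#' Remove SNP-overlapping CpGs and whole chromosomes
#'
#' A CpG site at position p is removed if a variant lies at p or p + 1 --
#' either base of the dinucleotide corrupts the bisulfite call. All sites
#' on `drop_chroms` (e.g. the X chromosome) are removed.
#'
#' @param matrix a [cpg_matrix]
#' @param snp_positions table with chrom, pos (0-based), or NULL
#' @param drop_chroms chromosomes to drop entirely (default `"chrX"`)
#' @return filtered [cpg_matrix]
#' @export
mask_snps_and_chroms <- function(matrix, snp_positions = NULL,
                                 drop_chroms = "chrX") {
  keep <- !(matrix$sites$chrom %in% drop_chroms)
  if (!is.null(snp_positions) && nrow(as.data.table(snp_positions)) > 0L) {
    snp <- as.data.table(snp_positions)
    key <- paste(snp$chrom, snp$pos)
    hit <- paste(matrix$sites$chrom, matrix$sites$pos) %in% key |
      paste(matrix$sites$chrom, matrix$sites$pos + 1L) %in% key
    keep <- keep & !hit
  }
  keep <- which(keep)
  cpg_matrix(matrix$sites[keep], matrix$meth[keep, , drop = FALSE],
             matrix$total[keep, , drop = FALSE], matrix$samples)
}

#' Beta values: methylated fraction per cell
#'
#' beta = meth / (meth + unmeth) = meth / total; missing cells stay `NA`.
#'
#' @param matrix a [cpg_matrix]
#' @return numeric matrix, sites x samples
#' @export
beta_values <- function(matrix) {
  zero <- which(!is.na(matrix$total) & matrix$total == 0L)
  if (length(zero))
    data_error("total = 0 at a non-missing cell; encode absent data as NA")
  matrix$meth / matrix$total
}

#' Pairwise Spearman correlation of sample methylomes
#'
#' Average ranks for ties. A sample with zero variance yields `NA`
#' correlations with a warning.
#'
#' @param beta complete numeric matrix, sites x samples
#' @return samples x samples symmetric correlation matrix, unit diagonal
#' @export
pairwise_spearman <- function(beta) {
  if (ncol(beta) < 2L) config_error("need >= 2 samples")
  if (anyNA(beta)) data_error("beta matrix must be complete (filter first)")
  const <- apply(beta, 2L, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(cor(beta, method = "spearman"))
  if (any(const)) {
    warning("sample(s) with zero variance: correlation undefined")
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  diag(rho) <- 1
  rho
}

#' Bisulfite conversion rate from non-CpG-context cytosines
#'
#' @param non_cg_converted converted (read-as-T) non-CG cytosine count
#' @param non_cg_total total non-CG cytosine count
#' @return conversion rate in [0, 1]
#' @export
conversion_rate <- function(non_cg_converted, non_cg_total) {
  if (non_cg_total <= 0) config_error("non_cg_total must be positive")
  if (non_cg_converted > non_cg_total || non_cg_converted < 0)
    data_error("converted count outside [0, total]")
  non_cg_converted / non_cg_total
}

#' Scaled meta-profile of methylation across gene bodies
#'
#' Each gene body is linearly rescaled to `body_bins` bins; `flank_bp` of
#' upstream and downstream sequence are split into `flank_bins` bins each.
#' Minus-strand genes are reversed so bin 0 is always the 5' flank edge.
#' Bin value = mean of per-site mean beta over all CpGs falling in the
#' bin, pooled across genes; empty bins are `NA`.
#'
#' @param site_beta per-site mean beta (mean across samples), aligned with
#'   `sites`
#' @param sites `data.table` with chrom, pos for `site_beta`
#' @param genes strand-aware gene intervals
#' @param body_bins bins across the gene body (default 100)
#' @param flank_bp flank width in bp (default 2000)
#' @param flank_bins bins per flank (default 40)
#' @return `data.table` with bin, zone (upstream/body/downstream),
#'   mean_beta, n_sites
#' @export
gene_metaprofile <- function(site_beta, sites, genes, body_bins = 100L,
                             flank_bp = 2000L, flank_bins = 40L) {
  g <- as.data.table(genes)
  if (!all(g$strand %in% c("+", "-"))) data_error("genes must be stranded")
  short <- g$end - g$start < body_bins
  if (any(short)) {
    warning(sprintf("%d gene(s) shorter than body_bins skipped", sum(short)))
    g <- g[!short]
  }
  n_bins <- 2L * flank_bins + body_bins
  acc_sum <- numeric(n_bins); acc_n <- integer(n_bins)
  st <- as.data.table(sites)
  for (i in seq_len(nrow(g))) {
    on_chrom <- which(st$chrom == g$chrom[i])
    pos <- st$pos[on_chrom]
    b <- site_beta[on_chrom]
    s <- g$start[i]; e <- g$end[i]; len <- e - s
    in_up <- pos >= s - flank_bp & pos < s
    in_body <- pos >= s & pos < e
    in_dn <- pos >= e & pos < e + flank_bp
    bin <- rep(NA_integer_, length(pos))
    bin[in_up] <- as.integer((pos[in_up] - (s - flank_bp)) /
                               flank_bp * flank_bins)
    bin[in_body] <- flank_bins +
      as.integer((pos[in_body] - s) / len * body_bins)
    bin[in_dn] <- flank_bins + body_bins +
      as.integer((pos[in_dn] - e) / flank_bp * flank_bins)
    ok <- which(!is.na(bin))
    if (!length(ok)) next
    bn <- bin[ok]
    if (g$strand[i] == "-") bn <- n_bins - 1L - bn  # mirror so bin 0 is 5'
    tb <- tapply(b[ok], bn, sum)
    idx <- as.integer(names(tb)) + 1L
    acc_sum[idx] <- acc_sum[idx] + as.numeric(tb)
    cnt <- tapply(rep(1L, length(ok)), bn, sum)
    acc_n[idx] <- acc_n[idx] + as.integer(cnt)
  }
  zone <- rep(c("upstream", "body", "downstream"),
              c(flank_bins, body_bins, flank_bins))
  data.table(bin = seq_len(n_bins) - 1L, zone = zone,
             mean_beta = ifelse(acc_n > 0L, acc_sum / pmax(acc_n, 1L),
                                NA_real_),
             n_sites = acc_n)
}
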