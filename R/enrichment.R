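#' Over/under-representation of high-SD CpGs across genomic features
#'
#' For each feature the background proportion p0 is the fraction of all
#' eligible CpGs falling in the feature; observed is the number of
#' high-SD CpGs in the feature; expected = p0 x #high-SD. The p-value is
#' the exact binomial test, two-sided via the doubled smaller tail
#' (capped at 1) -- the analytic limit of comparing against random CpG
#' sets. A seeded resampling mode is available for fidelity to the
#' random-set procedure.
#'
#' @param high_sd_sites table (chrom, pos) of high-SD CpGs, a subset of
#'   `all_sites`
#' @param all_sites table (chrom, pos) of all eligible CpGs
#' @param catalog a [build_feature_catalog()] result (or any named list
#'   of interval tables)
#' @param resample number of random draws for the Monte-Carlo mode
#'   (0 = analytic binomial, the default)
#' @param seed seed for the resampling mode
#' @return `data.table`: feature, n_feature_sites, observed, expected,
#'   obs_exp_ratio, direction, p_value, q_value
#' @export
feature_enrichment <- function(high_sd_sites, all_sites, catalog,
                               resample = 0L, seed = 1L) {
  hs <- as.data.table(high_sd_sites); al <- as.data.table(all_sites)
  if (!all(paste(hs$chrom, hs$pos) %in% paste(al$chrom, al$pos)))
    data_error("high_sd_sites must be a subset of all_sites")
  n_all <- nrow(al); n_high <- nrow(hs)
  pts <- function(x) data.table(chrom = x$chrom, start = x$pos,
                                end = x$pos + 1L)
  feats <- catalog[!vapply(catalog, is.null, TRUE)]
  rows <- vector("list", 0L)
  in_feature_all <- lapply(feats, function(f) overlaps_any(pts(al), f))
  key_high <- paste(hs$chrom, hs$pos)
  idx_high <- match(key_high, paste(al$chrom, al$pos))
  for (nm in names(feats)) {
    inf <- in_feature_all[[nm]]
    n_f <- sum(inf)
    if (n_f == 0L) {
      warning(sprintf("feature %s has no eligible sites; skipped", nm))
      next
    }
    p0 <- n_f / n_all
    obs <- sum(inf[idx_high])
    expd <- p0 * n_high
    if (resample > 0L) {
      draws <- with_seed(seed, vapply(seq_len(resample), function(i)
        sum(inf[sample.int(n_all, n_high)]), numeric(1)))
      lower <- (sum(draws <= obs) + 1) / (resample + 1)
      upper <- (sum(draws >= obs) + 1) / (resample + 1)
    } else {
      lower <- pbinom(obs, n_high, p0)
      upper <- pbinom(obs - 1L, n_high, p0, lower.tail = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.table(
      feature = nm, n_feature_sites = n_f, observed = obs, expected = expd,
      obs_exp_ratio = if (expd > 0) obs / expd else NA_real_,
      direction = if (obs >= expd) "over" else "under",
      p_value = min(1, 2 * min(lower, upper)))
  }
  out <- rbindlist(rows)
  out[, q_value := bh_fdr(p_value)]
  out[]
}

#' Repeat-subfamily enrichment within CGI methylation classes
#'
#' Per subfamily the background p0 is the fraction of all classified CGIs
#' overlapping the subfamily (>= 1 bp); per methylation class, observed
#' is the count of that class's CGIs overlapping, tested one-tailed
#' (upper) binomial with n = class size. Subfamilies overlapping fewer
#' than `min_regions` CGIs are omitted before testing; BH adjustment runs
#' across all retained (subfamily, class) pairs.
#'
#' @param cgis classified CGI table with a `meth_class` column
#' @param repeats repeat intervals with a `subfamily` column
#' @param min_regions minimum CGI overlap count per subfamily (default 100)
#' @return `data.table`: subfamily, meth_class, n_class, observed,
#'   expected, obs_exp_ratio, p_value, q_value
#' @export
repeat_class_enrichment <- function(cgis, repeats, min_regions = 100L) {
  ci <- as.data.table(cgis)
  if (!"meth_class" %in% names(ci) || anyNA(ci$meth_class))
    data_error("every CGI must carry a meth_class (score them first)")
  rp <- as.data.table(repeats)
  if (!"subfamily" %in% names(rp) || any(!nzchar(rp$subfamily)))
    data_error("repeats must carry a non-empty subfamily")
  n_cgi <- nrow(ci)
  classes <- unique(ci$meth_class)
  rows <- vector("list", 0L)
  for (sf in unique(rp$subfamily)) {
    ov <- overlaps_any(ci, rp[subfamily == sf])
    n_ov <- sum(ov)
    if (n_ov < min_regions) next
    p0 <- n_ov / n_cgi
    for (cl in classes) {
      is_cl <- ci$meth_class == cl
      n_cl <- sum(is_cl)
      obs <- sum(ov & is_cl)
      expd <- p0 * n_cl
      rows[[length(rows) + 1L]] <- data.table(
        subfamily = sf, meth_class = cl, n_class = n_cl, observed = obs,
        expected = expd,
        obs_exp_ratio = if (expd > 0) obs / expd else NA_real_,
        p_value = pbinom(obs - 1L, n_cl, p0, lower.tail = FALSE))
    }
  }
  out <- rbindlist(rows)
  if (nrow(out) == 0L)
    return(data.table(subfamily = character(), meth_class = character(),
                      n_class = integer(), observed = integer(),
                      expected = numeric(), obs_exp_ratio = numeric(),
                      p_value = numeric(), q_value = numeric()))
  out[, q_value := bh_fdr(p_value)]
  out[]
}

#' Hypergeometric gene-set over-representation test
#'
#' Per set: p = P(X >= observed) with X ~ Hypergeometric(N = #background,
#' K = #(set intersect background), n = #hits); BH adjustment across sets.
#' Annotation is user-supplied (e.g. GO/KEGG as a two-column set_id ->
#' gene_id table); no databases are downloaded.
#'
#' @param hit_genes character vector of hit gene ids (subset of background)
#' @param background_genes character vector of background gene ids
#' @param sets named list mapping set_id to character vectors of gene ids
#' @return `data.table`: set_id, set_size, observed, expected, p_value,
#'   q_value
#' @export
gene_set_enrichment <- function(hit_genes, background_genes, sets) {
  bg <- unique(background_genes)
  if (length(bg) == 0L) config_error("empty background")
  hits <- unique(hit_genes)
  if (!all(hits %in% bg)) data_error("hit_genes must be within background")
  N <- length(bg); n <- length(hits)
  rows <- lapply(names(sets), function(id) {
    K <- length(intersect(sets[[id]], bg))
    obs <- length(intersect(sets[[id]], hits))
    data.table(set_id = id, set_size = K, observed = obs,
               expected = n * K / N,
               p_value = if (obs == 0L) 1 else
                 phyper(obs - 1L, K, N - K, n, lower.tail = FALSE))
  })
  out <- rbindlist(rows)
  if (nrow(out)) out[, q_value := bh_fdr(p_value)]
  out[]
}

#' Read a two-column gene-set TSV (set_id, gene_id) into a named list
#' @param path TSV file
#' @return named list of gene id vectors
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) config_error(sprintf("missing input: %s", path))
  x <- fread(path, sep = "\t", header = FALSE,
             col.names = c("set_id", "gene_id"),
             colClasses = "character")
  split(x$gene_id, x$set_id)
}
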