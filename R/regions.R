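#' One-way fixed-effects ANOVA per CpG site
#'
#' F = (SSB/(k-1)) / (SSW/(n-k)) comparing inter-group to intra-group
#' variance of beta values. Degenerate sites: SSW = 0 with SSB > 0 get
#' p = 0 and `degenerate = TRUE`; SSB = SSW = 0 gets F = 0, p = 1.
#'
#' @param beta complete numeric matrix, sites x samples
#' @param groups factor/character of group labels, one per sample;
#'   every group needs >= 2 samples
#' @param sites optional site table (chrom, pos) carried into the result
#' @return `data.table` with statistic (F), p_value, q_value (BH),
#'   degenerate flag
#' @export
anova_per_cpg <- function(beta, groups, sites = NULL) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(beta)) config_error("one group label per sample")
  if (nlevels(groups) < 2L) config_error("need >= 2 groups")
  if (any(table(groups) < 2L)) config_error("every group needs >= 2 samples")
  if (anyNA(beta)) data_error("beta matrix must be complete")
  n <- ncol(beta); k <- nlevels(groups)
  ind <- stats::model.matrix(~ groups - 1L)
  ng <- colSums(ind)
  gm <- beta %*% ind %*% diag(1 / ng)          # per-site group means
  tm <- rowMeans(beta)
  ssb <- rowSums(sweep(gm, 1L, tm)^2 %*% diag(ng))
  sst <- rowSums(sweep(beta, 1L, tm)^2)
  ssw <- pmax(sst - ssb, 0)
  eps <- 1e-12 * pmax(sst, 1e-300)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(f, k - 1, n - k, lower.tail = FALSE)
  degenerate <- ssw <= eps & ssb > eps
  p[degenerate] <- 0
  f[degenerate] <- Inf
  null_site <- ssb <= eps & ssw <= eps
  f[null_site] <- 0; p[null_site] <- 1
  out <- data.table(statistic = f, p_value = p,
                    q_value = bh_fdr(p), degenerate = degenerate)
  if (!is.null(sites)) out <- cbind(as.data.table(sites)[, .(chrom, pos)], out)
  out[]
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' q_i = min over j with p_(j) >= p_(i) of p_(j) * n / j, capped at 1;
#' monotone non-decreasing in p.
#'
#' @param p_values numeric vector in [0, 1]
#' @return q-values in input order
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    data_error("p-values must lie in [0, 1]")
  n <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p_values[o]))[ro]
  q
}

#' Call differentially methylated cytosines at an FDR threshold
#'
#' @param site_stats table from [anova_per_cpg()] or [logistic_dmc()]
#'   carrying chrom, pos, q_value
#' @param fdr_threshold strict cutoff: DMC iff q < threshold (default 0.05)
#' @return `data.table` of DMC sites (chrom, pos) in genomic order
#' @export
call_dmcs <- function(site_stats, fdr_threshold = 0.05) {
  x <- as.data.table(site_stats)
  out <- x[!is.na(q_value) & q_value < fdr_threshold, .(chrom, pos)]
  setorder(out, chrom, pos)
  out[]
}

#' Merge significant positions into regions by gap chaining
#'
#' Greedy left-to-right chaining per chromosome: consecutive positions at
#' most `gap_bp` apart (inclusive) belong to one run; runs with at least
#' `min_count` members are returned as intervals `[first, last + 1)`.
#' Unsorted input is sorted internally. Used both for DMRs (runs of DMCs)
#' and highly variable regions (runs of top-SD CpGs).
#'
#' @param positions table with chrom, pos
#' @param gap_bp maximum distance between consecutive members (default 100)
#' @param min_count minimum member count (default 5)
#' @return `gintervals` with extra column `n_sites`
#' @export
merge_runs <- function(positions, gap_bp = 100L, min_count = 5L) {
  x <- unique(as.data.table(positions)[, .(chrom, pos)])
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_sites = integer())
  if (nrow(x) == 0L) {
    class(empty) <- c("gintervals", class(empty))
    return(empty)
  }
  setorder(x, chrom, pos)
  x[, run := cumsum(c(1L, as.integer(diff(pos) > gap_bp |
                                       chrom[-1] != chrom[-.N])))]
  out <- x[, .(chrom = chrom[1], start = pos[1], end = pos[.N] + 1L,
               strand = ".", n_sites = .N), by = run][, run := NULL]
  out <- out[n_sites >= min_count]
  if (nrow(out) == 0L) out <- empty
  class(out) <- c("gintervals", class(out))
  out[]
}

#' Across-sample standard deviation of beta per CpG site
#'
#' Sample SD (n - 1 denominator) per row.
#'
#' @param beta complete numeric matrix, sites x samples (>= 2 samples)
#' @return numeric vector of SDs
#' @export
sd_per_cpg <- function(beta) {
  if (ncol(beta) < 2L) config_error("need >= 2 samples")
  if (anyNA(beta)) data_error("beta matrix must be complete")
  n <- ncol(beta)
  m <- rowMeans(beta)
  sqrt(pmax(rowSums((beta - m)^2), 0) / (n - 1))
}

#' Top-fraction SD threshold (order statistic, no interpolation)
#'
#' The threshold is the k-th largest SD with k = ceiling(fraction * n); a
#' site is "high-SD" iff SD >= threshold, so exactly k sites qualify in
#' the absence of ties.
#'
#' @param sds numeric vector of per-site SDs
#' @param fraction top fraction in (0, 1] (default 0.01)
#' @return the threshold value
#' @export
top_fraction_threshold <- function(sds, fraction = 0.01) {
  if (!(fraction > 0 && fraction <= 1))
    config_error("fraction must be in (0, 1]")
  k <- ceiling(fraction * length(sds))
  sort(sds, decreasing = TRUE)[k]
}

#' Associate regions with sex, breed and age
#'
#' Per region the across-member mean beta per sample is tested: sex
#' (two-group ANOVA), breed (k-group ANOVA) and age (Spearman rank
#' correlation). Each family of p-values is BH-adjusted across regions
#' separately; a region is flagged associated when the adjusted p-value
#' is below `alpha` (default 0.01). A covariate constant across samples
#' is skipped with a warning.
#'
#' @param regions interval table from [merge_runs()]
#' @param beta complete numeric beta matrix, sites x samples (columns
#'   named by sample id)
#' @param sites site table (chrom, pos) aligned with `beta` rows
#' @param metadata sample metadata (sample_id, breed, sex, age_years)
#' @param alpha adjusted-p threshold (default 0.01)
#' @return `data.table`: one row per region with p/adjusted p per test,
#'   Spearman rho, and logical assoc_* flags
#' @export
associate_regions <- function(regions, beta, sites, metadata, alpha = 0.01) {
  reg <- as.data.table(regions)
  md <- as.data.table(metadata)
  md <- md[match(colnames(beta), sample_id)]
  if (anyNA(md$sample_id)) data_error("metadata missing some samples")
  st <- as.data.table(sites)
  pts <- data.table(chrom = st$chrom, start = st$pos, end = st$pos + 1L)
  hits <- interval_overlap(pts, reg)
  n_reg <- nrow(reg)
  rb <- matrix(NA_real_, n_reg, ncol(beta))  # region x sample mean beta
  for (r in seq_len(n_reg)) {
    i <- hits$query[hits$subject == r]
    if (length(i)) rb[r, ] <- colMeans(beta[i, , drop = FALSE])
  }
  test_anova <- function(labels) {
    labels <- as.factor(labels)
    if (nlevels(labels) < 2L || any(table(labels) < 2L)) {
      warning("covariate constant or group too small; test skipped")
      return(rep(NA_real_, n_reg))
    }
    anova_per_cpg(rb, labels)$p_value
  }
  p_sex <- test_anova(md$sex)
  p_breed <- test_anova(md$breed)
  if (length(unique(md$age_years)) < 2L) {
    warning("age constant across samples; test skipped")
    p_age <- rep(NA_real_, n_reg); rho_age <- rep(NA_real_, n_reg)
  } else {
    age_test <- apply(rb, 1L, function(v) {
      if (all(is.na(v)) || length(unique(v)) == 1L) return(c(NA, 1))
      ct <- suppressWarnings(stats::cor.test(v, md$age_years,
                                             method = "spearman",
                                             exact = FALSE))
      c(unname(ct$estimate), ct$p.value)
    })
    rho_age <- age_test[1, ]; p_age <- age_test[2, ]
  }
  adj <- function(p) {
    q <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(ok)) q[ok] <- bh_fdr(p[ok])
    q
  }
  out <- cbind(reg, data.table(
    p_sex = p_sex, q_sex = adj(p_sex),
    p_breed = p_breed, q_breed = adj(p_breed),
    rho_age = rho_age, p_age = p_age, q_age = adj(p_age)))
  out[, `:=`(assoc_sex = !is.na(q_sex) & q_sex < alpha,
             assoc_breed = !is.na(q_breed) & q_breed < alpha,
             assoc_age = !is.na(q_age) & q_age < alpha)]
  out[]
}

#' Per-CpG logistic regression against a binary outcome
#'
#' Per site: outcome ~ intercept + beta (+ covariates), fit by maximum
#' likelihood; p is the Wald test on the beta coefficient. Sites with no
#' beta variance are skipped (`NA`); non-converged or separated fits are
#' flagged and get `NA` p-values.
#'
#' @param beta complete numeric matrix, sites x samples
#' @param outcome logical/0-1 vector with both classes present
#' @param covariates optional numeric matrix/data.frame of per-sample
#'   covariates (e.g. age)
#' @param sites optional site table carried into the result
#' @return `data.table` with statistic (Wald z), p_value, q_value,
#'   separated flag
#' @export
logistic_dmc <- function(beta, outcome, covariates = NULL, sites = NULL) {
  y <- as.integer(outcome)
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L)
    config_error("outcome must be binary with both classes present")
  if (length(y) != ncol(beta)) config_error("one outcome per sample")
  if (anyNA(beta)) data_error("beta matrix must be complete")
  covm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  n_sites <- nrow(beta)
  z <- p <- rep(NA_real_, n_sites)
  sep <- rep(FALSE, n_sites)
  for (i in seq_len(n_sites)) {
    x <- beta[i, ]
    if (length(unique(x)) == 1L) next
    X <- cbind(`(Intercept)` = 1, beta = x, covm)
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { sep[i] <- TRUE; next }
    mu <- fit$fitted.values
    if (any(mu < 1e-8) || any(mu > 1 - 1e-8) || abs(fit$coef[2]) > 1e3) {
      sep[i] <- TRUE; next   # (quasi-)separation: Wald statistic diverges
    }
    W <- mu * (1 - mu)
    XtWX <- crossprod(X * W, X)
    vc <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(vc) || vc[2, 2] <= 0) { sep[i] <- TRUE; next }
    z[i] <- fit$coefficients[2] / sqrt(vc[2, 2])
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  q <- rep(NA_real_, n_sites)
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- bh_fdr(p[ok])
  out <- data.table(statistic = z, p_value = p, q_value = q, separated = sep)
  if (!is.null(sites)) out <- cbind(as.data.table(sites)[, .(chrom, pos)], out)
  out[]
}
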