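mk_tbl <- function(pos, meth, total, chrom = "chr1", strand = "+") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, meth = as.integer(meth),
                         total = as.integer(total))
}

test_that("collapse_strands sums the dinucleotide pair", {
  x <- rbind(mk_tbl(100, 5, 10, strand = "+"),
             mk_tbl(101, 3, 10, strand = "-"))
  out <- collapse_strands(x)
  expect_equal(out$pos, 100L)
  expect_equal(out$meth, 8L)
  expect_equal(out$total, 20L)

  # one-strand-only sites keep their counts, at the forward-C coordinate
  out <- collapse_strands(mk_tbl(100, 5, 10, strand = "+"))
  expect_equal(out[, c("pos", "meth", "total")],
               mk_tbl(100, 5, 10)[, c("pos", "meth", "total")])
  out <- collapse_strands(mk_tbl(101, 3, 10, strand = "-"))
  expect_equal(out$pos, 100L)

  expect_error(collapse_strands(rbind(mk_tbl(100, 5, 10),
                                      mk_tbl(100, 5, 10))),
               "duplicate", class = "islandmeth_data_error")
})

test_that("build_matrix unions sites and marks absences missing", {
  t1 <- mk_tbl(c(10, 20, 30, 40), 1, 10)
  t2 <- mk_tbl(c(10, 20, 30), 2, 12)
  m <- build_matrix(list(a = t1, b = t2))
  expect_equal(dim(m), c(4L, 2L))
  expect_equal(sum(is.na(m$meth)), 1L)
  expect_true(is.na(m$total[4, "b"]))

  # single sample: matrix equals its table
  m1 <- build_matrix(list(only = t1))
  expect_equal(m1$sites$pos, t1$pos)
  expect_equal(as.vector(m1$meth), t1$meth)

  # order-permuted input rows give the identical matrix
  m2 <- build_matrix(list(a = t1[c(3, 1, 4, 2)], b = t2[c(2, 3, 1)]))
  expect_identical(m2$meth, m$meth)
  expect_identical(m2$sites, m$sites)

  expect_error(build_matrix(list(a = t1, a = t2)),
               class = "islandmeth_data_error")
})

test_that("quality filters enforce the closed [10, 500] depth band", {
  depth_cases <- rbind(
    c(9, 50, FALSE),     # below floor in one sample
    c(10, 50, TRUE),     # exactly at floor
    c(500, 500, TRUE),   # exactly at ceiling in all
    c(501, 50, FALSE))   # above ceiling in one sample
  sites <- data.table::data.table(chrom = "chr1",
                                  pos = seq_len(nrow(depth_cases)) * 10L)
  tot <- cbind(as.integer(depth_cases[, 1]), as.integer(depth_cases[, 2]))
  m <- cpg_matrix(sites, meth = matrix(0L, 4, 2), total = tot,
                  samples = c("s1", "s2"))
  out <- apply_quality_filters(m)
  expect_equal(out$sites$pos, c(20L, 30L))

  # a site missing in any one sample is removed under require_all
  tot2 <- tot; tot2[2, 2] <- NA
  meth2 <- matrix(0L, 4, 2); meth2[2, 2] <- NA
  m2 <- cpg_matrix(sites, meth2, tot2, c("s1", "s2"))
  out2 <- apply_quality_filters(m2)
  expect_equal(out2$sites$pos, 30L)
  expect_equal(sum(is.na(out2$meth)), 0L)
  st <- attr(out2, "filter_stats")
  expect_equal(unname(st["n_missing"]), 1)

  expect_error(apply_quality_filters(m, min_depth = 100, max_depth = 10),
               class = "islandmeth_config_error")
})

test_that("SNP masking hits either base of the dinucleotide", {
  sites <- data.table::data.table(chrom = c("chr1", "chr1", "chrX"),
                                  pos = c(100L, 200L, 300L))
  m <- cpg_matrix(sites, matrix(1L, 3, 2), matrix(10L, 3, 2), c("a", "b"))
  # SNP at the G (pos + 1) removes the site
  snp <- data.table::data.table(chrom = "chr1", pos = 101L)
  out <- mask_snps_and_chroms(m, snp, drop_chroms = "chrX")
  expect_equal(out$sites$pos, 200L)
  # SNP at the C also removes it
  out <- mask_snps_and_chroms(m, data.table::data.table(chrom = "chr1",
                                                        pos = 200L),
                              drop_chroms = character())
  expect_equal(out$sites$pos, c(100L, 300L))
  # empty SNP list + empty drop set is the identity
  out <- mask_snps_and_chroms(m, NULL, drop_chroms = character())
  expect_equal(out$sites, m$sites)
  # dropping every chromosome empties the matrix
  out <- mask_snps_and_chroms(m, NULL, drop_chroms = c("chr1", "chrX"))
  expect_equal(nrow(out$meth), 0L)
})

test_that("filter composition is order-independent", {
  withr::local_seed(11)
  n <- 200
  sites <- data.table::data.table(chrom = "chr1", pos = sort(sample.int(1e5, n)))
  tot <- matrix(sample(c(5L, 50L, 600L), n * 3, TRUE,
                       prob = c(.2, .6, .2)), n, 3)
  m <- cpg_matrix(sites, matrix(0L, n, 3), tot, c("a", "b", "c"))
  snp <- data.table::data.table(chrom = "chr1",
                                pos = sample(sites$pos, 30) + sample(0:1, 30, TRUE))
  a <- mask_snps_and_chroms(apply_quality_filters(m), snp)
  b <- apply_quality_filters(mask_snps_and_chroms(m, snp))
  expect_identical(a$sites, b$sites)
  expect_identical(a$total, b$total)
})

test_that("beta values follow meth/total and flag impossible zeros", {
  m <- cpg_matrix(data.table::data.table(chrom = "chr1", pos = 1:3 * 10L),
                  meth = matrix(c(7L, 0L, 10L, NA, 5L, 2L), 3, 2),
                  total = matrix(c(10L, 8L, 10L, NA, 10L, 4L), 3, 2),
                  samples = c("a", "b"))
  b <- beta_values(m)
  expect_equal(unname(b[1, 1]), 0.7)
  expect_equal(unname(b[2, 1]), 0)
  expect_equal(unname(b[3, 1]), 1)
  expect_true(is.na(b[1, 2]))

  m$total[2, 1] <- 0L; m$meth[2, 1] <- 0L
  expect_error(beta_values(m), class = "islandmeth_data_error")
})

test_that("pairwise_spearman matches rank-correlation ground truth", {
  b <- cbind(s1 = c(0.1, 0.2, 0.3), s2 = c(0.3, 0.1, 0.2))
  rho <- pairwise_spearman(b)
  expect_equal(rho["s1", "s2"], -0.5)
  expect_equal(diag(rho), c(s1 = 1, s2 = 1))

  # rank invariance under a monotone transform
  b2 <- cbind(x = runif(20), y = 0)
  b2[, "y"] <- exp(3 * b2[, "x"])
  expect_equal(pairwise_spearman(b2)["x", "y"], 1)

  # reference-implementation agreement on random matrices
  withr::local_seed(5)
  for (i in 1:5) {
    bm <- matrix(runif(200), 50, 4)
    expect_equal(pairwise_spearman(bm),
                 {r <- cor(bm, method = "spearman"); diag(r) <- 1; r},
                 tolerance = 1e-12)
  }

  bz <- cbind(a = rep(0.5, 4), b = runif(4))
  expect_warning(rz <- pairwise_spearman(bz), "zero variance")
  expect_true(is.na(rz["a", "b"]))
})

test_that("conversion_rate is the converted fraction", {
  expect_equal(conversion_rate(990, 1000), 0.99)
  expect_equal(conversion_rate(1000, 1000), 1)
  expect_equal(conversion_rate(0, 1000), 0)
  expect_error(conversion_rate(1, 0), class = "islandmeth_config_error")
})

test_that("gene meta-profile bins, reverses strands and dips", {
  sites <- data.table::data.table(chrom = "chr1", pos = seq(0L, 9999L, 7L))
  genes <- gintervals("chr1", 4000L, 6000L, "+")
  flat <- rep(0.8, nrow(sites))
  pr <- gene_metaprofile(flat, sites, genes, body_bins = 20L,
                         flank_bp = 1000L, flank_bins = 10L)
  expect_equal(nrow(pr), 40L)
  expect_true(all(abs(pr$mean_beta - 0.8) < 1e-12, na.rm = TRUE))

  # reversal symmetry: a constant profile is identical on the - strand
  pr_m <- gene_metaprofile(flat, sites, gintervals("chr1", 4000L, 6000L, "-"),
                           body_bins = 20L, flank_bp = 1000L,
                           flank_bins = 10L)
  expect_equal(pr$mean_beta, pr_m$mean_beta)

  # dip: beta 0 inside the body, 0.8 in the flanks
  dip <- ifelse(sites$pos >= 4000 & sites$pos < 6000, 0, 0.8)
  pr_d <- gene_metaprofile(dip, sites, genes, body_bins = 20L,
                           flank_bp = 1000L, flank_bins = 10L)
  expect_true(all(pr_d$mean_beta[pr_d$zone == "body"] == 0))
  expect_true(all(pr_d$mean_beta[pr_d$zone != "body"] == 0.8, na.rm = TRUE))

  # directional check on the minus strand: signal upstream of the TSS
  # (right of the gene in genome coordinates) must appear in early bins
  asym <- ifelse(sites$pos >= 6000, 1, 0)
  pr_a <- gene_metaprofile(asym, sites,
                           gintervals("chr1", 4000L, 6000L, "-"),
                           body_bins = 20L, flank_bp = 1000L,
                           flank_bins = 10L)
  expect_true(all(pr_a$mean_beta[1:10] == 1))
  expect_true(all(pr_a$mean_beta[31:40] == 0))

  expect_warning(gene_metaprofile(flat, sites,
                                  gintervals("chr1", 100L, 110L, "+"),
                                  body_bins = 20L),
                 "skipped")
})
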