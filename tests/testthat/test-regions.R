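test_that("anova_per_cpg reproduces the sum-of-squares oracle", {
  beta <- rbind(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9))
  groups <- rep(c("A", "B", "C"), each = 3)
  st <- anova_per_cpg(beta, groups)
  expect_equal(st$statistic, 27)   # SSB=0.54 (df 2), SSW=0.06 (df 6)
  expect_equal(st$p_value, pf(27, 2, 6, lower.tail = FALSE))

  # all values identical: F = 0, p = 1
  st0 <- anova_per_cpg(matrix(0.5, 1, 9), groups)
  expect_equal(st0$statistic, 0)
  expect_equal(st0$p_value, 1)

  # degenerate: zero within-group variance, nonzero between
  stx <- anova_per_cpg(rbind(rep(c(0.1, 0.9, 0.5), each = 3)), groups)
  expect_equal(stx$p_value, 0)
  expect_true(stx$degenerate)

  # permuting samples within groups leaves F unchanged
  perm <- c(2, 3, 1, 5, 4, 6, 9, 7, 8)
  expect_equal(anova_per_cpg(beta[, perm, drop = FALSE],
                             groups[perm])$statistic, st$statistic)

  expect_error(anova_per_cpg(beta, c("A", rep("B", 8))),
               class = "islandmeth_config_error")
})

test_that("anova matches lm/anova and F = t^2 for two groups", {
  withr::local_seed(21)
  groups3 <- rep(c("A", "B", "C"), times = c(4, 5, 6))
  beta <- matrix(runif(15 * 20), 20, 15)
  st <- anova_per_cpg(beta, groups3)
  for (i in c(1, 7, 20)) {
    a <- anova(lm(beta[i, ] ~ factor(groups3)))
    expect_equal(st$statistic[i], a$`F value`[1], tolerance = 1e-10)
    expect_equal(st$p_value[i], a$`Pr(>F)`[1], tolerance = 1e-10)
  }
  groups2 <- rep(c("M", "F"), times = c(7, 8))
  st2 <- anova_per_cpg(beta, groups2)
  for (i in c(2, 11)) {
    tt <- t.test(beta[i, groups2 == "M"], beta[i, groups2 == "F"],
                 var.equal = TRUE)
    expect_equal(st2$statistic[i], unname(tt$statistic)^2,
                 tolerance = 1e-10)
  }
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "islandmeth_data_error")

  # reference agreement on random draws, including ties
  withr::local_seed(8)
  for (i in 1:20) {
    p <- round(runif(50), sample(c(1, 3, 10), 1))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("call_dmcs applies a strict threshold in genomic order", {
  st <- data.table::data.table(chrom = c("chr2", "chr1"), pos = c(5L, 9L),
                               q_value = c(0.049, 0.05))
  out <- call_dmcs(st)
  expect_equal(out, data.table::data.table(chrom = "chr2", pos = 5L))
  expect_equal(nrow(call_dmcs(st[0])), 0L)
  expect_equal(nrow(call_dmcs(st, fdr_threshold = 1.0)), 2L)
})

test_that("merge_runs chains with inclusive gaps and a count floor", {
  pos <- data.table::data.table(chrom = "chr1",
                                pos = c(100L, 150L, 240L, 500L, 560L,
                                        600L, 650L, 700L))
  out <- merge_runs(pos, gap_bp = 100L, min_count = 5L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 500L)
  expect_equal(out$end, 701L)
  expect_equal(out$n_sites, 5L)

  # exactly-100 bp gaps chain (inclusive boundary)
  pos2 <- data.table::data.table(chrom = "chr1", pos = seq(0L, 400L, 100L))
  expect_equal(nrow(merge_runs(pos2, 100L, 5L)), 1L)
  # 101 bp gaps do not
  pos3 <- data.table::data.table(chrom = "chr1", pos = seq(0L, 404L, 101L))
  expect_equal(nrow(merge_runs(pos3, 100L, 5L)), 0L)
  # four members under a floor of five: nothing
  expect_equal(nrow(merge_runs(pos2[1:4], 100L, 5L)), 0L)
})

test_that("merge_runs equals the chaining oracle and is idempotent", {
  withr::local_seed(13)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    pos <- data.table::data.table(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos = sample.int(3000, n))
    got <- merge_runs(pos, gap_bp = 100L, min_count = 3L)
    want <- oracle_merge_runs(pos$chrom, pos$pos, 100L, 3L)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_sites, want$n)
    }
    # order invariance and member-count conservation
    got2 <- merge_runs(pos[sample.int(n)], gap_bp = 100L, min_count = 3L)
    expect_equal(got2, got)
    expect_lte(sum(got$n_sites), nrow(unique(pos)))
  }
})

test_that("sd_per_cpg and the top-fraction threshold are order statistics", {
  expect_equal(sd_per_cpg(matrix(0.5, 1, 3)), 0)
  expect_equal(sd_per_cpg(rbind(c(0, 1))), sqrt(0.5))
  sds <- 0.01 * (1:100)
  expect_equal(top_fraction_threshold(sds, 0.01), 1.00)
  expect_equal(sum(sds >= top_fraction_threshold(sds, 0.01)), 1L)
  expect_equal(sum(sds >= top_fraction_threshold(sds, 0.10)), 10L)
  expect_error(top_fraction_threshold(sds, 0),
               class = "islandmeth_config_error")
  withr::local_seed(3)
  bm <- matrix(runif(300), 30, 10)
  expect_equal(sd_per_cpg(bm), apply(bm, 1, sd), tolerance = 1e-12)
})

test_that("associate_regions tests sex, breed and age per region", {
  withr::local_seed(31)
  n <- 16
  md <- data.table::data.table(
    sample_id = sprintf("s%02d", 1:n),
    breed = rep(c("A", "B"), each = n / 2),
    sex = rep(c("M", "F"), n / 2),
    neutered = TRUE,
    age_years = seq(2, 17, length.out = n),
    condition = "healthy")
  sites <- data.table::data.table(chrom = "chr1",
                                  pos = c(100L, 110L, 120L, 500L, 510L,
                                          520L))
  # region 1: exact monotone age effect; region 2: constant
  beta <- rbind(matrix(rep(0.05 * seq_len(n) / n, 3), 3, n, byrow = TRUE),
                matrix(0.5, 3, n))
  colnames(beta) <- md$sample_id
  regions <- merge_runs(sites, gap_bp = 100, min_count = 3)
  out <- associate_regions(regions, beta, sites, md)
  expect_equal(nrow(out), 2L)
  expect_equal(out$rho_age[1], 1)
  expect_lt(out$p_age[1], 1e-6)
  expect_equal(out$p_sex[2], 1)
  expect_equal(out$p_breed[2], 1)

  # constant covariate: warning, tests skipped
  md$sex <- "F"
  expect_warning(out2 <- associate_regions(regions, beta, sites, md),
                 "skipped")
  expect_true(all(is.na(out2$q_sex)))
})

test_that("logistic_dmc fits per-site models and flags separation", {
  withr::local_seed(41)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  age <- runif(n, 3, 14)
  beta <- rbind(
    rep(0.5, n),                                   # constant: skipped
    ifelse(y == 1, 0.9, 0.1) + rnorm(n, 0, 0.001), # separated
    runif(n))                                      # null
  st <- logistic_dmc(beta, y, covariates = cbind(age = age))
  expect_true(is.na(st$p_value[1]) && !st$separated[1])
  expect_true(st$separated[2] && is.na(st$p_value[2]))
  expect_false(is.na(st$p_value[3]))

  # Wald p matches glm on a well-behaved site
  fit <- glm(y ~ beta[3, ] + age, family = binomial())
  expect_equal(st$p_value[3], summary(fit)$coefficients[2, 4],
               tolerance = 1e-6)

  expect_error(logistic_dmc(beta, rep(1L, n)),
               class = "islandmeth_config_error")
})
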