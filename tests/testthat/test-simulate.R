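small_cfg <- function(...) {
  args <- list(...)
  if (!"mean_depth" %in% names(args)) args$mean_depth <- 30
  do.call(sim_config,
          c(list(seed = 7L, n_chroms = 1L, chrom_length = 60000L,
                 n_cgis = 3L, n_samples_per_breed = c(A = 3L, B = 3L)),
            args))
}

test_that("genome simulation is deterministic and plants detectable islands", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth$true_cgis, g2$truth$true_cgis)

  # every planted island is recovered by the GGF detector
  det <- detect_cgis(g1$genome, ggf_criteria())
  hit <- overlaps_any(g1$truth$true_cgis, det)
  expect_true(all(hit))

  # islands are far enough apart for shore/shelf annotation
  tc <- g1$truth$true_cgis[order(start)]
  if (nrow(tc) > 1) expect_true(all(diff(tc$start) - (tc$end[-nrow(tc)] -
                                                        tc$start[-nrow(tc)]) >= 4000))
})

test_that("a genome with no islands yields no GGF detections", {
  cfg <- sim_config(seed = 2L, n_chroms = 1L, chrom_length = 40000L,
                    n_cgis = 0L)
  g <- simulate_genome(cfg)
  expect_equal(nrow(detect_cgis(g$genome, ggf_criteria())), 0L)
})

test_that("a strong island is found by both criteria sets", {
  cfg <- sim_config(seed = 5L, n_chroms = 1L, chrom_length = 30000L,
                    n_cgis = 1L, cgi_length_range = c(600L, 600L),
                    cgi_gc = 0.7, cgi_oe = 0.8)
  g <- simulate_genome(cfg)
  expect_true(all(overlaps_any(g$truth$true_cgis,
                               detect_cgis(g$genome, ggf_criteria()))))
  expect_true(all(overlaps_any(g$truth$true_cgis,
                               detect_cgis(g$genome,
                                           takai_jones_criteria()))))
})

test_that("methylome noise model recovers the planted means", {
  # beta_precision -> Inf with fixed depth: empirical beta within 0.8 +- 0.01
  cfg <- sim_config(seed = 11L, n_chroms = 1L, chrom_length = 150000L,
                    n_cgis = 0L, n_samples_per_breed = c(A = 2L),
                    mean_depth = 100, depth_overdispersion = 0,
                    beta_precision = Inf, background_beta = 0.8)
  g <- simulate_genome(cfg)
  met <- simulate_methylomes(g$genome, g$truth, cfg)
  t1 <- met$tables[[1]]
  expect_gt(nrow(t1), 1000)
  expect_lt(abs(mean(t1$meth / t1$total) - 0.8), 0.01)
})

test_that("planted DMR offsets appear as between-breed differences", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  sites <- cpg_positions(g$genome)
  plant <- plant_regions(sites, n = 1, n_cpgs = 8,
                         avoid = g$truth$true_cgis, seed = 3)
  cfg$planted_dmrs <- list(c(plant[[1]],
                             list(offsets = list(A = 0, B = -0.4))))
  met <- simulate_methylomes(g$genome, g$truth, cfg)
  idx <- which(sites$pos >= plant[[1]]$start & sites$pos < plant[[1]]$end &
                 sites$chrom == plant[[1]]$chrom)
  tb <- met$true_beta[idx, , drop = FALSE]
  is_b <- met$metadata$breed == "B"
  expect_equal(mean(tb[, !is_b]) - mean(tb[, is_b]), 0.4, tolerance = 1e-9)
})

test_that("zero-depth cells are absent, not 0/0", {
  cfg <- small_cfg(mean_depth = 2, depth_overdispersion = 0.5)
  g <- simulate_genome(cfg)
  met <- simulate_methylomes(g$genome, g$truth, cfg)
  for (t in met$tables) expect_true(all(t$total > 0L))
  # with depth this low some cells must genuinely be missing
  expect_true(any(vapply(met$tables, nrow, integer(1)) <
                    nrow(met$sites)))
})

test_that("SNP placement respects rate and CpG fraction", {
  cfg <- small_cfg(snp_rate = 0)
  g <- simulate_genome(cfg)
  ann <- simulate_annotations(g$genome, g$truth, cfg)
  expect_equal(nrow(ann$snps), 0L)

  cfg2 <- small_cfg(snp_rate = 0.001, snp_cpg_fraction = 1.0)
  g2 <- simulate_genome(cfg2)
  ann2 <- simulate_annotations(g2$genome, g2$truth, cfg2)
  cpgs <- cpg_positions(g2$genome)
  on_cpg <- ann2$snps$pos %in% c(cpgs$pos, cpgs$pos + 1L)
  expect_true(all(on_cpg))
  expect_equal(nrow(ann2$snps), round(0.001 * cfg2$chrom_length))
})

test_that("the full dataset writes valid, re-readable pipeline inputs", {
  out <- withr::local_tempdir()
  cfg <- small_cfg(n_genes = 6L, n_repeats_per_subfamily = 5L)
  ds <- simulate_dataset(cfg, out)
  genome <- read_fasta(file.path(out, "genome.fa"))
  expect_identical(genome, ds$genome)
  md <- read_sample_metadata(file.path(out, "metadata.tsv"))
  expect_equal(nrow(md), 6L)
  tab <- read_methylation_table(
    file.path(out, "meth", paste0(md$sample_id[1], ".tsv")))
  expect_equal(as.data.frame(tab),
               as.data.frame(ds$methylomes$tables[[md$sample_id[1]]]))
  gt <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(nrow(gt$true_cgis), nrow(ds$truth$true_cgis))
})

test_that("metadata generation honours the breed design and ranges", {
  cfg <- sim_config(seed = 9L)
  md <- simulate_metadata(cfg)
  expect_equal(nrow(md), 19L)
  expect_equal(as.integer(table(md$breed)[c("Shiba", "Dachshund",
                                            "Poodle")]),
               c(3L, 3L, 13L))
  expect_true(all(md$age_years >= 3 & md$age_years <= 14))
  expect_true(all(md$sex %in% c("M", "F")))
  expect_identical(md, simulate_metadata(cfg))
})

test_that("sim configs round-trip through JSON", {
  cfg <- small_cfg(snp_rate = 0.002,
                   planted_dmrs = list(list(chrom = "chr1", start = 100L,
                                            end = 400L,
                                            offsets = list(A = 0,
                                                           B = -0.3))))
  f <- withr::local_tempfile(fileext = ".json")
  payload <- unclass(cfg)
  payload$n_samples_per_breed <- as.list(payload$n_samples_per_breed)
  jsonlite::write_json(payload, f, auto_unbox = TRUE, digits = NA)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$n_samples_per_breed, cfg$n_samples_per_breed)
  expect_equal(cfg2$chrom_length, cfg$chrom_length)
  expect_equal(cfg2$planted_dmrs[[1]]$offsets$B, -0.3)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg2)
  expect_identical(g1$genome, g2$genome)
})

test_that("plant_regions returns runs mergeable at the stated gap", {
  cfg <- small_cfg()
  g <- simulate_genome(cfg)
  sites <- cpg_positions(g$genome)
  pl <- plant_regions(sites, n = 3, n_cpgs = 6, gap_bp = 100, seed = 5)
  expect_length(pl, 3L)
  for (p in pl) {
    inside <- sites[chrom == p$chrom & pos >= p$start & pos < p$end]
    expect_gte(nrow(inside), 6L)
    expect_true(all(diff(inside$pos) <= 100))
  }
})
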