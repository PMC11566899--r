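test_that("seq_stats counts composition directly", {
  s <- seq_stats("CGCGCG")
  expect_equal(s$gc_ratio, 1)
  expect_equal(s$n_cpg, 3L)
  expect_equal(s$cpg_oe, 2)

  s <- seq_stats("ATATAT")
  expect_equal(s$gc_ratio, 0)
  expect_equal(s$n_cpg, 0L)
  expect_equal(s$cpg_oe, 0)

  s <- seq_stats("GCGCGC")
  expect_equal(s$n_cpg, 2L)
  expect_equal(s$cpg_oe, 2 * 6 / 9)

  expect_error(seq_stats(""), class = "islandmeth_data_error")
})

test_that("detect_cgis finds the qualifying segment and honors length rules", {
  cg300 <- strrep("CG", 150)
  genome <- c(chr1 = paste0(strrep("AT", 500), cg300, strrep("AT", 500)))
  isl <- detect_cgis(genome, ggf_criteria())
  # exactly one island, covering the CpG-rich segment; composition
  # criteria cannot be base-sharp, so boundaries may absorb flanking
  # sequence only as far as a seed window can still qualify (150 bp here,
  # where window GC drops to 0.5)
  expect_equal(nrow(isl), 1L)
  expect_lte(isl$start, 1000L)
  expect_gte(isl$end, 1300L)
  expect_gte(isl$start, 850L)
  expect_lte(isl$end, 1450L)

  # a 200 bp CpG run is too dilute for any 500 bp Takai-Jones window
  genome200 <- c(chr1 = paste0(strrep("AT", 500), strrep("CG", 100),
                               strrep("AT", 500)))
  expect_equal(nrow(detect_cgis(genome200, takai_jones_criteria())), 0L)
  expect_equal(nrow(detect_cgis(genome200, ggf_criteria())), 1L)

  # islands containing N are disqualified
  withN <- c(chr1 = paste0(strrep("AT", 500),
                           substr(cg300, 1, 140), "N",
                           substr(cg300, 142, 300), strrep("AT", 500)))
  islN <- detect_cgis(withN, ggf_criteria())
  expect_true(all(islN$end <= 1140 | islN$start >= 1141))
})

test_that("every returned island satisfies its criteria when re-scored", {
  withr::local_seed(42)
  for (gc in c(0.5, 0.6)) {
    genome <- c(chr1 = random_dna(3000, gc))
    for (cr in list(ggf_criteria(), takai_jones_criteria())) {
      isl <- detect_cgis(genome, cr)
      for (i in seq_len(nrow(isl))) {
        st <- seq_stats(substr(genome, isl$start[i] + 1, isl$end[i]))
        if (cr$strict) {
          expect_gt(st$gc_ratio, cr$min_gc)
          expect_gt(st$cpg_oe, cr$min_oe)
          expect_gt(st$length, cr$min_length)
        } else {
          expect_gte(st$gc_ratio, cr$min_gc)
          expect_gte(st$cpg_oe, cr$min_oe)
          expect_gte(st$length, cr$min_length)
        }
      }
    }
  }
})

test_that("detect_cgis equals the naive brute-force oracle", {
  withr::local_seed(99)
  for (rep in 1:12) {
    gc <- sample(c(0.45, 0.52, 0.6), 1)
    s <- random_dna(800, gc)
    got <- detect_cgis(c(chr1 = s), ggf_criteria())
    want <- oracle_detect_cgis(s, ggf_criteria())
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want[, 1])
      expect_equal(got$end, want[, 2])
    }
  }
})

test_that("detection is strand-symmetric up to coordinate mirroring", {
  withr::local_seed(17)
  s <- random_dna(2000, 0.58)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""))
  a <- detect_cgis(c(chr1 = s), ggf_criteria())
  b <- detect_cgis(c(chr1 = rc), ggf_criteria())
  # GC and CpG counts are strand-symmetric, so islands mirror
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    expect_setequal(2000 - a$end, b$start)
    expect_setequal(2000 - a$start, b$end)
  }
})

test_that("CGI methylation classes follow the printed thresholds", {
  expect_equal(classify_cgi_methylation(c(0.05, 0.10, 0.50, 0.51)),
               c("unmethylated", "low", "low", "high"))
  expect_equal(classify_cgi_methylation(0), "unmethylated")
  expect_equal(classify_cgi_methylation(1), "high")
  expect_true(is.na(classify_cgi_methylation(NA)))
  expect_error(classify_cgi_methylation(1.2),
               class = "islandmeth_data_error")
})

test_that("feature catalog places promoters, shores, shelves and others", {
  sizes <- c(chr1 = 20000L)
  genes <- gintervals("chr1", 5000L, 8000L, "+")
  cgis <- gintervals("chr1", 10000L, 11000L)
  cat <- build_feature_catalog(genes, cgis, cgis[0], cgis[0], sizes)
  expect_equal(cat$promoters$start, 3500L)
  expect_equal(cat$promoters$end, 5000L)
  expect_equal(cat$shores$start, c(8000L, 11000L))
  expect_equal(cat$shores$end, c(10000L, 13000L))
  expect_equal(cat$shelves$start, c(6000L, 13000L))
  expect_equal(cat$shelves$end, c(8000L, 15000L))
  # minus-strand promoter is downstream of the end coordinate
  catm <- build_feature_catalog(gintervals("chr1", 5000L, 8000L, "-"),
                                cgis, cgis[0], cgis[0], sizes)
  expect_equal(catm$promoters$start, 8000L)
  expect_equal(catm$promoters$end, 9500L)
  # others is the complement of the union
  covered <- rbind(cat$promoters[, c("chrom", "start", "end")],
                   cat$gene_bodies[, c("chrom", "start", "end")],
                   cat$cgis[, c("chrom", "start", "end")],
                   cat$shores[, c("chrom", "start", "end")],
                   cat$shelves[, c("chrom", "start", "end")])
  expect_false(any(overlaps_any(cat$others, covered)))
  tot_len <- sum(covered[!duplicated(covered)][, end - start])
  expect_equal(sum(cat$others$end - cat$others$start),
               20000L - (15000L - 3500L))
  # full coverage leaves others empty
  catf <- build_feature_catalog(gintervals("chr1", 0L, 20000L, "+"),
                                cgis, cgis[0], cgis[0], sizes,
                                promoter_bp = 0L)
  expect_equal(nrow(catf$others), 0L)
})

test_that("gene-end CGI presence is strand-resolved with half-open windows", {
  # a CGI overlapping the 3' end of a minus-strand gene (its start coord)
  genes <- gintervals("chr1", c(5000L, 5000L), c(8000L, 8000L),
                      c("-", "+"))
  cgis <- gintervals("chr1", 4900L, 5100L)
  expect_equal(gene_end_cgi_presence(genes, cgis, window_bp = 500L),
               c(TRUE, FALSE))
  # no CGIs: all false
  expect_equal(gene_end_cgi_presence(genes, cgis[0]), c(FALSE, FALSE))
  # abutting the half-open window edge does not count
  g <- gintervals("chr1", 1000L, 2000L, "+")
  cgi_abut <- gintervals("chr1", 2500L, 2600L)   # window [1500, 2500)
  expect_false(gene_end_cgi_presence(g, cgi_abut, window_bp = 500L))
  cgi_in <- gintervals("chr1", 2499L, 2600L)
  expect_true(gene_end_cgi_presence(g, cgi_in, window_bp = 500L))
})

test_that("score_cgis attaches mean beta and class per island", {
  sites <- data.table::data.table(chrom = "chr1",
                                  pos = c(100L, 110L, 500L, 510L))
  beta <- matrix(c(0.0, 0.1, 0.8, 0.9,
                   0.1, 0.0, 0.9, 0.8), ncol = 2)
  m <- cpg_matrix(sites, meth = matrix(as.integer(round(beta * 10)), 4, 2),
                  total = matrix(10L, 4, 2), samples = c("a", "b"))
  cgis <- gintervals("chr1", c(90L, 490L, 900L), c(120L, 520L, 950L))
  sc <- score_cgis(cgis, m)
  expect_equal(sc$mean_beta, c(0.05, 0.85, NA))
  expect_equal(sc$meth_class, c("unmethylated", "high", NA))
  expect_equal(sc$n_sites, c(2L, 2L, 0L))
})
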