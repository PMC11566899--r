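#' Simulation configuration
#'
#' Declares the synthetic world: a CpG-depleted background genome with
#' planted CpG-rich islands, per-sample beta-binomial methylation counts
#' with planted breed, variance and age effects, plus gene/repeat/CTCF
#' annotations and SNP positions. Defaults emulate a mammalian whole-blood
#' WGBS cohort at desk scale: ~41% background GC, strong CpG depletion,
#' high global methylation (background beta 0.8) with unmethylated islands
#' (beta 0.05), 70x mean coverage, and a 3-breed cohort of 3 + 3 + 13
#' samples.
#'
#' @param seed master seed; all randomness flows from it through named
#'   substreams (genome, counts, annotations, metadata)
#' @param n_chroms,chrom_length genome shape
#' @param background_gc background GC fraction
#' @param background_cpg_rate background CpG dinucleotides per bp (sets
#'   the depletion; 0.01 at GC 0.41 gives CpG O/E ~ 0.24)
#' @param n_cgis number of planted islands
#' @param cgi_length_range island length range in bp
#' @param cgi_gc,cgi_oe island composition targets (realized values meet
#'   or exceed them)
#' @param methylated_cgi_fraction fraction of islands planted at the
#'   background (high) methylation level rather than the island (low) one
#' @param n_samples_per_breed named integer vector breed -> sample count
#' @param mean_depth mean read depth per site
#' @param depth_overdispersion negative-binomial depth overdispersion d
#'   (variance = mu(1 + d mu); 0 = Poisson)
#' @param beta_precision beta-binomial concentration (Inf = pure binomial)
#' @param background_beta,cgi_beta true methylation outside / inside
#'   unmethylated islands
#' @param planted_dmrs list of `list(chrom, start, end, offsets =
#'   c(breed = delta, ...))`
#' @param planted_variable_loci list of `list(chrom, start, end, sd)`
#' @param planted_age_loci list of `list(chrom, start, end, slope)` (beta
#'   change per year)
#' @param snp_rate SNPs per bp
#' @param snp_cpg_fraction fraction of SNPs placed on CpG bases
#' @param n_genes,repeat_subfamilies,n_repeats_per_subfamily,n_ctcf
#'   annotation richness
#' @param age_range sampling range for ages in years
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 200000L,
                       background_gc = 0.41,
                       background_cpg_rate = 0.01,
                       n_cgis = 10L,
                       cgi_length_range = c(500L, 1500L),
                       cgi_gc = 0.65,
                       cgi_oe = 0.75,
                       methylated_cgi_fraction = 0.3,
                       n_samples_per_breed = c(Shiba = 3L, Dachshund = 3L,
                                               Poodle = 13L),
                       mean_depth = 70,
                       depth_overdispersion = 0.05,
                       beta_precision = 50,
                       background_beta = 0.8,
                       cgi_beta = 0.05,
                       planted_dmrs = list(),
                       planted_variable_loci = list(),
                       planted_age_loci = list(),
                       snp_rate = 0.001,
                       snp_cpg_fraction = 0.25,
                       n_genes = 20L,
                       repeat_subfamilies = c("SINEC_Cf", "MIR", "MLT1",
                                              "G_rich"),
                       n_repeats_per_subfamily = 30L,
                       n_ctcf = 30L,
                       age_range = c(3, 14)) {
  cfg <- as.list(environment())
  fracs <- c(background_gc = background_gc, cgi_gc = cgi_gc,
             background_cpg_rate = background_cpg_rate,
             methylated_cgi_fraction = methylated_cgi_fraction,
             background_beta = background_beta, cgi_beta = cgi_beta,
             snp_rate = snp_rate, snp_cpg_fraction = snp_cpg_fraction)
  if (any(fracs < 0 | fracs > 1))
    config_error(sprintf("fraction out of [0,1]: %s",
                         names(fracs)[which(fracs < 0 | fracs > 1)[1]]))
  if (cfg$cgi_length_range[1] > cfg$cgi_length_range[2] ||
      cfg$cgi_length_range[1] < 1)
    config_error("bad cgi_length_range")
  if (mean_depth <= 0 || beta_precision <= 0)
    config_error("mean_depth and beta_precision must be positive")
  if (is.null(names(n_samples_per_breed)))
    config_error("n_samples_per_breed must be a named vector")
  structure(cfg, class = "sim_config")
}

#' Read a simulation config from JSON (1:1 with [sim_config()] fields)
#' @param path JSON file
#' @return `sim_config`
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("missing input: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$n_samples_per_breed))
    raw$n_samples_per_breed <- unlist(raw$n_samples_per_breed)
  for (f in c("planted_dmrs", "planted_variable_loci", "planted_age_loci"))
    if (!is.null(raw[[f]]) && is.data.frame(raw[[f]]))
      raw[[f]] <- lapply(seq_len(nrow(raw[[f]])), function(i)
        as.list(raw[[f]][i, , drop = FALSE]))
  do.call(sim_config, raw)
}

# count CG dinucleotides in a base vector
count_cpg <- function(b) {
  L <- length(b)
  if (L < 2L) return(0L)
  sum(b[-L] == "C" & b[-1L] == "G")
}

# fixed-composition sequence whose CpG count is steered into
# [need_lo, need_hi] by composition-preserving swaps (GC ratio is exact
# by construction; the CpG O/E lands at its target)
make_composition_seq <- function(len, gc, oe, slack = 0.05) {
  n_gc <- ceiling(gc * len)
  n_c <- n_gc %/% 2L + n_gc %% 2L; n_g <- n_gc %/% 2L
  n_at <- len - n_gc
  exp_cpg <- n_c * n_g / len
  need_lo <- as.integer(ceiling(oe * exp_cpg))
  need_hi <- as.integer(ceiling((oe + slack) * exp_cpg))
  for (try in 1:50) {
    b <- sample(c(rep("C", n_c), rep("G", n_g),
                  sample(c("A", "T"), n_at, replace = TRUE)))
    n_cpg <- count_cpg(b)
    for (it in 1:5000) {
      if (n_cpg >= need_lo && n_cpg <= need_hi) break
      i <- sample.int(len, 1L); j <- sample.int(len, 1L)
      if (b[i] == b[j]) next
      b2 <- b; b2[c(i, j)] <- b[c(j, i)]
      n2 <- count_cpg(b2)
      target <- (need_lo + need_hi) / 2
      if (abs(n2 - target) < abs(n_cpg - target)) {
        b <- b2; n_cpg <- n2
      }
    }
    st <- seq_stats_vec(b, 1L, len)
    if (st$gc_ratio >= gc && st$cpg_oe >= oe &&
        st$cpg_oe <= oe + 2 * slack) return(b)
  }
  config_error("could not realize island composition targets")
}

make_island_seq <- function(len, gc, oe) make_composition_seq(len, gc, oe)

#' Random CGI-like sequences at stated composition targets
#'
#' Generates sequences whose realized GC ratio and CpG O/E sit at (just
#' above) the targets -- the substrate for tokenizer/embedding
#' experiments contrasting, e.g., unmethylated-like (high GC, high O/E)
#' with methylated-like (lower GC, lower O/E) islands.
#'
#' @param n number of sequences
#' @param length_range length range in bp
#' @param gc,oe composition targets
#' @param seed RNG seed
#' @param prefix id prefix for names
#' @return named character vector
#' @export
random_cgi_like_seqs <- function(n, length_range = c(400L, 800L), gc = 0.7,
                                 oe = 0.8, seed = 1L, prefix = "cgi") {
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    out <- vapply(seq_len(n), function(i)
      paste(make_composition_seq(lens[i], gc, oe), collapse = ""),
      character(1))
    names(out) <- sprintf("%s%04d", prefix, seq_len(n))
    out
  })
}

#' Simulate a genome with planted CpG islands
#'
#' The background is drawn per base at the stated GC with CpG
#' dinucleotides thinned to `background_cpg_rate` (CpG depletion). Each
#' island is a contiguous segment rejection-sampled until its realized GC
#' ratio and CpG O/E meet or exceed the targets. Islands are
#' non-overlapping and >= 4 kb apart so shore/shelf annotation never
#' collides. Deterministic given the config seed.
#'
#' @param config a [sim_config()]
#' @return list with `genome` (named character vector) and `truth` (list
#'   with `true_cgis` including the planted methylation status)
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gap <- 4000L
  with_seed(substream_seed(config$seed, "genome"), {
    L <- config$chrom_length
    chroms <- paste0("chr", seq_len(config$n_chroms))
    # assign islands to chromosomes round-robin
    isl_chrom <- rep(chroms, length.out = config$n_cgis)
    genome <- character(config$n_chroms); names(genome) <- chroms
    cgi_rows <- vector("list", 0L)
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      gc <- config$background_gc
      bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      # thin CpGs down to the stated background rate
      cg_at <- which(bases[-L] == "C" & bases[-1] == "G")
      target_n <- round(config$background_cpg_rate * L)
      if (length(cg_at) > target_n) {
        drop <- sample(cg_at, length(cg_at) - target_n)
        bases[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
      }
      # place this chromosome's islands
      n_here <- sum(isl_chrom == ch)
      if (n_here > 0L) {
        lens <- sample(seq(config$cgi_length_range[1],
                           config$cgi_length_range[2]), n_here,
                       replace = TRUE)
        slack <- L - 2L * gap - sum(lens) - (n_here - 1L) * gap
        if (slack < 0L)
          config_error("cannot place n_cgis without overlap; enlarge genome")
        offs <- sort(sample.int(slack + 1L, n_here, replace = TRUE)) - 1L
        starts <- gap + offs + cumsum(c(0L, lens[-n_here] + gap))
        for (k in seq_len(n_here)) {
          isl <- make_island_seq(lens[k], config$cgi_gc, config$cgi_oe)
          bases[(starts[k] + 1L):(starts[k] + lens[k])] <- isl
          cgi_rows[[length(cgi_rows) + 1L]] <- data.table(
            chrom = ch, start = starts[k], end = starts[k] + lens[k])
        }
      }
      genome[ch] <- paste(bases, collapse = "")
    }
    true_cgis <- if (length(cgi_rows)) rbindlist(cgi_rows) else
      data.table(chrom = character(), start = integer(), end = integer())
    if (nrow(true_cgis)) {
      n_meth <- round(config$methylated_cgi_fraction * nrow(true_cgis))
      meth_flag <- rep(FALSE, nrow(true_cgis))
      if (n_meth > 0L)
        meth_flag[sample.int(nrow(true_cgis), n_meth)] <- TRUE
      true_cgis[, `:=`(strand = ".", methylated = meth_flag)]
    } else {
      true_cgis[, `:=`(strand = character(), methylated = logical())]
    }
    list(genome = genome,
         truth = list(true_cgis = true_cgis,
                      true_dmrs = config$planted_dmrs,
                      true_variable_regions = config$planted_variable_loci,
                      true_age_regions = config$planted_age_loci))
  })
}

#' All forward-strand CpG positions of a genome
#' @param genome named character vector
#' @return `data.table` with chrom, pos (0-based position of the C)
#' @export
cpg_positions <- function(genome) {
  rows <- lapply(names(genome), function(ch) {
    b <- strsplit(genome[[ch]], "", fixed = TRUE)[[1]]
    L <- length(b)
    data.table(chrom = ch,
               pos = which(b[-L] == "C" & b[-1] == "G") - 1L)
  })
  out <- rbindlist(rows)
  setorder(out, chrom, pos)
  out[]
}

#' Generate the per-sample cohort metadata
#'
#' Breeds follow `n_samples_per_breed`; sex, neutering, age (uniform over
#' `age_range`) and condition (healthy / injured_acl / injured_hd at
#' 10:7:2 odds, echoing a small orthopaedic cohort) are drawn from the
#' metadata substream.
#'
#' @param config a [sim_config()]
#' @return `data.table` of sample metadata
#' @export
simulate_metadata <- function(config) {
  with_seed(substream_seed(config$seed, "metadata"), {
    breeds <- rep(names(config$n_samples_per_breed),
                  config$n_samples_per_breed)
    n <- length(breeds)
    data.table(
      sample_id = sprintf("S%02d", seq_len(n)),
      breed = breeds,
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(6, 13) / 19),
      neutered = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.7, .3)),
      age_years = round(runif(n, config$age_range[1], config$age_range[2]),
                        1),
      condition = sample(c("healthy", "injured_acl", "injured_hd"), n,
                         replace = TRUE, prob = c(10, 7, 2) / 19))
  })
}

in_planted <- function(sites, plant) {
  hit <- rep(FALSE, nrow(sites))
  iv <- data.table(chrom = plant$chrom,
                   start = as.integer(plant$start),
                   end = as.integer(plant$end))
  w <- interval_overlap(data.table(chrom = sites$chrom, start = sites$pos,
                                   end = sites$pos + 1L), iv)
  hit[unique(w$query)] <- TRUE
  hit
}

#' Simulate per-sample methylation count tables
#'
#' For each CpG site and sample the true beta is the clipped sum of the
#' base level (background outside islands, island level inside
#' unmethylated islands), the breed offset of any planted DMR, the age
#' slope of any planted age locus and, in planted variable loci, a
#' per-sample Gaussian perturbation. Depth is negative-binomial around
#' `mean_depth`; methylated counts are beta-binomial at `beta_precision`.
#' Zero-depth cells are absent from the sample's table (missing, not
#' 0/0). Deterministic given the config seed.
#'
#' @param genome named character vector from [simulate_genome()]
#' @param truth its ground truth
#' @param config the [sim_config()]
#' @param metadata optional pre-built metadata (default
#'   [simulate_metadata()])
#' @return list with `tables` (named list of per-sample collapsed count
#'   tables), `metadata`, `sites` and `true_beta` (site x sample matrix)
#' @export
simulate_methylomes <- function(genome, truth, config, metadata = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(metadata)) metadata <- simulate_metadata(config)
  sites <- cpg_positions(genome)
  n_sites <- nrow(sites)
  if (n_sites == 0L) data_error("genome contains no CpG sites")
  n_samp <- nrow(metadata)
  base <- rep(config$background_beta, n_sites)
  tc <- truth$true_cgis
  if (!is.null(tc) && nrow(tc)) {
    unmeth <- in_planted(sites, tc[tc$methylated == FALSE])
    base[unmeth] <- config$cgi_beta
  }
  beta <- matrix(base, n_sites, n_samp)
  for (d in config$planted_dmrs) {
    idx <- which(in_planted(sites, d))
    if (!length(idx)) next
    off <- unlist(d$offsets)[metadata$breed]
    off[is.na(off)] <- 0
    beta[idx, ] <- beta[idx, ] + matrix(off, length(idx), n_samp,
                                        byrow = TRUE)
  }
  for (a in config$planted_age_loci) {
    idx <- which(in_planted(sites, a))
    if (!length(idx)) next
    delta <- a$slope * (metadata$age_years - mean(metadata$age_years))
    beta[idx, ] <- beta[idx, ] + matrix(delta, length(idx), n_samp,
                                        byrow = TRUE)
  }
  with_seed(substream_seed(config$seed, "counts"), {
    for (v in config$planted_variable_loci) {
      idx <- which(in_planted(sites, v))
      if (!length(idx)) next
      pert <- rnorm(n_samp, 0, v$sd)   # shared across the locus's CpGs
      beta[idx, ] <- beta[idx, ] + matrix(pert, length(idx), n_samp,
                                          byrow = TRUE)
    }
    beta <- pmin(pmax(beta, 0), 1)
    nc <- n_sites * n_samp
    depth <- if (config$depth_overdispersion > 0) {
      matrix(rnbinom(nc, mu = config$mean_depth,
                     size = 1 / config$depth_overdispersion),
             n_sites, n_samp)
    } else {
      matrix(stats::rpois(nc, config$mean_depth), n_sites, n_samp)
    }
    p <- if (is.finite(config$beta_precision)) {
      bc <- pmin(pmax(beta, 1e-9), 1 - 1e-9)
      matrix(rbeta(nc, bc * config$beta_precision,
                   (1 - bc) * config$beta_precision), n_sites, n_samp)
    } else beta
    meth <- matrix(rbinom(nc, as.vector(depth), as.vector(p)),
                   n_sites, n_samp)
    tables <- lapply(seq_len(n_samp), function(j) {
      keep <- which(depth[, j] > 0L)
      data.table(chrom = sites$chrom[keep], pos = sites$pos[keep],
                 strand = "+", meth = meth[keep, j],
                 total = depth[keep, j])
    })
    names(tables) <- metadata$sample_id
    list(tables = tables, metadata = metadata, sites = sites,
         true_beta = beta)
  })
}

#' Simulate gene, repeat and CTCF annotations plus SNP positions
#'
#' Genes are stranded intervals, roughly half placed so their 3' end
#' falls inside a planted island (exercising gene-end CGI analysis). The
#' first repeat subfamily is planted preferentially inside methylated
#' (high-beta) islands so repeat-class enrichment has signal; the rest
#' are uniform. Half the CTCF sites sit in unmethylated islands. SNPs are
#' placed at `snp_rate` per bp with `snp_cpg_fraction` of them on CpG
#' bases.
#'
#' @inheritParams simulate_methylomes
#' @return list with `genes`, `repeats`, `ctcf`, `snps`
#' @export
simulate_annotations <- function(genome, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  chroms <- names(genome)
  lens <- vapply(genome, nchar, integer(1))
  tc <- truth$true_cgis
  with_seed(substream_seed(config$seed, "annotations"), {
    rand_iv <- function(n, min_len, max_len) {
      ch <- sample(chroms, n, replace = TRUE)
      ln <- sample(seq(min_len, max_len), n, replace = TRUE)
      st <- vapply(seq_len(n), function(i)
        sample.int(lens[[ch[i]]] - ln[i], 1L) - 1L, integer(1))
      data.table(chrom = ch, start = st, end = st + ln)
    }
    # genes: half anchored with their 3' end inside an island
    n_genes <- config$n_genes
    g_len <- sample(2000:8000, n_genes, replace = TRUE)
    g_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    g <- vector("list", n_genes)
    n_anchor <- if (nrow(tc)) min(n_genes %/% 2L, nrow(tc)) else 0L
    anchor_isl <- if (n_anchor) sample.int(nrow(tc), n_anchor) else integer()
    for (i in seq_len(n_genes)) {
      if (i <= n_anchor) {
        isl <- tc[anchor_isl[i]]
        end3 <- isl$start + (isl$end - isl$start) %/% 2L
        if (g_strand[i] == "+") {
          st <- max(end3 - g_len[i], 0L); en <- end3
        } else {
          st <- end3; en <- min(end3 + g_len[i], lens[[isl$chrom]])
        }
        g[[i]] <- data.table(chrom = isl$chrom, start = st, end = en,
                             strand = g_strand[i])
      } else {
        ch <- sample(chroms, 1L)
        st <- sample.int(max(lens[[ch]] - g_len[i], 1L), 1L) - 1L
        g[[i]] <- data.table(chrom = ch, start = st, end = st + g_len[i],
                             strand = g_strand[i])
      }
    }
    genes <- rbindlist(g)
    genes[, name := sprintf("gene%03d", .I)]
    # repeats
    reps <- vector("list", 0L)
    meth_isl <- tc[tc$methylated == TRUE]
    for (si in seq_along(config$repeat_subfamilies)) {
      sf <- config$repeat_subfamilies[si]
      n_r <- config$n_repeats_per_subfamily
      if (si == 1L && nrow(meth_isl)) {
        # designated subfamily: inside methylated islands
        pick <- meth_isl[sample.int(nrow(meth_isl), n_r, replace = TRUE)]
        ln <- sample(50:150, n_r, replace = TRUE)
        st <- pick$start + vapply(seq_len(n_r), function(i)
          sample.int(max(pick$end[i] - pick$start[i] - ln[i], 1L), 1L) - 1L,
          integer(1))
        iv <- data.table(chrom = pick$chrom, start = st,
                         end = pmin(st + ln, pick$end))
      } else {
        iv <- rand_iv(n_r, 100L, 300L)
      }
      iv[, `:=`(subfamily = sf,
                class_family = if (si == 1L) "SINE" else "other")]
      reps[[length(reps) + 1L]] <- iv
    }
    repeats <- rbindlist(reps)
    # CTCF sites: half in unmethylated islands
    unmeth_isl <- tc[tc$methylated == FALSE]
    n_c <- config$n_ctcf
    ctcf <- rand_iv(n_c, 19L, 20L)
    if (nrow(unmeth_isl)) {
      n_in <- n_c %/% 2L
      pick <- unmeth_isl[sample.int(nrow(unmeth_isl), n_in, replace = TRUE)]
      st <- pick$start + vapply(seq_len(n_in), function(i)
        sample.int(max(pick$end[i] - pick$start[i] - 20L, 1L), 1L) - 1L,
        integer(1))
      ctcf[seq_len(n_in), `:=`(chrom = pick$chrom, start = st,
                               end = st + 20L)]
    }
    # SNPs
    snp_rows <- vector("list", 0L)
    if (config$snp_rate > 0) {
      cpgs <- cpg_positions(genome)
      for (ch in chroms) {
        n_snp <- round(config$snp_rate * lens[[ch]])
        if (n_snp == 0L) next
        n_on <- round(config$snp_cpg_fraction * n_snp)
        pos <- integer(0)
        ch_cpg <- cpgs[chrom == ch]$pos
        if (n_on > 0L && length(ch_cpg)) {
          at <- sample(ch_cpg, min(n_on, length(ch_cpg)))
          pos <- at + sample(0:1, length(at), replace = TRUE)  # C or G base
        }
        pos <- c(pos, sample.int(lens[[ch]], n_snp - length(pos)) - 1L)
        snp_rows[[length(snp_rows) + 1L]] <- data.table(chrom = ch,
                                                        pos = sort(pos))
      }
    }
    snps <- if (length(snp_rows)) unique(rbindlist(snp_rows)) else
      data.table(chrom = character(), pos = integer())
    list(genes = genes, repeats = repeats, ctcf = ctcf, snps = snps)
  })
}

#' Pick plantable regions: runs of CpGs dense enough to merge
#'
#' Finds non-overlapping windows of `n_cpgs` consecutive CpGs whose
#' successive gaps are all <= `gap_bp`, optionally avoiding given
#' intervals -- the natural anchors for planting DMRs, variable loci or
#' age loci whose member CpGs can later be re-merged into one region.
#'
#' @param cpgs CpG position table ([cpg_positions()])
#' @param n number of regions wanted
#' @param n_cpgs CpGs per region
#' @param gap_bp maximum within-region CpG gap (default 100)
#' @param avoid optional intervals to avoid (e.g. islands)
#' @param seed selection seed
#' @return list of `list(chrom, start, end)`, error if too few candidates
#' @export
plant_regions <- function(cpgs, n, n_cpgs, gap_bp = 100L, avoid = NULL,
                          seed = 1L) {
  x <- as.data.table(cpgs)
  setorder(x, chrom, pos)
  cands <- vector("list", 0L)
  for (ch in unique(x$chrom)) {
    pos <- x[chrom == ch]$pos
    if (length(pos) < n_cpgs) next
    gaps_ok <- diff(pos) <= gap_bp
    # window of n_cpgs consecutive CpGs: all n_cpgs - 1 gaps must be ok
    run_ok <- stats::filter(as.integer(gaps_ok), rep(1L, n_cpgs - 1L),
                            sides = 1L)
    at <- which(run_ok == n_cpgs - 1L) - (n_cpgs - 1L) + 1L
    for (s in at)
      cands[[length(cands) + 1L]] <- data.table(
        chrom = ch, start = pos[s], end = pos[s + n_cpgs - 1L] + 2L)
  }
  if (!length(cands)) config_error("no plantable CpG runs found")
  cd <- rbindlist(cands)
  if (!is.null(avoid) && nrow(as.data.table(avoid)))
    cd <- cd[!overlaps_any(cd, as.data.table(avoid))]
  picked <- vector("list", 0L)
  with_seed(seed, {
    cd <- cd[sample.int(nrow(cd))]
    for (i in seq_len(nrow(cd))) {
      if (length(picked) == n) break
      row <- cd[i]
      clash <- length(picked) &&
        any(vapply(picked, function(p)
          p$chrom == row$chrom && p$start < row$end + gap_bp &&
            row$start < p$end + gap_bp, logical(1)))
      if (!clash)
        picked[[length(picked) + 1L]] <- list(chrom = row$chrom,
                                              start = row$start,
                                              end = row$end)
    }
  })
  if (length(picked) < n)
    config_error(sprintf("only %d of %d regions plantable", length(picked),
                         n))
  picked
}

#' Run the whole simulator and optionally write all pipeline inputs
#'
#' @param config a [sim_config()]
#' @param out_dir if non-NULL, writes genome.fa, genes.bed, repeats.bed,
#'   ctcf.bed, snps.tsv, metadata.tsv, meth/<sample>.tsv and
#'   ground_truth.json there
#' @return list with genome, truth, annotations, methylomes
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  gen <- simulate_genome(config)
  ann <- simulate_annotations(gen$genome, gen$truth, config)
  met <- simulate_methylomes(gen$genome, gen$truth, config)
  gen$truth$snp_positions <- ann$snps
  gen$truth$gene_models <- ann$genes
  gen$truth$repeats <- ann$repeats
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "meth"), recursive = TRUE,
               showWarnings = FALSE)
    write_fasta(gen$genome, file.path(out_dir, "genome.fa"))
    write_bed(ann$genes[, .(chrom, start, end, name, score = 0L,
                            strand)], file.path(out_dir, "genes.bed"))
    write_bed(ann$repeats[, .(chrom, start, end, name = subfamily,
                              score = 0L, strand = ".")],
              file.path(out_dir, "repeats.bed"))
    write_bed(ann$ctcf, file.path(out_dir, "ctcf.bed"))
    fwrite(ann$snps, file.path(out_dir, "snps.tsv"), sep = "\t",
           col.names = FALSE)
    fwrite(met$metadata, file.path(out_dir, "metadata.tsv"), sep = "\t")
    for (s in names(met$tables))
      write_methylation_table(met$tables[[s]],
                              file.path(out_dir, "meth",
                                        paste0(s, ".tsv")))
    jsonlite::write_json(
      list(true_cgis = gen$truth$true_cgis,
           true_dmrs = config$planted_dmrs,
           true_variable_regions = config$planted_variable_loci,
           true_age_regions = config$planted_age_loci,
           n_snps = nrow(ann$snps)),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(genome = gen$genome, truth = gen$truth, annotations = ann,
       methylomes = met)
}
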