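#' CpG-island composition criteria
#'
#' Two printed rule sets are bundled:
#' \describe{
#'   \item{GGF (Gardiner-Garden & Frommer)}{GC ratio > 0.5, CpG
#'     observed/expected > 0.6, length > 200 bp -- all strict.}
#'   \item{Takai-Jones}{GC ratio >= 0.55, CpG O/E >= 0.65, length >= 500
#'     bp -- all inclusive.}
#' }
#'
#' @param min_gc minimum GC ratio
#' @param min_oe minimum CpG observed/expected ratio
#' @param min_length minimum island length in bp
#' @param strict if `TRUE` all three thresholds are strict (`>`), else
#'   inclusive (`>=`)
#' @param name label carried into outputs
#' @return list of class `cgi_criteria`
#' @export
cgi_criteria <- function(min_gc, min_oe, min_length, strict = FALSE,
                         name = "custom") {
  if (!(min_gc > 0 && min_gc < 1)) config_error("min_gc must be in (0,1)")
  if (min_oe <= 0) config_error("min_oe must be positive")
  if (min_length < 1) config_error("min_length must be >= 1")
  structure(list(min_gc = min_gc, min_oe = min_oe,
                 min_length = as.integer(min_length),
                 strict = isTRUE(strict), name = name),
            class = "cgi_criteria")
}

#' @rdname cgi_criteria
#' @export
ggf_criteria <- function() cgi_criteria(0.5, 0.6, 200L, strict = TRUE,
                                        name = "GGF")

#' @rdname cgi_criteria
#' @export
takai_jones_criteria <- function() cgi_criteria(0.55, 0.65, 500L,
                                                strict = FALSE,
                                                name = "TakaiJones")

# smallest admissible island length under the criteria
min_island_len <- function(criteria) {
  if (criteria$strict) criteria$min_length + 1L else criteria$min_length
}

#' Composition statistics of a DNA sequence
#'
#' GC ratio (#C + #G)/L, CpG observed/expected ratio
#' (#CpG x L)/(#C x #G) -- defined as 0 when #C or #G is 0 -- and the CpG
#' dinucleotide count.
#'
#' @param sequence a non-empty A/C/G/T(/N) string
#' @return list with `gc_ratio`, `cpg_oe`, `n_cpg`, `length`, `n_n`
#' @export
#' @examples
#' seq_stats("CGCGCG") # gc 1, oe 2, 3 CpGs
seq_stats <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    data_error("seq_stats needs one non-empty sequence")
  b <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  seq_stats_vec(b, 1L, length(b))
}

# stats over bases[s:e] of a pre-split base vector (internal fast path)
seq_stats_vec <- function(bases, s, e) {
  seg <- bases[s:e]
  L <- e - s + 1L
  nc <- sum(seg == "C"); ng <- sum(seg == "G")
  ncpg <- if (L >= 2L) sum(seg[-L] == "C" & seg[-1L] == "G") else 0L
  list(gc_ratio = (nc + ng) / L,
       cpg_oe = if (nc == 0L || ng == 0L) 0 else ncpg * L / (nc * ng),
       n_cpg = as.integer(ncpg), length = L, n_n = sum(seg == "N"))
}

# prefix-sum index over one chromosome for O(1) window stats
cgi_index <- function(sequence) {
  b <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  isC <- b == "C"; isG <- b == "G"
  L <- length(b)
  list(L = L,
       cumC = cumsum(isC), cumG = cumsum(isG),
       cumGC = cumsum(isC | isG),
       cumCpG = cumsum(c(isC[-L] & isG[-1L], FALSE)),
       cumN = cumsum(b == "N"))
}

# window [s, e] 1-based closed; returns gc, oe, n, ncpg
idx_stats <- function(ix, s, e) {
  at <- function(cs, i) if (i == 0L) 0L else cs[i]
  len <- e - s + 1L
  nc <- at(ix$cumC, e) - at(ix$cumC, s - 1L)
  ng <- at(ix$cumG, e) - at(ix$cumG, s - 1L)
  gc <- (at(ix$cumGC, e) - at(ix$cumGC, s - 1L)) / len
  # CpG starting positions within [s, e-1]
  ncpg <- if (len >= 2L) at(ix$cumCpG, e - 1L) - at(ix$cumCpG, s - 1L) else 0L
  list(gc = gc,
       oe = if (nc == 0L || ng == 0L) 0 else ncpg * len / (nc * ng),
       nn = at(ix$cumN, e) - at(ix$cumN, s - 1L),
       ncpg = ncpg)
}

idx_qualifies <- function(ix, s, e, cr) {
  len <- e - s + 1L
  if (if (cr$strict) len <= cr$min_length else len < cr$min_length)
    return(FALSE)
  st <- idx_stats(ix, s, e)
  if (st$nn > 0L) return(FALSE)
  if (cr$strict) st$gc > cr$min_gc && st$oe > cr$min_oe
  else st$gc >= cr$min_gc && st$oe >= cr$min_oe
}

#' Detect CpG islands de novo under composition criteria
#'
#' Deterministic seed-merge-trim scan. A window of the minimum admissible
#' length slides in 1 bp steps; qualifying windows are seeds; overlapping
#' or adjacent seeds are merged; each merged region is greedily trimmed
#' (removing the end whose removal raises the CpG O/E more; ties trim the
#' 3' end) until it satisfies all thresholds, then extended 1 bp at a time
#' within its merged region while it keeps qualifying (the side raising
#' O/E more first; ties extend 5'). Windows containing N are disqualified.
#' Returned islands are disjoint, each satisfies the criteria, and each is
#' maximal under 1 bp extension within its merged seed region.
#'
#' @param genome named character vector of chromosome sequences
#' @param criteria a [cgi_criteria()] object
#' @return `gintervals` with extra columns `gc_ratio`, `cpg_oe`, `n_cpg`
#' @export
detect_cgis <- function(genome, criteria = ggf_criteria()) {
  if (!inherits(criteria, "cgi_criteria"))
    config_error("criteria must be a cgi_criteria object")
  out <- vector("list", 0L)
  for (ch in names(genome)) {
    ix <- cgi_index(genome[[ch]])
    w <- min_island_len(criteria)
    if (ix$L < w) next
    # vectorized seed scan over all windows of width w
    starts <- seq_len(ix$L - w + 1L)
    ends <- starts + w - 1L
    win_sum <- function(cs, s, e) cs[e] - c(0L, cs)[s]
    nc <- win_sum(ix$cumC, starts, ends)
    ng <- win_sum(ix$cumG, starts, ends)
    gc <- win_sum(ix$cumGC, starts, ends) / w
    ncpg <- win_sum(ix$cumCpG, starts, pmax(ends - 1L, starts))
    oe <- ifelse(nc == 0L | ng == 0L, 0, ncpg * w / (nc * ng))
    nn <- win_sum(ix$cumN, starts, ends)
    ok <- if (criteria$strict) gc > criteria$min_gc & oe > criteria$min_oe
          else gc >= criteria$min_gc & oe >= criteria$min_oe
    ok <- ok & nn == 0L
    if (!any(ok)) next
    # merge overlapping/adjacent seed windows into regions
    ss <- starts[ok]
    gaps <- which(diff(ss) > w)
    reg_start <- ss[c(1L, gaps + 1L)]
    reg_end <- ss[c(gaps, length(ss))] + w - 1L
    for (k in seq_along(reg_start)) {
      isl <- refine_island(ix, reg_start[k], reg_end[k], criteria, w)
      if (is.null(isl)) next
      st <- idx_stats(ix, isl[1], isl[2])
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, start = isl[1] - 1L, end = isl[2],
        strand = ".", gc_ratio = st$gc, cpg_oe = st$oe, n_cpg = st$ncpg)
    }
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L)
    res <- data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      gc_ratio = numeric(), cpg_oe = numeric(),
                      n_cpg = integer())
  class(res) <- c("gintervals", class(res))
  res[]
}

# trim-then-extend refinement of one merged region [s0, e0] (1-based closed)
refine_island <- function(ix, s0, e0, cr, w) {
  s <- s0; e <- e0
  # greedy trim until qualifying
  while (!idx_qualifies(ix, s, e, cr)) {
    if (e - s + 1L <= w) {
      # greedy trim overshot: fall back to the leftmost qualifying seed
      # window inside the merged region (one exists by construction)
      s <- NA_integer_
      for (cand in s0:(e0 - w + 1L)) {
        if (idx_qualifies(ix, cand, cand + w - 1L, cr)) {
          s <- cand; e <- cand + w - 1L; break
        }
      }
      if (is.na(s)) return(NULL)
      break
    }
    oe_l <- idx_stats(ix, s + 1L, e)$oe  # O/E after trimming 5' base
    oe_r <- idx_stats(ix, s, e - 1L)$oe  # O/E after trimming 3' base
    if (oe_l > oe_r) s <- s + 1L else e <- e - 1L
  }
  # extend within the merged region while still qualifying
  repeat {
    can_l <- s > s0 && idx_qualifies(ix, s - 1L, e, cr)
    can_r <- e < e0 && idx_qualifies(ix, s, e + 1L, cr)
    if (can_l && can_r) {
      if (idx_stats(ix, s - 1L, e)$oe >= idx_stats(ix, s, e + 1L)$oe)
        s <- s - 1L else e <- e + 1L
    } else if (can_l) s <- s - 1L
    else if (can_r) e <- e + 1L
    else break
  }
  c(s, e)
}

#' Classify a CpG island by its mean methylation level
#'
#' Mean beta is the mean over the island's filtered CpG sites of per-site
#' means across samples; classes follow the printed thresholds:
#' unmethylated `[0, 0.1)`, low `[0.1, 0.5]`, high `(0.5, 1]`.
#'
#' @param mean_beta one or more island-level mean beta values
#' @return character vector of classes; `NA` for `NA` input (unscorable)
#' @export
classify_cgi_methylation <- function(mean_beta) {
  if (any(mean_beta < 0 | mean_beta > 1, na.rm = TRUE))
    data_error("mean_beta outside [0,1]")
  out <- ifelse(is.na(mean_beta), NA_character_,
                ifelse(mean_beta < 0.1, "unmethylated",
                       ifelse(mean_beta <= 0.5, "low", "high")))
  out
}

#' Score CGIs with methylation level and class
#'
#' @param cgis interval table of islands
#' @param matrix a filtered [cpg_matrix] (complete beta rows)
#' @return `cgis` with `mean_beta`, `meth_class`, `n_sites` columns added
#' @export
score_cgis <- function(cgis, matrix) {
  x <- as.data.table(copy(cgis))
  site_mean <- rowMeans(beta_values(matrix))
  sites <- data.table(chrom = matrix$sites$chrom,
                      start = matrix$sites$pos,
                      end = matrix$sites$pos + 1L)
  hits <- interval_overlap(sites, x)
  mb <- rep(NA_real_, nrow(x)); ns <- integer(nrow(x))
  if (nrow(hits)) {
    agg <- hits[, .(mb = mean(site_mean[query]), n = .N), by = subject]
    mb[agg$subject] <- agg$mb; ns[agg$subject] <- agg$n
  }
  x[, `:=`(mean_beta = mb, n_sites = ns,
           meth_class = classify_cgi_methylation(mb))]
  class(x) <- c("gintervals", class(x))
  x[]
}

#' Build the genomic feature catalog
#'
#' Promoters are `promoter_bp` upstream of each gene (strand-resolved);
#' shores are the 0-2 kb flanks outside each CGI and shelves the next
#' 2 kb; everything is clipped to chromosome bounds. Features may overlap
#' each other; `others` is the complement of their union.
#'
#' @param genes strand-aware gene intervals
#' @param cgis CGI intervals
#' @param ctcf CTCF-site intervals
#' @param repeats repeat intervals
#' @param chrom_sizes named integer vector of chromosome lengths
#' @param promoter_bp,shore_bp,shelf_bp widths in bp
#' @return list of class `feature_catalog` with one interval table per
#'   feature: promoters, gene_bodies, cgis, shores, shelves, ctcf_sites,
#'   repeats, others
#' @export
build_feature_catalog <- function(genes, cgis, ctcf, repeats, chrom_sizes,
                                  promoter_bp = 1500L, shore_bp = 2000L,
                                  shelf_bp = 2000L) {
  g <- as.data.table(genes)
  if (nrow(g) && !all(g$strand %in% c("+", "-")))
    data_error("genes must be stranded (+/-)")
  clip <- function(x) {
    if (nrow(x) == 0L) return(x)
    x[, `:=`(start = pmax(start, 0L),
             end = pmin(end, chrom_sizes[chrom]))]
    x <- x[start < end]
    x
  }
  prom <- if (nrow(g)) clip(data.table(
    chrom = g$chrom,
    start = ifelse(g$strand == "+", g$start - promoter_bp, g$end),
    end = ifelse(g$strand == "+", g$start, g$end + promoter_bp),
    strand = g$strand)) else empty_iv()
  ci <- as.data.table(cgis)
  flank <- function(off1, off2) {
    if (nrow(ci) == 0L) return(empty_iv())
    clip(rbindlist(list(
      data.table(chrom = ci$chrom, start = ci$start - off2,
                 end = ci$start - off1, strand = "."),
      data.table(chrom = ci$chrom, start = ci$end + off1,
                 end = ci$end + off2, strand = "."))))
  }
  shores <- flank(0L, shore_bp)
  shelves <- flank(shore_bp, shore_bp + shelf_bp)
  feats <- list(promoters = prom,
                gene_bodies = as_iv(g),
                cgis = as_iv(ci),
                shores = shores, shelves = shelves,
                ctcf_sites = as_iv(as.data.table(ctcf)),
                repeats = as_iv(as.data.table(repeats)))
  feats$others <- interval_complement(
    rbindlist(lapply(feats, function(f)
      f[, c("chrom", "start", "end"), with = FALSE])), chrom_sizes)
  structure(feats, class = "feature_catalog")
}

empty_iv <- function() data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character())

as_iv <- function(x) {
  if (nrow(x) == 0L) return(empty_iv())
  out <- x[, c("chrom", "start", "end"), with = FALSE]
  out[, `:=`(strand = if ("strand" %in% names(x)) x$strand else ".")]
  out
}

# complement of the union of intervals within chromosome bounds
interval_complement <- function(ivs, chrom_sizes) {
  out <- vector("list", 0L)
  for (ch in names(chrom_sizes)) {
    sub <- ivs[ivs$chrom == ch]
    L <- chrom_sizes[[ch]]
    if (nrow(sub) == 0L) {
      out[[length(out) + 1L]] <- data.table(chrom = ch, start = 0L, end = L,
                                            strand = ".")
      next
    }
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = L)
    if (length(gaps))
      out[[length(out) + 1L]] <- data.table(
        chrom = ch, start = IRanges::start(gaps) - 1L,
        end = IRanges::end(gaps), strand = ".")
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) res <- empty_iv()
  res[]
}

#' Is there a CGI at each gene's 3' terminus?
#'
#' True iff any CGI overlaps `[gene_end - window_bp, gene_end + window_bp)`
#' where `gene_end` is the strand-resolved 3' coordinate (the `end` of a
#' `+` gene, the `start` of a `-` gene).
#'
#' @param genes strand-aware gene intervals
#' @param cgis CGI intervals
#' @param window_bp half-window around the 3' end (default 2000)
#' @return logical vector along genes
#' @export
gene_end_cgi_presence <- function(genes, cgis, window_bp = 2000L) {
  g <- as.data.table(genes)
  if (nrow(g) == 0L) return(logical())
  if (!all(g$strand %in% c("+", "-"))) data_error("genes must be stranded")
  end3 <- ifelse(g$strand == "+", g$end, g$start)
  win <- data.table(chrom = g$chrom,
                    start = pmax(end3 - window_bp, 0L),
                    end = end3 + window_bp)
  win <- win[, `:=`(end = pmax(end, start + 1L))]
  overlaps_any(win, as.data.table(cgis))
}
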