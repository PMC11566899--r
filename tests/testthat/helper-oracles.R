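# Independent brute-force oracles. These deliberately avoid the package's
# fast paths (prefix sums, interval indexes, vectorized closed forms) so
# that agreement is evidence, not tautology.

# --- sequence statistics by direct recounting of the interval -----------
# (no prefix sums or sliding updates: every interval is counted afresh)
oracle_stats <- function(bases, s, e) {
  seg <- bases[s:e]
  L <- length(seg)
  nc <- sum(seg == "C"); ng <- sum(seg == "G"); nn <- sum(seg == "N")
  ncpg <- if (L >= 2L) sum(seg[-L] == "C" & seg[-1L] == "G") else 0L
  list(gc = (nc + ng) / L,
       oe = if (nc == 0L || ng == 0L) 0 else ncpg * L / (nc * ng),
       nn = nn)
}

oracle_qualifies <- function(bases, s, e, cr) {
  len <- e - s + 1L
  len_ok <- if (cr$strict) len > cr$min_length else len >= cr$min_length
  if (!len_ok) return(FALSE)
  st <- oracle_stats(bases, s, e)
  if (st$nn > 0L) return(FALSE)
  if (cr$strict) st$gc > cr$min_gc && st$oe > cr$min_oe
  else st$gc >= cr$min_gc && st$oe >= cr$min_oe
}

# Naive reimplementation of the seed-merge-trim-extend definition with all
# statistics recomputed by direct counting (O(L^2) overall).
oracle_detect_cgis <- function(sequence, cr) {
  bases <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(bases)
  w <- if (cr$strict) cr$min_length + 1L else cr$min_length
  if (L < w) return(matrix(integer(0), ncol = 2))
  seeds <- integer(0)
  for (s in 1:(L - w + 1L))
    if (oracle_qualifies(bases, s, s + w - 1L, cr)) seeds <- c(seeds, s)
  if (!length(seeds)) return(matrix(integer(0), ncol = 2))
  regions <- list(); cur <- c(seeds[1], seeds[1] + w - 1L)
  for (s in seeds[-1]) {
    if (s <= cur[2] + 1L) cur[2] <- s + w - 1L
    else { regions[[length(regions) + 1L]] <- cur; cur <- c(s, s + w - 1L) }
  }
  regions[[length(regions) + 1L]] <- cur
  out <- matrix(integer(0), ncol = 2)
  for (r in regions) {
    s <- r[1]; e <- r[2]
    fell_back <- FALSE
    while (!oracle_qualifies(bases, s, e, cr)) {
      if (e - s + 1L <= w) {
        s <- NA
        for (cand in r[1]:(r[2] - w + 1L))
          if (oracle_qualifies(bases, cand, cand + w - 1L, cr)) {
            s <- cand; e <- cand + w - 1L; break
          }
        fell_back <- TRUE
        break
      }
      oel <- oracle_stats(bases, s + 1L, e)$oe
      oer <- oracle_stats(bases, s, e - 1L)$oe
      if (oel > oer) s <- s + 1L else e <- e - 1L
    }
    if (is.na(s)) next
    repeat {
      cl <- s > r[1] && oracle_qualifies(bases, s - 1L, e, cr)
      crr <- e < r[2] && oracle_qualifies(bases, s, e + 1L, cr)
      if (cl && crr) {
        if (oracle_stats(bases, s - 1L, e)$oe >=
            oracle_stats(bases, s, e + 1L)$oe) s <- s - 1L else e <- e + 1L
      } else if (cl) s <- s - 1L
      else if (crr) e <- e + 1L
      else break
    }
    out <- rbind(out, c(s - 1L, e))   # convert to 0-based half-open
  }
  out
}

# --- all-pairs interval overlap -----------------------------------------
oracle_overlap <- function(q, s) {
  hits <- matrix(integer(0), ncol = 2)
  for (i in seq_len(nrow(q))) for (j in seq_len(nrow(s))) {
    if (q$chrom[i] == s$chrom[j] && q$start[i] < s$end[j] &&
        s$start[j] < q$end[i])
      hits <- rbind(hits, c(i, j))
  }
  hits
}

# --- greedy run chaining by explicit loop -------------------------------
oracle_merge_runs <- function(chrom, pos, gap, min_n) {
  o <- order(chrom, pos); chrom <- chrom[o]; pos <- pos[o]
  out <- data.frame(chrom = character(), start = integer(),
                    end = integer(), n = integer())
  i <- 1L
  while (i <= length(pos)) {
    j <- i
    while (j < length(pos) && chrom[j + 1L] == chrom[j] &&
           pos[j + 1L] - pos[j] <= gap) j <- j + 1L
    if (j - i + 1L >= min_n)
      out <- rbind(out, data.frame(chrom = chrom[i], start = pos[i],
                                   end = pos[j] + 1L, n = j - i + 1L))
    i <- j + 1L
  }
  out
}

# --- exact tails by term-wise summation (log-space binomials) -----------
oracle_binom_upper <- function(x, n, p) {
  if (x > n) return(0)
  k <- x:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

oracle_binom_lower <- function(x, n, p) {
  k <- 0:x
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

oracle_hyper_upper <- function(x, N, K, n) {
  k <- x:min(K, n)
  if (!length(k)) return(0)
  sum(exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)))
}

# --- BH step-up straight from the definition ----------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    pi <- p[o[i]]
    cand <- Inf
    for (j in seq_len(n)) {
      pj <- p[o[j]]
      if (pj >= pi) cand <- min(cand, pj * n / j)
    }
    q[o[i]] <- min(1, cand)
  }
  q
}

# --- random DNA ----------------------------------------------------------
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
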