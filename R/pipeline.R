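#' Configuration-driven pipeline and command-line interface
#'
#' `islandmeth_cli()` is the package's command-line surface:
#'
#' ```
#' islandmeth <subcommand> --config cfg.json --out DIR [--seed N]
#' ```
#'
#' Subcommands: `simulate`, `qc`, `cgi`, `dmr`, `varreg`, `enrich`,
#' `embed`, `all`. Each reads/writes only documented text formats under
#' the output directory; `all` chains
#' simulate -> qc -> cgi -> dmr -> varreg -> enrich -> embed. Every run
#' writes a `manifest_<stage>.json` (config echo, seed, package version,
#' input checksums). Exit codes: 0 success, 2 configuration/usage error
#' (missing input, unknown flag), 3 data/invariant error.
#'
#' The JSON config has one section per stage (`simulate`, `qc`, `cgi`,
#' `dmr`, `varreg`, `enrich`, `embed`) plus a global `seed`; flags
#' override config values.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments)
#' @return integer exit code, invisibly
#' @export
islandmeth_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    run_cli(args)
    0L
  },
  islandmeth_config_error = function(e) {
    message("config error: ", conditionMessage(e)); 2L
  },
  islandmeth_data_error = function(e) {
    message("data error: ", conditionMessage(e)); 3L
  },
  error = function(e) {
    message("error: ", conditionMessage(e)); 1L
  })
  invisible(code)
}

cli_usage <- function() {
  paste("usage: islandmeth <simulate|qc|cgi|dmr|varreg|enrich|embed|all>",
        "--config cfg.json --out DIR [--seed N]")
}

run_cli <- function(args) {
  subcommands <- c("simulate", "qc", "cgi", "dmr", "varreg", "enrich",
                   "embed", "all")
  if (length(args) < 1L || !args[1] %in% subcommands) {
    message(cli_usage())
    config_error(sprintf("unknown subcommand: %s",
                         if (length(args)) args[1] else "<none>"))
  }
  sub <- args[1]; rest <- args[-1]
  opts <- list(config = NULL, out = NULL, seed = NULL)
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[i]
    if (!key %in% c("--config", "--out", "--seed") ||
        i + 1L > length(rest)) {
      message(cli_usage())
      config_error(sprintf("unknown or incomplete flag: %s", key))
    }
    opts[[sub("^--", "", key)]] <- rest[i + 1L]
    i <- i + 2L
  }
  if (is.null(opts$out)) config_error("--out is required")
  cfg <- if (!is.null(opts$config)) {
    if (!file.exists(opts$config))
      config_error(sprintf("missing input: %s", opts$config))
    jsonlite::read_json(opts$config, simplifyVector = TRUE)
  } else list()
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  cfg$seed <- cfg$seed %||% 1L
  run_pipeline(sub, cfg, opts$out)
}

#' Run one pipeline stage (or all) programmatically
#'
#' @param stage stage name (see [islandmeth_cli()])
#' @param cfg configuration list (per-stage sections + global `seed`)
#' @param out_dir output directory (created if absent)
#' @return invisibly, the output directory
#' @export
run_pipeline <- function(stage, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all")
    c("simulate", "qc", "cgi", "dmr", "varreg", "enrich", "embed")
  else stage
  for (st in stages) {
    log_line(out_dir, st, "start")
    switch(st,
           simulate = stage_simulate(cfg, out_dir),
           qc = stage_qc(cfg, out_dir),
           cgi = stage_cgi(cfg, out_dir),
           dmr = stage_dmr(cfg, out_dir),
           varreg = stage_varreg(cfg, out_dir),
           enrich = stage_enrich(cfg, out_dir),
           embed = stage_embed(cfg, out_dir))
    log_line(out_dir, st, "done")
  }
  invisible(out_dir)
}

log_line <- function(out_dir, stage, what) {
  cat(sprintf("[%s] %s %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage, what),
      file = file.path(out_dir, "pipeline.log"), append = TRUE)
}

write_manifest <- function(out_dir, stage, cfg, inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(stage = stage, seed = cfg$seed,
         package_version = as.character(utils::packageVersion("islandmeth")),
         config = cfg, input_md5 = sums),
    file.path(out_dir, sprintf("manifest_%s.json", stage)),
    auto_unbox = TRUE, digits = NA, null = "null")
}

stage_simulate <- function(cfg, out_dir) {
  sc <- do.call(sim_config, c(list(seed = cfg$seed),
                              cfg$simulate %||% list()))
  simulate_dataset(sc, file.path(out_dir, "sim"))
  write_manifest(out_dir, "simulate", cfg)
  invisible(NULL)
}

sim_dir <- function(cfg, out_dir) {
  d <- cfg$input_dir %||% file.path(out_dir, "sim")
  if (!dir.exists(d))
    config_error(sprintf("missing input directory: %s (run simulate first)", d))
  d
}

load_filtered_beta <- function(out_dir) {
  path <- file.path(out_dir, "beta_filtered.tsv")
  if (!file.exists(path))
    config_error(sprintf("missing input: %s (run qc first)", path))
  x <- fread(path, sep = "\t")
  list(sites = x[, .(chrom, pos)],
       beta = as.matrix(x[, -(1:2)]))
}

stage_qc <- function(cfg, out_dir) {
  sd <- sim_dir(cfg, out_dir)
  qc <- cfg$qc %||% list()
  meta <- read_sample_metadata(file.path(sd, "metadata.tsv"))
  files <- file.path(sd, "meth", paste0(meta$sample_id, ".tsv"))
  tables <- lapply(files, read_methylation_table, dialect = "collapsed")
  names(tables) <- meta$sample_id
  mat <- build_matrix(tables)
  mat <- apply_quality_filters(mat,
                               min_depth = qc$min_depth %||% 10L,
                               max_depth = qc$max_depth %||% 500L)
  stats <- attr(mat, "filter_stats")
  snps <- read_snp_positions(file.path(sd, "snps.tsv"))
  mat <- mask_snps_and_chroms(mat, snps,
                              drop_chroms = qc$drop_chroms %||% character())
  beta <- beta_values(mat)
  out <- cbind(mat$sites, as.data.table(round(beta, 6)))
  fwrite(out, file.path(out_dir, "beta_filtered.tsv"), sep = "\t")
  rho <- pairwise_spearman(beta)
  fwrite(as.data.table(rho, keep.rownames = "sample"),
         file.path(out_dir, "spearman.tsv"), sep = "\t")
  jsonlite::write_json(as.list(stats),
                       file.path(out_dir, "filter_stats.json"),
                       auto_unbox = TRUE)
  write_manifest(out_dir, "qc", cfg, c(files, file.path(sd, "snps.tsv")))
  invisible(NULL)
}

stage_cgi <- function(cfg, out_dir) {
  sd <- sim_dir(cfg, out_dir)
  genome <- read_fasta(file.path(sd, "genome.fa"))
  crit <- switch(cfg$cgi$criteria %||% "ggf",
                 ggf = ggf_criteria(),
                 takai_jones = takai_jones_criteria(),
                 config_error("cgi$criteria must be ggf or takai_jones"))
  cgis <- detect_cgis(genome, crit)
  fb <- load_filtered_beta(out_dir)
  site_mean <- rowMeans(fb$beta)
  hits <- interval_overlap(data.table(chrom = fb$sites$chrom,
                                      start = fb$sites$pos,
                                      end = fb$sites$pos + 1L), cgis)
  mb <- rep(NA_real_, nrow(cgis))
  if (nrow(hits)) {
    agg <- hits[, .(m = mean(site_mean[query])), by = subject]
    mb[agg$subject] <- agg$m
  }
  cgis[, `:=`(mean_beta = mb, meth_class = classify_cgi_methylation(mb))]
  out <- cgis[, .(chrom, start, end,
                  name = ifelse(is.na(meth_class), "unscorable", meth_class),
                  score = ifelse(is.na(mean_beta), 0L,
                                 as.integer(round(1000 * mean_beta))),
                  strand = ".", gc_ratio, cpg_oe, n_cpg)]
  fwrite(out, file.path(out_dir, "cgis.bed"), sep = "\t",
         col.names = FALSE)
  write_manifest(out_dir, "cgi", cfg, file.path(sd, "genome.fa"))
  invisible(NULL)
}

stage_dmr <- function(cfg, out_dir) {
  sd <- sim_dir(cfg, out_dir)
  fb <- load_filtered_beta(out_dir)
  meta <- read_sample_metadata(file.path(sd, "metadata.tsv"))
  meta <- meta[match(colnames(fb$beta), sample_id)]
  st <- anova_per_cpg(fb$beta, meta$breed, sites = fb$sites)
  dmcs <- call_dmcs(st, cfg$dmr$fdr %||% 0.05)
  dmrs <- merge_runs(dmcs, gap_bp = cfg$dmr$gap_bp %||% 100L,
                     min_count = cfg$dmr$min_dmcs %||% 5L)
  write_bed(dmrs[, .(chrom, start, end, name = "dmr", score = n_sites,
                     strand = ".")], file.path(out_dir, "dmrs.bed"))
  write_manifest(out_dir, "dmr", cfg)
  invisible(NULL)
}

stage_varreg <- function(cfg, out_dir) {
  sd <- sim_dir(cfg, out_dir)
  fb <- load_filtered_beta(out_dir)
  meta <- read_sample_metadata(file.path(sd, "metadata.tsv"))
  meta <- meta[match(colnames(fb$beta), sample_id)]
  sds <- sd_per_cpg(fb$beta)
  thr <- top_fraction_threshold(sds, cfg$varreg$fraction %||% 0.01)
  high <- fb$sites[sds >= thr]
  regions <- merge_runs(high, gap_bp = cfg$varreg$gap_bp %||% 100L,
                        min_count = cfg$varreg$min_cpgs %||% 5L)
  write_bed(regions[, .(chrom, start, end, name = "varreg",
                        score = n_sites, strand = ".")],
            file.path(out_dir, "variable_regions.bed"))
  if (nrow(regions)) {
    assoc <- associate_regions(regions, fb$beta, fb$sites, meta,
                               alpha = cfg$varreg$alpha %||% 0.01)
    fwrite(assoc, file.path(out_dir, "variable_region_assoc.tsv"),
           sep = "\t")
  }
  write_manifest(out_dir, "varreg", cfg)
  invisible(NULL)
}

stage_enrich <- function(cfg, out_dir) {
  sd <- sim_dir(cfg, out_dir)
  fb <- load_filtered_beta(out_dir)
  genes <- read_bed(file.path(sd, "genes.bed"))
  repeats <- read_bed(file.path(sd, "repeats.bed"))
  setnames(repeats, "name", "subfamily")
  ctcf <- read_bed(file.path(sd, "ctcf.bed"))
  cgis <- fread(file.path(out_dir, "cgis.bed"), sep = "\t",
                col.names = c("chrom", "start", "end", "meth_class",
                              "score", "strand", "gc_ratio", "cpg_oe",
                              "n_cpg"))
  genome <- read_fasta(file.path(sd, "genome.fa"))
  sizes <- vapply(genome, nchar, integer(1))
  catalog <- build_feature_catalog(genes, cgis, ctcf, repeats, sizes)
  sds <- sd_per_cpg(fb$beta)
  thr <- top_fraction_threshold(sds, cfg$enrich$fraction %||% 0.01)
  fe <- feature_enrichment(fb$sites[sds >= thr], fb$sites, catalog)
  fwrite(fe, file.path(out_dir, "feature_enrichment.tsv"), sep = "\t")
  scored <- cgis[meth_class != "unscorable"]
  if (nrow(scored)) {
    re <- repeat_class_enrichment(scored, repeats,
                                  min_regions = cfg$enrich$min_regions %||% 2L)
    fwrite(re, file.path(out_dir, "repeat_enrichment.tsv"), sep = "\t")
  }
  write_manifest(out_dir, "enrich", cfg)
  invisible(NULL)
}

stage_embed <- function(cfg, out_dir) {
  sd <- sim_dir(cfg, out_dir)
  genome <- read_fasta(file.path(sd, "genome.fa"))
  cgis <- fread(file.path(out_dir, "cgis.bed"), sep = "\t",
                col.names = c("chrom", "start", "end", "meth_class",
                              "score", "strand", "gc_ratio", "cpg_oe",
                              "n_cpg"))
  if (nrow(cgis) == 0L) config_error("no CGIs to embed (run cgi first)")
  seqs <- vapply(seq_len(nrow(cgis)), function(i)
    substr(genome[[cgis$chrom[i]]], cgis$start[i] + 1L, cgis$end[i]),
    character(1))
  names(seqs) <- sprintf("%s:%d-%d", cgis$chrom, cgis$start, cgis$end)
  ec <- cfg$embed %||% list()
  tok <- train_bpe(seqs, vocab_size = ec$vocab_size %||% 512L)
  write_tokenizer(tok, file.path(out_dir, "tokenizer.json"))
  tk <- tokenize_and_filter(seqs, tok, max_tokens = ec$max_tokens %||% 512L)
  if (!length(tk$tokens)) config_error("all sequences exceeded max_tokens")
  mc <- mlm_config(embed_dim = ec$embed_dim %||% 64L,
                   n_layers = ec$n_layers %||% 2L,
                   n_heads = ec$n_heads %||% 4L,
                   epochs = ec$epochs %||% 10L,
                   max_tokens = ec$max_tokens %||% 512L,
                   seed = cfg$seed)
  model <- train_mlm(tk$tokens, tok$vocab_size, mc)
  write_mlm(model, file.path(out_dir, "mlm_model.rds"))
  emb <- embed_cgis(tk$tokens, model)
  fwrite(data.table(cgi_id = rownames(emb), as.data.table(emb)),
         file.path(out_dir, "embeddings.tsv"), sep = "\t")
  n <- nrow(emb)
  perp <- min(ec$perplexity %||% 30, floor((n - 1) / 3.5))
  if (perp >= 2) {
    xy <- project_tsne(emb, perplexity = perp,
                       n_iter = ec$tsne_iter %||% 500L, seed = cfg$seed)
    fwrite(data.table(cgi_id = rownames(emb), tsne1 = xy[, 1],
                      tsne2 = xy[, 2]),
           file.path(out_dir, "tsne.tsv"), sep = "\t")
  } else {
    message("too few CGIs for t-SNE; skipped")
  }
  write_manifest(out_dir, "embed", cfg, file.path(sd, "genome.fa"))
  invisible(NULL)
}
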