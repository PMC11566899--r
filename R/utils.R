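#' @importFrom data.table data.table as.data.table setkey setkeyv := rbindlist setorder fread fwrite setnames copy .N .SD .I
#' @importFrom stats pf pbinom phyper rbeta rbinom rnbinom runif rnorm sd cor pnorm qnorm binomial glm.fit model.matrix cor.test dist rpois
#' @importFrom utils head tail packageVersion
NULL

# condition constructors: config errors (bad parameters) vs data errors
# (malformed or inconsistent inputs); the CLI maps them to exit codes 2 / 3.
config_error <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("islandmeth_config_error", "error", "condition"),
                 list(message = msg, call = call)))
}

data_error <- function(msg, call = sys.call(-1)) {
  stop(structure(class = c("islandmeth_data_error", "error", "condition"),
                 list(message = msg, call = call)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named RNG substream seed from a master seed
#'
#' All randomness in the simulator flows from one master seed through named
#' substreams so that genome, counts and annotations can be regenerated
#' independently and deterministically.
#'
#' @param seed master integer seed
#' @param stream substream name
#' @return an integer seed below 2^31
#' @keywords internal
substream_seed <- function(seed, stream = c("genome", "counts", "annotations",
                                            "metadata", "model", "other")) {
  stream <- match.arg(stream)
  offset <- c(genome = 101L, counts = 20003L, annotations = 300007L,
              metadata = 4000037L, model = 50000017L, other = 600000011L)
  as.integer((as.numeric(seed) * 31L + offset[[stream]]) %% 2147483647)
}

# local RNG scope: run code under a seed without clobbering the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
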