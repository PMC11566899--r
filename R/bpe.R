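#' Train a byte-pair-encoding tokenizer on DNA sequences
#'
#' Native merge-based BPE: the vocabulary starts from the single bases
#' A/C/G/T; the most frequent adjacent token pair over the corpus is
#' repeatedly merged into a new token until `vocab_size` entries exist or
#' no pair occurs at least twice. Ties are broken by the
#' lexicographically smallest (left, right) string pair, making training
#' deterministic across platforms.
#'
#' @param sequences character vector of A/C/G/T sequences
#' @param vocab_size target vocabulary size (>= 4)
#' @param seed unused (training is deterministic); kept for interface
#'   stability
#' @return object of class `bpe_tokenizer`: `vocab` (ordered strings) and
#'   `merges` (ordered two-column matrix of token indices)
#' @export
train_bpe <- function(sequences, vocab_size = 8192L, seed = 1L) {
  alphabet <- c("A", "C", "G", "T")
  if (vocab_size < length(alphabet))
    config_error("vocab_size below alphabet size")
  if (!length(sequences) || any(!nzchar(sequences)))
    data_error("need non-empty sequences")
  if (any(grepl("[^ACGT]", sequences)))
    data_error("sequences must be A/C/G/T only")
  toks <- corpus_as_ints(sequences, alphabet)
  vocab <- alphabet
  merges <- matrix(integer(0), ncol = 2L)
  K <- vocab_size + 1L   # pair-id base; token ids never exceed vocab_size
  while (length(vocab) < vocab_size) {
    left <- toks[-length(toks)]; right <- toks[-1L]
    valid <- left != 0L & right != 0L
    if (!any(valid)) break
    pair_id <- left[valid] * K + right[valid]
    nbins <- (length(vocab) + 1L) * K
    if (nbins <= 8e6) {          # dense counting for desk-scale vocabs
      cnt <- tabulate(pair_id, nbins = nbins)
      best_n <- max(cnt)
      if (best_n < 2L) break
      cand <- which(cnt == best_n)
    } else {                     # sparse counting for large vocabularies
      tb <- data.table(id = pair_id)[, .N, by = id]
      best_n <- max(tb$N)
      if (best_n < 2L) break
      cand <- tb[N == best_n]$id
    }
    lefts <- cand %/% K; rights <- cand %% K
    pick <- order(vocab[lefts], vocab[rights])[1L]
    a <- lefts[pick]; b <- rights[pick]
    new_id <- length(vocab) + 1L
    vocab <- c(vocab, paste0(vocab[a], vocab[b]))
    merges <- rbind(merges, c(a, b))
    toks <- apply_merge(toks, a, b, new_id)
  }
  structure(list(vocab = vocab, merges = merges,
                 vocab_size = length(vocab)),
            class = "bpe_tokenizer")
}

# flatten sequences into one integer vector with 0 separators
corpus_as_ints <- function(sequences, alphabet) {
  per <- lapply(sequences, function(s)
    c(match(strsplit(s, "", fixed = TRUE)[[1]], alphabet), 0L))
  head(unlist(per), -1L)
}

# replace left-to-right non-overlapping occurrences of (a, b) by new_id
apply_merge <- function(toks, a, b, new_id) {
  idx <- which(toks[-length(toks)] == a & toks[-1L] == b)
  if (!length(idx)) return(toks)
  if (a == b) {
    # runs like (a a a) merge greedily left-to-right: keep 1st, 3rd, ...
    run <- cumsum(c(1L, as.integer(diff(idx) != 1L)))
    keep <- unlist(lapply(split(idx, run), function(r)
      r[seq(1L, length(r), by = 2L)]), use.names = FALSE)
    idx <- keep
  }
  toks[idx] <- new_id
  toks[-(idx + 1L)]
}

#' @export
print.bpe_tokenizer <- function(x, ...) {
  cat(sprintf("bpe_tokenizer: %d tokens, %d merges\n", x$vocab_size,
              nrow(x$merges)))
  invisible(x)
}

#' Tokenize sequences and drop those exceeding a token budget
#'
#' Merges are applied greedily in recorded training order; tokenizing
#' then concatenating reproduces the input exactly. Sequences yielding
#' more than `max_tokens` tokens are dropped and reported (a sequence of
#' exactly `max_tokens` is retained).
#'
#' @param sequences named character vector (names become ids)
#' @param tokenizer a [train_bpe()] model
#' @param max_tokens token cap (default 512)
#' @return list with `tokens` (named list of integer token-id vectors)
#'   and `dropped` (character ids)
#' @export
tokenize_and_filter <- function(sequences, tokenizer, max_tokens = 512L) {
  if (!length(sequences))
    return(list(tokens = list(), dropped = character()))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%05d", seq_along(sequences))
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    data_error(sprintf("sequence %s has characters outside the tokenizer alphabet",
                       names(sequences)[bad][1]))
  alphabet <- tokenizer$vocab[1:4]
  toks <- corpus_as_ints(sequences, alphabet)
  if (nrow(tokenizer$merges)) {
    for (m in seq_len(nrow(tokenizer$merges))) {
      a <- tokenizer$merges[m, 1L]; b <- tokenizer$merges[m, 2L]
      toks <- apply_merge(toks, a, b, 4L + m)
    }
  }
  # split back on separators
  br <- c(0L, which(toks == 0L), length(toks) + 1L)
  out <- lapply(seq_len(length(br) - 1L), function(i) {
    seg <- toks[(br[i] + 1L):(br[i + 1L] - 1L)]
    seg
  })
  names(out) <- names(sequences)
  n_tok <- lengths(out)
  dropped <- names(out)[n_tok > max_tokens]
  list(tokens = out[n_tok <= max_tokens], dropped = dropped)
}

#' Reassemble the input string from token ids (round-trip check)
#' @param token_ids integer vector
#' @param tokenizer the tokenizer
#' @return character scalar
#' @export
detokenize <- function(token_ids, tokenizer) {
  paste(tokenizer$vocab[token_ids], collapse = "")
}

#' Serialize / load a tokenizer as JSON (vocab + ordered merges)
#' @param tokenizer a `bpe_tokenizer`
#' @param path JSON file
#' @export
write_tokenizer <- function(tokenizer, path) {
  jsonlite::write_json(list(schema = "islandmeth-bpe-1",
                            vocab = tokenizer$vocab,
                            merges = apply(tokenizer$merges, 1L, identity,
                                           simplify = FALSE)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tokenizer
#' @export
read_tokenizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "islandmeth-bpe-1"))
    data_error("not an islandmeth BPE tokenizer file")
  merges <- if (is.matrix(x$merges)) {
    matrix(as.integer(x$merges), ncol = 2L)
  } else if (length(x$merges)) {
    matrix(as.integer(unlist(x$merges)), ncol = 2L, byrow = TRUE)
  } else matrix(integer(0), ncol = 2L)
  structure(list(vocab = x$vocab, merges = merges,
                 vocab_size = length(x$vocab)),
            class = "bpe_tokenizer")
}
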