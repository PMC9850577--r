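# SMILES token codec: regex tokenizer with an explicit ordered rule table,
# and a vocabulary mapping tokens to stable integer indices.

TOK_PAD <- "<pad>"; TOK_BOS <- "<bos>"; TOK_EOS <- "<eos>"; TOK_UNK <- "<unk>"
IDX_PAD <- 1L; IDX_BOS <- 2L; IDX_EOS <- 3L; IDX_UNK <- 4L

# ordered rules: bracket atoms > two-letter elements > %NN ring labels >
# single characters
.cg_token_regex <- "\\[[^]]*\\]|Cl|Br|%[0-9]{2}|."

#' Tokenize a SMILES string
#'
#' Atom-level tokenization: bracket atoms (`[nH]`, `[O-]`), the two-letter
#' elements `Cl`/`Br`, and two-digit ring-closure labels (`%NN`) are single
#' tokens; every other character is its own token. The tokenizer is lossless:
#' `detokenize_smiles(tokenize_smiles(s)) == s` for any input.
#'
#' @param smiles a single string.
#' @return character vector of tokens.
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) return(character(0))
  regmatches(smiles, gregexpr(.cg_token_regex, smiles))[[1]]
}

#' @rdname tokenize_smiles
#' @param tokens character vector of tokens.
#' @export
detokenize_smiles <- function(tokens) {
  paste0(tokens, collapse = "")
}

#' Build a token vocabulary from a SMILES corpus
#'
#' The vocabulary covers every token appearing in the corpus, in sorted
#' (locale-independent) order after the four reserved specials
#' `<pad>`, `<bos>`, `<eos>`, `<unk>` at indices 1-4. The same corpus in any
#' order yields an identical vocabulary.
#'
#' @param corpus non-empty character vector of SMILES strings.
#' @return an object of class `cg_vocab`: a character vector of tokens whose
#'   position is the integer index.
#' @export
build_vocab <- function(corpus) {
  stopifnot(is.character(corpus))
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  toks <- unique(unlist(lapply(corpus, tokenize_smiles)))
  withr_collate <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", withr_collate), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  tokens <- c(TOK_PAD, TOK_BOS, TOK_EOS, TOK_UNK, sort(toks))
  structure(tokens, class = "cg_vocab")
}

#' @export
print.cg_vocab <- function(x, ...) {
  cat(sprintf("<vocabulary: %d tokens (4 special)>\n", length(x)))
  cat(" ", paste(unclass(x)[-(1:4)], collapse = " "), "\n")
  invisible(x)
}

vocab_size <- function(vocab) length(vocab)

token_to_index <- function(tokens, vocab) {
  idx <- match(tokens, unclass(vocab))
  idx[is.na(idx)] <- IDX_UNK
  idx
}

#' Encode a SMILES string as vocabulary indices
#'
#' Produces `<bos>`, token indices, `<eos>`. Tokens absent from the
#' vocabulary map to `<unk>`. Sequences longer than `max_len` (including the
#' two sentinels) are an error, never a silent truncation.
#'
#' @param smiles a single SMILES string.
#' @param vocab a `cg_vocab`.
#' @param max_len maximum encoded length (default 120).
#' @return integer index vector.
#' @export
encode_smiles <- function(smiles, vocab, max_len = 120L) {
  toks <- tokenize_smiles(smiles)
  idx <- c(IDX_BOS, token_to_index(toks, vocab), IDX_EOS)
  if (length(idx) > max_len) {
    stop(sprintf("encoded length %d exceeds max_len %d for: %s",
                 length(idx), max_len, smiles), call. = FALSE)
  }
  idx
}

#' @rdname encode_smiles
#' @param indices integer index vector (with or without sentinels/padding).
#' @export
decode_indices <- function(indices, vocab) {
  eos <- which(indices == IDX_EOS)
  if (length(eos)) indices <- indices[seq_len(eos[1] - 1L)]
  indices <- indices[!(indices %in% c(IDX_PAD, IDX_BOS))]
  toks <- unclass(vocab)[indices]
  toks[indices == IDX_UNK] <- "?"  # unparseable on purpose
  detokenize_smiles(toks)
}

#' Read/write a vocabulary as a plain-text token list
#'
#' One token per line; the line number is the index.
#'
#' @param vocab a `cg_vocab`.
#' @param path file path.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(unclass(vocab), path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  tokens <- readLines(path, warn = FALSE)
  if (length(tokens) < 4L ||
      !identical(tokens[1:4], c(TOK_PAD, TOK_BOS, TOK_EOS, TOK_UNK))) {
    stop("not a vocabulary file (reserved specials missing)", call. = FALSE)
  }
  structure(tokens, class = "cg_vocab")
}
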