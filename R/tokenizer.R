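#' SMILES tokenization
#'
#' SMILES strings are split into the tokens that form the action alphabet of
#' the tree search: one token per atom symbol, bond symbol, ring-closure
#' digit or branch parenthesis. Bracket atoms (e.g. `"[nH]"`), two-character
#' halogen symbols (`"Cl"`, `"Br"`) and two-digit ring closures (`"%12"`)
#' are kept as single tokens so that arbitrary corpora load even when the
#' element filter would later reject them.
#'
#' @param text a single SMILES string.
#' @return character vector of tokens; concatenating them reproduces `text`.
#' @examples
#' smiles_tokens("c1cc[nH]c1")
#' @export
smiles_tokens <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    abort("cannot tokenize an empty SMILES string", class = "fluortree_vocab_error")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) {
        abort(sprintf("unterminated bracket atom in %s", text),
              class = "fluortree_vocab_error")
      }
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)]))) {
        abort(sprintf("malformed '%%' ring closure in %s", text),
              class = "fluortree_vocab_error")
      }
      out <- c(out, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] == c("l", "r")[match(ch, c("C", "B"))]) {
      # longest match: Cl / Br
      out <- c(out, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Token vocabulary of a SMILES corpus
#'
#' The vocabulary is exactly the set of tokens observed in the corpus plus a
#' begin and an end sentinel. Token order is fixed (sentinels first, then
#' sorted observed tokens) and is the deterministic tie-break order used in
#' the search.
#'
#' @param corpus character vector of SMILES strings.
#' @param begin_token,end_token sentinel tokens; must not occur in the corpus.
#' @return an object of class `ft_vocab`.
#' @export
smiles_vocabulary <- function(corpus, begin_token = "^", end_token = "$") {
  if (length(corpus) == 0L) {
    abort("empty corpus", class = "fluortree_input_error")
  }
  observed <- sort(unique(unlist(lapply(corpus, smiles_tokens))))
  if (any(c(begin_token, end_token) %in% observed)) {
    abort("sentinel tokens must not occur in the corpus",
          class = "fluortree_input_error")
  }
  structure(
    list(tokens = c(begin_token, end_token, observed),
         begin_token = begin_token,
         end_token = end_token),
    class = "ft_vocab"
  )
}

#' @export
print.ft_vocab <- function(x, ...) {
  cat("<ft_vocab> ", length(x$tokens), " tokens (incl. sentinels): ",
      paste(utils::head(setdiff(x$tokens, c(x$begin_token, x$end_token)), 15),
            collapse = " "),
      if (length(x$tokens) > 17) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Tokenize a SMILES string against a vocabulary
#'
#' @param text a SMILES string.
#' @param vocab an [smiles_vocabulary()] object.
#' @return character vector of tokens, all members of `vocab`.
#' @export
tokenize_smiles <- function(text, vocab) {
  stopifnot(inherits(vocab, "ft_vocab"))
  toks <- smiles_tokens(text)
  unknown <- setdiff(toks, vocab$tokens)
  if (length(unknown) > 0L) {
    abort(sprintf("token(s) not in vocabulary: %s",
                  paste(unique(unknown), collapse = " ")),
          class = "fluortree_vocab_error")
  }
  toks
}

#' Reassemble a SMILES string from tokens
#'
#' Sentinel tokens are dropped; everything up to (but excluding) the first
#' end token is concatenated.
#'
#' @param tokens character vector of tokens.
#' @param vocab an [smiles_vocabulary()] object.
#' @return a single SMILES string.
#' @export
detokenize <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "ft_vocab"))
  end_at <- match(vocab$end_token, tokens)
  if (!is.na(end_at)) tokens <- tokens[seq_len(end_at - 1L)]
  paste(tokens[tokens != vocab$begin_token], collapse = "")
}
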