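#' Construct a word-token table
#'
#' A token table is the package's representation of a time-aligned story
#' transcript: one row per spoken word, with onset/offset times in seconds,
#' an optional part-of-speech tag, a lexical surprisal value in bits (filled
#' by [annotate_tokens()] when absent), and a flag marking words that were
#' substituted to create a high-surprisal variant of the story.
#'
#' @param word character vector of (normalized) word strings.
#' @param onset,offset numeric vectors, seconds; `offset > onset` row-wise,
#'   rows sorted by onset with no overlapping intervals.
#' @param pos optional character vector of part-of-speech tags (`NA` allowed).
#' @param surprisal optional numeric vector, bits (`NA` = not yet annotated).
#' @param altered logical vector flagging substituted words.
#' @return A `data.frame` of class `token_table` with columns
#'   `word`, `onset`, `offset`, `pos`, `surprisal`, `altered`.
#' @export
token_table <- function(word, onset, offset, pos = NA_character_,
                        surprisal = NA_real_, altered = FALSE) {
  n <- length(word)
  tok <- data.frame(
    word      = as.character(word),
    onset     = as.numeric(onset),
    offset    = as.numeric(offset),
    pos       = rep_len(as.character(pos), n),
    surprisal = rep_len(as.numeric(surprisal), n),
    altered   = rep_len(as.logical(altered), n),
    stringsAsFactors = FALSE
  )
  validate_token_table(tok)
  class(tok) <- c("token_table", "data.frame")
  tok
}

validate_token_table <- function(tok) {
  stopifnot(is.data.frame(tok))
  if (nrow(tok) == 0L) return(invisible(tok))
  if (any(!is.finite(tok$onset)) || any(!is.finite(tok$offset)))
    stop("token timing must be finite", call. = FALSE)
  if (any(tok$onset < 0))
    stop("token onsets must be >= 0", call. = FALSE)
  bad <- which(tok$offset <= tok$onset)
  if (length(bad))
    stop("token offset must exceed onset (rows: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  if (is.unsorted(tok$onset))
    stop("tokens must be sorted by onset", call. = FALSE)
  if (nrow(tok) > 1L) {
    ov <- which(tok$offset[-nrow(tok)] > tok$onset[-1L] + 1e-9)
    if (length(ov))
      stop("overlapping token intervals (rows: ",
           paste(ov, collapse = ", "), ")", call. = FALSE)
  }
  s <- tok$surprisal[!is.na(tok$surprisal)]
  if (length(s) && (any(!is.finite(s)) || any(s < 0)))
    stop("surprisal values must be finite and >= 0", call. = FALSE)
  invisible(tok)
}

#' Tokenize raw text for language-model training
#'
#' Lowercases, and splits punctuation off into separate tokens so that
#' clause and sentence boundaries remain visible to the language model as
#' context, without ever becoming regressor events.
#'
#' @param text character vector (each element typically one sentence/line).
#' @return character vector of tokens.
#' @export
tokenize_text <- function(text) {
  x <- tolower(paste(text, collapse = " "))
  # split punctuation into standalone tokens; keep word-internal apostrophes
  x <- gsub("([.!?;:,\"()])", " \\1 ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1L]]
  toks[nzchar(toks)]
}
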