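#' Train a backoff n-gram language model
#'
#' Counts n-grams of orders `1..order` over a token sequence and wraps them
#' in a model object whose conditional distributions are proper probability
#' distributions over the vocabulary plus an unknown-word symbol. Word
#' surprisal, the negative log2 conditional probability of a word given its
#' preceding context, is computed from this model by [surprisal_of()].
#'
#' Three smoothing schemes are available:
#' \describe{
#'   \item{`"add_k"`}{(default) interpolated additive smoothing:
#'     `p_o(w|ctx) = (c(ctx,w) + k * p_{o-1}(w|ctx')) / (c(ctx) + k)`,
#'     recursing to an add-k unigram over the vocabulary plus `UNK`.
#'     Exactly hand-checkable, always strictly positive.}
#'   \item{`"kneser_ney"`}{interpolated Kneser-Ney with absolute discount
#'     `discount`, continuation counts at lower orders.}
#'   \item{`"mle"`}{raw maximum likelihood with backoff to the longest seen
#'     context; unseen continuations have probability zero (infinite
#'     surprisal), so MLE is for analysis of closed toy corpora only.}
#' }
#' Contexts never seen at a given order back off entirely to the next lower
#' order; story-initial positions are scored with the longest available
#' context rather than padded pseudo-words.
#'
#' @param corpus character vector of training tokens (see [tokenize_text()]),
#'   or raw untokenized text of length 1.
#' @param order maximum n-gram order, integer >= 1 (5 for the usual
#'   surprisal definition from four preceding words).
#' @param smoothing one of `"add_k"`, `"kneser_ney"`, `"mle"`.
#' @param k additive constant for `"add_k"` smoothing.
#' @param discount absolute discount for `"kneser_ney"` (in (0,1)).
#' @return An object of class `ngram_model`.
#' @examples
#' m <- train_ngram(tokenize_text("the cat sat . the cat ran ."), order = 2,
#'                  smoothing = "mle")
#' surprisal_of(m, "cat", "sat")   # 1 bit: p(sat | cat) = 1/2
#' @export
train_ngram <- function(corpus, order = 5L,
                        smoothing = c("add_k", "kneser_ney", "mle"),
                        k = 0.1, discount = 0.75) {
  smoothing <- match.arg(smoothing)
  if (length(corpus) == 1L && grepl("\\s", corpus)) corpus <- tokenize_text(corpus)
  corpus <- as.character(corpus)
  if (length(corpus) == 0L) stop("empty training corpus", call. = FALSE)
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop("order must be >= 1", call. = FALSE)
  if (smoothing == "add_k" && k <= 0) stop("k must be > 0", call. = FALSE)
  if (smoothing == "kneser_ney" && (discount <= 0 || discount >= 1))
    stop("discount must be in (0, 1)", call. = FALSE)

  n <- length(corpus)
  counts <- vector("list", order)
  for (o in seq_len(order)) {
    if (n >= o) {
      grams <- corpus[seq_len(n - o + 1L)]
      if (o > 1L) for (j in 2:o)
        grams <- paste(grams, corpus[j:(n - o + j)])
      tab <- table(grams)
      counts[[o]] <- stats::setNames(as.numeric(tab), names(tab))
    } else {
      counts[[o]] <- stats::setNames(numeric(0), character(0))
    }
  }

  # continuation counts for Kneser-Ney: number of distinct left contexts
  # in which each (o)-gram suffix appears
  cont <- NULL
  if (smoothing == "kneser_ney" && order > 1L) {
    cont <- vector("list", order - 1L)
    for (o in seq_len(order - 1L)) {
      hi <- names(counts[[o + 1L]])
      if (length(hi)) {
        suf <- sub("^\\S+ ", "", hi)
        tab <- table(suf)
        cont[[o]] <- stats::setNames(as.numeric(tab), names(tab))
      } else cont[[o]] <- stats::setNames(numeric(0), character(0))
    }
  }

  vocab <- sort(unique(corpus))
  structure(
    list(order = order, vocab = vocab, unk = "<unk>",
         counts = counts, cont = cont, n_tokens = n,
         smoothing = smoothing, k = k, discount = discount),
    class = "ngram_model")
}

#' @export
print.ngram_model <- function(x, ...) {
  cat(sprintf("<ngram_model> order %d, %s smoothing, |V| = %d, %d training tokens\n",
              x$order, x$smoothing, length(x$vocab), x$n_tokens))
  invisible(x)
}

# map out-of-vocabulary words to the UNK symbol
map_unk <- function(model, words) {
  words <- as.character(words)
  words[!(words %in% model$vocab)] <- model$unk
  words
}

# vocabulary size including UNK
vocab_size <- function(model) length(model$vocab) + 1L

cnt <- function(tab, key) {
  v <- tab[key]
  v[is.na(v)] <- 0
  unname(v)
}

#' Conditional n-gram probability
#'
#' `p(word | context)` under the trained model, using at most the last
#' `order - 1` context words, backing off through lower orders for unseen
#' contexts. Out-of-vocabulary words (in context or target) are mapped to
#' the unknown symbol.
#'
#' @param model an [ngram_model][train_ngram].
#' @param context character vector of preceding words (may be empty or
#'   shorter than `order - 1`).
#' @param word target word.
#' @return probability in `[0, 1]` (strictly positive for smoothed models).
#' @export
ngram_prob <- function(model, context, word) {
  word <- map_unk(model, word)
  context <- map_unk(model, context)
  ctx_len <- min(length(context), model$order - 1L)
  context <- if (ctx_len > 0L) utils::tail(context, ctx_len) else character(0)
  prob_rec(model, context, word, length(context) + 1L)
}

prob_rec <- function(model, context, word, o) {
  if (o <= 1L) return(unigram_prob(model, word))
  gram <- paste(c(context, word), collapse = " ")
  ctx_key <- paste(context, collapse = " ")
  c_ctx <- ctx_count(model, context, o)
  if (c_ctx == 0) # context unseen at this order: back off entirely
    return(prob_rec(model, context[-1L], word, o - 1L))
  c_gram <- cnt(model$counts[[o]], gram)
  switch(model$smoothing,
    mle = {
      if (c_gram > 0) c_gram / c_ctx
      else 0
    },
    add_k = {
      p_lower <- prob_rec(model, context[-1L], word, o - 1L)
      (c_gram + model$k * p_lower) / (c_ctx + model$k)
    },
    kneser_ney = {
      d <- model$discount
      n_types <- distinct_continuations(model, context, o)
      p_lower <- cont_prob_rec(model, context[-1L], word, o - 1L)
      max(c_gram - d, 0) / c_ctx + d * n_types / c_ctx * p_lower
    })
}

unigram_prob <- function(model, word) {
  c_w <- cnt(model$counts[[1L]], word)
  switch(model$smoothing,
    mle = c_w / model$n_tokens,
    add_k = (c_w + model$k) / (model$n_tokens + model$k * vocab_size(model)),
    kneser_ney = (c_w + model$k_uni %||% 1) /
      (model$n_tokens + (model$k_uni %||% 1) * vocab_size(model)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lower-order Kneser-Ney continuation distribution
cont_prob_rec <- function(model, context, word, o) {
  if (o <= 1L) {
    # continuation unigram: fraction of distinct bigram types ending in word,
    # add-1 smoothed over vocab+UNK so UNK has mass
    total <- length(model$counts[[2L]])
    if (total == 0L) return(unigram_prob(model, word))
    c_cont <- cnt(model$cont[[1L]], word)
    return((c_cont + 1) / (total + vocab_size(model)))
  }
  gram <- paste(c(context, word), collapse = " ")
  c_ctx_cont <- cont_ctx_count(model, context, o)
  if (c_ctx_cont == 0)
    return(cont_prob_rec(model, context[-1L], word, o - 1L))
  d <- model$discount
  c_gram_cont <- cnt(model$cont[[o]], gram)
  n_types <- distinct_cont_continuations(model, context, o)
  p_lower <- cont_prob_rec(model, context[-1L], word, o - 1L)
  max(c_gram_cont - d, 0) / c_ctx_cont + d * n_types / c_ctx_cont * p_lower
}

ctx_count <- function(model, context, o) {
  if (o - 1L < 1L) return(model$n_tokens)
  # occurrences of the context followed by anything = sum of o-gram counts
  # with that prefix; equals the (o-1)-gram count except at sequence edges.
  pre <- paste(context, collapse = " ")
  idx <- startsWith(names(model$counts[[o]]), paste0(pre, " "))
  sum(model$counts[[o]][idx])
}

distinct_continuations <- function(model, context, o) {
  pre <- paste(context, collapse = " ")
  sum(startsWith(names(model$counts[[o]]), paste0(pre, " ")))
}

cont_ctx_count <- function(model, context, o) {
  pre <- paste(context, collapse = " ")
  idx <- startsWith(names(model$cont[[o]]), paste0(pre, " "))
  sum(model$cont[[o]][idx])
}

distinct_cont_continuations <- function(model, context, o) {
  pre <- paste(context, collapse = " ")
  sum(startsWith(names(model$cont[[o]]), paste0(pre, " ")))
}

#' Word surprisal in bits
#'
#' `-log2 p(word | context)` under the model: the information-theoretic
#' unexpectedness of a word given (up to) the `order - 1` preceding words.
#'
#' @inheritParams ngram_prob
#' @return surprisal in bits, `>= 0`; finite for smoothed models, `Inf`
#'   for zero-probability continuations under MLE.
#' @export
surprisal_of <- function(model, context, word) {
  p <- ngram_prob(model, context, word)
  s <- -log2(p)
  if (is.finite(s)) max(s, 0) else s
}

#' Annotate a token table with per-word surprisal
#'
#' Fills the `surprisal` column of a token table using [surprisal_of()] with
#' each word's preceding story words as context (fewer than `order - 1` at
#' story start, via backoff). Timing columns are never modified, and the
#' operation is idempotent.
#'
#' @param model an [ngram_model][train_ngram].
#' @param tokens a [token_table()].
#' @return the token table with `surprisal` filled.
#' @export
annotate_tokens <- function(model, tokens) {
  validate_token_table(tokens)
  words <- tolower(tokens$word)
  ctx_len <- model$order - 1L
  surp <- vapply(seq_along(words), function(i) {
    ctx <- words[max(1L, i - ctx_len):max(0L, i - 1L)]
    if (i == 1L) ctx <- character(0)
    surprisal_of(model, ctx, words[i])
  }, numeric(1))
  tokens$surprisal <- surp
  tokens
}

#' Define a word-substitution plan
#'
#' Describes which story tokens are to be replaced by high-surprisal words
#' to create an altered story variant: replacements must be spaced at least
#' `min_spacing` seconds apart and each replacement word must exceed the
#' surprisal threshold in context.
#'
#' @param story_id identifier of the story the plan applies to.
#' @param index integer vector of token row indices to replace (strictly
#'   increasing).
#' @param replacement character vector of replacement words.
#' @param min_spacing minimum spacing between replacements, seconds.
#' @param threshold minimum surprisal of each replacement, bits.
#' @export
substitution_plan <- function(story_id, index, replacement,
                              min_spacing = 45, threshold = 20) {
  index <- as.integer(index)
  if (length(index) != length(replacement))
    stop("index and replacement lengths differ", call. = FALSE)
  if (length(index) > 1L && any(diff(index) <= 0L))
    stop("replacement indices must be strictly increasing", call. = FALSE)
  structure(list(story_id = story_id, index = index,
                 replacement = as.character(replacement),
                 min_spacing = min_spacing, threshold = threshold),
            class = "substitution_plan")
}

#' Validate a substitution plan against its criteria
#'
#' Checks, per replacement: (surprisal) the replacement word's surprisal in
#' its story context exceeds the plan threshold; (spacing) consecutive
#' replacements are at least `min_spacing` seconds apart; (pos) the
#' replacement is noun-for-noun when part-of-speech tags are available;
#' (clause_final) the replaced token ends a clause when clause boundaries
#' are supplied. Checks whose annotations are missing are reported as
#' `NA` ("not evaluated"), not as failures.
#'
#' @param tokens a [token_table()] for the story.
#' @param plan a [substitution_plan()].
#' @param model an [ngram_model][train_ngram] used to score replacements.
#' @param replacement_pos optional character vector of part-of-speech tags
#'   of the replacement words.
#' @param clause_ends optional integer vector of token indices that end a
#'   clause.
#' @return list with a per-replacement logical data.frame `checks`,
#'   `pass` (all evaluated checks passed) and `n_replacements`.
#' @export
validate_plan <- function(tokens, plan, model,
                          replacement_pos = NULL, clause_ends = NULL) {
  validate_token_table(tokens)
  stopifnot(inherits(plan, "substitution_plan"))
  m <- length(plan$index)
  if (m == 0L)
    return(list(checks = data.frame(), pass = TRUE, n_replacements = 0L))
  if (any(plan$index < 1L | plan$index > nrow(tokens)))
    stop("plan index outside token range", call. = FALSE)

  words <- tolower(tokens$word)
  ctx_len <- model$order - 1L
  surp <- vapply(seq_len(m), function(j) {
    i <- plan$index[j]
    ctx <- if (i > 1L) words[max(1L, i - ctx_len):(i - 1L)] else character(0)
    surprisal_of(model, ctx, tolower(plan$replacement[j]))
  }, numeric(1))

  onsets <- tokens$onset[plan$index]
  spacing_ok <- c(TRUE, diff(onsets) >= plan$min_spacing)

  pos_ok <- if (!is.null(replacement_pos) && !all(is.na(tokens$pos))) {
    tolower(tokens$pos[plan$index]) == "noun" & tolower(replacement_pos) == "noun"
  } else rep(NA, m)

  clause_ok <- if (!is.null(clause_ends)) plan$index %in% clause_ends
               else rep(NA, m)

  checks <- data.frame(
    index = plan$index, replacement = plan$replacement,
    surprisal = surp,
    surprisal_ok = surp > plan$threshold,
    spacing_ok = spacing_ok, pos_ok = pos_ok, clause_final_ok = clause_ok)
  evaluated <- checks[c("surprisal_ok", "spacing_ok", "pos_ok", "clause_final_ok")]
  pass <- all(unlist(evaluated), na.rm = TRUE)
  list(checks = checks, pass = pass, n_replacements = m)
}
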