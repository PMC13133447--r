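#' Score a listening span (working memory) session
#'
#' Blocks alternate sentence plausibility judgments with to-be-remembered
#' words at memory loads of 2-6 pairs; each load is presented three times
#' in the full design (15 blocks, 60 words). Recall is scored by
#' case-insensitive exact match, each presented instance creditable once;
#' judgment accuracy is the proportion of correct plausibility responses.
#'
#' @param blocks list of blocks, each a list with `presented` (character),
#'   `recalled` (character), `judgments` (logical or 0/1 correctness), and
#'   optionally `judgment_answers`/`judgment_responses` to be compared
#'   instead.
#' @return list with `recall_pct`, `judgment_pct`, `n_words`,
#'   `n_sentences`.
#' @export
score_listening_span <- function(blocks) {
  n_words <- 0L; n_recalled <- 0L; n_sent <- 0L; n_correct <- 0L
  for (b in blocks) {
    pres <- tolower(trimws(as.character(b$presented)))
    rec <- tolower(trimws(as.character(b$recalled)))
    n_words <- n_words + length(pres)
    # each presented instance can be credited by at most one recalled word
    avail <- pres
    for (w in rec) {
      hit <- match(w, avail)
      if (!is.na(hit)) {
        n_recalled <- n_recalled + 1L
        avail <- avail[-hit]
      }
    }
    if (!is.null(b$judgments)) {
      j <- as.logical(b$judgments)
    } else {
      j <- as.character(b$judgment_responses) == as.character(b$judgment_answers)
    }
    n_sent <- n_sent + length(j)
    n_correct <- n_correct + sum(j)
  }
  list(recall_pct = if (n_words) 100 * n_recalled / n_words else NA_real_,
       judgment_pct = if (n_sent) 100 * n_correct / n_sent else NA_real_,
       n_words = n_words, n_sentences = n_sent)
}

#' Score the Speech, Spatial and Qualities of hearing questionnaire
#'
#' Items are self-report ratings from 0 (worst) to 10 (best) tagged by
#' domain (speech: 14 items, spatial: 17, quality: 18 in the full
#' instrument); each domain is summarized by its mean, plus an overall
#' mean across all items.
#'
#' @param items data.frame with columns `domain` (one of `"speech"`,
#'   `"spatial"`, `"quality"`) and `rating` (0-10).
#' @return list with `speech`, `spatial`, `quality`, `all` means.
#' @export
score_ssq <- function(items) {
  stopifnot(all(c("domain", "rating") %in% names(items)))
  r <- as.numeric(items$rating)
  if (any(!is.finite(r)) || any(r < 0 | r > 10))
    stop("SSQ ratings must be within 0-10", call. = FALSE)
  dom <- tolower(items$domain)
  bad <- setdiff(unique(dom), c("speech", "spatial", "quality"))
  if (length(bad)) stop("unknown SSQ domain: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  m <- function(d) if (any(dom == d)) mean(r[dom == d]) else NA_real_
  list(speech = m("speech"), spatial = m("spatial"), quality = m("quality"),
       all = mean(r))
}
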