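# Descriptive statistics of sonographer speech: part-of-speech
# distribution, vocabulary size, and maximum sentence length, computed
# against a tagged lexicon (no statistical tagger: the tag is a property
# of the word).

#' Build the synthetic tagged sonographer lexicon
#'
#' A core vocabulary of words actually used while scanning (anatomy nouns,
#' instruction verbs, position adjectives, determiners, function words) is
#' padded with deterministic synthetic filler words to reach `n_words`
#' unique entries, keeping per-tag pool sizes roughly proportional to real
#' scan commentary.
#'
#' @param n_words Total unique words (default 344).
#' @return Data frame with columns `word`, `tag`; tags are
#'   `adjective`, `determiner`, `noun`, `verb`, `other`.
#' @export
build_lexicon <- function(n_words = 344) {
  core <- list(
    noun = c("head", "brain", "heart", "spine", "femur", "abdomen",
             "placenta", "fluid", "kidney", "bladder", "cord", "face",
             "profile", "ventricle", "cerebellum", "stomach", "bowel",
             "diaphragm", "lips", "nose", "hands", "feet", "legs", "arms",
             "skull", "orbit", "chamber", "valve", "aorta", "artery",
             "vein", "measurement", "circumference", "length", "position",
             "view", "plane", "image", "probe", "baby", "twin", "sac",
             "wall", "outlet", "tract", "spine", "section", "scan",
             "picture", "screen", "machine", "gel", "report", "heartbeat",
             "movement", "presentation", "insertion", "situs", "genitalia",
             "uterus", "cervix", "doppler", "flow", "gestation", "week"),
    verb = c("see", "look", "measure", "check", "move", "turn", "freeze",
             "save", "scan", "show", "find", "take", "press", "hold",
             "breathe", "relax", "lie", "come", "go", "try", "wait",
             "start", "finish", "zoom", "sweep", "angle", "confirm",
             "record", "point", "follow"),
    adjective = c("good", "nice", "clear", "normal", "small", "big",
                  "long", "short", "left", "right", "upper", "lower",
                  "anterior", "posterior", "fetal", "cephalic", "breech",
                  "transverse", "visible", "difficult", "four-chamber",
                  "sagittal", "coronal", "axial", "mid", "deep", "still",
                  "happy", "lovely", "tricky"),
    determiner = c("the", "a", "an", "this", "that", "these", "those",
                   "some", "any", "each", "every", "no"),
    other = c("of", "in", "on", "at", "to", "for", "with", "from", "we",
              "you", "i", "it", "here", "there", "now", "just", "very",
              "quite", "again", "so", "and", "or", "but", "if", "up",
              "down", "well", "okay", "then", "around", "through", "under",
              "over", "behind", "nicely", "really", "maybe", "yes",
              "please", "once", "twice", "she", "he", "they", "because",
              "while", "about", "today"))
  core <- lapply(core, unique)
  # target pool sizes roughly matching commentary structure
  target <- round(n_words * c(noun = 0.44, verb = 0.14, adjective = 0.13,
                              determiner = 0.04, other = 0.25))
  target["noun"] <- n_words - sum(target[c("verb", "adjective",
                                           "determiner", "other")])
  stem <- c(noun = "struct", verb = "act", adjective = "desc",
            determiner = "det", other = "link")
  rows <- lapply(names(core), function(tg) {
    words <- core[[tg]]
    need <- target[[tg]] - length(words)
    if (need > 0)
      words <- c(words, sprintf("%s%02d", stem[[tg]], seq_len(need)))
    else
      words <- words[seq_len(target[[tg]])]
    data.frame(word = words, tag = tg, stringsAsFactors = FALSE)
  })
  lex <- do.call(rbind, rows)
  lex[!duplicated(lex$word), , drop = FALSE]
}

#' Tokenize raw sentences
#'
#' Whitespace split, lowercasing, punctuation stripped (word-internal
#' hyphens kept).
#'
#' @param sentences Character vector of raw sentences.
#' @return List of character-vector sentences.
#' @export
tokenize_sentences <- function(sentences) {
  lapply(sentences, function(s) {
    w <- strsplit(tolower(s), "\\s+")[[1]]
    w <- gsub("(^[^a-z0-9-]+|[^a-z0-9-]+$)", "", w)
    w[grepl("[a-z0-9]", w)]
  })
}

#' Corpus statistics of a tagged transcript
#'
#' Token-level part-of-speech fractions, unique-word count, maximum
#' sentence length and token count.  Every corpus word must be covered by
#' the lexicon; unknown words raise an error naming them rather than being
#' silently dropped.
#'
#' @param corpus List of sentences (character vectors of lowercase words),
#'   e.g. from [simulate_transcript()] or [tokenize_sentences()].
#' @param lexicon Data frame `word`, `tag`.
#' @return List with `pos_fractions` (named, summing to 1),
#'   `n_unique_words`, `max_sentence_len`, `n_tokens`.
#' @export
corpus_stats <- function(corpus, lexicon = build_lexicon()) {
  tokens <- unlist(corpus, use.names = FALSE)
  if (length(tokens) == 0) stop("empty corpus", call. = FALSE)
  tag <- lexicon$tag[match(tokens, lexicon$word)]
  if (anyNA(tag)) {
    missing <- unique(tokens[is.na(tag)])
    stop(sprintf("words not in lexicon: %s",
                 paste(utils::head(missing, 10), collapse = ", ")),
         call. = FALSE)
  }
  frac <- table(tag) / length(tokens)
  list(pos_fractions = stats::setNames(as.numeric(frac), names(frac)),
       n_unique_words = length(unique(tokens)),
       max_sentence_len = max(lengths(corpus)),
       n_tokens = length(tokens))
}

#' Residual part-of-speech percentage
#'
#' Given the printed percentages of adjectives, determiners, nouns and
#' verbs, the remainder attributable to prepositions, pronouns, adverbs and
#' other classes is `100 - sum`.
#'
#' @param fractions Numeric vector of four percentages in `[0, 100]`.
#' @return Remainder percentage.
#' @export
residual_pos_fraction <- function(fractions) {
  stopifnot(length(fractions) == 4)
  if (any(fractions < 0) || any(fractions > 100))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  s <- sum(fractions)
  if (s > 100) stop("percentages sum to more than 100", call. = FALSE)
  100 - s
}
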