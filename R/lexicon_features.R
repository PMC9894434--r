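# Lexicon-based cue features: LCM abstraction, sentiment, negations,
# over-generalizations, detailed part-of-speech counts, and length measures.
# All raw counts are stored unnormalized; per-token normalization happens in
# the statistical and classification stages.

# Default NKJP/Morfeusz-style detailed tags tracked in the battery (28 tags,
# first colon-separated segment of XPOS). Includes the pronoun and
# infinitive families (ppron12, ppron3, inf).
default_pos_tags <- c(
  "subst", "depr", "num", "numcol", "adj", "adja", "adjp", "adjc", "adv",
  "ppron12", "ppron3", "siebie", "fin", "bedzie", "aglt", "praet", "impt",
  "imps", "inf", "pcon", "pant", "ger", "pact", "ppas", "winien", "pred",
  "prep", "qub")

#' Feature-extraction configuration
#'
#' Collects the tunable knobs of the battery: tracked detailed POS tags,
#' the dependency relations counted as adjectival modification and as
#' subject, the statement-level MDD/MHD aggregation, and the syllable
#' counter. The default battery has 43 variables: 3 length + 3 complexity +
#' 5 LCM + 2 sentiment + 1 negation + 1 over-generalization + 28 POS tags.
#'
#' @param pos_tags character vector of tracked detailed tags.
#' @param amod_deprels deprels treated as adjectival modification.
#' @param subject_deprels deprels of a head noun that make an attached
#'   adjective count for the LCM ADJ category.
#' @param aggregate statement-level MDD/MHD aggregation, `"mean"` or
#'   `"pooled"`.
#' @param exclude_punct_edges drop PUNCT tokens from MDD/MHD edges.
#' @param syllable_fun syllable counter for FOG.
#' @param ne_count include an `ne_count` column counting tokens whose MISC
#'   field carries an `NE=` annotation.
#' @return A `feature_config` list.
#' @export
feature_config <- function(pos_tags = default_pos_tags,
                           amod_deprels = "amod",
                           subject_deprels = "nsubj",
                           aggregate = "mean",
                           exclude_punct_edges = FALSE,
                           syllable_fun = count_syllables,
                           ne_count = FALSE) {
  structure(list(pos_tags = pos_tags, amod_deprels = amod_deprels,
                 subject_deprels = subject_deprels, aggregate = aggregate,
                 exclude_punct_edges = exclude_punct_edges,
                 syllable_fun = syllable_fun, ne_count = ne_count),
            class = "feature_config")
}

#' Canonical feature column order for a configuration
#' @param config a [feature_config()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(config = feature_config()) {
  c("n_sentences", "n_tokens", "n_characters", "mdd", "mhd", "fog",
    "dav", "iav", "sv", "adj", "lcm_general",
    "pos_sentiment", "neg_sentiment", "negations", "overgen",
    paste0("pos_", config$pos_tags),
    if (isTRUE(config$ne_count)) "ne_count")
}

#' Does an adjective token count for the LCM ADJ category?
#'
#' The LCM counts only adjectives that modify subject nouns: the token must
#' be attached by an adjectival-modifier relation (`amod` by default) and
#' its head must itself bear a subject relation (`nsubj` by default;
#' configure e.g. `nsubj:pass` via `subject_deprels`). Predicative
#' adjectives and modifiers of non-subject nouns do not qualify.
#'
#' @param token_index 1-based index of the adjective within `sentence`.
#' @param sentence a `parsed_sentence`.
#' @param config a [feature_config()].
#' @return logical.
#' @export
adjective_qualifies <- function(token_index, sentence,
                                config = feature_config()) {
  tok_deprel <- sentence$deprel[token_index]
  h <- sentence$head[token_index]
  if (!(tok_deprel %in% config$amod_deprels) || h == 0L) return(FALSE)
  sentence$deprel[h] %in% config$subject_deprels
}

#' LCM category counts for a statement
#'
#' Verb tokens are counted by case-insensitive lemma membership in the LCM
#' lexicon's DAV/IAV/SV classes; adjective tokens (lexicon class ADJ, or any
#' token with `upos == "ADJ"`) count only when [adjective_qualifies()].
#'
#' @param statement a `statement_record`.
#' @param lcm_lexicon a `lexicon` with family `"lcm"`.
#' @param config a [feature_config()].
#' @return list(dav, iav, sv, adj) of non-negative counts.
#' @export
lcm_counts <- function(statement, lcm_lexicon, config = feature_config()) {
  stopifnot(attr(lcm_lexicon, "family") == "lcm")
  counts <- c(dav = 0L, iav = 0L, sv = 0L, adj = 0L)
  for (s in statement$sentences) {
    cat <- unname(unclass(lcm_lexicon)[tolower(s$lemma)])
    for (i in seq_len(nrow(s))) {
      ci <- cat[i]
      if (is.na(ci)) next
      if (ci == "DAV") counts["dav"] <- counts["dav"] + 1L
      else if (ci == "IAV") counts["iav"] <- counts["iav"] + 1L
      else if (ci == "SV") counts["sv"] <- counts["sv"] + 1L
      else if (ci == "ADJ" && adjective_qualifies(i, s, config))
        counts["adj"] <- counts["adj"] + 1L
    }
  }
  as.list(counts)
}

#' LCM general abstraction score
#'
#' Weighted sum `DAV + 2*IAV + 3*SV + 4*ADJ`: weights increase with the
#' abstractness of the category, from descriptive action verbs (most
#' concrete) to subject-modifying adjectives (most abstract).
#'
#' @param counts list/vector with elements `dav`, `iav`, `sv`, `adj`.
#' @return Numeric score >= 0.
#' @export
lcm_general_score <- function(counts) {
  counts$dav + 2 * counts$iav + 3 * counts$sv + 4 * counts$adj
}

lemma_matches <- function(statement, lemmas) {
  toks <- unlist(lapply(statement$sentences, function(s) tolower(s$lemma)),
                 use.names = FALSE)
  toks[toks %in% lemmas]
}

#' Positive and negative sentiment counts
#'
#' Token-level case-insensitive lemma matches against a sentiment lexicon,
#' per polarity. Every occurrence counts (multiset counting).
#'
#' @param statement a `statement_record`.
#' @param sentiment_lexicon a `lexicon` with family `"sentiment"`.
#' @return list(positive, negative).
#' @export
sentiment_counts <- function(statement, sentiment_lexicon) {
  stopifnot(attr(sentiment_lexicon, "family") == "sentiment")
  entries <- unclass(sentiment_lexicon)
  hits <- lemma_matches(statement, names(entries))
  cats <- entries[hits]
  list(positive = sum(cats == "positive"),
       negative = sum(cats == "negative"))
}

#' Count tokens matching a membership word list
#'
#' For single-category lexicons (negations such as "nie"/"nigdy", or
#' over-generalizations such as "zawsze"/"wszyscy"): the number of tokens
#' whose lower-cased lemma is in the list.
#'
#' @param statement a `statement_record`.
#' @param lex a `lexicon` with family `"negation"` or `"overgen"`.
#' @return Integer count.
#' @export
wordlist_count <- function(statement, lex) {
  stopifnot(attr(lex, "family") %in% c("negation", "overgen"))
  length(lemma_matches(statement, names(unclass(lex))))
}

#' Detailed part-of-speech counts
#'
#' Counts tokens whose XPOS first segment (before `:`) equals each tracked
#' tag; untracked tags are ignored, and tracked tags absent from the
#' statement report 0.
#'
#' @param statement a `statement_record`.
#' @param config a [feature_config()] carrying `pos_tags`.
#' @return Named integer vector over `config$pos_tags`.
#' @export
pos_counts <- function(statement, config = feature_config()) {
  xpos <- unlist(lapply(statement$sentences, function(s) s$xpos),
                 use.names = FALSE)
  base <- sub(":.*$", "", xpos)
  tab <- table(factor(base, levels = config$pos_tags))
  stats::setNames(as.integer(tab), config$pos_tags)
}

#' Length features of a statement
#'
#' Sentences = parsed-sentence count; tokens = token count (multiword
#' ranges were already dropped at parse time); characters = non-whitespace
#' character count of the raw text (NA when raw text is missing).
#'
#' @param statement a `statement_record`.
#' @return list(n_sentences, n_tokens, n_characters).
#' @export
length_features <- function(statement) {
  n_char <- if (is.null(statement$raw_text) || is.na(statement$raw_text))
    NA_integer_
  else
    nchar(gsub("\\s", "", statement$raw_text))
  list(n_sentences = length(statement$sentences),
       n_tokens = sum(vapply(statement$sentences, nrow, 0L)),
       n_characters = n_char)
}

#' Extract the full feature vector for one statement
#'
#' Assembles the canonical battery (43 variables under the default config)
#' from the length, complexity, LCM, sentiment, word-list, and POS
#' operations. Counts are raw (unnormalized). A missing lexicon leaves its
#' columns `NA` rather than silently zero; an undefined measure (e.g. FOG of
#' an empty statement) propagates as `NA`.
#'
#' @param statement a `statement_record`.
#' @param lexicons named list with any of `lcm`, `sentiment`, `negation`,
#'   `overgen` lexicons.
#' @param config a [feature_config()].
#' @return Named list in [feature_columns()] order.
#' @export
extract_features <- function(statement, lexicons, config = feature_config()) {
  lf <- length_features(statement)
  cx <- statement_complexity(statement, aggregate = config$aggregate,
                             exclude_punct_edges = config$exclude_punct_edges,
                             syllable_fun = config$syllable_fun)
  if (!is.null(lexicons$lcm)) {
    lc <- lcm_counts(statement, lexicons$lcm, config)
    lcm_gen <- lcm_general_score(lc)
  } else {
    lc <- list(dav = NA_integer_, iav = NA_integer_, sv = NA_integer_,
               adj = NA_integer_)
    lcm_gen <- NA_real_
  }
  sent <- if (!is.null(lexicons$sentiment))
    sentiment_counts(statement, lexicons$sentiment)
  else list(positive = NA_integer_, negative = NA_integer_)
  negs <- if (!is.null(lexicons$negation))
    wordlist_count(statement, lexicons$negation) else NA_integer_
  over <- if (!is.null(lexicons$overgen))
    wordlist_count(statement, lexicons$overgen) else NA_integer_
  pc <- pos_counts(statement, config)
  out <- c(lf,
           list(mdd = cx$mdd, mhd = cx$mhd, fog = cx$fog,
                dav = lc$dav, iav = lc$iav, sv = lc$sv, adj = lc$adj,
                lcm_general = lcm_gen,
                pos_sentiment = sent$positive, neg_sentiment = sent$negative,
                negations = negs, overgen = over),
           stats::setNames(as.list(pc), paste0("pos_", names(pc))))
  if (isTRUE(config$ne_count)) {
    misc <- unlist(lapply(statement$sentences, function(s) s$misc),
                   use.names = FALSE)
    out$ne_count <- sum(grepl("(^|\\|)NE=", misc))
  }
  out[feature_columns(config)]
}

#' Extract a feature table for a whole corpus
#'
#' One row per statement: manifest metadata (`statement_id`, `subject_id`,
#' `topic`, `veracity`, `modality`) followed by the feature battery in
#' canonical order.
#'
#' @param corpus a `corpus` object.
#' @param lexicons named list of lexicons (see [extract_features()]).
#' @param config a [feature_config()].
#' @return data.frame, one row per statement.
#' @export
extract_feature_table <- function(corpus, lexicons,
                                  config = feature_config()) {
  rows <- lapply(corpus$statements, function(st) {
    fv <- extract_features(st, lexicons, config)
    cbind(data.frame(statement_id = st$statement_id,
                     subject_id = st$subject_id,
                     topic = st$topic,
                     veracity = st$veracity,
                     modality = st$modality,
                     stringsAsFactors = FALSE),
          as.data.frame(fv, check.names = FALSE))
  })
  do.call(rbind, rows)
}
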