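# Syntactic complexity (MDD, MHD) and readability (Gunning Fog).
#
# MDD = mean over the n = len - 1 dependency pairs of |pos(dependent) -
# pos(head)|; MHD = mean over non-root tokens of the number of edges on the
# path to the root. Both are pure functions of tree structure. FOG =
# 0.4 * (words/sentences + 100 * complex_words/words), complex = >= 3
# syllables.

#' Per-edge dependency distances of a sentence
#'
#' For every non-root token, the absolute surface distance
#' `|index(token) - index(head)|`. A valid tree of length n yields exactly
#' n - 1 distances, each >= 1.
#'
#' @param sentence a `parsed_sentence`.
#' @return Integer vector of distances (empty for a single-token sentence).
#' @export
edge_distances <- function(sentence) {
  dep <- sentence$head != 0L
  abs(sentence$index[dep] - sentence$head[dep])
}

#' Root-path depths of a sentence
#'
#' For every non-root token, the number of head-pointer steps to reach the
#' root (hierarchical distance).
#'
#' @param sentence a `parsed_sentence`.
#' @return Integer vector of depths for the non-root tokens, in token order.
#' @export
token_depths <- function(sentence) {
  h <- sentence$head
  n <- length(h)
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L
    j <- i
    while (h[j] != 0L) {
      j <- h[j]
      d <- d + 1L
      if (d > n) stop("cycle in sentence at token ", i)
    }
    depth[i] <- d
  }
  depth[h != 0L]
}

#' Mean dependency distance of a sentence
#'
#' Arithmetic mean of the per-edge absolute surface distances. Undefined
#' (NA) for sentences with fewer than two tokens, which contribute no
#' dependency pair.
#'
#' @param sentence a `parsed_sentence`.
#' @return MDD, a real >= 1, or `NA_real_`.
#' @export
mdd_sentence <- function(sentence) {
  if (nrow(sentence) < 2L) return(NA_real_)
  mean(edge_distances(sentence))
}

#' Mean hierarchical distance of a sentence
#'
#' Arithmetic mean of root-path lengths over the non-root tokens. Undefined
#' (NA) for sentences with fewer than two tokens.
#'
#' @param sentence a `parsed_sentence`.
#' @return MHD, a real >= 1, or `NA_real_`.
#' @export
mhd_sentence <- function(sentence) {
  if (nrow(sentence) < 2L) return(NA_real_)
  mean(token_depths(sentence))
}

#' Count syllables of a word
#'
#' Heuristic nucleus count: maximal runs of vowel letters, with `i`
#' immediately followed by another vowel merged into that vowel's nucleus
#' (the default vowel set covers Polish orthography, where prevocalic "i"
#' marks palatalization rather than a separate syllable). Vowel-less or
#' empty strings count 0. The counter is pluggable throughout the package
#' via the `syllable_fun` config entry.
#'
#' @param word character vector of words.
#' @param vowels string of vowel letters (matched case-insensitively).
#' @return Integer vector of syllable counts (0 for no vowels).
#' @export
count_syllables <- function(word, vowels = "aeiouy\u00f3\u0105\u0119") {
  w <- tolower(word)
  cls <- paste0("[", vowels, "]")
  # prevocalic i merges into the following nucleus
  w <- gsub(paste0("i(?=", cls, ")"), "", w, perl = TRUE)
  runs <- gregexpr(paste0(cls, "+"), w, perl = TRUE)
  vapply(runs, function(m) if (m[1] == -1L) 0L else length(m), integer(1))
}

#' Gunning Fog inputs of a statement
#'
#' Counts words (tokens excluding `upos == "PUNCT"`), sentences, and complex
#' words (>= 3 syllables of the surface form).
#'
#' @param statement a `statement_record`.
#' @param syllable_fun syllable counter, defaults to [count_syllables()].
#' @return list(words, sentences, complex_words).
#' @export
fog_inputs <- function(statement, syllable_fun = count_syllables) {
  surfaces <- unlist(lapply(statement$sentences, function(s)
    s$surface[s$upos != "PUNCT"]), use.names = FALSE)
  list(words = length(surfaces),
       sentences = length(statement$sentences),
       complex_words = sum(syllable_fun(surfaces) >= 3L))
}

#' Gunning Fog index of a statement
#'
#' `0.4 * (words / sentences + 100 * complex_words / words)`, computed over
#' the whole statement. The index was designed for passages of 100+ words;
#' shorter statements are still scored but a warning is emitted below
#' `min_words`.
#'
#' @param statement a `statement_record`.
#' @param syllable_fun syllable counter.
#' @param min_words warn when the statement has fewer words than this;
#'   set to 0 to silence.
#' @return FOG score, or `NA_real_` when the statement has no words.
#' @export
fog_statement <- function(statement, syllable_fun = count_syllables,
                          min_words = 0L) {
  fi <- fog_inputs(statement, syllable_fun)
  if (fi$words == 0L) return(NA_real_)
  if (fi$words < min_words)
    warning("statement ", statement$statement_id %||% "", " has only ",
            fi$words, " words; FOG is designed for longer passages")
  0.4 * (fi$words / fi$sentences + 100 * fi$complex_words / fi$words)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Statement-level complexity measures
#'
#' MDD and MHD are the unweighted mean of per-sentence values over sentences
#' with at least two tokens (sentences are treated as exchangeable units);
#' `aggregate = "pooled"` instead pools all edges/depths across sentences
#' before averaging. FOG comes from [fog_statement()].
#'
#' @param statement a `statement_record`.
#' @param aggregate `"mean"` (default) or `"pooled"`.
#' @param exclude_punct_edges drop `upos == "PUNCT"` tokens from the MDD/MHD
#'   edge and depth sets (distances still use original surface positions).
#' @param syllable_fun syllable counter for FOG.
#' @return list(mdd, mhd, fog); NA where undefined.
#' @export
statement_complexity <- function(statement,
                                 aggregate = c("mean", "pooled"),
                                 exclude_punct_edges = FALSE,
                                 syllable_fun = count_syllables) {
  aggregate <- match.arg(aggregate)
  per_sentence <- lapply(statement$sentences, function(s) {
    if (nrow(s) < 2L) return(NULL)
    keep <- if (exclude_punct_edges) s$upos != "PUNCT" else rep(TRUE, nrow(s))
    keep <- keep & s$head != 0L
    if (!any(keep)) return(NULL)
    d <- abs(s$index - s$head)[keep]
    list(dist = d, depth = token_depths(s)[keep[s$head != 0L]])
  })
  per_sentence <- Filter(Negate(is.null), per_sentence)
  if (length(per_sentence) == 0L) {
    mdd <- mhd <- NA_real_
  } else if (aggregate == "mean") {
    mdd <- mean(vapply(per_sentence, function(x) mean(x$dist), 0))
    mhd <- mean(vapply(per_sentence, function(x) mean(x$depth), 0))
  } else {
    mdd <- mean(unlist(lapply(per_sentence, `[[`, "dist")))
    mhd <- mean(unlist(lapply(per_sentence, `[[`, "depth")))
  }
  list(mdd = mdd, mhd = mhd,
       fog = fog_statement(statement, syllable_fun))
}
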