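# Synthetic corpus generator.
#
# Emulates the study design — n subjects x 4 statements in a 2x2
# truth/lie x written/transcribed within-subject layout — with configurable
# ground-truth effects per cue family. Condition effects and per-subject
# random intercepts act on latent scales (logit for emission probabilities
# and tree shape, log for lengths and word-length means) before the link
# transform, so the random-intercept model fitted downstream matches the
# generating process. Lemmas are synthetic CV-syllable strings, which makes
# the syllable counter and FOG meaningful; all generated files pass
# corpus_io validation.

# latent families that receive condition shifts / subject intercepts
prob_families <- c("dav", "iav", "sv", "adj", "pos_sent", "neg_sent",
                   "negation", "overgen", "ppron12", "ppron3", "inf")
latent_families <- c(prob_families, "tokens", "sentences", "syllables",
                     "shape")

#' Ground-truth effect specification for the generator
#'
#' Baselines: per-token emission probabilities for the lexical/POS cue
#' families, mean tokens per sentence and sentences per statement
#' (Poisson, floored at 2 and 1), mean extra syllables per filler word
#' (`syllables`; filler words carry `1 + Poisson(mean)` syllables), and the
#' chain/star tree-shape mixing parameter (`shape`; 0 = star, 1 = chain).
#' `shifts` is a named list: for family `f`, a vector with any of
#' `veracity`, `modality`, `interaction` — latent-scale coefficients
#' multiplied by the sum contrasts (truth/written = -0.5, lie/transcribed =
#' +0.5), so a veracity shift `d` is exactly the condition difference on the
#' latent scale, the estimand of the downstream mixed model. Zero shifts
#' define the null corpus.
#'
#' @param prob named baseline emission probabilities over the cue families
#'   (remaining mass goes to filler tokens).
#' @param mean_tokens,mean_sentences,mean_syllables,shape scalar baselines.
#' @param shifts named list of latent-scale condition effects.
#' @param sigma_subject sd of per-subject, per-family latent intercepts.
#' @param p_subject_head probability that a non-root, non-adjective token
#'   bears the `nsubj` relation (adjectives count for LCM only when their
#'   head is a subject).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(prob = c(dav = 0.04, iav = 0.03, sv = 0.03,
                                 adj = 0.06, pos_sent = 0.05,
                                 neg_sent = 0.05, negation = 0.04,
                                 overgen = 0.02, ppron12 = 0.03,
                                 ppron3 = 0.03, inf = 0.04),
                        mean_tokens = 12, mean_sentences = 5,
                        mean_syllables = 1, shape = 0.6,
                        shifts = list(), sigma_subject = 0.3,
                        p_subject_head = 0.3) {
  stopifnot(all(names(prob) %in% prob_families),
            all(prob > 0), sum(prob) < 1,
            mean_tokens >= 2, mean_sentences >= 1,
            mean_syllables >= 0, shape >= 0, shape <= 1,
            sigma_subject >= 0)
  bad <- setdiff(names(shifts), latent_families)
  if (length(bad))
    stop("shifts for unknown families: ", paste(bad, collapse = ", "))
  full_prob <- stats::setNames(rep(0, length(prob_families)), prob_families)
  full_prob[names(prob)] <- prob
  structure(list(prob = full_prob, mean_tokens = mean_tokens,
                 mean_sentences = mean_sentences,
                 mean_syllables = mean_syllables, shape = shape,
                 shifts = shifts, sigma_subject = sigma_subject,
                 p_subject_head = p_subject_head),
            class = "effect_spec")
}

#' Preset effect specifications
#'
#' `"null"`: all condition shifts zero (calibration corpus).
#' `"paper_like"`: modest latent shifts whose signs follow the deception
#' literature this package targets — truths longer and foggier with higher
#' overall LCM abstraction, lies with more positive and fewer negative
#' sentiment words and more infinitives, spoken statements longer and
#' syntactically more complex.
#' `"strong"`: large veracity shifts on several families, for
#' classifier-oriented checks.
#'
#' @param preset `"null"`, `"paper_like"`, or `"strong"`.
#' @param ... overrides passed on to [effect_spec()].
#' @return An `effect_spec`.
#' @export
preset_effects <- function(preset = c("null", "paper_like", "strong"), ...) {
  preset <- match.arg(preset)
  shifts <- switch(preset,
    null = list(),
    paper_like = list(
      syllables = c(veracity = -0.10, modality = 0.15),
      tokens = c(veracity = -0.08, modality = 0.30),
      sentences = c(veracity = -0.08, modality = 0.15),
      shape = c(modality = 0.15),
      dav = c(veracity = -0.06, modality = 0.10),
      iav = c(veracity = -0.06),
      sv = c(veracity = -0.08, modality = 0.15),
      adj = c(veracity = -0.08),
      pos_sent = c(veracity = 0.10, modality = -0.15),
      neg_sent = c(veracity = -0.10, modality = -0.15),
      inf = c(veracity = 0.15),
      ppron12 = c(modality = 0.10),
      ppron3 = c(modality = -0.10)),
    strong = list(
      pos_sent = c(veracity = 0.8),
      neg_sent = c(veracity = -0.8),
      inf = c(veracity = 0.8),
      negation = c(veracity = 0.8),
      overgen = c(veracity = -0.8),
      tokens = c(veracity = -0.3),
      syllables = c(veracity = -0.3),
      shape = c(veracity = -0.4)))
  effect_spec(shifts = shifts, ...)
}

# unique pronounceable words: consonant-vowel syllables (no "i", so the
# syllable counter sees exactly `n_syllables` nuclei)
make_words <- function(n, n_syllables = 2L) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "w", "z")
  vow <- c("a", "e", "o", "u", "y")
  syl <- as.vector(outer(cons, vow, paste0))
  n_syllables <- rep_len(n_syllables, n)
  out <- character(n)
  seen <- new.env(hash = TRUE)
  for (i in seq_len(n)) {
    repeat {
      w <- paste(sample(syl, max(1L, n_syllables[i]), replace = TRUE),
                 collapse = "")
      if (is.null(seen[[w]])) { seen[[w]] <- TRUE; break }
    }
    out[i] <- w
  }
  out
}

#' Generate disjoint synthetic lexicons and filler inventories
#'
#' Draws distinct two-syllable lemmas and partitions them into the four
#' lexicon families plus filler inventories (verbs for infinitive slots,
#' pronoun lemmas, plain filler), so category membership is unambiguous by
#' construction. Deterministic given the RNG state (call [set.seed()] or
#' let [generate_corpus()] manage it).
#'
#' @param sizes named sizes per lexicon category.
#' @param seed optional integer; when given, seeds the RNG first.
#' @return list(lexicons = list(lcm, sentiment, negation, overgen),
#'   inventories = list(filler_verb, ppron12, ppron3, filler)).
#' @export
generate_lexicons <- function(sizes = c(DAV = 30, IAV = 30, SV = 30,
                                        ADJ = 30, positive = 40,
                                        negative = 40, negation = 15,
                                        overgen = 15),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("DAV", "IAV", "SV", "ADJ", "positive", "negative", "negation",
            "overgen")
  if (!all(need %in% names(sizes)) || any(sizes < 1))
    stop("sizes must name all of ", paste(need, collapse = ", "),
         ", each >= 1")
  if (anyDuplicated(names(sizes))) stop("overlapping category requests")
  extra <- c(filler_verb = 20L, ppron12 = 4L, ppron3 = 4L, filler = 120L)
  all_sizes <- c(sizes[need], extra)
  words <- make_words(sum(all_sizes), 2L)
  parts <- split(words, rep(seq_along(all_sizes), all_sizes))
  names(parts) <- names(all_sizes)
  list(
    lexicons = list(
      lcm = lexicon(stats::setNames(
        rep(c("DAV", "IAV", "SV", "ADJ"),
            times = sizes[c("DAV", "IAV", "SV", "ADJ")]),
        c(parts$DAV, parts$IAV, parts$SV, parts$ADJ)), "lcm"),
      sentiment = lexicon(stats::setNames(
        rep(c("positive", "negative"),
            times = sizes[c("positive", "negative")]),
        c(parts$positive, parts$negative)), "sentiment"),
      negation = lexicon(stats::setNames(
        rep("member", sizes[["negation"]]), parts$negation), "negation"),
      overgen = lexicon(stats::setNames(
        rep("member", sizes[["overgen"]]), parts$overgen), "overgen")),
    inventories = parts[c("filler_verb", "ppron12", "ppron3", "filler")])
}

#' Generate a random dependency tree skeleton
#'
#' Token 1 is the root; each later token attaches to its predecessor with
#' probability `shape` (chain step) and to the root otherwise. `shape = 0`
#' gives a star (MHD = 1); `shape = 1` gives a chain rooted at one end
#' (MDD = 1, MHD = n/2); intermediate values interpolate the expected
#' depth. Uses the current RNG state.
#'
#' @param n_tokens sentence length (>= 2).
#' @param shape mixing parameter in `[0, 1]`.
#' @return Integer head vector (head of token i; 0 = root).
#' @export
generate_tree <- function(n_tokens, shape) {
  if (n_tokens < 2L) stop("generate_tree needs n_tokens >= 2")
  if (shape < 0 || shape > 1) stop("shape must lie in [0, 1]")
  heads <- integer(n_tokens)
  if (n_tokens >= 2L) {
    chain <- stats::runif(n_tokens - 1L) < shape
    heads[2:n_tokens] <- ifelse(chain, seq_len(n_tokens - 1L), 1L)
  }
  heads
}

latent_value <- function(base, family, shifts, intercepts, v, m,
                         link = c("logit", "log", "identity")) {
  link <- match.arg(link)
  sh <- shifts[[family]]
  d <- 0
  if (!is.null(sh)) {
    d <- sum(c(veracity = v, modality = m, interaction = v * m)[names(sh)] *
               sh)
  }
  u <- intercepts[[family]]
  switch(link,
         logit = stats::plogis(stats::qlogis(base) + d + u),
         log = exp(log(base) + d + u),
         identity = base + d + u)
}

#' Generate one synthetic statement
#'
#' Samples sentence count and lengths (Poisson with condition- and
#' subject-shifted means), a tree per sentence, per-token cue-family
#' emissions, lemmas from the matching lexicons/inventories, syllable-
#' bearing surface forms, NKJP-style detailed POS tags (including ppron12,
#' ppron3, inf), and dependency relations. The raw text is the
#' space-joined surface string.
#'
#' @param veracity `"truth"` or `"lie"`.
#' @param modality `"written"` or `"transcribed"`.
#' @param intercepts named list of this subject's latent intercepts.
#' @param effects an [effect_spec()].
#' @param lexset result of [generate_lexicons()].
#' @return A `statement_record` (metadata fields other than
#'   veracity/modality unset; [generate_corpus()] fills them).
#' @export
generate_statement <- function(veracity, modality, intercepts, effects,
                               lexset) {
  v <- if (veracity == "lie") 0.5 else -0.5
  m <- if (modality == "transcribed") 0.5 else -0.5
  sh <- effects$shifts
  p_emit <- vapply(prob_families, function(f)
    latent_value(effects$prob[[f]], f, sh, intercepts, v, m, "logit"),
    numeric(1))
  if (sum(p_emit) >= 1)
    stop("emission probabilities sum to ", round(sum(p_emit), 3),
         " >= 1 after shifts (families: ",
         paste(prob_families, collapse = ", "), ")")
  p_filler <- 1 - sum(p_emit)
  lam_tok <- latent_value(effects$mean_tokens, "tokens", sh, intercepts,
                          v, m, "log")
  lam_sent <- latent_value(effects$mean_sentences, "sentences", sh,
                           intercepts, v, m, "log")
  lam_syl <- latent_value(effects$mean_syllables, "syllables", sh,
                          intercepts, v, m, "log")
  shape <- latent_value(effects$shape, "shape", sh, intercepts, v, m,
                        "logit")
  n_sent <- max(1L, stats::rpois(1, lam_sent))
  lex <- lexset$lexicons
  inv <- lexset$inventories
  lcm_entries <- unclass(lex$lcm)
  pool <- list(
    dav = names(lcm_entries)[lcm_entries == "DAV"],
    iav = names(lcm_entries)[lcm_entries == "IAV"],
    sv = names(lcm_entries)[lcm_entries == "SV"],
    adj = names(lcm_entries)[lcm_entries == "ADJ"],
    pos_sent = names(unclass(lex$sentiment))[unclass(lex$sentiment) ==
                                               "positive"],
    neg_sent = names(unclass(lex$sentiment))[unclass(lex$sentiment) ==
                                               "negative"],
    negation = names(unclass(lex$negation)),
    overgen = names(unclass(lex$overgen)),
    ppron12 = inv$ppron12, ppron3 = inv$ppron3, inf = inv$filler_verb)
  upos_of <- c(dav = "VERB", iav = "VERB", sv = "VERB", adj = "ADJ",
               pos_sent = "NOUN", neg_sent = "NOUN", negation = "PART",
               overgen = "ADV", ppron12 = "PRON", ppron3 = "PRON",
               inf = "VERB", filler = "NOUN")
  xpos_of <- c(dav = "fin", iav = "fin", sv = "praet", adj = "adj",
               pos_sent = "subst", neg_sent = "subst", negation = "qub",
               overgen = "adv", ppron12 = "ppron12:sg:nom",
               ppron3 = "ppron3:sg:nom", inf = "inf")
  filler_xpos <- c("subst", "prep", "fin", "adv", "ger", "num", "pact",
                   "ppas")
  filler_xpos_p <- c(0.45, 0.15, 0.12, 0.10, 0.06, 0.05, 0.04, 0.03)
  other_deprels <- c("nsubj", "obj", "advmod", "obl")
  other_p <- c(effects$p_subject_head,
               (1 - effects$p_subject_head) * c(0.35, 0.3, 0.35))
  sentences <- vector("list", n_sent)
  for (si in seq_len(n_sent)) {
    n <- max(2L, stats::rpois(1, lam_tok))
    cat_idx <- sample.int(length(prob_families) + 1L, n, replace = TRUE,
                          prob = c(p_emit, p_filler))
    cat <- c(prob_families, "filler")[cat_idx]
    lemma <- character(n)
    for (f in unique(cat)) {
      idx <- which(cat == f)
      lemma[idx] <- if (f == "filler")
        sample(inv$filler, length(idx), replace = TRUE)
      else sample(pool[[f]], length(idx), replace = TRUE)
    }
    surface <- lemma
    fil <- which(cat == "filler")
    if (length(fil)) {
      syl_n <- 1L + stats::rpois(length(fil), lam_syl)
      surface[fil] <- make_words(length(fil), syl_n)
      lemma[fil] <- surface[fil]
    }
    heads <- generate_tree(n, shape)
    deprel <- character(n)
    deprel[heads == 0L] <- "root"
    nonroot <- which(heads != 0L)
    is_adj <- cat == "adj"
    dr <- sample(other_deprels, length(nonroot), replace = TRUE,
                 prob = other_p)
    deprel[nonroot] <- ifelse(is_adj[nonroot], "amod", dr)
    xpos <- ifelse(cat == "filler",
                   sample(filler_xpos, n, replace = TRUE,
                          prob = filler_xpos_p),
                   xpos_of[cat])
    sentences[[si]] <- parsed_sentence(
      head = heads, surface = surface, lemma = lemma,
      upos = unname(upos_of[cat]), xpos = unname(xpos), deprel = deprel)
  }
  raw_text <- paste(unlist(lapply(sentences, function(s) s$surface)),
                    collapse = " ")
  structure(list(statement_id = NA_character_, subject_id = NA_character_,
                 topic = NA_character_, veracity = veracity,
                 modality = modality, sentences = sentences,
                 raw_text = raw_text),
            class = "statement_record")
}

#' Generate a full synthetic corpus
#'
#' `n_subjects` subjects, four statements each (truth/lie x
#' written/transcribed), with per-subject latent intercepts drawn once per
#' family. Deterministic given `seed`. When `dir` is given, the corpus is
#' written to disk — one CoNLL-U and one text file per statement, a
#' manifest CSV, the four lexicon TSVs, and `ground_truth.json` recording
#' the effect specification, per-subject intercepts, and the expected
#' emission probabilities per condition (at zero intercept) — and is then
#' loadable with [read_corpus()].
#'
#' @param n_subjects number of subjects (>= 2).
#' @param effects an [effect_spec()] or [preset_effects()] result.
#' @param seed integer seed.
#' @param dir optional output directory (created if needed).
#' @return list(corpus, lexicons, ground_truth, dir).
#' @export
generate_corpus <- function(n_subjects, effects = preset_effects("null"),
                            seed = 1L, dir = NULL) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  lexset <- generate_lexicons()
  subj_ids <- sprintf("s%04d", seq_len(n_subjects))
  u <- matrix(stats::rnorm(n_subjects * length(latent_families), 0,
                           effects$sigma_subject),
              nrow = n_subjects,
              dimnames = list(subj_ids, latent_families))
  conditions <- expand.grid(veracity = c("truth", "lie"),
                            modality = c("written", "transcribed"),
                            stringsAsFactors = FALSE)
  statements <- vector("list", n_subjects * 4L)
  k <- 0L
  for (i in seq_len(n_subjects)) {
    intercepts <- as.list(u[i, ])
    topic <- as.character(sample.int(13L, 1))
    for (ci in seq_len(nrow(conditions))) {
      k <- k + 1L
      st <- generate_statement(conditions$veracity[ci],
                               conditions$modality[ci],
                               intercepts, effects, lexset)
      st$statement_id <- sprintf("%s_%s_%s", subj_ids[i],
                                 substr(conditions$veracity[ci], 1, 1),
                                 substr(conditions$modality[ci], 1, 1))
      st$subject_id <- subj_ids[i]
      st$topic <- topic
      statements[[k]] <- st
    }
  }
  corpus <- structure(list(statements = statements), class = "corpus")
  # expected emission probabilities per condition at zero intercept
  zero_int <- stats::setNames(as.list(rep(0, length(latent_families))),
                              latent_families)
  expected <- lapply(seq_len(nrow(conditions)), function(ci) {
    v <- if (conditions$veracity[ci] == "lie") 0.5 else -0.5
    m <- if (conditions$modality[ci] == "transcribed") 0.5 else -0.5
    as.list(vapply(prob_families, function(f)
      latent_value(effects$prob[[f]], f, effects$shifts, zero_int, v, m,
                   "logit"), numeric(1)))
  })
  names(expected) <- paste(conditions$veracity, conditions$modality,
                           sep = "_")
  ground_truth <- list(n_subjects = n_subjects, seed = seed,
                       effects = unclass(effects),
                       subject_intercepts = as.data.frame(u),
                       expected_prob = expected)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rows <- lapply(corpus$statements, function(st) {
      conllu <- paste0(st$statement_id, ".conllu")
      txt <- paste0(st$statement_id, ".txt")
      write_conllu(st$sentences, file.path(dir, conllu))
      con <- file(file.path(dir, txt), open = "wb")
      writeLines(enc2utf8(st$raw_text), con, useBytes = TRUE)
      close(con)
      data.frame(statement_id = st$statement_id,
                 subject_id = st$subject_id, topic = st$topic,
                 veracity = st$veracity, modality = st$modality,
                 text_file = txt, conllu_file = conllu,
                 stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    for (fam in names(lexset$lexicons))
      write_lexicon(lexset$lexicons[[fam]],
                    file.path(dir, paste0("lexicon_", fam, ".tsv")))
    gt <- ground_truth
    gt$effects$shifts <- lapply(gt$effects$shifts, as.list)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(corpus = corpus, lexicons = lexset$lexicons,
                 ground_truth = ground_truth, dir = dir))
}
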