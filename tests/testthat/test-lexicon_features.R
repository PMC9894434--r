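planted_lexicons <- function() {
  list(
    lcm = lexicon(c(biegac = "DAV", pomagac = "IAV", wiedziec = "SV",
                    czarny = "ADJ"), "lcm"),
    sentiment = lexicon(c(dobry = "positive", mily = "positive",
                          zly = "negative"), "sentiment"),
    negation = lexicon(c(nigdy = "member", nie = "member"), "negation"),
    overgen = lexicon(c(zawsze = "member"), "overgen"))
}

# statement with known plants: 2x biegac (DAV), 1x pomagac (IAV),
# 3 positive + 1 negative, 2x nigdy, 1x zawsze
planted_statement <- function() {
  s1 <- parsed_sentence(
    head = c(0L, 1L, 1L, 1L, 1L, 1L),
    lemma = c("biegac", "dobry", "dobry", "nigdy", "zly", "pomagac"),
    upos = c("VERB", "NOUN", "NOUN", "PART", "NOUN", "VERB"),
    deprel = c("root", "obj", "obj", "advmod", "obj", "conj"))
  s2 <- parsed_sentence(
    head = c(0L, 1L, 1L, 1L),
    lemma = c("biegac", "Nigdy", "zawsze", "Dobry"),
    upos = c("VERB", "PART", "ADV", "NOUN"),
    deprel = c("root", "advmod", "advmod", "obj"))
  make_statement(list(s1, s2))
}

test_that("LCM counting matches the planted fixture", {
  st <- planted_statement()
  lc <- lcm_counts(st, planted_lexicons()$lcm)
  expect_equal(lc, list(dav = 2L, iav = 1L, sv = 0L, adj = 0L))
  # empty lexicon counts nothing
  empty <- lexicon(c(x = "DAV"), "lcm")[0]
  attr(empty, "family") <- "lcm"; class(empty) <- "lexicon"
  expect_equal(lcm_counts(st, empty), list(dav = 0L, iav = 0L, sv = 0L,
                                           adj = 0L))
})

test_that("only adjectives modifying subject nouns count as LCM ADJ", {
  # "black" amod-attached to "cat" whose deprel is obj: does not qualify
  we <- worked_example()
  expect_false(adjective_qualifies(5, we))

  # same shape but the noun is a subject
  subj <- parsed_sentence(
    head = c(2L, 0L, 2L), lemma = c("czarny", "biegac", "kot"),
    upos = c("ADJ", "VERB", "NOUN"), deprel = c("amod", "root", "nsubj"))
  expect_false(adjective_qualifies(1, subj))  # head is the root verb
  subj2 <- parsed_sentence(
    head = c(2L, 3L, 0L), lemma = c("czarny", "kot", "biegac"),
    upos = c("ADJ", "NOUN", "VERB"), deprel = c("amod", "nsubj", "root"))
  expect_false(TRUE %in% adjective_qualifies(2, subj2))  # not an amod token
  expect_true(adjective_qualifies(1, subj2))

  lex <- planted_lexicons()$lcm
  st_obj <- make_statement(list(subj))
  expect_equal(lcm_counts(st_obj, lex)$adj, 0L)
  st_subj <- make_statement(list(subj2))
  expect_equal(lcm_counts(st_subj, lex)$adj, 1L)

  # predicative adjective (deprel root with copula) is excluded by default
  pred <- parsed_sentence(
    head = c(2L, 0L, 2L), lemma = c("kot", "czarny", "byc"),
    upos = c("NOUN", "ADJ", "AUX"), deprel = c("nsubj", "root", "cop"))
  expect_equal(lcm_counts(make_statement(list(pred)), lex)$adj, 0L)

  # configured subject relations extend the rule (e.g. passive subjects)
  pass <- parsed_sentence(
    head = c(2L, 3L, 0L), lemma = c("czarny", "kot", "biegac"),
    upos = c("ADJ", "NOUN", "VERB"),
    deprel = c("amod", "nsubj:pass", "root"))
  cfgp <- feature_config(subject_deprels = c("nsubj", "nsubj:pass"))
  expect_equal(lcm_counts(make_statement(list(pass)), lex)$adj, 0L)
  expect_equal(lcm_counts(make_statement(list(pass)), lex, cfgp)$adj, 1L)
})

test_that("the LCM general score applies the 1/2/3/4 weights", {
  expect_equal(lcm_general_score(list(dav = 0, iav = 0, sv = 0, adj = 0)), 0)
  expect_equal(lcm_general_score(list(dav = 1, iav = 1, sv = 1, adj = 1)), 10)
  expect_equal(lcm_general_score(list(dav = 2, iav = 1, sv = 0, adj = 3)), 16)
  # slopes are exactly 1, 2, 3, 4
  base <- list(dav = 3, iav = 3, sv = 3, adj = 3)
  for (i in seq_along(base)) {
    bumped <- base; bumped[[i]] <- bumped[[i]] + 1
    expect_equal(lcm_general_score(bumped) - lcm_general_score(base),
                 c(1, 2, 3, 4)[i])
  }
})

test_that("sentiment and word-list counts are lemma-based and case-insensitive", {
  st <- planted_statement()
  lex <- planted_lexicons()
  sc <- sentiment_counts(st, lex$sentiment)
  expect_equal(sc, list(positive = 3L, negative = 1L))
  expect_equal(wordlist_count(st, lex$negation), 2L)  # "nigdy" + "Nigdy"
  expect_equal(wordlist_count(st, lex$overgen), 1L)
  # no lexicon words at all
  none <- make_statement(list(parsed_sentence(head = c(0L, 1L),
                                              lemma = c("aaa", "bbb"))))
  expect_equal(sentiment_counts(none, lex$sentiment),
               list(positive = 0L, negative = 0L))
  expect_equal(wordlist_count(none, lex$negation), 0L)
})

test_that("POS counting keys on the first XPOS segment", {
  st <- make_statement(list(parsed_sentence(
    head = c(0L, 1L, 1L, 1L, 1L),
    xpos = c("fin:sg", "inf", "inf", "ppron3:sg:nom", "weird:tag"))))
  pc <- pos_counts(st)
  expect_equal(unname(pc["inf"]), 2L)
  expect_equal(unname(pc["ppron3"]), 1L)
  expect_equal(unname(pc["fin"]), 1L)
  expect_equal(sum(pc), 4L)  # untracked "weird" ignored
  # all-zero map when nothing is tracked
  st2 <- make_statement(list(parsed_sentence(head = 0L, xpos = "interp")))
  expect_true(all(pos_counts(st2) == 0L))
})

test_that("length features count sentences, tokens and characters", {
  st <- make_statement(list(worked_example()),
                       raw_text = "My neighbour has a black cat")
  lf <- length_features(st)
  expect_equal(lf, list(n_sentences = 1L, n_tokens = 6L,
                        n_characters = 23L))
  st$raw_text <- ""
  expect_equal(length_features(st)$n_characters, 0L)
  # doubling the statement doubles all three
  st2 <- make_statement(rep(list(worked_example()), 2),
                        raw_text = paste(rep("My neighbour has a black cat",
                                             2), collapse = " "))
  expect_equal(length_features(st2),
               list(n_sentences = 2L, n_tokens = 12L, n_characters = 46L))
})

test_that("extract_features assembles the documented 43-column battery", {
  cfg <- feature_config()
  cols <- feature_columns(cfg)
  expect_length(cols, 43)
  st <- planted_statement()
  fv <- extract_features(st, planted_lexicons(), cfg)
  expect_identical(names(fv), cols)
  expect_equal(fv$dav, 2L)
  expect_equal(fv$iav, 1L)
  expect_equal(fv$lcm_general, 4)
  expect_equal(fv$pos_sentiment, 3L)
  expect_equal(fv$neg_sentiment, 1L)
  expect_equal(fv$negations, 2L)
  expect_equal(fv$overgen, 1L)
  expect_equal(fv$n_tokens, 10L)
  # determinism: identical inputs, identical vector
  expect_identical(fv, extract_features(st, planted_lexicons(), cfg))
  # a missing lexicon leaves NA, never silent zeros
  fv2 <- extract_features(st, planted_lexicons()[c("lcm", "negation")], cfg)
  expect_true(is.na(fv2$pos_sentiment))
  expect_true(is.na(fv2$overgen))
  expect_equal(fv2$dav, 2L)
})

test_that("every count feature is bounded by token count", {
  set.seed(31)
  gen <- generate_corpus(6, preset_effects("null"), seed = 31)
  tab <- extract_feature_table(gen$corpus, gen$lexicons)
  counts <- names(tab)[is_count_feature(names(tab))]
  for (cc in counts)
    expect_true(all(tab[[cc]] <= tab$n_tokens * 4), info = cc)
  plain <- setdiff(counts, "lcm_general")  # general score is weighted
  for (cc in plain)
    expect_true(all(tab[[cc]] <= tab$n_tokens), info = cc)
})

test_that("features are invariant to sentence order within a statement", {
  set.seed(17)
  gen <- generate_corpus(2, preset_effects("null"), seed = 17)
  st <- gen$corpus$statements[[1]]
  st_rev <- st
  st_rev$sentences <- rev(st$sentences)
  f1 <- extract_features(st, gen$lexicons)
  f2 <- extract_features(st_rev, gen$lexicons)
  f1$n_characters <- f2$n_characters <- NULL  # raw_text untouched by reorder
  expect_identical(f1, f2)
})

test_that("NE annotations in MISC are counted only when configured", {
  s <- parsed_sentence(head = c(0L, 1L, 1L),
                       misc = c("NE=persName", "_", "SpaceAfter=No|NE=geog"))
  st <- make_statement(list(s))
  cfg <- feature_config(ne_count = TRUE)
  fv <- extract_features(st, list(), cfg)
  expect_equal(fv$ne_count, 2L)
  expect_false("ne_count" %in% names(extract_features(st, list())))
})
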