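test_that("generated lexicons are sized, disjoint, and seed-deterministic", {
  a <- generate_lexicons(seed = 401)
  b <- generate_lexicons(seed = 401)
  expect_identical(a, b)
  expect_false(identical(a, generate_lexicons(seed = 402)))
  sizes <- c(DAV = 5, IAV = 5, SV = 5, ADJ = 5, positive = 7, negative = 7,
             negation = 3, overgen = 3)
  lx <- generate_lexicons(sizes, seed = 403)
  expect_length(lx$lexicons$lcm, 20)
  expect_length(lx$lexicons$sentiment, 14)
  pools <- c(lapply(lx$lexicons, names), lx$inventories)
  all_words <- unlist(pools)
  expect_equal(anyDuplicated(all_words), 0)  # pairwise disjoint
  expect_error(generate_lexicons(c(DAV = 2), seed = 1), "sizes")
})

test_that("generate_tree hits the star and chain limits exactly", {
  set.seed(404)
  expect_equal(mhd_sentence(parsed_sentence(head = generate_tree(10, 0))),
               1.0)
  chain <- parsed_sentence(head = generate_tree(5, 1))
  expect_equal(mhd_sentence(chain), 2.5)
  expect_equal(mdd_sentence(chain), 1.0)
  expect_error(generate_tree(1, 0.5), "n_tokens")
  expect_error(generate_tree(5, 1.5), "shape")
  # 1000 generated trees all pass validation
  for (k in 1:1000) {
    n <- sample(2:20, 1)
    s <- sample(c(0, 1, runif(1)), 1)
    expect_silent(validate_sentence(
      data.frame(index = seq_len(n), surface = "w", lemma = "w",
                 upos = "X", xpos = "x", head = generate_tree(n, s),
                 deprel = "d", misc = "_")))
  }
  # intermediate shapes interpolate expected depth between star and chain
  set.seed(405)
  mhd_at <- function(sh) mean(replicate(300, mhd_sentence(
    parsed_sentence(head = generate_tree(12, sh)))))
  expect_lt(mhd_at(0.2), mhd_at(0.8))
})

test_that("generated statements round-trip through CoNLL-U and validate", {
  set.seed(406)
  lx <- generate_lexicons()
  zero_int <- stats::setNames(
    as.list(rep(0, length(veracue:::latent_families))),
    veracue:::latent_families)
  st <- generate_statement("lie", "transcribed", zero_int,
                           effect_spec(), lx)
  expect_s3_class(st, "statement_record")
  expect_gte(length(st$sentences), 1)
  tmp <- withr::local_tempfile(fileext = ".conllu")
  write_conllu(st$sentences, tmp)
  back <- read_conllu(tmp)
  expect_length(back, length(st$sentences))
  expect_identical(lapply(back, `[[`, "head"),
                   lapply(st$sentences, `[[`, "head"))
  # raw text is the space-joined surface forms
  expect_equal(st$raw_text,
               paste(unlist(lapply(st$sentences, `[[`, "surface")),
                     collapse = " "))
})

test_that("emission shifts move empirical rates by the latent amount", {
  lx <- generate_lexicons(seed = 407)
  eff <- effect_spec(shifts = list(pos_sent = c(veracity = 0.6)))
  zero_int <- stats::setNames(
    as.list(rep(0, length(veracue:::latent_families))),
    veracue:::latent_families)
  rate_of <- function(veracity, n = 400) {
    set.seed(408)
    counts <- replicate(n, {
      st <- generate_statement(veracity, "written", zero_int, eff, lx)
      toks <- unlist(lapply(st$sentences, `[[`, "lemma"))
      pos <- names(unclass(lx$lexicons$sentiment))[
        unclass(lx$lexicons$sentiment) == "positive"]
      c(sum(toks %in% pos), length(toks))
    })
    sum(counts[1, ]) / sum(counts[2, ])
  }
  p0 <- plogis(qlogis(0.05) - 0.3)   # truth cell
  p1 <- plogis(qlogis(0.05) + 0.3)   # lie cell
  expect_equal(rate_of("truth"), p0, tolerance = 0.15)
  expect_equal(rate_of("lie"), p1, tolerance = 0.15)
  # overflow after shifts is a named error
  bad <- effect_spec(shifts = list(pos_sent = c(veracity = 12)))
  expect_error(generate_statement("lie", "written", zero_int, bad, lx),
               "emission probabilities")
})

test_that("null-corpus condition cells differ only by sampling noise", {
  tab <- cached_corpus("null")
  for (v in c("pos_sentiment", "negations", "n_tokens", "mdd")) {
    x <- tab[[v]] / if (is_count_feature(v)) tab$n_tokens else 1
    tt <- stats::t.test(x[tab$veracity == "truth"],
                        x[tab$veracity == "lie"])
    expect_gt(tt$p.value, 0.001)
  }
})

test_that("corpus generation honours the 4-statements-per-subject design", {
  gen <- generate_corpus(2, preset_effects("null"), seed = 409)
  expect_length(gen$corpus$statements, 8)
  meta <- do.call(rbind, lapply(gen$corpus$statements, function(st)
    data.frame(subject = st$subject_id, veracity = st$veracity,
               modality = st$modality)))
  expect_equal(as.integer(table(meta$subject)), c(4L, 4L))
  cells <- table(meta$veracity, meta$modality)
  expect_true(all(cells == 2))
})

test_that("on-disk corpora are byte-identical across same-seed runs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_corpus(4, preset_effects("paper_like"), seed = 410, dir = d1)
  generate_corpus(4, preset_effects("paper_like"), seed = 410, dir = d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  expect_gt(length(f1), 8 * 2)  # statements + manifest + lexicons + truth
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  # and the written corpus loads back through corpus_io
  corp <- read_corpus(file.path(d1, "manifest.csv"))
  expect_length(corp$statements, 16)
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"))
  expect_equal(gt$n_subjects, 4)
  expect_true(all(c("effects", "subject_intercepts", "expected_prob") %in%
                    names(gt)))
})

test_that("planted effects are recovered by the full pipeline", {
  # sign recovery on a paper_like corpus: veracity effects of the shifted
  # families come out with the planted latent signs
  set.seed(411)
  gen <- generate_corpus(150, preset_effects("paper_like"), seed = 411)
  tab <- extract_feature_table(gen$corpus, gen$lexicons)
  res <- analyze_all(tab)
  ver <- res[res$effect == "veracity", ]
  b_of <- function(v) ver$b[ver$variable == v]
  expect_lt(b_of("n_tokens"), 0)     # truths longer
  expect_lt(b_of("fog"), 0)          # truths foggier
  expect_gt(b_of("pos_sentiment"), 0)  # lies more positive words
  expect_gt(b_of("pos_inf"), 0)      # lies more infinitives
  mod <- res[res$effect == "modality", ]
  expect_gt(mod$b[mod$variable == "mdd"], 0)  # speech more complex
})
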