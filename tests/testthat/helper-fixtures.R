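# Shared fixtures and independent oracles. Oracles are deliberately written
# with different algorithms/styles from the package implementations.

# the six-token worked-example sentence: "My neighbour has a black cat",
# heads (2, 3, 0, 6, 6, 3), root = "has"
worked_example <- function() {
  parsed_sentence(head = c(2L, 3L, 0L, 6L, 6L, 3L),
                  surface = c("My", "neighbour", "has", "a", "black", "cat"),
                  upos = c("PRON", "NOUN", "VERB", "DET", "ADJ", "NOUN"),
                  deprel = c("nmod", "nsubj", "root", "det", "amod", "obj"))
}

make_statement <- function(sentences, raw_text = NULL, statement_id = "st1",
                           subject_id = "s1", veracity = "truth",
                           modality = "written") {
  if (is.null(raw_text))
    raw_text <- paste(unlist(lapply(sentences, function(s) s$surface)),
                      collapse = " ")
  structure(list(statement_id = statement_id, subject_id = subject_id,
                 topic = "1", veracity = veracity, modality = modality,
                 sentences = sentences, raw_text = raw_text),
            class = "statement_record")
}

make_words_fixture <- function(n) paste0("w", seq_len(n))

# independent random-tree generator: random root, then attach each node (in
# shuffled order) to a uniformly chosen already-attached node
random_tree_heads <- function(n) {
  stopifnot(n >= 2)
  ord <- sample.int(n)
  heads <- integer(n)
  attached <- ord[1]
  heads[ord[1]] <- 0L
  for (k in 2:n) {
    node <- ord[k]
    heads[node] <- if (length(attached) == 1L) attached
                   else sample(attached, 1L)
    attached <- c(attached, node)
  }
  heads
}

# brute-force oracles: direct per-token scans, no shared code with the package
oracle_mdd <- function(heads) {
  total <- 0; npairs <- 0
  for (i in seq_along(heads)) {
    if (heads[i] == 0L) next
    total <- total + abs(i - heads[i])
    npairs <- npairs + 1
  }
  total / npairs
}

oracle_mhd <- function(heads) {
  depths <- c()
  for (i in seq_along(heads)) {
    if (heads[i] == 0L) next
    d <- 0; j <- i
    while (heads[j] != 0L) {   # one edge per head-pointer step, stop at root
      j <- heads[j]
      d <- d + 1
    }
    depths <- c(depths, d)
  }
  mean(depths)
}

# brute-force Holm step-down, by the definition: adjusted p of the i-th
# smallest is max over j <= i of min(1, (m - j + 1) * p_(j))
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- 0
    for (j in seq_len(i)) {
      val <- min(1, (m - j + 1) * p[ord[j]])
      if (val > best) best <- val
    }
    adj[ord[i]] <- best
  }
  adj
}

# balanced 2x2 within-subject metadata for n subjects
balanced_meta <- function(n_subjects) {
  data.frame(
    subject_id = rep(sprintf("s%04d", seq_len(n_subjects)), each = 4),
    veracity = rep(c("truth", "lie", "truth", "lie"), n_subjects),
    modality = rep(c("written", "written", "transcribed", "transcribed"),
                   n_subjects),
    stringsAsFactors = FALSE)
}

# simulate a response from the random-intercept model for balanced_meta
simulate_lmm_y <- function(design, beta, sigma_u, sigma) {
  subj <- unique(design$groups)
  u <- stats::rnorm(length(subj), 0, sigma_u)
  drop(design$X %*% beta) + u[match(design$groups, subj)] +
    stats::rnorm(nrow(design$X), 0, sigma)
}

# shared 400-subject corpora for the calibration/classifier checks, built
# once per test run
.corpus_cache <- new.env(parent = emptyenv())

cached_corpus <- function(preset, n_subjects = 400, seed = 2026) {
  key <- paste(preset, n_subjects, seed, sep = "_")
  if (is.null(.corpus_cache[[key]])) {
    gen <- generate_corpus(n_subjects, preset_effects(preset), seed = seed)
    .corpus_cache[[key]] <- extract_feature_table(gen$corpus, gen$lexicons)
  }
  .corpus_cache[[key]]
}
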