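# Reading and validation of CoNLL-U parses, corpus manifests, lexicons, and
# feature tables. Tokens are kept in a data.frame, one per sentence, with
# 1-based indices and head = 0 marking the root, exactly as CoNLL-U defines.

#' Construct a parsed sentence from token columns
#'
#' Builds and validates a `parsed_sentence` object: a data.frame of tokens
#' with columns `index`, `surface`, `lemma`, `upos`, `xpos`, `head`,
#' `deprel`, `misc`. Indices must be contiguous `1..n`, exactly one token
#' must have `head == 0` (the root), and the head pointers must form a tree.
#'
#' @param index integer token positions (1-based).
#' @param surface,lemma,upos,xpos,deprel,misc character vectors recycled to
#'   the sentence length; `misc` may carry `key=value` annotations such as
#'   `NE=persName`.
#' @param head integer head pointers; 0 denotes the root.
#' @return A data.frame of class `parsed_sentence`.
#' @examples
#' s <- parsed_sentence(head = c(2, 3, 0, 6, 6, 3),
#'                      surface = c("My", "neighbour", "has", "a", "black", "cat"))
#' mdd_sentence(s)
#' @export
parsed_sentence <- function(head, index = seq_along(head), surface = "_",
                            lemma = tolower(surface), upos = "_", xpos = "_",
                            deprel = "_", misc = "_") {
  n <- length(head)
  s <- data.frame(index = as.integer(index),
                  surface = rep_len(as.character(surface), n),
                  lemma = rep_len(as.character(lemma), n),
                  upos = rep_len(as.character(upos), n),
                  xpos = rep_len(as.character(xpos), n),
                  head = as.integer(head),
                  deprel = rep_len(as.character(deprel), n),
                  misc = rep_len(as.character(misc), n),
                  stringsAsFactors = FALSE)
  validate_sentence(s)
  class(s) <- c("parsed_sentence", "data.frame")
  s
}

#' Validate the tree structure of a sentence
#'
#' Checks the `parsed_sentence` invariants: contiguous 1-based indices,
#' integer heads in `0..n` with `head != index`, exactly one root, and no
#' cycles (every token reaches the root by following head pointers).
#'
#' @param s a token data.frame.
#' @param what label used in error messages.
#' @return `s`, invisibly. Errors on any violation.
#' @export
validate_sentence <- function(s, what = "sentence") {
  n <- nrow(s)
  if (n < 1L) stop(what, ": empty sentence")
  if (!identical(as.integer(s$index), seq_len(n)))
    stop(what, ": token indices are not contiguous 1..", n)
  h <- as.integer(s$head)
  if (anyNA(h) || any(h < 0L) || any(h > n))
    stop(what, ": head pointers must lie in 0..", n)
  if (any(h == s$index)) stop(what, ": token is its own head")
  if (sum(h == 0L) != 1L)
    stop(what, ": expected exactly one root, found ", sum(h == 0L))
  # walk each token towards the root; > n steps means a cycle
  for (i in seq_len(n)) {
    j <- i
    for (step in seq_len(n)) {
      j <- h[j]
      if (j == 0L) break
    }
    if (j != 0L) stop(what, ": cycle detected involving token ", i)
  }
  invisible(s)
}

#' Read a CoNLL-U file
#'
#' Parses a 10-column CoNLL-U file into a list of [parsed_sentence()]
#' objects. Multiword-token ranges (`1-2`) and empty nodes (`1.1`) are
#' skipped: they have no single surface position for distance computations.
#' Comment lines (`#`) are ignored; blank lines separate sentences.
#'
#' @param path path to a UTF-8 CoNLL-U file.
#' @return List of `parsed_sentence` objects.
#' @export
read_conllu <- function(path) {
  if (!file.exists(path)) stop("CoNLL-U file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  buf <- list()
  flush_sentence <- function(buf, n_sent) {
    s <- do.call(rbind, buf)
    validate_sentence(s, what = paste0(path, " sentence ", n_sent))
    class(s) <- c("parsed_sentence", "data.frame")
    s
  }
  for (k in seq_along(lines)) {
    line <- lines[[k]]
    if (startsWith(line, "#")) next
    if (!nzchar(trimws(line))) {
      if (length(buf)) {
        sentences[[length(sentences) + 1L]] <-
          flush_sentence(buf, length(sentences) + 1L)
        buf <- list()
      }
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 10L)
      stop("malformed CoNLL-U line ", k, " in ", path,
           ": expected 10 tab-separated fields, got ", length(f))
    if (grepl("[-.]", f[1])) next  # multiword range or empty node
    idx <- suppressWarnings(as.integer(f[1]))
    hd <- suppressWarnings(as.integer(f[7]))
    if (is.na(idx) || is.na(hd))
      stop("malformed CoNLL-U line ", k, " in ", path,
           ": non-integer ID or HEAD")
    buf[[length(buf) + 1L]] <- data.frame(
      index = idx, surface = f[2], lemma = f[3], upos = f[4], xpos = f[5],
      head = hd, deprel = f[8], misc = f[10], stringsAsFactors = FALSE)
  }
  if (length(buf))
    sentences[[length(sentences) + 1L]] <-
      flush_sentence(buf, length(sentences) + 1L)
  sentences
}

#' Write sentences to a CoNLL-U file
#'
#' Serializes a list of `parsed_sentence` objects using `_` for the FEATS
#' and DEPS columns. Round-trips losslessly through [read_conllu()].
#'
#' @param sentences list of `parsed_sentence` objects.
#' @param path output path.
#' @export
write_conllu <- function(sentences, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (s in sentences) {
    lines <- paste(s$index, s$surface, s$lemma, s$upos, s$xpos, "_",
                   s$head, s$deprel, "_", s$misc, sep = "\t")
    writeLines(enc2utf8(c(lines, "")), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a corpus manifest
#'
#' The manifest is a CSV with columns `statement_id`, `subject_id`, `topic`,
#' `veracity` (`truth`/`lie`), `modality` (`written`/`transcribed`),
#' `text_file`, `conllu_file`; file paths are resolved relative to the
#' manifest's directory. Returns metadata stubs only; [read_corpus()] loads
#' the parses and raw texts.
#'
#' @param path manifest CSV path.
#' @return data.frame of validated statement metadata.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", fileEncoding = "UTF-8")
  need <- c("statement_id", "subject_id", "topic", "veracity", "modality",
            "text_file", "conllu_file")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(m$statement_id))
    stop("duplicate statement_id in manifest: ",
         paste(unique(m$statement_id[duplicated(m$statement_id)]),
               collapse = ", "))
  bad_v <- !m$veracity %in% c("truth", "lie")
  if (any(bad_v))
    stop("invalid veracity in manifest row(s) ",
         paste(which(bad_v), collapse = ", "),
         " (value(s): ", paste(unique(m$veracity[bad_v]), collapse = ", "),
         "); must be 'truth' or 'lie'")
  bad_m <- !m$modality %in% c("written", "transcribed")
  if (any(bad_m))
    stop("invalid modality in manifest row(s) ",
         paste(which(bad_m), collapse = ", "),
         "; must be 'written' or 'transcribed'")
  m[need]
}

#' Load a full corpus from a manifest
#'
#' Reads the manifest, then each statement's CoNLL-U parse and raw text.
#' All referenced files must exist; missing paths are reported together.
#'
#' @param manifest_path manifest CSV path.
#' @return A `corpus` object: list of `statement_record`s, each with
#'   `statement_id`, `subject_id`, `topic`, `veracity`, `modality`,
#'   `sentences` (list of `parsed_sentence`) and `raw_text`.
#' @export
read_corpus <- function(manifest_path) {
  m <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  conllu <- resolve(m$conllu_file)
  txt <- resolve(m$text_file)
  gone <- c(conllu[!file.exists(conllu)], txt[!file.exists(txt)])
  if (length(gone))
    stop("manifest references missing files: ", paste(gone, collapse = ", "))
  statements <- lapply(seq_len(nrow(m)), function(i) {
    rec <- list(statement_id = m$statement_id[i],
                subject_id = m$subject_id[i],
                topic = m$topic[i],
                veracity = m$veracity[i],
                modality = m$modality[i],
                sentences = read_conllu(conllu[i]),
                raw_text = paste(readLines(txt[i], encoding = "UTF-8",
                                           warn = FALSE), collapse = "\n"))
    if (length(rec$sentences) < 1L)
      stop("statement ", rec$statement_id, " has no sentences")
    class(rec) <- "statement_record"
    rec
  })
  structure(list(statements = statements), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  v <- vapply(x$statements, `[[`, "", "veracity")
  mo <- vapply(x$statements, `[[`, "", "modality")
  cat("<corpus> ", length(x$statements), " statements, ",
      length(unique(vapply(x$statements, `[[`, "", "subject_id"))),
      " subjects (", sum(v == "truth"), " truth / ", sum(v == "lie"),
      " lie; ", sum(mo == "written"), " written / ",
      sum(mo == "transcribed"), " transcribed)\n", sep = "")
  invisible(x)
}

lexicon_categories <- list(
  lcm = c("DAV", "IAV", "SV", "ADJ"),
  sentiment = c("positive", "negative"),
  negation = "member",
  overgen = "member")

#' Read a category lexicon
#'
#' A lexicon is a two-column TSV, `lemma<TAB>category`. Lemmas are
#' lower-cased on load and matching is case-insensitive exact match on the
#' lemma. Valid categories per family: `lcm` = DAV/IAV/SV/ADJ, `sentiment` =
#' positive/negative, `negation`/`overgen` = member.
#'
#' @param path TSV path.
#' @param family one of `"lcm"`, `"sentiment"`, `"negation"`, `"overgen"`.
#' @return A `lexicon` object: named character vector (lemma -> category)
#'   with attribute `family`.
#' @export
read_lexicon <- function(path, family = c("lcm", "sentiment", "negation",
                                          "overgen")) {
  family <- match.arg(family)
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  rows <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character", fileEncoding = "UTF-8",
                            col.names = c("lemma", "category"))
  lexicon(stats::setNames(rows$category, rows$lemma), family)
}

#' Construct a lexicon from a named vector
#'
#' @param entries named character vector, lemma -> category.
#' @param family lexicon family (see [read_lexicon()]).
#' @return A validated `lexicon` object.
#' @export
lexicon <- function(entries, family = c("lcm", "sentiment", "negation",
                                        "overgen")) {
  family <- match.arg(family)
  lemmas <- tolower(names(entries))
  cats <- as.character(entries)
  if (any(!nzchar(lemmas))) stop("lexicon contains empty lemma")
  ok <- lexicon_categories[[family]]
  bad <- setdiff(unique(cats), ok)
  if (length(bad))
    stop("invalid category for family '", family, "': ",
         paste(bad, collapse = ", "), " (allowed: ",
         paste(ok, collapse = ", "), ")")
  if (anyDuplicated(lemmas)) {
    dup <- unique(lemmas[duplicated(lemmas)])
    conf <- dup[vapply(dup, function(l)
      length(unique(cats[lemmas == l])) > 1L, logical(1))]
    if (length(conf))
      stop("duplicate lemma(s) with conflicting categories: ",
           paste(conf, collapse = ", "))
    keep <- !duplicated(lemmas)
    lemmas <- lemmas[keep]; cats <- cats[keep]
  }
  structure(stats::setNames(cats, lemmas), family = family,
            class = "lexicon")
}

#' Write a lexicon to TSV
#' @param lex a `lexicon` object.
#' @param path output path.
#' @export
write_lexicon <- function(lex, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(paste(names(lex), unname(unclass(lex)), sep = "\t")),
             con, useBytes = TRUE)
  invisible(path)
}

#' Write a feature table to TSV
#'
#' One row per statement, columns in the canonical battery order (metadata
#' first). Missing values are serialized as empty fields and read back as
#' `NA` by [read_feature_table()]; the write/read pair is lossless.
#'
#' @param table feature table data.frame from [extract_feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("feature table must be a non-empty data.frame")
  utils::write.table(table, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return data.frame with empty fields restored as `NA`.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                           fileEncoding = "UTF-8", check.names = FALSE)
  meta_chr <- intersect(c("statement_id", "subject_id", "topic", "veracity",
                          "modality"), names(tab))
  for (cc in meta_chr) tab[[cc]] <- as.character(tab[[cc]])
  # feature columns are numeric; an all-NA column comes back logical
  for (cc in setdiff(names(tab), meta_chr))
    if (is.logical(tab[[cc]])) tab[[cc]] <- as.numeric(tab[[cc]])
  tab
}
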