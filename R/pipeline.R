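# End-to-end driver: simulate -> extract -> analyze -> classify, with all
# artifacts written as plain text so a rerun under the same seed is
# byte-identical.

#' Run the full pipeline on a synthetic corpus
#'
#' Generates a corpus (written under `out_dir/corpus`), extracts the
#' feature battery, fits the contrast mixed models with Holm correction,
#' and runs group-aware k-fold classification for the requested subsets.
#' Writes `features.tsv`, `results.tsv` and `cv.json` under `out_dir`.
#' Every stage is seeded from `seed`, so two runs with the same arguments
#' produce byte-identical files.
#'
#' @param out_dir output directory.
#' @param n_subjects subjects in the synthetic corpus.
#' @param preset effect preset name for [preset_effects()], or an
#'   [effect_spec()] object.
#' @param seed integer master seed.
#' @param k CV folds.
#' @param subsets modality subsets to classify.
#' @param model classifier name.
#' @return Invisibly, list(feature_table, results, cv).
#' @export
run_pipeline <- function(out_dir, n_subjects = 100, preset = "null",
                         seed = 1L, k = 20L, subsets = "all",
                         model = "baseline") {
  effects <- if (inherits(preset, "effect_spec")) preset
             else preset_effects(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_corpus(n_subjects, effects, seed = seed,
                         dir = file.path(out_dir, "corpus"))
  corpus <- read_corpus(file.path(out_dir, "corpus", "manifest.csv"))
  lexicons <- list(
    lcm = read_lexicon(file.path(out_dir, "corpus", "lexicon_lcm.tsv"),
                       "lcm"),
    sentiment = read_lexicon(
      file.path(out_dir, "corpus", "lexicon_sentiment.tsv"), "sentiment"),
    negation = read_lexicon(
      file.path(out_dir, "corpus", "lexicon_negation.tsv"), "negation"),
    overgen = read_lexicon(
      file.path(out_dir, "corpus", "lexicon_overgen.tsv"), "overgen"))
  tab <- extract_feature_table(corpus, lexicons)
  write_feature_table(tab, file.path(out_dir, "features.tsv"))
  results <- analyze_all(tab)
  write_results(results, file.path(out_dir, "results.tsv"))
  cv <- lapply(subsets, function(sub)
    classify_statements(tab, subset = sub, k = k, model = model,
                        seed = seed))
  names(cv) <- subsets
  cv_json <- lapply(cv, function(r)
    list(subset = r$subset, model = r$model_name, k = r$k,
         mean_acc = r$mean_acc, se_acc = r$se_acc,
         fold_accuracies = r$fold_accuracies, seed = r$seed, n = r$n))
  jsonlite::write_json(cv_json, file.path(out_dir, "cv.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(feature_table = tab, results = results, cv = cv))
}
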