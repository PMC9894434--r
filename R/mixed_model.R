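# Random-intercept linear mixed models for the condition contrasts.
#
# For each dependent variable y (log-transformed, count families first
# normalized per token):
#
#   y = X beta + u[subject] + eps,  u ~ N(0, sigma_u^2), eps ~ N(0, sigma^2)
#
# with X = (1, v, m, v*m) under sum contrasts v, m in {-0.5, +0.5}. The fit
# profiles beta and sigma^2 out of the REML criterion and optimizes the
# single variance ratio lambda = sigma_u^2 / sigma^2 on [0, lambda_max]; the
# grouped structure gives V^{-1} and log|V| in closed form per subject
# (Woodbury), so each criterion evaluation is O(N).

count_feature_families <- c("dav", "iav", "sv", "adj", "lcm_general",
                            "pos_sentiment", "neg_sentiment", "negations",
                            "overgen")

#' Is a feature normalized per token before the log transform?
#'
#' Count families (LCM, sentiment, negation, over-generalization, POS tag
#' counts) are divided by statement token count; length and complexity
#' measures are not.
#'
#' @param variable feature column name(s).
#' @return logical vector.
#' @export
is_count_feature <- function(variable) {
  variable %in% count_feature_families | startsWith(variable, "pos_") |
    variable == "ne_count"
}

#' Normalize and log-transform a feature
#'
#' Count features are converted to per-token rates, then `log(x + 1)` is
#' applied (adding 1 before the log keeps zeros at zero and every value
#' positive); non-count features get `log(x + 1)` directly. The rate is
#' formed before the +1 so the transform acts on a quantity in a comparable
#' range across statements. Missing values propagate.
#'
#' @param values numeric vector of raw per-statement feature values (>= 0).
#' @param n_tokens per-statement token counts.
#' @param normalize divide by `n_tokens` first?
#' @return Transformed numeric vector.
#' @export
normalize_and_transform <- function(values, n_tokens = NULL,
                                    normalize = FALSE) {
  if (normalize) {
    if (is.null(n_tokens)) stop("n_tokens required when normalize = TRUE")
    if (any(n_tokens[!is.na(values)] == 0))
      stop("n_tokens = 0 for a statement with a count value")
    values <- values / n_tokens
  }
  log(values + 1)
}

#' Build the sum-contrast design matrix
#'
#' Columns: intercept, veracity contrast (truth = -0.5, lie = +0.5),
#' modality contrast (written = -0.5, transcribed = +0.5), and their
#' product. The grouping vector is the subject id.
#'
#' @param metadata data.frame with `veracity`, `modality`, `subject_id`.
#' @return list(X = numeric matrix with columns `(Intercept)`, `veracity`,
#'   `modality`, `veracity:modality`; groups = character subject ids).
#' @export
build_design <- function(metadata) {
  if (!all(metadata$veracity %in% c("truth", "lie")))
    stop("veracity must be 'truth' or 'lie'")
  if (!all(metadata$modality %in% c("written", "transcribed")))
    stop("modality must be 'written' or 'transcribed'")
  v <- ifelse(metadata$veracity == "lie", 0.5, -0.5)
  m <- ifelse(metadata$modality == "transcribed", 0.5, -0.5)
  X <- cbind(`(Intercept)` = 1, veracity = v, modality = m,
             `veracity:modality` = v * m)
  list(X = X, groups = as.character(metadata$subject_id))
}

# Profiled REML criterion pieces for one lambda. Returns GLS quantities.
reml_pieces <- function(lambda, y, X, group_idx) {
  N <- length(y)
  p <- ncol(X)
  # V = I + lambda * J within each subject block;
  # V^{-1} x = x - (lambda / (1 + n_i lambda)) * J x  (Woodbury)
  n_i <- tabulate(group_idx)
  w <- lambda / (1 + n_i * lambda)           # per-group shrinkage
  Vinv <- function(M) {
    M <- as.matrix(M)
    gs <- rowsum(M, group_idx, reorder = TRUE)   # group sums, rows 1..G
    M - (w[group_idx] * gs[group_idx, , drop = FALSE])
  }
  XtViX <- crossprod(X, Vinv(X))
  XtViy <- crossprod(X, Vinv(y))
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) stop("singular design in REML fit")
  beta <- backsolve(cX, backsolve(cX, XtViy, transpose = TRUE))
  r <- y - X %*% beta
  rss <- sum(r * Vinv(r))
  logdetV <- sum(log1p(n_i * lambda))
  logdetXtViX <- 2 * sum(log(diag(cX)))
  # REML log-likelihood up to an additive constant
  sigma2 <- rss / (N - p)
  loglik <- -0.5 * (logdetV + logdetXtViX + (N - p) * log(rss))
  list(beta = drop(beta), sigma2 = sigma2, loglik = loglik,
       XtViX_chol = cX, rss = rss)
}

#' Fit a random-intercept linear mixed model by REML
#'
#' Deterministic profiled REML: for fixed variance ratio
#' `lambda = sigma_u^2 / sigma^2` the GLS estimate of `beta` and the
#' residual scale have closed forms, leaving a 1-D criterion optimized by
#' bounded golden-section/parabolic search on `[0, lambda_max]` with
#' tolerance `tol`. Rows with missing `y` are dropped (and counted in
#' `n_dropped`). Standard errors come from the profiled information,
#' `sigma^2 (X' V^{-1} X)^{-1}`.
#'
#' @param y numeric response.
#' @param design a list from [build_design()].
#' @param lambda_max upper bound of the variance-ratio search.
#' @param tol optimizer tolerance.
#' @return A `lmm_fit` object: `beta`, `se`, `sigma2_subject`,
#'   `sigma2_resid`, `loglik_reml`, `converged`, `p` (Wald), `n_used`,
#'   `n_dropped`, `lambda`.
#' @export
fit_lmm_reml <- function(y, design, lambda_max = 1e4, tol = 1e-8) {
  keep <- !is.na(y)
  y_use <- as.numeric(y[keep])
  X <- design$X[keep, , drop = FALSE]
  groups <- design$groups[keep]
  N <- length(y_use)
  p <- ncol(X)
  if (N <= p) stop("too few non-missing observations (", N, ")")
  group_idx <- match(groups, sort(unique(groups)))
  if (length(unique(group_idx)) < 2L)
    stop("need at least 2 subjects")
  if (stats::var(y_use) == 0) {
    # degenerate: constant response, exact zero-variance fit
    beta <- c(mean(y_use), 0, 0, 0)[seq_len(p)]
    fit <- list(beta = stats::setNames(beta, colnames(X)),
                se = stats::setNames(rep(0, p), colnames(X)),
                sigma2_subject = 0, sigma2_resid = 0,
                loglik_reml = Inf, converged = TRUE,
                p = stats::setNames(rep(NA_real_, p), colnames(X)),
                n_used = N, n_dropped = sum(!keep), lambda = 0)
    class(fit) <- "lmm_fit"
    return(fit)
  }
  crit <- function(lambda) -reml_pieces(lambda, y_use, X, group_idx)$loglik
  opt <- stats::optimize(crit, interval = c(0, lambda_max), tol = tol)
  lambda <- opt$minimum
  # the boundary lambda = 0 is excluded by optimize(); take it if better
  if (crit(0) <= opt$objective) lambda <- 0
  pieces <- reml_pieces(lambda, y_use, X, group_idx)
  covb <- pieces$sigma2 * chol2inv(pieces$XtViX_chol)
  se <- sqrt(diag(covb))
  beta <- stats::setNames(pieces$beta, colnames(X))
  fit <- list(beta = beta,
              se = stats::setNames(se, colnames(X)),
              sigma2_subject = lambda * pieces$sigma2,
              sigma2_resid = pieces$sigma2,
              loglik_reml = pieces$loglik,
              converged = is.finite(pieces$loglik) && all(is.finite(se)),
              n_used = N, n_dropped = sum(!keep), lambda = lambda)
  fit$p <- wald_pvalues(fit)
  class(fit) <- "lmm_fit"
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM (REML)\n")
  cat("  sigma2_subject =", format(x$sigma2_subject, digits = 4),
      " sigma2_resid =", format(x$sigma2_resid, digits = 4),
      " n =", x$n_used, "\n")
  print(cbind(b = x$beta, se = x$se, p = x$p), digits = 4)
  invisible(x)
}

#' Wald p-values for a mixed-model fit
#'
#' Normal-approximation Wald tests: `z = b/se`, `p = 2 * pnorm(-|z|)`.
#' Coefficients with `se = 0` get `NA` (flagged, not zero).
#'
#' @param fit an `lmm_fit`.
#' @return Named numeric vector of p-values.
#' @export
wald_pvalues <- function(fit) {
  z <- ifelse(fit$se > 0, fit$beta / fit$se, NA_real_)
  stats::setNames(2 * stats::pnorm(-abs(z)), names(fit$beta))
}

#' Holm step-down multiple-testing adjustment
#'
#' Sorts the raw p-values ascending, multiplies the i-th by `m - i + 1`,
#' enforces monotone non-decrease down the ranking, caps at 1, and maps
#' back to the input order. Controls family-wise error with no independence
#' assumption. `NA`s are passed through and do not count toward `m`.
#'
#' @param p_raw numeric vector of p-values in `[0, 1]`.
#' @param alpha significance level for the `significant` flag.
#' @param variable optional names for the result rows.
#' @return data.frame(variable, p_raw, p_adj, significant).
#' @export
holm_adjust <- function(p_raw, alpha = 0.05, variable = NULL) {
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (is.null(variable))
    variable <- names(p_raw) %||% paste0("p", seq_along(p_raw))
  p_adj <- rep(NA_real_, length(p_raw))
  ok <- which(!is.na(p_raw))
  m <- length(ok)
  if (m > 0) {
    ord <- order(p_raw[ok])
    stepped <- pmin(1, cummax(p_raw[ok][ord] * (m - seq_len(m) + 1)))
    p_adj[ok[ord]] <- stepped
  }
  data.frame(variable = variable, p_raw = unname(p_raw),
             p_adj = p_adj, significant = !is.na(p_adj) & p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Fit the contrast models for every feature in a table
#'
#' For each dependent variable: per-token normalization for count families,
#' `log(x + 1)` transform, random-intercept REML fit with the three
#' sum-contrast predictors (veracity, modality, interaction), Wald
#' p-values, then Holm correction applied across variables *within each
#' effect* (each effect forms its own family; set
#' `holm_family = "pooled"` to correct across all effects jointly).
#' Variables with fewer than `min_n` non-missing rows, or with no variance,
#' are skipped and listed in the `skipped` attribute.
#'
#' @param feature_table data.frame from [extract_feature_table()].
#' @param variables feature columns to analyze; defaults to every battery
#'   column present.
#' @param holm_family `"per_effect"` (default) or `"pooled"`.
#' @param min_n minimum non-missing rows per variable.
#' @param alpha significance level.
#' @return data.frame(variable, effect, b, se, p_raw, p_holm, significant,
#'   n_used, converged) with attribute `skipped`.
#' @export
analyze_all <- function(feature_table, variables = NULL,
                        holm_family = c("per_effect", "pooled"),
                        min_n = 8L, alpha = 0.05) {
  holm_family <- match.arg(holm_family)
  meta_cols <- c("statement_id", "subject_id", "topic", "veracity",
                 "modality")
  if (is.null(variables))
    variables <- setdiff(names(feature_table), meta_cols)
  design <- build_design(feature_table)
  effects <- c("veracity", "modality", "veracity:modality")
  rows <- list()
  skipped <- character()
  for (v in variables) {
    raw <- feature_table[[v]]
    y <- tryCatch(
      normalize_and_transform(raw, feature_table$n_tokens,
                              normalize = is_count_feature(v)),
      error = function(e) NULL)
    if (is.null(y) || sum(!is.na(y)) < min_n ||
        stats::var(y, na.rm = TRUE) == 0) {
      skipped <- c(skipped, v)
      next
    }
    fit <- tryCatch(fit_lmm_reml(y, design), error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- c(skipped, v)
      next
    }
    rows[[v]] <- data.frame(variable = v, effect = effects,
                            b = unname(fit$beta[effects]),
                            se = unname(fit$se[effects]),
                            p_raw = unname(fit$p[effects]),
                            n_used = fit$n_used,
                            converged = fit$converged,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no analyzable variables in feature table")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_holm <- NA_real_
  res$significant <- NA
  fam <- if (holm_family == "per_effect") res$effect
         else rep("all", nrow(res))
  for (f in unique(fam)) {
    idx <- which(fam == f)
    adj <- holm_adjust(res$p_raw[idx], alpha = alpha)
    res$p_holm[idx] <- adj$p_adj
    res$significant[idx] <- adj$significant
  }
  res <- res[, c("variable", "effect", "b", "se", "p_raw", "p_holm",
                 "significant", "n_used", "converged")]
  attr(res, "skipped") <- skipped
  res
}

#' Write an analysis results table
#' @param results data.frame from [analyze_all()].
#' @param path output TSV path.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
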