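#' Default response battery for the species comparison
#'
#' The eleven responses analysed in the standard workflow, with the
#' transform applied to each: relative leg I length and relative web area
#' are natural-log transformed (right-skewed, strictly positive); count
#' responses are modelled untransformed on the Gaussian scale.
#'
#' @return Data frame with columns `response` and `transform`.
#' @export
default_responses <- function() {
  data.frame(
    response = c("rel_leg1", "rel_leg3", "n_radii", "area_cm2",
                 "n_mooring", "n_frame", "asymmetry", "shape",
                 "rel_mesh", "rel_area", "spiral_turns"),
    transform = c("natural_log", "none", "none", "none",
                  "none", "none", "none", "none",
                  "none", "natural_log", "none"),
    stringsAsFactors = FALSE
  )
}

#' Run the full species-comparison workflow
#'
#' Executes the whole analysis battery on a study: derives web metrics,
#' runs the morphology PCA, fits one linear mixed model per response
#' (species fixed, location random; Type II Wald F with Kenward-Roger df)
#' and, for every response whose omnibus test is significant at `alpha`,
#' computes Tukey-adjusted pairwise species contrasts. Per-response group
#' means and SEMs are tabulated alongside.
#'
#' Per-response model failures are collected in the report rather than
#' aborting the batch.
#'
#' @param study An `orb_study` (from [make_study()]) or a pre-joined
#'   analysis data frame already carrying the metric columns.
#' @param responses Response battery as in [default_responses()].
#' @param alpha Significance level gating the posthoc contrasts
#'   (default 0.05).
#' @return An object of class `comparison_report`: list with `tests` (one
#'   row per response: F, numerator df, denominator df, P), `contrasts`
#'   (rows only for significant responses), `group_stats`
#'   (mean ± SEM by species and response), `pca`, `alpha`, `df_method` and
#'   `errors`.
#' @examples
#' \donttest{
#' rep <- compare_all(make_study(seed = 1))
#' print(rep)
#' }
#' @export
compare_all <- function(study, responses = default_responses(),
                        alpha = 0.05) {
  if (inherits(study, "orb_study")) {
    data <- web_metrics(study$webs, study$morphology)
    morph <- study$morphology
  } else {
    data <- study
    morph <- study
  }
  missing_cols <- setdiff(responses$response, names(data))
  if (length(missing_cols)) {
    stop("dataset lacks response column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  pca <- tryCatch(run_pca(morph), error = function(e) NULL)

  tests <- list()
  contrasts <- list()
  errors <- list()
  group_stats <- list()
  for (i in seq_len(nrow(responses))) {
    resp <- responses$response[i]
    tr <- responses$transform[i]
    sem <- function(x) sd(x) / sqrt(length(x))
    vals <- data[!is.na(data[[resp]]), c("species", resp)]
    if (nrow(vals)) {
      gs <- aggregate(vals[[resp]], list(species = vals$species),
                      function(x) c(mean = mean(x), sem = sem(x),
                                    n = length(x)))
      group_stats[[resp]] <- data.frame(response = resp,
                                        species = gs$species,
                                        mean = gs$x[, "mean"],
                                        sem = gs$x[, "sem"],
                                        n = gs$x[, "n"],
                                        stringsAsFactors = FALSE)
    }
    fit <- tryCatch(
      suppressMessages(suppressWarnings(fit_lmm(data, resp, transform = tr))),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      errors[[resp]] <- conditionMessage(fit)
      next
    }
    row <- fit$test
    row$transform <- tr
    row$significant <- !is.na(row$P) && row$P < alpha
    tests[[resp]] <- row
    if (row$significant && !fit$degenerate) {
      ct <- tryCatch(pairwise_contrasts(fit), error = function(e) NULL)
      if (!is.null(ct)) {
        ct <- cbind(response = resp, ct)
        contrasts[[resp]] <- ct
      }
    }
  }
  structure(list(
    tests = if (length(tests)) do.call(rbind, c(tests, make.row.names = FALSE))
            else NULL,
    contrasts = if (length(contrasts))
      do.call(rbind, c(contrasts, make.row.names = FALSE)) else NULL,
    group_stats = do.call(rbind, c(group_stats, make.row.names = FALSE)),
    pca = pca, alpha = alpha, df_method = "kenward-roger",
    errors = errors
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat("<comparison_report> Type II Wald F tests (", x$df_method,
      " df), alpha = ", x$alpha, "\n\n", sep = "")
  if (!is.null(x$tests)) {
    t <- x$tests
    out <- data.frame(response = t$response, transform = t$transform,
                      F = round(t$F, 2), df = t$df,
                      df_den = round(t$df_den, 1),
                      P = signif(t$P, digits),
                      sig = ifelse(t$significant, "*", ""))
    print(out, row.names = FALSE)
  }
  if (!is.null(x$contrasts)) {
    cat("\nTukey-adjusted contrasts (significant responses only):\n")
    ct <- x$contrasts
    out <- data.frame(response = ct$response, pair = ct$pair,
                      t = round(ct$t, 2), df = round(ct$df, 2),
                      p_adj = signif(ct$p_adj, digits))
    print(out, row.names = FALSE)
  }
  if (!is.null(x$pca)) {
    cat("\nMorphology PCA: PC1 + PC2 explain ",
        round(100 * sum(x$pca$proportion_variance[1:2]), 1), "%\n", sep = "")
  }
  if (length(x$errors)) {
    cat("\nResponses skipped with errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n",
                                    sep = "")
  }
  invisible(x)
}

#' Write a comparison report to CSV and JSON
#'
#' Emits `<prefix>_tests.csv`, `<prefix>_contrasts.csv`,
#' `<prefix>_group_stats.csv` and a combined `<prefix>_report.json`
#' (per-response F/df/P, contrasts, group means ± SEM, PCA variance
#' proportions).
#'
#' @param report A [compare_all()] report.
#' @param prefix Output path prefix (directory must exist).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, prefix) {
  files <- character(0)
  emit <- function(df, suffix) {
    f <- paste0(prefix, "_", suffix, ".csv")
    write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  if (!is.null(report$tests)) emit(report$tests, "tests")
  if (!is.null(report$contrasts)) emit(report$contrasts, "contrasts")
  emit(report$group_stats, "group_stats")
  j <- list(df_method = report$df_method, alpha = report$alpha,
            tests = report$tests, contrasts = report$contrasts,
            group_stats = report$group_stats,
            pca_proportion_variance =
              if (!is.null(report$pca)) report$pca$proportion_variance,
            errors = report$errors)
  jf <- paste0(prefix, "_report.json")
  jsonlite::write_json(j, jf, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, jf)
  invisible(files)
}
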