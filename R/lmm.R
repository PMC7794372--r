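#' Fit a species-comparison linear mixed model for one response
#'
#' REML fit of `response ~ species + (1 | location)`: species is the fixed
#' factor of interest and sampling location (cave or transect, nested
#' within species) is a random intercept absorbing spatial clustering.
#' The species term is tested with a Type II Wald F test using
#' Kenward-Roger denominator degrees of freedom.
#'
#' An optional natural-log transform is applied to the response first
#' (used for right-skewed, strictly positive responses such as relative web
#' area and relative leg I length). Count responses are modelled on the
#' Gaussian scale, untransformed.
#'
#' A fit whose random-effect variance lands on the boundary (singular fit)
#' is flagged via a warning but still returned — with location variance
#' zero the model collapses to ordinary one-way ANOVA. A response with
#' (numerically) zero variance is flagged degenerate and given `F = 0`.
#'
#' @param data Analysis data frame with columns `species`, `location` and
#'   the response.
#' @param response Name of the response column.
#' @param transform `"none"` or `"natural_log"`.
#' @return An object of class `lmm_fit`: list with the `lme4` `model`, a
#'   one-row `test` data frame (`response`, `F`, `df` numerator df,
#'   `df_den`, `P`), and flags `singular`, `degenerate`.
#' @export
fit_lmm <- function(data, response, transform = c("none", "natural_log")) {
  transform <- match.arg(transform)
  stopifnot(response %in% names(data))
  d <- data[!is.na(data[[response]]),
            c("species", "location", response)]
  names(d)[3] <- ".y"
  if (length(unique(d$location)) < 2) {
    stop("need at least 2 locations to fit a location random effect",
         call. = FALSE)
  }
  if (any(table(d$species) < 2)) {
    stop("every species needs at least 2 non-missing records for '",
         response, "'", call. = FALSE)
  }
  if (transform == "natural_log") {
    if (any(d$.y <= 0)) {
      stop("natural_log transform requires a strictly positive response ('",
           response, "')", call. = FALSE)
    }
    d$.y <- log(d$.y)
  }
  d$species <- factor(d$species)
  d$location <- factor(d$location)

  if (sd(d$.y) < 1e-12) {
    return(structure(list(model = NULL, response = response,
                          transform = transform,
                          test = data.frame(response = response, F = 0,
                                            df = nlevels(d$species) - 1L,
                                            df_den = NA_real_, P = 1),
                          singular = TRUE, degenerate = TRUE),
                     class = "lmm_fit"))
  }

  model <- lme4::lmer(.y ~ species + (1 | location), data = d, REML = TRUE)
  singular <- lme4::isSingular(model)
  if (singular) {
    warning("singular fit for '", response,
            "': location variance estimated at the boundary (0); the model ",
            "reduces to one-way ANOVA", call. = FALSE)
  }
  an <- suppressWarnings(
    car::Anova(model, type = 2, test.statistic = "F")
  )
  structure(list(model = model, response = response, transform = transform,
                 test = data.frame(response = response,
                                   F = an[["F"]][1],
                                   df = an[["Df"]][1],
                                   df_den = an[["Df.res"]][1],
                                   P = an[["Pr(>F)"]][1]),
                 singular = singular, degenerate = FALSE),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit> ", x$response,
      if (x$transform == "natural_log") " (natural log)", "\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate: response has no variance\n")
  } else {
    with(x$test, cat(sprintf(
      "  Type II Wald F = %.3f, df = %d, den. df = %.2f, P = %.4g%s\n",
      F, df, df_den, P, if (x$singular) "  [singular fit]" else "")))
  }
  invisible(x)
}

#' Tukey-adjusted pairwise species contrasts
#'
#' All pairwise differences between species estimated marginal means on the
#' model scale, with Kenward-Roger denominator degrees of freedom and the
#' Tukey method (studentised-range distribution) for multiplicity
#' adjustment. Run after — and only where — the omnibus species test is
#' significant.
#'
#' @param fit An [fit_lmm()] object.
#' @return Data frame with one row per species pair: `pair`, `estimate`,
#'   `se`, `t`, `df`, `p_unadj` (unadjusted) and `p_adj` (Tukey-adjusted).
#' @export
pairwise_contrasts <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (fit$degenerate || is.null(fit$model)) {
    stop("cannot compute contrasts on a degenerate fit", call. = FALSE)
  }
  emm <- emmeans::emmeans(fit$model, "species", lmer.df = "kenward-roger")
  ct_adj <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                            adjust = "tukey"))
  ct_raw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                            adjust = "none"))
  data.frame(pair = as.character(ct_adj$contrast),
             estimate = ct_adj$estimate, se = ct_adj$SE,
             t = ct_adj$t.ratio, df = ct_adj$df,
             p_unadj = ct_raw$p.value, p_adj = ct_adj$p.value,
             stringsAsFactors = FALSE)
}
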