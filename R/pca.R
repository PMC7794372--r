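#' Principal component analysis of spider morphology
#'
#' Ordination of the four morphology variables (total length, cephalothorax
#' width, patella-tibia lengths of legs I and III). Variables are centred
#' and, by default, scaled to unit variance; set `scale = FALSE` for a
#' covariance-matrix PCA (the variables are all in mm but span an order of
#' magnitude, so correlation-matrix PCA is the default).
#'
#' @param morphology Data frame in the morphology schema.
#' @param scale Scale variables to unit variance before decomposition
#'   (default `TRUE`).
#' @return An object of class `web_pca`: list with `scores` (one row per
#'   spider, with `species` labels for plotting), `proportion_variance`
#'   (per component, non-increasing), `rotation`, and `scale`.
#' @examples
#' study <- make_study(seed = 1)
#' p <- run_pca(study$morphology)
#' sum(p$proportion_variance[1:2])  # variance captured by the first plane
#' @export
run_pca <- function(morphology, scale = TRUE) {
  vars <- c("total_length_mm", "ceph_width_mm", "pt_leg1_mm", "pt_leg3_mm")
  x <- morphology[, vars]
  if (any(is.na(x))) {
    stop("morphology PCA requires complete records (no missing values)",
         call. = FALSE)
  }
  if (nrow(x) < length(vars)) {
    stop("morphology PCA needs at least as many records as variables (",
         length(vars), ")", call. = FALSE)
  }
  fit <- prcomp(x, center = TRUE, scale. = scale)
  prop <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as.data.frame(fit$x)
  scores$species <- morphology$species
  scores$spider_id <- morphology$spider_id
  structure(list(scores = scores,
                 proportion_variance = prop,
                 rotation = fit$rotation,
                 scale = scale),
            class = "web_pca")
}

#' @export
print.web_pca <- function(x, ...) {
  cat("<web_pca> ", nrow(x$scores), " spiders, ",
      if (x$scale) "correlation" else "covariance", "-matrix PCA\n",
      sep = "")
  pv <- round(100 * x$proportion_variance, 1)
  cat("  variance explained (%):", paste(pv, collapse = ", "), "\n")
  cat("  PC1 + PC2: ", round(100 * sum(x$proportion_variance[1:2]), 1),
      "%\n", sep = "")
  invisible(x)
}
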