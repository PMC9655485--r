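# Redundancy analysis (constrained ordination): PCA of the part of a
# multivariate response explained by least-squares regression on the
# explanatory design. Authored directly (regression + eigendecomposition);
# vegan is used only as an independent cross-check in the test suite.

#' Fit a redundancy analysis
#'
#' Each response column is centred (and scaled to unit variance under the
#' default correlation scaling), regressed on the centred explanatory
#' design by least squares, and the covariance matrix of the fitted values
#' is eigendecomposed. Categorical explanatory columns are dummy-coded;
#' ordinal codes should be supplied as numerics. Aliased (rank-deficient)
#' design columns are dropped with a warning.
#'
#' Scores follow the correlation-biplot ("scaling 2") convention: species
#' scores are eigenvectors scaled by the square roots of their eigenvalues,
#' site scores are projections of the fitted values on the eigenvectors,
#' and biplot scores are correlations of the explanatory variables with the
#' site scores.
#'
#' @param responses samples x variables numeric matrix (n >= covariates + 2).
#' @param explanatory samples x covariates data frame or matrix.
#' @param scale `"correlation"` (standardise responses) or `"covariance"`
#'   (centre only).
#' @return Object of class `rda_result`: `eigenvalues` (constrained,
#'   descending), `site_scores`, `species_scores`, `biplot_scores`,
#'   `constrained_proportion`, `total_variance`, `residual_variance`.
#' @export
#' @examples
#' Y <- matrix(rnorm(60), 20, 3)
#' X <- data.frame(a = rnorm(20), b = rnorm(20))
#' rda_fit(Y + X$a, X)$constrained_proportion
rda_fit <- function(responses, explanatory,
                    scale = c("correlation", "covariance")) {
  scale <- match.arg(scale)
  Y <- as.matrix(responses)
  if (!is.numeric(Y)) stop("responses must be numeric", call. = FALSE)
  if (anyNA(Y)) stop("responses contain missing values", call. = FALSE)
  if (is.data.frame(explanatory)) {
    X <- stats::model.matrix(~ ., data = explanatory)[, -1, drop = FALSE]
  } else {
    X <- as.matrix(explanatory)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  n <- nrow(Y)
  if (nrow(X) != n) stop("responses and explanatory row counts differ", call. = FALSE)
  if (n < ncol(X) + 2) {
    stop("need at least covariates + 2 samples (", ncol(X) + 2, "); got ", n,
         call. = FALSE)
  }
  Ys <- base::scale(Y, center = TRUE, scale = scale == "correlation")
  if (scale == "correlation" && any(attr(Ys, "scaled:scale") == 0)) {
    stop("constant response column(s): ",
         paste(colnames(Y)[attr(Ys, "scaled:scale") == 0], collapse = ", "),
         call. = FALSE)
  }
  Ys <- Ys[, , drop = FALSE]
  attr(Ys, "scaled:center") <- attr(Ys, "scaled:scale") <- NULL
  Xc <- base::scale(X, center = TRUE, scale = FALSE)

  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    dropped <- colnames(Xc)[qrX$pivot[(qrX$rank + 1):ncol(Xc)]]
    warning("dropping aliased explanatory column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    Xc <- Xc[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(Xc)
  }
  Yhat <- qr.fitted(qrX, Ys)

  C <- crossprod(Yhat) / (n - 1)
  eig <- eigen(C, symmetric = TRUE)
  k <- min(qrX$rank, ncol(Ys))
  lambda <- pmax(eig$values, 0)[seq_len(k)]
  pos <- lambda > max(lambda[1], 0) * 1e-12
  k <- max(sum(pos), 1L)
  lambda <- lambda[seq_len(k)]
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  axes <- paste0("RDA", seq_len(k))

  site <- Yhat %*% U
  species <- U %*% diag(sqrt(lambda), k, k)
  biplot <- suppressWarnings(stats::cor(Xc, site))
  biplot[!is.finite(biplot)] <- 0  # degenerate axes with zero site variance
  dimnames(site) <- list(rownames(Y), axes)
  dimnames(species) <- list(colnames(Y), axes)
  dimnames(biplot) <- list(colnames(Xc), axes)

  total_var <- sum(apply(Ys, 2, stats::var))
  resid_var <- sum(apply(Ys - Yhat, 2, stats::var))
  structure(list(eigenvalues = lambda,
                 site_scores = site,
                 species_scores = species,
                 biplot_scores = biplot,
                 constrained_proportion = sum(lambda) / total_var,
                 total_variance = total_var,
                 residual_variance = resid_var,
                 scale = scale),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, digits = 4, ...) {
  cat("Redundancy analysis (", x$scale, " scaling)\n", sep = "")
  cat("  constrained axes:", length(x$eigenvalues),
      "| proportion explained:",
      signif(x$constrained_proportion, digits), "\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, digits), collapse = ", "),
      "\n")
  invisible(x)
}

#' Alignment of a response with an explanatory variable in RDA space
#'
#' Inner product of a response's species scores with a covariate's biplot
#' scores across the constrained axes; its sign recovers the direction of
#' the fitted association (the quantity read off a biplot as the angle
#' between the two arrows).
#'
#' @param fit an [rda_fit()] result.
#' @param response response (species) name.
#' @param covariate explanatory-variable name.
#' @return Scalar alignment.
#' @export
rda_alignment <- function(fit, response, covariate) {
  stopifnot(inherits(fit, "rda_result"))
  sp <- fit$species_scores[response, ]
  bp <- fit$biplot_scores[covariate, ]
  sum(sp * bp)
}
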