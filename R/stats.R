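# Statistical layer: 0-1 scaling, negative-binomial regression with log
# link (NB2, dispersion by maximum likelihood), likelihood-ratio test
# against the intercept-only null, Kruskal-Wallis and pairwise Mann-Whitney
# tests for categorical properties, eCDF comparison and cross-correlation
# screening of the numeric explanatory variables.

#' Min-max scale a numeric vector to [0, 1]
#'
#' @param values Numeric vector with max > min.
#' @param name Column name used in the error message.
#' @return \code{(x - min) / (max - min)}.
#' @export
minmax_scale <- function(values, name = deparse(substitute(values))) {
  rng <- range(values, na.rm = TRUE)
  if (!all(is.finite(rng))) stop("non-finite values in column '", name, "'")
  if (rng[2] <= rng[1])
    stop("constant column '", name, "' cannot be scaled to [0, 1]")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Negative-binomial regression of signal scores on scaled properties
#'
#' Fits the log-link NB2 model \eqn{\log \mu = \beta_0 + \sum_i \beta_i x_i}
#' with the dispersion estimated by maximum likelihood jointly with the
#' coefficients. The response must be non-negative integers (signal scores
#' are rounded upstream for the regression only). The intercept-only null is
#' fitted on the same data for the likelihood-ratio test.
#'
#' @param X Numeric matrix or data.frame of explanatory variables, already
#'   scaled to [0, 1] columnwise.
#' @param y Non-negative integer response.
#' @return An object of class \code{nb_fit}: list with \code{coefficients},
#'   \code{standard_errors}, \code{p_values} (Wald, two-sided),
#'   \code{dispersion} (NB size parameter theta), \code{loglik},
#'   \code{loglik_null}, \code{lrt_p}, \code{df}, \code{model} (the
#'   underlying fit).
#' @export
fit_negative_binomial <- function(X, y) {
  X <- as.data.frame(X)
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("response must be non-negative integers ",
         "(round signal scores before regression)")
  y <- as.integer(round(y))
  if (all(y == 0)) stop("degenerate response: all scores are zero")
  dat <- cbind(X, .y = y)
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(.y ~ ., data = dat,
                                  control = stats::glm.control(maxit = 100))),
    error = function(e)
      stop("negative-binomial fit failed to converge: ",
           conditionMessage(e)))
  null <- suppressWarnings(
    MASS::glm.nb(.y ~ 1, data = dat,
                 control = stats::glm.control(maxit = 100)))
  sm <- summary(fit)
  co <- sm$coefficients
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null))
  df <- length(stats::coef(fit)) - 1L
  if (ll < ll0 - 1e-6)
    stop("fit failure: model log-likelihood below the null")
  lrt_p <- if (df == 0L) 1 else
    stats::pchisq(2 * max(ll - ll0, 0), df = df, lower.tail = FALSE)
  structure(list(
    coefficients = co[, "Estimate"],
    standard_errors = co[, "Std. Error"],
    p_values = co[, "Pr(>|z|)"],
    dispersion = fit$theta,
    loglik = ll,
    loglik_null = ll0,
    lrt_p = lrt_p,
    df = df,
    model = fit
  ), class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative-binomial regression (log link)\n")
  tab <- data.frame(estimate = x$coefficients,
                    std_error = x$standard_errors,
                    p_value = x$p_values)
  print(round(tab, 4))
  cat(sprintf("dispersion (theta): %.3f  logLik: %.2f  LRT p: %.3g\n",
              x$dispersion, x$loglik, x$lrt_p))
  invisible(x)
}

#' Likelihood-ratio test of a fitted model against its null
#'
#' Refers \eqn{2(\ell - \ell_0)} to a chi-square with as many degrees of
#' freedom as slope coefficients.
#'
#' @param fit An \code{nb_fit}.
#' @return Two-sided p-value.
#' @export
likelihood_ratio_test <- function(fit) {
  stopifnot(inherits(fit, "nb_fit"))
  fit$lrt_p
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction, referred to chi-square with
#' k-1 degrees of freedom. When every observation is identical, H = 0 and
#' p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, each non-empty).
#' @return List with \code{H} and \code{p}.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 1L))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p by enumeration of the U distribution when both samples have at
#' most 8 observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric samples.
#' @return Two-sided p-value.
#' @export
mann_whitney <- function(a, b) {
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= 8L && length(b) <= 8L && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Pairwise Mann-Whitney U tests between groups
#'
#' @param groups List of numeric samples.
#' @param labels Optional group labels (default list names or indices).
#' @return Symmetric matrix of two-sided p-values (diagonal 1).
#' @export
mann_whitney_pairwise <- function(groups, labels = NULL) {
  k <- length(groups)
  if (is.null(labels))
    labels <- if (!is.null(names(groups))) names(groups)
              else as.character(seq_len(k))
  p <- matrix(1, k, k, dimnames = list(labels, labels))
  if (k < 2L) return(p)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      pij <- if (identical(groups[[i]], groups[[j]])) 1
             else mann_whitney(groups[[i]], groups[[j]])
      p[i, j] <- p[j, i] <- pij
    }
  }
  p
}

#' Pearson correlation between two empirical CDFs
#'
#' Both eCDFs are evaluated on the sorted union of all observed values and
#' the Pearson correlation of the two evaluated vectors is returned. Used to
#' quantify the overlap of score distributions between residue classes.
#'
#' @param a,b Numeric samples (each >= 2 observations).
#' @return Pearson r, or NA when either evaluated vector is constant.
#' @export
ecdf_correlation <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  grid <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(grid)
  fb <- stats::ecdf(b)(grid)
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) return(NA_real_)
  stats::cor(fa, fb)
}

#' Cross-correlation screen of numeric explanatory variables
#'
#' Computes the pairwise Pearson correlation matrix and flags columns that
#' are perfectly correlated (|r| = 1 within tolerance) with an earlier
#' column; the later column of each such pair is dropped (this removes
#' strength, which duplicates degree under unit edge weights).
#'
#' @param X Numeric matrix or data.frame.
#' @param tol Tolerance on |r| - 1 (default 1e-12).
#' @return List with \code{correlation} (full matrix), \code{dropped}
#'   (character vector of dropped column names) and \code{X} (screened
#'   data.frame).
#' @export
cross_correlation_screen <- function(X, tol = 1e-12) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2L)
  cm <- stats::cor(as.matrix(X))
  dropped <- character(0)
  for (j in 2:ncol(cm)) {
    earlier <- setdiff(seq_len(j - 1L), match(dropped, colnames(cm)))
    if (any(abs(cm[earlier, j]) >= 1 - tol))
      dropped <- c(dropped, colnames(cm)[j])
  }
  list(correlation = cm, dropped = dropped,
       X = X[, setdiff(colnames(X), dropped), drop = FALSE])
}
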