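#' Canonical discriminant analysis
#'
#' Finds the linear combinations of the measurement variables that best
#' separate predefined groups: the eigenvectors of `W^-1 B`, where `W` and
#' `B` are the within- and between-group sum-of-squares-and-cross-products
#' matrices. There are `min(g - 1, p)` canonical functions, ordered by
#' decreasing eigenvalue; the i-th canonical correlation is
#' `sqrt(lambda_i / (1 + lambda_i))`, and the Wilks' lambda for functions
#' i..f is `prod_{j >= i} 1 / (1 + lambda_j)`, tested with Rao's F
#' approximation. Raw coefficients are scaled so each canonical variable
#' has unit pooled within-group variance; standardized coefficients
#' multiply by the pooled within-group standard deviations.
#'
#' The eigenproblem is solved through a Cholesky symmetrization of `W`
#' (numerically stable for the symmetric-definite pencil `B u = lambda W u`).
#'
#' @param formula a formula `group ~ var1 + var2 + ...`; the left-hand
#'   side must be a factor (or coercible) with at least two levels.
#' @param data data.frame holding the variables.
#' @return An object of class `cda`: `eigenvalues`, `canonical_correlation`,
#'   `wilks` (per function), `proportion` (of the eigenvalue trace), `F`,
#'   `df1`, `df2`, `p.value` (Rao approximation per function), `coef`
#'   (raw, p x f), `coef_std` (standardized), `group_means` (g x f means
#'   on the canonical variables), `means` (variable means), `W`, `B`,
#'   `counts`, `scores`, `classes`, and the model frame bookkeeping used
#'   by [predict.cda()].
#' @seealso [predict.cda()] for classification, [cda_classify()] for the
#'   resubstitution classification matrix, [manova_wilks()] for the
#'   overall test.
#' @examples
#' tab <- generate_group_tables(seed = 42)
#' fit <- cda(group ~ da + db + dc + bl + bs + ba, tab)
#' summary(fit)
#' @export
cda <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  g <- droplevels(as.factor(mf[[1L]]))
  x <- as.matrix(mf[-1L])
  if (!is.numeric(x)) stop("all discriminating variables must be numeric")
  n <- nrow(x); p <- ncol(x); ng <- nlevels(g)
  if (ng < 2L) stop("need at least two groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 specimens")
  if (n - ng <= p)
    stop("need n - g > p observations; reduce the variable set")
  sm <- scatter_matrices(x, g)
  W <- sm$W; B <- sm$B
  R <- tryCatch(chol(W), error = function(e)
    stop("singular within-group scatter; drop collinear variables"))
  Ri <- backsolve(R, diag(p))
  S <- crossprod(Ri, B %*% Ri)       # t(Ri) B Ri, symmetric
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  f <- min(ng - 1L, p)
  lam <- pmax(es$values[seq_len(f)], 0)
  u <- Ri %*% es$vectors[, seq_len(f), drop = FALSE]
  # unit pooled within-group variance: u' (W / (n - g)) u = 1
  u <- u * sqrt(n - ng)
  # deterministic sign: largest-|coefficient| entry positive
  for (j in seq_len(f)) {
    k <- which.max(abs(u[, j]))
    if (u[k, j] < 0) u[, j] <- -u[, j]
  }
  rownames(u) <- colnames(x)
  colnames(u) <- paste0("can", seq_len(f))
  canr <- sqrt(lam / (1 + lam))
  wilks <- rev(cumprod(rev(1 / (1 + lam))))
  prop <- if (sum(lam) > 0) lam / sum(lam) else rep(NA_real_, f)
  tests <- lapply(seq_len(f), function(i)
    rao_f(wilks[i], p - i + 1L, ng - i, n))
  pooled_sd <- sqrt(diag(W) / (n - ng))
  coef_std <- u * pooled_sd
  mu <- colMeans(x)
  scores <- sweep(x, 2L, mu) %*% u
  gmeans <- apply(scores, 2L, function(col) tapply(col, g, mean))
  gmeans <- matrix(gmeans, ng, f,
                   dimnames = list(levels(g), colnames(u)))
  structure(list(
    call = match.call(), formula = formula, variables = colnames(x),
    group = names(mf)[1L], levels = levels(g), counts = table(g),
    n = n, p = p,
    eigenvalues = lam, canonical_correlation = canr, wilks = wilks,
    proportion = prop,
    F = vapply(tests, `[[`, numeric(1), "F"),
    df1 = vapply(tests, `[[`, numeric(1), "df1"),
    df2 = vapply(tests, `[[`, numeric(1), "df2"),
    p.value = vapply(tests, `[[`, numeric(1), "p.value"),
    coef = u, coef_std = coef_std, means = mu,
    group_means = gmeans, W = W, B = B,
    scores = scores, classes = g), class = "cda")
}

#' @export
coef.cda <- function(object, standardized = FALSE, ...) {
  if (standardized) object$coef_std else object$coef
}

#' Classify specimens with a fitted canonical discriminant model
#'
#' Each specimen is projected onto the canonical variables and assigned to
#' the group with the nearest group mean (Euclidean distance over all
#' retained functions, equal priors).
#'
#' @param object a fitted [cda()] model.
#' @param newdata data.frame with the model's variables; default: the
#'   training data (resubstitution).
#' @param ... unused.
#' @return list with `class` (factor of assigned groups) and `scores`
#'   (canonical variables).
#' @export
predict.cda <- function(object, newdata = NULL, ...) {
  scores <- if (is.null(newdata)) object$scores else {
    if (!all(object$variables %in% names(newdata)))
      stop("newdata lacks model variables: ",
           paste(setdiff(object$variables, names(newdata)), collapse = ", "))
    x <- as.matrix(newdata[object$variables])
    sweep(x, 2L, object$means) %*% object$coef
  }
  d2 <- vapply(object$levels, function(lev)
    rowSums(sweep(scores, 2L, object$group_means[lev, ])^2),
    numeric(nrow(scores)))
  d2 <- matrix(d2, nrow(scores), length(object$levels))
  cls <- factor(object$levels[max.col(-d2, ties.method = "first")],
                levels = object$levels)
  list(class = cls, scores = scores)
}

#' Resubstitution classification matrix
#'
#' Cross-tabulates true against assigned groups under the nearest-group-
#' mean rule of [predict.cda()] and reports the overall correct rate
#' (trace over n) and per-group row percentages.
#'
#' @param object a fitted [cda()] model.
#' @param newdata optional data.frame with the model's variables and the
#'   grouping column; default: training data.
#' @return list with `matrix` (counts), `percent` (row percentages) and
#'   `correct_rate`.
#' @export
cda_classify <- function(object, newdata = NULL) {
  stopifnot(inherits(object, "cda"))
  if (is.null(newdata)) {
    truth <- object$classes
    pred <- predict(object)$class
  } else {
    truth <- factor(newdata[[object$group]], levels = object$levels)
    pred <- predict(object, newdata)$class
  }
  m <- table(truth = truth, assigned = pred)
  list(matrix = m,
       percent = prop.table(m, 1L) * 100,
       correct_rate = sum(diag(m)) / sum(m))
}

#' @export
print.cda <- function(x, ...) {
  cat("Canonical discriminant analysis\n")
  cat("  ", x$n, "specimens,", x$p, "variables,",
      length(x$levels), "groups:", paste(x$levels, collapse = ", "), "\n")
  cat("  ", length(x$eigenvalues), "canonical function(s)\n\n")
  tab <- data.frame(canonical_correlation = round(x$canonical_correlation, 3),
                    eigenvalue = round(x$eigenvalues, 3),
                    wilks_lambda = round(x$wilks, 3),
                    proportion = round(x$proportion, 4),
                    F = round(x$F, 3), num_df = x$df1,
                    p_value = signif(x$p.value, 3),
                    code = sig_codes(x$p.value))
  print(tab)
  invisible(x)
}

#' @export
summary.cda <- function(object, ...) {
  structure(list(fit = object, classification = cda_classify(object)),
            class = "summary.cda")
}

#' @export
print.summary.cda <- function(x, ...) {
  print(x$fit)
  cat("\nRaw coefficients (unit pooled within-group variance):\n")
  print(round(x$fit$coef, 3))
  cat("\nStandardized coefficients:\n")
  print(round(x$fit$coef_std, 3))
  cat("\nGroup means on canonical variables:\n")
  print(round(x$fit$group_means, 3))
  cat("\nResubstitution classification (rows = true group):\n")
  print(x$classification$matrix)
  cat(sprintf("\nOverall correct rate: %.1f%%\n",
              100 * x$classification$correct_rate))
  invisible(x)
}

#' Scatterplot of the first two canonical variables
#'
#' @param x a fitted [cda()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cda <- function(x, ...) {
  s <- x$scores
  if (ncol(s) < 2L) {
    graphics::stripchart(s[, 1L] ~ x$classes, method = "jitter",
                         xlab = colnames(s)[1L], ...)
    return(invisible(x))
  }
  graphics::plot(s[, 1L], s[, 2L], col = as.integer(x$classes),
                 pch = as.integer(x$classes),
                 xlab = sprintf("Can1 (%.1f%%)", 100 * x$proportion[1L]),
                 ylab = sprintf("Can2 (%.1f%%)", 100 * x$proportion[2L]), ...)
  graphics::points(x$group_means[, 1L], x$group_means[, 2L],
                   pch = 8, cex = 1.5)
  graphics::legend("topright", legend = x$levels,
                   col = seq_along(x$levels), pch = seq_along(x$levels))
  invisible(x)
}
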