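# Group-comparison statistics for per-specimen measurement tables: one row
# per specimen, numeric morphology columns, one grouping factor.

#' Significance codes
#'
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, `.` below 0.1,
#' `ns` otherwise.
#'
#' @param p vector of p-values.
#' @return character vector of codes.
#' @export
sig_codes <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
                   labels = c("***", "**", "*", ".", "ns")))
}

#' @keywords internal
#' @noRd
check_morph_table <- function(data, variables, group) {
  stopifnot(is.data.frame(data), group %in% names(data))
  if (is.null(variables))
    variables <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                         group)
  stopifnot(all(variables %in% names(data)))
  if (anyNA(data[variables])) stop("missing values in measurement columns")
  g <- droplevels(factor(data[[group]]))
  if (nlevels(g) < 2L) stop("need at least two groups")
  list(variables = variables, g = g)
}

#' Per-group descriptive statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) per variable and
#' group.
#'
#' @param data data.frame of per-specimen measurements.
#' @param variables character vector of measurement columns (default: all
#'   numeric columns).
#' @param group name of the grouping column.
#' @return data.frame with `variable`, `group`, `n`, `mean`, `sd`.
#' @export
descriptives <- function(data, variables = NULL, group = "group") {
  ck <- check_morph_table(data, variables, group)
  if (any(table(ck$g) < 2L))
    stop("every group needs at least 2 specimens for an SD")
  out <- expand.grid(variable = ck$variables, group = levels(ck$g),
                     stringsAsFactors = FALSE)
  out$n <- out$mean <- out$sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- data[[out$variable[i]]][ck$g == out$group[i]]
    out$n[i] <- length(v); out$mean[i] <- mean(v); out$sd[i] <- stats::sd(v)
  }
  out[c("variable", "group", "n", "mean", "sd")]
}

#' One-way ANOVA with Tukey pairwise comparisons
#'
#' For one measurement variable: the overall one-way ANOVA F test across
#' all groups, followed by all pairwise group comparisons with Tukey HSD
#' family-wise adjustment and significance codes.
#'
#' @param data data.frame of per-specimen measurements.
#' @param variable name of the measurement column to test.
#' @param group name of the grouping column.
#' @return list with `anova` (data.frame: F, df, p) and `pairwise`
#'   (data.frame: `pair`, `diff`, `p_adj`, `code`).
#' @export
anova_pairwise <- function(data, variable, group = "group") {
  ck <- check_morph_table(data, variable, group)
  y <- data[[variable]]
  if (all(tapply(y, ck$g, stats::var) == 0))
    stop("zero within-group variance in every group; ANOVA is degenerate")
  fit <- stats::aov(y ~ g, data = data.frame(y = y, g = ck$g))
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$g
  out_pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          code = sig_codes(tk[, "p adj"]),
                          row.names = NULL)
  list(anova = data.frame(variable = variable,
                          F = an$`F value`[1L],
                          df1 = an$Df[1L], df2 = an$Df[2L],
                          p = an$`Pr(>F)`[1L],
                          code = sig_codes(an$`Pr(>F)`[1L])),
       pairwise = out_pairs)
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson product-moment correlations between measurement
#' variables, with two-sided p-values from the t-distribution transform
#' `t = r sqrt(n-2) / sqrt(1-r^2)`. Pairs involving a zero-variance column
#' are set to `NA` with a warning.
#'
#' @param data data.frame of per-specimen measurements.
#' @param variables measurement columns (default: all numeric columns).
#' @return list with matrices `r`, `p` and `code` (significance codes,
#'   diagonal empty).
#' @export
correlation_matrix <- function(data, variables = NULL) {
  if (is.null(variables))
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  x <- as.matrix(data[variables])
  if (nrow(x) < 3L) stop("need at least 3 rows for correlations")
  const <- apply(x, 2L, stats::sd) == 0
  if (any(const))
    warning("zero-variance column(s): ",
            paste(variables[const], collapse = ", "),
            "; correlations set to NA")
  r <- suppressWarnings(stats::cor(x))
  r[const, ] <- NA; r[, const] <- NA
  diag(r) <- 1
  n <- nrow(x)
  tt <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  diag(p) <- NA
  code <- matrix(sig_codes(p), nrow(p), dimnames = dimnames(r))
  diag(code) <- ""
  list(r = r, p = p, code = code)
}

# within / between sums-of-squares-and-cross-products matrices
#' @keywords internal
#' @noRd
scatter_matrices <- function(x, g) {
  x <- as.matrix(x)
  gm <- colMeans(x)
  w <- matrix(0, ncol(x), ncol(x))
  b <- matrix(0, ncol(x), ncol(x))
  for (lev in levels(g)) {
    xi <- x[g == lev, , drop = FALSE]
    mi <- colMeans(xi)
    ci <- sweep(xi, 2L, mi)
    w <- w + crossprod(ci)
    b <- b + nrow(xi) * tcrossprod(mi - gm)
  }
  dimnames(w) <- dimnames(b) <- list(colnames(x), colnames(x))
  list(W = w, B = b)
}

# Rao's F approximation for Wilks' lambda
#' @keywords internal
#' @noRd
rao_f <- function(lambda, p, q, n) {
  # p variables, q hypothesis df, n observations
  m <- n - 1 - (p + q + 1) / 2
  s2 <- (p^2 * q^2 - 4) / (p^2 + q^2 - 5)
  s <- if (is.finite(s2) && s2 > 0) sqrt(s2) else 1
  df1 <- p * q
  df2 <- m * s - (p * q) / 2 + 1
  lam_s <- lambda^(1 / s)
  f <- (1 - lam_s) / lam_s * df2 / df1
  list(F = f, df1 = df1, df2 = df2,
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' MANOVA with Wilks' lambda
#'
#' Tests equality of multivariate group means:
#' `Lambda = det(W) / det(W + B)` over the within- and between-group
#' scatter matrices, with Rao's F approximation for the p-value. Small
#' values of lambda indicate separated group means.
#'
#' @param data data.frame of per-specimen measurements.
#' @param variables measurement columns (default: all numeric columns).
#' @param group name of the grouping column.
#' @return list with `lambda`, `F`, `df1`, `df2`, `p.value`, and the
#'   scatter matrices `W`, `B`.
#' @export
manova_wilks <- function(data, variables = NULL, group = "group") {
  ck <- check_morph_table(data, variables, group)
  x <- as.matrix(data[ck$variables])
  n <- nrow(x); p <- ncol(x); gl <- nlevels(ck$g)
  if (n - gl <= p)
    stop("need n - g > p observations for a nonsingular within matrix")
  sm <- scatter_matrices(x, ck$g)
  if (abs(det(sm$W)) < 1e-300)
    stop("singular within-group scatter; drop collinear variables")
  lambda <- det(sm$W) / det(sm$W + sm$B)
  rf <- rao_f(lambda, p, gl - 1, n)
  c(list(lambda = lambda), rf, sm)
}
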