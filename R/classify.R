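#' Two-class linear discriminant analysis in (solidity, convexity) space
#'
#' Textbook Fisher/Gaussian LDA: class means, pooled within-class
#' covariance, equal priors (the experimental design is balanced). The
#' feature convention is `x = solidity`, `y = convexity`.
#'
#' @param samples numeric n x 2 matrix (or data frame) of features, columns
#'   `(x, y)`.
#' @param labels factor or character vector of length n with exactly two
#'   levels, each with >= 2 samples.
#' @return An `lda_model`: list with `means` (2 x 2, row per class),
#'   `cov` (pooled 2 x 2), `labels` (the two class names), `w`, `c` such
#'   that the decision value is `w . (x, y) + c` (positive for the second
#'   class in `labels`).
#' @export
fit_lda <- function(samples, labels) {
  X <- as.matrix(samples)
  if (ncol(X) != 2L) stop("`samples` must have two columns (x, y)")
  labels <- as.character(labels)
  if (nrow(X) != length(labels)) stop("samples/labels length mismatch")
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("exactly two classes are required")
  n1 <- sum(labels == lv[1]); n2 <- sum(labels == lv[2])
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  X1 <- X[labels == lv[1], , drop = FALSE]
  X2 <- X[labels == lv[2], , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  S1 <- crossprod(sweep(X1, 2, mu1))
  S2 <- crossprod(sweep(X2, 2, mu2))
  Sp <- (S1 + S2) / (n1 + n2 - 2)
  det_sp <- Sp[1, 1] * Sp[2, 2] - Sp[1, 2] * Sp[2, 1]
  if (!is.finite(det_sp) || det_sp <= 1e-14 * (Sp[1, 1] + Sp[2, 2])^2 / 4)
    stop("singular pooled covariance: classes are degenerate")
  w <- solve(Sp, mu2 - mu1)
  cc <- -sum(w * (mu1 + mu2)) / 2  # equal priors
  structure(list(means = rbind(mu1, mu2), cov = Sp, labels = lv,
                 w = w, c = cc, n = c(n1, n2)),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> classes: %s (n=%d) vs %s (n=%d)\n",
              x$labels[1], x$n[1], x$labels[2], x$n[2]))
  cat(sprintf("  decision: %.4g*x + %.4g*y + %.4g > 0 -> %s\n",
              x$w[1], x$w[2], x$c, x$labels[2]))
  invisible(x)
}

#' Decision boundary of an LDA model as a line y = a*x + b
#'
#' Solves the equal-posterior locus `w . (x, y) + c = 0` for
#' `y = a*x + b`. The positive label is the class on the `y > a*x + b`
#' side - with the solidity/convexity convention, the higher-convexity
#' (wild-type-like) group.
#'
#' @param m an `lda_model` from [fit_lda()].
#' @return A `discriminant_line`: list with slope `a`, intercept `b`,
#'   `positive_label`.
#' @export
boundary_line <- function(m) {
  if (!inherits(m, "lda_model")) stop("`m` must be an lda_model")
  w <- m$w
  if (abs(w[2]) < 1e-14 * max(abs(w), 1))
    stop("vertical decision boundary: no y = a*x + b form; use w and c")
  a <- -w[1] / w[2]
  b <- -m$c / w[2]
  # class with positive decision value lies on the y > a*x + b side iff
  # w[2] > 0
  pos <- if (w[2] > 0) m$labels[2] else m$labels[1]
  neg <- setdiff(m$labels, pos)
  structure(list(a = unname(a), b = unname(b), positive_label = pos),
            negative_label = neg,
            class = "discriminant_line")
}

#' @export
print.discriminant_line <- function(x, ...) {
  cat(sprintf("<discriminant_line> y = %.4g*x + %.4g; y above -> %s\n",
              x$a, x$b, x$positive_label))
  invisible(x)
}

#' Build a discriminant line directly
#'
#' @param a slope.
#' @param b intercept.
#' @param positive_label label assigned when `y > a*x + b` (ties included).
#' @return A `discriminant_line`.
#' @export
discriminant_line <- function(a, b, positive_label = "WT") {
  if (!is.finite(a) || !is.finite(b)) stop("`a` and `b` must be finite")
  structure(list(a = a, b = b, positive_label = positive_label),
            class = "discriminant_line")
}

#' Classify a point against a discriminant line
#'
#' `y > a*x + b` (and ties, by convention) map to `positive_label`;
#' `y < a*x + b` maps to the complementary side, reported as
#' `"not <positive_label>"` unless the line carries a second label in
#' `attr(line, "negative_label")`.
#'
#' @param line a `discriminant_line`.
#' @param x,y feature coordinates (solidity, convexity); vectorized.
#' @return Character vector of labels.
#' @export
classify_point <- function(line, x, y) {
  if (!inherits(line, "discriminant_line"))
    stop("`line` must be a discriminant_line")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("`x` and `y` must be finite")
  neg <- attr(line, "negative_label")
  if (is.null(neg)) neg <- paste("not", line$positive_label)
  ifelse(y >= line$a * x + line$b, line$positive_label, neg)
}

#' Confusion matrix, accuracy and Cohen's kappa
#'
#' `confusion()` cross-tabulates truth against prediction;
#' `accuracy()` is trace/total; `cohen_kappa()` is
#' `(p_o - p_e) / (1 - p_e)` with the chance agreement `p_e` from the
#' products of row and column marginals. For balanced true classes
#' `p_e = 1/2`, so `kappa = 2 * accuracy - 1` exactly.
#'
#' @param truth,predicted equal-length label vectors.
#' @return `confusion()`: a `counts[true, predicted]` matrix.
#' @export
confusion <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth/predicted length mismatch")
  if (!length(truth)) stop("empty label vectors")
  lv <- sort(unique(c(truth, predicted)))
  table(factor(truth, lv), factor(predicted, lv), dnn = c("true", "predicted"))
}

#' @param cm a confusion matrix (any nonnegative square matrix of counts).
#' @rdname confusion
#' @export
accuracy <- function(cm) {
  cm <- as.matrix(unclass(cm))
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix total must be > 0")
  sum(diag(cm)) / total
}

#' @rdname confusion
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(unclass(cm))
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix total must be > 0")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-15)
    stop("kappa undefined: degenerate marginals (p_e = 1)")
  (po - pe) / (1 - pe)
}

#' Two-sample Student's / Welch's t-test
#'
#' Pooled-variance (Student's) two-sample t by default, matching the
#' original analysis; `equal_var = FALSE` gives Welch's test with
#' Satterthwaite degrees of freedom. Two-sided p-value.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param equal_var pool the variances (default `TRUE`).
#' @return A `test_result`: list with `statistic`, `df`, `p_value`.
#' @export
student_t_test <- function(group_a, group_b, equal_var = TRUE) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  va <- var(a); vb <- var(b)
  if (equal_var) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 <= 0) stop("zero pooled variance")
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    if (va <= 0 && vb <= 0) stop("zero pooled variance")
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  p <- 2 * pt(-abs(t), df)
  structure(list(statistic = t, df = df, p_value = p), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g\n", x$statistic, x$df,
              x$p_value))
  invisible(x)
}

#' Normalize size descriptors to a reference group
#'
#' Divides `V`, `Vc`, `A`, `Ac` by the reference group's means, so the
#' reference group's mean of each normalized quantity is exactly 1. The
#' dimensionless descriptors `C` and `S` are untouched.
#'
#' @param records a `morph_descriptors` data frame with a `label` column.
#' @param reference_label the reference group tag (e.g. the wild-type
#'   line).
#' @return The records with `V`, `Vc`, `A`, `Ac` replaced by relative
#'   values.
#' @export
relative_to_reference <- function(records, reference_label) {
  if (!is.data.frame(records)) stop("`records` must be a data.frame")
  ref <- records$label == reference_label
  if (!any(ref, na.rm = TRUE))
    stop("no records with reference label '", reference_label, "'")
  for (col in c("V", "Vc", "A", "Ac")) {
    m <- mean(records[[col]][which(ref)])
    records[[col]] <- records[[col]] / m
  }
  records
}
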