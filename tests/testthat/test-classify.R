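test_that("symmetric classes give the boundary y = 0", {
  set.seed(12)
  n <- 500
  x <- rnorm(2 * n, 0, 0.3)
  y <- c(rnorm(n, -1, 0.3), rnorm(n, 1, 0.3))
  m <- fit_lda(cbind(x = x, y = y), rep(c("a", "b"), each = n))
  line <- boundary_line(m)
  expect_equal(line$a, 0, tolerance = 0.05)
  expect_equal(line$b, 0, tolerance = 0.05)
  expect_equal(line$positive_label, "b")
})

test_that("boundary_line inverts the printed discriminant for any scaling", {
  for (k in c(0.5, 1, 3)) {
    m <- structure(list(w = c(-0.266 * k, k), c = -0.572 * k,
                        labels = c("mutant", "WT"), n = c(18, 18)),
                   class = "lda_model")
    line <- boundary_line(m)
    expect_equal(line$a, 0.266, tolerance = 1e-12)
    expect_equal(line$b, 0.572, tolerance = 1e-12)
    expect_equal(line$positive_label, "WT")
  }
})

test_that("LDA recovers a known boundary from seeded Gaussian classes", {
  set.seed(42)
  n <- 200
  a_true <- 0.25; b_true <- 0.5
  # class means mirrored across the line y = a x + b
  x <- rnorm(2 * n, 0.6, 0.1)
  offs <- rep(c(-0.2, 0.2), each = n)
  y <- a_true * x + b_true + offs + rnorm(2 * n, 0, 0.1)
  m <- fit_lda(cbind(x = x, y = y), rep(c("lo", "hi"), each = n))
  line <- boundary_line(m)
  expect_lt(abs(line$a - a_true), 0.05)
  expect_lt(abs(line$b - b_true), 0.05)
})

test_that("fit_lda agrees with the MASS reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(33)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 1), ncol = 2))
  lab <- rep(c("g1", "g2"), each = 30)
  m <- fit_lda(X, lab)
  ref <- MASS::lda(X, grouping = lab, prior = c(0.5, 0.5))
  # same direction up to scale
  w_ref <- ref$scaling[, 1]
  ratio <- m$w / w_ref
  expect_equal(ratio[1], ratio[2], tolerance = 1e-6)
  # same predictions
  line <- boundary_line(m)
  pred <- classify_point(line, X[, 1], X[, 2])
  pred_ref <- as.character(predict(ref, X)$class)
  expect_equal(pred, pred_ref)
})

test_that("degenerate LDA inputs fail", {
  X <- matrix(rep(c(1, 2), each = 4), ncol = 2)  # duplicated points
  expect_error(fit_lda(X, rep(c("a", "b"), 2)), "singular|degenerate")
  expect_error(fit_lda(matrix(rnorm(10), ncol = 2), rep("a", 5)),
               "two classes")
})

test_that("classify_point applies the printed line and the tie rule", {
  line <- discriminant_line(0.266, 0.572, positive_label = "WT")
  # 0.266 * 0.8 + 0.572 = 0.7848 < 0.9 -> WT side
  expect_equal(classify_point(line, 0.8, 0.9), "WT")
  # exactly on the line -> positive label
  expect_equal(classify_point(line, 0.5, 0.266 * 0.5 + 0.572), "WT")
  l0 <- discriminant_line(0, 0, positive_label = "pos")
  expect_equal(classify_point(l0, 5, -1), "not pos")
})

test_that("accuracy and kappa reproduce the published statistics", {
  # 18 per true class, 33/36 correct: accuracy 0.917, kappa 0.833
  cm <- matrix(c(17, 2, 1, 16), 2,
               dimnames = list(c("WT", "mut"), c("WT", "mut")))
  expect_equal(accuracy(cm), 33 / 36)
  expect_equal(round(accuracy(cm), 3), 0.917)
  expect_equal(cohen_kappa(cm), (33 / 36 - 0.5) / 0.5)
  expect_equal(confusion(rep(c("a", "b"), c(3, 2)),
                         c("a", "a", "b", "b", "b"))[1, 1], 2,
               ignore_attr = TRUE)
  perfect <- diag(c(10, 10))
  expect_equal(accuracy(perfect), 1)
  expect_equal(cohen_kappa(perfect), 1)
  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "undefined")
})

test_that("kappa = 2*accuracy - 1 for balanced true classes", {
  set.seed(55)
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    correct1 <- sample(0:n, 1); correct2 <- sample(0:n, 1)
    cm <- matrix(c(correct1, n - correct2, n - correct1, correct2), 2)
    if (abs(1 - sum(rowSums(cm) * colSums(cm)) / sum(cm)^2) < 1e-12) next
    expect_equal(cohen_kappa(cm), 2 * accuracy(cm) - 1, tolerance = 1e-12)
  }
})

test_that("student t-test matches hand computation and stats::t.test", {
  tt <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.0213, tolerance = 1e-3)

  set.seed(66)
  for (rep in 1:20) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), 0.5)
    for (ev in c(TRUE, FALSE)) {
      mine <- student_t_test(a, b, equal_var = ev)
      ref <- t.test(a, b, var.equal = ev)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
  expect_equal(student_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(student_t_test(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("relative_to_reference normalizes sizes, leaves C and S alone", {
  rec <- data.frame(name = letters[1:4], V = c(2, 4, 6, 8),
                    Vc = c(4, 4, 8, 8), A = c(1, 3, 2, 6),
                    Ac = c(2, 2, 4, 4), C = c(0.9, 1, 0.8, 0.85),
                    S = c(0.5, 1, 0.75, 1),
                    label = c("ref", "ref", "x", "x"))
  out <- relative_to_reference(rec, "ref")
  expect_equal(mean(out$V[out$label == "ref"]), 1)
  expect_equal(mean(out$Ac[out$label == "ref"]), 1)
  expect_equal(out$V[3:4], c(2, 8 / 3))
  expect_equal(out$C, rec$C)
  expect_equal(out$S, rec$S)
  expect_error(relative_to_reference(rec, "nope"), "no records")
  # normalization commutes with a global unit rescale
  rec2 <- rec
  for (col in c("V", "Vc")) rec2[[col]] <- rec2[[col]] * 8
  for (col in c("A", "Ac")) rec2[[col]] <- rec2[[col]] * 4
  out2 <- relative_to_reference(rec2, "ref")
  for (col in c("V", "Vc", "A", "Ac"))
    expect_equal(out2[[col]], out[[col]])
})
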