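test_that("the Gram matrix equals the direct cross product", {
  X <- expression_matrix(diag(3), paste0("g", 1:3), paste0("e", 1:3))
  expect_equal(unname(compute_gram(X)$values), diag(3))

  X2 <- expression_matrix(matrix(c(1, 3, 2, 4), 2, 2),
                          c("g1", "g2"), c("e1", "e2"))
  expect_equal(unname(compute_gram(X2)$values),
               matrix(c(5, 11, 11, 25), 2, 2))

  set.seed(1)
  V <- rand_X(8, 15, seed = 1)
  X3 <- expression_matrix(V, paste0("g", 1:8), paste0("e", 1:15))
  G <- compute_gram(X3)$values
  expect_lt(max(abs(G - V %*% t(V))), 1e-12 * max(abs(G)))
  expect_identical(G, t(G))                       # exact symmetry
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
             -1e-9 * sum(diag(G)))                # positive semidefinite
})

test_that("subset Gram submatrices match the direct product on the subset", {
  set.seed(2)
  V <- rand_X(10, 12, seed = 2)
  G <- compute_gram(expression_matrix(V, paste0("g", 1:10),
                                      paste0("e", 1:12)))$values
  for (r in 1:20) {
    s <- sort(sample(10, sample(1:6, 1)))
    direct <- V[s, , drop = FALSE] %*% t(V[s, , drop = FALSE])
    expect_lt(max(abs(G[s, s] - direct)), 1e-12 * max(1, max(abs(direct))))
  }
})

test_that("response projection: canonical fast path equals the general path", {
  set.seed(3)
  n <- 6
  V <- rand_X(n, n, seed = 3)
  ids <- paste0("g", 1:n); eids <- paste0("e", 1:n)
  X <- expression_matrix(V, ids, eids)
  P <- perturbation_design(diag(n), ids, eids)
  expect_true(P$canonical)
  for (i in seq_len(n)) {
    pr <- response_projection(X, P, i)
    expect_equal(pr$xty, unname(-V[, i]))  # minus the perturbed column
    expect_equal(pr$yty, 1)
    # general (non-canonical) route on the same numbers
    expect_equal(pr$xty, as.vector(V %*% -P$values[i, ]), tolerance = 1e-12)
  }

  # arbitrary multi-gene designs go through the explicit product
  Pv <- matrix(rnorm(n * n), n, n)
  P2 <- perturbation_design(Pv, ids, eids)
  expect_false(P2$canonical)
  for (i in c(1L, 4L)) {
    pr <- response_projection(X, P2, i)
    expect_equal(pr$xty, as.vector(V %*% -Pv[i, ]), tolerance = 1e-12)
    expect_equal(pr$yty, sum(Pv[i, ]^2))
  }
  expect_error(response_projection(X, P, n + 1L), "out of range")
})

test_that("an unperturbed gene projects to the zero response", {
  n <- 4
  V <- rand_X(n, 2, seed = 4)
  X <- expression_matrix(V, paste0("g", 1:n), c("e1", "e2"))
  Pv <- matrix(0, n, 2); Pv[1, 1] <- 1; Pv[2, 2] <- 1
  P <- perturbation_design(Pv, paste0("g", 1:n), c("e1", "e2"))
  pr <- response_projection(X, P, 3L)  # gene 3 never perturbed
  expect_equal(pr$xty, numeric(n))
  expect_equal(pr$yty, 0)
})

test_that("subset least squares reproduces closed-form cases", {
  # orthonormal regressors
  G1 <- structure(list(gene_ids = c("g1", "g2"), values = diag(2)),
                  class = "gram_matrix")
  s <- subset_least_squares(G1, proj_from(diag(2), c(1, 0)), c(1L, 2L))
  expect_s3_class(s, "subset_solution")
  expect_equal(s$coefficients, c(1, 0))
  expect_equal(s$rss, 0)

  # one regressor: b = xty / G, rss = yty - xty^2 / G
  G2 <- structure(list(gene_ids = "g1", values = matrix(4, 1, 1)),
                  class = "gram_matrix")
  pr <- structure(list(xty = 2, yty = 2, gene = 1L),
                  class = "response_projection")
  s2 <- subset_least_squares(G2, pr, 1L)
  expect_equal(s2$coefficients, 0.5)
  expect_equal(s2$rss, 1)

  # consistent 2-regressor system solved exactly
  V <- matrix(c(1, 0, 2, 1, 3, 1), 2, 3)
  y <- c(1, 1, 2)
  X <- expression_matrix(V, c("g1", "g2"), paste0("e", 1:3))
  G3 <- compute_gram(X)
  expect_equal(unname(G3$values), matrix(c(14, 5, 5, 2), 2, 2))
  pr3 <- proj_from(V, y)
  expect_equal(pr3$xty, c(9, 3))
  expect_equal(pr3$yty, 6)
  s3 <- subset_least_squares(G3, pr3, c(1L, 2L))
  expect_equal(s3$coefficients, c(1, -1), tolerance = 1e-10)
  expect_equal(s3$rss, 0, tolerance = 1e-10)
})

test_that("fast solver agrees with the QR oracle on random subsets", {
  set.seed(10)
  for (r in 1:200) {
    n <- sample(4:12, 1); m <- n + sample(3:10, 1)
    V <- matrix(rnorm(n * m), n, m)
    y <- rnorm(m)
    G <- structure(list(gene_ids = paste0("g", 1:n),
                        values = (tcrossprod(V) + t(tcrossprod(V))) / 2),
                   class = "gram_matrix")
    s <- sort(sample(n, sample(1:min(n, 10), 1)))
    fit <- subset_least_squares(G, proj_from(V, y), s)
    ref <- ls_oracle(V, y, s)
    expect_s3_class(fit, "subset_solution")
    scale <- max(1, max(abs(ref$coefficients)))
    expect_lt(max(abs(fit$coefficients - ref$coefficients)), 1e-8 * scale)
    expect_lt(abs(fit$rss - ref$rss), 1e-8 * max(1, ref$rss))
  }
})

test_that("adding a regressor never increases the residual sum of squares", {
  set.seed(11)
  for (r in 1:50) {
    n <- 8; m <- 14
    V <- matrix(rnorm(n * m), n, m)
    y <- rnorm(m)
    G <- compute_gram(expression_matrix(V, paste0("g", 1:n),
                                        paste0("e", 1:m)))
    pr <- proj_from(V, y)
    s <- sort(sample(n, sample(1:(n - 1), 1)))
    rest <- setdiff(seq_len(n), s)
    extra <- rest[sample.int(length(rest), 1)]
    f1 <- subset_least_squares(G, pr, s)
    f2 <- subset_least_squares(G, pr, sort(c(s, extra)))
    expect_lte(f2$rss, f1$rss + 1e-9 * max(1, pr$yty))
  }
})

test_that("full-rank noise-free systems reach zero residual", {
  set.seed(12)
  n <- 6
  V <- matrix(rnorm(n * n), n, n)
  b_true <- rnorm(n)
  y <- as.vector(t(V) %*% b_true)
  G <- compute_gram(expression_matrix(V, paste0("g", 1:n),
                                      paste0("e", 1:n)))
  pr <- proj_from(V, y)
  fit <- subset_least_squares(G, pr, seq_len(n))
  expect_lt(fit$rss, 1e-9 * pr$yty)
  expect_equal(fit$coefficients, b_true, tolerance = 1e-8)
})

test_that("linearly dependent regressors yield a singular signal, not a crash", {
  V <- matrix(c(1, 2, 2, 4, 3, 6), 2, 3)  # row 2 = 2 x row 1
  y <- c(1, 0, 1)
  G <- compute_gram(expression_matrix(V, c("g1", "g2"), paste0("e", 1:3)))
  fit <- subset_least_squares(G, proj_from(V, y), c(1L, 2L))
  expect_s3_class(fit, "singular_candidate")
  expect_identical(fit$subset, c(1L, 2L))
  # invalid subsets are rejected up front
  expect_error(subset_least_squares(G, proj_from(V, y), integer(0)),
               "non-empty")
  expect_error(subset_least_squares(G, proj_from(V, y), c(2L, 1L)),
               "strictly increasing")
  expect_error(subset_least_squares(G, proj_from(V, y), 5L), "out of range")
})
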