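# Dense-solver oracle: build the full symmetric matrix and use solve().
dense_solve <- function(a, b, r, parent) {
  n <- length(a)
  A <- diag(a, n)
  if (n > 1L) {
    for (i in 2:n) {
      A[i, parent[i]] <- b[i]
      A[parent[i], i] <- b[i]
    }
  }
  as.vector(solve(A, r))
}

random_spd_tree <- function(n) {
  parent <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  b <- c(0, -runif(n - 1, 0.1, 2))
  a <- numeric(n)
  for (i in seq_len(n)) a[i] <- runif(1, 0.5, 2)
  # diagonal dominance: a_i > sum of |b| couplings touching i
  for (i in 2:n) {
    a[i] <- a[i] + abs(b[i])
    a[parent[i]] <- a[parent[i]] + abs(b[i])
  }
  list(a = a, b = b, r = rnorm(n), parent = parent)
}

test_that("a single compartment reduces to scalar division", {
  expect_identical(hines_solve(2, 0, 8, 0L), 4)
})

test_that("a three-compartment chain matches the dense solve", {
  a <- c(2, 2, 2); b <- c(0, -1, -1); r <- c(1, 0, 1); parent <- c(0L, 1L, 2L)
  expect_equal(hines_solve(a, b, r, parent), dense_solve(a, b, r, parent),
               tolerance = 1e-14)
})

test_that("random SPD trees solve to f32-level accuracy", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    s <- random_spd_tree(n)
    # criterion is stated at f32: round the coefficients to single precision
    a <- flatbrain:::fb_round_f32(s$a); b <- flatbrain:::fb_round_f32(s$b)
    r <- flatbrain:::fb_round_f32(s$r)
    v1 <- hines_solve(a, b, r, s$parent)
    v2 <- dense_solve(a, b, r, s$parent)
    expect_lt(max(abs(v1 - v2)), 1e-6)
  }
})

test_that("a zero pivot raises SingularSystem", {
  expect_error(hines_solve(c(1, 0), c(0, -1), c(1, 1), c(0L, 1L)),
               class = "SingularSystem")
})
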