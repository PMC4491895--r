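test_that("recurrence matrix reproduces hand-computed cases", {
  # states 0, 10, 0.05 in one dimension, eps = 0.1: only (1,3) recurs
  tr <- structure(matrix(c(0, 10, 0.05), ncol = 1),
                  class = c("phase_trajectory", "matrix", "array"))
  rp <- recurrence_matrix(tr, 0.1)
  expect_equal(rp$pairs, cbind(i = 1L, j = 3L), ignore_attr = TRUE)
  m <- as.matrix(rp)
  expect_identical(diag(m), rep(1L, 3))
  expect_identical(m, t(m))
  expect_equal(rp$recurrence_rate, (2 * 1 + 3) / 9)
  # boundary: a tie at exactly eps recurs (Heaviside(0) = 1)
  tr2 <- structure(matrix(c(0, 0.1), ncol = 1),
                   class = c("phase_trajectory", "matrix", "array"))
  expect_equal(nrow(recurrence_matrix(tr2, 0.1)$pairs), 1)
})

test_that("constant series saturates the matrix at any positive epsilon", {
  tr <- embed_series(rep(3, 60), 1, 2)
  rp <- recurrence_matrix(tr, 1e-6)
  expect_equal(rp$recurrence_rate, 1)
  expect_true(all(as.matrix(rp) == 1L))
  expect_warning(cal <- calibrate_epsilon(tr, 0.03), "identical")
  expect_true(cal$flagged)
  expect_equal(cal$achieved_rate, 1)
})

test_that("epsilon calibration brackets and matches the quantile oracle", {
  set.seed(21)
  for (k in 1:10) {
    tr <- random_trajectory(21 + k)
    n <- nrow(tr)
    target <- runif(1, 0.02, 0.3)
    cal <- calibrate_epsilon(tr, target)
    # oracle: walk the sorted distance list (k = 0, 1, ... off-diagonal
    # recurrences) until the rate first reaches the target
    d <- sort(as.numeric(dist(unclass(tr))))
    rate_k <- (2 * (0:length(d)) + n) / n^2
    k_star <- which(rate_k >= target)[1] - 1L
    expect_gte(cal$achieved_rate, target)
    if (k_star == 0L) {
      # the diagonal alone meets the target
      expect_equal(cal$achieved_rate, 1 / n)
    } else {
      expect_equal(cal$epsilon, d[k_star])
      # smallest achievable: one fewer recurrence would undershoot
      expect_lt(rate_k[k_star], target)
    }
    # recomputing the rate from the matrix agrees
    rp <- recurrence_matrix(tr, cal$epsilon)
    expect_equal(rp$recurrence_rate, cal$achieved_rate)
  }
})

test_that("calibration saturation and floor cases behave", {
  tr <- random_trajectory(99)
  n <- nrow(tr)
  dmax <- max(dist(unclass(tr)))
  expect_equal(recurrence_matrix(tr, dmax)$recurrence_rate, 1)
  dmin <- min(dist(unclass(tr)))
  expect_equal(recurrence_matrix(tr, dmin / 2)$recurrence_rate, n / n^2)
  # a target below the diagonal floor still returns a valid epsilon
  cal <- calibrate_epsilon(tr, 1 / n^2)
  expect_equal(cal$achieved_rate, 1 / n)
})

test_that("achieved rate is non-decreasing in epsilon", {
  tr <- random_trajectory(7)
  d <- sort(as.numeric(dist(unclass(tr))))
  eps_grid <- d[round(seq(1, length(d), length.out = 8))]
  rates <- vapply(eps_grid, function(e)
    recurrence_matrix(tr, e)$recurrence_rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("recurrence and joint counting match the naive double loop exactly", {
  # tie-free epsilon: midway between consecutive observed distances, so
  # the package's dist() and the oracle's sqrt(sum()) cannot disagree on
  # a boundary by one ulp
  tie_free_eps <- function(tr, q = 0.1) {
    d <- sort(as.numeric(dist(unclass(tr))))
    k <- max(1, floor(q * length(d)))
    (d[k] + d[min(k + 1, length(d))]) / 2
  }
  for (k in 1:20) {
    trx <- random_trajectory(100 + k)
    try_ <- random_trajectory(200 + k)
    ex <- tie_free_eps(trx)
    ey <- tie_free_eps(try_)
    rx <- recurrence_matrix(trx, ex)
    ry <- recurrence_matrix(try_, ey)
    Rx <- naive_recurrence(unclass(trx), ex)
    Ry <- naive_recurrence(unclass(try_), ey)
    expect_identical(as.matrix(rx), Rx)
    expect_identical(joint_recurrence_count(rx, ry)$count,
                     naive_jr_count(Rx, Ry))
  }
})

test_that("joint recurrence identities: idempotence, bounds, symmetry, disjoint", {
  trx <- random_trajectory(31)
  try_ <- random_trajectory(32)
  rx <- recurrence_matrix(trx, calibrate_epsilon(trx, 0.15)$epsilon)
  ry <- recurrence_matrix(try_, calibrate_epsilon(try_, 0.15)$epsilon)
  n <- min(rx$n_states, ry$n_states)
  jc <- joint_recurrence_count(rx, ry)
  expect_identical(jc$count, joint_recurrence_count(ry, rx)$count)
  upper_count <- function(r, n) sum(r$pairs[, 2] <= n)
  expect_lte(jc$count, min(upper_count(rx, n), upper_count(ry, n)))
  # count(x, x) equals the upper-triangle recurrence count of x
  expect_identical(joint_recurrence_count(rx, rx)$count,
                   nrow(rx$pairs))
  # containment gives equality with the smaller marginal
  rbig <- recurrence_matrix(trx, calibrate_epsilon(trx, 0.5)$epsilon)
  expect_identical(joint_recurrence_count(rx, rbig)$count, nrow(rx$pairs))
  # disjoint recurrence sets give zero
  ra <- list(pairs = cbind(i = 1L, j = 2L), n_states = 10L,
             epsilon = 1, recurrence_rate = 0.12, residue_id = "a")
  rb <- list(pairs = cbind(i = 3L, j = 4L), n_states = 10L,
             epsilon = 1, recurrence_rate = 0.12, residue_id = "b")
  class(ra) <- class(rb) <- "recurrence_matrix"
  expect_identical(joint_recurrence_count(ra, rb)$count, 0L)
})

test_that("all-pairs counting agrees with pairwise counting after truncation", {
  rps <- lapply(1:4, function(k) {
    tr <- random_trajectory(300 + k)
    rp <- recurrence_matrix(tr, calibrate_epsilon(tr, 0.2)$epsilon)
    rp$residue_id <- k
    rp
  })
  all_counts <- joint_recurrence_counts(rps)
  expect_equal(nrow(all_counts), 6)
  for (r in seq_len(nrow(all_counts))) {
    a <- as.integer(all_counts$res_a[r])
    b <- as.integer(all_counts$res_b[r])
    # pairwise truncation window can be wider; recompute at the global one
    n_min <- attr(all_counts, "n_states")
    Ra <- as.matrix(rps[[a]])[1:n_min, 1:n_min]
    Rb <- as.matrix(rps[[b]])[1:n_min, 1:n_min]
    expect_identical(all_counts$count[r], naive_jr_count(Ra, Rb))
  }
})

test_that("independent noise series meet the product-of-rates null", {
  set.seed(7)
  r1 <- residue_recurrence(rnorm(1000), 1, 1, residue_id = "a")
  r2 <- residue_recurrence(rnorm(1000), 1, 1, residue_id = "b")
  expect_equal(r1$recurrence_rate, 0.03, tolerance = 0.002)
  jc <- joint_recurrence_count(r1, r2)
  ncells <- jc$n_states * (jc$n_states - 1) / 2
  p2 <- 0.03^2
  expect_lt(abs(jc$count / ncells - p2), 3 * sqrt(p2 * (1 - p2) / ncells))
})

test_that("recurrence grid and JR count exports are plain text round-trips", {
  tr <- random_trajectory(55)
  rp <- recurrence_matrix(tr, calibrate_epsilon(tr, 0.1)$epsilon)
  f <- withr::local_tempfile(fileext = ".txt")
  write_recurrence_grid(rp, f)
  grid <- as.matrix(read.table(f))
  expect_equal(unname(grid), unname(as.matrix(rp)))
  counts <- data.frame(res_a = c("1", "1"), res_b = c("2", "3"),
                       count = c(5L, 0L))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_jr_counts_tsv(counts, f2)
  expect_equal(read.delim(f2, colClasses = c("character", "character",
                                             "integer")),
               counts)
})
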