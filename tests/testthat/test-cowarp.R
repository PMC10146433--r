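test_that("target selection maximizes mean correlation with ties to the lowest index", {
  set.seed(3)
  a <- rnorm(30); b <- 0.5 * a + sqrt(0.75) * rnorm(30)
  expect_identical(select_target_profile(rbind(a, a, b)), 1L)
  expect_identical(select_target_profile(rbind(a, b)), 1L)   # symmetric tie
  expect_error(select_target_profile(list(rnorm(5), rnorm(6))),
               class = "herbscreen_invalid_argument")
})

test_that("target selection agrees with the brute-force pairwise table", {
  set.seed(11)
  tr <- matrix(rnorm(5 * 40), nrow = 5)
  means <- sapply(1:5, function(i)
    mean(sapply(setdiff(1:5, i), function(j) cor(tr[i, ], tr[j, ]))))
  expect_identical(select_target_profile(tr), which.max(means))
})

test_that("warping a trace onto itself is the identity with score = segment count", {
  x <- sin(seq(0, 6 * pi, length.out = 120)) + 0.1 * seq(0, 1, length.out = 120)
  w <- cow_warp(x, x, warp_spec(10, 2))
  expect_equal(w$score, length(w$segment_scores))
  expect_equal(w$warped, x)
  expect_identical(w$node_positions[1], 1L)
  expect_identical(w$node_positions[length(w$node_positions)], 120L)
})

test_that("a 2-point shifted triangular peak is recovered at the target apex", {
  x <- seq_len(41)
  tgt <- pmax(0, 1 - abs(x - 21) / 8)
  smp <- pmax(0, 1 - abs(x - 23) / 8)
  w <- cow_warp(smp, tgt, warp_spec(10, 2))
  expect_identical(which.max(w$warped), 21L)
  # path equals the brute-force enumeration optimum
  bf <- cow_brute_force(smp, tgt, 10, 2)
  expect_equal(w$score, bf$score, tolerance = 1e-9)
  expect_identical(as.integer(w$node_positions), as.integer(bf$nodes + 1))
})

test_that("a constant sample warps to a constant with score 0", {
  tgt <- rnorm(40)
  w <- cow_warp(rep(2, 40), tgt, warp_spec(8, 2))
  expect_equal(w$score, 0)
  expect_equal(w$warped, rep(2, 40))
})

test_that("warp preconditions are enforced", {
  expect_error(warp_spec(2, 1), class = "herbscreen_invalid_argument")
  expect_error(warp_spec(10, 10), class = "herbscreen_invalid_argument")
  expect_error(cow_warp(rnorm(10), rnorm(10), warp_spec(8, 2)),
               class = "herbscreen_invalid_argument")
})

test_that("DP equals exhaustive enumeration on random small instances", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(20:40, 1)
    L <- sample(5:8, 1)
    s <- sample(1:2, 1)
    smp <- as.vector(stats::filter(rnorm(n), rep(1 / 4, 4), sides = 1))
    smp[is.na(smp)] <- 0
    tgt <- as.vector(stats::filter(rnorm(n), rep(1 / 4, 4), sides = 1))
    tgt[is.na(tgt)] <- 0
    w <- cow_warp(smp, tgt, warp_spec(L, s))
    bf <- cow_brute_force(smp, tgt, L, s)
    expect_equal(w$score, bf$score, tolerance = 1e-9)
    expect_true(all(diff(w$node_positions) > 0))
    expect_length(w$warped, n)
  }
})

test_that("parameter grid search honours the tie rule and dominates no warping", {
  set.seed(7)
  base <- dnorm(seq(-4, 8, length.out = 100), 0, 0.6) +
    dnorm(seq(-4, 8, length.out = 100), 4, 0.8)
  aligned <- rbind(base, base, base)
  spec <- optimize_warp_params(aligned, segment_grid = c(10, 20), slack_grid = 1:2)
  expect_identical(spec$segment_length, 10L)     # all cells tie at mean r = 1
  expect_identical(spec$slack, 1L)

  shifted <- rbind(base, c(base[-(1:3)], rep(base[100], 3)),
                   c(rep(base[1], 3), base[-(98:100)]))
  spec2 <- optimize_warp_params(shifted, target_index = 1,
                                segment_grid = c(10, 20), slack_grid = 1:2)
  unwarped_score <- mean(apply(shifted, 1, cor, y = base))
  expect_gte(attr(spec2, "score"), unwarped_score)

  # equals exhaustive evaluation of the four grid cells, run independently
  cells <- expand.grid(L = c(10, 20), s = 1:2)
  cell_scores <- mapply(function(L, s) {
    mean(apply(shifted, 1, function(tr)
      cor(cow_warp(tr, base, warp_spec(L, s))$warped, base)))
  }, cells$L, cells$s)
  best_cells <- which(cell_scores > max(cell_scores) - 1e-9)
  expect_true(any(cells$L[best_cells] == spec2$segment_length &
                  cells$s[best_cells] == spec2$slack))
})

test_that("aligning replicate traces leaves the cube unchanged", {
  set.seed(13)
  trace <- dnorm(seq(-3, 9, length.out = 200), 1, 0.4) +
    0.6 * dnorm(seq(-3, 9, length.out = 200), 5, 0.7)
  vals <- array(0, c(4, 2, 200))
  for (i in 1:4) for (j in 1:2) vals[i, j, ] <- trace * j
  cube <- dad_cube(vals, sprintf("s%d", 1:4), c(254, 280),
                   seq(0, 8, length.out = 200))
  al <- align_cube(cube, warp_spec(20, 3))
  expect_equal(al$values, cube$values, tolerance = 1e-9)
  log <- attr(al, "warp_log")
  expect_length(log, 2L)
  expect_identical(log[[1]]$target_index, 1L)
})

test_that("alignment increases cross-sample correlation on a jittered cube", {
  set.seed(19)
  grid <- seq(0, 8, length.out = 300)
  n <- 6
  vals <- array(0, c(n, 1, 300))
  for (i in 1:n) {
    shift <- sample(-2:2, 1) * diff(grid)[1]
    vals[i, 1, ] <- dnorm(grid, 2 + shift, 0.15) + 0.5 * dnorm(grid, 5 + shift, 0.25)
  }
  cube <- dad_cube(vals, sprintf("s%d", 1:n), 254, grid)
  al <- align_cube(cube, warp_spec(15, 3))
  xcor <- function(c) {
    cc <- cor(t(matrix(c$values[, 1, ], nrow = n)))
    mean(cc[upper.tri(cc)])
  }
  expect_gt(xcor(al), xcor(cube))
})
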