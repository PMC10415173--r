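# helper: D=4 point sets where each row's grid cell is easy to control
cell_point <- function(v) matrix(v, nrow = 1)

test_that("grid discretization is equidistant with a closed last bin", {
  x <- matrix(c(0, 0.999, 1, 0.05, 0.55, 0.1), ncol = 1)
  idx <- grid_cell(x, grid_size = 10)
  expect_equal(as.integer(idx), c(0L, 9L, 9L, 0L, 5L, 1L))
  expect_error(grid_cell(matrix(1.2), 10), class = "kbalance_range_error")
  expect_error(grid_cell(matrix(-0.1), 10), class = "kbalance_range_error")
})

test_that("candidates are accepted below C_max and rejected at C_max", {
  # 5 samples in cell X, then 1 in cell Y enter during initialisation,
  # giving C_X = 5 = C_max, C_Y = 1. The next Y candidate (1 < 5) must be
  # accepted and the next X candidate (5 == 5) rejected.
  x_pt <- c(0.05, 0.05, 0.05, 0.05)
  y_pt <- c(0.95, 0.95, 0.95, 0.95)
  pts <- rbind(matrix(rep(x_pt, 5), 5, byrow = TRUE),  # rows 1-5: cell X
               y_pt,                                   # row 6: cell Y
               y_pt,                                   # row 7: cell Y
               matrix(rep(x_pt, 3), 3, byrow = TRUE))  # rows 8-10: cell X
  res <- suppressWarnings(balance_profiles(pts, budget = 20, grid_size = 10,
                                           init_fraction = 0.3, stream = 1:10))
  expect_equal(res$accepted[1:6], 1:6)   # init phase, unconditional
  expect_true(7 %in% res$accepted)       # C_Y = 1 < C_max = 5
  expect_false(8 %in% res$accepted)      # C_X = 5 == C_max
  expect_equal(res$c_max, 5L)
  expect_equal(res$n_reject, 3L)         # rows 8, 9, 10 all sit at C_max
})

test_that("all-distinct cells are never rejected and fill the budget", {
  # k=1-style profiles, one per grid cell (after the first initialising
  # acceptance raises C_max to 1, every empty cell has C_g = 0 < C_max)
  x <- rbind(diag(4) * 0.9 + 0.02, diag(4) * 0.5 + 0.02)
  res <- balance_profiles(x, budget = 6, grid_size = 4, seed = 99)
  expect_equal(res$n_reject, 0L)
  set.seed(99)
  expect_equal(res$accepted, sample.int(8)[1:6])
})

test_that("balance matches the dense-grid oracle index for index", {
  set.seed(7)
  x <- matrix(runif(200 * 4), 200, 4)
  res <- balance_profiles(x, budget = 100, grid_size = 4, seed = 7)
  expect_equal(res$accepted,
               dense_balance_oracle(x, budget = 100, grid_size = 4, seed = 7))

  for (s in 1:10) {
    set.seed(1000 + s)
    n <- sample(200:500, 1)
    # mixture: a dense corner blob plus uniform background, so rejections
    # and escape acceptances all get exercised
    x <- rbind(matrix(runif(floor(n / 2) * 4, 0, 0.2), ncol = 4),
               matrix(runif(ceiling(n / 2) * 4), ncol = 4))
    budget <- sample(50:n, 1)
    got <- balance_profiles(x, budget = budget, grid_size = 4, seed = s)
    expect_equal(got$accepted,
                 dense_balance_oracle(x, budget = budget, grid_size = 4,
                                      seed = s))
  }
})

test_that("balancing is a deterministic pure undersampling within budget", {
  set.seed(3)
  x <- matrix(rbeta(300 * 4, 0.5, 2), 300, 4)
  a <- balance_profiles(x, budget = 120, grid_size = 5, seed = 42)
  b <- balance_profiles(x, budget = 120, grid_size = 5, seed = 42)
  expect_identical(a$accepted, b$accepted)
  expect_identical(tidy(a), tidy(b))

  expect_lte(length(a$accepted), 120)
  expect_equal(anyDuplicated(a$accepted), 0L)
  expect_true(all(a$accepted %in% seq_len(300)))
  d <- tidy(a)
  expect_true(all(d$c_after <= d$c_before))
  expect_true(all(d$delta_c <= 0))
  expect_equal(d$c_bar, (d$c_before + d$c_after) / 2)
  # sparse map scaling: occupied cells never exceed the sample count
  expect_lte(nrow(d), 300)
  # conservation: per-cell counts add up to the totals
  expect_equal(sum(d$c_before), 300)
  expect_equal(sum(d$c_after), length(a$accepted))
})

test_that("oversized budgets warn and return at most the input size", {
  x <- matrix(runif(40), 10, 4)
  expect_warning(res <- balance_profiles(x, budget = 50, grid_size = 2,
                                         seed = 1),
                 "exceeds")
  expect_lte(length(res$accepted), 10)
  expect_error(balance_profiles(x[0, , drop = FALSE], budget = 5),
               class = "kbalance_empty_input")
})

test_that("balancing flattens a two-blob density", {
  # 90% of the mass in one tight blob, the rest spread out
  ratio <- function(counts) max(counts) / stats::median(counts)
  for (rep in 1:10) {
    set.seed(500 + rep)
    blob <- matrix(runif(360 * 4, 0.40, 0.45), ncol = 4)
    rest <- matrix(runif(40 * 4), ncol = 4)
    x <- rbind(blob, rest)
    res <- balance_profiles(x, budget = 150, grid_size = 5, seed = rep)
    d <- res$diagnostics
    expect_lte(ratio(d$c_after[d$c_after > 0]), ratio(d$c_before))
  }
})

test_that("denser cells lose more samples (diagnostics direction)", {
  # one dense Gaussian blob over a uniform background
  set.seed(314)
  blob <- matrix(pmin(pmax(stats::rnorm(700 * 4, 0.5, 0.02), 0), 1), ncol = 4)
  bg <- matrix(runif(300 * 4), ncol = 4)
  res <- balance_profiles(rbind(blob, bg), budget = 400, grid_size = 10,
                          seed = 314)
  d <- tidy(res)
  rho <- cor(d$c_before, -d$delta_c, method = "spearman")
  expect_gt(rho, 0)
  # tidy() orders by decreasing average occupancy
  expect_true(!is.unsorted(rev(d$c_bar)))
})

test_that("diagnostics report the removal arithmetic per cell", {
  a_pt <- c(0.05, 0.05, 0.05, 0.05)
  b_pt <- c(0.95, 0.95, 0.95, 0.95)
  pts <- rbind(matrix(rep(a_pt, 4), 4, byrow = TRUE),  # A1-A4 (init)
               matrix(rep(b_pt, 3), 3, byrow = TRUE),  # B1-B3
               matrix(rep(a_pt, 6), 6, byrow = TRUE),  # A5-A10 (rejected)
               b_pt)                                   # B4
  res <- balance_profiles(pts, budget = 8, grid_size = 10,
                          init_fraction = 0.5, stream = 1:14)
  d <- balance_diagnostics(res)
  cell_a <- d[d$c_before == 10, ]
  expect_equal(cell_a$c_after, 4L)
  expect_equal(cell_a$c_bar, 7)
  expect_equal(cell_a$delta_c, -6L)
  cell_b <- d[d$c_before == 4, ]
  expect_equal(cell_b$delta_c, 0L)   # untouched cell
})

test_that("the escape hatch force-accepts after consecutive rejections", {
  # all samples share one cell; after init every candidate sits at C_max,
  # so only every (escape_threshold+1)-th candidate can enter
  x <- matrix(0.5, 60, 4)
  res <- balance_profiles(x, budget = 30, grid_size = 10,
                          init_fraction = 0.1, escape_threshold = 10,
                          seed = 8)
  expect_gt(res$n_escape, 0)
  expect_equal(length(res$accepted), 3 + (60 - 3) %/% 11)
  expect_gt(res$n_reject, 0)
})
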