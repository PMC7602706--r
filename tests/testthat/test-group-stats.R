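test_that("exact Mann-Whitney matches full enumeration", {
  m <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$U, 0)
  expect_equal(m$p_value, 0.1) # 2/20 by enumeration of C(6,3) labelings
  expect_equal(m$method, "exact")
  set.seed(1)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- rnorm(n1); b <- rnorm(n2, sample(c(0, 2), 1))
    m <- mann_whitney(a, b)
    expect_equal(m$p_value, enum_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical samples give p = 1 and ties fall back with a message", {
  expect_message(m <- mann_whitney(c(1, 2, 3), c(1, 2, 3)), "ties")
  expect_equal(m$p_value, 1)
  expect_equal(m$method, "normal_approx")
})

test_that("U statistics of the two groups sum to n1 * n2", {
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(5)
    ua <- mann_whitney(a, b)$U
    ub <- mann_whitney(b, a)$U
    expect_equal(ua + ub, 35)
  }
})

test_that("normal approximation tracks the exact p for 10 vs 10", {
  set.seed(3)
  for (i in 1:100) {
    a <- rnorm(10); b <- rnorm(10, runif(1, 0, 1.5))
    pe <- mann_whitney(a, b)$p_value
    pa <- mann_whitney(a, b, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("channel difference map normalizes by the maximum absolute difference", {
  m <- channel_difference_map(c(C4 = 0.10, Cz = 0.08),
                              c(C4 = 0.06, Cz = 0.06))
  expect_equal(m$raw, c(0.04, 0.02))
  expect_equal(m$normalized, c(1.0, 0.5))
  z <- channel_difference_map(c(C4 = 0.1, Cz = 0.1), c(C4 = 0.1, Cz = 0.1))
  expect_equal(z$normalized, c(0, 0)) # guarded division
  expect_error(channel_difference_map(c(C4 = 1), c(Cz = 1)), "differ")
  # label permutation negates raw, preserves |normalized|
  m2 <- channel_difference_map(c(C4 = 0.06, Cz = 0.06),
                               c(C4 = 0.10, Cz = 0.08))
  expect_equal(m2$raw, -m$raw)
  expect_equal(abs(m2$normalized), abs(m$normalized))
})

test_that("compare_groups emits one cell per channel x segment x condition", {
  set.seed(4)
  grid <- expand.grid(subject = paste0("s", 1:4), channel = c("C3", "C4"),
                      segment = c("clench", "unclench"),
                      hand_condition = c("all", "LH", "RH"),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(grid$subject %in% c("s1", "s2"), "young", "elderly")
  grid$r <- rnorm(nrow(grid), ifelse(grid$group == "elderly", 0.12, 0.08), 0.01)
  rep <- compare_groups(grid)
  expect_equal(nrow(rep), 2 * 2 * 3)
  expect_true(all(c("U", "p_value", "significant") %in% names(rep)))
  # significance flags match elementwise recomputation
  for (i in seq_len(nrow(rep))) {
    sub <- grid[grid$channel == rep$channel[i] & grid$segment == rep$segment[i] &
                grid$hand_condition == rep$hand_condition[i], ]
    p <- mann_whitney(sub$r[sub$group == "elderly"],
                      sub$r[sub$group == "young"])$p_value
    expect_equal(rep$p_value[i], p)
    expect_equal(rep$significant[i], p < 0.05)
  }
  expect_error(compare_groups(grid[grid$group == "young", ]), "two groups")
})
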