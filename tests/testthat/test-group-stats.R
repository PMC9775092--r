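test_that("separated groups are detected with distinct letters", {
  set.seed(1)
  d <- tibble::tibble(group = rep(c("a", "b"), each = 6),
                      y = c(1, 1, 1, 1, 1, 1, 10, 10, 10, 10, 10, 10) +
                        rnorm(12, 0, 1e-3))
  cmp <- compare_groups(d, "group")
  expect_lt(cmp$omnibus_p, 0.001)
  lt <- cmp$letters[[1]]
  expect_false(lt[["a"]] == lt[["b"]])
})

test_that("the normality gate routes by Shapiro-Wilk on every group", {
  # with the all-groups-must-pass gate at 0.05, three Gaussian groups route
  # parametric with probability 0.95^3 = 0.857; check the 99% binomial band
  gauss <- tibble::tibble(group = rep(c("a", "b", "c"), each = 10), y = 0)
  routes <- purrr::map_chr(1:100, function(i) {
    gauss$y <- withr::with_seed(i, rnorm(30))
    compare_groups(gauss, "group")$route
  })
  p0 <- 0.95^3
  half <- 2.58 * sqrt(p0 * (1 - p0) / 100)
  expect_gt(mean(routes == "parametric"), p0 - half)
  expect_lt(mean(routes == "parametric"), min(p0 + half, 1))

  skew <- purrr::map_chr(1:100, function(i) {
    gauss$y <- withr::with_seed(i, rlnorm(30, 0, 1.5))
    compare_groups(gauss, "group")$route
  })
  expect_gte(mean(skew == "nonparametric"), 0.9)
})

test_that("summaries match the route taken", {
  set.seed(3)
  d <- tibble::tibble(group = rep(c("a", "b"), each = 12),
                      norm = rnorm(24), skew = rlnorm(24, 0, 1.6))
  cmp <- compare_groups(d, "group")
  g <- glance(cmp)
  s_norm <- cmp$summaries[[which(cmp$variable == "norm")]]
  s_skew <- cmp$summaries[[which(cmp$variable == "skew")]]
  if (cmp$route[cmp$variable == "norm"] == "parametric") {
    expect_equal(unique(s_norm$location_label), "mean")
    expect_equal(s_norm$location[1], mean(d$norm[d$group == "a"]))
  }
  expect_equal(cmp$route[cmp$variable == "skew"], "nonparametric")
  expect_equal(unique(s_skew$location_label), "median")
  expect_equal(s_skew$location[1], median(d$skew[d$group == "a"]))
  expect_equal(nrow(tidy(cmp)), 2)  # one pair per variable
  expect_equal(g$n_groups, c(2L, 2L))
})

test_that("constant groups are flagged and force the nonparametric route", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                      y = c(rep(5, 5), rnorm(5, 1)))
  cmp <- compare_groups(d, "group")
  expect_equal(cmp$route, "nonparametric")
  expect_equal(cmp$degenerate_groups[[1]], "a")
  tiny <- tibble::tibble(group = c("a", "a", "a", "b", "b"), y = rnorm(5))
  expect_error(compare_groups(tiny, "group"), "fewer than 3")
})

test_that("dunn pairwise matches kruskal at two groups and handles ties", {
  set.seed(8)
  x <- c(rnorm(10), rnorm(10, 2))
  g <- rep(c("a", "b"), each = 10)
  dn <- cardiohep:::dunn_pairwise(x, g)
  kw <- kruskal.test(x, factor(g))
  # with k = 2 groups, Dunn's z^2 equals the KW chi-square statistic
  expect_equal(dn$p_value, 2 * pnorm(-sqrt(kw$statistic[[1]])),
               ignore_attr = TRUE, tolerance = 1e-12)
  xt <- c(1, 1, 1, 2, 2, 3, 3, 3, 4, 5)
  gt <- rep(c("a", "b"), each = 5)
  expect_true(is.finite(cardiohep:::dunn_pairwise(xt, gt)$p_value))
})

test_that("letter display encodes the significance pattern exactly", {
  mk <- function(v, g = c("A", "B", "C")) {
    m <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
    m[lower.tri(m)] <- v
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    m
  }
  # all pairs significant -> a, b, c
  m <- mk(c(0.01, 0.01, 0.01))
  expect_equal(unname(letter_display(m, 0.05)), c("a", "b", "c"))
  # none significant -> everyone shares "a"
  expect_equal(unname(letter_display(mk(c(0.5, 0.5, 0.5)), 0.05)),
               c("a", "a", "a"))
  # chain: A != C, A-B and B-C not -> a, ab, b
  chain <- mk(c(0.2, 0.01, 0.3))  # order: (B,A), (C,A), (C,B)
  lt <- letter_display(chain, 0.05)
  expect_equal(unname(lt), c("a", "ab", "b"))
  expect_true(letters_match_pattern(lt, chain, 0.05))
  expect_error(letter_display(mk(c(0.2, 0.01, 0.3)) * upper.tri(mk(c(1, 1, 1)),
                                                                diag = TRUE),
                              0.05), "symmetric")
})

test_that("letter display matches significance for random matrices", {
  for (s in 1:25) {
    k <- withr::with_seed(s, sample(3:6, 1))
    g <- paste0("g", seq_len(k))
    m <- matrix(NA_real_, k, k, dimnames = list(g, g))
    v <- withr::with_seed(s + 100, runif(k * (k - 1) / 2))
    m[lower.tri(m)] <- v
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    lt <- letter_display(m, 0.3)
    expect_true(letters_match_pattern(lt, m, 0.3),
                info = sprintf("seed %d", s))
  }
})

test_that("lowering alpha never increases the number of distinctions", {
  set.seed(14)
  d <- tibble::tibble(group = rep(paste0("g", 1:4), each = 8),
                      y = rnorm(32, rep(c(0, 0.5, 1, 2), each = 8)))
  n_sig <- vapply(c(0.1, 0.05, 0.01, 0.001), function(a) {
    glance(compare_groups(d, "group", alpha = a))$n_significant_pairs
  }, integer(1))
  expect_true(all(diff(n_sig) <= 0))
})
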