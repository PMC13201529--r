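test_that("ROI aggregation averages in-mask voxels and bilateral pairs", {
  maps <- list(f_f = array(0.5, c(4, 4, 1)))
  m_all <- array(TRUE, c(4, 4, 1))
  rows <- aggregate_roi(maps, list(blob = m_all), metrics = "f_f")
  expect_equal(rows$value, 0.5)

  left <- array(FALSE, c(4, 4, 1)); left[1:2, , ] <- TRUE
  right <- !left
  maps$f_f[left] <- 10
  maps$f_f[right] <- 20
  rows <- aggregate_roi(maps, list(hippocampus = list(left, right)),
                        metrics = "f_f")
  expect_equal(rows$value, 15)

  # empty mask: region skipped
  none <- array(FALSE, c(4, 4, 1))
  rows <- aggregate_roi(maps, list(sn = none, ok = m_all), metrics = "f_f")
  expect_equal(rows$region, "ok")
})

test_that("spearman_ci matches the closed form and cor.test", {
  r <- spearman_ci(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)               # 1 - 6*4/(5*24)
  expect_equal(r$rho,
               unname(cor.test(1:5, c(2, 1, 4, 3, 5),
                               method = "spearman")$estimate))
  expect_true(r$ci95[1] <= r$rho && r$rho <= r$ci95[2])

  expect_equal(spearman_ci(1:10, (1:10)^3)$rho, 1)  # monotone => 1
  set.seed(1)
  x <- rnorm(30); y <- x + rnorm(30)
  a <- spearman_ci(x, y)
  b <- cor.test(x, y, method = "spearman")
  expect_equal(a$rho, unname(b$estimate))
  # Fisher-z CI reproduces the reported convention at n = 43
  expect_equal(spearman_ci(seq_len(43),
                           qnorm(seq_len(43) / 44))$rho, 1)
  expect_error(spearman_ci(1:3, 1:3), "at least 4")
  expect_warning(spearman_ci(rep(1, 10), rnorm(10)), "constant")
})

test_that("spearman_ci is invariant under strictly monotone transforms", {
  set.seed(2)
  x <- runif(25, 20, 90)
  y <- 0.05 * x + rnorm(25)
  base <- spearman_ci(x, y)$rho
  expect_equal(spearman_ci(exp(x / 30), y)$rho, base)
  expect_equal(spearman_ci(x, y^3)$rho, spearman_ci(x, y)$rho)
  expect_equal(spearman_ci(rank(x), y)$rho, base)
})

test_that("group comparison gates on normality and matches the exact U test", {
  # identical groups: no significance
  set.seed(3)
  g <- rnorm(12)
  r <- group_compare(c(g, g), rep(c("a", "b"), each = 12))
  expect_gt(r$p, 0.9)
  expect_false(r$significant)

  # disjoint 5 vs 5: exact Mann-Whitney p from full enumeration
  vals <- c(1:5, 6:10)
  grp <- rep(c("lo", "hi"), each = 5)
  res <- group_compare(vals, grp, test = "mann-whitney")
  expect_equal(res$test_used, "mann-whitney")
  # enumeration oracle: distribution of the rank sum over all 10C5 splits
  splits <- combn(10, 5)
  w <- apply(splits, 2, function(i) sum(rank(vals)[i]))
  obs <- sum(rank(vals)[1:5])
  p_exact <- 2 * mean(w <= obs)
  expect_equal(res$p, p_exact)           # 0.0079365
  expect_equal(res$p, 2 / choose(10, 5) * 1)

  # normal groups use the t test with mean (SD) summaries
  set.seed(4)
  a <- rnorm(15, 0); b <- rnorm(15, 2)
  rt <- group_compare(c(a, b), rep(c("a", "b"), each = 15))
  expect_equal(rt$test_used, "t")
  expect_match(rt$group_summaries$a$label, "^-?\\d+\\.\\d+ \\(")

  # heavy-tailed data routes to Mann-Whitney
  set.seed(5)
  c1 <- rcauchy(20); c2 <- rcauchy(20, 1)
  rmw <- group_compare(c(c1, c2), rep(c("a", "b"), each = 20))
  expect_equal(rmw$test_used, "mann-whitney")

  # tiny group: gate skipped with a warning
  expect_warning(group_compare(c(1, 2, 8, 9, 10, 11), c("a", "a", "b",
                                                        "b", "b", "b")),
                 "size")
})

test_that("group comparison is invariant to label order", {
  set.seed(6)
  v <- c(rnorm(10), rnorm(12, 1))
  g1 <- rep(c("young", "old"), c(10, 12))
  r1 <- group_compare(v, g1)
  r2 <- group_compare(v, factor(g1, levels = c("young", "old")))
  expect_equal(r1$p, r2$p)
  expect_equal(r1$estimate, -r2$estimate)
})

test_that("build_report reproduces injected trend signs end to end", {
  co <- simulate_cohort(cohort_spec(seed = 11))
  rep <- build_report(co)
  cors <- rep$correlations
  ffs <- cors[cors$metric == "f_f_pct", ]
  expect_true(all(ffs$rho > 0))
  expect_true(ffs$rho[ffs$region == "wm"] > 0 &&
                ffs$p[ffs$region == "wm"] < 0.05)
  # restricted-pool T2 cells are mostly null
  t2r <- cors[cors$metric == "t2r_us", ]
  expect_lt(mean(t2r$significant), 0.5)
  # comparisons carry the summary convention labels
  expect_true(all(grepl("\\(", rep$comparisons$younger)))
  # empty metric column warns and is omitted
  co2 <- co
  co2$value[co2$metric == "t2r_us"] <- NA
  w <- testthat::capture_warnings(rep2 <- build_report(co2))
  expect_true(any(grepl("omitted", w)))
  expect_false("t2r_us" %in% rep2$correlations$metric)
})

test_that("detection metrics format into rate cells", {
  co <- data.frame(subject_id = sprintf("S%02d", 1:43),
                   age = seq(23, 86, length.out = 43),
                   group = NA, region = "cortical_gm",
                   metric = "detected_hydroxyl",
                   value = c(rep(1, 41), 0, 0))
  rep <- build_report(co)
  expect_equal(rep$detection$label, "95.3% (41/43)")
})
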