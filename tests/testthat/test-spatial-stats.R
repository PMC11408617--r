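test_that("nearest distances: coincident cells, Pythagoras, calibration", {
  cells <- make_cells(c(0, 0, 3), c(0, 0, 4), c("Q", "T", "T"))
  dt <- nearest_type_distance(cells, query = "Q", target_types = "T")
  expect_equal(dt$distance_px, 0)   # coincident distinct cells
  expect_equal(dt$distance_um, 0)

  cells <- make_cells(c(0, 3), c(0, 4), c("Q", "T"))
  dt <- nearest_type_distance(cells, query = "Q", target_types = "T",
                              px_per_um = 2.65)
  expect_equal(dt$distance_px, 5)
  expect_equal(dt$distance_um, 5 / 2.65)
  expect_equal(dt$distance_um * 2.65, dt$distance_px)  # exact single division
  expect_error(nearest_type_distance(cells, "Q", "T", px_per_um = 0),
               "px_per_um")
})

test_that("self is excluded when the query is its own target type", {
  cells <- make_cells(c(0, 10), c(0, 0), c("T", "T"))
  dt <- nearest_type_distance(cells, query = "T", target_types = "T")
  expect_equal(dt$distance_px, c(10, 10))
})

test_that("distance table matches the brute-force oracle", {
  cells <- random_cells(300, types = c("A", "B", "C"), seed = 13)
  dt <- nearest_type_distance(cells, query = "A", target_types = c("B", "C"))
  qrows <- which(cells$cell_type == "A")
  for (tt in c("B", "C")) {
    got <- dt$distance_px[dt$target_type == tt]
    expect_equal(got, nearest_oracle(cells, qrows, tt), tolerance = 1e-12)
  }
})

test_that("distances are invariant to rigid transforms", {
  cells <- random_cells(150, types = c("A", "B"), seed = 5)
  th <- 1.2
  moved <- make_cells(cos(th) * cells$x_px - sin(th) * cells$y_px + 2000,
                      sin(th) * cells$x_px + cos(th) * cells$y_px + 2000,
                      cells$cell_type)
  d1 <- nearest_type_distance(cells, "A", "B")
  d2 <- nearest_type_distance(moved, "A", "B")
  expect_equal(d1$distance_px, d2$distance_px, tolerance = 1e-9)
})

test_that("missing targets warn and yield NA, not an error", {
  cells <- make_cells(c(0, 1), c(0, 0), c("A", "B"))
  expect_warning(dt <- nearest_type_distance(cells, "A", c("B", "Z")),
                 "no cells of target type")
  expect_true(is.na(dt$distance_px[dt$target_type == "Z"]))
})

test_that("distance summaries pool correctly", {
  cells <- make_cells(c(0, 1, 2, 3, 50), c(0, 0, 0, 0, 0),
                      c("Q", "Q", "Q", "T", "T"))
  dt <- nearest_type_distance(cells, "Q", "T", px_per_um = 1)
  sm <- summarize_distances(dt, bins = 5)
  expect_equal(sm$summary$mean_um, mean(c(3, 2, 1)))
  expect_equal(sm$summary$median_um, 2)
  expect_equal(sum(sm$density$count), 3)

  one <- summarize_distances(dt[1, , drop = FALSE], bins = 3)
  expect_equal(one$summary$mean_um, one$summary$median_um)
})

test_that("community type proportions are percentages summing to 100", {
  vocab <- type_vocabulary(c("A", "B", "C"))
  cells <- make_cells(1:7, 1:7, c("A", "A", "B", "C", "A", "A", "A"),
                      vocab = vocab)
  lab <- c(1, 1, 1, 1, 2, 2, 2)
  cp <- community_type_proportions(lab, cells, focus_types = c("A", "B"))
  c1 <- cp[cp$community == 1, ]
  expect_equal(c1$percent[c1$cell_type == "A"], 50)
  expect_equal(c1$percent[c1$cell_type == "B"], 25)
  # no focus members -> 0
  c2 <- cp[cp$community == 2, ]
  expect_equal(c2$percent[c2$cell_type == "B"], 0)
  # full vocabulary sums to 100 per community
  full <- community_type_proportions(lab, cells)
  sums <- tapply(full$percent, full$community, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-6)
})

test_that("Kruskal-Wallis: identical groups, closed form, tie correction", {
  same <- kruskal_wallis(list(1:3, 1:3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  # tie-corrected H agrees with the reference implementation
  set.seed(2)
  g <- list(sample(1:4, 12, TRUE), sample(2:6, 9, TRUE), sample(1:5, 15, TRUE))
  ref <- stats::kruskal.test(unlist(g), rep(1:3, lengths(g)))
  got <- kruskal_wallis(g)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, unname(ref$p.value))

  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(9)
  g <- list(rnorm(8), rnorm(10, 1), rnorm(6, 2))
  h0 <- kruskal_wallis(g)$statistic
  expect_equal(kruskal_wallis(lapply(g, exp))$statistic, h0)
  expect_equal(kruskal_wallis(lapply(g, function(v) v^3 + 5))$statistic, h0)
})

test_that("chi-squared p agrees with a permutation oracle on small inputs", {
  set.seed(31)
  g <- list(c(1.2, 3.4, 2.2, 5.0), c(2.9, 6.1, 4.4), c(7.3, 8.0, 6.6, 9.1))
  obs <- kruskal_wallis(g)$statistic
  pooled <- unlist(g)
  grp <- rep(seq_along(g), lengths(g))
  perm <- replicate(1e4, {
    kruskal_wallis(split(sample(pooled), grp))$statistic
  })
  p_perm <- mean(perm >= obs - 1e-12)
  p_chi <- kruskal_wallis(g)$p_value
  # Monte-Carlo error ~ sqrt(p(1-p)/1e4) ~ 0.002; chi2 approx error dominates
  expect_lt(abs(p_perm - p_chi), 0.02)
})
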