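test_that("log normalization: arithmetic, scale invariance, zero spots", {
  m <- rbind(s1 = c(1, 0, 0), s2 = c(2, 2, 2))
  colnames(m) <- c("g1", "g2", "g3")
  norm <- normalize_log(m, scale_total = 10)
  expect_equal(unname(norm["s1", ]), c(log(11), 0, 0))
  # all-equal rows normalize identically
  expect_equal(unname(norm["s2", ]), rep(log(1 + 10 / 3), 3))
  # doubling a spot's counts changes nothing
  expect_equal(normalize_log(2 * m, 10), norm, ignore_attr = TRUE)

  mz <- rbind(a = c(0, 0), b = c(1, 1)); colnames(mz) <- c("g1", "g2")
  expect_warning(nz <- normalize_log(mz), "zero total")
  expect_equal(unname(nz["a", ]), c(0, 0))
})

test_that("module score: constant matrix and degenerate closed form", {
  genes <- sprintf("g%02d", 1:40)
  const <- matrix(3, 10, 40, dimnames = list(paste0("s", 1:10), genes))
  suppressWarnings(  # 35 eligible controls < default n_ctrl: warns by contract
    expect_equal(unname(module_score(const, genes[1:5], seed = 1)), rep(0, 10),
                 ignore_attr = TRUE))

  set.seed(5)
  expr <- matrix(rnorm(10 * 40), 10, 40,
                 dimnames = list(paste0("s", 1:10), genes))
  sig <- genes[c(3, 11, 25)]
  got <- module_score(expr, sig, n_bins = 1, n_ctrl = 37, seed = 2)
  closed <- rowMeans(expr[, sig]) - rowMeans(expr[, setdiff(genes, sig)])
  expect_equal(unname(got), unname(closed), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("module score is reproducible and order-invariant", {
  set.seed(6)
  genes <- sprintf("g%02d", 1:50)
  expr <- matrix(rexp(20 * 50), 20, 50,
                 dimnames = list(paste0("s", 1:20), genes))
  sig <- c("g05", "g17", "g33")
  s1 <- module_score(expr, sig, n_bins = 5, n_ctrl = 8, seed = 11)
  s2 <- module_score(expr, sig, n_bins = 5, n_ctrl = 8, seed = 11)
  expect_identical(as.numeric(s1), as.numeric(s2))

  # permuting gene columns and spot rows leaves scores attached to spots
  gperm <- sample(50); sperm <- sample(20)
  s3 <- module_score(expr[sperm, gperm], sig, n_bins = 5, n_ctrl = 8, seed = 11)
  expect_equal(as.numeric(s3), as.numeric(s1[sperm]), tolerance = 1e-12)
})

test_that("missing signature genes are dropped; all-missing errors", {
  expr <- matrix(1:12, 3, 4, dimnames = list(NULL, paste0("g", 1:4)))
  expect_warning(module_score(expr, c("g1", "nope"), n_bins = 1, n_ctrl = 2,
                              seed = 1), "absent")
  expect_error(module_score(expr, c("nope1", "nope2"), seed = 1), "none")
})

test_that("planted uplift is recovered in the designated region", {
  regs <- bcc_preset_regions()
  for (seed in 1:3) {
    spec <- spot_gen_spec(delta = 2, n_genes = 120, n_signature = 16)
    sp <- generate_spots(spec, regs, seed = seed)
    expr <- normalize_log(sp)
    sc <- suppressWarnings(
      module_score(expr, spec$signature, n_bins = 12, n_ctrl = 10,
                   seed = seed))
    means <- tapply(sc, sp$cluster, mean)
    expect_equal(names(which.max(means)), "bit_band",
                 label = paste("seed", seed))
  }
})

test_that("high-score fractions follow the top-percentile definition", {
  # 20 distinct scores, one cluster: exactly 2 of 20 flagged
  sc <- seq_len(20)
  hf <- high_fraction_by_cluster(sc, rep("all", 20), top_pct = 10)
  expect_equal(hf$n_high, 2L)
  expect_equal(hf$percent_high, 10)

  # both top spots inside a 5-spot cluster -> 40% there, 0% elsewhere
  cl <- rep(c("small", "big"), c(5, 15))
  sc2 <- c(100, 99, 1, 2, 3, 4:18)
  hf2 <- high_fraction_by_cluster(sc2, cl, top_pct = 10)
  expect_equal(hf2$percent_high[hf2$cluster == "small"], 40)
  expect_equal(hf2$percent_high[hf2$cluster == "big"], 0)
  # conservation: sum over clusters of flagged counts = total flagged
  expect_equal(sum(hf2$n_high), sum(sc2 >= attr(hf2, "threshold")))

  # all scores tied: every spot passes, each cluster reports 100%
  hf3 <- high_fraction_by_cluster(rep(1, 12), rep(c("a", "b"), 6), 10)
  expect_equal(hf3$percent_high, c(100, 100))

  expect_error(high_fraction_by_cluster(1:3, 1:2), "cover")
})
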