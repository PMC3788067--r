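# Comparison statistics: regional totals, proportional fits, correlations,
# classification, sensitivity, backbone export.

test_that("regional counts sum densities per ROI with an outside ledger", {
  lab <- slab_labels()
  iface <- extract_interface(lab)
  roi <- array(0L, dim(lab)); roi[2:4, 2:4, 7:9] <- 1L; roi[8:10, 8:10, 7:9] <- 2L
  vals <- numeric(nrow(iface$voxels))
  in1 <- which(roi[cbind(iface$voxels[, 1], iface$voxels[, 2], iface$voxels[, 3])] == 1L)
  vals[in1] <- 2
  s <- surface_ddm(iface, vals, "bda_fiber")
  rc <- regional_counts(s, roi)
  expect_equal(unname(rc["1"]), 2 * length(in1))
  expect_equal(unname(rc["2"]), 0)
  expect_equal(attr(rc, "outside"), 0)
  s0 <- surface_ddm(iface, rep(0, nrow(iface$voxels)), "bda_fiber")
  expect_true(all(regional_counts(s0, roi) == 0))
})

test_that("proportional fit selects the through-origin model when warranted", {
  nb <- c(2000, 750, 300, 120, 50, 20, 8, 3)
  # exact proportional data: lm warns about the perfect fit, which is the point
  f <- suppressWarnings(fit_proportional(nb, 3 * nb))
  expect_equal(f$model_used, 2L)
  expect_equal(f$b, 3, tolerance = 1e-10)
  expect_equal(f$a, 0)
  expect_equal(f$r, 1, tolerance = 1e-12)

  set.seed(1)
  f2 <- fit_proportional(nb, 100 + 0 * nb + rnorm(8, 0, 0.01))
  expect_equal(f2$model_used, 1L)
  expect_false(f2$ci_a[1] <= 0 && f2$ci_a[2] >= 0)

  expect_error(fit_proportional(rep(5, 4), 1:4), "zero variance")
  expect_error(fit_proportional(1:2, 1:2), ">= 3")
})

test_that("intercept CI covers zero about 95% of the time under a true origin model", {
  set.seed(99)
  hits <- 0L; n_rep <- 400
  nb <- c(2000, 750, 300, 120, 50, 20, 8, 3)
  for (i in seq_len(n_rep)) {
    nd <- 2 * nb + rnorm(8, 0, 20)
    f <- fit_proportional(nb, nd)
    if (f$model_used == 2L) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.91)
  expect_lt(hits / n_rep, 0.99)
})

test_that("correlations match definitional oracles and flag degeneracy", {
  set.seed(5)
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(correlate(x, y, "pearson")$estimate, pearson_oracle(x, y),
                 tolerance = 1e-12)
    expect_equal(correlate(x, y, "spearman")$estimate, spearman_oracle(x, y),
                 tolerance = 1e-12)
  }
  # ties: average ranks
  x <- c(1, 2, 2, 3, 5); y <- c(2, 1, 4, 4, 7)
  expect_equal(correlate(x, y, "spearman")$estimate, spearman_oracle(x, y),
               tolerance = 1e-12)
  # monotone nonlinear transform: spearman 1, pearson < 1
  x <- c(1, 2, 4, 9, 16, 30)
  y <- exp(x / 10)
  expect_equal(correlate(x, y, "spearman")$estimate, 1)
  expect_lt(correlate(x, y, "pearson")$estimate, 1)
  # affine map: pearson exactly 1
  expect_equal(correlate(x, 2 * x + 1, "pearson")$estimate, 1, tolerance = 1e-12)
  # degenerate input
  z <- correlate(rep(1, 5), 1:5)
  expect_false(z$defined); expect_true(is.na(z$estimate)); expect_equal(z$p, 1)
  # permutation p-value agrees in direction with the t approximation
  set.seed(8)
  x <- rnorm(7); y <- x + rnorm(7, 0, 0.3)
  pt <- correlate(x, y, "pearson")$p
  pp <- correlate(x, y, "pearson", p_method = "permutation")$p
  expect_lt(pp, 0.05)
  expect_lt(pt, 0.05)
})

test_that("top-k Spearman restricts to the strongest connections", {
  nb <- c(2000, 750, 300, 120, 50, 20, 8, 3)
  nd <- c(96, 64, 33, 10, 57, 3, 15, 16)
  expect_error(topk_spearman(rep(1, 8), rep(1, 8), "threshold", 100), "fewer than 3")
  t1 <- topk_spearman(nb, nd, "threshold", 100)
  expect_equal(t1$k_used, 4L)
  expect_equal(sort(t1$selected), 1:4)
  t2 <- topk_spearman(nb, nd, "k_largest", k = 5)
  expect_equal(t2$k_used, 5L)
  # rank-concordant subset gives exactly 1
  t3 <- topk_spearman(nb, 0.1 * nb, "threshold", 100)
  expect_equal(t3$estimate, 1)
  # noise confined to the small-N_B ROIs: top-k beats the global rank measure
  nd2 <- nb; nd2[5:8] <- c(1, 90, 2, 60)
  full <- correlate(nb, nd2, "spearman")$estimate
  topk <- topk_spearman(nb, nd2, "threshold", 100)$estimate
  expect_gt(topk, full)
})

test_that("voxelwise Pearson follows the definitional formula", {
  set.seed(6)
  B <- rpois(40, 5); D <- rpois(40, 7)
  v <- voxelwise_pearson(B, D)
  expect_equal(v$r_p, pearson_oracle(B, D), tolerance = 1e-12)
  expect_equal(v$n, 40)
  # proportional densities give exactly 1
  expect_equal(voxelwise_pearson(B, 3 * B)$r_p, 1, tolerance = 1e-12)
  # constant D: undefined, sentinel p = 1
  vv <- voxelwise_pearson(B, rep(2, 40))
  expect_false(vv$defined); expect_equal(vv$p, 1)
})

test_that("false positive/negative classification and sensitivity", {
  tb <- data.frame(roi = 1:4, N_B = c(50, 0, 10, 0), N_D = c(0, 12, 5, 0))
  fp <- classify_fp_fn(tb)
  expect_equal(fp$false_negative, 1)
  expect_equal(fp$false_positive, 2)

  dims <- c(8L, 8L, 16L)
  tf <- uniform_field(dims, dir = c(0, 0, 1))
  roi <- array(0L, dims); roi[4, 4, 12:14] <- 1L; roi[6, 6, 12:14] <- 2L
  ss <- fact_track(tf, rbind(c(4L, 4L, 4L), c(6L, 6L, 4L)))
  s_all <- streamline_sensitivity(ss, c(1, 2), roi)
  expect_equal(s_all$sensitivity, 1)
  s_half <- streamline_sensitivity(ss, 1, roi)   # the (6,6) line hits a spurious ROI
  expect_equal(s_half$sensitivity, 0.5)
  s_none <- streamline_sensitivity(ss, 1, array(0L, dims))
  expect_true(is.na(s_none$sensitivity))
})

test_that("backbone export encodes strength and weight conventions", {
  tb <- data.frame(roi = 1:3, strength = c(100, 100, 0))
  vols <- stats::setNames(c(10, 20, 10), c("1", "2", "3"))
  g <- export_backbone(tb, vols, injection_volume = 40)
  expect_equal(igraph::ecount(g), 2)          # zero-strength edge omitted
  ea <- igraph::edge_attr(g)
  # equal strength, volumes V and 2V: connection weights in ratio 2:1
  expect_equal(ea$connection_weight[1] / ea$connection_weight[2], 2)
  expect_equal(ea$weight, rep(log10(101), 2))
  expect_equal(igraph::vertex_attr(g, "size")[1], sqrt(40))
  g1 <- export_backbone(data.frame(roi = 1:3, strength = c(5, 0, 0)), vols)
  expect_equal(igraph::ecount(g1), 1)
})

test_that("one-way ANOVA across seed depths runs on grouped correlations", {
  set.seed(3)
  r_p <- c(rnorm(8, 0.3, 0.05), rnorm(8, 0.31, 0.05), rnorm(8, 0.29, 0.05))
  av <- anova_seed_depth(r_p, rep(c(0, 0.3, 0.6), each = 8))
  expect_true(is.finite(av$F))
  expect_gt(av$p, 0.05)
})
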