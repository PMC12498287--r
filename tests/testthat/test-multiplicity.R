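test_that("connected-component labelling counts painted blobs", {
  g <- tiny_grid(c(10, 10, 10))
  m <- paint_mask(g, 1:5, 1, 1)            # 5-voxel line
  m[8:10, 5, 5] <- TRUE                    # separated 3-voxel line
  lab <- label_components(m, connectivity = 18)
  expect_equal(lab$n, 2L)
  expect_equal(sort(lab$sizes), c(3L, 5L))
  # empty mask -> nothing
  lab0 <- label_components(array(FALSE, g$shape), 18)
  expect_equal(lab0$n, 0L)
})

test_that("diagonal adjacency depends on the connectivity order", {
  g <- tiny_grid(c(5, 5, 5))
  m <- array(FALSE, g$shape)
  m[2, 2, 2] <- TRUE
  m[3, 3, 2] <- TRUE   # in-plane diagonal: shares an edge
  expect_equal(label_components(m, 6)$n, 2L)
  expect_equal(label_components(m, 18)$n, 1L)
  m2 <- array(FALSE, g$shape)
  m2[2, 2, 2] <- TRUE
  m2[3, 3, 3] <- TRUE  # 3D corner: shares only a vertex
  expect_equal(label_components(m2, 18)$n, 2L)
  expect_equal(label_components(m2, 26)$n, 1L)
  expect_error(label_components(m2, 10), "connectivity")
})

test_that("labelling is invariant to voxel visitation order", {
  set.seed(3)
  g <- tiny_grid(c(8, 8, 8))
  m <- array(runif(prod(g$shape)) < 0.25, g$shape)
  lab <- label_components(m, 18)
  # relabel after permuting the array along each axis and inverting:
  # component structure (multiset of sizes) must be identical
  perm <- m[8:1, , ]
  lab2 <- label_components(perm, 18)
  expect_equal(sort(lab$sizes), sort(lab2$sizes))
})

test_that("thresholding an all-zero t-map yields an empty cluster table", {
  p <- sim_fit_pieces(null_design(n_cs = 5, n_nc = 7, n_scanners = 1), seed = 41)
  fit <- fit_scn(p$sim$stack, p$design, mask = p$mask)
  fit$t[] <- 0
  cl <- threshold_and_label(fit)
  expect_equal(nrow(cl), 0L)
})

test_that("cluster tables report extents and peaks of painted signals", {
  p <- sim_fit_pieces(null_design(n_cs = 20, n_nc = 20, n_scanners = 1), seed = 43)
  fit <- fit_scn(p$sim$stack, p$design, mask = p$mask)
  fit$t[] <- 0
  vox_all <- which(fit$mask)
  # paint two suprathreshold islands in t: 5 and 3 voxels, well separated
  g <- p$sim$stack$grid
  isl1 <- ijk_box(g, 1:5, 1, 1)
  isl2 <- ijk_box(g, 14:16, 14, 14)
  fit$t[match(isl1, vox_all)] <- c(5, 9, 5, 5, 5)
  fit$t[match(isl2, vox_all)] <- 6
  cl <- threshold_and_label(fit, p_voxel = 0.001)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$extent, c(5L, 3L))
  expect_equal(cl$peak_t[1], 9)
  # peak voxel reported 0-based: (2,1,1) 1-based -> (1,0,0)
  expect_equal(unlist(cl[1, c("peak_i", "peak_j", "peak_k")], use.names = FALSE),
    c(1L, 0L, 0L)
  )
  # the label image matches the table
  lim <- cluster_label_image(cl)
  expect_equal(sum(lim == cl$cluster_id[1]), 5L)
})

test_that("BH adjustment matches the hand-worked example and edge cases", {
  res <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.2))
  expect_equal(res$p_adjusted, c(0.05, 0.05, 0.05, 0.05, 0.2))
  expect_true(all(fdr_bh(rep(1, 4))$rejected == FALSE))
  expect_equal(fdr_bh(0.037)$p_adjusted, 0.037)
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("BH rejection set equals the brute-force step-up rule", {
  brute_bh <- function(p, q) {
    # largest k with p_(k) <= k q / m; reject the k smallest
    m <- length(p)
    o <- order(p)
    ks <- which(p[o] <= seq_len(m) * q / m)
    rej <- rep(FALSE, m)
    if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
    rej
  }
  set.seed(7)
  for (r in 1:50) {
    n <- sample(1:10, 1)
    p <- round(runif(n), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_equal(fdr_bh(p, q = q)$rejected, brute_bh(p, q))
  }
})

test_that("Bonferroni adjustment scales, clips, and validates the family", {
  expect_equal(bonferroni(0.01, 4), 0.04)
  expect_equal(bonferroni(0.5, 10), 1.0)
  p <- runif(6)
  expect_true(all(bonferroni(p) >= p))
  expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
  expect_error(bonferroni(0.1, 0), ">= 1")
})

test_that("permutation FWE honours its estimator identity and lower bound", {
  p <- sim_fit_pieces(effect_design(), seed = 47)
  B <- 120
  cl <- cluster_fwe_permutation(
    p$sim$stack, p$design, mask = p$mask, B = B, seed = 9
  )
  expect_gte(nrow(cl), 1L)
  nullmax <- attr(cl, "null_max_extent")
  expect_length(nullmax, B)
  # p_fwe is exactly (1 + #{permuted max >= extent}) / (B + 1) ...
  expect_equal(
    cl$p_fwe,
    vapply(cl$extent, function(k) (1 + sum(nullmax >= k)) / (B + 1), numeric(1))
  )
  # ... so p can never reach 0, and a cluster beating every permuted
  # maximum sits exactly at the lower bound
  expect_true(all(cl$p_fwe >= 1 / (B + 1) & cl$p_fwe <= 1))
  expect_gt(max(cl$extent), max(nullmax))  # the planted cluster dominates
  expect_equal(min(cl$p_fwe), 1 / (B + 1))
})

test_that("permutation p-values are reproducible for a fixed seed", {
  p <- sim_fit_pieces(effect_design(), seed = 53)
  a <- cluster_fwe_permutation(p$sim$stack, p$design, mask = p$mask, B = 100, seed = 2)
  b <- cluster_fwe_permutation(p$sim$stack, p$design, mask = p$mask, B = 100, seed = 2)
  expect_equal(a$p_fwe, b$p_fwe)
  expect_identical(attr(a, "null_max_extent"), attr(b, "null_max_extent"))
})

test_that("too few permutations for the requested alpha warns", {
  p <- sim_fit_pieces(effect_design(n_cs = 8, n_nc = 10, n_scanners = 1), seed = 59)
  expect_warning(
    cluster_fwe_permutation(
      p$sim$stack, p$design, mask = p$mask, B = 100, seed = 1, alpha = 0.001
    ),
    "cannot reach"
  )
  expect_error(
    cluster_fwe_permutation(p$sim$stack, p$design, mask = p$mask, B = 50),
    "100"
  )
})
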