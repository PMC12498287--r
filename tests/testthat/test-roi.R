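test_that("binarize_significant keeps exactly the FWE-surviving clusters", {
  p <- sim_fit_pieces(effect_design(noise_sd = 0.3), seed = 61)
  cl <- cluster_fwe_permutation(p$sim$stack, p$design, mask = p$mask, B = 120, seed = 3)
  sig <- binarize_significant(cl, alpha_fwe = 0.05)
  keep <- cl$cluster_id[cl$p_fwe < 0.05]
  lim <- attr(cl, "labels")
  expect_equal(sum(sig), sum(lim %in% keep & lim > 0))
  # alpha = 1 keeps every suprathreshold voxel
  expect_equal(sum(binarize_significant(cl, 1)), sum(lim > 0))
  # no significant clusters -> empty mask
  expect_equal(sum(binarize_significant(cl, 1 / (attr(cl, "B") + 2))), 0)
  # clusters without p_fwe are refused
  raw <- threshold_and_label(attr(cl, "fit"))
  expect_error(binarize_significant(raw), "p_fwe")
})

test_that("union mask is a voxelwise OR with grid checks", {
  g <- tiny_grid()
  a <- paint_mask(g, 1:2, 1:5, 1)   # 10
  b <- paint_mask(g, 5, 1:5, 2)     # 5, disjoint
  expect_equal(sum(union_mask(list(a, b))), 15)
  expect_equal(union_mask(list(a, a)), as.vector(a))
  expect_error(union_mask(list()), "at least one")
  expect_error(union_mask(list(a, paint_mask(tiny_grid(c(4, 4, 4)), 1, 1, 1))), "length")
})

test_that("overlap selection uses the region size and a strict 10% rule", {
  g <- tiny_grid(c(10, 10, 10))
  lab <- array(0L, g$shape)
  lab[1:4, 1:10, 1] <- 1L    # region 1: 40 voxels
  lab[6:9, 1:10, 1] <- 2L    # region 2: 40 voxels
  at <- atlas_image(lab, g)
  u <- array(FALSE, g$shape)
  u[1:4, 1, 1] <- TRUE            # 4 voxels in region 1 (ratio exactly 0.10)
  u[6:9, 1, 1] <- TRUE
  u[6, 2, 1] <- TRUE              # 5 voxels in region 2 (0.125)
  rep <- select_rois(u, at, threshold = 0.10)
  expect_equal(rep$overlap_ratio, c(0.10, 0.125))
  expect_equal(rep$selected, c(FALSE, TRUE))   # strictly greater than
  # full coverage gives ratio 1
  u2 <- lab == 1L
  rep2 <- select_rois(u2, at)
  expect_equal(rep2$overlap_ratio[rep2$region_id == 1], 1.0)
})

test_that("ROI mean extraction equals a voxel-by-voxel reference loop", {
  p <- sim_fit_pieces(effect_design(n_cs = 5, n_nc = 7, n_scanners = 1), seed = 67)
  st <- p$sim$stack
  g <- st$grid
  rois <- list(
    roiA = paint_mask(g, 2:3, 2:3, 2),
    roiB = paint_mask(g, 14:16, 2:3, 12:13)
  )
  means <- extract_mean_gmv(st, rois, mask = p$mask)
  for (nm in names(rois)) {
    vox <- which(as.vector(rois[[nm]]) & st$mask & p$mask)
    ref <- vapply(seq_len(nrow(st$data)), function(i) {
      acc <- 0
      for (v in vox) acc <- acc + st$data[i, v]
      acc / length(vox)
    }, numeric(1))
    expect_equal(means[[nm]], ref, tolerance = 1e-12)
  }
  # constant image -> constant means
  st2 <- st
  st2$data[] <- 4.25
  st2$mask <- rep(TRUE, length(st2$mask))
  m2 <- extract_mean_gmv(st2, rois)
  expect_true(all(m2$roiA == 4.25 & m2$roiB == 4.25))
  # 2-voxel ROI with values 1 and 3 -> 2.0
  st3 <- st2
  vox2 <- ijk_box(g, 1:2, 1, 1)
  st3$data[1, vox2] <- c(1, 3)
  m3 <- extract_mean_gmv(st3, list(r = paint_mask(g, 1:2, 1, 1)))
  expect_equal(m3$r[1], 2.0)
})

test_that("ROIs emptied by the exclusion mask are dropped with a warning", {
  p <- sim_fit_pieces(effect_design(n_cs = 5, n_nc = 7, n_scanners = 1), seed = 71)
  g <- p$sim$stack$grid
  lesioned <- which(!p$mask)[1]
  ijk <- arrayInd(lesioned, g$shape)
  dead <- paint_mask(g, ijk[1], ijk[2], ijk[3])
  alive <- paint_mask(g, 1, 1, 1)
  expect_warning(
    means <- extract_mean_gmv(p$sim$stack, list(dead = dead, ok = alive), mask = p$mask),
    "dropped"
  )
  expect_equal(setdiff(names(means), "subject_id"), "ok")
})

test_that("post-hoc ROI GLM recovers the planted contrast direction", {
  hits <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    p <- sim_fit_pieces(effect_design(), seed = 700 + s)
    blob <- p$sim$truth$effects[[1]]$voxels
    roi <- rep(FALSE, prod(p$sim$stack$grid$shape))
    roi[blob] <- TRUE
    means <- extract_mean_gmv(p$sim$stack, list(blob_roi = roi), mask = p$mask)
    ph <- posthoc_roi_glm(p$sim$cohort, means, list(VPL_ipsi = p$seedvol))
    if (ph$estimate[1] > 0) hits <- hits + 1L  # planted slope_cs > slope_nc
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("a single (seed, ROI) test leaves Bonferroni p equal to raw p", {
  p <- sim_fit_pieces(effect_design(n_cs = 6, n_nc = 8, n_scanners = 1), seed = 73)
  roi <- paint_mask(p$sim$stack$grid, 3:4, 3:4, 3)
  means <- extract_mean_gmv(p$sim$stack, list(one = roi), mask = p$mask)
  ph <- posthoc_roi_glm(p$sim$cohort, means, p$seedvol)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$p_bonf, ph$p_value)
})

test_that("end-to-end chain selects the atlas region holding the planted blob", {
  hits <- 0L
  n_seeds <- 8
  for (s in seq_len(n_seeds)) {
    p <- sim_fit_pieces(effect_design(), seed = 800 + s)
    cl <- cluster_fwe_permutation(
      p$sim$stack, p$design, mask = p$mask, B = 200, seed = s
    )
    sig <- binarize_significant(cl)
    u <- union_mask(list(sig))
    rep <- select_rois(u, p$sim$atlas)
    blob <- p$sim$truth$effects[[1]]$voxels
    truth_region <- p$sim$atlas$labels[blob[ceiling(length(blob) / 2)]]
    sel_ids <- rep$region_id[rep$selected]
    if (truth_region %in% sel_ids) {
      rm_ <- roi_masks(rep, p$sim$atlas)
      means <- extract_mean_gmv(p$sim$stack, rm_, mask = p$mask)
      ph <- posthoc_roi_glm(p$sim$cohort, means, list(VPL_ipsi = p$seedvol))
      tr_name <- rep$region_name[rep$region_id == truth_region]
      if (ph$estimate[ph$roi == tr_name] > 0) hits <- hits + 1L
    }
  }
  expect_gte(hits / n_seeds, 0.9)
})
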