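test_that("zscore standardizes with the sample-sd convention", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscore(rnorm(20, 5, 3))
  expect_equal(zscore(z), z, tolerance = 1e-12)  # idempotent
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zscore(rep(2, 5)), "constant")
})

test_that("design matrix has the documented column structure", {
  co <- toy_cohort(n_cs = 4, n_nc = 6, n_scanners = 3)
  sv <- rnorm(10, 800, 60)
  des <- build_scn_design(co, sv)
  # 2 labels + 2 seed columns + age + gender + 2 scanner dummies + tiv
  expect_equal(ncol(des$X), 9L)
  expect_true(all(des$X[, "label_cs"] + des$X[, "label_nc"] == 1))
  # group-specific seed columns are zero in the other group
  cs <- co$group == "CS"
  expect_true(all(des$X[!cs, "seedvol_cs"] == 0))
  expect_true(all(des$X[cs, "seedvol_nc"] == 0))
  # pooled z-scoring: the combined column is the pooled z-score
  expect_equal(
    des$X[, "seedvol_cs"] + des$X[, "seedvol_nc"], zscore(sv),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  expect_equal(unname(des$contrast[c("seedvol_cs", "seedvol_nc")]), c(1, -1))
})

test_that("degenerate designs are rejected with named columns", {
  co <- toy_cohort()
  co$group <- factor(rep("CS", nrow(co)), levels = c("CS", "NC"))
  expect_error(build_scn_design(co, rnorm(nrow(co))), "non-empty")
  co2 <- toy_cohort()
  co2$tiv <- 1.4e6  # constant -> collinear with the two intercept columns
  expect_error(build_scn_design(co2, rnorm(nrow(co2))), "rank deficient")
})

test_that("mass-univariate fit matches single-voxel reference OLS to 1e-8", {
  p <- sim_fit_pieces(effect_design(), seed = 17)
  fit <- fit_scn(p$sim$stack, p$design, mask = p$mask)
  set.seed(99)
  vox_cols <- sort(sample(sum(fit$mask), 20))
  vox <- which(fit$mask)[vox_cols]
  X <- p$design$X
  for (m in seq_along(vox)) {
    y <- p$sim$stack$data[, vox[m]]
    ref <- lm(y ~ X - 1)
    expect_equal(unname(fit$beta[, vox_cols[m]]), unname(coef(ref)),
      tolerance = 1e-8
    )
    s2 <- sum(residuals(ref)^2) / ref$df.residual
    expect_equal(fit$sigma2[vox_cols[m]], s2, tolerance = 1e-8)
    # contrast t from the reference covariance matrix
    cvec <- unname(p$design$contrast)
    se <- sqrt(s2 * drop(t(cvec) %*% solve(crossprod(X)) %*% cvec))
    t_ref <- sum(cvec * coef(ref)) / se
    expect_equal(fit$t[vox_cols[m]], t_ref, tolerance = 1e-8)
  }
  expect_equal(fit$df, nrow(X) - ncol(X))
})

test_that("t-maps are invariant to constant shifts of age and TIV", {
  p <- sim_fit_pieces(effect_design(), seed = 23)
  fit1 <- fit_scn(p$sim$stack, p$design, mask = p$mask)
  co2 <- p$sim$cohort
  co2$age <- co2$age + 100
  co2$tiv <- co2$tiv + 5e5
  des2 <- build_scn_design(co2, p$seedvol, seed_name = "VPL_ipsi")
  st2 <- p$sim$stack
  st2$subject_id <- co2$subject_id
  fit2 <- fit_scn(st2, des2, mask = p$mask)
  expect_equal(fit1$t, fit2$t, tolerance = 1e-8)
})

test_that("contrast estimate is unbiased and tightens with sample size", {
  sizes <- list(c(10, 20), c(45, 93), c(130, 270))
  err <- vapply(seq_along(sizes), function(i) {
    ests <- vapply(1:10, function(s) {
      d <- effect_design(n_cs = sizes[[i]][1], n_nc = sizes[[i]][2])
      p <- sim_fit_pieces(d, seed = 1000 * i + s)
      fit <- fit_scn(p$sim$stack, p$design, mask = p$mask)
      blob <- p$sim$truth$effects[[1]]$voxels
      cols <- match(blob, which(fit$mask))
      mean(fit$beta["seedvol_cs", cols] - fit$beta["seedvol_nc", cols])
    }, numeric(1))
    abs(mean(ests) - 1)  # planted contrast is 2 - 1 = 1
  }, numeric(1))
  expect_lt(err[2], 0.25)
  expect_lt(err[3], err[1] + 0.05)  # shrinking bias/variance with n
})

test_that("whole-thalamus seed runs through the identical machinery", {
  p <- sim_fit_pieces(effect_design(), seed = 31)
  wt <- seed_volumes(p$sim$volumes, p$sim$cohort, "whole_thalamus", "both")
  expect_true(all(wt > 0))
  des <- build_scn_design(p$sim$cohort, wt, seed_name = "whole_thalamus")
  fit <- fit_scn(p$sim$stack, des, mask = p$mask)
  expect_s3_class(fit, "scn_fit")
  expect_equal(glance(fit)$seed, "whole_thalamus")
})

test_that("planted uniform ipsilesional atrophy is flagged by FDR in all 25", {
  n_seeds <- 10
  ipsi_all <- 0L
  contra_fp <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    sim <- simulate_cohort(
      simulation_design(atrophy = 0.2, effects = list()),
      seed = 400 + s
    )
    cmp <- compare_subfield_volumes(sim$cohort, sim$volumes)
    if (sum(cmp$significant[cmp$hemisphere == "ipsi"]) == 25L) ipsi_all <- ipsi_all + 1L
    contra_fp[s] <- sum(cmp$significant[cmp$hemisphere == "contra"])
  }
  expect_gte(ipsi_all / n_seeds, 0.9)
  # contralesional nuclei carry no planted effect: rejections there are the
  # false positives BH admits by design (FDR <= q over ~25 true rejections
  # implies an expected FP count of about q/(1-q) * 25 ~ 1.3)
  expect_equal(median(contra_fp), 0)
  expect_lte(mean(contra_fp), 25 * 0.05 / 0.95 + 2 * stats::sd(contra_fp) / sqrt(n_seeds))
})

test_that("atrophy confined to one subfield yields that subfield's largest |t|", {
  hits <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    sim <- simulate_cohort(
      simulation_design(atrophy = 0, effects = list()),
      seed = 600 + s
    )
    vols <- sim$volumes
    pick <- vols$subfield == "PuM" & vols$hemisphere == "ipsi" &
      vols$subject_id %in% sim$cohort$subject_id[sim$cohort$group == "CS"]
    vols$volume[pick] <- vols$volume[pick] * 0.8
    cmp <- compare_subfield_volumes(sim$cohort, vols)
    top <- cmp[which.max(abs(cmp$t)), ]
    if (top$subfield == "PuM" && top$hemisphere == "ipsi") hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("subfield comparison is calibrated without planted atrophy", {
  false_pos <- vapply(1:10, function(s) {
    sim <- simulate_cohort(
      simulation_design(atrophy = 0, effects = list()),
      seed = 500 + s
    )
    cmp <- compare_subfield_volumes(sim$cohort, sim$volumes)
    sum(cmp$p_value < 0.05)
  }, numeric(1))
  # expected raw false positives per run: 0.05 * 50 = 2.5
  expect_lt(mean(false_pos), 2.5 + 3 * sqrt(2.5 / 10))
})

test_that("tidy and glance expose the fit in broom shape", {
  p <- sim_fit_pieces(effect_design(n_cs = 5, n_nc = 7, n_scanners = 1), seed = 37)
  fit <- fit_scn(p$sim$stack, p$design, mask = p$mask)
  td <- tidy(fit)
  expect_equal(nrow(td), sum(fit$mask))
  expect_true(all(c("beta_cs", "beta_nc", "estimate", "t", "p_greater") %in% names(td)))
  expect_equal(td$estimate, td$beta_cs - td$beta_nc, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 12)
  expect_equal(gl$n_voxels, sum(fit$mask))
})
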