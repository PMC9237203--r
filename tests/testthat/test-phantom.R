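noiseless <- function(...) {
  phantom_params(noise_sd = 0, fwhm_mm = 0, subject_sd = 0,
                 gradient_sd = 0, ...)
}

test_that("atlas has seven non-empty regions with sensible anatomy", {
  atlas <- fixture_atlas()
  expect_setequal(atlas$regions$name,
                  c("caudate_L", "caudate_R", "putamen_L", "putamen_R",
                    "pallidum_L", "pallidum_R", "occipital"))
  counts <- vapply(atlas$regions$code, function(cd)
    sum(atlas$labels == cd), numeric(1))
  expect_true(all(counts > 0))
  # putamen larger than pallidum, as in the anatomy being imitated
  expect_gt(sum(atlas$labels == region_code_for_test(atlas, "putamen_L")),
            sum(atlas$labels == region_code_for_test(atlas, "pallidum_L")))
})

test_that("striatal labels are mirror-symmetric about the midline", {
  atlas <- fixture_atlas()
  lab <- atlas$labels
  mirrored <- lab[rev(seq_len(dim(lab)[1])), , ]
  for (rn in c("caudate", "putamen", "pallidum")) {
    l <- region_code_for_test(atlas, paste0(rn, "_L"))
    r <- region_code_for_test(atlas, paste0(rn, "_R"))
    expect_identical(which(mirrored == l), which(lab == r))
  }
})

test_that("grids too small for the structures raise a geometry error", {
  expect_error(build_atlas(shape = c(10, 10, 10)), "too small")
})

test_that("noiseless construction hits the closed-form levels", {
  atlas <- fixture_atlas()
  p <- noiseless(gradient_depth = 0)
  s <- simulate_subject(p, "NC", "dataset1", atlas = atlas)
  put <- extract_voi(s$volume, atlas, "putamen_L")$intensities
  occ <- extract_voi(s$volume, atlas, "occipital")$intensities
  expect_true(all(put == 2.5 * 100))
  expect_true(all(occ == 100))
  expect_error(simulate_subject(p, "XX", "dataset1", atlas = atlas),
               "invalid group")
  expect_error(simulate_subject(p, "NC", "dataset9", atlas = atlas),
               "invalid scanner")
})

test_that("the PD putaminal ramp has the stated endpoints", {
  atlas <- fixture_atlas()
  s <- simulate_subject(noiseless(gradient_depth = 0.5), "PD", "dataset1",
                        atlas = atlas)
  voi <- extract_voi(s$volume, atlas, "putamen_L")
  ys <- voi$coords[, 2]
  post <- voi$intensities[ys == min(ys)]
  ant <- voi$intensities[ys == max(ys)]
  expect_equal(unique(post), 0.5 * 2.5 * 100)
  expect_equal(unique(ant), 2.5 * 100)
})

test_that("deeper putaminal gradients strictly lower the mean uptake", {
  atlas <- fixture_atlas()
  means <- vapply(c(0.2, 0.5, 0.8), function(g) {
    s <- simulate_subject(noiseless(gradient_depth = g), "PD", "dataset1",
                          atlas = atlas)
    mean(extract_voi(s$volume, atlas, "putamen_L")$intensities)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("noiseless NC volumes are mirror-symmetric across the midline", {
  atlas <- fixture_atlas()
  s <- simulate_subject(noiseless(), "NC", "dataset1", atlas = atlas)
  v <- s$volume$values
  expect_equal(v, v[rev(seq_len(dim(v)[1])), , ])
})

test_that("cohorts are deterministic under the seed and sized as asked", {
  p <- phantom_params(sizes = c(nc1 = 3, pd1 = 4, nc2 = 2, pd2 = 2),
                      seed = 99, fwhm_mm = 0)
  atlas <- fixture_atlas()
  c1 <- simulate_cohort(p, atlas)
  c2 <- simulate_cohort(p, atlas)
  expect_equal(length(c1), 11)
  man <- attr(c1, "manifest")
  expect_equal(sum(man$group == "PD" & man$scanner == "dataset1"), 4)
  expect_false(anyDuplicated(man$id) > 0)
  expect_identical(c1[[5]]$volume$values, c2[[5]]$volume$values)
  p2 <- phantom_params(sizes = c(nc1 = 3, pd1 = 4, nc2 = 2, pd2 = 2),
                       seed = 100, fwhm_mm = 0)
  c3 <- simulate_cohort(p2, atlas)
  expect_false(identical(c1[[1]]$volume$values, c3[[1]]$volume$values))
  expect_error(
    cohort_manifest(phantom_params(sizes = c(nc1 = 0, pd1 = 1, nc2 = 1,
                                             pd2 = 1))),
    "positive")
})

test_that("paper-sized cohort design expands to 413 subjects", {
  man <- cohort_manifest(phantom_params())
  expect_equal(nrow(man), 413)
  expect_equal(as.vector(table(man$scanner)), c(320, 93))
})

test_that("PD putamen has higher intensity skewness than NC on average", {
  res <- fixture_pipeline()
  g <- res$scores$group
  sk <- res$features[, "stat_skew_putamen"]
  expect_gt(mean(sk[g == "PD"]), mean(sk[g == "NC"]))
})
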