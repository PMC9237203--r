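const_array <- function(d, level = 1L) array(as.integer(level), dim = d)

test_that("degenerate single-level GLCM features", {
  dv <- dvoi_from_array(const_array(c(3, 3, 3)), 4L)
  f <- glcm_features(dv)
  expect_equal(f[["cm_joint_max_3D_avg"]], 1)
  expect_equal(f[["cm_joint_max_3D_mrg"]], 1)
  expect_equal(f[["cm_contrast_3D_avg"]], 0)
  expect_equal(f[["cm_contrast_3D_mrg"]], 0)
})

test_that("merged GLCM equals brute-force pair counting on a 2x2x2 block", {
  arr <- array(c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L), dim = c(2, 2, 2))
  dv <- dvoi_from_array(arr, 2L)
  merged <- rowSums(glcm_matrices(dv), dims = 2)
  om <- oracle_glcm(arr, 2L)
  expect_equal(merged, om[, , 1] + apply(om[, , -1], c(1, 2), sum))
})

test_that("averaged and merged GLCM aggregations agree on balanced noise", {
  set.seed(12)
  arr <- array(sample.int(4L, 18^3, replace = TRUE), dim = c(18, 18, 18))
  f <- glcm_features(dvoi_from_array(arr, 4L))
  expect_equal(f[["cm_contrast_3D_avg"]], f[["cm_contrast_3D_mrg"]],
               tolerance = 0.02)
})

test_that("run-length structure on hand-built lines", {
  # all-distinct levels along a line: every run has length 1
  line <- array(1:4, dim = c(4, 1, 1))
  R <- glrlm_matrices(dvoi_from_array(line, 4L))
  expect_equal(sum(R[, 1, 1]), 4)        # x-direction: 4 unit runs
  expect_equal(sum(R[, -1, 1]), 0)
  expect_equal(sum(colSums(R[, , 1])^2) / sum(R[, , 1]), 4)  # RLNU = V
  # constant line: one run of length k
  k <- 6
  Rc <- glrlm_matrices(dvoi_from_array(const_array(c(k, 1, 1)), 2L))
  expect_equal(Rc[1, k, 1], 1L)
  expect_equal(sum(Rc[, , 1]), 1)
})

test_that("zone features on worked examples", {
  # constant VOI of V voxels: one zone, LZLGE = V^2
  V <- 4 * 3 * 2
  f <- glszm_features(dvoi_from_array(const_array(c(4, 3, 2)), 3L))
  expect_equal(f[["szm_lzlge_3D"]], V^2)
  # all-distinct levels: every zone is a singleton, SZE = 1
  arr <- array(1:8, dim = c(2, 2, 2))
  f2 <- glszm_features(dvoi_from_array(arr, 8L))
  expect_equal(f2[["szm_sze_3D"]], 1)
  expect_equal(f2[["szm_z_perc_3D"]], 1)
})

test_that("zone-distance non-uniformity on worked examples", {
  # one zone, any distance: ZDNU = 1
  f1 <- gldzm_features(dvoi_from_array(const_array(c(5, 5, 5)), 2L))
  expect_equal(f1[["dzm_zdnu_3D"]], 1)
  # two zones at the same distance: ZDNU = 2^2 / 2 = 2
  line <- array(c(1L, 1L, 1L, 2L, 2L, 2L, 2L), dim = c(7, 1, 1))
  f2 <- gldzm_features(dvoi_from_array(line, 2L))
  expect_equal(f2[["dzm_zdnu_3D"]], 2)
  # two zones at different distances (shell at 1, centre at 3): ZDNU = 1
  arr <- const_array(c(5, 5, 5))
  arr[3, 3, 3] <- 2L
  f3 <- gldzm_features(dvoi_from_array(arr, 2L))
  expect_equal(f3[["dzm_zdnu_3D"]], 1)
})

test_that("grey-tone difference features on worked examples", {
  # constant VOI: all s_i = 0, contrast 0, coarseness at its cap
  fc <- ngtdm_features(dvoi_from_array(const_array(c(3, 3, 3)), 2L))
  expect_equal(fc[["ngt_contrast_3D"]], 0)
  expect_equal(fc[["ngt_coarseness_3D"]], 1e6)
  # centre level 2 in a level-1 surround, hand enumeration via the oracle
  arr <- const_array(c(3, 3, 3))
  arr[2, 2, 2] <- 2L
  tab <- ngtdm_table(dvoi_from_array(arr, 2L))
  o <- oracle_ngtdm(arr, 2L)
  expect_equal(tab$n, o$n)
  expect_equal(tab$s, o$s)
  expect_equal(sum(tab$n), 27)  # every voxel has in-VOI neighbours
})

test_that("dependence-count features on worked examples", {
  # constant 3x3x3 cube: corners depend on 7, edges 11, faces 17, centre 26
  M <- ngldm_matrix(dvoi_from_array(const_array(c(3, 3, 3)), 2L))
  expect_equal(M[1, 7 + 1], 8L)
  expect_equal(M[1, 11 + 1], 12L)
  expect_equal(M[1, 17 + 1], 6L)
  expect_equal(M[1, 26 + 1], 1L)
  expect_equal(sum(M), 27)
  # single-voxel VOI: one entry at dependence 0; DCNU = normalised DCNU = 1
  f <- ngldm_features(dvoi_from_array(const_array(c(1, 1, 1)), 2L))
  expect_equal(f[["ngl_dcnu_3D"]], 1)
  expect_equal(f[["ngl_dcnu_norm_3D"]], 1)
})

voi_from_values <- function(x) {
  n <- length(x)
  structure(list(region = "test",
                 coords = cbind(seq_len(n) - 1L, 0L, 0L),
                 intensities = as.numeric(x), spacing = c(2, 2, 2)),
            class = "voi_sample")
}

test_that("first-order features on worked examples", {
  # constant VOI conventions
  v <- voi_from_values(rep(7, 10))
  f <- intensity_features(v, discretize(v, 8))
  expect_equal(f[["stat_mean"]], 7)
  expect_equal(f[["stat_median"]], 7)
  expect_equal(f[["stat_var"]], 0)
  expect_equal(f[["stat_skew"]], 0)
  expect_equal(f[["stat_kurt"]], 0)
  expect_equal(f[["loc_peak_global"]], 7)
  expect_equal(f[["loc_peak_local"]], 7)
  expect_equal(f[["ih_entropy"]], 0)
  expect_equal(f[["ih_uniformity"]], 1)
  # hand arithmetic on {1,2,3,4}
  v2 <- voi_from_values(1:4)
  f2 <- intensity_features(v2, discretize(v2, 4))
  expect_equal(f2[["stat_mean"]], 2.5)
  expect_equal(f2[["stat_energy"]], 30)
  expect_equal(f2[["stat_var"]], 1.25)
  expect_equal(f2[["stat_mad"]], 1)
  expect_equal(f2[["stat_rmad"]], 0.5)   # values within [p10, p90] = {2,3}
  expect_equal(f2[["stat_iqr"]], 1.5)
  # median of discretised levels {1,1,2,2}
  v3 <- voi_from_values(c(0, 10, 20, 30))
  expect_equal(ih_features(discretize(v3, 2))[["ih_median"]], 1.5)
})

test_that("the feature schema has the printed counts and layout", {
  tags <- region_feature_tags()
  expect_equal(length(tags), 186)
  fam <- function(p) sum(startsWith(tags, p))
  expect_equal(fam("loc_"), 2)
  expect_equal(fam("stat_"), 18)
  expect_equal(fam("ih_"), 23)
  expect_equal(fam("ivh_"), 7)
  expect_equal(fam("cm_"), 50)
  expect_equal(fam("rlm_"), 32)
  expect_equal(fam("szm_"), 16)
  expect_equal(fam("dzm_"), 16)
  expect_equal(fam("ngt_"), 5)
  expect_equal(fam("ngl_"), 17)
  nm <- feature_vector_names()
  expect_equal(length(nm), 930)
  expect_equal(unname(table(feature_block(nm))[c(
    "caudate", "putamen", "pallidum", "CRputamen", "CRpallidum")]),
    rep(186L, 5), ignore_attr = TRUE)
  # the published signature's features exist in the schema
  expect_true(all(published_pd_signature()$features %in% nm))
})

test_that("left/right features agree on mirror-symmetric volumes", {
  atlas <- fixture_atlas()
  p <- phantom_params(noise_sd = 0, subject_sd = 0, gradient_sd = 0)
  s <- simulate_subject(p, "PD", "dataset1", atlas = atlas)
  cfg <- radiomics_config()
  l <- region_features(extract_voi(s$volume, atlas, "putamen_L"), cfg,
                       s$volume)
  r <- region_features(extract_voi(s$volume, atlas, "putamen_R"), cfg,
                       s$volume)
  expect_equal(l, r)
  fv <- feature_vector(s, atlas, cfg)
  expect_equal(unname(fv["stat_mean_putamen"]),
               unname(l[["stat_mean"]]))
})

test_that("identical caudate and putamen content makes CRputamen one", {
  # regions that are translated copies of one another, with identical
  # intensity content, must have elementwise ratio 1 wherever defined
  lab <- array(0L, dim = c(32, 32, 16))
  offs <- list(c(5, 5, 5), c(5, 13, 5), c(13, 5, 5), c(13, 13, 5),
               c(21, 5, 5), c(21, 13, 5), c(5, 21, 5))
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    lab[o[1]:(o[1] + 2), o[2]:(o[2] + 2), o[3]:(o[3] + 2)] <- k
  }
  atlas <- atlas_mask(lab, data.frame(
    code = 1:7, name = c("caudate_L", "caudate_R", "putamen_L", "putamen_R",
                         "pallidum_L", "pallidum_R", "occipital")))
  vol <- volume_grid(array(rep(1:16, each = 32 * 32), dim = dim(lab)))
  fv <- feature_vector(vol, atlas)
  cr <- fv[feature_block(names(fv)) == "CRputamen"]
  expect_true(all(abs(cr[!is.na(cr)] - 1) < 1e-12))
})
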