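test_that("height and extent thresholds are strict", {
  tarr <- array(0, c(12, 12, 12))
  tarr[1:5, 1, 1] <- 5          # cluster of 5
  tarr[8:12, 3, 1] <- 2.7       # exactly at the height threshold
  cl <- threshold_and_cluster(tarr, threshold_spec(2.7, 4L))
  expect_equal(sum(cl$retained), 5)            # t = 2.7 voxels excluded
  cl2 <- threshold_and_cluster(tarr, threshold_spec(2.7, 5L))
  expect_equal(sum(cl2$retained), 0)           # k = size removed (strict)
  expect_error(threshold_and_cluster(tarr, mask = array(FALSE, dim(tarr))),
               "empty mask")
})

test_that("two components straddling k_min keep only the larger", {
  tarr <- array(0, c(40, 10, 10))
  tarr[1:13, 1:5, 1:4] <- 5   # 260 voxels
  tarr[20:29, 1:5, 1:5] <- 5  # 250 voxels
  cl <- threshold_and_cluster(tarr, threshold_spec(2.7, 250L))
  expect_equal(nrow(cl$table), 1)
  expect_equal(cl$table$size, 260)
})

test_that("cluster labels match the flood-fill oracle on random maps", {
  set.seed(99)
  for (i in 1:8) {
    bin <- array(runif(8000) < runif(1, 0.15, 0.5), c(20, 20, 20))
    for (conn in c(6L, 26L)) {
      got <- execonn:::label_components(bin, conn)
      want <- label_oracle(bin, conn)
      expect_true(same_partition(got, want, bin))
    }
  }
})

test_that("raising thresholds never grows the retained set", {
  set.seed(5)
  tarr <- array(rnorm(4000, 1, 2), c(20, 20, 10))
  prev <- NULL
  for (tmin in c(0.5, 1.5, 2.5)) {
    cur <- threshold_and_cluster(tarr, threshold_spec(tmin, 5L))$retained
    if (!is.null(prev)) expect_true(all(prev | !cur))
    prev <- cur
  }
  a <- threshold_and_cluster(tarr, threshold_spec(1, 5L))$retained
  b <- threshold_and_cluster(tarr, threshold_spec(1, 30L))$retained
  expect_true(all(a | !b))
})

test_that("overlap percentage follows the averaged-directional definition", {
  A <- array(FALSE, c(20, 10, 5)); B <- A
  A[1:200] <- TRUE              # |A| = 200
  B[151:250] <- TRUE            # |B| = 100, |A ∩ B| = 50
  ov <- overlap_percentage(A, B)
  expect_equal(as.numeric(ov), mean(c(25, 50)))       # 37.5
  expect_equal(attr(ov, "a_in_b"), 25)
  expect_equal(attr(ov, "b_in_a"), 50)
  expect_equal(attr(ov, "jaccard"), 100 * 50 / 250)
  expect_equal(as.numeric(overlap_percentage(A, A)), 100)
  expect_equal(as.numeric(overlap_percentage(B, A)), as.numeric(ov)) # symmetric
  empty <- array(FALSE, dim(A))
  expect_equal(as.numeric(overlap_percentage(empty, empty)), 0)
  expect_equal(as.numeric(overlap_percentage(A, empty)), 0)
  disj <- array(FALSE, dim(A)); disj[300:400] <- TRUE
  expect_equal(as.numeric(overlap_percentage(A, disj)), 0)
  expect_error(overlap_percentage(A, array(FALSE, c(2, 2, 2))), "mismatch")
})

test_that("overlap matrix and conjunction map behave on degenerate inputs", {
  A <- array(FALSE, c(6, 6, 6)); A[1:30] <- TRUE
  same <- list(DivA = A, DistrA = A, WM = A, ModSwi = A)
  M <- overlap_matrix(same)
  expect_true(all(M == 100))
  expect_true(isSymmetric(M))
  sets <- lapply(0:3, function(k) {
    x <- array(FALSE, c(6, 6, 6)); x[(k * 40 + 1):(k * 40 + 30)] <- TRUE; x
  })
  names(sets) <- c("DivA", "DistrA", "WM", "ModSwi")
  M2 <- overlap_matrix(sets)
  expect_true(all(M2[upper.tri(M2)] == 0))
  cj <- conjunction_count_map(same)
  expect_setequal(unique(as.vector(cj)), c(0L, 4L))
  # counting identity: sum of the count map = sum of set sizes
  cj2 <- conjunction_count_map(sets)
  expect_equal(sum(cj2), sum(vapply(sets, sum, numeric(1))))
  mixed <- conjunction_count_map(list(A, A, sets[[1]], sets[[2]]))
  expect_true(max(mixed) <= 4)
})

test_that("published ROI fixture has the printed centres", {
  rois <- paper_executive_rois()
  expect_length(rois$name, 8)
  expect_equal(rois$centers_mm[rois$name == "rMFG", ], c(36, 2, 50))
  expect_equal(rois$centers_mm[rois$name == "lMFG", ], c(-37, 13, 34))
  expect_equal(rois$centers_mm[rois$name == "lPrc", ], c(-13, -56, 50))
  expect_equal(rois$radius_mm, 7)
  expect_equal(rois$hemisphere, rep(c("R", "L"), 4))
  # every sphere holds voxels on the covering grid
  acq <- execonn:::paper_roi_acq()
  mem <- execonn:::roi_membership(rois, acq)
  expect_true(all(lengths(mem) >= 15))
  # spheres never share voxels
  expect_equal(anyDuplicated(unlist(mem)), 0)
})

test_that("ROI derivation recovers a shared blob centroid", {
  acq <- acq_spec(n_volumes = 10L, grid_shape = c(16L, 16L, 16L))
  co <- voxel_coords_mm(acq)
  blob <- array(sqrt(rowSums(sweep(co, 2, c(6, -3, 0))^2)) < 9,
                acq$grid_shape)
  rois <- derive_executive_rois(list(blob, blob, blob), acq$affine,
                                min_cohorts = 2)
  expect_length(rois$name, 1)
  expect_lt(max(abs(rois$centers_mm[1, ] - c(6, -3, 0))), 3) # within a voxel
  expect_warning(
    empty <- derive_executive_rois(list(blob, blob, blob), acq$affine,
                                   min_cohorts = 4),
    "empty ROI set")
  expect_length(empty$name, 0)
})

test_that("participant overlap analysis handles empty contrasts", {
  base <- array(0, c(15, 15, 15))
  act <- base; act[2:8, 2:8, 2:8] <- 3
  maps <- list(DivA = base, DistrA = act, WM = act, ModSwi = act)
  cms <- lapply(maps, function(m)
    structure(list(t = m, mask = NULL), class = "contrast_map"))
  res <- participant_overlap_analysis(cms,
                                      threshold_spec(1.3, 10L,
                                                     level = "participant"))
  expect_equal(unname(res$counts["DivA"]), 0)
  expect_true(all(res$overlaps[grep("DivA", names(res$overlaps))] == 0))
  expect_true(all(res$overlaps[!grepl("DivA", names(res$overlaps))] == 100))
})
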