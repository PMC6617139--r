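test_that("tortuosity is the mean geodesic-to-chord ratio", {
  b <- function(geo, euc) structure(list(geodesic_length = geo,
                                         euclidean_length = euc),
                                    class = "skeleton_branch")
  expect_equal(compute_bvt(list(b(10, 10))), 1)
  expect_equal(compute_bvt(list(b(10, 10), b(20, 10))), 1.5)
  expect_error(compute_bvt(list()), "undefined")
  # closed loops are excluded with a message
  expect_message(v <- compute_bvt(list(b(10, 10), b(12, 0))), "closed-loop")
  expect_equal(v, 1)
  expect_error(suppressMessages(compute_bvt(list(b(12, 0)))), "undefined")
  # length-weighted variant
  expect_equal(compute_bvt(list(b(10, 10), b(20, 10)), length_weighted = TRUE),
               (10 * 1 + 20 * 2) / 30)
})

test_that("caliber recovers bar width and scales with pixel pitch", {
  vm <- matrix(FALSE, 120, 120); vm[58:62, 11:110] <- TRUE
  sk <- skeletonize_vessels(vm)
  pitch <- 6 / 304
  bvc <- compute_bvc(vm, sk, pitch)
  expect_equal(bvc, 5 * pitch * 1000, tolerance = 0.10 * 5 * pitch * 1000)
  # doubling the width doubles the caliber
  vm2 <- matrix(FALSE, 120, 120); vm2[53:62, 11:110] <- TRUE
  bvc2 <- compute_bvc(vm2, skeletonize_vessels(vm2), pitch)
  expect_equal(bvc2 / bvc, 2, tolerance = 0.1)
  # linear in pixel pitch
  expect_equal(compute_bvc(vm, sk, 2 * pitch) / bvc, 2, tolerance = 1e-9)
  # mask == skeleton (1-px orthogonal line): caliber equals the pitch
  line <- matrix(FALSE, 40, 40); line[20, 5:35] <- TRUE
  expect_equal(compute_bvc(line, line, pitch), pitch * 1000, tolerance = 1e-9)
  expect_error(compute_bvc(vm, matrix(FALSE, 120, 120), pitch), "undefined")
})

test_that("perimeter index is the perimeter pixel fraction", {
  expect_equal(compute_vpi(matrix(FALSE, 10, 10)), 0)
  half <- matrix(FALSE, 10, 10); half[1:5, ] <- TRUE
  expect_equal(compute_vpi(half), 0.5)
})

test_that("regional vessel density thresholds the fd map per ring", {
  dim_px <- c(200, 200)
  reg <- region_spec(c(100.5, 100.5), 6 / 200, dim_px)
  # ring masks are disjoint and exclude the FAZ
  overlap <- reg$regions$C1 & reg$regions$C2 | reg$regions$C2 & reg$regions$C3 |
    reg$regions$C1 & reg$regions$C3
  expect_false(any(overlap))
  fd1 <- matrix(1, 200, 200)
  expect_equal(unname(compute_bvd(fd1, reg)), c(1, 1, 1))
  expect_equal(unname(compute_bvd(matrix(0.5, 200, 200), reg)), c(0, 0, 0))
  # hand-counted toy case: fd >= 0.7 on half the non-excluded ring pixels
  faz <- matrix(FALSE, 200, 200); faz[91:110, 91:110] <- TRUE
  reg2 <- region_spec(c(100.5, 100.5), 6 / 200, dim_px, exclusion_mask = faz)
  fd <- matrix(0, 200, 200)
  c1 <- which(reg2$regions$C1)
  fd[c1[seq_len(floor(length(c1) / 2))]] <- 0.8
  expect_equal(unname(compute_bvd(fd, reg2))[1],
               floor(length(c1) / 2) / length(c1))
  # fully excluded region errors
  reg3 <- region_spec(c(100.5, 100.5), 6 / 200, dim_px,
                      exclusion_mask = matrix(TRUE, 200, 200))
  expect_error(compute_bvd(fd1, reg3), "excluded")
})

test_that("FAZ area follows the pixel-count times pixel-area rule", {
  mk <- function(npx) {
    m <- matrix(FALSE, 50, 50); m[seq_len(npx)] <- TRUE
    faz_result(m, cbind(c(1, 2, 2, 1, 1), c(1, 1, 2, 2, 1)), 6 / 304)
  }
  expect_equal(compute_faz_area(mk(100), 6 / 304), 100 * (6 / 304 * 1000)^2)
  expect_equal(compute_faz_area(mk(1), 0.02), 400)
  # rasterized disk close to analytic area
  d <- matrix(FALSE, 100, 100)
  d[(row(d) - 50.5)^2 + (col(d) - 50.5)^2 <= 25^2] <- TRUE
  faz <- faz_result(d, circle_polygon(25), 0.02)
  expect_equal(compute_faz_area(faz, 0.02), pi * 25^2 * 400,
               tolerance = 0.02 * pi * 25^2 * 400)
  expect_error(compute_faz_area(mk(0), 0.02), "empty")
})

test_that("contour irregularity matches isoperimetric anchors", {
  msk <- matrix(TRUE, 2, 2)
  expect_equal(compute_faz_ci(faz_result(msk, circle_polygon(50, 360), 0.02)),
               1, tolerance = 0.005)
  sq <- cbind(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0))
  expect_equal(compute_faz_ci(faz_result(msk, sq, 0.02)), 2 / sqrt(pi),
               tolerance = 0.01 * 2 / sqrt(pi))
  # 2:1 ellipse against a numeric-quadrature oracle
  th <- seq(0, 2 * pi, length.out = 2001)
  ell <- cbind(100 * cos(th), 50 * sin(th))
  seg <- sum(sqrt(diff(ell[, 1])^2 + diff(ell[, 2])^2))
  oracle <- seg / (2 * sqrt(pi * pi * 100 * 50))
  expect_equal(compute_faz_ci(faz_result(msk, ell, 0.02)), oracle,
               tolerance = 0.02 * oracle)
  # self-intersecting contour warns
  bow <- cbind(c(0, 12, 0, 6, 0), c(0, 10, 10, 0, 0))
  expect_warning(compute_faz_ci(faz_result(msk, bow, 0.02)), "self-intersecting")
})

test_that("full extraction yields 13 finite features within type invariants", {
  ph <- generate_phantom(phantom_spec(seed = 1))
  fv <- extract_all_features(ph$scp, ph$dcp, subject_id = "P1", eye = "OD",
                             label = "control")
  feats <- unlist(fv[, octa_feature_names()])
  expect_length(feats, 13)
  expect_true(all(is.finite(feats)))
  expect_gte(fv$BVT_S, 1)
  expect_true(all(feats[grep("BVD|VPI", names(feats))] >= 0 &
                    feats[grep("BVD|VPI", names(feats))] <= 1))
  expect_true(all(feats[grep("FAZ_A", names(feats))] > 0))
  expect_true(all(feats[grep("FAZ_CI", names(feats))] >= 1 - 0.02))
  expect_true(fv$complete)
  # identical layers give identical foveal metrics; missing DCP flags partial
  fv2 <- extract_all_features(ph$scp, ph$scp)
  expect_equal(fv2$FAZ_A_S, fv2$FAZ_A_D)
  fv3 <- extract_all_features(ph$scp, NULL)
  expect_false(fv3$complete)
  expect_true(is.na(fv3$BVD_DC1))
})

test_that("straight-vessel phantoms yield tortuosity within [1, 1.05]", {
  ph <- generate_phantom(phantom_spec(seed = 6, tortuosity_amp = 0))
  fv <- extract_all_features(ph$scp, NULL)
  expect_gte(fv$BVT_S, 1)
  expect_lte(fv$BVT_S, 1.05)
})

test_that("features are resolution-stable under 2x upsampling", {
  ph <- generate_phantom(phantom_spec(seed = 12, image_px = 152))
  pre <- preprocess_angiogram(ph$scp)
  maps <- vessel_map_set(pre)
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  um <- up(maps$vessel_mask)
  # tortuosity is dimensionless: stable within 2%
  br1 <- extract_branches(skeletonize_vessels(maps$vessel_mask), 5)
  br2 <- extract_branches(skeletonize_vessels(um), 10)
  b1 <- suppressMessages(compute_bvt(br1))
  b2 <- suppressMessages(compute_bvt(br2))
  expect_equal(b2, b1, tolerance = 0.02 * b1)
  # regional density (window doubled with the image): stable within 5%
  fd1 <- local_fd_map(maps$vessel_mask, 16)
  fd2 <- local_fd_map(um, 32)
  r1 <- region_spec(c(76.5, 76.5), 6 / 152, dim(maps$vessel_mask))
  r2 <- region_spec(c(153, 153), 6 / 304, dim(um))
  expect_equal(unname(compute_bvd(fd2, r2)), unname(compute_bvd(fd1, r1)),
               tolerance = 0.05)
  # perimeter fraction scales inversely with resolution (it carries one
  # factor of pixel pitch); the scaled values agree up to staircase overhead
  vpi1 <- compute_vpi(perimeter_map(maps$vessel_mask))
  vpi2 <- compute_vpi(perimeter_map(um))
  expect_gt(vpi2 * 2 / vpi1, 0.8)
  expect_lt(vpi2 * 2 / vpi1, 1.35)
})
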