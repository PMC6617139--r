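test_that("skeletonization yields thin medial lines inside the mask", {
  rect <- matrix(FALSE, 120, 120); rect[50:56, 11:110] <- TRUE
  sk <- skeletonize_vessels(rect)
  expect_true(all(rect[sk]))                     # skeleton subset of mask
  expect_lt(abs(sum(sk) - 100), 10)              # midline of a 100x7 bar
  blocks <- sk[-120, -120] & sk[-1, -120] & sk[-120, -1] & sk[-1, -1]
  expect_false(any(blocks))                      # one pixel wide
  # already minimal input is preserved
  line <- matrix(FALSE, 40, 40); line[20, 5:35] <- TRUE
  expect_equal(skeletonize_vessels(line), line)
  expect_false(any(skeletonize_vessels(matrix(FALSE, 10, 10))))
})

test_that("skeletonization matches an independent thinning oracle on a vessel mask", {
  skip_if_not(nzchar(Sys.which("python3")))
  ph <- generate_phantom(phantom_spec(seed = 5, image_px = 128, n_vessels = 8))
  mask <- ph$truth$vessel_mask
  sk <- skeletonize_vessels(mask)
  f_in <- withr::local_tempfile(fileext = ".csv")
  f_out <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(mask * 1, f_in, row.names = FALSE, col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy as np\nfrom skimage.morphology import thin\n",
    "m = np.loadtxt('%s') > 0\n",
    "np.savetxt('%s', thin(m).astype(int), fmt='%%d')\n"), f_in, f_out)
  res <- system2("python3", c("-c", shQuote(code)))
  skip_if_not(res == 0, "scikit-image unavailable")
  ref <- as.matrix(utils::read.table(f_out)) > 0
  # different thinning schemes differ in detail; demand close global agreement
  expect_lt(abs(sum(sk) - sum(ref)) / sum(ref), 0.25)
  dil <- function(m) m | rbind(FALSE, m[-nrow(m), ]) | rbind(m[-1, ], FALSE) |
    cbind(FALSE, m[, -ncol(m)]) | cbind(m[, -1], FALSE)
  expect_gt(sum(sk & dil(dil(ref))) / sum(sk), 0.9)
})

test_that("perimeter map marks exactly the 4-boundary of the mask", {
  expect_false(any(perimeter_map(matrix(FALSE, 20, 20))))
  d <- matrix(FALSE, 100, 100)
  d[(row(d) - 50)^2 + (col(d) - 50)^2 <= 900] <- TRUE
  pm <- perimeter_map(d)
  expect_true(all(d[pm]))
  expect_lt(abs(sum(pm) - 2 * pi * 30) / (2 * pi * 30), 0.15)
  # every 1-px line pixel is a perimeter pixel
  line <- matrix(FALSE, 30, 30); line[15, 3:27] <- TRUE
  expect_equal(perimeter_map(line), line)
  # every perimeter pixel has a non-vessel 4-neighbour (border counts)
  idx <- which(pm, arr.ind = TRUE)
  has_bg <- apply(idx, 1, function(p) {
    nb <- rbind(p + c(1, 0), p + c(-1, 0), p + c(0, 1), p + c(0, -1))
    any(apply(nb, 1, function(q)
      q[1] < 1 || q[1] > 100 || q[2] < 1 || q[2] > 100 || !d[q[1], q[2]]))
  })
  expect_true(all(has_bg))
})

test_that("branch decomposition handles lines, junctions, and arcs", {
  # single straight orthogonal branch: unit steps, one branch
  sk <- matrix(FALSE, 20, 20); sk[10, 5:15] <- TRUE
  br <- extract_branches(sk, 5)
  expect_length(br, 1)
  expect_equal(br[[1]]$geodesic_length, 10)
  expect_equal(br[[1]]$euclidean_length, 10)
  # T junction: three branches
  skt <- matrix(FALSE, 60, 60); skt[30, 10:50] <- TRUE; skt[10:30, 30] <- TRUE
  expect_length(extract_branches(skt, 5), 3)
  # X crossing: four branches, and geodesic >= euclidean everywhere
  skx <- matrix(FALSE, 61, 61); skx[31, 6:56] <- TRUE; skx[6:56, 31] <- TRUE
  brx <- extract_branches(skx, 5)
  expect_length(brx, 4)
  for (b in brx) expect_gte(b$geodesic_length, b$euclidean_length - 1e-9)
  # semicircle: geodesic/chord close to pi/2
  bra <- extract_branches(semicircle_skeleton(40), 5)
  expect_length(bra, 1)
  expect_equal(compute_bvt(bra), pi / 2, tolerance = 0.05)
  # min-length filter discards short fragments
  frag <- matrix(FALSE, 20, 20); frag[5, 5:7] <- TRUE
  expect_length(extract_branches(frag, 5), 0)
  expect_length(extract_branches(frag, 0), 1)
})

test_that("branch decomposition partitions non-junction skeleton pixels", {
  ph <- generate_phantom(phantom_spec(seed = 9, image_px = 152, n_vessels = 12))
  sk <- skeletonize_vessels(ph$truth$vessel_mask)
  br <- extract_branches(sk, 0)
  all_px <- do.call(rbind, lapply(br, function(b) b$path))
  expect_equal(nrow(all_px), nrow(unique(all_px)))  # no pixel in two branches
  # every branch pixel is a skeleton pixel
  expect_true(all(sk[all_px]))
})

test_that("local fractal dimension hits the dimension anchors", {
  expect_error(local_fd_map(matrix(FALSE, 64, 64), 15), "power of 2")
  expect_error(local_fd_map(matrix(FALSE, 8, 8), 16), "larger than image")
  expect_equal(local_fd_map(matrix(FALSE, 64, 64), 16)[32, 32], 0)
  expect_equal(local_fd_map(matrix(TRUE, 64, 64), 16)[32, 32], 1)
  line <- matrix(FALSE, 64, 64); line[32, ] <- TRUE
  expect_equal(local_fd_map(line, 16)[32, 32], 0.5, tolerance = 0.05)
  diagonal <- matrix(FALSE, 64, 64); diag(diagonal) <- TRUE
  expect_equal(local_fd_map(diagonal, 16)[32, 32], 0.5, tolerance = 0.08)
  fd <- local_fd_map(line, 16)
  expect_true(all(fd >= 0 & fd <= 1))
})

test_that("local fd agrees with a brute-force box-counting oracle", {
  withr::with_seed(7, {
    m <- matrix(runif(64 * 64) < 0.3, 64, 64)
  })
  fd <- local_fd_map(m, 16)
  brute_fd <- function(mask, r0, c0, w = 16) {
    sizes <- c(1, 2, 4, 8, 16)
    counts <- sapply(sizes, function(s) {
      n <- 0
      for (a in seq(0, w - s, by = s)) for (b in seq(0, w - s, by = s)) {
        rr <- (r0 + a):(r0 + a + s - 1); cc <- (c0 + b):(c0 + b + s - 1)
        rr <- rr[rr >= 1 & rr <= nrow(mask)]; cc <- cc[cc >= 1 & cc <= ncol(mask)]
        if (length(rr) && length(cc) && any(mask[rr, cc])) n <- n + 1
      }
      n
    })
    if (counts[1] == 0) return(0)
    x <- log(1 / sizes)
    y <- log(pmax(counts, 1))
    min(max(sum((x - mean(x)) * y) / sum((x - mean(x))^2) / 2, 0), 1)
  }
  for (p in list(c(32, 32), c(20, 40), c(45, 18))) {
    expect_equal(fd[p[1], p[2]],
                 brute_fd(m, p[1] - 8 + 1, p[2] - 8 + 1),
                 tolerance = 1e-10)
  }
})

test_that("FAZ active contour finds a vessel-free disk accurately", {
  g <- grid_faz_phantom(200, disk_r = 25)
  img <- angiogram(matrix(0.5, 200, 200), "SCP")
  faz <- segment_faz(img, g$mask)
  expect_true(faz$converged)
  expect_lt(abs(sum(faz$mask) - pi * 25^2) / (pi * 25^2), 0.05)
  dice <- 2 * sum(faz$mask & g$truth) / (sum(faz$mask) + sum(g$truth))
  expect_gte(dice, 0.95)
  # single 4-connected component, closed contour
  expect_equal(faz$contour[1, ], faz$contour[nrow(faz$contour), ])
  # deterministic
  faz2 <- segment_faz(img, g$mask)
  expect_identical(faz$mask, faz2$mask)
})

test_that("FAZ segmentation warns when the region hits the image border", {
  img <- angiogram(matrix(0.5, 80, 80), "SCP")
  expect_warning(segment_faz(img, matrix(FALSE, 80, 80), max_radius_mm = Inf),
                 "border")
})

test_that("vessel map set maintains subset invariants on phantoms", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  pre <- preprocess_angiogram(ph$scp)
  maps <- vessel_map_set(pre)
  expect_true(all(maps$vessel_mask[maps$skeleton_mask]))
  expect_true(all(maps$vessel_mask[maps$perimeter_mask]))
  expect_true(all(maps$fd_map >= 0 & maps$fd_map <= 1))
  expect_gte(maps$vessel_area_fraction, 0.2)  # plausibility band, disease-free
  expect_lte(maps$vessel_area_fraction, 0.7)
})
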