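#' Binarize a vesselness map
#'
#' Local adaptive thresholding (window mean plus offset) followed by
#' morphological cleaning: connected components smaller than `min_object_px`
#' are removed and interior holes smaller than `max_hole_px` are closed. An
#' absolute response floor suppresses flat background where the local mean
#' itself is near zero.
#'
#' @param vesselness Numeric matrix in `[0, 1]` (e.g. from
#'   [frangi_vesselness()]).
#' @param window_px Side of the local-mean window in pixels (default 31).
#' @param offset Offset added to the local mean (default -0.02).
#' @param min_object_px Minimum component size kept (default 20).
#' @param max_hole_px Maximum hole size filled (default 10).
#' @param min_response Absolute vesselness floor (default 0.05).
#'
#' @return Logical matrix: the binary vessel mask.
#' @export
binarize_vessels <- function(vesselness, window_px = 31, offset = -0.02,
                             min_object_px = 20, max_hole_px = 10,
                             min_response = 0.05) {
  v <- as.matrix(vesselness)
  if (!any(v > 0)) return(matrix(FALSE, nrow(v), ncol(v)))
  local_mean <- box_blur(v, window_px)
  mask <- (v > local_mean + offset) & (v > min_response)
  mask <- remove_small_objects(mask, min_object_px)
  mask <- fill_small_holes(mask, max_hole_px)
  mask
}

#' Skeletonize a vessel mask
#'
#' Guo-Hall two-subiteration thinning: a topology-preserving, one-pixel-wide
#' medial skeleton (it also resolves two-pixel diagonal bands, which simpler
#' schemes leave behind). Every skeleton pixel is a vessel pixel. Residual
#' right-angle staircase corners are pruned so 8-connected path lengths are
#' not inflated.
#'
#' @param vessel_mask Logical matrix.
#' @return Logical matrix: the skeleton.
#' @export
skeletonize_vessels <- function(vessel_mask) {
  m <- vessel_mask & TRUE
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (parity in 0:1) {
      p <- m * 1
      # x1 = E, then counterclockwise: NE, N, NW, W, SW, S, SE
      x1 <- shift_mat(p, 0, -1);  x2 <- shift_mat(p, 1, -1)
      x3 <- shift_mat(p, 1, 0);   x4 <- shift_mat(p, 1, 1)
      x5 <- shift_mat(p, 0, 1);   x6 <- shift_mat(p, -1, 1)
      x7 <- shift_mat(p, -1, 0);  x8 <- shift_mat(p, -1, -1)
      ch <- (x1 == 0 & (x2 == 1 | x3 == 1)) + (x3 == 0 & (x4 == 1 | x5 == 1)) +
            (x5 == 0 & (x6 == 1 | x7 == 1)) + (x7 == 0 & (x8 == 1 | x1 == 1))
      n1 <- pmin(x1 + x2, 1) + pmin(x3 + x4, 1) + pmin(x5 + x6, 1) + pmin(x7 + x8, 1)
      n2 <- pmin(x2 + x3, 1) + pmin(x4 + x5, 1) + pmin(x6 + x7, 1) + pmin(x8 + x1, 1)
      nmin <- pmin(n1, n2)
      g3 <- if (parity == 0) ((x2 | x3 | !x8) & x1) == 0
            else ((x6 | x7 | !x4) & x5) == 0
      cond <- p == 1 & ch == 1 & nmin >= 2 & nmin <= 3 & g3
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m <- clear_residual_blocks(m)
  prune_redundant_corners(m)
}

# Parallel thinning can leave 2x2 blocks in rare configurations; delete block
# pixels that are simple points (their foreground neighbours stay mutually
# 8-connected without them), one at a time, until no solid square remains.
clear_residual_blocks <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ring <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  simple_point <- function(r, c) {
    rr <- r + ring[, 1]; cc <- c + ring[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    fg <- which(ok)[m[cbind(rr[ok], cc[ok])]]
    nfg <- length(fg)
    if (nfg < 2 || nfg > 7) return(FALSE)
    # union-find over the foreground ring cells, direct 8-adjacency only
    parent <- seq_len(nfg)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(nfg - 1)) for (j in (i + 1):nfg) {
      if (max(abs(ring[fg[i], ] - ring[fg[j], ])) <= 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    length(unique(vapply(seq_len(nfg), find, integer(1)))) == 1
  }
  repeat {
    blocks <- m & shift_mat(m, 1, 0) & shift_mat(m, 0, 1) & shift_mat(m, 1, 1)
    if (!any(blocks)) break
    idx <- which(blocks)
    cand <- unique(c(idx, idx - 1L, idx - nr, idx - nr - 1L))
    cand <- cand[m[cand]]
    removed <- FALSE
    for (i in cand) {
      r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
      if (simple_point(r, c)) {
        m[i] <- FALSE
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  m
}

# Rasterized curves and Zhang-Suen output keep staircase corner pixels: a
# degree-2 pixel whose two neighbours are themselves 8-adjacent lies on a
# shortcut and is redundant. Removed one at a time so chains never disconnect.
prune_redundant_corners <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  nbrs_of <- function(r, c) {
    rr <- r + c(-1, -1, -1, 0, 0, 1, 1, 1)
    cc <- c + c(-1, 0, 1, -1, 1, -1, 0, 1)
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    cbind(rr[ok], cc[ok])[m[cbind(rr[ok], cc[ok])], , drop = FALSE]
  }
  repeat {
    b <- neighbour_count8(m)
    cand <- which(m & b == 2)
    removed_any <- FALSE
    for (i in cand) {
      r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
      nb <- nbrs_of(r, c)
      both_orth <- nrow(nb) == 2 &&
        sum(abs(nb[1, ] - c(r, c))) == 1 && sum(abs(nb[2, ] - c(r, c))) == 1
      if (both_orth && max(abs(nb[1, ] - nb[2, ])) <= 1) {
        # right-angle apex whose neighbours connect diagonally: shortcut exists
        m[r, c] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  m
}

# Crossing number: 0->1 transitions around the 8-neighbourhood cycle.
transition_count8 <- function(mask) {
  p <- mask * 1
  p2 <- shift_mat(p, 1, 0);  p3 <- shift_mat(p, 1, -1)
  p4 <- shift_mat(p, 0, -1); p5 <- shift_mat(p, -1, -1)
  p6 <- shift_mat(p, -1, 0); p7 <- shift_mat(p, -1, 1)
  p8 <- shift_mat(p, 0, 1);  p9 <- shift_mat(p, 1, 1)
  (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
}

#' Vessel perimeter map
#'
#' Marks vessel pixels with at least one non-vessel 4-neighbour; the image
#' border counts as background.
#'
#' @param vessel_mask Logical matrix.
#' @return Logical matrix: the perimeter mask (subset of the vessel mask).
#' @export
perimeter_map <- function(vessel_mask) {
  m <- vessel_mask & TRUE
  if (!any(m)) return(m)
  up <- shift_mat(m * 1, -1, 0); down <- shift_mat(m * 1, 1, 0)
  left <- shift_mat(m * 1, 0, -1); right <- shift_mat(m * 1, 0, 1)
  interior <- up == 1 & down == 1 & left == 1 & right == 1
  # border pixels always have a background neighbour (outside the image)
  interior[1, ] <- FALSE; interior[nrow(m), ] <- FALSE
  interior[, 1] <- FALSE; interior[, ncol(m)] <- FALSE
  m & !interior
}

#' Decompose a skeleton into vessel branches
#'
#' Splits the one-pixel skeleton at junction pixels (three or more skeleton
#' 8-neighbours) into branches running endpoint-to-junction,
#' junction-to-junction, or endpoint-to-endpoint. The geodesic length is the
#' 8-connected weighted path length (orthogonal step 1, diagonal step
#' \eqn{\sqrt 2}); the Euclidean length is the straight-line distance between
#' the branch termini. Branches shorter than `min_length_px` are discarded.
#'
#' @param skeleton_mask Logical matrix, one pixel wide (thicker input is
#'   re-thinned with a warning).
#' @param min_length_px Minimum geodesic length retained (default 5).
#'
#' @return A list of `skeleton_branch` objects with fields `path` (n x 2
#'   matrix of row/col coordinates), `endpoints`, `geodesic_length`, and
#'   `euclidean_length`.
#' @export
extract_branches <- function(skeleton_mask, min_length_px = 5) {
  m <- skeleton_mask & TRUE
  if (!any(m)) return(list())
  # a 1-px-wide skeleton has no 2x2 solid block
  blocks <- m & shift_mat(m, 1, 0) & shift_mat(m, 0, 1) & shift_mat(m, 1, 1)
  if (any(blocks)) {
    m2 <- skeletonize_vessels(m)
    if (!identical(m2, m)) {
      warning("skeleton wider than 1 px in places; thinning again")
      m <- m2
    }
  } else {
    m <- prune_redundant_corners(m)
  }
  # pad so neighbour arithmetic never leaves the index space
  padded <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  padded[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  m <- padded
  # junctions by crossing number: >= 3 distinct arms leave the pixel; pixels
  # of irreducible 2x2 blocks (X-crossing centres) count as junctions too
  blk <- m & shift_mat(m, 1, 0) & shift_mat(m, 0, 1) & shift_mat(m, 1, 1)
  blk <- blk | shift_mat(blk, -1, 0) | shift_mat(blk, 0, -1) | shift_mat(blk, -1, -1)
  junctions <- m & (transition_count8(m) >= 3 | blk)
  segs <- m & !junctions
  if (!any(segs)) return(list())
  nr <- nrow(m)
  seg_idx <- which(segs)
  vmap <- integer(length(m)); vmap[seg_idx] <- seq_along(seg_idx)
  jun <- as.vector(junctions)
  sv <- as.vector(segs)
  edges <- NULL; weights <- NULL
  # orthogonal neighbours: always linked
  for (off in c(1L, nr)) {
    a <- seg_idx[sv[seg_idx + off]]
    if (length(a)) {
      edges <- rbind(edges, cbind(vmap[a], vmap[a + off]))
      weights <- c(weights, rep(1, length(a)))
    }
  }
  # diagonal neighbours: linked unless the link squeezes past a junction pixel
  # (otherwise arms meeting at a removed junction reconnect around it)
  for (off in c(nr + 1L, nr - 1L)) {
    corner1 <- if (off == nr + 1L) 1L else -1L
    a <- seg_idx[sv[seg_idx + off]]
    if (length(a)) {
      ok <- !(jun[a + corner1] | jun[a + off - corner1])
      a <- a[ok]
      if (length(a)) {
        edges <- rbind(edges, cbind(vmap[a], vmap[a + off]))
        weights <- c(weights, rep(sqrt(2), length(a)))
      }
    }
  }
  g <- igraph::make_empty_graph(n = length(seg_idx), directed = FALSE)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(edges))
    igraph::E(g)$weight <- weights
  }
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    pix <- seg_idx[vids]
    if (length(pix) == 1) {
      path <- cbind(((pix - 1) %% nr) + 1, ((pix - 1) %/% nr) + 1) - 1L
      br <- list(path = path, endpoints = path[c(1, 1), , drop = FALSE],
                 geodesic_length = 0, euclidean_length = 0)
    } else {
      sub <- igraph::induced_subgraph(g, vids)
      d1 <- igraph::distances(sub, v = 1)[1, ]
      u <- which.max(d1)
      du <- igraph::distances(sub, v = u)[1, ]
      v <- which.max(du)
      sp <- igraph::shortest_paths(sub, from = u, to = v,
                                   output = "vpath")$vpath[[1]]
      order_idx <- pix[as.integer(sp)]
      path <- cbind(((order_idx - 1) %% nr) + 1,
                    ((order_idx - 1) %/% nr) + 1) - 1L
      for (piece in split_at_hairpins(path)) {
        ep <- piece[c(1, nrow(piece)), , drop = FALSE]
        br <- list(path = piece, endpoints = ep,
                   geodesic_length = polyline_length_smoothed(piece),
                   euclidean_length = sqrt(sum((ep[1, ] - ep[2, ])^2)))
        class(br) <- "skeleton_branch"
        if (br$geodesic_length >= min_length_px) out[[length(out) + 1]] <- br
      }
      next
    }
    class(br) <- "skeleton_branch"
    if (br$geodesic_length >= min_length_px) out[[length(out) + 1]] <- br
  }
  out
}

# Medial-axis paths through tangential vessel merges double back in a hairpin
# no anatomical vessel follows; split such paths at direction reversals
# sharper than `max_turn` so each piece is a plausible vessel course.
split_at_hairpins <- function(path, w = 4, max_turn = 100 * pi / 180) {
  n <- nrow(path)
  if (n < 2 * w + 3) return(list(path))
  idx <- (w + 1):(n - w)
  vin <- path[idx, , drop = FALSE] - path[idx - w, , drop = FALSE]
  vout <- path[idx + w, , drop = FALSE] - path[idx, , drop = FALSE]
  dot <- rowSums(vin * vout)
  ang <- acos(pmin(1, pmax(-1, dot / (sqrt(rowSums(vin^2) * rowSums(vout^2)) + 1e-12))))
  sharp <- idx[ang > max_turn]
  if (!length(sharp)) return(list(path))
  cuts <- sharp[c(TRUE, diff(sharp) > w)]  # one cut per reversal
  bounds <- unique(c(1, cuts, n))
  out <- list()
  for (k in seq_len(length(bounds) - 1)) {
    seg <- path[bounds[k]:bounds[k + 1], , drop = FALSE]
    if (nrow(seg) >= 2) out[[length(out) + 1]] <- seg
  }
  out
}

# Geodesic length of a pixel path: length of the polyline after a light
# moving-average smoothing of the interior vertices (endpoints fixed). Exact
# for collinear paths and unbiased for rasterized arcs, unlike the raw
# (1, sqrt 2) chain length, which overestimates smooth curves by 3-8%
# depending on orientation.
polyline_length_smoothed <- function(path, window = 5) {
  n <- nrow(path)
  if (n < window + 2) {
    return(sum(sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)))
  }
  k <- stats::filter(path, rep(1 / window, window), sides = 2)
  sm <- path * 1
  inner <- (1 + (window - 1) / 2):(n - (window - 1) / 2)
  sm[inner, ] <- k[inner, ]
  sum(sqrt(diff(sm[, 1])^2 + diff(sm[, 2])^2))
}

#' Per-pixel local fractal-dimension map
#'
#' For each pixel, the box-counting dimension of the vessel mask inside a
#' centred `window_px` window: the least-squares slope of \eqn{\log N(s)}
#' against \eqn{\log(1/s)} over dyadic box sizes, divided by 2 (the maximal
#' planar dimension) so values lie in `[0, 1]`. Windows without vessel pixels
#' score 0; fully vessel-filled windows score 1.
#'
#' @param vessel_mask Logical matrix.
#' @param window_px Window side, a power of two not exceeding the image side
#'   (default 16).
#' @return Numeric matrix of local fractal dimensions in `[0, 1]`.
#' @export
local_fd_map <- function(vessel_mask, window_px = 16) {
  w <- as.integer(window_px)
  if (bitwAnd(w, w - 1L) != 0L || w < 2L) stop("window_px must be a power of 2")
  m <- vessel_mask & TRUE
  if (w > min(dim(m))) stop("window_px larger than image")
  nr <- nrow(m); nc <- ncol(m)
  pad <- w  # anchors may fall up to w-1 outside
  big <- matrix(0, nr + 2 * pad, nc + 2 * pad)
  big[pad + seq_len(nr), pad + seq_len(nc)] <- m * 1
  sizes <- 2^(0:log2(w))
  # occupancy of s x s blocks anchored at each pixel, by dyadic doubling
  occ <- big
  counts <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    s <- sizes[k]
    if (s > 1) {
      h <- s %/% 2L
      occ <- pmax(occ, shift_mat(occ, -h, 0))
      occ <- pmax(occ, shift_mat(occ, 0, -h))
      occ <- pmin(occ, 1)
    }
    # number of occupied s-tiles in the w-window anchored at each pixel
    cs <- occ
    t <- s
    while (t < w) {
      cs <- cs + shift_mat(cs, -t, 0)
      t <- t * 2L
    }
    t <- s
    cs2 <- cs
    while (t < w) {
      cs2 <- cs2 + shift_mat(cs2, 0, -t)
      t <- t * 2L
    }
    counts[[k]] <- cs2
  }
  # centred window anchor for pixel (r, c): top-left at (r - w/2 + 1, c - w/2 + 1)
  a0 <- pad - w %/% 2L + 2L
  rows <- a0 + seq_len(nr) - 1L
  cols <- a0 + seq_len(nc) - 1L
  x <- log(1 / sizes)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  num <- matrix(0, nr, nc)
  ysum <- matrix(0, nr, nc)
  ns <- lapply(counts, function(cm) cm[rows, cols, drop = FALSE])
  occupied <- ns[[1]] > 0
  for (k in seq_along(sizes)) {
    y <- log(pmax(ns[[k]], 1))
    num <- num + xc[k] * y
  }
  fd <- num / sxx / 2
  fd[!occupied] <- 0
  fd[fd < 0] <- 0
  fd[fd > 1] <- 1
  fd
}
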