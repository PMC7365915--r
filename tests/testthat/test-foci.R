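# Brute-force re-check of the three criteria on a constructed image,
# independent of the detector's labeling and distance-transform code.
brute_force_foci <- function(frame, cfg = foci_config()) {
  v <- frame$intensities
  mask <- frame$mask
  nr <- nrow(mask); nc <- ncol(mask)
  thr <- (1 + cfg$intensity_excess) * mean(v[mask])
  bw <- mask & v > thr
  # flood-fill labeling (8-connected)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  neighbors8 <- function(q) {
    i <- (q - 1L) %% nr + 1L
    j <- (q - 1L) %/% nr + 1L
    di <- rep(-1:1, 3); dj <- rep(-1:1, each = 3)
    ii <- i + di; jj <- j + dj
    ok <- (di != 0 | dj != 0) & ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    ii[ok] + (jj[ok] - 1L) * nr
  }
  for (p in which(bw)) {
    if (lab[p] > 0L) next
    nxt <- nxt + 1L
    frontier <- p
    lab[p] <- nxt
    while (length(frontier)) {
      nbr <- unique(unlist(lapply(frontier, neighbors8)))
      nbr <- nbr[bw[nbr] & lab[nbr] == 0L]
      lab[nbr] <- nxt
      frontier <- nbr
    }
  }
  # edge pixels: in-mask with an out-of-mask 4-neighbor (border counts)
  fg <- which(mask)
  fi <- (fg - 1L) %% nr + 1L
  fj <- (fg - 1L) %/% nr + 1L
  interior <- vapply(seq_along(fg), function(t) {
    i <- fi[t]; j <- fj[t]
    i > 1 && i < nr && j > 1 && j < nc &&
      mask[i - 1L, j] && mask[i + 1L, j] && mask[i, j - 1L] && mask[i, j + 1L]
  }, logical(1))
  ei <- fi[!interior]
  ej <- fj[!interior]
  count <- 0L
  for (l in seq_len(max(lab))) {
    pix <- which(lab == l)
    if (length(pix) <= cfg$min_area_px) next
    pi_ <- (pix - 1L) %% nr + 1L
    pj <- (pix - 1L) %/% nr + 1L
    dmin <- min(vapply(seq_along(pix), function(t) {
      sqrt(min((pi_[t] - ei)^2 + (pj[t] - ej)^2))
    }, numeric(1)))
    if (dmin <= cfg$edge_dist_px) count <- count + 1L
  }
  count
}

# Standard geometry: 200x200 image, disk mask of radius 95 centered at
# (100.5, 100.5). A 12x12 square at (cy = 100, cx = 189) lies fully in the
# mask with its outer column ~1 px from the cell edge.
edge_blob <- function(side = 12, intensity = 2) {
  list(cx = 189, cy = 100, side = side, intensity = intensity)
}

test_that("a qualifying blob is detected and single-criterion violations are not", {
  ok <- make_foci_frames(list(edge_blob()))
  expect_identical(ok$truth$area_px[1], 144L)
  expect_lte(ok$truth$min_edge_dist[1], 5)
  expect_true(ok$truth$qualifies[1])
  r <- detect_foci(ok$frames[[1]])
  expect_identical(r$n_foci, 1L)
  expect_identical(brute_force_foci(ok$frames[[1]]), 1L)
  expect_identical(r$regions[[1]]$area, 144L)

  # too small: 8x8 = 64 px
  small <- make_foci_frames(list(edge_blob(side = 8)))
  expect_identical(detect_foci(small$frames[[1]])$n_foci, 0L)
  expect_identical(brute_force_foci(small$frames[[1]]), 0L)
  expect_false(small$truth$qualifies[1])

  # too far from the edge: centered in the disk
  center <- make_foci_frames(list(list(cx = 100, cy = 100, side = 12,
                                       intensity = 2)))
  expect_gt(center$truth$min_edge_dist[1], 20)
  expect_identical(detect_foci(center$frames[[1]])$n_foci, 0L)
  expect_identical(brute_force_foci(center$frames[[1]]), 0L)

  # too dim: below the 60%-above-mean threshold
  dim_ <- make_foci_frames(list(edge_blob(intensity = 1.5)))
  expect_identical(detect_foci(dim_$frames[[1]])$n_foci, 0L)
  expect_false(dim_$truth$meets_intensity[1])
})

test_that("pixel sets of injected foci are recovered exactly", {
  fx <- make_foci_frames(list(edge_blob(intensity = 2),
                              list(cx = 100, cy = 12, side = 12,
                                   intensity = 3)))
  r <- detect_foci(fx$frames[[1]])
  expect_identical(r$n_foci, 2L)
  bright <- sort(which(fx$frames[[1]]$intensities > 1.9))
  expect_identical(sort(unlist(lapply(r$regions, `[[`, "pixels"))), bright)
})

test_that("the strict area boundary separates 100 from 101 pixels", {
  at100 <- make_foci_frames(list(edge_blob(side = 10)))  # rows 95..104, cols 184..193
  expect_identical(at100$truth$area_px[1], 100L)
  expect_identical(detect_foci(at100$frames[[1]])$n_foci, 0L)  # strict >
  fr <- at100$frames[[1]]
  fr$intensities[105, 184] <- 2  # one 8-connected extra pixel: area 101
  expect_identical(detect_foci(fr)$n_foci, 1L)
})

test_that("detection is invariant to positive rescaling of in-mask intensity", {
  blobs <- list(edge_blob(intensity = 2),
                list(cx = 100, cy = 188, side = 14, intensity = 2.5))
  fx <- make_foci_frames(blobs, noise_sd = 0.05, seed = 24)
  fr <- fx$frames[[1]]
  r1 <- detect_foci(fr)
  expect_gte(r1$n_foci, 1L)
  fr2 <- fr
  fr2$intensities[fr2$mask] <- fr2$intensities[fr2$mask] * 7.3
  r2 <- detect_foci(fr2)
  expect_identical(r1$n_foci, r2$n_foci)
  expect_identical(lapply(r1$regions, `[[`, "pixels"),
                   lapply(r2$regions, `[[`, "pixels"))
})

test_that("normalization maps the dim 5% of the cell to at most 1", {
  # in-mask values 1..100, one pixel each: 5th percentile (nearest rank) = 5
  mask <- matrix(FALSE, 20, 20)
  mask[3:12, 3:12] <- TRUE
  v <- matrix(0, 20, 20)
  v[mask] <- 1:100
  fr <- ratiometric_frame(v, mask)
  nf <- normalize_frame(fr)
  expect_equal(nf$intensities[mask], (1:100) / 5)
  expect_identical(sum(nf$intensities[mask] <= 1), 5L)
  expect_identical(nf$intensities[!mask], v[!mask])  # out-of-mask untouched

  # constant cell: everything becomes 1
  v2 <- matrix(0, 20, 20); v2[mask] <- 4.2
  nf2 <- normalize_frame(ratiometric_frame(v2, mask))
  expect_true(all(nf2$intensities[mask] == 1))

  # idempotent once the baseline is 1
  nf3 <- normalize_frame(nf2)
  expect_equal(nf3$intensities, nf2$intensities, tolerance = 1e-12)

  v3 <- matrix(0, 20, 20)
  expect_error(normalize_frame(ratiometric_frame(v3, mask)), "not positive")
})

test_that("connected-component labeling honors 4- vs 8-connectivity", {
  bw <- matrix(FALSE, 5, 5)
  bw[2, 2] <- bw[3, 3] <- TRUE  # diagonal touch
  expect_identical(max(prwmix:::label_components(bw, 8L)), 1L)
  expect_identical(max(prwmix:::label_components(bw, 4L)), 2L)
})

test_that("frame-count selection maximizes frames x cells", {
  brute <- function(lengths) {
    cand <- seq_len(max(lengths))
    score <- vapply(cand, function(n) n * sum(lengths >= n), numeric(1))
    max(cand[score == max(score)])
  }
  expect_identical(select_frame_count(c(10, 8, 5)), 8L)
  expect_identical(select_frame_count(c(10, 8, 5)), brute(c(10, 8, 5)))
  expect_identical(select_frame_count(c(7, 7, 7)), 7L)
  expect_identical(select_frame_count(12), 12L)
  set.seed(25)
  for (i in 1:20) {
    lens <- sample(1:30, sample(1:8, 1), replace = TRUE)
    expect_identical(select_frame_count(lens), brute(lens))
  }
  expect_error(select_frame_count(integer(0)), "non-empty")
})

test_that("per-state grouping of foci counts is faithful bookkeeping", {
  g <- foci_by_state(c(1, 3, 1, 4), c(1, 2, 1, 2))
  expect_identical(g$by_state[["1"]], c(1, 1))
  expect_identical(g$by_state[["2"]], c(3, 4))
  expect_equal(sum(unlist(g$by_state)), sum(c(1, 3, 1, 4)))

  all1 <- foci_by_state(c(2, 2), c(1, 1))
  expect_null(all1$by_state[["2"]])
  expect_error(foci_by_state(1:3, 1:2), "aligned")

  # frames in the slow state carry systematically more injected foci
  edge_sites <- list(c(189, 100), c(100, 12), c(12, 100))
  counts <- integer(6)
  states <- rep(c(1L, 2L), 3)
  for (i in seq_along(states)) {
    nb <- if (states[i] == 1L) 1L else 3L
    blobs <- lapply(seq_len(nb), function(b) {
      list(cx = edge_sites[[b]][1], cy = edge_sites[[b]][2], side = 12,
           intensity = 2.5)
    })
    counts[i] <- detect_foci(make_foci_frames(blobs)$frames[[1]])$n_foci
  }
  g2 <- foci_by_state(counts, states)
  expect_gt(g2$summary$mean[g2$summary$state == "2"],
            g2$summary$mean[g2$summary$state == "1"])
})
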