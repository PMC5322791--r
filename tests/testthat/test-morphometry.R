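test_that("distance map is the exact Euclidean transform", {
  single <- matrix(FALSE, 7, 7); single[4, 4] <- TRUE
  expect_equal(distance_map(single)[4, 4], 1)

  # solid disc of radius 10: centre value within half a pixel of 10
  rr <- matrix(rep(1:25, 25), 25); cc <- t(rr)
  disc <- (rr - 13)^2 + (cc - 13)^2 <= 10^2
  expect_lt(abs(distance_map(disc)[13, 13] - 10), 0.51)
  expect_equal(distance_map(disc), brute_edt(disc))

  set.seed(31)
  for (k in 1:10) {
    m <- matrix(runif(400) < 0.55, 20)
    expect_equal(distance_map(m), brute_edt(m))
  }

  # all-foreground image: the border acts as background
  full <- matrix(TRUE, 9, 9)
  expect_equal(distance_map(full), brute_edt(full))
  expect_equal(distance_map(full)[5, 5], 5)
})

test_that("junction thickness measures the crotch disc; bars have none", {
  bar <- matrix(FALSE, 20, 60); bar[8:13, 5:55] <- TRUE
  ms <- suppressWarnings(measure_thallus(bar))
  expect_equal(nrow(ms$da), 0L)

  gt <- generate_thallus(thallus_spec(depth = 1, branch_length = 80,
                                      width_junction = 15, width_branch = 15,
                                      width_terminal = 15,
                                      branch_angle = 90, seed = 1))
  ms <- measure_rooted(gt)
  expect_equal(nrow(ms$da), 1L)
  expect_lt(abs(ms$da$diameter_px - gt$truth$junctions$da_true), 2)
  # disc centre lies on the skeleton, disc inside the foreground
  expect_true(ms$skeleton$mask[ms$da$row, ms$da$col])
})

test_that("terminal thickness is twice the EDT at each tip", {
  single <- matrix(FALSE, 7, 7); single[4, 4] <- TRUE
  ms <- suppressWarnings(measure_thallus(single))
  expect_equal(ms$dc$diameter_px, 2)

  gt <- generate_thallus(thallus_spec(depth = 1, seed = 2))
  ms <- measure_rooted(gt)
  expect_equal(nrow(ms$dc), 3L)  # two branch tips plus the base
})

test_that("branch thickness walks non-overlapping discs along edges", {
  # constant-width horizontal bar, 11 px wide
  bar <- matrix(FALSE, 25, 120); bar[8:18, 6:114] <- TRUE
  ms <- suppressWarnings(measure_thallus(bar))
  expect_gt(nrow(ms$db), 3L)
  expect_true(all(abs(ms$db$diameter_px - 11) <= 2))
  # greedy tangent placement: centres about one diameter apart
  centers <- ms$db[order(ms$db$col), c("row", "col")]
  gaps <- sqrt(diff(centers$col)^2 + diff(centers$row)^2)
  expect_true(all(gaps > 7 & gaps < 16))
  # every disc lies inside the foreground (1 px discretization slack)
  dm <- ms$distance_map
  expect_true(all(ms$db$diameter_px / 2 <= dm[cbind(ms$db$row, ms$db$col)] + 1))

  # tapered bar: db sequence decreases along the walk
  taper <- matrix(FALSE, 40, 160)
  for (j in 10:150) {
    w <- 21 - (j - 10) * (16 / 140)
    taper[round(20 - w / 2):round(20 + w / 2), j] <- TRUE
  }
  mt <- suppressWarnings(measure_thallus(taper, prune = FALSE))
  db <- mt$db[order(mt$db$col), ]
  if (db$col[1] > db$col[nrow(db)]) db <- db[nrow(db):1, ]
  expect_gte(nrow(db), 4L)
  expect_true(all(diff(db$diameter_px) <= 2))
  expect_lt(db$diameter_px[nrow(db)], db$diameter_px[1])
})

test_that("an edge shorter than the parent disc yields no db discs", {
  dm <- matrix(5, 9, 9)
  vdf <- data.frame(id = 1:2, row = c(5, 5), col = c(4, 6),
                    kind = "terminal", component = 1, is_root = c(TRUE, FALSE))
  g <- structure(list(
    vertices = vdf,
    vertex_pixels = list(cbind(5, 4), cbind(5, 6)),
    edges = list(list(id = 1L, v1 = 1L, v2 = 2L,
                      path = cbind(row = 5, col = 5),
                      parent = 1L, closes_cycle = FALSE)),
    root = 1L, dims = c(9, 9)), class = "skeleton_graph")
  expect_equal(nrow(branch_thickness(dm, g)), 0L)
})

test_that("branch lengths report pixel-path and chord lengths", {
  m <- matrix(FALSE, 7, 40)
  m[4, 4:34] <- TRUE   # 31 px line: endpoints 30 apart, 29 interior
  g <- build_graph(classify_features(skeleton_image(m)))
  bl <- branch_length(g)
  expect_equal(bl$chord_length, 30)
  expect_equal(bl$pixel_path_length, 29)

  # 3-4-5 diagonal chord via a hand-built graph
  vdf <- data.frame(id = 1:2, row = c(1, 4), col = c(1, 5),
                    kind = "terminal", component = 1, is_root = c(TRUE, FALSE))
  gh <- structure(list(vertices = vdf,
                       vertex_pixels = list(cbind(1, 1), cbind(4, 5)),
                       edges = list(list(id = 1L, v1 = 1L, v2 = 2L,
                                         path = matrix(0L, 0, 2),
                                         parent = 1L, closes_cycle = FALSE)),
                       root = 1L, dims = c(5, 6)), class = "skeleton_graph")
  expect_equal(branch_length(gh)$chord_length, 5)

  # meandering path: pixel count >= chord and equals a re-walk of the path
  gt <- generate_thallus(thallus_spec(depth = 2, branch_angle = 100, seed = 3))
  ms <- measure_rooted(gt)
  expect_true(all(ms$bl$pixel_path_length + 1 >= ms$bl$chord_length - 1))
  g <- ms$graph
  expect_equal(ms$bl$pixel_path_length,
               vapply(g$edges, function(e) nrow(e$path), 1L))
})

test_that("branch angles hit the textbook degenerate cases", {
  mk_graph <- function(p1, p2) {
    vdf <- data.frame(id = 1:3, row = c(10, p1[nrow(p1), 1], p2[nrow(p2), 1]),
                      col = c(10, p1[nrow(p1), 2], p2[nrow(p2), 2]),
                      kind = c("junction", "terminal", "terminal"),
                      component = 1, is_root = FALSE)
    structure(list(vertices = vdf,
                   vertex_pixels = list(cbind(10, 10),
                                        p1[nrow(p1), , drop = FALSE],
                                        p2[nrow(p2), , drop = FALSE]),
                   edges = list(
                     list(id = 1L, v1 = 1L, v2 = 2L,
                          path = p1[-nrow(p1), , drop = FALSE],
                          parent = 1L, closes_cycle = FALSE),
                     list(id = 2L, v1 = 1L, v2 = 3L,
                          path = p2[-nrow(p2), , drop = FALSE],
                          parent = 1L, closes_cycle = FALSE)),
                   root = 2L, dims = c(40, 40)), class = "skeleton_graph")
  }
  dm <- matrix(2, 40, 40)
  east <- cbind(10, 11:25); west <- cbind(10, 9:1)
  g180 <- mk_graph(east, west)
  a <- branch_angle(g180, dm)
  expect_equal(a$angle_deg, 180, tolerance = 1e-6)

  g0 <- mk_graph(cbind(10, 11:25), cbind(10, 11:25))
  a0 <- branch_angle(g0, dm)
  expect_lt(a0$angle_deg, 1e-6)
  expect_true(all(a0$angle_deg >= 0 & a0$angle_deg <= 180))
})

test_that("terminal spacing is the nearest-tip distance", {
  mk_tips <- function(coords) {
    vdf <- data.frame(id = seq_len(nrow(coords)), row = coords[, 1],
                      col = coords[, 2], kind = "terminal",
                      component = 1, is_root = FALSE)
    structure(list(vertices = vdf,
                   vertex_pixels = lapply(seq_len(nrow(coords)), function(i)
                     coords[i, , drop = FALSE]),
                   edges = list(), root = 1L, dims = c(200, 200)),
              class = "skeleton_graph")
  }
  bs <- terminal_spacing(mk_tips(rbind(c(1, 1), c(4, 5), c(101, 101))))
  # nearest other tip of (101,101) is (4,5): sqrt(97^2 + 96^2) = 136.4734
  expect_equal(bs$distance_px, c(5, 5, sqrt(97^2 + 96^2)))
  expect_equal(bs$distance_px[3], 136.4734, tolerance = 1e-4)

  two <- terminal_spacing(mk_tips(rbind(c(1, 1), c(7, 9))))
  expect_equal(two$distance_px[1], two$distance_px[2])

  expect_warning(one <- terminal_spacing(mk_tips(rbind(c(1, 1)))),
                 "fewer than two")
  expect_equal(nrow(one), 0L)
})

test_that("apply_scale converts lengths and leaves angles alone", {
  gt <- generate_thallus(thallus_spec(depth = 1, seed = 6))
  ms <- measure_rooted(gt)
  s1 <- apply_scale(ms, 1)
  expect_equal(s1$means_scaled, s1$means)

  # an 80 px junction disc at 0.005 mm/px is a 0.4 mm thallus axis
  expect_equal(80 * 0.005, 0.4)
  sc <- apply_scale(ms, 0.005)
  expect_equal(sc$da$diameter_scaled, sc$da$diameter_px * 0.005)
  expect_equal(sc$means_scaled[["ba"]], ms$means[["ba"]])
  expect_equal(sc$means_scaled[["da"]], ms$means[["da"]] * 0.005)
  expect_error(apply_scale(ms, 0), "positive")
  expect_error(apply_scale(ms, -2), "positive")
})

test_that("measurements recover generator ground truth across the battery", {
  # widths x lengths at the realistic 120 degree opening, plus the three
  # openings at a thin width; sharp crotches at large widths put the whole
  # junction zone inside the branch and are excluded by design
  cases <- rbind(
    expand.grid(w = c(7, 11, 15, 21), L = c(40, 80), th = 120),
    expand.grid(w = 7, L = 80, th = c(60, 90))
  )
  for (i in seq_len(nrow(cases))) {
    w <- cases$w[i]; L <- cases$L[i]; th <- cases$th[i]
    gt <- generate_thallus(thallus_spec(depth = 1, branch_length = L,
                                        width_junction = w, width_branch = w,
                                        width_terminal = w, branch_angle = th,
                                        seed = 1))
    ms <- measure_rooted(gt)
    lbl <- sprintf("w=%d L=%d th=%d", w, L, th)
    expect_lt(abs(mean(ms$da$diameter_px) - mean(gt$truth$junctions$da_true)),
              2, label = paste("da", lbl))
    expect_lt(abs(mean(ms$db$diameter_px) - w), 2, label = paste("db", lbl))
    expect_lt(abs(mean(ms$dc$diameter_px) - mean(gt$truth$tips$dc_true)),
              2, label = paste("dc", lbl))
    expect_lt(abs(mean(ms$ba$angle_deg) -
                    mean(gt$truth$junctions$sibling_angle)),
              5, label = paste("ba", lbl))
    bl_true <- mean(gt$truth$branches$skeleton_length_true)
    expect_lt(abs(mean(ms$bl$arc_length) - bl_true) / bl_true, 0.05,
              label = paste("bl", lbl))
    expect_lt(abs(mean(ms$bs$distance_px) - mean(gt$truth$tips$bs_true)),
              2, label = paste("bs", lbl))
  }
})

test_that("tapered thalli show the junction > branch > terminal ordering", {
  for (sd in 1:3) {
    gt <- generate_thallus(thallus_spec(depth = 2, branch_angle = 100 + 5 * sd,
                                        seed = sd))
    ms <- measure_rooted(gt)
    expect_gt(ms$means[["da"]], ms$means[["db"]])
    expect_gt(ms$means[["db"]], ms$means[["dc"]])
  }
})

test_that("measurements are stable under a 90 degree rotation", {
  # a reasonably large specimen, so per-variable means pool enough local
  # measurements that one disc more or fewer cannot dominate
  gt <- generate_thallus(thallus_spec(depth = 2, branch_length = 95,
                                      branch_angle = 105, seed = 10))
  m1 <- suppressWarnings(measure_thallus(gt$image))
  rot <- t(gt$image$mask[nrow(gt$image$mask):1, ])
  m2 <- suppressWarnings(measure_thallus(rot))
  for (v in c("da", "db", "dc", "bl", "bs"))
    expect_lt(abs(m1$means[[v]] - m2$means[[v]]) / m1$means[[v]], 0.05,
              label = v)
  expect_lt(abs(m1$means[["ba"]] - m2$means[["ba"]]), 5)
})
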