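test_that("kabsch superposition is exact on rigid copies and fixed cases", {
  set.seed(20)
  X <- matrix(rnorm(30, sd = 4), 10, 3)
  fit <- kabsch_superpose(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$R, diag(3), tolerance = 1e-9)

  R <- rotation_about(c(1, 2, 0.5), 30)
  Y <- sweep(X %*% t(R), 2, c(5, -3, 11), `+`)
  expect_lt(kabsch_superpose(X, Y)$rmsd, 1e-9)

  # fixed 4-point pair: value frozen from the quaternion-grid oracle
  X4 <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 1.2), 4, 3,
               byrow = TRUE)
  Y4 <- matrix(c(0.1, 0, 0, 1.2, 0.1, -0.2, -0.1, 1.1, 0.3, 0.5, 0.2, 1.0),
               4, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(X4, Y4)$rmsd, 0.14246097, tolerance = 1e-4)
  expect_equal(kabsch_superpose(X4, Y4)$rmsd, oracle_rmsd_grid(X4, Y4),
               tolerance = 1e-4)
  expect_error(kabsch_superpose(X[0, , drop = FALSE], X[0, , drop = FALSE]),
               "no points")
})

test_that("superposition excludes reflections and handles degenerate sets", {
  set.seed(21)
  for (i in 1:10) {
    Z <- matrix(rnorm(15, sd = 3), 5, 3)
    fit <- kabsch_superpose(Z, -Z)
    expect_equal(det(fit$R), 1, tolerance = 1e-9)
    expect_equal(fit$rmsd, oracle_rmsd_quaternion(Z, -Z), tolerance = 1e-8)
  }
  # collinear points: residual still defined and optimal
  line <- cbind(0:4 * 1.5, 0, 0)
  tilted <- cbind(0, 0:4 * 1.5, 0)
  expect_lt(kabsch_superpose(line, tilted)$rmsd, 1e-9)
  # symmetry of the minimal residual
  set.seed(22)
  A <- matrix(rnorm(24), 8, 3); B <- matrix(rnorm(24), 8, 3)
  expect_equal(kabsch_superpose(A, B)$rmsd, kabsch_superpose(B, A)$rmsd,
               tolerance = 1e-9)
  # cross-check against an established implementation
  expect_equal(kabsch_superpose(A, B)$rmsd,
               bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE),
               tolerance = 1e-3)
})

test_that("self-comparison yields an all-zero matrix with the right count", {
  ch <- serpentine_rung(n_res = 25)
  m <- window_rmsd_matrix(ch, ch, min_window = 3)
  L <- 25
  expect_equal(nrow(m), (L - 3 + 1) * (L - 3 + 2) / 2)
  expect_lt(max(m$rmsd), 1e-9)
  expect_equal(localized_rmsd(m), 0, tolerance = 1e-9)
})

test_that("matrix entries respect segment boundaries and the count formula", {
  a <- random_chain(30, seed = 23)
  # remove an internal block from b so the correspondence has two segments
  keep <- c(1:12, 20:30)
  b <- residue_chain("B", a$resno[keep], a$aa[keep],
                     list(CA = a$xyz$CA[keep, ] + 0.1))
  corr <- correspond_by_numbering(a, b)
  expect_equal(max(corr$segment), 2L)
  m <- window_rmsd_matrix(a, b, corr, min_window = 4)
  count <- function(L, w) max(0, (L - w + 1) * (L - w + 2) / 2)
  expect_equal(nrow(m), count(12, 4) + count(11, 4))
  # no window crosses the gap
  expect_false(any(m$start_res <= a$resno[12] & m$end_res >= a$resno[20]))
})

test_that("matrix is symmetric in A/B and invariant to rigid motions", {
  a <- random_chain(18, seed = 24)
  b <- random_chain(18, seed = 25, chain_id = "B")
  m_ab <- window_rmsd_matrix(a, b)
  m_ba <- window_rmsd_matrix(b, a)
  expect_equal(m_ab$rmsd, m_ba$rmsd, tolerance = 1e-9)
  R <- rotation_about(c(0.2, -1, 0.7), 113)
  b_moved <- transform_chain(b, R, c(20, -7, 3))
  m_moved <- window_rmsd_matrix(a, b_moved)
  expect_equal(m_ab$rmsd, m_moved$rmsd, tolerance = 1e-9)
})

test_that("every entry matches the independent quaternion oracle", {
  for (seed in c(26, 27)) {
    a <- random_chain(24, seed = seed)
    b <- random_chain(24, seed = seed + 100, chain_id = "B")
    corr <- correspond_by_numbering(a, b)
    m <- window_rmsd_matrix(a, b, corr, min_window = 3)
    o <- oracle_window_matrix(a, b, corr, min_window = 3)
    expect_equal(nrow(m), nrow(o))
    key_m <- order(m$start_res, m$length)
    key_o <- order(o[, "start_res"], o[, "length"])
    expect_equal(m$rmsd[key_m], o[key_o, "rmsd"], tolerance = 1e-8)
  }
})

test_that("per-window optimum dominates residuals inherited from a superset", {
  set.seed(28)
  for (i in 1:8) {
    a <- random_chain(20, seed = 300 + i)
    b <- random_chain(20, seed = 400 + i, chain_id = "B")
    corr <- correspond_by_numbering(a, b)
    # big window W = 1..20, sub-window w = 5..12
    big <- kabsch_superpose(a$xyz$CA, b$xyz$CA)
    sub <- 5:12
    inherited <- sqrt(sum((a$xyz$CA[sub, ] - big$fitted[sub, ])^2) /
                        length(sub))
    optimal <- kabsch_superpose(a$xyz$CA[sub, ], b$xyz$CA[sub, ])$rmsd
    expect_lte(optimal, inherited + 1e-12)
  }
})

test_that("localized RMSD is the plain mean and is monotone", {
  a <- random_chain(15, seed = 29)
  b <- random_chain(15, seed = 30, chain_id = "B")
  m <- window_rmsd_matrix(a, b)
  expect_equal(localized_rmsd(m), mean(m$rmsd))
  m_up <- m
  m_up$rmsd <- m$rmsd + 0.5
  expect_gt(localized_rmsd(m_up), localized_rmsd(m))
  empty <- suppressWarnings(window_rmsd_matrix(
    random_chain(4, seed = 31), random_chain(4, seed = 32, chain_id = "B"),
    min_window = 5))
  expect_equal(nrow(empty), 0L)
  expect_error(localized_rmsd(empty), "no admissible windows")
})

test_that("region RMSD isolates exactly the named residue range", {
  a <- serpentine_rung(n_res = 60, first_resno = 300)
  b <- perturb_region(a, c(320, 340), 2, seed = 33)
  expect_equal(region_rmsd(a, b, start_res = 300, end_res = 315), 0,
               tolerance = 1e-9)
  expect_gt(region_rmsd(a, b, start_res = 320, end_res = 340), 0.3)
  # matches a single-window matrix entry
  corr <- correspond_by_numbering(a, b)
  idx <- match(320:340, corr$resnoA)
  direct <- kabsch_superpose(a$xyz$CA[corr$pairs[idx, 1], ],
                             b$xyz$CA[corr$pairs[idx, 2], ])$rmsd
  expect_equal(region_rmsd(a, b, start_res = 320, end_res = 340), direct)
  gap <- residue_chain("C", setdiff(300:359, 330L),
                       rep("A", 59), list(CA = a$xyz$CA[-31, ]))
  expect_error(region_rmsd(a, gap, start_res = 325, end_res = 335), "330")
})

test_that("fold ranking orders by localized RMSD with stable tie-breaks", {
  q <- serpentine_rung(n_res = 40)
  near <- perturb_region(q, c(280, 290), 0.6, seed = 34)
  far <- perturb_region(q, c(275, 310), 4.0, seed = 35)
  lib <- list(zelf = q, near = near, far = far)
  rk <- rank_folds(q, lib)
  expect_identical(rk$label, c("zelf", "near", "far"))
  expect_equal(rk$localized_rmsd[1], 0, tolerance = 1e-9)
  expect_true(all(diff(rk$localized_rmsd) >= 0))
  # identical copies under different labels tie, label order decides
  rk2 <- rank_folds(q, list(bb = q, aa = q))
  expect_identical(rk2$label, c("aa", "bb"))
  # a member with no shared numbering is incomparable, not dropped
  alien <- random_chain(20, seed = 36, first_resno = 900L)
  rk3 <- rank_folds(q, list(ok = near, off = alien))
  expect_identical(rk3$label, c("ok", "off"))
  expect_false(rk3$comparable[2])
})

test_that("matrix export and heat-map rendering write the expected files", {
  a <- serpentine_rung(n_res = 30)
  b <- perturb_region(a, c(285, 295), 2, seed = 37)
  m <- window_rmsd_matrix(a, b)
  tsv <- tempfile(fileext = ".tsv")
  write_rmsd_matrix(m, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_identical(names(back), c("start_res", "end_res", "length",
                                  "rmsd_A"))
  expect_equal(nrow(back), nrow(m))
  js <- tempfile(fileext = ".json")
  summ <- write_comparison_summary(m, js,
                                   motifs = list(bump = c(285, 295)))
  expect_equal(jsonlite::read_json(js)$localized_rmsd, mean(m$rmsd))
  expect_equal(summ$motifs$bump,
               m$rmsd[m$start_res == 285 & m$end_res == 295][1])
  out <- tempfile(fileext = ".png")
  files <- render_heatmap(m, out)
  expect_true(all(file.exists(files)))
  expect_match(files, "png|svg")
  empty <- suppressWarnings(window_rmsd_matrix(a, b, min_window = 31))
  expect_error(render_heatmap(empty, tempfile()), "empty matrix")
})
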