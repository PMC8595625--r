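def1 <- function(n) segment_definition(list(H = c(1, n)))

test_that("endpoint selection follows the 11-atom rule", {
  h <- make_ideal_helix(20, sequence = "A")
  d <- def1(20)
  ep_n <- endpoint_atoms(h, "H", "N", d)
  expect_equal(nrow(ep_n$atom_set), 11)
  # gap residue 1 skipped; window residues 2-5; C of residue 5 eliminated
  expect_equal(sort(unique(ep_n$atom_set$residue_number)), 2:5)
  expect_false(any(ep_n$atom_set$residue_number == 5 & ep_n$atom_set$atom_name == "C"))
  expect_true(all(ep_n$atom_set$atom_name %in% c("N", "CA", "C")))
  ep_c <- endpoint_atoms(h, "H", "C", d)
  expect_equal(nrow(ep_c$atom_set), 11)
  expect_equal(sort(unique(ep_c$atom_set$residue_number)), 16:19)
  expect_false(any(ep_c$atom_set$residue_number == 16 & ep_c$atom_set$atom_name == "N"))
  # endpoint equals the brute-force mean of the 11 selected coordinates
  expect_equal(ep_n$point,
               colMeans(h$coords[ep_n$indices, ]), tolerance = 1e-12)
  # rule independent of residue types
  h2 <- make_ideal_helix(20, sequence = "ADKSNEQR")
  expect_equal(nrow(endpoint_atoms(h2, "H", "N", d)$atom_set), 11)
  expect_error(endpoint_atoms(h, "H", "N",
                              segment_definition(list(H = c(1, 5)))),
               "fewer than 6")
  expect_error(endpoint_atoms(h, "H7", "N", d), "unknown segment")
})

test_that("helix angle matches axis-aligned, rotated and antiparallel cases", {
  expect_equal(helix_angle(c(0, 0, 1)), 0)
  expect_equal(helix_angle(c(0, 0, -1)), 180)
  expect_equal(helix_angle(c(1, 0, 0)), 90)
  expect_error(helix_angle(c(0, 0, 0)), "degenerate")

  # rotation-matrix oracle: measure the axis of a generated helix, rotate the
  # structure by a known rotation, and compare to the rotated measured axis
  h0 <- make_ideal_helix(24, tilt = 0)
  d <- def1(24)
  v0 <- helix_vector(h0, "H", d)$direction
  theta <- 30 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(theta), -sin(theta), 0, sin(theta), cos(theta)),
               3, 3, byrow = TRUE)
  hr <- h0
  hr$coords <- h0$coords %*% t(Rx)
  vr <- helix_vector(hr, "H", d)$direction
  oracle <- acos(max(-1, min(1, (Rx %*% v0)[3]))) * 180 / pi
  expect_equal(helix_angle(vr), oracle, tolerance = 1e-6)
})

test_that("helix angle is invariant under rotation about the membrane normal", {
  h <- make_ideal_helix(24, tilt = 35, azimuth = 10)
  d <- def1(24)
  a0 <- helix_angle(helix_vector(h, "H", d))
  for (az in c(17, 123, 299)) {
    t <- az * pi / 180
    Rz <- matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    hz <- h
    hz$coords <- h$coords %*% t(Rz)
    expect_equal(helix_angle(helix_vector(hz, "H", d)), a0, tolerance = 1e-9)
  }
})

test_that("alignment removes rigid motions and never increases fit RMSD", {
  b <- make_bundle(n_helices = 3)
  def <- attr(b, "definition")
  nfr <- 6
  base <- as.numeric(t(b$coords))
  sel <- atom_select(b, atom_names = "CA")
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  set.seed(5)
  # frames = reference translated and rotated rigidly
  xyz <- t(vapply(seq_len(nfr), function(f) {
    t3 <- stats::runif(3, -8, 8)
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
    co <- sweep(b$coords %*% t(R), 2, t3, `+`)
    as.numeric(t(co))
  }, numeric(length(base))))
  al <- align_to_reference(new_trajectory(b, xyz), b, definition = def)
  for (f in seq_len(nfr)) {
    dev <- matrix(al$xyz[f, cols] - base[cols], ncol = 3, byrow = TRUE)
    expect_lt(sqrt(mean(rowSums(dev^2))), 1e-6)
  }
  # noisy frames: post-alignment RMSD <= pre-alignment RMSD, and matches an
  # independent Kabsch oracle
  noisy <- make_noisy_trajectory(b, sigma = 0.1, n_frames = 5, seed = 9)
  shifted <- noisy
  shifted$xyz <- sweep(noisy$xyz, 2, rep(c(2, -1, 3), n_atoms(b)), `+`)
  al2 <- align_to_reference(shifted, b, definition = def)
  ref_sel <- b$coords[sel, ]
  for (f in seq_len(5)) {
    pre <- sqrt(mean(rowSums((matrix(shifted$xyz[f, cols], ncol = 3, byrow = TRUE) - ref_sel)^2)))
    post <- sqrt(mean(rowSums((matrix(al2$xyz[f, cols], ncol = 3, byrow = TRUE) - ref_sel)^2)))
    oracle <- kabsch_rmsd(matrix(shifted$xyz[f, cols], ncol = 3, byrow = TRUE), ref_sel)
    expect_lte(post, pre + 1e-12)
    expect_equal(post, oracle, tolerance = 1e-6)
  }
  expect_error(align_to_reference(noisy, b, selection = 1:2), "at least 3")
})

test_that("no-fit segment RMSD equals |t| under pure translation and a direct oracle otherwise", {
  h <- make_ideal_helix(12, sequence = "A")
  d <- def1(12)
  expect_equal(segment_rmsd_nofit(h$coords, h, "H", d), 0)
  shifted <- sweep(h$coords, 2, c(3, 4, 0), `+`)
  expect_equal(segment_rmsd_nofit(shifted, h, "H", d), 5.0, tolerance = 1e-12)
  # direct summation oracle on a random perturbation
  set.seed(2)
  pert <- h$coords + matrix(stats::rnorm(length(h$coords), sd = 0.4),
                            ncol = 3)
  idx <- atom_select(h, atom_names = c("C", "CA", "O", "N"))
  oracle <- sqrt(mean(rowSums((pert[idx, ] - h$coords[idx, ])^2)))
  expect_equal(segment_rmsd_nofit(pert, h, "H", d), oracle, tolerance = 1e-9)
})

test_that("no-fit RMSD under translation equals |t| for every bundle segment", {
  b <- make_bundle(n_helices = 4, pivot_helices = 2)
  def <- attr(b, "definition")
  shifted <- sweep(b$coords, 2, c(1, -2, 2), `+`)
  for (s in names(reporting_segments(def)))
    expect_equal(segment_rmsd_nofit(shifted, b, s, def), 3.0, tolerance = 1e-12)
})

test_that("RMSF matches the direct two-pass oracle and is translation invariant", {
  h <- make_ideal_helix(10, sequence = "A")
  tr <- make_noisy_trajectory(h, sigma = 0.25, n_frames = 40, seed = 4)
  rp <- rmsf_profile(tr)
  ca <- atom_select(h, atom_names = "CA")
  for (k in seq_along(ca)) {
    cols <- (3 * ca[k] - 2):(3 * ca[k])
    pos <- tr$xyz[, cols]
    mu <- colMeans(pos)
    oracle <- sqrt(mean(rowSums(sweep(pos, 2, mu)^2)))
    expect_equal(rp$rmsf[k], oracle, tolerance = 1e-9)
  }
  shifted <- tr
  shifted$xyz <- tr$xyz + 17.3
  expect_equal(rmsf_profile(shifted)$rmsf, rp$rmsf, tolerance = 1e-9)
  # static trajectory -> zero everywhere; single frame -> error
  static <- make_noisy_trajectory(h, sigma = 0, n_frames = 3, seed = 1)
  expect_true(all(rmsf_profile(static)$rmsf == 0))
  expect_error(rmsf_profile(make_noisy_trajectory(h, 0, 1, 1)), "at least 2")
})

test_that("angle/RMSD series covers every frame and segment and flags planted motion", {
  b <- make_bundle(n_helices = 3, pivot_helices = 3)
  def <- attr(b, "definition")
  tr <- make_noisy_trajectory(b, sigma = 0, n_frames = 4, seed = 1)
  s <- angle_rmsd_series(tr, b, def)
  segs <- names(reporting_segments(def))
  expect_equal(nrow(s), 4 * length(segs))
  expect_true(all(s$rmsd_A == 0))
  expect_true(all(s$angle_deg >= 0 & s$angle_deg <= 180))
  # 1-frame trajectory equal to the reference: angles equal reference angles
  ref_ang <- vapply(segs, function(sg)
    helix_angle(helix_vector(b, sg, def)), numeric(1))
  one <- angle_rmsd_series(make_noisy_trajectory(b, 0, 1, 1), b, def)
  expect_equal(one$angle_deg, unname(ref_ang[one$segment]), tolerance = 1e-9)

  # planted +10 degree tilt of TM1 from frame 11 onward
  tr2 <- make_noisy_trajectory(b, sigma = 0.02, n_frames = 20, seed = 8,
                               motions = list(list(segment = "TM1",
                                                   start_frame = 11, tilt = 10)),
                               definition = def)
  # frames carry no global motion, so the series is read off directly
  s2 <- angle_rmsd_series(tr2, b, def)
  tm1 <- s2[s2$segment == "TM1", ]
  jump <- mean(tm1$angle_deg[11:20]) - mean(tm1$angle_deg[1:10])
  expect_equal(abs(jump), 10, tolerance = 0.5)
  others <- s2[s2$segment != "TM1", ]
  drift <- tapply(others$angle_deg, others$segment,
                  function(a) mean(a[11:20]) - mean(a[1:10]))
  expect_true(all(abs(drift) < 0.5))
})
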