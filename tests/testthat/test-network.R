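planted_avg <- function(nres, pairs, mask_window = NA) {
  # build an avg_energy directly from a list of (i, j, value)
  m <- matrix(0, nres, nres)
  for (p in pairs) {
    m[p[1], p[2]] <- p[3]
    m[p[2], p[1]] <- p[3]
  }
  mask <- matrix(FALSE, nres, nres)
  diag(mask) <- TRUE
  structure(list(residues = data.frame(chain_id = "A",
                                       residue_number = seq_len(nres),
                                       residue_name = "ALA"),
                 mean = m, sem = 0 * m, n = 1, mask = mask,
                 meta = list(exclusion_window = NA_integer_)),
            class = "avg_energy")
}

test_that("residue-wise profile sums unmasked partners and conserves totals", {
  z <- planted_avg(3, list())
  expect_true(all(residue_wise(z)$energy == 0))
  one <- planted_avg(3, list(c(1, 3, -2)))
  expect_equal(residue_wise(one)$energy, c(-2, 0, -2))
  # random matrix against brute-force row sums; profile total = 2x pair total
  set.seed(12)
  pairs <- lapply(1:20, function(k) c(sample(10, 2), stats::rnorm(1)))
  rnd <- planted_avg(10, pairs)
  prof <- residue_wise(rnd)
  m <- rnd$mean
  m[rnd$mask] <- 0
  expect_equal(prof$energy, rowSums(m), tolerance = 1e-12)
  expect_equal(sum(prof$energy), 2 * unmasked_total(rnd), tolerance = 1e-9)
})

test_that("group matrix aggregates planted blocks and conserves the pair total", {
  def <- segment_definition(list(A = c(1, 5), B = c(6, 10), C = c(11, 15)))
  gb <- planted_avg(15, list(c(2, 8, -5)))
  gm <- group_matrix(gb, def)
  expect_equal(gm$groups, c("A", "B", "C"))
  expect_equal(gm$energy[1, 2], -5)
  expect_equal(sum(abs(gm$energy)) , 10)  # (A,B) and (B,A) only
  # conservation on a dense random matrix
  set.seed(13)
  pairs <- lapply(1:40, function(k) c(sample(15, 2), stats::rnorm(1)))
  rnd <- planted_avg(15, pairs)
  gm2 <- group_matrix(rnd, def)
  expect_equal(sum(gm2$energy[upper.tri(gm2$energy, diag = TRUE)]),
               unmasked_total(rnd), tolerance = 1e-9)
  # single group holds the whole total
  gm3 <- group_matrix(rnd, segment_definition(list(ALL = c(1, 15))))
  expect_equal(gm3$energy[1, 1], unmasked_total(rnd), tolerance = 1e-9)
  # residues outside every segment are collected into "other"
  part <- segment_definition(list(A = c(1, 5)))
  expect_message(gm4 <- group_matrix(rnd, part), "other")
  expect_true("other" %in% gm4$groups)
  expect_equal(sum(gm4$energy[upper.tri(gm4$energy, diag = TRUE)]),
               unmasked_total(rnd), tolerance = 1e-9)
})

test_that("difference network is zero on identical inputs and antisymmetric under swap", {
  set.seed(14)
  pairs <- lapply(1:15, function(k) c(sample(8, 2), stats::rnorm(1)))
  a <- planted_avg(8, pairs)
  expect_true(all(diff_network(a, a)$delta == 0))
  b <- planted_avg(8, lapply(1:15, function(k) c(sample(8, 2), stats::rnorm(1))))
  expect_equal(diff_network(a, b)$delta, -diff_network(b, a)$delta)
})

test_that("difference network recovers planted perturbations exactly", {
  wt <- planted_avg(10, list(c(2, 7, -3), c(3, 9, -1.5)))
  mut <- planted_avg(10, list(c(3, 9, -1.5)))    # pair (2,7) zeroed
  dn <- diff_network(wt, mut)
  expect_equal(dn$delta[2, 7], 3)
  d <- dn$delta
  d[2, 7] <- 0; d[7, 2] <- 0
  expect_true(all(d == 0))
  expect_equal(classify_diff(dn)[2, 7], "attractive-lost")
  # multi-pair planted set recovered identically to brute-force comparison
  set.seed(15)
  planted <- list(c(1, 5, 2), c(2, 8, -1.4), c(4, 10, 3.1))
  mut2 <- planted_avg(10, c(list(c(2, 7, -3)), planted))
  wt2 <- planted_avg(10, list(c(2, 7, -3)))
  dn2 <- diff_network(wt2, mut2)
  found <- diff_pairs(dn2, threshold = 1e-9)
  brute <- sort(vapply(planted, function(p)
    paste(min(p[1], p[2]), max(p[1], p[2])), character(1)))
  expect_equal(sort(paste(found$res_i, found$res_j)), brute)
  # unmatchable universes rejected
  expect_error(diff_network(wt, planted_avg(9, list())), "aligned")
})

test_that("significant residues are the thresholded |delta| set, ranked", {
  p <- data.frame(chain_id = "A", residue_number = 1:6,
                  energy = c(0, -2, 1, 0.4, -0.1, 3))
  expect_equal(nrow(significant_residues(p, p, threshold = 0.5)), 0)
  q <- p
  q$energy <- p$energy + c(0, -4, 0, 0, 0, 0)
  sig <- significant_residues(p, q, threshold = 1)
  expect_equal(sig$residue_number, 2)
  expect_equal(sig$delta, -4)
  expect_equal(sig$rank, 1)
  # random profiles against a brute-force filter
  set.seed(16)
  q2 <- p
  q2$energy <- p$energy + stats::rnorm(6, sd = 2)
  for (thr in c(0.5, 1, 2)) {
    sig2 <- significant_residues(p, q2, threshold = thr)
    brute <- which(abs(q2$energy - p$energy) >= thr)
    expect_setequal(sig2$residue_number, brute)
  }
})

test_that("hydrogen-bond detection honours distance and angle criteria", {
  hit <- make_contact_fixture("hbond", distance = 2.9, angle = 165)
  found <- detect_hbonds(hit)
  expect_equal(nrow(found), 1)
  expect_equal(found$occupancy, 1.0)
  expect_equal(found$distance, 2.9, tolerance = 1e-6)
  expect_equal(found$angle, 165, tolerance = 1e-6)
  expect_true(found$angle_checked)

  # beyond d_max: nothing
  expect_equal(nrow(detect_hbonds(make_contact_fixture("hbond", 4.5, 165))), 0)
  # good distance, bad angle
  expect_equal(nrow(detect_hbonds(make_contact_fixture("hbond", 2.9, 90))), 0)
  # alternating-frame trajectory: occupancy 0.5
  a <- make_contact_fixture("hbond", 2.9, 165)
  b <- make_contact_fixture("hbond", 4.5, 165)
  tr <- new_trajectory(a, rbind(as.numeric(t(a$coords)), as.numeric(t(b$coords)),
                                as.numeric(t(a$coords)), as.numeric(t(b$coords))))
  occ <- detect_hbonds(tr)
  expect_equal(occ$occupancy, 0.5)
  # occupancy invariant under frame reordering
  tr2 <- new_trajectory(a, tr$xyz[c(4, 2, 1, 3), ])
  expect_equal(detect_hbonds(tr2)$occupancy, occ$occupancy)
})

test_that("salt-bridge detection requires opposite charges within the cutoff", {
  sb <- detect_salt_bridges(make_contact_fixture("saltbridge", 3.5))
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance, 3.5, tolerance = 1e-6)
  expect_equal(nrow(detect_salt_bridges(make_contact_fixture("saltbridge", 4.6))), 0)

  # same-sign pair (Asp-Glu) never reported
  asp <- make_contact_fixture("saltbridge", 3.0)
  a <- asp$atoms
  a$residue_name[a$residue_number == 2] <- "GLU"
  a$atom_name[a$residue_number == 2] <- c("N", "CA", "C", "O", "CB", "CG",
                                          "CD", "OE1", "OE2")[seq_len(sum(a$residue_number == 2))]
  same <- new_structure(a, asp$coords)
  expect_equal(nrow(detect_salt_bridges(same)), 0)
})

test_that("salt-bridge contact sets match a brute-force minimum-distance scan", {
  set.seed(17)
  for (k in 1:5) {
    d <- stats::runif(1, 2.5, 6)
    fx <- make_contact_fixture("saltbridge", d)
    found <- nrow(detect_salt_bridges(fx, cutoff = 4.0)) == 1
    # brute force: min distance over charged-group atoms
    a <- fx$atoms
    neg <- which(a$residue_name == "ASP" & a$atom_name %in% c("OD1", "OD2"))
    pos <- which(a$residue_name == "LYS" & a$atom_name == "NZ")
    mind <- min(apply(expand.grid(neg, pos), 1, function(ij)
      sqrt(sum((fx$coords[ij[1], ] - fx$coords[ij[2], ])^2))))
    expect_equal(found, mind <= 4.0)
  }
})
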