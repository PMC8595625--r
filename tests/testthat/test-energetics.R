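opt0 <- gb_options(salt_M = 0)   # salt-free for closed-form comparisons

one_atom_structure <- function(radius = 2.0, charge = -1) {
  atoms <- data.frame(atom_name = "O", residue_number = 1L,
                      residue_name = "ALA", chain_id = "A", element = "O",
                      stringsAsFactors = FALSE)
  s <- new_structure(atoms, matrix(0, 1, 3))
  ap <- data.frame(charge = charge, lj_rmin_half = 1.7, lj_epsilon = 0.1,
                   gb_radius = radius, gb_scale = 0.85)
  list(s = s, ap = ap)
}

test_that("effective Born radii: vacuum limit, separation limit, direct-sum oracle", {
  x <- one_atom_structure()
  expect_equal(effective_born_radii(x$s, x$ap, opt0), 2.0, tolerance = 1e-9)

  # two atoms far apart approach their isolated radii
  atoms <- x$s$atoms[c(1, 1), ]
  atoms$residue_number <- 1:2
  far <- new_structure(atoms, rbind(c(0, 0, 0), c(100, 0, 0)))
  ap2 <- x$ap[c(1, 1), ]
  expect_equal(effective_born_radii(far, ap2, opt0), c(2, 2), tolerance = 1e-6)

  # compact cluster matches the scalar descreening-sum oracle
  cl <- cluster_structure(10)
  ap <- match_atom_params(cl, default_atom_params())
  expect_equal(effective_born_radii(cl, ap, opt0),
               direct_born_radii(cl, ap, opt0), tolerance = 1e-9)
  # effective radius never below the descreened intrinsic radius... it grows
  # with burial: all radii >= intrinsic - tolerance
  expect_true(all(effective_born_radii(cl, ap, opt0) >= ap$gb_radius - 1e-9))
})

test_that("one-atom GB self energy matches the Born closed form", {
  x <- one_atom_structure(radius = 2.0, charge = -1)
  e <- pairwise_interaction_energy(x$s, x$ap, options = opt0)
  born <- -0.5 * (1 / opt0$epsilon_in - 1 / opt0$epsilon_out) * 332.0636 * 1 / 2.0
  expect_equal(e$self$gb[1], born, tolerance = 1e-6)
  expect_equal(e$self$total[1], born, tolerance = 1e-6)
})

test_that("pairwise decomposition matches a direct double-loop oracle and conserves the total", {
  h <- make_ideal_helix(10, sequence = "ADKSA")   # ~50 heavy atoms
  ap <- match_atom_params(h, default_atom_params())
  radii <- effective_born_radii(h, ap, opt0)
  e <- pairwise_interaction_energy(h, ap, radii = radii, options = opt0)
  expect_equal(e$total, e$coulomb + e$vdw + e$gb, tolerance = 1e-12)
  expect_equal(e$total, t(e$total), tolerance = 1e-9)

  # two-residue toy entry against a scalar atom-pair loop
  idx1 <- atom_select(h, residues = 1)
  idx2 <- atom_select(h, residues = 7)
  kc <- 332.0636
  acc <- 0
  for (i in idx1) for (j in idx2) {
    r <- sqrt(sum((h$coords[i, ] - h$coords[j, ])^2))
    acc <- acc + kc * ap$charge[i] * ap$charge[j] / r
    rmin <- ap$lj_rmin_half[i] + ap$lj_rmin_half[j]
    acc <- acc + sqrt(ap$lj_epsilon[i] * ap$lj_epsilon[j]) *
      ((rmin / r)^12 - 2 * (rmin / r)^6)
    bb <- radii[i] * radii[j]
    f <- sqrt(r^2 + bb * exp(-r^2 / (4 * bb)))
    acc <- acc - kc * (1 - exp(-opt0$kappa * f) / opt0$epsilon_out) *
      ap$charge[i] * ap$charge[j] / f
  }
  expect_equal(e$total[1, 7], acc, tolerance = 1e-9)

  # decomposition conservation: unmasked pairs + self terms = direct total
  direct <- direct_system_energy(h, ap, radii, opt0)
  expect_equal(unmasked_total(e) + sum(e$self$total), direct, tolerance = 1e-6)

  # all charges and epsilons zero -> all entries zero
  ap0 <- ap
  ap0$charge <- 0
  ap0$lj_epsilon <- 0
  e0 <- pairwise_interaction_energy(h, ap0, options = opt0)
  expect_true(all(abs(e0$total) < 1e-12))

  # doubling all charges quadruples coulomb and gb, leaves vdw unchanged
  ap2 <- ap
  ap2$charge <- 2 * ap$charge
  e2 <- pairwise_interaction_energy(h, ap2, radii = radii, options = opt0)
  expect_equal(e2$coulomb, 4 * e$coulomb, tolerance = 1e-9)
  expect_equal(e2$gb, 4 * e$gb, tolerance = 1e-9)
  expect_equal(e2$vdw, e$vdw, tolerance = 1e-12)
})

test_that("pair energy vanishes at large separation", {
  atoms <- data.frame(atom_name = c("O", "N"), residue_number = 1:2,
                      residue_name = "ALA", chain_id = "A",
                      element = c("O", "N"), stringsAsFactors = FALSE)
  s <- new_structure(atoms, rbind(c(0, 0, 0), c(200, 0, 0)))
  ap <- data.frame(charge = c(-1, 1), lj_rmin_half = c(1.7, 1.85),
                   lj_epsilon = c(0.12, 0.2), gb_radius = c(1.5, 1.55),
                   gb_scale = c(0.85, 0.79))
  e <- pairwise_interaction_energy(s, ap, options = gb_options())
  expect_lt(abs(e$total[1, 2]), 1e-4)
  # and the salt-free limit approaches the screened-Coulomb difference
  e0 <- pairwise_interaction_energy(s, ap, options = opt0)
  screened <- 332.0636 * (-1) / 200 / opt0$epsilon_out
  expect_equal(e0$total[1, 2], screened, tolerance = 1e-4)
})

test_that("overlapping atoms are rejected", {
  atoms <- data.frame(atom_name = c("O", "N"), residue_number = 1:2,
                      residue_name = "ALA", chain_id = "A",
                      element = c("O", "N"), stringsAsFactors = FALSE)
  s <- new_structure(atoms, rbind(c(0, 0, 0), c(0.05, 0, 0)))
  ap <- data.frame(charge = c(-1, 1), lj_rmin_half = c(1.7, 1.85),
                   lj_epsilon = c(0.12, 0.2), gb_radius = c(1.5, 1.55),
                   gb_scale = c(0.85, 0.79))
  expect_error(pairwise_interaction_energy(s, ap, options = opt0), "overlapping")
})

test_that("neighbour exclusion matches brute-force enumeration and chain rules", {
  # 10-residue single chain, window 4: pairs with |i-j| > 4 survive
  h <- make_ideal_helix(10, sequence = "A")
  e <- apply_exclusion(pairwise_interaction_energy(h, options = opt0), 4)
  up <- upper.tri(e$mask)
  expect_equal(sum(!e$mask[up]), 15)
  # brute-force oracle
  resno <- e$residues$residue_number
  brute <- outer(resno, resno, function(a, b) abs(a - b) > 4)
  expect_equal(!e$mask, brute)

  # window 0 masks only self-pairs: all 45 off-diagonal pairs survive
  e0 <- apply_exclusion(e, 0)
  expect_equal(sum(!e0$mask[up]), 45)

  # masking is idempotent and preserves values
  e44 <- apply_exclusion(e, 4)
  expect_identical(e44$mask, e$mask)
  expect_identical(e44$total, e$total)
  expect_error(apply_exclusion(e, -1), ">= 0")
})

test_that("inter-chain pairs are never masked", {
  a1 <- make_ideal_helix(6, sequence = "A", chain = "A")
  a2 <- make_ideal_helix(6, sequence = "A", chain = "B", origin = c(20, 0, 0))
  two <- new_structure(rbind(a1$atoms, a2$atoms), rbind(a1$coords, a2$coords))
  e <- apply_exclusion(pairwise_interaction_energy(two, options = opt0), 4)
  chains <- e$residues$chain_id
  inter <- outer(chains, chains, `!=`)
  expect_true(all(!e$mask[inter]))
})

test_that("replicate averaging reproduces per-entry mean and sem", {
  h <- make_ideal_helix(6, sequence = "AD")
  e <- pairwise_interaction_energy(h, options = opt0)
  # identical matrices: mean = input, sem = 0
  av <- average_matrices(list(e, e, e))
  expect_equal(av$mean, e$total)
  expect_true(all(av$sem == 0))
  expect_equal(av$n, 3)
  # two-point case {0, 2}: mean 1, sem 1
  z <- e; z$total <- 0 * e$total
  w <- e; w$total <- 0 * e$total; w$total[1, 3] <- 2; w$total[3, 1] <- 2
  av2 <- average_matrices(list(z, w))
  expect_equal(av2$mean[1, 3], 1)
  expect_equal(av2$sem[1, 3], 1)
  # random stack against a direct per-entry oracle
  set.seed(6)
  reps <- lapply(1:4, function(k) {
    ek <- e
    noise <- matrix(stats::rnorm(length(e$total)), nrow(e$total))
    ek$total <- e$total + noise + t(noise)
    ek
  })
  av3 <- average_matrices(reps)
  stack <- simplify2array(lapply(reps, `[[`, "total"))
  expect_equal(av3$mean, apply(stack, c(1, 2), mean), tolerance = 1e-12)
  expect_equal(av3$sem, apply(stack, c(1, 2), sd) / 2, tolerance = 1e-12)
  # inconsistent residue lists rejected
  other <- pairwise_interaction_energy(make_ideal_helix(7, sequence = "AD"),
                                       options = opt0)
  expect_error(average_matrices(list(e, other)), "different residue lists")
})

test_that("decomposition CSV import: fixture, symmetrization warning, round-trip", {
  p <- system.file("extdata", "example_decomposition.csv", package = "helixnet")
  m <- import_decomposition(p)
  expect_equal(nrow(m$residues), 4)
  tab <- utils::read.csv(p)
  for (k in seq_len(nrow(tab))) {
    i <- match(tab$residue_i[k], m$residues$residue_number)
    j <- match(tab$residue_j[k], m$residues$residue_number)
    expect_equal(m$total[i, j], tab$total[k])
  }
  # asymmetric duplicates averaged with a warning
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(residue_i = c(1, 2), residue_j = c(2, 1),
                              internal = 0, vdw = 0, electrostatic = 0,
                              polar_solv = 0, nonpolar_solv = 0,
                              total = c(-2.0, -2.2)), p2, row.names = FALSE)
  expect_warning(m2 <- import_decomposition(p2), "symmetrized")
  expect_equal(m2$total[1, 2], -2.1)
  # export -> import round-trip of a computed matrix
  h <- make_ideal_helix(8, sequence = "ADKS")
  e <- pairwise_interaction_energy(h, options = opt0)
  p3 <- tempfile(fileext = ".csv")
  export_decomposition(e, p3)
  back <- import_decomposition(p3)
  expect_equal(back$total, e$total, tolerance = 1e-6)
  expect_equal(back$coulomb, e$coulomb, tolerance = 1e-6)
  # missing columns rejected
  p4 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(residue_i = 1, residue_j = 2, total = -1), p4,
                   row.names = FALSE)
  expect_error(import_decomposition(p4), "missing columns")
})

test_that("averaging commutes with masking", {
  h <- make_ideal_helix(9, sequence = "ADS")
  e1 <- pairwise_interaction_energy(h, options = opt0)
  set.seed(3)
  e2 <- e1
  noise <- matrix(stats::rnorm(length(e1$total), sd = 0.1), nrow(e1$total))
  e2$total <- e1$total + noise + t(noise)
  mask_then_avg <- average_matrices(lapply(list(e1, e2), apply_exclusion, window = 4))
  avg_then_mask <- average_matrices(list(apply_exclusion(e1, 4), apply_exclusion(e2, 4)))
  expect_equal(mask_then_avg$mean, avg_then_mask$mean)
  expect_equal(mask_then_avg$mask, avg_then_mask$mask)
})
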