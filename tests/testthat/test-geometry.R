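# Ideal amino-acid geometry (Chemical Component Dictionary reference
# coordinates) used to calibrate the virtual C-beta construction.
ccd_residues <- list(
  ALA = list(n = c(-0.966, 0.493, 1.500), ca = c(0.257, 0.418, 0.692),
             c = c(-0.094, 0.017, -0.716), cb = c(1.204, -0.620, 1.296)),
  VAL = list(n = c(1.564, -0.642, 0.454), ca = c(0.145, -0.698, 0.079),
             c = c(-0.037, -0.093, -1.288), cb = c(-0.682, 0.086, 1.098)),
  LEU = list(n = c(-1.661, 0.627, -0.406), ca = c(-0.205, 0.441, -0.467),
             c = c(0.180, -0.055, -1.836), cb = c(0.221, -0.583, 0.585)),
  SER = list(n = c(1.525, 0.493, -0.608), ca = c(0.100, 0.469, -0.252),
             c = c(-0.053, 0.004, 1.173), cb = c(-0.642, -0.489, -1.184)),
  THR = list(n = c(1.543, -0.702, 0.430), ca = c(0.122, -0.706, 0.056),
             c = c(-0.038, -0.090, -1.309), cb = c(-0.675, 0.104, 1.079)),
  ARG = list(n = c(-0.469, 1.110, -0.993), ca = c(0.004, 2.294, -1.708),
             c = c(-0.907, 2.521, -2.901), cb = c(1.475, 2.150, -2.127)),
  PHE = list(n = c(1.317, 0.962, 1.014), ca = c(-0.020, 0.426, 1.300),
             c = c(-0.109, 0.047, 2.756), cb = c(-0.270, -0.809, 0.434)))

test_that("virtual_cb places an ideal tetrahedral C-beta", {
  # bond length is exact and the atom leaves the backbone plane
  p <- virtual_cb(n = c(-1.458, 0, 0), ca = c(0, 0, 0), c = c(0.551, 1.420, 0))
  expect_equal(sqrt(sum(p^2)), 1.521, tolerance = 1e-9)
  expect_gt(abs(p[3]), 0.5)

  # reproduces ideal side-chain positions within 0.35 A on reference residues
  for (res in names(ccd_residues)) {
    r <- ccd_residues[[res]]
    p <- virtual_cb(r$n, r$ca, r$c)
    expect_lt(sqrt(sum((p - r$cb)^2)), 0.35)
    # and on the L-chirality side of the N-CA-C plane
    expect_gt(sum(lspprn:::cross3(matrix(r$n - r$ca, 1), matrix(r$c - r$ca, 1)) *
                    (p - r$ca)), 0)
  }

  # construction commutes with rigid motion
  set.seed(7)
  for (k in 1:5) {
    R <- random_rotation_matrix(); tr <- runif(3, -20, 20)
    r <- ccd_residues$VAL
    p0 <- virtual_cb(r$n, r$ca, r$c)
    p1 <- virtual_cb(drop(r$n %*% t(R)) + tr, drop(r$ca %*% t(R)) + tr,
                     drop(r$c %*% t(R)) + tr)
    expect_equal(p1, drop(p0 %*% t(R)) + tr, tolerance = 1e-9)
  }

  expect_error(virtual_cb(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), labels = "G17"),
               "degenerate.*G17")
})

test_that("link_descriptor returns internal coordinates with IUPAC dihedral", {
  d <- link_descriptor(ca1 = c(0, 0, 0), cb1 = c(0, 0, 1.5),
                       ca2 = c(6, 0, 0), cb2 = c(6, 0, 1.5))
  expect_equal(d$d_caca, 6)
  expect_equal(d$d_ca1cb2, sqrt(38.25))
  expect_equal(d$d_ca2cb1, sqrt(38.25))
  expect_equal(d$theta, 0)

  d <- link_descriptor(ca1 = c(0, 0, 0), cb1 = c(0, 0, 1.5),
                       ca2 = c(6, 0, 0), cb2 = c(6, 0, -1.5))
  expect_equal(d$theta, 180)  # trans planar; sign convention puts 180 not -180

  expect_error(link_descriptor(c(0, 0, 0), c(1.5, 0, 0), c(6, 0, 0), c(7.5, 0, 0)),
               "degenerate dihedral")
})

test_that("descriptors are rigid-motion invariant and mirror-sensitive", {
  set.seed(11)
  for (k in 1:20) {
    ca1 <- runif(3, -10, 10); ca2 <- runif(3, -10, 10)
    u <- rnorm(3); u <- u / sqrt(sum(u^2)); v <- rnorm(3); v <- v / sqrt(sum(v^2))
    cb1 <- ca1 + 1.5 * u; cb2 <- ca2 + 1.5 * v
    d0 <- link_descriptor(ca1, cb1, ca2, cb2)

    R <- random_rotation_matrix(); tr <- runif(3, -50, 50)
    mv <- function(p) drop(p %*% t(R)) + tr
    d1 <- link_descriptor(mv(ca1), mv(cb1), mv(ca2), mv(cb2))
    expect_equal(unlist(d1[1:3]), unlist(d0[1:3]), tolerance = 1e-9)
    expect_lt(lspprn:::circ_diff_deg(d1$theta, d0$theta), 1e-6)

    # improper transform: distances unchanged, theta flips sign
    mirror <- function(p) c(p[1], p[2], -p[3])
    d2 <- link_descriptor(mirror(ca1), mirror(cb1), mirror(ca2), mirror(cb2))
    expect_equal(unlist(d2[1:3]), unlist(d0[1:3]), tolerance = 1e-9)
    expect_equal(d2$theta, -d0$theta, tolerance = 1e-6)

    # symmetry: reversed atom sequence swaps cross distances, keeps theta
    d3 <- link_descriptor(ca2, cb2, ca1, cb1)
    expect_equal(d3$d_caca, d0$d_caca)
    expect_equal(d3$d_ca1cb2, d0$d_ca2cb1)
    expect_equal(d3$d_ca2cb1, d0$d_ca1cb2)
    expect_equal(d3$theta, d0$theta, tolerance = 1e-9)
  }
})

test_that("contact_pairs uses a strict cutoff and matches the brute-force oracle", {
  two <- function(d) tibble::tibble(
    frame = 1L, residue_index = 1:2, residue_label = c("A1", "A2"),
    ca_x = c(0, d), ca_y = 0, ca_z = 0, cb_x = c(0, d), cb_y = 0, cb_z = 1.5,
    cb_virtual = FALSE)
  expect_equal(nrow(contact_pairs(two(11.99))), 1)
  expect_equal(nrow(contact_pairs(two(12.00))), 0)

  collinear <- tibble::tibble(
    frame = 1L, residue_index = 1:3, residue_label = paste0("A", 1:3),
    ca_x = c(0, 10, 20), ca_y = 0, ca_z = 0,
    cb_x = c(0, 10, 20), cb_y = 0, cb_z = 1.5, cb_virtual = FALSE)
  cp <- contact_pairs(collinear)
  expect_equal(cp[order(cp$i, cp$j), c("i", "j")],
               tibble::tibble(i = c(1L, 2L), j = c(2L, 3L)),
               ignore_attr = TRUE)

  set.seed(3)
  for (k in 1:4) {
    fr <- random_frame(50)
    got <- contact_pairs(fr)[, c("i", "j")]
    want <- oracle_contact_pairs(fr)
    expect_equal(dplyr::arrange(got, i, j), dplyr::arrange(want, i, j),
                 ignore_attr = TRUE)
  }
})
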