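test_that("descriptors_match applies strict tolerances and circular theta", {
  cuts <- lsp_cutoffs()
  a <- tibble::tibble(d_caca = 6, d_ca1cb2 = 6.2, d_ca2cb1 = 6.2, theta = 40)
  expect_true(descriptors_match(a, a, cuts))

  b <- a; b$d_caca <- a$d_caca + 0.2      # boundary: strict
  expect_false(descriptors_match(a, b, cuts))
  b <- a; b$d_caca <- a$d_caca + 0.199999
  expect_true(descriptors_match(a, b, cuts))
  b <- a; b$d_ca1cb2 <- a$d_ca1cb2 + 0.45
  expect_false(descriptors_match(a, b, cuts))
  b <- a; b$theta <- a$theta + 10
  expect_false(descriptors_match(a, b, cuts))

  # -179 vs +179 is a 2-degree circular difference
  a$theta <- 179; b <- a; b$theta <- -179
  expect_true(descriptors_match(a, b, cuts))
})

test_that("self-alignment is complete and rigid motion changes nothing", {
  set.seed(5)
  for (k in 1:3) {
    fr <- random_frame(40)
    cp <- contact_pairs(fr)[, c("i", "j")]
    self <- align_pair(fr, fr)
    expect_equal(dplyr::arrange(self, i, j), dplyr::arrange(cp, i, j),
                 ignore_attr = TRUE)
    moved <- rigidify(fr)
    expect_equal(dplyr::arrange(align_pair(fr, moved), i, j),
                 dplyr::arrange(cp, i, j), ignore_attr = TRUE)
  }
})

test_that("align_pair matches the per-pair brute-force recheck", {
  set.seed(9)
  fr <- random_frame(30)
  # genuinely perturbed second frame: one residue displaced, others jittered
  f2 <- fr
  f2$ca_x[12] <- f2$ca_x[12] + 5; f2$cb_x[12] <- f2$cb_x[12] + 5
  jit <- matrix(rnorm(3 * 30, 0, 0.12), 30, 3)
  f2$ca_x <- f2$ca_x + jit[, 1]; f2$ca_y <- f2$ca_y + jit[, 2]
  f2$ca_z <- f2$ca_z + jit[, 3]
  f2$cb_x <- f2$cb_x + jit[, 1]; f2$cb_y <- f2$cb_y + jit[, 2]
  f2$cb_z <- f2$cb_z + jit[, 3]

  got <- dplyr::arrange(align_pair(fr, f2), i, j)
  want <- oracle_align_pair(fr, f2)
  expect_equal(got, dplyr::arrange(tibble::as_tibble(want), i, j),
               ignore_attr = TRUE)
  # symmetric in its two arguments
  expect_equal(dplyr::arrange(align_pair(f2, fr), i, j), got)
  # displaced residue lost at least one link
  before <- align_pair(fr, fr)
  expect_lt(sum(got$i == 12 | got$j == 12),
            sum(before$i == 12 | before$j == 12))
})

test_that("align_pair rejects discordant rosters naming the residue", {
  fr <- random_frame(10)
  f2 <- fr[fr$residue_index != 7, ]
  expect_error(align_pair(fr, f2), "A7")
})

test_that("window_network averages 0/1 adjacencies over all frame pairs", {
  set.seed(21)
  base <- random_frame(20)
  identical4 <- dplyr::bind_rows(lapply(1:4, function(f) {
    b <- base; b$frame <- f; b
  }))
  ens <- as_lsp_ensemble(identical4)
  net <- window_network(ens)
  expect_equal(attr(net, "n_pairs_aggregated"), 6L)
  expect_true(all(net$weight == 1))
  cp <- contact_pairs(base)
  expect_equal(nrow(net), nrow(cp))

  # five noisy frames against the triple-loop oracle
  frames5 <- dplyr::bind_rows(lapply(1:5, function(f) {
    b <- base
    jit <- matrix(rnorm(3 * 20, 0, 0.25), 20, 3)
    b$frame <- f
    b$ca_x <- b$ca_x + jit[, 1]; b$ca_y <- b$ca_y + jit[, 2]
    b$ca_z <- b$ca_z + jit[, 3]
    b$cb_x <- b$cb_x + jit[, 1]; b$cb_y <- b$cb_y + jit[, 2]
    b$cb_z <- b$cb_z + jit[, 3]
    b
  }))
  ens5 <- as_lsp_ensemble(frames5)
  net5 <- window_network(ens5)
  want <- oracle_window_weights(ens5)
  expect_equal(dplyr::arrange(tibble::as_tibble(net5)[, c("i", "j", "weight")], i, j),
               want, ignore_attr = TRUE)
  # weights are proportions k / C(n,2)
  expect_true(all(abs(net5$weight * 10 - round(net5$weight * 10)) < 1e-9))
  expect_true(all(net5$weight > 0 & net5$weight <= 1))
})

test_that("a 3-of-6 retained edge has weight 0.5", {
  # two residues 6 A apart; in frame 4 residue 2's CB is rotated far enough
  # that only the 3 pairs among frames 1-3 match
  mk <- function(f, cby) tibble::tibble(
    frame = f, residue_index = 1:2, residue_label = c("A1", "A2"),
    ca_x = c(0, 6), ca_y = 0, ca_z = 0,
    cb_x = c(0, 6), cb_y = c(0, cby), cb_z = c(1.5, ifelse(cby == 0, 1.5, 0)),
    cb_virtual = FALSE)
  ens <- as_lsp_ensemble(dplyr::bind_rows(
    mk(1, 0), mk(2, 0), mk(3, 0), mk(4, 1.5)))
  net <- window_network(ens)
  expect_equal(net$weight[net$i == 1 & net$j == 2], 0.5)
})

test_that("noisier copies never gain matched links on average", {
  set.seed(33)
  base <- random_frame(30)
  mean_edges <- vapply(c(0, 0.1, 0.3, 0.8), function(sigma) {
    mean(vapply(1:8, function(k) {
      f2 <- base
      jit <- matrix(rnorm(3 * 30, 0, sigma), 30, 3)
      f2$ca_x <- f2$ca_x + jit[, 1]; f2$ca_y <- f2$ca_y + jit[, 2]
      f2$ca_z <- f2$ca_z + jit[, 3]
      f2$cb_x <- f2$cb_x + jit[, 1]; f2$cb_y <- f2$cb_y + jit[, 2]
      f2$cb_z <- f2$cb_z + jit[, 3]
      nrow(align_pair(base, f2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_edges) <= 0))
})

test_that("split_windows reproduces the 3 x 500 -> 15 window design", {
  mk_traj <- function(nf) {
    as_lsp_ensemble(dplyr::bind_rows(lapply(seq_len(nf), function(f) {
      tibble::tibble(frame = f, residue_index = 1:3,
                     residue_label = paste0("A", 1:3),
                     ca_x = c(0, 5, 10), ca_y = 0, ca_z = 0,
                     cb_x = c(0, 5, 10), cb_y = 0, cb_z = 1.5,
                     cb_virtual = FALSE)
    })))
  }
  w <- split_windows(list(mk_traj(500), mk_traj(500), mk_traj(500)), 100)
  expect_equal(nrow(w), 15)
  expect_equal(w$trajectory, rep(1:3, each = 5))
  expect_equal(lengths(w$frames), rep(100L, 15))
  expect_equal(w$frames[[2]], 101:200)          # consecutive, non-overlapping

  expect_warning(w2 <- split_windows(mk_traj(250), 100), "dropping 50")
  expect_equal(nrow(w2), 2)

  w3 <- split_windows(mk_traj(100), 100)
  expect_equal(nrow(w3), 1)
  expect_equal(w3$frames[[1]], 1:100)

  expect_error(split_windows(mk_traj(60), 100), "fewer than one window")
})

test_that("window networks are invariant to per-frame rigid motion, bit for bit", {
  spec <- ensemble_spec(n_residues = 30, n_frames = 12, seed = 4,
                        global_motion = FALSE)
  ens <- generate_ensemble(spec)
  set.seed(99)
  moved <- transform_ensemble(
    ens,
    rotation = function(f) random_rotation_matrix(),
    translation = function(f) runif(3, -40, 40))
  n1 <- window_network(ens)
  n2 <- window_network(moved)
  expect_identical(tibble::as_tibble(n1), tibble::as_tibble(n2))
})
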