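test_that("degree centrality is the weighted row sum, isolated nodes included", {
  net <- make_lsp_network(
    tibble::tibble(i = c(1, 1, 1, 2, 2, 3), j = c(2, 3, 4, 3, 4, 4), weight = 1), 4)
  expect_equal(degree_centrality(net)$dc, rep(3, 4))

  path <- make_lsp_network(
    tibble::tibble(i = c(1, 2), j = c(2, 3), weight = c(0.5, 0.25)), 3)
  expect_equal(degree_centrality(path)$dc, c(0.5, 0.75, 0.25))

  set.seed(14)
  for (k in 1:5) {
    net <- random_network(20)
    W <- matrix(0, 20, 20)
    W[cbind(net$i, net$j)] <- net$weight
    W <- W + t(W)
    expect_equal(degree_centrality(net)$dc, rowSums(W))
  }
})

test_that("edge distances are -log(W) and reject invalid weights", {
  net <- make_lsp_network(
    tibble::tibble(i = c(1, 2), j = c(2, 3), weight = c(1, exp(-1))), 3)
  d <- edge_distances(net)
  expect_equal(d$distance, c(0, 1))

  bad <- make_lsp_network(tibble::tibble(i = 1, j = 2, weight = 1.2), 2)
  expect_error(edge_distances(bad), "\\(0, 1\\]")
  bad2 <- make_lsp_network(tibble::tibble(i = 1, j = 2, weight = 0), 2)
  expect_error(edge_distances(bad2), "\\(0, 1\\]")

  # monotone: higher retention, shorter distance
  w <- sort(runif(20, 0.01, 1))
  expect_true(all(diff(-log(w)) <= 0))
})

test_that("betweenness matches hand values on path and cycle graphs", {
  path <- make_lsp_network(
    tibble::tibble(i = c(1, 2), j = c(2, 3), weight = c(0.5, 0.9)), 3)
  expect_equal(betweenness_centrality(path)$bc, c(0, 1, 0))

  cyc <- make_lsp_network(
    tibble::tibble(i = c(1, 2, 3, 1), j = c(2, 3, 4, 4), weight = 0.5), 4)
  expect_equal(betweenness_centrality(cyc)$bc, rep(0.5, 4))
})

test_that("betweenness agrees exactly with exhaustive path enumeration", {
  set.seed(42)
  for (k in 1:25) {
    n <- sample(4:8, 1)
    net <- random_network(n, p = 0.45)
    if (nrow(net) == 0) next
    got <- betweenness_centrality(net)$bc
    want <- oracle_betweenness(edge_distances(net), n)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("W = 1 edges (zero distance) are handled", {
  # 1 -0- 2 -0- 3 plus a detour 1 - 4 - 3 of positive length: 1-3 traffic
  # crosses 2; the 2-4 pair ties between its two 2-hop routes; hop-minimal
  # counting keeps the direct 1-4 and 3-4 edges over equal-length detours
  net <- make_lsp_network(
    tibble::tibble(i = c(1, 2, 1, 4), j = c(2, 3, 4, 3),
                   weight = c(1, 1, 0.1, 0.1)), 4)
  bc <- betweenness_centrality(net)$bc
  expect_equal(bc, oracle_betweenness(edge_distances(net), 4), tolerance = 1e-12)
  expect_equal(bc, c(0.5, 1, 0.5, 0))

  # all-conserved clique: no through-traffic inside, BC identically zero
  cl <- make_lsp_network(clique_edges(1:5, w = 1), 5)
  expect_equal(betweenness_centrality(cl)$bc, rep(0, 5))
})

test_that("power-transforming weights rescales distances, leaving BC unchanged", {
  # W^c multiplies every D = -log W by c: all shortest-path trees survive
  set.seed(77)
  net <- random_network(12, p = 0.4)
  bc0 <- betweenness_centrality(net)$bc
  for (cc in c(0.9, 0.5, 2)) {
    scaled <- net
    scaled$weight <- scaled$weight^cc
    expect_equal(betweenness_centrality(scaled)$bc, bc0, tolerance = 1e-9)
  }
})

test_that("aggregate_windows computes means and sample-SD standard errors", {
  mk_long <- function(vals_dc, vals_bc) {
    dplyr::bind_rows(lapply(seq_along(vals_dc), function(w) {
      tibble::tibble(window = w, residue_index = 1:2,
                     residue_label = c("A1", "A2"),
                     dc = c(vals_dc[w], 1), bc = c(vals_bc[w], 0))
    }))
  }
  p <- aggregate_windows(mk_long(c(1, 3), c(2, 2)))
  expect_equal(p$dc_mean[1], 2)
  expect_equal(p$dc_se[1], 1)           # sd(c(1,3))/sqrt(2) = sqrt(2)/sqrt(2)
  expect_equal(p$bc_se[1], 0)
  expect_equal(p$n_windows, c(2L, 2L), ignore_attr = TRUE)

  # identical windows -> SE exactly 0
  p2 <- aggregate_windows(mk_long(c(2, 2, 2), c(5, 5, 5)))
  expect_equal(p2$dc_se[1], 0)
  expect_equal(p2$dc_mean[1], 2)

  # 15 windows of seeded noise vs the direct formula
  set.seed(6)
  vals <- rnorm(15, 10, 2)
  p3 <- aggregate_windows(mk_long(vals, vals))
  expect_equal(p3$dc_mean[1], mean(vals))
  expect_equal(p3$dc_se[1], sd(vals) / sqrt(15))
})

test_that("SE scales as 1/sqrt(m) for iid window values", {
  set.seed(8)
  m_small <- 10; m_big <- 40
  se_of <- function(m) {
    vals <- rnorm(m)
    long <- dplyr::bind_rows(lapply(seq_len(m), function(w) {
      tibble::tibble(window = w, residue_index = 1, residue_label = "A1",
                     dc = vals[w], bc = 0)
    }))
    aggregate_windows(long)$dc_se
  }
  r <- mean(replicate(40, se_of(m_small))) / mean(replicate(40, se_of(m_big)))
  expect_equal(r, sqrt(m_big / m_small), tolerance = 0.25)
})

test_that("percent difference handles identity, scaling and undefined residues", {
  long <- function(dc, construct) {
    p <- aggregate_windows(dplyr::bind_rows(lapply(1:2, function(w) {
      tibble::tibble(window = w, residue_index = seq_along(dc),
                     residue_label = paste0("A", seq_along(dc)),
                     dc = dc, bc = 1)
    })), construct = construct)
    p
  }
  ref <- long(c(2, 2, 0), "WT")
  expect_equal(percent_difference(ref, ref)$pct_diff[1:2], c(0, 0))

  mut <- long(c(3, 1, 0), "MUT")
  cmp <- percent_difference(mut, ref)
  expect_equal(cmp$pct_diff[1], 50)
  expect_equal(cmp$pct_diff[2], -50)
  expect_true(is.na(cmp$pct_diff[3]))
  expect_true(cmp$undefined[3])         # flagged, not dropped
  expect_equal(nrow(cmp), 3)

  ref2 <- long(c(2, 2), "WT")
  expect_error(percent_difference(mut, ref2), "discordant")
})
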