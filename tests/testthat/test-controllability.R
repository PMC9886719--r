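# Normalization, modal controllability, network means, topography.

test_that("normalization divides by the largest absolute eigenvalue plus one", {
  N <- normalize_connectome(connectome(matrix(c(0, 1, 1, 0), 2)))
  expect_equal(N$lambda_max, 1)
  expect_equal(N$A_norm, matrix(c(0, 0.5, 0.5, 0), 2,
                                dimnames = list(1:2, 1:2)))

  N2 <- normalize_connectome(connectome(matrix(c(0, 2, 2, 0), 2)))
  expect_equal(unname(N2$A_norm[1, 2]), 2 / 3)

  Z <- normalize_connectome(connectome(matrix(0, 3, 3)))
  expect_equal(Z$lambda_max, 0)
  expect_true(all(Z$A_norm == 0))

  # spectral radius of the normalized system is always < 1
  C <- connectome(random_symmetric_counts(15, seed = 42))
  sr <- max(abs(eigen(normalize_connectome(C)$A_norm,
                      only.values = TRUE)$values))
  expect_lt(sr, 1)
})

test_that("modal controllability matches hand-derived special cases", {
  # zero matrix: every mode has xi = 0, phi is identically 1
  P0 <- modal_controllability(normalize_connectome(connectome(matrix(0, 4, 4))))
  expect_equal(unname(P0$phi), rep(1, 4))

  # 2-node closed form: phi = 1 - (w/(w+1))^2 for any edge weight w > 0
  for (w in c(0.1, 1, 2, 7, 250)) {
    C <- connectome(matrix(c(0, w, w, 0), 2))
    P <- modal_controllability(normalize_connectome(C))
    expect_equal(unname(P$phi), rep(1 - (w / (w + 1))^2, 2),
                 tolerance = 1e-12)
  }
})

test_that("pipeline phi equals independent brute-force oracles", {
  for (k in 1:30) {
    n <- sample(5:30, 1)
    C <- connectome(random_symmetric_counts(n, seed = 7000 + k))
    A <- normalize_connectome(C)$A_norm
    phi <- unname(modal_controllability(normalize_connectome(C))$phi)
    expect_lt(max(abs(phi - phi_bruteforce(A))), 1e-10)
    expect_lt(max(abs(phi - phi_matrix_square(A))), 1e-10)
  }
})

test_that("phi respects eigenvalue bounds and lies in (0, 1]", {
  for (k in 1:20) {
    C <- connectome(random_symmetric_counts(20, seed = 300 + k))
    N <- normalize_connectome(C)
    xi <- eigen(N$A_norm, symmetric = TRUE, only.values = TRUE)$values
    phi <- modal_controllability(N)$phi
    expect_true(all(phi >= 1 - max(xi^2) - 1e-10))
    expect_true(all(phi <= 1 - min(xi^2) + 1e-10))
    expect_true(all(phi > 0 & phi <= 1))
  }
})

test_that("relabeling parcels permutes phi identically", {
  W <- random_symmetric_counts(12, seed = 99)
  phi <- unname(modal_controllability(normalize_connectome(connectome(W)))$phi)
  set.seed(1)
  perm <- sample(12)
  phi_p <- unname(modal_controllability(
    normalize_connectome(connectome(W[perm, perm]))
  )$phi)
  expect_equal(phi_p, phi[perm], tolerance = 1e-12)
})

test_that("automorphic nodes receive equal phi", {
  # both ends of a 2-node graph
  phi2 <- modal_controllability(normalize_connectome(
    connectome(matrix(c(0, 3, 3, 0), 2))))$phi
  expect_lt(abs(phi2[1] - phi2[2]), 1e-12)
  # all nodes of an equal-weight complete graph
  K <- matrix(5, 6, 6); diag(K) <- 0
  phiK <- modal_controllability(normalize_connectome(connectome(K)))$phi
  expect_lt(max(phiK) - min(phiK), 1e-12)
  # degenerate eigenvalues perturbed: result stays close and finite
  K2 <- K; K2[1, 2] <- K2[2, 1] <- 5 + 1e-9
  phiK2 <- modal_controllability(normalize_connectome(connectome(K2)))$phi
  expect_lt(max(abs(phiK2 - phiK)), 1e-6)
})

test_that("invalid inputs to modal_controllability are rejected", {
  A <- matrix(c(0, 0.9, 0.1, 0), 2)
  expect_error(modal_controllability(A), "asymmetric")
  B <- matrix(c(0, 1.2, 1.2, 0), 2)
  expect_error(modal_controllability(B), "spectral radius")
})

test_that("network means average phi over member parcels", {
  C <- connectome(random_symmetric_counts(6, seed = 5))
  P <- modal_controllability(normalize_connectome(C))
  D <- network_definition(data.frame(
    parcel_id = c(1, 2, 3, 999),
    parcel_name = c("a", "b", "c", "x"),
    network_label = c("net", "net", "solo", "ghost")
  ))
  expect_equal(network_mean_controllability(P, D, "net"),
               mean(P$phi[c("1", "2")]))
  expect_equal(network_mean_controllability(P, D, "solo"),
               unname(P$phi["3"]))
  expect_error(network_mean_controllability(P, D, "ghost"), "absent")
})

test_that("group topography averages subjects and ranks with tie-averaging", {
  C <- connectome(random_symmetric_counts(8, seed = 77))
  P <- modal_controllability(normalize_connectome(C))
  topo <- group_topography(list(P, P))
  expect_equal(topo$mean_phi, unname(P$phi))
  expect_equal(sort(topo$rank), 1:8)
  expect_equal(mean(topo$rank), (8 + 1) / 2)

  fake <- function(phi) structure(
    list(phi = phi, parcel_ids = seq_along(phi), subject_id = "s",
         timepoint = "T1"), class = "controllability_profile")
  expect_equal(group_topography(list(fake(c(0.2, 0.5, 0.4))))$rank,
               c(1, 3, 2))
  expect_equal(group_topography(list(fake(c(0.3, 0.3))))$rank, c(1.5, 1.5))
  expect_error(group_topography(list()), "empty")
  mismatched <- fake(c(0.1, 0.2, 0.3, 0.4))
  expect_error(group_topography(list(fake(c(0.1, 0.2)), mismatched)),
               "mismatched")
})

test_that("topography similarity is a Spearman correlation with t-test p", {
  mk <- function(x) {
    structure(data.frame(parcel_id = seq_along(x), mean_phi = x,
                         rank = rank(x)),
              class = c("topography_map", "data.frame"))
  }
  expect_equal(topography_similarity(mk(c(1, 2, 3, 4)), mk(c(1, 2, 3, 4)))$rho, 1)
  expect_equal(topography_similarity(mk(c(1, 2, 3, 4)), mk(c(4, 3, 2, 1)))$rho, -1)
  res <- topography_similarity(mk(c(1, 2, 3, 4)), mk(c(1, 3, 2, 4)))
  expect_equal(res$rho, 0.8)
  expect_error(topography_similarity(mk(c(1, 2)), mk(c(1, 2))), "at least 3")
  expect_error(topography_similarity(mk(c(1, 1, 1)), mk(c(1, 2, 3))),
               "zero rank variance")
})
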