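test_that("sparsity grids match the atlas conventions", {
  g116 <- sparsity_grid("AAL116")
  g68 <- sparsity_grid("DK68")
  expect_length(g116, 26)
  expect_length(g68, 24)
  expect_equal(g116[1], 0.05)
  expect_equal(g68[1], 0.07)
  expect_equal(g116[26], 0.30)
  # exact to 2 decimals, constant step 0.01
  expect_identical(sprintf("%.2f", g116),
                   sprintf("%.2f", 5:30 / 100))
  expect_equal(g116 * 100, as.numeric(5:30), tolerance = 1e-12)
  expect_true(all(abs(diff(g116) - 0.01) < 1e-15))
  expect_true(all(diff(g68) > 0))
})

test_that("binarization keeps exactly the k largest weights", {
  m <- random_similarity(5, seed = 1)
  g <- binarize_at_sparsity(m, 0.3)
  expect_equal(sum(g$adjacency) / 2, 3)
  w <- m$values[upper.tri(m$values)]
  kept <- m$values[upper.tri(m$values) & g$adjacency == 1]
  expect_setequal(kept, sort(w, decreasing = TRUE)[1:3])
  # full graph at s = 1
  expect_equal(sum(binarize_at_sparsity(m, 1)$adjacency) / 2, 10)
  # structural invariants
  expect_identical(g$adjacency, t(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))
  # deterministic under ties straddling the cutoff
  v <- matrix(0.5, 4, 4); diag(v) <- 1
  v[1, 2] <- v[2, 1] <- 0.9
  dimnames(v) <- list(letters[1:4], letters[1:4])
  tied <- new_similarity_matrix(v)
  g1 <- binarize_at_sparsity(tied, 0.5)  # k = 3, five tied at 0.5
  g2 <- binarize_at_sparsity(tied, 0.5)
  expect_identical(g1$adjacency, g2$adjacency)
  expect_equal(sum(g1$adjacency) / 2, 3)
  expect_error(binarize_at_sparsity(m, 0), class = "klsnet_contract_error")
  expect_warning(binarize_at_sparsity(m, 1e-4), "zero edges")
})

test_that("edge-count contract holds across the whole grid", {
  for (seed in 1:3) {
    m <- random_similarity(30, seed = seed)
    for (s in sparsity_grid("AAL116")) {
      g <- binarize_at_sparsity(m, s)
      expect_equal(sum(g$adjacency) / 2, round(s * 30 * 29 / 2))
    }
  }
})

test_that("global metrics match hand-enumerated small cases", {
  k5 <- graph_fixture(matrix(1, 5, 5) - diag(5))
  gm <- global_metrics(k5)
  expect_equal(gm$Cp, 1)
  expect_equal(gm$Lp, 1)
  expect_equal(gm$Eg, 1)
  expect_equal(gm$Eloc, 1)
  # path a-b-c: pairs (a,b)=1, (b,c)=1, (a,c)=2 -> Lp = 4/3
  p3 <- graph_fixture(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  gm3 <- global_metrics(p3)
  expect_equal(gm3$Lp, 4 / 3)
  expect_equal(gm3$Cp, 0)
  empty <- graph_fixture(matrix(0L, 5, 5))
  expect_equal(global_metrics(empty)$Eg, 0)
  expect_true(is.na(global_metrics(empty)$Lp))
  expect_error(global_metrics(graph_fixture(matrix(0L, 2, 2))),
               class = "klsnet_contract_error")
})

test_that("nodal metrics match hand-enumerated small cases", {
  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- 1L
  star <- star + t(star)
  nm <- nodal_metrics(graph_fixture(star))
  expect_equal(nm$degree, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(nm$betweenness[1], 1)
  expect_equal(nm$betweenness[2:5], rep(0, 4))
  p3 <- graph_fixture(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  nm3 <- nodal_metrics(p3)
  expect_equal(nm3$betweenness, c(0, 1, 0))
  # isolated node
  iso <- matrix(0L, 4, 4)
  iso[1, 2] <- iso[2, 1] <- iso[2, 3] <- iso[3, 2] <- 1L
  nmi <- nodal_metrics(graph_fixture(iso))
  expect_equal(nmi$degree[4], 0L)
  expect_equal(nmi$nodal_efficiency[4], 0)
  expect_equal(nmi$nodal_local_efficiency[4], 0)
})

test_that("metrics agree with brute-force oracles on all small graphs", {
  cases <- list()
  # exhaustive over several edge probabilities and sizes
  for (n in 4:6) {
    for (p in c(0.2, 0.4, 0.6, 0.9)) {
      for (seed in 1:4) {
        cases[[length(cases) + 1]] <- random_adj(n, p, seed * 100 + n)
      }
    }
  }
  # plus structured graphs
  cases[[length(cases) + 1]] <- matrix(1L, 6, 6) - diag(6L)
  ring <- matrix(0L, 6, 6)
  for (i in 1:6) ring[i, i %% 6 + 1] <- 1L
  cases[[length(cases) + 1]] <- ring + t(ring)
  for (adj in cases) {
    g <- graph_fixture(adj)
    gm <- global_metrics(g)
    nm <- nodal_metrics(g)
    expect_equal(gm$Cp, oracle_cp(adj), tolerance = 1e-10)
    expect_equal(gm$Eg, oracle_eg(adj), tolerance = 1e-10)
    if (!is.na(gm$Lp)) {
      expect_equal(gm$Lp, oracle_lp(adj), tolerance = 1e-10)
    }
    expect_equal(nm$betweenness, oracle_betweenness(adj),
                 tolerance = 1e-10)
    expect_equal(nm$degree, as.integer(rowSums(adj)))
  }
})

test_that("null ensembles preserve the degree sequence", {
  k5 <- graph_fixture(matrix(1, 5, 5) - diag(5))
  nulls <- random_null_ensemble(k5, 5, seed = 1)
  for (x in nulls) expect_identical(x$adjacency, k5$adjacency)
  m <- random_similarity(20, seed = 8)
  g <- binarize_at_sparsity(m, 0.2)
  nulls <- random_null_ensemble(g, 20, seed = 3)
  deg <- rowSums(g$adjacency)
  for (x in nulls) {
    expect_equal(rowSums(x$adjacency), deg)
    expect_identical(x$adjacency, t(x$adjacency))
    expect_true(all(diag(x$adjacency) == 0))
  }
  # reproducible
  n2 <- random_null_ensemble(g, 20, seed = 3)
  expect_identical(lapply(nulls, `[[`, "adjacency"),
                   lapply(n2, `[[`, "adjacency"))
  tiny <- graph_fixture(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_warning(random_null_ensemble(tiny, 3, seed = 1), "fewer than 2")
})

test_that("small-world normalization behaves on lattices and identities", {
  # ring lattice C10 with 2 neighbors per side: strongly clustered
  n <- 10
  adj <- matrix(0L, n, n)
  for (i in 1:n) {
    for (k in 1:2) {
      j <- (i + k - 1) %% n + 1
      adj[i, j] <- adj[j, i] <- 1L
    }
  }
  lat <- graph_fixture(adj)
  nulls <- random_null_ensemble(lat, 50, seed = 5)
  sw <- smallworld_normalize(lat, nulls)
  mean_null_cp <- mean(vapply(nulls,
                              function(x) global_metrics(x)$Cp,
                              numeric(1)))
  expect_lt(mean_null_cp, global_metrics(lat)$Cp)
  expect_gt(sw$gamma, 1)
  # algebraic identity sigma * lambda = gamma
  expect_equal(sw$sigma * sw$lambda, sw$gamma, tolerance = 1e-12)
  # g identical to every null -> all indices 1 (K5 rewires to itself)
  k5 <- graph_fixture(matrix(1, 5, 5) - diag(5))
  sw5 <- smallworld_normalize(k5, random_null_ensemble(k5, 10, seed = 1))
  expect_equal(c(sw5$gamma, sw5$lambda, sw5$sigma), c(1, 1, 1))
})

test_that("AUC across thresholds is the trapezoidal integral", {
  thr <- sparsity_grid("AAL116")
  expect_equal(metric_auc(rep(1, 26), thr), 0.25)
  expect_equal(metric_auc(c(0, 2), c(0.05, 0.06)), 0.01)
  # linearity
  set.seed(2)
  a <- runif(26); b <- runif(26)
  expect_equal(metric_auc(a + b, thr),
               metric_auc(a, thr) + metric_auc(b, thr), tolerance = 1e-12)
  expect_error(metric_auc(1, 0.05), class = "klsnet_contract_error")
  expect_error(metric_auc(c(1, 2), c(0.2, 0.1)),
               class = "klsnet_contract_error")
  expect_warning(v <- metric_auc(c(1, NA, 1), c(0.1, 0.2, 0.3)),
                 "missing")
  expect_equal(v, 0.2)
})

test_that("density curve counts suprathreshold weights", {
  m <- random_similarity(5, seed = 4)
  w <- m$values[upper.tri(m$values)]
  expect_equal(density_curve(m, min(w) / 2), 1)
  expect_equal(density_curve(m, max(w) + (1 - max(w)) / 2), 0)
  tau <- sort(w)[6]  # 4 of 10 weights strictly above
  expect_equal(density_curve(m, tau), 0.4)
  expect_error(density_curve(m, 1.5), class = "klsnet_contract_error")
})

test_that("global efficiency is monotone over nested edge sets", {
  m <- random_similarity(25, seed = 10)
  eg <- vapply(sparsity_grid("AAL116"), function(s)
    global_metrics(binarize_at_sparsity(m, s))$Eg, numeric(1))
  expect_true(all(diff(eg) >= -1e-12))
})

test_that("topology_profile assembles per-threshold metrics and AUCs", {
  m <- random_similarity(20, seed = 6)
  thr <- c(0.1, 0.2, 0.3)
  tp <- topology_profile(m, thresholds = thr, n_nulls = 10, seed = 2)
  expect_equal(tp$global$threshold, thr)
  expect_equal(nrow(tp$nodal), 3 * 20)
  expect_equal(tp$auc$global[["Eg"]],
               metric_auc(tp$global$Eg, thr))
  expect_equal(dim(tp$auc$nodal), c(20, 4))
  # identity gamma/lambda = sigma within each threshold
  ok <- !is.na(tp$global$sigma)
  expect_equal(tp$global$sigma[ok],
               (tp$global$gamma / tp$global$lambda)[ok], tolerance = 1e-12)
  # deterministic
  tp2 <- topology_profile(m, thresholds = thr, n_nulls = 10, seed = 2)
  expect_identical(tp$global, tp2$global)
})
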