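test_that("NPV is the difference of embedded class centroids", {
  cfg <- embedding_config(2, "uniform", "full")
  # identical positive and negative sets give the zero query
  q0 <- npv_fit(c("AA", "CC"), c("AA", "CC"), cfg)
  expect_equal(unname(q0$t), rep(0, 24))
  expect_equal(site_scores(q0, c("AA", "GT")), c(0, 0))

  q <- npv_fit("AA", "CC", cfg)
  nz <- q$t[q$t != 0]
  expect_equal(nz[c("A@1", "A@2", "AA@1:2")], c("A@1" = 1, "A@2" = 1,
                                                "AA@1:2" = 1))
  expect_equal(nz[c("C@1", "C@2", "CC@1:2")], c("C@1" = -1, "C@2" = -1,
                                                "CC@1:2" = -1))
  expect_equal(site_scores(q, "AA"), 3)
  expect_equal(site_scores(q, "CC"), -3)

  q2 <- npv_fit(c("AA", "AC"), "CC", cfg)
  expect_equal(unname(q2$mu_pos[c("A@2", "C@2", "G@2", "T@2")]),
               c(0.5, 0.5, 0, 0))
})

test_that("NPV score decomposes as s'mu+ minus s'mu-", {
  set.seed(43)
  cfg <- embedding_config(5, "uniform", "full")
  q <- npv_fit(rand_sites(12, 5), rand_sites(30, 5), cfg)
  for (s in rand_sites(20, 5)) {
    v <- embed_lmer(s, cfg)
    expect_equal(site_scores(q, s), sum(v * q$mu_pos) - sum(v * q$mu_neg),
                 tolerance = 1e-12)
  }
})

test_that("scaling the embedding scales the NPV query and keeps rankings", {
  set.seed(47)
  l <- 5
  P <- rand_sites(10, l)
  N <- rand_sites(40, l)
  cfg_u <- embedding_config(l, "uniform", "full")
  # constant weights c for every feature = embedding scaled by c
  cfg_c <- embedding_config(l, "ic", "full",
                            ic = uniform_ic_profile(l, 2, 2))
  qu <- npv_fit(P, N, cfg_u)
  qc <- npv_fit(P, N, cfg_c)
  expect_equal(unname(qc$t), 2 * unname(qu$t), tolerance = 1e-12)
  test <- rand_sites(30, l)
  expect_equal(auc(site_scores(qc, P), site_scores(qc, test)),
               auc(site_scores(qu, P), site_scores(qu, test)))
})

test_that("ODV reaches the hard-margin solution on separated points", {
  cfg <- embedding_config(1, "uniform", "mono")
  f <- odv_fit("A", "C", cfg, C = 100)
  expect_equal(unname(f$beta), c(1, -1, 0, 0), tolerance = 1e-6)
  expect_equal(f$b, 0, tolerance = 1e-6)
  expect_equal(unname(f$xi), c(0, 0), tolerance = 1e-8)
  expect_equal(f$objective, 1, tolerance = 1e-6)
})

test_that("ODV is antisymmetric under class swap with balanced classes", {
  set.seed(53)
  cfg <- embedding_config(4, "uniform", "full")
  P <- rand_sites(8, 4)
  N <- rand_sites(8, 4)
  f1 <- odv_fit(P, N, cfg, C = 1)
  f2 <- odv_fit(N, P, cfg, C = 1)
  expect_equal(f2$beta, -f1$beta, tolerance = 1e-5)
  expect_equal(f2$b, -f1$b, tolerance = 1e-5)
  expect_equal(f2$objective, f1$objective, tolerance = 1e-8)
})

test_that("ODV is invariant to duplicating every training site", {
  set.seed(59)
  cfg <- embedding_config(4, "uniform", "full")
  P <- rand_sites(6, 4)
  N <- rand_sites(10, 4)
  f1 <- odv_fit(P, N, cfg, C = 2^-6)
  f2 <- odv_fit(rep(P, 2), rep(N, 2), cfg, C = 2^-6)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
})

test_that("ODV agrees with an independent soft-margin reference", {
  set.seed(61)
  for (rep in 1:8) {
    l <- sample(3:6, 1)
    np <- sample(3:15, 1)
    nn <- sample(3:15, 1)
    C <- sample(c(2^-6, 1, 100), 1)
    P <- rand_sites(np, l)
    N <- rand_sites(nn, l)
    cfg <- embedding_config(l, "uniform", "full")
    fit <- odv_fit(P, N, cfg, C = C, tol = 1e-10)
    X <- rbind(embed_sites(P, cfg), embed_sites(N, cfg))
    ref <- ref_soft_margin(X, np, nn, C)
    expect_equal(fit$dual_objective, ref$dual_objective, tolerance = 1e-6)
    expect_equal(fit$objective, fit$dual_objective, tolerance = 1e-6)
    expect_equal(unname(fit$beta), ref$beta, tolerance = 1e-4)
  }
})

test_that("returned ODV solutions satisfy every constraint", {
  set.seed(67)
  cfg <- embedding_config(5, "uniform", "full")
  P <- rand_sites(10, 5)
  N <- rand_sites(20, 5)
  f <- odv_fit(P, N, cfg, C = 1)
  X <- rbind(embed_sites(P, cfg), embed_sites(N, cfg))
  y <- rep(c(1, -1), c(10, 20))
  margins <- drop(X %*% f$beta) - f$b
  expect_true(all(y * margins >= 1 - f$xi - 1e-8))
  expect_true(all(f$xi >= 0))
})

test_that("k-means subtype clustering recovers obvious partitions", {
  cfg <- embedding_config(4, "uniform", "full")
  cl <- cluster_subtypes(c("AAAA", "TTTT"), cfg, k = 2, seed = 3)
  expect_length(unique(cl$labels), 2L)
  # duplicated points: partition must equal the two identity groups,
  # which any other 2-partition of the embedded points cannot beat on SSE
  P <- c(rep("AAAA", 4), rep("TTTT", 3))
  cl2 <- cluster_subtypes(P, cfg, k = 2, seed = 5)
  expect_length(unique(cl2$labels[1:4]), 1L)
  expect_length(unique(cl2$labels[5:7]), 1L)
  expect_false(cl2$labels[1] == cl2$labels[5])
  expect_equal(cl2$tot_withinss, 0)
  expect_error(cluster_subtypes("AAAA", cfg, k = 2, seed = 1),
               "at least")
  expect_error(cluster_subtypes(rep("AAAA", 5), cfg, k = 2, seed = 1),
               "distinct")
})

test_that("kNPV scores by the best subtype branch", {
  cfg <- embedding_config(4, "uniform", "full")
  P <- c(rep("AAAA", 3), rep("TTTT", 3))
  N <- "ACGT"
  q <- knpv_fit(P, N, cfg, k = 2, seed = 7)
  mu_neg <- colMeans(embed_sites(N, cfg))
  mu_a <- colMeans(embed_sites(rep("AAAA", 3), cfg))
  s <- embed_lmer("AAAA", cfg)
  expect_equal(site_scores(q, "AAAA"), sum(s * (mu_a - mu_neg)))
  # branch scores are symmetric in the cluster labels
  branch <- drop(embed_sites("AAAA", cfg) %*% q$ts)
  expect_equal(site_scores(q, "AAAA"), max(branch))
  expect_equal(max(branch[2:1]), max(branch))
})

test_that("kODV stores unit directions and scores by their best projection", {
  set.seed(71)
  spec <- make_two_subtype_spec("ACGTAC", "TGCATG", fidelity = 1)
  drawn <- sample_sites(spec, 20, seed = 9)
  cfg <- embedding_config(6, "uniform", "full")
  N <- rand_sites(40, 6)
  q <- kodv_fit(drawn$sites, N, cfg, k = 2, seed = 11, C = 1)
  expect_equal(colSums(q$dirs^2), rep(1, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  s <- rand_sites(1, 6)
  expect_equal(site_scores(q, s),
               max(drop(embed_sites(s, cfg) %*% q$dirs)))
})
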