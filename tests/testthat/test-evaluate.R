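test_that("training negatives exclude site windows and both neighbors", {
  seqs <- c(s1 = paste(rep("A", 20), collapse = ""))
  coords <- data.frame(seq_id = "s1", start = 5)
  pool <- build_training_negatives(seqs, coords, l = 8)
  expect_equal(pool$n, 10L)  # 13 windows minus starts {4, 5, 6}
  # boundary site: only starts {0, 1} are excluded
  pool2 <- build_training_negatives(seqs,
                                    data.frame(seq_id = "s1", start = 0),
                                    l = 8)
  expect_equal(pool2$n, 11L)
  # no returned window equals a site window
  set.seed(107)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  start <- 23
  site <- substr(seq, start + 1, start + 8)
  pool3 <- build_training_negatives(c(g = seq),
                                    data.frame(seq_id = "g", start = start),
                                    l = 8)
  expect_equal(pool3$n, 53L - 3L)
  expect_false(site %in% pool3$sites)
})

test_that("ambiguous windows are dropped from the training pool", {
  seqs <- c(s1 = "AAAANAAAAAAA")
  pool <- suppressMessages(
    build_training_negatives(seqs, data.frame(seq_id = "s1", start = 0),
                             l = 4))
  expect_false(any(grepl("N", pool$sites)))
  expect_equal(attr(pool, "n_skipped"), 3L)
})

test_that("test negatives drop either-strand copies of positives", {
  pos <- c("ACGTAA", "TTTTTT")
  other <- c("ACGTAA",                       # exact copy
             "TTACGT",                       # revcomp of ACGTAA
             "GGGGGG", "CCCCCCC", "ACG")     # keep, keep (longer), drop
  out <- build_test_negatives(other, pos, l = 6)
  expect_setequal(out, c("GGGGGG", "CCCCCCC"))
  expect_error(build_test_negatives(c("ACGTAA"), pos, 6), "no test negatives")
  # distinct sites pass through unchanged
  other2 <- c("GGGGGG", "CACACA")
  expect_length(build_test_negatives(other2, pos, 6), 2L)
})

test_that("negative sampling honors the ratio, seed and pool size", {
  pool <- rand_sites(500, 6)
  s1 <- sample_negatives(pool, 20, ratio = 10, seed = 5)
  expect_length(s1, 200L)
  expect_identical(s1, sample_negatives(pool, 20, ratio = 10, seed = 5))
  expect_false(identical(s1, sample_negatives(pool, 20, ratio = 10,
                                              seed = 6)))
  small <- pool[1:30]
  expect_length(suppressMessages(
    sample_negatives(small, 20, ratio = 10, seed = 1)), 30L)
})

test_that("fold sizes follow the floor / floor + 1 rule", {
  f <- assign_folds(26, 10, seed = 3)
  expect_equal(sort(tabulate(f, 10), decreasing = TRUE),
               c(3, 3, 3, 3, 3, 3, 2, 2, 2, 2))
  expect_equal(tabulate(assign_folds(20, 10, seed = 1), 10), rep(2L, 10))
  expect_error(assign_folds(5, 10, seed = 1), "smaller than")
  set.seed(109)
  for (rep in 1:25) {
    nu <- sample(2:12, 1)
    n <- nu + sample(0:80, 1)
    f <- assign_folds(n, nu, seed = rep)
    sizes <- tabulate(f, nbins = nu)
    expect_equal(sum(sizes), n)
    expect_true(all(sizes %in% c(n %/% nu, n %/% nu + 1L)))
  }
})

test_that("inner CV prefers a pair-aware subspace for pair-driven motifs", {
  # mononucleotide columns near-uniform, strong adjacent-copy dependence:
  # only pair features carry signal
  spec <- motif_spec("ACGTACGTAC", fidelity = 0.26, pair_dependence = 0.85)
  drawn <- sample_sites(spec, 40, seed = 113)
  pool <- rand_sites(1500, 10)
  cv <- cv_config(nu = 6, seed = 11)
  sel <- select_combo(drawn$sites, pool, "npv", cv, seed = 17)
  expect_true(sel$subspace %in% c("markov", "full"))
  grid <- combo_grid()
  mono_auc <- max(sel$mean_auc[grid$subspace == "mono"])
  pair_auc <- max(sel$mean_auc[grid$subspace != "mono"])
  expect_gt(pair_auc, mono_auc + 0.05)
})

test_that("combo selection sees only training-fold positives", {
  spec <- motif_spec("ACGTAGCTAGGT", ic_per_column = 1.5)
  ds <- plant_motif(spec, 24, 30, seed = 127)
  positives <- site_set(ds$sites, coords = ds$coords)
  audit <- new.env()
  audit$seen <- list()
  recorder <- function(x) audit$seen[[length(audit$seen) + 1L]] <- x
  tracer <- bquote(.(recorder)(train_pos))
  suppressMessages(trace(select_combo, where = asNamespace("vecsite"),
                         tracer = tracer, print = FALSE))
  on.exit(suppressMessages(untrace(select_combo,
                                   where = asNamespace("vecsite"))))
  res <- run_cv(positives, ds$seqs, rand_sites(100, 12), "npv",
                cv_config(nu = 4, seed = 19))
  expect_length(audit$seen, 4L)
  for (f in 1:4) {
    test_sites <- ds$sites[res$fold_assignment == f]
    train_sites <- ds$sites[res$fold_assignment != f]
    expect_identical(audit$seen[[f]], train_sites)
  }
  # outer folds partition the positives
  idx <- sort(unlist(lapply(res$fold_indices, `[[`, "test")))
  expect_identical(idx, seq_len(24))
})

test_that("rank aggregation reproduces oracle AUCs", {
  # a scorer ranking every positive first
  expect_equal(auc_from_ranks(rep(1L, 8), rep(0L, 8), 100), 1)
  # a constant scorer ties with every negative
  expect_equal(auc_from_ranks(rep(101L, 8), rep(100L, 8), 100), 0.5)
  # agreement with pairwise counting through the rank formula
  set.seed(131)
  neg <- rnorm(50)
  pos <- rnorm(20, 0.5)
  ranks <- rank_among_negatives(pos, neg)
  ties <- vapply(pos, function(s) sum(neg == s), integer(1))
  expect_equal(auc_from_ranks(ranks, ties, 50), auc(pos, neg))
})

test_that("run_cv is reproducible from the master seed", {
  spec <- motif_spec("ACGTACAA", ic_per_column = 1.2)
  ds <- plant_motif(spec, 20, 25, seed = 137)
  positives <- site_set(ds$sites, coords = ds$coords)
  tn <- rand_sites(80, 8)
  r1 <- run_cv(positives, ds$seqs, tn, "npv", cv_config(nu = 4, seed = 23))
  r2 <- run_cv(positives, ds$seqs, tn, "npv", cv_config(nu = 4, seed = 23))
  expect_identical(r1$ranks, r2$ranks)
  expect_identical(r1$combos, r2$combos)
  expect_equal(r1$auc, r2$auc)
})

test_that("pairwise method comparison has the expected extremes", {
  A <- seq(0.9, 0.95, length.out = 26)
  tab <- cbind(A = A, B = A)
  P <- compare_methods(tab)
  expect_equal(P["A", "B"], 1)
  expect_equal(P["B", "A"], 1)
  # A strictly better everywhere: only one sign assignment reaches the
  # maximal signed-rank statistic, so the exact one-sided p is 2^-26
  tab2 <- cbind(A = A + seq(0.001, 0.026, length.out = 26), B = A)
  P2 <- compare_methods(tab2)
  expect_equal(P2["A", "B"], 2^-26, tolerance = 1e-12)
  expect_gt(P2["B", "A"], 0.99)
})
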