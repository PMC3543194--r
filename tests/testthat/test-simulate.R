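test_that("background sampling follows the transition model", {
  # absorbing chain: everything after the start is A
  bg <- manual_background(matrix(c(1, 0, 0, 0), 4, 4, byrow = TRUE,
                                 dimnames = list(c("A","C","G","T"),
                                                 c("A","C","G","T"))))
  bg$init <- c(A = 1, C = 0, G = 0, T = 0)
  s <- sample_background(3, 10, bg, seed = 2)
  expect_identical(s, rep("AAAAAAAAAA", 3))
  # determinism
  d <- default_background()
  expect_identical(sample_background(5, 40, d, seed = 9),
                   sample_background(5, 40, d, seed = 9))
  # empirical transitions over 100 kb close to the generator's
  long <- sample_background(1, 1e5, d, seed = 10)
  est <- estimate_background(long, alpha = 0)
  expect_true(max(abs(est$trans - d$trans)) < 0.02)
  bad <- d
  bad$trans[1, 1] <- 2
  expect_error(sample_background(1, 10, bad), "invalid transition")
})

test_that("fidelity_for_ic inverts the column information content", {
  for (ic in c(0.5, 1, 1.5, 1.9)) {
    p <- fidelity_for_ic(ic)
    col <- c(p, rep((1 - p) / 3, 3))
    expect_equal(2 + sum(col * log2(col)), ic, tolerance = 1e-8)
  }
  expect_equal(fidelity_for_ic(2), 1)
})

test_that("planted sites are recoverable from the recorded coordinates", {
  spec <- motif_spec("ACGTACGTACGT", ic_per_column = 1.5)
  ds <- plant_motif(spec, 30, 40, seed = 15)
  expect_identical(
    unname(substring(ds$seqs, ds$coords$start + 1, ds$coords$end)),
    ds$sites)
  expect_true(all(nchar(ds$seqs) == 12 + 2 * 40))
  # degenerate spec: every site equals the consensus
  ds2 <- plant_motif(motif_spec("ACGTAC", fidelity = 1), 10, 5, seed = 16)
  expect_true(all(ds2$sites == "ACGTAC"))
  # reproducibility
  ds3 <- plant_motif(spec, 30, 40, seed = 15)
  expect_identical(ds$seqs, ds3$seqs)
})

test_that("planted column IC approaches the specification", {
  spec <- motif_spec("ACGTACGTACGT", ic_per_column = 1.5)
  drawn <- sample_sites(spec, 5000, seed = 17)
  ic <- information_content(estimate_frequencies(drawn$sites, alpha = 0))
  expect_true(max(abs(ic$mono - 1.5)) < 0.05)
})

test_that("two-subtype specs mix subtypes and are cluster-recoverable", {
  spec <- make_two_subtype_spec("ACGTACGTACGT", "ACGTACCATGTA",
                                fidelity = 0.9)
  drawn <- sample_sites(spec, 200, seed = 19)
  expect_setequal(unique(drawn$subtype), c(1L, 2L))
  expect_gt(mean(drawn$subtype == 1), 0.35)
  # fidelity 1: every site is one of the two consensi
  exact <- sample_sites(make_two_subtype_spec("AAAAAA", "TTTTTT",
                                              fidelity = 1), 50, seed = 20)
  expect_true(all(exact$sites %in% c("AAAAAA", "TTTTTT")))
  expect_identical(exact$sites == "AAAAAA", exact$subtype == 1L)
  # k-means on embedded sites recovers the subtype labels
  cfg <- embedding_config(12, "uniform", "full")
  cl <- cluster_subtypes(drawn$sites, cfg, k = 2, seed = 21)
  agree <- max(mean(cl$labels == drawn$subtype),
               mean(cl$labels == 3L - drawn$subtype))
  expect_gte(agree, 0.95)
})

test_that("identical consensi collapse to a single effective subtype", {
  spec <- make_two_subtype_spec("ACGTAC", "ACGTAC", fidelity = 0.95)
  drawn <- sample_sites(spec, 60, seed = 22)
  cfg <- embedding_config(6, "uniform", "full")
  N <- rand_sites(100, 6)
  qk <- knpv_fit(drawn$sites, N, cfg, k = 2, seed = 23)
  q1 <- npv_fit(drawn$sites, N, cfg)
  test <- rand_sites(50, 6)
  # max over two near-identical branches tracks the single-branch score
  expect_equal(site_scores(qk, test), site_scores(q1, test),
               tolerance = 0.35)
})

test_that("datasets round-trip through FASTA + BED", {
  spec <- motif_spec("ACGTACGT", ic_per_column = 1.3)
  ds <- plant_motif(spec, 12, 20, seed = 25)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  seqs <- read_fasta(paths$fasta)
  bed <- read_intervals(paths$bed)
  expect_identical(unname(seqs[bed$chrom]), unname(ds$seqs[bed$chrom]))
  re_extracted <- substring(seqs[bed$chrom], bed$start + 1, bed$end)
  expect_identical(unname(re_extracted), ds$sites)
  expect_identical(read_sites(paths$sites)$sites, ds$sites)
  manifest <- read_config(paths$manifest)
  expect_identical(unname(manifest["seed"]), "25")
})
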