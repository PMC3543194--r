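# Cross-validation protocol: negative construction, fold assignment,
# nested weight/subspace selection, rank-based AUC and method comparison.

#' Cross-validation configuration
#'
#' @param nu Number of outer folds (default 10); the inner selection CV
#'   uses `nu - 1` folds on the training sites.
#' @param negative_ratio Ratio of sampled training negatives to training
#'   positives (default 10).
#' @param C Soft-margin cost for ODV-family fits (default `2^-6`).
#' @param k Number of motif subtypes for the k-variants (default 2).
#' @param alpha Pseudocount for frequency and IC estimation.
#' @param seed Master seed; all fold assignment, negative sampling and
#'   clustering randomness is derived deterministically from it.
#' @param combos Candidate weight/subspace grid searched by the inner CV,
#'   a `data.frame` with columns `weights` and `subspace`; ties are broken
#'   by grid order.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(nu = 10L, negative_ratio = 10, C = 2^-6, k = 2L,
                      alpha = 1, seed = 1L, combos = combo_grid()) {
  stopifnot(nu >= 2L, negative_ratio > 0, C > 0, alpha >= 0)
  structure(
    list(nu = as.integer(nu), negative_ratio = negative_ratio, C = C,
         k = as.integer(k), alpha = alpha, seed = as.integer(seed),
         combos = combos),
    class = "cv_config"
  )
}

#' Default weight/subspace search grid
#'
#' @return `data.frame` of the six combinations `{uniform, ic} x
#'   {mono, markov, full}`.
#' @export
combo_grid <- function() {
  expand.grid(subspace = c("mono", "markov", "full"),
              weights = c("uniform", "ic"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
}

#' Build the training negative pool from embedding sequences
#'
#' All l-length windows of the sequences embedding the binding sites,
#' excluding each site's own window and the two neighboring windows
#' (start offsets -1 and +1).  Windows containing non-ACGT characters are
#' skipped; their count is attached as attribute `n_skipped`.
#'
#' @param seqs Named character vector of embedding sequences.
#' @param coords `data.frame` with columns `seq_id` and `start` (0-based)
#'   locating each site in `seqs`.
#' @param l Site length.
#' @return A [site_set()] of negative l-mers (attribute `n_skipped`).
#' @export
build_training_negatives <- function(seqs, coords, l) {
  stopifnot(is.data.frame(coords), all(c("seq_id", "start") %in% names(coords)))
  seqs <- toupper(seqs)
  if (is.null(names(seqs))) {
    stop("`seqs` must be named so coordinates can be resolved", call. = FALSE)
  }
  if (!all(coords$seq_id %in% names(seqs))) {
    stop("coordinate seq_id not found among sequences", call. = FALSE)
  }
  out <- character(0)
  n_skipped <- 0L
  for (id in names(seqs)) {
    s <- seqs[[id]]
    L <- nchar(s)
    if (L < l) next
    starts0 <- 0:(L - l)  # 0-based
    site_starts <- coords$start[coords$seq_id == id]
    if (any(site_starts < 0 | site_starts > L - l)) {
      stop(sprintf("site coordinates out of range for sequence '%s'", id),
           call. = FALSE)
    }
    excl <- unique(c(site_starts - 1L, site_starts, site_starts + 1L))
    keep <- setdiff(starts0, excl)
    if (length(keep) == 0L) next
    win <- substring(s, keep + 1L, keep + l)
    ok <- !grepl("[^ACGT]", win)
    n_skipped <- n_skipped + sum(!ok)
    out <- c(out, win[ok])
  }
  if (length(out) == 0L) {
    stop("no training negatives could be constructed", call. = FALSE)
  }
  if (n_skipped > 0L) {
    message(sprintf("build_training_negatives: skipped %d window(s) with non-ACGT characters",
                    n_skipped))
  }
  res <- site_set(out)
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Build test negatives from the sites of other transcription factors
#'
#' Filters a pool of other-TF binding sites: entries identical to a
#' positive on either strand are removed, entries shorter than `l` are
#' removed, entries longer than `l` are kept whole (they are later scored
#' by their best window).
#'
#' @param other_sites Character vector of other-TF sites (any lengths).
#' @param positives Positive sites (character vector or [site_set()]).
#' @param l Site length of the positives.
#' @return Character vector of test negatives.
#' @export
build_test_negatives <- function(other_sites, positives, l) {
  other_sites <- toupper(as.character(other_sites))
  pos <- as_site_chr(positives)
  banned <- unique(c(pos, reverse_complement(pos)))
  keep <- nchar(other_sites) >= l & !(other_sites %in% banned)
  out <- other_sites[keep]
  if (length(out) == 0L) {
    stop("no test negatives remain after filtering", call. = FALSE)
  }
  out
}

#' Sample training negatives at a fixed ratio
#'
#' Draws `min(floor(ratio * n_pos), |pool|)` sites uniformly without
#' replacement, reproducibly for a fixed seed.
#'
#' @param pool Negative pool (character vector or [site_set()]).
#' @param n_pos Number of training positives.
#' @param ratio Negative:positive ratio (default 10).
#' @param seed Integer seed.
#' @return Character vector of sampled negatives.
#' @export
sample_negatives <- function(pool, n_pos, ratio = 10, seed = 1L) {
  pool <- as_site_chr(pool)
  stopifnot(length(pool) > 0L, n_pos >= 1L)
  want <- floor(ratio * n_pos)
  n <- min(want, length(pool))
  if (n < want) {
    message(sprintf("sample_negatives: pool (%d) smaller than requested (%d); using whole pool",
                    length(pool), want))
  }
  idx <- with_preserved_seed({
    set.seed(seed)
    sample.int(length(pool), n)
  })
  pool[idx]
}

#' Assign positives to cross-validation folds
#'
#' Seeded random permutation followed by round-robin assignment, so fold
#' sizes are `floor(n_pos / nu)` or `floor(n_pos / nu) + 1`.
#'
#' @param n_pos Number of positives.
#' @param nu Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..nu`.
#' @export
assign_folds <- function(n_pos, nu, seed = 1L) {
  if (nu < 2L) stop("`nu` must be at least 2", call. = FALSE)
  if (n_pos < nu) {
    stop(sprintf("n_pos = %d is smaller than nu = %d folds", n_pos, nu),
         call. = FALSE)
  }
  perm <- with_preserved_seed({
    set.seed(seed)
    sample.int(n_pos)
  })
  folds <- integer(n_pos)
  folds[perm] <- rep_len(seq_len(nu), n_pos)
  folds
}

# fit one scorer for a given method and weight/subspace combination
fit_scorer <- function(method, P, N, l, combo, cv, background = NULL,
                       seed = 1L) {
  cfg <- if (identical(combo$weights, "ic")) {
    embedding_config(l, "ic", combo$subspace,
                     ic = ic_weights(P, alpha = cv$alpha))
  } else {
    embedding_config(l, "uniform", combo$subspace)
  }
  switch(method,
    npv  = npv_fit(P, N, cfg),
    odv  = odv_fit(P, N, cfg, C = cv$C),
    knpv = knpv_fit(P, N, cfg, k = cv$k, seed = seed),
    kodv = kodv_fit(P, N, cfg, k = cv$k, seed = seed, C = cv$C),
    pssm = pssm_fit(P, alpha = cv$alpha),
    ulpb = ulpb_fit(P, background, alpha = cv$alpha),
    stop(sprintf("unknown method '%s'", method), call. = FALSE)
  )
}

methods_with_combo <- c("npv", "odv", "knpv", "kodv")

#' Inner cross-validation for weight/subspace selection
#'
#' Runs an inner `nu - 1`-fold CV on the training positives only.  In each
#' inner fold a fit-negative and a disjoint evaluation-negative sample are
#' drawn from the training negative pool, every combination in the grid is
#' fitted on the inner-training positives and scored on the held-out
#' positives versus the evaluation negatives, and the combination with the
#' highest mean inner AUC wins (ties broken by grid order).  Test-fold
#' sites and external test negatives are never touched.
#'
#' @param train_pos Training positives (character vector).
#' @param neg_pool Training negative pool.
#' @param method One of `"npv"`, `"odv"`, `"knpv"`, `"kodv"`.
#' @param cv A [cv_config()].
#' @param seed Integer seed for inner folds and sampling.
#' @return List with `weights`, `subspace` and the matrix of per-fold
#'   inner AUCs (`auc_matrix`, folds x combos).
#' @export
select_combo <- function(train_pos, neg_pool, method, cv, seed = 1L) {
  stopifnot(method %in% methods_with_combo)
  train_pos <- as_site_chr(train_pos)
  pool <- as_site_chr(neg_pool)
  n <- length(train_pos)
  nu_in <- cv$nu - 1L
  l <- nchar(train_pos[1L])
  folds <- assign_folds(n, nu_in, derive_seed(seed, 11L))
  combos <- cv$combos
  aucs <- matrix(NA_real_, nu_in, nrow(combos))
  for (f in seq_len(nu_in)) {
    it <- train_pos[folds != f]
    iv <- train_pos[folds == f]
    idx_fit <- with_preserved_seed({
      set.seed(derive_seed(seed, 13L, f))
      sample.int(length(pool), min(floor(cv$negative_ratio * length(it)),
                                   length(pool)))
    })
    remaining <- setdiff(seq_len(length(pool)), idx_fit)
    if (length(remaining) == 0L) {
      stop("training negative pool too small for inner-CV evaluation",
           call. = FALSE)
    }
    idx_eval <- with_preserved_seed({
      set.seed(derive_seed(seed, 17L, f))
      remaining[sample.int(length(remaining),
                           min(floor(cv$negative_ratio * length(iv)),
                               length(remaining)))]
    })
    fit_negs <- pool[idx_fit]
    eval_negs <- pool[idx_eval]
    for (cmb in seq_len(nrow(combos))) {
      scorer <- fit_scorer(method, it, fit_negs, l, combos[cmb, ], cv,
                           seed = derive_seed(seed, 19L, f, cmb))
      aucs[f, cmb] <- auc(score_sites_bidir(scorer, iv),
                          score_sites_bidir(scorer, eval_negs))
    }
  }
  mean_auc <- colMeans(aucs)
  best <- which.max(mean_auc)  # first maximum = grid order tie-break
  list(weights = combos$weights[best], subspace = combos$subspace[best],
       mean_auc = mean_auc, auc_matrix = aucs)
}

#' Run the nu-fold cross-validation protocol for one method
#'
#' For each outer fold: the held-out positives form the test set; the
#' method is fitted on the remaining positives plus negatives sampled at
#' the configured ratio from the training negative pool (built from the
#' embedding sequences, excluding every site window and its two
#' neighbors).  For NPV/ODV-family methods the weight/subspace combination
#' is first chosen by an inner `nu - 1`-fold CV on the training positives.
#' Test positives and the external test negatives are scored by their
#' best l-mer window on either strand; each positive's rank among the test
#' negatives is `1 + #{negatives scoring >= it}`.  The overall AUC uses
#' the half-tie Mann-Whitney convention.
#'
#' @param positives A [site_set()] with coordinates into `embedding_seqs`.
#' @param embedding_seqs Named character vector of sequences containing
#'   the positives (source of training negatives and of the ULPB
#'   background).
#' @param test_negatives Character vector of test-negative sequences
#'   (lengths >= l), e.g. from [build_test_negatives()].
#' @param method One of `"npv"`, `"odv"`, `"knpv"`, `"kodv"`, `"pssm"`,
#'   `"ulpb"`.
#' @param config A [cv_config()].
#' @return Object of class `eval_result`: `ranks` data.frame (one row per
#'   positive: `site`, `fold`, `score`, `rank`, `n_ties`), `auc`,
#'   `combos` per fold, `n_neg`, `fold_assignment`, `method`, `config`.
#' @export
run_cv <- function(positives, embedding_seqs, test_negatives, method,
                   config = cv_config()) {
  stopifnot(inherits(positives, "site_set"), inherits(config, "cv_config"))
  method <- match.arg(method, c("npv", "odv", "knpv", "kodv", "pssm", "ulpb"))
  l <- positives$l
  sites <- positives$sites
  n_pos <- positives$n
  if (any(nchar(test_negatives) < l)) {
    stop("test negatives shorter than l present; filter them first",
         call. = FALSE)
  }
  needs_negatives <- method %in% methods_with_combo
  pool <- NULL
  if (needs_negatives) {
    if (is.null(positives$coords)) {
      stop("positives need coordinates to build training negatives",
           call. = FALSE)
    }
    pool <- build_training_negatives(embedding_seqs, positives$coords, l)
  }
  background <- if (method == "ulpb") {
    estimate_background(embedding_seqs, alpha = config$alpha)
  } else {
    NULL
  }
  seed <- config$seed
  folds <- assign_folds(n_pos, config$nu, derive_seed(seed, 1L))
  ranks <- data.frame(site = sites, fold = folds, score = NA_real_,
                      rank = NA_integer_, n_ties = NA_integer_,
                      stringsAsFactors = FALSE)
  combos <- data.frame(fold = seq_len(config$nu),
                       weights = NA_character_, subspace = NA_character_,
                       stringsAsFactors = FALSE)
  fold_indices <- vector("list", config$nu)
  n_neg <- length(test_negatives)
  for (f in seq_len(config$nu)) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    fold_indices[[f]] <- list(train = train_idx, test = test_idx)
    train_pos <- sites[train_idx]
    if (needs_negatives) {
      combo <- select_combo(train_pos, pool, method, config,
                            seed = derive_seed(seed, 2L, f))
      negs <- sample_negatives(pool, length(train_pos),
                               ratio = config$negative_ratio,
                               seed = derive_seed(seed, 3L, f))
      scorer <- fit_scorer(method, train_pos, negs, l,
                           list(weights = combo$weights,
                                subspace = combo$subspace),
                           config, seed = derive_seed(seed, 4L, f))
      combos$weights[f] <- combo$weights
      combos$subspace[f] <- combo$subspace
    } else {
      scorer <- fit_scorer(method, train_pos, NULL, l,
                           list(weights = "uniform", subspace = "mono"),
                           config, background = background)
    }
    pos_scores <- score_sequences(sites[test_idx], scorer, l = l)
    neg_scores <- score_sequences(test_negatives, scorer, l = l)
    ranks$score[test_idx] <- pos_scores
    ranks$rank[test_idx] <- rank_among_negatives(pos_scores, neg_scores)
    ranks$n_ties[test_idx] <- vapply(pos_scores, function(s) {
      sum(neg_scores == s)
    }, integer(1))
  }
  structure(
    list(method = method, ranks = ranks,
         auc = auc_from_ranks(ranks$rank, ranks$n_ties, n_neg),
         combos = if (needs_negatives) combos else NULL,
         n_neg = n_neg, fold_assignment = folds,
         fold_indices = fold_indices, config = config),
    class = "eval_result"
  )
}

#' AUC from ranks among a fixed negative set
#'
#' Converts per-positive ranks (`1 + #{neg >= pos}`) and tie counts into
#' the half-tie Mann-Whitney AUC: the mean over positives of
#' `(n_neg - (rank - 1) + n_ties / 2) / n_neg`.
#'
#' @param ranks Integer ranks.
#' @param n_ties Number of negatives tied with each positive.
#' @param n_neg Size of the negative set.
#' @return AUC in [0, 1].
#' @export
auc_from_ranks <- function(ranks, n_ties, n_neg) {
  mean((n_neg - (ranks - 1) + n_ties / 2) / n_neg)
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: method = %s, %d positives vs %d test negatives\n",
              x$method, nrow(x$ranks), x$n_neg))
  cat(sprintf("  AUC = %.4f (median rank %d)\n", x$auc,
              as.integer(stats::median(x$ranks$rank))))
  if (!is.null(x$combos)) {
    tab <- table(paste(x$combos$weights, x$combos$subspace))
    cat("  chosen combos:", paste(names(tab), tab, sep = " x ",
                                  collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pairwise comparison of methods across transcription factors
#'
#' One-sided Wilcoxon signed-rank tests on paired per-TF AUCs for every
#' ordered pair of methods.  Entry (i, j) is the p-value for "method i
#' outperforms method j".  A pair with all-zero differences reports p = 1.
#' At least ~6 paired observations are needed for the test to reach
#' conventional significance levels.
#'
#' @param auc_table Numeric matrix or data.frame, one row per TF, one
#'   column per method.
#' @return Square matrix of p-values with NA on the diagonal.
#' @export
compare_methods <- function(auc_table) {
  M <- as.matrix(auc_table)
  stopifnot(is.numeric(M), ncol(M) >= 2L, nrow(M) >= 2L)
  k <- ncol(M)
  P <- matrix(NA_real_, k, k, dimnames = list(colnames(M), colnames(M)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      d <- M[, i] - M[, j]
      P[i, j] <- if (all(d == 0)) {
        1
      } else {
        suppressWarnings(
          stats::wilcox.test(M[, i], M[, j], paired = TRUE,
                             alternative = "greater")$p.value
        )
      }
    }
  }
  P
}
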