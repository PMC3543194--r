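# Shared fixtures and independent oracles used across the suite.

rand_sites <- function(n, l) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# string-comparison oracle for uniform-weight full-subspace scores:
# number of equal nucleotides plus equal adjacent and gap-1 pairs
str_match_score <- function(s, t) {
  a <- strsplit(s, "")[[1]]
  b <- strsplit(t, "")[[1]]
  l <- length(a)
  mono <- sum(a == b)
  adj <- sum(a[-l] == b[-l] & a[-1] == b[-1])
  gap <- if (l >= 3) {
    i <- seq_len(l - 2)
    sum(a[i] == b[i] & a[i + 2] == b[i + 2])
  } else 0
  mono + adj + gap
}

# brute-force Mann-Whitney AUC by pair counting with half-tie credit
brute_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# independent reference for the class-weighted soft-margin separator
# (libsvm via e1071, per-class upper bounds C/n+ and C/n-)
ref_soft_margin <- function(X, np, nn, C, tolerance = 1e-9) {
  y <- factor(rep(c("pos", "neg"), c(np, nn)), levels = c("pos", "neg"))
  m <- e1071::svm(X, y, kernel = "linear", scale = FALSE, cost = 1,
                  class.weights = c(pos = C / np, neg = C / nn),
                  tolerance = tolerance)
  a <- abs(as.vector(m$coefs))
  sv <- X[m$index, , drop = FALSE]
  ysv <- ifelse(y[m$index] == "pos", 1, -1)
  beta <- unname(drop(crossprod(sv, a * ysv)))
  K <- tcrossprod(sv)
  dual <- sum(a) - 0.5 * drop(t(a * ysv) %*% K %*% (a * ysv))
  list(beta = beta, b = m$rho, dual_objective = dual)
}

# exhaustive both-strand window-scan oracle
exhaustive_best_hit <- function(seq, scorer, l) {
  L <- nchar(seq)
  best <- NULL
  for (start0 in 0:(L - l)) {
    w <- substr(seq, start0 + 1, start0 + l)
    if (grepl("[^ACGT]", w)) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") w else reverse_complement(w)
      sc <- site_scores(scorer, s)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && start0 < best$start) ||
          (sc == best$score && start0 == best$start && strand == "+" &&
           best$strand == "-")) {
        best <- list(start = start0, strand = strand, score = sc)
      }
    }
  }
  best
}

# freq_model constructed by hand (for scoring-formula micro-examples)
manual_freq_model <- function(mono, pos_trans, l) {
  structure(
    list(l = l, n = NA_integer_, alpha = NA_real_, mono = mono,
         mono_counts = NULL, adj = NULL, gap = NULL,
         pos_trans = pos_trans),
    class = "freq_model"
  )
}

manual_background <- function(trans) {
  structure(
    list(trans = trans, init = rep(0.25, 4), n_dinuc = NA, n_skipped = 0L,
         alpha = NA_real_),
    class = "background_model"
  )
}

uniform_ic_profile <- function(l, w_mono, w_pair) {
  structure(
    list(mono = rep(w_mono, l), adj = rep(w_pair, l - 1),
         gap = if (l >= 3) rep(w_pair, l - 2) else NULL),
    class = "ic_profile"
  )
}
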