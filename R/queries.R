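# Query-vector construction: NPV (mean difference), ODV (soft-margin
# quadratic program) and their two-subtype variants.

#' Fit a negative-to-positive query vector (NPV)
#'
#' Embeds positives and negatives and returns the vector pointing from the
#' centroid of the embedded non-binding sites to the centroid of the
#' embedded binding sites, `t = mu_plus - mu_minus`.  Scoring an l-mer with
#' the result takes the dot product with `t`, i.e. the difference between
#' its similarity to the positive centroid and to the negative centroid.
#'
#' @param P Positive sites (character vector or [site_set()]), all of
#'   length `cfg$l`.
#' @param N Negative sites, same length.
#' @param cfg An [embedding_config()].
#' @return Object of class `c("npv_query", "tfbs_scorer")` with the query
#'   vector `t`, the two centroids and `cfg`.
#' @export
npv_fit <- function(P, N, cfg) {
  XP <- embed_sites(P, cfg)
  XN <- embed_sites(N, cfg)
  mu_pos <- colMeans(XP)
  mu_neg <- colMeans(XN)
  structure(
    list(t = mu_pos - mu_neg, mu_pos = mu_pos, mu_neg = mu_neg, cfg = cfg),
    class = c("npv_query", "tfbs_scorer")
  )
}

#' Fit an optimal discriminating vector (ODV)
#'
#' Solves the class-weighted soft-margin quadratic program
#' \deqn{\min_{\beta, b, \xi} \tfrac12\|\beta\|^2
#'   + \tfrac{C}{n_+}\sum_{i \le n_+} \xi_i
#'   + \tfrac{C}{n_-}\sum_{i > n_+} \xi_i}
#' subject to \eqn{\beta^\top s_{(i)} \ge b + 1 - \xi_i} for positives,
#' \eqn{\beta^\top s_{(i)} \le b - 1 + \xi_i} for negatives and
#' \eqn{\xi_i \ge 0}.  The dual is solved by sequential minimal
#' optimization to the KKT tolerance `tol`; slacks are recovered from
#' `(beta, b)` so the returned solution is feasible by construction.
#'
#' @inheritParams npv_fit
#' @param C Soft-margin cost, `> 0`; the per-class per-example costs are
#'   `C/n_plus` and `C/n_minus`.  The default `2^-6` works well across
#'   transcription factors.
#' @param tol KKT convergence tolerance of the solver.
#' @param max_iter Iteration cap for the solver.
#' @return Object of class `c("odv_query", "tfbs_scorer")`: `beta`, `b`,
#'   `xi`, `alpha` (dual variables), `objective` (primal value),
#'   `dual_objective`, `kkt_gap`, `iterations`, `C`, `cfg`.
#' @export
odv_fit <- function(P, N, cfg, C = 2^-6, tol = 1e-8, max_iter = 1e7) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    stop("`C` must be a positive scalar", call. = FALSE)
  }
  XP <- embed_sites(P, cfg)
  XN <- embed_sites(N, cfg)
  np <- nrow(XP)
  nn <- nrow(XN)
  X <- rbind(XP, XN)
  y <- rep(c(1L, -1L), c(np, nn))
  Cvec <- rep(c(C / np, C / nn), c(np, nn))
  K <- tcrossprod(X)
  sol <- .smo_solve(K, y, Cvec, tol = tol, max_iter = as.integer(max_iter))
  if (!sol$converged) {
    stop(sprintf(
      "ODV solver did not converge: KKT gap %.3g after %d iterations",
      sol$kkt_gap, sol$iterations), call. = FALSE)
  }
  beta <- drop(crossprod(X, sol$alpha * y))
  b <- sol$b
  margins <- drop(X %*% beta) - b
  xi <- pmax(0, 1 - y * margins)
  objective <- 0.5 * sum(beta^2) + sum(Cvec * xi)
  structure(
    list(beta = beta, b = b, xi = xi, alpha = sol$alpha,
         objective = objective, dual_objective = sol$dual_objective,
         kkt_gap = sol$kkt_gap, iterations = sol$iterations,
         C = C, n_pos = np, n_neg = nn, cfg = cfg),
    class = c("odv_query", "tfbs_scorer")
  )
}

#' Cluster binding sites into motif subtypes
#'
#' Runs k-means (Euclidean, Lloyd iterations) on the embedded sites with
#' `restarts` seeded initializations, keeping the partition with the lowest
#' within-cluster sum of squares.  Restarts that produce an empty cluster
#' are discarded; after `max_retries` rounds of additional restarts without
#' a valid partition an error is raised.
#'
#' @param P Sites to cluster.
#' @param cfg An [embedding_config()].
#' @param k Number of subtypes (default 2).
#' @param seed Integer seed making the clustering reproducible.
#' @param restarts Random initializations per round.
#' @param max_retries Additional rounds allowed when all restarts fail.
#' @return List with `labels` (integer vector), `centers` (k x dim),
#'   `tot_withinss`, `k`, `seed`.
#' @export
cluster_subtypes <- function(P, cfg, k = 2L, seed = 1L, restarts = 10L,
                             max_retries = 5L) {
  X <- embed_sites(P, cfg)
  n <- nrow(X)
  if (n < k) stop(sprintf("need at least k = %d sites, got %d", k, n),
                  call. = FALSE)
  ux <- unique(X)
  if (nrow(ux) < k) {
    stop(sprintf("only %d distinct embedded sites; cannot form %d clusters",
                 nrow(ux), k), call. = FALSE)
  }
  best <- NULL
  with_preserved_seed({
    set.seed(seed)
    for (round in seq_len(max_retries + 1L)) {
      for (r in seq_len(restarts)) {
        init <- ux[sample.int(nrow(ux), k), , drop = FALSE]
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(X, centers = init,
                                         iter.max = 100L,
                                         algorithm = "Lloyd")),
          error = function(e) NULL
        )
        if (is.null(fit) || any(fit$size == 0L)) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) {
          best <- fit
        }
      }
      if (!is.null(best)) break
    }
  })
  if (is.null(best)) {
    stop("k-means produced an empty cluster in every restart", call. = FALSE)
  }
  list(labels = unname(best$cluster), centers = unname(best$centers),
       tot_withinss = best$tot.withinss, k = k, seed = seed)
}

#' Fit a k-subtype NPV query
#'
#' Clusters the positives into `k` subtypes in embedding space, computes
#' one positive centroid per subtype and scores an l-mer by the maximum
#' over subtypes of its NPV score, `max_m s' (mu_plus_m - mu_minus)`, with
#' a single shared negative centroid.
#'
#' @inheritParams npv_fit
#' @inheritParams cluster_subtypes
#' @return Object of class `c("knpv_query", "tfbs_scorer")` with the
#'   per-subtype query matrix `ts` (dim x k), `mu_neg`, cluster `labels`,
#'   `cfg`.
#' @export
knpv_fit <- function(P, N, cfg, k = 2L, seed = 1L) {
  P <- as_site_chr(P)
  cl <- cluster_subtypes(P, cfg, k = k, seed = seed)
  XN <- embed_sites(N, cfg)
  mu_neg <- colMeans(XN)
  ts <- vapply(seq_len(k), function(m) {
    colMeans(embed_sites(P[cl$labels == m], cfg)) - mu_neg
  }, numeric(subspace_dim(cfg$l, cfg$subspace)))
  structure(
    list(ts = ts, mu_neg = mu_neg, labels = cl$labels, k = k,
         seed = seed, cfg = cfg),
    class = c("knpv_query", "tfbs_scorer")
  )
}

#' Fit a k-subtype ODV query
#'
#' Clusters the positives into `k` subtypes, fits one ODV per subtype
#' against the shared negative set, normalizes each discriminating vector
#' to unit length (their raw lengths are not comparable) and scores an
#' l-mer by `max_m s' beta_m / ||beta_m||`.  The per-subtype intercepts are
#' not used for scoring.
#'
#' @inheritParams odv_fit
#' @inheritParams cluster_subtypes
#' @return Object of class `c("kodv_query", "tfbs_scorer")` with unit
#'   direction matrix `dirs` (dim x k), the per-subtype `fits`, cluster
#'   `labels`, `cfg`.
#' @export
kodv_fit <- function(P, N, cfg, k = 2L, seed = 1L, C = 2^-6, tol = 1e-8) {
  P <- as_site_chr(P)
  cl <- cluster_subtypes(P, cfg, k = k, seed = seed)
  fits <- lapply(seq_len(k), function(m) {
    odv_fit(P[cl$labels == m], N, cfg, C = C, tol = tol)
  })
  dirs <- vapply(fits, function(f) f$beta / sqrt(sum(f$beta^2)),
                 numeric(subspace_dim(cfg$l, cfg$subspace)))
  structure(
    list(dirs = dirs, fits = fits, labels = cl$labels, k = k,
         seed = seed, C = C, cfg = cfg),
    class = c("kodv_query", "tfbs_scorer")
  )
}

#' Score aligned l-mers with a fitted scorer
#'
#' Generic dispatch over the scorer classes (`npv_query`, `odv_query`,
#' `knpv_query`, `kodv_query`, `pssm_scorer`, `ulpb_scorer`).  Sites must
#' have the scorer's length; scoring is strand-specific (see
#' [score_sites_bidir()] for both-strand scoring).
#'
#' @param scorer A fitted scorer.
#' @param sites Character vector of l-mers or a [site_set()].
#' @return Numeric vector of scores.
#' @export
site_scores <- function(scorer, sites) UseMethod("site_scores")

#' @export
site_scores.npv_query <- function(scorer, sites) {
  unname(drop(embed_sites(sites, scorer$cfg) %*% scorer$t))
}

#' @export
site_scores.odv_query <- function(scorer, sites) {
  unname(drop(embed_sites(sites, scorer$cfg) %*% scorer$beta))
}

#' @export
site_scores.knpv_query <- function(scorer, sites) {
  S <- embed_sites(sites, scorer$cfg) %*% scorer$ts
  unname(apply(S, 1L, max))
}

#' @export
site_scores.kodv_query <- function(scorer, sites) {
  S <- embed_sites(sites, scorer$cfg) %*% scorer$dirs
  unname(apply(S, 1L, max))
}

#' Score l-mers on both strands
#'
#' Scores each site and its reverse complement and returns the per-site
#' maximum, as in the evaluation protocol where candidate words may bind
#' either strand.
#'
#' @inheritParams site_scores
#' @return Numeric vector of scores.
#' @export
score_sites_bidir <- function(scorer, sites) {
  sites <- as_site_chr(sites)
  pmax(site_scores(scorer, sites),
       site_scores(scorer, reverse_complement(sites)))
}

# length of the l-mers a scorer expects
scorer_length <- function(scorer) {
  if (!is.null(scorer$cfg)) scorer$cfg$l else scorer$l
}
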