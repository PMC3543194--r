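# Indicator-variable embedding of fixed-length DNA words and dot-product
# scoring against query vectors.

.BASES <- c("A", "C", "G", "T")
.PAIRS <- as.vector(outer(.BASES, .BASES, function(a, b) paste0(a, b)))
# .PAIRS order is second-letter major under outer(); the embedding uses
# first-letter-major order (AA, AC, AG, AT, CA, ...) so pair code is
# 4*(first - 1) + second.
.PAIR_NAMES <- as.vector(t(outer(.BASES, .BASES, function(a, b) paste0(a, b))))

#' Dimension of an embedding subspace
#'
#' An l-mer is embedded with 4 indicator variables per nucleotide and 16 per
#' nucleotide pair; pairs are considered only when adjacent or separated by
#' one position.  The three supported subspaces are `mono` (single
#' nucleotides only, dimension 4l), `markov` (first nucleotide plus the l-1
#' adjacent pairs, as in a first-order Markov chain, dimension 16l-12) and
#' `full` (nucleotides plus adjacent and gap-1 pairs, dimension 36l-48).
#'
#' @param l Site length (nucleotides).
#' @param subspace One of `"mono"`, `"markov"`, `"full"`.
#' @return Integer dimension of the subspace.
#' @examples
#' subspace_dim(8, "full")   # 240
#' subspace_dim(10, "markov") # 148
#' @export
subspace_dim <- function(l, subspace = c("full", "markov", "mono")) {
  subspace <- match.arg(subspace)
  l <- check_length_for_subspace(l, subspace)
  switch(subspace,
    mono   = 4L * l,
    markov = 16L * l - 12L,
    full   = 36L * l - 48L
  )
}

check_length_for_subspace <- function(l, subspace) {
  if (length(l) != 1L || !is.finite(l) || l != as.integer(l)) {
    stop("`l` must be a single integer", call. = FALSE)
  }
  l <- as.integer(l)
  # full needs l >= 2: the gap-1 block is then empty and 36l - 48 still
  # equals 4l + 16(l - 1)
  min_l <- switch(subspace, mono = 1L, markov = 2L, full = 2L)
  if (l < min_l) {
    stop(sprintf("subspace '%s' requires l >= %d (got l = %d)",
                 subspace, min_l, l), call. = FALSE)
  }
  l
}

#' Embedding configuration
#'
#' Bundles the site length, the weight scheme and the subspace used to embed
#' l-mers.  Uniform weights set every indicator weight to 1; information
#' content (IC) weights multiply the indicators of position i by IC_i (in
#' [0, 2]) and those of a position pair by the pair IC (in [0, 4]).  IC
#' weights must be supplied through `ic`, typically from
#' [information_content()] computed on training sites only.
#'
#' @param l Site length.
#' @param weights `"uniform"` or `"ic"`.
#' @param subspace `"mono"`, `"markov"` or `"full"`.
#' @param ic An information profile (see [information_content()]); required
#'   when `weights = "ic"`.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(l,
                             weights = c("uniform", "ic"),
                             subspace = c("full", "markov", "mono"),
                             ic = NULL) {
  weights <- match.arg(weights)
  subspace <- match.arg(subspace)
  l <- check_length_for_subspace(l, subspace)
  if (weights == "ic") {
    if (is.null(ic)) {
      stop("`ic` profile required when weights = \"ic\"", call. = FALSE)
    }
    if (!inherits(ic, "ic_profile")) {
      stop("`ic` must be an 'ic_profile' object", call. = FALSE)
    }
    if (length(ic$mono) != l) {
      stop(sprintf("IC profile is for l = %d, config has l = %d",
                   length(ic$mono), l), call. = FALSE)
    }
  }
  structure(
    list(l = l, weights = weights, subspace = subspace, ic = ic),
    class = "embedding_config"
  )
}

#' @export
print.embedding_config <- function(x, ...) {
  cat(sprintf("embedding_config: l = %d, weights = %s, subspace = %s (dim %d)\n",
              x$l, x$weights, x$subspace, subspace_dim(x$l, x$subspace)))
  invisible(x)
}

# per-group weights for the three feature blocks
embedding_weights <- function(cfg) {
  l <- cfg$l
  if (cfg$weights == "uniform") {
    list(mono = rep(1, l),
         adj  = rep(1, max(l - 1L, 0L)),
         gap  = rep(1, max(l - 2L, 0L)))
  } else {
    list(mono = cfg$ic$mono, adj = cfg$ic$adj, gap = cfg$ic$gap)
  }
}

# sites (character) -> integer code matrix, codes 1..4 = A,C,G,T
site_code_matrix <- function(sites, l = NULL) {
  if (length(sites) == 0L) stop("empty site set", call. = FALSE)
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("sites have unequal lengths: %s",
                 paste(unique(lens), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(l) && lens[1L] != l) {
    stop(sprintf("sites have length %d but l = %d expected", lens[1L], l),
         call. = FALSE)
  }
  chars <- strsplit(sites, "", fixed = TRUE)
  codes <- match(unlist(chars, use.names = FALSE), .BASES)
  if (anyNA(codes)) {
    bad <- which(vapply(chars, function(ch) anyNA(match(ch, .BASES)), logical(1)))
    stop(sprintf("non-ACGT character in site(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  matrix(codes, nrow = length(sites), byrow = TRUE)
}

mono_block <- function(codes, positions, w) {
  n <- nrow(codes)
  M <- matrix(0, n, 4L * length(positions))
  for (k in seq_along(positions)) {
    M[cbind(seq_len(n), 4L * (k - 1L) + codes[, positions[k]])] <- w[k]
  }
  M
}

pair_block <- function(codes, gap, w) {
  l <- ncol(codes)
  npair <- l - gap
  n <- nrow(codes)
  M <- matrix(0, n, 16L * npair)
  for (k in seq_len(npair)) {
    pc <- 4L * (codes[, k] - 1L) + codes[, k + gap]
    M[cbind(seq_len(n), 16L * (k - 1L) + pc)] <- w[k]
  }
  M
}

#' Feature names of an embedding subspace
#'
#' Mono features are named `A@i`; pair features `AC@i:j` for the pair at
#' positions (i, j).  The fixed order is: mono block by position, adjacent
#' pairs, then gap-1 pairs (the `markov` subspace keeps position-1 mono
#' features and adjacent pairs only).
#'
#' @inheritParams subspace_dim
#' @return Character vector of length `subspace_dim(l, subspace)`.
#' @export
feature_names <- function(l, subspace = c("full", "markov", "mono")) {
  subspace <- match.arg(subspace)
  l <- check_length_for_subspace(l, subspace)
  mono_pos <- if (subspace == "markov") 1L else seq_len(l)
  nm <- as.vector(vapply(mono_pos, function(i) paste0(.BASES, "@", i),
                         character(4)))
  if (subspace %in% c("markov", "full")) {
    nm <- c(nm, as.vector(vapply(seq_len(l - 1L), function(i) {
      paste0(.PAIR_NAMES, "@", i, ":", i + 1L)
    }, character(16))))
  }
  if (subspace == "full") {
    nm <- c(nm, as.vector(vapply(seq_len(l - 2L), function(i) {
      paste0(.PAIR_NAMES, "@", i, ":", i + 2L)
    }, character(16))))
  }
  nm
}

#' Embed a set of l-mers as indicator vectors
#'
#' Each l-mer becomes one row: 4 indicator variables per nucleotide
#' (weighted by the per-position weight) and 16 per considered nucleotide
#' pair (adjacent and gap-1 pairs for `full`; adjacent only for `markov`,
#' which also keeps the 4 indicators of position 1).
#'
#' @param sites Character vector of equal-length ACGT strings, or a
#'   [site_set()].
#' @param cfg An [embedding_config()].
#' @return Numeric matrix, one row per site, `subspace_dim(cfg$l,
#'   cfg$subspace)` named columns.
#' @export
embed_sites <- function(sites, cfg) {
  stopifnot(inherits(cfg, "embedding_config"))
  sites <- as_site_chr(sites)
  codes <- site_code_matrix(sites, cfg$l)
  w <- embedding_weights(cfg)
  blocks <- switch(cfg$subspace,
    mono = list(mono_block(codes, seq_len(cfg$l), w$mono)),
    markov = list(mono_block(codes, 1L, w$mono[1L]),
                  pair_block(codes, 1L, w$adj)),
    full = list(mono_block(codes, seq_len(cfg$l), w$mono),
                pair_block(codes, 1L, w$adj),
                pair_block(codes, 2L, w$gap))
  )
  M <- do.call(cbind, blocks)
  colnames(M) <- feature_names(cfg$l, cfg$subspace)
  rownames(M) <- sites
  M
}

#' Embed a single l-mer
#'
#' @param s A single ACGT string of length `cfg$l`.
#' @inheritParams embed_sites
#' @return Named numeric vector.
#' @export
embed_lmer <- function(s, cfg) {
  stopifnot(length(s) == 1L)
  drop(embed_sites(s, cfg))
}

#' Reverse complement of DNA strings
#'
#' @param s Character vector of ACGT strings.
#' @return Character vector of Watson-Crick reverse complements.
#' @export
reverse_complement <- function(s) {
  comp <- chartr("ACGT", "TGCA", s)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Score an l-mer against a query vector
#'
#' The score is the dot product of the embedded l-mer with the query
#' vector; with uniform weights and a query that is itself an embedded
#' l-mer this counts the nucleotides and nucleotide pairs the two words
#' share.
#'
#' @param s A single l-mer.
#' @param t Numeric query vector in the subspace of `cfg`.
#' @inheritParams embed_sites
#' @return Numeric scalar.
#' @export
score_lmer <- function(s, t, cfg) {
  v <- embed_lmer(s, cfg)
  if (length(t) != length(v)) {
    stop(sprintf("query vector has length %d, subspace dimension is %d",
                 length(t), length(v)), call. = FALSE)
  }
  sum(v * t)
}
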