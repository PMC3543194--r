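# Aligned site collections.

#' Aligned binding-site set
#'
#' A set of equal-length binding sites (or a negative pool) for one
#' transcription factor, optionally with the coordinates the sites were
#' extracted from.  Coordinates are 0-based half-open, BED style.
#'
#' @param sites Character vector of equal-length uppercase ACGT strings.
#' @param coords Optional `data.frame` with columns `seq_id`, `start`
#'   (0-based) and optionally `strand`, one row per site.
#' @return An object of class `site_set` with elements `sites`, `l`, `n`
#'   and `coords`.
#' @export
site_set <- function(sites, coords = NULL) {
  if (length(sites) == 0L) stop("empty site set", call. = FALSE)
  sites <- toupper(as.character(sites))
  codes <- site_code_matrix(sites)  # validates alphabet and equal length
  if (!is.null(coords)) {
    if (!is.data.frame(coords) || nrow(coords) != length(sites)) {
      stop("`coords` must be a data.frame with one row per site",
           call. = FALSE)
    }
    if (!all(c("seq_id", "start") %in% names(coords))) {
      stop("`coords` needs columns `seq_id` and `start`", call. = FALSE)
    }
  }
  structure(
    list(sites = sites, l = ncol(codes), n = length(sites), coords = coords),
    class = "site_set"
  )
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("site_set: %d sites of length %d%s\n", x$n, x$l,
              if (is.null(x$coords)) "" else " (with coordinates)"))
  utils::str(utils::head(x$sites, 5))
  invisible(x)
}

# accept site_set or plain character
as_site_chr <- function(x) {
  if (inherits(x, "site_set")) x$sites else as.character(x)
}
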