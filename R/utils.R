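# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic entry points funnel through this
# so that a single integer seed makes a whole run reproducible.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a parent seed and stream labels, staying well
# inside 32-bit integer range.
child_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
  }, numeric(1))
  as.integer((as.numeric(seed) * 7919 + sum(parts * 104729)) %% 2147483647)
}

check_positive_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || any(x != as.integer(x)) || any(x < min) || anyNA(x)) {
    abort(sprintf("`%s` must be integer-valued and >= %d", name, min))
  }
  as.integer(x)
}

#' Coerce an array to the five-axis volume layout
#'
#' Volumes are numeric arrays indexed `(n, c, d, h, w)`: batch, channel and
#' three spatial axes. Lower-rank inputs are promoted by prepending singleton
#' axes: a 2D `h x w` map becomes `1 x 1 x 1 x h x w`, a 3D `d x h x w`
#' volume becomes `1 x 1 x d x h x w`, and a 4D `c x d x h x w` stack
#' becomes a single-sample batch.
#'
#' @param x A numeric array of rank 2 to 5.
#' @return A 5-axis numeric array.
#' @export
as_volume <- function(x) {
  if (!is.numeric(x)) abort("volume data must be numeric")
  d <- dim(x)
  if (is.null(d)) abort("`x` must be an array or matrix")
  if (any(!is.finite(x))) abort("volumes must contain finite values only")
  nd <- length(d)
  if (nd > 5L) abort("volumes have at most 5 axes (n, c, d, h, w)")
  if (nd < 2L) abort("volumes need at least 2 axes")
  array(x, dim = c(rep(1L, 5L - nd), d))
}

# Undo as_volume()'s promotion so outputs match the caller's rank.
restore_rank <- function(y, rank) {
  d <- dim(y)
  if (rank < 5L) dim(y) <- d[(5L - rank + 1L):5L]
  y
}

stop_if_not_installed <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    abort(sprintf("package '%s' is required here", pkg))
  }
}
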