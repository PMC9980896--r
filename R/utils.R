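# Internal helpers shared across modules.

#' @keywords internal
nm_condition <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "neomotion_error")))
}

abort_validation <- function(msg) nm_condition(msg, "neomotion_validation_error")
abort_degenerate <- function(msg) nm_condition(msg, "neomotion_degenerate_error")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Fisher z transform with clamping of perfect correlations
#'
#' `atanh()` of a Pearson correlation, with `|r| >= 1 - 1e-12` clamped so the
#' transform stays finite. Clamped entries are flagged via the `"clamped"`
#' attribute.
#'
#' @param r numeric vector/matrix of correlations in `[-1, 1]`.
#' @param clamp clamp point for `|r|` (default `1 - 1e-12`).
#' @return `atanh(r)` with clamping; attribute `"clamped"` marks affected
#'   entries when any were clamped.
#' @export
fisher_z <- function(r, clamp = 1 - 1e-12) {
  hit <- is.finite(r) & abs(r) >= clamp
  z <- atanh(pmin(pmax(r, -clamp), clamp))
  if (any(hit)) attr(z, "clamped") <- hit
  z
}

# Upper-triangle edge index table for an n x n symmetric matrix.
edge_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2])
}

# Extract the upper-triangle edge vector of a symmetric matrix.
edge_vector <- function(m) m[upper.tri(m)]

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x >= 0
is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
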