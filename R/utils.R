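#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats coef mad median pchisq phyper pt quantile rbinom rexp
#'   rnorm runif sd setNames p.adjust rweibull
#' @importFrom utils head read.delim write.table packageVersion combn
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic fan-out of a master seed into named sub-streams, so adding
# one generated object never shifts another's draws. Plain polynomial string
# hash folded into [0, 2^31 - 2].
substreamSeed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483646 + 1)
}

.assertScalarNum <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Two-group label vector -> list(g1, g2) of column indices, with checks.
.splitGroups <- function(labels, min_per_group = 1L) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) {
    stop("expected exactly two groups, got: ", paste(lev, collapse = ", "),
         call. = FALSE)
  }
  idx <- list(which(labels == lev[1L]), which(labels == lev[2L]))
  names(idx) <- lev
  if (any(lengths(idx) < min_per_group)) {
    stop("each group needs at least ", min_per_group, " samples", call. = FALSE)
  }
  idx
}
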