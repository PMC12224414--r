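# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators are pure functions of their
# arguments.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a substream seed
#'
#' Mixes a master seed with integer or character tags into a 31-bit seed,
#' so per-dataset random streams are order-independent (one named stream
#' per (seed, condition, level, rep) or similar key).
#'
#' @param seed master integer seed.
#' @param ... integer or character tags identifying the substream.
#' @return An integer seed below 2^31.
#' @export
mix_seed <- function(seed, ...) {
  tags <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (tag in tags) {
    if (is.character(tag)) tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    for (t in as.double(tag)) {
      h <- (h * 69069 + t * 12345 + 1) %% 2147483647
    }
  }
  as.integer(h)
}

# Strict lower-triangle vector of a square matrix.
lower_tri <- function(M) M[lower.tri(M, diag = FALSE)]

# Pearson or Spearman correlation that returns NA (not an error) on
# zero-variance input, with a `strict` switch for callers that must fail.
safe_cor <- function(x, y, method = "pearson", strict = FALSE) {
  if (sd(x) == 0 || sd(y) == 0) {
    if (strict) stop("undefined correlation: zero-variance input", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y, method = method)
}

stopifnot_matrix <- function(X, name = deparse(substitute(X))) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (any(!is.finite(X))) {
    stop(sprintf("`%s` contains non-finite entries", name), call. = FALSE)
  }
  invisible(X)
}
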