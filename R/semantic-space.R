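# Target semantic space: cosine similarity matrix from feature norms, its
# low-rank SVD embedding, and similarity reconstruction from coordinates.

#' Construct a feature-norm matrix
#'
#' Bundles a binary item-by-feature matrix with item identifiers and
#' animate/inanimate domain labels, validating the invariants the rest of
#' the pipeline relies on: entries in \{0, 1\}, no all-zero item row, unique
#' item ids, and at least one item per domain.
#'
#' @param values numeric matrix, items in rows, binary features in columns.
#' @param item_ids character vector of unique item labels; defaults to
#'   `rownames(values)`.
#' @param domains character vector with one of two labels per item
#'   (conventionally `"animate"` / `"inanimate"`).
#' @return An object of class `feature_norms` with elements `values`,
#'   `item_ids`, `domains`, and `constant_features` (indices of zero-variance
#'   feature columns, retained but flagged).
#' @export
feature_norms <- function(values, item_ids = rownames(values), domains) {
  stopifnot_matrix(values)
  if (!all(values %in% c(0, 1))) {
    stop("feature norm entries must be binary (0/1)", call. = FALSE)
  }
  zero_rows <- which(rowSums(values) == 0)
  if (length(zero_rows) > 0) {
    stop("all-zero feature rows for item(s): ",
         paste(if (is.null(item_ids)) zero_rows else item_ids[zero_rows],
               collapse = ", "), call. = FALSE)
  }
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(nrow(values)))
  if (anyDuplicated(item_ids)) stop("item_ids must be unique", call. = FALSE)
  if (length(domains) != nrow(values)) {
    stop("domains must have one label per item", call. = FALSE)
  }
  if (length(unique(domains)) != 2) {
    stop("exactly two domain labels are required", call. = FALSE)
  }
  constant <- which(apply(values, 2, function(x) length(unique(x)) == 1))
  structure(
    list(values = values, item_ids = as.character(item_ids),
         domains = as.character(domains), constant_features = constant),
    class = "feature_norms"
  )
}

#' Read feature norms from delimited text
#'
#' Expects the first column to hold item ids, an optional `domain` column,
#' and binary feature columns otherwise.
#'
#' @param path file path to a tab- or comma-delimited table with header.
#' @param sep field separator; guessed from the extension by default.
#' @return A [feature_norms()] object.
#' @export
read_feature_norms <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  tab <- tab[-1]
  if ("domain" %in% names(tab)) {
    domains <- as.character(tab[["domain"]])
    tab <- tab[setdiff(names(tab), "domain")]
  } else {
    stop("feature norm file must contain a `domain` column", call. = FALSE)
  }
  feature_norms(as.matrix(tab), item_ids = ids, domains = domains)
}

#' Construct a similarity matrix object
#'
#' @param values square numeric matrix of item-pair similarities.
#' @param item_ids item labels (rows and columns).
#' @param kind one of `"target-semantic"`, `"binary-animacy"`, `"neural"`,
#'   `"predicted"`. Cosine/correlation kinds must be symmetric with unit
#'   diagonal and values in `[-1, 1]`; `"predicted"` (an outer product of
#'   coordinates) is only required to be symmetric.
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, item_ids = rownames(values),
                              kind = c("target-semantic", "binary-animacy",
                                       "neural", "predicted")) {
  kind <- match.arg(kind)
  stopifnot_matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-10) {
    stop("similarity matrix must be symmetric within 1e-10", call. = FALSE)
  }
  if (kind %in% c("target-semantic", "binary-animacy", "neural")) {
    if (max(abs(diag(values) - 1)) > 1e-10) {
      stop("similarity diagonal must equal 1 for kind ", kind, call. = FALSE)
    }
    if (min(values) < -1 - 1e-10 || max(values) > 1 + 1e-10) {
      stop("similarity values must lie in [-1, 1] for kind ", kind, call. = FALSE)
    }
  }
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(nrow(values)))
  dimnames(values) <- list(item_ids, item_ids)
  structure(list(values = values, item_ids = as.character(item_ids), kind = kind),
            class = "similarity_matrix")
}

#' Cosine similarity matrix from feature norms
#'
#' Feature columns are mean-centered, then the similarity between two items
#' is the cosine of their centered feature vectors. The diagonal is set to
#' exactly 1.
#'
#' @param norms a [feature_norms()] object, or a plain numeric matrix.
#' @return A `similarity_matrix` of kind `"target-semantic"`.
#' @export
build_cosine_rsm <- function(norms) {
  X <- if (inherits(norms, "feature_norms")) norms$values else norms
  ids <- if (inherits(norms, "feature_norms")) norms$item_ids else rownames(X)
  stopifnot_matrix(X)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need at least 2 items and 2 features", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  nrm <- sqrt(rowSums(Xc^2))
  if (any(nrm == 0)) {
    bad <- which(nrm == 0)
    labs <- if (is.null(ids)) bad else ids[bad]
    stop("degenerate item(s) with all-zero centered features: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  S <- tcrossprod(Xc / nrm)
  S <- (S + t(S)) / 2
  S[S > 1] <- 1
  S[S < -1] <- -1
  diag(S) <- 1
  similarity_matrix(S, item_ids = ids, kind = "target-semantic")
}

#' Low-rank embedding of a similarity matrix
#'
#' Decomposes a symmetric similarity matrix and returns item coordinates on
#' the first `r` components as root-weighted singular vectors (each singular
#' vector scaled by the square root of its singular value), so that the
#' outer product of the coordinates reproduces the rank-`r` truncation of
#' the input. Negative eigenvalues arising from centering/rounding are
#' clipped to zero before the square root; the clipped mass is recorded.
#'
#' Sign convention: when `domains` are supplied each component is oriented
#' so the mean coordinate of the first (animate) domain is nonnegative;
#' otherwise the entry of largest magnitude in each singular vector is made
#' positive. SVD signs are otherwise arbitrary and correlations downstream
#' are sign-sensitive.
#'
#' @param rsm a `similarity_matrix` (or square symmetric matrix).
#' @param r number of components to retain, `1 <= r <= n`.
#' @param domains optional per-item domain labels used for the sign
#'   convention; the alphabetically first label plays the "animate" role
#'   unless a label literally equals `"animate"`.
#' @return An object of class `semantic_embedding` with elements `coords`
#'   (items x r), `singular_values` (length r, nonincreasing),
#'   `variance_explained` (each singular value over the sum of all n),
#'   `r`, `item_ids`, `domains`, and `clipped` (total negative eigenvalue
#'   magnitude set to zero).
#' @export
svd_embed <- function(rsm, r, domains = NULL) {
  S <- if (inherits(rsm, "similarity_matrix")) rsm$values else rsm
  ids <- if (inherits(rsm, "similarity_matrix")) rsm$item_ids else rownames(S)
  stopifnot_matrix(S)
  n <- nrow(S)
  if (max(abs(S - t(S))) > 1e-10) stop("similarity matrix must be symmetric", call. = FALSE)
  if (r < 1 || r > n) stop("r must satisfy 1 <= r <= n", call. = FALSE)
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev <- eg$values
  clipped <- sum(abs(ev[ev < 0]))
  ev[ev < 0] <- 0
  tol <- max(ev) * n * .Machine$double.eps
  num_rank <- sum(ev > tol)
  if (r > num_rank) {
    warning(sprintf("r = %d exceeds numerical rank %d; trailing components are zero",
                    r, num_rank))
  }
  d <- ev[seq_len(r)]
  V <- eg$vectors[, seq_len(r), drop = FALSE]
  # fix signs
  for (k in seq_len(r)) {
    flip <- if (!is.null(domains)) {
      lev <- sort(unique(domains))
      anim <- if ("animate" %in% lev) "animate" else lev[1]
      mean(V[domains == anim, k]) < 0
    } else {
      V[which.max(abs(V[, k])), k] < 0
    }
    if (flip) V[, k] <- -V[, k]
  }
  coords <- V %*% diag(sqrt(d), r, r)
  if (!is.null(ids)) rownames(coords) <- ids
  colnames(coords) <- paste0("dim", seq_len(r))
  structure(
    list(coords = coords, singular_values = d,
         variance_explained = d / sum(ev), r = r,
         item_ids = ids, domains = domains, clipped = clipped),
    class = "semantic_embedding"
  )
}

#' Reconstruct similarities from (predicted) coordinates
#'
#' The predicted similarity between two items is the inner product of their
#' coordinate vectors: the outer product `coords %*% t(coords)`.
#'
#' @param coords items x r matrix of (predicted) component coordinates, or a
#'   `semantic_embedding`.
#' @param item_ids optional item labels.
#' @return A `similarity_matrix` of kind `"predicted"`.
#' @export
reconstruct_similarity <- function(coords, item_ids = NULL) {
  if (inherits(coords, "semantic_embedding")) {
    if (is.null(item_ids)) item_ids <- coords$item_ids
    coords <- coords$coords
  }
  coords <- as.matrix(coords)
  stopifnot_matrix(coords)
  if (is.null(item_ids)) item_ids <- rownames(coords)
  S <- tcrossprod(coords)
  S <- (S + t(S)) / 2
  similarity_matrix(S, item_ids = item_ids, kind = "predicted")
}

#' Binary animacy similarity matrix
#'
#' Encodes only the categorical domain distinction: 1 for same-domain pairs
#' (and the diagonal), 0 otherwise.
#'
#' @param domains per-item domain labels (exactly two distinct values).
#' @param item_ids optional item labels.
#' @return A `similarity_matrix` of kind `"binary-animacy"`.
#' @export
binary_animacy_rsm <- function(domains, item_ids = NULL) {
  if (length(unique(domains)) > 2) stop("more than two domain labels", call. = FALSE)
  S <- outer(domains, domains, FUN = "==") * 1
  diag(S) <- 1
  similarity_matrix(S, item_ids = item_ids, kind = "binary-animacy")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> kind=%s, %d items\n", x$kind, nrow(x$values)))
  invisible(x)
}

#' @export
print.semantic_embedding <- function(x, ...) {
  cat(sprintf("<semantic_embedding> %d items x %d components\n",
              nrow(x$coords), x$r))
  cat("variance explained:",
      paste(sprintf("%.3f", x$variance_explained), collapse = " "), "\n")
  invisible(x)
}

#' Write an embedding as a columnar table
#'
#' Writes a tab-delimited table with columns `item`, `domain` (if present)
#' and `dim1..dimr`.
#'
#' @param embedding a `semantic_embedding`.
#' @param path output file path.
#' @export
write_embedding <- function(embedding, path) {
  tab <- data.frame(item = embedding$item_ids %||% seq_len(nrow(embedding$coords)))
  if (!is.null(embedding$domains)) tab$domain <- embedding$domains
  tab <- cbind(tab, as.data.frame(embedding$coords))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
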