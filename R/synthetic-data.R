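# Synthetic data: simulated feature sets under five signal conditions with
# graded uniform noise, a synthetic hierarchical feature-norm generator (the
# stand-in target structure for all simulations), and synthetic
# multi-electrode time-series with a planted row-sparse semantic code.

#' Define a signal condition for the simulated feature sets
#'
#' Five conditions describe how signal-carrying features encode the target
#' embedding: `binary` (one state for animate items, the opposite for
#' inanimate — discrete and unidimensional), `oneD-1`/`oneD-2`/`oneD-3`
#' (scaled copies of a single embedding component — graded but
#' unidimensional), and `full` (signal features split evenly across the
#' three components — graded and multidimensional).
#'
#' @param name one of `"binary"`, `"oneD-1"`, `"oneD-2"`, `"oneD-3"`,
#'   `"full"`.
#' @param n_features total simulated features (default 24).
#' @param n_signal number of signal-carrying features (default half).
#' @return An object of class `signal_condition`.
#' @export
signal_condition <- function(name = c("binary", "oneD-1", "oneD-2", "oneD-3", "full"),
                             n_features = 24, n_signal = n_features / 2) {
  name <- match.arg(name)
  if (n_signal > n_features) stop("n_signal must not exceed n_features", call. = FALSE)
  if (n_features %% 2 != 0) stop("n_features must be even", call. = FALSE)
  dims_encoded <- switch(name,
    "binary" = integer(0),
    "oneD-1" = 1L, "oneD-2" = 2L, "oneD-3" = 3L,
    "full" = 1:3
  )
  if (name == "full" && n_signal %% length(dims_encoded) != 0) {
    stop("for `full`, n_signal must divide evenly across the encoded dimensions",
         call. = FALSE)
  }
  structure(list(name = name, n_features = as.integer(n_features),
                 n_signal = as.integer(n_signal), dims_encoded = dims_encoded),
            class = "signal_condition")
}

#' All five standard signal conditions
#' @param n_features total features per condition (default 24).
#' @return Named list of [signal_condition()] objects.
#' @export
standard_conditions <- function(n_features = 24) {
  names <- c("binary", "oneD-1", "oneD-2", "oneD-3", "full")
  stats::setNames(lapply(names, signal_condition, n_features = n_features), names)
}

#' Define the noise sweep
#'
#' Measurement noise is sampled independently per cell from a uniform
#' distribution centered on 0 with the given half-widths. Signal features
#' are standardized to unit variance before planting, so half-widths are in
#' signal-SD units; the default grid of 11 levels on \[0, 8\] spans from
#' noiseless to a regime where the weakest conditions decay to null.
#'
#' @param levels strictly increasing nonnegative half-widths.
#' @param reps simulated runs per level (default 20).
#' @param seed master seed for the sweep.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(levels = seq(0, 8, length.out = 11), reps = 20, seed = 1) {
  if (any(levels < 0) || any(diff(levels) <= 0)) {
    stop("noise levels must be nonnegative and strictly increasing", call. = FALSE)
  }
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  structure(list(levels = levels, reps = as.integer(reps), seed = as.integer(seed)),
            class = "noise_spec")
}

#' Synthetic hierarchical feature norms
#'
#' Generates a binary item-by-feature matrix with the hierarchical
#' structure typical of semantic feature norms: two domains (animate /
#' inanimate), subcategories within each domain, and idiosyncratic item
#' features. Animate subcategories receive more distinctive features than
#' inanimate ones, so the cosine-RSM embedding has a dominant first
#' component separating the domains, a second component mostly organizing
#' animate items, and a third mostly organizing inanimate items. This is a
#' synthetic stand-in for empirically collected norms, used as the target
#' structure of all simulation studies.
#'
#' @param n_items total items (split evenly across domains; default 100).
#' @param n_subcats subcategories per domain (default 5).
#' @param seed RNG seed.
#' @return A [feature_norms()] object.
#' @export
simulate_feature_norms <- function(n_items = 100, n_subcats = 5, seed = 1) {
  if (n_items %% 2 != 0) stop("n_items must be even", call. = FALSE)
  per_dom <- n_items / 2
  if (per_dom %% n_subcats != 0) {
    stop("items per domain must divide evenly into subcategories", call. = FALSE)
  }
  with_seed(mix_seed(seed, "norms"), {
    domains <- rep(c("animate", "inanimate"), each = per_dom)
    subcat <- c(rep(seq_len(n_subcats), each = per_dom / n_subcats),
                rep(seq_len(n_subcats) + n_subcats, each = per_dom / n_subcats))
    # graded typicality: subcategories vary in how many domain-typical
    # features their members carry, so the first component grades items
    # within each domain instead of encoding a pure category indicator
    typ_sub <- c(seq(0.95, 0.55, length.out = n_subcats),
                 seq(0.95, 0.55, length.out = n_subcats))
    typicality <- pmin(0.98, pmax(0.4, typ_sub[subcat] +
                                    runif(n_items, -0.08, 0.08)))
    blocks <- list()
    # domain-level features: on with item-typicality probability inside the
    # domain, rarely outside it
    for (d in c("animate", "inanimate")) {
      p <- ifelse(domains == d, typicality, 0.03)
      blocks[[length(blocks) + 1]] <-
        sapply(seq_len(30), function(j) stats::rbinom(n_items, 1, p))
    }
    # a coarse split among inanimates (e.g. manipulable vs large artifacts)
    # so inanimate structure is present beyond subcategories, though weaker
    # than animate structure
    p <- ifelse(subcat %in% (n_subcats + seq_len(ceiling(n_subcats / 2))), 0.7, 0.04)
    blocks[[length(blocks) + 1]] <-
      sapply(seq_len(9), function(j) stats::rbinom(n_items, 1, p))
    # subcategory features; animate subcategories are better differentiated
    # than inanimate ones (and unevenly so), as in feature-norming studies
    k_anim <- round(seq(16, 3, length.out = n_subcats))
    for (s in unique(subcat)) {
      k <- if (s <= n_subcats) k_anim[s] else 4
      p_in <- if (s <= n_subcats) 0.85 else 0.7
      p <- ifelse(subcat == s, p_in, 0.04)
      blocks[[length(blocks) + 1]] <-
        sapply(seq_len(k), function(j) stats::rbinom(n_items, 1, p))
    }
    # idiosyncratic features: each on for one item plus sparse spillover
    idio <- sapply(seq_len(n_items), function(i) {
      v <- stats::rbinom(n_items, 1, 0.02)
      v[i] <- 1
      v
    })
    M <- cbind(do.call(cbind, blocks), idio)
    rownames(M) <- sprintf("%s_%02d", domains, seq_len(n_items))
    feature_norms(M, domains = domains)
  })
}

#' Simulated feature set for one condition at one noise level
#'
#' Signal features encode the condition's aspect of the embedding: for
#' `binary`, each signal feature takes -1 or 1 for animate items and the
#' opposite state for inanimate items; for `oneD-k`, each signal feature is
#' a (z-scored) copy of embedding component k; for `full`, signal features
#' are split evenly across the three components. Noise features sample a
#' uniform distribution over the range of the signal features, and uniform
#' measurement noise on `[-noise_halfwidth, noise_halfwidth]` is then added
#' to every entry.
#'
#' @param embedding a `semantic_embedding` with `r >= 3` and domain labels.
#' @param condition a [signal_condition()].
#' @param noise_halfwidth nonnegative half-width of the uniform measurement
#'   noise, in signal-SD units.
#' @param seed RNG seed for this dataset.
#' @return items x n_features numeric matrix with attributes
#'   `signal_columns` (indices) and `condition`.
#' @export
make_condition_dataset <- function(embedding, condition, noise_halfwidth, seed) {
  if (noise_halfwidth < 0) stop("noise_halfwidth must be nonnegative", call. = FALSE)
  if (embedding$r < 3) stop("embedding must have at least 3 components", call. = FALSE)
  if (is.null(embedding$domains)) stop("embedding must carry domain labels", call. = FALSE)
  cond <- condition
  n <- nrow(embedding$coords)
  m <- cond$n_features
  ns <- cond$n_signal
  with_seed(seed, {
    Z <- scale(embedding$coords[, 1:3, drop = FALSE])  # unit-variance components
    lev <- sort(unique(embedding$domains))
    anim <- if ("animate" %in% lev) "animate" else lev[1]
    sig <- matrix(0, n, ns)
    if (cond$name == "binary") {
      base <- ifelse(embedding$domains == anim, 1, -1)
      states <- sample(c(-1, 1), ns, replace = TRUE)  # which state codes animate
      for (j in seq_len(ns)) sig[, j] <- base * states[j]
    } else if (cond$name == "full") {
      per <- ns / 3
      for (k in 1:3) {
        sig[, (k - 1) * per + seq_len(per)] <- Z[, k]
      }
    } else {
      k <- cond$dims_encoded
      sig[, ] <- Z[, k]
    }
    rng <- range(sig)
    noise_feats <- matrix(runif(n * (m - ns), rng[1], rng[2]), n, m - ns)
    X <- cbind(sig, noise_feats)
    # shuffle column order so signal features are interleaved with noise
    ord <- sample(m)
    X <- X[, ord]
    signal_cols <- match(seq_len(ns), ord)
    if (noise_halfwidth > 0) {
      X <- X + matrix(runif(n * m, -noise_halfwidth, noise_halfwidth), n, m)
    }
    rownames(X) <- embedding$item_ids
    attr(X, "signal_columns") <- sort(signal_cols)
    attr(X, "condition") <- cond$name
    X
  })
}

#' Generate the full condition-by-noise sweep
#'
#' @param embedding target `semantic_embedding`.
#' @param conditions list of [signal_condition()] objects.
#' @param noise a [noise_spec()].
#' @return A list with one element per (condition, level, rep), named
#'   `"<condition>|L<level index>|R<rep>"`, each a dataset from
#'   [make_condition_dataset()]. Reproducible from `noise$seed`; per-dataset
#'   seeds are derived substreams so generation order does not matter.
#' @export
sweep_conditions <- function(embedding, conditions, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  out <- list()
  for (cond in conditions) {
    for (li in seq_along(noise$levels)) {
      for (rep in seq_len(noise$reps)) {
        key <- sprintf("%s|L%02d|R%02d", cond$name, li, rep)
        out[[key]] <- make_condition_dataset(
          embedding, cond, noise$levels[li],
          seed = mix_seed(noise$seed, cond$name, li, rep)
        )
      }
    }
  }
  out
}

#' Synthetic multi-electrode time-series with a planted semantic code
#'
#' Emulates trial-averaged voltage recordings: an items x (electrodes x
#' timepoints) feature matrix in which a row-sparse, correlated,
#' non-axis-aligned linear code for the first three embedding components is
#' planted within a latency band. Active columns come in `group_size`-sized
#' near-duplicate groups (pairwise correlation at least 0.9 before noise)
#' whose mixing vectors are dense across all three components, matching the
#' row-sparsity + redundancy + spanning assumptions of the grOWL decoder.
#' Outside the signal window columns contain pure noise.
#'
#' @param embedding target `semantic_embedding` (r >= 3, with domains).
#' @param n_electrodes,n_timepoints grid dimensions (default 20 x 100, i.e.
#'   a 1 s epoch at 100 Hz).
#' @param n_signal_columns number of signal-carrying columns (default 40).
#' @param group_size near-duplicate group size (default 4).
#' @param signal_window latency band `c(onset, offset)` in ms containing all
#'   signal columns (default 150-700 ms).
#' @param snr ratio of planted signal variance to additive noise variance
#'   over the signal columns.
#' @param seed RNG seed.
#' @return An object of class `synthetic_ephys`: `X`, `column_map`
#'   (data.frame with `electrode`, `time_ms` per column),
#'   `ground_truth_mixing` (r x m, column-sparse), `signal_window`,
#'   `group_structure` (list of column-index groups), `item_ids`,
#'   `domains`, `seed`.
#' @export
make_synthetic_ephys <- function(embedding, n_electrodes = 20, n_timepoints = 100,
                                 n_signal_columns = 40, group_size = 4,
                                 signal_window = c(150, 700), snr = 4, seed = 1) {
  m <- n_electrodes * n_timepoints
  if (n_signal_columns > m) stop("n_signal_columns exceeds feature count", call. = FALSE)
  if (group_size < 1) stop("group_size must be >= 1", call. = FALSE)
  if (n_signal_columns %% group_size != 0) {
    stop("n_signal_columns must be a multiple of group_size", call. = FALSE)
  }
  r <- 3
  C <- scale(embedding$coords[, 1:r, drop = FALSE])
  n <- nrow(C)
  with_seed(mix_seed(seed, "ephys"), {
    step_ms <- 1000 / n_timepoints
    column_map <- data.frame(
      electrode = rep(seq_len(n_electrodes), each = n_timepoints),
      time_ms = rep((seq_len(n_timepoints) - 1) * step_ms, times = n_electrodes)
    )
    in_band <- which(column_map$time_ms >= signal_window[1] &
                       column_map$time_ms < signal_window[2])
    if (length(in_band) < n_signal_columns) {
      stop("signal window too narrow for requested signal columns", call. = FALSE)
    }
    support <- sort(sample(in_band, n_signal_columns))
    n_groups <- n_signal_columns / group_size
    groups <- split(support, rep(seq_len(n_groups), each = group_size))
    G <- matrix(0, r, m)
    for (g in groups) {
      base <- rnorm(r)
      base <- base / sqrt(sum(base^2))
      # dense mixing: ensure no component loading is (near) zero
      base <- sign(base) * pmax(abs(base), 0.2)
      for (j in g) {
        G[, j] <- base + rnorm(r, sd = 0.03)  # near-duplicate within group
      }
    }
    signal <- C %*% G
    sig_var <- var(as.vector(signal[, support]))
    if (!is.finite(sig_var) || sig_var <= 0) {
      stop("infeasible snr: planted signal has zero variance", call. = FALSE)
    }
    noise_sd <- sqrt(sig_var / snr)
    X <- signal + matrix(rnorm(n * m, sd = noise_sd), n, m)
    rownames(X) <- embedding$item_ids
    structure(
      list(X = X, column_map = column_map, ground_truth_mixing = G,
           signal_window = signal_window, group_structure = unname(groups),
           item_ids = embedding$item_ids, domains = embedding$domains,
           seed = seed),
      class = "synthetic_ephys"
    )
  })
}
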