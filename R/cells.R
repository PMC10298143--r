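#' Correlation-based cell-cell distance matrix
#'
#' For every pair of cells, computes the Pearson correlation of their
#' allele-frequency profiles over the sites where both cells have
#' non-missing AF, and returns one minus its absolute value. Pairs
#' sharing fewer than `min_shared_sites` sites, or where either profile
#' is constant over the shared sites (correlation undefined), are
#' assigned the maximal distance 1; their count is kept in the
#' `"n_fallback_pairs"` attribute.
#'
#' @param af A `mito_af` object.
#' @param sites Variant labels (character, or a tibble with a `label`
#'   column such as the output of [select_variable_sites()]) to use as
#'   features.
#' @param min_shared_sites Minimum shared non-missing sites for a
#'   correlation to be trusted (default 20).
#' @return A symmetric numeric matrix (cells x cells) with zero diagonal
#'   and values in \[0, 1\], of class `mito_distance`.
#' @export
correlation_distance <- function(af, sites, min_shared_sites = 20L) {
  stopifnot(inherits(af, "mito_af"))
  if (ncol(af$af) < 2L) abort("Need at least 2 cells.")
  x <- af_values(af, sites) # sites x cells, NA = missing
  obs <- !is.na(x)
  shared <- crossprod(obs) # cells x cells shared-site counts
  suppressWarnings(r <- cor(x, use = "pairwise.complete.obs"))
  d <- 1 - abs(r)
  fallback <- is.na(d) | shared < min_shared_sites
  n_fallback <- (sum(fallback) - sum(diag(fallback))) / 2
  d[fallback] <- 1
  diag(d) <- 0
  # numerical guard: |r| can exceed 1 by eps
  d[d < 0] <- 0
  d[d > 1] <- 1
  dimnames(d) <- list(af$cells$cell_id, af$cells$cell_id)
  if (n_fallback > 0) {
    inform(paste0(
      n_fallback, " cell pair(s) had < ", min_shared_sites,
      " shared sites or an undefined correlation; assigned distance 1."
    ))
  }
  structure(d, class = c("mito_distance", "matrix"), n_fallback_pairs = n_fallback)
}

#' Embed cells in two dimensions by t-SNE on a precomputed distance
#'
#' Runs t-SNE (Barnes-Hut, via the Rtsne package) directly on a
#' cell-cell distance matrix. The conventional perplexity for these
#' mitochondrial AF profiles is 10; duplicate checking is disabled
#' because distinct cells can legitimately have identical profiles.
#'
#' @param dist A `mito_distance` (or any square symmetric) matrix.
#' @param perplexity t-SNE perplexity (default 10); must be below
#'   `(n_cells - 1) / 3`.
#' @param seed Integer seed; fixed seeds give identical coordinates.
#' @param ... Passed on to [Rtsne::Rtsne()].
#' @return A tibble of class `mito_embedding`: `cell_id`, `tsne1`,
#'   `tsne2`.
#' @export
embed_cells <- function(dist, perplexity = 10, seed = 1L, ...) {
  n <- nrow(dist)
  if (perplexity >= (n - 1) / 3) {
    abort(paste0(
      "perplexity ", perplexity, " too large for ", n,
      " cells (need perplexity < (n - 1) / 3)."
    ))
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(stats::as.dist(dist),
    dims = 2L, perplexity = perplexity,
    is_distance = TRUE, check_duplicates = FALSE, pca = FALSE, ...
  )
  out <- tibble(
    cell_id = rownames(dist) %||% as.character(seq_len(n)),
    tsne1 = fit$Y[, 1L],
    tsne2 = fit$Y[, 2L]
  )
  class(out) <- c("mito_embedding", class(out))
  out
}

#' Classify cells to donors from allele-frequency profiles
#'
#' Trains a random forest on per-cell allele frequencies at the given
#' sites and reports held-out accuracy: out-of-bag by default, or k-fold
#' cross-validation. Missing AFs are encoded as -1, a sentinel outside
#' the [0, 1] AF range, so trees can split "uncovered" away from any
#' real frequency instead of an imputation inventing reference alleles.
#'
#' @param af A `mito_af` object.
#' @param sites Variant labels (character or tibble with `label`).
#' @param labels Cell-to-donor labels (data frame or TSV path); every
#'   donor needs at least 5 labeled cells.
#' @param seed Integer seed (forest growth and fold assignment).
#' @param scheme `"out_of_bag"` (default) or `"k_fold"`.
#' @param k Number of folds when `scheme = "k_fold"` (default 5).
#' @param ntree Number of trees (default 500).
#' @return A `donor_classifier` object; see [tidy.donor_classifier()] for
#'   per-cell predictions and [glance.donor_classifier()] for the
#'   accuracy summary.
#' @export
classify_donors <- function(af, sites, labels, seed = 1L,
                            scheme = c("out_of_bag", "k_fold"),
                            k = 5L, ntree = 500L) {
  scheme <- match.arg(scheme)
  grp <- .match_labels(af, labels)
  too_few <- grp$donors[vapply(grp$cols, length, integer(1L)) < 5L]
  if (length(too_few) > 0L) {
    abort(paste0(
      "Every donor needs >= 5 labeled cells; too few for: ",
      paste(too_few, collapse = ", ")
    ))
  }
  if (is.data.frame(sites)) sites <- sites$label
  if (length(sites) == 0L) abort("Empty feature (site) set.")
  cols <- unlist(grp$cols)
  y <- factor(rep(grp$donors, times = vapply(grp$cols, length, integer(1L))))
  x <- t(af_values(af, sites))[cols, , drop = FALSE]
  x[is.na(x)] <- -1
  colnames(x) <- make.names(sites)
  set.seed(seed)
  if (scheme == "out_of_bag") {
    fit <- randomForest::randomForest(x = x, y = y, ntree = ntree)
    predicted <- fit$predicted
  } else {
    fold <- sample(rep_len(seq_len(k), length(y)))
    predicted <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- randomForest::randomForest(x = x[tr, , drop = FALSE], y = y[tr], ntree = ntree)
      predicted[!tr] <- predict(fit, x[!tr, , drop = FALSE])
    }
    fit <- NULL
  }
  predictions <- tibble(
    cell_id = af$cells$cell_id[cols],
    donor_id = as.character(y),
    predicted = as.character(predicted)
  )
  structure(
    list(
      predictions = predictions,
      accuracy = mean(predictions$predicted == predictions$donor_id),
      scheme = scheme, k = if (scheme == "k_fold") as.integer(k) else NA_integer_,
      n_sites = length(sites), seed = as.integer(seed), forest = fit
    ),
    class = "donor_classifier"
  )
}

#' @export
print.donor_classifier <- function(x, ...) {
  cat(
    "<donor_classifier> ", nrow(x$predictions), " cells, ",
    length(unique(x$predictions$donor_id)), " donors, ",
    x$n_sites, " sites; ", x$scheme, " accuracy = ",
    format(x$accuracy, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-cell predictions of a donor classifier
#'
#' @param x A `donor_classifier`.
#' @param ... Unused.
#' @return A tibble: `cell_id`, `donor_id` (truth), `predicted`,
#'   `correct`.
#' @method tidy donor_classifier
#' @export
tidy.donor_classifier <- function(x, ...) {
  dplyr::mutate(x$predictions, correct = .data$predicted == .data$donor_id)
}

#' One-row summary of a donor classifier
#'
#' @param x A `donor_classifier`.
#' @param ... Unused.
#' @return A one-row tibble: `accuracy`, `n_cells`, `n_donors`,
#'   `n_sites`, `scheme`, `seed`.
#' @method glance donor_classifier
#' @export
glance.donor_classifier <- function(x, ...) {
  tibble(
    accuracy = x$accuracy,
    n_cells = nrow(x$predictions),
    n_donors = length(unique(x$predictions$donor_id)),
    n_sites = x$n_sites,
    scheme = x$scheme,
    seed = x$seed
  )
}
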