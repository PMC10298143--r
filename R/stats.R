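#' Analysis parameters for the variant statistics layer
#'
#' Defaults follow the published analysis conventions for this framework:
#' 500 highly-variable sites, donor-mean AF > 0.9 for a discriminative
#' germline call, ANOVA p < 1e-100 for informative variants, and the
#' (1%, 25%) donor-mean band for heteroplasmies.
#'
#' @param n_variable_sites Number of sites kept by
#'   [select_variable_sites()] (default 500).
#' @param germline_af_threshold Donor-mean AF above which a variant counts
#'   as fixed in that donor (default 0.9).
#' @param anova_p_threshold Raw p-value cutoff for
#'   [informative_variants()] (default 1e-100).
#' @param het_lo,het_hi Open interval of donor-mean AF defining the
#'   heteroplasmy band (defaults 0.01 and 0.25).
#' @param min_cells_per_group Minimum non-missing cells per donor for that
#'   donor to enter an ANOVA (default 2).
#' @param min_covered_cells Minimum non-missing cells for a site to be
#'   eligible for variable-site selection (default 10).
#' @param het_alpha Bonferroni-adjusted significance level for the
#'   heteroplasmy scan (default 0.05).
#' @param af_mean How donor means are computed: `"cell"` (unweighted mean
#'   over cells with non-missing AF; the default) or `"pooled"`
#'   (pseudobulk, sum(alt)/sum(coverage), robust to uneven depth).
#' @return An `analysis_params` object.
#' @export
analysis_params <- function(n_variable_sites = 500L,
                            germline_af_threshold = 0.9,
                            anova_p_threshold = 1e-100,
                            het_lo = 0.01, het_hi = 0.25,
                            min_cells_per_group = 2L,
                            min_covered_cells = 10L,
                            het_alpha = 0.05,
                            af_mean = c("cell", "pooled")) {
  af_mean <- match.arg(af_mean)
  if (!(0 < het_lo && het_lo < het_hi && het_hi < germline_af_threshold &&
    germline_af_threshold <= 1)) {
    abort("Require 0 < het_lo < het_hi < germline_af_threshold <= 1.")
  }
  if (anova_p_threshold <= 0 || anova_p_threshold > 1) {
    abort("anova_p_threshold must be in (0, 1].")
  }
  structure(
    list(
      n_variable_sites = as.integer(n_variable_sites),
      germline_af_threshold = germline_af_threshold,
      anova_p_threshold = anova_p_threshold,
      het_lo = het_lo, het_hi = het_hi,
      min_cells_per_group = as.integer(min_cells_per_group),
      min_covered_cells = as.integer(min_covered_cells),
      het_alpha = het_alpha, af_mean = af_mean
    ),
    class = "analysis_params"
  )
}

#' Read a cell-to-donor label table
#'
#' @param path TSV with a header and columns `cell_id`, `donor_id`.
#' @return A tibble with those two character columns.
#' @export
read_donor_labels <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("cell_id", "donor_id") %in% names(d))) {
    abort("Labels TSV must have header columns 'cell_id' and 'donor_id'.")
  }
  dplyr::select(d, "cell_id", "donor_id")
}

# Validate labels against an af object; returns donors (sorted) and the
# column indices per donor. Labeled cells absent from the matrix are an
# error; unlabeled cells are simply excluded from tests.
.match_labels <- function(af, labels) {
  if (is.character(labels) && length(labels) == 1L) {
    labels <- read_donor_labels(labels)
  }
  if (!is.data.frame(labels) || !all(c("cell_id", "donor_id") %in% names(labels))) {
    abort("labels must be a data frame with columns cell_id, donor_id (or a TSV path).")
  }
  labels <- dplyr::distinct(labels, .data$cell_id, .keep_all = TRUE)
  unknown <- setdiff(labels$cell_id, af$cells$cell_id)
  if (length(unknown) > 0L) {
    abort(paste0(
      "Labeled cell(s) absent from the matrix: ",
      paste(head(unknown, 5L), collapse = ", ")
    ))
  }
  donors <- sort(unique(labels$donor_id))
  if (length(donors) < 2L) abort("Need at least 2 donors.")
  cols <- lapply(donors, function(d) {
    match(labels$cell_id[labels$donor_id == d], af$cells$cell_id)
  })
  names(cols) <- donors
  list(donors = donors, cols = cols)
}

# Per-donor sufficient statistics over non-missing AFs:
# N (cells observed), S (sum AF), SS (sum AF^2), each variants x donors.
.donor_group_stats <- function(af, grp) {
  obs <- af$cov >= af$min_coverage
  af2 <- af$af
  af2@x <- af2@x^2
  K <- length(grp$donors)
  nv <- nrow(af$af)
  N <- S <- SS <- matrix(0, nv, K, dimnames = list(NULL, grp$donors))
  for (k in seq_len(K)) {
    cl <- grp$cols[[k]]
    N[, k] <- Matrix::rowSums(obs[, cl, drop = FALSE])
    S[, k] <- Matrix::rowSums(af$af[, cl, drop = FALSE])
    SS[, k] <- Matrix::rowSums(af2[, cl, drop = FALSE])
  }
  list(N = N, S = S, SS = SS)
}

# Classical one-way fixed-effects ANOVA from group sums, vectorised over
# rows. Donors with fewer than min_cells observed cells are dropped from
# that row's test. p-values are kept in log10 space: the framework's
# 1e-100 informative-variant threshold is far below what a plain
# survival-function evaluation can represent.
.anova_from_stats <- function(N, S, SS, min_cells) {
  mask <- N >= min_cells
  Nm <- N * mask
  Sm <- S * mask
  SSm <- SS * mask
  k <- rowSums(mask)
  n_tot <- rowSums(Nm)
  s_tot <- rowSums(Sm)
  ssq_tot <- rowSums(SSm)
  # centered computation: group means vs the grand mean (numerically stable
  # when between-group differences are tiny)
  means <- ifelse(mask, Sm / pmax(Nm, 1L), 0)
  grand_mean <- ifelse(n_tot > 0, s_tot / pmax(n_tot, 1L), 0)
  SSB <- pmax(rowSums(Nm * (means - grand_mean)^2), 0)
  sb <- rowSums(Nm * means^2)
  SSW <- pmax(ssq_tot - sb, 0)
  SST <- SSB + SSW
  testable <- k >= 2L & (n_tot - k) >= 1L
  df_b <- ifelse(testable, k - 1L, NA_integer_)
  df_w <- ifelse(testable, n_tot - k, NA_integer_)
  tol <- 1e-12 * pmax(SST, .Machine$double.xmin)
  zero_w <- SSW <= tol
  zero_b <- SSB <= tol
  F <- ifelse(zero_w, ifelse(zero_b, 0, Inf), (SSB / df_b) / (SSW / df_w))
  log_p <- rep(NA_real_, length(F))
  reg <- which(testable & !zero_w)
  if (length(reg) > 0L) {
    log_p[reg] <- pf(F[reg], df_b[reg], df_w[reg],
      lower.tail = FALSE, log.p = TRUE
    )
  }
  log_p[testable & zero_w & !zero_b] <- -Inf
  log_p[testable & zero_w & zero_b] <- 0
  F[!testable] <- NA_real_
  tibble(
    F = F, df_between = as.integer(df_b), df_within = as.integer(df_w),
    log10_p = log_p / log(10), p = exp(log_p),
    n_cells = as.integer(n_tot), n_donors = as.integer(k),
    testable = testable
  )
}

#' One-way ANOVA of allele frequency across donors at a single site
#'
#' Fits the per-position model "AF explained by donor identity" as a
#' classical one-way fixed-effects ANOVA computed from group sums (a
#' linear regression on a categorical donor predictor gives the identical
#' F and p). Missing AFs (uncovered cells) are dropped; donors left with
#' fewer than `min_cells_per_group` observations are excluded from the
#' test.
#'
#' @param af_values Numeric vector of allele frequencies, `NA` = missing.
#' @param donor Character or factor vector of donor ids, same length.
#' @param min_cells_per_group Minimum observations per donor (default 2).
#' @return A one-row tibble: `F`, `df_between`, `df_within`, `log10_p`,
#'   `p`, `n_cells`, `n_donors`, plus list-columns `group_means` and
#'   `group_n` (named per donor). If all within-group variance is zero
#'   but group means differ, `F = Inf` and `p = 0`; if all values are
#'   identical, `F = 0` and `p = 1`.
#' @examples
#' site_anova(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9), rep(c("a", "b"), each = 3))
#' @export
site_anova <- function(af_values, donor, min_cells_per_group = 2L) {
  if (length(af_values) != length(donor)) {
    abort("af_values and donor must have the same length.")
  }
  ok <- !is.na(af_values) & !is.na(donor)
  x <- af_values[ok]
  g <- as.character(donor[ok])
  donors <- sort(unique(g))
  N <- matrix(0, 1L, length(donors), dimnames = list(NULL, donors))
  S <- SS <- N
  for (k in seq_along(donors)) {
    v <- x[g == donors[k]]
    N[1L, k] <- length(v)
    S[1L, k] <- sum(v)
    SS[1L, k] <- sum(v^2)
  }
  res <- .anova_from_stats(N, S, SS, min_cells_per_group)
  if (!res$testable) {
    abort(paste0(
      "Site untestable: need >= 2 donors with >= ", min_cells_per_group,
      " non-missing AFs and residual degrees of freedom."
    ))
  }
  keep <- N[1L, ] >= 1L
  res$group_means <- list(setNames(
    ifelse(keep, S[1L, ] / pmax(N[1L, ], 1L), NA_real_)[keep],
    donors[keep]
  ))
  res$group_n <- list(setNames(as.integer(N[1L, keep]), donors[keep]))
  res$testable <- NULL
  res
}

# Full genome-wide ANOVA scan, returning the stats joined to the variant
# table (one row per variant in the universe, testable or not).
.anova_all <- function(af, grp, params) {
  st <- .donor_group_stats(af, grp)
  res <- .anova_from_stats(st$N, st$S, st$SS, params$min_cells_per_group)
  dplyr::bind_cols(af$variants, res)
}

#' Per-donor mean allele frequencies
#'
#' @param af A `mito_af` object.
#' @param labels Cell-to-donor labels (data frame with `cell_id`,
#'   `donor_id`, or a TSV path).
#' @param method `"cell"`: unweighted mean over cells with non-missing AF;
#'   `"pooled"`: pseudobulk sum(alt)/sum(coverage) over those cells.
#' @return A tibble: `label`, `position`, `ref`, `alt`, `donor_id`,
#'   `mean_af`, `n_cells`. Donors with no covered cell at a site have
#'   `mean_af = NA`.
#' @export
donor_af_means <- function(af, labels, method = c("cell", "pooled")) {
  method <- match.arg(method)
  grp <- .match_labels(af, labels)
  m <- .donor_mean_matrix(af, grp, method)
  tibble(
    label = rep(af$variants$label, times = length(grp$donors)),
    position = rep(af$variants$position, times = length(grp$donors)),
    ref = rep(af$variants$ref, times = length(grp$donors)),
    alt = rep(af$variants$alt, times = length(grp$donors)),
    donor_id = rep(grp$donors, each = nrow(af$af)),
    mean_af = as.vector(m$mean),
    n_cells = as.integer(m$n)
  )
}

.donor_mean_matrix <- function(af, grp, method = "cell") {
  K <- length(grp$donors)
  nv <- nrow(af$af)
  M <- Nc <- matrix(0, nv, K, dimnames = list(NULL, grp$donors))
  obs <- af$cov >= af$min_coverage
  if (method == "pooled") altm <- af$af * af$cov
  for (k in seq_len(K)) {
    cl <- grp$cols[[k]]
    n <- Matrix::rowSums(obs[, cl, drop = FALSE])
    Nc[, k] <- n
    if (method == "cell") {
      s <- Matrix::rowSums(af$af[, cl, drop = FALSE])
      M[, k] <- ifelse(n > 0, s / pmax(n, 1L), NA_real_)
    } else {
      num <- Matrix::rowSums(altm[, cl, drop = FALSE])
      den <- Matrix::rowSums((af$cov * obs)[, cl, drop = FALSE])
      M[, k] <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
    }
  }
  list(mean = M, n = Nc)
}

#' Select the most highly variable variant sites
#'
#' Ranks variants by the unbiased sample variance of their non-missing
#' allele frequencies (descending) and returns the top `n`. Sites
#' observed in fewer than `min_covered_cells` cells are excluded; ties are
#' broken by position, then alt base.
#'
#' @param af A `mito_af` object.
#' @param n Number of sites to return (default 500); fewer are returned
#'   when fewer are eligible.
#' @param min_covered_cells Minimum cells with non-missing AF (default 10).
#' @return A tibble: `label`, `position`, `ref`, `alt`, `n_obs`,
#'   `variance`, ordered by decreasing variance.
#' @export
select_variable_sites <- function(af, n = 500L, min_covered_cells = 10L) {
  stopifnot(inherits(af, "mito_af"))
  if (n < 1L) abort("n must be >= 1")
  obs <- af$cov >= af$min_coverage
  af2 <- af$af
  af2@x <- af2@x^2
  n_obs <- Matrix::rowSums(obs)
  s <- Matrix::rowSums(af$af)
  ss <- Matrix::rowSums(af2)
  v <- ifelse(n_obs >= 2L, pmax(ss - s^2 / pmax(n_obs, 1L), 0) / pmax(n_obs - 1L, 1L), NA_real_)
  out <- dplyr::bind_cols(af$variants, tibble(n_obs = as.integer(n_obs), variance = v)) |>
    dplyr::filter(.data$n_obs >= min_covered_cells, !is.na(.data$variance)) |>
    dplyr::arrange(dplyr::desc(.data$variance), .data$position, .data$alt)
  if (nrow(out) == 0L) {
    abort("No variant site has enough covered cells for variance ranking.")
  }
  head(out, n)
}

#' Variants whose allele frequency differs across donors
#'
#' Runs the per-site one-way ANOVA genome-wide and keeps variants with a
#' raw p-value below `params$anova_p_threshold` (default 1e-100; the
#' comparison is done in log space). These are the variants informative
#' for assigning cells to donors.
#'
#' @param af A `mito_af` object.
#' @param labels Cell-to-donor labels (data frame or TSV path).
#' @param params An [analysis_params()] object.
#' @return A tibble of passing variants, sorted by p ascending (ties:
#'   position, then alt), with the ANOVA columns of [site_anova()].
#' @export
informative_variants <- function(af, labels, params = analysis_params()) {
  grp <- .match_labels(af, labels)
  res <- .anova_all(af, grp, params)
  cut <- log10(params$anova_p_threshold)
  res |>
    dplyr::filter(.data$testable, .data$log10_p < cut) |>
    dplyr::arrange(.data$log10_p, .data$position, .data$alt) |>
    dplyr::select(-"testable")
}

#' Discriminative germline variants: fixed in exactly one donor
#'
#' Keeps variants whose mean allele frequency exceeds
#' `params$germline_af_threshold` (default 0.9) in exactly one donor,
#' with every other donor at or below the threshold. Variants fixed in
#' several donors (shared haplogroup markers) or in all donors
#' (reference-dialect differences) are excluded: they do not discriminate.
#' Results are annotated with the carrier donor and sorted by ANOVA p.
#'
#' @inheritParams informative_variants
#' @return A tibble: variant columns, `carrier`, `carrier_mean_af`,
#'   `carrier_n`, and the ANOVA columns (NA when the site is untestable;
#'   such rows sort last).
#' @export
discriminative_germline <- function(af, labels, params = analysis_params()) {
  grp <- .match_labels(af, labels)
  m <- .donor_mean_matrix(af, grp, params$af_mean)
  exceeds <- !is.na(m$mean) & m$mean > params$germline_af_threshold
  n_exceed <- rowSums(exceeds)
  keep <- which(n_exceed == 1L)
  carrier_idx <- max.col(exceeds[keep, , drop = FALSE], ties.method = "first")
  anova <- .anova_all(af, grp, params)
  out <- dplyr::bind_cols(
    af$variants[keep, ],
    tibble(
      carrier = grp$donors[carrier_idx],
      carrier_mean_af = m$mean[cbind(keep, carrier_idx)],
      carrier_n = as.integer(m$n[cbind(keep, carrier_idx)])
    ),
    anova[keep, c("F", "df_between", "df_within", "log10_p", "p", "n_cells", "n_donors")]
  )
  dplyr::arrange(out, dplyr::desc(!is.na(.data$log10_p)), .data$log10_p, .data$position, .data$alt)
}

#' Scan for donor-specific heteroplasmies
#'
#' Three-step pipeline: (1) identify and exclude the discriminative
#' germline set (or, optionally, all ANOVA-informative variants);
#' (2) keep variants where at least one donor's mean AF lies strictly
#' inside the heteroplasmy band `(het_lo, het_hi)` (defaults 1% and 25%);
#' (3) test the remaining candidates for differential AF across donors by
#' one-way ANOVA and keep those significant at a Bonferroni-adjusted
#' `het_alpha` over the candidates tested. Carriers are the donors whose
#' mean AF falls inside the band.
#'
#' @inheritParams informative_variants
#' @param exclude Which variant set to exclude before the band filter:
#'   `"germline"` (the discriminative AF > 0.9 set; default) or
#'   `"anova"` (every variant passing [informative_variants()]).
#' @return A tibble of heteroplasmy calls: variant columns, `carrier`
#'   (comma-separated when several donors sit in the band),
#'   `n_carriers`, `carrier_mean_af` (mean over carrier donors), the
#'   ANOVA columns, and `p_adj`. The number of candidates tested is in
#'   the `"n_tested"` attribute.
#' @export
heteroplasmy_scan <- function(af, labels, params = analysis_params(),
                              exclude = c("germline", "anova")) {
  exclude <- match.arg(exclude)
  grp <- .match_labels(af, labels)
  excluded <- if (exclude == "germline") {
    discriminative_germline(af, labels, params)$label
  } else {
    informative_variants(af, labels, params)$label
  }
  m <- .donor_mean_matrix(af, grp, params$af_mean)
  in_band <- !is.na(m$mean) & m$mean > params$het_lo & m$mean < params$het_hi
  cand <- which(rowSums(in_band) >= 1L & !(af$variants$label %in% excluded))
  anova <- .anova_all(af, grp, params)[cand, ]
  n_tested <- sum(anova$testable, na.rm = TRUE)
  carriers <- vapply(seq_along(cand), function(i) {
    paste(grp$donors[in_band[cand[i], ]], collapse = ",")
  }, character(1L))
  carrier_mean <- vapply(seq_along(cand), function(i) {
    mean(m$mean[cand[i], in_band[cand[i], ]])
  }, numeric(1L))
  log10_adj <- anova$log10_p + log10(max(n_tested, 1L))
  out <- dplyr::bind_cols(
    af$variants[cand, ],
    tibble(
      carrier = carriers,
      n_carriers = as.integer(rowSums(in_band[cand, , drop = FALSE])),
      carrier_mean_af = carrier_mean
    ),
    anova[, c("F", "df_between", "df_within", "log10_p", "p", "n_cells", "n_donors", "testable")],
    tibble(p_adj = pmin(exp(log10_adj * log(10)), 1))
  ) |>
    dplyr::filter(.data$testable, log10_adj < log10(params$het_alpha)) |>
    dplyr::select(-"testable") |>
    dplyr::arrange(.data$log10_p, .data$position, .data$alt)
  attr(out, "n_tested") <- n_tested
  out
}
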