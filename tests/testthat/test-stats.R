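test_that("site_anova reproduces the closed-form worked example", {
  res <- site_anova(
    c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
    rep(c("a", "b"), each = 3)
  )
  # SSB = 0.54, SSW = 0.04, df (1, 4): F = (0.54/1)/(0.04/4) = 54
  expect_equal(res$F, 54, tolerance = 1e-12)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  # two independent oracles: aov() and the pooled-variance t-test (F = t^2)
  d <- data.frame(y = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9), g = rep(c("a", "b"), each = 3))
  aov_tab <- summary(stats::aov(y ~ g, data = d))[[1]]
  expect_equal(res$F, aov_tab$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, aov_tab$`Pr(>F)`[1], tolerance = 1e-12)
  tt <- stats::t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$group_means[[1]], c(a = 0.2, b = 0.8))
  expect_equal(res$group_n[[1]], c(a = 3L, b = 3L))
})

test_that("degenerate variance cases follow the stated conventions", {
  flat <- site_anova(rep(0.2, 4), rep(c("a", "b"), each = 2))
  expect_equal(flat$F, 0)
  expect_equal(flat$p, 1)
  sep <- site_anova(c(0, 0, 0, 1, 1, 1), rep(c("a", "b"), each = 3))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p, 0)
  expect_equal(sep$log10_p, -Inf)
})

test_that("site_anova matches anova(lm()) on random datasets incl. missing data", {
  set.seed(31)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    n <- sample((2 * k + 1):40, 1)
    g <- sample(letters[1:k], n, replace = TRUE)
    y <- round(runif(n), 3)
    y[sample(n, floor(n * 0.1))] <- NA
    counts <- table(g[!is.na(y)])
    if (sum(counts >= 2) < 2 || sum(counts[counts >= 2]) - sum(counts >= 2) < 1) next
    keepg <- names(counts)[counts >= 2]
    ok <- !is.na(y) & g %in% keepg
    res <- site_anova(y, g, min_cells_per_group = 2L)
    fit <- stats::anova(stats::lm(y[ok] ~ factor(g[ok])))
    expect_equal(res$F, fit$`F value`[1], tolerance = 1e-10)
    expect_equal(res$df_between, fit$Df[1])
    expect_equal(res$df_within, fit$Df[2])
    if (fit$`Pr(>F)`[1] > 1e-300) {
      expect_equal(res$p, fit$`Pr(>F)`[1], tolerance = 1e-8)
    }
  }
})

test_that("ANOVA is invariant to donor relabeling and cell reordering", {
  set.seed(5)
  y <- runif(30)
  g <- sample(c("x", "y", "z"), 30, replace = TRUE)
  base <- site_anova(y, g)
  relab <- site_anova(y, c(x = "d3", y = "d1", z = "d2")[g])
  expect_equal(base$F, relab$F)
  expect_equal(base$log10_p, relab$log10_p)
  ord <- sample(30)
  expect_equal(site_anova(y[ord], g[ord])$F, base$F)
})

test_that("groups below min_cells_per_group are dropped; untestable sites error", {
  y <- c(0.1, 0.2, 0.8, 0.9, 0.5) # donor c has a single cell
  g <- c("a", "a", "b", "b", "c")
  res <- site_anova(y, g, min_cells_per_group = 2L)
  expect_equal(res$n_donors, 2L)
  expect_equal(res$n_cells, 4L)
  expect_error(
    site_anova(c(0.1, 0.5), c("a", "b"), min_cells_per_group = 2L),
    "untestable"
  )
})

test_that("variable-site selection ranks by variance with stated exclusions", {
  af <- toy_af(rbind(
    c(0, 1, 0, 1), # var = 1/3
    c(0.4, 0.6, 0.4, 0.6), # var = 0.04/3
    c(0.5, 0.5, 0.5, 0.5), # constant
    c(0.9, NA, NA, NA) # 1 covered cell only
  ))
  sel <- select_variable_sites(af, n = 10, min_covered_cells = 2)
  expect_equal(sel$position, c(1L, 2L, 3L)) # variance order, constant last
  expect_equal(sel$variance[1], var(c(0, 1, 0, 1)))
  expect_equal(sel$variance[3], 0)
  top1 <- select_variable_sites(af, n = 1, min_covered_cells = 2)
  expect_equal(top1$position, 1L)
  expect_error(
    select_variable_sites(af, n = 5, min_covered_cells = 10),
    "covered cells"
  )
})

test_that("informative_variants filters by the log-space p threshold", {
  # donor-exclusive fixed variant (row 1) among noise rows
  set.seed(9)
  n <- 60
  donors <- rep(c("d1", "d2"), each = n / 2)
  afm <- rbind(
    c(rep(1, n / 2), rep(0, n / 2)),
    matrix(runif(3 * n, 0, 0.02), nrow = 3)
  )
  af <- toy_af(afm)
  labels <- toy_labels(af$cells$cell_id, donors)
  hits <- informative_variants(af, labels)
  expect_equal(hits$position[1], 1L)
  expect_equal(hits$log10_p[1], -Inf) # zero within-group variance
  all_testable <- informative_variants(af, labels, analysis_params(anova_p_threshold = 1))
  expect_equal(nrow(all_testable), 4L)

  # same donor split under two names: no signal at any threshold < 1
  null_labels <- toy_labels(af$cells$cell_id, rep(c("a", "b"), n / 2))
  af_null <- toy_af(afm[2:4, , drop = FALSE])
  expect_equal(nrow(informative_variants(af_null, null_labels, analysis_params(anova_p_threshold = 1e-4))), 0L)
})

test_that("discriminative germline keeps variants fixed in exactly one donor", {
  n <- 40
  donors <- rep(c("d1", "d2", "d3", "d4"), each = 10)
  afm <- rbind(
    c(rep(0.98, 10), rep(0.01, 30)), # carrier d1
    c(rep(0.95, 20), rep(0.0, 20)), # two donors above 0.9 -> excluded
    rep(0.99, n), # fixed everywhere -> excluded
    c(rep(0.5, 10), rep(0.0, 30)) # not above threshold anywhere
  )
  af <- toy_af(afm)
  labels <- toy_labels(af$cells$cell_id, donors)
  g <- discriminative_germline(af, labels)
  expect_equal(g$position, 1L)
  expect_equal(g$carrier, "d1")
  expect_equal(g$carrier_mean_af, 0.98)
  # threshold is strict ">"
  g2 <- discriminative_germline(af, labels, analysis_params(germline_af_threshold = 0.5))
  expect_true(!4L %in% g2$position) # 0.5 is not > 0.5
})

test_that("heteroplasmy scan applies band, exclusion and significance rules", {
  n <- 60
  donors <- rep(c("d1", "d2", "d3"), each = 20)
  afm <- rbind(
    c(rep(0.10, 20), rep(0.001, 40)), # heteroplasmy in d1
    c(rep(0.30, 20), rep(0.001, 40)), # above band
    c(rep(0.98, 20), rep(0.001, 40)), # germline -> excluded
    c(rep(0.008, 20), rep(0.001, 40)) # below band
  )
  af <- toy_af(afm)
  labels <- toy_labels(af$cells$cell_id, donors)
  calls <- heteroplasmy_scan(af, labels)
  expect_equal(calls$position, 1L)
  expect_equal(calls$carrier, "d1")
  expect_equal(calls$carrier_mean_af, 0.10)
  expect_true(all(calls$p_adj < 0.05))
  # no call may sit in the germline exclusion set
  germ <- discriminative_germline(af, labels)
  expect_length(intersect(calls$label, germ$label), 0)
  # a germline-band variant becomes callable only if the band allows it
  wide <- heteroplasmy_scan(af, labels, analysis_params(het_lo = 0.01, het_hi = 0.5))
  expect_setequal(wide$position, c(1L, 2L))
})

test_that("donor means: unweighted cell average vs pooled pseudobulk", {
  # cell 1 low coverage: alt 1/10; cell 2 high: alt 90/100
  m <- list(
    af = as(Matrix::Matrix(matrix(c(0.1, 0.9), 1), sparse = TRUE), "CsparseMatrix"),
    cov = as(Matrix::Matrix(matrix(c(10, 100), 1), sparse = TRUE), "CsparseMatrix"),
    variants = tibble::tibble(label = "1A>G", position = 1L, ref = "A", alt = "G"),
    cells = tibble::tibble(cell_id = c("c1", "c2"), n_reads = NA_integer_, n_bases = NA_integer_),
    min_coverage = 1L, reference = list(contig = "toy", length = 1L)
  )
  class(m) <- "mito_af"
  labels <- toy_labels(c("c1", "c2"), c("d", "d"))
  labels2 <- rbind(labels, toy_labels("x", "e")) # second donor needed
  m$af <- cbind(m$af, Matrix::Matrix(0, 1, 1, sparse = TRUE))
  m$cov <- cbind(m$cov, Matrix::Matrix(5, 1, 1, sparse = TRUE))
  m$cells <- tibble::tibble(cell_id = c("c1", "c2", "x"), n_reads = NA_integer_, n_bases = NA_integer_)
  cellwise <- donor_af_means(m, labels2, method = "cell")
  pooled <- donor_af_means(m, labels2, method = "pooled")
  expect_equal(cellwise$mean_af[cellwise$donor_id == "d"], 0.5)
  expect_equal(pooled$mean_af[pooled$donor_id == "d"], 91 / 110)
})
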