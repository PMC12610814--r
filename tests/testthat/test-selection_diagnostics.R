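# Profiles reused across the diagnostics tests.
diag_profile <- local({
  prof <- NULL
  function() {
    if (is.null(prof)) {
      prof <<- cub_profile(
        generate_cds_set(usage_regime("at_biased", n_genes = 30, seed = 21)))
    }
    prof
  }
})

test_that("ENC-ratio classification follows the windowed definition", {
  prof <- diag_profile()
  res <- enc_plot(prof)
  expect_equal(res$n_inside + res$n_outside, sum(prof$enc_defined))
  expect_equal(res$frac_inside + res$frac_outside, 1)
  # direct arithmetic on the ratio definition
  genes <- res$genes
  expect_equal(genes$enc_ratio,
               (genes$enc_exp - genes$enc_obs) / genes$enc_exp)
  expect_equal(genes$classification,
               ifelse(abs(genes$enc_ratio) <= 0.05, "inside", "outside"))
  # toy values: exp 50/obs 60 -> -0.2 outside; exp 50/obs 49 -> 0.02 inside
  expect_equal((50 - 60) / 50, -0.2)
  toy <- prof[1:2, ]
  toy$enc_exp <- c(50, 50)
  toy$enc_obs <- c(60, 49)
  toy$enc_ratio <- (toy$enc_exp - toy$enc_obs) / toy$enc_exp
  cls <- enc_plot(toy)$genes$classification
  expect_equal(cls, c("outside", "inside"))
  # invariant to gene order
  shuffled <- enc_plot(prof[rev(seq_len(nrow(prof))), ])
  expect_equal(shuffled$n_inside, res$n_inside)
})

test_that("PR2 coordinates and quadrants follow the axis definitions", {
  prof <- diag_profile()
  pts <- pr2_points(prof)
  expect_true(all(pts$pr2_x >= 0 & pts$pr2_x <= 1, na.rm = TRUE))
  expect_true(all(pts$pr2_y >= 0 & pts$pr2_y <= 1, na.rm = TRUE))
  # A3 = T3 and G3 = C3 -> the (0.5, 0.5) center
  ctr <- cub_profile(tibble::tibble(
    gene = "c", sequence = cds_from_codons("GGA", "GGU", "GGG", "GGC")))
  cpt <- pr2_points(ctr)
  expect_equal(cpt$pr2_x, 0.5)
  expect_equal(cpt$pr2_y, 0.5)
  expect_equal(cpt$quadrant, "center")
  # A3=1, T3=3, G3=3, C3=1 -> x = 0.75, y = 0.25, lower-right
  lr <- cub_profile(tibble::tibble(
    gene = "lr",
    sequence = cds_from_codons("GCA", "GCU", "ACU", "UCU",
                               "GGG", "AGG", "CGG", "GCC")))
  lpt <- pr2_points(lr)
  expect_equal(lpt$pr2_x, 0.75)
  expect_equal(lpt$pr2_y, 0.25)
  expect_equal(lpt$quadrant, "lower_right")
  # A/U-biased synthesis puts most genes in the lower half (T3 > A3 with
  # the U-rich preferred set)
  expect_gt(mean(pts$pr2_y < 0.5), 0.5)
})

test_that("neutrality regression recovers forced slopes", {
  prof <- diag_profile()
  # gc12 identical to gc3 -> slope 1, r 1
  ident <- prof
  ident$gc12 <- ident$gc3
  fit1 <- neutrality(ident)
  expect_equal(fit1$slope, 1, tolerance = 1e-12)
  expect_equal(fit1$r, 1, tolerance = 1e-12)
  expect_equal(fit1$n_below_diagonal, 0) # on-diagonal counts as above
  # gc12 constant -> slope 0
  flat <- prof
  flat$gc12 <- 0.4
  # constant gc12: slope is exactly 0 (Pearson r is undefined and warns)
  expect_equal(suppressWarnings(neutrality(flat))$slope, 0, tolerance = 1e-12)
  # degenerate inputs
  expect_error(neutrality(prof[1:2, ]), ">= 3")
  same <- prof
  same$gc3 <- 0.3
  expect_error(neutrality(same), "identical")
  g <- glance(neutrality(prof))
  expect_true(is.finite(g$slope) && is.finite(g$p_value))
})

test_that("correlation tables match hand Pearson values and transpose", {
  prof <- diag_profile()
  # x correlated with itself -> r = 1
  self <- correlation_table(prof, rows = "gc3", cols = "gc3")
  expect_equal(self$r, 1)
  # hand example x = (1,2,3), y = (1,2,4) -> r = 3/sqrt(28/3)
  toy <- tibble::tibble(gene = letters[1:3], x = c(1, 2, 3), y = c(1, 2, 4))
  r <- correlation_table(toy, rows = "x", cols = "y")
  expect_equal(r$r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_equal(round(r$r, 4), 0.982)
  # p-value is the exact two-tailed t transform with n - 2 df
  tstat <- r$r * sqrt((3 - 2) / (1 - r$r^2))
  expect_equal(r$p_value, 2 * stats::pt(-abs(tstat), df = 1),
               tolerance = 1e-12)
  # transpose symmetry over the full composition table
  fwd <- correlation_table(prof)
  rev <- correlation_table(prof, rows = c("a3", "t3", "g3", "c3", "gc3"),
                           cols = c("a", "t", "g", "c", "gc"))
  merged <- merge(fwd, rev, by.x = c("row", "col"), by.y = c("col", "row"))
  expect_equal(merged$r.x, merged$r.y, tolerance = 1e-12)
  expect_true(all(abs(fwd$r) <= 1))
  # zero-variance variable flagged
  zv <- prof
  zv$gc <- 0.5
  expect_warning(zt <- correlation_table(zv, rows = "gc", cols = "gc3"),
                 "zero-variance")
  expect_true(is.na(zt$r))
  expect_error(correlation_table(prof, rows = "nope"), "unknown")
})
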