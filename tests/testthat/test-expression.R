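# Small helper: build an amp_rpkm whose log2 RPKM values are exactly the
# supplied per-group vectors (length 1000 bp, depth 1e6 makes RPKM = count).
rpkm_from_log2 <- function(log2_by_sample, design) {
  counts <- round(2^log2_by_sample)
  cm <- count_matrix(counts, setNames(rep(1000, nrow(counts)), rownames(counts)),
                     totals = setNames(rep(1e6, ncol(counts)), colnames(counts)))
  compute_rpkm(cm, design)
}

two_group_design <- function() {
  d <- default_design()
  d$group <- paste0(d$context, d$sex)
  d[d$group %in% c("Mm", "Cm"), ]
}

test_that("RPKM follows the count x 1e9 / (length x depth) formula", {
  counts <- matrix(c(10L, 0L, 200L), 3, 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  cm <- count_matrix(counts, c(a = 1000, b = 1000, c = 500),
                     totals = c(s1 = 1e6))
  d <- data.frame(sample = "s1", sex = "m", context = "M", replicate = 1)
  # depth 1e6: RPKM = count for 1 kb genes; 500 bp at depth 2e7 below
  rk <- compute_rpkm(cm, d)
  expect_equal(unname(rk$rpkm["a", ]), 10)
  expect_equal(unname(rk$rpkm["b", ]), 0)
  expect_equal(unname(rk$log2_rpkm["b", ]), log2(2^-4))  # floored, finite
  cm2 <- count_matrix(counts, c(a = 1000, b = 1000, c = 500),
                      totals = c(s1 = 2e7))
  expect_equal(unname(compute_rpkm(cm2, d)$rpkm["c", ]), 20)

  # round trip: count = RPKM x length x total / 1e9, exactly
  fx <- sim_expression_fixture(seed = 51)
  rk <- compute_rpkm(fx$counts, fx$design)
  back <- rk$rpkm * fx$counts$lengths * rep(rk$totals, each = nrow(rk$rpkm)) / 1e9
  expect_equal(back, fx$counts$counts[, colnames(rk$rpkm)], tolerance = 1e-12)

  cm_bad <- cm; cm_bad$totals["s1"] <- 0
  expect_error(compute_rpkm(cm_bad, d), "zero total")
})

test_that("count matrix construction validates its invariants", {
  m <- matrix(1L, 1, 1, dimnames = list("g", "s"))
  expect_error(count_matrix(m, c(g = -1)), "positive")
  expect_error(count_matrix(matrix(-1L, 1, 1, dimnames = list("g", "s")),
                            c(g = 10)), "non-negative")
  expect_error(count_matrix(m, c(g = 10), totals = c(s = 0)), "below the column sums")
  # totals may exceed column sums (matrix holds a gene subset)
  expect_silent(count_matrix(m, c(g = 10), totals = c(s = 100)))
})

test_that("low-expression filtering excludes by group means with strict threshold", {
  d <- default_design()
  samples <- d$sample
  log2v <- rbind(
    all_low = rep(0.5, 18),
    one_high = rep(c(3, 0, 0, 0, 0, 0), each = 3),
    at_threshold = rep(1, 18),
    high = rep(5, 18))
  colnames(log2v) <- samples
  rk <- rpkm_from_log2(log2v, d)
  kept_all <- filter_low_expression(rk, threshold_log2 = 1, mode = "all")
  kept_any <- filter_low_expression(rk, threshold_log2 = 1, mode = "any")
  expect_false("all_low" %in% kept_all)
  expect_false("all_low" %in% kept_any)
  # low in five groups but high in one: kept by default, dropped by "any"
  expect_true("one_high" %in% kept_all)
  expect_false("one_high" %in% kept_any)
  # "less than" is strict: exactly at threshold stays
  expect_true("at_threshold" %in% kept_all)
  expect_true("at_threshold" %in% kept_any)
})

test_that("housekeeping stability uses fold range of group means, strictly below 1.3", {
  d <- default_design()
  d$group <- paste0(d$context, d$sex)
  log2v <- rbind(
    constant = rep(3, 18),
    at_limit = rep(c(3, 3 + log2(1.3), 3, 3, 3, 3), each = 3),
    slight = rep(c(3, 3.1, 3, 3, 3, 3), each = 3))
  colnames(log2v) <- d$sample
  rk <- rpkm_from_log2(log2v, d)
  # counts are rounded to integers; recompute on exact group means instead
  rk$group_means <- t(vapply(rownames(log2v), function(g)
    tapply(log2v[g, ], d$group[match(colnames(log2v), d$sample)], mean)[amp_groups()],
    numeric(6)))
  hk <- housekeeping_stability(rk, rownames(log2v))
  expect_equal(hk$fold[hk$gene == "constant"], 1)
  expect_true(hk$pass[hk$gene == "constant"])
  expect_equal(hk$fold[hk$gene == "at_limit"], 1.3)
  expect_false(hk$pass[hk$gene == "at_limit"])   # strict inequality
  expect_equal(hk$fold[hk$gene == "slight"], 2^0.1, tolerance = 1e-12)
  expect_true(hk$pass[hk$gene == "slight"])
  expect_error(housekeeping_stability(rk, "nope"), "unknown gene")
})

test_that("pooled t-test matches the closed form and stats::t.test", {
  d <- two_group_design()
  log2v <- matrix(c(1, 2, 3, 4, 5, 6), 1,
                  dimnames = list("g1", c(d$sample[d$group == "Mm"],
                                          d$sample[d$group == "Cm"])))
  rk <- rpkm_from_log2(log2v, d)
  rk$log2_rpkm[] <- log2v[, colnames(rk$log2_rpkm)]  # exact values
  res <- t_test_bh(rk, "Mm-vs-Cm")
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  # closed form on {1,2,3} vs {4,5,6}: t = -3/sqrt(2/3)
  o <- pooled_t_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(o$t, -3 / sqrt(2 / 3), tolerance = 1e-12)

  # random data: vectorized implementation equals stats::t.test gene-wise
  withr::with_seed(77, {
    x <- matrix(rnorm(60), 10)
    colnames(x) <- colnames(rk$log2_rpkm)
    rownames(x) <- sprintf("g%02d", 1:10)
    rk$log2_rpkm <- x
    res <- t_test_bh(rk, "Mm-vs-Cm")
    for (i in c(1, 5, 10)) {
      tt <- t.test(x[i, 1:3], x[i, 4:6], var.equal = TRUE)
      expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
      expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
    }
    # Welch option
    resw <- t_test_bh(rk, "Mm-vs-Cm", var_equal = FALSE)
    tw <- t.test(x[1, 1:3], x[1, 4:6])
    expect_equal(resw$t[1], unname(tw$statistic), tolerance = 1e-10)
    expect_equal(resw$df[1], unname(tw$parameter), tolerance = 1e-10)
  })
})

test_that("degenerate zero-variance genes follow the stated conventions", {
  d <- two_group_design()
  log2v <- rbind(flat = rep(2, 6), split = rep(c(1, 5), each = 3))
  colnames(log2v) <- c(d$sample[d$group == "Mm"], d$sample[d$group == "Cm"])
  rk <- rpkm_from_log2(log2v, d)
  rk$log2_rpkm[] <- log2v[, colnames(rk$log2_rpkm)]
  res <- t_test_bh(rk, "Mm-vs-Cm")
  expect_equal(res$t[res$gene == "flat"], 0)
  expect_equal(res$p[res$gene == "flat"], 1)
  expect_equal(res$star[res$gene == "flat"], "")
  expect_true(res$degenerate[res$gene == "split"])
  expect_equal(res$p[res$gene == "split"], 0)
})

test_that("BH adjustment and stars respect their invariants", {
  d <- two_group_design()
  withr::with_seed(19, {
    x <- matrix(rnorm(300), 50)
    colnames(x) <- d$sample
    rownames(x) <- sprintf("g%02d", 1:50)
  })
  rk <- rpkm_from_log2(x, d)
  rk$log2_rpkm <- x
  res <- t_test_bh(rk, "Mm-vs-Cm")
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
  # monotone in rank order
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  expect_true(all(res$star[res$p_adj >= 0.05] == ""))
})

test_that("contrasts are antisymmetric and cover the full design", {
  fx <- sim_expression_fixture(seed = 61)
  rk <- compute_rpkm(fx$counts, fx$design)
  a <- t_test_bh(rk, "Cm-vs-Cf")
  b <- t_test_bh(rk, "Cf-vs-Cm")
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)

  # |log2FC| equals the difference of group-mean log2 values
  expect_equal(a$log2fc,
               unname(rk$group_means[a$gene, "Cm"] - rk$group_means[a$gene, "Cf"]))

  out <- run_contrasts(rk)
  expect_named(out$results, amp_contrasts())
  # missing group reported by name
  part <- fx$design[fx$design$group != "CLf", ]
  rk2 <- compute_rpkm(fx$counts, part)
  expect_error(run_contrasts(rk2), "CLf")
})

test_that("reference genes ride through to the heat map unfiltered", {
  fx <- sim_expression_fixture(seed = 62)
  # silence one housekeeping gene so it fails the expression filter
  cm <- fx$counts
  cm$counts["housekeeping_01", ] <- 0L
  rk <- compute_rpkm(cm, fx$design)
  expect_false("housekeeping_01" %in% filter_low_expression(rk))
  out <- run_contrasts(rk, reference_genes = c("housekeeping_01", "housekeeping_02"))
  expect_true(all(c("housekeeping_01", "housekeeping_02") %in% out$heatmap$gene))
  # reference genes are annotated but not tested
  expect_false("housekeeping_01" %in% out$results[["Mm-vs-Cm"]]$gene)
  expect_equal(out$heatmap[out$heatmap$gene == "housekeeping_01", "star_Mm-vs-Cm"], "")
  # heat map carries the six group-mean columns
  expect_true(all(amp_groups() %in% colnames(out$heatmap)))
})
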