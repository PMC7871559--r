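test_that("p-value selection is strict and order-preserving", {
  tab <- stab(c("a", "b", "c"), c(0.1, 0.1, 0.1), 0.01,
              pval = c(1e-6, 1e-5, 1e-4))
  sel <- select_by_pvalue(tab, 1e-5)
  expect_equal(sel$snp_id, "a")                  # strict <
  expect_equal(select_by_pvalue(tab, 1)$snp_id, c("a", "b", "c"))
  expect_warning(select_by_pvalue(tab, 1e-10), "no records")
  fx <- load_fixture("5-oxoproline")
  expect_equal(nrow(select_by_pvalue(fx$exposure, 1e-5)), 25L)
})

test_that("greedy clumping follows the hand-traced rule", {
  tab <- stab(c("s1", "s2", "s3"), c(0.1, 0.1, 0.1), 0.01,
              pval = c(1e-8, 1e-7, 1e-6))
  pos <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "1",
                    bp = c(100000, 200000, 300000))
  ld <- ld_table(data.frame(snp_a = c("s1", "s1", "s2"),
                            snp_b = c("s2", "s3", "s3"),
                            r2 = c(0.5, 0.05, 0.02)), pos)
  out <- clump_greedy(tab, ld, r2_threshold = 0.1, window_kb = 500)
  expect_equal(out$snp_id, c("s1", "s3"))
  expect_equal(attr(out, "clumped_out")$snp_id, "s2")
  expect_equal(attr(out, "clumped_out")$index_snp, "s1")

  # all-zero r2: everything kept
  ld0 <- ld_table(positions = pos)
  expect_equal(clump_greedy(tab, ld0)$snp_id, c("s1", "s2", "s3"))

  # high r2 but outside the window: both kept
  pos2 <- data.frame(snp_id = c("s1", "s2"), chrom = "1",
                     bp = c(0, 600000))
  ld2 <- ld_table(data.frame(snp_a = "s1", snp_b = "s2", r2 = 0.5), pos2)
  tab2 <- stab(c("s1", "s2"), c(0.1, 0.1), 0.01, pval = c(1e-8, 1e-7))
  expect_equal(clump_greedy(tab2, ld2)$snp_id, c("s1", "s2"))
})

test_that("clumping rejects invalid parameters and handles missing positions", {
  tab <- stab("s1", 0.1, 0.01)
  ld <- ld_table()
  expect_error(clump_greedy(tab, ld, r2_threshold = 1.2), "\\[0, 1\\]")
  expect_error(clump_greedy(tab, ld, window_kb = -5), "non-negative")
  out <- clump_greedy(tab, ld)
  expect_equal(attr(out, "no_position"), "s1")
  expect_equal(out$snp_id, "s1")
})

test_that("clumped output is an independent set retaining the top hit", {
  for (s in 1:8) {
    set.seed(s)
    J <- 12
    ids <- paste0("v", 1:J)
    tab <- stab(ids, runif(J, 0.05, 0.2), 0.01,
                pval = 10^-runif(J, 5, 12))
    pos <- data.frame(snp_id = ids, chrom = sample(1:2, J, TRUE),
                      bp = sample.int(2e6, J))
    pairs <- t(combn(ids, 2))
    r2 <- data.frame(snp_a = pairs[, 1], snp_b = pairs[, 2],
                     r2 = runif(nrow(pairs)))
    ld <- ld_table(r2, pos)
    kept <- clump_greedy(tab, ld, 0.1, 500)
    # the globally smallest p-value is always retained
    expect_true(tab$snp_id[which.min(tab$pval)] %in% kept$snp_id)
    # exhaustive pair check: no retained pair violates both conditions
    look <- function(a, b) r2$r2[(r2$snp_a == a & r2$snp_b == b) |
                                 (r2$snp_a == b & r2$snp_b == a)]
    for (i in seq_len(nrow(kept))) for (j in seq_len(nrow(kept))) {
      if (i >= j) next
      a <- kept$snp_id[i]; b <- kept$snp_id[j]
      pa <- pos[match(a, pos$snp_id), ]; pb <- pos[match(b, pos$snp_id), ]
      same_window <- pa$chrom == pb$chrom &&
        abs(pa$bp - pb$bp) <= 5e5
      expect_false(same_window && look(a, b) >= 0.1)
    }
    # tightening the r2 threshold never increases the retained count
    expect_lte(nrow(clump_greedy(tab, ld, 0.05, 500)), nrow(kept))
  }
})

test_that("strength statistics match the closed form F = z^2", {
  tab <- stab("rs11986602", 0.0620, 0.0029, n = 7824)
  rep <- instrument_strength(tab)
  z <- 0.0620 / 0.0029
  expect_equal(rep$f, z^2, tolerance = 1e-12)
  expect_equal(rep$r2, z^2 / (z^2 + 7822), tolerance = 1e-12)
  expect_equal(rep$r2, 0.0552, tolerance = 1e-3)
  expect_equal(rep$f, 457.1, tolerance = 1e-3)
  expect_equal(rep$total_r2, sum(rep$r2))

  # z = 0 gives R2 = 0, F = 0
  rep0 <- instrument_strength(stab("a", 0, 0.01, n = 100))
  expect_equal(rep0$f, 0)
  expect_equal(rep0$r2, 0)

  # n_override fills missing n; error when nothing available
  fx <- load_fixture("5-oxoproline")
  expect_error(instrument_strength(fx$exposure), "sample size required")
  repo <- instrument_strength(fx$exposure, n_override = 7824)
  expect_equal(repo$f, (fx$exposure$beta / fx$exposure$se)^2,
               tolerance = 1e-12)
  expect_lte(repo$min_f, repo$mean_f)
})

test_that("F >= 10 is equivalent to z^2 >= 10 over a parameter grid", {
  grid <- expand.grid(beta = c(0.001, 0.01, 0.05, 0.2),
                      se = c(0.001, 0.01, 0.05),
                      n = c(50, 1000, 7824, 1e5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    rep <- instrument_strength(stab("x", g$beta, g$se, n = g$n))
    z2 <- (g$beta / g$se)^2
    expect_equal(rep$f >= 10, z2 >= 10)
    expect_equal(rep$f, z2, tolerance = 1e-10)
  }
})

test_that("weak-instrument filtering keeps strictly F > f_min", {
  # F exactly 10: dropped under the strict rule
  tab <- stab(c("a", "b"), c(0.05, 0.2), 0.01, n = 102)
  rep <- instrument_strength(tab)
  rep$f <- c(10, 400)  # pin the boundary value exactly
  expect_equal(filter_weak(tab, rep, 10)$snp_id, "b")

  n <- 102
  se <- 0.01
  tab3 <- stab(c("a", "b", "c"), sqrt(c(5, 20, 30)) * se, se, n = n)
  rep3 <- instrument_strength(tab3)
  expect_equal(filter_weak(tab3, rep3)$snp_id, c("b", "c"))
  expect_equal(filter_weak(tab3, rep3, 1)$snp_id, c("a", "b", "c"))
  expect_error(filter_weak(tab, rep3), "aligned")
})

test_that("LD tables validate and read from disk", {
  expect_error(ld_table(data.frame(snp_a = "a", snp_b = "b", r2 = 1.5)),
               "\\[0, 1\\]")
  r2f <- tempfile(); posf <- tempfile()
  writeLines(c("snp_a\tsnp_b\tr2", "s1\ts2\t0.4"), r2f)
  writeLines(c("snp_id\tchrom\tbp", "s1\t1\t100", "s2\t1\t200"), posf)
  ld <- read_ld_table(r2f, posf)
  expect_s3_class(ld, "ld_table")
  expect_equal(ld$r2$r2, 0.4)
})
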