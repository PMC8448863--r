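test_that("BH step-up matches the hand example and p.adjust on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  # monotone non-decreasing on sorted input
  p <- sort(runif(50))
  expect_true(all(diff(bh_adjust(p)) >= -1e-12))
  withr::with_seed(42, {
    for (i in 1:25) {
      p <- runif(sample(3:200, 1))
      expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH q <= alpha reproduces the classical step-up rejection set", {
  withr::with_seed(7, {
    for (i in 1:50) {
      m <- sample(5:300, 1)
      p <- runif(m)^sample(1:3, 1)
      alpha <- runif(1, 0.01, 0.2)
      # classical step-up: reject 1..k*, k* = max{ i : p_(i) <= i/m alpha }
      ps <- sort(p)
      kstar <- max(c(0, which(ps <= seq_len(m) / m * alpha)))
      classical <- p <= (if (kstar == 0) -1 else ps[kstar])
      expect_identical(bh_adjust(p) <= alpha, classical)
    }
  })
})

test_that("hypergeometric upper tail is exact (enumeration + phyper)", {
  expect_equal(hypergeom_pvalue(0, 5, 5, 20), 1)          # whole support
  expect_equal(hypergeom_pvalue(5, 5, 5, 10), 1 / 252)    # all marked drawn
  withr::with_seed(11, {
    for (i in 1:30) {
      N <- sample(2:11, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
      klo <- max(0, n + K - N); khi <- min(K, n)
      k <- klo + sample.int(khi - klo + 1, 1) - 1
      p <- hypergeom_pvalue(k, K, n, N)
      expect_equal(p, hyper_tail_enum(k, K, n, N), tolerance = 1e-12)
      expect_equal(p, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  })
  expect_error(hypergeom_pvalue(6, 5, 5, 10), "bounds")
})

test_that("two-sided Fisher follows the point-probability rule", {
  # extreme off-diagonal table and independence case against enumeration
  expect_equal(fisher_exact_2x2(0, 3, 4, 0), fisher_enum(0, 3, 4, 0))
  expect_equal(fisher_exact_2x2(2, 2, 2, 2), 1)
  withr::with_seed(13, {
    for (i in 1:30) {
      tb <- sample(0:6, 4, replace = TRUE)
      p <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
      expect_equal(p, fisher_enum(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-10)
      expect_equal(p, stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-7)
      # transposition invariance
      expect_equal(p, fisher_exact_2x2(tb[1], tb[3], tb[2], tb[4]), tolerance = 1e-12)
    }
  })
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "integer|\\[")
})

test_that("enrichment factor is (k/n)/(K/N) with guarded denominators", {
  expect_equal(enrichment_factor(4, 20, 10, 200), 4)
  expect_equal(enrichment_factor(0, 20, 10, 200), 0)
  expect_equal(enrichment_factor(1, 20, 10, 200), 1)
  expect_error(enrichment_factor(0, 20, 0, 200), "undefined")
})

test_that("fold-change z-score behaves as a standardised set shift", {
  all_fc <- rnorm(500)
  members <- sample(all_fc, 30)
  expect_equal(ksea_zscore(all_fc, all_fc), 0, tolerance = 1e-12)
  z <- ksea_zscore(all_fc, members)
  expect_equal(ksea_zscore(-all_fc, -members), -z, tolerance = 1e-12)
  expect_error(ksea_zscore(rep(1, 10), 1), "zero")
  # planted +1 sigma shift, m = 25 -> E[z] ~ 5
  withr::with_seed(19, {
    zs <- replicate(1000, {
      bg <- rnorm(1000)
      mem <- rnorm(25, mean = 1)
      ksea_zscore(c(bg, mem), mem)
    })
    expect_lt(abs(mean(zs) - 5), 0.5)
  })
})

test_that("z classification thresholds are inclusive", {
  expect_identical(classify_z(1.5), "overrepresented")
  expect_identical(classify_z(-1.5), "underrepresented")
  expect_identical(classify_z(0), "neutral")
  expect_identical(classify_z(c(2, -2, 1.49)),
                   c("overrepresented", "underrepresented", "neutral"))
})

test_that("KSEA recovers a planted kinase and zeroes out absent ones", {
  withr::with_seed(23, {
    p <- phospho_sim_params(n_peptides = 400, fraction_regulated = 0.15,
                            planted_log2fc = 1, planted_kinases = c(K1 = 25),
                            n_decoy_kinases = 10, noise_sd_log2 = 0.1, seed = 5)
    sim <- gen_phospho_raw(p)
    amp <- as.matrix(sim$truth[, paste0("amp_", sim$samples$sample)])
    rownames(amp) <- sim$truth$peptide_id
    attr(amp, "condition") <- sim$samples$condition
    d <- differential(amp)
    ks <- ksea(d, sim$setdb)
    # planted kinase: best (smallest) p overall, direction "up"
    best <- ks[which.min(ks$p), ]
    expect_identical(best$set, "K1")
    expect_identical(best$direction, "up")
    # invariants on every row
    expect_true(all(ks$k <= pmin(ks$K, ks$n)))
    expect_true(all(ks$q >= ks$p - 1e-12))
    expect_true(all(ks$p >= 0 & ks$p <= 1))
    expect_true(all(ks$enrichment_factor >= 0))
    # a kinase with no significant members in either direction
    db2 <- c(sim$setdb, list(empty_kinase = sim$truth$peptide_id[
      !sim$truth$regulated][1:20]))
    ks2 <- ksea(d, db2)
    row <- ks2[ks2$set == "empty_kinase" & ks2$k == 0, ]
    expect_true(all(row$enrichment_factor == 0))
  })
})

test_that("ontology enrichment recovers a planted term and validates inputs", {
  withr::with_seed(29, {
    universe <- sprintf("g%04d", 1:1000)
    term <- sample(universe, 30)
    hits <- unique(c(sample(term, 24), sample(setdiff(universe, term), 97)))
    db <- list(planted = term,
               random1 = sample(universe, 40),
               random2 = sample(universe, 25))
    res <- ontology_enrichment(hits, universe, db)
    expect_lt(res$q[res$set == "planted"], 0.05)
    expect_true(all(res$q >= res$p - 1e-12))
    expect_error(ontology_enrichment(c(hits, "novel"), universe, db),
                 "not contained")
  })
})
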