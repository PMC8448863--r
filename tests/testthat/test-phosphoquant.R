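test_that("XIC window follows the ppm definition exactly", {
  raw <- data.frame(rt_s = c(100, 100, 100, 100),
                    mz = c(499.9949, 499.9951, 500.0049, 500.0051),
                    intensity = 1:4)
  pep <- list(mz = 500, rt_apex_s = 100)
  tr <- extract_xic(raw, pep, xic_params(ppm_tol = 10))
  expect_equal(nrow(tr), 2)                          # [499.995, 500.005]
  expect_setequal(tr$intensity, c(2, 3))
  # rt window and ordering
  raw2 <- data.frame(rt_s = c(200, 90, 129, 69), mz = 500, intensity = 1:4)
  tr2 <- extract_xic(raw2, list(mz = 500, rt_apex_s = 100),
                     xic_params(rt_half_window_s = 30))
  expect_equal(tr2$rt_s, c(90, 129))   # inside [70, 130], rt-ordered
  # nothing near the target -> empty trace, not an error
  expect_equal(nrow(extract_xic(raw, list(mz = 900, rt_apex_s = 100),
                                xic_params())), 0)
})

test_that("peak height is the max intensity with a minimum-point gate", {
  tr <- data.frame(rt_s = 1:12, mz = 500, intensity = c(1:6, 6:1) * 10)
  expect_equal(peak_height(tr, xic_params(min_points = 10)), 60)
  expect_true(is.na(peak_height(tr[1:3, ], xic_params(min_points = 10))))
  tr2 <- tr; tr2$intensity <- tr$intensity * 2
  expect_equal(peak_height(tr2, xic_params(min_points = 10)),
               2 * peak_height(tr, xic_params(min_points = 10)))
})

test_that("end-to-end quantification recovers planted amplitudes exactly", {
  p <- phospho_sim_params(n_peptides = 60, noise_sd_log2 = 0,
                          fraction_regulated = 0, planted_kinases = c(),
                          mz_jitter_ppm = 2, seed = 8)
  sim <- gen_phospho_raw(p)
  hm <- quantify_peptides(sim$raw, sim$peptides, sim$samples)
  amp <- as.matrix(sim$truth[, paste0("amp_", sim$samples$sample)])
  expect_false(anyNA(hm))
  expect_equal(as.vector(hm), as.vector(amp), tolerance = 1e-9)
})

test_that("sum normalisation equalises totals and is scale invariant", {
  withr::with_seed(41, {
    m <- matrix(rexp(60, 1e-6), 20, 3, dimnames = list(NULL, c("A1", "A2", "B1")))
    m[3, 2] <- NA
    nm <- normalize_heights(m)
    tots <- colSums(nm, na.rm = TRUE)
    expect_lt(max(abs(tots / tots[1] - 1)), 1e-9)
    # multiplying one sample's raw heights by 10 leaves its normalised values unchanged
    m2 <- m; m2[, 2] <- m2[, 2] * 10
    expect_equal(normalize_heights(m2)[, 2] / mean(colSums(m2, na.rm = TRUE)),
                 nm[, 2] / mean(colSums(m, na.rm = TRUE)), tolerance = 1e-12)
    # single-sample matrix is unchanged
    m1 <- m[, 1, drop = FALSE]
    expect_equal(normalize_heights(m1), m1)
    mz <- m; mz[, 3] <- NA
    expect_error(normalize_heights(mz), "B1")
  })
})

test_that("normalisation removes a planted per-sample scale factor from fold changes", {
  withr::with_seed(43, {
    m <- matrix(2^rnorm(400, 20, 1), 100, 4,
                dimnames = list(sprintf("p%03d", 1:100), c("A1", "A2", "B1", "B2")))
    attr(m, "condition") <- c("A", "A", "B", "B")
    d0 <- differential(normalize_heights(m))
    scales <- c(1, 3.7, 0.4, 12)
    m2 <- sweep(m, 2, scales, "*")
    attr(m2, "condition") <- c("A", "A", "B", "B")
    d1 <- differential(normalize_heights(m2))
    expect_equal(d1$log2fc, d0$log2fc, tolerance = 1e-9)
  })
})

test_that("differential testing is antisymmetric and matches t.test", {
  withr::with_seed(47, {
    m <- matrix(2^rnorm(300, 20, 0.5), 50, 6,
                dimnames = list(sprintf("p%03d", 1:50),
                                c("A1", "A2", "A3", "B1", "B2", "B3")))
    cond <- rep(c("A", "B"), each = 3)
    attr(m, "condition") <- cond
    d <- differential(m)
    # identical replicated values in both groups -> fold change 0
    mc <- m; mc[1, ] <- 1000
    dc <- differential(mc, cond)
    expect_equal(dc$log2fc[1], 0)
    expect_equal(dc$p[1], 1)
    # swapping condition labels negates fold changes, p unchanged
    d_swap <- differential(m, rev(cond))
    expect_equal(d_swap$log2fc, -d$log2fc, tolerance = 1e-12)
    expect_equal(d_swap$p, d$p, tolerance = 1e-12)
    # equal-variance Student t oracle
    for (i in c(2, 17, 50)) {
      tt <- stats::t.test(log2(m[i, 4:6]), log2(m[i, 1:3]), var.equal = TRUE)
      expect_equal(d$p[i], tt$p.value, tolerance = 1e-12)
      expect_equal(d$log2fc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
    }
    # Welch flag matches Welch t.test
    dw <- differential(m, welch = TRUE)
    tw <- stats::t.test(log2(m[2, 4:6]), log2(m[2, 1:3]))
    expect_equal(dw$p[2], tw$p.value, tolerance = 1e-12)
    # missing-value gate: < 2 present in a condition -> NA p, kept row
    mna <- m; mna[5, 1:2] <- NA
    dna <- differential(mna, cond)
    expect_true(is.na(dna$p[5]))
    expect_false(is.na(dna$log2fc[5]))
    expect_error(differential(m[, 1:3], c("A", "A", "B")), "at least 2")
  })
})

test_that("planted fold change is recovered within the expected band", {
  p <- phospho_sim_params(n_peptides = 200, fraction_regulated = 1,
                          planted_log2fc = 2, planted_kinases = c(K1 = 200),
                          noise_sd_log2 = 0.1, seed = 17)
  sim <- gen_phospho_raw(p)
  hm <- quantify_peptides(sim$raw, sim$peptides, sim$samples)
  d <- differential(hm)
  expect_gte(mean(d$log2fc >= 1.7 & d$log2fc <= 2.3), 0.95)
})
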