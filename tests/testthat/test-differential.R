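test_that("TMM factors are 1 for pure scaling and identical columns", {
  withr::with_seed(1, {
    base <- rnbinom(500, size = 5, mu = 200)
  })
  m <- cbind(s1 = base + 1, s2 = 2 * (base + 1))
  f <- tmm_factors(m)
  expect_equal(f$norm_factor, c(1, 1), tolerance = 1e-12)
  m2 <- cbind(a = base + 1, b = base + 1, c = base + 1)
  expect_equal(tmm_factors(m2)$norm_factor, c(1, 1, 1), tolerance = 1e-12)
})

test_that("TMM matches the direct-formula oracle and edgeR", {
  withr::with_seed(2, {
    for (i in 1:5) {
      m <- matrix(rnbinom(300 * 4, size = 2, mu = exp(runif(300, 2, 7))),
                  300, 4, dimnames = list(NULL, paste0("s", 1:4)))
      m[1:10, 3] <- m[1:10, 3] * 20  # composition spike
      f <- tmm_factors(m)$norm_factor
      expect_equal(f, tmm_oracle(m), tolerance = 1e-8)
      expect_equal(prod(f), 1, tolerance = 1e-12)
      if (requireNamespace("edgeR", quietly = TRUE)) {
        expect_equal(f, unname(edgeR::calcNormFactors(m, method = "TMM")),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("TMM absorbs a global rescaling of one column", {
  withr::with_seed(3, {
    m <- matrix(rnbinom(400 * 3, size = 5, mu = 150), 400, 3,
                dimnames = list(NULL, paste0("s", 1:3)))
  })
  f1 <- tmm_factors(m, ref = "s1")$norm_factor
  m2 <- m; m2[, 2] <- m2[, 2] * 4
  f2 <- tmm_factors(m2, ref = "s1")$norm_factor
  # M and A (and hence the trimmed set) are scale-invariant; only the
  # precision weights move, so the factors agree to first order
  expect_equal(unname(f2), unname(f1), tolerance = 0.02)
})

test_that("dispersion estimates recover Poisson and NB truths", {
  p <- nb_counts(2000, mu = 100, phi = 0, seed = 4)
  expect_lt(estimate_common_dispersion(p$counts, p$samples), 0.02)
  nb <- nb_counts(2000, mu = 100, phi = 0.1, seed = 5)
  est <- estimate_common_dispersion(nb$counts, nb$samples)
  expect_gt(est, 0.07); expect_lt(est, 0.13)
  est_p <- estimate_common_dispersion(nb$counts, nb$samples,
                                      method = "profile")
  expect_gt(est_p, 0.07); expect_lt(est_p, 0.13)
  flat <- matrix(7, 50, 4, dimnames = list(NULL, c("C1", "C2", "A1", "A2")))
  sheet <- tibble::tibble(sample_id = colnames(flat),
                          group = c("g1", "g1", "g2", "g2"))
  expect_warning(phi0 <- estimate_common_dispersion(flat, sheet), "constant")
  expect_equal(phi0, 0)
})

test_that("the exact test reproduces closed forms in degenerate designs", {
  sheet2 <- tibble::tibble(sample_id = c("x", "y"), group = c("a", "b"))
  # balanced split, phi = 0: p must be exactly 1
  m <- matrix(c(5, 5), 1, 2, dimnames = list("r1", c("x", "y")))
  r <- nb_exact_test(m, sheet2, dispersion = 0)
  expect_equal(r$p_value, 1)
  # extreme split (0, 20) at equal library sizes: matches the enumeration
  # oracle and the exact binomial test (second row balances the libraries)
  m2 <- matrix(c(0, 20, 20, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("r1", "r2"), c("x", "y")))
  r2 <- nb_exact_test(m2, sheet2, dispersion = 0)
  expect_equal(r2$p_value[1], exact_pvalue_oracle(0, 20, 1, 1, 0),
               tolerance = 1e-12)
  expect_equal(r2$p_value[1], binom.test(0, 20, 0.5)$p.value,
               tolerance = 1e-12)
})

test_that("exact test equals full conditional enumeration (dual route)", {
  sheet <- sheet_6v6()
  withr::with_seed(6, {
    for (phi in c(0, 0.2)) {
      m <- matrix(rnbinom(50 * 12, size = 4, mu = 2.5), 50, 12,
                  dimnames = list(sprintf("r%02d", 1:50), sheet$sample_id))
      r <- nb_exact_test(m, sheet, dispersion = phi)
      # the oracle enumerates splits of the library-equalized group sums
      N <- colSums(m); common <- exp(mean(log(N)))
      y <- round(sweep(m, 2, common / N, `*`))
      want <- vapply(seq_len(nrow(y)), function(i) {
        exact_pvalue_oracle(sum(y[i, 1:6]), sum(y[i, 7:12]), 6, 6, phi)
      }, 0)
      expect_equal(r$p_value, want, tolerance = 1e-10)
    }
  })
})

test_that("exact test p-values agree with edgeR on equalized counts", {
  skip_if_not_installed("edgeR")
  sheet <- sheet_6v6()
  withr::with_seed(7, {
    m <- matrix(rnbinom(200 * 12, size = 10, mu = 100), 200, 12,
                dimnames = list(sprintf("r%03d", 1:200), sheet$sample_id))
  })
  r <- nb_exact_test(m, sheet, dispersion = 0.1)
  N <- colSums(m); common <- exp(mean(log(N)))
  y <- round(sweep(m, 2, common / N, `*`))
  p_er <- edgeR::exactTestBySmallP(y[, 1:6], y[, 7:12], dispersion = 0.1)
  expect_equal(r$p_value, as.numeric(p_er), tolerance = 1e-9)
})

test_that("null p-values are roughly uniform in the tail", {
  nb <- nb_counts(2000, mu = 100, phi = 0.1, seed = 8)
  fac <- tmm_factors(nb$counts)
  phi <- estimate_common_dispersion(nb$counts, nb$samples, fac)
  r <- nb_exact_test(nb$counts, nb$samples, fac, phi)
  rate <- mean(r$p_value < 0.05)
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("permutation cutoff is zero for identical columns and ordered by mode", {
  m <- matrix(rep(c(3, 9, 27, 81), 12), 4, 12, byrow = FALSE,
              dimnames = list(paste0("r", 1:4), sheet_6v6()$sample_id))
  cut <- permutation_fc_cutoff(m, sheet_6v6(), n_permutations = 50, seed = 1)
  expect_equal(cut$cutoff, 0)
  nb <- nb_counts(200, mu = 50, phi = 0.1, seed = 9)
  lit <- permutation_fc_cutoff(nb$counts, nb$samples, n_permutations = 100,
                               mode = "literal", seed = 2)
  up <- permutation_fc_cutoff(nb$counts, nb$samples, n_permutations = 100,
                              mode = "upper_tail", seed = 2)
  expect_lte(lit$cutoff, up$cutoff)
  expect_equal(lit$null_pool_size, 100 * 200)
  expect_equal(lit$n_distinct_splits, choose(12, 6) - 1)
})

test_that("permutation cutoff matches a pooled-quantile oracle on 2v2", {
  # 2v2: five non-identity splits, all used when n_permutations = 5,
  # so the pooled null is enumerable independently of the sampling order
  sheet <- tibble::tibble(sample_id = c("c1", "c2", "a1", "a2"),
                          group = c("g", "g", "h", "h"))
  withr::with_seed(10, {
    m <- matrix(rnbinom(200 * 4, size = 5, mu = 80), 200, 4,
                dimnames = list(sprintf("r%03d", 1:200), sheet$sample_id))
  })
  N <- colSums(m); common <- exp(mean(log(N)))
  y <- round(sweep(m, 2, common / N, `*`))
  splits <- list(c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  pool <- unlist(lapply(splits, function(s) {
    abs(log2((rowMeans(y[, -s]) + 0.5) / (rowMeans(y[, s]) + 0.5)))
  }))
  for (mode in c("literal", "upper_tail")) {
    q <- if (mode == "literal") 0.10 else 0.90
    got <- permutation_fc_cutoff(m, sheet, n_permutations = 5,
                                 percentile = 0.10, mode = mode, seed = 3)
    expect_equal(got$cutoff, unname(quantile(pool, q)), tolerance = 1e-12)
  }
  # deterministic under a fixed seed
  c1 <- permutation_fc_cutoff(m, sheet, n_permutations = 5, seed = 4)
  c2 <- permutation_fc_cutoff(m, sheet, n_permutations = 5, seed = 4)
  expect_identical(c1, c2)
  expect_error(permutation_fc_cutoff(m, sheet, n_permutations = 0), ">= 1")
})

test_that("differential calls follow the strict dual criterion", {
  res <- tibble::tibble(
    row_id = paste0("r", 1:5),
    log2fc = c(2, 0.5, -3, 1.2, 0.49),
    p_value = c(0.04, 0.04, 0.06, 0.001, 0.01),
    mean_A = 1, mean_B = 1)
  called <- call_differential(res, alpha = 0.05, cutoff = 0.5)
  # r1: both criteria; r2: |fc| equals the cutoff exactly -> fails;
  # r3: huge fc but p >= alpha -> fails; r4 passes; r5 below cutoff
  expect_equal(called$passes, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(called$direction, c("up", NA, NA, "up", NA))
  boundary <- call_differential(
    tibble::tibble(row_id = "b", log2fc = 1, p_value = 0.05,
                   mean_A = 1, mean_B = 2), alpha = 0.05, cutoff = 0.5)
  expect_false(boundary$passes)  # p == alpha fails the strict rule
})

test_that("the full chain recovers planted effects with high sensitivity", {
  d <- nb_counts(600, mu = 100, phi = 0.1, n_effect = 150, log2fc = 2,
                 seed = 11)
  fit <- diff_test(d$counts, d$samples, n_permutations = 200,
                   mode = "upper_tail", seed = 12)
  tab <- tidy(fit)
  truth_pos <- d$delta != 0
  sens <- mean(tab$passes[truth_pos])
  fdr <- sum(tab$passes & !truth_pos) / max(1, sum(tab$passes))
  expect_gt(sens, 0.85)
  expect_lt(fdr, 0.2)
  g <- glance(fit)
  expect_equal(g$n_pass, sum(tab$passes))
  expect_s3_class(autoplot(fit), "ggplot")
  # directions match the planted signs among true positives
  hit <- tab$passes & truth_pos
  expect_true(all(tab$direction[hit] ==
                    ifelse(d$delta[hit] > 0, "up", "down")))
})
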