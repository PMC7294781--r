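#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization for count
#' libraries. For each sample against the reference, log ratios
#' M = log2((x_k/N_k)/(x_r/N_r)) and average abundances
#' A = (1/2) log2((x_k/N_k)(x_r/N_r)) are computed over rows where both
#' samples have positive counts; the most extreme `trim_m` fraction by M
#' and `trim_a` by A (each side, rank-based) are discarded; the factor is
#' 2 to the precision-weighted mean of the remaining M, with inverse
#' delta-method weights w = (N_k - x_k)/(N_k x_k) + (N_r - x_r)/(N_r x_r).
#' Factors are centered to have product 1. The automatic reference is the
#' sample whose 75th-percentile count fraction is closest to the mean.
#'
#' @param counts Count tibble (id column + one column per sample) or
#'   matrix.
#' @param trim_m,trim_a Two-sided trim fractions on M and A (defaults 0.30
#'   and 0.05).
#' @param ref `"auto"` or a sample id.
#' @param lib_sizes Optional named vector overriding column sums.
#' @return Tibble `sample_id, lib_size, norm_factor` (product of factors
#'   is 1).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, ref = "auto",
                        lib_sizes = NULL) {
  m <- count_matrix(counts)
  N <- lib_sizes %||% colSums(m)
  if (any(N <= 0)) abort("every sample needs a positive library size")
  if (ref == "auto") {
    f75 <- apply(m, 2, quantile, probs = 0.75) / N
    ref <- colnames(m)[which.min(abs(f75 - mean(f75)))]
  }
  if (!ref %in% colnames(m)) abort("unknown reference sample")
  xr <- m[, ref]
  Nr <- N[ref]
  logf <- vapply(colnames(m), function(k) {
    xk <- m[, k]
    keep <- xk > 0 & xr > 0
    if (!any(keep)) {
      abort(sprintf("sample '%s' shares no co-detected rows with reference", k))
    }
    x <- xk[keep]; r <- xr[keep]; Nk <- N[k]
    M <- log2(x / Nk) - log2(r / Nr)
    A <- (log2(x / Nk) + log2(r / Nr)) / 2
    w <- (Nk - x) / (Nk * x) + (Nr - r) / (Nr * r)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(sel)) abort(sprintf("trimming removed all rows for sample '%s'", k))
    sum(M[sel] / w[sel]) / sum(1 / w[sel])
  }, 0)
  f <- 2^logf
  f <- f / geometric_mean(f)
  tibble(sample_id = colnames(m), lib_size = unname(N),
         norm_factor = unname(f))
}

factor_vector <- function(factors, sample_ids) {
  if (is.null(factors)) return(setNames(rep(1, length(sample_ids)), sample_ids))
  if (is.data.frame(factors)) {
    f <- setNames(factors$norm_factor, factors$sample_id)
  } else f <- factors
  if (!all(sample_ids %in% names(f))) abort("missing normalization factor")
  f[sample_ids]
}

# counts rescaled to the geometric-mean effective library (rounding half-even)
equalize_counts <- function(m, factors, lib_sizes = NULL) {
  N <- lib_sizes %||% colSums(m)
  f <- factor_vector(factors, colnames(m))
  L <- f * N
  common <- geometric_mean(L)
  y <- round(sweep(m, 2, common / L, `*`))
  list(y = y, common_lib = common, eff_lib = L)
}

#' Common negative-binomial dispersion
#'
#' Method-of-moments default: counts are scaled to a common effective
#' library; per row the within-group estimate
#' phi = max(0, (s^2 - xbar)/xbar^2) is formed (groups pooled by degrees
#' of freedom) and the trimmed mean over rows is returned. The
#' `"profile"` alternative maximizes the summed NB log-likelihood with
#' per-row group means profiled out.
#'
#' @param counts Count tibble or matrix.
#' @param samples Sample sheet tibble (`sample_id, group`).
#' @param factors Output of [tmm_factors()] (or `NULL` for none).
#' @param method `"moments"` (default) or `"profile"`.
#' @param trim Trim fraction for the moments row average (default 0.1).
#' @return Dispersion estimate phi >= 0.
#' @export
estimate_common_dispersion <- function(counts, samples, factors = NULL,
                                       method = c("moments", "profile"),
                                       trim = 0.1) {
  method <- match.arg(method)
  check_sample_sheet(samples)
  m <- count_matrix(counts)[, samples$sample_id, drop = FALSE]
  y <- equalize_counts(m, factors)$y
  groups <- split(seq_len(ncol(y)), samples$group)
  if (max(vapply(groups, length, 0L)) < 2) {
    abort("dispersion estimation needs >= 2 samples in some group")
  }
  if (all(apply(y, 1, function(r) length(unique(r))) == 1)) {
    warn("all rows constant; dispersion set to 0")
    return(0)
  }
  if (method == "moments") {
    per_row <- apply(y, 1, function(r) {
      ests <- c(); wts <- c()
      for (g in groups) {
        if (length(g) < 2) next
        xb <- mean(r[g])
        if (xb <= 0) next
        s2 <- var(r[g])
        ests <- c(ests, (s2 - xb) / xb^2)
        wts <- c(wts, length(g) - 1)
      }
      if (!length(ests)) return(NA_real_)
      max(0, sum(ests * wts) / sum(wts))
    })
    per_row <- per_row[!is.na(per_row)]
    if (!length(per_row)) {
      warn("no informative rows; dispersion set to 0")
      return(0)
    }
    mean(per_row, trim = trim)
  } else {
    mu <- matrix(0, nrow(y), ncol(y))
    for (g in groups) mu[, g] <- rowMeans(y[, g, drop = FALSE])
    keep <- rowSums(mu) > 0
    yk <- y[keep, , drop = FALSE]; muk <- pmax(mu[keep, , drop = FALSE], 1e-8)
    nll <- function(phi) {
      r <- 1 / phi
      -sum(lgamma(yk + r) - lgamma(r) - lgamma(yk + 1) +
             r * log(r / (r + muk)) + yk * log(muk / (r + muk)))
    }
    opt <- optimize(nll, interval = c(1e-6, 30))
    if (nll(1e-6) <= opt$objective) 0 else opt$minimum
  }
}

# conditional two-group exact test for one row of equalized counts
exact_test_pvalue <- function(s_a, s_b, n_a, n_b, phi) {
  S <- s_a + s_b
  if (S == 0) return(1)
  a <- 0:S
  if (phi > 0) {
    mu <- S / (n_a + n_b)
    lp <- dnbinom(a, size = n_a / phi, mu = n_a * mu, log = TRUE) +
      dnbinom(S - a, size = n_b / phi, mu = n_b * mu, log = TRUE)
    p_a <- exp(lp - max(lp))
    p_a <- p_a / sum(p_a)
  } else {
    p_a <- stats::dbinom(a, S, n_a / (n_a + n_b))
  }
  p_obs <- p_a[s_a + 1]
  min(1, sum(p_a[p_a <= p_obs * (1 + 1e-8)]))
}

#' Negative-binomial conditional exact test
#'
#' Two-group exact test in the classic count-data framework: counts are
#' rescaled to a common effective library size (TMM factor times library
#' size, rounded half-even), group sums are formed per row, and
#' conditional on the row total the probability of every possible split
#' between the groups is computed under NB group-sum distributions with
#' common dispersion `phi` (a binomial split when `phi = 0`). The
#' two-sided p-value sums the probabilities of all splits no more likely
#' than the observed one. Log2 fold-changes (group B vs group A, where A is
#' the first group by factor levels or order of appearance in the sample
#' sheet — list the reference group first) use prior-count-augmented
#' normalized means.
#'
#' @inheritParams estimate_common_dispersion
#' @param dispersion Common NB dispersion phi >= 0.
#' @param prior_count Added to normalized means for the fold-change
#'   (default 0.5).
#' @return Tibble `row_id, log2fc, p_value, mean_A, mean_B`.
#' @export
nb_exact_test <- function(counts, samples, factors = NULL, dispersion = 0,
                          prior_count = 0.5) {
  if (dispersion < 0) abort("dispersion must be >= 0")
  check_sample_sheet(samples)
  m <- count_matrix(counts)[, samples$sample_id, drop = FALSE]
  y <- equalize_counts(m, factors)$y
  lev <- group_levels(samples$group)
  ia <- which(samples$group == lev[1])
  ib <- which(samples$group == lev[2])
  s_a <- rowSums(y[, ia, drop = FALSE])
  s_b <- rowSums(y[, ib, drop = FALSE])
  p <- vapply(seq_along(s_a), function(i) {
    exact_test_pvalue(s_a[i], s_b[i], length(ia), length(ib), dispersion)
  }, 0)
  mean_a <- s_a / length(ia)
  mean_b <- s_b / length(ib)
  tibble(row_id = rownames(y),
         log2fc = unname(log2((mean_b + prior_count) /
                                (mean_a + prior_count))),
         p_value = p, mean_A = unname(mean_a), mean_B = unname(mean_b))
}

#' Permutation-derived fold-change cutoff
#'
#' Randomly relabels samples into two groups of the original sizes
#' (identity labeling excluded; distinct splits are enumerated and sampled
#' without replacement first, then with replacement once exhausted),
#' recomputes every row's |log2FC| for each relabeling exactly as
#' [nb_exact_test()] does, pools all values, and takes a quantile:
#' `mode = "literal"` returns the `percentile` quantile of the pooled null
#' distribution (the permissive literal reading of a "10th percentile"
#' fold-change cutoff); `mode = "upper_tail"` returns the
#' `1 - percentile` quantile (the conventional null-tail threshold).
#'
#' @inheritParams nb_exact_test
#' @param n_permutations Number of relabelings (default 1000).
#' @param percentile Quantile parameter in (0, 1) (default 0.10).
#' @param mode `"literal"` or `"upper_tail"`.
#' @param seed Optional integer seed for reproducible sampling.
#' @return A `permutation_cutoff` list: `cutoff`, `n_permutations`,
#'   `percentile`, `mode`, `n_distinct_splits` (distinct non-identity
#'   relabelings available), `null_pool_size`.
#' @export
permutation_fc_cutoff <- function(counts, samples, factors = NULL,
                                  n_permutations = 1000, percentile = 0.10,
                                  mode = c("literal", "upper_tail"),
                                  prior_count = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  if (n_permutations < 1) abort("n_permutations must be >= 1")
  stopifnot(percentile > 0, percentile < 1)
  check_sample_sheet(samples)
  m <- count_matrix(counts)[, samples$sample_id, drop = FALSE]
  y <- equalize_counts(m, factors)$y
  lev <- group_levels(samples$group)
  ia <- which(samples$group == lev[1])
  n <- ncol(y); n_a <- length(ia)
  draw <- function() {
    splits <- if (choose(n, n_a) <= 1e5) {
      all_s <- combn(n, n_a)
      ident <- apply(all_s, 2, function(s) identical(sort(s), sort(ia)))
      all_s <- all_s[, !ident, drop = FALSE]
      nd <- ncol(all_s)
      if (nd >= n_permutations) {
        all_s[, sample.int(nd, n_permutations), drop = FALSE]
      } else {
        extra <- all_s[, sample.int(nd, n_permutations - nd, replace = TRUE),
                       drop = FALSE]
        cbind(all_s, extra)
      }
    } else {
      replicate(n_permutations, sample.int(n, n_a))
    }
    splits
  }
  splits <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  n_distinct <- min(choose(n, n_a) - 1, .Machine$integer.max)
  mask <- matrix(0, n, ncol(splits))
  mask[cbind(as.vector(splits),
             rep(seq_len(ncol(splits)), each = n_a))] <- 1
  mean_a <- (y %*% mask) / n_a
  mean_b <- (y %*% (1 - mask)) / (n - n_a)
  pool <- abs(log2((mean_b + prior_count) / (mean_a + prior_count)))
  q <- if (mode == "literal") percentile else 1 - percentile
  structure(list(cutoff = unname(quantile(pool, q)),
                 n_permutations = n_permutations, percentile = percentile,
                 mode = mode, n_distinct_splits = n_distinct,
                 null_pool_size = length(pool)),
            class = "permutation_cutoff")
}

#' @export
print.permutation_cutoff <- function(x, ...) {
  cat(sprintf("permutation |log2FC| cutoff: %.4f (%s mode, %d permutations, pool %d)\n",
              x$cutoff, x$mode, x$n_permutations, x$null_pool_size))
  invisible(x)
}

#' Apply significance and fold-change criteria
#'
#' A row passes when `p < alpha` and `|log2FC|` strictly exceeds the
#' cutoff. Direction is the sign of the fold-change for passing rows.
#'
#' @param result Tibble from [nb_exact_test()].
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param cutoff A [permutation_fc_cutoff()] result or a number.
#' @param p_adjust `"none"` (default, as in a raw `p < .05` rule) or a
#'   [stats::p.adjust()] method such as `"BH"`.
#' @return `result` with `passes` (logical) and `direction`
#'   (`"up"`/`"down"`/`NA`) columns.
#' @export
call_differential <- function(result, alpha = 0.05, cutoff = 0,
                              p_adjust = "none") {
  cut <- if (inherits(cutoff, "permutation_cutoff")) cutoff$cutoff else cutoff
  p <- if (p_adjust == "none") result$p_value else
    stats::p.adjust(result$p_value, method = p_adjust)
  result |>
    mutate(passes = p < alpha & abs(.data$log2fc) > cut,
           direction = ifelse(.data$passes,
                              ifelse(.data$log2fc > 0, "up", "down"),
                              NA_character_))
}

#' Full two-group differential test
#'
#' Runs the whole chain on a count matrix: TMM factors, common-dispersion
#' estimation, NB conditional exact test, permutation fold-change cutoff,
#' and the `p < alpha` + `|log2FC| > cutoff` call. This is the per-matrix
#' engine behind both differential marking and differential expression.
#'
#' @inheritParams nb_exact_test
#' @inheritParams permutation_fc_cutoff
#' @inheritParams call_differential
#' @param dispersion Numeric phi to use directly, or `"moments"` /
#'   `"profile"` to estimate.
#' @return A `diff_test` object; see [tidy()], [glance()], [autoplot()].
#' @export
diff_test <- function(counts, samples, alpha = 0.05, dispersion = "moments",
                      n_permutations = 1000, percentile = 0.10,
                      mode = c("literal", "upper_tail"), prior_count = 0.5,
                      trim_m = 0.30, trim_a = 0.05, p_adjust = "none",
                      seed = NULL) {
  mode <- match.arg(mode)
  check_sample_sheet(samples)
  factors <- tmm_factors(counts, trim_m = trim_m, trim_a = trim_a)
  phi <- if (is.numeric(dispersion)) dispersion else
    estimate_common_dispersion(counts, samples, factors, method = dispersion)
  res <- nb_exact_test(counts, samples, factors, phi, prior_count)
  cut <- permutation_fc_cutoff(counts, samples, factors, n_permutations,
                               percentile, mode, prior_count, seed)
  table <- call_differential(res, alpha, cut, p_adjust)
  lev <- group_levels(samples$group)
  structure(list(table = table, factors = factors, dispersion = phi,
                 cutoff = cut, alpha = alpha, p_adjust = p_adjust,
                 group_levels = lev, prior_count = prior_count),
            class = "diff_test")
}

#' @export
print.diff_test <- function(x, ...) {
  cat(sprintf(
    "diff_test: %d rows, %s vs %s; phi=%.4g, |log2FC| cutoff=%.4g (%s), %d passing\n",
    nrow(x$table), x$group_levels[2], x$group_levels[1], x$dispersion,
    x$cutoff$cutoff, x$cutoff$mode, sum(x$table$passes)))
  invisible(x)
}

#' @rdname diff_test
#' @param x A `diff_test`.
#' @param ... Unused.
#' @export
tidy.diff_test <- function(x, ...) x$table

#' @rdname diff_test
#' @export
glance.diff_test <- function(x, ...) {
  tibble(n_rows = nrow(x$table), dispersion = x$dispersion,
         fc_cutoff = x$cutoff$cutoff, cutoff_mode = x$cutoff$mode,
         alpha = x$alpha, n_pass = sum(x$table$passes),
         n_up = sum(x$table$direction == "up", na.rm = TRUE),
         n_down = sum(x$table$direction == "down", na.rm = TRUE),
         n_permutations = x$cutoff$n_permutations,
         n_distinct_splits = x$cutoff$n_distinct_splits)
}

#' @rdname diff_test
#' @param object A `diff_test`.
#' @export
autoplot.diff_test <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$log2fc, y = -log10(.data$p_value),
                               colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$cutoff$cutoff,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
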