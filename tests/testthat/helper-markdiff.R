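# Shared fixtures and independent oracles, all built in code.

# two-gene toy annotation on one 50 kb chromosome:
#   gA: '+' [10000, 20000), exons [10000,12000)+[18000,20000),
#       CDS [11000,12000)+[18000,19000)
#   gB: '-' [26000, 40000), single exon = whole body, CDS [30000,36000)
toy_index <- function() {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(10000, 26000), end = c(20000, 40000),
    strand = c("+", "-"))
  exons <- tibble::tibble(
    gene_id = c("gA", "gA", "gB"), chrom = "chr1",
    start = c(10000, 18000, 26000), end = c(12000, 20000, 40000))
  cds <- tibble::tibble(
    gene_id = c("gA", "gA", "gB"), chrom = "chr1",
    start = c(11000, 18000, 30000), end = c(12000, 19000, 36000))
  annotation_index(genes, exons, cds, chrom_sizes = c(chr1 = 50000))
}

# per-base classification oracle: literal loop over category definitions
classify_oracle <- function(index, chrom, pos, promoter_bp = 3000) {
  inside <- function(tbl, p) {
    any(tbl$chrom == chrom & tbl$start <= p & p < tbl$end)
  }
  prom <- promoter_regions(index, promoter_bp)
  vapply(pos, function(p) {
    if (inside(index$cds, p)) return("CDS")
    if (inside(index$utr, p)) return("UTR")
    if (inside(index$genes, p)) return("intron")
    if (inside(prom, p)) return("promoter")
    "intergenic"
  }, "")
}

# brute-force tag-in-region counter (double loop)
count_oracle <- function(tags, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(tags$chrom == regions$chrom[i] &
          tags$pos >= regions$start[i] & tags$pos < regions$end[i])
  }, 0)
}

# direct-formula TMM oracle, written against the method definition,
# independent of the package implementation
tmm_oracle <- function(m, trim_m = 0.30, trim_a = 0.05) {
  N <- colSums(m)
  f75 <- vapply(seq_len(ncol(m)),
                function(k) unname(quantile(m[, k], 0.75)) / N[k], 0)
  r <- which.min(abs(f75 - mean(f75)))
  logf <- vapply(seq_len(ncol(m)), function(k) {
    ok <- m[, k] > 0 & m[, r] > 0
    x <- m[ok, k]; y <- m[ok, r]
    M <- log2(x / N[k]) - log2(y / N[r])
    A <- (log2(x / N[k]) + log2(y / N[r])) / 2
    w <- (N[k] - x) / (N[k] * x) + (N[r] - y) / (N[r] * y)
    n <- length(M)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(M) >= lo_m & rank(M) <= hi_m &
      rank(A) >= lo_a & rank(A) <= hi_a
    stats::weighted.mean(M[keep], 1 / w[keep])
  }, 0)
  f <- 2^logf
  unname(f / exp(mean(log(f))))
}

# conditional exact-test oracle by explicit enumeration of all splits
exact_pvalue_oracle <- function(s_a, s_b, n_a, n_b, phi) {
  S <- s_a + s_b
  if (S == 0) return(1)
  nb_logpmf <- function(y, mu, r) {
    lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
      r * log(r / (r + mu)) + y * log(mu / (r + mu))
  }
  a <- 0:S
  lp <- if (phi > 0) {
    mu <- S / (n_a + n_b)
    nb_logpmf(a, n_a * mu, n_a / phi) + nb_logpmf(S - a, n_b * mu, n_b / phi)
  } else {
    stats::dbinom(a, S, n_a / (n_a + n_b), log = TRUE)
  }
  p_a <- exp(lp - max(lp)); p_a <- p_a / sum(p_a)
  min(1, sum(p_a[p_a <= p_a[s_a + 1] * (1 + 1e-8)]))
}

# Ward (ward.D2 criterion) agglomeration oracle via the Lance-Williams
# update on squared Euclidean distances
ward_heights_oracle <- function(x) {
  d2 <- as.matrix(dist(x))^2
  n <- nrow(d2)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (i < j && d2[active[i], active[j]] < bd) {
        bd <- d2[active[i], active[j]]; best <- c(active[i], active[j])
      }
    }
    heights <- c(heights, sqrt(bd))
    i <- best[1]; j <- best[2]
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, best)) {
      nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * bd) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# sample sheet for a 6-vs-6 design
sheet_6v6 <- function() {
  tibble::tibble(sample_id = c(paste0("C", 1:6), paste0("A", 1:6)),
                 group = rep(c("control", "case"), each = 6))
}

# NB count tibble with planted effects on the first n_effect rows
nb_counts <- function(n_rows, n_per_group = 6, mu = 100, phi = 0.1,
                      n_effect = 0, log2fc = 2, seed = 1) {
  withr::with_seed(seed, {
    delta <- c(rep(log2fc * sample(c(-1, 1), n_effect, TRUE), 1),
               rep(0, n_rows - n_effect))
    grp <- rep(c(-1, 1), each = n_per_group)
    m <- sapply(grp, function(g) {
      mus <- mu * 2^(g * delta / 2)
      if (phi > 0) rnbinom(n_rows, size = 1 / phi, mu = mus)
      else rpois(n_rows, mus)
    })
    colnames(m) <- c(paste0("C", seq_len(n_per_group)),
                     paste0("A", seq_len(n_per_group)))
    rownames(m) <- sprintf("r%04d", seq_len(n_rows))
    list(counts = m, delta = delta,
         samples = tibble::tibble(
           sample_id = colnames(m),
           group = rep(c("control", "case"), each = n_per_group)))
  })
}

# random gene-call table for integration-logic fuzzing
random_calls <- function(n = 1000, seed = 1) {
  withr::with_seed(seed, {
    dmg <- runif(n) < 0.3
    deg <- runif(n) < 0.3
    tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(n)),
      dmg = dmg, deg = deg,
      dmg_direction = ifelse(dmg, sample(c("up", "down"), n, TRUE), NA),
      deg_direction = ifelse(deg, sample(c("up", "down"), n, TRUE), NA),
      dmg_p = ifelse(dmg, runif(n), NA), deg_p = ifelse(deg, runif(n), NA))
  })
}
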