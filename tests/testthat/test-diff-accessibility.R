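test_that("fragment counting matches a brute-force overlap tally", {
  peaks <- data.frame(chrom = "c", start = c(100L, 180L), end = c(200L, 300L))
  frag <- data.frame(chrom = "c", start = 190L, end = 195L)
  cnt <- count_fragments_in_peaks(frag, peaks)
  expect_equal(cnt$counts, c(1L, 1L))   # one fragment, two peaks
  expect_equal(cnt$library_size, 1L)
  expect_equal(count_fragments_in_peaks(frag[0, ], peaks)$counts, c(0L, 0L))

  set.seed(51)
  frags <- random_regions(400, max_width = 60)
  pks <- random_regions(50, max_width = 300)
  cnt <- count_fragments_in_peaks(frags, pks)
  oracle <- vapply(seq_len(nrow(pks)), function(i)
    sum(frags$chrom == pks$chrom[i] & frags$start < pks$end[i] &
          frags$end > pks$start[i]), integer(1))
  expect_equal(cnt$counts, oracle)
})

test_that("MA fit recovers pure scaling and identity", {
  x1 <- c(100, 200, 400, 800, 1600, 3200)
  fit <- fit_ma_normalization(x1, 4 * x1)
  expect_equal(fit$intercept + fit$slope * mean(log2(4) / 2 + log2(x1)),
               -2, tolerance = 0.02)
  fit0 <- fit_ma_normalization(x1, x1)
  expect_equal(fit0$intercept, 0, tolerance = 1e-6)
  expect_equal(fit0$slope, 0, tolerance = 1e-6)
  expect_error(fit_ma_normalization(c(1, 0), c(0, 2)), "common peaks")
})

test_that("MA fit recovers a known scale factor from noisy counts", {
  set.seed(52)
  s <- 2.5
  lam <- rlnorm(2000, meanlog = 5, sdlog = 1)
  x1 <- rpois(2000, lam)
  x2 <- rpois(2000, s * lam)
  fit <- fit_ma_normalization(x1, x2)
  A <- 0.5 * log2((x1 + 0.5) * (x2 + 0.5))
  est <- fit$intercept + fit$slope * mean(A[x1 > 0 & x2 > 0])
  expect_equal(est, -log2(s), tolerance = 0.1)
})

test_that("applying the normalization removes the M trend", {
  x1 <- c(100, 200, 400, 800, 1600, 3200)
  x2 <- 4 * x1
  fit <- fit_ma_normalization(x1, x2)
  x2n <- apply_normalization(x1, x2, fit)
  expect_equal(median(log2((x1 + 0.5) / (x2n + 0.5))), 0,
               tolerance = 0.01)
  ## identity fit leaves counts unchanged
  id <- list(intercept = 0, slope = 0)
  expect_equal(apply_normalization(x1, x2, id), x2)

  ## intensity-dependent trend: post-normalization M uncorrelated with A
  set.seed(53)
  lam <- rlnorm(2000, meanlog = 5, sdlog = 1.2)
  y1 <- rpois(2000, lam)
  y2 <- rpois(2000, lam * 2^(0.5 + 0.1 * log2(lam)))
  fit2 <- fit_ma_normalization(y1, y2)
  y2n <- apply_normalization(y1, y2, fit2)
  keep <- y1 > 0 & y2 > 0
  M2 <- log2((y1 + 0.5) / (y2n + 0.5))[keep]
  A2 <- (0.5 * log2((y1 + 0.5) * (y2n + 0.5)))[keep]
  expect_lt(abs(cor(M2, A2)), 0.05)
  ## self-consistency: refitting after normalization is near-null
  refit <- fit_ma_normalization(y1, y2n)
  expect_lt(abs(refit$intercept +
                  refit$slope * mean(A2)), 0.05)
  expect_lt(abs(refit$slope), 0.02)
})

test_that("exact binomial p-values match closed forms and binom.test", {
  expect_equal(diff_pvalue(10, 10), 1)
  expect_equal(diff_pvalue(10, 0), 2 * 0.5^10)
  expect_equal(diff_pvalue(0, 0), 1)
  set.seed(54)
  x1 <- rpois(50, 40); x2 <- rpois(50, 60)
  p <- diff_pvalue(x1, x2)
  oracle <- vapply(seq_along(x1), function(i)
    stats::binom.test(x1[i], x1[i] + x2[i], 0.5)$p.value, numeric(1))
  expect_equal(p, oracle, tolerance = 1e-12)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("compound selection applies both branches and exclusions", {
  peaks <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2a"),
    logCPM = c(2, 0.5, 2, 2),
    logFC = c(1, 5, 3.5, 3.5),
    p = c(0.5, 1e-10, 0.004, 0.004),
    q = c(0.005, 1e-9, 0.05, 0.05))
  out <- select_differential(peaks)
  expect_equal(out$selected, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$direction[1:3], c("HD_up", "not_differential", "HD_up"))
  ## monotone in q_cut: lowering it never adds peaks
  set.seed(55)
  rnd <- data.frame(chrom = "chr1", logCPM = runif(200, 0, 4),
                    logFC = rnorm(200, 0, 2), p = runif(200),
                    q = runif(200))
  loose <- select_differential(rnd, selection_criteria(q_cut = 0.05))
  strict <- select_differential(rnd, selection_criteria(q_cut = 0.005))
  expect_true(all(which(strict$selected) %in% which(loose$selected)))
  ## direction counts partition the selection
  expect_equal(sum(loose$direction %in% c("HD_up", "HD_down")),
               sum(loose$selected))
})

test_that("null counts from a shared intensity are calibrated", {
  set.seed(56)
  ## deep counts keep the exact test's discreteness negligible so the
  ## realized size can be compared against the nominal level
  n <- 3000
  lam <- 1000 * rgamma(n, shape = 20, rate = 20)
  x1 <- rpois(n, lam); x2 <- rpois(n, lam)
  peaks <- data.frame(chrom = "chr1", start = seq_len(n) * 10L,
                      end = seq_len(n) * 10L + 5L)
  d <- differential_from_counts(x1, x2, sum(x1), sum(x2), peaks)
  for (alpha in c(0.01, 0.05)) {
    se <- sqrt(alpha * (1 - alpha) / n)
    expect_lt(abs(mean(d$p < alpha) - alpha), 3 * se)
  }
})

test_that("planted promoter occupancy differences are recovered", {
  set.seed(57)
  n_gene <- 500L
  genes <- data.frame(gene_id = sprintf("g%03d", 1:n_gene), chrom = "c",
                      strand = "+", start = (1:n_gene) * 4000L,
                      end = (1:n_gene) * 4000L + 2000L,
                      tss = (1:n_gene) * 4000L,
                      tes = (1:n_gene) * 4000L + 1999L)
  lam <- 60 * rgamma(n_gene, 15, 15)
  planted <- 1:10
  mk <- function(mu) {
    counts <- rpois(n_gene, mu)
    do.call(rbind, lapply(which(counts > 0), function(g) {
      len <- sample(180:250, counts[g], replace = TRUE)
      st <- pmax(0L, as.integer(round(
        rnorm(counts[g], genes$tss[g] - len / 2, 200))))
      data.frame(chrom = "c", start = st, end = st + len)
    }))
  }
  mu_hd <- lam; mu_hd[planted] <- mu_hd[planted] * 3
  occ <- diff_promoter_occupancy(mk(mu_hd), mk(lam), genes)
  hits <- occ$gene_id[occ$selected]
  expect_gte(sum(genes$gene_id[planted] %in% hits), 8)
  expect_lte(sum(!(hits %in% genes$gene_id[planted])), 2)
  ## identical samples: false selections stay below 1% of promoters
  occ0 <- diff_promoter_occupancy(mk(lam), mk(lam), genes)
  expect_lte(sum(occ0$selected), 0.01 * n_gene)
  ## zero fragments: empty result
  none <- data.frame(chrom = character(), start = integer(),
                     end = integer())
  expect_equal(nrow(diff_promoter_occupancy(none, none, genes)), 0L)
})

test_that("replicate correlation behaves on identical, noisy and constant input", {
  set.seed(58)
  x <- rpois(1000, 50)
  expect_equal(replicate_correlation(x, x), 1)
  ## independent Poisson counting noise around shared per-peak means
  lam <- rlnorm(1000, meanlog = log(50), sdlog = 0.6)
  y1 <- rpois(1000, lam); y2 <- rpois(1000, lam)
  expect_gt(replicate_correlation(y1, y2), 0.9)
  expect_true(is.na(replicate_correlation(rep(5, 10), rpois(10, 5))))
})

test_that("summary arithmetic reproduces component counts and shares", {
  s <- summarize_differential(data.frame(stage = "PSC", n_up = 1923L,
                                         n_down = 753L))
  expect_equal(s$per_stage$n_diff, 2676L)
  expect_equal(s$per_stage$pct_up, 71.9)
  z <- summarize_differential(data.frame(stage = "x", n_up = 0L,
                                         n_down = 0L))
  expect_true(is.na(z$per_stage$pct_up))
  pr <- summarize_differential(data.frame(
    stage = c("a", "b"), n_up = c(200L, 115L), n_down = c(1000L, 1152L),
    n_up_proximal = c(200L, 115L), n_down_proximal = c(1000L, 1152L)))
  expect_equal(pr$totals$proximal_differential, 2467L)
})
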