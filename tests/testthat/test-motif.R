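make_test_pwm <- function(word, id = "m1", major = 0.85) {
  L <- nchar(word)
  cons <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  probs <- matrix((1 - major) / 3, L, 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  probs[cbind(seq_len(L), cons)] <- major
  list(motif_id = id, probs = probs,
       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

test_that("exact score distribution matches enumeration over all words", {
  ## L = 1: four-point distribution equals base probabilities
  pwm1 <- make_test_pwm("A")
  tab1 <- score_pvalue_table(pwm1)
  expect_equal(sum(tab1$density), 1, tolerance = 1e-12)
  expect_equal(sort(tab1$density[tab1$density > 0], decreasing = TRUE),
               c(0.75, 0.25), tolerance = 1e-12)
  ## best score tail equals the consensus word probability
  pwm5 <- make_test_pwm("ACGTA")
  tab5 <- score_pvalue_table(pwm5)
  expect_equal(tab5$pvals[length(tab5$pvals)], 0.25^5, tolerance = 1e-12)
  ## full enumeration oracle at L = 5
  S <- thssdiff:::pwm_int_scores(pwm5)
  words <- as.matrix(expand.grid(rep(list(1:4), 5)))
  scores <- rowSums(matrix(S[cbind(rep(1:5, each = nrow(words)),
                                   as.vector(words))], nrow(words), 5))
  for (s in unique(scores)) {
    expect_equal(thssdiff:::score_to_pvalue(s, tab5),
                 sum(0.25^5 * (scores >= s)), tolerance = 1e-12)
  }
  ## tail mass at the minimum score is exactly 1
  expect_equal(tab5$pvals[1], 1, tolerance = 1e-12)
})

test_that("scanning finds planted consensus sites on both strands", {
  set.seed(61)
  pwm <- make_test_pwm("ACGTACGTAC")
  bg <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  planted <- bg
  substr(planted, 51, 60) <- "ACGTACGTAC"
  hits <- scan_peak_windows(c(w1 = planted), list(pwm))
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$offset, 50L)
  expect_lte(fwd$p, 1e-4)
  ## reverse complement -> minus-strand hit at the same offset
  rc <- bg
  substr(rc, 51, 60) <- "GTACGTACGT"
  hits_rc <- scan_peak_windows(c(w1 = rc), list(pwm))
  expect_true(any(hits_rc$strand == "-" & hits_rc$offset == 50L))
  ## windows shorter than the motif yield nothing
  expect_equal(nrow(scan_peak_windows(c(w = "ACGT"), list(pwm))), 0L)
  ## N positions are skipped
  withN <- planted
  substr(withN, 55, 55) <- "N"
  expect_false(any(scan_peak_windows(c(w1 = withN), list(pwm))$offset == 50))
})

test_that("hit counts on random sequence match the exact null rate", {
  set.seed(62)
  pwm <- make_test_pwm("ACGTACG", major = 0.9)
  n_win <- 25L
  seqs <- setNames(vapply(seq_len(n_win), function(i)
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
          collapse = ""), character(1)),
    paste0("w", seq_len(n_win)))
  hits <- scan_peak_windows(seqs, list(pwm), p_threshold = 1e-3)
  tab <- score_pvalue_table(pwm)
  rate <- tab$pvals[which(tab$pvals <= 1e-3)[1]]
  expected <- 2 * n_win * (400 - 7 + 1) * rate
  expect_lt(abs(nrow(hits) - expected), 3 * sqrt(expected) + 1)
})

test_that("best-hit deduplication keeps the most significant motif", {
  hits <- data.frame(
    peak_id = c("p1", "p1", "p2", "p2"),
    motif_id = c("b", "a", "b", "a"),
    offset = c(5L, 9L, 7L, 3L), strand = c("+", "+", "+", "+"),
    score = c(10, 8, 6, 6), p = c(1e-6, 1e-3, 1e-4, 1e-4))
  best <- best_hit_per_peak(hits)
  expect_equal(best$motif_id[best$peak_id == "p1"], "b")   # lower p
  expect_equal(best$offset[best$peak_id == "p2"], 3L)      # tie: leftmost
  expect_equal(nrow(best_hit_per_peak(hits[0, ])), 0L)
})

test_that("contingency tables count the literal nested cells", {
  dedup <- data.frame(
    peak_id = paste0("p", 1:10),
    motif_id = c(rep("X", 5), rep("Y", 5)))
  ct <- build_contingency("X", dedup, direction_peaks = paste0("p", 1:3),
                          all_peaks = paste0("p", 1:10))
  expect_equal(unlist(ct[c("N11", "N12", "N21", "N22")]),
               c(N11 = 3, N12 = 0, N21 = 5, N22 = 5))
  ## absent motif still yields a table
  ct0 <- build_contingency("Z", dedup, paste0("p", 1:3), paste0("p", 1:10))
  expect_equal(ct0$N11, 0)
  expect_equal(ct0$N21, 0)
  ## randomized assignment vs recount oracle
  set.seed(63)
  dedup2 <- data.frame(peak_id = paste0("p", 1:200),
                       motif_id = sample(LETTERS[1:6], 200, TRUE))
  dirset <- sample(dedup2$peak_id, 40)
  for (m in LETTERS[1:6]) {
    ct <- build_contingency(m, dedup2, dirset, dedup2$peak_id)
    expect_equal(ct$N11, sum(dedup2$motif_id == m &
                               dedup2$peak_id %in% dirset))
    expect_equal(ct$N22, sum(dedup2$motif_id != m))
  }
  ## sum of N11 over motifs equals direction peaks carrying any hit
  n11s <- vapply(LETTERS[1:6], function(m)
    build_contingency(m, dedup2, dirset, dedup2$peak_id)$N11, numeric(1))
  expect_equal(sum(n11s), sum(dedup2$peak_id %in% dirset))
})

test_that("Fisher exact p matches closed forms and independent oracles", {
  expect_equal(fisher_exact(5, 5, 5, 5), 1)
  expect_equal(fisher_exact(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_warning(p0 <- fisher_exact(0, 0, 3, 4), "zero row")
  expect_equal(p0, 1)
  set.seed(64)
  for (i in 1:60) {
    t <- as.list(sample(0:15, 4, replace = TRUE))
    if (t[[1]] + t[[2]] == 0 || t[[3]] + t[[4]] == 0) next
    p <- fisher_exact(t[[1]], t[[2]], t[[3]], t[[4]])
    expect_equal(p, enumerate_fisher(t[[1]], t[[2]], t[[3]], t[[4]]),
                 tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(matrix(unlist(t), 2,
                                              byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
  ## symmetric under swapping rows together with direction
  expect_equal(fisher_exact(3, 7, 12, 8), fisher_exact(12, 8, 3, 7))
})

test_that("label-shuffled enrichment stays near the nominal rate", {
  set.seed(65)
  dedup <- data.frame(peak_id = paste0("p", 1:1000),
                      motif_id = sample(sprintf("m%02d", 1:20), 1000, TRUE))
  info <- data.frame(peak_id = paste0("p", 1:1000),
                     direction = sample(c("HD_up", "HD_down",
                                          "not_differential"),
                                        1000, TRUE, prob = c(.1, .1, .8)),
                     proximity = sample(c("proximal", "distal"), 1000,
                                        TRUE))
  res <- enrichment_scan(dedup, info)
  expect_lte(mean(res$significant), 0.15)
  expect_true(all(res$p > 0 & res$p <= 1))
  ## no differential peaks in a direction -> all p = 1
  info2 <- info
  info2$direction[info2$direction == "HD_up"] <- "not_differential"
  res2 <- enrichment_scan(dedup, info2)
  expect_true(all(res2$p[res2$direction == "HD_up"] == 1))
})
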