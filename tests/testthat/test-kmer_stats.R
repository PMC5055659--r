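# Hand-built single-event profile: one 86-base region with one instance of
# a chosen 6-mer on a controllable conservation background.
one_event_profile <- function(kmer = "ACGTCA", cons_instance = 1.0,
                              cons_bg = 0.5, L = 86L, at = 21L) {
  base <- paste(rep("T", L), collapse = "")
  substr(base, at, at + 5L) <- kmer
  cons <- matrix(cons_bg, 1L, L)
  cons[1L, at:(at + 5L)] <- cons_instance
  kmer_profile_from_regions(c(ev1 = base), cons)
}

test_that("conservation enrichment matches the arithmetic definition", {
  # uniform track: every present k-mer has enrichment exactly 1
  set.seed(70)
  regs <- vapply(1:15, function(i)
    paste(sample(c("A", "C", "G", "T"), 86, TRUE), collapse = ""), "")
  names(regs) <- sprintf("e%d", 1:15)
  prof_u <- kmer_profile_from_regions(regs, matrix(0.7, 15, 86))
  ge <- global_enrichment(prof_u)
  expect_equal(unname(ge[!is.na(ge)]), rep(1, sum(!is.na(ge))))

  # 6 instance bases at 1.0, 80 bases at 0.5 in a single event
  prof <- one_event_profile("ACGTCA", 1.0, 0.5)
  ge2 <- global_enrichment(prof)
  expected <- 1.0 / ((6 * 1.0 + 80 * 0.5) / 86)
  expect_equal(unname(ge2[["ACGTCA"]]), expected, tolerance = 1e-12)
  expect_equal(round(expected, 3), 1.870)
  # absent k-mer: undefined
  expect_true(is.na(ge2[["GGGGGG"]]))
})

test_that("instance coverage counts overlapping occurrences and unions bases", {
  # "AAAAAAA" contains two overlapping "AAAAAA" instances over 7 bases
  L <- 40L
  base <- paste(c(rep("C", 10), rep("A", 7), rep("C", L - 17)), collapse = "")
  cons <- matrix(0.2, 1, L); cons[1, 11:17] <- 0.9
  prof <- kmer_profile_from_regions(c(e = base), cons)
  tr <- prof$trip[prof$trip$kmer == match("AAAAAA", prof$kmers), ]
  expect_equal(tr$count, 2L)
  expect_equal(tr$cov_n, 7L)               # union of covered bases
  expect_equal(tr$cov_sum, 7 * 0.9)
  expect_equal(tr$wcount, 2 * 0.9)         # each instance contributes its min
})

test_that("conservation-weighted counts apply the minimum rule", {
  # uniform conservation c: weighted count = c x raw count
  set.seed(71)
  regs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), "")
  names(regs) <- sprintf("e%d", 1:10)
  cval <- 0.6
  prof <- kmer_profile_from_regions(regs, matrix(cval, 10, 60))
  present <- unique(prof$kmers[prof$trip$kmer])
  w <- conservation_weighted_counts(prof, present)
  raw <- as.matrix(prof$counts[, present, drop = FALSE])
  expect_equal(w, cval * raw, ignore_attr = TRUE, tolerance = 1e-12)

  # an instance spanning (0.9 x5, 0.1) weighs 0.1
  prof2 <- one_event_profile("ACGTCA", cons_instance = 0.9, cons_bg = 0.3)
  prof2$cons[1, 26] <- 0.1   # last base of the instance
  prof2 <- kmer_profile_from_regions(prof2$regions, prof2$cons)
  expect_equal(unname(conservation_weighted_counts(prof2, "ACGTCA")[1, 1]), 0.1)

  # random fixture against a brute-force per-instance minimum scan
  set.seed(72)
  regs3 <- vapply(1:8, function(i)
    paste(sample(c("A", "C"), 30, TRUE), collapse = ""), "")
  names(regs3) <- sprintf("e%d", 1:8)
  cons3 <- matrix(runif(8 * 30), 8, 30)
  prof3 <- kmer_profile_from_regions(regs3, cons3)
  for (kk in c("AAAAAA", "ACACAC", "CCCCCC")) {
    w3 <- conservation_weighted_counts(prof3, kk)
    manual <- vapply(1:8, function(e) {
      tot <- 0
      for (i in 1:25) if (substr(regs3[e], i, i + 5) == kk)
        tot <- tot + min(cons3[e, i:(i + 5)])
      tot
    }, 0)
    expect_equal(unname(w3[, 1]), manual, tolerance = 1e-12)
  }
})

test_that("brute-force recounting matches the count matrix column sums", {
  sim <- small_sim()
  ev <- sim$events[1:20, ]
  prof <- kmer_profile(ev, sim$genome, sim$track_mammal, "upstream")
  regs <- prof$regions
  for (kk in c("GTAACG", "TTCATC", "AAAAAA", "CGCGCG")) {
    manual <- sum(vapply(regs, function(s) {
      n <- 0L
      for (i in 1:(nchar(s) - 5L)) if (substr(s, i, i + 5L) == kk) n <- n + 1L
      n
    }, 0L))
    expect_equal(unname(Matrix::colSums(prof$counts)[kk]), manual)
  }
})

test_that("the eligibility filter reproduces its definition exactly", {
  # 99 events, twice in one -> excluded; 100 singleton events -> excluded;
  # 100 events with one doubleton -> eligible
  make_counts_profile <- function(n_events, counts_per_event) {
    L <- 12L
    regs <- character(n_events)
    cons <- matrix(0.5, n_events, L)
    for (i in seq_len(n_events)) {
      s <- rep("C", L)
      if (counts_per_event[i] >= 1L) s[1:6] <- strsplit("AGAGAG", "")[[1]]
      if (counts_per_event[i] >= 2L) s[7:12] <- strsplit("AGAGAG", "")[[1]]
      regs[i] <- paste(s, collapse = "")
    }
    names(regs) <- sprintf("e%d", seq_len(n_events))
    kmer_profile_from_regions(regs, cons)
  }
  r1 <- kmer_records(make_counts_profile(120L, c(rep(1L, 98L), 2L, rep(0L, 21L))),
                     residuals = rnorm(120), min_events = 100L)
  expect_false(r1$eligible[r1$kmer == "AGAGAG"])
  r2 <- kmer_records(make_counts_profile(120L, c(rep(1L, 100L), rep(0L, 20L))),
                     residuals = rnorm(120), min_events = 100L)
  expect_false(r2$eligible[r2$kmer == "AGAGAG"])
  r3 <- kmer_records(make_counts_profile(120L, c(rep(1L, 99L), 2L, rep(0L, 20L))),
                     residuals = rnorm(120), min_events = 100L)
  expect_true(r3$eligible[r3$kmer == "AGAGAG"])
})

test_that("bias and character behave on constructed subsets", {
  # enrichment identical across events -> undefined; ranks aligned -> 1
  set.seed(73)
  n <- 40L
  regs <- character(n)
  cons <- matrix(0.2, n, 30L)
  kmer <- "ACGTCA"
  counts_true <- sample(1:3, n, TRUE)
  for (i in seq_len(n)) {
    s <- rep("T", 30L)
    for (j in seq_len(counts_true[i])) s[(j - 1) * 8 + 1:6] <- strsplit(kmer, "")[[1]]
    regs[i] <- paste(s, collapse = "")
  }
  names(regs) <- sprintf("e%d", 1:n)
  prof <- kmer_profile_from_regions(regs, cons)
  r_aligned <- counts_true + runif(n, -0.1, 0.1)
  rec <- kmer_records(prof, r_aligned, min_events = 10L)
  expect_equal(rec$character[rec$kmer == kmer], spearman_rho(counts_true, r_aligned))
  expect_true(is.na(rec$bias[rec$kmer == kmer]))   # uniform enrichment

  # permuted residuals: characters fall in the null band for most k-mers
  sim <- recovery_sim()
  prof2 <- kmer_profile(sim$events[1:1000, ], sim$genome, sim$track_mammal,
                        "upstream")
  set.seed(74)
  r_perm <- rnorm(length(prof2$event_ids))
  rec2 <- kmer_records(prof2, r_perm, min_events = 20L)
  el <- rec2[rec2$eligible & is.finite(rec2$character), ]
  band <- 1.5 * 2 / sqrt(el$n_events)
  expect_gte(mean(abs(el$character) < band), 0.9)
})

test_that("the meta-correlation flags tiny inputs and detects aligned structure", {
  rec <- data.frame(eligible = rep(TRUE, 30),
                    bias = seq(-1, 1, length.out = 30),
                    character = seq(-1, 1, length.out = 30))
  expect_equal(meta_correlation(rec)$rho, 1)
  set.seed(75)
  rec2 <- data.frame(eligible = TRUE, bias = rnorm(200), character = rnorm(200))
  mc2 <- meta_correlation(rec2)
  expect_lt(abs(mc2$rho), 2.5 / sqrt(200))
  rec3 <- data.frame(eligible = c(rep(TRUE, 5), rep(FALSE, 40)),
                     bias = rnorm(45), character = rnorm(45))
  expect_false(meta_correlation(rec3)$defined)
})

test_that("the permutation test is deterministic, calibrated at the degenerate extreme", {
  # degenerate: per-event conservation of each k-mer's instances tracks its
  # count exactly, so character and bias coincide and the meta-correlation
  # is 1 for the observed and for every permuted residual
  set.seed(76)
  n <- 60L
  L <- 80L
  kmers <- c("ACGTCA", "GGATCC", "TTGACA")
  regs <- character(n)
  cons <- matrix(0.05, n, L)
  for (i in seq_len(n)) {
    s <- rep("N", L)   # N fillers: no k-mer windows outside the instances
    for (j in seq_along(kmers)) {
      cnt <- 1L + (i + j) %% 3L
      for (m in seq_len(cnt)) {
        at <- (j - 1L) * 26L + (m - 1L) * 8L + 1L
        s[at:(at + 5L)] <- strsplit(kmers[j], "")[[1]]
        cons[i, at:(at + 5L)] <- 0.1 + 0.2 * cnt
      }
    }
    regs[i] <- paste(s, collapse = "")
  }
  names(regs) <- sprintf("e%d", 1:n)
  prof <- kmer_profile_from_regions(regs, cons)
  comp <- composition_features(regs, non_acgt = "skip")
  y <- setNames(runif(n), names(regs))
  model <- residual_psi(y, comp, sides = "upstream")$model
  p1 <- permutation_test(prof, y, model, n_perm = 120L, seed = 9L,
                         min_events = 10L)
  p2 <- permutation_test(prof, y, model, n_perm = 120L, seed = 9L,
                         min_events = 10L)
  expect_identical(p1$p, p2$p)
  expect_equal(p1$rho_obs, 1, tolerance = 1e-12)
  expect_equal(p1$p, 0)                 # no permutation exceeds |rho| = 1
  expect_warning(permutation_test(prof, y, model, n_perm = 50L, seed = 9L,
                                  min_events = 10L), "coarse")
})

test_that("count-vs-enrichment degenerates correctly and recovers planted coupling", {
  set.seed(77)
  regs <- vapply(1:12, function(i)
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""), "")
  names(regs) <- sprintf("e%d", 1:12)
  prof_u <- kmer_profile_from_regions(regs, matrix(0.5, 12, 50))
  cve <- count_vs_enrichment(prof_u)
  expect_true(is.na(cve$rho) ||
              all(cve$table$global_enrichment[!is.na(cve$table$global_enrichment)] == 1))
  # generator couples conserved elements to common planted motifs
  sim <- recovery_sim()
  prof <- kmer_profile(sim$events[1:1500, ], sim$genome, sim$track_mammal,
                       "upstream")
  cve2 <- count_vs_enrichment(prof)
  expect_gt(cve2$count_sd, 0)
  expect_gt(cve2$rho, 0)
})

test_that("pooled ISE/ISS conservation comparisons respect symmetry and direction", {
  # identical conservation for both sets: medians equal, p not small
  set.seed(78)
  regs <- character(30)
  for (i in 1:30) {
    s <- rep("T", 40)
    s[3:8] <- strsplit("ACGTCA", "")[[1]]
    s[21:26] <- strsplit("GGATCC", "")[[1]]
    regs[i] <- paste(s, collapse = "")
  }
  names(regs) <- sprintf("e%d", 1:30)
  prof <- kmer_profile_from_regions(regs, matrix(0.4, 30, 40))
  cmp <- ise_iss_conservation_comparison(prof, "ACGTCA", "GGATCC")
  expect_equal(cmp$median_iss, cmp$median_ise)
  expect_gt(cmp$p, 0.5)
  # swapping the sets flips the reported direction
  cons2 <- matrix(0.4, 30, 40); cons2[, 21:26] <- 0.9
  prof2 <- kmer_profile_from_regions(regs, cons2)
  a <- ise_iss_conservation_comparison(prof2, "ACGTCA", "GGATCC")
  b <- ise_iss_conservation_comparison(prof2, "GGATCC", "ACGTCA")
  expect_equal(a$larger, "ISS")
  expect_equal(b$larger, "ISE")
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$diff, -b$diff)
  # empty sets are flagged
  expect_false(ise_iss_conservation_comparison(prof, character(0), "GGATCC")$defined)
})

test_that("ISSs are more conserved than ISEs near the planted New exons", {
  sim <- recovery_sim()
  gt <- sim$ground_truth$events
  prof <- kmer_profile(sim$events, sim$genome, sim$track_mammal, "upstream")
  new_ids <- gt$event_id[gt$regime == "new"]
  cmp <- ise_iss_conservation_comparison(
    prof, sim$config$planted_ise$upstream, sim$config$planted_iss$upstream,
    event_ids = new_ids)
  expect_true(cmp$defined)
  expect_equal(cmp$larger, "ISS")
})
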