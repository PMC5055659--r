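test_that("composition features match a brute-force counter", {
  cf <- composition_features(c(r1 = "AAAA"))
  expect_equal(unname(cf[1, "A"]), 1)
  expect_equal(unname(cf[1, "AA"]), 1)
  expect_equal(sum(cf[1, 1:4]), 1)
  cf2 <- composition_features(c(r2 = "ACGT"))
  expect_equal(unname(cf2[1, c("A", "C", "G", "T")]), rep(0.25, 4),
               ignore_attr = TRUE)
  expect_equal(unname(cf2[1, c("AC", "CG", "GT")]), rep(1 / 3, 3),
               ignore_attr = TRUE)
  # random 86-mer against substring counting
  set.seed(60)
  s <- paste(sample(c("A", "C", "G", "T"), 86, TRUE), collapse = "")
  cf3 <- composition_features(c(x = s))
  for (b in c("A", "C", "G", "T")) {
    n <- sum(strsplit(s, "")[[1]] == b)
    expect_equal(unname(cf3[1, b]), n / 86)
  }
  for (d in c("AC", "GG", "TA")) {
    n <- sum(vapply(1:85, function(i) substr(s, i, i + 1) == d, TRUE))
    expect_equal(unname(cf3[1, d]), n / 85)
  }
  expect_error(composition_features("ACGN"), "non-ACGT")
  expect_equal(unname(composition_features("ACGN", non_acgt = "skip")[1, "A"]),
               1 / 3)
})

test_that("the composition regression produces exact and confound-free residuals", {
  # constant PSI -> all residuals zero
  set.seed(61)
  regs <- vapply(1:120, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""), "")
  names(regs) <- sprintf("e%d", 1:120)
  comp <- composition_features(regs)
  rp0 <- residual_psi(setNames(rep(0.4, 120), names(regs)), comp,
                      sides = "upstream")
  expect_equal(max(abs(rp0$residuals)), 0, tolerance = 1e-10)
  # PSI an exact linear function of GC -> perfect fit
  gc <- comp[, "C"] + comp[, "G"]
  y <- setNames(0.2 + 0.5 * gc, names(regs))
  rp1 <- residual_psi(y, comp, sides = "upstream")
  expect_lt(max(abs(rp1$residuals)), 1e-10)
  expect_lt(abs(sum(rp1$residuals)), 1e-8)
})

test_that("residualization removes the GC confound from the generator", {
  sim <- cached_sim("gc_conf", clean_config(1500L, 14L, gc_confound_beta = 2.0))
  regs_up <- extract_region_sequence(sim$events, sim$genome, "upstream", 15L, 101L)
  regs_dn <- extract_region_sequence(sim$events, sim$genome, "downstream", 15L, 101L)
  cu <- composition_features(regs_up); cd <- composition_features(regs_dn)
  gc <- (cu[, "C"] + cu[, "G"] + cd[, "C"] + cd[, "G"]) / 2
  pa <- psi_avg(sim$psi)
  expect_gt(spearman_rho(pa, gc), 0.05)     # the confound is real
  rp <- residual_psi(pa, cu, cd)
  expect_lt(abs(spearman_rho(rp$residuals, gc)), 0.05)
})

test_that("the rank-sum test agrees with enumeration and wilcox.test", {
  set.seed(62)
  for (i in 1:100) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    r <- round(rnorm(n1 + n2), 1)
    pres <- matrix(0, n1 + n2, 1)
    pres[seq_len(n1), 1] <- 1
    mw <- spliceCons:::mw_presence_test(pres, r)
    expect_equal(mw$U, u_oracle(r[seq_len(n1)], r[-seq_len(n1)]),
                 tolerance = 1e-12)
  }
  # normal-approximation p agrees with wilcox.test for larger samples
  for (i in 1:20) {
    n1 <- sample(20:40, 1); n2 <- sample(20:40, 1)
    r <- round(rnorm(n1 + n2), 1)
    pres <- matrix(0, n1 + n2, 1); pres[seq_len(n1), 1] <- 1
    mw <- spliceCons:::mw_presence_test(pres, r)
    wt <- suppressWarnings(wilcox.test(r[seq_len(n1)], r[-seq_len(n1)],
                                       exact = FALSE, correct = TRUE))
    expect_equal(mw$p, wt$p.value, tolerance = 1e-9)
  }
})

test_that("ISE/ISS calls are directional, corrected, and degenerate-safe", {
  set.seed(63)
  n <- 200L
  counts <- cbind(up1 = rbinom(n, 2, 0.4), everywhere = rep(1L, n),
                  nowhere = rep(0L, n), noise = rbinom(n, 1, 0.3))
  r <- 0.2 * counts[, "up1"] + rnorm(n, 0, 0.1)
  calls <- discover_isres(counts, r)
  expect_equal(calls$label[calls$kmer == "up1"], "ISE")
  expect_equal(calls$label[calls$kmer == "everywhere"], "none")
  expect_match(calls$reason[calls$kmer == "everywhere"], "present in all")
  expect_equal(calls$label[calls$kmer == "nowhere"], "none")
  expect_match(calls$reason[calls$kmer == "nowhere"], "absent")
  expect_equal(calls$n_with + calls$n_without, rep(n, 4))
  # q-values are BH: non-decreasing in p and >= p
  ok <- !is.na(calls$p)
  expect_true(all(calls$q[ok] >= calls$p[ok]))
  # complementation: negating residuals swaps every ISE/ISS call
  calls_neg <- discover_isres(counts, -r)
  swap <- c(ISE = "ISS", ISS = "ISE", none = "none")
  expect_equal(unname(swap[calls$label]), calls_neg$label)
  expect_equal(calls$p, calls_neg$p, tolerance = 1e-12)
})

test_that("BH q-values are monotone over a full k-mer matrix", {
  sim <- small_sim()
  prof <- kmer_profile(sim$events, sim$genome, sim$track_mammal, "upstream")
  regs_dn <- extract_region_sequence(sim$events, sim$genome, "downstream", 15L, 101L)
  rp <- residual_psi(psi_avg(sim$psi), composition_features(prof$regions),
                     composition_features(regs_dn))
  calls <- discover_isres(prof$counts, rp$residuals)
  ok <- !is.na(calls$p)
  o <- order(calls$p[ok])
  expect_true(all(diff(calls$q[ok][o]) >= -1e-12))
})

test_that("no ISREs are called when residuals carry no signal", {
  sim <- cached_sim("gc_conf", clean_config(1500L, 14L, gc_confound_beta = 2.0))
  prof <- kmer_profile(sim$events, sim$genome, sim$track_mammal, "upstream")
  regs_dn <- extract_region_sequence(sim$events, sim$genome, "downstream", 15L, 101L)
  rp <- residual_psi(psi_avg(sim$psi), composition_features(prof$regions),
                     composition_features(regs_dn))
  set.seed(64)
  r_perm <- sample(rp$residuals)
  calls <- discover_isres(prof$counts, r_perm)
  expect_lte(sum(calls$label != "none") / 4096, 0.05)
})

test_that("the ISRE-count predictor beats its null and benefits from NMD features", {
  sim <- recovery_sim()
  ev <- sim$events
  prof_up <- kmer_profile(ev, sim$genome, sim$track_mammal, "upstream")
  prof_dn <- kmer_profile(ev, sim$genome, sim$track_mammal, "downstream")
  cu <- composition_features(prof_up$regions)
  cd <- composition_features(prof_dn$regions)
  counts_up <- as.matrix(prof_up$counts)
  counts_dn <- as.matrix(prof_dn$counts)
  pa <- psi_avg(sim$psi)
  lab <- label_and_filter(sim$psi)
  res <- isre_predictor(counts_up, counts_dn, cu, cd, pa, lab,
                        n_folds = 5L, seed = 2L)
  expect_true(is.finite(res$auc))

  # null: permuted PSI assignments; discovery within folds finds nothing
  # (or chance-level features), so the AUC is NA or near 0.5
  set.seed(65)
  pa0 <- setNames(sample(pa), names(pa))
  perm <- match(names(pa0), names(pa))
  psi0 <- psi_table(sim$psi$psi[perm, , drop = FALSE] |>
                      (\(m) { rownames(m) <- sim$psi$event_id; m })(),
                    sim$psi$sigma)
  lab0 <- label_and_filter(psi0)
  res0 <- isre_predictor(counts_up, counts_dn, cu, cd, pa0, lab0,
                         n_folds = 5L, seed = 2L)
  null_auc <- if (is.finite(res0$auc)) res0$auc else 0.5
  expect_gt(null_auc, 0.42); expect_lt(null_auc, 0.58)
  expect_gte(res$auc, null_auc + 0.1)

  # a deterministic NMD column strictly increases the AUC
  low_forced <- ev$event_id[seq_len(600)]
  psi_nmd <- sim$psi$psi
  psi_nmd[low_forced, ] <- 0.03
  pt_nmd <- psi_table(psi_nmd, sim$psi$sigma)
  lab_nmd <- label_and_filter(pt_nmd)
  nmd <- data.frame(event_id = ev$event_id,
                    translatable_c1ac2 = as.integer(!ev$event_id %in% low_forced))
  res_plain <- isre_predictor(counts_up, counts_dn, cu, cd, psi_avg(pt_nmd),
                              lab_nmd, n_folds = 5L, seed = 2L)
  res_nmd <- isre_predictor(counts_up, counts_dn, cu, cd, psi_avg(pt_nmd),
                            lab_nmd, nmd = nmd, n_folds = 5L, seed = 2L)
  expect_gt(res_nmd$auc, res_plain$auc)
})

test_that("overlap expectations reproduce the analytic arithmetic", {
  expect_equal(round(overlap_expectation(296, 42, 4096), 1), 3.0)
  expect_equal(round(overlap_expectation(278, 101, 4096), 1), 6.9)
  expect_equal(overlap_expectation(0, 1000, 4096), 0)
  expect_error(overlap_expectation(-1, 10), "non-negative")
  expect_error(overlap_expectation(5000, 10, 4096), "exceeds")
})

test_that("catalogue matching reports intersections and expectations", {
  isres <- c("AAAAAA", "CCCCCC", "GGGGGG")
  cat42 <- c("AAAAAA", "TTTTTT")
  m <- match_reference_catalogue(isres, cat42)
  expect_equal(m$matched, 1L)
  expect_equal(m$expected, 3 * 2 / 4096)
  expect_equal(m$kmers, "AAAAAA")
  expect_equal(match_reference_catalogue(isres, isres)$matched, 3L)
  expect_equal(match_reference_catalogue(isres, c("ACACAC"))$matched, 0L)
  expect_error(match_reference_catalogue(isres, "AAA"), "6-mers")
  expect_equal(round(overlap_expectation(42, 793, 4096), 1), 8.1)

  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "acgtac", "", "TTTTTT"), path)
  expect_equal(read_catalogue(path), c("ACGTAC", "TTTTTT"))
  writeLines("TOOLONGG", path)
  expect_error(read_catalogue(path), "6-mers")
})

test_that("recovery scoring distinguishes exact and shift-tolerant matching", {
  calls <- data.frame(kmer = c("GTAACG", "TAACGC", "TTTTTT"),
                      label = c("ISE", "ISE", "ISS"),
                      stringsAsFactors = FALSE)
  sc <- score_isre_recovery(calls, planted_ise = "GTAACG",
                            planted_iss = character(0))
  expect_equal(sc$recall, 1)
  expect_equal(sc$tp, 2L)          # the shifted neighbour counts under shift1
  expect_equal(sc$fp, 1L)
  sc_exact <- score_isre_recovery(calls, "GTAACG", character(0),
                                  match = "exact")
  expect_equal(sc_exact$tp, 1L)
})
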