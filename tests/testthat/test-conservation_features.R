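make_event <- function(strand = "+", up = 200L, ex = 80L, dn = 200L,
                       start = 50L) {
  b <- cumsum(c(start, up, ex, dn))
  if (strand == "+")
    df <- data.frame(event_id = "e1", chrom = "chr1", strand = strand,
                     c1_donor = b[1], a_acceptor = b[2], a_donor = b[3],
                     c2_acceptor = b[4])
  else
    df <- data.frame(event_id = "e1", chrom = "chr1", strand = strand,
                     c1_donor = b[4], a_acceptor = b[3], a_donor = b[2],
                     c2_acceptor = b[1])
  validate_events(df)
}

const_track <- function(value, n = 600L, mode = "bounded01") {
  cons_track(list(chr1 = rep(value, n)), mode = mode)
}

test_that("junction conservation is the score of the first intronic base", {
  ev <- make_event()
  expect_equal(unname(junction_conservation(ev, const_track(0.8), "upstream")), 0.8)
  expect_equal(unname(junction_conservation(ev, const_track(0.8), "downstream")), 0.8)

  # 0.9 only at offset 0 of the downstream side (base = a_donor), else 0.1
  v <- rep(0.1, 600L); v[ev$a_donor + 1L] <- 0.9
  tr2 <- cons_track(list(chr1 = v))
  expect_equal(unname(junction_conservation(ev, tr2, "downstream")), 0.9)
  expect_equal(unname(junction_conservation(ev, tr2, "upstream")), 0.1)

  # minus-strand event: the genomically mirrored base (a_donor - 1)
  evm <- make_event("-")
  vm <- rep(0.1, 600L); vm[evm$a_donor] <- 0.9
  trm <- cons_track(list(chr1 = vm))
  expect_equal(unname(junction_conservation(evm, trm, "downstream")), 0.9)
})

test_that("average conservation is the windowed mean with truncation and drop rules", {
  ev <- make_event()
  expect_equal(unname(average_conservation(ev, const_track(0.8), "downstream", 100L)),
               0.8)
  # 1.0 on offsets [0,50), 0.0 on [50,100) -> 0.5
  v <- rep(0, 600L)
  v[(ev$a_donor + 1L):(ev$a_donor + 50L)] <- 1
  expect_equal(unname(average_conservation(ev, cons_track(list(chr1 = v)),
                                           "downstream", 100L)), 0.5)
  # intron shorter than the window: mean over the available bases
  ev60 <- make_event(dn = 60L)
  v2 <- rep(NA_real_, 600L)
  v2[(ev60$a_donor + 1L):(ev60$a_donor + 60L)] <- seq(0, 1, length.out = 60L)
  tr60 <- cons_track(list(chr1 = v2))
  expect_equal(unname(average_conservation(ev60, tr60, "downstream", 100L)),
               mean(seq(0, 1, length.out = 60L)))
  # missing bases reduce the denominator; all-missing is an error
  v3 <- rep(NA_real_, 600L)
  v3[(ev$a_donor + 1L):(ev$a_donor + 10L)] <- 0.6
  expect_equal(unname(average_conservation(ev, cons_track(list(chr1 = v3)),
                                           "downstream", 100L)), 0.6)
  expect_error(average_conservation(ev, cons_track(list(chr1 = v3)),
                                    "upstream", 100L), "undefined average")
  expect_error(average_conservation(ev, const_track(0.5), "upstream", 0L), "w must")
})

test_that("the Junc/Avg ratio applies the zero and epsilon rules", {
  expect_equal(junc_avg(0.9, 0.3), 3.0)
  expect_equal(junc_avg(0, 0), 0)
  expect_equal(junc_avg(0.5, 0), 500)
  expect_equal(junc_avg(c(0.9, 0, 0.5), c(0.3, 0, 0)), c(3, 0, 500))
  expect_error(junc_avg(-0.1, 0.5), "non-negative")
})

test_that("uniform tracks give R = 1 for every event, side and window", {
  sim <- small_sim()
  ev <- sim$events[1:25, ]
  tr <- uniform_track(sim$genome, 0.7)
  for (w in c(1L, 10L, 100L, 250L)) {
    for (side in c("upstream", "downstream")) {
      J <- junction_conservation(ev, tr, side)
      A <- average_conservation(ev, tr, side, w)
      expect_equal(unname(junc_avg(J, A)), rep(1, nrow(ev)))
    }
  }
  # monotone truncation: A_w constant once w exceeds the intron length
  ilen <- min(intron_length(ev, "upstream"))
  tr2 <- sim$track_mammal
  a1 <- average_conservation(ev, tr2, "upstream", ilen)
  a2 <- average_conservation(ev, tr2, "upstream", ilen + 50L)
  expect_equal(a1[which.min(intron_length(ev, "upstream"))],
               a2[which.min(intron_length(ev, "upstream"))])
})

test_that("GERP-style features pass unbounded scores through unclamped", {
  ev <- make_event()
  g2 <- gerp_features(ev, const_track(2.0, mode = "unbounded"))
  expect_equal(unname(unlist(g2[c("J_up", "A_up", "J_down", "A_down")])),
               rep(2, 4))
  gn <- gerp_features(ev, const_track(-1.5, mode = "unbounded"))
  expect_equal(unname(unlist(gn[c("J_up", "A_up", "J_down", "A_down")])),
               rep(-1.5, 4))
  # mixed fixture against hand-computed means
  v <- rep(0, 600L)
  v[(ev$a_donor + 1L):(ev$a_donor + 100L)] <- rep(c(-2, 4), 50L)
  tr <- cons_track(list(chr1 = v), mode = "unbounded")
  gm <- gerp_features(ev, tr)
  expect_equal(gm$J_down, -2)
  expect_equal(gm$A_down, 1)
  expect_error(gerp_features(ev, const_track(0.5)), "unbounded")
})

test_that("the Spearman estimator matches the rank-then-Pearson oracle", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    x <- sample(round(rnorm(n), 1))        # rounded -> ties
    y <- round(rnorm(n), 1)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
  }
  expect_true(is.na(spearman_rho(rep(1, 10), rnorm(10))))
  expect_true(is.na(spearman_rho(1:2, 2:1)))
})

test_that("the window sweep reports undefined correlations and rank identities", {
  sim <- small_sim()
  ev <- sim$events[1:30, ]
  # PSI identical for all events -> every correlation undefined
  sw0 <- window_sweep(ev, sim$track_mammal,
                      setNames(rep(0.5, 30), ev$event_id), W = 20L)
  expect_true(all(is.na(sw0$rho)))
  # PSI equal to R_100 -> correlation exactly 1 at w = 100
  J <- junction_conservation(ev, sim$track_mammal, "upstream")
  A <- average_conservation(ev, sim$track_mammal, "upstream", 100L)
  sw1 <- window_sweep(ev, sim$track_mammal,
                      setNames(plogis(junc_avg(J, A)), ev$event_id),
                      W = 110L)
  expect_equal(sw1$rho[sw1$side == "upstream" & sw1$w == 100L], 1)
  expect_error(window_sweep(ev[1:2, ], sim$track_mammal,
                            setNames(runif(2), ev$event_id[1:2]), W = 10L),
               ">= 3 events")
})
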