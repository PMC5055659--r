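## Synthetic cassette-exon data with planted ground truth.
##
## The generator emulates the statistical structure of a bulk RNA-Seq
## cassette-exon compendium (16 tissues, PSI in [0,1] with per-measurement
## noise), a phastCons-like mammalian conservation track with piecewise-
## constant conserved "elements" over a low background, a primate track
## derived from the mammalian one by element birth/death, planted ISE/ISS
## 6-mers in the 15-100 bp intronic regions that shift PSI on the logit
## scale, and a GC-composition confound on PSI.

DEFAULT_TISSUES <- c("Adipose", "Adrenal", "Brain", "Breast", "Colon",
                     "Heart", "Kidney", "Liver", "Lung", "Lymph", "Ovary",
                     "Prostate", "SkelMuscle", "Testes", "Thyroid",
                     "WhiteBlood")

#' Simulation configuration
#'
#' Defaults describe the study conditions the package's analyses are
#' validated under: 10689 cassette exons across 16 tissues, three
#' conservation regimes, a handful of planted intronic splicing
#' enhancer/silencer 6-mers with a one-logit per-occurrence effect, and a
#' GC confound on inclusion.
#'
#' @param n_exons number of cassette exons.
#' @param n_tissues number of tissues.
#' @param tissues tissue names (length `n_tissues`).
#' @param regime_probs probabilities of the Old-, Old+ and New conservation
#'   regimes (must sum to 1).
#' @param planted_ise,planted_iss lists with `upstream`/`downstream`
#'   character vectors of planted 6-mers; the two sets must be disjoint.
#' @param motif_prob per-(event, motif) success probability; each planted
#'   motif receives `Binomial(2, motif_prob)` instances per event.
#' @param effect_size_logit logit-PSI shift per planted-motif occurrence
#'   (+ for ISEs, - for ISSs).
#' @param gc_confound_beta logit-PSI shift per unit (GC fraction - 0.5) of
#'   the 15-100 bp regions.
#' @param sigma_measurement typical standard deviation of a confident PSI
#'   measurement; confident sigmas are drawn uniformly on
#'   `(0.01, 2 * sigma_measurement - 0.01)`.
#' @param frac_low_confidence fraction of measurements whose sigma exceeds
#'   the 0.1 confidence threshold (drawn uniformly on (0.101, 0.25)).
#' @param junction_high_dist,junction_low_dist Beta(a, b) parameters for
#'   junction conservation of old (high) and new (low) exons.
#' @param avg_high_dist,avg_low_dist Beta(a, b) parameters for the target
#'   mean conservation of the ISRE region for Old+ (high) versus Old-/New
#'   (low) sides; realised as piecewise-constant conserved element blocks
#'   over a low background.
#' @param tissue_diff_frac fraction of Old+ exons given tissue-differential
#'   PSI (the remainder are uniformly high or low across all tissues).
#' @param regime_logits named vector: logit-PSI intercepts `old_minus`,
#'   `old_plus` (magnitude of the bimodal Old+ split), `new`.
#' @param polarity_slope coupling of the Old+ high/low split to conserved
#'   element load: the probability that an Old+ exon is lowly included is
#'   `plogis(polarity_slope * (mean target average conservation - 0.75))`,
#'   so exons with more conserved cis elements tend to be skipped.
#' @param latent_sd standard deviation of the per-exon logit-PSI noise.
#' @param region_start,region_end half-open offset window of the ISRE
#'   region (0-based; defaults 15 and 101 give the 86-base 15-100 bp
#'   region).
#' @param intron_len_range,exon_len_range integer ranges for flanking
#'   intron and alternative exon lengths.
#' @param gc_range range of per-exon GC propensity for sequence generation.
#' @param distal_high_prob probability that the intron beyond the ISRE
#'   region carries a conserved distal stretch (drawn from
#'   `avg_high_dist`, else `avg_low_dist`), independent of the exon's
#'   regime and PSI.  Distal conservation therefore has the same
#'   magnitude distribution as proximal conservation but no relation to
#'   splicing, which is what makes averaging windows wider than the
#'   regulatory depth uninformative.
#' @param cons_coupling probabilities that an Old+ planted-motif instance is
#'   covered by a conserved element when the motif's effect sign is
#'   consistent with the exon's inclusion level (`consistent`) versus not
#'   (`inconsistent`); the gap couples conservation enrichment to residual
#'   PSI.
#' @param primate_gain_frac fraction of exons whose upstream intron gains
#'   primate-only conserved elements (lowering latent PSI).
#' @param primate_loss_frac fraction of Old+ exons whose conserved elements
#'   are absent from the primate track (raising latent PSI).
#' @param primate_effect_logit logit-PSI magnitude of the primate
#'   gain/loss effects.
#' @param seed integer random seed (the generator is fully deterministic
#'   given the seed).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_exons = 10689L,
                       n_tissues = 16L,
                       tissues = DEFAULT_TISSUES[seq_len(n_tissues)],
                       regime_probs = c(old_minus = 0.4, old_plus = 0.3, new = 0.3),
                       planted_ise = list(upstream = c("GTAACG", "CGTTGA"),
                                          downstream = c("ACGTGA", "TGACCG")),
                       planted_iss = list(upstream = c("TTCATC", "ATCGGA", "CATTGC"),
                                          downstream = c("GCTTAT", "TAGGCA", "CAATGG")),
                       motif_prob = 0.2,
                       effect_size_logit = 1.0,
                       gc_confound_beta = 2.0,
                       sigma_measurement = 0.015,
                       frac_low_confidence = 0.3,
                       junction_high_dist = c(10, 2),
                       junction_low_dist = c(2, 10),
                       avg_high_dist = c(10, 3),
                       avg_low_dist = c(2, 10),
                       tissue_diff_frac = 0.26,
                       regime_logits = c(old_minus = 2.6, old_plus = 3.0, new = -2.2),
                       polarity_slope = 8,
                       latent_sd = 0.8,
                       region_start = 15L,
                       region_end = 101L,
                       intron_len_range = c(400L, 900L),
                       exon_len_range = c(60L, 150L),
                       gc_range = c(0.3, 0.7),
                       distal_high_prob = 0.3,
                       cons_coupling = c(consistent = 0.9, inconsistent = 0.2),
                       primate_gain_frac = 0.15,
                       primate_loss_frac = 0.3,
                       primate_effect_logit = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(regime_probs) - 1) > 1e-8)
    stop("regime_probs must sum to 1")
  if (any(regime_probs < 0)) stop("regime_probs must be non-negative")
  all_ise <- unlist(planted_ise); all_iss <- unlist(planted_iss)
  if (length(intersect(all_ise, all_iss)) > 0L)
    stop("planted_ise and planted_iss must be disjoint")
  kmers <- c(all_ise, all_iss)
  if (length(kmers) > 0L) {
    if (any(nchar(kmers) != 6L)) stop("planted motifs must be 6-mers")
    if (any(!grepl("^[ACGT]+$", kmers))) stop("planted motifs must be ACGT")
    if (any(nchar(kmers) > region_end - region_start))
      stop("planted motif longer than the ISRE region")
  }
  if (any(c(junction_high_dist, junction_low_dist,
            avg_high_dist, avg_low_dist) <= 0))
    stop("Beta distribution parameters must be > 0")
  if (region_end - region_start < 6L) stop("ISRE region shorter than a 6-mer")
  cfg$n_exons <- as.integer(n_exons)
  cfg$n_tissues <- as.integer(n_tissues)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Truncated-normal draws on [0, 1] via inverse-CDF sampling.
rtrunc01 <- function(n, mean, sd) {
  sd <- pmax(sd, 1e-12)
  plo <- pnorm(0, mean, sd); phi <- pnorm(1, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# Sample one DNA segment of length L at GC propensity g.
rand_seq <- function(L, g) {
  sample(c("A", "C", "G", "T"), L, replace = TRUE,
         prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2))
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulate a cassette-exon dataset with planted ground truth
#'
#' Generates event geometry, a genome, mammalian and primate conservation
#' tracks, and an events-by-tissues PSI table, together with the ground
#' truth needed to score recovery of conservation regimes, planted ISE/ISS
#' motifs, tissue-differential exons and primate element birth/death.
#' Identical configurations (including the seed) produce bit-identical
#' output.
#'
#' @param config `sim_config` object.
#' @return list of class `splice_sim` with elements `events`, `genome`
#'   (`DNAStringSet`), `track_mammal`, `track_primate`, `psi`
#'   (`psi_table`), `ground_truth`, and `config`.
#' @export
simulate_splice_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_exons
  Tn <- cfg$n_tissues
  rs <- cfg$region_start; re <- cfg$region_end
  pad <- 10L

  ## ---- geometry -------------------------------------------------------
  up_len <- sample(cfg$intron_len_range[1L]:cfg$intron_len_range[2L], n, TRUE)
  dn_len <- sample(cfg$intron_len_range[1L]:cfg$intron_len_range[2L], n, TRUE)
  ex_len <- sample(cfg$exon_len_range[1L]:cfg$exon_len_range[2L], n, TRUE)
  strand <- sample(c("+", "-"), n, TRUE)
  seg_len <- pad + up_len + ex_len + dn_len + pad
  seg_start <- cumsum(c(0L, seg_len[-n]))
  b1 <- seg_start + pad
  b2 <- b1 + up_len
  b3 <- b2 + ex_len
  b4 <- b3 + dn_len
  # on the minus strand transcription runs right-to-left, so the genomic
  # leftmost boundary is the C2 acceptor
  events <- data.frame(
    event_id = sprintf("ev%05d", seq_len(n)),
    chrom = "chr1",
    strand = strand,
    c1_donor = ifelse(strand == "+", b1, b4),
    a_acceptor = ifelse(strand == "+", b2, b3),
    a_donor = ifelse(strand == "+", b3, b2),
    c2_acceptor = ifelse(strand == "+", b4, b1),
    stringsAsFactors = FALSE)
  events <- validate_events(events)
  genome_len <- b4[n] + pad

  ## ---- sequence with planted motifs -----------------------------------
  gc <- runif(n, cfg$gc_range[1L], cfg$gc_range[2L])
  motif_df <- data.frame(side = character(0), kmer = character(0),
                         label = character(0), stringsAsFactors = FALSE)
  for (side in c("upstream", "downstream")) {
    if (length(cfg$planted_ise[[side]]))
      motif_df <- rbind(motif_df, data.frame(
        side = side, kmer = cfg$planted_ise[[side]], label = "ISE",
        stringsAsFactors = FALSE))
    if (length(cfg$planted_iss[[side]]))
      motif_df <- rbind(motif_df, data.frame(
        side = side, kmer = cfg$planted_iss[[side]], label = "ISS",
        stringsAsFactors = FALSE))
  }
  seg_seqs <- character(n)
  plant_list <- vector("list", n)
  max_start <- re - 1L - 6L   # last offset whose instance fits in the region
  for (i in seq_len(n)) {
    chars <- rand_seq(seg_len[i], gc[i])
    ev <- events[i, , drop = FALSE]
    plants <- list()
    if (nrow(motif_df) > 0L) {
      for (m in seq_len(nrow(motif_df))) {
        n_inst <- rbinom(1L, 2L, cfg$motif_prob)
        if (n_inst == 0L) next
        side <- motif_df$side[m]
        used <- vapply(plants, function(p)
          if (p$side == side) p$offset else NA_integer_, 0L)
        used <- used[!is.na(used)]
        for (j in seq_len(n_inst)) {
          o <- NA_integer_
          for (try in 1:20) {
            cand <- sample(rs:max_start, 1L)
            if (all(abs(cand - used) >= 6L)) { o <- cand; break }
          }
          if (is.na(o)) next
          used <- c(used, o)
          # write the motif 5'->3' along the pre-mRNA: string index within
          # the window maps to decreasing offsets on the upstream side
          offs <- if (side == "downstream") o + 0:5 else o + 5:0
          pos <- if (side == "downstream") {
            if (ev$strand == "+") ev$a_donor + offs else ev$a_donor - 1L - offs
          } else {
            if (ev$strand == "+") ev$a_acceptor - 1L - offs else ev$a_acceptor + offs
          }
          bases <- strsplit(motif_df$kmer[m], "")[[1L]]
          if (ev$strand == "-") bases <- DNA_COMP[bases]
          chars[pos - seg_start[i] + 1L] <- bases
          plants[[length(plants) + 1L]] <-
            list(side = side, kmer = motif_df$kmer[m],
                 label = motif_df$label[m], offset = o)
        }
      }
    }
    seg_seqs[i] <- paste(chars, collapse = "")
    plant_list[[i]] <- plants
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(seg_seqs, collapse = ""), "chr1"))
  motifs <- do.call(rbind, lapply(seq_len(n), function(i) {
    ps <- plant_list[[i]]
    if (length(ps) == 0L) return(NULL)
    data.frame(event_id = events$event_id[i],
               side = vapply(ps, `[[`, "", "side"),
               kmer = vapply(ps, `[[`, "", "kmer"),
               label = vapply(ps, `[[`, "", "label"),
               offset = vapply(ps, `[[`, 0L, "offset"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(motifs))
    motifs <- data.frame(event_id = character(0), side = character(0),
                         kmer = character(0), label = character(0),
                         offset = integer(0), stringsAsFactors = FALSE)

  ## ---- realized motif counts and GC ----------------------------------
  reg_up <- extract_region_sequence(events, genome, "upstream", rs, re)
  reg_dn <- extract_region_sequence(events, genome, "downstream", rs, re)
  count_planted <- function(regions, kmers) {
    if (length(kmers) == 0L) return(matrix(0L, length(regions), 0L))
    dss <- Biostrings::DNAStringSet(regions)
    vapply(kmers, function(k) Biostrings::vcountPattern(k, dss),
           integer(length(regions)))
  }
  ise_counts <- count_planted(reg_up, cfg$planted_ise$upstream)
  ise_counts <- cbind(ise_counts, count_planted(reg_dn, cfg$planted_ise$downstream))
  iss_counts <- count_planted(reg_up, cfg$planted_iss$upstream)
  iss_counts <- cbind(iss_counts, count_planted(reg_dn, cfg$planted_iss$downstream))
  net_motif <- (if (ncol(ise_counts)) rowSums(ise_counts) else rep(0, n)) -
               (if (ncol(iss_counts)) rowSums(iss_counts) else rep(0, n))
  region_gc <- (Biostrings::letterFrequency(
                  Biostrings::DNAStringSet(reg_up), "GC")[, 1L] +
                Biostrings::letterFrequency(
                  Biostrings::DNAStringSet(reg_dn), "GC")[, 1L]) /
               (2 * (re - rs))

  ## ---- regimes, flags, latent PSI -------------------------------------
  regime <- sample(c("old_minus", "old_plus", "new"), n, TRUE,
                   prob = cfg$regime_probs)
  old_plus_idx <- which(regime == "old_plus")
  # per-side target average conservation, drawn up front because the Old+
  # inclusion polarity is coupled to conserved-element load
  draw_A <- function() ifelse(regime == "old_plus",
                              rbeta(n, cfg$avg_high_dist[1L], cfg$avg_high_dist[2L]),
                              rbeta(n, cfg$avg_low_dist[1L], cfg$avg_low_dist[2L]))
  A_target_up <- draw_A(); A_target_dn <- draw_A()
  polarity <- rep(NA_integer_, n)                      # +1 high, -1 low
  p_low <- plogis(cfg$polarity_slope *
                  ((A_target_up + A_target_dn) / 2 - 0.75))
  polarity[old_plus_idx] <-
    ifelse(runif(length(old_plus_idx)) < p_low[old_plus_idx], -1L, 1L)
  tissue_diff <- rep(FALSE, n)
  tissue_diff[old_plus_idx] <-
    runif(length(old_plus_idx)) < cfg$tissue_diff_frac
  primate_gain <- runif(n) < cfg$primate_gain_frac
  primate_loss <- regime == "old_plus" & runif(n) < cfg$primate_loss_frac
  primate_gain[primate_loss] <- FALSE

  base_logit <- ifelse(regime == "old_minus", cfg$regime_logits[["old_minus"]],
                ifelse(regime == "new", cfg$regime_logits[["new"]],
                       polarity * cfg$regime_logits[["old_plus"]]))
  event_noise <- rnorm(n, 0, cfg$latent_sd)
  shared <- base_logit + event_noise +
    cfg$effect_size_logit * net_motif +
    cfg$gc_confound_beta * (region_gc - 0.5) +
    ifelse(primate_gain, -cfg$primate_effect_logit, 0) +
    ifelse(primate_loss, cfg$primate_effect_logit, 0)
  latent_logit <- matrix(shared, n, Tn)
  # tissue-differential Old+ exons: per-tissue high/low intercepts drawn
  # with tissue-specific propensities, replacing the shared intercept
  prop <- seq(0.25, 0.75, length.out = Tn)
  for (i in which(tissue_diff)) {
    dir <- ifelse(runif(Tn) < prop, 1, -1)
    latent_logit[i, ] <- shared[i] - base_logit[i] +
      dir * cfg$regime_logits[["old_plus"]]
  }
  latent_psi <- plogis(latent_logit)
  dimnames(latent_psi) <- list(events$event_id, cfg$tissues)

  ## ---- observed PSI ---------------------------------------------------
  low_conf <- matrix(runif(n * Tn) < cfg$frac_low_confidence, n, Tn)
  sig_hi <- pmax(2 * cfg$sigma_measurement - 0.01, 0.02)
  sigma <- matrix(runif(n * Tn, 0.01, min(sig_hi, 0.099)), n, Tn)
  sigma[low_conf] <- runif(sum(low_conf), 0.101, 0.25)
  psi_obs <- matrix(rtrunc01(n * Tn, as.vector(latent_psi), as.vector(sigma)),
                    n, Tn)
  dimnames(psi_obs) <- dimnames(sigma) <- dimnames(latent_psi)
  psi <- psi_table(psi_obs, sigma)

  ## ---- conservation tracks --------------------------------------------
  bg <- runif(n, 0.02, 0.08)
  mam <- rep(0.05, genome_len)
  for (i in seq_len(n)) mam[(seg_start[i] + 1L):(seg_start[i] + seg_len[i])] <- bg[i]
  pri <- mam
  el <- list(event_id = list(), side = list(), start = list(), end = list(),
             value = list(), track = list())
  add_element <- function(eid, side, lo, hi, val, track) {
    k <- length(el$event_id) + 1L
    el$event_id[[k]] <<- eid; el$side[[k]] <<- side
    el$start[[k]] <<- lo; el$end[[k]] <<- hi
    el$value[[k]] <<- val; el$track[[k]] <<- track
  }
  # offset -> genomic interval [lo, hi) for a run of offsets [a, b] (helper)
  off_interval <- function(ev, side, a, b) {
    p1 <- region_positions(ev, side, a, a + 1L)
    p2 <- region_positions(ev, side, b, b + 1L)
    c(min(p1, p2), max(p1, p2) + 1L)
  }
  elem_len_mean <- 10
  J_up <- numeric(n); J_dn <- numeric(n)
  for (i in seq_len(n)) {
    ev <- events[i, , drop = FALSE]
    old <- regime[i] != "new"
    jd <- if (old) cfg$junction_high_dist else cfg$junction_low_dist
    incl_high <- shared[i] > 0
    for (side in c("upstream", "downstream")) {
      J <- rbeta(1L, jd[1L], jd[2L])
      if (side == "upstream") J_up[i] <- J else J_dn[i] <- J
      A_target <- if (side == "upstream") A_target_up[i] else A_target_dn[i]
      covered <- rep(FALSE, re)       # offsets 0 .. re-1
      # junction element: offsets 0-2 at the junction score
      jiv <- off_interval(ev, side, 0L, 2L)
      mam[(jiv[1L] + 1L):jiv[2L]] <- J
      pri[(jiv[1L] + 1L):jiv[2L]] <- J
      # splice-site consensus stretch (offsets 3-14): moderate, variable
      # conservation unrelated to the exon's regime
      if (rs > 3L) {
        cons_val <- rbeta(1L, 2, 2)
        civ <- off_interval(ev, side, 3L, rs - 1L)
        mam[(civ[1L] + 1L):civ[2L]] <- cons_val
        pri[(civ[1L] + 1L):civ[2L]] <- cons_val
      }
      # conserved elements over planted motifs, with coverage probability
      # coupled to the consistency of the motif's effect sign and the
      # exon's inclusion level (conserved ISSs sit near low-PSI exons,
      # conserved ISEs near high-PSI exons)
      if (length(plant_list[[i]]) > 0L) {
        for (p in plant_list[[i]]) {
          if (p$side != side) next
          consistent <- (p$label == "ISE") == incl_high
          p_cov <- if (consistent) cfg$cons_coupling[["consistent"]]
                   else cfg$cons_coupling[["inconsistent"]]
          if (runif(1L) > p_cov) next
          ext <- sample(0:3, 1L)
          a <- max(rs, p$offset - ext); b <- min(re - 1L, p$offset + 5L + ext)
          covered[(a + 1L):(b + 1L)] <- TRUE
        }
      }
      # extra random elements up to the coverage implied by the target
      # (A_target is the target mean conservation of the ISRE region)
      c_need <- (re - rs) * (A_target - bg[i]) / (0.925 - bg[i])
      c_need <- min(max(ceiling(c_need), sum(covered)), re - rs)
      tries <- 0L
      while (sum(covered) < c_need && tries < 60L) {
        tries <- tries + 1L
        a <- sample(rs:(re - 5L), 1L)
        len <- 4L + stats::rgeom(1L, 1 / elem_len_mean)
        b <- min(re - 1L, a + len - 1L)
        covered[(a + 1L):(b + 1L)] <- TRUE
      }
      if (any(covered)) {
        r <- rle(covered)
        hi_off <- cumsum(r$lengths) - 1L
        lo_off <- hi_off - r$lengths + 1L
        for (k in which(r$values)) {
          val <- runif(1L, 0.85, 1.0)
          iv <- off_interval(ev, side, lo_off[k], hi_off[k])
          mam[(iv[1L] + 1L):iv[2L]] <- val
          if (!primate_loss[i]) pri[(iv[1L] + 1L):iv[2L]] <- val
          add_element(ev$event_id, side, iv[1L], iv[2L], val,
                      if (primate_loss[i]) "mammal" else "both")
        }
      }
      # distal PSI-independent conserved elements beyond the ISRE region:
      # same magnitude distribution as proximal conservation, but drawn
      # independently of the exon's regime and inclusion level
      ilen <- intron_length(ev, side)
      span <- ilen - re
      if (span > 8L && cfg$distal_high_prob > 0) {
        dd <- if (runif(1L) < cfg$distal_high_prob) cfg$avg_high_dist
              else cfg$avg_low_dist
        d_target <- rbeta(1L, dd[1L], dd[2L])
        d_cov <- (d_target - bg[i]) / (0.925 - bg[i])
        m_need <- round(max(0, min(1, d_cov)) * span)
        dcov <- rep(FALSE, span)        # distal offsets re .. ilen-1
        tries <- 0L
        while (sum(dcov) < m_need && tries < 200L) {
          tries <- tries + 1L
          a <- sample.int(span, 1L)
          len <- 4L + stats::rgeom(1L, 1 / elem_len_mean)
          b <- min(span, a + len - 1L)
          dcov[a:b] <- TRUE
        }
        if (any(dcov)) {
          r <- rle(dcov)
          hi_off <- cumsum(r$lengths) - 1L
          lo_off <- hi_off - r$lengths + 1L
          for (k in which(r$values)) {
            val <- runif(1L, 0.85, 1.0)
            iv <- off_interval(ev, side, re + lo_off[k], re + hi_off[k])
            mam[(iv[1L] + 1L):iv[2L]] <- val
            pri[(iv[1L] + 1L):iv[2L]] <- val
            add_element(ev$event_id, side, iv[1L], iv[2L], val, "distal")
          }
        }
      }
      # primate-only element birth in the upstream intron
      if (side == "upstream" && primate_gain[i]) {
        A_pri <- rbeta(1L, cfg$avg_high_dist[1L], cfg$avg_high_dist[2L])
        c_pri <- (re - rs) * (A_pri - bg[i]) / (0.925 - bg[i])
        c_pri <- min(max(ceiling(c_pri), 0), re - rs)
        tries <- 0L
        pcov <- covered
        while (sum(pcov) < c_pri && tries < 60L) {
          tries <- tries + 1L
          a <- sample(rs:(re - 5L), 1L)
          len <- 4L + stats::rgeom(1L, 1 / elem_len_mean)
          b <- min(re - 1L, a + len - 1L)
          pcov[(a + 1L):(b + 1L)] <- TRUE
        }
        newcov <- pcov & !covered
        if (any(newcov)) {
          r <- rle(newcov)
          hi_off <- cumsum(r$lengths) - 1L
          lo_off <- hi_off - r$lengths + 1L
          for (k in which(r$values)) {
            val <- runif(1L, 0.85, 1.0)
            iv <- off_interval(ev, side, lo_off[k], hi_off[k])
            pri[(iv[1L] + 1L):iv[2L]] <- val
            add_element(ev$event_id, side, iv[1L], iv[2L], val, "primate")
          }
        }
      }
    }
  }
  elements <- data.frame(
    event_id = as.character(unlist(el$event_id)),
    side = as.character(unlist(el$side)),
    start = as.integer(unlist(el$start)),
    end = as.integer(unlist(el$end)),
    value = as.numeric(unlist(el$value)),
    track = as.character(unlist(el$track)),
    stringsAsFactors = FALSE)
  if (nrow(elements) == 0L)
    elements <- data.frame(event_id = character(0), side = character(0),
                           start = integer(0), end = integer(0),
                           value = numeric(0), track = character(0),
                           stringsAsFactors = FALSE)
  track_mammal <- cons_track(list(chr1 = mam), mode = "bounded01")
  track_primate <- cons_track(list(chr1 = pri), mode = "bounded01")

  gt_events <- data.frame(
    event_id = events$event_id,
    regime = regime,
    old_plus_polarity = polarity,
    tissue_diff = tissue_diff,
    primate_gain = primate_gain,
    primate_loss = primate_loss,
    gc_propensity = gc,
    region_gc = region_gc,
    net_motif = net_motif,
    shared_logit = shared,
    stringsAsFactors = FALSE)

  ground_truth <- structure(list(
    events = gt_events,
    latent_psi = latent_psi,
    motifs = motifs,
    elements = elements,
    planted_ise = cfg$planted_ise,
    planted_iss = cfg$planted_iss), class = "ground_truth")

  structure(list(events = events, genome = genome,
                 track_mammal = track_mammal, track_primate = track_primate,
                 psi = psi, ground_truth = ground_truth, config = cfg),
            class = "splice_sim")
}

#' @exportS3Method base::print
print.splice_sim <- function(x, ...) {
  cat(sprintf("splice_sim: %d events x %d tissues, genome %d bp, seed %d\n",
              nrow(x$events), x$config$n_tissues,
              Biostrings::width(x$genome)[1L], x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to disk in the package's exchange formats
#'
#' Emits the event TSV, genome FASTA, bedGraph tracks and PSI TSV that the
#' readers in this package consume, plus the ground-truth dump.
#'
#' @param sim `splice_sim` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "splice_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_events(sim$events, file.path(dir, "events.tsv"))
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_track(sim$track_mammal, file.path(dir, "cons_mammal.bedgraph"))
  write_track(sim$track_primate, file.path(dir, "cons_primate.bedgraph"))
  write_psi_table(sim$psi, file.path(dir, "psi.tsv"))
  emit_ground_truth(sim$ground_truth, file.path(dir, "ground_truth"))
  invisible(dir)
}

#' Dump ground truth to JSON + TSV files
#'
#' @param gt `ground_truth` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
emit_ground_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(gt$events, file.path(dir, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gt$motifs, file.path(dir, "motifs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gt$elements, file.path(dir, "elements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lp <- data.frame(event_id = rownames(gt$latent_psi),
                   gt$latent_psi, check.names = FALSE)
  write.table(lp, file.path(dir, "latent_psi.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(planted_ise = gt$planted_ise,
                            planted_iss = gt$planted_iss),
                       file.path(dir, "planted_motifs.json"))
  invisible(dir)
}

#' Read back a ground-truth dump
#'
#' @param dir directory written by [emit_ground_truth()].
#' @return `ground_truth` object.
#' @export
read_ground_truth <- function(dir) {
  events <- read.delim(file.path(dir, "events.tsv"), stringsAsFactors = FALSE)
  motifs <- read.delim(file.path(dir, "motifs.tsv"), stringsAsFactors = FALSE,
                       colClasses = c(event_id = "character", side = "character",
                                      kmer = "character", label = "character",
                                      offset = "integer"))
  elements <- read.delim(file.path(dir, "elements.tsv"), stringsAsFactors = FALSE)
  lp <- read.delim(file.path(dir, "latent_psi.tsv"), stringsAsFactors = FALSE,
                   check.names = FALSE)
  latent <- as.matrix(lp[, -1L, drop = FALSE])
  rownames(latent) <- lp$event_id
  planted <- jsonlite::read_json(file.path(dir, "planted_motifs.json"),
                                 simplifyVector = TRUE)
  structure(list(events = events, latent_psi = latent, motifs = motifs,
                 elements = elements,
                 planted_ise = as.list(planted$planted_ise),
                 planted_iss = as.list(planted$planted_iss)),
            class = "ground_truth")
}
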