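# Shared simulation fixtures, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg) {
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_splice_data(cfg)
  .sim_cache[[key]]
}

# no planted motifs and (unless overridden) no GC confound: isolates the
# regime / tissue structure
clean_config <- function(n_exons, seed, ...) {
  args <- utils::modifyList(
    list(n_exons = n_exons, seed = seed,
         planted_ise = list(upstream = character(0), downstream = character(0)),
         planted_iss = list(upstream = character(0), downstream = character(0)),
         effect_size_logit = 0, gc_confound_beta = 0),
    list(...))
  do.call(sim_config, args)
}

small_sim <- function() cached_sim("small", sim_config(n_exons = 150L, seed = 42L))

clean_sim <- function() cached_sim("clean", clean_config(2000L, 5L))

# the main planted-recovery dataset used by the acceptance suite
recovery_sim <- function() cached_sim("recovery", sim_config(n_exons = 3000L, seed = 1L))

# flat PSI structure: conservation carries no information about inclusion
null_config <- function(n_exons, seed) {
  clean_config(n_exons, seed,
               regime_logits = c(old_minus = 0, old_plus = 0, new = 0),
               polarity_slope = 0, latent_sd = 1.2, tissue_diff_frac = 0)
}

null_sim <- function() cached_sim("null", null_config(2000L, 6L))

# brute-force Spearman: rank both vectors, then Pearson on the ranks
spearman_oracle <- function(x, y) cor(rank(x), rank(y))

# brute-force AUC: enumerate all positive/negative pairs, ties count 1/2
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# brute-force Mann-Whitney U (group-1 wins over group-2, ties 1/2)
u_oracle <- function(x1, x2) {
  tot <- 0
  for (a in x1) for (b in x2)
    tot <- tot + (if (a > b) 1 else if (a == b) 0.5 else 0)
  tot
}

# uniform conservation track covering a genome
uniform_track <- function(genome, value, mode = "bounded01") {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  scores <- lapply(seq_along(genome), function(i)
    rep(value, Biostrings::width(genome)[i]))
  names(scores) <- names(genome)
  cons_track(scores, mode = mode)
}
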