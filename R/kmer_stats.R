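## k-mer conservation statistics over the 15-100 bp intronic regions:
## conservation enrichment (global and per event), enrichment bias,
## ISE/ISS character, their meta-correlation with a permutation null,
## count-vs-enrichment statistics, conservation-weighted counts, and the
## pooled ISE-vs-ISS conservation comparison.

#' All DNA k-mers in canonical (alphabetical) order
#'
#' @param k k-mer length.
#' @return character vector of `4^k` k-mers, ordered as in
#'   `Biostrings::oligonucleotideFrequency` columns.
#' @export
all_kmers <- function(k = 6L) {
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
}

#' Per-event k-mer occurrence and conservation profile of one side
#'
#' Extracts the 15-100 bp region sequences and their per-base conservation
#' for one side, and tabulates for every (event, k-mer) pair the
#' occurrence count (overlaps allowed), the distinct region bases covered
#' by instances of the k-mer, their conservation sum, and the
#' conservation-weighted count (each instance weighted by the minimum
#' conservation over its k bases).
#'
#' @param events validated event data.frame.
#' @param genome `DNAStringSet` or named character vector.
#' @param track `cons_track`.
#' @param side `"upstream"` or `"downstream"`.
#' @param region_start,region_end half-open offset window (defaults 15,
#'   101: the 86-base 15-100 bp region).
#' @param k k-mer length (default 6).
#' @return object of class `kmer_profile`.
#' @export
kmer_profile <- function(events, genome, track,
                         side = c("upstream", "downstream"),
                         region_start = 15L, region_end = 101L, k = 6L) {
  side <- match.arg(side)
  events <- validate_events(events)
  regions <- extract_region_sequence(events, genome, side,
                                     region_start, region_end)
  cons <- region_cons_matrix(events, track, side, region_start, region_end)
  if (track$missing_policy == "zero") cons[is.na(cons)] <- 0
  kmer_profile_from_regions(regions, cons, side = side, k = k)
}

#' Build a k-mer profile directly from region sequences
#'
#' Lower-level constructor used by [kmer_profile()]: takes region strings
#' (all the same length, transcription orientation) and a matrix of
#' per-base conservation aligned with them.
#'
#' @param regions named character vector of equal-length ACGT sequences
#'   (names = event ids).
#' @param cons numeric matrix, events x region length, per-base
#'   conservation aligned with the region strings (`NA` = missing base).
#' @param side label stored on the profile.
#' @param k k-mer length (default 6).
#' @return object of class `kmer_profile`.
#' @export
kmer_profile_from_regions <- function(regions, cons,
                                      side = "upstream", k = 6L) {
  L <- unique(nchar(regions))
  if (length(L) != 1L) stop("regions must all have the same length")
  cons <- as.matrix(cons)
  if (!identical(dim(cons), c(length(regions), L)))
    stop("cons must be an events x region-length matrix")
  if (is.null(names(regions))) names(regions) <- paste0("ev", seq_along(regions))
  chars <- matrix(unlist(strsplit(regions, ""), use.names = FALSE),
                  nrow = length(regions), ncol = L, byrow = TRUE)
  codes <- matrix(match(chars, c("A", "C", "G", "T")) - 1L,
                  nrow = nrow(chars), ncol = L)
  codes[is.na(codes)] <- -1L
  trip <- cpp_kmer_coverage(codes, cons, as.integer(k))
  trip <- data.frame(event = trip$event, kmer = trip$kmer,
                     count = trip$count, cov_n = trip$cov_n,
                     cov_sum = trip$cov_sum, wcount = trip$wcount)
  background <- mean(cons, na.rm = TRUE)
  kmers <- all_kmers(k)
  counts <- Matrix::sparseMatrix(i = trip$event, j = trip$kmer,
                                 x = trip$count,
                                 dims = c(length(regions), length(kmers)),
                                 dimnames = list(names(regions), kmers))
  structure(list(side = side, k = as.integer(k), kmers = kmers,
                 event_ids = names(regions), trip = trip, counts = counts,
                 cons = cons, background = background,
                 regions = regions),
            class = "kmer_profile")
}

#' @exportS3Method base::print
print.kmer_profile <- function(x, ...) {
  cat(sprintf("kmer_profile (%s): %d events, %d-mers, %d (event,kmer) pairs\n",
              x$side, length(x$event_ids), x$k, nrow(x$trip)))
  invisible(x)
}

#' Global conservation enrichment per k-mer
#'
#' Average conservation of all bases that are part of an instance of the
#' k-mer (pooled across events), divided by the average conservation of
#' the 15-100 bp region across all events.  Values above 1 mark k-mers
#' more conserved than a typical region base.
#'
#' @param profile `kmer_profile`.
#' @return named numeric vector over all k-mers (`NA` where the k-mer is
#'   absent or no covered base has a defined score).
#' @export
global_enrichment <- function(profile) {
  stopifnot(inherits(profile, "kmer_profile"))
  if (profile$background <= 0 || is.na(profile$background))
    stop("global region conservation background is zero or undefined")
  s <- tapply(profile$trip$cov_sum, profile$trip$kmer, sum)
  n <- tapply(profile$trip$cov_n, profile$trip$kmer, sum)
  out <- setNames(rep(NA_real_, length(profile$kmers)), profile$kmers)
  ki <- as.integer(names(s))
  vals <- ifelse(n > 0, (s / n) / profile$background, NA_real_)
  out[ki] <- vals
  out
}

# Subset structures for the per-k-mer Spearman statistics: for each
# k-mer passing the eligibility filter, the containing-event indices and
# the pre-ranked fixed variable (count; per-event enrichment).
kmer_subset_prep <- function(profile, min_events = 100L) {
  trip <- profile$trip
  n_events <- tapply(trip$count, trip$kmer, length)
  max_count <- tapply(trip$count, trip$kmer, max)
  elig_ids <- as.integer(names(n_events))[n_events >= min_events & max_count > 1L]
  tr <- trip[trip$kmer %in% elig_ids, , drop = FALSE]
  tr <- tr[order(tr$kmer), , drop = FALSE]
  # ranked at 12 significant digits so exactly-equal enrichments (up to
  # floating-point summation order) tie rather than rank on noise
  enrich <- ifelse(tr$cov_n > 0,
                   signif((tr$cov_sum / tr$cov_n) / profile$background, 12L),
                   NA_real_)
  by_kmer <- split(seq_len(nrow(tr)), tr$kmer)
  kmer_ids <- as.integer(names(by_kmer))
  idx_count <- lapply(by_kmer, function(i) tr$event[i])
  ranks_count <- lapply(by_kmer, function(i) rank(tr$count[i]))
  idx_enrich <- lapply(by_kmer, function(i) {
    ok <- !is.na(enrich[i]); tr$event[i][ok]
  })
  ranks_enrich <- lapply(by_kmer, function(i) {
    v <- enrich[i]; rank(v[!is.na(v)])
  })
  list(kmer_ids = kmer_ids, kmers = profile$kmers[kmer_ids],
       idx_count = idx_count, ranks_count = ranks_count,
       idx_enrich = idx_enrich, ranks_enrich = ranks_enrich)
}

#' Per-k-mer record table: counts, enrichment, bias and character
#'
#' For every k-mer of one side: total occurrence count, number of
#' containing events, global conservation enrichment, enrichment bias `B`
#' (Spearman correlation of per-event conservation enrichment with
#' residual PSI over containing events), ISE/ISS character `X` (Spearman
#' correlation of the count with residual PSI over containing events),
#' and the eligibility flag (>= `min_events` containing events and > 1
#' occurrence in at least one event; `B` and `X` are reported only for
#' eligible k-mers).
#'
#' @param profile `kmer_profile`.
#' @param residuals named residual-PSI vector aligned with the profile's
#'   events.
#' @param min_events eligibility threshold (default 100).
#' @return data.frame `kmer`, `side`, `total_count`, `n_events`,
#'   `max_count`, `global_enrichment`, `bias`, `character`, `eligible`.
#' @export
kmer_records <- function(profile, residuals, min_events = 100L) {
  stopifnot(inherits(profile, "kmer_profile"))
  residuals <- align_residuals(profile, residuals)
  trip <- profile$trip
  K <- length(profile$kmers)
  total <- setNames(rep(0, K), profile$kmers)
  tc <- tapply(trip$count, trip$kmer, sum)
  total[as.integer(names(tc))] <- tc
  nev <- setNames(rep(0L, K), profile$kmers)
  ne <- tapply(trip$count, trip$kmer, length)
  nev[as.integer(names(ne))] <- ne
  mx <- setNames(rep(0L, K), profile$kmers)
  mc <- tapply(trip$count, trip$kmer, max)
  mx[as.integer(names(mc))] <- mc
  ge <- global_enrichment(profile)
  prep <- kmer_subset_prep(profile, min_events)
  B <- X <- rep(NA_real_, K)
  if (length(prep$kmer_ids) > 0L) {
    X[prep$kmer_ids] <- cpp_subset_spearman(prep$idx_count,
                                            prep$ranks_count, residuals)
    B[prep$kmer_ids] <- cpp_subset_spearman(prep$idx_enrich,
                                            prep$ranks_enrich, residuals)
  }
  data.frame(kmer = profile$kmers, side = profile$side,
             total_count = unname(total), n_events = unname(nev),
             max_count = unname(mx), global_enrichment = unname(ge),
             bias = B, character = X,
             eligible = unname(nev >= min_events & mx > 1L),
             stringsAsFactors = FALSE)
}

align_residuals <- function(profile, residuals) {
  if (!is.null(names(residuals))) {
    if (!all(profile$event_ids %in% names(residuals)))
      stop("residuals missing for some profile events")
    residuals <- residuals[profile$event_ids]
  } else if (length(residuals) != length(profile$event_ids)) {
    stop("residuals length does not match profile events")
  }
  unname(residuals)
}

#' Meta-correlation of ISE/ISS character with enrichment bias
#'
#' Spearman correlation, across eligible k-mers, of the character `X`
#' (count vs residual PSI) with the enrichment bias `B` (conservation
#' enrichment vs residual PSI).  A positive value means ISEs tend to be
#' conserved near high-PSI exons and ISSs near low-PSI exons.
#'
#' @param records output of [kmer_records()].
#' @return list with `rho`, `n` (k-mers used), `defined` (FALSE when
#'   fewer than 10 eligible k-mers have both statistics).
#' @export
meta_correlation <- function(records) {
  sel <- records$eligible & is.finite(records$bias) & is.finite(records$character)
  if (sum(sel) < 10L)
    return(list(rho = NA_real_, n = sum(sel), defined = FALSE))
  list(rho = spearman_rho(records$character[sel], records$bias[sel]),
       n = sum(sel), defined = TRUE)
}

#' Permutation test of the meta-correlation
#'
#' Permutes tissue-averaged PSI across exons, recomputes residual PSI
#' through the composition-regression model inside each permutation, then
#' recomputes character, bias and their meta-correlation.  The p-value is
#' the fraction of permutations whose |meta-correlation| exceeds the
#' observed one.
#'
#' @param profile `kmer_profile`.
#' @param psi_average named tissue-averaged PSI vector.
#' @param model `residual_model` (from [residual_psi()]`$model`) fit on
#'   the same events.
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param seed seed for the permutation stream.
#' @param min_events eligibility threshold (default 100).
#' @return list with `p`, `rho_obs`, `rho_perm` (vector), `n_kmers`.
#' @export
permutation_test <- function(profile, psi_average, model, n_perm = 1000L,
                             seed = 1L, min_events = 100L) {
  stopifnot(inherits(profile, "kmer_profile"),
            inherits(model, "residual_model"))
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse p-value")
  y <- psi_average[profile$event_ids]
  if (any(is.na(y))) stop("psi_average missing for some profile events")
  prep <- kmer_subset_prep(profile, min_events)
  meta_of <- function(res) {
    X <- cpp_subset_spearman(prep$idx_count, prep$ranks_count, res)
    B <- cpp_subset_spearman(prep$idx_enrich, prep$ranks_enrich, res)
    spearman_rho(X, B)
  }
  r_obs <- unname(model$resid_fun(unname(y)))
  rho_obs <- meta_of(r_obs)
  if (is.na(rho_obs)) stop("observed meta-correlation undefined")
  set.seed(seed)
  rho_perm <- vapply(seq_len(n_perm), function(i) {
    yp <- sample(unname(y))
    meta_of(unname(model$resid_fun(yp)))
  }, 0)
  p <- sum(abs(rho_perm) > abs(rho_obs), na.rm = TRUE) / n_perm
  list(p = p, rho_obs = rho_obs, rho_perm = rho_perm,
       n_kmers = length(prep$kmer_ids))
}

#' Total count versus global conservation enrichment
#'
#' Per-k-mer scatter of total occurrence count against global conservation
#' enrichment, with the overall Spearman correlation (over k-mers with a
#' defined enrichment) and the standard deviation of counts across all
#' k-mers.
#'
#' @param profile `kmer_profile`.
#' @return list with `table` (data.frame `kmer`, `total_count`,
#'   `global_enrichment`), `rho`, `count_sd`.
#' @export
count_vs_enrichment <- function(profile) {
  ge <- global_enrichment(profile)
  total <- setNames(rep(0, length(profile$kmers)), profile$kmers)
  tc <- tapply(profile$trip$count, profile$trip$kmer, sum)
  total[as.integer(names(tc))] <- tc
  tab <- data.frame(kmer = profile$kmers, total_count = unname(total),
                    global_enrichment = unname(ge), stringsAsFactors = FALSE)
  list(table = tab,
       rho = spearman_rho(tab$total_count, tab$global_enrichment),
       count_sd = sd(tab$total_count))
}

#' Conservation-weighted k-mer counts
#'
#' Each k-mer instance contributes the minimum conservation over its k
#' bases (so non-functional instances partially overlapping functional
#' ones are down-weighted); the per-event weighted count is the sum over
#' instances.  Instances containing a base with no defined conservation
#' are dropped under the `"drop"` missing policy.
#'
#' @param profile `kmer_profile`.
#' @param kmer_set character vector of k-mers (columns of the result).
#' @return dense numeric matrix, events x k-mers.
#' @export
conservation_weighted_counts <- function(profile, kmer_set) {
  stopifnot(inherits(profile, "kmer_profile"))
  ki <- match(kmer_set, profile$kmers)
  if (any(is.na(ki))) stop("unknown k-mer in kmer_set")
  out <- matrix(0, length(profile$event_ids), length(kmer_set),
                dimnames = list(profile$event_ids, kmer_set))
  tr <- profile$trip[profile$trip$kmer %in% ki, , drop = FALSE]
  if (nrow(tr) > 0L)
    out[cbind(tr$event, match(tr$kmer, ki))] <- tr$wcount
  out
}

# Conservation scores of every region base covered by an instance of any
# k-mer in `kmer_set` (union across the set, each base once per event),
# over the given events.
pooled_base_scores <- function(profile, kmer_set, event_ids = NULL) {
  stopifnot(inherits(profile, "kmer_profile"))
  ki <- match(kmer_set, profile$kmers)
  if (any(is.na(ki))) stop("unknown k-mer in kmer_set")
  rows <- if (is.null(event_ids)) seq_along(profile$event_ids)
          else match(event_ids, profile$event_ids)
  rows <- rows[!is.na(rows)]
  k <- profile$k
  L <- ncol(profile$cons)
  W <- L - k + 1L
  codes_id <- window_id_matrix(profile)
  vals <- vector("list", length(rows))
  set <- rep(FALSE, length(profile$kmers))
  set[ki] <- TRUE
  for (j in seq_along(rows)) {
    e <- rows[j]
    w <- which(set[codes_id[e, ]])
    if (length(w) == 0L) next
    mask <- rep(FALSE, L)
    for (t in 0:(k - 1L)) mask[w + t] <- TRUE
    v <- profile$cons[e, mask]
    vals[[j]] <- v[!is.na(v)]
  }
  unlist(vals, use.names = FALSE)
}

# events x windows matrix of k-mer ids (NA where the window is invalid),
# cached on the profile's environment-free list via attribute.
window_id_matrix <- function(profile) {
  cached <- attr(profile, "window_ids")
  if (!is.null(cached)) return(cached)
  k <- profile$k
  L <- nchar(profile$regions[1L])
  chars <- matrix(unlist(strsplit(profile$regions, ""), use.names = FALSE),
                  nrow = length(profile$regions), ncol = L, byrow = TRUE)
  codes <- matrix(match(chars, c("A", "C", "G", "T")) - 1L,
                  nrow = nrow(chars), ncol = L)
  W <- L - k + 1L
  id <- matrix(0L, nrow(codes), W)
  ok <- matrix(TRUE, nrow(codes), W)
  for (t in 0:(k - 1L)) {
    blk <- codes[, (1L + t):(W + t), drop = FALSE]
    ok <- ok & !is.na(blk)
    blk[is.na(blk)] <- 0L
    id <- id * 4L + blk
  }
  id <- id + 1L
  id[!ok] <- NA_integer_
  id
}

#' Pooled ISE-versus-ISS conservation comparison
#'
#' Pools the conservation scores of every region base covered by any ISS
#' instance, and separately by any ISE instance, over a subset of events,
#' and compares the two distributions with a two-sided Mann-Whitney test.
#'
#' @param profile `kmer_profile`.
#' @param ise_kmers,iss_kmers character vectors of called ISE and ISS
#'   k-mers.
#' @param event_ids optional subset of events (default: all).
#' @return list with `median_iss`, `median_ise`, `diff`
#'   (`median_iss - median_ise`), `larger` (`"ISS"`, `"ISE"` or `"tie"`),
#'   `p`, `n_iss`, `n_ise`, `defined`.
#' @export
ise_iss_conservation_comparison <- function(profile, ise_kmers, iss_kmers,
                                            event_ids = NULL) {
  if (length(ise_kmers) == 0L || length(iss_kmers) == 0L)
    return(list(median_iss = NA_real_, median_ise = NA_real_,
                diff = NA_real_, larger = NA_character_, p = NA_real_,
                n_iss = 0L, n_ise = 0L, defined = FALSE))
  iss_v <- pooled_base_scores(profile, iss_kmers, event_ids)
  ise_v <- pooled_base_scores(profile, ise_kmers, event_ids)
  if (length(iss_v) == 0L || length(ise_v) == 0L)
    return(list(median_iss = NA_real_, median_ise = NA_real_,
                diff = NA_real_, larger = NA_character_, p = NA_real_,
                n_iss = length(iss_v), n_ise = length(ise_v),
                defined = FALSE))
  r <- rank(c(iss_v, ise_v))
  mean_iss <- mean(r[seq_along(iss_v)])
  mean_ise <- mean(r[-seq_along(iss_v)])
  p <- if (length(unique(c(iss_v, ise_v))) == 1L) 1 else
    suppressWarnings(stats::wilcox.test(iss_v, ise_v, exact = FALSE))$p.value
  list(median_iss = median(iss_v), median_ise = median(ise_v),
       diff = median(iss_v) - median(ise_v),
       larger = if (mean_iss > mean_ise) "ISS"
                else if (mean_iss < mean_ise) "ISE" else "tie",
       p = p, n_iss = length(iss_v), n_ise = length(ise_v),
       defined = TRUE)
}
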