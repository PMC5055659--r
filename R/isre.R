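## Discovery of intronic splicing regulatory elements (ISEs/ISSs):
## composition regression -> residual PSI, presence/absence Mann-Whitney
## tests with BH FDR control, ISRE-count predictors, and set-overlap
## arithmetic against reference k-mer catalogues.

#' Mono- and di-nucleotide composition of region sequences
#'
#' Returns, per sequence, the 4 mononucleotide frequencies and the 16
#' overlapping-dinucleotide frequencies (denominator `L - 1`).
#'
#' @param regions character vector of ACGT sequences (names = event ids).
#' @param non_acgt `"error"` (default) or `"skip"`: skip drops non-ACGT
#'   bases/windows from the denominators.
#' @return numeric matrix, rows = events, 20 columns (`A`,`C`,`G`,`T`,
#'   `AA`..`TT`).
#' @export
composition_features <- function(regions, non_acgt = c("error", "skip")) {
  non_acgt <- match.arg(non_acgt)
  if (any(nchar(regions) < 2L)) stop("regions must have length >= 2")
  if (non_acgt == "error" && any(grepl("[^ACGT]", regions)))
    stop("non-ACGT base in region sequence (use non_acgt='skip' to drop)")
  dss <- Biostrings::DNAStringSet(regions)
  mono <- Biostrings::oligonucleotideFrequency(dss, width = 1L)
  di <- Biostrings::oligonucleotideFrequency(dss, width = 2L)
  mono_n <- rowSums(mono); di_n <- rowSums(di)
  if (any(mono_n == 0L) || any(di_n == 0L))
    stop("no usable bases/dinucleotides in some region")
  out <- cbind(mono / mono_n, di / di_n)
  rownames(out) <- names(regions)
  out
}

# Composition regression machinery.  One reference column per frequency
# block is dropped (each block sums to 1, so keeping all would make the
# design collinear with the intercept).
residual_model <- function(comp_up, comp_dn,
                           sides = c("both", "upstream", "downstream"),
                           ridge_lambda = 1e-6) {
  sides <- match.arg(sides)
  drop_ref <- function(m, suffix) {
    m <- m[, setdiff(colnames(m), c("T", "TT")), drop = FALSE]
    colnames(m) <- paste0(colnames(m), suffix)
    m
  }
  X <- switch(sides,
    both = cbind(drop_ref(comp_up, "_up"), drop_ref(comp_dn, "_down")),
    upstream = drop_ref(comp_up, "_up"),
    downstream = drop_ref(comp_dn, "_down"))
  if (nrow(X) < ncol(X) + 2L)
    stop("need at least ", ncol(X) + 2L, " events for the composition regression")
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_obj <- qr(Xi)
  if (qr_obj$rank < ncol(Xi)) {
    message("rank-deficient composition design; ridge fallback with lambda = ",
            ridge_lambda)
    XtX <- crossprod(Xi) + diag(ridge_lambda, ncol(Xi))
    H <- Xi %*% solve(XtX, t(Xi))
    resid_fun <- function(y) as.vector(y - H %*% y)
  } else {
    resid_fun <- function(y) qr.resid(qr_obj, y)
  }
  structure(list(X = Xi, resid_fun = resid_fun,
                 rank_deficient = qr_obj$rank < ncol(Xi)),
            class = "residual_model")
}

#' Residual PSI after composition regression
#'
#' Fits an ordinary least-squares regression (with intercept) of
#' tissue-averaged PSI on the mono- and di-nucleotide frequencies of the
#' 15-100 bp regions (both sides jointly by default; 40 features) and
#' returns the residuals -- the component of PSI not attributable to
#' sequence composition.  A rank-deficient design falls back to a ridge
#' fit with a logged lambda.
#'
#' @param psi_average named numeric vector of tissue-averaged PSI.
#' @param comp_up,comp_dn composition matrices from
#'   [composition_features()], rows aligned with `psi_average`.
#' @param sides fit on both sides' features jointly (default) or one side.
#' @return list with `residuals` (named vector) and `model` (reusable for
#'   recomputing residuals of permuted PSI).
#' @export
residual_psi <- function(psi_average, comp_up, comp_dn = NULL,
                         sides = c("both", "upstream", "downstream")) {
  sides <- match.arg(sides)
  if (sides == "both" && is.null(comp_dn))
    stop("comp_dn required when sides='both'")
  model <- residual_model(comp_up, comp_dn, sides)
  if (nrow(model$X) != length(psi_average))
    stop("psi_average length does not match composition rows")
  r <- model$resid_fun(psi_average)
  names(r) <- names(psi_average)
  list(residuals = r, model = model)
}

# Vectorised two-sided Mann-Whitney tests of a response against the
# presence/absence columns of a logical matrix.  Normal approximation with
# tie correction and continuity correction; exact agreement of U with pair
# enumeration is guaranteed by the rank formulation.
mw_presence_test <- function(presence, response) {
  n <- length(response)
  stopifnot(nrow(presence) == n)
  g <- rank(response)
  n1 <- Matrix::colSums(presence)
  n2 <- n - n1
  S1 <- as.vector(Matrix::crossprod(presence, g))
  U1 <- S1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_tab <- table(g)
  tie_sum <- sum(tie_tab^3 - tie_tab)
  varU <- (n1 * n2 / 12) * ((n + 1) - tie_sum / (n * (n - 1)))
  z <- rep(NA_real_, length(U1))
  ok <- n1 > 0 & n2 > 0 & varU > 0
  cc <- pmin(abs(U1 - mu), 0.5)            # continuity correction
  z[ok] <- ((abs(U1 - mu) - cc) / sqrt(varU))[ok]
  p <- 2 * pnorm(-z)
  p[ok & p > 1] <- 1
  p[n1 > 0 & n2 > 0 & varU == 0] <- 1      # all responses tied
  list(U = U1, p = p, n1 = n1, n2 = n2, mu = mu)
}

#' Discover ISE/ISS k-mers from residual PSI
#'
#' For every k-mer, compares residual PSI between events containing the
#' k-mer (count >= 1 in the 15-100 bp region) and events not containing
#' it with a two-sided Mann-Whitney test, applies Benjamini-Hochberg
#' correction over the full k-mer universe, and labels significant k-mers
#' ISE (rank sums higher in containing events) or ISS (lower).
#'
#' @param counts events x k-mers count matrix (dense or `Matrix` sparse;
#'   colnames = k-mer strings), occurrences counted with overlaps allowed.
#' @param residuals numeric residual-PSI vector aligned with rows.
#' @param q_threshold FDR threshold (default 0.05).
#' @return data.frame `kmer`, `n_with`, `n_without`, `U`, `p`, `q`,
#'   `label` (`ISE`/`ISS`/`none`), `median_with`, `median_without`
#'   (complement median, materialised for called k-mers), `reason` (why
#'   untestable k-mers were not called).
#' @export
discover_isres <- function(counts, residuals, q_threshold = 0.05) {
  if (nrow(counts) != length(residuals))
    stop("counts rows must align with residuals")
  presence <- counts > 0
  if (!methods::is(presence, "Matrix")) presence <- as.matrix(presence) * 1
  mw <- mw_presence_test(presence, residuals)
  K <- ncol(counts)
  q <- p.adjust(mw$p, method = "BH", n = K)
  pw <- Matrix::which(presence > 0, arr.ind = TRUE)
  med_with <- rep(NA_real_, K)
  mt <- tapply(residuals[pw[, 1L]], pw[, 2L], median)
  med_with[as.integer(names(mt))] <- mt
  label <- rep("none", K)
  reason <- rep("", K)
  degenerate <- mw$n1 == 0 | mw$n2 == 0
  reason[mw$n1 == 0] <- "absent from all events"
  reason[mw$n2 == 0] <- "present in all events"
  sig <- !degenerate & !is.na(q) & q < q_threshold
  label[sig & mw$U > mw$mu] <- "ISE"
  label[sig & mw$U < mw$mu] <- "ISS"
  # complement medians are only materialised for the called k-mers (the
  # full complement scan over every k-mer would dominate the runtime)
  med_without <- rep(NA_real_, K)
  for (k in which(sig)) {
    med_without[k] <- median(residuals[presence[, k] == 0])
  }
  data.frame(kmer = colnames(counts), n_with = mw$n1, n_without = mw$n2,
             U = mw$U, p = mw$p, q = q, label = label,
             median_with = med_with, median_without = med_without,
             reason = reason, stringsAsFactors = FALSE, row.names = NULL)
}

#' Out-of-fold AUC of an ISRE-count predictor
#'
#' Validates discovered ISREs by using only their counts as features for
#' high/low PSI classification.  To avoid selection bias, ISRE discovery
#' (composition regression, Mann-Whitney tests, FDR) is re-run inside each
#' training fold on the training exons only.
#'
#' @param counts_up,counts_dn events x k-mers count matrices for the two
#'   sides (rownames = event ids).
#' @param comp_up,comp_dn composition matrices (same rows).
#' @param psi_average named tissue-averaged PSI vector.
#' @param labeled output of [label_and_filter()].
#' @param nmd optional data.frame `event_id` plus binary NMD translatability
#'   columns appended to the feature set.
#' @param n_folds,seed fold control (grouped by exon).
#' @param q_threshold FDR threshold for within-fold discovery.
#' @param lambda ridge penalty of the logistic fit.
#' @return list with `auc`, `scores`, `n_isres` (per-fold discovered
#'   counts), `skipped_folds`.
#' @export
isre_predictor <- function(counts_up, counts_dn, comp_up, comp_dn,
                           psi_average, labeled, nmd = NULL,
                           n_folds = 5L, seed = 1L, q_threshold = 0.05,
                           lambda = 1e-4) {
  ids <- rownames(counts_up)
  stopifnot(!is.null(ids), identical(ids, rownames(counts_dn)))
  folds <- make_folds(ids, n_folds, seed)
  train_rows <- labeled[labeled$confident & labeled$class != "medium" &
                          labeled$event_id %in% ids, , drop = FALSE]
  scored <- NULL
  n_isres <- integer(0)
  skipped <- integer(0)
  for (f in seq_len(n_folds)) {
    tr_ids <- ids[folds[ids] != f]
    te_ids <- ids[folds[ids] == f]
    rp <- residual_psi(psi_average[tr_ids],
                       comp_up[tr_ids, , drop = FALSE],
                       comp_dn[tr_ids, , drop = FALSE])
    calls_up <- discover_isres(counts_up[tr_ids, , drop = FALSE],
                               rp$residuals, q_threshold)
    calls_dn <- discover_isres(counts_dn[tr_ids, , drop = FALSE],
                               rp$residuals, q_threshold)
    sel_up <- calls_up$kmer[calls_up$label != "none"]
    sel_dn <- calls_dn$kmer[calls_dn$label != "none"]
    n_isres <- c(n_isres, length(sel_up) + length(sel_dn))
    if (length(sel_up) + length(sel_dn) == 0L) {
      skipped <- c(skipped, f)
      next
    }
    feat <- cbind(as.matrix(counts_up[, sel_up, drop = FALSE]),
                  as.matrix(counts_dn[, sel_dn, drop = FALSE]))
    colnames(feat) <- c(if (length(sel_up)) paste0("up_", sel_up),
                        if (length(sel_dn)) paste0("down_", sel_dn))
    rownames(feat) <- ids
    if (!is.null(nmd)) {
      nm <- as.matrix(nmd[match(ids, nmd$event_id),
                          setdiff(names(nmd), "event_id"), drop = FALSE])
      rownames(nm) <- ids
      feat <- cbind(feat, nm)
    }
    tr <- train_rows[train_rows$event_id %in% tr_ids, , drop = FALSE]
    y <- as.integer(tr$class == "high")
    if (length(unique(y)) < 2L) stop("single-class training fold ", f)
    Xtr <- feat[tr$event_id, , drop = FALSE]
    if (ncol(Xtr) == 1L) { Xtr <- cbind(Xtr, Xtr); feat <- cbind(feat, feat) }
    fit <- glmnet::glmnet(Xtr, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = TRUE)
    te_rows <- labeled[labeled$event_id %in% te_ids, c("event_id", "tissue")]
    te_rows$score <- as.vector(predict(
      fit, feat[te_rows$event_id, , drop = FALSE], type = "response"))
    scored <- rbind(scored, te_rows)
  }
  if (is.null(scored))
    return(list(auc = NA_real_, scores = NULL, n_isres = n_isres,
                skipped_folds = skipped))
  key <- paste(labeled$event_id, labeled$tissue)
  m <- match(paste(scored$event_id, scored$tissue), key)
  ev <- labeled[m, , drop = FALSE]
  keep <- ev$confident & ev$class != "medium"
  list(auc = auc(scored$score[keep], ev$class[keep] == "high"),
       scores = scored, n_isres = n_isres, skipped_folds = skipped)
}

#' Expected overlap of two random k-mer sets
#'
#' If two sets of sizes `n_a` and `n_b` are drawn independently at random
#' from a universe of `universe` k-mers, the expected intersection size is
#' `n_a * n_b / universe`.
#'
#' @param n_set_a,n_set_b set sizes.
#' @param universe universe size (default `4^6 = 4096`).
#' @return expected overlap count.
#' @export
overlap_expectation <- function(n_set_a, n_set_b, universe = 4096) {
  if (n_set_a < 0 || n_set_b < 0 || universe <= 0)
    stop("set sizes must be non-negative and universe positive")
  if (n_set_a > universe || n_set_b > universe)
    stop("set size exceeds universe")
  n_set_a * n_set_b / universe
}

#' Match ISRE calls against a reference 6-mer catalogue
#'
#' @param isre_kmers character vector of called ISRE 6-mers.
#' @param catalogue character vector of reference 6-mers (e.g. known RBP
#'   binding sites).
#' @return list with `matched` (intersection size), `expected` (random
#'   overlap expectation), `kmers` (the matching 6-mers).
#' @export
match_reference_catalogue <- function(isre_kmers, catalogue) {
  catalogue <- unique(catalogue)
  if (any(nchar(catalogue) != 6L))
    stop("catalogue entries must be 6-mers")
  isre_kmers <- unique(isre_kmers)
  hit <- intersect(isre_kmers, catalogue)
  list(matched = length(hit),
       expected = overlap_expectation(length(isre_kmers), length(catalogue)),
       kmers = hit)
}

#' Score ISRE discovery against planted ground truth
#'
#' Compares the called ISE/ISS sets with the planted motifs of a
#' simulation.  With `match = "shift1"` (the usual convention for scoring
#' motif discovery), a called 6-mer counts as a correct recovery when it
#' matches a planted 6-mer of consistent label either exactly or at a
#' single-base shift (5 of 6 bases aligned): single-shift neighbours of a
#' planted motif co-occur with it by construction, so a presence/absence
#' test cannot distinguish them from the motif itself.  `match = "exact"`
#' scores strict set identity.
#'
#' @param calls output of [discover_isres()].
#' @param planted_ise,planted_iss character vectors of planted 6-mers for
#'   this side.
#' @param match `"shift1"` (default) or `"exact"`.
#' @return list with `recall` (fraction of planted k-mers called exactly,
#'   with the correct label), `precision` (fraction of calls that are
#'   correct recoveries under `match`), `n_called`, `tp`, `fp`.
#' @export
score_isre_recovery <- function(calls, planted_ise, planted_iss,
                                match = c("shift1", "exact")) {
  match <- match.arg(match)
  called <- calls[calls$label != "none", , drop = FALSE]
  matches <- function(k, p) {
    k == p || (match == "shift1" &&
               (substr(k, 2L, 6L) == substr(p, 1L, 5L) ||
                substr(k, 1L, 5L) == substr(p, 2L, 6L)))
  }
  match_any <- function(kmers, planted) {
    if (length(planted) == 0L) return(rep(FALSE, length(kmers)))
    vapply(kmers, function(k)
      any(vapply(planted, function(p) matches(k, p), TRUE)), TRUE,
      USE.NAMES = FALSE)
  }
  ok <- (match_any(called$kmer, planted_ise) & called$label == "ISE") |
        (match_any(called$kmer, planted_iss) & called$label == "ISS")
  planted <- c(planted_ise, planted_iss)
  lab <- c(rep("ISE", length(planted_ise)), rep("ISS", length(planted_iss)))
  hit <- vapply(seq_along(planted), function(i)
    any(called$kmer == planted[i] & called$label == lab[i]), TRUE)
  list(recall = if (length(planted)) mean(hit) else NA_real_,
       precision = if (nrow(called)) mean(ok) else NA_real_,
       n_called = nrow(called), tp = sum(ok), fp = sum(!ok))
}

#' Read a k-mer catalogue file
#'
#' Plain text, one 6-mer per line; blank lines and `#` comments ignored.
#'
#' @param path input file.
#' @return character vector of 6-mers.
#' @export
read_catalogue <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (any(nchar(x) != 6L)) stop("catalogue entries must be 6-mers")
  toupper(x)
}
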