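## Labelling, the Junc/Avg inclusion predictor and its ablations, and the
## three evaluation protocols: pooled AUC over high/low PSI classes,
## Spearman correlation on intermediate-PSI events, and delta-PSI Spearman
## over tissue pairs.

#' Label and confidence-filter PSI measurements
#'
#' Expands a PSI table into one row per (event, tissue) measurement with an
#' inclusion class -- low (PSI < 1/3), medium, high (PSI > 2/3) -- and a
#' confidence flag (sigma <= 0.1).  Medium-class entries are excluded from
#' AUC computations downstream; low-confidence entries are pruned from
#' model training and evaluation.
#'
#' @param pt `psi_table`.
#' @param sigma_max confidence threshold on the measurement standard
#'   deviation (default 0.1).
#' @param psi_low,psi_high class cutpoints (defaults 1/3 and 2/3).
#' @return data.frame with columns `event_id`, `tissue`, `psi`, `sigma`,
#'   `class`, `confident`.
#' @export
label_and_filter <- function(pt, sigma_max = 0.1, psi_low = 1/3, psi_high = 2/3) {
  stopifnot(inherits(pt, "psi_table"))
  out <- data.frame(
    event_id = rep(pt$event_id, times = length(pt$tissues)),
    tissue = rep(pt$tissues, each = length(pt$event_id)),
    psi = as.vector(pt$psi),
    sigma = as.vector(pt$sigma),
    stringsAsFactors = FALSE)
  out$class <- ifelse(out$psi < psi_low, "low",
               ifelse(out$psi > psi_high, "high", "medium"))
  out$confident <- out$sigma <= sigma_max
  out
}

#' Area under the ROC curve via the Mann-Whitney statistic
#'
#' `AUC = U / (n_pos * n_neg)` with tied score pairs contributing 1/2,
#' computed from average ranks.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (logical, or 0/1) marking positives.
#' @return AUC in \[0,1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (any(is.na(scores)) || any(is.na(labels))) stop("NA in scores or labels")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Deterministic exon-grouped fold assignment: all tissues of an exon share
# a fold.  Returns a named integer vector over unique event ids.
make_folds <- function(event_ids, n_folds, seed) {
  ids <- unique(event_ids)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  setNames(sample(rep_len(seq_len(n_folds), length(ids))), ids)
}

#' Cross-validated inclusion scores from a feature table
#'
#' Trains an L2-regularised logistic classifier of high versus low PSI on
#' the confident measurements of the training exons in each fold, and
#' returns out-of-fold scores for every (event, tissue) measurement.
#' Cross-validation is grouped by exon: all tissues of one exon share a
#' fold, so no exon contributes to both training and scoring.
#'
#' @param features data.frame with `event_id` plus numeric feature columns
#'   (one row per event).
#' @param labeled output of [label_and_filter()].
#' @param n_folds number of folds (default 5).
#' @param seed seed controlling the fold assignment.
#' @param lambda ridge penalty of the logistic fit (default 1e-4).
#' @return data.frame `event_id`, `tissue`, `score` with out-of-fold scores
#'   in \[0,1\] for every measurement (all classes; training used only
#'   confident high/low rows).
#' @export
fit_predict <- function(features, labeled, n_folds = 5L, seed = 1L,
                        lambda = 1e-4) {
  fcols <- setdiff(names(features), "event_id")
  if (length(fcols) == 0L) stop("no feature columns")
  X_all <- as.matrix(features[fcols])
  if (any(!is.finite(X_all))) {
    bad <- features$event_id[which(rowSums(!is.finite(X_all)) > 0)]
    stop("non-finite features for events: ",
         paste(head(bad, 5L), collapse = ", "))
  }
  rownames(X_all) <- features$event_id
  train <- labeled[labeled$confident & labeled$class != "medium", , drop = FALSE]
  train <- train[train$event_id %in% features$event_id, , drop = FALSE]
  folds <- make_folds(features$event_id, n_folds, seed)
  out <- labeled[labeled$event_id %in% features$event_id,
                 c("event_id", "tissue"), drop = FALSE]
  out$score <- NA_real_
  for (f in seq_len(n_folds)) {
    tr <- train[folds[train$event_id] != f, , drop = FALSE]
    y <- as.integer(tr$class == "high")
    if (length(unique(y)) < 2L)
      stop("single-class training fold ", f)
    Xtr <- X_all[tr$event_id, , drop = FALSE]
    te_ids <- names(folds)[folds == f]
    sel <- out$event_id %in% te_ids
    if (ncol(X_all) == 1L) {
      # glmnet needs >= 2 columns; duplicate and halve the penalty effect
      fit <- glmnet::glmnet(cbind(Xtr, Xtr), y, family = "binomial",
                            alpha = 0, lambda = lambda, standardize = TRUE)
      out$score[sel] <- as.vector(predict(
        fit, cbind(X_all[out$event_id[sel], , drop = FALSE],
                   X_all[out$event_id[sel], , drop = FALSE]),
        type = "response"))
    } else {
      fit <- glmnet::glmnet(Xtr, y, family = "binomial", alpha = 0,
                            lambda = lambda, standardize = TRUE)
      out$score[sel] <- as.vector(predict(
        fit, X_all[out$event_id[sel], , drop = FALSE], type = "response"))
    }
  }
  out
}

#' Pooled out-of-fold AUC of a feature set
#'
#' Convenience wrapper: cross-validated scores from [fit_predict()], then
#' AUC over all confident high/low (event, tissue) measurements pooled
#' across tissues.
#'
#' @inheritParams fit_predict
#' @return list with `auc` and the scored data.frame.
#' @export
evaluate_predictor <- function(features, labeled, n_folds = 5L, seed = 1L,
                               lambda = 1e-4) {
  scored <- fit_predict(features, labeled, n_folds = n_folds, seed = seed,
                        lambda = lambda)
  key <- paste(labeled$event_id, labeled$tissue)
  m <- match(paste(scored$event_id, scored$tissue), key)
  eval_rows <- labeled[m, , drop = FALSE]
  keep <- eval_rows$confident & eval_rows$class != "medium"
  list(auc = auc(scored$score[keep], eval_rows$class[keep] == "high"),
       scores = scored)
}

#' Spearman evaluation on intermediate-PSI events
#'
#' Restricts to events whose tissue-averaged PSI lies at least one full
#' across-tissue standard deviation inside the given range (both
#' `PSI - sigma` and `PSI + sigma` strictly inside), then correlates a
#' per-event score with tissue-averaged PSI on that subset.
#'
#' @param pt `psi_table`.
#' @param scores named numeric vector of per-event scores.
#' @param range numeric length-2 PSI range, a subset of (0, 1).
#' @return list with `rho`, `n` (subset size), and `defined` (FALSE when
#'   fewer than 3 events qualify, in which case `rho` is `NA`).
#' @export
intermediate_psi_eval <- function(pt, scores, range = c(0.1, 0.9)) {
  stopifnot(inherits(pt, "psi_table"), length(range) == 2L)
  pa <- psi_avg(pt)
  s <- psi_sd_across_tissues(pt)
  keep <- (pa - s) > range[1L] & (pa + s) < range[2L]
  ids <- pt$event_id[keep]
  if (length(ids) < 3L)
    return(list(rho = NA_real_, n = length(ids), defined = FALSE))
  list(rho = spearman_rho(scores[ids], pa[ids]), n = length(ids),
       defined = TRUE)
}

#' Delta-PSI evaluation over tissue pairs
#'
#' For every event and unordered tissue pair, computes the true
#' `dPSI = PSI_t1 - PSI_t2` and its standard deviation
#' `sigma(dPSI) = sqrt(sigma_t1^2 + sigma_t2^2)`, drops statistically
#' indistinguishable pairs (`sigma(dPSI) > |dPSI|`), concatenates the
#' survivors over all tissue pairs, and returns the Spearman correlation
#' of the predicted score differences with the true dPSI.
#'
#' @param pt `psi_table`.
#' @param scores data.frame `event_id`, `tissue`, `score` (per-measurement
#'   predictions, e.g. from [fit_predict()]).
#' @return list with `rho`, `n` (surviving pairs), `defined`.
#' @export
delta_psi_eval <- function(pt, scores) {
  stopifnot(inherits(pt, "psi_table"))
  Tn <- length(pt$tissues)
  if (Tn < 2L) stop("delta_psi_eval needs >= 2 tissues")
  smat <- matrix(NA_real_, nrow(pt$psi), Tn, dimnames = dimnames(pt$psi))
  idx <- cbind(match(scores$event_id, pt$event_id),
               match(scores$tissue, pt$tissues))
  smat[idx] <- scores$score
  pairs <- utils::combn(Tn, 2L)
  d_true <- d_pred <- s_d <- NULL
  for (p in seq_len(ncol(pairs))) {
    t1 <- pairs[1L, p]; t2 <- pairs[2L, p]
    d_true <- c(d_true, pt$psi[, t1] - pt$psi[, t2])
    s_d <- c(s_d, sqrt(pt$sigma[, t1]^2 + pt$sigma[, t2]^2))
    d_pred <- c(d_pred, smat[, t1] - smat[, t2])
  }
  keep <- !is.na(d_pred) & s_d <= abs(d_true)
  if (sum(keep) < 3L)
    return(list(rho = NA_real_, n = sum(keep), defined = FALSE))
  list(rho = spearman_rho(d_pred[keep], d_true[keep]), n = sum(keep),
       defined = TRUE)
}

#' Events with substantial tissue differences in inclusion
#'
#' Selects events whose maximum pairwise |dPSI| across confident tissues
#' exceeds a threshold (default 10%).
#'
#' @param pt `psi_table`.
#' @param threshold minimum max cross-tissue |dPSI| (default 0.10).
#' @param sigma_max confidence threshold on sigma (default 0.1).
#' @return character vector of event ids.
#' @export
tissue_differential_subset <- function(pt, threshold = 0.10, sigma_max = 0.1) {
  stopifnot(inherits(pt, "psi_table"))
  conf <- pt$sigma <= sigma_max
  p <- pt$psi
  p[!conf] <- NA_real_
  n_conf <- rowSums(conf)
  spread <- apply(p, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    max(v) - min(v)
  })
  pt$event_id[!is.na(spread) & spread > threshold]
}
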