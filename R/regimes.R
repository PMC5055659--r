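## Conservation-regime classification of cassette exons and the regime-level
## summaries: PSI breakdowns per regime and tissue, the primate-conservation
## contrast, and the Old+ tissue-specificity fraction.

#' Classify exons into conservation regimes
#'
#' Regimes are defined by thresholding junction conservation `J` and 100-bp
#' average conservation `A` at 0.5: `OldMinus` (J high, A low: old exon,
#' few conserved cis elements), `OldPlus` (both high), `New` (both low),
#' and the rare `Other` (J low, A high).  Values exactly at the threshold
#' count as low ("high" means strictly greater).
#'
#' @param J,A numeric vectors in \[0,1\].
#' @param threshold regime threshold (default 0.5).
#' @return character vector of labels.
#' @export
classify_regime <- function(J, A, threshold = 0.5) {
  if (any(!is.finite(J)) || any(!is.finite(A)))
    stop("J and A must be finite")
  if (any(J < 0 | J > 1) || any(A < 0 | A > 1))
    stop("classify_regime expects J and A in [0,1]")
  jh <- J > threshold; ah <- A > threshold
  ifelse(jh & !ah, "OldMinus",
  ifelse(jh & ah, "OldPlus",
  ifelse(!jh & !ah, "New", "Other")))
}

#' Per-regime and per-(regime, tissue) PSI class proportions
#'
#' Among confident measurements, tabulates the proportions of low, medium
#' and high PSI within each regime, per tissue and overall, together with
#' the standard deviation of each proportion across tissues.
#'
#' @param regimes named character vector of per-event regime labels (names
#'   = event ids), e.g. from [classify_regime()] on one side's features.
#' @param labeled output of [label_and_filter()].
#' @return list with `per_tissue` (data.frame regime x tissue x class
#'   proportions), `overall` (per-regime proportions), and `sd_across_tissues`
#'   (per-regime, per-class standard deviation of the tissue proportions).
#' @export
regime_psi_breakdown <- function(regimes, labeled) {
  lab <- labeled[labeled$confident, , drop = FALSE]
  lab$regime <- regimes[lab$event_id]
  lab <- lab[!is.na(lab$regime), , drop = FALSE]
  classes <- c("low", "medium", "high")
  per_tissue <- expand.grid(regime = sort(unique(lab$regime)),
                            tissue = sort(unique(lab$tissue)),
                            stringsAsFactors = FALSE)
  props <- t(mapply(function(rg, ti) {
    v <- lab$class[lab$regime == rg & lab$tissue == ti]
    if (length(v) == 0L) return(c(low = NA_real_, medium = NA_real_, high = NA_real_))
    vapply(classes, function(cl) mean(v == cl), 0)
  }, per_tissue$regime, per_tissue$tissue))
  per_tissue <- cbind(per_tissue, as.data.frame(props))
  overall <- do.call(rbind, lapply(sort(unique(lab$regime)), function(rg) {
    v <- lab$class[lab$regime == rg]
    data.frame(regime = rg, n = length(v),
               low = mean(v == "low"), medium = mean(v == "medium"),
               high = mean(v == "high"), stringsAsFactors = FALSE)
  }))
  sds <- do.call(rbind, lapply(sort(unique(lab$regime)), function(rg) {
    sub <- per_tissue[per_tissue$regime == rg, , drop = FALSE]
    data.frame(regime = rg,
               low = sd(sub$low), medium = sd(sub$medium), high = sd(sub$high),
               stringsAsFactors = FALSE)
  }))
  list(per_tissue = per_tissue, overall = overall, sd_across_tissues = sds)
}

#' PSI by mammalian regime and primate conservation class
#'
#' Splits each mammalian conservation regime by whether the primate 100-bp
#' average conservation of the upstream flanking intron is high (> 0.5),
#' and reports the mean and standard error of tissue-averaged PSI in each
#' of the six cells.
#'
#' @param regimes named character vector of per-event mammalian regime
#'   labels.
#' @param A_primate named numeric vector of primate average conservation.
#' @param psi_average named numeric vector of tissue-averaged PSI.
#' @param threshold primate high/low threshold (default 0.5).
#' @return data.frame `regime`, `primate`, `n`, `mean_psi`, `se` (`se` is
#'   `NA` for cells with < 2 events; empty cells have `n = 0`).
#' @export
primate_breakdown <- function(regimes, A_primate, psi_average, threshold = 0.5) {
  ids <- intersect(names(regimes), intersect(names(A_primate), names(psi_average)))
  grid <- expand.grid(regime = c("OldMinus", "OldPlus", "New"),
                      primate = c("low", "high"), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- ids[regimes[ids] == grid$regime[i] &
               (A_primate[ids] > threshold) == (grid$primate[i] == "high")]
    v <- psi_average[sel]
    data.frame(regime = grid$regime[i], primate = grid$primate[i],
               n = length(v),
               mean_psi = if (length(v)) mean(v) else NA_real_,
               se = if (length(v) >= 2L) sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Fraction of Old+ exons without tissue-specific inclusion
#'
#' Among exons labelled Old+ that have confident measurements in at least
#' half of the tissues, the fraction whose confident measurements are all
#' high (PSI > 2/3) or all low (PSI < 1/3) across every tissue.
#'
#' @param regimes named character vector of per-event regime labels.
#' @param pt `psi_table`.
#' @param sigma_max confidence threshold (default 0.1).
#' @param psi_low,psi_high class cutpoints.
#' @return list with `fraction`, `n_qualifying`, `defined`.
#' @export
tissue_specificity_fraction <- function(regimes, pt, sigma_max = 0.1,
                                        psi_low = 1/3, psi_high = 2/3) {
  stopifnot(inherits(pt, "psi_table"))
  ids <- pt$event_id[regimes[pt$event_id] == "OldPlus"]
  ids <- ids[!is.na(ids)]
  Tn <- length(pt$tissues)
  conf <- pt$sigma[ids, , drop = FALSE] <= sigma_max
  qual <- rowSums(conf) >= Tn / 2
  ids <- ids[qual]
  if (length(ids) == 0L)
    return(list(fraction = NA_real_, n_qualifying = 0L, defined = FALSE))
  p <- pt$psi[ids, , drop = FALSE]
  conf <- conf[qual, , drop = FALSE]
  uniform <- vapply(seq_along(ids), function(i) {
    v <- p[i, conf[i, ]]
    all(v > psi_high) || all(v < psi_low)
  }, TRUE)
  list(fraction = mean(uniform), n_qualifying = length(ids), defined = TRUE)
}
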