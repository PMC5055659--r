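## Junction conservation, windowed average conservation, and the Junc/Avg
## ratio -- the package's central per-event features.

#' Spearman rank correlation
#'
#' Thin wrapper over [stats::cor()] with `method = "spearman"` (average
#' ranks for ties).  Returns `NA` (not 0) when either vector is constant or
#' fewer than 3 complete pairs remain.
#'
#' @param x,y numeric vectors.
#' @return correlation in \[-1,1\], or `NA_real_` when undefined.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Junction conservation
#'
#' The conservation score of the single first intronic base adjacent to the
#' alternative exon's splice site (offset 0) on the given side.
#'
#' @param events validated event data.frame.
#' @param track `cons_track`.
#' @param side `"upstream"` or `"downstream"`.
#' @return numeric vector of scores, one per event.
#' @export
junction_conservation <- function(events, track, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  events <- validate_events(events)
  pos <- vapply(seq_len(nrow(events)), function(i)
    region_positions(events[i, , drop = FALSE], side, 0L, 1L), 0L)
  setNames(track_values(track, events$chrom, pos)[seq_len(nrow(events))],
           events$event_id)
}

#' Average conservation over the first w bp of a flanking intron
#'
#' Arithmetic mean of per-base scores over intronic offsets
#' `[0, min(w, intron_length))`.  Under the `"drop"` missing policy,
#' uncovered bases shrink the denominator; if no usable base remains the
#' average is an error.
#'
#' @inheritParams junction_conservation
#' @param w window size in bp (>= 1).
#' @return numeric vector of means, one per event.
#' @export
average_conservation <- function(events, track, side = c("upstream", "downstream"),
                                 w = 100L) {
  side <- match.arg(side)
  if (w < 1L) stop("w must be >= 1")
  events <- validate_events(events)
  m <- region_cons_matrix(events, track, side, 0L, as.integer(w))
  a <- rowMeans(m, na.rm = TRUE)
  if (any(is.nan(a)))
    stop("undefined average: no usable conserved base for event '",
         events$event_id[which(is.nan(a))[1L]], "'")
  setNames(a, events$event_id)
}

#' Junc/Avg conservation ratio
#'
#' `R = J / max(A, eps)`, with the override `R = 0` whenever `J = 0`.  The
#' epsilon floor keeps the ratio finite when the 100-bp average is (near)
#' zero.
#'
#' @param J junction conservation score(s), >= 0 in bounded01 mode.
#' @param A average conservation score(s), >= 0.
#' @param eps denominator floor (default 1e-3).
#' @return numeric vector of ratios.
#' @export
junc_avg <- function(J, A, eps = 1e-3) {
  if (any(J < 0, na.rm = TRUE) || any(A < 0, na.rm = TRUE))
    stop("junc_avg requires non-negative J and A (bounded01 mode)")
  r <- J / pmax(A, eps)
  r[J == 0] <- 0
  r
}

#' Per-event conservation feature table
#'
#' Computes junction conservation `J`, average conservation `A_w`, and the
#' Junc/Avg ratio `R = J / A_w` for both flanking introns of every event.
#'
#' @inheritParams junction_conservation
#' @param w averaging window in bp (default 100).
#' @param eps epsilon floor passed to [junc_avg()].
#' @return data.frame with columns `event_id`, `J_up`, `A_up`, `R_up`,
#'   `J_down`, `A_down`, `R_down`.
#' @export
cons_features <- function(events, track, w = 100L, eps = 1e-3) {
  events <- validate_events(events)
  J_up <- junction_conservation(events, track, "upstream")
  J_dn <- junction_conservation(events, track, "downstream")
  A_up <- average_conservation(events, track, "upstream", w)
  A_dn <- average_conservation(events, track, "downstream", w)
  data.frame(event_id = events$event_id,
             J_up = unname(J_up), A_up = unname(A_up),
             R_up = unname(junc_avg(J_up, A_up, eps)),
             J_down = unname(J_dn), A_down = unname(A_dn),
             R_down = unname(junc_avg(J_dn, A_dn, eps)),
             stringsAsFactors = FALSE)
}

#' GERP-style 4-feature vectors
#'
#' For unbounded conservation scores the Junc/Avg normalisation is not
#' applicable, so junction and average scores enter a model individually:
#' `(J_up, A100_up, J_down, A100_down)`, unclamped.
#'
#' @param events validated event data.frame.
#' @param track `cons_track` in `"unbounded"` mode.
#' @param w averaging window in bp (default 100).
#' @return data.frame with columns `event_id`, `J_up`, `A_up`, `J_down`,
#'   `A_down`.
#' @export
gerp_features <- function(events, track, w = 100L) {
  if (track$mode != "unbounded")
    stop("gerp_features expects an unbounded-mode track")
  events <- validate_events(events)
  data.frame(event_id = events$event_id,
             J_up = unname(junction_conservation(events, track, "upstream")),
             A_up = unname(average_conservation(events, track, "upstream", w)),
             J_down = unname(junction_conservation(events, track, "downstream")),
             A_down = unname(average_conservation(events, track, "downstream", w)),
             stringsAsFactors = FALSE)
}

#' Window-sweep correlation profile
#'
#' For each averaging window `w = 1..W` and each side, the Spearman
#' correlation across events of the ratio `R_w = J / A_w` with
#' tissue-averaged PSI.  Localises how deep into the flanking intron
#' conservation remains informative about inclusion.
#'
#' @param events validated event data.frame.
#' @param track `cons_track`.
#' @param psi_average named numeric vector of tissue-averaged PSI (names =
#'   event ids), computed before confidence pruning.
#' @param W largest window (default 384).
#' @param eps epsilon floor for the ratio.
#' @return data.frame with columns `side`, `w`, `rho` (rho is `NA` where
#'   the correlation is undefined).
#' @export
window_sweep <- function(events, track, psi_average, W = 384L, eps = 1e-3) {
  events <- validate_events(events)
  if (nrow(events) < 3L) stop("window_sweep needs >= 3 events")
  psi_average <- psi_average[events$event_id]
  if (any(is.na(psi_average))) stop("psi_average missing for some events")
  out <- vector("list", 2L)
  for (si in 1:2) {
    side <- c("upstream", "downstream")[si]
    m <- region_cons_matrix(events, track, side, 0L, as.integer(W))
    if (side == "upstream") m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    # m columns now in increasing-offset order; cumulative NA-aware means
    filled <- !is.na(m)
    m0 <- m; m0[!filled] <- 0
    csum <- t(apply(m0, 1L, cumsum))
    cnt <- t(apply(filled, 1L, cumsum))
    A <- csum / ifelse(cnt > 0L, cnt, NA_real_)
    J <- junction_conservation(events, track, side)
    rho <- vapply(seq_len(ncol(A)), function(wi)
      spearman_rho(junc_avg(J, A[, wi], eps), psi_average), 0)
    out[[si]] <- data.frame(side = side, w = seq_len(ncol(A)), rho = rho,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
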