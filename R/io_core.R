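#' @useDynLib spliceCons, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor coef lm median p.adjust pnorm predict qlogis qnorm
#'   plogis rbeta rbinom rnorm runif sd setNames quantile
#' @importFrom utils read.delim write.table head
NULL

# All genomic coordinates in this package are 0-based between-base boundaries
# (BED convention).  A "base p" occupies the slot [p, p+1).  For a cassette
# event the four boundaries are, in transcription order: C1 donor, A acceptor,
# A donor, C2 acceptor.  On the + strand they are increasing genomic
# positions; on the - strand, decreasing.

EVENT_COLUMNS <- c("event_id", "chrom", "strand",
                   "c1_donor", "a_acceptor", "a_donor", "c2_acceptor")

#' Validate a table of cassette-exon splice events
#'
#' Checks the splice-event invariants: strand is "+" or "-", the four
#' splice-site boundaries are ordered along the direction of transcription,
#' and both flanking introns and the alternative exon have length >= 1.
#'
#' @param events data.frame with columns `event_id`, `chrom`, `strand`,
#'   `c1_donor`, `a_acceptor`, `a_donor`, `c2_acceptor` (0-based boundary
#'   coordinates) and optionally `gene_id`.
#' @return The validated data.frame, invisibly coerced to canonical column
#'   types.
#' @export
validate_events <- function(events) {
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_cols) > 0L)
    stop("event table is missing columns: ", paste(missing_cols, collapse = ", "))
  events$event_id <- as.character(events$event_id)
  events$chrom <- as.character(events$chrom)
  events$strand <- as.character(events$strand)
  coords <- c("c1_donor", "a_acceptor", "a_donor", "c2_acceptor")
  for (cc in coords) {
    v <- suppressWarnings(as.numeric(events[[cc]]))
    bad <- which(is.na(v) | v != floor(v) | v < 0)
    if (length(bad) > 0L)
      stop(sprintf("malformed coordinate in column '%s' at line %d", cc, bad[1L]))
    events[[cc]] <- as.integer(v)
  }
  bad_strand <- which(!events$strand %in% c("+", "-"))
  if (length(bad_strand) > 0L)
    stop(sprintf("invalid strand '%s' at line %d",
                 events$strand[bad_strand[1L]], bad_strand[1L]))
  s <- ifelse(events$strand == "+", 1L, -1L)
  up_len <- s * (events$a_acceptor - events$c1_donor)
  ex_len <- s * (events$a_donor - events$a_acceptor)
  dn_len <- s * (events$c2_acceptor - events$a_donor)
  bad <- which(up_len < 1L | ex_len < 1L | dn_len < 1L)
  if (length(bad) > 0L)
    stop(sprintf(paste0("splice-site ordering violated at line %d: boundaries",
                        " must follow transcription order with intron/exon",
                        " lengths >= 1"), bad[1L]))
  if (anyDuplicated(events$event_id))
    stop("duplicated event_id values")
  events
}

#' Read a cassette-exon event table
#'
#' @param path tab-separated file with a header line and the columns of
#'   [validate_events()].
#' @return data.frame of validated events, input order preserved.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file does not exist: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 7L) stop("event table needs at least 7 columns")
  validate_events(df)
}

#' Write a cassette-exon event table
#'
#' @param events validated event data.frame.
#' @param path output TSV path.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flanking intron lengths of events
#'
#' @param events validated event data.frame.
#' @param side `"upstream"` (between C1 donor and A acceptor) or
#'   `"downstream"` (between A donor and C2 acceptor), in transcription
#'   orientation.
#' @return integer vector of intron lengths in bp.
#' @export
intron_length <- function(events, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  if (side == "upstream") abs(events$a_acceptor - events$c1_donor)
  else abs(events$c2_acceptor - events$a_donor)
}

# Genomic interval [lo, hi) covering intronic offsets [s, e) of one side.
# Offset 0 is the first intronic base adjacent to the alternative exon's
# splice site; offsets increase into the intron (away from the exon).
region_interval <- function(events, side, s, e) {
  if (side == "upstream") {
    anchor <- events$a_acceptor
    outward <- ifelse(events$strand == "+", -1L, 1L)
  } else {
    anchor <- events$a_donor
    outward <- ifelse(events$strand == "+", 1L, -1L)
  }
  lo <- ifelse(outward == 1L, anchor + s, anchor - e)
  hi <- ifelse(outward == 1L, anchor + e, anchor - s)
  data.frame(chrom = events$chrom, lo = lo, hi = hi,
             strand = events$strand, stringsAsFactors = FALSE)
}

# Genomic base positions of the region string, in string (transcription)
# order, for one event.  String index i (0-based) of a window [s, e) maps to
# offset s + i on the downstream side and offset e - 1 - i on the upstream
# side: the upstream intron is transcribed from its far end towards the
# alternative exon, so transcription order runs from large offsets to 0.
region_positions <- function(event, side, s, e) {
  stopifnot(nrow(event) == 1L)
  i <- seq_len(e - s) - 1L
  plus <- event$strand == "+"
  if (side == "downstream") {
    if (plus) event$a_donor + s + i else event$a_donor - 1L - (s + i)
  } else {
    if (plus) event$a_acceptor - e + i else event$a_acceptor + (e - 1L - i)
  }
}

#' Extract intronic region sequences in transcription orientation
#'
#' Pulls, for each event, the intronic bases at offsets `[start_offset,
#' end_offset)` from the alternative exon's splice site on the given side.
#' Bases are returned 5'->3' of the pre-mRNA: minus-strand sequences are
#' reverse-complemented, and upstream-side strings run from the most distal
#' requested offset down to the most proximal one.
#'
#' @param events validated event data.frame.
#' @param genome named `Biostrings::DNAStringSet` (or named character vector)
#'   of chromosome sequences.
#' @param side `"upstream"` or `"downstream"`.
#' @param start_offset,end_offset half-open offset window, 0-based; offset 0
#'   is the first intronic base adjacent to the splice site.
#' @return character vector of sequences, names = event_id.
#' @export
extract_region_sequence <- function(events, genome, side = c("upstream", "downstream"),
                                    start_offset = 15L, end_offset = 101L) {
  side <- match.arg(side)
  events <- validate_events(events)
  if (start_offset < 0L || end_offset <= start_offset)
    stop("need 0 <= start_offset < end_offset")
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  ilen <- intron_length(events, side)
  short <- which(ilen < end_offset)
  if (length(short) > 0L)
    stop(sprintf("short intron: event '%s' has %s intron length %d < end_offset %d",
                 events$event_id[short[1L]], side, ilen[short[1L]], end_offset))
  iv <- region_interval(events, side, start_offset, end_offset)
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  if (any(!iv$chrom %in% names(genome)))
    stop("genome is missing chromosome: ",
         iv$chrom[which(!iv$chrom %in% names(genome))[1L]])
  if (any(iv$lo < 0L) || any(iv$hi > chrom_len[iv$chrom]))
    stop("region extends beyond chromosome bounds")
  seqs <- Biostrings::subseq(genome[iv$chrom], start = iv$lo + 1L, end = iv$hi)
  minus <- iv$strand == "-"
  if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  setNames(as.character(seqs), events$event_id)
}

## --- Conservation tracks -----------------------------------------------

#' Construct a per-base conservation track
#'
#' @param scores named list of numeric vectors, one per chromosome; element
#'   `i` is the score of 0-based base `i - 1`; `NA` marks uncovered bases.
#' @param mode `"bounded01"` for phastCons-like probabilities in \[0,1\], or
#'   `"unbounded"` for GERP-like scores.
#' @param missing_policy what a lookup of an uncovered base returns:
#'   `"drop"` (excluded from averages; `NA` from point queries), `"zero"`
#'   (treated as 0), or `"error"`.
#' @return object of class `cons_track`.
#' @export
cons_track <- function(scores, mode = c("bounded01", "unbounded"),
                       missing_policy = c("drop", "zero", "error")) {
  mode <- match.arg(mode)
  missing_policy <- match.arg(missing_policy)
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("scores must be a named list of per-chromosome vectors")
  if (mode == "bounded01") {
    rng <- range(unlist(lapply(scores, range, na.rm = TRUE), use.names = FALSE))
    if (rng[1L] < 0 || rng[2L] > 1)
      stop("bounded01 track has scores outside [0,1]")
  }
  structure(list(scores = scores, mode = mode, missing_policy = missing_policy),
            class = "cons_track")
}

#' @exportS3Method base::print
print.cons_track <- function(x, ...) {
  cov <- sum(vapply(x$scores, function(v) sum(!is.na(v)), 0))
  cat(sprintf("cons_track: %d chromosome(s), %d covered bases, mode=%s, missing=%s\n",
              length(x$scores), cov, x$mode, x$missing_policy))
  invisible(x)
}

#' Read a conservation track from bedGraph
#'
#' Accepts 4-column bedGraph (`chrom start end value`, 0-based half-open,
#' no header) or a 2-column `position value` TSV interpreted as single
#' bases on a chromosome named `chr1`.
#'
#' @param path input file.
#' @inheritParams cons_track
#' @return `cons_track` object.
#' @export
read_track <- function(path, mode = c("bounded01", "unbounded"),
                       missing_policy = c("drop", "zero", "error")) {
  mode <- match.arg(mode)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("track file does not exist: ", path)
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) == 2L) {
    df <- data.frame(chrom = "chr1", start = as.integer(df[[1L]]),
                     end = as.integer(df[[1L]]) + 1L, value = as.numeric(df[[2L]]))
  } else if (ncol(df) >= 4L) {
    df <- data.frame(chrom = as.character(df[[1L]]), start = as.integer(df[[2L]]),
                     end = as.integer(df[[3L]]), value = as.numeric(df[[4L]]))
  } else stop("track file must have 2 (pos, value) or 4 (bedGraph) columns")
  if (any(is.na(df$value)) || any(is.na(df$start)) || any(is.na(df$end)))
    stop("malformed track row")
  if (any(df$end <= df$start)) stop("track interval with end <= start")
  if (mode == "bounded01" && (any(df$value < 0) || any(df$value > 1)))
    stop("bounded01 track has value outside [0,1]")
  scores <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping track intervals on ", ch)
    v <- rep(NA_real_, max(d$end))
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1L):d$end[i]] <- d$value[i]
    scores[[ch]] <- v
  }
  cons_track(scores, mode = mode, missing_policy = missing_policy)
}

#' Write a conservation track as bedGraph
#'
#' Runs of equal scores are collapsed into single intervals; uncovered
#' (`NA`) bases are omitted.
#'
#' @param track `cons_track` object.
#' @param path output path.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "cons_track"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$scores)) {
    v <- track$scores[[ch]]
    r <- rle(ifelse(is.na(v), "NA", format(v, digits = 15L)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != "NA"
    if (!any(keep)) next
    writeLines(paste(ch, starts[keep], ends[keep], r$values[keep], sep = "\t"), con)
  }
  invisible(path)
}

#' Query per-base conservation scores
#'
#' @param track `cons_track` object.
#' @param chrom chromosome name (scalar, or vector parallel to `pos`).
#' @param pos 0-based base positions.
#' @return numeric scores; uncovered bases follow the track's missing
#'   policy (`NA` under `"drop"`, `0` with a `missing` attribute count under
#'   `"zero"`, error under `"error"`).
#' @export
track_values <- function(track, chrom, pos) {
  stopifnot(inherits(track, "cons_track"))
  chrom <- rep_len(as.character(chrom), length(pos))
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    v <- track$scores[[ch]]
    p <- pos[sel]
    ok <- !is.na(p) & p >= 0L & (!is.null(v)) & p < length(v)
    res <- rep(NA_real_, sum(sel))
    if (!is.null(v) && any(ok)) res[ok] <- v[p[ok] + 1L]
    out[sel] <- res
  }
  n_missing <- sum(is.na(out))
  if (n_missing > 0L) {
    if (track$missing_policy == "error")
      stop(n_missing, " uncovered base(s) queried under missing_policy='error'")
    if (track$missing_policy == "zero") {
      out[is.na(out)] <- 0
      attr(out, "missing") <- n_missing
    }
  }
  out
}

# Matrix of conservation scores over intronic offsets [s, e), one row per
# event, columns in *string order* (aligned with extract_region_sequence).
# Offsets beyond the intron length are NA regardless of policy.
region_cons_matrix <- function(events, track, side, s, e) {
  n <- nrow(events)
  L <- e - s
  out <- matrix(NA_real_, nrow = n, ncol = L, dimnames = list(events$event_id, NULL))
  for (i in seq_len(n)) {
    ev <- events[i, , drop = FALSE]
    usable <- min(e, intron_length(ev, side))
    if (usable <= s) next
    pos <- region_positions(ev, side, s, e)
    off <- if (side == "downstream") s + seq_len(L) - 1L else e - seq_len(L)
    keep <- off < usable
    vals <- rep(NA_real_, L)
    vals[keep] <- track_values(track, ev$chrom, pos[keep])
    out[i, ] <- vals
  }
  out
}

## --- PSI tables --------------------------------------------------------

#' Construct a PSI (percent-spliced-in) table
#'
#' Holds per-event, per-tissue inclusion levels and their measurement
#' standard deviations.
#'
#' @param psi numeric matrix, events x tissues, values in \[0,1\];
#'   rownames = event ids, colnames = tissue names.
#' @param sigma numeric matrix of the same shape, per-entry standard
#'   deviation of PSI, values >= 0.
#' @return object of class `psi_table`.
#' @export
psi_table <- function(psi, sigma) {
  psi <- as.matrix(psi); sigma <- as.matrix(sigma)
  if (!identical(dim(psi), dim(sigma)))
    stop("psi and sigma must have identical dimensions")
  if (is.null(rownames(psi)) || is.null(colnames(psi)))
    stop("psi needs event rownames and tissue colnames")
  if (any(is.na(psi)) || any(psi < 0) || any(psi > 1))
    stop("psi values must be in [0,1]")
  if (any(is.na(sigma)) || any(sigma < 0))
    stop("sigma values must be >= 0")
  dimnames(sigma) <- dimnames(psi)
  structure(list(psi = psi, sigma = sigma,
                 event_id = rownames(psi), tissues = colnames(psi)),
            class = "psi_table")
}

#' @exportS3Method base::print
print.psi_table <- function(x, ...) {
  cat(sprintf("psi_table: %d events x %d tissues\n",
              nrow(x$psi), ncol(x$psi)))
  invisible(x)
}

#' Tissue-averaged PSI
#'
#' Mean PSI per event over all tissues, computed on the full table before
#' any confidence pruning.
#'
#' @param pt `psi_table`.
#' @return named numeric vector, one value per event.
#' @export
psi_avg <- function(pt) {
  stopifnot(inherits(pt, "psi_table"))
  rowMeans(pt$psi)
}

#' Across-tissue standard deviation of PSI
#'
#' @param pt `psi_table`.
#' @return named numeric vector: for each event, the standard deviation of
#'   its PSI values across tissues (distinct from per-measurement `sigma`).
#' @export
psi_sd_across_tissues <- function(pt) {
  stopifnot(inherits(pt, "psi_table"))
  apply(pt$psi, 1L, sd)
}

#' Read a PSI table from TSV
#'
#' Expects a header with `event_id` and paired `psi_<tissue>` /
#' `sigma_<tissue>` columns.
#'
#' @param path input TSV.
#' @return `psi_table`.
#' @export
read_psi_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!"event_id" %in% names(df)) stop("psi table needs an event_id column")
  psi_cols <- grep("^psi_", names(df), value = TRUE)
  tissues <- sub("^psi_", "", psi_cols)
  sigma_cols <- paste0("sigma_", tissues)
  if (!all(sigma_cols %in% names(df)))
    stop("missing sigma_<tissue> columns: ",
         paste(setdiff(sigma_cols, names(df)), collapse = ", "))
  psi <- as.matrix(df[psi_cols]); sigma <- as.matrix(df[sigma_cols])
  rownames(psi) <- rownames(sigma) <- df$event_id
  colnames(psi) <- colnames(sigma) <- tissues
  psi_table(psi, sigma)
}

#' Write a PSI table to TSV
#'
#' @param pt `psi_table`.
#' @param path output path.
#' @export
write_psi_table <- function(pt, path) {
  stopifnot(inherits(pt, "psi_table"))
  out <- data.frame(event_id = pt$event_id, stringsAsFactors = FALSE)
  for (t in pt$tissues) {
    out[[paste0("psi_", t)]] <- format(pt$psi[, t], digits = 15L, trim = TRUE)
    out[[paste0("sigma_", t)]] <- format(pt$sigma[, t], digits = 15L, trim = TRUE)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return `Biostrings::DNAStringSet`.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome FASTA
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
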