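# Alternative genetic-code detection: a deterministic six-frame ORF scanner
# run under four stop-codon sets; a genome is called recoded when the coding
# density under a reassigned set exceeds the standard-code density by 10%.

.START_CODONS <- c("ATG", "GTG", "TTG")

.DEFAULT_STOP_MAP <- list(
  "11" = c("TAA", "TAG", "TGA"),
  "15" = c("TAA", "TGA"),   # TAG reassigned
  "90" = c("TAG", "TGA"),   # TAA reassigned
  "91" = c("TAA", "TAG"))   # TGA reassigned

#' Stop codons of a genetic code
#'
#' Code 11 is the standard bacterial code; codes 15, 90 and 91 reassign TAG,
#' TAA and TGA respectively. The mapping is an argument because the
#' literature is not unanimous on which stop codes 90 and 91 reassign.
#'
#' @param code one of 11, 15, 90, 91.
#' @param stop_map named list code -> stop-codon set (default above).
#' @return character vector of stop codons.
#' @export
stopCodons <- function(code, stop_map = .DEFAULT_STOP_MAP) {
  key <- as.character(code)
  if (!key %in% names(stop_map))
    stop("unknown genetic code: ", code)
  stop_map[[key]]
}

# ORFs in one strand orientation of `s` (already reverse-complemented for the
# minus strand); returns codon-index ranges per frame.
.scanFrames <- function(s, stops, min_codons) {
  L <- nchar(s)
  out <- list()
  for (f in 0:2) {
    n_codons <- (L - f) %/% 3L
    if (n_codons < 1L) next
    pos <- f + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(s, pos, pos + 2L)
    start_idx <- which(codons %in% .START_CODONS)
    stop_idx <- which(codons %in% stops)
    if (!length(start_idx)) next
    # segment k runs from after stop k-1 up to (and including) stop k;
    # the ORF of a segment starts at its first start codon
    seg_of_start <- findInterval(start_idx - 0.5, stop_idx) + 1L
    first_start <- tapply(start_idx, seg_of_start, min)
    seg_ids <- as.integer(names(first_start))
    orf_end <- ifelse(seg_ids <= length(stop_idx), stop_idx[seg_ids], n_codons)
    orf_start <- as.integer(first_start)
    keep <- (orf_end - orf_start + 1L) * 3L >= min_codons * 3L
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(frame = f,
                                            start_codon = orf_start[keep],
                                            end_codon = orf_end[keep])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Six-frame ORF scan under a chosen stop-codon set
#'
#' Within each of the six reading frames, an ORF runs from the first start
#' codon (ATG/GTG/TTG) after the previous stop to the next in-frame stop of
#' the active code (inclusive); a trailing ORF without a terminal stop runs
#' to the last complete codon. Codons containing N never match a start or
#' stop. ORFs shorter than `min_orf_nt` are dropped.
#'
#' @param seq DNA sequence (character or `DNAString`) over A/C/G/T/N.
#' @param code genetic code (11, 15, 90, 91).
#' @param min_orf_nt minimum ORF length in nt (>= 3, multiple of 3).
#' @param stop_map optional stop-codon mapping, see [stopCodons()].
#' @return `data.frame` with `strand`, `frame`, `start`, `end` (0-based
#'   half-open on forward coordinates) and `length` (nt).
#' @export
scanOrfs <- function(seq, code = 11, min_orf_nt = 90, stop_map = .DEFAULT_STOP_MAP) {
  seq <- toupper(as.character(seq))
  if (min_orf_nt < 3 || min_orf_nt %% 3 != 0)
    stop("min_orf_nt must be >= 3 and a multiple of 3")
  empty <- data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(), length = integer())
  L <- nchar(seq)
  if (L < 3L) return(empty)
  stops <- stopCodons(code, stop_map)
  min_codons <- min_orf_nt %/% 3L
  res <- list()
  fwd <- .scanFrames(seq, stops, min_codons)
  if (!is.null(fwd)) {
    res[["+"]] <- data.frame(
      strand = "+", frame = fwd$frame,
      start = fwd$frame + (fwd$start_codon - 1L) * 3L,
      end = fwd$frame + fwd$end_codon * 3L)
  }
  rev <- .scanFrames(revComp(seq), stops, min_codons)
  if (!is.null(rev)) {
    res[["-"]] <- data.frame(
      strand = "-", frame = rev$frame,
      start = L - (rev$frame + rev$end_codon * 3L),
      end = L - (rev$frame + (rev$start_codon - 1L) * 3L))
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out$length <- out$end - out$start
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Coding density of a genome given its ORFs
#'
#' The fraction of genome bp covered by the union of ORF intervals over both
#' strands. Positions that are N are excluded from the covered set.
#'
#' @param seq the genome sequence (used for its length and N positions); a
#'   bare integer length is also accepted.
#' @param orfs `data.frame` from [scanOrfs()] (0-based half-open `start`/`end`).
#' @return fraction in `[0, 1]`.
#' @export
codingDensity <- function(seq, orfs) {
  if (is.numeric(seq)) {
    L <- as.integer(seq)
    n_pos <- integer()
  } else {
    seq <- toupper(as.character(seq))
    L <- nchar(seq)
    n_pos <- as.integer(gregexpr("N", seq, fixed = TRUE)[[1L]])
    n_pos <- n_pos[n_pos > 0]
  }
  if (L == 0L || nrow(orfs) == 0L) return(0)
  if (any(orfs$start < 0) || any(orfs$end > L))
    stop("ORFs must lie within the sequence")
  cov <- IRanges::reduce(IRanges::IRanges(start = orfs$start + 1L, end = orfs$end))
  if (length(n_pos))
    cov <- IRanges::setdiff(cov, IRanges::IRanges(start = n_pos, width = 1L))
  sum(IRanges::width(cov)) / L
}

#' Assign a genetic code from per-code coding densities
#'
#' Candidate alternative codes are those whose density exceeds the
#' standard-code density by at least `min_gain` (relative by default: ratio
#' >= 1 + min_gain). The assigned code is the candidate with maximal density,
#' ties broken in code order 15 < 90 < 91; if none qualifies the genome keeps
#' code 11. `gain` is the best relative density increase observed over code
#' 11, whether or not it qualifies.
#'
#' @param densities named numeric vector with entries `"11"`, `"15"`, `"90"`,
#'   `"91"`.
#' @param min_gain decision threshold (default 0.10, i.e. a 10% increase).
#' @param gain_mode `"relative"` (ratio >= 1 + min_gain) or `"absolute"`
#'   (difference >= min_gain in density units).
#' @return list: `assigned_code` (integer), `gain` (best relative increase).
#' @export
assignGeneticCode <- function(densities, min_gain = 0.10,
                              gain_mode = c("relative", "absolute")) {
  gain_mode <- match.arg(gain_mode)
  d11 <- densities[["11"]]
  alt <- c("15", "90", "91")
  alt <- alt[alt %in% names(densities)]
  if (is.na(d11) || d11 <= 0)
    return(list(assigned_code = 11L, gain = 0))
  rel_gain <- vapply(alt, function(k) densities[[k]] / d11 - 1, numeric(1L))
  qualifies <- if (gain_mode == "relative") {
    rel_gain >= min_gain
  } else {
    vapply(alt, function(k) densities[[k]] - d11, numeric(1L)) >= min_gain
  }
  best_gain <- if (length(rel_gain)) max(rel_gain) else 0
  if (!any(qualifies))
    return(list(assigned_code = 11L, gain = best_gain))
  cand <- alt[qualifies]
  dens <- vapply(cand, function(k) densities[[k]], numeric(1L))
  # maximal density wins; ties broken by code order 15 < 90 < 91 (cand is
  # already in that order, and which.max takes the first maximum)
  pick <- cand[which.max(dens)]
  list(assigned_code = as.integer(pick), gain = best_gain)
}

#' Per-genome coding-density profile under codes 11, 15, 90 and 91
#'
#' @param seq DNA sequence.
#' @param min_orf_nt minimum ORF length (nt) for the scanner.
#' @param min_gain,gain_mode decision rule, see [assignGeneticCode()].
#' @param stop_map optional stop-codon mapping.
#' @return list: `densities` (named vector), `assigned_code`, `gain`.
#' @export
codeProfile <- function(seq, min_orf_nt = 90, min_gain = 0.10,
                        gain_mode = "relative", stop_map = .DEFAULT_STOP_MAP) {
  codes <- c("11", "15", "90", "91")
  densities <- vapply(codes, function(k)
    codingDensity(seq, scanOrfs(seq, as.integer(k), min_orf_nt, stop_map)),
    numeric(1L))
  call <- assignGeneticCode(densities, min_gain, gain_mode)
  list(densities = densities, assigned_code = call$assigned_code, gain = call$gain)
}

#' Detect alternative genetic codes across a set of genomes
#'
#' @param genomes named `DNAStringSet` (or character vector).
#' @inheritParams codeProfile
#' @return `data.frame`, one row per genome: densities per code,
#'   `assigned_code`, `gain`.
#' @export
detectRecoding <- function(genomes, min_orf_nt = 90, min_gain = 0.10,
                           gain_mode = "relative", stop_map = .DEFAULT_STOP_MAP) {
  ids <- names(genomes)
  if (is.null(ids)) ids <- sprintf("genome_%03d", seq_along(genomes))
  rows <- lapply(seq_along(genomes), function(i) {
    pr <- codeProfile(genomes[[i]], min_orf_nt, min_gain, gain_mode, stop_map)
    data.frame(genome_id = ids[i],
               density_11 = pr$densities[["11"]], density_15 = pr$densities[["15"]],
               density_90 = pr$densities[["90"]], density_91 = pr$densities[["91"]],
               assigned_code = pr$assigned_code, gain = pr$gain,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
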