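# CRISPR repeat-spacer arrays, spacer-protospacer matching (full-length,
# ungapped, at most one mismatch, both strands), host prediction and typed
# phage-phage interaction networks.

#' Detect CRISPR repeat-spacer arrays in a genome
#'
#' Simplified direct-repeat detector: candidate arrays are seeded by an exact
#' k-mer (k = minimum repeat length) recurring at least `min_repeats` times
#' with consecutive periods inside the repeat+spacer length window; the
#' repeat is then extended around the seed over the maximal span on which
#' all copies are identical. Spacers are the sequences between consecutive repeats and
#' must fall inside the spacer length window. Arrays are reported greedily
#' left to right without overlap. Parameter ranges mirror CRT defaults.
#'
#' @param seq DNA sequence (character or `DNAString`).
#' @param genome_id id recorded in the output tables.
#' @param repeat_range,spacer_range length windows in bp (defaults 23-47 and
#'   26-50).
#' @param min_repeats minimum number of repeat copies (default 3).
#' @return list: `arrays` (`data.frame`: `array_id`, `genome_id`, `start`,
#'   `end`, `repeat_seq`, `n_repeats`) and `spacers` (`data.frame`:
#'   `spacer_id`, `array_id`, `genome_id`, `spacer_index`, `seq`, `start`,
#'   `end`, `array_start`, `array_end`); coordinates 0-based half-open.
#' @export
findArrays <- function(seq, genome_id = "genome", repeat_range = c(23L, 47L),
                       spacer_range = c(26L, 50L), min_repeats = 3L) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  k <- repeat_range[1L]
  empty <- list(
    arrays = data.frame(array_id = character(), genome_id = character(),
                        start = integer(), end = integer(),
                        repeat_seq = character(), n_repeats = integer()),
    spacers = data.frame(spacer_id = character(), array_id = character(),
                         genome_id = character(), spacer_index = integer(),
                         seq = character(), start = integer(), end = integer(),
                         array_start = integer(), array_end = integer()))
  if (L < min_repeats * k) return(empty)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n_kmer <- L - k + 1L
  kmers <- substring(s, seq_len(n_kmer), seq_len(n_kmer) + k - 1L)
  tab <- table(kmers)
  seeds <- names(tab)[tab >= min_repeats & !grepl("N", names(tab), fixed = TRUE)]
  if (!length(seeds)) return(empty)
  period_min <- repeat_range[1L] + spacer_range[1L]
  period_max <- repeat_range[2L] + spacer_range[2L]
  pos_by_seed <- split(seq_len(n_kmer), kmers)[seeds]
  # order candidate seeds by first occurrence for greedy left-to-right reporting
  pos_by_seed <- pos_by_seed[order(vapply(pos_by_seed, min, numeric(1L)))]

  covered <- logical(L)
  arrays <- list()
  spacers <- list()
  ai <- 0L

  consensusExtend <- function(occ) {
    # occ: 1-based seed start positions of the repeat copies. The reported
    # repeat is the maximal *identical* extension of the exact seed shared by
    # all copies: extension stops at the first non-unanimous column, so
    # planted identical repeats are recovered exactly and spacers verbatim.
    left <- 0L; right <- k - 1L  # offsets relative to seed start
    repeat {
      if (right - left + 2L > repeat_range[2L]) break
      cand <- occ + right + 1L
      if (max(cand) > L) break
      # keep spacers at least spacer_range[1] long
      gaps <- diff(occ) + left - (right + 1L) - 1L
      if (any(gaps < spacer_range[1L])) break
      col <- chars[cand]
      if (any(col != col[1L])) break
      right <- right + 1L
    }
    repeat {
      if (right - left + 2L > repeat_range[2L]) break
      cand <- occ + left - 1L
      if (min(cand) < 1L) break
      gaps <- diff(occ) + (left - 1L) - right - 1L
      if (any(gaps < spacer_range[1L])) break
      col <- chars[cand]
      if (any(col != col[1L])) break
      left <- left - 1L
    }
    list(left = left, right = right)
  }

  for (seed in names(pos_by_seed)) {
    occ_all <- pos_by_seed[[seed]]
    occ_all <- occ_all[!covered[occ_all]]
    if (length(occ_all) < min_repeats) next
    # maximal chains with consecutive periods inside the window
    d <- diff(occ_all)
    ok <- d >= period_min & d <= period_max
    run_id <- cumsum(c(TRUE, !ok))
    for (chain in split(occ_all, run_id)) {
      if (length(chain) < min_repeats) next
      ext <- consensusExtend(chain)
      rep_starts <- chain + ext$left
      rep_len <- ext$right - ext$left + 1L
      if (rep_len < repeat_range[1L] || rep_len > repeat_range[2L]) next
      sp_start <- rep_starts[-length(rep_starts)] + rep_len  # 1-based
      sp_end <- rep_starts[-1L] - 1L
      sp_len <- sp_end - sp_start + 1L
      if (any(sp_len < spacer_range[1L] | sp_len > spacer_range[2L])) next
      a_start <- rep_starts[1L]
      a_end <- rep_starts[length(rep_starts)] + rep_len - 1L
      if (any(covered[a_start:a_end])) next
      covered[a_start:a_end] <- TRUE
      ai <- ai + 1L
      array_id <- sprintf("%s_array%02d", genome_id, ai)
      cons <- paste(vapply(seq_len(rep_len), function(o) {
        col <- chars[rep_starts + o - 1L]
        names(which.max(table(col)))
      }, character(1L)), collapse = "")
      arrays[[ai]] <- data.frame(
        array_id = array_id, genome_id = genome_id,
        start = a_start - 1L, end = a_end, repeat_seq = cons,
        n_repeats = length(rep_starts), stringsAsFactors = FALSE)
      spacers[[ai]] <- data.frame(
        spacer_id = sprintf("%s_sp%02d", array_id, seq_along(sp_start)),
        array_id = array_id, genome_id = genome_id,
        spacer_index = seq_along(sp_start),
        seq = substring(s, sp_start, sp_end),
        start = sp_start - 1L, end = sp_end,
        array_start = a_start - 1L, array_end = a_end,
        stringsAsFactors = FALSE)
    }
  }
  if (!ai) return(empty)
  list(arrays = do.call(rbind, arrays), spacers = do.call(rbind, spacers))
}

#' Detect arrays across a set of genomes
#'
#' @param genomes named `DNAStringSet`.
#' @inheritParams findArrays
#' @return as [findArrays()], concatenated over genomes.
#' @export
findArraysAll <- function(genomes, repeat_range = c(23L, 47L),
                          spacer_range = c(26L, 50L), min_repeats = 3L) {
  res <- lapply(seq_along(genomes), function(i)
    findArrays(genomes[[i]], names(genomes)[i], repeat_range, spacer_range,
               min_repeats))
  list(arrays = do.call(rbind, lapply(res, `[[`, "arrays")),
       spacers = do.call(rbind, lapply(res, `[[`, "spacers")))
}

.countMismatches <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' Match CRISPR spacers against target genomes
#'
#' Full-length ungapped scan of both strands of every target genome,
#' reporting every window at Hamming distance at most `max_mismatch`
#' (default 1) from the spacer -- the "maximum of one mismatch and 100%
#' sequence alignment" rule. A spacer never matches its own array locus
#' (hits overlapping the source array region of the source genome are
#' suppressed). Duplicate spacer sequences are scanned once and the hits
#' attributed to every carrying spacer. Output is deterministic and sorted.
#'
#' @param spacers `data.frame` with at least `spacer_id`, `genome_id`, `seq`
#'   (plus `array_start`/`array_end` for self-locus exclusion), e.g. from
#'   [findArraysAll()] or [spacerTable()].
#' @param targets named `DNAStringSet` of target genomes.
#' @param max_mismatch maximum Hamming distance (default 1).
#' @param min_spacer_length spacers shorter than this are skipped with a
#'   warning (default 20 bp).
#' @return `data.frame`: `spacer_id`, `source_genome`, `target_genome`,
#'   `target_start` (0-based), `strand`, `mismatches`.
#' @export
matchSpacers <- function(spacers, targets, max_mismatch = 1L,
                         min_spacer_length = 20L) {
  empty <- data.frame(spacer_id = character(), source_genome = character(),
                      target_genome = character(), target_start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(spacers)) return(empty)
  short <- nchar(spacers$seq) < min_spacer_length
  if (any(short)) {
    warning(sum(short), " spacer(s) below the ", min_spacer_length,
            " bp floor were skipped")
    spacers <- spacers[!short, , drop = FALSE]
  }
  if (!nrow(spacers)) return(empty)
  tids <- names(targets)
  hits <- list()
  for (us in unique(spacers$seq)) {
    carriers <- spacers[spacers$seq == us, , drop = FALSE]
    pat <- Biostrings::DNAString(us)
    pat_rc <- Biostrings::reverseComplement(pat)
    sl <- nchar(us)
    for (ti in seq_along(targets)) {
      tgt <- targets[[ti]]
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else pat_rc
        m <- Biostrings::matchPattern(p, tgt, max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (!length(m)) next
        winseq <- as.character(m)
        qry <- as.character(p)
        mm <- vapply(winseq, .countMismatches, integer(1L), b = qry,
                     USE.NAMES = FALSE)
        keep <- mm <= max_mismatch & IRanges::width(m) == sl
        if (!any(keep)) next
        st0 <- IRanges::start(m)[keep] - 1L
        for (ci in seq_len(nrow(carriers))) {
          src <- carriers$genome_id[ci]
          sel <- rep(TRUE, length(st0))
          if (src == tids[ti] && !is.null(carriers$array_start)) {
            # self-locus exclusion: drop hits overlapping the source array
            sel <- !(st0 < carriers$array_end[ci] &
                     (st0 + sl) > carriers$array_start[ci])
          }
          if (!any(sel)) next
          hits[[length(hits) + 1L]] <- data.frame(
            spacer_id = carriers$spacer_id[ci], source_genome = src,
            target_genome = tids[ti], target_start = st0[sel],
            strand = strand, mismatches = mm[keep][sel],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$spacer_id, out$target_genome, out$target_start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Predict hosts of phages from microbial spacer hits
#'
#' Hosts of a phage are the distinct microbial genomes whose CRISPR spacers
#' hit the phage. A phage targeting exactly one host genus is a specialist,
#' several genera a generalist, none `"none"`. Genomes absent from the
#' taxonomy are labelled `"unclassified:<genome id>"`.
#'
#' @param hits `data.frame` from [matchSpacers()] where sources are microbial
#'   genomes and targets are phages.
#' @param taxonomy `data.frame` with columns `genome_id`, `genus` (optional
#'   `phylum`).
#' @param phage_ids universe of phages to report (defaults to the targets
#'   present in `hits`).
#' @return `data.frame`: `phage`, `n_hosts`, `hosts`, `genera`, `n_genera`,
#'   `range_class` (and `phyla` when available).
#' @export
predictHosts <- function(hits, taxonomy, phage_ids = NULL) {
  if (is.null(phage_ids)) phage_ids <- sort(unique(hits$target_genome))
  genus_of <- function(g) {
    i <- match(g, taxonomy$genome_id)
    ifelse(is.na(i) | is.na(taxonomy$genus[i]) | taxonomy$genus[i] == "",
           paste0("unclassified:", g), taxonomy$genus[i])
  }
  has_phylum <- "phylum" %in% names(taxonomy)
  rows <- lapply(phage_ids, function(p) {
    src <- sort(unique(hits$source_genome[hits$target_genome == p]))
    genera <- sort(unique(genus_of(src)))
    range_class <- if (!length(src)) "none"
                   else if (length(genera) == 1L) "specialist" else "generalist"
    out <- data.frame(phage = p, n_hosts = length(src),
                      hosts = paste(src, collapse = ","),
                      genera = paste(genera, collapse = ","),
                      n_genera = length(genera), range_class = range_class,
                      stringsAsFactors = FALSE)
    if (has_phylum) {
      i <- match(src, taxonomy$genome_id)
      out$phyla <- paste(sort(unique(taxonomy$phylum[i[!is.na(i)]])), collapse = ",")
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Typed phage-phage interaction network from spacer hits
#'
#' One edge per unordered phage pair with any spacer hit between them:
#' single-directed when spacers match in one direction only, double-directed
#' when both phages' spacers match the other's genome. An edge is competitive
#' iff the two phages share at least one predicted host.
#'
#' @param hits `data.frame` from [matchSpacers()] restricted to phage
#'   sources and phage targets.
#' @param host_predictions optional `data.frame` from [predictHosts()] used
#'   for the competitive flag.
#' @return `data.frame`: `phage_a`, `phage_b` (lexicographic), `direction`
#'   (`"single"`/`"double"`), `competitive`.
#' @export
buildInteractionNetwork <- function(hits, host_predictions = NULL) {
  hits <- hits[hits$source_genome != hits$target_genome, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(phage_a = character(), phage_b = character(),
                      direction = character(), competitive = logical(),
                      stringsAsFactors = FALSE))
  directed <- unique(hits[, c("source_genome", "target_genome")])
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  dir_key <- paste(directed$source_genome, directed$target_genome, sep = "\r")
  pair_key <- key(directed$source_genome, directed$target_genome)
  hostsOf <- function(p) {
    if (is.null(host_predictions)) return(character())
    h <- host_predictions$hosts[host_predictions$phage == p]
    if (!length(h) || !nzchar(h[1L])) character() else strsplit(h[1L], ",", fixed = TRUE)[[1L]]
  }
  upairs <- unique(pair_key)
  rows <- lapply(upairs, function(pk) {
    ab <- strsplit(pk, "\r", fixed = TRUE)[[1L]]
    fwd <- paste(ab[1L], ab[2L], sep = "\r") %in% dir_key
    rev <- paste(ab[2L], ab[1L], sep = "\r") %in% dir_key
    data.frame(phage_a = ab[1L], phage_b = ab[2L],
               direction = if (fwd && rev) "double" else "single",
               competitive = length(intersect(hostsOf(ab[1L]), hostsOf(ab[2L]))) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$phage_a, out$phage_b), ]
  rownames(out) <- NULL
  out
}

#' Write an interaction network as GraphML
#'
#' @param network `data.frame` from [buildInteractionNetwork()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeNetworkGraphML <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network[, c("phage_a", "phage_b", "direction", "competitive")],
    directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
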