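# Synthetic phage community generator.
#
# Genomes are assembled from planted protein-coding genes separated by short
# "stop-dense" pads, then diversified by substitution-only evolution so that
# pairwise identity has a closed-form (binomial) expectation and every planted
# signal can be re-found by naive search. Coordinates are 0-based half-open
# throughout.

# Codon pool for gene bodies. The five codons form a "junction-clean" set:
# within any codon stream drawn from them, no reading frame of either strand
# ever contains a stop codon (TAA/TAG/TGA), a start codon (ATG/GTG/TTG), or
# the reverse complement of one (TTA/CTA/TCA, CAT/CAC/CAA) -- checked over
# all ordered codon pairs, including each codon with itself, and at the
# junctions with the gene start, the terminator and the intergenic pad.
# Off-frame ORFs therefore cannot exist in unmutated genes, and an ORF
# started by a substitution runs to the next pad under *every* genetic code,
# so it never differentiates the codes. Each codon is additionally at
# Hamming distance >= 2 from every stop codon, so single substitutions
# cannot plant premature in-frame stops either. Coding density under a given
# code thus measures exactly the planted gene structure, robustly under the
# generator's divergence levels.
.CODON_POOL <- c("CCG", "CGG", "CTG", "GCG", "GGG")

.geneBody <- function(n_codons) {
  paste(sample(.CODON_POOL, n_codons, replace = TRUE), collapse = "")
}

# Length of the accessory region: a high-entropy, start-codon-free stretch at
# the 3' end of every genome. It gives each genome unique sequence for
# protospacer windows and CRISPR array placement (the five-codon gene lattice
# is too low-complexity for 0/1-mismatch uniqueness), contributes no ORF
# under any genetic code (no start codon on either strand), and raises
# between-cluster divergence since it is drawn independently per ancestor.
.accessoryLength <- function(genome_length) {
  max(800L, as.integer(round(0.12 * genome_length)))
}

# Accessory sequence: random DNA interleaved with the cassette TGATAGTAA
# (all three stop codons in one frame, no start codon, reverse complement
# TTACTATCA carries all three reverse-strand stops; the 53 bp unit length
# rotates the cassette through the reading frames). Start codons on either
# strand (ATG/GTG/TTG forward, i.e. also CAT/CAC/CAA as forward substrings)
# are then destroyed by substituting their middle base, iterating until
# clean. Result: high-entropy sequence in which no ORF can begin, and in
# which any mutation-born ORF meets a stop of every genetic code within a
# short, code-balanced distance.
.startFreeRandom <- function(n) {
  units <- ceiling(n / 53L)
  chars <- strsplit(paste(vapply(seq_len(units), function(i)
    paste0(randomDna(44L), "TGATAGTAA"), character(1L)), collapse = ""), "",
    fixed = TRUE)[[1L]][seq_len(n)]
  forb <- c("ATG", "GTG", "TTG", "CAT", "CAC", "CAA")
  for (it in 1:50) {
    s <- paste(chars, collapse = "")
    hit <- integer()
    for (f in forb) {
      m <- gregexpr(f, s, fixed = TRUE)[[1L]]
      if (m[1L] > 0) hit <- c(hit, m)
    }
    if (!length(hit)) break
    chars[unique(hit) + 1L] <- "C"
  }
  paste(chars, collapse = "")
}

# Intergenic pad: contains, in every reading frame of both strands, an active
# stop codon of every code (11, 15, 90, 91) and no start codon anywhere, even
# when self-concatenated -- ORFs can never read through an intergenic region.
.PAD_MOTIF <- "CTATTAATAGTTAATAGTTAATAGCCTATCTA"

.padSeq <- function(n) {
  if (n <= 0) return("")
  substr(strrep(.PAD_MOTIF, ceiling(n / nchar(.PAD_MOTIF)) + 1L), 1L, n)
}

# All planted genes start with ATG, are a multiple of 3 long and end with the
# double terminator TAATAG: every stop-codon mapping keeps at least one of
# TAA/TAG, so translation under any code stops within 6 bp.
.TERMINATOR <- "TAATAG"

.standardGene <- function(n_codons = 160L) {
  paste0("ATG", .geneBody(n_codons), .TERMINATOR)
}

# A recoded gene carries two in-frame copies of the reassigned stop codon,
# each flanked by continued coding sequence; under the standard code only the
# first segment is recovered as an ORF, under the planted code the gene reads
# through to the terminator.
.recodedGene <- function(code, seg_codons = c(66L, 65L, 64L)) {
  stop_codon <- switch(as.character(code),
                       "15" = "TAG", "90" = "TAA", "91" = "TGA",
                       stop("recoded_code must be one of 15, 90, 91"))
  segs <- lapply(seg_codons, function(k) .geneBody(k))
  paste0("ATG", segs[[1L]], stop_codon, segs[[2L]], stop_codon, segs[[3L]],
         .TERMINATOR)
}

#' Configuration of a synthetic phage community
#'
#' Validates and returns the configuration consumed by [generateCommunity()]
#' and [plantCrisprLinks()]. Defaults describe a small two-habitat community
#' of five planted clusters; tests and the pipeline override fields per
#' scenario.
#'
#' @param seed integer seed; all randomness is derived from it.
#' @param n_clusters number of planted clusters (independent random ancestors).
#' @param genomes_per_cluster members per cluster.
#' @param habitats character vector of habitat labels (members of a cluster
#'   are spread round-robin across habitats).
#' @param genome_length genome length in bp (>= 3000; >= 16000 when
#'   `n_recoded > 0` so that recoded genomes carry at least 20 planted genes).
#' @param within_habitat_divergence,between_habitat_divergence per-site
#'   substitution probabilities; members of the same habitat diverge from a
#'   shared habitat ancestor at the within rate, habitat ancestors diverge
#'   from the cluster ancestor at the between rate. Must satisfy
#'   `within < between`.
#' @param habitat_structured if `FALSE`, habitat labels carry no signal: every
#'   member diverges independently from the cluster ancestor at the between
#'   rate (null model for coevolution testing).
#' @param n_recoded number of genomes planted with an alternative genetic
#'   code; must be a multiple of `genomes_per_cluster` (recoding is a property
#'   of whole clusters, so cluster ground truth stays valid).
#' @param recoded_code code(s) from `{15, 90, 91}`; a vector is recycled over
#'   the recoded clusters.
#' @param n_arrays number of CRISPR repeat-spacer arrays planted into phage
#'   genomes by [plantCrisprLinks()].
#' @param repeat_length,spacer_length,spacers_per_array array geometry (bp /
#'   bp / count); `spacers_per_array >= 2` gives the minimum three repeats.
#' @param planted_link_mismatches Hamming distance (0 or 1) between each
#'   planted spacer and its protospacer.
#' @param n_hosts number of bacterial host genomes, each carrying one array
#'   whose spacers target phage genomes.
#'
#' @return a validated list of class `CommunityConfig`.
#' @export
communityConfig <- function(seed = 1L,
                            n_clusters = 5L,
                            genomes_per_cluster = 4L,
                            habitats = c("pig_gut", "human_gut"),
                            genome_length = 6000L,
                            within_habitat_divergence = 0.005,
                            between_habitat_divergence = 0.01,
                            habitat_structured = TRUE,
                            n_recoded = 0L,
                            recoded_code = 15L,
                            n_arrays = 0L,
                            repeat_length = 30L,
                            spacer_length = 32L,
                            spacers_per_array = 4L,
                            planted_link_mismatches = 0L,
                            n_hosts = 0L) {
  cfg <- list(seed = as.integer(seed), n_clusters = as.integer(n_clusters),
              genomes_per_cluster = as.integer(genomes_per_cluster),
              habitats = as.character(habitats),
              genome_length = as.integer(genome_length),
              within_habitat_divergence = within_habitat_divergence,
              between_habitat_divergence = between_habitat_divergence,
              habitat_structured = isTRUE(habitat_structured),
              n_recoded = as.integer(n_recoded),
              recoded_code = as.integer(recoded_code),
              n_arrays = as.integer(n_arrays),
              repeat_length = as.integer(repeat_length),
              spacer_length = as.integer(spacer_length),
              spacers_per_array = as.integer(spacers_per_array),
              planted_link_mismatches = as.integer(planted_link_mismatches),
              n_hosts = as.integer(n_hosts))
  bad <- function(what) stop("invalid CommunityConfig: ", what, call. = FALSE)
  counts <- c("n_clusters", "genomes_per_cluster", "n_recoded", "n_arrays",
              "repeat_length", "spacer_length", "spacers_per_array", "n_hosts")
  for (fld in counts)
    if (!.isCount(cfg[[fld]])) bad(paste(fld, "must be a non-negative count"))
  if (!.isCount(cfg$genome_length, min = 3000))
    bad("genome_length must be >= 3000 bp")
  if (!.isFraction(cfg$within_habitat_divergence) ||
      !.isFraction(cfg$between_habitat_divergence))
    bad("divergences must be fractions in [0, 1]")
  if (cfg$within_habitat_divergence >= cfg$between_habitat_divergence)
    bad("within_habitat_divergence must be < between_habitat_divergence")
  if (!length(cfg$habitats)) bad("habitats must be non-empty")
  if (!all(cfg$recoded_code %in% c(15L, 90L, 91L)))
    bad("recoded_code must be drawn from {15, 90, 91}")
  if (cfg$n_recoded > 0) {
    if (cfg$genomes_per_cluster == 0L ||
        cfg$n_recoded %% cfg$genomes_per_cluster != 0L)
      bad("n_recoded must be a multiple of genomes_per_cluster")
    if (cfg$n_recoded > cfg$n_clusters * cfg$genomes_per_cluster)
      bad("n_recoded exceeds the community size")
    if (cfg$genome_length < 16000L)
      bad("genome_length must be >= 16000 bp when n_recoded > 0 (>= 20 planted genes per recoded genome)")
  }
  if (!cfg$planted_link_mismatches %in% c(0L, 1L))
    bad("planted_link_mismatches must be 0 or 1")
  class(cfg) <- "CommunityConfig"
  cfg
}

# Build one ancestor genome: alternating pads and genes up to `len` bp.
# Returns the sequence and the gene table (0-based half-open coordinates).
.buildAncestor <- function(len, recoded_code = NULL) {
  pad_len <- nchar(.PAD_MOTIF)
  acc_len <- .accessoryLength(len)
  gene_region <- len - acc_len - pad_len
  pieces <- character()
  genes <- list()
  pos <- 0L
  gi <- 0L
  while (pos < gene_region) {
    pad <- .padSeq(pad_len)
    gene <- if (is.null(recoded_code)) .standardGene() else .recodedGene(recoded_code)
    gstart <- pos + pad_len
    gend <- gstart + nchar(gene)
    if (gend > gene_region) break
    gi <- gi + 1L
    pieces <- c(pieces, pad, gene)
    genes[[gi]] <- data.frame(gene_index = gi, start = gstart, end = gend,
                              recoded = !is.null(recoded_code))
    pos <- gend
  }
  seq <- paste(pieces, collapse = "")
  if (nchar(seq) < gene_region) {
    # fill the remainder with pad + start-free random sequence: a repeated
    # pad motif here would itself look like a tandem repeat array
    fill <- gene_region - nchar(seq)
    seq <- if (fill <= 2L * pad_len) paste0(seq, .padSeq(fill)) else
      paste0(seq, .padSeq(pad_len), .startFreeRandom(fill - pad_len))
  }
  acc_start <- nchar(seq) + pad_len
  seq <- paste0(seq, .padSeq(pad_len), .startFreeRandom(len - acc_start))
  list(seq = seq, genes = do.call(rbind, genes), accessory_start = acc_start)
}

#' Generate a synthetic phage community with known ground truth
#'
#' Cluster ancestors are independent random gene-structured genomes; members
#' are substitution-only mutants of a habitat ancestor (itself a mutant of the
#' cluster ancestor), so pairwise identity is analytically predictable and no
#' alignment is required to verify divergence. Recoded clusters carry genes
#' interrupted by in-frame reassigned stop codons. Annotation tables plant at
#' least two virus-keyword genes per phage. The generator is deterministic for
#' a fixed configuration: every genome is drawn from a private RNG stream
#' keyed by `(seed, genome index)`.
#'
#' @param config a [communityConfig()].
#' @return a [PhageCommunity-class]; `groundTruth(x)` holds the planted
#'   cluster, habitat and genetic-code assignments.
#' @export
generateCommunity <- function(config) {
  if (!inherits(config, "CommunityConfig"))
    config <- do.call(communityConfig, config)
  nc <- config$n_clusters
  gpc <- config$genomes_per_cluster
  n_rec_clusters <- if (gpc > 0) config$n_recoded %/% gpc else 0L
  codes <- rep(config$recoded_code, length.out = max(n_rec_clusters, 1L))

  genome_seqs <- character()
  genome_ids <- character()
  cluster_of <- character()
  habitat_of <- character()
  recoded <- character()
  ann_rows <- list()

  for (ci in seq_len(nc)) {
    cluster_id <- sprintf("cluster_%02d", ci)
    code <- if (ci <= n_rec_clusters) codes[ci] else NULL
    anc <- withLocalSeed(derivedSeed(config$seed, ci * 1000L),
                         .buildAncestor(config$genome_length, code))
    # habitat ancestors diverge from the cluster ancestor at the between rate
    hab_anc <- withLocalSeed(derivedSeed(config$seed, ci * 1000L + 500L), {
      lapply(seq_along(config$habitats), function(hi)
        mutateDna(anc$seq, config$between_habitat_divergence))
    })
    for (gi in seq_len(gpc)) {
      hab_i <- ((gi - 1L) %% length(config$habitats)) + 1L
      gid <- sprintf("phage_c%02d_g%02d", ci, gi)
      seq <- withLocalSeed(derivedSeed(config$seed, ci * 1000L + gi), {
        if (config$habitat_structured)
          mutateDna(hab_anc[[hab_i]], config$within_habitat_divergence)
        else
          mutateDna(anc$seq, config$between_habitat_divergence)
      })
      genome_ids <- c(genome_ids, gid)
      genome_seqs <- c(genome_seqs, seq)
      cluster_of[gid] <- cluster_id
      habitat_of[gid] <- config$habitats[hab_i]
      recoded[gid] <- if (is.null(code)) "11" else as.character(code)
      gt <- anc$genes
      ann_text <- rep("hypothetical protein", nrow(gt))
      ann_text[1L] <- "major capsid protein"
      if (nrow(gt) >= 2L) ann_text[2L] <- "terminase large subunit"
      if (nrow(gt) >= 3L) ann_text[3L] <- "portal protein"
      ann_rows[[gid]] <- data.frame(
        gene_id = sprintf("%s_gene%03d", gid, gt$gene_index),
        genome_id = gid, start = gt$start, end = gt$end, strand = "+",
        annotation = ann_text, source_db = "synthetic",
        stringsAsFactors = FALSE)
    }
  }

  annotations <- do.call(rbind, ann_rows)
  rownames(annotations) <- NULL
  total_genes <- vapply(split(annotations$gene_id, annotations$genome_id)[genome_ids],
                        length, integer(1L))

  # Lifestyle scores emulate the reported composition of jumbo phage
  # communities: ~80% virulent, ~15% uncertain, ~5% temperate, rare proviruses.
  meta_rand <- withLocalSeed(derivedSeed(config$seed, 999983L), {
    n <- length(genome_ids)
    band <- sample(c("v", "u", "t"), n, replace = TRUE, prob = c(0.80, 0.15, 0.05))
    score <- numeric(n)
    score[band == "v"] <- stats::runif(sum(band == "v"), 0, 0.49)
    score[band == "u"] <- stats::runif(sum(band == "u"), 0.51, 0.89)
    score[band == "t"] <- stats::runif(sum(band == "t"), 0.91, 1)
    list(score = round(score, 4), provirus = stats::runif(n) < 0.023)
  })

  metadata <- S4Vectors::DataFrame(
    genome_id = genome_ids,
    habitat = unname(habitat_of[genome_ids]),
    source_collection = "study",
    length = nchar(genome_seqs),
    total_genes = unname(total_genes),
    busco_hits = 0L,
    lifestyle_score = meta_rand$score,
    is_provirus = meta_rand$provirus,
    spacer_evidence = 1L)

  gset <- Biostrings::DNAStringSet(genome_seqs)
  names(gset) <- genome_ids

  empty_links <- data.frame(source_genome = character(), target_genome = character(),
                            array_id = character(), spacer_index = integer(),
                            mismatches = integer(), strand = character(),
                            target_start = integer(), decoy = logical(),
                            stringsAsFactors = FALSE)
  methods::new("PhageCommunity",
    genomes = gset,
    hosts = Biostrings::DNAStringSet(),
    metadata = metadata,
    annotations = annotations,
    arrays = data.frame(),
    spacers = data.frame(),
    truth = list(cluster_of = cluster_of, habitat_of = habitat_of,
                 recoded = recoded,
                 planted_spacer_links = empty_links,
                 planted_host_links = empty_links),
    config = unclass(config))
}

# Substitute exactly `n_mm` positions of `seq`, each to a different base.
.planMismatches <- function(seq, n_mm) {
  if (n_mm == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(chars), n_mm)
  chars[pos] <- vapply(chars[pos], function(b) sample(DNA_BASES[DNA_BASES != b], 1L),
                       character(1L), USE.NAMES = FALSE)
  paste(chars, collapse = "")
}

# Build one repeat-spacer array string and its spacer coordinate table
# relative to the array start.
.assembleArray <- function(repeat_seq, spacer_seqs) {
  rl <- nchar(repeat_seq)
  pieces <- character(2L * length(spacer_seqs) + 1L)
  pieces[1L] <- repeat_seq
  sp_start <- integer(length(spacer_seqs))
  pos <- rl
  for (i in seq_along(spacer_seqs)) {
    sp_start[i] <- pos
    pieces[2L * i] <- spacer_seqs[i]
    pieces[2L * i + 1L] <- repeat_seq
    pos <- pos + nchar(spacer_seqs[i]) + rl
  }
  list(seq = paste(pieces, collapse = ""), spacer_start = sp_start)
}

#' Plant CRISPR arrays and spacer-protospacer links into a community
#'
#' Plants `n_arrays` repeat-spacer arrays into distinct phage genomes and
#' creates `n_hosts` bacterial host genomes each carrying one array. Every
#' spacer is copied from a random window (protospacer) of another genome on a
#' random strand and then substituted at exactly `planted_link_mismatches`
#' positions, so the matcher's recovery is checkable by a naive Hamming scan.
#' Each array additionally carries one 2-mismatch decoy spacer that must not
#' be recovered under the one-mismatch rule. Arrays overwrite a window near
#' the end of the carrier genome (sequence length is preserved).
#'
#' @param community a [PhageCommunity-class] from [generateCommunity()].
#' @param config the same [communityConfig()] (fields `n_arrays`, `n_hosts`,
#'   `repeat_length`, `spacer_length`, `spacers_per_array`,
#'   `planted_link_mismatches` are used).
#' @return the modified community; `groundTruth()` gains
#'   `planted_spacer_links` (phage to phage) and `planted_host_links`
#'   (host to phage), `crisprArrays()`/`spacerTable()` the planted geometry.
#' @export
plantCrisprLinks <- function(community, config) {
  if (!inherits(config, "CommunityConfig"))
    config <- do.call(communityConfig, config)
  if (config$n_arrays == 0L && config$n_hosts == 0L) return(community)
  ids <- names(genomes(community))
  n_phage <- length(ids)
  rl <- config$repeat_length
  sl <- config$spacer_length
  spa <- config$spacers_per_array
  if (spa < 2L)
    stop("spacers_per_array must be >= 2 so that arrays have >= 3 repeats")
  array_len <- function(n_sp) (n_sp + 1L) * rl + n_sp * sl
  seqs <- as.character(genomes(community))
  min_len <- min(nchar(seqs))
  if (array_len(spa + 1L) + 100L > min_len)
    stop("array placement error: genome too short to place an array of ",
         array_len(spa + 1L), " bp")

  links <- list()
  host_links <- list()
  arrays <- list()
  spacer_rows <- list()

  # protospacer windows stay clear of the tail zone into which arrays are
  # written, so later placements cannot destroy an earlier planted link
  tail_reserve <- array_len(spa + 1L) + 100L

  make_array <- function(carrier_id, k) {
    withLocalSeed(derivedSeed(config$seed, 777000L + k), {
      repeat_seq <- randomDna(rl)
      targets <- sample(setdiff(ids, carrier_id), spa, replace = spa > length(ids) - 1L)
      sp <- character(spa + 1L)
      meta <- vector("list", spa + 1L)
      for (i in seq_len(spa + 1L)) {
        mm <- if (i <= spa) config$planted_link_mismatches else 2L
        tgt <- if (i <= spa) targets[i] else sample(setdiff(ids, carrier_id), 1L)
        tseq <- seqs[[match(tgt, ids)]]
        # protospacer windows come from the high-entropy accessory region
        acc0 <- nchar(tseq) - .accessoryLength(nchar(tseq))
        hi <- nchar(tseq) - sl - tail_reserve
        if (hi <= acc0 + 1L)
          stop("array placement error: accessory region too small for protospacer windows")
        w0 <- sample.int(hi - acc0, 1L) + acc0  # 1-based window start
        window <- substr(tseq, w0, w0 + sl - 1L)
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        spacer <- if (strand == "+") window else revComp(window)
        spacer <- .planMismatches(spacer, mm)
        sp[i] <- spacer
        meta[[i]] <- data.frame(target_genome = tgt, mismatches = mm,
                                strand = strand, target_start = w0 - 1L,
                                decoy = i > spa, stringsAsFactors = FALSE)
      }
      list(repeat_seq = repeat_seq, spacers = sp, meta = do.call(rbind, meta))
    })
  }

  # arrays planted into phage genomes
  carrier_idx <- withLocalSeed(derivedSeed(config$seed, 777L),
                               sample(n_phage, min(config$n_arrays, n_phage)))
  for (k in seq_along(carrier_idx)) {
    cid <- ids[carrier_idx[k]]
    arr <- make_array(cid, k)
    asm <- .assembleArray(arr$repeat_seq, arr$spacers)
    alen <- nchar(asm$seq)
    at0 <- nchar(seqs[[carrier_idx[k]]]) - alen - 50L  # 0-based array start
    substr(seqs[[carrier_idx[k]]], at0 + 1L, at0 + alen) <- asm$seq
    array_id <- sprintf("array_%s_%02d", cid, k)
    arrays[[array_id]] <- data.frame(
      array_id = array_id, genome_id = cid, start = at0, end = at0 + alen,
      repeat_seq = arr$repeat_seq, n_repeats = spa + 2L, stringsAsFactors = FALSE)
    sp_df <- data.frame(
      spacer_id = sprintf("%s_sp%02d", array_id, seq_len(spa + 1L)),
      array_id = array_id, genome_id = cid,
      spacer_index = seq_len(spa + 1L),
      seq = arr$spacers,
      start = at0 + asm$spacer_start,
      end = at0 + asm$spacer_start + nchar(arr$spacers),
      array_start = at0, array_end = at0 + alen, stringsAsFactors = FALSE)
    spacer_rows[[array_id]] <- sp_df
    lk <- arr$meta
    lk$source_genome <- cid
    lk$array_id <- array_id
    lk$spacer_index <- seq_len(nrow(lk))
    links[[array_id]] <- lk
  }

  # host genomes, one array each
  host_seqs <- character()
  host_ids <- character()
  if (config$n_hosts > 0L) {
    host_len <- max(5000L, array_len(spa + 1L) + 1000L)
    for (h in seq_len(config$n_hosts)) {
      hid <- sprintf("host_%02d", h)
      base <- withLocalSeed(derivedSeed(config$seed, 888000L + h), randomDna(host_len))
      arr <- make_array(hid, 100L + h)
      asm <- .assembleArray(arr$repeat_seq, arr$spacers)
      alen <- nchar(asm$seq)
      at0 <- host_len - alen - 200L
      substr(base, at0 + 1L, at0 + alen) <- asm$seq
      host_ids <- c(host_ids, hid)
      host_seqs <- c(host_seqs, base)
      array_id <- sprintf("array_%s", hid)
      arrays[[array_id]] <- data.frame(
        array_id = array_id, genome_id = hid, start = at0, end = at0 + alen,
        repeat_seq = arr$repeat_seq, n_repeats = spa + 2L, stringsAsFactors = FALSE)
      spacer_rows[[array_id]] <- data.frame(
        spacer_id = sprintf("%s_sp%02d", array_id, seq_len(spa + 1L)),
        array_id = array_id, genome_id = hid,
        spacer_index = seq_len(spa + 1L),
        seq = arr$spacers,
        start = at0 + asm$spacer_start,
        end = at0 + asm$spacer_start + nchar(arr$spacers),
        array_start = at0, array_end = at0 + alen, stringsAsFactors = FALSE)
      lk <- arr$meta
      lk$source_genome <- hid
      lk$array_id <- array_id
      lk$spacer_index <- seq_len(nrow(lk))
      host_links[[array_id]] <- lk
    }
  }

  link_cols <- c("source_genome", "target_genome", "array_id", "spacer_index",
                 "mismatches", "strand", "target_start", "decoy")
  bindLinks <- function(lst) {
    if (!length(lst)) return(community@truth$planted_spacer_links[0, ])
    out <- do.call(rbind, lst)[, link_cols]
    rownames(out) <- NULL
    out
  }

  gset <- Biostrings::DNAStringSet(seqs)
  names(gset) <- ids
  hset <- Biostrings::DNAStringSet(host_seqs)
  if (length(host_ids)) names(hset) <- host_ids

  out <- community
  out@genomes <- gset
  out@hosts <- hset
  out@arrays <- { a <- do.call(rbind, arrays); if (is.null(a)) data.frame() else { rownames(a) <- NULL; a } }
  out@spacers <- { s <- do.call(rbind, spacer_rows); if (is.null(s)) data.frame() else { rownames(s) <- NULL; s } }
  out@truth$planted_spacer_links <- bindLinks(links)
  out@truth$planted_host_links <- bindLinks(host_links)
  methods::validObject(out)
  out
}

#' Write a community to disk (FASTA + TSV + JSON ground truth)
#'
#' @param community a [PhageCommunity-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCommunity <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genomes = file.path(dir, "genomes.fasta"),
    hosts = file.path(dir, "hosts.fasta"),
    metadata = file.path(dir, "metadata.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  Biostrings::writeXStringSet(genomes(community), paths["genomes"], width = 80L)
  if (length(hostGenomes(community)))
    Biostrings::writeXStringSet(hostGenomes(community), paths["hosts"], width = 80L)
  .writeTsv(as.data.frame(communityMetadata(community)), paths["metadata"])
  .writeTsv(annotationTable(community), paths["annotations"])
  jsonlite::write_json(groundTruth(community), paths["truth"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
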