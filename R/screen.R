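# Screening rules: length, size class, keyword evidence, BUSCO contamination
# ratio, lifestyle thresholds. All verdicts are pure functions of their inputs.

#' Default keyword lists for phage identification
#'
#' Virus-specific and prokaryote-specific keyword lists used by
#' [keywordScreen()], shipped as editable plain-text files under
#' `inst/extdata/` (one keyword per line; matching is case-insensitive
#' substring).
#'
#' @return character vector of keywords.
#' @export
virusKeywords <- function() {
  readLines(system.file("extdata", "virus_keywords.txt", package = "jumbophage"))
}

#' @rdname virusKeywords
#' @export
prokaryoteKeywords <- function() {
  readLines(system.file("extdata", "prokaryote_keywords.txt", package = "jumbophage"))
}

#' Size classification of phage genomes
#'
#' Genomes of more than 200 kb are jumbo phages; genomes of more than 500 kb
#' are megaphages (a megaphage is also a jumbo phage; the returned class is
#' the most specific label). Both thresholds are strict.
#'
#' @param length genome length(s) in bp; must be positive.
#' @return character vector in `{"conventional", "jumbo", "megaphage"}`.
#' @export
classifySize <- function(length) {
  if (any(!is.finite(length)) || any(length <= 0))
    stop("genome length must be positive")
  ifelse(length > 500000, "megaphage",
         ifelse(length > 200000, "jumbo", "conventional"))
}

#' Minimum-length filter
#'
#' @param length genome length(s) in bp (>= 0).
#' @param min_length minimum retained length (default 3000 bp).
#' @return logical: `TRUE` iff the genome is retained.
#' @export
lengthFilter <- function(length, min_length = 3000) {
  if (any(length < 0)) stop("genome length must be non-negative")
  length >= min_length
}

.matchesAnyKeyword <- function(text, keywords) {
  text <- tolower(text)
  hit <- rep(FALSE, length(text))
  for (kw in tolower(keywords)) hit <- hit | grepl(kw, text, fixed = TRUE)
  hit
}

#' Keyword and spacer-evidence screen for one genome's annotations
#'
#' A candidate passes iff it has at least two genes annotated with a
#' virus-specific keyword, no gene annotated with a prokaryote-specific
#' keyword, and at least one supporting CRISPR spacer match from a microbial
#' genome. Matching is case-insensitive substring on the annotation text.
#'
#' @param annotations `data.frame` of gene annotations for one genome (column
#'   `annotation`); an empty table fails the two-gene rule.
#' @param virus_keywords,prokaryote_keywords keyword vectors
#'   (defaults: [virusKeywords()], [prokaryoteKeywords()]).
#' @param n_spacer_evidence count of microbial spacers matching the genome.
#' @return list: `n_virus_keyword_genes`, `has_prokaryote_keyword`,
#'   `n_spacer_evidence`, `passed`.
#' @export
keywordScreen <- function(annotations, virus_keywords = virusKeywords(),
                          prokaryote_keywords = prokaryoteKeywords(),
                          n_spacer_evidence = 0L) {
  if (!length(virus_keywords) || !length(prokaryote_keywords))
    stop("keyword lists must be non-empty")
  txt <- if (nrow(annotations)) annotations$annotation else character()
  nv <- sum(.matchesAnyKeyword(txt, virus_keywords))
  prok <- any(.matchesAnyKeyword(txt, prokaryote_keywords))
  list(n_virus_keyword_genes = nv,
       has_prokaryote_keyword = prok,
       n_spacer_evidence = as.integer(n_spacer_evidence),
       passed = nv >= 2L && !prok && n_spacer_evidence >= 1L)
}

#' BUSCO contamination screen
#'
#' The BUSCO ratio is the fraction of a genome's predicted genes hitting
#' bacterial universal single-copy ortholog models; genomes pass iff the
#' ratio is strictly below `max_ratio` (default 0.067, the acceptable
#' baseline for viral genomes).
#'
#' @param busco_hits,total_genes hit and gene counts (`total_genes > 0`).
#' @param max_ratio strict upper bound on the ratio.
#' @return list: `busco_ratio`, `passed`.
#' @export
buscoScreen <- function(busco_hits, total_genes, max_ratio = 0.067) {
  if (any(total_genes == 0))
    stop("BUSCO ratio undefined: total_genes must be > 0")
  ratio <- busco_hits / total_genes
  list(busco_ratio = ratio, passed = ratio < max_ratio)
}

#' Lifestyle classification from a lysogeny score
#'
#' Scores above 0.9 are temperate, below 0.5 virulent, anything else
#' (including the boundary values 0.5 and 0.9) uncertain. A genome flagged as
#' a provirus is temperate regardless of its score.
#'
#' @param score lysogeny score(s) in `[0, 1]`.
#' @param is_provirus logical provirus flag(s).
#' @return character vector in `{"temperate", "uncertain", "virulent"}`.
#' @export
lifestyleCall <- function(score, is_provirus = FALSE) {
  if (any(score < 0 | score > 1 | !is.finite(score)))
    stop("lifestyle score must lie in [0, 1]")
  out <- ifelse(score > 0.9, "temperate",
                ifelse(score < 0.5, "virulent", "uncertain"))
  out[as.logical(is_provirus)] <- "temperate"
  out
}

#' Screen every genome of a community
#'
#' Applies the length, keyword, spacer-evidence, BUSCO and lifestyle rules to
#' each phage genome, reading annotation rows and the `busco_hits`,
#' `total_genes`, `lifestyle_score`, `is_provirus` and `spacer_evidence`
#' metadata columns.
#'
#' @param community a [PhageCommunity-class].
#' @param virus_keywords,prokaryote_keywords keyword vectors.
#' @param min_length minimum genome length in bp.
#' @param busco_max strict BUSCO-ratio bound.
#' @return `data.frame`, one row per genome: the screen fragments, the
#'   combined `passed` flag, `size_class` and `lifestyle`.
#' @export
screenGenomes <- function(community,
                          virus_keywords = virusKeywords(),
                          prokaryote_keywords = prokaryoteKeywords(),
                          min_length = 3000, busco_max = 0.067) {
  md <- as.data.frame(communityMetadata(community))
  ann <- annotationTable(community)
  rows <- lapply(seq_len(nrow(md)), function(i) {
    gid <- md$genome_id[i]
    kw <- keywordScreen(ann[ann$genome_id == gid, , drop = FALSE],
                        virus_keywords, prokaryote_keywords,
                        n_spacer_evidence = md$spacer_evidence[i])
    bu <- buscoScreen(md$busco_hits[i], md$total_genes[i], busco_max)
    len_ok <- lengthFilter(md$length[i], min_length)
    data.frame(
      genome_id = gid,
      length = md$length[i],
      length_ok = len_ok,
      n_virus_keyword_genes = kw$n_virus_keyword_genes,
      has_prokaryote_keyword = kw$has_prokaryote_keyword,
      n_spacer_evidence = kw$n_spacer_evidence,
      busco_hits = md$busco_hits[i],
      total_genes = md$total_genes[i],
      busco_ratio = bu$busco_ratio,
      passed = len_ok && kw$passed && bu$passed,
      size_class = classifySize(md$length[i]),
      lifestyle = lifestyleCall(md$lifestyle_score[i], md$is_provirus[i]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
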