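# End-to-end orchestration: screen -> recode -> cluster -> phylo -> crisprnet,
# driven by one declarative config, writing flat TSV/JSON/Newick outputs.
# All internal coordinates are 0-based half-open; all randomness derives from
# config$seed, so identical config + inputs give identical outputs.

#' Read a community from FASTA + TSV files
#'
#' Counterpart of [writeCommunity()] for user-supplied data; the ground-truth
#' slot is left empty. Missing metadata columns are filled with neutral
#' defaults (`busco_hits = 0`, `spacer_evidence = 1`, `lifestyle_score = 0`,
#' `is_provirus = FALSE`).
#'
#' @param genomes_fasta path to the phage genome FASTA.
#' @param metadata_tsv,annotations_tsv paths to the metadata and annotation
#'   tables (optional; minimal tables are synthesised when absent).
#' @param hosts_fasta optional host genome FASTA.
#' @return a [PhageCommunity-class].
#' @export
readCommunity <- function(genomes_fasta, metadata_tsv = NULL,
                          annotations_tsv = NULL, hosts_fasta = NULL) {
  gset <- Biostrings::readDNAStringSet(genomes_fasta)
  names(gset) <- sub("\\s.*$", "", names(gset))
  ids <- names(gset)
  md <- if (!is.null(metadata_tsv)) .readTsv(metadata_tsv) else data.frame(genome_id = ids)
  md <- md[match(ids, md$genome_id), , drop = FALSE]
  defaults <- list(habitat = "unknown", source_collection = "user",
                   length = Biostrings::width(gset), total_genes = 1L,
                   busco_hits = 0L, lifestyle_score = 0, is_provirus = FALSE,
                   spacer_evidence = 1L)
  for (fld in names(defaults))
    if (is.null(md[[fld]])) md[[fld]] <- defaults[[fld]]
  ann <- if (!is.null(annotations_tsv)) .readTsv(annotations_tsv) else
    data.frame(gene_id = character(), genome_id = character(), start = integer(),
               end = integer(), strand = character(), annotation = character(),
               source_db = character())
  hosts <- if (!is.null(hosts_fasta)) {
    h <- Biostrings::readDNAStringSet(hosts_fasta)
    names(h) <- sub("\\s.*$", "", names(h))
    h
  } else Biostrings::DNAStringSet()
  empty_links <- data.frame(source_genome = character(), target_genome = character(),
                            array_id = character(), spacer_index = integer(),
                            mismatches = integer(), strand = character(),
                            target_start = integer(), decoy = logical())
  methods::new("PhageCommunity", genomes = gset, hosts = hosts,
               metadata = S4Vectors::DataFrame(md), annotations = ann,
               arrays = data.frame(), spacers = data.frame(),
               truth = list(cluster_of = character(), habitat_of = character(),
                            recoded = character(),
                            planted_spacer_links = empty_links,
                            planted_host_links = empty_links),
               config = list())
}

#' Proteins of a genome from its ORFs
#'
#' Translates the forward-coordinate ORFs of a six-frame scan (standard code
#' by default, terminal stop removed) into an `AAStringSet`, used as the
#' proteome for AAI computations.
#'
#' @param seq DNA sequence.
#' @param code genetic code for the ORF scan.
#' @param min_orf_nt minimum ORF length (default 240 nt, i.e. 80 aa).
#' @return `AAStringSet`.
#' @export
genomeProteins <- function(seq, code = 11, min_orf_nt = 240) {
  orfs <- scanOrfs(seq, code = code, min_orf_nt = min_orf_nt)
  s <- Biostrings::DNAString(toupper(as.character(seq)))
  if (!nrow(orfs)) return(Biostrings::AAStringSet())
  aas <- lapply(seq_len(nrow(orfs)), function(i) {
    sub <- Biostrings::subseq(s, orfs$start[i] + 1L, orfs$end[i])
    if (orfs$strand[i] == "-") sub <- Biostrings::reverseComplement(sub)
    aa <- suppressWarnings(Biostrings::translate(sub, if.fuzzy.codon = "X"))
    gsub("\\*.*$", "", as.character(aa))
  })
  out <- Biostrings::AAStringSet(unlist(aas))
  out <- out[Biostrings::width(out) >= min_orf_nt / 3 - 1]
  names(out) <- sprintf("orf_%03d", seq_along(out))
  out
}

.defaultRunParams <- function() {
  list(min_length = 3000, busco_max = 0.067,
       min_orf_nt = 90, min_gain = 0.10,
       ani_min = 95, af_min = 0.85, fragment_bp = 1000,
       min_genomes = 4, min_habitats = 2, alpha = 0.05,
       coevolution_distance = "ani", coevolution_p_adjust = "none",
       max_mismatch = 1)
}

#' Demonstration pipeline configuration on a synthetic community
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @return a config list accepted by [runPipeline()].
#' @export
demoRunConfig <- function(outdir, seed = 1L) {
  list(seed = as.integer(seed), outdir = outdir,
       synth = list(n_clusters = 3L, genomes_per_cluster = 4L,
                    habitats = c("pig_gut", "human_gut"),
                    genome_length = 8000L,
                    within_habitat_divergence = 0.002,
                    between_habitat_divergence = 0.006,
                    n_arrays = 2L, n_hosts = 2L,
                    spacers_per_array = 2L),
       reference_ids = character(),
       stages = list(screen = TRUE, recode = TRUE, cluster = TRUE,
                     phylo = TRUE, crisprnet = TRUE),
       params = utils::modifyList(.defaultRunParams(),
                                  list(coevolution_distance = "hamming")))
}

.loadRunConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$outdir)) stop("run config must name an output directory")
  stages <- list(screen = TRUE, recode = TRUE, cluster = TRUE,
                 phylo = TRUE, crisprnet = TRUE)
  for (s in names(config$stages)) stages[[s]] <- isTRUE(config$stages[[s]])
  config$stages <- stages
  params <- .defaultRunParams()
  for (p in names(config$params)) params[[p]] <- config$params[[p]]
  config$params <- params
  if (is.null(config$reference_ids)) config$reference_ids <- character()
  if (length(config$reference_ids) == 1L && file.exists(config$reference_ids))
    config$reference_ids <- readLines(config$reference_ids)
  config
}

#' Run the full analysis pipeline
#'
#' Stages run in order screen -> recode -> cluster -> phylo (coevolution) ->
#' crisprnet; each stage reads only declared inputs and prior-stage results.
#' A failing stage aborts with the stage named and leaves a
#' `_FAILED_<stage>` marker next to the partial outputs. Outputs are flat
#' TSV/JSON/Newick files; everything except the timing report is
#' byte-reproducible for a fixed config.
#'
#' @param config a config list (see [demoRunConfig()]) or the path of a YAML
#'   file with the same structure: `seed`, `outdir`, either `synth`
#'   (a [communityConfig()] field list) or `inputs` (paths `genomes_fasta`,
#'   `metadata_tsv`, `annotations_tsv`, `hosts_fasta`, `taxonomy_tsv`),
#'   `reference_ids`, `stages`, `params`.
#' @return invisibly, the run report (per-stage row counts, parameter echo,
#'   warnings, timings), also written to `report.json`.
#' @export
runPipeline <- function(config) {
  config <- .loadRunConfig(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = config$params, seed = config$seed,
                 stages = list(), files = list(), warnings = character())
  t_all <- proc.time()[["elapsed"]]

  emit <- function(name, df) {
    path <- file.path(outdir, name)
    .writeTsv(df, path)
    report$files[[name]] <<- nrow(df)
  }
  stage <- function(name, enabled, fun) {
    if (!enabled) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      writeLines(conditionMessage(e), file.path(outdir, paste0("_FAILED_", name)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(ok)
  }

  # inputs ------------------------------------------------------------------
  taxonomy <- NULL
  if (!is.null(config$synth)) {
    syn <- config$synth
    syn$seed <- config$seed
    ccfg <- do.call(communityConfig, syn)
    community <- generateCommunity(ccfg)
    community <- plantCrisprLinks(community, ccfg)
    if (length(hostGenomes(community))) {
      genera <- c("Prevotella", "Lachnospira", "Bacteroides")
      taxonomy <- data.frame(
        genome_id = names(hostGenomes(community)),
        genus = rep(genera, length.out = length(hostGenomes(community))),
        phylum = "Bacteroidota", stringsAsFactors = FALSE)
    }
    writeCommunity(community, outdir)
  } else {
    inp <- config$inputs
    community <- readCommunity(inp$genomes_fasta, inp$metadata_tsv,
                               inp$annotations_tsv, inp$hosts_fasta)
    if (!is.null(inp$taxonomy_tsv)) taxonomy <- .readTsv(inp$taxonomy_tsv)
  }
  md <- as.data.frame(communityMetadata(community))
  prm <- config$params

  # screen -------------------------------------------------------------------
  verdicts <- NULL
  stage("screen", config$stages$screen, function() {
    verdicts <<- screenGenomes(community, min_length = prm$min_length,
                               busco_max = prm$busco_max)
    emit("screen_verdicts.tsv", verdicts)
  })
  retained <- if (is.null(verdicts)) names(genomes(community)) else
    verdicts$genome_id[verdicts$passed]
  gset <- genomes(community)[retained]

  # recode -------------------------------------------------------------------
  stage("recode", config$stages$recode, function() {
    rec <- detectRecoding(gset, min_orf_nt = prm$min_orf_nt,
                          min_gain = prm$min_gain)
    emit("genetic_codes.tsv", rec)
  })

  # cluster ------------------------------------------------------------------
  species <- NULL
  genus <- NULL
  stage("cluster", config$stages$cluster, function() {
    species <<- speciesClusters(gset, ani_min = prm$ani_min, af_min = prm$af_min,
                                fragment_bp = prm$fragment_bp)
    species <<- flagNovel(species, config$reference_ids)
    emit("species_clusters.tsv",
         data.frame(genome_id = names(clusterAssignment(species)),
                    cluster_id = unname(clusterAssignment(species))))
    emit("species_novelty.tsv",
         data.frame(cluster_id = names(isNovel(species)),
                    novel = unname(isNovel(species))))
    # genus/family AAI runs on species representatives; membership propagates
    # through the species assignment (dereplication keeps this desk-scale)
    cents <- clusterCentroids(species)
    prots <- lapply(cents, function(g) genomeProteins(gset[[g]]))
    names(prots) <- names(cents)
    rows <- list()
    cn <- names(cents)
    if (length(cn) > 1L) {
      for (i in seq_len(length(cn) - 1L)) for (j in seq.int(i + 1L, length(cn))) {
        ps <- proteomeSimilarity(prots[[cn[i]]], prots[[cn[j]]])
        rows[[length(rows) + 1L]] <- data.frame(
          a = cn[i], b = cn[j], aai = ps$aai,
          shared_fraction = ps$shared_fraction, n_rbh = ps$n_rbh)
      }
    }
    sim <- if (length(rows)) do.call(rbind, rows) else
      data.frame(a = character(), b = character(), aai = numeric(),
                 shared_fraction = numeric(), n_rbh = integer())
    emit("aai_pairs.tsv", sim)
    for (rank in c("genus", "family")) {
      oc <- operationalClusters(sim, rank = rank, nodes = cn)
      asg_c <- clusterAssignment(oc)
      asg <- asg_c[clusterAssignment(species)]  # propagate via species cluster
      names(asg) <- names(clusterAssignment(species))
      full <- methods::new("ClusterSet", rank = rank, assignment = asg,
                           centroids = character(), novel = logical())
      full <- flagNovel(full, config$reference_ids)
      if (rank == "genus") genus <<- full
      emit(paste0(rank, "_clusters.tsv"),
           data.frame(genome_id = names(asg), cluster_id = unname(asg)))
    }
    acc <- accumulationCurve(species)
    emit("species_accumulation.tsv", acc)
  })

  # phylo / coevolution ------------------------------------------------------
  stage("phylo", config$stages$phylo && !is.null(genus), function() {
    habitats <- stats::setNames(md$habitat, md$genome_id)
    rows <- list()
    pd_rows <- list()
    asg <- clusterAssignment(genus)
    for (cl in sort(unique(asg))) {
      members <- sort(names(asg)[asg == cl])
      res_row <- data.frame(cluster_id = cl, n = length(members),
                            eligible = FALSE, reason = NA_character_,
                            p_between_greater = NA_real_,
                            p_within_greater = NA_real_, coevolved = FALSE,
                            stringsAsFactors = FALSE)
      if (length(members) >= prm$min_genomes &&
          length(unique(habitats[members])) >= prm$min_habitats) {
        # hamming is exact for equal-length substitution-only genomes (the
        # synthetic generator); fragment ANI is the general route
        if (identical(prm$coevolution_distance, "hamming") &&
            length(unique(Biostrings::width(gset[members]))) == 1L) {
          dm <- hammingDistances(gset[members])
        } else {
          sim <- aniPairs(gset[members], fragment_bp = prm$fragment_bp)
          dm <- matrix(1, length(members), length(members),
                       dimnames = list(members, members))
          diag(dm) <- 0
          for (r in seq_len(nrow(sim))) {
            v <- 1 - sim$ani[r] / 100
            dm[sim$a[r], sim$b[r]] <- v
            dm[sim$b[r], sim$a[r]] <- v
          }
        }
        res <- coevolutionTest(dm, habitats[members],
                               min_genomes = prm$min_genomes,
                               min_habitats = prm$min_habitats,
                               alpha = prm$alpha)
        res_row$eligible <- res$eligible
        res_row$reason <- res$reason
        res_row$p_between_greater <- res$p_between_greater
        res_row$p_within_greater <- res$p_within_greater
        res_row$coevolved <- res$coevolved
        tree <- njTree(dm)
        ape::write.tree(tree, file.path(outdir, paste0("tree_", cl, ".nwk")))
        report$files[[paste0("tree_", cl, ".nwk")]] <<- length(tree$tip.label)
        for (h in unique(habitats[members])) {
          tips <- members[habitats[members] == h]
          pd_rows[[paste0(cl, h)]] <- data.frame(
            cluster_id = cl, habitat = h, n_tips = length(tips),
            pd_coverage = pdCoverage(tree, tips), stringsAsFactors = FALSE)
        }
      } else {
        res_row$reason <- "ineligible by size or habitat count"
      }
      rows[[cl]] <- res_row
    }
    coev <- do.call(rbind, rows)
    if (identical(prm$coevolution_p_adjust, "BH")) {
      # multiplicity correction across clusters; the verdict then uses the
      # adjusted p-values
      coev$p_adjusted <- stats::p.adjust(coev$p_between_greater, method = "BH")
      coev$coevolved <- !is.na(coev$p_adjusted) & coev$p_adjusted < prm$alpha
    }
    emit("coevolution.tsv", coev)
    if (length(pd_rows)) emit("pd_coverage.tsv", do.call(rbind, pd_rows))
  })

  # crisprnet ----------------------------------------------------------------
  stage("crisprnet", config$stages$crisprnet, function() {
    all_genomes <- c(genomes(community), hostGenomes(community))
    found <- findArraysAll(all_genomes)
    if (is.null(found$arrays)) {
      found <- list(arrays = data.frame(), spacers = data.frame())
    }
    emit("crispr_arrays.tsv", found$arrays)
    if (nrow(found$spacers)) {
      sp <- Biostrings::DNAStringSet(found$spacers$seq)
      names(sp) <- found$spacers$spacer_id
      Biostrings::writeXStringSet(sp, file.path(outdir, "crispr_spacers.fasta"),
                                  width = 80L)
      report$files[["crispr_spacers.fasta"]] <<- length(sp)
    }
    hits <- if (nrow(found$spacers))
      matchSpacers(found$spacers, genomes(community),
                   max_mismatch = prm$max_mismatch) else
      matchSpacers(data.frame(), genomes(community))
    emit("spacer_hits.tsv", hits)
    host_ids <- names(hostGenomes(community))
    host_hits <- hits[hits$source_genome %in% host_ids, , drop = FALSE]
    phage_hits <- hits[!hits$source_genome %in% host_ids, , drop = FALSE]
    tax <- if (is.null(taxonomy))
      data.frame(genome_id = character(), genus = character()) else taxonomy
    hp <- predictHosts(host_hits, tax, phage_ids = names(genomes(community)))
    emit("host_predictions.tsv", hp)
    net <- buildInteractionNetwork(phage_hits, hp)
    emit("interaction_network.tsv", net)
    if (nrow(net)) {
      writeNetworkGraphML(net, file.path(outdir, "interaction_network.graphml"))
      report$files[["interaction_network.graphml"]] <<- nrow(net)
    }
  })

  # summary ------------------------------------------------------------------
  summary <- summarizeRun(outdir)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$seconds_total <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.tallyOrAbsent <- function(path, fun) {
  if (!file.exists(path)) return("absent")
  fun(.readTsv(path))
}

#' Summary tallies of a pipeline run
#'
#' Recomputes the study-style tallies from the flat output files of
#' [runPipeline()]: genomes per size class, lifestyle fractions,
#' alternative-code counts, clusters per rank, novel and coevolved cluster
#' fractions, host-range classes and interaction edge types. A missing stage
#' output yields the tally `"absent"` rather than an error.
#'
#' @param outdir the pipeline output directory.
#' @return nested list of tallies.
#' @export
summarizeRun <- function(outdir) {
  list(
    size_class = .tallyOrAbsent(file.path(outdir, "screen_verdicts.tsv"),
      function(v) as.list(table(v$size_class))),
    screened_passed = .tallyOrAbsent(file.path(outdir, "screen_verdicts.tsv"),
      function(v) sum(v$passed)),
    lifestyle_fractions = .tallyOrAbsent(file.path(outdir, "screen_verdicts.tsv"),
      function(v) as.list(round(table(v$lifestyle) / nrow(v), 4))),
    genetic_codes = .tallyOrAbsent(file.path(outdir, "genetic_codes.tsv"),
      function(v) as.list(table(v$assigned_code))),
    clusters_per_rank = list(
      species = .tallyOrAbsent(file.path(outdir, "species_clusters.tsv"),
        function(v) length(unique(v$cluster_id))),
      genus = .tallyOrAbsent(file.path(outdir, "genus_clusters.tsv"),
        function(v) length(unique(v$cluster_id))),
      family = .tallyOrAbsent(file.path(outdir, "family_clusters.tsv"),
        function(v) length(unique(v$cluster_id)))),
    novel_species_fraction = .tallyOrAbsent(file.path(outdir, "species_novelty.tsv"),
      function(v) round(mean(v$novel), 4)),
    coevolved_fraction = .tallyOrAbsent(file.path(outdir, "coevolution.tsv"),
      function(v) if (any(v$eligible)) round(mean(v$coevolved[v$eligible]), 4) else NA),
    host_range = .tallyOrAbsent(file.path(outdir, "host_predictions.tsv"),
      function(v) as.list(table(v$range_class))),
    interaction_edges = .tallyOrAbsent(file.path(outdir, "interaction_network.tsv"),
      function(v) list(single = sum(v$direction == "single"),
                       double = sum(v$direction == "double"),
                       competitive = sum(v$competitive))))
}
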