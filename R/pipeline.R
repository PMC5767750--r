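#' Pipeline configuration
#'
#' Collects the input paths (or in-memory tables) and stage parameters of
#' a full run. Only \code{evidence} is mandatory; stages whose inputs are
#' absent are skipped. A config round-trips losslessly through YAML/JSON
#' when all inputs are given as paths.
#'
#' @param evidence path to an evidence TSV, or an evidence data.frame.
#' @param fasta optional protein FASTA path (or named character vector)
#'   for the phospho stage.
#' @param phosphopeptides optional phosphopeptide TSV path (or
#'   data.frame).
#' @param hits optional BLAST outfmt-6 path (or data.frame) for ortholog
#'   mapping.
#' @param edges optional 3-column edge-list TSV path (or data.frame).
#' @param terms optional term-to-gene TSV path (or data.frame).
#' @param filter a \code{\link{filter_config}}.
#' @param scd an \code{\link{scd_config}}.
#' @param align an \code{\link{align_params}}.
#' @param score_threshold edge retention threshold (default 0.4).
#' @param e_max ortholog E-value threshold (default 1e-5).
#' @param seed integer seed recorded in the summary.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(evidence, fasta = NULL, phosphopeptides = NULL,
                            hits = NULL, edges = NULL, terms = NULL,
                            filter = filter_config(), scd = scd_config(),
                            align = align_params(), score_threshold = 0.4,
                            e_max = 1e-5, seed = 1L) {
  structure(list(evidence = evidence, fasta = fasta,
                 phosphopeptides = phosphopeptides, hits = hits,
                 edges = edges, terms = terms, filter = filter, scd = scd,
                 align = align, score_threshold = score_threshold,
                 e_max = e_max, seed = seed),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Scalar keys map to \code{\link{pipeline_config}} arguments; nested
#' \code{filter}/\code{scd}/\code{align} blocks map to their constructors.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw
  if (!is.null(raw$filter)) args$filter <- do.call(filter_config, raw$filter)
  if (!is.null(raw$scd)) args$scd <- do.call(scd_config, raw$scd)
  if (!is.null(raw$align)) args$align <- do.call(align_params, raw$align)
  do.call(pipeline_config, args)
}

resolve_input <- function(x, reader) {
  if (is.null(x) || is.data.frame(x) ||
      (is.character(x) && !is.null(names(x)))) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) return(reader(x))
  if (is.character(x) && length(x) == 1)
    stop("input file not found: ", x)
  x
}

stage_fail <- function(stage, msg) {
  stop("pipeline stage '", stage, "' failed: ", msg, call. = FALSE)
}

#' Run the full co-IP analysis pipeline
#'
#' Executes, in order: peptide-to-protein aggregation and per-dataset
#' moderated-t quantification; two-tier protein acceptance; ortholog
#' best-hit assignment and locus collapse; tissue overlap; interaction
#' network construction and component analysis; term over-representation;
#' and phosphosite annotation with cluster-domain detection. Stages with
#' missing inputs are skipped; a stage error aborts the run with the
#' failing stage named. Per-stage TSVs are written under \code{out_dir}
#' together with a machine-readable \code{summary.json}; every number in
#' the summary is recomputable from those TSVs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage progress messages on stderr.
#' @return the summary, invisibly (a named list).
#' @export
run_pipeline <- function(config, out_dir = tempfile("coipnet_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[coipnet] ", ...)
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    say(sprintf("%-14s %6.2fs", stage, proc.time()[["elapsed"]] - t0))
  }
  summary <- list(seed = config$seed)

  # --- quantification -------------------------------------------------
  evidence <- resolve_input(config$evidence, read_evidence)
  if (is.null(evidence) || nrow(evidence) == 0L)
    stage_fail("quantify", "evidence table is empty")
  quant <- quantify_all(evidence, fc_min = config$filter$fc_min,
                        p_max = config$filter$p_max)
  write_tsv(quant, file.path(out_dir, "quantification.tsv"))
  summary$n_datasets <- length(unique(evidence$dataset_id))
  summary$n_proteins_quantified <- length(unique(quant$protein_id))
  summary$n_significant_calls <- sum(quant$significant)
  tick("quantify")

  # --- acceptance -----------------------------------------------------
  accepted <- accept_proteins(evidence, quant, config$filter)
  write_tsv(accepted, file.path(out_dir, "accepted_proteins.tsv"))
  summary$n_accepted <- nrow(accepted)
  summary$n_quantitative <- sum(accepted$tier == "quantitative")
  summary$n_qualitative <- sum(accepted$tier == "qualitative")
  tick("accept")

  # --- ortholog mapping -----------------------------------------------
  assignments <- NULL
  if (!is.null(config$hits)) {
    hits <- resolve_input(config$hits, read_blast_tab)
    assignments <- assign_best_hits(hits, e_max = config$e_max,
                                    query_ids = accepted$protein_id)
    assignments <- assignments[assignments$query_id %in%
                                 accepted$protein_id, , drop = FALSE]
    collapse <- collapse_to_loci(assignments)
    write_tsv(assignments, file.path(out_dir, "ortholog_assignments.tsv"))
    write_tsv(collapse$many_to_one, file.path(out_dir, "locus_collapse.tsv"))
    summary$n_loci <- length(collapse$loci)
    summary$n_unassigned <- length(collapse$unassigned)
    tick("map-orthologs")
  }

  # --- tissue overlap -------------------------------------------------
  ov <- tissue_overlap(accepted, assignments)
  summary$tissue_overlap_protein <- as.list(ov$protein)
  if (!is.null(ov$locus)) summary$tissue_overlap_locus <- as.list(ov$locus)
  tick("tissue-overlap")

  # --- network --------------------------------------------------------
  if (!is.null(config$edges)) {
    edges <- resolve_input(config$edges, read_edge_list)
    universe <- if (!is.null(assignments))
      sort(unique(assignments$subject_locus[!is.na(assignments$subject_locus)]))
    else accepted$protein_id
    graph <- build_graph(edges, universe, config$score_threshold)
    cs <- component_summary(graph)
    write_graph_files(graph,
                      sif = file.path(out_dir, "network.sif"),
                      membership = file.path(out_dir,
                                             "network_membership.tsv"))
    summary$network <- list(n_nodes = length(graph$node_universe),
                            n_edges = nrow(graph$edges),
                            main_size = cs$main_size,
                            n_orphans = cs$n_orphans,
                            main_fraction = cs$main_fraction,
                            orphan_ids = cs$orphan_ids)
    tick("network")
  }

  # --- enrichment -----------------------------------------------------
  if (!is.null(config$terms)) {
    terms <- resolve_input(config$terms, read_term_map)
    background <- sort(unique(terms$gene_id))
    study <- if (!is.null(assignments))
      intersect(unique(assignments$subject_locus), background)
    else intersect(accepted$protein_id, background)
    if (length(study) == 0L)
      stage_fail("enrich", "no accepted ids in the annotation background")
    enr <- hypergeometric_enrichment(study, background, terms)
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    summary$n_terms_tested <- nrow(enr)
    summary$n_terms_q05 <- sum(enr$q_value < 0.05)
    tick("enrich")
  }

  # --- phospho --------------------------------------------------------
  if (!is.null(config$phosphopeptides)) {
    peptides <- resolve_input(config$phosphopeptides, read_phosphopeptides)
    proteins <- resolve_input(config$fasta, read_fasta)
    sites <- phospho_sites(peptides, proteins)
    write_tsv(sites, file.path(out_dir, "phospho_sites.tsv"))
    psum <- phospho_summary(sites)
    write_tsv(psum, file.path(out_dir, "phospho_summary.tsv"))
    summary$phospho <- lapply(seq_len(nrow(psum)), function(i)
      as.list(psum[i, ]))
    names(summary$phospho) <- psum$protein_id
    if (!is.null(proteins)) {
      scds <- do.call(rbind, lapply(names(proteins), function(pid) {
        r <- detect_scd(proteins[[pid]], config$scd)
        if (nrow(r)) cbind(protein_id = pid, r) else NULL
      }))
      if (!is.null(scds))
        write_tsv(scds, file.path(out_dir, "scd_regions.tsv"))
      summary$n_scd_regions <- if (is.null(scds)) 0L else nrow(scds)
    }
    tick("phospho")
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("summary written to ", file.path(out_dir, "summary.json"))
  invisible(summary)
}

#' Phospho-only report from a phosphopeptide table
#'
#' Convenience mode for running only the phosphosite stage, e.g. on the
#' packaged BoASY1/BoASY3 phosphopeptide table.
#'
#' @param peptides phosphopeptide table path or data.frame (default: the
#'   packaged BoASY1/BoASY3 table).
#' @param proteins optional FASTA path or named character vector of full
#'   sequences.
#' @return list with \code{sites} and \code{summary} data.frames.
#' @export
phospho_report <- function(peptides = system.file(
                             "extdata", "boasy_phosphopeptides_tbl1.tsv",
                             package = "coipnet"),
                           proteins = NULL) {
  peptides <- resolve_input(peptides, read_phosphopeptides)
  proteins <- resolve_input(proteins, read_fasta)
  sites <- phospho_sites(peptides, proteins)
  list(sites = sites, summary = phospho_summary(sites))
}

#' Generate a complete synthetic demonstration bundle
#'
#' Writes every pipeline input (evidence, FASTA, phosphopeptides, BLAST
#' hits, edges, terms) for a self-contained run with known ground truth,
#' and returns the matching \code{\link{pipeline_config}} plus truth
#' objects.
#'
#' @param dir directory for the bundle files.
#' @param seed integer seed driving every generator.
#' @return list: \code{config}, \code{truth} (per generator),
#'   \code{files}.
#' @export
demo_bundle <- function(dir = tempfile("coipnet_demo_"), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coip <- simulate_coip(coip_sim_config(seed = seed))
  write_evidence(coip$evidence, file.path(dir, "evidence.tsv"))

  prot <- simulate_proteome(seed = seed + 1L)
  write_fasta(prot$sequences, file.path(dir, "proteome.fasta"))
  peps <- simulate_phosphopeptides(prot, seed = seed + 2L)
  write_tsv(peps, file.path(dir, "phosphopeptides.tsv"))

  accepted_ids <- sort(c(coip$truth$true_complex_ids,
                         coip$truth$sample_specific_ids))
  hits <- simulate_ortholog_hits(accepted_ids, triplication_factor = 1.2,
                                 n_no_hit = 1, seed = seed + 3L)
  utils::write.table(hits, file.path(dir, "hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  loci <- sort(unique(normalize_locus(
    assign_best_hits(hits, query_ids = accepted_ids)$subject_locus)))
  net <- simulate_network(loci, main_fraction = 0.9,
                          n_orphans = length(loci) - ceiling(0.9 * length(loci)),
                          seed = seed + 4L)
  write_tsv(net$edges, file.path(dir, "edges.tsv"))

  terms <- do.call(rbind, lapply(sprintf("TERM%02d", 1:8), function(t) {
    set.seed(seed + 5L + match(t, sprintf("TERM%02d", 1:8)))
    data.frame(term_id = t,
               gene_id = sample(loci, min(length(loci),
                                          sample(5:15, 1))),
               stringsAsFactors = FALSE)
  }))
  write_tsv(terms, file.path(dir, "terms.tsv"))

  files <- list(evidence = file.path(dir, "evidence.tsv"),
                fasta = file.path(dir, "proteome.fasta"),
                phosphopeptides = file.path(dir, "phosphopeptides.tsv"),
                hits = file.path(dir, "hits.tsv"),
                edges = file.path(dir, "edges.tsv"),
                terms = file.path(dir, "terms.tsv"))
  config <- pipeline_config(evidence = files$evidence, fasta = files$fasta,
                            phosphopeptides = files$phosphopeptides,
                            hits = files$hits, edges = files$edges,
                            terms = files$terms, seed = seed)
  list(config = config,
       truth = list(coip = coip$truth, proteome = prot$truth,
                    network = net$truth),
       files = files)
}
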