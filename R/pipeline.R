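#' Configuration for the consensus genome-recovery pipeline
#'
#' Bundles the synthetic community, per-stage parameters and the global
#' seed. Depths are mean target-genome depths; per-cell read counts follow
#' as `depth * genome_length / mean_read_length`.
#'
#' @param community A [community_spec()] (default [default_community()]).
#' @param n_cells Number of single cells (default 5).
#' @param cell_depth Mean target depth per cell (default 20).
#' @param bulk_depth Mean target depth of the bulk enrichment (default 20).
#' @param n_pairs Bulk paired-end pairs used for scaffolding (default 500).
#' @param model A [read_model()].
#' @param filter A [filter_params()]; when `derive_threshold` is TRUE the
#'   GC threshold is re-derived from the single-cell read sets.
#' @param derive_threshold Derive the GC cutoff from the cells (default
#'   TRUE).
#' @param map A [map_criteria()] for mapping/rescue/chimera calls.
#' @param shred A [shred_params()].
#' @param min_overlap,min_overlap_identity Assembler thresholds.
#' @param rescue_references Optional sequence-record tibble of related
#'   reference genomes for high-GC read rescue (`NULL` = skip rescue).
#' @param contaminant_references Contaminant genomes for the final screen;
#'   `NULL` (default) screens against the community's own contaminant
#'   genomes, mirroring screening against known reagent contaminants.
#' @param order_reference Reference genome for orientation/ordering;
#'   `NULL` (default) uses the community's target genome as the related
#'   reference.
#' @param scoring An [align_scoring()].
#' @param seed Global seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(community = default_community(),
                            n_cells = 5L, cell_depth = 20, bulk_depth = 20,
                            n_pairs = 500L, model = read_model(),
                            filter = filter_params(),
                            derive_threshold = TRUE,
                            map = map_criteria(), shred = shred_params(),
                            min_overlap = 40L, min_overlap_identity = 0.97,
                            rescue_references = NULL,
                            contaminant_references = NULL,
                            order_reference = NULL,
                            scoring = align_scoring(), seed = 1L) {
  structure(list(
    community = community, n_cells = as.integer(n_cells),
    cell_depth = cell_depth, bulk_depth = bulk_depth,
    n_pairs = as.integer(n_pairs), model = model, filter = filter,
    derive_threshold = derive_threshold, map = map, shred = shred,
    min_overlap = as.integer(min_overlap),
    min_overlap_identity = min_overlap_identity,
    rescue_references = rescue_references,
    contaminant_references = contaminant_references,
    order_reference = order_reference, scoring = scoring,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the end-to-end consensus genome-recovery pipeline
#'
#' Stage order: simulate per-cell and bulk datasets; derive the stringent
#' GC filter from the single-cell reads and remove high-GC bulk reads
#' (rescuing those that map to related references); assemble the filtered
#' bulk reads; map single-cell reads to that initial assembly and exclude
#' split-aligning chimeras; assemble the single-cell reads; shred their
#' contigs into 550-mer pseudo-reads; assemble the consensus from filtered
#' bulk reads, rescued reads and pseudo-reads; scaffold with bulk pairs;
#' screen contigs against known contaminants; orient and order the
#' surviving elements against the reference. Fully deterministic under the
#' config seed.
#'
#' @param config A [pipeline_config()].
#' @return A `consensus_run` list: `config`, `community`, `cells`
#'   (simulated samples), `bulk`, `gc_threshold`, `filtered`, `rescued`,
#'   `initial_assembly`, `enrichment_clean` (bulk reads surviving the
#'   chimera check against the single-cell assembly),
#'   `bulk_chimera_calls`, `chimera_calls` (single-cell reads),
#'   `cell_assembly`, `pseudo_reads`, `consensus` (final screened
#'   assembly), `screen`, `layout`, `stats`, `provenance`.
#' @export
run_consensus <- function(config = pipeline_config()) {
  seed <- config$seed
  comm <- build_community(config$community, seed = derive_seed(seed, "comm"))
  target_id <- comm$weights$genome[comm$weights$role == "target"][1]
  target_len <- comm$weights$length[comm$weights$role == "target"][1]
  mean_len <- config$model$mean_len
  prov <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    prov[[length(prov) + 1]] <<- tibble(stage = stage, n_in = n_in,
                                        n_out = n_out, detail = detail)
  }

  # single cells: pure target, independent bias profiles
  target_only <- build_community(
    community_spec(config$community$target, list(), target_fraction = 1),
    seed = derive_seed(seed, "comm"))
  n_cell_reads <- round(config$cell_depth * target_len / mean_len)
  cells <- lapply(seq_len(config$n_cells), function(i) {
    prof <- simulate_bias_profile(target_len,
                                  seed = derive_seed(seed, paste0("cell", i)))
    sim <- simulate_reads(target_only,
                          bias = setNames(list(prof), target_id),
                          n_reads = n_cell_reads, model = config$model,
                          sample_label = sprintf("cell%02d", i),
                          seed = derive_seed(seed, paste0("cellreads", i)))
    sim$bias <- prof
    sim
  })

  # bulk enrichment: all genomes, mild bias, no dropout
  bulk_bias <- setNames(lapply(seq_len(nrow(comm$genomes)), function(i) {
    bulk_bias_profile(nchar(comm$genomes$bases[i]),
                      seed = derive_seed(seed, paste0("bulkbias", i)))
  }), comm$genomes$id)
  target_share <- comm$weights$cell_fraction[comm$weights$role == "target"][1]
  n_bulk <- round(config$bulk_depth * target_len / mean_len / target_share)
  bulk <- simulate_reads(comm, bias = bulk_bias, n_reads = n_bulk,
                         model = config$model, sample_label = "enrichment",
                         seed = derive_seed(seed, "bulkreads"))
  pairs <- if (config$n_pairs > 0) {
    simulate_reads(comm, bias = bulk_bias, n_reads = 2L * config$n_pairs,
                   model = config$model, paired = TRUE,
                   sample_label = "enrichment_pe",
                   seed = derive_seed(seed, "bulkpairs"))
  } else NULL

  # stringent GC filter derived from the single-cell datasets
  gc_thr <- if (config$derive_threshold) {
    derive_gc_threshold(lapply(cells, function(x) x$reads))
  } else config$filter$gc_threshold
  fp <- filter_params(gc_threshold = gc_thr,
                      rescue_criteria = config$filter$rescue_criteria)
  flt <- gc_filter(bulk$reads, fp)
  note("gc_filter", nrow(bulk$reads), nrow(flt$retained),
       sprintf("threshold %.2f", gc_thr))

  rescued <- if (!is.null(config$rescue_references)) {
    rescue_high_gc(flt$removed, config$rescue_references,
                   criteria = fp$rescue_criteria, scoring = config$scoring)
  } else flt$removed[0, , drop = FALSE]
  note("rescue_high_gc", nrow(flt$removed), nrow(rescued))

  enrichment_reads <- bind_rows(flt$retained, rescued)
  initial <- greedy_assemble(enrichment_reads,
                             min_overlap = config$min_overlap,
                             min_overlap_identity = config$min_overlap_identity)
  note("initial_assembly", nrow(enrichment_reads), nrow(initial$contigs))

  # chimera exclusion: single-cell reads vs the initial bulk assembly
  cell_reads <- bind_rows(lapply(cells, function(x) x$reads))
  calls <- flag_chimeras(cell_reads, initial$contigs, criteria = config$map,
                         scoring = config$scoring)
  keep_ids <- calls$read_id[!calls$is_chimeric]
  cell_clean <- cell_reads[cell_reads$id %in% keep_ids, , drop = FALSE]
  note("chimera_exclusion", nrow(cell_reads), nrow(cell_clean),
       sprintf("%d flagged", sum(calls$is_chimeric)))

  cell_asm <- greedy_assemble(cell_clean, min_overlap = config$min_overlap,
                              min_overlap_identity = config$min_overlap_identity)
  pseudo <- shred_contigs(cell_asm$contigs, config$shred)
  note("shred", nrow(cell_asm$contigs), nrow(pseudo))

  # chimeras are independent across datasets, so enrichment chimeras are
  # caught against the single-cell assembly (their own assembly absorbed
  # them contiguously) and excluded from the consensus
  bulk_calls <- flag_chimeras(enrichment_reads, cell_asm$contigs,
                              criteria = config$map,
                              scoring = config$scoring)
  enrichment_clean <- enrichment_reads[
    enrichment_reads$id %in% bulk_calls$read_id[!bulk_calls$is_chimeric], ,
    drop = FALSE]
  note("enrichment_chimera_exclusion", nrow(enrichment_reads),
       nrow(enrichment_clean),
       sprintf("%d flagged", sum(bulk_calls$is_chimeric)))

  consensus_input <- bind_rows(enrichment_clean, pseudo)
  consensus <- greedy_assemble(consensus_input,
                               min_overlap = config$min_overlap,
                               min_overlap_identity = config$min_overlap_identity)
  note("consensus_assembly", nrow(consensus_input), nrow(consensus$contigs))

  if (!is.null(pairs)) {
    consensus <- scaffold_with_pairs(consensus, pairs$reads,
                                     criteria = config$map,
                                     span = config$model$pair_span,
                                     sd_span = config$model$sd_span,
                                     scoring = config$scoring)
  }

  contam_refs <- config$contaminant_references
  if (is.null(contam_refs)) {
    contam_refs <- comm$genomes[comm$genomes$source == "contaminant", ,
                                drop = FALSE]
  }
  screen <- contaminant_screen(consensus$contigs, contam_refs,
                               criteria = config$map,
                               scoring = config$scoring)
  final <- new_assembly(screen$kept,
                        consensus$scaffolds[
                          consensus$scaffolds$contig_id %in% screen$kept$id, ,
                          drop = FALSE])
  note("contaminant_screen", nrow(consensus$contigs), nrow(final$contigs))

  order_ref <- config$order_reference
  if (is.null(order_ref)) {
    order_ref <- comm$genomes[comm$genomes$id == target_id, , drop = FALSE]
  }
  layout <- layout_elements(final$contigs, order_ref,
                            scoring = config$scoring)

  structure(list(
    config = config, community = comm, cells = cells, bulk = bulk,
    pairs = pairs, gc_threshold = gc_thr, filtered = flt,
    rescued = rescued, initial_assembly = initial,
    enrichment_clean = enrichment_clean, bulk_chimera_calls = bulk_calls,
    chimera_calls = calls,
    cell_assembly = cell_asm, pseudo_reads = pseudo, consensus = final,
    screen = screen, layout = layout, stats = assembly_stats(final),
    provenance = bind_rows(prov)
  ), class = "consensus_run")
}

#' @export
print.consensus_run <- function(x, ...) {
  cat("<consensus_run>\n")
  print(x$provenance)
  print(x$stats)
  invisible(x)
}

#' Fraction of a genome covered by assembly contigs
#'
#' Aligns contigs to the genome and measures the covered fraction of the
#' genome (union of accepted hit footprints).
#'
#' @param contigs Contig or sequence-record tibble.
#' @param genome One-row sequence-record tibble.
#' @param criteria A [map_criteria()].
#' @param scoring An [align_scoring()].
#' @return Fraction of genome positions covered.
#' @export
assembly_coverage <- function(contigs, genome, criteria = map_criteria(),
                              scoring = align_scoring()) {
  genome <- as_records(genome)
  if (nrow(contigs) == 0) return(0)
  hits <- local_align(contigs, genome, scoring = scoring, mode = "seeded")
  ok <- accept_hits(hits, criteria)
  if (nrow(ok) == 0) return(0)
  cov <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = ok$s_start + 1L, end = ok$s_end))))
  cov / nchar(genome$bases)
}

#' Consolidated run report
#'
#' A single summary of a completed run: per-dataset read counts, assembly
#' statistics, contaminant screening and layout placement, as a list ready
#' for JSON serialisation.
#'
#' @param run A `consensus_run`.
#' @param path Optional file to write the report to as JSON.
#' @return The report list, invisibly when writing.
#' @export
report <- function(run, path = NULL) {
  stopifnot(inherits(run, "consensus_run"))
  rep <- list(
    datasets = c(
      list(enrichment = nrow(run$bulk$reads)),
      setNames(lapply(run$cells, function(x) nrow(x$reads)),
               paste0("cell", seq_along(run$cells)))
    ),
    gc_threshold = run$gc_threshold,
    reads_retained = nrow(run$filtered$retained),
    reads_removed = nrow(run$filtered$removed),
    reads_rescued = nrow(run$rescued),
    chimeras_excluded = sum(run$chimera_calls$is_chimeric),
    assembly = as.list(run$stats),
    contaminant_contigs_excluded = nrow(run$screen$excluded),
    elements_placed = sum(run$layout$placed),
    provenance = run$provenance
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(rep))
  }
  rep
}
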