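# Configuration-driven orchestration of the full stage-series analysis.

#' Write a complete synthetic dataset to disk
#'
#' Materializes a [synthetic_spec()]'s stage series and annotations as the
#' standard file formats the pipeline consumes (dense-text matrices with
#' bins sidecars, BED, bedGraph, TSV) plus a ready-to-run YAML config.
#' The default four-stage series mimics a developmental progression:
#' strong structure, structureless (TAD and compartment terms off), weak,
#' strong again.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed driving the spec and all sampling.
#' @param stages list of `(tau_mult, kappa_mult, eta_mult)` per stage.
#' @param spec optional `synthetic_spec`; default uses the toy genome.
#' @param params named list of pipeline parameter overrides written into the
#'   config (see [read_run_config()] for the defaults).
#' @return path to the written `config.yaml` (invisibly, with attribute
#'   `truth`).
#' @export
write_synthetic_dataset <- function(dir, seed = 1,
                                    stages = list(c(1, 1, 1), c(0, 0, 1),
                                                  c(0.3, 0.3, 1), c(1, 1, 1)),
                                    spec = NULL, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(spec)) spec <- synthetic_spec(seed = seed)
  truth <- simulate_annotations(spec)
  mats <- stage_series(spec, stages)
  stage_files <- list()
  for (s in names(mats)) {
    f <- file.path(dir, paste0(s, ".matrix"))
    write_contact_matrix(mats[[s]], f)
    stage_files[[s]] <- f
  }
  write_bed(truth$tads, file.path(dir, "tads.bed"))
  write_bed(truth$motifs, file.path(dir, "motifs.bed"))
  write_bed(truth$super_enhancers, file.path(dir, "super_enhancers.bed"))
  write_bed(truth$genes, file.path(dir, "genes.bed"))
  write_bedgraph(truth$gc, file.path(dir, "gc.bedgraph"))
  write_bedgraph(truth$active, file.path(dir, "active.bedgraph"))
  write_bedgraph(truth$reptime, file.path(dir, "reptime.bedgraph"))
  data.table::fwrite(truth$orthologs, file.path(dir, "orthologs.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(gene = rownames(truth$tomoseq),
                                            truth$tomoseq),
                     file.path(dir, "tomoseq.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(gene = rownames(truth$tpm),
                                            truth$tpm),
                     file.path(dir, "tpm.tsv"), sep = "\t")
  cfg <- list(
    stages = stage_files,
    tad_reference_stage = names(mats)[length(mats)],
    annotations = list(
      motifs = file.path(dir, "motifs.bed"),
      super_enhancers = file.path(dir, "super_enhancers.bed"),
      genes = file.path(dir, "genes.bed"),
      gc = file.path(dir, "gc.bedgraph"),
      active = file.path(dir, "active.bedgraph"),
      reptime = file.path(dir, "reptime.bedgraph"),
      orthologs = file.path(dir, "orthologs.tsv"),
      tomoseq = file.path(dir, "tomoseq.tsv"),
      tpm = file.path(dir, "tpm.tsv")),
    params = utils::modifyList(
      list(window_bins = 25, min_strength = 0.1, min_sep = 5e6,
           shift = 1e6, radius_bins = 10, rho_threshold = 0.5,
           dmax = 5, bin_edges = c(100e3, 235e3, 534e3, 1212e3),
           n_subsample = 100, n_shuffles = 50,
           k_entropy = 50, min_section_genes = 100,
           rcf_bins = 50, seed = seed),
      params),
    out_dir = file.path(dir, "results"))
  cfgf <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfgf)
  invisible(structure(cfgf, truth = truth))
}

#' Read and validate a pipeline run configuration
#'
#' @param config a YAML path or an equivalent named list (`stages`,
#'   `tad_reference_stage`, `annotations`, `params`, `out_dir`).
#' @return the validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config$stages), length(config$stages) >= 1,
            !is.null(config$out_dir))
  if (is.null(config$tad_reference_stage))
    config$tad_reference_stage <- names(config$stages)[length(config$stages)]
  files <- c(unlist(config$stages),
             paste0(unlist(config$stages), ".bins"),
             unlist(config$annotations))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing input files: ", paste(missing, collapse = ", "))
  defaults <- list(window_bins = 25, min_strength = 0.1, min_sep = 5e6,
                   shift = 1e6, radius_bins = 10, rho_threshold = 0.5,
                   dmax = 5, bin_edges = c(100e3, 235e3, 534e3, 1212e3),
                   n_subsample = 100, n_shuffles = 50, k_entropy = 1000,
                   min_section_genes = 6000, rcf_bins = 50, seed = 1)
  config$params <- utils::modifyList(defaults, as.list(config$params))
  config
}

#' Run the full stage-series analysis
#'
#' Executes, per stage: insulation scoring, border calling and coverage
#' filtering, aggregate TAD analysis against the reference stage's TAD
#' calls, compartment eigenvector at 100 kb with GC selection and
#' active-mark orientation, relative contact frequency, and intra- and
#' inter-chromosomal PE-SCAn on the super-enhancer anchors. Once, on the
#' reference stage: motif orientation at borders, replication-timing
#' stratification by compartment, TAD synteny conservation, sectioned
#' co-expression and Shannon-entropy classification. All tabular results
#' are written under `out_dir` together with a deterministic
#' `summary.json`.
#'
#' @param config see [read_run_config()].
#' @return the summary list (invisibly); side effect: files under
#'   `config$out_dir`.
#' @export
run_all <- function(config) {
  config <- read_run_config(config)
  p <- config$params
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out, "resolved_config.yaml"))
  ann <- config$annotations
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  log_lines <- c(paste("devhic", as.character(utils::packageVersion("devhic"))),
                 paste("R", getRversion()),
                 paste("seed", p$seed))

  mats <- lapply(config$stages, function(f) run_stage(f, read_contact_matrix(f)))
  asm <- mats[[1]]$assembly
  gc100 <- read_bedgraph(ann$gc, genome_assembly(
    stats::setNames(asm$chrom_lengths, asm$chrom_names), 1e5))
  active100 <- read_bedgraph(ann$active, gc100$assembly)
  reptime100 <- read_bedgraph(ann$reptime, gc100$assembly)
  ses <- read_bed(ann$super_enhancers)

  # reference TAD calls drive ATA, motif profiles, conservation, coexpression
  ref <- config$tad_reference_stage
  refm <- mats[[ref]]
  ins_ref <- insulation_score(refm, w = p$window_bins)
  borders_ref <- filter_borders(call_borders(ins_ref, p$min_strength), refm)
  tads_ref <- borders_to_tads(borders_ref, asm)

  summary <- list(stages = list())
  profiles <- list()
  for (s in names(mats)) {
    m <- mats[[s]]
    st <- list()
    ins <- run_stage(paste0(s, "/insulation"), insulation_score(m, w = p$window_bins))
    write_insulation(ins, file.path(out, paste0(s, "_insulation.bedgraph")))
    bd <- run_stage(paste0(s, "/borders"),
                    filter_borders(call_borders(ins, p$min_strength), m))
    write_borders(bd, file.path(out, paste0(s, "_borders.bed")), asm)
    st$n_borders <- nrow(bd)
    ata <- run_stage(paste0(s, "/ata"), aggregate_tads(m, tads_ref))
    data.table::fwrite(data.table::as.data.table(ata$matrix),
                       file.path(out, paste0(s, "_ata.tsv")), sep = "\t")
    st$ata_strength <- ata$strength
    m100 <- rebin(m, 1e5)
    cp <- run_stage(paste0(s, "/compartments"),
                    compartment_eigenvector(m100, gc100, active100))
    write_compartments(cp, file.path(out, paste0(s, "_compartments")))
    st$compartment_gc_r_abs <- abs(attr(cp, "gc_correlation_genome"))
    profiles[[s]] <- cp
    rcf <- run_stage(paste0(s, "/rcf"), relative_contact_frequency(m, p$rcf_bins))
    data.table::fwrite(rcf, file.path(out, paste0(s, "_rcf.tsv")), sep = "\t")
    pe <- run_stage(paste0(s, "/pescan"),
                    pescan_intra(m, ses, min_sep = p$min_sep, shift = p$shift,
                                 radius_bins = p$radius_bins))
    data.table::fwrite(data.table::as.data.table(pe$normalized),
                       file.path(out, paste0(s, "_pescan.tsv")), sep = "\t")
    st$pescan_center_intra <- pe$normalized[p$radius_bins + 1, p$radius_bins + 1]
    pei <- run_stage(paste0(s, "/pescan_inter"),
                     pescan_inter(m, ses, shift = p$shift,
                                  radius_bins = p$radius_bins))
    st$pescan_center_inter <- pei$normalized[p$radius_bins + 1, p$radius_bins + 1]
    summary$stages[[s]] <- st
  }

  motifs <- read_bed(ann$motifs)
  mp <- run_stage("motif_profile",
                  motif_orientation_profile(motifs, tad_borders(tads_ref),
                                            min_score = 12))
  data.table::fwrite(mp, file.path(out, "motif_orientation.tsv"), sep = "\t")

  strata <- run_stage("replication_timing",
                      stratify_by_compartment(reptime100, profiles[[ref]]))
  summary$reptime_a_median <- strata$summary$median[strata$summary$label == "A"]
  summary$reptime_b_median <- strata$summary$median[strata$summary$label == "B"]
  summary$reptime_p_a_gt_b <- strata$p_a_gt_b

  cons <- run_stage("conservation",
                    tad_conservation(tads_ref, as.data.frame(
                      data.table::fread(ann$orthologs)),
                      bin_edges = p$bin_edges, n_subsample = p$n_subsample,
                      seed = p$seed))
  data.table::fwrite(cons, file.path(out, "conservation.tsv"), sep = "\t")
  summary$conservation_intra <- mean(cons$intra_score, na.rm = TRUE)
  summary$conservation_inter <- mean(cons$inter_score, na.rm = TRUE)

  genes <- read_bed(ann$genes)
  tomo <- as.data.frame(data.table::fread(ann$tomoseq))
  expr <- as.matrix(tomo[, -1]); rownames(expr) <- tomo[[1]]
  expr <- run_stage("coexpression/qc", qc_sections(expr, p$min_section_genes))
  cx <- run_stage("coexpression",
                  coexpression_stratified(expr, genes, tads_ref,
                                          rho_threshold = p$rho_threshold,
                                          dmax = p$dmax))
  data.table::fwrite(cx, file.path(out, "coexpression.tsv"), sep = "\t")
  summary$coexpression_combined_p <- attr(cx, "combined_p")

  tpmdf <- as.data.frame(data.table::fread(ann$tpm))
  tpm <- as.matrix(tpmdf[, -1]); rownames(tpm) <- tpmdf[[1]]
  ent <- run_stage("entropy", shannon_classify(tpm, k = p$k_entropy))
  data.table::fwrite(ent, file.path(out, "entropy.tsv"), sep = "\t")
  summary$entropy_housekeeping_mean <-
    mean(ent$entropy[ent$class == "housekeeping"])
  summary$entropy_tissue_specific_mean <-
    mean(ent$entropy[ent$class == "tissue-specific"])

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(log_lines, paste("stages", paste(names(mats), collapse = " "))),
             file.path(out, "run.log"))
  invisible(summary)
}

write_insulation <- function(ins, file) {
  keep <- !is.na(ins$normalized)
  gr <- GenomicRanges::GRanges(ins$chrom[keep],
                               IRanges::IRanges(ins$start[keep] + 1, ins$end[keep]),
                               score = ins$normalized[keep])
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

write_borders <- function(borders, file, assembly) {
  if (!nrow(borders)) {
    file.create(file)
    return(invisible(file))
  }
  bs <- assembly$bin_size
  write_bed(intervals(chrom = borders$chrom,
                      start = pmax(0, borders$pos - bs / 2),
                      end = borders$pos + bs / 2,
                      score = borders$strength), file)
}

write_compartments <- function(profile, stem) {
  keep <- !is.na(profile$pc)
  gr <- GenomicRanges::GRanges(profile$chrom[keep],
                               IRanges::IRanges(profile$start[keep] + 1, profile$end[keep]),
                               score = profile$pc[keep])
  rtracklayer::export(gr, paste0(stem, ".bedgraph"), format = "bedGraph")
  write_bed(intervals(chrom = profile$chrom[keep], start = profile$start[keep],
                      end = profile$end[keep], name = profile$label[keep]),
            paste0(stem, "_labels.bed"))
  invisible(stem)
}
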