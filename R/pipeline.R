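#' Build and validate an analysis configuration
#'
#' Collects every knob of the pipeline into one validated list. Defaults
#' reproduce the standard analysis: seven-pathway analysis set after
#' excluding the culture-sensitive growth-factor pathways, Ward/Euclidean
#' clustering into seven clusters, uncorrected pairwise tests at
#' alpha = 0.05, and five-pathway least-squares matching.
#'
#' @param expression,metadata,pathway_definitions Input paths (TSV / CSV /
#'   JSON). May be `NULL` when `simulate` is given.
#' @param tumor_expression,tumor_metadata Optional tumor cohort paths; when
#'   present the matching stage runs.
#' @param out_dir Output directory.
#' @param excluded_pathways Pathways dropped before analysis.
#' @param k,linkage,distance Clustering settings.
#' @param alpha,p_adjust Statistics settings (`alpha` in (0, 1)).
#' @param matching_pathways Pathway subset for matching.
#' @param histologies Tumor histology labels expected in the tumor
#'   metadata.
#' @param slope,kappa Scoring settings.
#' @param seed Seed controlling any stochastic stage; default 1.
#' @param simulate Optional list of arguments for the synthetic demo
#'   (passed to [generate_matched_cohorts()]); when given, input paths are
#'   ignored and cohorts are generated in memory.
#' @return Validated list of class `stp_config`.
#' @export
analysis_config <- function(expression = NULL, metadata = NULL,
                            pathway_definitions = NULL,
                            tumor_expression = NULL, tumor_metadata = NULL,
                            out_dir = "stp_results",
                            excluded_pathways = c("MAPK", "PI3K", "JAK-STAT3"),
                            k = 7, linkage = "ward.D2",
                            distance = "euclidean",
                            alpha = 0.05, p_adjust = "none",
                            matching_pathways = default_matching_pathways(),
                            histologies = c("SBOT", "HGSOC", "LGOC"),
                            slope = 1, kappa = 0.45, seed = 1,
                            simulate = NULL) {
  cfg <- list(expression = expression, metadata = metadata,
              pathway_definitions = pathway_definitions,
              tumor_expression = tumor_expression,
              tumor_metadata = tumor_metadata,
              out_dir = out_dir, excluded_pathways = excluded_pathways,
              k = k, linkage = linkage, distance = distance,
              alpha = alpha, p_adjust = p_adjust,
              matching_pathways = matching_pathways,
              histologies = histologies,
              slope = slope, kappa = kappa, seed = seed,
              simulate = simulate)
  validate_analysis_config(cfg)
  structure(cfg, class = "stp_config")
}

#' Validate an analysis configuration
#'
#' @param cfg Configuration list.
#' @return `cfg`, invisibly; errors on the first invalid field.
#' @export
validate_analysis_config <- function(cfg) {
  if (!is.numeric(cfg$alpha) || length(cfg$alpha) != 1L ||
      cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config: 'alpha' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(cfg$k) || cfg$k < 1)
    stop("config: 'k' must be >= 1", call. = FALSE)
  if (!is.numeric(cfg$slope) || cfg$slope <= 0)
    stop("config: 'slope' must be positive", call. = FALSE)
  if (!is.numeric(cfg$kappa) || cfg$kappa <= 0 || cfg$kappa >= 0.5)
    stop("config: 'kappa' must lie in (0, 0.5)", call. = FALSE)
  if (!cfg$p_adjust %in% c("none", "holm"))
    stop("config: 'p_adjust' must be \"none\" or \"holm\"", call. = FALSE)
  if (is.null(cfg$simulate)) {
    for (f in c("expression", "metadata", "pathway_definitions")) {
      if (is.null(cfg[[f]]))
        stop("config: '", f, "' path is required unless 'simulate' is set",
             call. = FALSE)
      if (!file.exists(cfg[[f]]))
        stop("config: '", f, "' path not found: ", cfg[[f]], call. = FALSE)
    }
    for (f in c("tumor_expression", "tumor_metadata"))
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
        stop("config: '", f, "' path not found: ", cfg[[f]], call. = FALSE)
  }
  invisible(cfg)
}

#' Load an analysis configuration from YAML
#'
#' Keys mirror the arguments of [analysis_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return Validated `stp_config`.
#' @export
load_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, raw)
}

.stage <- function(name, expr) {
  message(sprintf("[stpmatch] stage '%s' ...", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes score -> filter/average -> pathway selection -> cluster ->
#' characterize -> (optionally) match -> summarize -> rank -> export, and
#' writes every result plus a manifest (config, seed, package version,
#' input checksums) to the output directory. Re-running with the same
#' configuration and seed reproduces the outputs byte for byte.
#'
#' Outputs written under `cfg$out_dir`: `cellline_profile.csv`,
#' `dendrogram.nwk`, `cluster_characterization.csv`,
#' `histology_characterization.csv`, `exclusion_log.json`, and when a
#' tumor cohort is supplied `tumor_profile.csv`, `matches.csv`,
#' `composition.csv`, `coverage.csv`, `ranking_<histology>.csv` and a
#' `radar/` directory; always `manifest.json`.
#'
#' @param cfg An `stp_config` from [analysis_config()] or
#'   [load_analysis_config()].
#' @return Invisible list with the main in-memory results (profiles,
#'   clusters, characterizations, matches, summaries, output paths).
#' @export
run_full_analysis <- function(cfg) {
  validate_analysis_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list()

  if (!is.null(cfg$simulate)) {
    sim <- .stage("simulate", {
      args <- cfg$simulate
      defs <- generate_pathway_definitions(
        n_pathways = args$n_pathways %||% 7,
        seed = args$definitions_seed %||% cfg$seed)
      arks <- if (!is.null(args$archetypes)) args$archetypes
        else default_archetypes(vapply(defs, `[[`, "", "name"))
      hmap <- if (!is.null(args$histology_map))
        unlist(args$histology_map)
      else stats::setNames(
        rep(cfg$histologies, length.out = length(arks)), names(arks))
      pair <- generate_matched_cohorts(
        defs, arks,
        n_celllines_per_archetype = args$n_celllines_per_archetype %||% 2,
        n_tumors_per_archetype = args$n_tumors_per_archetype %||% 5,
        histology_map = hmap,
        noise_sd = args$noise_sd %||% 1,
        seed = cfg$seed)
      list(defs = defs, pair = pair)
    })
    defs <- sim$defs
    expr <- sim$pair$celllines$expression
    meta <- sim$pair$celllines$metadata
    tumor_expr <- sim$pair$tumors$expression
    tumor_meta <- sim$pair$tumors$metadata
  } else {
    defs <- .stage("load definitions",
                   load_pathway_definitions(cfg$pathway_definitions))
    expr <- .stage("read expression",
                   read_expression_matrix(cfg$expression))
    meta <- .stage("read metadata", read_sample_metadata(cfg$metadata))
    tumor_expr <- tumor_meta <- NULL
    if (!is.null(cfg$tumor_expression)) {
      tumor_expr <- .stage("read tumor expression",
                           read_expression_matrix(cfg$tumor_expression))
      tumor_meta <- .stage("read tumor metadata",
                           read_sample_metadata(cfg$tumor_metadata))
    }
    inputs <- list(expression = cfg$expression, metadata = cfg$metadata,
                   pathway_definitions = cfg$pathway_definitions,
                   tumor_expression = cfg$tumor_expression,
                   tumor_metadata = cfg$tumor_metadata)
  }

  filt <- .stage("filter samples", filter_samples(meta))
  message(sprintf("[stpmatch]   %d/%d samples eligible (treated: %d, contaminated: %d, non-ovarian: %d)",
                  filt$log$output, filt$log$input, filt$log$treated,
                  filt$log$contaminated, filt$log$non_ovarian))
  expr <- expr[, filt$eligible$sample_id, drop = FALSE]

  prof <- .stage("score cell lines",
                 score_cohort(expr, defs, slope = cfg$slope,
                              kappa = cfg$kappa,
                              metadata = filt$eligible))
  prof <- .stage("average replicates",
                 average_replicates(prof, filt$eligible))
  prof <- .stage("select pathways",
                 select_pathways(prof, intersect(cfg$excluded_pathways,
                                                 pathway_names(prof))))
  message(sprintf("[stpmatch]   %d cell-line profiles x %d pathways",
                  nrow(prof$scores), ncol(prof$scores)))

  k_eff <- min(cfg$k, nrow(prof$scores))
  clus <- .stage("cluster",
                 hierarchical_cluster(prof, k = k_eff,
                                      linkage = cfg$linkage,
                                      distance = cfg$distance))
  chr_clus <- .stage("characterize clusters",
                     characterize_clusters(prof, clus, alpha = cfg$alpha,
                                           p_adjust = cfg$p_adjust))
  chr_hist <- NULL
  hist_lab <- prof$metadata$histology_of_origin
  if (!is.null(hist_lab) && length(unique(hist_lab)) >= 2L) {
    names(hist_lab) <- prof$metadata$sample_id
    chr_hist <- .stage("characterize histology",
                       characterize_histology(prof, hist_lab,
                                              alpha = cfg$alpha,
                                              p_adjust = cfg$p_adjust))
  }

  out <- list(profile = prof, clusters = clus,
              cluster_characterization = chr_clus,
              histology_characterization = chr_hist,
              exclusion_log = filt$log)

  paths <- c(
    profile = write_stp_profile(prof,
      file.path(cfg$out_dir, "cellline_profile.csv")),
    dendrogram = export_newick(clus,
      file.path(cfg$out_dir, "dendrogram.nwk")),
    cluster_characterization = write_characterization(chr_clus,
      file.path(cfg$out_dir, "cluster_characterization.csv")),
    exclusion_log = write_exclusion_log(filt$log,
      file.path(cfg$out_dir, "exclusion_log.json")))
  if (!is.null(chr_hist))
    paths["histology_characterization"] <- write_characterization(chr_hist,
      file.path(cfg$out_dir, "histology_characterization.csv"))

  if (!is.null(tumor_expr)) {
    tprof <- .stage("score tumors",
                    score_cohort(tumor_expr, defs, slope = cfg$slope,
                                 kappa = cfg$kappa, metadata = tumor_meta))
    matches <- .stage("match",
                      match_nearest(tprof, prof,
                                    pathways = cfg$matching_pathways))
    th <- stats::setNames(tumor_meta$histology_of_origin,
                          tumor_meta$sample_id)
    comp <- .stage("summarize composition",
                   summarize_composition(matches, th,
                                         histologies = cfg$histologies))
    sizes <- table(factor(th, levels = cfg$histologies))
    cov <- .stage("histology coverage",
                  histology_coverage(matches, th,
                                     stats::setNames(as.integer(sizes),
                                                     names(sizes))))
    message(sprintf("[stpmatch]   %d tumors matched to %d cell line(s)",
                    nrow(matches), length(unique(matches$cell_line))))
    ranks <- lapply(stats::setNames(nm = cfg$histologies), function(h)
      suppressWarnings(rank_representatives(comp, h)))
    radar <- .stage("export radar",
                    export_radar(matches, tprof, prof, th,
                                 file.path(cfg$out_dir, "radar")))
    paths <- c(paths,
      tumor_profile = write_stp_profile(tprof,
        file.path(cfg$out_dir, "tumor_profile.csv")))
    utils::write.csv(matches, file.path(cfg$out_dir, "matches.csv"),
                     row.names = FALSE)
    utils::write.csv(comp, file.path(cfg$out_dir, "composition.csv"),
                     row.names = FALSE)
    utils::write.csv(cov, file.path(cfg$out_dir, "coverage.csv"),
                     row.names = FALSE)
    for (h in names(ranks))
      utils::write.csv(ranks[[h]],
                       file.path(cfg$out_dir,
                                 paste0("ranking_", h, ".csv")),
                       row.names = FALSE)
    paths <- c(paths, matches = file.path(cfg$out_dir, "matches.csv"),
               composition = file.path(cfg$out_dir, "composition.csv"),
               coverage = file.path(cfg$out_dir, "coverage.csv"))
    out <- c(out, list(tumor_profile = tprof, matches = matches,
                       composition = comp, coverage = cov,
                       rankings = ranks, radar_files = radar))
  }

  manifest <- list(
    package = "stpmatch",
    version = as.character(utils::packageVersion("stpmatch")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "simulate")],
    simulate = !is.null(cfg$simulate),
    input_md5 = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs[!vapply(inputs, is.null, NA)])))
    else NULL,
    outputs = as.list(paths))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  out$paths <- c(paths, manifest = file.path(cfg$out_dir, "manifest.json"))
  invisible(out)
}
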