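#' Default cluster archetypes
#'
#' Seven qualitative activity templates used by the synthetic generators,
#' one per prototypical cell-line cluster: each names a pathway pattern
#' such as "hormonally active" (high AR/ER/TGF-B) or "developmentally
#' quiet" (low TGF-B/Notch/Wnt). High and low flags become latent activity
#' levels 0.9 and 0.1; pathways not mentioned sit at 0.5. These are test
#' fixtures for recovery experiments, not claims about real tumor biology.
#'
#' @param pathways Pathway names the archetypes are defined over; default
#'   the seven-pathway analysis set.
#' @return Named list of numeric activity-level vectors in [0, 1].
#' @export
default_archetypes <- function(pathways = c("AR", "ER", "HH", "NFKB",
                                            "NOTCH", "TGFB", "WNT")) {
  base <- stats::setNames(rep(0.5, length(pathways)), pathways)
  set <- function(hi = character(), lo = character()) {
    a <- base
    a[intersect(hi, pathways)] <- 0.9
    a[intersect(lo, pathways)] <- 0.1
    a
  }
  list(
    C1 = set(hi = c("AR", "ER", "TGFB")),
    C2 = set(lo = c("AR", "ER")),
    C3 = set(hi = "AR", lo = "HH"),
    C4 = set(hi = "HH", lo = "NFKB"),
    C5 = set(hi = c("WNT", "HH")),
    C6 = set(lo = c("TGFB", "NOTCH", "WNT")),
    C7 = set(hi = c("AR", "ER"), lo = "HH")
  )
}

#' Generate synthetic pathway definitions
#'
#' Builds a set of pathway models with unique synthetic target genes.
#' Per-gene evidence weights are drawn from Uniform(0.3, 1) and about 20%
#' of the targets are down-regulated, mirroring the make-up of curated
#' target-gene panels (roughly 25-35 genes per pathway). Calibration mode
#' is `"extremes"`.
#'
#' @param n_pathways Number of pathways (>= 1).
#' @param genes_per_pathway Integer range `c(min, max)` sampled per
#'   pathway; default `c(25, 35)`.
#' @param seed Mandatory RNG seed; identical seeds reproduce identical
#'   definitions.
#' @param pathway_names Optional names; defaults to the seven-pathway
#'   analysis set extended with `STP<i>` beyond seven.
#' @return Named list of [stp_pathway()] objects.
#' @export
generate_pathway_definitions <- function(n_pathways = 7,
                                         genes_per_pathway = c(25, 35),
                                         seed,
                                         pathway_names = NULL) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (n_pathways < 1L) stop("'n_pathways' must be >= 1", call. = FALSE)
  if (is.null(pathway_names)) {
    std <- c("AR", "ER", "HH", "NFKB", "NOTCH", "TGFB", "WNT")
    pathway_names <- if (n_pathways <= length(std)) std[seq_len(n_pathways)]
      else c(std, paste0("STP", seq_len(n_pathways - length(std))))
  }
  if (length(pathway_names) != n_pathways)
    stop("'pathway_names' must have length n_pathways", call. = FALSE)
  set.seed(seed)
  defs <- lapply(seq_len(n_pathways), function(i) {
    ng <- if (genes_per_pathway[1L] == genes_per_pathway[2L])
      genes_per_pathway[1L]
    else sample(genes_per_pathway[1L]:genes_per_pathway[2L], 1L)
    targets <- data.frame(
      gene_id = sprintf("%s_T%02d", pathway_names[i], seq_len(ng)),
      direction = ifelse(stats::runif(ng) < 0.2, "down", "up"),
      weight = stats::runif(ng, 0.3, 1),
      stringsAsFactors = FALSE)
    stp_pathway(name = pathway_names[i], targets = targets)
  })
  stats::setNames(defs, pathway_names)
}

#' Generate a synthetic expression cohort with known pathway activity
#'
#' Emulates a log2-intensity microarray cohort. Entities (cell lines or
#' patients) are assigned to archetypes; an entity's latent activity level
#' `a` on pathway P shifts each of P's up-targets by
#' `a * effect * weight` log2 units above a per-gene baseline drawn from
#' Normal(8, 1) (down-targets are shifted below it), and every sample adds
#' independent Normal(0, `noise_sd`) measurement noise. Replicates of an
#' entity share the latent state and differ only by noise. The generator
#' never writes scores — only expression — so recovery tests exercise the
#' whole scoring path.
#'
#' @param definitions Pathway definitions, e.g. from
#'   [generate_pathway_definitions()].
#' @param archetypes Named list of activity-level vectors (see
#'   [default_archetypes()]); levels must cover the definitions' names.
#' @param n_per_archetype Entities generated per archetype; default 5.
#' @param noise_sd Per-gene Gaussian noise SD on the log2 scale
#'   (>= 0); default 1.
#' @param replicates Samples per entity; default 1.
#' @param effect Maximum log2 shift of a weight-1 target between activity
#'   0 and 1; default 3.
#' @param seed Mandatory RNG seed.
#' @param dataset_id Dataset label stamped on the metadata; default
#'   `"SYN1"`.
#' @param tissue_class `"cell_line"` or `"tumor"`.
#' @param histology Optional named map archetype -> histology label;
#'   defaults to the archetype name itself.
#' @return List with `expression` (genes x samples matrix), `metadata`
#'   (`data.frame`) and `truth` (`data.frame` with the planted archetype
#'   per sample plus an `activity` attribute holding the latent
#'   sample x pathway levels).
#' @export
generate_cohort <- function(definitions, archetypes = default_archetypes(),
                            n_per_archetype = 5, noise_sd = 1,
                            replicates = 1, effect = 3, seed,
                            dataset_id = "SYN1",
                            tissue_class = "cell_line",
                            histology = NULL) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (length(archetypes) == 0L)
    stop("'archetypes' must be non-empty", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  pnames <- vapply(definitions, `[[`, "", "name")
  for (a in archetypes)
    if (!all(pnames %in% names(a)))
      stop("every archetype must give a level for every pathway",
           call. = FALSE)
  if (is.null(histology))
    histology <- stats::setNames(names(archetypes), names(archetypes))

  set.seed(seed)
  genes <- unlist(lapply(definitions, function(d) d$targets$gene_id),
                  use.names = FALSE)
  baseline <- stats::setNames(stats::rnorm(length(genes), 8, 1), genes)

  ark <- rep(names(archetypes), each = n_per_archetype)
  n_ent <- length(ark)
  if (n_ent == 0L) {
    expr <- base::matrix(numeric(), nrow = length(genes), ncol = 0,
                         dimnames = list(genes, character()))
    meta <- data.frame(sample_id = character(), entity_name = character(),
                       dataset_id = character(), tissue_class = character(),
                       histology_of_origin = character(),
                       treated = logical(), contaminated = logical(),
                       non_ovarian = logical(), replicate = integer(),
                       stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = character(), entity_name = character(),
                        archetype = character(), stringsAsFactors = FALSE)
    return(list(expression = expr, metadata = meta, truth = truth))
  }
  entity <- sprintf("%s_E%02d", ark,
                    as.integer(stats::ave(seq_len(n_ent), ark,
                                          FUN = seq_along)))
  # latent per-entity activity = archetype levels (shared by replicates)
  act <- do.call(rbind, lapply(ark, function(a) archetypes[[a]][pnames]))
  rownames(act) <- entity; colnames(act) <- pnames

  sample_entity <- rep(entity, each = replicates)
  sample_ark <- rep(ark, each = replicates)
  rep_idx <- rep(seq_len(replicates), times = n_ent)
  sample_id <- sprintf("%s_R%d", sample_entity, rep_idx)

  signal <- base::matrix(0, nrow = length(genes), ncol = n_ent,
                         dimnames = list(genes, entity))
  for (d in definitions) {
    sgn <- ifelse(d$targets$direction == "up", 1, -1)
    shift <- outer(sgn * effect * d$targets$weight, act[, d$name])
    signal[d$targets$gene_id, ] <- shift
  }
  expr <- baseline + signal[, sample_entity, drop = FALSE]
  noise <- base::matrix(stats::rnorm(length(expr), 0, 1) * noise_sd,
                        nrow = nrow(expr))
  expr <- expr + noise
  colnames(expr) <- sample_id

  meta <- data.frame(
    sample_id = sample_id,
    entity_name = sample_entity,
    dataset_id = dataset_id,
    tissue_class = tissue_class,
    histology_of_origin = unname(histology[sample_ark]),
    treated = FALSE, contaminated = FALSE, non_ovarian = FALSE,
    replicate = rep_idx,
    stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = sample_id, entity_name = sample_entity,
                      archetype = sample_ark, stringsAsFactors = FALSE)
  attr(truth, "activity") <- act[sample_entity, , drop = FALSE]
  list(expression = expr, metadata = meta, truth = truth)
}

#' Generate paired cell-line and tumor cohorts sharing archetypes
#'
#' Draws a cell-line cohort and a tumor cohort from the same archetypes
#' with independent noise, so the ground-truth "correct" match for a tumor
#' is any cell line of its own archetype. Tumor histology labels are taken
#' from `histology_map`, which must assign every archetype one of the
#' tumor histologies.
#'
#' @param definitions Pathway definitions.
#' @param archetypes Named list of activity templates.
#' @param n_celllines_per_archetype,n_tumors_per_archetype Entities per
#'   archetype in each cohort.
#' @param histology_map Named character vector archetype -> histology
#'   (e.g. `c(C1 = "SBOT", C3 = "HGSOC", ...)`); must cover every
#'   archetype.
#' @param noise_sd Gaussian noise SD for both cohorts; default 1.
#' @param effect Passed to [generate_cohort()].
#' @param seed Mandatory RNG seed (cohorts use derived sub-seeds).
#' @return List with `celllines` and `tumors`, each as returned by
#'   [generate_cohort()].
#' @export
generate_matched_cohorts <- function(definitions,
                                     archetypes = default_archetypes(),
                                     n_celllines_per_archetype = 2,
                                     n_tumors_per_archetype = 5,
                                     histology_map, noise_sd = 1,
                                     effect = 3, seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  miss <- setdiff(names(archetypes), names(histology_map))
  if (length(miss))
    stop("histology_map missing archetype(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  cl <- generate_cohort(definitions, archetypes,
                        n_per_archetype = n_celllines_per_archetype,
                        noise_sd = noise_sd, effect = effect,
                        seed = seed %% 2147483647L,
                        dataset_id = "SYN_CL", tissue_class = "cell_line")
  tu <- generate_cohort(definitions, archetypes,
                        n_per_archetype = n_tumors_per_archetype,
                        noise_sd = noise_sd, effect = effect,
                        seed = (seed + 1L) %% 2147483647L,
                        dataset_id = "SYN_TU", tissue_class = "tumor",
                        histology = histology_map)
  list(celllines = cl, tumors = tu)
}

#' Write a synthetic cohort to disk
#'
#' Emits the TSV/CSV pair consumed by [read_expression_matrix()] and
#' [read_sample_metadata()], plus the ground truth as CSV.
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; default `"cohort"`.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, paste0(prefix, "_expression.tsv"))
  df <- data.frame(gene_id = rownames(cohort$expression),
                   cohort$expression, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta_path <- file.path(dir, paste0(prefix, "_metadata.csv"))
  utils::write.csv(cohort$metadata, meta_path, row.names = FALSE)
  truth_path <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(c(expression = expr_path, metadata = meta_path,
              truth = truth_path))
}
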