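#' Read a genes x samples expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers
#' and remaining columns one sample each, with a header row; lines starting
#' with `#` are comments. Duplicate gene rows are collapsed by their mean
#' with a warning. Non-numeric cells and ragged rows are reported with
#' their coordinates.
#'
#' @param path Path to the TSV file.
#' @return Numeric genes x samples matrix with gene row names and sample
#'   column names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path))
    stop("expression file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("expression file is empty or has no data rows: ", path,
         call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- length(fields[[1L]])
  bad <- which(lengths(fields) != n_col)
  if (length(bad))
    stop(sprintf("ragged row(s) in %s: line(s) %s have a different number of fields than the header (%d)",
                 path, paste(utils::head(bad, 5L), collapse = ", "), n_col),
         call. = FALSE)
  samples <- fields[[1L]][-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  body <- fields[-1L]
  genes <- vapply(body, `[[`, "", 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(n_col - 1L)))
  vals <- base::matrix(vals, nrow = length(body), ncol = n_col - 1L,
                       byrow = TRUE, dimnames = list(genes, samples))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in %s at gene row %d ('%s'), sample column %d ('%s')",
                 path, idx[1L], genes[idx[1L]], idx[2L], samples[idx[2L]]),
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning("duplicate gene row(s) collapsed by mean: ",
            paste(dups, collapse = ", "), call. = FALSE)
    vals <- do.call(rbind, lapply(split(seq_along(genes), genes),
                                  function(i) colMeans(vals[i, , drop = FALSE])))
    vals <- vals[unique(genes), , drop = FALSE]
  }
  vals
}

#' Read sample metadata from CSV
#'
#' Metadata travels as a sidecar CSV joined to the expression matrix by
#' `sample_id`. Recognized columns: `sample_id`, `entity_name` (cell line
#' or patient), `dataset_id`, `tissue_class` (`cell_line` or `tumor`),
#' `histology_of_origin`, and the logical eligibility flags `treated`,
#' `contaminated`, `non_ovarian` (absent flags default to `FALSE`).
#'
#' @param path CSV path.
#' @return A `data.frame` with normalized flag columns.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path))
    stop("metadata file not found: ", path, call. = FALSE)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta))
    stop("metadata must have a 'sample_id' column", call. = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id(s) in metadata", call. = FALSE)
  for (fl in c("treated", "contaminated", "non_ovarian")) {
    if (!fl %in% names(meta)) meta[[fl]] <- FALSE
    meta[[fl]] <- as.logical(meta[[fl]]) %in% TRUE
  }
  meta
}

#' Apply sample eligibility filters
#'
#' Removes treated, contaminated and non-ovarian samples, mirroring the
#' eligibility funnel used when assembling public cell-line cohorts: only
#' untreated, uncontaminated samples of ovarian origin are analyzed. Rules
#' are applied independently, so the result does not depend on their
#' order; a sample failing several rules is counted once under each rule
#' it fails.
#'
#' @param meta Metadata `data.frame` from [read_sample_metadata()] (absent
#'   flag columns are treated as all-`FALSE`).
#' @return List with `eligible` (the retained metadata rows), and
#'   `log` (named integer exclusion counts per rule plus `input`/`output`
#'   totals).
#' @export
filter_samples <- function(meta) {
  for (fl in c("treated", "contaminated", "non_ovarian"))
    if (!fl %in% names(meta)) meta[[fl]] <- FALSE
  drop <- with(meta, treated | contaminated | non_ovarian)
  log <- list(input = nrow(meta),
              treated = sum(meta$treated),
              contaminated = sum(meta$contaminated),
              non_ovarian = sum(meta$non_ovarian),
              excluded = sum(drop),
              output = sum(!drop))
  if (log$output == 0L)
    warning("no samples remain after eligibility filtering", call. = FALSE)
  list(eligible = meta[!drop, , drop = FALSE], log = log)
}

#' Average replicate STP profiles
#'
#' Within each (entity, dataset) group the replicate rows are replaced by
#' their arithmetic mean per pathway. Averaging operates on activity
#' scores, not on expression. An entity profiled in several datasets keeps
#' one row per dataset — this is what makes cross-laboratory comparison of
#' the same cell line possible — and such rows are renamed
#' `<entity>_<k>` in dataset order; entities seen in a single dataset keep
#' their plain name.
#'
#' @param profile An [stp_profile()] scored per physical sample.
#' @param meta Metadata `data.frame` with `sample_id`, `entity_name` and
#'   `dataset_id` covering the profile's samples.
#' @return An `stp_profile` with one row per (entity, dataset), metadata
#'   carrying `entity_name`, `dataset_id` and `n_replicates`.
#' @export
average_replicates <- function(profile, meta) {
  ids <- rownames(profile$scores)
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(m$sample_id))
    stop("metadata missing for sample(s): ",
         paste(ids[is.na(m$sample_id)], collapse = ", "), call. = FALSE)
  key <- paste(m$entity_name, m$dataset_id, sep = "\r")
  groups <- split(seq_along(ids), key)
  # keep first-appearance order of groups
  groups <- groups[order(vapply(groups, min, 1L))]
  agg <- function(mat) do.call(rbind, lapply(groups, function(i)
    colMeans(mat[i, , drop = FALSE])))
  scores <- agg(profile$scores)
  l2o <- if (!is.null(profile$log2odds)) agg(profile$log2odds) else NULL
  first <- vapply(groups, `[[`, 1L, 1L)
  ent <- m$entity_name[first]
  ds <- m$dataset_id[first]
  new_id <- ent
  for (e in unique(ent[duplicated(ent)])) {
    idx <- which(ent == e)
    new_id[idx[order(ds[idx])]] <- paste0(e, "_", seq_along(idx))
  }
  rownames(scores) <- new_id
  if (!is.null(l2o)) rownames(l2o) <- new_id
  keep <- setdiff(names(m), c("sample_id"))
  meta_out <- cbind(data.frame(sample_id = new_id, stringsAsFactors = FALSE),
                    m[first, keep, drop = FALSE])
  meta_out$n_replicates <- lengths(groups)
  rownames(meta_out) <- NULL
  stp_profile(scores, log2odds = l2o, metadata = meta_out)
}

#' Drop excluded pathways from a profile
#'
#' Growth-factor-driven pathways (MAPK, PI3K, JAK-STAT3) respond to cell
#' culture conditions such as the amount of serum in the medium, so they
#' are excluded by default from cell-line analyses; the default analysis
#' set is AR, ER, HH, NF-kB, Notch, TGF-B and Wnt. Excluded names not
#' present in the profile produce a warning.
#'
#' @param profile An [stp_profile()].
#' @param excluded Character vector of pathway names to drop; default
#'   `c("MAPK", "PI3K", "JAK-STAT3")`.
#' @return The profile restricted to the remaining pathways.
#' @export
select_pathways <- function(profile, excluded = c("MAPK", "PI3K", "JAK-STAT3")) {
  have <- pathway_names(profile)
  unknown <- setdiff(excluded, have)
  if (length(unknown))
    warning("excluded pathway(s) not in profile: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  keep <- setdiff(have, excluded)
  if (length(keep) == 0L)
    stop("pathway exclusion leaves no pathways in the profile",
         call. = FALSE)
  stp_profile(profile$scores[, keep, drop = FALSE],
              log2odds = if (!is.null(profile$log2odds))
                profile$log2odds[, keep, drop = FALSE],
              metadata = profile$metadata)
}

#' Write an exclusion log as JSON
#'
#' @param log Exclusion log from [filter_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
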