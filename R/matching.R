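#' Default pathway subset for tumor/cell-line matching
#'
#' The hormonal (AR, ER) and developmental (HH, Notch, TGF-B) pathways
#' used to match patient tumor samples to cell lines.
#'
#' @return Character vector of pathway names.
#' @export
default_matching_pathways <- function() c("AR", "ER", "HH", "NOTCH", "TGFB")

#' Match tumor samples to their nearest cell line
#'
#' Nearest-neighbor analysis in STP-score space: each tumor sample is
#' assigned to the cell line minimizing the sum of squared pathway-score
#' differences over the requested pathway subset (least squares). Ties are
#' broken by lexicographic cell-line id and flagged.
#'
#' @param tumors An [stp_profile()] of tumor samples.
#' @param celllines An [stp_profile()] of cell lines.
#' @param pathways Pathway subset to match on; default
#'   [default_matching_pathways()]. Both profiles must contain it.
#' @return `data.frame` of class `stp_matches` with one row per tumor:
#'   `tumor_id`, `cell_line`, `distance` (squared), `tie`; the pathway
#'   subset used is recorded in the `"pathways"` attribute.
#' @export
match_nearest <- function(tumors, celllines,
                          pathways = default_matching_pathways()) {
  if (length(pathways) == 0L)
    stop("'pathways' must name at least one pathway", call. = FALSE)
  if (nrow(celllines$scores) == 0L)
    stop("cell-line profile is empty", call. = FALSE)
  for (nm in c("tumors", "celllines")) {
    have <- pathway_names(get(nm))
    miss <- setdiff(pathways, have)
    if (length(miss))
      stop(sprintf("%s profile missing pathway(s): %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  tt <- tumors$scores[, pathways, drop = FALSE]
  cc <- celllines$scores[, pathways, drop = FALSE]
  cc <- cc[order(rownames(cc)), , drop = FALSE]  # lexicographic tie policy
  d2 <- outer(rowSums(tt^2), rowSums(cc^2), `+`) - 2 * tt %*% t(cc)
  d2 <- pmax(d2, 0)
  best <- apply(d2, 1L, which.min)
  tie <- vapply(seq_len(nrow(tt)), function(i)
    sum(abs(d2[i, ] - d2[i, best[i]]) < 1e-9) > 1L, NA)
  out <- data.frame(tumor_id = rownames(tt),
                    cell_line = rownames(cc)[best],
                    distance = d2[cbind(seq_len(nrow(tt)), best)],
                    tie = tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pathways") <- pathways
  class(out) <- c("stp_matches", "data.frame")
  out
}

# half-up integer percent, matching how match-composition tables are
# conventionally printed (round() would round halves to even)
.pct <- function(count, total) as.integer(floor(100 * count / total + 0.5))

#' Summarize match composition per cell line
#'
#' For every cell line that attracted at least one tumor sample, counts
#' the matched samples per tumor histology and expresses them as integer
#' percentages of that cell line's total matches. Cell lines with zero
#' matches are omitted.
#'
#' @param matches An `stp_matches` table from [match_nearest()].
#' @param histology Character vector of tumor histology labels, named by
#'   tumor sample id (values among `histologies`).
#' @param histologies Allowed histology labels; default
#'   `c("SBOT", "HGSOC", "LGOC")`.
#' @return `data.frame` with one row per matched cell line: `cell_line`,
#'   `total`, and per-histology `<h>_n` and `<h>_pct` columns.
#' @export
summarize_composition <- function(matches, histology,
                                  histologies = c("SBOT", "HGSOC", "LGOC")) {
  h <- histology[matches$tumor_id]
  bad <- is.na(h) | !h %in% histologies
  if (any(bad))
    stop("unknown or missing histology label for sample(s): ",
         paste(matches$tumor_id[bad], collapse = ", "), call. = FALSE)
  cl <- sort(unique(matches$cell_line))
  rows <- lapply(cl, function(c) {
    hc <- h[matches$cell_line == c]
    counts <- vapply(histologies, function(x) sum(hc == x), 0L)
    total <- length(hc)
    row <- data.frame(cell_line = c, total = total,
                      stringsAsFactors = FALSE)
    for (x in histologies) {
      row[[paste0(x, "_n")]] <- counts[[x]]
      row[[paste0(x, "_pct")]] <- .pct(counts[[x]], total)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-histology cohort coverage of each cell line
#'
#' Expresses, for each (cell line, histology) pair, the share of that
#' histology's whole tumor cohort matched to the cell line, as an integer
#' percent (e.g. 11 of 50 HGSOC samples matched to one cell line = 22%).
#'
#' @param matches An `stp_matches` table.
#' @param histology Named histology labels as in [summarize_composition()].
#' @param cohort_sizes Named integer vector giving each histology's cohort
#'   size; must be positive and at least the matched count.
#' @return `data.frame` with `cell_line`, `histology`, `count`,
#'   `share_pct`.
#' @export
histology_coverage <- function(matches, histology, cohort_sizes) {
  h <- histology[matches$tumor_id]
  if (any(cohort_sizes <= 0))
    stop("cohort sizes must be positive", call. = FALSE)
  cl <- sort(unique(matches$cell_line))
  out <- expand.grid(cell_line = cl, histology = names(cohort_sizes),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$count <- mapply(function(c, x) sum(matches$cell_line == c & h == x),
                      out$cell_line, out$histology)
  over <- out$count > cohort_sizes[out$histology]
  if (any(over))
    stop("matched count exceeds cohort size for histology: ",
         paste(unique(out$histology[over]), collapse = ", "), call. = FALSE)
  out$share_pct <- .pct(out$count, cohort_sizes[out$histology])
  out
}

#' Rank cell lines as representatives of a tumor histology
#'
#' Two-tier recommendation rule (rule id `"majority-then-count"`): tier 1
#' holds the cell lines whose matched samples are in the majority (> 50%)
#' of the target histology, ordered by the matched count of that histology
#' descending; tier 2 holds the remaining cell lines with at least one
#' match of the histology, in the same order. Ties (equal target count,
#' then equal total matches) share a rank and are flagged; remaining order
#' among ties is lexicographic. The rule identifier is recorded in the
#' result so rankings are always traceable to the rule that produced them.
#'
#' @param summary Composition table from [summarize_composition()].
#' @param histology Target histology (a `<h>_n` column of `summary`).
#' @return `data.frame` with `rank`, `cell_line`, `count`, `pct`, `tier`,
#'   `tie`; the `"rule"` attribute names the ranking rule.
#' @export
rank_representatives <- function(summary, histology) {
  n_col <- paste0(histology, "_n"); p_col <- paste0(histology, "_pct")
  if (!all(c(n_col, p_col) %in% names(summary)))
    stop("summary has no columns for histology '", histology, "'",
         call. = FALSE)
  cand <- summary[summary[[n_col]] > 0L, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no cell line matched any '", histology, "' sample",
            call. = FALSE)
    out <- data.frame(rank = integer(), cell_line = character(),
                      count = integer(), pct = integer(),
                      tier = integer(), tie = logical())
    attr(out, "rule") <- "majority-then-count"
    return(out)
  }
  tier <- ifelse(cand[[p_col]] > 50L, 1L, 2L)
  ord <- order(tier, -cand[[n_col]], -cand$total, cand$cell_line)
  cand <- cand[ord, , drop = FALSE]; tier <- tier[ord]
  key <- paste(tier, cand[[n_col]], cand$total)
  rank <- as.integer(factor(key, levels = unique(key)))
  tie <- key %in% key[duplicated(key)]
  out <- data.frame(rank = rank, cell_line = cand$cell_line,
                    count = cand[[n_col]], pct = cand[[p_col]],
                    tier = tier, tie = tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "rule") <- "majority-then-count"
  out
}

#' Export radar-map data for matched cell lines
#'
#' For every cell line with at least one matched tumor, writes a CSV with
#' the cell line's reference scores and each matched tumor's scores over
#' the matching pathway subset, tagged by role and histology. These are
#' the data behind per-cell-line radar plots; no figures are rendered.
#'
#' @param matches An `stp_matches` table.
#' @param tumors,celllines The profiles that produced `matches`.
#' @param histology Named tumor histology labels.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths written, invisibly.
#' @export
export_radar <- function(matches, tumors, celllines, histology, dir) {
  if (nrow(matches) == 0L) {
    warning("no matches: no radar files written", call. = FALSE)
    return(invisible(character()))
  }
  pathways <- attr(matches, "pathways")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cl in sort(unique(matches$cell_line))) {
    tid <- matches$tumor_id[matches$cell_line == cl]
    ref <- data.frame(sample_id = cl, role = "reference",
                      histology = NA_character_,
                      stringsAsFactors = FALSE)
    ref <- cbind(ref, as.data.frame(t(celllines$scores[cl, pathways])))
    tum <- data.frame(sample_id = tid, role = "tumor",
                      histology = unname(histology[tid]),
                      stringsAsFactors = FALSE)
    tscores <- as.data.frame(tumors$scores[tid, pathways, drop = FALSE])
    rownames(tscores) <- NULL
    tum <- cbind(tum, tscores)
    out <- rbind(ref, tum)
    f <- file.path(dir, paste0("radar_", gsub("[^A-Za-z0-9._-]", "_", cl),
                               ".csv"))
    utils::write.csv(out, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
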