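#' Hierarchically cluster STP profiles
#'
#' Agglomerative clustering of samples on their pathway-score vectors.
#' Defaults are Euclidean distance with Ward linkage (`"ward.D2"`), the
#' standard choice for compact profile clusters; both are configurable.
#' The tree is cut into `k` groups; cluster ids are numbered by first
#' appearance in the sample order, so the result is deterministic given
#' the input order.
#'
#' @param profile An [stp_profile()] without missing scores.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param distance Distance method passed to [stats::dist()].
#' @return An object of class `stp_clusters`: list with `assignment`
#'   (named integer vector of cluster ids), `tree` (the `hclust` object),
#'   `k` and `sizes`.
#' @export
hierarchical_cluster <- function(profile, k = 7, linkage = "ward.D2",
                                 distance = "euclidean") {
  x <- profile$scores
  if (anyNA(x)) stop("profile contains missing scores", call. = FALSE)
  n <- nrow(x)
  if (k < 1L || k > n)
    stop(sprintf("'k' must lie in [1, %d], got %s", n, k), call. = FALSE)
  d <- stats::dist(x, method = distance)
  if (all(d == 0))
    warning("all samples identical: every merge height is 0", call. = FALSE)
  tree <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(tree, k = k)
  # renumber by first appearance so ids are stable in sample order
  relab <- stats::setNames(seq_along(unique(raw)), unique(raw))
  assignment <- stats::setNames(as.integer(relab[as.character(raw)]),
                                rownames(x))
  structure(list(assignment = assignment, tree = tree, k = k,
                 sizes = table(assignment)),
            class = "stp_clusters")
}

#' @export
print.stp_clusters <- function(x, ...) {
  cat(sprintf("STP clustering: %d samples in %d clusters (sizes: %s)\n",
              length(x$assignment), x$k,
              paste(as.integer(x$sizes), collapse = ", ")))
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Writes the linkage tree with merge heights as branch lengths, for
#' interoperable viewing in any tree tool.
#'
#' @param clusters An `stp_clusters` object (or a raw `hclust`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(clusters, path) {
  tree <- if (inherits(clusters, "stp_clusters")) clusters$tree else clusters
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

# Two-sided rank-sum p-value, guarded for the fully degenerate case where
# every observation in both groups is identical (no evidence either way).
.pairwise_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
}

.stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 1e-4) "****" else if (p < 1e-3) "***"
  else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Characterize groups of samples per pathway
#'
#' Nonparametric characterization used both for hierarchical clusters and
#' for histological subtypes. Per pathway, an omnibus Kruskal-Wallis test
#' across groups is followed by pairwise two-sided Mann-Whitney
#' (Wilcoxon rank-sum) tests between every pair of groups; pairwise
#' p-values are uncorrected by default (`p_adjust = "holm"` applies a Holm
#' correction within each pathway). Significance stars follow the usual
#' 0.05 / 0.01 / 0.001 / 0.0001 ladder.
#'
#' A group is labelled `High` (resp. `Low`) for a pathway when it differs
#' significantly (p < `alpha`) from at least `min_other` other groups and
#' every significant difference points the same way; significant
#' differences against fewer groups, or in mixed directions, yield `CNBD`
#' ("cannot be determined"), and no significant difference yields a blank
#' label. Pairwise tests involving a single-member group are not
#' interpretable and are reported as `CNBD` comparisons; single-member
#' groups receive no High/Low label.
#'
#' @param profile An [stp_profile()].
#' @param groups Factor or character vector of group labels, either named
#'   by sample id or in profile row order.
#' @param alpha Significance level; default 0.05.
#' @param p_adjust `"none"` (default) or `"holm"` for the pairwise tests.
#' @param min_other Number of other groups a significant, direction-
#'   consistent difference must reach for a High/Low call; default 3.
#' @return List of class `stp_characterization`: `table` (one row per
#'   group x pathway with omnibus p, counts of significantly higher/lower
#'   comparisons and the label) and `pairwise` (one row per ordered group
#'   pair x pathway with p-value, stars and direction).
#' @export
characterize_groups <- function(profile, groups, alpha = 0.05,
                                p_adjust = c("none", "holm"),
                                min_other = 3) {
  p_adjust <- match.arg(p_adjust)
  x <- profile$scores
  if (!is.null(names(groups))) groups <- groups[rownames(x)]
  if (length(groups) != nrow(x))
    stop("'groups' must label every profile sample", call. = FALSE)
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (length(lev) < min_other + 1L)
    warning(sprintf("with %d groups, no group can differ from >= %d others: High/Low labels unreachable",
                    length(lev), min_other), call. = FALSE)
  sizes <- table(groups)
  pw_rows <- list(); tab_rows <- list()
  for (p in colnames(x)) {
    v <- x[, p]
    omni <- if (length(unique(v)) == 1L) 1 else
      suppressWarnings(stats::kruskal.test(v, groups)$p.value)
    pmat <- base::matrix(NA_real_, length(lev), length(lev),
                         dimnames = list(lev, lev))
    dirmat <- pmat
    for (i in seq_along(lev)) for (j in seq_along(lev)) {
      if (i == j) next
      gi <- v[groups == lev[i]]; gj <- v[groups == lev[j]]
      if (length(gi) < 2L || length(gj) < 2L) next  # CNBD comparison
      pmat[i, j] <- .pairwise_p(gi, gj)
      dirmat[i, j] <- sign(stats::median(gi) - stats::median(gj))
    }
    if (p_adjust == "holm") {
      ut <- upper.tri(pmat)
      pmat[ut] <- stats::p.adjust(pmat[ut], method = "holm")
      pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
    }
    for (i in seq_along(lev)) {
      ps <- pmat[i, -i]; ds <- dirmat[i, -i]
      others <- lev[-i]
      cnbd_cmp <- sizes[lev[i]] < 2L | sizes[others] < 2L
      pw_rows[[length(pw_rows) + 1L]] <- data.frame(
        pathway = p, group = lev[i], other = others,
        p_value = ps,
        stars = vapply(ps, .stars, ""),
        direction = ifelse(is.na(ds), NA_character_,
                           ifelse(ds > 0, "higher",
                                  ifelse(ds < 0, "lower", "equal"))),
        comparable = !cnbd_cmp,
        stringsAsFactors = FALSE)
      sig <- !is.na(ps) & ps < alpha
      n_hi <- sum(sig & ds > 0); n_lo <- sum(sig & ds < 0)
      label <- if (sizes[lev[i]] < 2L) "" else
        if (n_hi + n_lo == 0L) "" else
          if (n_hi >= min_other && n_lo == 0L) "High" else
            if (n_lo >= min_other && n_hi == 0L) "Low" else "CNBD"
      tab_rows[[length(tab_rows) + 1L]] <- data.frame(
        group = lev[i], pathway = p, n = as.integer(sizes[lev[i]]),
        omnibus_p = omni, n_sig_higher = n_hi, n_sig_lower = n_lo,
        label = label, stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, tab_rows),
                 pairwise = do.call(rbind, pw_rows),
                 alpha = alpha, p_adjust = p_adjust,
                 min_other = min_other),
            class = "stp_characterization")
}

#' @export
print.stp_characterization <- function(x, ...) {
  lab <- x$table[x$table$label %in% c("High", "Low"), , drop = FALSE]
  cat(sprintf("Group characterization: %d groups x %d pathways, alpha = %g; %d High/Low call(s)\n",
              length(unique(x$table$group)),
              length(unique(x$table$pathway)), x$alpha, nrow(lab)))
  if (nrow(lab)) print(lab[, c("group", "pathway", "label")],
                       row.names = FALSE)
  invisible(x)
}

#' Characterize hierarchical clusters
#'
#' Convenience wrapper around [characterize_groups()] using the cluster
#' assignment of [hierarchical_cluster()] as the grouping.
#'
#' @param profile An [stp_profile()].
#' @param clusters An `stp_clusters` object.
#' @param ... Passed to [characterize_groups()].
#' @return An `stp_characterization`.
#' @export
characterize_clusters <- function(profile, clusters, ...) {
  grp <- paste0("cluster", clusters$assignment)
  names(grp) <- names(clusters$assignment)
  characterize_groups(profile, grp, ...)
}

#' Characterize histological subtypes
#'
#' [characterize_groups()] with histology-of-origin labels: a subtype is
#' called High/Low on a pathway only when it differs significantly from
#' three or more other subtypes in a consistent direction.
#'
#' @param profile An [stp_profile()].
#' @param histology Character vector of subtype labels, named by sample id
#'   or in profile row order.
#' @param ... Passed to [characterize_groups()].
#' @return An `stp_characterization`.
#' @export
characterize_histology <- function(profile, histology, ...) {
  characterize_groups(profile, histology, ...)
}

#' Write a characterization table as CSV
#'
#' Emits the pairwise comparisons with a star-notation column, merged with
#' the per-group labels.
#'
#' @param chr An `stp_characterization`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_characterization <- function(chr, path) {
  lab <- chr$table[, c("group", "pathway", "label")]
  out <- merge(chr$pairwise, lab, by = c("group", "pathway"), sort = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Assign profiles to predefined reference clusters by least squares
#'
#' Each sample is assigned to the reference centroid minimizing the sum of
#' squared pathway-score differences. This is how profiles are placed into
#' externally defined molecular subtypes whose per-pathway centroids are
#' known. Ties are broken by the lowest centroid index and flagged.
#'
#' @param profile An [stp_profile()].
#' @param centroids Numeric clusters x pathways matrix with cluster row
#'   names; its pathway set must cover the profile's.
#' @return `data.frame` with `sample_id`, `cluster`, `distance` (squared)
#'   and `tie`.
#' @export
assign_to_reference_clusters <- function(profile, centroids) {
  if (is.null(dim(centroids)) || nrow(centroids) == 0L)
    stop("'centroids' must be a non-empty clusters x pathways matrix",
         call. = FALSE)
  paths <- pathway_names(profile)
  miss <- setdiff(paths, colnames(centroids))
  if (length(miss))
    stop("centroids missing pathway(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ctr <- centroids[, paths, drop = FALSE]
  x <- profile$scores
  d2 <- outer(rowSums(x^2), rowSums(ctr^2), `+`) - 2 * x %*% t(ctr)
  d2 <- pmax(d2, 0)
  best <- apply(d2, 1L, which.min)
  tie <- vapply(seq_len(nrow(x)), function(i)
    sum(abs(d2[i, ] - d2[i, best[i]]) < 1e-9) > 1L, NA)
  data.frame(sample_id = rownames(x),
             cluster = rownames(ctr)[best],
             distance = d2[cbind(seq_len(nrow(x)), best)],
             tie = tie,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read reference centroids from CSV
#'
#' Expects one row per cluster: a `cluster` identifier column followed by
#' one numeric column per pathway.
#'
#' @param path CSV path.
#' @return Numeric clusters x pathways matrix.
#' @export
read_centroids <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ctr <- as.matrix(df[, setdiff(names(df), "cluster"), drop = FALSE])
  rownames(ctr) <- df$cluster
  ctr
}
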