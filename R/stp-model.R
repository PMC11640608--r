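#' Soft-discretize expression into per-gene evidence
#'
#' Observation layer of the two-layer pathway model: each gene's log2
#' expression is converted into the probability that the gene is in its
#' "up-expressed" state, via a logistic curve centred on a per-gene
#' threshold,
#' \deqn{e = 1 / (1 + exp(-slope (x - t_g))).}
#' By default the threshold is the cohort median of the gene, which is
#' robust to the arbitrary intensity scale of microarray platforms; a named
#' vector of per-gene thresholds can be supplied instead (e.g. from a
#' reference cohort). A zero-variance gene under the median policy has its
#' threshold at that constant, so its evidence is 0.5 everywhere and it is
#' uninformative.
#'
#' @param matrix Numeric genes x samples matrix of log2 expression, with
#'   gene identifiers as row names and sample identifiers as column names.
#' @param thresholds Optional named numeric vector of per-gene thresholds;
#'   genes not named fall back to the cohort median.
#' @param slope Positive steepness of the logistic; default 1 (per log2
#'   unit).
#' @return Numeric matrix of the same shape with entries in [0, 1], plus a
#'   `"thresholds"` attribute recording the thresholds used.
#' @export
discretize_expression <- function(matrix, thresholds = NULL, slope = 1) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("'matrix' must be a numeric genes x samples matrix", call. = FALSE)
  if (is.null(rownames(matrix)))
    stop("'matrix' must have gene identifiers as row names", call. = FALSE)
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0)
    stop("'slope' must be a single positive number", call. = FALSE)
  t_g <- apply(matrix, 1L, stats::median, na.rm = TRUE)
  if (!is.null(thresholds)) {
    if (is.null(names(thresholds)))
      stop("'thresholds' must be a named numeric vector", call. = FALSE)
    hit <- intersect(names(thresholds), rownames(matrix))
    t_g[hit] <- thresholds[hit]
  }
  e <- stats::plogis(slope * (matrix - t_g))
  attr(e, "thresholds") <- t_g
  e
}

# Conditional probability that a target gene is up-expressed given the
# latent pathway state, p = 0.5 +/- kappa * weight; kappa < 0.5 keeps the
# table bounded away from 0/1 so likelihood ratios stay finite.
.cpt_up <- function(direction, weight, kappa) {
  sgn <- ifelse(direction == "up", 1, -1)
  list(active   = 0.5 + sgn * kappa * weight,
       inactive = 0.5 - sgn * kappa * weight)
}

#' Infer pathway log2-odds from gene evidence
#'
#' Core of the two-layer Bayesian network. The latent binary node is the
#' pathway's transcription-factor activity; each target gene is a child
#' whose conditional probability of being up-expressed is
#' `0.5 + kappa * weight` when the pathway is active (direction `"up"`;
#' roles swap for `"down"` targets). Given soft evidence `e_g` per gene,
#' each gene contributes the likelihood ratio
#' \deqn{LR_g = (e_g p_a + (1 - e_g)(1 - p_a)) / (e_g p_i + (1 - e_g)(1 - p_i))}
#' and the posterior log2-odds of activity are
#' \deqn{L = \log_2(\pi / (1 - \pi)) + \sum_g \log_2 LR_g.}
#' Because the gene layer is conditionally independent given the pathway
#' state, this equals exhaustive enumeration over all joint gene-state
#' configurations.
#'
#' Target genes absent from the evidence matrix are skipped with a warning
#' and contribute a likelihood ratio of exactly 1 (cross-platform gene
#' coverage varies); if no target is present the prior log2-odds are
#' returned with a warning.
#'
#' @param evidence Genes x samples matrix from [discretize_expression()].
#' @param definition An [stp_pathway()].
#' @param kappa Evidence-strength bound in (0, 0.5); default 0.45.
#' @return Named numeric vector of per-sample log2-odds.
#' @export
infer_pathway_log2odds <- function(evidence, definition, kappa = 0.45) {
  validate_stp_pathway(definition)
  if (!is.numeric(kappa) || kappa <= 0 || kappa >= 0.5)
    stop("'kappa' must lie in (0, 0.5)", call. = FALSE)
  tg <- definition$targets
  present <- tg$gene_id %in% rownames(evidence)
  if (!all(present))
    warning(sprintf("pathway '%s': %d target gene(s) absent from matrix, contributing LR = 1: %s",
                    definition$name, sum(!present),
                    paste(tg$gene_id[!present], collapse = ", ")),
            call. = FALSE)
  prior_l2o <- log2(definition$prior_active / (1 - definition$prior_active))
  n_s <- ncol(evidence)
  if (!any(present)) {
    warning(sprintf("pathway '%s': no target gene present; returning prior log2-odds",
                    definition$name), call. = FALSE)
    return(stats::setNames(rep(prior_l2o, n_s), colnames(evidence)))
  }
  tg <- tg[present, , drop = FALSE]
  e <- evidence[tg$gene_id, , drop = FALSE]
  cpt <- .cpt_up(tg$direction, tg$weight, kappa)
  num <- e * cpt$active + (1 - e) * (1 - cpt$active)
  den <- e * cpt$inactive + (1 - e) * (1 - cpt$inactive)
  stats::setNames(prior_l2o + colSums(log2(num) - log2(den)),
                  colnames(evidence))
}

#' Calibration anchors of a pathway
#'
#' Returns the log2-odds mapped to score 0 (inactive anchor) and score 100
#' (active anchor). In `"extremes"` mode the anchors are the log2-odds of
#' the two extreme evidence configurations consistent with the target
#' directions: every up-target at evidence 1 and every down-target at 0
#' (fully active), and the mirror image (fully inactive). With the
#' symmetric conditional table these are
#' `prior log2-odds +/- sum_g log2((0.5 + kappa w_g) / (0.5 - kappa w_g))`,
#' so the active anchor always exceeds the inactive one. `"explicit"` mode
#' returns the stored reference-sample anchors.
#'
#' @param definition An [stp_pathway()].
#' @param kappa Evidence-strength bound used by the model; must match the
#'   value used for inference.
#' @return List with `log2odds_inactive` and `log2odds_active`.
#' @export
calibration_anchors <- function(definition, kappa = 0.45) {
  cal <- definition$calibration
  if (identical(cal$mode, "explicit"))
    return(list(log2odds_inactive = cal$log2odds_inactive,
                log2odds_active   = cal$log2odds_active))
  w <- definition$targets$weight
  span <- sum(log2((0.5 + kappa * w) / (0.5 - kappa * w)))
  prior_l2o <- log2(definition$prior_active / (1 - definition$prior_active))
  list(log2odds_inactive = prior_l2o - span,
       log2odds_active   = prior_l2o + span)
}

#' Normalize log2-odds to the 0-100 activity scale
#'
#' Linear map sending the inactive anchor to 0 and the active anchor to
#' 100, clipped to [0, 100]:
#' \deqn{score = clip(100 (L - L_0) / (L_{100} - L_0), 0, 100).}
#' A score of 0 corresponds to the odds of the pathway being inactive and
#' a score of 100 to the odds of an active pathway.
#'
#' @param log2odds Numeric vector of log2-odds.
#' @param calibration List with `log2odds_inactive` and `log2odds_active`
#'   (`active > inactive`), e.g. from [calibration_anchors()].
#' @return Numeric vector of scores in [0, 100].
#' @export
normalize_score <- function(log2odds, calibration) {
  lo <- calibration$log2odds_inactive
  hi <- calibration$log2odds_active
  if (is.null(lo) || is.null(hi) || !(hi > lo))
    stop("degenerate calibration: log2odds_active must exceed log2odds_inactive",
         call. = FALSE)
  pmin(pmax(100 * (log2odds - lo) / (hi - lo), 0), 100)
}

#' Construct an STP profile
#'
#' Container for a samples x pathways table of activity scores on the
#' 0-100 scale, the raw log2-odds behind them, and pass-through sample
#' metadata.
#'
#' @param scores Numeric samples x pathways matrix of scores in [0, 100];
#'   row names are sample identifiers, column names pathway names.
#' @param log2odds Optional matrix of the same shape with the raw
#'   log2-odds.
#' @param metadata Optional `data.frame` with a `sample_id` column matching
#'   the score rows (tissue class, histology, dataset id, ...).
#' @return An object of class `stp_profile`.
#' @export
stp_profile <- function(scores, log2odds = NULL, metadata = NULL) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("'scores' must be a numeric samples x pathways matrix", call. = FALSE)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("'scores' must have sample row names and pathway column names",
         call. = FALSE)
  if (any(scores < 0 | scores > 100, na.rm = TRUE))
    stop("scores must lie in [0, 100]", call. = FALSE)
  if (!is.null(log2odds) && !identical(dim(log2odds), dim(scores)))
    stop("'log2odds' must match the dimensions of 'scores'", call. = FALSE)
  if (!is.null(metadata)) {
    if (!"sample_id" %in% names(metadata))
      stop("'metadata' must have a 'sample_id' column", call. = FALSE)
    metadata <- metadata[match(rownames(scores), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(scores = scores, log2odds = log2odds, metadata = metadata),
            class = "stp_profile")
}

#' @export
print.stp_profile <- function(x, ...) {
  cat(sprintf("STP profile: %d samples x %d pathways (%s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(colnames(x$scores), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.stp_profile <- function(x, ...) {
  df <- data.frame(sample_id = rownames(x$scores), x$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Pathway names of a profile
#' @param profile An `stp_profile`.
#' @return Character vector of pathway names.
#' @export
pathway_names <- function(profile) colnames(profile$scores)

#' Score a cohort against a set of pathway models
#'
#' Runs the full scoring chain per pathway and sample: logistic evidence
#' from expression ([discretize_expression()]), two-layer Bayesian
#' inference of the log2-odds of pathway activity
#' ([infer_pathway_log2odds()]), and normalization to the 0-100 scale
#' ([normalize_score()]). Deterministic given the inputs and settings.
#'
#' @param matrix Numeric genes x samples log2 expression matrix.
#' @param definitions List of [stp_pathway()] objects.
#' @param slope,thresholds Passed to [discretize_expression()].
#' @param kappa Passed to [infer_pathway_log2odds()].
#' @param metadata Optional sample metadata `data.frame` carried through to
#'   the profile.
#' @return An [stp_profile()] with one row per sample and one column per
#'   pathway.
#' @export
score_cohort <- function(matrix, definitions, slope = 1, kappa = 0.45,
                         thresholds = NULL, metadata = NULL) {
  if (!is.matrix(matrix) || ncol(matrix) < 1L || nrow(matrix) < 1L)
    stop("'matrix' must be a non-empty genes x samples matrix", call. = FALSE)
  if (length(definitions) < 1L)
    stop("at least one pathway definition is required", call. = FALSE)
  covered <- vapply(definitions, function(d)
    any(d$targets$gene_id %in% rownames(matrix)), NA)
  if (!any(covered))
    stop("no pathway has any target gene in the expression matrix",
         call. = FALSE)
  evidence <- discretize_expression(matrix, thresholds = thresholds,
                                    slope = slope)
  nm <- unname(vapply(definitions, `[[`, "", "name"))
  l2o <- vapply(definitions, function(d)
    infer_pathway_log2odds(evidence, d, kappa = kappa),
    numeric(ncol(matrix)))
  l2o <- base::matrix(l2o, nrow = ncol(matrix), ncol = length(definitions),
                      dimnames = list(colnames(matrix), nm))
  scores <- vapply(seq_along(definitions), function(i)
    normalize_score(l2o[, i], calibration_anchors(definitions[[i]], kappa)),
    numeric(nrow(l2o)))
  scores <- base::matrix(scores, nrow = nrow(l2o), ncol = ncol(l2o),
                         dimnames = dimnames(l2o))
  stp_profile(scores, log2odds = l2o, metadata = metadata)
}

#' Write an STP profile to CSV
#'
#' One row per sample; pathway score columns followed by `_log2odds`
#' companion columns when raw log2-odds are available. UTF-8, `.` decimal
#' separator.
#'
#' @param profile An `stp_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stp_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  if (!is.null(profile$log2odds)) {
    l2o <- as.data.frame(profile$log2odds)
    names(l2o) <- paste0(names(l2o), "_log2odds")
    df <- cbind(df, l2o)
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an STP profile written by [write_stp_profile()]
#'
#' @param path CSV path.
#' @return An `stp_profile`.
#' @export
read_stp_profile <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  l2o_cols <- grep("_log2odds$", names(df), value = TRUE)
  score_cols <- setdiff(names(df), c("sample_id", l2o_cols))
  scores <- as.matrix(df[, score_cols, drop = FALSE])
  rownames(scores) <- df$sample_id
  l2o <- NULL
  if (length(l2o_cols)) {
    l2o <- as.matrix(df[, l2o_cols, drop = FALSE])
    colnames(l2o) <- sub("_log2odds$", "", l2o_cols)
    rownames(l2o) <- df$sample_id
    l2o <- l2o[, score_cols, drop = FALSE]
  }
  stp_profile(scores, log2odds = l2o)
}
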