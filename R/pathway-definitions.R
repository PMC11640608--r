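#' Construct a pathway definition
#'
#' A pathway definition names a signal transduction pathway (STP) and lists
#' the direct target genes of its terminal transcription factor. Each target
#' carries the direction of regulation (`"up"` if the active transcription
#' factor induces the gene, `"down"` if it represses it) and a literature
#' evidence weight in (0, 1] that scales how strongly the gene's expression
#' state bears on the pathway's latent activity.
#'
#' @param name Pathway identifier, e.g. `"AR"`, `"ER"`, `"HH"`.
#' @param targets `data.frame` with columns `gene_id` (character, unique),
#'   `direction` (`"up"` or `"down"`) and `weight` (numeric in (0, 1]).
#' @param prior_active Prior probability that the pathway is active, in
#'   (0, 1). Default 0.5 (uninformative).
#' @param calibration List describing how log2-odds are anchored to the
#'   0-100 score scale. Either `list(mode = "extremes")`, in which case the
#'   anchors are the log2-odds of the maximally inactive and maximally
#'   active evidence configurations, or
#'   `list(mode = "explicit", log2odds_inactive =, log2odds_active =)`.
#' @return An object of class `stp_pathway`.
#' @seealso [load_pathway_definitions()], [calibration_anchors()]
#' @export
stp_pathway <- function(name, targets, prior_active = 0.5,
                        calibration = list(mode = "extremes")) {
  x <- structure(
    list(name = name, targets = targets, prior_active = prior_active,
         calibration = calibration),
    class = "stp_pathway")
  validate_stp_pathway(x)
  x
}

#' Validate a pathway definition
#'
#' Checks the invariants of an `stp_pathway`: at least one target, unique
#' gene identifiers, directions in `{up, down}`, weights in (0, 1], a prior
#' in (0, 1), and a well-formed calibration block (explicit anchors must
#' satisfy active > inactive).
#'
#' @param x An `stp_pathway`.
#' @return `x`, invisibly; errors with a field-level message otherwise.
#' @export
validate_stp_pathway <- function(x) {
  if (!is.character(x$name) || length(x$name) != 1L || !nzchar(x$name))
    stop("pathway 'name' must be a non-empty string", call. = FALSE)
  tg <- x$targets
  if (!is.data.frame(tg) || nrow(tg) < 1L)
    stop(sprintf("pathway '%s': 'targets' must be a data.frame with >= 1 row",
                 x$name), call. = FALSE)
  need <- c("gene_id", "direction", "weight")
  miss <- setdiff(need, names(tg))
  if (length(miss))
    stop(sprintf("pathway '%s': targets missing column(s): %s",
                 x$name, paste(miss, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(tg$gene_id))
    stop(sprintf("pathway '%s': duplicate target gene_id(s): %s", x$name,
                 paste(unique(tg$gene_id[duplicated(tg$gene_id)]),
                       collapse = ", ")), call. = FALSE)
  if (!all(tg$direction %in% c("up", "down")))
    stop(sprintf("pathway '%s': 'direction' must be \"up\" or \"down\"",
                 x$name), call. = FALSE)
  if (!is.numeric(tg$weight) || any(!is.finite(tg$weight)) ||
      any(tg$weight <= 0) || any(tg$weight > 1))
    stop(sprintf("pathway '%s': 'weight' must lie in (0, 1]", x$name),
         call. = FALSE)
  if (!is.numeric(x$prior_active) || length(x$prior_active) != 1L ||
      x$prior_active <= 0 || x$prior_active >= 1)
    stop(sprintf("pathway '%s': 'prior_active' must lie in (0, 1)", x$name),
         call. = FALSE)
  cal <- x$calibration
  if (is.null(cal$mode) || !cal$mode %in% c("extremes", "explicit"))
    stop(sprintf("pathway '%s': calibration mode must be \"extremes\" or \"explicit\"",
                 x$name), call. = FALSE)
  if (identical(cal$mode, "explicit")) {
    if (is.null(cal$log2odds_inactive) || is.null(cal$log2odds_active))
      stop(sprintf("pathway '%s': explicit calibration requires log2odds_inactive and log2odds_active",
                   x$name), call. = FALSE)
    if (!(cal$log2odds_active > cal$log2odds_inactive))
      stop(sprintf("pathway '%s': calibration requires log2odds_active > log2odds_inactive",
                   x$name), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.stp_pathway <- function(x, ...) {
  n_dn <- sum(x$targets$direction == "down")
  cat(sprintf("STP pathway '%s': %d target genes (%d down-regulated), prior P(active) = %g, calibration: %s\n",
              x$name, nrow(x$targets), n_dn, x$prior_active,
              x$calibration$mode))
  invisible(x)
}

#' Read pathway definitions from JSON
#'
#' Reads a list of pathway definitions from the documented JSON schema:
#' `[{name, prior_active, targets: [{gene_id, direction, weight}],
#' calibration: {mode, log2odds_inactive?, log2odds_active?}}, ...]`.
#' Every definition is validated; schema violations are rejected with
#' field-level messages.
#'
#' @param path Path to a JSON file.
#' @return Named list of `stp_pathway` objects.
#' @export
load_pathway_definitions <- function(path) {
  if (!file.exists(path))
    stop("pathway definition file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.list(raw) || length(raw) == 0L)
    stop("pathway definition file must contain a non-empty JSON array",
         call. = FALSE)
  defs <- lapply(raw, function(d) {
    if (is.null(d$name))
      stop("pathway definition missing 'name'", call. = FALSE)
    tg <- d$targets
    if (is.null(tg) || length(tg) == 0L)
      stop(sprintf("pathway '%s': missing 'targets'", d$name), call. = FALSE)
    targets <- data.frame(
      gene_id   = vapply(tg, function(t) as.character(t$gene_id %||% NA), ""),
      direction = vapply(tg, function(t) as.character(t$direction %||% NA), ""),
      weight    = vapply(tg, function(t) as.numeric(t$weight %||% NA), 0),
      stringsAsFactors = FALSE)
    if (is.null(d$calibration))
      stop(sprintf("pathway '%s': missing 'calibration'", d$name),
           call. = FALSE)
    stp_pathway(name = d$name,
                targets = targets,
                prior_active = d$prior_active %||% 0.5,
                calibration = d$calibration)
  })
  nm <- vapply(defs, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate pathway name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  stats::setNames(defs, nm)
}

#' Write pathway definitions to JSON
#'
#' Inverse of [load_pathway_definitions()]; a write/read round trip
#' preserves all fields.
#'
#' @param definitions List of `stp_pathway` objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pathway_definitions <- function(definitions, path) {
  out <- lapply(definitions, function(d) {
    list(name = d$name,
         prior_active = d$prior_active,
         targets = lapply(seq_len(nrow(d$targets)), function(i)
           list(gene_id = d$targets$gene_id[i],
                direction = d$targets$direction[i],
                weight = d$targets$weight[i])),
         calibration = d$calibration)
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
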