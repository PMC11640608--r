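# Shared fixtures and independent oracles for the test suite.

# Exhaustive joint-enumeration oracle for the two-layer network: sums the
# joint probability over all 2^n gene-state configurations, independently
# of the product-form implementation under test.
enumeration_log2odds <- function(e, direction, weight, prior = 0.5,
                                 kappa = 0.45) {
  n <- length(e)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  p_up <- function(active) ifelse((direction == "up") == active,
                                  0.5 + kappa * weight,
                                  0.5 - kappa * weight)
  joint <- function(p) sum(apply(states, 1L, function(s)
    prod(ifelse(s == 1, p, 1 - p) * ifelse(s == 1, e, 1 - e))))
  log2(prior * joint(p_up(TRUE))) - log2((1 - prior) * joint(p_up(FALSE)))
}

# Small pathway definition with deterministic fields.
tiny_pathway <- function(n = 3, name = "TP", direction = NULL,
                         weight = NULL, prior = 0.5) {
  stp_pathway(
    name,
    data.frame(gene_id = paste0(name, "_g", seq_len(n)),
               direction = direction %||% rep("up", n),
               weight = weight %||% rep(0.8, n),
               stringsAsFactors = FALSE),
    prior_active = prior)
}

# Random pathway definition under a local seed (does not disturb the
# caller's RNG stream).
random_pathway <- function(n, name = "RP", seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  stp_pathway(
    name,
    data.frame(gene_id = paste0(name, "_g", seq_len(n)),
               direction = sample(c("up", "down"), n, replace = TRUE),
               weight = runif(n, 0.3, 1),
               stringsAsFactors = FALSE))
}

# Build a profile straight from a score matrix (sample x pathway).
profile_from_scores <- function(scores, metadata = NULL) {
  stp_profile(scores, metadata = metadata)
}

# Matched-cohort archetype subset separable on the default matching
# pathways (C4 and C5 coincide on {AR, ER, HH, NOTCH, TGFB}, so C5 is
# left out of matching fixtures).
matching_archetypes <- function() {
  default_archetypes()[c("C1", "C2", "C3", "C4", "C6", "C7")]
}

matching_histology_map <- function() {
  c(C1 = "SBOT", C2 = "HGSOC", C3 = "HGSOC", C4 = "HGSOC",
    C6 = "LGOC", C7 = "LGOC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
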