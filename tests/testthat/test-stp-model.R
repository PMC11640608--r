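test_that("logistic evidence has the right midpoint, limits and closed form", {
  x <- matrix(c(5, 7, 5 + 2, 5 - 50, 5 + 50, 5), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  # per-gene threshold fixed at 5 so the values are interpretable
  e <- discretize_expression(x, thresholds = c(g1 = 5), slope = 1)
  expect_equal(unname(e[1, "s1"]), 0.5)                      # at threshold
  expect_equal(unname(e[1, "s3"]), 1 / (1 + exp(-2)))        # closed form
  expect_equal(unname(e[1, "s4"]), 0, tolerance = 1e-12)     # x -> -Inf
  expect_equal(unname(e[1, "s5"]), 1, tolerance = 1e-12)     # x -> +Inf
  expect_true(all(diff(e[1, order(x[1, ])]) >= 0))           # increasing in x
})

test_that("median threshold policy handles zero-variance genes", {
  x <- matrix(c(3, 3, 3, 1, 2, 9), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "var"), paste0("s", 1:3)))
  e <- discretize_expression(x)
  expect_equal(unname(e["flat", ]), rep(0.5, 3))
  expect_equal(unname(attr(e, "thresholds")["var"]), 2)
})

test_that("neutral evidence and prior give zero log2-odds", {
  def <- tiny_pathway(4)
  e <- matrix(0.5, 4, 3,
              dimnames = list(def$targets$gene_id, paste0("s", 1:3)))
  expect_equal(unname(infer_pathway_log2odds(e, def)), rep(0, 3))
})

test_that("inference equals exhaustive joint enumeration on small pathways", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    def <- random_pathway(n, name = "RP")
    e_vec <- runif(n)
    e <- matrix(e_vec, n, 1, dimnames = list(def$targets$gene_id, "s1"))
    got <- infer_pathway_log2odds(e, def)
    want <- enumeration_log2odds(e_vec, def$targets$direction,
                                 def$targets$weight)
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("flipping every target direction negates the log2-odds at flat prior", {
  set.seed(102)
  def <- random_pathway(5, name = "FL")
  flipped <- def
  flipped$targets$direction <- ifelse(def$targets$direction == "up",
                                      "down", "up")
  e <- matrix(runif(5), 5, 1, dimnames = list(def$targets$gene_id, "s1"))
  expect_equal(unname(infer_pathway_log2odds(e, def)),
               -unname(infer_pathway_log2odds(e, flipped)))
})

test_that("log2-odds are monotone in the evidence of each target", {
  set.seed(103)
  def <- random_pathway(6, name = "MO")
  base_e <- runif(6)
  for (g in 1:6) {
    for (delta in c(0.05, 0.2)) {
      lo <- base_e; hi <- base_e
      hi[g] <- min(1, base_e[g] + delta)
      e2 <- matrix(c(lo, hi), 6, 2,
                   dimnames = list(def$targets$gene_id, c("lo", "hi")))
      l <- infer_pathway_log2odds(e2, def)
      if (def$targets$direction[g] == "up") {
        expect_gte(l["hi"], l["lo"])
      } else {
        expect_lte(l["hi"], l["lo"])
      }
    }
  }
})

test_that("absent target genes contribute exactly LR = 1", {
  def <- tiny_pathway(3)
  e_full <- matrix(c(0.9, 0.7, 0.5), 3, 1,
                   dimnames = list(def$targets$gene_id, "s1"))
  # third gene absent entirely: same answer as e = 0.5 (LR = 1) for it
  e_missing <- e_full[1:2, , drop = FALSE]
  expect_warning(got <- infer_pathway_log2odds(e_missing, def),
                 "absent from matrix")
  expect_equal(got, infer_pathway_log2odds(e_full, def))
})

test_that("no target present returns the prior log2-odds with a warning", {
  def <- tiny_pathway(2, prior = 0.8)
  e <- matrix(0.9, 1, 2, dimnames = list("other_gene", c("s1", "s2")))
  expect_warning(
    expect_warning(got <- infer_pathway_log2odds(e, def), "absent"),
    "prior log2-odds")
  expect_equal(unname(got), rep(log2(0.8 / 0.2), 2))
})

test_that("normalization maps anchors to 0/100, midpoint to 50, and clips", {
  cal <- list(log2odds_inactive = -12, log2odds_active = 20)
  expect_equal(normalize_score(-12, cal), 0)
  expect_equal(normalize_score(20, cal), 100)
  expect_equal(normalize_score(4, cal), 50)
  expect_equal(normalize_score(-100, cal), 0)
  expect_equal(normalize_score(100, cal), 100)
  # non-decreasing in L
  L <- seq(-30, 30, length.out = 101)
  expect_true(all(diff(normalize_score(L, cal)) >= 0))
  expect_error(normalize_score(0, list(log2odds_inactive = 1,
                                       log2odds_active = 1)),
               "degenerate calibration")
})

test_that("extreme-mode anchors bracket all reachable log2-odds symmetrically", {
  set.seed(104)
  def <- random_pathway(7, name = "AN")
  cal <- calibration_anchors(def)
  expect_gt(cal$log2odds_active, cal$log2odds_inactive)
  # direction-consistent extreme evidence attains the anchors exactly
  e_active <- ifelse(def$targets$direction == "up", 1, 0)
  e_inactive <- 1 - e_active
  em <- matrix(c(e_active, e_inactive), 7, 2,
               dimnames = list(def$targets$gene_id, c("act", "inact")))
  l <- infer_pathway_log2odds(em, def)
  expect_equal(unname(l["act"]), cal$log2odds_active)
  expect_equal(unname(l["inact"]), cal$log2odds_inactive)
})

test_that("explicit calibration anchors are honored and validated", {
  def <- tiny_pathway(2)
  def$calibration <- list(mode = "explicit", log2odds_inactive = -3,
                          log2odds_active = 5)
  expect_equal(calibration_anchors(def),
               list(log2odds_inactive = -3, log2odds_active = 5))
  expect_error(stp_pathway("B", tiny_pathway(2)$targets,
                           calibration = list(mode = "explicit",
                                              log2odds_inactive = 2,
                                              log2odds_active = 2)),
               "log2odds_active > log2odds_inactive")
})

test_that("score_cohort produces bounded, deterministic profiles", {
  defs <- generate_pathway_definitions(n_pathways = 3,
                                       genes_per_pathway = c(5, 8),
                                       seed = 7)
  arks <- list(on = setNames(rep(0.9, 3), names(defs)),
               off = setNames(rep(0.1, 3), names(defs)))
  coh <- generate_cohort(defs, arks, n_per_archetype = 4, noise_sd = 0.3,
                         seed = 8)
  p1 <- score_cohort(coh$expression, defs, metadata = coh$metadata)
  p2 <- score_cohort(coh$expression, defs, metadata = coh$metadata)
  expect_identical(p1$scores, p2$scores)          # bit-identical rerun
  expect_true(all(p1$scores >= 0 & p1$scores <= 100))
  expect_identical(rownames(p1$scores), colnames(coh$expression))
  # ground-truth active group scores above inactive group, every pathway
  on_rows <- coh$truth$archetype == "on"
  for (p in colnames(p1$scores))
    expect_gt(mean(p1$scores[on_rows, p]), mean(p1$scores[!on_rows, p]))
})

test_that("a cohort sitting at its thresholds scores at normalize(0)", {
  defs <- list(A = tiny_pathway(3, "A"), B = tiny_pathway(2, "B"))
  genes <- c(defs$A$targets$gene_id, defs$B$targets$gene_id)
  x <- matrix(6, length(genes), 2, dimnames = list(genes, c("s1", "s2")))
  prof <- score_cohort(x, defs)
  expect_true(all(prof$log2odds == 0))
  for (nm in names(defs)) {
    cal <- calibration_anchors(defs[[nm]])
    expect_equal(unname(prof$scores[, nm]),
                 rep(normalize_score(0, cal), 2))
  }
})

test_that("single-sample cohorts and uncovered definitions are handled", {
  def <- tiny_pathway(3, "A")
  x <- matrix(c(8, 9, 7), 3, 1,
              dimnames = list(def$targets$gene_id, "only"))
  prof <- score_cohort(x, list(A = def))
  expect_equal(dim(prof$scores), c(1L, 1L))
  expect_true(prof$scores[1, 1] >= 0 && prof$scores[1, 1] <= 100)
  rownames(x) <- paste0("unrelated", 1:3)
  expect_error(score_cohort(x, list(A = def)), "no pathway has any target")
})

test_that("pathway definition JSON round-trips and rejects bad schemas", {
  defs <- generate_pathway_definitions(n_pathways = 2,
                                       genes_per_pathway = c(4, 6),
                                       seed = 5)
  defs[[1]]$calibration <- list(mode = "explicit", log2odds_inactive = -2,
                                log2odds_active = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_pathway_definitions(defs, path)
  back <- load_pathway_definitions(path)
  expect_equal(length(back), 2L)
  for (i in 1:2) {
    expect_equal(back[[i]]$name, defs[[i]]$name)
    expect_equal(back[[i]]$targets, defs[[i]]$targets)
    expect_equal(back[[i]]$prior_active, defs[[i]]$prior_active)
    expect_equal(back[[i]]$calibration$mode, defs[[i]]$calibration$mode)
  }
  # weight outside (0,1] rejected with a field-level message
  bad <- defs
  bad[[1]]$targets$weight[1] <- 0
  path2 <- withr::local_tempfile(fileext = ".json")
  expect_error(write_pathway_definitions(bad, path2), NA)
  expect_error(load_pathway_definitions(path2), "weight")
  # a realistic 30-target definition is accepted
  big <- generate_pathway_definitions(n_pathways = 1,
                                      genes_per_pathway = c(30, 30),
                                      seed = 6)
  path3 <- withr::local_tempfile(fileext = ".json")
  write_pathway_definitions(big, path3)
  expect_equal(nrow(load_pathway_definitions(path3)[[1]]$targets), 30L)
})

test_that("pathway validation enforces the documented invariants", {
  tg <- data.frame(gene_id = c("a", "b"), direction = c("up", "down"),
                   weight = c(0.5, 0.7))
  expect_s3_class(stp_pathway("OK", tg), "stp_pathway")
  expect_error(stp_pathway("D", tg[c(1, 1), ]), "duplicate")
  expect_error(stp_pathway("W", transform(tg, weight = c(0.5, 1.2))),
               "weight")
  expect_error(stp_pathway("P", tg, prior_active = 1), "prior_active")
  expect_error(stp_pathway("E", tg[0, ]), ">= 1 row")
})

test_that("profile CSV export round-trips scores and log2-odds", {
  defs <- list(A = tiny_pathway(3, "A"))
  x <- matrix(rnorm(6, 8), 3, 2,
              dimnames = list(defs$A$targets$gene_id, c("s1", "s2")))
  prof <- score_cohort(x, defs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stp_profile(prof, path)
  back <- read_stp_profile(path)
  expect_equal(back$scores, prof$scores)
  expect_equal(back$log2odds, prof$log2odds)
})
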