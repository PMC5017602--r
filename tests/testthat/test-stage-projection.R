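# Bidirectional cross-projection and arrest-stage calling.

# Hand-built projection grid over 2 stages x 2 subtypes; p/es per cell.
fake_grid <- function(fwd, rev) {
  mk <- function(tab, direction) {
    do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
      data.frame(direction = direction, signature = tab$signature[i],
                 contrast = tab$contrast[i], es = tab$es[i], nes = 1,
                 p_perm = tab$p[i], n_permutations = 99, mode = "phenotype",
                 stringsAsFactors = FALSE)))
  }
  sig <- function(nm) gene_signature(nm, paste0(nm, "_g", 1:3), source_group = nm)
  structure(list(forward = mk(fwd, "healthy_to_leukemia"),
                 reverse = mk(rev, "leukemia_to_healthy"),
                 stage_signatures = list(`pre-B` = sig("pre-B"), `pro-B` = sig("pro-B")),
                 subtype_signatures = list(X = sig("X"), Y = sig("Y")),
                 n_shared_genes = 100),
            class = "projection_grid")
}

grid_tab <- function(signatures, contrasts, p, es) {
  g <- expand.grid(signature = signatures, contrast = contrasts,
                   stringsAsFactors = FALSE)
  g$p <- p; g$es <- es
  g
}

test_that("a uniquely qualifying pair is called; anything else is unassigned", {
  # only (pre-B, X) passes both directions
  fwd <- grid_tab(c("pre-B", "pro-B"), c("X", "Y"),
                  p = c(0.01, 0.8, 0.9, 0.7), es = c(0.5, 0.1, -0.2, 0.1))
  rev <- grid_tab(c("X", "Y"), c("pre-B", "pro-B"),
                  p = c(0.02, 0.6, 0.9, 0.9), es = c(0.6, 0.2, -0.1, 0.1))
  calls <- call_arrest_stage(fake_grid(fwd, rev))
  expect_identical(calls$stage[calls$subtype == "X"], "pre-B")
  expect_equal(calls$forward_p[calls$subtype == "X"], 0.01)
  expect_equal(calls$reverse_p[calls$subtype == "X"], 0.02)
  expect_identical(calls$stage[calls$subtype == "Y"], "unassigned")
})

test_that("forward significance alone does not assign a stage", {
  fwd <- grid_tab(c("pre-B", "pro-B"), c("X", "Y"),
                  p = c(0.01, 0.8, 0.9, 0.7), es = c(0.5, 0.1, -0.2, 0.1))
  rev <- grid_tab(c("X", "Y"), c("pre-B", "pro-B"),
                  p = c(0.4, 0.6, 0.9, 0.9), es = c(0.6, 0.2, -0.1, 0.1))
  calls <- call_arrest_stage(fake_grid(fwd, rev))
  expect_identical(unique(calls$stage), "unassigned")
})

test_that("two qualifying stages for one subtype give unassigned", {
  fwd <- grid_tab(c("pre-B", "pro-B"), c("X", "Y"),
                  p = c(0.01, 0.02, 0.9, 0.7), es = c(0.5, 0.4, -0.2, 0.1))
  rev <- grid_tab(c("X", "Y"), c("pre-B", "pro-B"),
                  p = c(0.02, 0.6, 0.03, 0.9), es = c(0.6, 0.2, 0.5, 0.1))
  expect_message(calls <- call_arrest_stage(fake_grid(fwd, rev)),
                 "multiple qualifying stages")
  expect_identical(unique(calls$stage), "unassigned")
})

test_that("a stage qualifying for two subtypes is not specific to either", {
  # (pre-B, X) and (pre-B, Y) both pass both directions
  fwd <- grid_tab(c("pre-B", "pro-B"), c("X", "Y"),
                  p = c(0.01, 0.8, 0.02, 0.7), es = c(0.5, 0.1, 0.4, 0.1))
  rev <- grid_tab(c("X", "Y"), c("pre-B", "pro-B"),
                  p = c(0.02, 0.03, 0.6, 0.9), es = c(0.6, 0.5, 0.2, 0.1))
  msgs <- capture_messages(calls <- call_arrest_stage(fake_grid(fwd, rev)))
  expect_match(msgs, "not specific", all = TRUE)
  expect_length(msgs, 2L)
  expect_identical(unique(calls$stage), "unassigned")
})

test_that("cross_project fills the full Cartesian grids and finds a planted arrest", {
  spec <- cohort_spec(n_genes = 800, genes_per_stage_signature = 60,
                      genes_per_subtype_signature = 60,
                      samples_per_group = 10, seed = 21)
  h <- simulate_healthy(spec)
  l <- simulate_leukemia(spec)
  expect_message(
    grid <- cross_project(h$matrix[1:790, ], h$annotations, l$matrix,
                          l$annotations, n = 120, n_perm = 99, seed = 5),
    "790 shared genes")
  expect_identical(nrow(grid$forward), 4L * 6L)
  expect_identical(nrow(grid$reverse), 4L * 6L)

  fwd <- grid$forward[grid$forward$signature == "pre-B" &
                      grid$forward$contrast == "TCF3-PBX1", ]
  rev <- grid$reverse[grid$reverse$signature == "TCF3-PBX1" &
                      grid$reverse$contrast == "pre-B", ]
  expect_gt(fwd$es, 0); expect_lte(fwd$p_perm, 0.05)
  expect_gt(rev$es, 0); expect_lte(rev$p_perm, 0.05)

  calls <- suppressMessages(call_arrest_stage(grid))
  expect_identical(calls$stage[calls$subtype == "TCF3-PBX1"], "pre-B")
  expect_identical(calls$stage[calls$subtype == "ETV6-RUNX1"], "pro-B")

  out <- withr::local_tempfile(fileext = ".tsv")
  write_projection_grid(grid, out)
  tab <- utils::read.delim(out)
  expect_identical(nrow(tab), 48L)
})

test_that("disjoint gene universes are rejected", {
  spec <- cohort_spec(n_genes = 400, genes_per_stage_signature = 30,
                      genes_per_subtype_signature = 20,
                      samples_per_group = 5, seed = 1)
  h <- simulate_healthy(spec)
  l <- simulate_leukemia(spec)
  l2 <- l$matrix
  rownames(l2) <- paste0("other_", rownames(l2))
  expect_error(cross_project(h$matrix, h$annotations, l2, l$annotations),
               "no genes")
})

test_that("stage calls with no planted structure are all unassigned", {
  # leukemia independent of any stage profile: every subtype maps to "none"
  map <- c("A" = "none", "B" = "none", "C" = "none")
  spec <- cohort_spec(n_genes = 600, genes_per_stage_signature = 40,
                      genes_per_subtype_signature = 40,
                      samples_per_group = 8, subtype_map = map, seed = 33)
  h <- simulate_healthy(spec)
  l <- simulate_leukemia(spec)
  grid <- cross_project(h$matrix, h$annotations, l$matrix, l$annotations,
                        n = 80, n_perm = 99, seed = 13)
  calls <- suppressMessages(call_arrest_stage(grid))
  expect_identical(unique(calls$stage), "unassigned")
})
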