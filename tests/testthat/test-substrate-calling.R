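fixture_calls <- function(...) {
  call_candidates(table1_calling_table(), "bTRCP", calling_config(...))
}

test_that("printed-table detection patterns call as expected", {
  calls <- fixture_calls()
  pick <- function(p) calls[calls$protein == p, ]
  expect_true(pick("CReP")$is_candidate)
  expect_equal(pick("CReP")$n_bait_detected, 3L)
  # two-of-three detection still qualifies
  expect_true(pick("SUN2")$is_candidate)
  expect_equal(pick("SUN2")$n_bait_detected, 2L)
  # control-detected known substrate fails the rule despite high counts
  expect_false(pick("β-catenin")$is_candidate)
  expect_gte(pick("β-catenin")$n_control_detected, 1L)
  expect_equal(sum(calls$is_candidate), 28L)
})

test_that("an undetected protein is never a candidate", {
  tab <- spectral_counts(
    data.frame(protein = "ghost", run_id = c("b1", "b2", "c1"),
               count = 0L),
    data.frame(run_id = c("b1", "b2", "c1"),
               bait = c("trap", "trap", "control"))
  )
  calls <- call_candidates(tab, "trap")
  expect_false(calls$is_candidate)
  expect_equal(calls$enrichment_score, 0)
})

test_that("calling matches an independent re-derivation of the rule", {
  for (seed in 1:40) {
    st <- random_small_table(seed)
    calls <- call_candidates(st$table, "trap")
    expected <- oracle_call(st$matrix, st$bait_cols, st$control_cols)
    expect_equal(calls$is_candidate, expected, info = paste("seed", seed))
  }
})

test_that("raising thresholds can only shrink the candidate set", {
  candidate_set <- function(tab, mbr, thr) {
    calls <- call_candidates(
      tab, "trap",
      calling_config(min_bait_runs = mbr, presence_threshold = thr))
    calls$protein[calls$is_candidate]
  }
  for (seed in 1:15) {
    st <- random_small_table(seed + 100)
    n_bait <- length(st$bait_cols)
    for (mbr in seq_len(n_bait - 1)) {
      for (thr in 1:3) {
        here <- candidate_set(st$table, mbr, thr)
        expect_true(all(candidate_set(st$table, mbr + 1, thr) %in% here),
                    info = paste("seed", seed, "mbr", mbr, "thr", thr))
        expect_true(all(candidate_set(st$table, mbr, thr + 1) %in% here),
                    info = paste("seed", seed, "mbr", mbr, "thr", thr))
      }
    }
  }
})

test_that("adding a control detection removes exactly that protein", {
  st <- random_small_table(7)
  base <- call_candidates(st$table, "trap")
  tab2 <- st$table
  extra_run <- tibble::tibble(run_id = "c_extra", bait = "control",
                              replicate = 9L, condition = "none")
  p <- base$protein[1]
  extra_counts <- tibble::tibble(
    protein = unique(tab2$counts$protein), run_id = "c_extra", count = 0L)
  extra_counts$count[extra_counts$protein == p] <- 3L
  tab2 <- spectral_counts(rbind(tab2$counts, extra_counts),
                          rbind(tab2$runs, extra_run))
  after <- call_candidates(tab2, "trap")
  expect_false(after$is_candidate[after$protein == p])
  others <- setdiff(base$protein, p)
  expect_equal(after$is_candidate[match(others, after$protein)],
               base$is_candidate[match(others, base$protein)])
})

test_that("family exclusion removes all members once one is control-detected", {
  tab <- spectral_counts(
    data.frame(
      protein = rep(c("HLA-A", "HLA-B", "HLA-C", "other"), each = 4),
      run_id = rep(c("b1", "b2", "b3", "c1"), times = 4),
      count = as.integer(c(5, 4, 3, 0,   6, 2, 1, 0,   0, 0, 2, 7,
                           3, 3, 3, 0))
    ),
    data.frame(run_id = c("b1", "b2", "b3", "c1"),
               bait = c("trap", "trap", "trap", "control"))
  )
  grp <- list(c("HLA-A", "HLA-B", "HLA-C"))
  calls <- call_candidates(tab, "trap",
                           calling_config(exclusion_groups = grp))
  expect_false(any(calls$is_candidate[calls$protein %in% grp[[1]]]))
  expect_match(calls$excluded_reason[calls$protein == "HLA-A"], "HLA-C")
  expect_true(calls$is_candidate[calls$protein == "other"])
  # without the group, the control-clean alleles are called
  no_grp <- call_candidates(tab, "trap")
  expect_true(no_grp$is_candidate[no_grp$protein == "HLA-A"])
})

test_that("missing bait errors and missing controls degrade with a warning", {
  st <- random_small_table(3)
  expect_error(call_candidates(st$table, "nosuchbait"),
               class = "ligasetrap_config_error")
  bait_run_ids <- st$table$runs$run_id[st$table$runs$bait == "trap"]
  bait_only <- spectral_counts(
    st$table$counts[st$table$counts$run_id %in% bait_run_ids, ],
    st$table$runs[st$table$runs$bait == "trap", ])
  expect_warning(calls <- call_candidates(bait_only, "trap"),
                 "vacuously")
  expect_equal(calls$n_control_detected, rep(0L, nrow(calls)))
})

test_that("enrichment score follows the average-over-background formula", {
  expect_equal(enrichment_score(c(12, 11, 13), c(2, 2)), 6)
  expect_equal(enrichment_score(c(0, 0, 0), c(5, 1)), 0)
  expect_equal(enrichment_score(10, c(0, 0), pseudocount = 0.5), 20)
  expect_identical(enrichment_score(10, c(0, 0), pseudocount = 0), Inf)
  expect_error(enrichment_score(c(-1, 2), c(0)),
               class = "ligasetrap_validation_error")
  expect_error(enrichment_score(numeric(), c(1)),
               class = "ligasetrap_validation_error")
})

test_that("NSAF is length-normalized and conserves the 1e5 total", {
  tab <- spectral_counts(
    data.frame(protein = c("a", "b"), run_id = "r1", count = c(10L, 10L)),
    data.frame(run_id = "r1", bait = "trap"),
    lengths = data.frame(protein = c("a", "b"), length = c(100L, 100L))
  )
  expect_equal(nsaf(tab, "r1")$nsaf, c(50000, 50000))

  tab2 <- spectral_counts(
    data.frame(protein = c("a", "b", "c"), run_id = "r1",
               count = c(10L, 20L, 30L)),
    data.frame(run_id = "r1", bait = "trap"),
    lengths = data.frame(protein = c("a", "b", "c"),
                         length = c(100L, 200L, 300L))
  )
  expect_equal(nsaf(tab2, "r1")$nsaf, rep(1e5 / 3, 3))

  for (seed in 1:25) {
    sim <- simulate_ipms(ipms_sim_config(n_proteins = 40, seed = seed))
    for (r in sim$table$runs$run_id) {
      vals <- suppressWarnings(nsaf(sim$table, r))
      if (nrow(vals) == 0) next
      expect_equal(sum(vals$nsaf), 1e5, tolerance = 1e-6)
      m <- count_matrix(sim$table)[vals$protein, r]
      lens <- sim$table$lengths$length[
        match(vals$protein, sim$table$lengths$protein)]
      expect_equal(vals$nsaf, oracle_nsaf(m, lens), ignore_attr = TRUE)
    }
  }
})

test_that("NSAF error and warning paths", {
  tab <- spectral_counts(
    data.frame(protein = "a", run_id = c("r1", "r2"), count = c(3L, 0L)),
    data.frame(run_id = c("r1", "r2"), bait = "trap")
  )
  expect_error(nsaf(tab, "r1"), class = "ligasetrap_validation_error")
  tab_len <- spectral_counts(
    data.frame(protein = "a", run_id = c("r1", "r2"), count = c(3L, 0L)),
    data.frame(run_id = c("r1", "r2"), bait = "trap"),
    lengths = data.frame(protein = "a", length = 100L)
  )
  expect_warning(empty <- nsaf(tab_len, "r2"), "no spectral counts")
  expect_equal(nrow(empty), 0)
})

test_that("ranking is by abundance with deterministic tie-breaks", {
  calls <- rank_candidates(fixture_calls())
  expect_lt(which(calls$protein == "HIVEP1/2"),
            which(calls$protein == "CReP"))

  toy <- tibble::tibble(
    protein = c("zeta", "alpha"),
    n_bait_detected = 2L, n_control_detected = 0L,
    total_bait_tsc = 10L, is_candidate = TRUE,
    excluded_reason = NA_character_, enrichment_score = 5)
  expect_equal(rank_candidates(toy)$protein, c("alpha", "zeta"))

  shuffled <- fixture_calls()[sample(28 + 4), ]
  expect_equal(rank_candidates(shuffled)$protein,
               rank_candidates(fixture_calls())$protein)
})
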