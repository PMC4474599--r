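test_that("canonical and acidic-variant windows are recognised", {
  hit <- scan_degrons(c(RIPK4 = "DSGAS"))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 1L)
  expect_equal(hit$spacer_len, 1L)
  expect_equal(hit$variant_class, "canonical_DSG")

  best <- best_degron(c(CReP = "DDGFDSDSSLSDSD"))
  expect_equal(best$start, 1L)
  expect_match(best$matched_string, "^DDGFDSD")
  expect_equal(best$variant_class, "acidic_variant")

  expect_equal(nrow(scan_degrons(c(polyA = strrep("A", 50)))), 0)
  expect_equal(nrow(scan_degrons(c(short = "DSG"))), 0)
})

test_that("best degron per protein follows the score/spacer/start tie rules", {
  # FNIP1-type window with a 3-residue spacer
  fnip <- best_degron(c(FNIP1 = "MKLDSGIARSPQ"))
  expect_equal(fnip$matched_string, "DSGIARS")

  # two identical-score hits: earlier start wins
  two <- best_degron(c(x = "DSGASXXXXDSGAS"))
  expect_equal(two$start, 1L)

  # both printed ZNF704 motifs score; the DDG window wins
  z <- "MDDGIDEAEKKSDGEEDL"
  hits <- scan_degrons(c(ZNF704 = z))
  expect_true(any(hits$start == 2))            # DDGIDEAE region
  expect_true(any(grepl("^SDGEED", hits$matched_string)))
  best <- best_degron(c(ZNF704 = z))
  expect_match(best$matched_string, "^DDGIDE")
})

test_that("scanner equals exhaustive window enumeration on random sequences", {
  seqs <- random_aa(150, 60, seed = 5)
  model <- degron_model()
  for (i in seq_along(seqs)) {
    got <- scan_degrons(c(s = seqs[i]), model)
    exp <- oracle_scan(seqs[i], model)
    expect_equal(nrow(got), nrow(exp), info = paste("seq", i))
    if (nrow(got) > 0) {
      expect_equal(got$start, exp$start, info = paste("seq", i))
      expect_equal(got$score, exp$score, ignore_attr = TRUE,
                   info = paste("seq", i))
      expect_equal(got$matched_string, exp$matched_string,
                   info = paste("seq", i))
      expect_equal(got$variant_class, exp$variant_class,
                   info = paste("seq", i))
    }
  }
})

test_that("relaxed transposed-glycine mode is off by default", {
  expect_equal(nrow(scan_degrons(c(ALDH2 = "DGDFFSYT"))), 0)
  relaxed <- scan_degrons(c(ALDH2 = "DGDFFSYT"),
                          degron_model(relaxed = TRUE))
  expect_gte(nrow(relaxed), 1)
  expect_equal(relaxed$variant_class[1], "relaxed")
  # oracle agrees in relaxed mode too
  m <- degron_model(relaxed = TRUE)
  seqs <- random_aa(40, 45, seed = 21)
  for (s in seqs) {
    expect_equal(scan_degrons(c(x = s), m)$score,
                 oracle_scan(s, m)$score, ignore_attr = TRUE)
  }
})

test_that("substituting a higher-weighted same-class residue never lowers a score", {
  model <- degron_model()
  score_of <- function(s) scan_degrons(c(x = s), model, min_score = 0)$score[1]
  check_position <- function(weights, make) {
    for (r1 in names(weights)) {
      for (r2 in names(weights)) {
        if (weights[[r2]] >= weights[[r1]]) {
          expect_gte(score_of(make(r2)), score_of(make(r1)))
        }
      }
    }
  }
  check_position(model$p1_weights, function(r) paste0(r, "TGAT"))
  check_position(model$p2_weights, function(r) paste0("T", r, "GAT"))
  check_position(model$p_last_weights, function(r) paste0("TTGA", r))
})

test_that("every printed motif string except DGDFFSYT contains a window", {
  motifs <- table1_motif_strings()
  expect_gte(length(motifs), 16)
  hits <- vapply(motifs, function(m) {
    nrow(scan_degrons(stats::setNames(m, "m"))) > 0
  }, logical(1))
  expect_false(hits[["DGDFFSYT"]])
  expect_true(all(hits[names(hits) != "DGDFFSYT"]))
})

test_that("ortholog comparison reports window identity and conservation", {
  hum <- "MKKLDSGASTPQRWVNML"
  rec <- tibble::tibble(
    protein = "p", species = c("human", "mouse"),
    sequence = c(hum, hum))
  cons <- compare_orthologs(rec)
  expect_equal(cons$species$window_identity, c(1, 1))
  expect_true(all(cons$positions$identity == 1))

  # one substitution inside the window: identity (len-1)/len
  mouse <- sub("DSGAS", "DSGAT", hum)
  cons2 <- compare_orthologs(tibble::tibble(
    protein = "p", species = c("human", "mouse"),
    sequence = c(hum, mouse)))
  len <- nchar(cons2$species$aligned_window[1])
  expect_equal(cons2$species$window_identity[2], (len - 1) / len)

  # conserved degron inside shuffled flanks is still located
  set.seed(9)
  flank1 <- random_aa(1, 30, seed = 31,
                      alphabet = strsplit("ACFGHIKLMNPQRVWY", "")[[1]])
  flank2 <- random_aa(1, 30, seed = 32,
                      alphabet = strsplit("ACFGHIKLMNPQRVWY", "")[[1]])
  sp1 <- paste0(flank1, "DSGNNS",
                random_aa(1, 30, seed = 33,
                          alphabet = strsplit("ACFGHIKLMNPQRVWY", "")[[1]]))
  sp2 <- paste0(flank2, "DSGNNS",
                random_aa(1, 30, seed = 34,
                          alphabet = strsplit("ACFGHIKLMNPQRVWY", "")[[1]]))
  cons3 <- compare_orthologs(tibble::tibble(
    protein = "p", species = c("a", "b"), sequence = c(sp1, sp2)))
  expect_equal(cons3$species$best_degron[1], cons3$species$best_degron[2])
  expect_equal(cons3$species$window_identity[2], 1)

  # ortholog lacking any scoring window is recorded as absent
  cons4 <- compare_orthologs(tibble::tibble(
    protein = "p", species = c("a", "b"),
    sequence = c(hum, strrep("A", 20))))
  expect_true(is.na(cons4$species$best_degron[2]))

  expect_error(compare_orthologs(tibble::tibble(
    protein = "p", species = "a", sequence = hum)),
    class = "ligasetrap_validation_error")
})
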