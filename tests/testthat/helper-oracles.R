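# Independent oracles: literal re-derivations of the rules from their
# plain-language statements, kept deliberately naive and separate from the
# package's implementation paths.

# "identified in at least `min_bait` of the bait purifications, but not in
# any of the negative control purifications"
oracle_call <- function(counts, bait_cols, control_cols,
                        min_bait = 2, presence = 1, control_presence = 1) {
  out <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    n_bait <- 0
    for (j in bait_cols) {
      if (counts[i, j] >= presence) n_bait <- n_bait + 1
    }
    in_control <- FALSE
    for (j in control_cols) {
      if (counts[i, j] >= control_presence) in_control <- TRUE
    }
    out[i] <- (n_bait >= min_bait) && !in_control
  }
  out
}

# NSAF by the definition: (SpC/L) over the run total of SpC/L, times 1e5
oracle_nsaf <- function(counts, lengths) {
  saf <- counts / lengths
  saf[counts == 0] <- 0
  1e5 * saf / sum(saf)
}

# exhaustive enumeration of every degron window of a sequence, scored by
# explicit per-window arithmetic
oracle_scan <- function(sequence, model = degron_model(),
                        min_score = model$min_score) {
  chars <- strsplit(sequence, "")[[1]]
  rows <- list()
  for (start in seq_along(chars)) {
    for (spacer in model$spacer_range[1]:model$spacer_range[2]) {
      end <- start + 3 + spacer
      if (end > length(chars)) next
      p1 <- chars[start]; p2 <- chars[start + 1]; p3 <- chars[start + 2]
      plast <- chars[end]
      sp <- chars[(start + 3):(end - 1)]
      score_for <- function(p2v, mid, transposed) {
        if (!p1 %in% names(model$p1_weights)) return(NULL)
        if (!p2v %in% names(model$p2_weights)) return(NULL)
        if (!plast %in% names(model$p_last_weights)) return(NULL)
        w3 <- if (mid == "G") model$glycine_weight
              else if (transposed) 0 else model$non_glycine_weight
        bonus <- min(model$acidity_bonus * sum(sp %in% c("D","E","S","T")),
                     model$acidity_cap)
        s <- (model$p1_weights[[p1]] + model$p2_weights[[p2v]] +
                model$p_last_weights[[plast]] + bonus) * w3
        if (s <= 0 || s < min_score) return(NULL)
        variant <- if (mid == "G" && !transposed) {
          if (p1 == "D" && p2v %in% c("S", "T")) "canonical_DSG"
          else "acidic_variant"
        } else "relaxed"
        data.frame(start = start, end = end, spacer_len = spacer,
                   score = s, variant_class = variant,
                   matched_string = paste(chars[start:end], collapse = ""))
      }
      cand <- list(score_for(p2, p3, transposed = FALSE))
      if (model$relaxed) {
        cand <- c(cand, list(score_for(p3, p2, transposed = TRUE)))
      }
      cand <- cand[!vapply(cand, is.null, logical(1))]
      if (length(cand) > 0) {
        best <- cand[[which.max(vapply(cand, function(x) x$score,
                                       numeric(1)))]]
        rows[[length(rows) + 1]] <- best
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      spacer_len = integer(), score = numeric(),
                      variant_class = character(),
                      matched_string = character()))
  }
  res <- do.call(rbind, rows)
  res[order(-res$score, res$start), ]
}

random_aa <- function(n, len, seed,
                      alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

random_small_table <- function(seed) {
  set.seed(seed)
  n_prot <- sample(2:6, 1)
  n_bait <- sample(2:3, 1)
  n_ctrl <- sample(1:2, 1)
  m <- matrix(rpois(n_prot * (n_bait + n_ctrl), 1.2),
              nrow = n_prot)
  proteins <- paste0("p", seq_len(n_prot))
  runs <- tibble::tibble(
    run_id = c(paste0("b", seq_len(n_bait)), paste0("c", seq_len(n_ctrl))),
    bait = c(rep("trap", n_bait), rep("control", n_ctrl))
  )
  counts <- tibble::tibble(
    protein = rep(proteins, times = ncol(m)),
    run_id = rep(runs$run_id, each = n_prot),
    count = as.integer(m)
  )
  list(table = spectral_counts(counts, runs), matrix = m,
       bait_cols = seq_len(n_bait), control_cols = n_bait + seq_len(n_ctrl))
}

table1_motif_strings <- function() {
  fx <- load_table1_fixture()
  motifs <- fx$annotations$degron[!is.na(fx$annotations$degron)]
  unlist(strsplit(motifs, "/"))
}
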