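#' Configuration for the IP-MS count simulator
#'
#' Emulates the design of a ligase-trap screen: a few bait purifications
#' of one trap plus negative-control purifications, with three protein
#' classes — true substrates (bait-enriched, absent from controls), sticky
#' background proteins (present everywhere), and proteins absent from all
#' runs. Substrate counts suffer per-run dropout, mimicking low-abundance
#' substrates that miss detection in one replicate.
#'
#' Defaults describe the simulated study used throughout the package's
#' tests: 500 proteins, 5 percent substrates, mean substrate TSC 8, mean
#' background TSC 3, 20 percent sticky proteins, 10 percent per-run
#' dropout, three bait and two control runs.
#'
#' @param n_proteins Number of simulated proteins.
#' @param substrate_fraction Fraction of proteins that are true substrates.
#' @param n_bait_runs,n_control_runs Numbers of bait and control runs.
#' @param lambda_substrate Poisson mean TSC of substrates in bait runs.
#' @param lambda_background Poisson mean TSC of sticky proteins in all
#'   runs.
#' @param sticky_fraction Fraction of proteins that are sticky background.
#' @param dropout Per-run probability that a substrate yields zero counts.
#' @param length_range Range (residues) for uniform protein lengths, used
#'   for NSAF.
#' @param seed Integer seed; simulations are bit-reproducible.
#' @return A list of class `ipms_sim_config`.
#' @export
ipms_sim_config <- function(n_proteins = 500, substrate_fraction = 0.05,
                            n_bait_runs = 3, n_control_runs = 2,
                            lambda_substrate = 8, lambda_background = 3,
                            sticky_fraction = 0.2, dropout = 0.1,
                            length_range = c(100, 2000), seed = 1) {
  stopifnot(
    n_proteins >= 1,
    substrate_fraction > 0, substrate_fraction < 1,
    sticky_fraction > 0, sticky_fraction < 1,
    substrate_fraction + sticky_fraction <= 1,
    n_bait_runs >= 1, n_control_runs >= 0,
    lambda_substrate > 0, lambda_background >= 0,
    dropout >= 0, dropout < 1,
    length(length_range) == 2, length_range[1] >= 1,
    length_range[2] >= length_range[1]
  )
  structure(
    list(n_proteins = as.integer(n_proteins),
         substrate_fraction = substrate_fraction,
         n_bait_runs = as.integer(n_bait_runs),
         n_control_runs = as.integer(n_control_runs),
         lambda_substrate = lambda_substrate,
         lambda_background = lambda_background,
         sticky_fraction = sticky_fraction,
         dropout = dropout,
         length_range = as.integer(length_range),
         seed = as.integer(seed)),
    class = "ipms_sim_config"
  )
}

#' Simulate an IP-MS spectral-count table with known truth
#'
#' Substrates draw Poisson(`lambda_substrate`) counts in bait runs, zeroed
#' per run with probability `dropout`, and are exactly zero in control
#' runs (the detection regime the candidate criteria assume). Sticky
#' proteins draw Poisson(`lambda_background`) in every run; the remaining
#' proteins are zero everywhere. Lengths are uniform over `length_range`.
#'
#' @param config An [ipms_sim_config()].
#' @return A list with `table` (a [spectral_counts] with lengths) and
#'   `truth` (tibble `protein`, `class` in
#'   `substrate` / `sticky_background` / `absent`).
#' @examples
#' sim <- simulate_ipms(ipms_sim_config(n_proteins = 50, seed = 7))
#' dplyr::count(sim$truth, class)
#' @export
simulate_ipms <- function(config = ipms_sim_config()) {
  stopifnot(inherits(config, "ipms_sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  n_sub <- max(1L, round(n * config$substrate_fraction))
  n_sticky <- round(n * config$sticky_fraction)
  classes <- rep("absent", n)
  classes[seq_len(n_sub)] <- "substrate"
  classes[n_sub + seq_len(n_sticky)] <- "sticky_background"
  proteins <- sprintf("prot%04d", seq_len(n))
  runs <- tibble(
    run_id = c(paste0("bait_", seq_len(config$n_bait_runs)),
               if (config$n_control_runs > 0)
                 paste0("control_", seq_len(config$n_control_runs))),
    bait = c(rep("trap", config$n_bait_runs),
             rep("control", config$n_control_runs)),
    replicate = c(seq_len(config$n_bait_runs),
                  seq_len(config$n_control_runs)),
    condition = "none"
  )
  is_bait <- runs$bait == "trap"
  counts <- matrix(0L, nrow = n, ncol = nrow(runs))
  for (j in seq_len(nrow(runs))) {
    col <- integer(n)
    sub_idx <- classes == "substrate"
    sticky_idx <- classes == "sticky_background"
    if (is_bait[j]) {
      draws <- rpois(sum(sub_idx), config$lambda_substrate)
      dropped <- runif(sum(sub_idx)) < config$dropout
      draws[dropped] <- 0L
      col[sub_idx] <- draws
    }
    if (config$lambda_background > 0) {
      col[sticky_idx] <- rpois(sum(sticky_idx), config$lambda_background)
    }
    counts[, j] <- col
  }
  long <- tibble(
    protein = rep(proteins, times = nrow(runs)),
    run_id = rep(runs$run_id, each = n),
    count = as.integer(counts)
  )
  lengths <- tibble(
    protein = proteins,
    length = sample(seq(config$length_range[1], config$length_range[2]),
                    n, replace = TRUE)
  )
  list(
    table = spectral_counts(long, runs, lengths = lengths),
    truth = tibble(protein = proteins, class = classes)
  )
}

#' Recall and precision of candidate calling against simulation truth
#'
#' @param calls A [call_candidates()] result on a simulated table.
#' @param truth The `truth` tibble from [simulate_ipms()].
#' @return A one-row tibble with `tp`, `fp`, `fn`, `recall`, `precision`.
#' @export
calling_performance <- function(calls, truth) {
  joined <- dplyr::left_join(calls, truth, by = "protein")
  tp <- sum(joined$is_candidate & joined$class == "substrate")
  fp <- sum(joined$is_candidate & joined$class != "substrate")
  fn <- sum(!joined$is_candidate & joined$class == "substrate")
  tibble(
    tp = tp, fp = fp, fn = fn,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
}

#' Generate random protein sequences with planted degron motifs
#'
#' Background residues are drawn from a composition in which D, E, S and T
#' are down-weighted (`dest_weight`), keeping spurious degron-like windows
#' rare; planted motifs are written verbatim at their stated positions.
#' Setting `dest_weight = 0` removes all phospho-acceptor/acidic residues
#' from the background, so unplanted sequences contain no scoring window
#' at all.
#'
#' @param n Number of sequences.
#' @param length Sequence length (residues).
#' @param planted Optional data frame with columns `seq` (sequence index
#'   in 1..n), `motif`, `position` (1-based start). Windows planted in the
#'   same sequence must not overlap.
#' @param seed Integer seed.
#' @param dest_weight Relative background weight of D/E/S/T versus the
#'   other residues (default 0.3).
#' @return A list with `records` (tibble `protein`, `sequence`) and
#'   `truth` (tibble `protein`, `motif`, `start`, `end`).
#' @export
generate_sequences <- function(n, length, planted = NULL, seed = 1,
                               dest_weight = 0.3) {
  stopifnot(n >= 1, length >= 1, dest_weight >= 0)
  set.seed(seed)
  aa <- strsplit(AA_ALPHABET, "")[[1]]
  w <- ifelse(aa %in% c("D", "E", "S", "T"), dest_weight, 1)
  if (all(w == 0)) {
    abort("Background composition has zero total weight.",
          class = "ligasetrap_config_error")
  }
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(aa, length, replace = TRUE, prob = w), collapse = "")
  }, character(1))
  truth <- tibble(protein = character(), motif = character(),
                  start = integer(), end = integer())
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    stopifnot(all(c("seq", "motif", "position") %in% names(planted)))
    if (any(planted$position < 1 |
            planted$position + nchar(planted$motif) - 1 > length)) {
      abort("Planted motif does not fit within the sequence length.",
            class = "ligasetrap_config_error")
    }
    for (s in unique(planted$seq)) {
      p <- planted[planted$seq == s, ]
      p <- p[order(p$position), ]
      ends <- p$position + nchar(p$motif) - 1
      if (nrow(p) > 1 && any(p$position[-1] <= ends[-nrow(p)])) {
        abort("Planted windows overlap within one sequence.",
              class = "ligasetrap_config_error")
      }
      for (i in seq_len(nrow(p))) {
        substr(seqs[s], p$position[i], ends[i]) <- p$motif[i]
      }
    }
    truth <- tibble(
      protein = sprintf("synth%03d", planted$seq),
      motif = planted$motif,
      start = as.integer(planted$position),
      end = as.integer(planted$position + nchar(planted$motif) - 1)
    )
  }
  list(
    records = tibble(protein = sprintf("synth%03d", seq_len(n)),
                     sequence = seqs),
    truth = truth
  )
}

#' Simulate an exponential-decay chase timecourse
#'
#' Intensity is exp(-k t) with multiplicative lognormal noise
#' (`exp(rnorm(0, noise_sigma))` per point); the loading control is
#' identically 1.
#'
#' @param k Decay rate per hour (>= 0; 0 simulates a stable protein).
#' @param times Sampling times in hours (must include 0).
#' @param noise_sigma Lognormal sigma of the multiplicative noise.
#' @param seed Integer seed.
#' @return A tibble with `time`, `intensity`, `loading`.
#' @examples
#' simulate_decay(k = log(2), times = c(0, 1, 2), noise_sigma = 0)
#' @export
simulate_decay <- function(k, times = c(0, 0.5, 1, 2), noise_sigma = 0.05,
                           seed = 1) {
  stopifnot(k >= 0, noise_sigma >= 0, 0 %in% times)
  set.seed(seed)
  noise <- if (noise_sigma > 0) exp(rnorm(length(times), 0, noise_sigma))
           else rep(1, length(times))
  tibble(
    time = times,
    intensity = exp(-k * times) * noise,
    loading = 1
  )
}
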