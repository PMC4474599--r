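#' Configuration for candidate-substrate calling
#'
#' The calling rule is presence/absence over replicated purifications: a
#' protein is a candidate substrate when it is identified (TSC at or above
#' `presence_threshold`) in at least `min_bait_runs` bait purifications and
#' in none of the negative-control purifications, and is not removed by a
#' family exclusion group. Exclusion groups encode the treatment of
#' multi-allele families (e.g. HLA class I): when any member of a group is
#' control-detected, every member of the group is excluded, because
#' shared peptides make the family collectively background.
#'
#' @param min_bait_runs Minimum number of bait runs a protein must be
#'   detected in (default 2, the two-of-three rule).
#' @param presence_threshold TSC at which a protein counts as "identified"
#'   in a bait run (default 1; the two-unique-peptide / <5 percent FDR
#'   identification filter is assumed applied upstream of the count table,
#'   and this knob is exposed for stricter reanalysis).
#' @param control_presence_threshold TSC at which a protein counts as
#'   detected in a control run (default 1).
#' @param exclusion_groups A list of character vectors of protein ids with
#'   shared-family exclusion semantics.
#' @param pseudocount Value replacing a zero mean background in the
#'   enrichment score (default 0.5); set to 0 to flag unique-to-bait
#'   proteins as infinite instead.
#' @return A list of class `calling_config`.
#' @export
calling_config <- function(min_bait_runs = 2, presence_threshold = 1,
                           control_presence_threshold = 1,
                           exclusion_groups = list(), pseudocount = 0.5) {
  if (min_bait_runs < 1 || presence_threshold < 1 ||
      control_presence_threshold < 1) {
    abort("Calling thresholds must be >= 1.",
          class = "ligasetrap_config_error")
  }
  if (pseudocount < 0) {
    abort("`pseudocount` must be non-negative.",
          class = "ligasetrap_config_error")
  }
  structure(
    list(min_bait_runs = as.integer(min_bait_runs),
         presence_threshold = as.integer(presence_threshold),
         control_presence_threshold = as.integer(control_presence_threshold),
         exclusion_groups = exclusion_groups,
         pseudocount = pseudocount),
    class = "calling_config"
  )
}

#' Call candidate substrates from a spectral-count table
#'
#' Applies the replicated presence/absence rule of [calling_config()] to
#' one bait against the table's negative-control runs and scores each
#' protein's bait enrichment (mean bait TSC over mean control TSC). When
#' protein lengths are attached, per-bait-run NSAF values are included as a
#' list-column.
#'
#' @param table A [spectral_counts] object containing runs for `bait` and
#'   (normally) control runs.
#' @param bait Bait name to call against (must appear in the run metadata).
#' @param config A [calling_config()].
#' @param controls Bait label(s) identifying negative-control runs
#'   (default `"control"`).
#' @param condition Optional condition label; when given, only runs with
#'   that condition are used (default: all runs pooled).
#' @return A tibble of class `substrate_calls`, one row per protein, with
#'   columns `protein`, `n_bait_detected`, `n_control_detected`,
#'   `total_bait_tsc`, `is_candidate`, `excluded_reason`,
#'   `enrichment_score` (and `nsaf` when lengths are available).
#' @examples
#' fx <- load_table1_fixture()
#' calls <- call_candidates(table1_calling_table(fx), bait = "bTRCP")
#' sum(calls$is_candidate)
#' @export
call_candidates <- function(table, bait, config = calling_config(),
                            controls = "control", condition = NULL) {
  stopifnot(inherits(table, "spectral_counts"))
  runs <- table$runs
  if (!is.null(condition)) {
    runs <- dplyr::filter(runs, .data$condition %in% !!condition)
  }
  bait_runs <- runs$run_id[runs$bait %in% bait]
  control_runs <- runs$run_id[runs$bait %in% controls]
  if (length(bait_runs) == 0) {
    abort(paste0("Bait '", bait, "' has no runs in the metadata."),
          class = "ligasetrap_config_error")
  }
  if (length(control_runs) == 0) {
    warn(paste0("No control runs found (controls = '",
                paste(controls, collapse = ", "),
                "'); control absence is vacuously true."))
  }
  if (config$min_bait_runs > length(bait_runs)) {
    abort("`min_bait_runs` exceeds the number of bait runs.",
          class = "ligasetrap_config_error")
  }

  long <- table$counts
  per_protein <- long |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      n_bait_detected = sum(.data$run_id %in% bait_runs &
                              .data$count >= config$presence_threshold),
      n_control_detected = sum(.data$run_id %in% control_runs &
                                 .data$count >= config$control_presence_threshold),
      total_bait_tsc = sum(.data$count[.data$run_id %in% bait_runs]),
      mean_bait = mean(.data$count[.data$run_id %in% bait_runs]),
      mean_control = if (length(control_runs) == 0) 0
                     else mean(.data$count[.data$run_id %in% control_runs]),
      .groups = "drop"
    )
  per_protein <- per_protein[match(unique(long$protein), per_protein$protein), ]

  excluded_reason <- rep(NA_character_, nrow(per_protein))
  for (grp in config$exclusion_groups) {
    members <- intersect(grp, per_protein$protein)
    hit <- per_protein$protein[per_protein$protein %in% members &
                                 per_protein$n_control_detected > 0]
    if (length(hit) > 0) {
      idx <- per_protein$protein %in% members
      excluded_reason[idx] <- paste0(
        "family member(s) ", paste(hit, collapse = "/"),
        " detected in control runs")
    }
  }

  calls <- per_protein |>
    dplyr::mutate(
      excluded_reason = excluded_reason,
      is_candidate = .data$n_bait_detected >= config$min_bait_runs &
        .data$n_control_detected == 0 & is.na(excluded_reason),
      enrichment_score = score_enrichment(.data$mean_bait,
                                          .data$mean_control,
                                          config$pseudocount)
    ) |>
    dplyr::select("protein", "n_bait_detected", "n_control_detected",
                  "total_bait_tsc", "is_candidate", "excluded_reason",
                  "enrichment_score")

  if (!is.null(table$lengths)) {
    nsaf_by_run <- lapply(bait_runs, function(r) {
      suppressWarnings(nsaf(table, r))
    })
    names(nsaf_by_run) <- bait_runs
    calls$nsaf <- lapply(calls$protein, function(p) {
      vapply(nsaf_by_run, function(tab) {
        v <- tab$nsaf[tab$protein == p]
        if (length(v) == 0) 0 else v
      }, numeric(1))
    })
  }

  attr(calls, "bait") <- bait
  attr(calls, "config") <- config
  class(calls) <- c("substrate_calls", class(calls))
  calls
}

# vectorized core of enrichment_score()
score_enrichment <- function(mean_bait, mean_control, pseudocount) {
  denom <- pmax(mean_control, pseudocount)
  score <- ifelse(mean_bait == 0, 0,
                  ifelse(denom == 0, Inf, mean_bait / denom))
  score
}

#' Bait-enrichment score for one protein
#'
#' Mean spectral counts across bait purifications divided by mean counts
#' across background (negative-control) purifications. A zero background
#' mean is replaced by `pseudocount`; with `pseudocount = 0` a protein
#' unique to the bait is flagged infinite rather than raising an error.
#'
#' @param bait_counts Non-empty vector of non-negative integer counts.
#' @param control_counts Vector of non-negative integer counts (may be
#'   empty, meaning no background observations).
#' @param pseudocount Non-negative replacement for a zero background mean.
#' @return A single non-negative number (possibly `Inf`).
#' @examples
#' enrichment_score(c(12, 11, 13), c(2, 2))    # 6
#' enrichment_score(10, c(0, 0), pseudocount = 0.5)  # 20
#' @export
enrichment_score <- function(bait_counts, control_counts,
                             pseudocount = 0.5) {
  if (length(bait_counts) == 0) {
    abort("`bait_counts` must be non-empty.",
          class = "ligasetrap_validation_error")
  }
  if (any(bait_counts < 0) || any(control_counts < 0)) {
    abort("Counts must be non-negative.",
          class = "ligasetrap_validation_error")
  }
  mc <- if (length(control_counts) == 0) 0 else mean(control_counts)
  score_enrichment(mean(bait_counts), mc, pseudocount)
}

#' Normalized spectral abundance factor (NSAF) for one run
#'
#' For each protein i with spectral count SpC and length L (residues),
#' NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j), multiplied by 1e5 for
#' readability. Values sum to 1e5 over the proteins with nonzero counts in
#' the run.
#'
#' @param table A [spectral_counts] object with lengths attached for every
#'   protein counted in the run.
#' @param run_id Run identifier.
#' @return A tibble with columns `protein` and `nsaf` (x 1e5 scale;
#'   zero-count proteins get 0). Empty, with a warning, for an all-zero
#'   run.
#' @export
nsaf <- function(table, run_id) {
  stopifnot(inherits(table, "spectral_counts"))
  if (!run_id %in% table$runs$run_id) {
    abort(paste0("Unknown run '", run_id, "'."),
          class = "ligasetrap_config_error")
  }
  keep <- table$counts$run_id == run_id
  prot <- table$counts$protein[keep]
  cnt <- table$counts$count[keep]
  if (all(cnt == 0)) {
    warn(paste0("Run '", run_id, "' has no spectral counts; empty NSAF."))
    return(tibble(protein = character(), nsaf = numeric()))
  }
  if (is.null(table$lengths)) {
    abort("NSAF requires protein lengths.",
          class = "ligasetrap_validation_error")
  }
  len <- table$lengths$length[match(prot, table$lengths$protein)]
  missing_len <- prot[cnt > 0 & is.na(len)]
  if (length(missing_len) > 0) {
    abort(paste0("Missing length for counted protein(s): ",
                 paste(missing_len, collapse = ", ")),
          class = "ligasetrap_validation_error")
  }
  saf <- ifelse(cnt > 0, cnt / len, 0)
  tibble(protein = prot, nsaf = 1e5 * saf / sum(saf))
}

#' Order calls by abundance
#'
#' Stable sort by descending total bait TSC, ties broken by descending
#' enrichment score and then lexicographic protein id — the ordering used
#' to present discovery tables.
#'
#' @param calls A [call_candidates()] result.
#' @return The same tibble, reordered.
#' @export
rank_candidates <- function(calls) {
  ord <- order(-calls$total_bait_tsc, -calls$enrichment_score,
               calls$protein, method = "radix")
  calls[ord, ]
}

#' @rdname call_candidates
#' @param object,x A `substrate_calls` tibble.
#' @param ... Unused.
#' @method autoplot substrate_calls
#' @export
autoplot.substrate_calls <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$total_bait_tsc,
                 y = pmin(.data$enrichment_score, max(
                   object$enrichment_score[is.finite(object$enrichment_score)],
                   1)),
                 colour = .data$is_candidate)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::labs(x = "total bait TSC", y = "enrichment score (capped)",
                  colour = "candidate",
                  title = paste0("Candidate calling: bait ",
                                 attr(object, "bait") %||% "")) +
    ggplot2::theme_minimal()
}
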