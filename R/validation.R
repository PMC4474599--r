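#' Tally discovery and validation outcomes
#'
#' Summarizes an annotated candidate list into the headline statistics of
#' a trapping screen: how many candidates were previously known
#' substrates, how many novel candidates confirmed (polyubiquitinated
#' forms purified by the trap), how many were false positives, and how
#' many went untested. The confirmation rate is computed over known plus
#' *tested* candidates — untested candidates are removed from the
#' denominator — and the known fraction over all candidates. Percentages
#' are rounded half away from zero for display; unrounded values are
#' retained in `*_exact` columns.
#'
#' @param annotations A [load_table1_fixture()] result or a data frame
#'   with columns `status` (`known` / `novel`; `below_bar` rows are
#'   dropped) and `ubiquitinated_forms` (`yes` / `no` / `untested`, `NA`
#'   treated as untested).
#' @return A one-row tibble of class `validation_summary`: `n_candidates`,
#'   `n_known`, `n_novel`, `n_novel_confirmed`, `n_false_positive`,
#'   `n_untested`, `confirmation_rate_pct`, `known_fraction_pct` and their
#'   `*_exact` counterparts. Rates are `NA` for empty input.
#' @examples
#' tally_validation(load_table1_fixture())
#' @export
tally_validation <- function(annotations) {
  if (inherits(annotations, "table1_fixture")) {
    annotations <- annotations$annotations
  }
  ann <- as_tibble(annotations)
  if (!all(c("status", "ubiquitinated_forms") %in% names(ann))) {
    abort("Annotations need columns `status` and `ubiquitinated_forms`.",
          class = "ligasetrap_validation_error")
  }
  ann <- dplyr::filter(ann, .data$status != "below_bar")
  bad_status <- setdiff(unique(ann$status), c("known", "novel"))
  if (length(bad_status) > 0) {
    abort(paste0("Unknown candidate status: ",
                 paste(bad_status, collapse = ", ")),
          class = "ligasetrap_validation_error")
  }
  flags <- ifelse(is.na(ann$ubiquitinated_forms), "untested",
                  ann$ubiquitinated_forms)
  bad_flag <- setdiff(unique(flags), c("yes", "no", "untested"))
  if (length(bad_flag) > 0) {
    abort(paste0("Invalid ubiquitinated_forms flag: ",
                 paste(bad_flag, collapse = ", ")),
          class = "ligasetrap_validation_error")
  }
  novel <- ann$status == "novel"
  n_candidates <- nrow(ann)
  n_known <- sum(ann$status == "known")
  n_novel <- sum(novel)
  n_novel_confirmed <- sum(novel & flags == "yes")
  n_false_positive <- sum(novel & flags == "no")
  n_untested <- sum(novel & flags == "untested")
  n_tested <- n_candidates - n_untested
  conf_exact <- if (n_tested > 0) {
    100 * (n_known + n_novel_confirmed) / n_tested
  } else NA_real_
  known_exact <- if (n_candidates > 0) {
    100 * n_known / n_candidates
  } else NA_real_
  out <- tibble(
    n_candidates = n_candidates, n_known = n_known, n_novel = n_novel,
    n_novel_confirmed = n_novel_confirmed,
    n_false_positive = n_false_positive, n_untested = n_untested,
    confirmation_rate_pct = round_half_away(conf_exact),
    known_fraction_pct = round_half_away(known_exact),
    confirmation_rate_exact = conf_exact,
    known_fraction_exact = known_exact
  )
  class(out) <- c("validation_summary", class(out))
  out
}

# round() rounds half to even; report percentages round half away from zero
round_half_away <- function(x) {
  ifelse(is.na(x), NA_real_, sign(x) * floor(abs(x) + 0.5))
}

#' Compare mean spectral counts between two conditions
#'
#' Per-protein arithmetic mean TSC within each condition label, with the
#' difference and the pseudocounted ratio — the comparison used to ask how
#' a drug condition (e.g. proteasome inhibition) shifts recovery of each
#' protein.
#'
#' @param table A [spectral_counts] object.
#' @param cond_a,cond_b Condition labels present in the run metadata.
#' @param pseudocount Replacement for a zero `cond_b` mean in the ratio,
#'   as in [enrichment_score()].
#' @return A tibble with columns `protein`, `mean_a`, `mean_b`,
#'   `difference` and `ratio`.
#' @export
compare_conditions <- function(table, cond_a, cond_b, pseudocount = 0.5) {
  stopifnot(inherits(table, "spectral_counts"))
  runs_a <- table$runs$run_id[table$runs$condition == cond_a]
  runs_b <- table$runs$run_id[table$runs$condition == cond_b]
  if (length(runs_a) == 0 || length(runs_b) == 0) {
    abort("Both condition labels must have at least one run.",
          class = "ligasetrap_config_error")
  }
  table$counts |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      mean_a = mean(.data$count[.data$run_id %in% runs_a]),
      mean_b = mean(.data$count[.data$run_id %in% runs_b]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      difference = .data$mean_a - .data$mean_b,
      ratio = score_enrichment(.data$mean_a, .data$mean_b, pseudocount)
    )
}

#' Percent of input represented by an IP band at a given loading ratio
#'
#' A two-step trap purification is loaded at a large excess over input
#' (e.g. 5,000:1 for the second step). An IP band of intensity equal to
#' the input band then represents only `100 / loading_ratio` percent of
#' the input material — 0.02 percent at 5,000:1 — which is why unmodified
#' bait carried through the purification constitutes negligible
#' background.
#'
#' @param loading_ratio Positive loading ratio (IP over input).
#' @return Percentage of input (numeric, same length as `loading_ratio`).
#' @examples
#' ip_background_fraction(5000)  # 0.02
#' ip_background_fraction(250)   # 0.4
#' @export
ip_background_fraction <- function(loading_ratio) {
  if (any(!is.finite(loading_ratio)) || any(loading_ratio <= 0)) {
    abort("`loading_ratio` must be positive and finite.",
          class = "ligasetrap_validation_error")
  }
  100 / loading_ratio
}
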