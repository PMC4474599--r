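#' Configuration for the end-to-end pipeline
#'
#' Collects file paths and per-stage parameters for [run_pipeline()]:
#' candidate calling from a counts table, degron scanning of a FASTA of
#' candidate sequences, chase-decay fitting from a densitometry table, and
#' the validation report.
#'
#' @param counts Path to the delimited counts file (see
#'   [read_counts_table()]).
#' @param metadata Path to (or data frame of) run metadata.
#' @param bait Bait name to call.
#' @param fasta Optional FASTA of candidate protein sequences.
#' @param annotations Optional delimited file (or data frame) of validation
#'   annotations (`protein`, `status`, `ubiquitinated_forms`).
#' @param densitometry Optional delimited file (or data frame) of chase
#'   timecourses (`protein`, `condition`, `time`, `intensity`, optional
#'   `loading`).
#' @param reference_condition Reference condition label for stabilization
#'   classification of the decay stage.
#' @param calling A [calling_config()].
#' @param degron A [degron_model()].
#' @param decay_window Fitting window in hours.
#' @param out_dir Output directory for per-stage TSVs and the log; created
#'   if missing. `NULL` disables writing.
#' @param delim Field delimiter of the input tables.
#' @param verbose Print INFO-level stage summaries.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, bait,
                            fasta = NULL, annotations = NULL,
                            densitometry = NULL,
                            reference_condition = "reference",
                            calling = calling_config(),
                            degron = degron_model(),
                            decay_window = c(0, 2),
                            out_dir = NULL, delim = "\t",
                            verbose = TRUE) {
  structure(
    list(counts = counts, metadata = metadata, bait = bait,
         fasta = fasta, annotations = annotations,
         densitometry = densitometry,
         reference_condition = reference_condition,
         calling = calling, degron = degron,
         decay_window = decay_window, out_dir = out_dir,
         delim = delim, verbose = verbose),
    class = "pipeline_config"
  )
}

stage <- function(name, verbose, expr) {
  tryCatch(
    force(expr),
    error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)),
            class = "ligasetrap_stage_error", parent = e)
    }
  )
}

pipeline_log <- function(lines, config) {
  if (isTRUE(config$verbose)) message(paste(lines, collapse = "\n"))
  invisible(lines)
}

#' Run the calling / degron / decay / report pipeline
#'
#' Executes the stages configured in [pipeline_config()] in order and
#' (when `out_dir` is set) writes one TSV per stage plus a combined
#' candidate table mirroring a discovery-table layout (protein, detection
#' tallies, enrichment, candidate flag, best degron), and a log recording
#' the parameters used. Stage outputs are deterministic for identical
#' inputs; timestamps appear only in the log.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `calls`,
#'   `degrons` (or `NULL`), `decay_fits` (or `NULL`), `summary` (or
#'   `NULL`) and `candidate_table`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(
    paste0("# pipeline run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("bait: ", config$bait),
    paste0("min_bait_runs: ", config$calling$min_bait_runs),
    paste0("presence_threshold: ", config$calling$presence_threshold),
    paste0("pseudocount: ", config$calling$pseudocount),
    paste0("decay_window: ", paste(config$decay_window, collapse = "-"))
  )

  table <- stage("read", config$verbose, {
    if (inherits(config$counts, "spectral_counts")) config$counts
    else read_counts_table(config$counts, config$metadata,
                           delim = config$delim)
  })
  log_lines <- c(log_lines, sprintf(
    "read: %d proteins x %d runs",
    length(unique(table$counts$protein)), nrow(table$runs)))

  calls <- stage("call", config$verbose,
                 call_candidates(table, config$bait, config$calling))
  calls <- rank_candidates(calls)
  log_lines <- c(log_lines, sprintf(
    "call: %d candidates of %d proteins", sum(calls$is_candidate),
    nrow(calls)))

  degrons <- NULL
  if (!is.null(config$fasta)) {
    degrons <- stage("degron", config$verbose, {
      recs <- if (is.character(config$fasta)) read_fasta(config$fasta)
              else as_tibble(config$fasta)
      best_degron(recs, config$degron)
    })
    log_lines <- c(log_lines, sprintf(
      "degron: best windows for %d sequences (%d with a hit)",
      nrow(degrons), sum(!is.na(degrons$score))))
  }

  decay_fits <- NULL
  if (!is.null(config$densitometry)) {
    decay_fits <- stage("decay", config$verbose, {
      dens <- if (is.character(config$densitometry)) {
        read_delim_quiet(config$densitometry, config$delim)
      } else as_tibble(config$densitometry)
      fit_decay_table(dens, window = config$decay_window,
                      reference_condition = config$reference_condition)
    })
    log_lines <- c(log_lines, sprintf(
      "decay: %d (protein, condition) fits", nrow(decay_fits)))
  }

  summary_tbl <- NULL
  if (!is.null(config$annotations)) {
    summary_tbl <- stage("report", config$verbose, {
      ann <- if (is.character(config$annotations)) {
        read_delim_quiet(config$annotations, config$delim)
      } else as_tibble(config$annotations)
      called <- calls$protein[calls$is_candidate]
      tally_validation(ann[ann$protein %in% called, ])
    })
    log_lines <- c(log_lines, sprintf(
      "report: confirmation rate %s%%",
      format(summary_tbl$confirmation_rate_pct)))
  }

  candidate_table <- calls
  if (!is.null(degrons)) {
    candidate_table <- dplyr::left_join(
      candidate_table,
      dplyr::select(degrons, "protein", best_degron = "matched_string",
                    degron_score = "score"),
      by = "protein")
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) {
      readr::write_tsv(x, file.path(config$out_dir, f))
    }
    wr(strip_list_cols(calls), "calls.tsv")
    if (!is.null(degrons)) wr(degrons, "degrons.tsv")
    if (!is.null(decay_fits)) wr(decay_fits, "decay_fits.tsv")
    if (!is.null(summary_tbl)) wr(as_tibble(summary_tbl), "summary.tsv")
    wr(strip_list_cols(candidate_table), "candidate_table.tsv")
    writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  }
  pipeline_log(log_lines[-1], config)

  structure(
    list(calls = calls, degrons = degrons, decay_fits = decay_fits,
         summary = summary_tbl, candidate_table = candidate_table),
    class = "pipeline_result"
  )
}

strip_list_cols <- function(x) {
  x[!vapply(x, is.list, logical(1))]
}

# fit every (protein, condition) chase and classify against the reference
fit_decay_table <- function(dens, window, reference_condition) {
  stopifnot(all(c("protein", "condition", "time", "intensity") %in%
                  names(dens)))
  groups <- dplyr::distinct(dens, .data$protein, .data$condition)
  fits <- purrr::pmap(groups, function(protein, condition) {
    tc <- dens[dens$protein == protein & dens$condition == condition, ]
    fit <- fit_halflife(tc[, intersect(names(tc),
                                       c("time", "intensity", "loading"))],
                        window = window)
    dplyr::bind_cols(tibble(protein = protein, condition = condition),
                     glance(fit))
  })
  out <- dplyr::bind_rows(fits)
  refs <- out[out$condition == reference_condition, ]
  if (nrow(refs) > 0) {
    out$stabilization_ratio <- NA_real_
    out$stabilization_class <- NA_character_
    for (i in seq_len(nrow(out))) {
      ref <- refs[refs$protein == out$protein[i], ]
      if (nrow(ref) == 0 || out$condition[i] == reference_condition) next
      cls <- classify_ratio(out$half_life[i], out$stable[i],
                            ref$half_life[1], ref$stable[1])
      out$stabilization_ratio[i] <- cls$ratio
      out$stabilization_class[i] <- cls$class
    }
  }
  out
}

classify_ratio <- function(hl_t, stable_t, hl_r, stable_r,
                           full_threshold = 2.0, partial_threshold = 1.3) {
  if (stable_t && stable_r) return(list(ratio = NA_real_, class = "stable"))
  if (stable_t) return(list(ratio = Inf, class = "stable"))
  ratio <- hl_t / hl_r
  cls <- if (ratio >= full_threshold) "yes"
         else if (ratio >= partial_threshold) "partial"
         else "no"
  list(ratio = ratio, class = cls)
}

#' Reproduce the packaged discovery-table summary
#'
#' One-command reproduction of the screen summary from the packaged
#' fixture: candidate calling on the fixture counts with synthetic
#' negative controls (zeros for candidate rows, detections for below-bar
#' rows), the validation tally over the called candidates, and a degron
#' scan of either the printed motif strings or a user-supplied FASTA of
#' candidate sequences.
#'
#' @param min_bait_runs Minimum bait detections (default 2; raising it
#'   drops the two-of-three candidates).
#' @param fasta Optional FASTA path (or `protein`/`sequence` data frame)
#'   of candidate sequences to scan instead of the printed motif strings.
#' @param model A [degron_model()] for the scan.
#' @param exclusion_groups Exclusion groups passed to the calling stage.
#' @return A list of class `table1_reproduction` with `calls`, `summary`,
#'   and `degrons` (per printed motif string: `protein`, `motif`,
#'   `matched`, `score`, `variant_class`; or [best_degron()] output for a
#'   FASTA).
#' @examples
#' rep <- reproduce_table1()
#' rep$summary$n_candidates
#' @export
reproduce_table1 <- function(min_bait_runs = 2, fasta = NULL,
                             model = degron_model(),
                             exclusion_groups = list()) {
  fixture <- load_table1_fixture()
  table <- table1_calling_table(fixture)
  cfg <- calling_config(min_bait_runs = min_bait_runs,
                        exclusion_groups = exclusion_groups)
  calls <- rank_candidates(call_candidates(table, "bTRCP", cfg))
  called <- calls$protein[calls$is_candidate]
  summary_tbl <- tally_validation(
    fixture$annotations[fixture$annotations$protein %in% called, ])

  if (is.null(fasta)) {
    motifs <- fixture$annotations |>
      dplyr::filter(!is.na(.data$degron)) |>
      dplyr::mutate(motif = strsplit(.data$degron, "/")) |>
      tidyr::unnest("motif") |>
      dplyr::select("protein", "motif")
    hits <- best_degron(tibble(protein = motifs$motif,
                               sequence = motifs$motif), model)
    degrons <- tibble(
      protein = motifs$protein, motif = motifs$motif,
      matched = !is.na(hits$score),
      score = hits$score, variant_class = hits$variant_class
    )
  } else {
    recs <- if (is.character(fasta)) read_fasta(fasta)
            else as_tibble(fasta)
    degrons <- best_degron(recs, model)
  }

  structure(
    list(calls = calls, summary = summary_tbl, degrons = degrons),
    class = "table1_reproduction"
  )
}

#' @export
print.table1_reproduction <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<table1_reproduction> %d candidates: %d known, %d novel ",
           "(%d confirmed / %d false positive / %d untested)\n",
           "  confirmation rate %g%%, previously-published fraction %g%%\n"),
    s$n_candidates, s$n_known, s$n_novel, s$n_novel_confirmed,
    s$n_false_positive, s$n_untested,
    s$confirmation_rate_pct, s$known_fraction_pct))
  invisible(x)
}
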