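#' Build a spectral-count table
#'
#' Constructs the central data structure of the pipeline: an integer
#' total-spectral-count (TSC) matrix over proteins and purification runs,
#' together with per-run metadata (bait identity, replicate index,
#' drug-condition label) and optional per-protein sequence lengths used for
#' NSAF normalization.
#'
#' @param counts A data frame of counts, either *long* (columns `protein`,
#'   `run_id`, `count`) or *wide* (first column `protein`, one column per
#'   run id). Counts must be non-negative integers. Missing (protein, run)
#'   cells are treated as 0, matching the presence/absence semantics of
#'   spectral counting.
#' @param runs A data frame of run metadata with columns `run_id`, `bait`
#'   (ligase-trap name or `"control"`), `replicate` (positive integer) and
#'   `condition` (free-text label, e.g. `"MG132"`). `replicate` and
#'   `condition` are filled with defaults when absent.
#' @param lengths Optional data frame with columns `protein` and `length`
#'   (residues, positive integers), one row per protein.
#'
#' @return An object of class `spectral_counts`: a list with tibbles
#'   `counts` (long form, complete over the protein x run grid), `runs`,
#'   and `lengths` (or `NULL`).
#' @examples
#' sc <- spectral_counts(
#'   counts = data.frame(protein = "p1", run_id = "b1", count = 5L),
#'   runs = data.frame(run_id = "b1", bait = "TRAP")
#' )
#' sc
#' @export
spectral_counts <- function(counts, runs, lengths = NULL) {
  runs <- as_tibble(runs)
  if (!all(c("run_id") %in% names(runs)) || nrow(runs) == 0) {
    abort("`runs` must have a `run_id` column and at least one row.",
          class = "ligasetrap_validation_error")
  }
  if (!"bait" %in% names(runs)) {
    abort("`runs` must declare a `bait` for every run.",
          class = "ligasetrap_validation_error")
  }
  if (anyDuplicated(runs$run_id)) {
    abort("`run_id` must be unique within a table.",
          class = "ligasetrap_validation_error")
  }
  if (any(is.na(runs$bait) | runs$bait == "")) {
    abort("`bait` must be non-empty for every run.",
          class = "ligasetrap_validation_error")
  }
  if (!"replicate" %in% names(runs)) {
    runs$replicate <- stats::ave(seq_len(nrow(runs)), runs$bait,
                                 FUN = seq_along)
  }
  if (!"condition" %in% names(runs)) runs$condition <- "none"
  runs$run_id <- as.character(runs$run_id)
  runs$replicate <- as.integer(runs$replicate)
  if (any(runs$replicate < 1L)) {
    abort("`replicate` indices must be positive.",
          class = "ligasetrap_validation_error")
  }
  runs <- dplyr::select(runs, "run_id", "bait", "replicate", "condition")

  counts <- as_tibble(counts)
  if (!all(c("protein", "run_id", "count") %in% names(counts))) {
    counts <- pivot_counts_long(counts)
  }
  counts$protein <- as.character(counts$protein)
  counts$run_id <- as.character(counts$run_id)
  bad_run <- setdiff(counts$run_id, runs$run_id)
  if (length(bad_run) > 0) {
    abort(paste0("Count column(s) not declared in run metadata: ",
                 paste(bad_run, collapse = ", ")),
          class = "ligasetrap_format_error")
  }
  check_counts_integral(counts$count)
  counts$count <- as.integer(round(counts$count))
  if (anyDuplicated(counts[c("protein", "run_id")])) {
    abort("Duplicated (protein, run) count cells.",
          class = "ligasetrap_validation_error")
  }
  proteins <- unique(counts$protein)
  # dense fast path: grid already complete, just order it
  ord <- order(match(counts$run_id, runs$run_id),
               match(counts$protein, proteins), method = "radix")
  counts <- counts[ord, c("protein", "run_id", "count")]
  if (nrow(counts) != length(proteins) * nrow(runs)) {
    counts <- tidyr::complete(
      counts,
      protein = proteins,
      run_id = runs$run_id,
      fill = list(count = 0L)
    )
    counts <- dplyr::arrange(
      counts,
      match(.data$run_id, runs$run_id),
      match(.data$protein, proteins)
    )
  }

  if (!is.null(lengths)) {
    lengths <- as_tibble(lengths)
    if (!all(c("protein", "length") %in% names(lengths))) {
      abort("`lengths` needs columns `protein` and `length`.",
            class = "ligasetrap_validation_error")
    }
    lengths$protein <- as.character(lengths$protein)
    if (anyDuplicated(lengths$protein)) {
      abort("Duplicated protein id in `lengths`.",
            class = "ligasetrap_validation_error")
    }
    if (any(is.na(lengths$length)) || any(lengths$length <= 0)) {
      abort("Protein lengths must be positive.",
            class = "ligasetrap_validation_error")
    }
    lengths$length <- as.integer(lengths$length)
  }

  structure(
    list(counts = counts, runs = runs, lengths = lengths),
    class = "spectral_counts"
  )
}

# wide (first column protein, one column per run) -> long
pivot_counts_long <- function(wide) {
  if (ncol(wide) < 2) {
    abort("Count table needs a protein column plus at least one run column.",
          class = "ligasetrap_format_error")
  }
  names(wide)[1] <- "protein"
  if (anyDuplicated(wide$protein)) {
    dup <- unique(wide$protein[duplicated(wide$protein)])
    abort(paste0("Duplicated protein id(s): ", paste(dup, collapse = ", ")),
          class = "ligasetrap_validation_error")
  }
  tidyr::pivot_longer(wide, -"protein",
                      names_to = "run_id", values_to = "count")
}

check_counts_integral <- function(x, missing_as_zero = FALSE) {
  if (any(is.na(x))) {
    abort("Missing counts in table (set `missing_as_zero = TRUE` to accept).",
          class = "ligasetrap_validation_error")
  }
  if (!is.numeric(x)) {
    abort("Counts must be numeric.", class = "ligasetrap_format_error")
  }
  if (any(x < 0)) {
    abort("Negative spectral counts are invalid.",
          class = "ligasetrap_validation_error")
  }
  if (any(abs(x - round(x)) > 1e-8)) {
    abort("Fractional spectral counts are invalid.",
          class = "ligasetrap_validation_error")
  }
  invisible(x)
}

#' @export
print.spectral_counts <- function(x, ...) {
  n_prot <- length(unique(x$counts$protein))
  cat(sprintf(
    "<spectral_counts> %d proteins x %d runs (%s)\n",
    n_prot, nrow(x$runs),
    paste(sprintf("%s: %d", unique(x$runs$bait),
                  tabulate(factor(x$runs$bait,
                                  levels = unique(x$runs$bait)))),
          collapse = ", ")
  ))
  if (!is.null(x$lengths)) cat("  protein lengths attached\n")
  invisible(x)
}

#' Extract the counts matrix of a spectral-count table
#'
#' @param x A [spectral_counts] object.
#' @return An integer matrix, proteins in rows, runs in columns.
#' @export
count_matrix <- function(x) {
  stopifnot(inherits(x, "spectral_counts"))
  wide <- tidyr::pivot_wider(x$counts, names_from = "run_id",
                             values_from = "count")
  m <- as.matrix(wide[, x$runs$run_id, drop = FALSE])
  rownames(m) <- wide$protein
  m
}

#' Read a spectral-count table from delimited text
#'
#' The counts file must have a header row, protein identifiers in the first
#' column and one column per purification run. Run metadata is supplied
#' either as a second delimited file (columns `run_id`, `bait`, and
#' optionally `replicate`, `condition`) or inline as a data frame.
#'
#' @param path Path to the delimited counts file.
#' @param metadata Path to a run-metadata file, or a data frame of run
#'   metadata.
#' @param delim Field delimiter; tab by default, `","` for CSV.
#' @param lengths Optional path to (or data frame of) per-protein lengths
#'   (`protein`, `length`).
#' @param missing_as_zero Treat empty cells as 0 (with a warning) instead of
#'   failing. Defaults to `TRUE`: the matrices this pipeline consumes are
#'   dense and absence means "not identified".
#' @return A [spectral_counts] object.
#' @export
read_counts_table <- function(path, metadata, delim = "\t",
                              lengths = NULL, missing_as_zero = TRUE) {
  wide <- read_delim_quiet(path, delim)
  if (nrow(wide) == 0 || ncol(wide) < 2) {
    abort(paste0("Empty or malformed counts file: ", path),
          class = "ligasetrap_format_error")
  }
  if (is.character(metadata) && length(metadata) == 1) {
    metadata <- read_delim_quiet(metadata, delim)
  }
  metadata <- as_tibble(metadata)
  run_cols <- names(wide)[-1]
  undeclared <- setdiff(run_cols, metadata$run_id)
  if (length(undeclared) > 0) {
    abort(paste0("Counts column(s) missing from run metadata: ",
                 paste(undeclared, collapse = ", ")),
          class = "ligasetrap_format_error")
  }
  vals <- unlist(wide[-1], use.names = FALSE)
  if (any(is.na(vals))) {
    if (missing_as_zero) {
      warn("Missing count cells set to 0 (absence = not identified).")
      wide[-1] <- lapply(wide[-1], function(v) ifelse(is.na(v), 0, v))
    } else {
      abort("Missing count cells in input table.",
            class = "ligasetrap_validation_error")
    }
  }
  if (is.character(lengths) && length(lengths) == 1) {
    lengths <- read_delim_quiet(lengths, delim)
  }
  spectral_counts(wide, metadata, lengths = lengths)
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Write a spectral-count table to delimited text
#'
#' Inverse of [read_counts_table()]; `write` then `read` is the identity on
#' any valid table.
#'
#' @param x A [spectral_counts] object.
#' @param path Output path for the wide counts file.
#' @param metadata_path Optional output path for the run-metadata file.
#' @param lengths_path Optional output path for the protein-lengths file.
#' @param delim Field delimiter.
#' @return `x`, invisibly.
#' @export
write_counts_table <- function(x, path, metadata_path = NULL,
                               lengths_path = NULL, delim = "\t") {
  stopifnot(inherits(x, "spectral_counts"))
  wide <- tidyr::pivot_wider(x$counts, names_from = "run_id",
                             values_from = "count")
  wide <- wide[, c("protein", x$runs$run_id)]
  readr::write_delim(wide, path, delim = delim)
  if (!is.null(metadata_path)) {
    readr::write_delim(x$runs, metadata_path, delim = delim)
  }
  if (!is.null(lengths_path) && !is.null(x$lengths)) {
    readr::write_delim(x$lengths, lengths_path, delim = delim)
  }
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning a tidy
#' tibble. Identifiers are the first whitespace-delimited token of each
#' header; sequences are upper-cased and checked against the canonical
#' 20-letter amino-acid alphabet.
#'
#' @param path Path to a FASTA file (wrapped lines allowed).
#' @param stops How to treat `*` (stop) characters: `"reject"` (default)
#'   fails; `"strip"` removes them.
#' @return A tibble with columns `protein` and `sequence`.
#' @export
read_fasta <- function(path, stops = c("reject", "strip")) {
  stops <- match.arg(stops)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      abort(paste0("Could not parse FASTA file ", path, ": ",
                   conditionMessage(e)),
            class = "ligasetrap_format_error")
    }
  )
  if (length(set) == 0) {
    abort(paste0("No FASTA records in ", path),
          class = "ligasetrap_format_error")
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  seqs <- toupper(as.character(set))
  if (stops == "strip") {
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  } else if (any(grepl("*", seqs, fixed = TRUE))) {
    abort("FASTA sequence contains stop character '*' (use stops = \"strip\").",
          class = "ligasetrap_format_error")
  }
  if (any(!nzchar(seqs))) {
    abort("FASTA record with empty sequence.",
          class = "ligasetrap_format_error")
  }
  bad <- grepl(paste0("[^", AA_ALPHABET, "]"), seqs)
  if (any(bad)) {
    abort(paste0("Non-canonical residues in record(s): ",
                 paste(ids[bad], collapse = ", ")),
          class = "ligasetrap_format_error")
  }
  tibble(protein = ids, sequence = unname(seqs))
}

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"

#' Write protein sequences to FASTA
#'
#' @param records A data frame with columns `protein` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `records`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$protein))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(records)
}
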