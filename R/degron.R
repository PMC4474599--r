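#' Relaxed beta-TRCP phosphodegron model
#'
#' Position-weighted model of the beta-TRCP consensus DpSGX(1-4)pS with
#' acidic substitutions for phosphorylations tolerated. A window is
#' `p1 p2 G spacer(1-4) p_last`:
#' \describe{
#'   \item{p1}{acidic or phospho-acceptor, weights D = 1.0, E = 0.8,
#'     S = 0.6, T = 0.6}
#'   \item{p2}{phospho-acceptor or acidic, weights S = 1.0, T = 0.9,
#'     D = 0.8, E = 0.8}
#'   \item{position 3}{glycine strongly preferred: the score is multiplied
#'     by `glycine_weight` (1.0) for G, by `non_glycine_weight` (0.5)
#'     otherwise. Setting `non_glycine_weight = 0` makes glycine a hard
#'     requirement.}
#'   \item{spacer}{1 to 4 residues of any identity; each additional
#'     D/E/S/T in the spacer adds `acidity_bonus` (0.05), capped at
#'     `acidity_cap` (0.2)}
#'   \item{p_last}{as p2}
#' }
#' The window score is `(w_p1 + w_p2 + w_plast + bonus) * w_pos3`, bounded
#' by 3.2; the canonical DSGX(1-4)S always outranks acidic variants.
#' Phospho-status is not modelled: S/T are treated as potential
#' phospho-acceptors on the unmodified sequence.
#'
#' @param p1_weights,p2_weights,p_last_weights Named numeric vectors of
#'   per-residue weights in (0, 1]; names define the position's residue
#'   class.
#' @param glycine_weight,non_glycine_weight Multiplicative weight of
#'   position 3 for G and for any other residue.
#' @param spacer_range Integer range of allowed spacer lengths.
#' @param acidity_bonus,acidity_cap Additive bonus per D/E/S/T spacer
#'   residue and its cap.
#' @param min_score Default score threshold used by the scanning
#'   functions.
#' @param relaxed Also accept windows with a transposed glycine
#'   (`p1 G p2 spacer p_last`); off by default.
#' @return A list of class `degron_model`.
#' @export
degron_model <- function(p1_weights = c(D = 1.0, E = 0.8, S = 0.6, T = 0.6),
                         p2_weights = c(S = 1.0, T = 0.9, D = 0.8, E = 0.8),
                         p_last_weights = p2_weights,
                         glycine_weight = 1.0,
                         non_glycine_weight = 0.5,
                         spacer_range = c(1L, 4L),
                         acidity_bonus = 0.05,
                         acidity_cap = 0.2,
                         min_score = 1.0,
                         relaxed = FALSE) {
  stopifnot(
    all(p1_weights > 0), all(p1_weights <= 1),
    all(p2_weights > 0), all(p2_weights <= 1),
    all(p_last_weights > 0), all(p_last_weights <= 1),
    glycine_weight > 0, glycine_weight <= 1,
    non_glycine_weight >= 0, non_glycine_weight <= 1,
    length(spacer_range) == 2, spacer_range[1] >= 1,
    spacer_range[2] >= spacer_range[1],
    acidity_bonus >= 0, acidity_cap >= 0, min_score >= 0
  )
  structure(
    list(p1_weights = p1_weights, p2_weights = p2_weights,
         p_last_weights = p_last_weights,
         glycine_weight = glycine_weight,
         non_glycine_weight = non_glycine_weight,
         spacer_range = as.integer(spacer_range),
         acidity_bonus = acidity_bonus, acidity_cap = acidity_cap,
         min_score = min_score, relaxed = relaxed),
    class = "degron_model"
  )
}

# all scored windows for one sequence; zero-score windows are dropped
scan_one_sequence <- function(sequence, model) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- list()
  for (spacer in seq(model$spacer_range[1], model$spacer_range[2])) {
    win <- 4L + spacer
    if (L < win) next
    starts <- seq_len(L - win + 1L)
    p1 <- chars[starts]
    a2 <- chars[starts + 1L]
    a3 <- chars[starts + 2L]
    plast <- chars[starts + 3L + spacer]
    bonus <- vapply(starts, function(s) {
      sp <- chars[(s + 3L):(s + 2L + spacer)]
      min(model$acidity_bonus * sum(sp %in% c("D", "E", "S", "T")),
          model$acidity_cap)
    }, numeric(1))

    orientations <- list(
      list(p2 = a2, w3res = a3, transposed = FALSE),
      if (model$relaxed) list(p2 = a3, w3res = a2, transposed = TRUE)
    )
    for (ori in orientations) {
      if (is.null(ori)) next
      w1 <- unname(model$p1_weights[p1])
      w2 <- unname(model$p2_weights[ori$p2])
      wl <- unname(model$p_last_weights[plast])
      w3 <- if (ori$transposed) {
        ifelse(ori$w3res == "G", model$glycine_weight, 0)
      } else {
        ifelse(ori$w3res == "G", model$glycine_weight,
               model$non_glycine_weight)
      }
      score <- (w1 + w2 + wl + bonus) * w3
      keep <- !is.na(score) & score > 0
      if (!any(keep)) next
      g_pos3 <- !ori$transposed & ori$w3res == "G"
      variant <- ifelse(
        g_pos3 & p1 == "D" & ori$p2 %in% c("S", "T"), "canonical_DSG",
        ifelse(g_pos3, "acidic_variant", "relaxed"))
      out[[length(out) + 1L]] <- tibble(
        start = starts[keep],
        end = starts[keep] + win - 1L,
        spacer_len = spacer,
        score = score[keep],
        variant_class = variant[keep],
        matched_string = vapply(starts[keep], function(s)
          substr(sequence, s, s + win - 1L), character(1))
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(start = integer(), end = integer(),
                  spacer_len = integer(), score = numeric(),
                  variant_class = character(),
                  matched_string = character()))
  }
  res <- dplyr::bind_rows(out)
  # same window can match in both orientations under relaxed mode
  res <- res |>
    dplyr::group_by(.data$start, .data$spacer_len) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  res
}

normalize_records <- function(records) {
  if (is.character(records)) {
    ids <- names(records) %||% paste0("seq", seq_along(records))
    records <- tibble(protein = ids, sequence = unname(records))
  }
  records <- as_tibble(records)
  if (!all(c("protein", "sequence") %in% names(records))) {
    abort("`records` needs columns `protein` and `sequence`.",
          class = "ligasetrap_validation_error")
  }
  records$sequence <- toupper(records$sequence)
  records
}

#' Scan protein sequences for beta-TRCP degron windows
#'
#' Reports every window of [degron_model()] scoring at or above
#' `min_score`, per protein, sorted by descending score then ascending
#' start. Overlapping matches are allowed. Positions are 1-based inclusive.
#'
#' @param records A data frame with columns `protein` and `sequence`, or a
#'   (optionally named) character vector of sequences.
#' @param model A [degron_model()].
#' @param min_score Score threshold; defaults to the model's `min_score`.
#' @return A tibble with columns `protein`, `start`, `end`,
#'   `matched_string`, `spacer_len`, `score`, `variant_class`. Proteins
#'   without matches contribute no rows.
#' @examples
#' scan_degrons(c(RIPK4 = "DSGAS"))
#' scan_degrons(c(CReP_region = "DDGFDSDSSLSDSD"))
#' @export
scan_degrons <- function(records, model = degron_model(),
                         min_score = NULL) {
  records <- normalize_records(records)
  min_score <- min_score %||% model$min_score
  if (min_score < 0) {
    abort("`min_score` must be >= 0.", class = "ligasetrap_config_error")
  }
  res <- purrr::map2_dfr(records$protein, records$sequence, function(id, sq) {
    m <- scan_one_sequence(sq, model)
    m <- m[m$score >= min_score, ]
    if (nrow(m) == 0) return(m[0, ])
    m$protein <- id
    m[order(-m$score, m$start), ]
  })
  if (nrow(res) == 0) {
    return(tibble(protein = character(), start = integer(),
                  end = integer(), matched_string = character(),
                  spacer_len = integer(), score = numeric(),
                  variant_class = character()))
  }
  dplyr::select(res, "protein", "start", "end", "matched_string",
                "spacer_len", "score", "variant_class")
}

#' Closest-to-consensus degron per protein
#'
#' The highest-scoring window per protein; ties are broken by smaller
#' spacer length, then smaller start position. Proteins with no window at
#' or above `min_score` get a row of `NA`s.
#'
#' @inheritParams scan_degrons
#' @return A tibble with one row per input protein (input order), same
#'   columns as [scan_degrons()].
#' @export
best_degron <- function(records, model = degron_model(), min_score = NULL) {
  records <- normalize_records(records)
  hits <- scan_degrons(records, model, min_score)
  purrr::map_dfr(records$protein, function(id) {
    h <- hits[hits$protein == id, ]
    if (nrow(h) == 0) {
      return(tibble(protein = id, start = NA_integer_, end = NA_integer_,
                    matched_string = NA_character_,
                    spacer_len = NA_integer_, score = NA_real_,
                    variant_class = NA_character_))
    }
    h[order(-h$score, h$spacer_len, h$start), ][1, ]
  })
}

#' Cross-species conservation of best degrons
#'
#' Alignment-free comparison of degron windows across orthologous
#' sequences. For each protein, the best degron of the reference species
#' is located in every other species by sliding the reference window
#' (extended by `flank` residues on each side) along the ortholog and
#' maximizing identity; per-position identity fractions over the reference
#' window are then computed across species. Orthologs in which no window
#' reaches the model's score threshold are recorded as absent
#' (`best_degron = NA`) but still contribute to the positional identity.
#'
#' @param records A data frame with columns `protein`, `species`,
#'   `sequence` (at least two species per protein).
#' @param model A [degron_model()].
#' @param reference Species to take the focal window from; default the
#'   first species of each protein.
#' @param flank Residues of context on each side of the window used for
#'   locating it in orthologs.
#' @return A list of class `ortholog_conservation` with tibbles
#'   `species` (per protein x species: `best_degron`, `aligned_window`,
#'   `window_identity`) and `positions` (per protein x window position:
#'   reference `residue` and cross-species `identity` fraction).
#' @export
compare_orthologs <- function(records, model = degron_model(),
                              reference = NULL, flank = 5L) {
  records <- as_tibble(records)
  if (!all(c("protein", "species", "sequence") %in% names(records))) {
    abort("`records` needs columns `protein`, `species`, `sequence`.",
          class = "ligasetrap_validation_error")
  }
  records$sequence <- toupper(records$sequence)
  species_rows <- list()
  position_rows <- list()
  for (prot in unique(records$protein)) {
    sub <- records[records$protein == prot, ]
    if (nrow(sub) < 2) {
      abort(paste0("Protein '", prot, "' needs sequences from >= 2 species."),
            class = "ligasetrap_validation_error")
    }
    ref_sp <- reference %||% sub$species[1]
    if (!ref_sp %in% sub$species) {
      abort(paste0("Reference species '", ref_sp, "' absent for ", prot),
            class = "ligasetrap_config_error")
    }
    ref_seq <- sub$sequence[sub$species == ref_sp][1]
    ref_best <- best_degron(tibble(protein = prot, sequence = ref_seq),
                            model)
    if (is.na(ref_best$start)) {
      species_rows[[length(species_rows) + 1L]] <- tibble(
        protein = prot, species = sub$species,
        best_degron = NA_character_, aligned_window = NA_character_,
        window_identity = NA_real_)
      next
    }
    win_len <- ref_best$end - ref_best$start + 1L
    ref_win <- strsplit(ref_best$matched_string, "")[[1]]
    aligned <- matrix(NA_character_, nrow = nrow(sub), ncol = win_len)
    for (i in seq_len(nrow(sub))) {
      sq <- sub$sequence[i]
      if (sub$species[i] == ref_sp) {
        pos <- ref_best$start
      } else {
        pos <- locate_window(ref_seq, ref_best$start, ref_best$end,
                             sq, flank)
      }
      if (is.na(pos) || pos + win_len - 1L > nchar(sq)) next
      aligned[i, ] <- strsplit(substr(sq, pos, pos + win_len - 1L), "")[[1]]
    }
    sp_best <- best_degron(tibble(protein = sub$species,
                                  sequence = sub$sequence), model)
    species_rows[[length(species_rows) + 1L]] <- tibble(
      protein = prot,
      species = sub$species,
      best_degron = sp_best$matched_string,
      aligned_window = apply(aligned, 1, function(r)
        if (all(is.na(r))) NA_character_ else paste(r, collapse = "")),
      window_identity = apply(aligned, 1, function(r)
        if (all(is.na(r))) NA_real_ else mean(r == ref_win))
    )
    others <- aligned[sub$species != ref_sp, , drop = FALSE]
    position_rows[[length(position_rows) + 1L]] <- tibble(
      protein = prot,
      position = ref_best$start + seq_len(win_len) - 1L,
      residue = ref_win,
      identity = vapply(seq_len(win_len), function(j) {
        col <- others[, j]
        if (all(is.na(col))) return(NA_real_)
        mean(col == ref_win[j], na.rm = TRUE)
      }, numeric(1))
    )
  }
  structure(
    list(species = dplyr::bind_rows(species_rows),
         positions = dplyr::bind_rows(position_rows)),
    class = "ortholog_conservation"
  )
}

# best sliding-window placement of [start, end] (plus flank) in `target`
locate_window <- function(ref_seq, start, end, target, flank) {
  ext_start <- max(1L, start - flank)
  ext <- strsplit(substr(ref_seq, ext_start, min(nchar(ref_seq),
                                                 end + flank)), "")[[1]]
  offset <- start - ext_start
  tchars <- strsplit(target, "")[[1]]
  n <- length(tchars) - length(ext) + 1L
  if (n < 1) return(NA_integer_)
  best_pos <- NA_integer_
  best_id <- -1
  for (p in seq_len(n)) {
    id <- sum(tchars[p:(p + length(ext) - 1L)] == ext)
    if (id > best_id) {
      best_id <- id
      best_pos <- p
    }
  }
  best_pos + offset
}

#' @export
print.ortholog_conservation <- function(x, ...) {
  cat(sprintf("<ortholog_conservation> %d proteins, %d species rows\n",
              length(unique(x$species$protein)), nrow(x$species)))
  print(x$species, ...)
  invisible(x)
}
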