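#' Curation parameters
#'
#' Tuning constants for hit curation. Defaults follow the pipeline's rules:
#' same-clan neighbours may overlap by less than 33% and different-clan
#' neighbours by less than 45% (the latter removal also requires a
#' 10,000-fold E-value ratio); hits with adjusted E-value below 1e-7 are
#' treated as high-quality ("significant"); the calculated start may extend a
#' hit up to 20 residues upstream of its alignment start; a vFAM/pVOG hit
#' overlapping a PFAM hit survives only when its log10 E-value beats five
#' times the PFAM hit's; adjusted E-values above 1 are excluded outright.
#'
#' @param same_clan_max_overlap Overlap fraction allowed between same-clan
#'   hits (default 0.33).
#' @param diff_clan_max_overlap Overlap fraction allowed between
#'   different-clan hits when only one is significant (default 0.45).
#' @param fold_ratio E-value ratio required before a different-clan overlap
#'   removes the worse hit (default 1e4).
#' @param significance_threshold Adjusted E-value below which a hit counts as
#'   high quality (default 1e-7).
#' @param calc_start_slack Maximum upstream extension of the calculated start,
#'   in residues (default 20).
#' @param db_log_factor Multiplier in the vFAM/pVOG-vs-PFAM log10 E-value
#'   precedence test (default 5).
#' @param max_adj_evalue Exclusion threshold for adjusted E-values (default 1).
#' @return A named list of class `curation_params`.
#' @export
curation_params <- function(same_clan_max_overlap = 0.33,
                            diff_clan_max_overlap = 0.45,
                            fold_ratio = 1e4,
                            significance_threshold = 1e-7,
                            calc_start_slack = 20,
                            db_log_factor = 5,
                            max_adj_evalue = 1.0) {
  if (!(same_clan_max_overlap > 0 && same_clan_max_overlap < 1 &&
        diff_clan_max_overlap > 0 && diff_clan_max_overlap < 1))
    abort("overlap thresholds must lie in (0, 1)")
  if (fold_ratio <= 1) abort("fold_ratio must exceed 1")
  structure(list(same_clan_max_overlap = same_clan_max_overlap,
                 diff_clan_max_overlap = diff_clan_max_overlap,
                 fold_ratio = fold_ratio,
                 significance_threshold = significance_threshold,
                 calc_start_slack = calc_start_slack,
                 db_log_factor = db_log_factor,
                 max_adj_evalue = max_adj_evalue),
            class = "curation_params")
}

#' Adjust per-domain E-values for the windowed search space
#'
#' HMMER reports per-domain independent E-values scaled to the whole target
#' set of a search. These are rescaled in two steps: first normalised to a
#' single-sequence search space (division by the number of targets in the
#' search), then rescaled linearly by the ratio of the full translated-frame
#' length to the searched segment length, to undo the sensitivity gain of
#' searching short windows. Whole-frame (and gene) searches skip the second
#' factor.
#'
#' `adjust_evalue()` is the scalar/vector kernel; `adjust_evalues()` applies
#' it to a hit table, joining frame lengths from the translation table.
#'
#' @param i_evalue Per-domain independent E-value(s), > 0.
#' @param searched_length Length of the searched sequence (residues).
#' @param frame_aa_length Length of the full translated frame (residues).
#' @param n_targets Number of target sequences in the hmmsearch run.
#' @param search_mode `"window"`, `"genome"` or `"gene"`.
#' @return Adjusted E-value(s).
#' @examples
#' adjust_evalue(1e-10, searched_length = 200, frame_aa_length = 10000,
#'               n_targets = 1, search_mode = "window")  # 5e-09
#' @export
adjust_evalue <- function(i_evalue, searched_length, frame_aa_length,
                          n_targets = 1, search_mode = "window") {
  if (any(i_evalue <= 0)) abort("i_evalue must be positive")
  if (any(searched_length < 1) || any(frame_aa_length < 1, na.rm = TRUE) ||
      any(n_targets < 1))
    abort("lengths and target counts must be >= 1")
  factor <- ifelse(search_mode == "window", frame_aa_length / searched_length, 1)
  i_evalue / n_targets * factor
}

#' @rdname adjust_evalue
#' @param hits A hit tibble from [parse_domtblout()].
#' @param frames The translation table from [six_frame_translate()], used to
#'   look up each hit's full frame length.
#' @return `adjust_evalues()`: `hits` with `adj_evalue` filled.
#' @export
adjust_evalues <- function(hits, frames, n_targets = 1) {
  if (nrow(hits) == 0) return(hits)
  flen <- frames |> dplyr::select("accession", "frame", frame_aa_length = "aa_length")
  h <- dplyr::left_join(hits, flen, by = c("accession", "frame"))
  need <- h$search_mode == "window" & is.na(h$frame_aa_length)
  if (any(need))
    abort(paste0("no frame length available for windowed hits on: ",
                 paste(unique(h$accession[need]), collapse = ", ")))
  h$adj_evalue <- adjust_evalue(h$i_evalue, h$searched_length,
                                dplyr::coalesce(h$frame_aa_length, h$searched_length),
                                n_targets, h$search_mode)
  h$frame_aa_length <- NULL
  h
}

#' Exclude hits with large adjusted E-values
#'
#' @param hits A hit tibble with `adj_evalue` populated.
#' @param max_adj Exclusion threshold (default 1): hits with
#'   `adj_evalue > max_adj` are dropped, survivors pass through unchanged.
#' @return The filtered tibble.
#' @export
filter_hits <- function(hits, max_adj = 1.0) {
  if (nrow(hits) == 0) return(hits)
  if (anyNA(hits$adj_evalue)) abort("adj_evalue not populated; run adjust_evalues() first")
  hits[hits$adj_evalue <= max_adj, , drop = FALSE]
}

#' Collapse hits that overlap 100%
#'
#' The windowing step finds the same domain in every window that spans it, so
#' identical hits (same profile, genome, frame and alignment interval) are
#' pruned to a single copy, keeping the smallest adjusted E-value. The
#' redundant copies are retained with `kept = FALSE` and
#' `removal_reason = "duplicate"` for audit.
#'
#' @param hits A hit tibble (after [adjust_evalues()]).
#' @return `hits` with `kept` and `removal_reason` columns added/updated.
#' @export
prune_exact_duplicates <- function(hits) {
  hits <- init_kept(hits)
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::group_by(.data$profile, .data$accession, .data$frame,
                    .data$ali_start, .data$ali_end) |>
    dplyr::mutate(
      .rank = order(order(.data$adj_evalue, -.data$bit_score, .data$target_id)),
      kept = .data$kept & .data$.rank == 1L,
      removal_reason = ifelse(.data$.rank == 1L, .data$removal_reason, "duplicate")
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".rank")
}

init_kept <- function(hits) {
  if (!"kept" %in% names(hits)) hits$kept <- TRUE
  if (!"removal_reason" %in% names(hits)) hits$removal_reason <- "none"
  hits
}

#' Calculated start of a domain hit
#'
#' The effective start used in overlap comparisons: where the domain would
#' normally begin, up to `slack` (default 20) residues before the alignment
#' start, bounded by how much of the profile is missing upstream
#' (`hmm_from - 1`) and by the start of the frame.
#'
#' @param ali_start Alignment start(s), 1-based.
#' @param hmm_from First matched profile position(s), 1-based.
#' @param slack Maximum upstream extension in residues.
#' @return Integer vector of calculated starts.
#' @export
calc_start <- function(ali_start, hmm_from, slack = 20) {
  pmax(as.integer(ali_start) - pmin(as.integer(hmm_from) - 1L, as.integer(slack)), 1L)
}

#' Overlap fraction between two domain hits
#'
#' Fraction of the shorter hit covered by the intersection of the two hits'
#' effective intervals `[calc_start, ali_end]` (1-based inclusive). Using the
#' shorter hit as denominator makes a small domain nested inside a large one
#' register as a high overlap. Overlap is defined per frame only.
#'
#' @param a,b One-row hit tibbles with `frame`, `ali_start`, `ali_end`,
#'   `hmm_from` columns (and optionally a precomputed `calc_start`).
#' @param slack Upstream extension used for the calculated start.
#' @return Overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b, slack = 20) {
  if (a$frame != b$frame || a$accession != b$accession)
    abort("overlap is defined per (accession, frame) only")
  sa <- if ("calc_start" %in% names(a)) a$calc_start else calc_start(a$ali_start, a$hmm_from, slack)
  sb <- if ("calc_start" %in% names(b)) b$calc_start else calc_start(b$ali_start, b$hmm_from, slack)
  interval_overlap_frac(sa, a$ali_end, sb, b$ali_end)
}

# inclusive-interval overlap / shorter length; vectorised
interval_overlap_frac <- function(s1, e1, s2, e2) {
  inter <- pmin(e1, e2) - pmax(s1, s2) + 1
  shorter <- pmin(e1 - s1 + 1, e2 - s2 + 1)
  pmax(inter, 0) / shorter
}

#' Resolve overlapping domain hits (clan-aware de-overlap)
#'
#' Within each (accession, frame), hits are sorted by calculated start and
#' every adjacent and skip-1 neighbour pair (A-B, B-C and A-C) is examined:
#'
#' * same clan (both carry the same non-missing clan): overlap of 33% or more
#'   removes the hit with the larger adjusted E-value;
#' * different clans: both are kept if both are significant (adjusted
#'   E-value at or below `significance_threshold`); otherwise an overlap of
#'   45% or more removes the worse hit, provided the better one is at least
#'   `fold_ratio` (10,000-fold) better in E-value;
#' * database precedence: a vFAM/pVOG hit overlapping a PFAM hit at all is
#'   kept only when `log10(E_vfam) < db_log_factor * log10(E_pfam)` (both
#'   E-values taken below 1, so the logs are negative); ties favour PFAM.
#'
#' Removed hits drop out of later comparisons and the pass repeats until a
#' fixed point, which makes the kept-set independent of input order. Hits in
#' different frames never compete, preserving genuine double coding on
#' opposite strands.
#'
#' @param hits A hit tibble after [adjust_evalues()], [filter_hits()] and
#'   [prune_exact_duplicates()].
#' @param params A [curation_params()] object.
#' @return `hits` with `calc_start` added and `kept`/`removal_reason` updated
#'   (`same_clan_overlap`, `diff_clan_overlap`, `db_precedence`).
#' @export
deoverlap <- function(hits, params = curation_params()) {
  hits <- init_kept(hits)
  if (nrow(hits) == 0) { hits$calc_start <- integer(); return(hits) }
  if (anyNA(hits$adj_evalue)) abort("adj_evalue not populated; run adjust_evalues() first")
  hits$calc_start <- calc_start(hits$ali_start, hits$hmm_from, params$calc_start_slack)
  hits |>
    dplyr::group_by(.data$accession, .data$frame) |>
    dplyr::group_modify(function(df, key) deoverlap_group(df, params)) |>
    dplyr::ungroup()
}

deoverlap_group <- function(df, params, neighbor_span = 2L) {
  repeat {
    alive <- which(df$kept)
    if (length(alive) < 2) return(df)
    alive <- alive[order(df$calc_start[alive], df$ali_end[alive], df$profile[alive])]
    removed_any <- FALSE
    n <- length(alive)
    dead <- rep(FALSE, n)
    for (i in seq_len(n - 1)) {
      if (dead[i]) next
      for (d in seq_len(min(neighbor_span, n - i))) {
        j <- i + d
        if (dead[i] || dead[j]) next
        verdict <- pair_rules(df[alive[i], ], df[alive[j], ], params)
        if (verdict$remove != 0L) {
          loser <- if (verdict$remove == 1L) i else j
          df$kept[alive[loser]] <- FALSE
          df$removal_reason[alive[loser]] <- verdict$reason
          dead[loser] <- TRUE
          removed_any <- TRUE
        }
      }
    }
    if (!removed_any) return(df)
  }
}

# Apply the de-overlap rules to one pair of kept hits.
# Returns list(remove = 0 (neither) / 1 / 2, reason).
pair_rules <- function(a, b, params) {
  ov <- interval_overlap_frac(a$calc_start, a$ali_end, b$calc_start, b$ali_end)
  if (ov <= 0) return(list(remove = 0L, reason = "none"))
  worse <- pair_worse(a, b)
  same_clan <- !is.na(a$clan) && !is.na(b$clan) && a$clan == b$clan
  if (same_clan) {
    if (ov >= params$same_clan_max_overlap)
      return(list(remove = worse, reason = "same_clan_overlap"))
  } else {
    both_sig <- a$adj_evalue <= params$significance_threshold &&
      b$adj_evalue <= params$significance_threshold
    if (!both_sig && ov >= params$diff_clan_max_overlap) {
      better <- min(a$adj_evalue, b$adj_evalue)
      worse_e <- max(a$adj_evalue, b$adj_evalue)
      if (better <= worse_e / params$fold_ratio)
        return(list(remove = worse, reason = "diff_clan_overlap"))
    }
  }
  # database precedence: vFAM/pVOG riding on top of a PFAM hit
  a_pfam <- a$source_db == "PFAM"
  b_pfam <- b$source_db == "PFAM"
  if (a_pfam != b_pfam) {
    v <- if (a_pfam) b else a
    p <- if (a_pfam) a else b
    lv <- log10(pmin(v$adj_evalue, 1 - 1e-12))
    lp <- log10(pmin(p$adj_evalue, 1 - 1e-12))
    if (!(lv < params$db_log_factor * lp))
      return(list(remove = if (a_pfam) 2L else 1L, reason = "db_precedence"))
  }
  list(remove = 0L, reason = "none")
}

# which of a pair is the worse hit (1 or 2): larger adjusted E-value, ties by
# lower bit score, later calculated start, later profile name
pair_worse <- function(a, b) {
  if (a$adj_evalue != b$adj_evalue) return(if (a$adj_evalue > b$adj_evalue) 1L else 2L)
  if (a$bit_score != b$bit_score) return(if (a$bit_score < b$bit_score) 1L else 2L)
  if (a$calc_start != b$calc_start) return(if (a$calc_start > b$calc_start) 1L else 2L)
  if (a$profile >= b$profile) 1L else 2L
}

#' Full hit curation: adjust, filter, deduplicate, de-overlap
#'
#' Convenience wrapper chaining [adjust_evalues()], [filter_hits()],
#' [prune_exact_duplicates()] and [deoverlap()]. The result keeps removed
#' rows (with `kept = FALSE` and a `removal_reason`) for audit; downstream
#' steps use the `kept` rows.
#'
#' @param hits A hit tibble from [parse_domtblout()] / [compile_hits()].
#' @param frames Translation table from [six_frame_translate()].
#' @param n_targets Number of target sequences in each hmmsearch run.
#' @param params A [curation_params()] object.
#' @return A curated hit tibble with `calc_start`, `kept`, `removal_reason`.
#' @export
curate_hits <- function(hits, frames, n_targets = 1, params = curation_params()) {
  hits |>
    adjust_evalues(frames, n_targets) |>
    filter_hits(params$max_adj_evalue) |>
    prune_exact_duplicates() |>
    deoverlap(params)
}

#' Read/write curated hit tables
#'
#' Tab-delimited with a header row; one row per domain hit including the
#' audit columns (`kept`, `removal_reason`).
#'
#' @param hits A hit tibble.
#' @param path File path.
#' @return `read_hits()`: the tibble; `write_hits()`: `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    profile = "c", clan = "c", source_db = "c", accession = "c", frame = "i",
    search_mode = "c", target_id = "c", .default = readr::col_guess()
  ), progress = FALSE)
}
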