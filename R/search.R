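#' Read profile metadata (clan and source database)
#'
#' Profile HMM files do not carry clan membership uniformly, so clan and
#' source-database assignments travel in a sidecar TSV with columns
#' `profile`, `clan` and `source_db`. Profiles without a clan use an empty
#' string or `NA` in the `clan` column.
#'
#' @param path Tab-separated file with a header row.
#' @return A tibble with `profile`, `clan` (`NA` when absent) and `source_db`
#'   (one of `"PFAM"`, `"VFAM"`, `"PVOG"`).
#' @export
read_profile_meta <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!all(c("profile", "clan", "source_db") %in% names(m)))
    abort("profile metadata needs columns profile, clan, source_db")
  m$clan[!is.na(m$clan) & m$clan == ""] <- NA_character_
  m$source_db <- toupper(m$source_db)
  bad <- setdiff(unique(m$source_db), c("PFAM", "VFAM", "PVOG"))
  if (length(bad)) abort(paste0("unknown source_db: ", paste(bad, collapse = ", ")))
  if (anyDuplicated(m$profile)) abort("profile names must be unique across the database")
  tibble::as_tibble(m[c("profile", "clan", "source_db")])
}

#' Balanced partition sizes
#'
#' Sizes of a near-even partition of `n` items into `k` ordered groups:
#' all sizes are `floor(n/k)` or `ceiling(n/k)` (they differ by at most 1)
#' and larger groups come first, so concatenating the groups in order
#' reproduces the input order.
#'
#' @param n Number of items (>= 1).
#' @param k Number of groups (>= 1).
#' @return Integer vector of length `min(n, k)` summing to `n`.
#' @examples
#' bundle_sizes(30947, 40)  # 27 bundles of 774 profiles, 13 of 773
#' @export
bundle_sizes <- function(n, k) {
  if (n < 1) abort("empty database")
  if (k < 1) abort("need at least one bundle")
  k <- min(n, k)
  base <- n %/% k
  extra <- n %% k
  as.integer(c(rep(base + 1L, extra), rep(base, k - extra)))
}

#' Split a profile-HMM database into bundle files
#'
#' Partitions a HMMER3 ASCII `.hmm` database into `n_bundles` files of
#' near-equal profile counts, preserving the input order, so searches can be
#' fanned out as (frame, bundle) jobs. Concatenating the bundles reproduces
#' the database.
#'
#' @param db_path A HMMER3 ASCII `.hmm` file (profiles terminated by `//`).
#' @param out_dir Directory for the bundle files.
#' @param n_bundles Number of bundles (default 40).
#' @return A tibble with `bundle` (1-based), `path` and `n_profiles`.
#' @export
bundle_profiles <- function(db_path, out_dir, n_bundles = 40) {
  lines <- readLines(db_path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0) abort(paste0("no profiles found in ", db_path))
  starts <- c(1L, head(ends, -1) + 1L)
  sizes <- bundle_sizes(length(ends), n_bundles)
  grp <- rep(seq_along(sizes), sizes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(seq_along(sizes), function(b) {
    idx <- which(grp == b)
    p <- file.path(out_dir, sprintf("bundle%03d.hmm", b))
    writeLines(unlist(purrr::map(idx, function(i) lines[starts[i]:ends[i]])), p)
    p
  })
  tibble(bundle = seq_along(sizes), path = paths, n_profiles = sizes)
}

#' Plan the search job fan-out
#'
#' One `hmmsearch` job per (translated-frame FAA, profile bundle) pair; with
#' the 6 frames of a genome set and the default 40 bundles this is the 240-job
#' fan-out the pipeline runs in parallel.
#'
#' @param frames Either a count of frame files or a character vector of FAA
#'   paths.
#' @param bundles Either a count of bundles or a character vector of bundle
#'   paths.
#' @return A tibble with one row per job: `job`, `faa`, `bundle`.
#' @examples
#' nrow(plan_jobs(6, 40))  # 240
#' @export
plan_jobs <- function(frames, bundles) {
  fa <- if (is.numeric(frames)) {
    if (frames < 1) abort("need at least one frame")
    paste0("frame", seq_len(frames))
  } else frames
  bu <- if (is.numeric(bundles)) {
    if (bundles < 1) abort("need at least one bundle")
    paste0("bundle", seq_len(bundles))
  } else bundles
  if (length(fa) < 1 || length(bu) < 1) abort("need at least one frame and one bundle")
  g <- tidyr::expand_grid(faa = fa, bundle = bu)
  tibble(job = seq_len(nrow(g)), faa = g$faa, bundle = g$bundle)
}

hmmer_available <- function() nzchar(Sys.which("hmmsearch"))

#' Run hmmsearch on one (FAA, bundle) job
#'
#' Invokes `hmmsearch --noali --domT <domT> -o /dev/null --domtblout <out>`
#' so reporting is gated by a bit-score floor rather than an E-value; the
#' bespoke E-value handling happens downstream in [adjust_evalues()]. When
#' HMMER3 is not on the `PATH`, the pipeline runs in ingest mode on
#' user-supplied `--domtblout` tables instead.
#'
#' @param faa Amino-acid FASTA of search targets.
#' @param bundle Profile-HMM bundle file.
#' @param out Output path for the per-domain table.
#' @param domT Bit-score reporting floor (default -5).
#' @return `out`, invisibly.
#' @export
run_search <- function(faa, bundle, out, domT = -5) {
  if (!hmmer_available())
    abort(paste0("hmmsearch not found on PATH; either install HMMER3 or supply ",
                 "precomputed --domtblout tables to parse_domtblout()"))
  status <- system2("hmmsearch",
                    c("--noali", "--domT", as.character(domT), "-o", "/dev/null",
                      "--domtblout", shQuote(out), shQuote(bundle), shQuote(faa)))
  if (status != 0) abort(paste0("hmmsearch exited with status ", status,
                                " for ", faa, " vs ", bundle))
  invisible(out)
}

#' Run a planned set of search jobs, resumably
#'
#' Executes each (FAA, bundle) job whose output table does not yet exist;
#' finished outputs are written to a temporary name and moved into place only
#' when the job completes, so an interrupted run can be resumed and only the
#' missing jobs are recomputed. Failures are recorded in the tracking log and
#' retried on the next pass.
#'
#' @param jobs A job tibble from [plan_jobs()] whose `faa` and `bundle`
#'   columns are file paths.
#' @param out_dir Directory for the per-job `--domtblout` tables.
#' @param domT Bit-score floor passed to [run_search()].
#' @param tracking Optional tracking-log path (see [update_tracking()]).
#' @return The job tibble with `out` and `status` (`"done"`, `"skipped"` for
#'   pre-existing outputs, or `"failed"`) columns added.
#' @export
run_search_jobs <- function(jobs, out_dir, domT = -5, tracking = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(out_dir, sprintf("job%04d.domtblout", jobs$job))
  status <- purrr::map_chr(seq_len(nrow(jobs)), function(i) {
    if (file.exists(out[i])) return("skipped")
    tmp <- paste0(out[i], ".part")
    ok <- tryCatch({ run_search(jobs$faa[i], jobs$bundle[i], tmp, domT); TRUE },
                   error = function(e) { warn(conditionMessage(e)); FALSE })
    if (ok) { file.rename(tmp, out[i]); "done" } else { unlink(tmp); "failed" }
  })
  if (!is.null(tracking)) {
    for (i in seq_len(nrow(jobs)))
      update_tracking(tracking, basename(jobs$faa[i]), "searched",
                      if (status[i] == "failed") "failed" else "done")
  }
  dplyr::mutate(jobs, out = out, status = status)
}

#' Decode search-target FASTA headers
#'
#' Search targets are named so hit coordinates can be placed back onto the
#' genome: whole frames as `<accession>|frame<k>`, windows as
#' `<accession>|frame<k>|win<index>|start<aa_start>` and gene peptides as
#' `<accession>|gene|<name>|<nt_start>|<nt_end>|<strand>`.
#'
#' @param ids Character vector of target identifiers.
#' @return A tibble with `accession`, `search_mode` (`"genome"`, `"window"`
#'   or `"gene"`), `frame` (`NA` for gene mode) and `win_aa_start` (0-based
#'   window offset within the frame; 0 for whole frames, `NA` for genes).
#' @export
parse_target_id <- function(ids) {
  parts <- str_split(ids, fixed("|"))
  rows <- purrr::map2(parts, ids, function(p, id) {
    if (length(p) == 2 && grepl("^frame[1-6]$", p[2])) {
      tibble(accession = p[1], search_mode = "genome",
             frame = as.integer(sub("frame", "", p[2])), win_aa_start = 0L)
    } else if (length(p) == 4 && grepl("^frame[1-6]$", p[2]) &&
               grepl("^win[0-9]+$", p[3]) && grepl("^start[0-9]+$", p[4])) {
      tibble(accession = p[1], search_mode = "window",
             frame = as.integer(sub("frame", "", p[2])),
             win_aa_start = as.integer(sub("start", "", p[4])))
    } else if (length(p) == 6 && p[2] == "gene") {
      tibble(accession = p[1], search_mode = "gene",
             frame = NA_integer_, win_aa_start = NA_integer_)
    } else {
      abort(paste0("unrecognised target naming: ", id))
    }
  })
  dplyr::bind_rows(rows)
}

#' Parse a HMMER3 --domtblout per-domain table
#'
#' Reads one or more HMMER3 `--domtblout` files into a tidy hit table, one
#' row per reported domain. Window-relative alignment and envelope
#' coordinates are shifted by the window's offset so that all coordinates are
#' frame-relative (1-based inclusive). Hits from overlapping windows are
#' genuinely duplicated at this stage; [prune_exact_duplicates()] collapses
#' them later.
#'
#' @param path Character vector of `--domtblout` file paths.
#' @param profile_meta Optional tibble from [read_profile_meta()]; when given,
#'   `clan` and `source_db` are joined on, and profiles missing from the
#'   metadata get `clan = NA`, `source_db = "PFAM"`.
#' @return A tibble with columns `profile`, `clan`, `source_db`, `accession`,
#'   `frame`, `search_mode`, `target_id`, `searched_length`, `ali_start`,
#'   `ali_end`, `env_start`, `env_end`, `hmm_from`, `hmm_to`, `qlen`,
#'   `bit_score`, `i_evalue`, plus placeholder `adj_evalue`, `nt_start`,
#'   `nt_end`, `strand` columns filled by [adjust_evalues()] and
#'   [map_hits_to_genomic()]. Sorted deterministically, so re-compiling the
#'   same set of tables yields an identical tibble.
#' @export
parse_domtblout <- function(path, profile_meta = NULL) {
  rows <- purrr::map(path, parse_domtblout_one)
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) == 0) {
    hits <- empty_hits()
  } else {
    tid <- parse_target_id(hits$target_id)
    hits <- dplyr::bind_cols(hits, tid)
    win <- hits$search_mode == "window"
    for (col in c("ali_start", "ali_end", "env_start", "env_end"))
      hits[[col]][win] <- hits[[col]][win] + hits$win_aa_start[win]
    hits$win_aa_start <- NULL
    hits$adj_evalue <- NA_real_
    hits$nt_start <- NA_integer_
    hits$nt_end <- NA_integer_
    hits$strand <- NA_character_
  }
  if (!is.null(profile_meta)) {
    hits <- dplyr::left_join(hits, profile_meta, by = "profile")
    hits$source_db[is.na(hits$source_db)] <- "PFAM"
  } else if (!"clan" %in% names(hits)) {
    hits$clan <- NA_character_
    hits$source_db <- "PFAM"
  }
  bad <- hits$i_evalue <= 0 | hits$ali_start > hits$ali_end |
    hits$env_start > hits$ali_start | hits$ali_end > hits$env_end
  if (any(bad)) abort("inconsistent domain coordinates or non-positive E-value in input")
  dplyr::arrange(
    hits[c("profile", "clan", "source_db", "accession", "frame", "search_mode",
           "target_id", "searched_length", "ali_start", "ali_end", "env_start",
           "env_end", "hmm_from", "hmm_to", "qlen", "bit_score", "i_evalue",
           "adj_evalue", "nt_start", "nt_end", "strand")],
    .data$accession, .data$frame, .data$ali_start, .data$ali_end,
    .data$profile, .data$target_id)
}

empty_hits <- function() {
  tibble(profile = character(), clan = character(), source_db = character(),
         accession = character(), frame = integer(), search_mode = character(),
         target_id = character(), searched_length = integer(),
         ali_start = integer(), ali_end = integer(),
         env_start = integer(), env_end = integer(),
         hmm_from = integer(), hmm_to = integer(), qlen = integer(),
         bit_score = double(), i_evalue = double(), adj_evalue = double(),
         nt_start = integer(), nt_end = integer(), strand = character())
}

# one file -> raw per-row tibble (22 fixed whitespace-separated columns)
parse_domtblout_one <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) return(NULL)
  fields <- str_split(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 22))
    abort(sprintf("malformed domtblout row at %s line %d (%d of 22 columns)",
                  path, keep[which(nf < 22)[1]], min(nf)))
  f <- function(i) purrr::map_chr(fields, i)
  num <- function(i, line_field) {
    v <- suppressWarnings(as.numeric(f(i)))
    if (anyNA(v))
      abort(sprintf("malformed domtblout row at %s line %d (non-numeric %s)",
                    path, keep[which(is.na(v))[1]], line_field))
    v
  }
  tibble(
    target_id = f(1),
    searched_length = as.integer(num(3, "tlen")),
    profile = f(4),
    qlen = as.integer(num(6, "qlen")),
    i_evalue = num(13, "i-Evalue"),
    bit_score = num(14, "dom score"),
    hmm_from = as.integer(num(16, "hmm from")),
    hmm_to = as.integer(num(17, "hmm to")),
    ali_start = as.integer(num(18, "ali from")),
    ali_end = as.integer(num(19, "ali to")),
    env_start = as.integer(num(20, "env from")),
    env_end = as.integer(num(21, "env to"))
  )
}

#' Compile per-job domain tables into one hit table
#'
#' @param results_dir Directory of `--domtblout` files (searched for
#'   `*.domtblout`), or a character vector of file paths.
#' @param profile_meta Optional profile metadata (see [parse_domtblout()]).
#' @return One deterministic hit tibble; compiling the same inputs twice
#'   yields identical results.
#' @export
compile_hits <- function(results_dir, profile_meta = NULL) {
  paths <- if (length(results_dir) == 1 && dir.exists(results_dir))
    sort(list.files(results_dir, pattern = "\\.domtblout$", full.names = TRUE))
  else results_dir
  parse_domtblout(paths, profile_meta)
}

#' Pipeline tracking log
#'
#' A line-oriented TSV (`accession`, `stage`, `status`, `timestamp`) that
#' records each genome's progress through the pipeline stages
#' `compiled`, `translated`, `searched`, `curated`, `neighborhoods`.
#' `update_tracking()` appends a row; `read_tracking()` returns the latest
#' status per (accession, stage). A stage should be marked `done` only after
#' its outputs exist on disk; re-running a pipeline skips `done` stages, which
#' is what makes interrupted runs resumable.
#'
#' @param path Tracking-log path (created on first update).
#' @param accession Genome (or job) identifier.
#' @param stage One of the pipeline stage names.
#' @param status `"pending"`, `"failed"` or `"done"`.
#' @return `read_tracking()`: a tibble with `accession`, `stage`, `status`;
#'   `update_tracking()`: the path, invisibly.
#' @export
update_tracking <- function(path, accession, stage, status) {
  stage <- match.arg(stage, c("compiled", "translated", "searched", "curated",
                              "neighborhoods"))
  status <- match.arg(status, c("pending", "failed", "done"))
  cat(sprintf("%s\t%s\t%s\t%s\n", accession, stage, status,
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      file = path, append = TRUE)
  invisible(path)
}

#' @rdname update_tracking
#' @export
read_tracking <- function(path) {
  if (!file.exists(path))
    return(tibble(accession = character(), stage = character(), status = character()))
  log <- readr::read_tsv(path, col_names = c("accession", "stage", "status", "timestamp"),
                         col_types = "cccc", progress = FALSE)
  log |>
    dplyr::group_by(.data$accession, .data$stage) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("accession", "stage", "status")
}
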