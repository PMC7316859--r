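#' Synthetic domain-architecture specification
#'
#' Describes one synthetic "family": an ordered list of domain profiles that
#' every genome of the family carries (subject to dropout), with random
#' nucleotide gaps between them. Each profile corresponds to a fixed,
#' high-information 50-residue motif (see [synthetic_motif()]) encoded
#' in-frame in the genome, so planted domains can be recovered either by a
#' real profile search or from generated hit tables.
#'
#' @param family Family label.
#' @param profiles A tibble with columns `profile`, `clan` (`NA` allowed) and
#'   `source_db` (`PFAM`/`VFAM`/`PVOG`).
#' @param spacing Length-2 integer vector: uniform bounds (nt) of the random
#'   gaps before/between/after domains.
#' @param dropout_prob Per-domain probability of omission from a genome.
#' @param decoy_rate Per-genome probability of a spurious near-threshold hit
#'   in generated hit tables.
#' @param strands `"forward"` plants every domain on the + strand;
#'   `"alternate"` alternates + / - along the architecture.
#' @return An `architecture_spec` list.
#' @export
architecture_spec <- function(family, profiles, spacing = c(30L, 150L),
                              dropout_prob = 0, decoy_rate = 0,
                              strands = c("forward", "alternate")) {
  strands <- match.arg(strands)
  if (!all(c("profile", "clan", "source_db") %in% names(profiles)))
    abort("profiles needs columns profile, clan, source_db")
  if (nrow(profiles) < 1) abort("need at least one profile")
  spacing <- as.integer(spacing)
  if (length(spacing) != 2 || spacing[1] < 0 || spacing[2] < spacing[1])
    abort("spacing must be nonneg bounds c(min, max) with min <= max")
  if (dropout_prob < 0 || dropout_prob >= 1 || decoy_rate < 0 || decoy_rate >= 1)
    abort("dropout_prob and decoy_rate must lie in [0, 1)")
  structure(list(family = family, profiles = tibble::as_tibble(profiles),
                 spacing = spacing, dropout_prob = dropout_prob,
                 decoy_rate = decoy_rate, strands = strands),
            class = "architecture_spec")
}

# run code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

#' Deterministic synthetic motif for a profile name
#'
#' A fixed 50-residue amino-acid string derived from the profile name by a
#' small linear congruential generator, independent of R's RNG state: the
#' same profile always maps to the same motif, across sessions and seeds.
#'
#' @param profile Profile name(s).
#' @param length Motif length in residues (default 50).
#' @return Character vector of motifs.
#' @export
synthetic_motif <- function(profile, length = 50) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  purrr::map_chr(profile, function(p) {
    x <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) %% 2147483647
    out <- character(length)
    for (i in seq_len(length)) {
      x <- (1103515245 * x + 12345) %% 2147483648
      out[i] <- aa[(x %/% 65536) %% 20 + 1]
    }
    paste(out, collapse = "")
  })
}

# reverse-translate an amino-acid string, sampling synonymous codons
reverse_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  codons <- split(names(gc), unname(gc))
  paste(purrr::map_chr(strsplit(aa, "")[[1]], function(a) {
    opts <- codons[[a]]
    if (is.null(opts)) abort(paste0("no codon for residue ", a))
    opts[sample.int(length(opts), 1)]
  }), collapse = "")
}

#' Generate one synthetic genome with planted domains
#'
#' Builds a nucleotide sequence in which each (non-dropped) profile's motif
#' is encoded in-frame at a random position, separated by random-sequence
#' gaps; minus-strand placements insert the reverse complement of the coding
#' sequence. Returns the genome together with the ground-truth placements
#' (genomic coordinates, strand, frame and frame-relative amino-acid
#' coordinates) used by recovery tests. Deterministic under `seed`.
#'
#' @param spec An [architecture_spec()].
#' @param accession Accession to assign.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list with `genome` (one-row tibble in [read_genomes()] layout)
#'   and `placements` (tibble of planted domains).
#' @export
generate_genome <- function(spec, accession, seed = 1) {
  with_local_seed(seed, generate_genome_impl(spec, accession))
}

generate_genome_impl <- function(spec, accession) {
  gap <- function() {
    n <- sample(spec$spacing[1]:spec$spacing[2], 1)
    if (n == 0) "" else paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
  }
  parts <- gap()
  placed <- list()
  for (i in seq_len(nrow(spec$profiles))) {
    if (spec$dropout_prob > 0 && runif(1) < spec$dropout_prob) next
    motif <- synthetic_motif(spec$profiles$profile[i])
    cds <- reverse_translate(motif)
    strand <- if (spec$strands == "alternate" && i %% 2 == 0) "-" else "+"
    ins <- if (strand == "-") reverse_complement(cds) else cds
    start <- nchar(parts) + 1L
    parts <- paste0(parts, ins, gap())
    placed[[length(placed) + 1]] <- tibble(
      accession = accession, family = spec$family,
      profile = spec$profiles$profile[i], clan = spec$profiles$clan[i],
      source_db = spec$profiles$source_db[i], arch_index = i, motif = motif,
      nt_start = start, nt_end = start + nchar(ins) - 1L, strand = strand
    )
  }
  seq <- parts
  L <- nchar(seq)
  placements <- dplyr::bind_rows(placed)
  if (nrow(placements) > 0) {
    fwd <- placements$strand == "+"
    p0 <- ifelse(fwd, placements$nt_start, L - placements$nt_end + 1L)
    off <- (p0 - 1L) %% 3L
    placements$frame <- as.integer(off + ifelse(fwd, 1L, 4L))
    placements$aa_start <- as.integer((p0 - 1L - off) %/% 3L + 1L)
    placements$aa_end <- placements$aa_start + nchar(placements$motif) - 1L
  }
  genome <- tibble(accession = accession,
                   description = paste0("synthetic ", spec$family, " genome"),
                   sequence = seq, family = spec$family,
                   genes = list(empty_genes()))
  list(genome = genome, placements = placements)
}

#' Generate a labeled set of synthetic genomes
#'
#' Draws `n_per_family` genomes from each architecture and collects the
#' genome table, ground-truth placements, family labels and the combined
#' profile metadata (planted profiles plus the decoy pool).
#'
#' @param specs A list of [architecture_spec()] objects.
#' @param n_per_family Genomes per family (default 10).
#' @param seed Master seed; per-genome seeds derive from it.
#' @return A list with `genomes`, `placements`, `labels` (tibble `accession`,
#'   `family`), `profile_meta` and `specs`.
#' @export
generate_genomes <- function(specs, n_per_family = 10, seed = 1) {
  if (inherits(specs, "architecture_spec")) specs <- list(specs)
  sims <- list()
  idx <- 0
  for (f in seq_along(specs)) {
    for (g in seq_len(n_per_family)) {
      idx <- idx + 1
      acc <- sprintf("SYN%02d_%04d", f, g)
      sims[[idx]] <- generate_genome(specs[[f]], acc, seed = seed * 10000 + idx)
    }
  }
  genomes <- dplyr::bind_rows(purrr::map(sims, "genome"))
  placements <- dplyr::bind_rows(purrr::map(sims, "placements"))
  meta <- dplyr::bind_rows(
    purrr::map(specs, function(s) s$profiles[c("profile", "clan", "source_db")]),
    tibble(profile = paste0("DECOY_", 1:5), clan = NA_character_,
           source_db = "PFAM")
  ) |> dplyr::distinct(.data$profile, .keep_all = TRUE)
  list(genomes = genomes, placements = placements,
       labels = genomes[c("accession", "family")],
       profile_meta = meta, specs = specs)
}

#' Generate a synthetic HMMER3 per-domain table for planted genomes
#'
#' Emits `--domtblout`-format rows for every planted placement — in window
#' mode one duplicate row per window that fully contains the motif, which is
#' exactly the redundancy [prune_exact_duplicates()] later collapses —
#' with independent E-values drawn log-uniformly from `evalue_range`.
#' Spurious decoy hits with E-values near 1 are added per genome at each
#' family's `decoy_rate`. The output parses with [parse_domtblout()].
#'
#' @param sim Output of [generate_genomes()].
#' @param seed Seed for E-value and decoy draws.
#' @param mode `"window"` (default) or `"genome"` target naming.
#' @param window_width,step Windowing parameters (defaults 200 / 13).
#' @param evalue_range Log-uniform bounds for planted-hit independent
#'   E-values (default `c(1e-30, 1e-12)`).
#' @param path Optional file to write; when `NULL` a tempfile is used.
#' @return The path of the written table.
#' @export
generate_hit_table <- function(sim, seed = 1, mode = c("window", "genome"),
                               window_width = 200, step = 13,
                               evalue_range = c(1e-30, 1e-12), path = NULL) {
  mode <- match.arg(mode)
  path <- path %||% tempfile(fileext = ".domtblout")
  with_local_seed(seed, {
    rows <- generate_hit_rows(sim, mode, window_width, step, evalue_range)
    writeLines(c(
      "# --- synthetic per-domain hits (HMMER3 --domtblout column layout) ---",
      "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
      rows), path)
  })
  path
}

generate_hit_rows <- function(sim, mode, window_width, step, evalue_range) {
  glen <- setNames(nchar(sim$genomes$sequence), sim$genomes$accession)
  decoy_rate <- setNames(purrr::map_dbl(sim$specs, "decoy_rate"),
                         purrr::map_chr(sim$specs, "family"))
  rows <- character()
  pl <- sim$placements
  for (i in seq_len(nrow(pl))) {
    L <- glen[[pl$accession[i]]]
    aa_len <- (L - (pl$frame[i] - 1L) %% 3L) %/% 3L
    ie <- 10^runif(1, log10(evalue_range[1]), log10(evalue_range[2]))
    mlen <- nchar(pl$motif[i])
    a0 <- pl$aa_start[i] - 1L
    if (mode == "genome") {
      rows <- c(rows, domtbl_row(
        target = sprintf("%s|frame%d", pl$accession[i], pl$frame[i]),
        tlen = aa_len, profile = pl$profile[i], qlen = mlen, ie = ie,
        ali = c(pl$aa_start[i], pl$aa_end[i]), hmm = c(1L, mlen)))
    } else {
      starts <- seq(0L, aa_len - 1L, by = step)
      covering <- which(starts <= a0 & a0 + mlen <= starts + window_width)
      if (length(covering) == 0)
        abort(paste0("no window fully covers planted motif ", pl$profile[i],
                     " in ", pl$accession[i]))
      for (w in covering) {
        ws <- starts[w]
        rows <- c(rows, domtbl_row(
          target = sprintf("%s|frame%d|win%d|start%d",
                           pl$accession[i], pl$frame[i], w - 1L, ws),
          tlen = min(window_width, aa_len - ws), profile = pl$profile[i],
          qlen = mlen, ie = ie,
          ali = c(a0 - ws + 1L, a0 - ws + mlen), hmm = c(1L, mlen)))
      }
    }
  }
  # spurious near-threshold decoys
  for (acc in names(glen)) {
    fam <- sim$labels$family[sim$labels$accession == acc][1]
    dr <- decoy_rate[[fam]] %||% 0
    if (dr > 0 && runif(1) < dr) {
      fr <- sample(1:6, 1)
      aa_len <- (glen[[acc]] - (fr - 1L) %% 3L) %/% 3L
      if (aa_len < 60) next
      a0 <- sample.int(aa_len - 50L, 1)
      ie <- runif(1, 0.05, 0.95)
      if (mode == "genome") {
        rows <- c(rows, domtbl_row(sprintf("%s|frame%d", acc, fr), aa_len,
                                   paste0("DECOY_", sample(5, 1)), 40L, ie,
                                   ali = c(a0, a0 + 39L), hmm = c(1L, 40L)))
      } else {
        starts <- seq(0L, aa_len - 1L, by = step)
        w <- which(starts <= a0 - 1L & a0 - 1L + 40L <= starts + window_width)[1]
        if (is.na(w)) next
        ws <- starts[w]
        rows <- c(rows, domtbl_row(
          sprintf("%s|frame%d|win%d|start%d", acc, fr, w - 1L, ws),
          min(window_width, aa_len - ws), paste0("DECOY_", sample(5, 1)), 40L,
          ie, ali = c(a0 - ws, a0 - ws + 39L), hmm = c(1L, 40L)))
      }
    }
  }
  rows
}

domtbl_row <- function(target, tlen, profile, qlen, ie, ali, hmm) {
  score <- round(-2.2 * log10(ie) + 8, 1)
  sprintf(paste("%s - %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0",
                "%d %d %d %d %d %d 0.98 -"),
          target, tlen, profile, qlen, ie, score, ie, ie, score,
          hmm[1], hmm[2], ali[1], ali[2], ali[1], ali[2])
}

#' Two-family demonstration architectures
#'
#' A pair of synthetic families sharing one anchor domain (the natural domain
#' of interest) but carrying disjoint, differently-clanned flanking domains,
#' so clan-keyed neighborhood features separate the families cleanly.
#'
#' @param dropout_prob,decoy_rate Passed to both [architecture_spec()]s.
#' @return A list of two `architecture_spec` objects.
#' @export
demo_architectures <- function(dropout_prob = 0, decoy_rate = 0) {
  fam <- function(family, tags, clans) {
    architecture_spec(
      family = family,
      profiles = tibble(
        profile = c(tags[1:2], "ANCHOR_HEL", tags[3:4]),
        clan = c(clans[1:2], "CL_HEL", clans[3:4]),
        source_db = c("PFAM", "VFAM", "PFAM", "PFAM", "PVOG")
      ),
      dropout_prob = dropout_prob, decoy_rate = decoy_rate
    )
  }
  list(
    fam("synfamA", paste0("ALPHA_", 1:4), paste0("CL_A", 1:4)),
    fam("synfamB", paste0("BETA_", 1:4), paste0("CL_B", 1:4))
  )
}

#' Build a real profile-HMM database from synthetic motifs
#'
#' Writes one HMMER3 profile per synthetic profile name by running `hmmbuild`
#' on a small alignment of identical copies of the motif, then concatenates
#' the profiles into a single `.hmm` database — so the plant-and-recover
#' fixtures can also exercise a real `hmmsearch`.
#'
#' @param profiles Character vector of profile names.
#' @param path Output `.hmm` database path.
#' @param n_copies Sequences per alignment (default 5).
#' @return `path`, invisibly.
#' @export
build_profile_db <- function(profiles, path, n_copies = 5) {
  if (!nzchar(Sys.which("hmmbuild")))
    abort("hmmbuild not found on PATH; cannot build profile databases")
  tmp <- tempfile("hmmbuild")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  parts <- purrr::map_chr(profiles, function(p) {
    motif <- synthetic_motif(p)
    afa <- file.path(tmp, paste0(p, ".afa"))
    writeLines(as.vector(rbind(paste0(">", p, "_", seq_len(n_copies)),
                               rep(motif, n_copies))), afa)
    hmm <- file.path(tmp, paste0(p, ".hmm"))
    status <- system2("hmmbuild", c("-n", shQuote(p), "--amino", shQuote(hmm),
                                    shQuote(afa)), stdout = FALSE, stderr = FALSE)
    if (status != 0) abort(paste0("hmmbuild failed for ", p))
    hmm
  })
  writeLines(unlist(purrr::map(parts, readLines)), path)
  invisible(path)
}
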