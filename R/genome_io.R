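#' Read genome records from FASTA or GenBank
#'
#' Parses nucleotide genome records into a tibble with one row per record.
#' GenBank flat files additionally contribute gene annotations (CDS features)
#' and a taxonomy family, when present; FASTA input yields empty gene lists.
#'
#' @param path Path to a FASTA (`.fna`/`.fasta`) or GenBank (`.gb`/`.gbk`)
#'   file, possibly multi-record.
#' @param format `"auto"` (by extension), `"fasta"` or `"genbank"`.
#' @return A tibble with columns `accession`, `description`, `sequence`
#'   (nucleotide string over A/C/G/T/N), `family` (taxonomy family or `NA`)
#'   and `genes`, a list-column of tibbles with `name`, `start`, `end`
#'   (1-based inclusive nucleotide coordinates) and `strand` (`"+"`/`"-"`).
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' writeLines(c(">v1 a tiny genome", "ATGAAATAA"), fa)
#' read_genomes(fa)
#' @export
read_genomes <- function(path, format = c("auto", "fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  g <- switch(format,
    fasta   = read_genomes_fasta(path),
    genbank = read_genomes_genbank(path)
  )
  validate_genomes(g)
  g
}

read_genomes_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) abort(paste0("cannot parse FASTA ", path, ": ",
                                                  conditionMessage(e))))
  if (length(ss) == 0) abort(paste0("no records in ", path))
  hdr <- names(ss)
  acc <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  tibble(
    accession = acc,
    description = desc,
    sequence = unname(clean_nt(as.character(ss))),
    family = NA_character_,
    genes = rep(list(empty_genes()), length(ss))
  )
}

empty_genes <- function() {
  tibble(name = character(), start = integer(), end = integer(),
         strand = character())
}

# restrict to the A/C/G/T/N alphabet; other IUPAC ambiguity codes become N
clean_nt <- function(x) {
  toupper(gsub("[^ACGTNacgtn]", "N", x))
}

validate_genomes <- function(g) {
  if (anyDuplicated(g$accession))
    abort("duplicate accessions in genome set")
  if (any(!nzchar(g$accession)) || any(nchar(g$sequence) < 1))
    abort("every record needs a non-empty accession and sequence")
  ok <- purrr::map2_lgl(g$genes, nchar(g$sequence), function(genes, len) {
    nrow(genes) == 0 ||
      all(genes$start >= 1 & genes$end <= len & genes$start <= genes$end)
  })
  if (!all(ok))
    abort(paste0("gene interval outside sequence bounds in: ",
                 paste(g$accession[!ok], collapse = ", ")))
  invisible(g)
}

# Minimal GenBank flat-file reader: LOCUS/ACCESSION/DEFINITION/ORGANISM
# lineage, CDS features (simple and complement() locations; join() spans are
# collapsed to their extremes with a warning -- splicing is out of scope),
# and the ORIGIN sequence.
read_genomes_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0) abort(paste0("no GenBank record terminator (//) in ", path))
  starts <- c(1L, head(ends, -1) + 1L)
  recs <- purrr::map2(starts, ends, function(s, e) {
    parse_genbank_record(lines[s:(e - 1)], path)
  })
  dplyr::bind_rows(recs)
}

parse_genbank_record <- function(rl, path) {
  field <- function(key) {
    i <- grep(paste0("^", key, "\\s"), rl)
    if (length(i) == 0) return(NA_character_)
    trimws(sub(paste0("^", key, "\\s+"), "", rl[i[1]]))
  }
  locus <- field("LOCUS")
  accession <- field("ACCESSION")
  accession <- if (is.na(accession)) sub("\\s.*$", "", locus %||% NA_character_)
               else sub("\\s.*$", "", accession)
  if (is.na(accession) || !nzchar(accession))
    abort(paste0("GenBank record without ACCESSION/LOCUS in ", path))
  description <- field("DEFINITION") %||% ""

  # taxonomy lineage: indented lines after ORGANISM, semicolon separated
  family <- NA_character_
  io <- grep("^\\s{2}ORGANISM\\s", rl)
  if (length(io)) {
    j <- io[1] + 1
    lin <- character()
    while (j <= length(rl) && grepl("^\\s{8,}\\S", rl[j])) {
      lin <- c(lin, trimws(rl[j])); j <- j + 1
    }
    taxa <- trimws(strsplit(gsub("\\.$", "", paste(lin, collapse = " ")), ";")[[1]])
    fam <- taxa[grepl("viridae$|viricetes$|idae$", taxa, ignore.case = TRUE) &
                grepl("viridae$", taxa, ignore.case = TRUE)]
    if (length(fam)) family <- fam[1]
  }

  genes <- parse_genbank_cds(rl, accession)
  seq <- parse_genbank_origin(rl, accession)
  tibble(accession = accession, description = description, sequence = seq,
         family = family, genes = list(genes))
}

parse_genbank_cds <- function(rl, accession) {
  fstart <- grep("^FEATURES", rl)
  ostart <- grep("^ORIGIN", rl)
  if (length(fstart) == 0) return(empty_genes())
  fend <- if (length(ostart)) ostart[1] - 1 else length(rl)
  fl <- rl[(fstart[1] + 1):fend]
  key_idx <- grep("^\\s{5}\\S", fl)
  cds_idx <- key_idx[grepl("^\\s{5}CDS\\s", fl[key_idx])]
  out <- purrr::map(cds_idx, function(i) {
    nxt <- key_idx[key_idx > i]
    block <- fl[i:(if (length(nxt)) nxt[1] - 1 else length(fl))]
    loc <- sub("^\\s{5}CDS\\s+", "", block[1])
    k <- 2
    while (k <= length(block) && !grepl("^\\s+/", block[k])) {
      loc <- paste0(loc, trimws(block[k])); k <- k + 1
    }
    q <- function(name) {
      m <- str_match(block, paste0('/', name, '="?([^"]*)"?\\s*$'))[, 2]
      m <- m[!is.na(m)]
      if (length(m)) m[1] else NA_character_
    }
    name <- q("gene") %||% NA_character_
    if (is.na(name)) name <- q("locus_tag")
    if (is.na(name)) name <- q("product")
    if (is.na(name)) name <- paste0("CDS_", i)
    strand <- if (grepl("complement", loc)) "-" else "+"
    if (grepl("join", loc)) {
      warn(paste0(accession, "/", name,
                  ": join() location collapsed to its outer span (no splicing support)"))
    }
    pos <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
    if (length(pos) < 1) {
      abort(paste0("unparseable CDS location in ", accession, ": ", loc))
    }
    tibble(name = name, start = min(pos), end = max(pos), strand = strand)
  })
  if (length(out) == 0) return(empty_genes())
  dplyr::bind_rows(out)
}

parse_genbank_origin <- function(rl, accession) {
  o <- grep("^ORIGIN", rl)
  if (length(o) == 0) abort(paste0("GenBank record ", accession, " has no ORIGIN sequence"))
  seq_lines <- rl[(o[1] + 1):length(rl)]
  s <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
  if (!nzchar(s)) abort(paste0("empty ORIGIN in ", accession))
  clean_nt(s)
}

#' Six-frame translation of genome records
#'
#' Translates each genome in all six reading frames with the standard genetic
#' code: frames 1-3 read the forward strand at offsets 0-2, frames 4-6 read
#' the reverse complement at offsets 0-2. Stop codons are kept as the `*`
#' sentinel (frames are searched whole, not split into ORFs) and any codon
#' containing an ambiguous base translates to `X`.
#'
#' @param genomes A genome tibble from [read_genomes()] (or any tibble with
#'   `accession` and `sequence` columns).
#' @return A tibble with one row per (genome, frame): `accession`, `frame`
#'   (1-6), `strand`, `offset` (0-2), `aa_sequence` and `aa_length`, where
#'   `aa_length == floor((nt_length - offset) / 3)`.
#' @export
six_frame_translate <- function(genomes) {
  stopifnot(all(c("accession", "sequence") %in% names(genomes)))
  if (any(nchar(genomes$sequence) < 1)) abort("empty sequence")
  per_genome <- purrr::map2(genomes$accession, genomes$sequence, function(acc, nt) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    aa <- purrr::map_chr(1:6, function(f) {
      src <- if (f <= 3) nt else rc
      translate_aa(substring(src, (f - 1) %% 3 + 1))
    })
    tibble(
      accession = acc,
      frame = 1:6,
      strand = rep(c("+", "-"), each = 3),
      offset = rep(0:2, 2),
      aa_sequence = aa,
      aa_length = nchar(aa)
    )
  })
  dplyr::bind_rows(per_genome)
}

# translate the leading codon-multiple of a nucleotide string (table 1);
# ambiguous codons -> X, stops -> '*'
translate_aa <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

reverse_complement <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Partition translated frames into overlapping windows
#'
#' Cuts each translated frame into windows of `window_width` residues whose
#' starts advance by `step`, so consecutive full windows overlap by
#' `window_width - step` residues. The trailing window may be shorter than
#' `window_width`; every residue of the frame is covered and no new sequence
#' content is introduced.
#'
#' @param frames A frame tibble from [six_frame_translate()].
#' @param window_width Window width in residues (default 200).
#' @param step Offset between consecutive window starts (default 13).
#' @return A tibble with `accession`, `frame`, `window` (0-based ordinal),
#'   `aa_start` (0-based offset of the window within the frame),
#'   `aa_sequence` and `target_id` (the FAA header used for searching, see
#'   [parse_target_id()]).
#' @export
make_windows <- function(frames, window_width = 200, step = 13) {
  if (!(window_width >= step && step >= 1))
    abort("need window_width >= step >= 1")
  per_frame <- purrr::pmap(
    frames[c("accession", "frame", "aa_sequence", "aa_length")],
    function(accession, frame, aa_sequence, aa_length) {
      if (aa_length == 0) return(NULL)
      starts <- seq(0L, aa_length - 1L, by = step)
      tibble(
        accession = accession,
        frame = frame,
        window = seq_along(starts) - 1L,
        aa_start = starts,
        aa_sequence = substring(aa_sequence, starts + 1L,
                                pmin(starts + window_width, aa_length))
      )
    }
  )
  out <- dplyr::bind_rows(per_frame)
  if (nrow(out) == 0) return(out)
  out$target_id <- sprintf("%s|frame%d|win%d|start%d",
                           out$accession, out$frame, out$window, out$aa_start)
  out
}

#' Translate annotated gene regions
#'
#' Extracts each annotated gene's nucleotide span (reverse-complemented for
#' minus-strand genes) and translates it in frame 1 of the span. Spans that
#' are not a codon multiple are truncated by 1-2 nt with a warning.
#'
#' @param genomes A genome tibble from [read_genomes()] with gene annotations.
#' @return A tibble with `accession`, `gene`, `nt_start`, `nt_end`, `strand`,
#'   `aa_sequence` and `target_id`; zero rows when no genes are annotated.
#' @export
extract_gene_sequences <- function(genomes) {
  per_genome <- purrr::pmap(genomes[c("accession", "sequence", "genes")],
    function(accession, sequence, genes) {
      if (nrow(genes) == 0) return(NULL)
      aa <- purrr::pmap_chr(genes, function(name, start, end, strand) {
        span <- substr(sequence, start, end)
        if (strand == "-") span <- reverse_complement(span)
        if (nchar(span) %% 3 != 0)
          warn(sprintf("%s/%s: span of %d nt is not a codon multiple; trailing %d nt dropped",
                       accession, name, nchar(span), nchar(span) %% 3))
        translate_aa(span)
      })
      tibble(accession = accession, gene = genes$name,
             nt_start = genes$start, nt_end = genes$end,
             strand = genes$strand, aa_sequence = aa)
    })
  out <- dplyr::bind_rows(per_genome)
  if (nrow(out) == 0) return(out)
  out$target_id <- sprintf("%s|gene|%s|%d|%d|%s", out$accession, out$gene,
                           out$nt_start, out$nt_end, out$strand)
  out
}

#' Map frame amino-acid coordinates to genomic nucleotide coordinates
#'
#' Converts a half-open, 0-based amino-acid interval within a translation
#' frame to 1-based inclusive nucleotide coordinates on the forward strand of
#' the genome. Reverse-frame (4-6) intervals are reflected so that
#' `nt_start <= nt_end` always holds, with `strand = "-"`.
#'
#' @param frame Frame number 1-6 (vectorised).
#' @param aa_start 0-based start of the amino-acid interval within the frame.
#' @param aa_end_exclusive 0-based exclusive end of the interval.
#' @param nt_length Genome length in nucleotides.
#' @return A tibble with `nt_start`, `nt_end` (1-based inclusive, forward
#'   axis) and `strand`; the span length is always
#'   `3 * (aa_end_exclusive - aa_start)`.
#' @examples
#' map_to_genomic(1, 0, 1, 9)  # first codon: nt 1..3, "+"
#' map_to_genomic(4, 0, 1, 9)  # first reverse codon: nt 7..9, "-"
#' @export
map_to_genomic <- function(frame, aa_start, aa_end_exclusive, nt_length) {
  n <- max(length(frame), length(aa_start), length(aa_end_exclusive), length(nt_length))
  frame <- rep_len(as.integer(frame), n)
  aa_start <- rep_len(as.integer(aa_start), n)
  aa_end <- rep_len(as.integer(aa_end_exclusive), n)
  nt_length <- rep_len(as.integer(nt_length), n)
  if (any(frame < 1 | frame > 6)) abort("frame must be in 1..6")
  offset <- (frame - 1L) %% 3L
  aa_len <- (nt_length - offset) %/% 3L
  if (any(aa_start < 0 | aa_start >= aa_end | aa_end > aa_len))
    abort("amino-acid coordinates out of frame bounds")
  fwd <- frame <= 3
  nt_start <- ifelse(fwd,
                     offset + 3L * aa_start + 1L,
                     nt_length - (offset + 3L * aa_end) + 1L)
  nt_end <- ifelse(fwd,
                   offset + 3L * aa_end,
                   nt_length - (offset + 3L * aa_start))
  tibble(nt_start = as.integer(nt_start), nt_end = as.integer(nt_end),
         strand = ifelse(fwd, "+", "-"))
}

#' Attach genomic coordinates to domain hits
#'
#' Fills the `nt_start`, `nt_end` and `strand` columns of a hit table from
#' each hit's frame-relative alignment coordinates (`ali_start`/`ali_end`,
#' 1-based inclusive). Gene-mode hits are mapped through the gene span
#' recorded in their `target_id`.
#'
#' @param hits A hit tibble from [parse_domtblout()].
#' @param genomes The genome tibble the hits refer to.
#' @return `hits` with `nt_start`, `nt_end`, `strand` populated.
#' @export
map_hits_to_genomic <- function(hits, genomes) {
  if (nrow(hits) == 0) {
    hits$nt_start <- integer(); hits$nt_end <- integer(); hits$strand <- character()
    return(hits)
  }
  len <- setNames(nchar(genomes$sequence), genomes$accession)
  missing <- setdiff(unique(hits$accession), names(len))
  if (length(missing))
    abort(paste0("hits reference unknown accessions: ", paste(missing, collapse = ", ")))
  is_gene <- hits$search_mode == "gene"
  out <- hits
  if (any(!is_gene)) {
    m <- map_to_genomic(hits$frame[!is_gene],
                        hits$ali_start[!is_gene] - 1L,
                        hits$ali_end[!is_gene],
                        len[hits$accession[!is_gene]])
    out$nt_start[!is_gene] <- m$nt_start
    out$nt_end[!is_gene] <- m$nt_end
    out$strand[!is_gene] <- m$strand
  }
  if (any(is_gene)) {
    gi <- str_split(hits$target_id[is_gene], fixed("|"), simplify = TRUE)
    gstart <- as.integer(gi[, 4]); gend <- as.integer(gi[, 5]); gstr <- gi[, 6]
    a0 <- hits$ali_start[is_gene] - 1L
    a1 <- hits$ali_end[is_gene]
    out$nt_start[is_gene] <- ifelse(gstr == "+", gstart + 3L * a0, gend - 3L * a1 + 1L)
    out$nt_end[is_gene] <- ifelse(gstr == "+", gstart + 3L * a1 - 1L, gend - 3L * a0)
    out$strand[is_gene] <- gstr
  }
  out
}

#' Write standardized FNA and per-frame FAA files
#'
#' `write_fna()` writes one standardized nucleotide FASTA per genome set;
#' `write_frame_faa()` writes each translated frame as
#' `<accession>.frame<k>.faa`; `write_faa()` writes any tibble with
#' `target_id` and `aa_sequence` columns (e.g. windows or gene peptides) as a
#' single amino-acid FASTA whose headers downstream parsers can decode.
#'
#' @param genomes,frames,targets Tibbles from [read_genomes()],
#'   [six_frame_translate()], [make_windows()]/[extract_gene_sequences()].
#' @param dir,path Output directory / file path.
#' @return The written path(s), invisibly.
#' @export
write_fna <- function(genomes, path) {
  writeLines(as.vector(rbind(paste0(">", genomes$accession, " ", genomes$description),
                             genomes$sequence)), path)
  invisible(path)
}

#' @rdname write_fna
#' @export
write_frame_faa <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::pmap_chr(frames[c("accession", "frame", "aa_sequence")],
    function(accession, frame, aa_sequence) {
      p <- file.path(dir, sprintf("%s.frame%d.faa", accession, frame))
      writeLines(c(sprintf(">%s|frame%d", accession, frame), aa_sequence), p)
      p
    })
  invisible(paths)
}

#' @rdname write_fna
#' @export
write_faa <- function(targets, path) {
  keep <- nchar(targets$aa_sequence) > 0
  writeLines(as.vector(rbind(paste0(">", targets$target_id[keep]),
                             targets$aa_sequence[keep])), path)
  invisible(path)
}
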