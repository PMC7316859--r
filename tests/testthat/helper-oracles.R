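# Independent oracles used to check the package's implementations.

# -- translation oracle: explicit codon-table walk (standard code) -----------
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",  # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- unlist(lapply(bases, function(b1)
    unlist(lapply(bases, function(b2) paste0(b1, b2, bases)))))
  setNames(aas, codons)
})

oracle_translate <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3
  if (n == 0) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    cod <- substr(nt, 3 * i - 2, 3 * i)
    out[i] <- if (grepl("[^ACGT]", cod)) "X" else .codon_table[[cod]]
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(nt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(nt), "")[[1]]]), collapse = "")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# -- de-overlap oracle: all-pairs rule application to fixed point ------------
# Independent of the package's windowed adjacent/skip-1 scan: repeatedly find
# the first (in sorted pair order) pair for which a rule fires, remove the
# loser, and restart, until no pair fires.
oracle_deoverlap <- function(df, params = domainhood::curation_params()) {
  df$calc_start <- pmax(df$ali_start - pmin(df$hmm_from - 1, params$calc_start_slack), 1)
  df$kept <- TRUE
  df$removal_reason <- "none"
  for (grp in split(seq_len(nrow(df)), paste(df$accession, df$frame))) {
    repeat {
      alive <- grp[df$kept[grp]]
      alive <- alive[order(df$calc_start[alive], df$ali_end[alive], df$profile[alive])]
      if (length(alive) < 2) break
      fired <- FALSE
      for (i in seq_len(length(alive) - 1)) {
        for (j in (i + 1):length(alive)) {
          v <- oracle_pair(df[alive[i], ], df[alive[j], ], params)
          if (v$remove != 0) {
            loser <- alive[if (v$remove == 1) i else j]
            df$kept[loser] <- FALSE
            df$removal_reason[loser] <- v$reason
            fired <- TRUE
            break
          }
        }
        if (fired) break
      }
      if (!fired) break
    }
  }
  df
}

oracle_pair <- function(a, b, params) {
  inter <- min(a$ali_end, b$ali_end) - max(a$calc_start, b$calc_start) + 1
  shorter <- min(a$ali_end - a$calc_start, b$ali_end - b$calc_start) + 1
  ov <- max(inter, 0) / shorter
  if (ov <= 0) return(list(remove = 0, reason = "none"))
  worse <- if (a$adj_evalue > b$adj_evalue) 1
    else if (b$adj_evalue > a$adj_evalue) 2
    else if (a$bit_score < b$bit_score) 1
    else if (b$bit_score < a$bit_score) 2
    else if (a$calc_start > b$calc_start) 1
    else if (b$calc_start > a$calc_start) 2
    else if (a$profile >= b$profile) 1 else 2
  same_clan <- !is.na(a$clan) && !is.na(b$clan) && a$clan == b$clan
  if (same_clan && ov >= params$same_clan_max_overlap)
    return(list(remove = worse, reason = "same_clan_overlap"))
  if (!same_clan) {
    both_sig <- max(a$adj_evalue, b$adj_evalue) <= params$significance_threshold
    if (!both_sig && ov >= params$diff_clan_max_overlap &&
        min(a$adj_evalue, b$adj_evalue) * params$fold_ratio <= max(a$adj_evalue, b$adj_evalue))
      return(list(remove = worse, reason = "diff_clan_overlap"))
  }
  pfams <- c(a$source_db, b$source_db) == "PFAM"
  if (xor(pfams[1], pfams[2])) {
    vi <- which(!pfams); pi <- which(pfams)
    ev <- c(a$adj_evalue, b$adj_evalue)
    lv <- log10(min(ev[vi], 1 - 1e-12))
    lp <- log10(min(ev[pi], 1 - 1e-12))
    if (!(lv < params$db_log_factor * lp))
      return(list(remove = vi, reason = "db_precedence"))
  }
  list(remove = 0, reason = "none")
}

# -- ARI oracle: exhaustive pair counting ------------------------------------
oracle_ari <- function(la, lb) {
  n <- length(la)
  a <- b <- c <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- la[i] == la[j]
      sb <- lb[i] == lb[j]
      if (sa && sb) a <- a + 1
      else if (sa && !sb) b <- b + 1
      else if (!sa && sb) c <- c + 1
      else d <- d + 1
    }
  }
  den <- (a + b) * (b + d) + (a + c) * (c + d)
  if (den == 0) return(1)
  2 * (a * d - b * c) / den
}

# -- fixture builders --------------------------------------------------------

# minimal curated-hit rows for de-overlap tests
make_hits <- function(ali_start, ali_end, adj_evalue,
                      clan = NA_character_, source_db = "PFAM",
                      profile = NULL, hmm_from = 1, bit_score = NULL,
                      accession = "G1", frame = 1) {
  n <- length(ali_start)
  tibble::tibble(
    profile = profile %||% sprintf("P%02d", seq_len(n)),
    clan = rep_len(clan, n),
    source_db = rep_len(source_db, n),
    accession = rep_len(accession, n),
    frame = rep_len(as.integer(frame), n),
    search_mode = "window",
    target_id = sprintf("%s|frame%d|win%d|start0", accession, frame, seq_len(n)),
    searched_length = 200L,
    ali_start = as.integer(ali_start),
    ali_end = as.integer(ali_end),
    env_start = as.integer(ali_start),
    env_end = as.integer(ali_end),
    hmm_from = as.integer(rep_len(hmm_from, n)),
    hmm_to = as.integer(ali_end - ali_start + rep_len(hmm_from, n)),
    qlen = as.integer(ali_end - ali_start + 1L),
    bit_score = bit_score %||% round(-2 * log10(adj_evalue), 1),
    i_evalue = adj_evalue,
    adj_evalue = adj_evalue,
    nt_start = NA_integer_, nt_end = NA_integer_, strand = NA_character_
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random de-overlap instance: <= n_max hits along a chain so that only
# adjacent and skip-1 neighbours can overlap
random_chain_instance <- function(n_max = 6) {
  n <- sample(2:n_max, 1)
  starts <- 1 + 40 * (seq_len(n) - 1)
  clans <- sample(c("CLX", "CLY", NA_character_), n, replace = TRUE)
  make_hits(
    ali_start = starts,
    ali_end = starts + 99,
    adj_evalue = 10^runif(n, -25, -1),
    clan = clans,
    source_db = sample(c("PFAM", "VFAM", "PVOG"), n, replace = TRUE),
    profile = sprintf("P%02d", sample(n))
  )
}

# ordered profile string per genome, from curated + ordered hits
arch_string <- function(ordered) {
  s <- split(ordered$profile, ordered$accession)
  vapply(s, paste, character(1), collapse = ",")
}

kept_ids <- function(cur) sort(cur$profile[cur$kept])
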