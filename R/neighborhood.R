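#' Order curated domains along each genome
#'
#' Merges the kept hits of all six frames into one linear order per genome by
#' genomic start coordinate (ties broken by end coordinate, then profile
#' name), interleaving strands. The 0-based `order_index` is the
#' ordered-domain rank used for neighborhood distances.
#'
#' @param curated A curated hit tibble with genomic coordinates (see
#'   [curate_hits()] and [map_hits_to_genomic()]); only `kept` rows are used.
#' @return The kept hits with an `order_index` column, sorted by genome and
#'   rank.
#' @export
order_domains <- function(curated) {
  if ("kept" %in% names(curated)) curated <- curated[curated$kept, , drop = FALSE]
  if (nrow(curated) == 0) {
    curated$order_index <- integer()
    return(curated)
  }
  if (anyNA(curated$nt_start))
    abort("genomic coordinates missing; run map_hits_to_genomic() first")
  curated |>
    dplyr::arrange(.data$accession, .data$nt_start, .data$nt_end, .data$profile) |>
    dplyr::group_by(.data$accession) |>
    dplyr::mutate(order_index = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
}

#' Build domain neighborhoods around domains of interest
#'
#' Every occurrence of a domain of interest (DOI) becomes the center of a
#' neighborhood; the members are the domains whose ordered-domain rank lies
#' within `radius` of the center's, with
#' `signed_distance = order_index - center order_index` (upstream negative,
#' downstream positive; the center itself sits at 0). Distances count
#' domains, not nucleotides. Genomes lacking the DOI contribute no
#' neighborhoods; neighborhoods at a genome edge are truncated, never wrapped.
#'
#' @param ordered Output of [order_domains()].
#' @param doi Domain-of-interest selector: profile name(s), or clan name(s)
#'   with `by = "clan"`.
#' @param radius Maximum |signed_distance| included (default 10).
#' @param by Match `doi` against `"profile"` (default) or `"clan"`.
#' @return A long tibble, one row per (neighborhood, member): `neighborhood`
#'   (identifier `<accession>@<center order_index>`), `accession`,
#'   `center_profile`, `center_adj_evalue`, member `profile`, `clan`,
#'   `source_db`, `signed_distance`, `nt_start`, `nt_end`, `strand`.
#' @export
build_neighborhoods <- function(ordered, doi, radius = 10, by = c("profile", "clan")) {
  by <- match.arg(by)
  if (radius < 1) abort("radius must be >= 1")
  if (nrow(ordered) == 0) return(empty_neighborhoods())
  centers <- ordered[!is.na(ordered[[by]]) & ordered[[by]] %in% doi, , drop = FALSE]
  if (nrow(centers) == 0) return(empty_neighborhoods())
  nb <- purrr::pmap(list(centers$accession, centers$order_index,
                         centers$profile, centers$adj_evalue),
    function(acc, center_idx, center_profile, center_e) {
      g <- ordered[ordered$accession == acc, , drop = FALSE]
      m <- g[abs(g$order_index - center_idx) <= radius, , drop = FALSE]
      tibble(
        neighborhood = paste0(acc, "@", center_idx),
        accession = acc,
        center_profile = center_profile,
        center_adj_evalue = center_e,
        profile = m$profile,
        clan = m$clan,
        source_db = m$source_db,
        signed_distance = m$order_index - center_idx,
        adj_evalue = m$adj_evalue,
        nt_start = m$nt_start,
        nt_end = m$nt_end,
        strand = m$strand
      )
    })
  dplyr::bind_rows(nb)
}

empty_neighborhoods <- function() {
  tibble(neighborhood = character(), accession = character(),
         center_profile = character(), center_adj_evalue = double(),
         profile = character(), clan = character(), source_db = character(),
         signed_distance = integer(), adj_evalue = double(),
         nt_start = integer(), nt_end = integer(), strand = character())
}

#' Inverse-square distance weight
#'
#' The weight of a neighborhood member at signed ordered-domain distance `d`
#' is `1 / d^2`: the nearest neighbours score `1/1^2 = 1` and a domain four
#' positions away scores `1/4^2 = 0.0625`. The center itself (distance 0)
#' contributes 1 by convention, and a clan absent from a row scores 0
#' (equivalent to an infinite distance).
#'
#' @param distance Signed ordered-domain distance(s).
#' @return Weight(s) in `(0, 1]`.
#' @examples
#' inv_sq_weight(c(-4, -1, 0, 1, 4))
#' @export
inv_sq_weight <- function(distance) {
  1 / pmax(abs(distance), 1)^2
}

#' Clan-keyed inverse-square-distance feature matrix
#'
#' Turns neighborhoods into the matrix used for clustering: one row per
#' neighborhood (or per genome), one column per clan (profiles without a clan
#' key by profile name), with each cell the inverse-square-distance weight of
#' that key's occurrence(s) in the row — `reduce = "max"` keeps the nearest
#' occurrence, `reduce = "sum"` accumulates all of them. Keys never observed
#' in a row are 0.
#'
#' @param neighborhoods Long tibble from [build_neighborhoods()].
#' @param key Column the features are keyed by: `"clan"` (default; falls back
#'   to the profile name where clan is missing) or `"profile"`.
#' @param reduce `"max"` (default) or `"sum"` over multiple occurrences.
#' @param rows `"neighborhood"` (default) for one row per DOI occurrence, or
#'   `"genome"` to keep only the best-scoring (smallest center adjusted
#'   E-value) neighborhood of each genome.
#' @return A wide tibble whose first column `row` identifies the
#'   neighborhood/genome and whose remaining columns are key weights in
#'   `[0, 1]` for `reduce = "max"` (sums may exceed 1).
#' @export
build_feature_matrix <- function(neighborhoods, key = c("clan", "profile"),
                                 reduce = c("max", "sum"),
                                 rows = c("neighborhood", "genome")) {
  key <- match.arg(key)
  reduce <- match.arg(reduce)
  rows <- match.arg(rows)
  if (nrow(neighborhoods) == 0) abort("no neighborhoods to featurise")
  nb <- neighborhoods
  if (rows == "genome") {
    best <- nb |>
      dplyr::distinct(.data$accession, .data$neighborhood, .data$center_adj_evalue) |>
      dplyr::group_by(.data$accession) |>
      dplyr::arrange(.data$center_adj_evalue, .data$neighborhood, .by_group = TRUE) |>
      dplyr::slice_head(n = 1) |>
      dplyr::ungroup()
    nb <- nb[nb$neighborhood %in% best$neighborhood, , drop = FALSE]
    nb$row <- nb$accession
  } else {
    nb$row <- nb$neighborhood
  }
  nb$feature_key <- if (key == "clan") dplyr::coalesce(nb$clan, nb$profile) else nb$profile
  nb$w <- inv_sq_weight(nb$signed_distance)
  agg <- nb |>
    dplyr::group_by(.data$row, .data$feature_key) |>
    dplyr::summarise(w = if (reduce == "max") max(.data$w) else sum(.data$w),
                     .groups = "drop")
  agg |>
    tidyr::pivot_wider(names_from = "feature_key", values_from = "w",
                       values_fill = 0, names_sort = TRUE) |>
    dplyr::arrange(.data$row)
}

#' Mosaic weights: summed co-proximity with the domain of interest
#'
#' Aggregates all neighborhoods together, summing the inverse-square-distance
#' weight of every occurrence of each key; large values mark domains that
#' are conserved partners of the domain of interest. This is the quantity a
#' mosaic plot tiles by.
#'
#' @param neighborhoods Long tibble from [build_neighborhoods()].
#' @param key `"profile"` (default) or `"clan"`.
#' @param drop_center Drop the center occurrences themselves (distance 0),
#'   default `TRUE` so the DOI does not dominate its own mosaic.
#' @return A tibble `key`, `weight` sorted by decreasing weight.
#' @export
mosaic_weights <- function(neighborhoods, key = c("profile", "clan"),
                           drop_center = TRUE) {
  key <- match.arg(key)
  if (nrow(neighborhoods) == 0)
    return(tibble(key = character(), weight = double()))
  nb <- neighborhoods
  if (drop_center) nb <- nb[nb$signed_distance != 0, , drop = FALSE]
  if (nrow(nb) == 0) return(tibble(key = character(), weight = double()))
  nb$feature_key <- if (key == "clan") dplyr::coalesce(nb$clan, nb$profile) else nb$profile
  nb |>
    dplyr::mutate(w = inv_sq_weight(.data$signed_distance)) |>
    dplyr::group_by(key = .data$feature_key) |>
    dplyr::summarise(weight = sum(.data$w), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$key)
}

#' Hierarchical clustering of feature-matrix rows
#'
#' Agglomerative clustering of the rows of an inverse-square-distance feature
#' matrix, so genomes or neighborhoods with similar domain patterns end up on
#' adjacent branches. Deterministic given the matrix.
#'
#' @param m A feature matrix tibble from [build_feature_matrix()] (first
#'   column `row`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param metric Distance metric for [stats::dist()] (default `"euclidean"`).
#' @param k Number of flat clusters to cut, or `NULL`.
#' @param h Cut height, used when `k` is `NULL`; when both are `NULL`,
#'   `k = 2`.
#' @return A `domain_clust` object: list with `hclust`, `labels` (tibble
#'   `row`, `cluster`), `k`, `linkage`, `metric`. Supports [generics::tidy()],
#'   [generics::glance()], [ggplot2::autoplot()] and [write_dendrogram()].
#' @export
cluster_rows <- function(m, linkage = "average", metric = "euclidean",
                         k = NULL, h = NULL) {
  if (nrow(m) < 2) abort("clustering needs at least 2 rows")
  x <- as.matrix(m[, -1, drop = FALSE])
  rownames(x) <- m$row
  hc <- stats::hclust(stats::dist(x, method = metric), method = linkage)
  if (is.null(k) && is.null(h)) k <- 2L
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  structure(list(
    hclust = hc,
    labels = tibble(row = m$row, cluster = unname(labels[m$row])),
    k = length(unique(labels)),
    linkage = linkage,
    metric = metric,
    n_features = ncol(x)
  ), class = "domain_clust")
}

#' @export
print.domain_clust <- function(x, ...) {
  cat(sprintf("<domain_clust> %d rows x %d features, %s linkage / %s distance, %d clusters\n",
              nrow(x$labels), x$n_features, x$linkage, x$metric, x$k))
  invisible(x)
}

#' Tidy a domain clustering
#'
#' @param x A `domain_clust` from [cluster_rows()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per clustered item (`row`,
#'   `cluster`); `glance()`: a one-row tibble with `n_rows`, `n_features`,
#'   `k`, `linkage`, `metric`, `height_max`.
#' @export
tidy.domain_clust <- function(x, ...) x$labels

#' @rdname tidy.domain_clust
#' @export
glance.domain_clust <- function(x, ...) {
  tibble(n_rows = nrow(x$labels), n_features = x$n_features, k = x$k,
         linkage = x$linkage, metric = x$metric,
         height_max = max(x$hclust$height))
}

#' Write a dendrogram as Newick
#'
#' @param x A `domain_clust` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(x, path) {
  ape::write.tree(ape::as.phylo(x$hclust), file = path)
  invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie chance-corrected agreement between two partitions of the
#' same items: 1 for identical partitions (up to label names), about 0 for
#' independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return A number in `[-1, 1]`.
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    abort("label vectors must have equal length")
  n <- length(labels_a)
  if (n == 0) abort("empty labelings")
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  total <- ch2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_index - expected)
}

#' Cluster-vs-taxonomy contingency matrix, scaled per cluster
#'
#' Cross-tabulates cluster assignments against taxonomy families and divides
#' each cluster's row by its maximum, so every row's dominant family scores
#' exactly 1. Clusters containing a single family produce an identity-like
#' pattern.
#'
#' @param labels Cluster ids.
#' @param families Taxonomy labels, same length.
#' @return A numeric matrix (clusters x families) with values in `[0, 1]` and
#'   each row's maximum equal to 1.
#' @export
contingency_scaled <- function(labels, families) {
  if (length(labels) != length(families)) abort("label vectors must have equal length")
  if (length(labels) == 0) abort("empty input")
  tab <- unclass(table(labels, families))
  sweep(tab, 1, apply(tab, 1, max), "/")
}

#' Write neighborhoods in long "domain spacing" format
#'
#' One row per (neighborhood, member) with the key, signed ordered-domain
#' distance and inverse-square weight — the machine-readable spacing table.
#'
#' @param neighborhoods Long tibble from [build_neighborhoods()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_spacing <- function(neighborhoods, path) {
  out <- neighborhoods |>
    dplyr::mutate(weight = inv_sq_weight(.data$signed_distance)) |>
    dplyr::select("neighborhood", "accession", "center_profile", "profile",
                  "clan", "source_db", "signed_distance", "weight",
                  "nt_start", "nt_end", "strand")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
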