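# minimal ordered-domain fixture: profiles at given genomic starts
ordered_fixture <- function(profiles, nt_start, clan = NA_character_,
                            strand = "+", accession = "G1", adj = 1e-12) {
  h <- tibble::tibble(
    profile = profiles, clan = rep_len(clan, length(profiles)),
    source_db = "PFAM", accession = rep_len(accession, length(profiles)),
    frame = 1L, search_mode = "window",
    target_id = paste0(accession, "|frame1|win0|start0"),
    searched_length = 200L, ali_start = 1L, ali_end = 50L,
    env_start = 1L, env_end = 50L, hmm_from = 1L, hmm_to = 50L, qlen = 50L,
    bit_score = 100, i_evalue = rep_len(adj, length(profiles)),
    adj_evalue = rep_len(adj, length(profiles)),
    nt_start = as.integer(nt_start), nt_end = as.integer(nt_start) + 149L,
    strand = rep_len(strand, length(profiles)),
    kept = TRUE, removal_reason = "none"
  )
  order_domains(h)
}

test_that("domains are ordered along the genome with strands interleaved", {
  o <- ordered_fixture(c("A", "B", "C"), c(10, 200, 50),
                       strand = c("+", "-", "+"))
  expect_equal(o$profile, c("A", "C", "B"))
  expect_equal(o$order_index, 0:2)
  expect_equal(nrow(order_domains(ordered_fixture(character(), integer()))), 0)
})

test_that("neighborhoods carry signed ordered-domain distances around each DOI", {
  o <- ordered_fixture(c("A", "B", "C", "D"), c(10, 200, 400, 600))
  nb <- build_neighborhoods(o, "B", radius = 2)
  expect_equal(nb$profile, c("A", "B", "C", "D"))
  expect_equal(nb$signed_distance, c(-1L, 0L, 1L, 2L))

  # DOI at the edge: truncated, no wraparound
  nb_a <- build_neighborhoods(o, "A", radius = 2)
  expect_equal(nb_a$signed_distance, 0:2)

  # duplicated DOI: one neighborhood per occurrence
  o2 <- ordered_fixture(c("A", "X", "A"), c(10, 200, 400))
  expect_equal(length(unique(build_neighborhoods(o2, "A", radius = 1)$neighborhood)), 2)

  # absent DOI: empty result, not an error
  expect_equal(nrow(build_neighborhoods(o, "ZZ", radius = 2)), 0)
  expect_error(build_neighborhoods(o, "B", radius = 0), "radius")
})

test_that("neighborhood distances are antisymmetric between mutual centers", {
  o <- ordered_fixture(c("A", "B", "C", "D", "E"), c(1, 100, 300, 500, 900))
  nb <- build_neighborhoods(o, c("B", "D"), radius = 4)
  d_b_d <- nb$signed_distance[nb$center_profile == "B" & nb$profile == "D"]
  d_d_b <- nb$signed_distance[nb$center_profile == "D" & nb$profile == "B"]
  expect_equal(d_b_d, -d_d_b)
})

test_that("inverse-square weights match the printed reference values", {
  expect_equal(inv_sq_weight(4), 0.0625)
  expect_equal(inv_sq_weight(1), 1)
  expect_equal(inv_sq_weight(-4), 0.0625)
  expect_equal(inv_sq_weight(0), 1)  # the center's own contribution
})

test_that("feature matrix keys by clan with inverse-square values and 0 for absences", {
  o <- ordered_fixture(c("DOI", "N1", "N2", "N3", "N4"),
                       c(1, 200, 400, 600, 800),
                       clan = c("CL0", "CLA", "CLB", "CLC", "CLD"))
  m <- build_feature_matrix(build_neighborhoods(o, "DOI", radius = 4))
  expect_equal(m$CLD, 0.0625)  # 4 domains away
  expect_equal(m$CLA, 1)       # nearest neighbor
  expect_equal(m$CL0, 1)       # the center clan anchors the row

  # a clan occurring at distances 2 and 3: max-reduce keeps the nearest
  o2 <- ordered_fixture(c("DOI", "N1", "P", "P2"), c(1, 200, 400, 600),
                        clan = c("CL0", "CLA", "CLP", "CLP"))
  nb2 <- build_neighborhoods(o2, "DOI", radius = 3)
  expect_equal(build_feature_matrix(nb2, reduce = "max")$CLP, 0.25)
  expect_equal(build_feature_matrix(nb2, reduce = "sum")$CLP, 0.25 + 1 / 9)

  # absent clan: the column exists for other rows and is 0 here
  o3 <- ordered_fixture(c("DOI", "N1"), c(1, 200), clan = c("CL0", "CLZ"),
                        accession = "G2")
  m2 <- build_feature_matrix(dplyr::bind_rows(
    build_neighborhoods(o, "DOI", radius = 4),
    build_neighborhoods(o3, "DOI", radius = 4)))
  expect_equal(m2$CLZ[m2$row == "G1@0"], 0)
  expect_equal(m2$CLA[m2$row == "G2@0"], 0)

  # identical genomes produce identical rows; all max-values within [0, 1]
  expect_true(all(as.matrix(m2[, -1]) >= 0 & as.matrix(m2[, -1]) <= 1))
  o_dup <- ordered_fixture(c("DOI", "N1"), c(1, 200), clan = c("CL0", "CLZ"),
                           accession = "G3")
  m3 <- build_feature_matrix(dplyr::bind_rows(
    build_neighborhoods(o3, "DOI", radius = 4),
    build_neighborhoods(o_dup, "DOI", radius = 4)))
  expect_equal(unlist(m3[1, -1]), unlist(m3[2, -1]))
})

test_that("mosaic weights sum inverse-square distances over all neighborhoods", {
  o <- ordered_fixture(c("P", "DOI", "X", "P"), c(1, 200, 600, 900))
  nb <- build_neighborhoods(o, "DOI", radius = 2)
  w <- mosaic_weights(nb)
  expect_equal(w$weight[w$key == "P"], 1 + 0.25)
  expect_equal(nrow(mosaic_weights(nb[0, ])), 0)

  # a profile flanking every DOI at distance 1 dominates the mosaic
  nbs <- dplyr::bind_rows(lapply(1:4, function(i) {
    o_i <- ordered_fixture(c("FLANK", "DOI", sprintf("OTHER%d", i)),
                           c(1, 200, 400), accession = paste0("G", i))
    build_neighborhoods(o_i, "DOI", radius = 2)
  }))
  w2 <- mosaic_weights(nbs)
  expect_equal(w2$key[1], "FLANK")
})

test_that("hierarchical clustering separates identical rows from orthogonal ones", {
  m <- tibble::tibble(row = c("r1", "r2", "r3"),
                      a = c(1, 1, 0), b = c(0.25, 0.25, 0), c = c(0, 0, 1))
  cl <- cluster_rows(m, k = 2)
  lab <- tidy(cl)
  expect_equal(lab$cluster[lab$row == "r1"], lab$cluster[lab$row == "r2"])
  expect_false(lab$cluster[lab$row == "r1"] == lab$cluster[lab$row == "r3"])
  expect_identical(tidy(cluster_rows(m, k = 2)), lab)  # deterministic
  expect_error(cluster_rows(m[1, ]), "at least 2 rows")

  g <- glance(cl)
  expect_equal(g$n_rows, 3)
  expect_equal(g$k, 2)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(cl, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, m$row)
  expect_s3_class(autoplot(cl), "ggplot")
})

test_that("adjusted Rand index matches exhaustive pair counting and is 1/0-calibrated", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2, 3, 3), c(1, 1, 1, 2, 2, 2)),
               oracle_ari(c(1, 1, 2, 2, 3, 3), c(1, 1, 1, 2, 2, 2)))
  set.seed(12)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    la <- sample(1:3, n, replace = TRUE)
    lb <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand(la, lb), oracle_ari(la, lb), tolerance = 1e-12)
    m_ari <- mclust::adjustedRandIndex(la, lb)
    if (is.finite(m_ari))  # mclust yields NaN on degenerate one-cluster cases
      expect_equal(adjusted_rand(la, lb), m_ari, tolerance = 1e-12)
  }
  expect_error(adjusted_rand(1:3, 1:4), "equal length")
})

test_that("ARI of independent random labelings is centred on zero", {
  set.seed(2024)
  vals <- replicate(1000, {
    adjusted_rand(sample(1:3, 30, replace = TRUE), sample(1:3, 30, replace = TRUE))
  })
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("contingency matrix scales each cluster row to its maximum", {
  m <- contingency_scaled(c(1, 1, 1, 1, 2, 2), c("a", "a", "a", "b", "b", "b"))
  expect_equal(unname(m), rbind(c(1, 1 / 3), c(0, 1)))
  expect_true(all(apply(m, 1, max) == 1))

  pure <- contingency_scaled(c(1, 1, 2, 2), c("x", "x", "y", "y"))
  expect_equal(unname(pure), rbind(c(1, 0), c(0, 1)))
  expect_error(contingency_scaled(integer(), character()), "empty")
  expect_error(contingency_scaled(1:3, 1:2), "equal length")
})
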