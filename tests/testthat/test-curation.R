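test_that("E-value adjustment rescales window hits to the frame search space", {
  expect_equal(adjust_evalue(1e-10, 200, 10000, 1, "window"), 5e-9)
  expect_equal(adjust_evalue(3e-4, 200, 10000, 1, "genome"), 3e-4)
  expect_equal(adjust_evalue(0.5, 200, 200, 1, "window"), 0.5)
  expect_equal(adjust_evalue(1e-6, 200, 1000, 10, "window"), 1e-6 / 10 * 5)
  expect_error(adjust_evalue(0, 200, 1000), "positive")
  expect_error(adjust_evalue(1e-5, 0, 1000), ">= 1")
})

test_that("adjust_evalues joins frame lengths onto the hit table", {
  h <- make_hits(c(10, 10), c(60, 60), c(1e-10, 1e-10))
  h$adj_evalue <- NA_real_
  h$search_mode <- c("window", "genome")
  frames <- tibble::tibble(accession = "G1", frame = 1L, aa_length = 2000L)
  a <- adjust_evalues(h, frames, n_targets = 1)
  expect_equal(a$adj_evalue, c(1e-10 * 2000 / 200, 1e-10))
  expect_error(adjust_evalues(dplyr::mutate(h, accession = "other"), frames),
               "no frame length")
})

test_that("the E <= 1 exclusion drops exactly the hits above threshold", {
  h <- make_hits(c(1, 50, 100), c(40, 90, 140), c(0.99, 1.0, 1.01))
  f <- filter_hits(h)
  expect_equal(f$adj_evalue, c(0.99, 1.0))
  expect_equal(nrow(filter_hits(h[0, ])), 0)
  set.seed(1)
  h10 <- make_hits(seq(1, 500, length.out = 10), seq(40, 540, length.out = 10),
                   c(runif(4, 1.5, 9), runif(6, 0, 0.9)))
  expect_equal(nrow(filter_hits(h10)), 6)
})

test_that("100%-overlapping window duplicates collapse to the best single copy", {
  h <- make_hits(c(20, 20, 20), c(80, 80, 80), c(1e-9, 1e-12, 1e-10),
                 profile = rep("DOM", 3))
  p <- prune_exact_duplicates(h)
  expect_equal(sum(p$kept), 1)
  expect_equal(p$adj_evalue[p$kept], 1e-12)
  expect_equal(p$removal_reason[!p$kept], rep("duplicate", 2))

  h2 <- make_hits(c(20, 20), c(80, 81), 1e-9, profile = c("DOM", "DOM"))
  expect_equal(sum(prune_exact_duplicates(h2)$kept), 2)
  expect_equal(sum(prune_exact_duplicates(h[1, ])$kept), 1)
})

test_that("overlap fraction is intersection over the shorter effective interval", {
  h <- make_hits(c(1, 61), c(100, 160), c(1e-9, 1e-9))
  expect_equal(overlap_fraction(h[1, ], h[1, ]), 1.0)
  expect_equal(overlap_fraction(h[1, ], h[2, ]), 0.40)
  far <- make_hits(c(1, 500), c(100, 600), c(1e-9, 1e-9))
  expect_equal(overlap_fraction(far[1, ], far[2, ]), 0)
  other_frame <- make_hits(61, 160, 1e-9, frame = 4)
  expect_error(overlap_fraction(h[1, ], other_frame), "per \\(accession, frame\\)")
  # calculated start: up to 20 aa upstream, bounded by missing profile start
  expect_equal(calc_start(50, 1), 50L)
  expect_equal(calc_start(50, 10), 41L)
  expect_equal(calc_start(50, 100), 30L)
  expect_equal(calc_start(5, 100), 1L)
  nested <- make_hits(c(1, 40), c(200, 60), c(1e-9, 1e-9))  # small inside large
  expect_equal(overlap_fraction(nested[1, ], nested[2, ]), 1.0)
})

test_that("same-clan overlaps >= 33% drop the worse hit", {
  h <- make_hits(c(1, 51), c(100, 150), c(1e-20, 1e-5), clan = "CL1")
  d <- deoverlap(h)
  expect_equal(d$kept, c(TRUE, FALSE))
  expect_equal(d$removal_reason[2], "same_clan_overlap")
  # below the threshold both survive: overlap 32/100
  h2 <- make_hits(c(1, 69), c(100, 168), c(1e-20, 1e-5), clan = "CL1")
  expect_true(all(deoverlap(h2)$kept))
})

test_that("different-clan pairs keep both significant hits, else apply the 45%/10^4 rule", {
  both_sig <- make_hits(c(1, 21), c(100, 120), c(1e-12, 1e-12), clan = c("C1", "C2"))
  expect_true(all(deoverlap(both_sig)$kept))  # overlap 0.80 but both significant

  one_weak <- make_hits(c(1, 41), c(100, 140), c(1e-12, 1e-4), clan = c("C1", "C2"))
  d <- deoverlap(one_weak)  # overlap 0.60, ratio 1e8 > 1e4
  expect_equal(d$kept, c(TRUE, FALSE))
  expect_equal(d$removal_reason[2], "diff_clan_overlap")

  small_ratio <- make_hits(c(1, 41), c(100, 140), c(1e-6, 1e-4), clan = c("C1", "C2"))
  expect_true(all(deoverlap(small_ratio)$kept))  # ratio 100 < 1e4: keep both
})

test_that("vFAM/pVOG hits overlapping PFAM survive only past the 5x log10 boundary", {
  h <- make_hits(c(1, 41), c(100, 140), c(1e-20, 1e-10),
                 clan = c(NA, "CP"), source_db = c("VFAM", "PFAM"))
  d <- deoverlap(h)  # log10: -20 vs 5 * -10 = -50 -> vFAM removed
  expect_equal(d$kept, c(FALSE, TRUE))
  expect_equal(d$removal_reason[1], "db_precedence")

  h2 <- make_hits(c(1, 41), c(100, 140), c(1e-60, 1e-10),
                  clan = c(NA, "CP"), source_db = c("VFAM", "PFAM"))
  expect_true(all(deoverlap(h2)$kept))  # -60 < -50 -> kept

  h3 <- make_hits(c(1, 41), c(100, 140), c(1e-50, 1e-10),
                  clan = c(NA, "CP"), source_db = c("PVOG", "PFAM"))
  expect_equal(deoverlap(h3)$kept, c(FALSE, TRUE))  # equality favours PFAM
})

test_that("hits in different frames never compete (double coding preserved)", {
  h <- dplyr::bind_rows(
    make_hits(10, 100, 1e-20, clan = "CL1", frame = 1),
    make_hits(10, 100, 1e-3, clan = "CL1", frame = 4)
  )
  expect_true(all(deoverlap(h)$kept))
})

test_that("de-overlap matches the all-pairs brute-force oracle on chain instances", {
  set.seed(42)
  for (rep in 1:300) {
    inst <- random_chain_instance(6)
    impl <- deoverlap(inst)
    orac <- oracle_deoverlap(inst)
    expect_equal(kept_ids(impl), kept_ids(orac))
  }
})

test_that("de-overlap is idempotent and invariant to input permutation", {
  set.seed(99)
  for (rep in 1:200) {
    inst <- random_chain_instance(6)
    d1 <- deoverlap(inst)
    d2 <- deoverlap(d1[d1$kept, ])
    expect_equal(kept_ids(d2), kept_ids(d1))
    perm <- inst[sample(nrow(inst)), ]
    expect_equal(kept_ids(deoverlap(perm)), kept_ids(d1))
  }
})

test_that("improving a kept hit's E-value never gets it removed", {
  set.seed(7)
  for (rep in 1:50) {
    inst <- random_chain_instance(5)
    d <- deoverlap(inst)
    kept <- which(d$kept)
    if (length(kept) == 0) next
    i <- kept[sample.int(length(kept), 1)]
    better <- inst
    better$adj_evalue[better$profile == d$profile[i]] <- d$adj_evalue[i] / 1e6
    d2 <- deoverlap(better)
    expect_true(d2$kept[d2$profile == d$profile[i]])
  }
})

test_that("curate_hits chains adjustment, filtering, dedup and de-overlap", {
  sim <- generate_genomes(demo_architectures(decoy_rate = 0.8), n_per_family = 2,
                          seed = 31)
  frames <- six_frame_translate(sim$genomes)
  tbl <- generate_hit_table(sim, seed = 31)
  hits <- parse_domtblout(tbl, sim$profile_meta)
  cur <- curate_hits(hits, frames)
  expect_true(all(cur$kept == (cur$removal_reason == "none")))
  # decoys carry near-threshold E-values: none is ever significant
  decoy <- cur$kept & grepl("^DECOY", cur$profile)
  expect_true(all(cur$adj_evalue[decoy] > curation_params()$significance_threshold))
  # every planted hit survives curation
  expect_true(all(
    paste(sim$placements$accession, sim$placements$profile) %in%
      paste(cur$accession[cur$kept], cur$profile[cur$kept])))
})
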