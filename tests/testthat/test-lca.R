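test_that("hit filtering enforces the e-value and coverage bounds inclusively", {
  hits <- dplyr::bind_rows(
    hit_row(subject = "g1", identity = 96, evalue = 1e-5, aln = 790, slen = 1000),
    hit_row(subject = "g2", identity = 96, evalue = 1e-5, aln = 800, slen = 1000),
    hit_row(subject = "g3", identity = 96, evalue = 2e-5, aln = 900, slen = 1000)
  )
  kept <- filter_hits(hits, lca_params())
  expect_equal(kept$subject_id, "g2")  # 0.79 coverage out, 1e-5 e-value in
  expect_equal(nrow(filter_hits(hits[0, ], lca_params())), 0)
})

test_that("coverage filtering without subject lengths is an explicit error", {
  hits <- hit_row(subject = "g1", identity = 96)
  hits$subject_length <- NULL
  expect_error(filter_hits(hits, lca_params()), "subject_length")
  expect_equal(nrow(filter_hits(hits, lca_params(coverage_min = NULL))), 1)
})

test_that("single strong hit assigns at species; weak identities lift the rank", {
  lin <- fixture_lineages()
  a <- assign_lca(hit_row(subject = "g1", identity = 96), lin)
  expect_equal(a$assignment_rank, "species")
  expect_equal(a$species, "Pseudomonas stutzeri")

  a <- assign_lca(hit_row(subject = "g1", identity = 88), lin)
  expect_equal(a$assignment_rank, "genus")
  expect_true(is.na(a$species))

  a <- assign_lca(hit_row(subject = "g1", identity = 70), lin)
  expect_equal(a$assignment_rank, "phylum")
  expect_equal(a$phylum, "Proteobacteria")

  a <- assign_lca(hit_row(subject = "g1", identity = 60), lin)
  expect_equal(a$assignment_rank, "unassigned")
})

test_that("tied best hits resolve by lowest common ancestor", {
  lin <- fixture_lineages()
  hits <- dplyr::bind_rows(
    hit_row(subject = "g1", identity = 96, bitscore = 500),
    hit_row(subject = "g2", identity = 96, bitscore = 500)
  )
  a <- assign_lca(hits, lin)
  expect_equal(a$assignment_rank, "genus")  # same genus, different species
  expect_equal(a$genus, "Pseudomonas")

  # cross-phylum tie collapses to domain
  hits <- dplyr::bind_rows(
    hit_row(subject = "g1", identity = 96, bitscore = 500),
    hit_row(subject = "g4", identity = 96, bitscore = 500)
  )
  expect_equal(assign_lca(hits, lin)$assignment_rank, "domain")

  # a lower-score hit does not participate in the LCA
  hits <- dplyr::bind_rows(
    hit_row(subject = "g1", identity = 96, bitscore = 500),
    hit_row(subject = "g4", identity = 96, bitscore = 400)
  )
  expect_equal(assign_lca(hits, lin)$assignment_rank, "species")
})

test_that("queries without hits and unknown subjects are handled", {
  lin <- fixture_lineages()
  a <- assign_lca(hit_row(subject = "g1", identity = 96), lin, query_ids = c("q1", "q9"))
  expect_equal(a$assignment_rank, c("species", "unassigned"))
  expect_error(assign_lca(hit_row(subject = "gX", identity = 96), lin), "gX")
})

test_that("assign_lca matches the brute-force oracle on random small instances", {
  lin <- nested_lineages(16)
  withr::local_seed(402)
  for (rep in 1:40) {
    n_hits <- sample(1:10, 1)
    hits <- tibble::tibble(
      query_id = "q",
      subject_id = sample(lin$subject_id, n_hits, replace = TRUE),
      pct_identity = round(runif(n_hits, 55, 100), 1),
      aln_length = 900,
      evalue = 1e-30,
      bitscore = sample(c(300, 400, 500), n_hits, replace = TRUE),
      subject_length = 1000
    )
    got <- assign_lca(hits, lin)
    want <- oracle_lca(hits, lin)
    expect_equal(got$assignment_rank, want$rank)
    expect_equal(unname(unlist(got[RANKS])), want$lineage)
  }
})

test_that("raising identity thresholds never deepens an assignment", {
  lin <- nested_lineages(16)
  withr::local_seed(403)
  depth_of <- function(rank) if (rank == "unassigned") 0 else match(rank, RANKS)
  for (rep in 1:20) {
    n_hits <- sample(1:6, 1)
    hits <- tibble::tibble(
      query_id = "q", subject_id = sample(lin$subject_id, n_hits),
      pct_identity = round(runif(n_hits, 55, 100), 1), aln_length = 900,
      evalue = 1e-30, bitscore = 500, subject_length = 1000
    )
    d1 <- depth_of(assign_lca(hits, lin, lca_params())$assignment_rank)
    d2 <- depth_of(assign_lca(hits, lin,
                              lca_params(identity_species = 98, identity_genus = 90,
                                         identity_phylum = 75))$assignment_rank)
    expect_lte(d2, d1)
  }
})

test_that("low-abundance OTU filtering is inclusive at the threshold", {
  tbl <- as_abundance_tbl(matrix(c(50, 50, 51, 50, 100, 0), nrow = 3, byrow = TRUE,
                                 dimnames = list(c("o1", "o2", "o3"), c("s1", "s2"))))
  kept <- filter_low_abundance_otus(tbl)
  expect_equal(kept$feature_id, "o2")  # totals 100, 101, 100 -> only 101 kept
  expect_warning(empty <- filter_low_abundance_otus(tbl[c(1, 3), ]), "empty")
  expect_equal(nrow(empty), 0)
})
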