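test_that("assembly statistics follow the standard conventions", {
  one <- assembly_stats(c(c1 = "GGCC"))
  expect_equal(one$n_contigs, 1)
  expect_equal(one$total_length, 4)
  expect_equal(one$gc_percent, 100)

  two <- assembly_stats(c(c1 = "AT", c2 = "GC"))
  expect_equal(two$gc_percent, 50)
  expect_equal(two$n50, 2)

  # ambiguity codes drop out of both numerator and denominator
  amb <- assembly_stats(c(c1 = "ATGCN"))
  expect_equal(amb$gc_percent, 50)
  expect_equal(amb$total_length, 5)

  expect_error(assembly_stats(character()),
               class = "nitrosponge_validation_error")
  expect_error(assembly_stats(c(ok = "ACGT", bad = "ACXT")), "bad",
               class = "nitrosponge_validation_error")
})

test_that("total assembly length matches an independent FASTA parser", {
  sim <- simulate_genome_pair(5, 95, seed = 3, gene_length = 400)
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">contig_a", sim$genome_a), fa)
  stats <- assembly_stats(fa)
  oracle_len <- sum(Biostrings::width(Biostrings::readDNAStringSet(fa)))
  expect_equal(stats$total_length, oracle_len)
  unlink(fa)
})

test_that("AAI is the length-weighted mean identity over reciprocal best hits", {
  mk <- function(q, s, id, ql) {
    tibble::tibble(query = q, subject = s, identity = id,
                   align_length = ql, bitscore = id * ql,
                   query_length = ql, subject_length = ql)
  }
  ab <- mk(c("a1", "a2", "a3"), c("b1", "b2", "b3"),
           c(50, 60, 70), c(100, 200, 300))
  ba <- mk(c("b1", "b2", "b3"), c("a1", "a2", "a3"),
           c(50, 60, 70), c(100, 200, 300))
  out <- aai(ab, ba)
  expect_equal(out$aai, 190 / 3, tolerance = 1e-9)
  expect_equal(out$n_bbh, 3L)
  expect_equal(out$aai_unweighted, 60)

  # a pair covering only 65% of the query is dropped by the 70% filter
  ab_short <- ab; ab_short$align_length[1] <- 65
  out2 <- aai(ab_short, ba)
  expect_equal(out2$n_bbh, 2L)
  expect_equal(out2$aai, (60 * 200 + 70 * 300) / 500)

  # no survivors is an explicit error
  ab_none <- ab; ab_none$align_length <- 10
  expect_error(aai(ab_none, ba), class = "nitrosponge_no_bbh")
})

test_that("AAI equals the exhaustive brute-force oracle on random tables", {
  for (s in 1:25) {
    tabs <- random_hit_tables(n_genes = sample(5:20, 1), seed = 7000 + s)
    oracle <- oracle_aai(tabs$ab, tabs$ba)
    if (oracle$n == 0) {
      expect_error(aai(tabs$ab, tabs$ba), class = "nitrosponge_no_bbh")
    } else {
      got <- aai(tabs$ab, tabs$ba)
      expect_equal(got$aai, oracle$aai, tolerance = 1e-12)
      expect_equal(got$n_bbh, oracle$n)
    }
  }
})

test_that("genome fragmentation yields half-open non-overlapping windows", {
  frags <- fragment_genome(c(ctg = strrep("A", 2500)), width = 1020)
  expect_equal(length(frags), 2)
  expect_identical(names(frags), c("ctg:0-1020", "ctg:1020-2040"))
  expect_true(all(nchar(frags) == 1020))

  expect_length(fragment_genome(c(ctg = strrep("A", 900)), width = 1020), 0)

  # conservation: total fragment length is width * floor(L / width) per contig
  lens <- c(a = 3333, b = 1020, c = 999)
  contigs <- vapply(lens, function(n) strrep("G", n), character(1))
  frags2 <- fragment_genome(contigs, width = 1020)
  expect_equal(sum(nchar(frags2)), sum(1020 * (lens %/% 1020)))
})

test_that("fragment ANI reports mean identity and aligned fraction", {
  mk <- function(q, s, id, n, w = 1020) {
    tibble::tibble(query = q, subject = s, identity = id,
                   align_length = w, bitscore = id * w,
                   query_length = w, subject_length = w)
  }
  ids_a <- sprintf("a:%d-%d", 0:9 * 1020, 1:10 * 1020)
  ids_b <- sprintf("b:%d-%d", 0:9 * 1020, 1:10 * 1020)
  ab <- mk(ids_a, ids_b, 100, 10)
  ba <- mk(ids_b, ids_a, 100, 10)
  out <- ani_fragment(ab, ba, smaller_genome_length = 10 * 1020)
  expect_equal(out$ani, 100)
  expect_equal(out$aligned_fraction, 1)

  # half the fragments unmapped -> aligned fraction 0.5
  out_half <- ani_fragment(ab[1:5, ], ba[1:5, ],
                           smaller_genome_length = 10 * 1020)
  expect_equal(out_half$aligned_fraction, 0.5)

  # fragments below the identity floor do not count
  ab_low <- ab; ab_low$identity[1:4] <- 60
  ba_low <- ba; ba_low$identity[1:4] <- 60
  out_low <- ani_fragment(ab_low, ba_low, smaller_genome_length = 10 * 1020)
  expect_equal(out_low$n_fragments, 6)
  expect_error(ani_fragment(ab_low[1:4, ], ba_low[1:4, ],
                            smaller_genome_length = 10 * 1020),
               class = "nitrosponge_no_alignment")
})

test_that("a 2% mutated genome pair gives ANI near 98 within binomial error", {
  sim <- simulate_genome_pair(n_genes = 12, mean_identity = 98, seed = 5,
                              gene_length = 1020)
  hits <- colinear_fragment_hits(sim$genome_a, sim$genome_b, width = 1020)
  out <- ani_fragment(hits$a_to_b, hits$b_to_a,
                      smaller_genome_length = nchar(sim$genome_a))
  n_sites <- out$n_fragments * 1020
  se <- 100 * sqrt(0.02 * 0.98 / n_sites)
  expect_lt(abs(out$ani - 98), 4 * se + 0.1)
})

test_that("exclusively shared families need presence in all focal, absence elsewhere", {
  m <- matrix(c(1, 1, 0, 0,
                1, 1, 1, 0,
                0, 1, 0, 0,
                2, 3, 0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("f", 1:4), c("A", "B", "C", "D")))
  out <- exclusive_shared_families(m, c("A", "B"))
  expect_setequal(out$family, c("f1", "f4"))
  expect_error(exclusive_shared_families(m, c("A", "Z")),
               class = "nitrosponge_validation_error")
  expect_error(exclusive_shared_families(m, "A"),
               class = "nitrosponge_validation_error")
})

test_that("exclusive sharing matches brute force and partitions across pairs", {
  genomes <- c("A", "B", "C", "D", "E")
  for (s in 1:20) {
    m <- random_presence_matrix(50, genomes, seed = 300 + s)
    pair_sets <- list()
    for (i in 1:4) for (j in (i + 1):5) {
      focal <- genomes[c(i, j)]
      got <- exclusive_shared_families(m, focal)$family
      expect_setequal(got, oracle_exclusive(m, focal))
      pair_sets[[paste(focal, collapse = "")]] <- got
    }
    # a family exclusively shared by one pair belongs to no other pair
    all_fams <- unlist(pair_sets)
    expect_equal(anyDuplicated(all_fams), 0)
  }
})

test_that("core/unique/other fractions partition the focal gene content", {
  m <- matrix(c(2, 1, 1,
                1, 0, 0,
                1, 1, 0,
                0, 1, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("f", 1:4), c("A", "B", "C")))
  out <- family_category_fractions(m, "A")
  expect_equal(out$fraction[out$category == "core"], 0.5)    # f1: 2 of 4 genes
  expect_equal(out$fraction[out$category == "unique"], 0.25) # f2
  expect_equal(out$fraction[out$category == "other"], 0.25)  # f3
  expect_equal(sum(out$fraction), 1)

  all_core <- matrix(1, 2, 3, dimnames = list(c("f1", "f2"), c("A", "B", "C")))
  expect_equal(
    family_category_fractions(all_core, "A")$fraction[1], 1)
})
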