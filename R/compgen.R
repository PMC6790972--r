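#' Assembly summary statistics
#'
#' Contig count, total length, GC content and N50 for a genome assembly.
#' GC is computed as (G+C)/(A+C+G+T) pooled over all contigs, with IUPAC
#' ambiguity codes excluded from both numerator and denominator. N50 is the
#' standard cumulative-half definition: the length of the contig at which
#' the cumulative length of contigs sorted longest-first first reaches half
#' the total.
#'
#' @param contigs A `Biostrings::DNAStringSet`, a named character vector of
#'   sequences, or the path to a FASTA file.
#' @return One-row tibble: `n_contigs`, `total_length` (bp), `gc_percent`,
#'   `n50` (bp).
#' @export
#' @examples
#' assembly_stats(c(c1 = "AT", c2 = "GC"))
assembly_stats <- function(contigs) {
  seqs <- as_dna_charvec(contigs)
  if (!length(seqs) || all(!nchar(seqs))) {
    abort("assembly contains no non-empty sequences",
          class = "nitrosponge_validation_error")
  }
  valid <- "ACGTRYSWKMBDHVN"
  for (i in seq_along(seqs)) {
    bad <- gsub(sprintf("[%s%s]", valid, tolower(valid)), "", seqs[[i]])
    if (nzchar(bad)) {
      abort(sprintf("record '%s' contains non-nucleotide characters: %s",
                    names(seqs)[i] %||% i,
                    paste(unique(strsplit(bad, "")[[1]]), collapse = "")),
            class = "nitrosponge_validation_error")
    }
  }
  lens <- nchar(seqs)
  counts <- colSums(do.call(rbind, lapply(seqs, function(s) {
    tab <- table(factor(strsplit(toupper(s), "")[[1]],
                        levels = c("A", "C", "G", "T")))
    as.integer(tab)
  })))
  names(counts) <- c("A", "C", "G", "T")
  unambiguous <- sum(counts)
  gc <- 100 * (counts[["G"]] + counts[["C"]]) / unambiguous
  sorted <- sort(unname(lens), decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1]]
  tibble(n_contigs = length(seqs), total_length = sum(lens),
         gc_percent = gc, n50 = n50)
}

# normalize contig input to a named character vector
as_dna_charvec <- function(contigs) {
  if (inherits(contigs, "DNAStringSet") || inherits(contigs, "XStringSet")) {
    setNames(as.character(contigs), names(contigs))
  } else if (is.character(contigs) && length(contigs) == 1 &&
             file.exists(contigs)) {
    x <- Biostrings::readDNAStringSet(contigs)
    setNames(as.character(x), sub("\\s.*", "", names(x)))
  } else if (is.character(contigs)) {
    if (length(contigs) && is.null(names(contigs))) {
      names(contigs) <- paste0("contig", seq_along(contigs))
    }
    contigs
  } else {
    abort("`contigs` must be a DNAStringSet, character vector or FASTA path",
          class = "nitrosponge_validation_error")
  }
}

#' Read a tabular alignment hit table
#'
#' Reads the 14-column BLAST tabular dialect (the standard 12 columns of
#' `-outfmt 6` followed by `qlen` and `slen`) into the tibble layout used by
#' [aai()] and [ani_fragment()].
#'
#' @param path Path to a tab-separated hit table without header.
#' @return Tibble with columns `query`, `subject`, `identity`,
#'   `align_length`, `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`, `query_length`, `subject_length`.
#' @export
read_hit_table <- function(path) {
  cols <- c("query", "subject", "identity", "align_length", "mismatches",
            "gap_opens", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore", "query_length", "subject_length")
  readr::read_tsv(path, col_names = cols,
                  col_types = "ccdiiiiiiiddii", progress = FALSE)
}

# best hit per query: highest bitscore, then identity, then smallest subject id
best_hits <- function(hits) {
  hits |>
    arrange(.data$query, desc(.data$bitscore), desc(.data$identity),
            .data$subject) |>
    distinct(.data$query, .keep_all = TRUE)
}

# reciprocal best-hit pairs between two directed hit tables, with the
# per-direction alignment-coverage filter applied before pairing
bbh_pairs <- function(a_to_b, b_to_a, coverage_threshold) {
  cols <- c("query", "subject", "identity", "align_length", "bitscore",
            "query_length")
  check_cols(a_to_b, cols, "a_to_b hits")
  check_cols(b_to_a, cols, "b_to_a hits")
  covered <- function(h) {
    filter(h, .data$align_length >= coverage_threshold * .data$query_length)
  }
  fwd <- best_hits(covered(a_to_b))
  rev <- best_hits(covered(b_to_a))
  fwd |>
    dplyr::inner_join(
      rev |> select(rev_query = "query", rev_subject = "subject",
                    rev_identity = "identity",
                    rev_query_length = "query_length"),
      by = c(subject = "rev_query")) |>
    filter(.data$query == .data$rev_subject)
}

#' Average amino acid identity between two proteomes
#'
#' AAI from bidirectional best blastp hits. Per direction the best hit per
#' query is chosen by bitscore (ties broken by identity, then subject id),
#' hits aligning over less than `coverage_threshold` of the query length
#' are discarded, and only reciprocal pairs are retained. AAI is the mean
#' pairwise identity weighted by gene length (the forward-direction query
#' length by default):
#' \deqn{AAI = \sum_i id_i \ell_i / \sum_i \ell_i}
#'
#' Because the weights come from one genome's gene lengths the statistic is
#' very slightly asymmetric; the reverse-weighted and unweighted means and
#' their symmetrized average are reported alongside.
#'
#' @param a_to_b,b_to_a Directed hit tables (see [read_hit_table()]);
#'   self-hits must already be excluded.
#' @param coverage_threshold Minimum alignment length as a fraction of the
#'   query length, applied in each direction (default 0.70).
#' @return One-row tibble: `aai` (%), `n_bbh`, `aai_unweighted`,
#'   `aai_reverse_weighted`, `aai_symmetric`. The retained pair table is
#'   attached as attribute `"pairs"`.
#' @export
aai <- function(a_to_b, b_to_a, coverage_threshold = 0.70) {
  pairs <- bbh_pairs(a_to_b, b_to_a, coverage_threshold)
  if (!nrow(pairs)) {
    abort(sprintf(
      "no bidirectional best hits survive the %.0f%% coverage filter (%d forward, %d reverse hits supplied)",
      100 * coverage_threshold, nrow(a_to_b), nrow(b_to_a)),
      class = "nitrosponge_no_bbh")
  }
  wmean <- function(id, w) sum(id * w) / sum(w)
  fwd <- wmean(pairs$identity, pairs$query_length)
  rev <- wmean(pairs$rev_identity, pairs$rev_query_length)
  out <- tibble(
    aai = fwd, n_bbh = nrow(pairs),
    aai_unweighted = mean(pairs$identity),
    aai_reverse_weighted = rev,
    aai_symmetric = (fwd + rev) / 2)
  attr(out, "pairs") <- pairs
  out
}

#' Cut an assembly into fixed-width fragments
#'
#' Non-overlapping windows of `width` bp per contig; the terminal remainder
#' shorter than `width` is discarded. Fragment ids encode the source contig
#' and the 0-based half-open window, `contig:start-end`.
#'
#' @param contigs Assembly as accepted by [assembly_stats()].
#' @param width Fragment width in bp (default 1020).
#' @return Named character vector of fragment sequences.
#' @export
fragment_genome <- function(contigs, width = 1020) {
  check_positive(width, "width")
  seqs <- as_dna_charvec(contigs)
  frags <- purrr::imap(seqs, function(s, nm) {
    n <- nchar(s) %/% width
    if (n == 0) return(character())
    starts <- (seq_len(n) - 1) * width
    setNames(substring(s, starts + 1, starts + width),
             sprintf("%s:%d-%d", nm, starts, starts + width))
  })
  out <- unlist(unname(frags))
  if (is.null(out)) character() else out
}

#' Fragment-based average nucleotide identity
#'
#' ANI over reciprocal best fragment mappings: both genomes are cut into
#' fixed-width fragments, fragments are matched by reciprocal best hit
#' (same selection rules as [aai()], with the coverage filter applied to
#' the fragment length), pairs below `identity_floor` are dropped, and ANI
#' is the unweighted mean identity of the retained pairs. The aligned
#' fraction is the retained fragment length relative to the smaller genome.
#'
#' @param a_to_b,b_to_a Directed fragment hit tables.
#' @param identity_floor Minimum percent identity for a fragment pair to
#'   count (default 70).
#' @param fragment_width Width of the fragments (bp), as used by
#'   [fragment_genome()].
#' @param smaller_genome_length Length (bp) of the smaller of the two
#'   genomes, the denominator of the aligned fraction.
#' @param coverage_threshold Minimum alignment length as a fraction of the
#'   fragment length.
#' @return One-row tibble: `ani` (%), `aligned_fraction` (0-1),
#'   `n_fragments`.
#' @export
ani_fragment <- function(a_to_b, b_to_a, identity_floor = 70,
                         fragment_width = 1020, smaller_genome_length,
                         coverage_threshold = 0.70) {
  check_positive(fragment_width, "fragment_width")
  check_positive(smaller_genome_length, "smaller_genome_length")
  pairs <- bbh_pairs(a_to_b, b_to_a, coverage_threshold)
  pairs <- filter(pairs, .data$identity >= identity_floor)
  if (!nrow(pairs)) {
    abort("no fragment pairs retained above the identity floor",
          class = "nitrosponge_no_alignment")
  }
  tibble(
    ani = mean(pairs$identity),
    aligned_fraction = nrow(pairs) * fragment_width / smaller_genome_length,
    n_fragments = nrow(pairs))
}

# coerce a families-by-genomes count input (matrix with dimnames, or tibble
# with a `family` column) to an integer matrix
as_presence_matrix <- function(matrix) {
  if (is.data.frame(matrix)) {
    check_cols(matrix, "family", "presence matrix")
    m <- as.matrix(matrix[setdiff(names(matrix), "family")])
    rownames(m) <- matrix$family
    matrix <- m
  }
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      is.null(colnames(matrix))) {
    abort("presence matrix needs family row names and genome column names",
          class = "nitrosponge_validation_error")
  }
  if (any(matrix < 0) || any(matrix != round(matrix))) {
    abort("presence matrix entries must be non-negative integer gene counts",
          class = "nitrosponge_validation_error")
  }
  matrix
}

#' Gene families exclusively shared by a set of genomes
#'
#' Families present (count >= 1) in every genome of `focal_set` and absent
#' (count 0) from every other genome in the matrix. Used to find candidate
#' symbiosis factors shared only among sponge-associated lineages.
#'
#' @param matrix Families-by-genomes gene-count matrix (or a tibble with a
#'   `family` column and one column per genome).
#' @param focal_set Character vector of at least two genome ids.
#' @return Tibble with one row per exclusively shared `family`; the count
#'   is `nrow()` of the result.
#' @export
exclusive_shared_families <- function(matrix, focal_set) {
  m <- as_presence_matrix(matrix)
  unknown <- setdiff(focal_set, colnames(m))
  if (length(unknown)) {
    abort(sprintf("unknown genome id(s): %s", paste(unknown, collapse = ", ")),
          class = "nitrosponge_validation_error")
  }
  if (length(focal_set) < 2) {
    abort("`focal_set` must contain at least two genomes",
          class = "nitrosponge_validation_error")
  }
  others <- setdiff(colnames(m), focal_set)
  in_all_focal <- rowSums(m[, focal_set, drop = FALSE] >= 1) == length(focal_set)
  in_no_other <- if (length(others)) {
    rowSums(m[, others, drop = FALSE]) == 0
  } else TRUE
  tibble(family = rownames(m)[in_all_focal & in_no_other])
}

#' Core / unique / other gene-family fractions for one genome
#'
#' Partitions the genes of a focal genome by the distribution of their
#' families: `core` families occur in every genome of the matrix, `unique`
#' families only in the focal genome, `other` covers the rest. Fractions
#' are computed over the focal genome's gene counts and sum to 1.
#'
#' @inheritParams exclusive_shared_families
#' @param focal A single genome id present in the matrix.
#' @return Tibble with columns `category`, `n_families`, `n_genes`,
#'   `fraction`.
#' @export
family_category_fractions <- function(matrix, focal) {
  m <- as_presence_matrix(matrix)
  if (!focal %in% colnames(m)) {
    abort(sprintf("unknown genome id: %s", focal),
          class = "nitrosponge_validation_error")
  }
  present <- m >= 1
  focal_counts <- m[, focal]
  has_genes <- focal_counts >= 1
  core <- has_genes & rowSums(present) == ncol(m)
  unique_fam <- has_genes & rowSums(present) == 1
  other <- has_genes & !core & !unique_fam
  total <- sum(focal_counts)
  purrr::map(
    list(core = core, unique = unique_fam, other = other),
    function(idx) tibble(n_families = sum(idx),
                         n_genes = sum(focal_counts[idx]),
                         fraction = if (total > 0) sum(focal_counts[idx]) / total else 0)
  ) |>
    bind_rows(.id = "category")
}
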