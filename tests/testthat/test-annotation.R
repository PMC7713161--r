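# a hand-built two-gene toy locus: one gene per strand, known coordinates
toy_locus <- function() {
  # chr1A, 30 kb; plus-strand gene at 12001..13999, minus-strand at 20001..21999
  seqs <- strrep("ACGT", 7500)
  # plus gene: 5'UTR 12001..12100, CDS1 12101..12400, intron 12401..12800,
  # CDS2 12801..13300, 3'UTR 13301..13999 ; CDS length 300+500 piece of 800
  # build coding sequence: ATG + sense codons, total 800 bases... use 801
  # (267 codons) -> CDS1 300, CDS2 501
  set.seed(99)
  coding <- paste0(
    c("ATG", sample(SENSE, 265, replace = TRUE), "TGA"),
    collapse = ""
  )
  stopifnot(nchar(coding) == 801)
  raw <- charToRaw(seqs)
  raw[12101:12400] <- charToRaw(substr(coding, 1, 300))
  raw[12801:13301] <- charToRaw(substr(coding, 301, 801))
  feats_plus <- tibble::tibble(
    chrom = "chr1A",
    type = c(
      "gene", "mRNA", "five_prime_UTR", "CDS", "CDS", "three_prime_UTR",
      "exon", "exon"
    ),
    start = c(12001, 12001, 12001, 12101, 12801, 13302, 12001, 12801),
    end = c(13999, 13999, 12100, 12400, 13301, 13999, 12400, 13999),
    strand = "+",
    phase = c(NA, NA, NA, 0, 0, NA, NA, NA),
    gene_id = "gplus", transcript_id = c(NA, rep("gplus.1", 7))
  )
  # minus gene: genomic 20001..21999; 3'UTR 20001..20199 (left),
  # CDS 20200..21000 (801 bp single exon), 5'UTR 21001..21999
  coding2 <- paste0(
    c("ATG", sample(SENSE, 265, replace = TRUE), "TAA"),
    collapse = ""
  )
  raw[20200:21000] <- charToRaw(
    rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", coding2))))
  )
  genome <- at_genome(c(chr1A = rawToChar(raw)))
  feats_minus <- tibble::tibble(
    chrom = "chr1A",
    type = c(
      "gene", "mRNA", "three_prime_UTR", "CDS", "five_prime_UTR", "exon"
    ),
    start = c(20001, 20001, 20001, 20200, 21001, 20001),
    end = c(21999, 21999, 20199, 21000, 21999, 21999),
    strand = "-",
    phase = c(NA, NA, NA, 0, NA, NA),
    gene_id = "gminus", transcript_id = c(NA, rep("gminus.1", 5))
  )
  list(
    genome = genome,
    models = at_gene_models(dplyr::bind_rows(feats_plus, feats_minus)),
    coding_plus = coding, coding_minus = coding2
  )
}

SENSE <- setdiff(
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"], "ATG"
)

test_that("coding changes are classified by codon arithmetic on both strands", {
  loc <- toy_locus()
  gc <- Biostrings::GENETIC_CODE
  # plus strand: pick 30 random CDS positions and classify independently
  withr::with_seed(4, {
    for (i in 1:30) {
      cds_index <- sample(4:798, 1) # avoid start/stop codons
      pos <- if (cds_index <= 300) 12100 + cds_index else 12800 + cds_index - 300
      codon_i <- ceiling(cds_index / 3)
      off <- cds_index - 3 * (codon_i - 1)
      codon <- substr(loc$coding_plus, 3 * codon_i - 2, 3 * codon_i)
      ref <- substr(codon, off, off)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      alt_codon <- codon
      substr(alt_codon, off, off) <- alt
      want <- if (gc[[alt_codon]] == "*") {
        "other_genic"
      } else if (gc[[alt_codon]] == gc[[codon]]) "synonymous" else "missense"
      got <- classify_sites(
        tibble::tibble(chrom = "chr1A", pos = pos, ref = ref, alt = alt),
        loc$models, loc$genome
      )$annot_class
      expect_equal(got, want, label = paste("cds_index", cds_index))
    }
    # minus strand: coding position maps to genomic 21000 - cds_index + 1
    for (i in 1:30) {
      cds_index <- sample(4:798, 1)
      pos <- 21000 - cds_index + 1
      codon_i <- ceiling(cds_index / 3)
      off <- cds_index - 3 * (codon_i - 1)
      codon <- substr(loc$coding_minus, 3 * codon_i - 2, 3 * codon_i)
      ref_coding <- substr(codon, off, off)
      alt_coding <- sample(setdiff(c("A", "C", "G", "T"), ref_coding), 1)
      alt_codon <- codon
      substr(alt_codon, off, off) <- alt_coding
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      want <- if (gc[[alt_codon]] == "*") {
        "other_genic"
      } else if (gc[[alt_codon]] == gc[[codon]]) "synonymous" else "missense"
      got <- classify_sites(
        tibble::tibble(
          chrom = "chr1A", pos = pos,
          ref = comp[[ref_coding]], alt = comp[[alt_coding]]
        ),
        loc$models, loc$genome
      )$annot_class
      expect_equal(got, want, label = paste("minus cds_index", cds_index))
    }
  })
})

test_that("textbook codon examples classify as expected", {
  # build a minimal one-codon-context gene: CDS ATG AAA TGA on plus strand
  s <- paste0(strrep("C", 100), "ATGAAATGA", strrep("C", 20100))
  genome <- at_genome(c(chr1A = s))
  models <- at_gene_models(tibble::tibble(
    chrom = "chr1A",
    type = c("gene", "mRNA", "CDS", "exon"),
    start = 101, end = 109, strand = "+",
    phase = c(NA, NA, 0, NA),
    gene_id = "g1", transcript_id = c(NA, "g1.1", "g1.1", "g1.1")
  ))
  # third position of AAA: A->G gives AAG (Lys -> Lys): synonymous
  expect_equal(
    classify_sites(
      tibble::tibble(chrom = "chr1A", pos = 106L, ref = "A", alt = "G"),
      models, genome
    )$annot_class,
    "synonymous"
  )
  # first position of AAA: A->G gives GAA (Lys -> Glu): missense
  expect_equal(
    classify_sites(
      tibble::tibble(chrom = "chr1A", pos = 104L, ref = "A", alt = "G"),
      models, genome
    )$annot_class,
    "missense"
  )
  # start codon and stop codon changes fold into other_genic
  expect_equal(
    classify_sites(
      tibble::tibble(chrom = "chr1A", pos = 101L, ref = "A", alt = "G"),
      models, genome
    )$annot_class,
    "other_genic"
  )
  # site 10 kb beyond the gene is intergenic; 2 kb is gene-proximal
  expect_equal(
    classify_sites(
      tibble::tibble(chrom = "chr1A", pos = 10200L, ref = "C", alt = "T"),
      models, genome
    )$annot_class,
    "intergenic"
  )
  expect_equal(
    classify_sites(
      tibble::tibble(chrom = "chr1A", pos = 2100L, ref = "C", alt = "T"),
      models, genome
    )$annot_class,
    "gene_proximal"
  )
})

test_that("non-coding gene features map to utr, intron, splice and proximal", {
  loc <- toy_locus()
  sites <- tibble::tibble(
    chrom = "chr1A",
    pos = c(12050L, 13500L, 12600L, 12402L, 5000L, 12000L - 3000L),
    ref = "A", alt = "G"
  )
  # force ref to the actual genome base so the example is well-formed
  sites$ref <- substring(loc$genome$seq[[1]], sites$pos, sites$pos)
  sites$alt <- vapply(sites$ref, function(b) {
    setdiff(c("A", "C", "G", "T"), b)[1]
  }, character(1))
  got <- classify_sites(sites, loc$models, loc$genome)$annot_class
  expect_equal(
    got,
    c("utr", "utr", "intronic", "other_genic", "intergenic", "gene_proximal")
  )
})

test_that("classification recovers planted classes on simulated gene models", {
  cfg <- sim_config(
    seed = 31,
    chromosomes = c(chr1A = 3e5), genes_per_mb = 15
  )
  refs <- simulate_references(cfg)
  gm <- simulate_gene_models(cfg, refs$hexaploid)
  feats <- tibble::as_tibble(gm$models)
  utr <- dplyr::filter(feats, type == "five_prime_UTR")
  mk_sites <- function(pos) {
    ref <- substring(gm$genome$seq[[1]], pos, pos)
    tibble::tibble(
      chrom = "chr1A", pos = pos, ref = ref,
      alt = vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
        character(1)
      )
    )
  }
  # utr midpoints classify as utr
  utr_sites <- mk_sites(as.integer((utr$start + utr$end) %/% 2))
  expect_true(
    all(classify_sites(utr_sites, gm$models, gm$genome)$annot_class == "utr")
  )
  # gene-free midpoints between consecutive genes are intergenic
  genes <- dplyr::arrange(dplyr::filter(feats, type == "gene"), start)
  gaps <- as.integer((head(genes$end, -1) + tail(genes$start, -1)) / 2)
  gap_sites <- mk_sites(gaps[tail(genes$start, -1) - head(genes$end, -1) > 10000])
  expect_true(
    all(classify_sites(
      gap_sites, gm$models, gm$genome
    )$annot_class == "intergenic")
  )
})

test_that("frame-anomalous transcripts are skipped with a warning", {
  s <- paste0(strrep("C", 100), "ATGAAATG", strrep("C", 6000))
  genome <- at_genome(c(chr1A = s))
  models <- at_gene_models(tibble::tibble(
    chrom = "chr1A",
    type = c("gene", "mRNA", "CDS", "exon"),
    start = 101, end = 108, strand = "+", # 8 bp CDS
    phase = c(NA, NA, 0, NA),
    gene_id = "g1", transcript_id = c(NA, "g1.1", "g1.1", "g1.1")
  ))
  expect_warning(
    got <- classify_sites(
      tibble::tibble(chrom = "chr1A", pos = 104L, ref = "A", alt = "G"),
      models, genome
    ),
    "frame-anomalous"
  )
})

test_that("genic/non-genic merge is a partition of the seven classes", {
  cls <- c(
    "intergenic", "gene_proximal", "utr", "intronic", "synonymous",
    "missense", "other_genic"
  )
  m <- merge_sets(cls)
  expect_equal(m[1:2], c("non_genic", "non_genic"))
  expect_true(all(m[3:7] == "genic"))
  expect_equal(length(m), length(cls))
  tb <- merge_sets(tibble::tibble(annot_class = cls))
  expect_equal(sum(tb$annot_set == "genic") + sum(tb$annot_set == "non_genic"),
    length(cls))
})

test_that("equal-size subsampling is deterministic and unbiased", {
  x <- tibble::tibble(id = 1:100, at = rep(c(1, 0), c(60, 40)))
  y <- tibble::tibble(id = 1:7)
  s1 <- subsample_equal(x, y, seed = 5)
  s2 <- subsample_equal(x, y, seed = 5)
  expect_equal(nrow(s1$x), 7)
  expect_equal(nrow(s1$y), 7)
  expect_identical(s1$x$id, s2$x$id)
  # unbiasedness: mean subsample composition approaches the full-set value
  m <- vapply(1:200, function(s) {
    mean(subsample_equal(x, y, seed = s)$x$at)
  }, numeric(1))
  expect_lt(abs(mean(m) - 0.6), 0.03)
})
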