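small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(
      seed = seed,
      chromosomes = c(chr1A = 3e5, chr1B = 3e5, chr1D = 3e5),
      group_sizes = c(
        wild_emmer = 8, durum = 4, ae_tauschii = 6,
        landrace_east = 5, landrace_west = 5, variety = 8
      ),
      standing_per_mb = 400, new_per_mb = 300,
      sweeps_per_chrom = 1, sweep_snps = 10,
      genes_per_mb = 10
    ),
    list(...)
  )
  do.call(sim_config, args)
}

test_that("reference simulation is seed-deterministic with the configured GC", {
  cfg <- sim_config(seed = 3, chromosomes = c(chr1A = 1e6, chr1D = 1e6))
  r1 <- simulate_references(cfg)
  r2 <- simulate_references(cfg)
  expect_identical(r1$hexaploid$seq, r2$hexaploid$seq)
  ct <- count_bases(r1$hexaploid, by = "genome")
  gc <- (ct$nC + ct$nG) / ct$total
  expect_lt(abs(gc - 0.46), 0.002)
  # byte-identical FASTA under the same seed
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(r1$hexaploid, f1)
  write_genome(r2$hexaploid, f2)
  expect_identical(readLines(f1), readLines(f2))
  # degenerate composition
  all_gc <- simulate_references(
    sim_config(seed = 1, chromosomes = c(chr1A = 5e4), gc = 1)
  )
  expect_equal(count_bases(all_gc$hexaploid, by = "genome")$nA, 0)
  # progenitor references partition the subgenomes
  expect_setequal(names(r1$tetraploid$seq), "chr1A")
  expect_setequal(names(r1$diploid$seq), "chr1D")
})

test_that("configuration validation rejects inconsistent plans", {
  expect_error(sim_config(chromosomes = c(foo = 1e6)), "wheat pattern")
  expect_error(sim_config(group_sizes = c(wild_emmer = 1)), "group_sizes")
  expect_error(
    sim_config(rate_multiplier = c(A = 0, B = 1, D = 1)),
    "rate_multiplier"
  )
  expect_error(
    sim_config(hotspot_motifs = "A(A/G)G"), "C/T"
  )
})

test_that("population simulation is deterministic and internally consistent", {
  cfg <- small_cfg(seed = 5)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$geno$dosage, s2$geno$dosage)
  expect_identical(s1$truth$pos, s2$truth$pos)

  # every site appears in the truth ledger with matching alleles
  key_geno <- paste(s1$geno$sites$chrom, s1$geno$sites$pos,
    s1$geno$sites$ref, s1$geno$sites$alt)
  key_truth <- paste(s1$truth$chrom, s1$truth$pos, s1$truth$ref, s1$truth$alt)
  expect_setequal(key_geno, key_truth)

  # dosages live on the {0, 0.5, 1, NA} grid
  d <- s1$geno$dosage
  expect_true(all(d[!is.na(d)] %in% c(0, 0.5, 1)))

  # groups not carrying a subgenome are structurally missing there
  emmer <- tibble::as_tibble(s1$panel)
  emmer <- emmer$accession[emmer$group == "wild_emmer"]
  d_sites <- s1$geno$sites$subgenome == "D"
  expect_true(all(is.na(
    d[match(emmer, s1$geno$accessions), d_sites]
  )))

  # new variants are absent from all progenitor groups
  truth_new <- s1$truth[s1$truth$stratum != "standing", ]
  prog <- tibble::as_tibble(s1$panel)
  prog <- prog$accession[prog$group %in% c(
    "wild_emmer", "durum", "ae_tauschii"
  )]
  cols <- match(
    paste0(truth_new$chrom, ":", truth_new$pos),
    colnames(s1$geno$dosage)
  )
  block <- d[match(prog, s1$geno$accessions), cols]
  expect_true(all(is.na(block) | block == 0))

  # swept variants fall inside the declared sweep intervals
  sw <- s1$truth[s1$truth$stratum == "sweep_new", ]
  lab <- site_region_label(sw, s1$sweeps)
  expect_true(all(!is.na(lab)))
})

test_that("a fully symmetric configuration obeys PR2 and yields no [AT] gap", {
  sym_cfg <- function(seed) {
    sim_config(
      seed = seed,
      chromosomes = c(
        chr1A = 5e5, chr1B = 5e5, chr1D = 5e5
      ),
      gc = 0.5,
      group_sizes = c(
        wild_emmer = 12, durum = 4, ae_tauschii = 12,
        landrace_east = 8, landrace_west = 8, variety = 8
      ),
      standing_per_mb = 600, new_per_mb = 600,
      rate_multiplier = c(A = 1, B = 1, D = 1),
      gc_to_at_bias = 1, hotspot_multiplier = 1,
      sweeps_per_chrom = 0, genes_per_mb = 0
    )
  }
  sim <- simulate_population(sym_cfg(11))
  # PR2 on the emitted reference
  dev <- pr2_deviation(count_bases(sim$genome, by = "genome"))
  expect_lt(abs(dev$dAT), 0.005)
  expect_lt(abs(dev$dCG), 0.005)
  # site spectrum symmetric under reverse-complement pairing
  sp <- spectrum_frequencies(sim$truth)
  tf <- setNames(sp$types$frequency, sp$types$type)
  expect_lt(abs(tf[["A/G"]] - tf[["C/T"]]), 0.03)
  expect_lt(abs(tf[["A/C"]] - tf[["G/T"]]), 0.03)
  # wild vs domesticated [AT] difference: zero-mean over replicate cohorts
  # (single cohorts carry +-0.02 site-sampling noise at this size)
  deltas <- purrr::map_dfr(11:16, function(s) {
    pipeline_delta_at(simulate_population(sym_cfg(s)))
  })
  expect_lt(abs(mean(deltas$delta)), 0.01)
})

test_that("gene-free configurations emit an empty but valid GFF", {
  cfg <- sim_config(
    seed = 2, chromosomes = c(chr1A = 5e4), genes_per_mb = 0,
    standing_per_mb = 100, new_per_mb = 100, sweeps_per_chrom = 0
  )
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$models), 0)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$models, f)
  expect_equal(readLines(f), "##gff-version 3")
})

test_that("a simulated dataset round-trips through its on-disk formats", {
  cfg <- small_cfg(seed = 9)
  sim <- simulate_population(cfg)
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  geno <- read_genotypes(file.path(dir, "cohort.vcf"))
  expect_identical(geno$dosage, sim$geno$dosage)
  expect_identical(geno$sites$ref, sim$geno$sites$ref)
  genome <- read_genome(file.path(dir, "hexaploid.fa"))
  expect_identical(genome$seq, sim$genome$seq)
  panel <- read_panel(file.path(dir, "panel.tsv"))
  expect_identical(panel$accession, sim$panel$accession)
  sweeps <- read_bed(file.path(dir, "sweeps.bed"))
  expect_equal(sweeps$start, sim$sweeps$start)
  expect_equal(sweeps$end, sim$sweeps$end)
  models <- read_gene_models(file.path(dir, "genes.gff3"))
  cds1 <- dplyr::filter(tibble::as_tibble(models), type == "CDS")
  cds0 <- dplyr::filter(tibble::as_tibble(sim$models), type == "CDS")
  expect_equal(
    dplyr::arrange(cds1, chrom, start)$start,
    dplyr::arrange(cds0, chrom, start)$start
  )
  # classifier agrees between the written+reread and in-memory models
  some_sites <- head(sim$geno$sites, 40)
  expect_equal(
    classify_sites(some_sites, models, genome)$annot_class,
    classify_sites(some_sites, sim$models, sim$genome)$annot_class
  )
})

test_that("raising the D rate multiplier raises D's [AT] gap and derived rate", {
  mults <- c(1, 1.5, 2.5)
  gaps <- numeric(0)
  rates <- numeric(0)
  for (m in mults) {
    cfg <- small_cfg(
      seed = 77,
      rate_multiplier = c(A = 1, B = 1, D = m),
      group_sizes = c(
        wild_emmer = 10, durum = 4, ae_tauschii = 10,
        landrace_east = 6, landrace_west = 6, variety = 8
      )
    )
    sim <- simulate_population(cfg)
    deltas <- pipeline_delta_at(sim)
    gaps <- c(gaps, deltas$delta[deltas$subgenome == "D"])
    ps <- call_private_sites(
      sim$geno, sim$panel, hexaploid_groups,
      c("wild_emmer", "durum", "ae_tauschii")
    )
    r <- derived_rate(
      sim$geno, dplyr::filter(ps, subgenome == "D"),
      panel = sim$panel
    )
    rates <- c(rates, mean(
      r$rate[r$group %in% hexaploid_groups],
      na.rm = TRUE
    ))
  }
  expect_true(all(diff(gaps) > 0))
  expect_true(all(diff(rates) > 0))
})
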