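test_that("transition types are canonical unordered pairs", {
  expect_equal(transition_type("C", "T"), "C/T")
  expect_equal(transition_type("T", "C"), "C/T")
  expect_equal(transition_type("A", "C"), "A/C")
  expect_error(transition_type("A", "A"), "differ")
  expect_error(transition_type("A", "N"), "A, C, G or T")
  expect_equal(length(all_types()), 6)
  expect_equal(length(all_motifs()), 96)
})

test_that("motif context comes from the reference flanks and edge sites are unusable", {
  g <- at_genome(c(chr1A = "TACGTT"))
  sites <- tibble::tibble(
    chrom = "chr1A", pos = c(3L, 1L, 6L),
    ref = c("C", "T", "T"), alt = c("T", "G", "A")
  )
  m <- motif_of(sites, g)
  expect_equal(m[1], "A(C/T)G")
  expect_true(is.na(m[2])) # chromosome start
  expect_true(is.na(m[3])) # chromosome end
  gN <- at_genome(c(chr1A = "TANCGT"))
  expect_true(is.na(motif_of(
    tibble::tibble(chrom = "chr1A", pos = 4L, ref = "C", alt = "A"), gN
  )))
})

test_that("motif extraction matches brute-force string slicing", {
  withr::with_seed(17, {
    g <- at_genome(c(chr1A = random_dna(5000), chr1D = random_dna(3000)))
    n <- 500
    cn <- sample(c("chr1A", "chr1D"), n, replace = TRUE)
    pos <- ifelse(cn == "chr1A", sample(5000, n, TRUE), sample(3000, n, TRUE))
    sites <- tibble::tibble(chrom = cn, pos = as.integer(pos))
    sites <- dplyr::distinct(sites, chrom, pos)
    sites$ref <- sample(c("A", "C", "G", "T"), nrow(sites), TRUE)
    sites$alt <- vapply(sites$ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    expect_equal(motif_of(sites, g), oracle_motif_of(sites, g))
  })
})

test_that("motif reverse complement is an involution with the expected fixed points", {
  expect_equal(revcomp_motif("A(C/T)G"), "C(A/G)T")
  m <- all_motifs()
  expect_equal(revcomp_motif(revcomp_motif(m)), m)
  # self-paired motifs only at the self-complementary types A/T and C/G
  self_paired <- m[revcomp_motif(m) == m]
  p <- parse_motif(self_paired)
  expect_true(all(paste(p$b1, p$b2, sep = "/") %in% c("A/T", "C/G")))
  # and their flanks are reverse-complementary palindromes
  expect_true(all(p$left == chartr("ACGT", "TGCA", p$right)))
})

test_that("spectrum frequencies normalise over the right denominators", {
  g <- at_genome(c(chr1A = "AACTGACTGA"))
  sites <- tibble::tibble(
    chrom = "chr1A", pos = c(3L, 7L, 1L, 10L),
    ref = c("C", "C", "A", "A"), alt = c("T", "T", "G", "C")
  )
  sp <- spectrum_frequencies(sites, g)
  expect_equal(sum(sp$types$frequency), 1)
  expect_equal(sp$types$frequency[sp$types$type == "C/T"], 0.5)
  # two of four sites are at chromosome ends: motif denominator is 2
  expect_equal(sp$n_motif_usable, 2)
  expect_equal(sum(sp$motifs$frequency), 1)
  expect_equal(sp$motifs$n[sp$motifs$motif == "A(C/T)T"], 2L)
  expect_equal(
    sp$motifs$frequency[sp$motifs$motif == "A(C/T)T"], 1
  )
})

test_that("type frequencies are the marginals of motif frequencies", {
  withr::with_seed(23, {
    g <- at_genome(c(chr1A = random_dna(20000, p_n = 0)))
    pos <- sort(sample(2:19999, 800))
    ref <- substring(g$seq[[1]], pos, pos)
    alt <- vapply(ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    sites <- tibble::tibble(chrom = "chr1A", pos = pos, ref = ref, alt = alt)
    sp <- spectrum_frequencies(sites, g)
    marg <- dplyr::summarise(
      dplyr::group_by(sp$motifs, type),
      n = sum(n), .groups = "drop"
    )
    # every site has usable context here, so the marginals match exactly
    expect_equal(
      marg$n[match(sp$types$type, marg$type)], sp$types$n
    )
  })
})

test_that("high-frequency motif tiers use a strict threshold", {
  flat <- tibble::tibble(
    motif = all_motifs(), type = "x", n = 1L, frequency = 1 / 96
  )
  expect_equal(nrow(high_frequency_motifs(flat, factor = 1)), 0)
  one_up <- dplyr::mutate(flat,
    frequency = ifelse(motif == "A(C/T)G", 0.25, frequency)
  )
  expect_equal(
    high_frequency_motifs(one_up, factor = 2)$motif, "A(C/T)G"
  )
})

test_that("strand symmetry: motif frequencies match their reverse complements on the flipped representation", {
  withr::with_seed(29, {
    g <- at_genome(c(chr1A = random_dna(20000, p_n = 0)))
    pos <- sort(sample(2:19999, 600))
    ref <- substring(g$seq[[1]], pos, pos)
    alt <- vapply(ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    sites <- tibble::tibble(chrom = "chr1A", pos = pos, ref = ref, alt = alt)
    sp <- spectrum_frequencies(sites, g)
    # reverse-complement the genome and the site representation
    L <- 20000
    grc <- at_genome(c(
      chr1A = rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", g$seq[[1]]))))
    ))
    sites_rc <- tibble::tibble(
      chrom = "chr1A", pos = L - pos + 1L,
      ref = chartr("ACGT", "TGCA", ref),
      alt = chartr("ACGT", "TGCA", alt)
    )
    sp_rc <- spectrum_frequencies(sites_rc, grc)
    want <- sp$motifs$n[match(
      revcomp_motif(sp_rc$motifs$motif), sp$motifs$motif
    )]
    expect_equal(sp_rc$motifs$n, want)
  })
})

test_that("per-type base values use the dosage weighting on matching sites", {
  g <- at_geno(
    tibble::tibble(
      chrom = "chr1A", pos = 1:3, ref = c("C", "C", "A"),
      alt = c("T", "T", "G")
    ),
    matrix(c(1, 0.5, 0), 1), "a1"
  )
  v <- per_type_base_value(g, type = "C/T")
  expect_equal(v$value[v$base == "T"], 0.75) # hom T + het over two C/T sites
  expect_equal(v$value[v$base == "C"], 0.25)
  expect_equal(unique(v$n_sites_used), 2L)
  expect_error(per_type_base_value(g, type = "C/G"), "no matching sites")
})

test_that("AT-changing types are exactly the four mixed pairs", {
  # at A/T sites both alleles are A or T: at_value pinned to 1;
  # at C/G sites neither is: pinned to 0
  g <- at_geno(
    tibble::tibble(
      chrom = "chr1A", pos = 1:2, ref = c("A", "C"), alt = c("T", "G")
    ),
    matrix(c(0, 0.5, 1, 0, 0.5, 1), 3, 2), c("x", "y", "z")
  )
  at_AT <- accession_composition(g, sites = 1)$at_value
  at_CG <- accession_composition(g, sites = 2)$at_value
  expect_equal(at_AT, c(1, 1, 1))
  expect_equal(at_CG, c(0, 0, 0))
  mixed <- setdiff(all_types(), c("A/T", "C/G"))
  p <- parse_motif(make_motif("A", mixed, "A"))
  expect_true(all(
    (p$b1 %in% c("A", "T")) != (p$b2 %in% c("A", "T"))
  ))
})

test_that("motif value correlations flag degenerate vectors and recover shared rates", {
  vals <- tibble::tibble(
    accession = rep(sprintf("a%02d", 1:30), 2),
    motif = rep(c("m1", "m2"), each = 30),
    at_value = rep(seq(0, 1, length.out = 30), 2)
  )
  cc <- motif_value_correlation(vals)
  expect_equal(cc$r[cc$motif_x == "m1" & cc$motif_y == "m2"], 1)
  withr::with_seed(31, {
    noise <- tibble::tibble(
      accession = rep(sprintf("a%03d", 1:100), 2),
      motif = rep(c("m1", "m2"), each = 100),
      at_value = rnorm(200)
    )
    r <- motif_value_correlation(noise)
    expect_lt(abs(r$r[r$motif_x == "m1" & r$motif_y == "m2"]), 0.3)
    flat <- dplyr::mutate(noise,
      at_value = ifelse(motif == "m2", 1, at_value)
    )
    r2 <- motif_value_correlation(flat)
    expect_true(is.na(r2$r[r2$motif_x == "m1" & r2$motif_y == "m2"]))
  })
  # shared accession effect drives near-perfect correlation
  withr::with_seed(37, {
    eff <- rnorm(40, sd = 1)
    shared <- tidyr::crossing(
      accession = sprintf("a%02d", 1:40), motif = paste0("m", 1:4)
    )
    shared$at_value <- eff[as.integer(factor(shared$accession))] +
      rnorm(nrow(shared), sd = 0.05)
    rs <- motif_value_correlation(shared)
    expect_gt(min(rs$r[rs$motif_x != rs$motif_y]), 0.95)
  })
})
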