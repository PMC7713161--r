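#' Simulation configuration for an allopolyploid domestication cohort
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate a
#' wheat-like design: six chromosomes over three subgenomes (A and B from a
#' tetraploid progenitor, D from a diploid progenitor), the six canonical
#' groups with a 93-accession worldwide panel, a transition-rich
#' GC-to-AT-biased mutation spectrum with five C-to-T motif hotspots, a
#' faster post-polyploidization mutation rate on D, a domestication
#' bottleneck and clustered selective sweeps.
#'
#' @param seed Integer master seed; every random draw derives from it.
#' @param chromosomes Named integer vector of chromosome lengths (bp).
#' @param gc Genome GC content for the simulated references.
#' @param genes_per_mb Gene density for the simulated gene models.
#' @param group_sizes Named integer vector of accessions per group.
#' @param standing_per_mb Expected standing (shared ancestral) SNPs per Mb
#'   per subgenome.
#' @param new_per_mb Expected domesticated-branch new SNPs per Mb before the
#'   subgenome rate multiplier.
#' @param rate_multiplier Per-subgenome multiplier on the new-mutation
#'   count and on the mean derived-allele frequency (a lineage with a higher
#'   per-generation rate accumulates both more and, on average, older
#'   private mutations).
#' @param type_weights Baseline unordered transition-type weights of the
#'   mutation spectrum (strand-symmetric).
#' @param gc_to_at_bias Weight multiplier applied to mutations whose donor
#'   is G/C and derived allele is A/T (new variants only; standing variation
#'   uses the symmetric baseline).
#' @param hotspot_motifs C/T-type motif labels receiving the C-to-T hotspot
#'   multiplier (their reverse complements receive the G-to-A mirror).
#' @param hotspot_multiplier Rate multiplier at hotspot contexts.
#' @param standing_freq List `shape1`, `shape2`, `min`, `max`: standing
#'   allele frequencies are Beta(shape1, shape2) rescaled to `[min, max]`
#'   (shared ancestral polymorphism is bounded away from fixation).
#' @param derived_freq Optional named per-subgenome mean derived-allele
#'   frequency of new variants; default `derived_freq_base * rate_multiplier`
#'   capped at 0.45.
#' @param derived_freq_base Base mean derived frequency.
#' @param derived_freq_shape Beta concentration of per-site derived
#'   frequencies around their mean.
#' @param bottleneck_retention Probability that a standing variant stays
#'   polymorphic through the domestication bottleneck.
#' @param drift_kappa,group_kappa Beta concentrations for lineage drift and
#'   per-group jitter of allele frequencies.
#' @param inbreeding Within-accession inbreeding coefficient F (wheat selfs;
#'   heterozygotes are rare).
#' @param missing_rate Per-call missing probability.
#' @param sweeps_per_chrom,sweep_width Number and width (bp) of selective
#'   sweeps per chromosome.
#' @param sweep_snps Extra swept new variants per sweep.
#' @param sweep_freq Mean derived frequency of swept variants in the
#'   domesticated groups.
#' @param sweep_at_bias GC-to-AT bias of swept variants (elevates [AT]
#'   inside sweeps).
#' @param causal Optional `list(n_markers, gamma)`: standing markers whose
#'   dosage linearly scales an accession-level mutation-dose latent
#'   variable, making the [AT] phenotype heritable for association tests.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    chromosomes = c(
      chr1A = 2e6, chr2A = 2e6, chr1B = 2e6,
      chr2B = 2e6, chr1D = 2e6, chr2D = 2e6
    ),
    gc = 0.46,
    genes_per_mb = 20,
    group_sizes = c(
      wild_emmer = 20, durum = 5, ae_tauschii = 5,
      landrace_east = 15, landrace_west = 14, variety = 34
    ),
    standing_per_mb = 850,
    new_per_mb = 400,
    rate_multiplier = c(A = 1, B = 1, D = 1.5),
    type_weights = c(
      "A/C" = 0.12, "A/G" = 0.25, "A/T" = 0.09,
      "C/G" = 0.08, "C/T" = 0.25, "G/T" = 0.12
    ),
    gc_to_at_bias = 3,
    hotspot_motifs = c(
      "A(C/T)G", "C(C/T)A", "T(C/T)G", "G(C/T)G", "A(C/T)A"
    ),
    hotspot_multiplier = 5,
    standing_freq = list(shape1 = 0.8, shape2 = 0.8, min = 0.1, max = 0.9),
    derived_freq = NULL,
    derived_freq_base = 0.15,
    derived_freq_shape = 15,
    bottleneck_retention = 0.9,
    drift_kappa = 30,
    group_kappa = 60,
    inbreeding = 0.95,
    missing_rate = 0.02,
    sweeps_per_chrom = 3,
    sweep_width = 1e5,
    sweep_snps = 30,
    sweep_freq = 0.6,
    sweep_at_bias = 5,
    causal = NULL) {
  stopifnot(
    length(chromosomes) >= 1, all(chromosomes >= 1e4),
    gc >= 0, gc <= 1,
    all(group_sizes >= 2),
    standing_per_mb >= 0, new_per_mb >= 0,
    all(rate_multiplier > 0),
    all(type_weights >= 0), length(type_weights) == 6,
    gc_to_at_bias > 0, hotspot_multiplier >= 1,
    bottleneck_retention >= 0, bottleneck_retention <= 1,
    inbreeding >= 0, inbreeding <= 1,
    missing_rate >= 0, missing_rate < 1
  )
  sg <- subgenome_of(names(chromosomes))
  if (any(sg == "unassigned")) {
    stop("chromosome names must follow the wheat pattern (chr1A...)",
      call. = FALSE
    )
  }
  if (!setequal(names(type_weights), all_types())) {
    stop("type_weights must be named by the 6 transition types",
      call. = FALSE
    )
  }
  hp <- parse_motif(hotspot_motifs)
  if (any(paste(hp$b1, hp$b2, sep = "/") != "C/T")) {
    stop("hotspot motifs must be C/T-type", call. = FALSE)
  }
  if (is.null(derived_freq)) {
    derived_freq <- pmin(derived_freq_base * rate_multiplier, 0.45)
  }
  structure(
    list(
      seed = as.integer(seed), chromosomes = chromosomes, gc = gc,
      genes_per_mb = genes_per_mb, group_sizes = group_sizes,
      standing_per_mb = standing_per_mb, new_per_mb = new_per_mb,
      rate_multiplier = rate_multiplier, type_weights = type_weights,
      gc_to_at_bias = gc_to_at_bias, hotspot_motifs = hotspot_motifs,
      hotspot_multiplier = hotspot_multiplier,
      standing_freq = standing_freq, derived_freq = derived_freq,
      derived_freq_shape = derived_freq_shape,
      bottleneck_retention = bottleneck_retention,
      drift_kappa = drift_kappa, group_kappa = group_kappa,
      inbreeding = inbreeding, missing_rate = missing_rate,
      sweeps_per_chrom = sweeps_per_chrom, sweep_width = sweep_width,
      sweep_snps = sweep_snps, sweep_freq = sweep_freq,
      sweep_at_bias = sweep_at_bias, causal = causal
    ),
    class = "sim_config"
  )
}

random_seq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  idx <- sample.int(4, n, replace = TRUE, prob = p)
  rawToChar(charToRaw("ACGT")[idx])
}

#' Simulate reference genomes
#'
#' I.i.d. bases at the configured GC content; the hexaploid reference holds
#' all chromosomes, and progenitor references are its A+B (tetraploid) and D
#' (diploid) subsets. Byte-identical under the same seed.
#'
#' @param config A [sim_config] object.
#' @return List with [at_genome] elements `hexaploid`, `tetraploid`,
#'   `diploid`.
#' @export
simulate_references <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- with_seed(config$seed, {
    vapply(
      config$chromosomes,
      function(L) random_seq(L, config$gc), character(1)
    )
  })
  names(seqs) <- names(config$chromosomes)
  sg <- subgenome_of(names(seqs))
  maybe_genome <- function(x) if (length(x)) at_genome(x) else NULL
  list(
    hexaploid = at_genome(seqs),
    tetraploid = maybe_genome(seqs[sg %in% c("A", "B")]),
    diploid = maybe_genome(seqs[sg == "D"])
  )
}

SENSE_CODONS <- setdiff(
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"], "ATG"
)
STOP_CODONS <- names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE == "*"
]

# one gene: coding-order segment plan plus genomic feature rows
build_gene <- function(chrom, slot_start, slot_end, gene_id) {
  u5 <- sample(80:250, 1)
  u3 <- sample(120:300, 1)
  n_exon <- sample(1:3, 1)
  codons <- sample(100:300, 1)
  cds_len <- 3 * codons
  cut <- sort(sample(seq_len(cds_len - 1), n_exon - 1))
  cds_pieces <- diff(c(0, cut, cds_len)) # widths in coding (5'->3') order
  introns <- if (n_exon > 1) sample(100:400, n_exon - 1, replace = TRUE) else integer(0)
  span <- u5 + cds_len + sum(introns) + u3
  lo <- slot_start
  hi <- slot_end - span
  if (hi <= lo) {
    return(NULL)
  }
  start <- sample(lo:hi, 1)
  strand <- sample(c("+", "-"), 1)
  # genomic widths left to right: for "-" the coding order runs right to
  # left, so the leftmost genomic piece is the last coding piece
  w_gen <- if (strand == "+") cds_pieces else rev(cds_pieces)
  # coding-sequence offset of each genomic piece
  offs <- if (strand == "+") {
    c(0, cumsum(w_gen))[seq_len(n_exon)]
  } else {
    cds_len - cumsum(w_gen)
  }
  # genomic layout left to right: utrL, cds1, intron1, cds2, ..., utrR
  pos <- start
  utrL <- c(pos, pos + u5 - 1)
  pos <- pos + u5
  cds <- matrix(NA_integer_, n_exon, 2)
  for (k in seq_len(n_exon)) {
    cds[k, ] <- c(pos, pos + w_gen[k] - 1)
    pos <- pos + w_gen[k]
    if (k < n_exon) pos <- pos + introns[k]
  }
  utrR <- c(pos, pos + u3 - 1)
  end <- pos + u3 - 1
  # coding sequence: ATG + sense codons + stop
  coding <- paste0(
    c("ATG", sample(SENSE_CODONS, codons - 2, replace = TRUE),
      sample(STOP_CODONS, 1)),
    collapse = ""
  )
  pieces_seq <- vapply(seq_len(n_exon), function(k) {
    piece <- substring(coding, offs[k] + 1, offs[k] + w_gen[k])
    if (strand == "-") revcomp_string(piece) else piece
  }, character(1))
  if (strand == "-") {
    utr5 <- utrR
    utr3 <- utrL
  } else {
    utr5 <- utrL
    utr3 <- utrR
  }
  # GFF phase per genomic CDS row, accumulated in coding order
  ord <- if (strand == "+") seq_len(n_exon) else rev(seq_len(n_exon))
  phase <- integer(n_exon)
  done <- 0
  for (k in ord) {
    phase[k] <- (3 - done %% 3) %% 3
    done <- done + w_gen[k]
  }
  tx <- paste0(gene_id, ".1")
  feat <- tibble::tibble(
    chrom = chrom,
    type = c(
      "gene", "mRNA", "five_prime_UTR", "three_prime_UTR",
      rep("CDS", n_exon)
    ),
    start = c(start, start, utr5[1], utr3[1], cds[, 1]),
    end = c(end, end, utr5[2], utr3[2], cds[, 2]),
    strand = strand,
    phase = c(rep(NA_integer_, 4), phase),
    gene_id = gene_id,
    transcript_id = c(NA, rep(tx, 3 + n_exon))
  )
  # exon rows: utr blocks merged with adjacent CDS
  blocks <- rbind(utrL, cds, utrR)
  blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
  merged <- list(blocks[1, ])
  for (k in 2:nrow(blocks)) {
    last <- merged[[length(merged)]]
    if (blocks[k, 1] <= last[2] + 1) {
      merged[[length(merged)]][2] <- max(last[2], blocks[k, 2])
    } else {
      merged[[length(merged) + 1]] <- blocks[k, ]
    }
  }
  exons <- do.call(rbind, merged)
  feat <- dplyr::bind_rows(
    feat,
    tibble::tibble(
      chrom = chrom, type = "exon",
      start = exons[, 1], end = exons[, 2], strand = strand,
      phase = NA_integer_, gene_id = gene_id, transcript_id = tx
    )
  )
  list(features = feat, cds = cds, pieces_seq = pieces_seq)
}

#' Simulate gene models and write their coding sequences into the genome
#'
#' Places non-overlapping genes (UTR / CDS / intron structure on both
#' strands) with at least 10 kb of intergenic space between neighbours.
#' Every CDS starts with ATG, ends with a stop codon, contains no internal
#' stop and has length divisible by three; the coding sequence is written
#' into the reference so downstream codon arithmetic is consistent.
#'
#' @param config A [sim_config] object.
#' @param genome The hexaploid [at_genome] from [simulate_references()].
#' @return List with `models` ([at_gene_models]) and `genome` (the edited
#'   [at_genome]).
#' @export
simulate_gene_models <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "at_genome"))
  res <- with_seed(config$seed + 1L, {
    feats <- list()
    seqs <- genome$seq
    for (cn in names(seqs)) {
      L <- genome$lengths[[cn]]
      n_genes <- round(config$genes_per_mb * L / 1e6)
      if (n_genes < 1) next
      slot <- floor(L / n_genes)
      margin <- 6000 # keeps >= 10 kb between genes and space for proximal
      raw <- charToRaw(seqs[[cn]])
      for (g in seq_len(n_genes)) {
        gid <- sprintf("gene.%s.%03d", cn, g)
        s0 <- (g - 1) * slot + margin
        s1 <- g * slot - margin
        gene <- build_gene(cn, s0, s1, gid)
        if (is.null(gene)) next
        for (k in seq_len(nrow(gene$cds))) {
          raw[gene$cds[k, 1]:gene$cds[k, 2]] <-
            charToRaw(gene$pieces_seq[k])
        }
        feats[[length(feats) + 1]] <- gene$features
      }
      seqs[[cn]] <- rawToChar(raw)
    }
    ft <- dplyr::bind_rows(feats)
    if (nrow(ft) == 0) {
      ft <- tibble::tibble(
        chrom = character(), type = character(), start = integer(),
        end = integer(), strand = character(), phase = integer(),
        gene_id = character(), transcript_id = character()
      )
    }
    list(feats = ft, seqs = seqs)
  })
  list(
    models = at_gene_models(res$feats),
    genome = at_genome(res$seqs)
  )
}

# donor -> candidate derived bases with spectrum weights; returns an
# n x 3 weight matrix and the matching derived-base matrix
derived_weight_matrix <- function(ref, left, right, config,
                                  at_bias, use_hotspots) {
  alts <- t(vapply(ref, function(b) setdiff(BASES, b), character(3)))
  w <- matrix(0, nrow = length(ref), ncol = 3)
  hot_ct <- parse_motif(config$hotspot_motifs)
  ct_contexts <- paste0(hot_ct$left, "C", hot_ct$right)
  ga_contexts <- vapply(ct_contexts, revcomp_string, character(1))
  ctx <- paste0(left, ref, right)
  for (j in 1:3) {
    d <- alts[, j]
    key <- paste(pmin(ref, d), pmax(ref, d), sep = "/")
    wj <- unname(config$type_weights[key])
    bias <- ifelse(ref %in% c("C", "G") & d %in% c("A", "T"), at_bias, 1)
    hot <- rep(1, length(ref))
    if (use_hotspots) {
      hot <- ifelse(
        (ref == "C" & d == "T" & ctx %in% ct_contexts) |
          (ref == "G" & d == "A" & ctx %in% ga_contexts),
        config$hotspot_multiplier, 1
      )
    }
    w[, j] <- wj * bias * hot
  }
  list(weights = w, alts = alts)
}

# maximum possible total mutability of a single site, for rejection sampling
max_site_weight <- function(config, at_bias, use_hotspots) {
  tw <- config$type_weights
  mult <- if (use_hotspots) config$hotspot_multiplier else 1
  max(
    tw[["A/C"]] * at_bias + tw[["C/G"]] + tw[["C/T"]] * at_bias * mult,
    tw[["A/C"]] + tw[["A/G"]] + tw[["A/T"]],
    tw[["A/T"]] + tw[["C/T"]] + tw[["G/T"]]
  )
}

# sample `n` mutated sites on the given chromosomes; returns a tibble with
# chrom, pos, ref (donor), alt (derived)
sample_mutations <- function(n, chroms, genome, config,
                             at_bias = 1, use_hotspots = FALSE,
                             mutability_weighted = FALSE,
                             intervals = NULL) {
  if (n <= 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(),
      ref = character(), alt = character()
    ))
  }
  lens <- genome$lengths[chroms]
  wmax <- max_site_weight(config, at_bias, use_hotspots)
  out <- list()
  got <- 0
  tries <- 0
  while (got < n && tries < 50) {
    tries <- tries + 1
    m <- ceiling((n - got) * (if (mutability_weighted) wmax * 1.3 else 1.2))
    m <- min(m, 5e6)
    if (is.null(intervals)) {
      ci <- sample(seq_along(chroms), m, replace = TRUE, prob = lens)
      cn <- chroms[ci]
      pos <- 2L + as.integer(floor(runif(m) * (lens[ci] - 2)))
    } else {
      ii <- sample(nrow(intervals), m, replace = TRUE,
        prob = intervals$end - intervals$start
      )
      cn <- intervals$chrom[ii]
      pos <- intervals$start[ii] +
        as.integer(floor(runif(m) * (intervals$end[ii] - intervals$start[ii])))
    }
    ref <- unname(substring(genome$seq[cn], pos, pos))
    left <- unname(substring(genome$seq[cn], pos - 1, pos - 1))
    right <- unname(substring(genome$seq[cn], pos + 1, pos + 1))
    dw <- derived_weight_matrix(ref, left, right, config, at_bias,
      use_hotspots
    )
    tot <- rowSums(dw$weights)
    acc <- if (mutability_weighted) runif(m) < tot / wmax else tot > 0
    idx <- which(acc)
    if (!length(idx)) next
    # derived base drawn proportionally to its weight
    u <- runif(length(idx)) * tot[idx]
    cw1 <- dw$weights[idx, 1]
    cw2 <- cw1 + dw$weights[idx, 2]
    pick <- 1L + (u >= cw1) + (u >= cw2)
    alt <- dw$alts[cbind(idx, pick)]
    out[[length(out) + 1]] <- tibble::tibble(
      chrom = cn[idx], pos = pos[idx], ref = ref[idx], alt = alt
    )
    got <- got + length(idx)
  }
  dplyr::bind_rows(out) |>
    dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    head(n)
}

rbeta_jitter <- function(f, kappa) {
  out <- f
  mid <- f > 0 & f < 1
  out[mid] <- rbeta(sum(mid), f[mid] * kappa, (1 - f[mid]) * kappa)
  out
}

# genotype draws under partial selfing: P(hom alt) = f^2 + F f (1-f),
# P(het) = 2 f (1-f) (1-F); mean dosage is exactly f
draw_dosage <- function(fmat, inbreeding, missing_rate) {
  p_hom <- fmat^2 + inbreeding * fmat * (1 - fmat)
  p_het <- 2 * fmat * (1 - fmat) * (1 - inbreeding)
  u <- matrix(runif(length(fmat)), nrow = nrow(fmat))
  g <- (u < p_hom) * 1 + (u >= p_hom & u < p_hom + p_het) * 0.5
  if (missing_rate > 0) {
    g[matrix(runif(length(g)) < missing_rate, nrow = nrow(g))] <- NA
  }
  g
}

#' Simulate an allopolyploid domestication cohort
#'
#' Generates references, gene models, selective sweeps and a genotyped
#' population with two variant strata per subgenome: standing variants
#' shared between wild and domesticated groups (symmetric baseline
#' spectrum, Beta-distributed frequencies, thinned in the domesticated
#' groups by the bottleneck) and domesticated-branch new variants private
#' to the hexaploid groups (GC-to-AT-biased spectrum with motif hotspots,
#' count and mean frequency scaled by the per-subgenome rate multiplier).
#' Sweep intervals receive extra clustered, strongly AT-biased swept
#' variants. Every emitted site is recorded in a truth ledger.
#'
#' @param config A [sim_config] object.
#' @return List of class `at_sim` with elements `geno` ([at_geno]),
#'   `panel` ([at_panel]), `genome` (gene-edited hexaploid [at_genome]),
#'   `references` (progenitor genomes), `models`, `sweeps`, `truth`
#'   (ledger tibble), `config`. The ledger's attributes record the hotspot
#'   motif set (both strands) and any causal-marker plan.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  refs <- simulate_references(config)
  gm <- simulate_gene_models(config, refs$hexaploid)
  genome <- gm$genome
  groups <- names(config$group_sizes)
  panel <- at_panel(tibble::tibble(
    accession = unlist(purrr::imap(
      config$group_sizes,
      function(nacc, g) sprintf("%s_%02d", g, seq_len(nacc))
    ), use.names = FALSE),
    group = rep(groups, config$group_sizes)
  ))
  sgmap <- group_subgenomes(panel)
  chrom_sg <- subgenome_of(names(config$chromosomes))

  with_seed(config$seed + 2L, {
    # selective sweep intervals
    sweeps <- purrr::map_dfr(names(config$chromosomes), function(cn) {
      k <- config$sweeps_per_chrom
      if (k < 1) {
        return(NULL)
      }
      L <- config$chromosomes[[cn]]
      slot <- floor(L / k)
      starts <- vapply(seq_len(k), function(i) {
        lo <- (i - 1) * slot + 1
        hi <- i * slot - config$sweep_width
        if (hi <= lo) NA_integer_ else sample(lo:hi, 1)
      }, integer(1))
      starts <- starts[!is.na(starts)]
      tibble::tibble(
        chrom = cn, start = as.integer(starts),
        end = as.integer(starts + config$sweep_width - 1),
        label = sprintf("sweep_%s_%d", cn, seq_along(starts))
      )
    })
    if (nrow(sweeps) == 0) {
      sweeps <- tibble::tibble(
        chrom = character(), start = integer(), end = integer(),
        label = character()
      )
    }

    site_list <- list()
    freq_list <- list()
    for (sg in unique(chrom_sg)) {
      chroms <- names(config$chromosomes)[chrom_sg == sg]
      mb <- sum(config$chromosomes[chroms]) / 1e6
      mult <- config$rate_multiplier[[sg]]
      wild_grp <- if (sg == "D") "ae_tauschii" else "wild_emmer"
      dom_grps <- c("landrace_east", "landrace_west", "variety")

      # stratum 1: standing shared variation
      n_st <- round(config$standing_per_mb * mb)
      st <- sample_mutations(n_st, chroms, genome, config)
      sf <- config$standing_freq
      f_w <- sf$min + (sf$max - sf$min) *
        rbeta(nrow(st), sf$shape1, sf$shape2)
      lost <- runif(nrow(st)) > config$bottleneck_retention
      f_dom <- rbeta_jitter(f_w, config$drift_kappa)
      f_dom[lost] <- rbinom(sum(lost), 1, f_w[lost])
      f_dur <- rbeta_jitter(f_w, config$drift_kappa)
      fq <- matrix(NA_real_, nrow(st), length(groups),
        dimnames = list(NULL, groups)
      )
      fq[, wild_grp] <- f_w
      if (sg != "D") fq[, "durum"] <- f_dur
      for (g in dom_grps) {
        fq[, g] <- rbeta_jitter(f_dom, config$group_kappa)
      }
      st$stratum <- "standing"
      st$freq_wild <- f_w
      st$freq_dom <- f_dom

      # stratum 2: domesticated-branch new variants (hexaploid-private)
      n_new <- round(config$new_per_mb * mb * mult)
      nv <- sample_mutations(n_new, chroms, genome, config,
        at_bias = config$gc_to_at_bias, use_hotspots = TRUE,
        mutability_weighted = TRUE
      )
      m_new <- config$derived_freq[[sg]]
      k <- config$derived_freq_shape
      f_site <- rbeta(nrow(nv), m_new * k, (1 - m_new) * k)
      fq_new <- matrix(NA_real_, nrow(nv), length(groups),
        dimnames = list(NULL, groups)
      )
      fq_new[, wild_grp] <- 0
      if (sg != "D") fq_new[, "durum"] <- 0
      for (g in dom_grps) {
        fq_new[, g] <- rbeta_jitter(f_site, config$group_kappa)
      }
      nv$stratum <- "new"
      nv$freq_wild <- 0
      nv$freq_dom <- f_site

      # stratum 3: swept variants clustered inside sweep intervals
      sw_here <- dplyr::filter(sweeps, .data$chrom %in% chroms)
      n_sw <- config$sweep_snps * nrow(sw_here)
      sv <- sample_mutations(n_sw, chroms, genome, config,
        at_bias = config$sweep_at_bias, use_hotspots = TRUE,
        mutability_weighted = TRUE, intervals = sw_here
      )
      f_sw <- rbeta(
        nrow(sv), config$sweep_freq * 10, (1 - config$sweep_freq) * 10
      )
      fq_sw <- matrix(NA_real_, nrow(sv), length(groups),
        dimnames = list(NULL, groups)
      )
      fq_sw[, wild_grp] <- 0
      if (sg != "D") fq_sw[, "durum"] <- 0
      for (g in dom_grps) {
        fq_sw[, g] <- rbeta_jitter(f_sw, config$group_kappa)
      }
      sv$stratum <- "sweep_new"
      sv$freq_wild <- 0
      sv$freq_dom <- f_sw

      sites_sg <- dplyr::bind_rows(st, nv, sv)
      fq_all <- rbind(fq, fq_new, fq_sw)
      dup <- duplicated(paste(sites_sg$chrom, sites_sg$pos))
      sites_sg <- sites_sg[!dup, , drop = FALSE]
      fq_all <- fq_all[!dup, , drop = FALSE]
      sites_sg$subgenome <- sg
      site_list[[sg]] <- sites_sg
      freq_list[[sg]] <- fq_all
    }

    sites <- dplyr::bind_rows(site_list)
    fq <- do.call(rbind, freq_list)
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    fq <- fq[ord, , drop = FALSE]
    n_sites <- nrow(sites)

    # genotypes: standing sites first (they feed the causal latent), then
    # new/swept sites whose per-accession frequency the latent may modulate
    acc <- panel$accession
    dosage <- matrix(NA_real_, length(acc), n_sites)
    is_new <- sites$stratum != "standing"
    for (g in groups) {
      rows <- which(panel$group == g)
      carried <- sites$subgenome %in% sgmap[[g]]
      cols <- which(carried & !is_new)
      if (length(cols)) {
        fmat <- matrix(fq[cols, g],
          nrow = length(rows), ncol = length(cols), byrow = TRUE
        )
        dosage[rows, cols] <- draw_dosage(
          fmat, config$inbreeding, config$missing_rate
        )
      }
    }

    causal_plan <- NULL
    latent <- setNames(rep(0, length(acc)), acc)
    if (!is.null(config$causal)) {
      ncm <- config$causal$n_markers %||% 2L
      gamma <- config$causal$gamma %||% 0.5
      hex_rows <- which(panel$group %in% c(
        "landrace_east", "landrace_west", "variety"
      ))
      cand <- which(!is_new)
      pvar <- colMeans(dosage[hex_rows, cand, drop = FALSE], na.rm = TRUE)
      cand <- cand[!is.na(pvar) & pvar > 0.2 & pvar < 0.8]
      cm <- sample(cand, min(ncm, length(cand)))
      z <- scale(rowSums(dosage[hex_rows, cm, drop = FALSE], na.rm = TRUE))
      latent[hex_rows] <- as.numeric(z)
      causal_plan <- tibble::tibble(
        chrom = sites$chrom[cm], pos = sites$pos[cm], gamma = gamma
      )
    }
    gamma <- if (is.null(config$causal)) 0 else config$causal$gamma %||% 0.5
    for (g in groups) {
      rows <- which(panel$group == g)
      carried <- sites$subgenome %in% sgmap[[g]]
      cols <- which(carried & is_new)
      if (length(cols)) {
        fmat <- matrix(fq[cols, g],
          nrow = length(rows), ncol = length(cols), byrow = TRUE
        )
        if (gamma != 0) {
          fac <- pmin(pmax(1 + gamma * latent[panel$accession[rows]], 0.1), 3)
          fmat <- pmin(fmat * fac, 0.99)
        }
        dosage[rows, cols] <- draw_dosage(
          fmat, config$inbreeding, config$missing_rate
        )
      }
    }

    truth <- sites |>
      dplyr::mutate(
        donor = ifelse(.data$stratum == "standing", NA_character_, .data$ref),
        derived = ifelse(.data$stratum == "standing", NA_character_, .data$alt),
        motif = motif_of(
          tibble::tibble(
            chrom = sites$chrom, pos = sites$pos,
            ref = sites$ref, alt = sites$alt
          ),
          genome
        )
      )
    attr(truth, "hotspot_motifs") <- unique(c(
      config$hotspot_motifs, revcomp_motif(config$hotspot_motifs)
    ))
    attr(truth, "causal") <- causal_plan

    geno <- at_geno(
      dplyr::select(
        sites, "chrom", "pos", "ref", "alt", "subgenome"
      ),
      dosage, acc
    )
    structure(
      list(
        geno = geno, panel = panel, genome = genome,
        references = refs, models = gm$models, sweeps = sweeps,
        truth = truth, config = config
      ),
      class = "at_sim"
    )
  })
}

#' @export
print.at_sim <- function(x, ...) {
  cat("<at_sim> ", length(x$geno$accessions), " accessions, ",
    nrow(x$geno$sites), " SNPs on ",
    length(x$config$chromosomes), " chromosomes\n",
    sep = ""
  )
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the hexaploid and progenitor FASTAs, the cohort VCF, the panel
#' TSV, the gene models GFF3, the sweep BED and the truth ledger TSV.
#'
#' @param sim An `at_sim` object from [simulate_population()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "at_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$genome, file.path(dir, "hexaploid.fa"))
  write_genome(sim$references$tetraploid, file.path(dir, "tetraploid.fa"))
  write_genome(sim$references$diploid, file.path(dir, "diploid.fa"))
  write_vcf(sim$geno, file.path(dir, "cohort.vcf"))
  write_panel(sim$panel, file.path(dir, "panel.tsv"))
  write_gff3(sim$models, file.path(dir, "genes.gff3"))
  if (nrow(sim$sweeps)) write_bed(sim$sweeps, file.path(dir, "sweeps.bed"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
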