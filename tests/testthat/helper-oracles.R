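# Independent brute-force oracles and tiny fixture builders. Every oracle
# deliberately uses plain loops / first-principles formulas so it shares no
# code path with the implementation it checks.

oracle_count_bases <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
  for (b in ch) n[b] <- n[b] + 1
  unname(n)
}

random_dna <- function(n, p_n = 0.02) {
  paste0(
    sample(c("A", "C", "G", "T", "N"), n,
      replace = TRUE,
      prob = c(rep((1 - p_n) / 4, 4), p_n)
    ),
    collapse = ""
  )
}

# random small genotype matrix
random_geno <- function(n_acc, n_sites, miss = 0.1,
                        chrom = "chr1A") {
  pos <- sort(sample.int(n_sites * 20, n_sites))
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  d <- matrix(
    sample(c(0, 0.5, 1, NA), n_acc * n_sites,
      replace = TRUE,
      prob = c((1 - miss) * c(0.5, 0.15, 0.35), miss)
    ),
    nrow = n_acc
  )
  at_geno(
    tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt),
    d, sprintf("acc%02d", seq_len(n_acc))
  )
}

# per-accession composition by explicit per-site loop
oracle_accession_composition <- function(geno) {
  out <- NULL
  for (i in seq_along(geno$accessions)) {
    s <- c(A = 0, C = 0, G = 0, T = 0)
    used <- 0
    for (j in seq_len(nrow(geno$sites))) {
      d <- geno$dosage[i, j]
      if (is.na(d)) next
      used <- used + 1
      s[geno$sites$ref[j]] <- s[geno$sites$ref[j]] + (1 - d)
      s[geno$sites$alt[j]] <- s[geno$sites$alt[j]] + d
    }
    out <- rbind(out, data.frame(
      accession = geno$accessions[i],
      sumA = s["A"], sumC = s["C"], sumG = s["G"], sumT = s["T"],
      n_sites_used = used,
      at_value = if (used > 0) (s["A"] + s["T"]) / sum(s) else NA_real_,
      row.names = NULL
    ))
  }
  out
}

oracle_site_filter <- function(geno, maf_min = 0.05, missing_max = 0.2) {
  keep <- logical(nrow(geno$sites))
  for (j in seq_len(nrow(geno$sites))) {
    d <- geno$dosage[, j]
    miss <- mean(is.na(d))
    f <- mean(d, na.rm = TRUE)
    maf <- min(f, 1 - f)
    keep[j] <- !is.nan(f) && maf >= maf_min && miss <= missing_max
  }
  which(keep)
}

oracle_motif_of <- function(sites, genome) {
  out <- character(nrow(sites))
  for (j in seq_len(nrow(sites))) {
    s <- genome$seq[[sites$chrom[j]]]
    p <- sites$pos[j]
    if (p <= 1 || p >= nchar(s)) {
      out[j] <- NA_character_
      next
    }
    l <- substr(s, p - 1, p - 1)
    r <- substr(s, p + 1, p + 1)
    if (l == "N" || r == "N") {
      out[j] <- NA_character_
      next
    }
    pair <- sort(c(sites$ref[j], sites$alt[j]))
    out[j] <- paste0(l, "(", pair[1], "/", pair[2], ")", r)
  }
  out
}

oracle_window_at <- function(geno, panel, chrom_lengths, window, step,
                             min_sites) {
  panel_tb <- tibble::as_tibble(panel)
  rows <- NULL
  for (cn in names(chrom_lengths)) {
    starts <- seq(1, chrom_lengths[[cn]], by = step)
    for (s in starts) {
      e <- min(s + window - 1, chrom_lengths[[cn]])
      if (e < s) next
      idx <- which(geno$sites$chrom == cn & geno$sites$pos >= s &
        geno$sites$pos <= e)
      for (g in unique(panel_tb$group)) {
        val <- NA_real_
        if (length(idx) >= min_sites) {
          accs <- panel_tb$accession[panel_tb$group == g]
          vals <- c()
          for (a in accs) {
            i <- match(a, geno$accessions)
            prof <- oracle_accession_composition(
              geno_subset(geno, sites = idx, accessions = geno$accessions[i])
            )
            vals <- c(vals, prof$at_value)
          }
          val <- mean(vals, na.rm = TRUE)
          if (is.nan(val)) val <- NA_real_
        }
        rows <- rbind(rows, data.frame(
          chrom = cn, start = s, end = e, group = g,
          at_value = val
        ))
      }
    }
  }
  rows
}

# independent recursive implementation of the protected multiple range
# procedure: returns the significance matrix over rank-ordered means
oracle_duncan_sig <- function(m, nn, mse, dfe, alpha) {
  k <- length(m)
  sig <- matrix(NA, k, k)
  mark_ns <- function(i, j) {
    for (a in i:j) for (b in i:j) if (a != b) sig[a, b] <<- FALSE
  }
  test_span <- function(i, j) {
    if (!is.na(sig[i, j])) {
      return(invisible())
    }
    p <- j - i + 1
    crit <- qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, dfe) *
      sqrt(mse / (2 / (1 / nn[i] + 1 / nn[j])))
    if ((m[i] - m[j]) > crit) {
      sig[i, j] <<- sig[j, i] <<- TRUE
      if (p > 2) {
        test_span(i, j - 1)
        test_span(i + 1, j)
      }
    } else {
      mark_ns(i, j)
    }
  }
  # top-level spans from widest to narrowest, left to right
  for (p in seq(k, 2)) {
    for (i in seq_len(k - p + 1)) test_span(i, i + p - 1)
  }
  diag(sig) <- FALSE
  sig
}

# derive the implied significance matrix from assigned letters: two groups
# differ iff they share no letter
letters_to_sig <- function(letter) {
  k <- length(letter)
  chars <- strsplit(letter, "")
  outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
    length(intersect(chars[[i]], chars[[j]])) == 0
  }))
}

# structured cohort for LMM tests: two subpopulations, Balding-Nichols-type
# frequency divergence, dosages on the {0, 0.5, 1} scale
sim_structured_geno <- function(n_acc = 60, n_sites = 500, fst = 0.15,
                                chrom = "chr1A") {
  half <- n_acc %/% 2
  p0 <- runif(n_sites, 0.1, 0.9)
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  p1 <- rbeta(n_sites, a, b)
  p2 <- rbeta(n_sites, a, b)
  draw <- function(p, n) {
    f <- matrix(p, nrow = n, ncol = length(p), byrow = TRUE)
    u <- matrix(runif(n * length(p)), nrow = n)
    (u < f^2) * 1 + (u >= f^2 & u < f^2 + 2 * f * (1 - f) * 0.1) * 0.5
  }
  d <- rbind(draw(p1, half), draw(p2, n_acc - half))
  d[d != 0 & d != 0.5 & d != 1] <- 0
  keep <- apply(d, 2, var) > 0
  d <- d[, keep, drop = FALSE]
  at_geno(
    tibble::tibble(
      chrom = chrom, pos = seq_len(ncol(d)) * 1000L,
      ref = "A", alt = "G"
    ),
    d, sprintf("acc%03d", seq_len(n_acc))
  )
}

hexaploid_groups <- c("landrace_east", "landrace_west", "variety")

# group-mean Delta[AT] per subgenome through the standard pipeline
pipeline_delta_at <- function(sim, per_accession = FALSE) {
  panel <- sim$panel
  res <- list()
  for (sg in c("A", "B", "D")) {
    idx <- which(sim$geno$sites$subgenome == sg)
    g <- geno_subset(sim$geno,
      sites = idx,
      accessions = carriers_of(panel, sg)
    )
    g <- suppressMessages(filter_sites(g))
    prof <- accession_composition(g)
    prof <- dplyr::inner_join(prof, tibble::as_tibble(panel),
      by = "accession"
    )
    wild <- if (sg == "D") "ae_tauschii" else "wild_emmer"
    wild_mean <- mean(prof$at_value[prof$group == wild], na.rm = TRUE)
    dom <- prof[prof$group %in% hexaploid_groups, ]
    if (per_accession) {
      res[[sg]] <- tibble::tibble(
        subgenome = sg, accession = dom$accession,
        delta = dom$at_value - wild_mean
      )
    } else {
      res[[sg]] <- tibble::tibble(
        subgenome = sg, delta = mean(dom$at_value, na.rm = TRUE) - wild_mean
      )
    }
  }
  dplyr::bind_rows(res)
}
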