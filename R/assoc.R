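#' Pairwise linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of the dosage vectors of two sites over the
#' accessions non-missing at both.
#'
#' @param geno An [at_geno] object.
#' @param site_i,site_j Site indices (into `geno$sites`).
#' @return r-squared in `[0, 1]`, `NA` when either site has no variance
#'   over the shared accessions.
#' @export
ld_r2 <- function(geno, site_i, site_j) {
  x <- geno$dosage[, site_i]
  y <- geno$dosage[, site_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2 || var(x[ok]) == 0 || var(y[ok]) == 0) {
    return(NA_real_)
  }
  cor(x[ok], y[ok])^2
}

#' Window-based LD pruning
#'
#' PLINK-style variant thinning: within each `window`-SNP window (per
#' chromosome, sites in position order) any pair with r-squared above
#' `r2_max` loses its later-position member; the window then slides by
#' `step` SNPs. Deterministic, and idempotent on its own output when
#' `step == window`.
#'
#' @param geno An [at_geno] object.
#' @param window Window size in SNPs.
#' @param step Slide in SNPs.
#' @param r2_max Maximum allowed pairwise r-squared.
#' @return Integer vector of retained site indices.
#' @export
ld_prune <- function(geno, window = 50, step = 50, r2_max = 0.3) {
  stopifnot(inherits(geno, "at_geno"), window >= 2, step >= 1)
  keep <- rep(TRUE, nrow(geno$sites))
  for (cn in unique(geno$sites$chrom)) {
    idx <- which(geno$sites$chrom == cn) # already position-sorted
    for (w0 in seq(1, length(idx), by = step)) {
      w <- idx[w0:min(w0 + window - 1, length(idx))]
      w <- w[keep[w]]
      if (length(w) < 2) next
      cc <- suppressWarnings(
        cor(geno$dosage[, w, drop = FALSE], use = "pairwise.complete.obs")^2
      )
      for (a in seq_len(length(w) - 1)) {
        if (!keep[w[a]]) next
        drop <- which(!is.na(cc[a, ]) & cc[a, ] > r2_max)
        drop <- drop[drop > a]
        keep[w[drop]] <- FALSE
      }
    }
  }
  which(keep)
}

#' Kinship (genomic relationship) matrix
#'
#' Frequency-standardized cross-product of centered dosages averaged over
#' markers (VanRaden-type GRM on the allele-fraction scale). Missing
#' dosages are mean-imputed per site; monomorphic sites are dropped.
#'
#' @param geno An [at_geno] object.
#' @return Symmetric accession x accession matrix.
#' @export
kinship <- function(geno) {
  stopifnot(inherits(geno, "at_geno"), length(geno$accessions) >= 2)
  z <- impute_standardize(geno$dosage)
  k <- tcrossprod(z) / ncol(z)
  dimnames(k) <- list(geno$accessions, geno$accessions)
  k
}

impute_standardize <- function(d, standardize = TRUE) {
  p <- colMeans(d, na.rm = TRUE)
  keep <- !is.na(p) & p > 0 & p < 1
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- p[idx[, 2]]
  z <- sweep(d, 2, p)
  if (standardize) z <- sweep(z, 2, sqrt(p * (1 - p)), "/")
  z
}

#' Correlation between the [AT] phenotype and PC1 of the genotypes
#'
#' PCA of the centered (mean-imputed) dosage matrix; reports the absolute
#' Pearson correlation between per-accession [AT] values and the first
#' principal-component score, since the sign of a PC is arbitrary.
#'
#' @param geno An [at_geno] object.
#' @param profiles Tibble with `accession` and `at_value` (e.g. from
#'   [accession_composition()]).
#' @return One-row tibble with `r_abs`, `r_signed` (PC1 oriented to
#'   correlate positively with the first accession's... see Details),
#'   `pc1_var_frac`.
#' @details The signed correlation is reported with PC1 oriented so that
#'   its loading-sum is positive, a fixed but arbitrary convention; use
#'   `r_abs` for interpretation.
#' @export
at_pc1_correlation <- function(geno, profiles) {
  stopifnot(inherits(geno, "at_geno"), length(geno$accessions) >= 3)
  at <- profiles$at_value[match(geno$accessions, profiles$accession)]
  ok <- !is.na(at)
  z <- impute_standardize(geno$dosage[ok, , drop = FALSE],
    standardize = FALSE
  )
  z <- z[, apply(z, 2, var) > 0, drop = FALSE]
  if (ncol(z) < 2) stop("degenerate genotype matrix for PCA", call. = FALSE)
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  score <- pc$x[, 1]
  if (sum(pc$rotation[, 1]) < 0) score <- -score
  r <- cor(at[ok], score)
  tibble::tibble(
    r_abs = abs(r), r_signed = r,
    pc1_var_frac = pc$sdev[1]^2 / sum(pc$sdev^2)
  )
}

# restricted log-likelihood of the single-variance-ratio mixed model in the
# eigenrotated basis; delta = sigma_e^2 / sigma_g^2
reml_loglik <- function(delta, yr, xr, ev) {
  v <- ev + delta
  w <- 1 / v
  xtx <- crossprod(xr, xr * w)
  xty <- crossprod(xr, yr * w)
  beta <- solve(xtx, xty)
  res <- yr - xr %*% beta
  rss <- sum(res^2 * w)
  n <- length(yr)
  q <- ncol(xr)
  -0.5 * ((n - q) * log(rss) + sum(log(v)) + determinant(xtx)$modulus)
}

#' Single-marker linear mixed model scan
#'
#' Fits `y = mu + x beta + g + e` with `g ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`. The kinship matrix is eigendecomposed once; the
#' variance ratio `delta = sigma_e^2 / sigma_g^2` is estimated by restricted
#' maximum likelihood under the null (log-spaced grid search with local
#' refinement) and reused for every marker, which are then tested by a Wald
#' t-test in the whitened model. With `K = I` the scan reduces exactly to
#' ordinary least-squares marker regression.
#'
#' @param geno An [at_geno] object (typically LD-pruned).
#' @param phenotype Named numeric vector (names = accessions) or a tibble
#'   with `accession` and `at_value` columns.
#' @param K Kinship matrix from [kinship()]; accessions must match `geno`.
#' @return An object of class `at_lmm_scan`: list with `results` (per-marker
#'   tibble: `chrom`, `pos`, `beta`, `se`, `statistic`, `p_value`,
#'   `neg_log10_p`), `delta`, `sigma_g2`, `sigma_e2`, `h2`, `n`, `n_markers`.
#' @export
lmm_scan <- function(geno, phenotype, K) {
  stopifnot(inherits(geno, "at_geno"))
  if (is.data.frame(phenotype)) {
    phenotype <- setNames(phenotype$at_value, phenotype$accession)
  }
  acc <- geno$accessions
  if (!all(acc %in% names(phenotype)) || anyNA(phenotype[acc])) {
    stop("phenotype must be defined for every accession", call. = FALSE)
  }
  y <- unname(phenotype[acc])
  K <- K[acc, acc]
  n <- length(y)
  ee <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(ee$values) < -1e-8) {
    warning("kinship not positive semidefinite; negative eigenvalues clipped",
      call. = FALSE
    )
  }
  ev <- pmax(ee$values, 0)
  U <- ee$vectors
  yr <- drop(crossprod(U, y))
  ones_r <- drop(crossprod(U, rep(1, n)))

  grid <- 10^seq(-5, 5, length.out = 61)
  ll <- vapply(
    grid, reml_loglik,
    numeric(1),
    yr = yr, xr = cbind(ones_r), ev = ev
  )
  i0 <- which.max(ll)
  lo <- grid[max(1, i0 - 1)]
  hi <- grid[min(length(grid), i0 + 1)]
  opt <- optimize(
    function(ld) {
      reml_loglik(exp(ld), yr, cbind(ones_r), ev)
    },
    interval = log(c(lo, hi)), maximum = TRUE
  )
  delta <- exp(opt$maximum)

  w <- 1 / (ev + delta)
  d <- geno$dosage
  p <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- p[idx[, 2]]
  xr <- crossprod(U, d) # n x m rotated markers

  # vectorized weighted regression of yr on [1, x] per marker
  s11 <- sum(w * ones_r^2)
  s1y <- sum(w * ones_r * yr)
  syy <- sum(w * yr^2)
  s1x <- unname(drop(crossprod(ones_r * w, xr)))
  sxx <- unname(drop(crossprod(rep(1, n), xr^2 * w)))
  sxy <- unname(drop(crossprod(yr * w, xr)))
  det2 <- s11 * sxx - s1x^2
  singular <- det2 <= 1e-12 * s11 * pmax(sxx, .Machine$double.eps)
  beta <- (s11 * sxy - s1x * s1y) / det2
  mu <- (sxx * s1y - s1x * sxy) / det2
  rss <- syy - mu * s1y - beta * sxy
  dfres <- n - 2
  se <- sqrt(pmax(rss, 0) / dfres * s11 / det2)
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), dfres)
  beta[singular] <- se[singular] <- tstat[singular] <- pval[singular] <- NA

  # null-model variance components at the estimated ratio
  b0 <- s1y / s11
  rss0 <- syy - 2 * b0 * s1y + b0^2 * s11
  sigma_g2 <- rss0 / (n - 1)
  sigma_e2 <- delta * sigma_g2

  results <- tibble::tibble(
    chrom = geno$sites$chrom, pos = geno$sites$pos,
    ref = geno$sites$ref, alt = geno$sites$alt,
    beta = beta, se = se, statistic = tstat, p_value = pval,
    neg_log10_p = -log10(pval)
  )
  structure(
    list(
      results = results, delta = delta,
      sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
      h2 = 1 / (1 + delta), n = n, n_markers = sum(!singular)
    ),
    class = "at_lmm_scan"
  )
}

#' @export
print.at_lmm_scan <- function(x, ...) {
  cat("<at_lmm_scan> ", x$n_markers, " markers, n = ", x$n,
    ", h2 = ", signif(x$h2, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.at_lmm_scan <- function(x, ...) {
  x$results
}

#' @exportS3Method generics::glance
glance.at_lmm_scan <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_markers = x$n_markers, delta = x$delta,
    sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, h2 = x$h2,
    min_p = min(x$results$p_value, na.rm = TRUE)
  )
}

#' Significant loci from a scan
#'
#' Markers at or above the `-log10(p)` threshold, merged into loci when
#' within `merge_bp` of each other on the same chromosome.
#'
#' @param scan An `at_lmm_scan` object.
#' @param threshold_neglogp Significance threshold on `-log10(p)`.
#' @param merge_bp Markers closer than this are one locus.
#' @return Tibble with `locus`, `chrom`, `start`, `end`, `n_snps`,
#'   `peak_pos`, `peak_neg_log10_p`.
#' @export
significant_loci <- function(scan, threshold_neglogp = 6, merge_bp = 5e6) {
  hits <- scan$results |>
    dplyr::filter(!is.na(.data$p_value), .data$neg_log10_p >= threshold_neglogp) |>
    dplyr::arrange(.data$chrom, .data$pos)
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      locus = character(), chrom = character(), start = integer(),
      end = integer(), n_snps = integer(), peak_pos = integer(),
      peak_neg_log10_p = double()
    ))
  }
  hits |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      cluster = cumsum(
        c(1, diff(.data$pos) > merge_bp)
      )
    ) |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos),
      n_snps = dplyr::n(),
      peak_pos = .data$pos[which.max(.data$neg_log10_p)],
      peak_neg_log10_p = max(.data$neg_log10_p),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      locus = paste0("qAT-", .data$chrom, "-", seq_len(dplyr::n()))
    ) |>
    dplyr::select(
      "locus", "chrom", "start", "end", "n_snps", "peak_pos",
      "peak_neg_log10_p"
    )
}

#' LD-defined candidate interval around a peak SNP
#'
#' All same-chromosome SNPs with r-squared above `r2_min` to the peak define
#' the interval (peak included); genes overlapping the interval are listed
#' when gene models are supplied.
#'
#' @param geno An [at_geno] object (the marker set used for LD).
#' @param peak_chrom,peak_pos Peak SNP coordinates.
#' @param r2_min Minimum r-squared to the peak for membership.
#' @param models Optional [at_gene_models] for the gene list.
#' @return List with `interval` (one-row tibble `chrom`, `start`, `end`,
#'   `peak_pos`, `n_members`), `members` (per-SNP r-squared tibble) and
#'   `genes` (character vector).
#' @export
candidate_interval <- function(geno, peak_chrom, peak_pos, r2_min = 0.6,
                               models = NULL) {
  pk <- which(geno$sites$chrom == peak_chrom & geno$sites$pos == peak_pos)
  if (length(pk) != 1) stop("peak SNP not found in scan set", call. = FALSE)
  x <- geno$dosage[, pk]
  if (var(x, na.rm = TRUE) == 0 || all(is.na(x))) {
    stop("peak SNP is monomorphic", call. = FALSE)
  }
  on_chrom <- which(geno$sites$chrom == peak_chrom)
  r2 <- vapply(on_chrom, function(j) ld_r2(geno, pk, j), numeric(1))
  member <- !is.na(r2) & r2 > r2_min
  member[on_chrom == pk] <- TRUE
  members <- tibble::tibble(
    chrom = peak_chrom,
    pos = geno$sites$pos[on_chrom][member],
    r2 = r2[member]
  )
  interval <- tibble::tibble(
    chrom = peak_chrom,
    start = min(members$pos), end = max(members$pos),
    peak_pos = peak_pos, n_members = nrow(members)
  )
  genes <- character(0)
  if (!is.null(models)) {
    g <- dplyr::filter(
      tibble::as_tibble(models),
      .data$type == "gene", .data$chrom == peak_chrom,
      .data$end >= interval$start, .data$start <= interval$end
    )
    genes <- unique(g$gene_id)
  }
  list(interval = interval, members = members, genes = genes)
}

#' Filter candidate genes on stable expression
#'
#' Keeps genes with TPM strictly above `tpm_min` in all listed tissues.
#' Genes absent from the expression table are treated as unexpressed, with
#' a warning.
#'
#' @param genes Character vector of gene ids.
#' @param expression Tibble with `gene`, `tissue`, `tpm` (see
#'   [read_expression()]).
#' @param tissues Tissues that must all pass.
#' @param tpm_min Expression threshold (strict).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(genes, expression,
                             tissues = c("root", "shoot"), tpm_min = 1) {
  missing_genes <- setdiff(
    genes, unique(expression$gene[expression$tissue %in% tissues])
  )
  if (length(missing_genes)) {
    warning(
      length(missing_genes),
      " gene(s) absent from the expression table treated as TPM 0",
      call. = FALSE
    )
  }
  keep <- expression |>
    dplyr::filter(.data$gene %in% genes, .data$tissue %in% tissues) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      ok = dplyr::n_distinct(.data$tissue) == length(tissues) &
        all(.data$tpm > tpm_min),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$ok)
  genes[genes %in% keep$gene]
}
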