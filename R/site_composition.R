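#' Per-site allele-frequency and missingness statistics
#'
#' Alternate-allele frequency is the mean dosage over non-missing accessions;
#' the minor-allele frequency is `min(f, 1 - f)`. A site missing in every
#' accession gets `maf = NA` and `missing_rate = 1`.
#'
#' @param geno An [at_geno] object.
#' @param within Optional character vector of accession ids to compute the
#'   statistics within.
#' @return Tibble with columns `chrom`, `pos`, `n_called`, `f_alt`, `maf`,
#'   `missing_rate`.
#' @export
site_stats <- function(geno, within = NULL) {
  stopifnot(inherits(geno, "at_geno"))
  if (!is.null(within)) geno <- geno_subset(geno, accessions = within)
  d <- geno$dosage
  n_called <- colSums(!is.na(d))
  f <- colMeans(d, na.rm = TRUE)
  f[n_called == 0] <- NA_real_
  tibble::tibble(
    chrom = geno$sites$chrom, pos = geno$sites$pos,
    n_called = n_called,
    f_alt = unname(f),
    maf = unname(pmin(f, 1 - f)),
    missing_rate = unname(1 - n_called / nrow(d))
  )
}

#' Filter sites on minor-allele frequency and missingness
#'
#' Keeps sites with `maf >= maf_min` and `missing_rate <= missing_max`,
#' reporting removed counts by reason.
#'
#' @inheritParams site_stats
#' @param maf_min Minimum minor-allele frequency (sites below are removed).
#' @param missing_max Maximum missing rate (sites above are removed).
#' @return A filtered [at_geno] object.
#' @export
filter_sites <- function(geno, maf_min = 0.05, missing_max = 0.20,
                         within = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 1, missing_max >= 0, missing_max <= 1)
  st <- site_stats(geno, within = within)
  low_maf <- is.na(st$maf) | st$maf < maf_min
  high_miss <- st$missing_rate > missing_max
  keep <- !low_maf & !high_miss
  message(
    "filter_sites: removed ", sum(low_maf), " low-MAF and ",
    sum(high_miss & !low_maf), " high-missingness site(s); ",
    sum(keep), " kept"
  )
  if (!any(keep)) warning("no sites left after filtering", call. = FALSE)
  geno_subset(geno, sites = keep)
}

#' Dosage-weighted base composition per accession
#'
#' At each non-missing site an accession contributes weight 1 to its
#' homozygous base, or 0.5 to the reference and 0.5 to the alternate base
#' when heterozygous. Missing sites contribute nothing and are excluded from
#' the denominator. The [AT] value is
#' `(sumA + sumT) / (sumA + sumC + sumG + sumT)`.
#'
#' @param geno An [at_geno] object.
#' @param sites Optional site subset (logical or integer index).
#' @param accessions Optional accession subset.
#' @return Tibble with columns `accession`, `sumA`, `sumC`, `sumG`, `sumT`,
#'   `n_sites_used`, `at_value`. Accessions with no non-missing site get
#'   `at_value = NA`.
#' @export
accession_composition <- function(geno, sites = NULL, accessions = NULL) {
  stopifnot(inherits(geno, "at_geno"))
  if (!is.null(sites) || !is.null(accessions)) {
    geno <- geno_subset(geno, sites = sites, accessions = accessions)
  }
  d <- geno$dosage
  miss <- is.na(d)
  w_alt <- ifelse(miss, 0, d)
  w_ref <- ifelse(miss, 0, 1 - d)
  sums <- vapply(BASES, function(b) {
    as.numeric(
      w_ref %*% (geno$sites$ref == b) + w_alt %*% (geno$sites$alt == b)
    )
  }, numeric(length(geno$accessions)))
  if (length(geno$accessions) == 1) sums <- matrix(sums, nrow = 1)
  n_used <- unname(rowSums(!miss))
  tot <- unname(rowSums(sums))
  tibble::tibble(
    accession = geno$accessions,
    sumA = sums[, 1], sumC = sums[, 2], sumG = sums[, 3], sumT = sums[, 4],
    n_sites_used = n_used,
    at_value = ifelse(tot > 0, (sums[, 1] + sums[, 4]) / tot, NA_real_)
  )
}

#' Group summaries of per-accession [AT] values
#'
#' @param profiles Tibble from [accession_composition()] (or any tibble with
#'   `accession` and `at_value`).
#' @param panel An [at_panel] object.
#' @param conf_level Confidence level for the t-based interval.
#' @return Tibble with per-group `n`, `mean_at`, `sd_at`, `ci_lower`,
#'   `ci_upper`.
#' @export
group_summary <- function(profiles, panel, conf_level = 0.95) {
  profiles |>
    dplyr::inner_join(tibble::as_tibble(panel), by = "accession") |>
    dplyr::filter(!is.na(.data$at_value)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_at = mean(.data$at_value),
      sd_at = ifelse(dplyr::n() > 1, sd(.data$at_value), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      half = ifelse(
        .data$n > 1,
        qt(1 - (1 - conf_level) / 2, pmax(.data$n - 1, 1)) *
          .data$sd_at / sqrt(.data$n),
        NA_real_
      ),
      ci_lower = .data$mean_at - .data$half,
      ci_upper = .data$mean_at + .data$half
    ) |>
    dplyr::select(-"half")
}

window_grid <- function(chrom_lengths, window, step) {
  purrr::map_dfr(names(chrom_lengths), function(cn) {
    starts <- seq(1L, max(1L, chrom_lengths[[cn]]), by = step)
    tibble::tibble(
      chrom = cn,
      start = starts,
      end = pmin(starts + window - 1, chrom_lengths[[cn]])
    )
  }) |>
    dplyr::filter(.data$end >= .data$start)
}

#' Sliding-window [AT] values per group
#'
#' For each 2-Mb window (1-Mb step by default) the per-accession [AT] value
#' is computed from the sites inside the window and averaged within each
#' panel group. Windows with fewer than `min_sites` sites are kept in the
#' track but flagged by `at_value = NA`.
#'
#' @param geno An [at_geno] object.
#' @param panel An [at_panel] object.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param window,step Window span and slide step in bp.
#' @param min_sites Minimum sites for a window value.
#' @param groups Optional subset of panel groups.
#' @return Tibble with columns `chrom`, `start`, `end`, `group`, `n_sites`,
#'   `at_value`.
#' @export
window_at <- function(geno, panel, chrom_lengths,
                      window = 2e6, step = 1e6, min_sites = 10,
                      groups = NULL) {
  stopifnot(inherits(geno, "at_geno"))
  panel_tb <- tibble::as_tibble(panel)
  if (is.null(groups)) groups <- unique(panel_tb$group)
  panel_tb <- dplyr::filter(panel_tb, .data$group %in% groups)
  grid <- window_grid(
    chrom_lengths[names(chrom_lengths) %in% unique(geno$sites$chrom)],
    window, step
  )
  purrr::pmap_dfr(grid, function(chrom, start, end) {
    idx <- which(
      geno$sites$chrom == chrom &
        geno$sites$pos >= start & geno$sites$pos <= end
    )
    base <- tibble::tibble(
      chrom = chrom, start = start, end = end,
      group = groups, n_sites = length(idx), at_value = NA_real_
    )
    if (length(idx) < min_sites) {
      return(base)
    }
    prof <- accession_composition(geno, sites = idx) |>
      dplyr::inner_join(panel_tb, by = "accession") |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        at_value = mean(.data$at_value, na.rm = TRUE), .groups = "drop"
      )
    base |>
      dplyr::select(-"at_value") |>
      dplyr::left_join(prof, by = "group") |>
      dplyr::mutate(at_value = ifelse(is.nan(.data$at_value), NA_real_,
        .data$at_value
      ))
  })
}

#' Per-window [AT] difference between two tracks
#'
#' The primary difference is absolute, `domesticated - wild`, on the [AT]
#' fraction scale (the scale on which the 0 and 0.1 boundaries are drawn); a
#' relative difference `(dom - wild) / wild` is also reported. Windows
#' missing on either side are excluded.
#'
#' @param track_dom,track_wild Window tracks from [window_at()], each with a
#'   single group (or pre-filtered to one group).
#' @return Tibble with columns `chrom`, `start`, `end`, `at_dom`, `at_wild`,
#'   `delta` (absolute) and `delta_rel` (relative).
#' @export
window_difference <- function(track_dom, track_wild) {
  out <- dplyr::inner_join(
    dplyr::select(track_dom, "chrom", "start", "end", at_dom = "at_value"),
    dplyr::select(track_wild, "chrom", "start", "end", at_wild = "at_value"),
    by = c("chrom", "start", "end")
  ) |>
    dplyr::filter(!is.na(.data$at_dom), !is.na(.data$at_wild)) |>
    dplyr::mutate(
      delta = .data$at_dom - .data$at_wild,
      delta_rel = (.data$at_dom - .data$at_wild) / .data$at_wild
    )
  if (nrow(out) == 0) {
    stop("no shared non-missing windows between the two tracks",
      call. = FALSE
    )
  }
  out
}

#' Fractions of windows above [AT]-difference thresholds
#'
#' @param diff Tibble from [window_difference()].
#' @param thresholds Numeric thresholds on the absolute difference scale.
#' @return Tibble with `threshold`, `n_above`, `n_total`, `fraction`.
#' @export
at_increase_fractions <- function(diff, thresholds = c(0, 0.1)) {
  purrr::map_dfr(thresholds, function(th) {
    tibble::tibble(
      threshold = th,
      n_above = sum(diff$delta > th),
      n_total = nrow(diff),
      fraction = sum(diff$delta > th) / nrow(diff)
    )
  })
}

#' Region membership of sites
#'
#' @param sites Site tibble with `chrom`, `pos`.
#' @param regions Region tibble (1-based inclusive `chrom`, `start`, `end`,
#'   `label`).
#' @return Character vector: label of the first containing region per site,
#'   `NA` outside all regions.
#' @export
site_region_label <- function(sites, regions) {
  out <- rep(NA_character_, nrow(sites))
  for (cn in unique(regions$chrom)) {
    ri <- which(regions$chrom == cn)
    si <- which(sites$chrom == cn)
    if (!length(si)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[si], sites$pos[si]),
      IRanges::IRanges(regions$start[ri], regions$end[ri]),
      select = "first"
    )
    out[si] <- regions$label[ri][hits]
  }
  out
}

#' Region-stratified [AT] profiles with group letters
#'
#' Restricts the dosage-weighted composition to sites inside (and, for
#' `inside_vs_outside`, outside) a region set, and compares panel groups
#' within each stratum with Duncan's multiple range test. Strata with fewer
#' than `min_sites` sites are skipped with a message (mirroring the practice
#' of skipping sweeps that contain too few SNPs for a fair comparison).
#'
#' @inheritParams window_at
#' @param regions Region tibble (e.g. selective sweeps from [read_bed()]).
#' @param mode `"inside_vs_outside"` pools all regions into one `inside`
#'   stratum and its complement; `"per_region"` makes one stratum per region
#'   label.
#' @param min_sites Minimum number of sites per stratum.
#' @param alpha Significance level for the Duncan letters.
#' @return List with `profiles` (stratum x accession [AT] values) and
#'   `letters` (per-stratum group means with Duncan letters).
#' @export
stratified_at <- function(geno, panel, regions,
                          mode = c("inside_vs_outside", "per_region"),
                          min_sites = 10, alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(nrow(regions) > 0)
  lab <- site_region_label(geno$sites, regions)
  strata <- switch(mode,
    inside_vs_outside = list(
      inside = which(!is.na(lab)),
      outside = which(is.na(lab))
    ),
    per_region = split(which(!is.na(lab)), lab[!is.na(lab)])
  )
  panel_tb <- tibble::as_tibble(panel)
  profiles <- purrr::imap_dfr(strata, function(idx, nm) {
    if (length(idx) < min_sites) {
      message(
        "stratified_at: skipping stratum '", nm, "' with ",
        length(idx), " site(s) < min_sites = ", min_sites
      )
      return(NULL)
    }
    accession_composition(geno, sites = idx) |>
      dplyr::mutate(stratum = nm, .before = 1) |>
      dplyr::inner_join(panel_tb, by = "accession")
  })
  letters <- NULL
  if (nrow(profiles) > 0) {
    letters <- profiles |>
      dplyr::filter(!is.na(.data$at_value)) |>
      dplyr::group_by(.data$stratum) |>
      dplyr::group_modify(function(df, key) {
        counts <- table(df$group)
        ok <- names(counts)[counts >= 2]
        if (length(ok) < 2) {
          return(tibble::tibble(
            group = unique(df$group), n = as.integer(counts[unique(df$group)]),
            mean = NA_real_, letter = NA_character_
          ))
        }
        duncan_mrt(
          dplyr::filter(df, .data$group %in% ok),
          alpha = alpha
        )
      }) |>
      dplyr::ungroup()
  }
  list(profiles = profiles, letters = letters)
}
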