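#' Call focal-group-private SNPs against progenitor panels
#'
#' A site is private to the focal group when (a) it is polymorphic within
#' the focal accessions (alternate-allele frequency strictly between 0 and 1
#' over non-missing calls) and (b) every non-missing reference-panel call is
#' the same homozygous allele, with the reference missing rate at most
#' `max_ref_missing`. Heterozygous or conflicting reference calls disqualify
#' the site. The fixed reference allele is the donor; the other allele is
#' the derived (new) allele.
#'
#' Reference accessions are restricted, per site, to groups that carry the
#' site's subgenome (so a D-subgenome site is judged against the D-carrying
#' progenitor panel only).
#'
#' @param geno An [at_geno] object.
#' @param panel An [at_panel] object.
#' @param focal_groups Character vector of focal group labels (e.g. the
#'   bread wheat groups).
#' @param reference_groups Character vector of progenitor group labels.
#' @param max_ref_missing Maximum missing rate among carrying reference
#'   accessions.
#' @return Tibble of private sites: the site columns plus `site_idx` (index
#'   into `geno$sites`), `donor`, `derived`, `focal_f_derived` (derived
#'   frequency over non-missing focal calls).
#' @export
call_private_sites <- function(geno, panel, focal_groups, reference_groups,
                               max_ref_missing = 0.2) {
  stopifnot(inherits(geno, "at_geno"), inherits(panel, "at_panel"))
  panel_tb <- tibble::as_tibble(panel)
  bad <- setdiff(
    c(focal_groups, reference_groups),
    unique(panel_tb$group)
  )
  if (length(bad)) {
    stop("group(s) absent from panel: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  focal_acc <- intersect(
    geno$accessions, panel_tb$accession[panel_tb$group %in% focal_groups]
  )
  sgmap <- group_subgenomes(panel)
  d <- geno$dosage
  foc <- d[match(focal_acc, geno$accessions), , drop = FALSE]
  f_called <- unname(colSums(!is.na(foc)))
  f_freq <- unname(colMeans(foc, na.rm = TRUE))
  focal_poly <- f_called > 0 & f_freq > 0 & f_freq < 1

  out <- purrr::map_dfr(unique(geno$sites$subgenome), function(sg) {
    ref_groups_sg <- reference_groups[vapply(
      reference_groups, function(g) sg %in% sgmap[[g]], logical(1)
    )]
    sidx <- which(geno$sites$subgenome == sg)
    if (!length(ref_groups_sg)) {
      message(
        "call_private_sites: no reference group carries subgenome ", sg,
        "; its ", length(sidx), " site(s) skipped"
      )
      return(NULL)
    }
    ref_acc <- intersect(
      geno$accessions, panel_tb$accession[panel_tb$group %in% ref_groups_sg]
    )
    ref <- d[match(ref_acc, geno$accessions), sidx, drop = FALSE]
    r_called <- unname(colSums(!is.na(ref)))
    r_miss <- 1 - r_called / length(ref_acc)
    r_min <- unname(suppressWarnings(apply(ref, 2, min, na.rm = TRUE)))
    r_max <- unname(suppressWarnings(apply(ref, 2, max, na.rm = TRUE)))
    fixed0 <- r_called > 0 & r_min == 0 & r_max == 0
    fixed1 <- r_called > 0 & r_min == 1 & r_max == 1
    ok <- focal_poly[sidx] & (fixed0 | fixed1) & r_miss <= max_ref_missing
    if (!any(ok)) {
      return(NULL)
    }
    keep <- sidx[ok]
    donor_is_ref <- fixed0[ok]
    geno$sites[keep, , drop = FALSE] |>
      dplyr::mutate(
        site_idx = keep,
        donor = ifelse(donor_is_ref, .data$ref, .data$alt),
        derived = ifelse(donor_is_ref, .data$alt, .data$ref),
        focal_f_derived = ifelse(
          donor_is_ref, f_freq[keep], 1 - f_freq[keep]
        )
      )
  })
  if (nrow(out) == 0) {
    return(out)
  }
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Per-accession derived-allele frequency at private sites
#'
#' For each focal accession, the sum of derived-allele dosage over the
#' qualifying private sites divided by the number of those sites with a
#' non-missing call. Restriction to a motif set and a donor-to-derived base
#' change (e.g. C to T at the five high-frequency C/T motifs) selects the
#' mutation class whose rate is being estimated.
#'
#' @param geno An [at_geno] object (with a `motif` site column when
#'   `motif_set` is used; see [add_spectrum_columns()]).
#' @param private_sites Tibble from [call_private_sites()].
#' @param motif_set Optional character vector of motif labels. Sites whose
#'   motif is the reverse complement of a listed motif also qualify when
#'   `include_revcomp` is `TRUE`, with the donor/derived bases complemented.
#' @param donor_base,derived_base Optional single bases restricting the
#'   direction of change (applied on the strand where the motif matches).
#' @param include_revcomp Also accept reverse-complement motif matches.
#' @param panel Optional [at_panel]; adds group labels and enables the
#'   group summary attribute.
#' @param accessions Optional accession subset (defaults to all accessions
#'   with at least one qualifying call).
#' @return Tibble with `accession`, (`group`,) `n_sites`, `rate`.
#' @export
derived_rate <- function(geno, private_sites, motif_set = NULL,
                         donor_base = NULL, derived_base = NULL,
                         include_revcomp = TRUE, panel = NULL,
                         accessions = NULL) {
  stopifnot(inherits(geno, "at_geno"))
  ps <- private_sites
  if (nrow(ps) == 0) stop("empty private site table", call. = FALSE)
  qual <- rep(TRUE, nrow(ps))
  if (!is.null(motif_set)) {
    if (!"motif" %in% names(ps)) {
      key <- paste0(geno$sites$chrom, ":", geno$sites$pos)
      ps$motif <- geno$sites$motif[match(
        paste0(ps$chrom, ":", ps$pos), key
      )]
    }
    fwd <- !is.na(ps$motif) & ps$motif %in% motif_set
    rev <- !is.na(ps$motif) &
      ps$motif %in% setdiff(revcomp_motif(motif_set), motif_set)
    if (!include_revcomp) rev <- rep(FALSE, nrow(ps))
    match_dir <- ifelse(fwd, "fwd", ifelse(rev, "rev", NA))
    qual <- qual & !is.na(match_dir)
  } else {
    match_dir <- rep("fwd", nrow(ps))
  }
  if (!is.null(donor_base)) {
    donor_eff <- ifelse(
      match_dir == "rev", complement_base(ps$donor), ps$donor
    )
    derived_eff <- ifelse(
      match_dir == "rev", complement_base(ps$derived), ps$derived
    )
    qual <- qual & donor_eff == donor_base
    if (!is.null(derived_base)) qual <- qual & derived_eff == derived_base
  }
  ps <- ps[which(qual), , drop = FALSE]
  if (nrow(ps) == 0) {
    stop("no private sites qualify for the requested motif/base class",
      call. = FALSE
    )
  }
  d <- geno$dosage[, ps$site_idx, drop = FALSE]
  # derived dosage: complement of the dosage where the donor is the alt
  flip <- ps$derived == ps$ref
  d[, flip] <- 1 - d[, flip, drop = FALSE]
  n_sites <- unname(rowSums(!is.na(d)))
  rate <- unname(rowSums(d, na.rm = TRUE)) / n_sites
  out <- tibble::tibble(
    accession = geno$accessions,
    n_sites = n_sites,
    rate = ifelse(n_sites > 0, rate, NA_real_)
  )
  if (!is.null(accessions)) {
    out <- dplyr::filter(out, .data$accession %in% accessions)
  }
  if (!is.null(panel)) {
    out <- dplyr::inner_join(out, tibble::as_tibble(panel), by = "accession")
  }
  out
}
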