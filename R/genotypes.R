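#' Genotype matrix container
#'
#' Holds bi-allelic SNP genotypes as alternate-allele dosages in
#' `{0, 0.5, 1}` (homozygous reference, heterozygous, homozygous alternate)
#' with `NA` for missing calls, together with the site table.
#'
#' @param sites Tibble with one row per site; required columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`. A `subgenome` column is added from
#'   [subgenome_of()] when absent. Sites are sorted by `(chrom, pos)`.
#' @param dosage Numeric matrix, accessions in rows and sites in columns,
#'   values in `{0, 0.5, 1, NA}`.
#' @param accessions Character vector of accession ids (row order of
#'   `dosage`).
#' @return An object of class `at_geno`: list with elements `sites`,
#'   `dosage`, `accessions`.
#' @export
at_geno <- function(sites, dosage, accessions) {
  sites <- tibble::as_tibble(sites)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns chrom, pos, ref, alt", call. = FALSE)
  }
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(accessions) || ncol(dosage) != nrow(sites)) {
    stop("dosage must be accessions x sites", call. = FALSE)
  }
  if (any(!dosage[!is.na(dosage)] %in% c(0, 0.5, 1))) {
    stop("dosage values must be 0, 0.5, 1 or NA", call. = FALSE)
  }
  if (any(sites$ref == sites$alt) ||
    any(!sites$ref %in% BASES) || any(!sites$alt %in% BASES)) {
    stop("sites must be bi-allelic SNPs over A/C/G/T with ref != alt",
      call. = FALSE
    )
  }
  if (any(sites$pos < 1)) stop("positions must be >= 1", call. = FALSE)
  if (anyDuplicated(paste(sites$chrom, sites$pos))) {
    stop("duplicate (chrom, pos)", call. = FALSE)
  }
  if (!"subgenome" %in% names(sites)) {
    sites$subgenome <- subgenome_of(sites$chrom)
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  rownames(dosage) <- accessions
  colnames(dosage) <- if (nrow(sites)) {
    paste0(sites$chrom, ":", sites$pos)
  } else {
    character(0)
  }
  structure(
    list(sites = sites, dosage = dosage, accessions = accessions),
    class = "at_geno"
  )
}

#' @export
print.at_geno <- function(x, ...) {
  cat("<at_geno> ", length(x$accessions), " accessions x ",
    nrow(x$sites), " sites (",
    paste(unique(x$sites$subgenome), collapse = ","), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.at_geno <- function(x, ...) {
  tibble::as_tibble(x$sites) |>
    dplyr::mutate(.col = dplyr::row_number()) |>
    tidyr::crossing(accession = x$accessions) |>
    dplyr::mutate(
      dosage = x$dosage[cbind(
        match(.data$accession, x$accessions), .data$.col
      )]
    ) |>
    dplyr::select(-".col")
}

#' Subset a genotype matrix by sites and/or accessions
#'
#' @param geno An [at_geno] object.
#' @param sites Logical or integer index into the site table, or `NULL`.
#' @param accessions Character vector of accession ids, or `NULL`.
#' @return An [at_geno] object.
#' @export
geno_subset <- function(geno, sites = NULL, accessions = NULL) {
  stopifnot(inherits(geno, "at_geno"))
  s <- geno$sites
  d <- geno$dosage
  acc <- geno$accessions
  if (!is.null(sites)) {
    s <- s[sites, , drop = FALSE]
    d <- d[, sites, drop = FALSE]
  }
  if (!is.null(accessions)) {
    missing_acc <- setdiff(accessions, acc)
    if (length(missing_acc)) {
      stop("unknown accession(s): ", paste(missing_acc, collapse = ", "),
        call. = FALSE
      )
    }
    d <- d[match(accessions, acc), , drop = FALSE]
    acc <- accessions
  }
  at_geno(s, d, acc)
}

gt_to_dosage <- function(gt) {
  gt <- sub("\\|", "/", gt)
  gt <- sub("^([0-9.])/([0-9.]).*", "\\1/\\2", gt)
  out <- rep(NA_real_, length(gt))
  out[gt %in% c("0/0")] <- 0
  out[gt %in% c("0/1", "1/0")] <- 0.5
  out[gt %in% c("1/1")] <- 1
  out
}

#' Read genotypes from a VCF file
#'
#' Diploid GT calls are converted to alternate-allele dosages: `0/0` to 0,
#' `0/1` or `1/0` to 0.5, `1/1` to 1, `./.` to missing. Phased separators are
#' treated as unphased. Multi-allelic records and indels are skipped and the
#' skipped count reported as a message.
#'
#' @param path Path to a VCF file (v4.x with a GT field).
#' @param biallelic_only Keep only bi-allelic SNP records (default `TRUE`).
#' @return An [at_geno] object.
#' @export
read_genotypes <- function(path, biallelic_only = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(v))
  keep <- fix$REF %in% BASES & fix$ALT %in% BASES & !is.na(fix$ALT)
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    if (!biallelic_only) {
      stop("non-bi-allelic-SNP records present; set biallelic_only = TRUE",
        call. = FALSE
      )
    }
    message("skipped ", n_skip, " non-bi-allelic-SNP record(s)")
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT($|:)", fmt))) {
    stop("VCF records without a GT field", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dosage <- t(apply(gt, 2, gt_to_dosage))
  if (nrow(fix) == 1) dosage <- matrix(dosage, ncol = 1)
  sites <- tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  at_geno(sites, dosage, colnames(gt))
}

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0] <- "0/0"
  out[!is.na(d) & d == 0.5] <- "0/1"
  out[!is.na(d) & d == 1] <- "1/1"
  out
}

#' Write genotypes to a VCF file
#'
#' @param geno An [at_geno] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "at_geno"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=atshift",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(
      c(
        "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", geno$accessions
      ),
      collapse = "\t"
    )
  )
  gt <- apply(geno$dosage, 1, dosage_to_gt)
  if (nrow(geno$sites) == 1) gt <- matrix(gt, nrow = 1)
  body <- paste(
    geno$sites$chrom, geno$sites$pos, ".",
    geno$sites$ref, geno$sites$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Accession panel
#'
#' An accession panel maps accession ids to group labels and records which
#' subgenomes each group carries (its ploidy context).
#'
#' @param x Data frame with columns `accession` and `group`.
#' @param subgenomes Named list, group label to character vector of carried
#'   subgenomes. Defaults to the wheat scheme from
#'   [wheat_group_subgenomes()] for known group names; unknown groups are
#'   assumed to carry all of A, B, D.
#' @return A tibble of class `at_panel` with a `subgenomes` attribute.
#' @export
at_panel <- function(x, subgenomes = NULL) {
  x <- tibble::as_tibble(x)
  if (!all(c("accession", "group") %in% names(x))) {
    stop("panel needs columns accession, group", call. = FALSE)
  }
  if (anyDuplicated(x$accession)) {
    stop("duplicate accession ids in panel", call. = FALSE)
  }
  groups <- unique(x$group)
  if (is.null(subgenomes)) {
    default <- wheat_group_subgenomes()
    subgenomes <- lapply(groups, function(g) default[[g]] %||% c("A", "B", "D"))
    names(subgenomes) <- groups
  }
  missing_grp <- setdiff(groups, names(subgenomes))
  if (length(missing_grp)) {
    stop("no subgenome context for group(s): ",
      paste(missing_grp, collapse = ", "),
      call. = FALSE
    )
  }
  structure(x, subgenomes = subgenomes, class = c("at_panel", class(x)))
}

#' Wheat group ploidy contexts
#'
#' Which subgenomes each canonical group carries: wild emmer and durum are
#' tetraploid (A, B), *Ae. tauschii* is diploid (D), and the three bread
#' wheat groups are hexaploid (A, B, D).
#'
#' @return Named list of subgenome letters per group.
#' @export
wheat_group_subgenomes <- function() {
  list(
    wild_emmer = c("A", "B"),
    durum = c("A", "B"),
    ae_tauschii = "D",
    landrace_east = c("A", "B", "D"),
    landrace_west = c("A", "B", "D"),
    variety = c("A", "B", "D")
  )
}

#' Subgenome context of panel groups
#'
#' @param panel An [at_panel] object.
#' @return Named list of subgenomes per group.
#' @export
group_subgenomes <- function(panel) {
  attr(panel, "subgenomes")
}

#' Accessions carrying a given subgenome
#'
#' @param panel An [at_panel] object.
#' @param subgenome Subgenome letter.
#' @return Character vector of accession ids.
#' @export
carriers_of <- function(panel, subgenome) {
  sg <- group_subgenomes(panel)
  grp <- names(sg)[vapply(sg, function(s) subgenome %in% s, logical(1))]
  panel$accession[panel$group %in% grp]
}

#' Read / write an accession panel (TSV with columns accession, group)
#'
#' @param path Path to a TSV file.
#' @inheritParams at_panel
#' @return An [at_panel] object.
#' @export
read_panel <- function(path, subgenomes = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  at_panel(x, subgenomes = subgenomes)
}

#' @rdname read_panel
#' @param panel An [at_panel] object.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(tibble::as_tibble(panel)[, c("accession", "group")], path)
  invisible(path)
}

#' Read / write region sets as BED
#'
#' BED files are 0-based half-open on disk; internally regions are 1-based
#' inclusive tibbles with columns `chrom`, `start`, `end`, `label`.
#'
#' @param path Path to a BED file.
#' @return A tibble of regions.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lbl <- gr$name
  if (is.null(lbl) || all(is.na(lbl))) {
    lbl <- paste0("region", seq_along(gr))
  }
  tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    label = lbl
  )
}

#' @rdname read_bed
#' @param regions Region tibble (1-based inclusive).
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(regions$start >= 1), all(regions$start <= regions$end))
  out <- tibble::tibble(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = regions$label %||% paste0("region", seq_len(nrow(regions)))
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read / write a gene-expression table
#'
#' Long TSV with columns `gene`, `tissue`, `tpm`.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `gene`, `tissue`, `tpm`.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene = "c", tissue = "c", tpm = "d"
    )
  )
  if (any(x$tpm < 0)) stop("TPM values must be >= 0", call. = FALSE)
  x
}

#' @rdname read_expression
#' @param expression Expression tibble.
#' @export
write_expression <- function(expression, path) {
  readr::write_tsv(expression, path)
  invisible(path)
}
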