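#' Transition type of a bi-allelic SNP
#'
#' The unordered ref/alt base pair, canonicalised so the two bases are in
#' alphabetical order: one of `A/C`, `A/G`, `A/T`, `C/G`, `C/T`, `G/T`.
#'
#' @param ref,alt Character vectors of single bases.
#' @return Character vector of canonical type labels.
#' @export
#' @examples
#' transition_type(c("C", "T", "A"), c("T", "C", "C"))
transition_type <- function(ref, alt) {
  if (any(!ref %in% BASES) || any(!alt %in% BASES)) {
    stop("ref and alt must be A, C, G or T", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref must differ from alt", call. = FALSE)
  paste(pmin(ref, alt), pmax(ref, alt), sep = "/")
}

#' The six transition types and the 96 tri-nucleotide motifs
#'
#' Motifs are rendered `X(B1/B2)Y` for the 5'-XNY-3' context around an
#' unordered transition type.
#'
#' @return Character vectors of the 6 type labels / 96 motif labels.
#' @export
all_types <- function() {
  cmb <- utils::combn(BASES, 2)
  paste(cmb[1, ], cmb[2, ], sep = "/")
}

#' @rdname all_types
#' @export
all_motifs <- function() {
  g <- expand.grid(
    left = BASES, type = all_types(), right = BASES,
    stringsAsFactors = FALSE
  )
  sort(paste0(g$left, "(", g$type, ")", g$right))
}

make_motif <- function(left, type, right) {
  paste0(left, "(", type, ")", right)
}

parse_motif <- function(motif) {
  m <- stringr::str_match(motif, "^([ACGT])\\(([ACGT])/([ACGT])\\)([ACGT])$")
  if (anyNA(m[, 1])) stop("malformed motif label", call. = FALSE)
  tibble::tibble(left = m[, 2], b1 = m[, 3], b2 = m[, 4], right = m[, 5])
}

#' Tri-nucleotide motif of each SNP from its reference context
#'
#' The immediately flanking reference bases (forward strand) are combined
#' with the site's transition type. Sites at chromosome ends or with an `N`
#' flank are unusable and get `NA`.
#'
#' @param sites Site tibble (`chrom`, `pos`, `ref`, `alt`) or [at_geno].
#' @param genome [at_genome] supplying the flanking context (conventionally
#'   the focal species' reference).
#' @return Character vector of motif labels, `NA` where unusable.
#' @export
motif_of <- function(sites, genome) {
  if (inherits(sites, "at_geno")) sites <- sites$sites
  stopifnot(inherits(genome, "at_genome"))
  unknown <- setdiff(unique(sites$chrom), names(genome$seq))
  if (length(unknown)) {
    stop("sites on chromosome(s) absent from genome: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  len <- genome$lengths[sites$chrom]
  ok <- sites$pos > 1 & sites$pos < len
  left <- right <- rep(NA_character_, nrow(sites))
  seqs <- genome$seq[sites$chrom[ok]]
  left[ok] <- substring(seqs, sites$pos[ok] - 1, sites$pos[ok] - 1)
  right[ok] <- substring(seqs, sites$pos[ok] + 1, sites$pos[ok] + 1)
  usable <- ok & left %in% BASES & right %in% BASES
  out <- rep(NA_character_, nrow(sites))
  out[usable] <- make_motif(
    left[usable],
    transition_type(sites$ref[usable], sites$alt[usable]),
    right[usable]
  )
  out
}

#' Reverse complement of a motif
#'
#' The flanks swap and complement, and the transition type is complemented
#' and re-canonicalised; the operation is an involution over the 96 motifs.
#'
#' @param motif Character vector of motif labels.
#' @return Character vector of motif labels.
#' @export
#' @examples
#' revcomp_motif("A(C/T)G")
revcomp_motif <- function(motif) {
  p <- parse_motif(motif)
  b1c <- complement_base(p$b1)
  b2c <- complement_base(p$b2)
  make_motif(
    complement_base(p$right),
    paste(pmin(b1c, b2c), pmax(b1c, b2c), sep = "/"),
    complement_base(p$left)
  )
}

#' Transition-type and motif frequency spectrum
#'
#' Type frequencies are over all sites; motif frequencies are over the
#' usable-context sites only (context-less sites are counted but excluded
#' from the motif denominator). All 6 types and 96 motifs are present in the
#' output, with zero counts where unobserved.
#'
#' @param sites Site tibble; a `motif` column is used if present, otherwise
#'   supply `genome` to derive it.
#' @param genome Optional [at_genome] for motif context.
#' @return List of class `at_spectrum` with tibbles `types` (`type`, `n`,
#'   `frequency`) and `motifs` (`motif`, `type`, `n`, `frequency`), plus
#'   counts `n_sites` and `n_motif_usable`.
#' @export
spectrum_frequencies <- function(sites, genome = NULL) {
  if (inherits(sites, "at_geno")) sites <- sites$sites
  sites <- tibble::as_tibble(sites)
  stopifnot(nrow(sites) > 0)
  tt <- transition_type(sites$ref, sites$alt)
  motif <- if ("motif" %in% names(sites)) {
    sites$motif
  } else if (!is.null(genome)) {
    motif_of(sites, genome)
  } else {
    stop("supply a genome or a precomputed motif column", call. = FALSE)
  }
  n_total <- length(tt)
  types <- tibble::tibble(type = all_types()) |>
    dplyr::left_join(
      tibble::tibble(type = tt) |> dplyr::count(.data$type),
      by = "type"
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      frequency = .data$n / n_total
    )
  usable <- !is.na(motif)
  motifs <- tibble::tibble(motif = all_motifs()) |>
    dplyr::left_join(
      tibble::tibble(motif = motif[usable]) |> dplyr::count(.data$motif),
      by = "motif"
    ) |>
    dplyr::mutate(
      type = parse_motif(.data$motif) |>
        (\(p) paste(p$b1, p$b2, sep = "/"))(),
      n = dplyr::coalesce(.data$n, 0L),
      frequency = if (sum(usable) > 0) .data$n / sum(usable) else NA_real_
    ) |>
    dplyr::select("motif", "type", "n", "frequency")
  structure(
    list(
      types = types, motifs = motifs,
      n_sites = n_total, n_motif_usable = sum(usable)
    ),
    class = "at_spectrum"
  )
}

#' @export
print.at_spectrum <- function(x, ...) {
  cat("<at_spectrum> ", x$n_sites, " sites (", x$n_motif_usable,
    " with usable context)\n",
    sep = ""
  )
  print(dplyr::arrange(x$types, dplyr::desc(.data$frequency)))
  invisible(x)
}

#' High-frequency motifs
#'
#' Motifs whose frequency strictly exceeds `factor` times the expected
#' uniform frequency (1/96). `factor = 1` targets the broad high-frequency
#' tier, `factor = 2` the doubled-expectation tier.
#'
#' @param spectrum An `at_spectrum` from [spectrum_frequencies()] (or its
#'   `motifs` tibble).
#' @param expected Expected frequency under uniformity.
#' @param factor Multiplier on the expectation (>= 1).
#' @return Tibble of qualifying motifs ordered by decreasing frequency.
#' @export
high_frequency_motifs <- function(spectrum, expected = 1 / 96, factor = 1) {
  stopifnot(factor >= 1)
  motifs <- if (inherits(spectrum, "at_spectrum")) {
    spectrum$motifs
  } else {
    spectrum
  }
  motifs |>
    dplyr::filter(.data$frequency > factor * expected) |>
    dplyr::arrange(dplyr::desc(.data$frequency))
}

#' Add transition-type and motif columns to a genotype matrix
#'
#' @param geno An [at_geno] object.
#' @param genome Optional [at_genome] for motif context.
#' @return `geno` with `type` (and `motif`) columns in its site table.
#' @export
add_spectrum_columns <- function(geno, genome = NULL) {
  stopifnot(inherits(geno, "at_geno"))
  geno$sites$type <- transition_type(geno$sites$ref, geno$sites$alt)
  if (!is.null(genome)) geno$sites$motif <- motif_of(geno$sites, genome)
  geno
}

#' Per-accession base values at sites of one transition type or motif
#'
#' Restricts the dosage-weighted composition (homozygote 1, heterozygote
#' 0.5 per allele) to the matching sites and reports, per accession, the
#' fraction of each base over its non-missing matching sites - for example
#' the \[T\] value at C/T sites.
#'
#' @param geno An [at_geno] object (motif restriction needs a `motif` site
#'   column; see [add_spectrum_columns()]).
#' @param type Transition-type label, or `NULL`.
#' @param motif Motif label(s), or `NULL`. Exactly one of `type`/`motif`
#'   must be given.
#' @param panel Optional [at_panel] to attach group labels.
#' @return Long tibble with `accession`, (`group`,) `base`, `value`,
#'   `n_sites_used`.
#' @export
per_type_base_value <- function(geno, type = NULL, motif = NULL,
                                panel = NULL) {
  stopifnot(inherits(geno, "at_geno"), xor(is.null(type), is.null(motif)))
  if (!is.null(type)) {
    idx <- transition_type(geno$sites$ref, geno$sites$alt) %in% type
  } else {
    if (!"motif" %in% names(geno$sites)) {
      stop("no motif column; run add_spectrum_columns() first", call. = FALSE)
    }
    idx <- !is.na(geno$sites$motif) & geno$sites$motif %in% motif
  }
  if (!any(idx)) stop("no matching sites", call. = FALSE)
  prof <- accession_composition(geno, sites = idx)
  out <- prof |>
    tidyr::pivot_longer(
      dplyr::all_of(paste0("sum", BASES)),
      names_to = "base", names_prefix = "sum", values_to = "sum"
    ) |>
    dplyr::mutate(
      value = ifelse(.data$n_sites_used > 0,
        .data$sum / .data$n_sites_used, NA_real_
      )
    ) |>
    dplyr::select("accession", "base", "value", "n_sites_used")
  if (!is.null(panel)) {
    out <- dplyr::inner_join(out, tibble::as_tibble(panel), by = "accession")
  }
  out
}

#' Per-accession [AT] value at each of a set of motifs
#'
#' @param geno An [at_geno] with a `motif` site column.
#' @param motifs Character vector of motif labels.
#' @return Tibble with `accession`, `motif`, `at_value`, `n_sites_used`.
#' @export
per_motif_at_value <- function(geno, motifs) {
  stopifnot("motif" %in% names(geno$sites))
  purrr::map_dfr(motifs, function(m) {
    idx <- !is.na(geno$sites$motif) & geno$sites$motif == m
    if (!any(idx)) {
      return(tibble::tibble(
        accession = geno$accessions, motif = m,
        at_value = NA_real_, n_sites_used = 0L
      ))
    }
    accession_composition(geno, sites = idx) |>
      dplyr::transmute(
        accession = .data$accession, motif = m,
        at_value = .data$at_value, n_sites_used = .data$n_sites_used
      )
  })
}

#' Pairwise correlation of per-accession motif values
#'
#' Pearson correlation between the per-accession value vectors of every
#' motif pair; pairs involving a zero-variance vector are flagged with
#' `NA`.
#'
#' @param values Tibble with columns `accession`, `motif` and a value
#'   column (default `at_value`).
#' @param value_col Name of the value column.
#' @return Tibble with `motif_x`, `motif_y`, `r`.
#' @export
motif_value_correlation <- function(values, value_col = "at_value") {
  wide <- values |>
    dplyr::select("accession", "motif", dplyr::all_of(value_col)) |>
    tidyr::pivot_wider(
      names_from = "motif", values_from = dplyr::all_of(value_col)
    )
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (nrow(m) < 3) stop("need at least 3 accessions", call. = FALSE)
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  zero_var <- apply(m, 2, function(x) var(x) == 0)
  cc <- suppressWarnings(cor(m))
  cc[zero_var, ] <- NA_real_
  cc[, zero_var] <- NA_real_
  as.data.frame(cc) |>
    tibble::rownames_to_column("motif_x") |>
    tidyr::pivot_longer(-"motif_x", names_to = "motif_y", values_to = "r") |>
    tibble::as_tibble()
}
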