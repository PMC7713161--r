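#' Genome sequence container
#'
#' A minimal container for a set of chromosome sequences. Sequences are stored
#' as uppercase character strings over the alphabet `A`, `C`, `G`, `T`, `N`.
#'
#' @param sequences Named character vector of chromosome sequences.
#' @param ambiguous How to treat IUPAC ambiguity codes other than `N`:
#'   `"error"` (default) rejects them, `"to_n"` converts them to `N`.
#'
#' @return An object of class `at_genome`: a list with elements `seq`
#'   (named character vector) and `lengths` (named integer vector).
#' @export
#' @examples
#' g <- at_genome(c(chr1A = "ACGTNacgt"))
#' g$lengths
at_genome <- function(sequences, ambiguous = c("error", "to_n")) {
  ambiguous <- match.arg(ambiguous)
  if (length(sequences) == 0) {
    stop("genome must contain at least one sequence", call. = FALSE)
  }
  nm <- names(sequences)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop(
      "duplicate chromosome name(s): ",
      paste(unique(nm[duplicated(nm)]), collapse = ", "),
      call. = FALSE
    )
  }
  seqs <- toupper(sequences)
  bad <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(bad)) {
    if (ambiguous == "to_n") {
      seqs[bad] <- stringr::str_replace_all(seqs[bad], "[^ACGTN]", "N")
    } else {
      stop(
        "non-ACGTN characters in sequence(s): ",
        paste(nm[bad], collapse = ", "),
        " (use ambiguous = \"to_n\" to mask them)",
        call. = FALSE
      )
    }
  }
  structure(
    list(seq = seqs, lengths = setNames(nchar(seqs), nm)),
    class = "at_genome"
  )
}

#' @export
print.at_genome <- function(x, ...) {
  cat("<at_genome> ", length(x$seq), " sequence(s), ",
    format(sum(as.numeric(x$lengths)), big.mark = ","), " bp total\n",
    sep = ""
  )
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased (soft-masked lowercase bases are kept as their
#' base), so whole-genome totals include masked regions.
#'
#' @param path Path to a FASTA file.
#' @inheritParams at_genome
#' @return An [at_genome] object.
#' @export
read_genome <- function(path, ambiguous = c("error", "to_n")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  if (length(ss) == 0) stop("empty FASTA: ", path, call. = FALSE)
  seqs <- as.character(ss)
  # FASTA headers: keep the first whitespace-delimited word
  names(seqs) <- stringr::str_extract(names(ss), "^\\S+")
  at_genome(seqs, ambiguous = match.arg(ambiguous))
}

#' Write a genome to a FASTA file
#'
#' @param genome An [at_genome] object.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "at_genome"))
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Map chromosome names to subgenomes
#'
#' Wheat-style chromosome names (`1A` ... `7D`, optionally prefixed with
#' `chr`) are mapped to their subgenome letter. Names that do not match the
#' pattern are routed to the `"unassigned"` bucket rather than dropped.
#'
#' @param chrom Character vector of chromosome names.
#' @param pattern Regular expression whose first capture group is the
#'   subgenome letter.
#' @return Character vector with values in `c("A", "B", "D", "unassigned")`.
#' @export
#' @examples
#' subgenome_of(c("chr3A", "7D", "scaffold12"))
subgenome_of <- function(chrom, pattern = "^(?:[Cc]hr)?[1-7]([ABD])$") {
  m <- stringr::str_match(chrom, pattern)[, 2]
  ifelse(is.na(m), "unassigned", m)
}

count_bases_string <- function(s) {
  n <- unname(vapply(
    c(BASES, "N"),
    function(b) sum(stringr::str_count(s, stringr::fixed(b))),
    numeric(1)
  ))
  tibble::tibble(nA = n[1], nC = n[2], nG = n[3], nT = n[4], nN = n[5])
}

#' Count bases by scope
#'
#' Tallies the four bases and `N` per chromosome, subgenome, whole genome, or
#' per region of a region set. `N` is reported but excluded from downstream
#' fractions.
#'
#' @param genome An [at_genome] object.
#' @param regions Optional region tibble (columns `chrom`, `start`, `end`,
#'   `label`; 1-based inclusive coordinates as returned by [read_bed()]).
#'   When given, counts are per region label.
#' @param by Scope when `regions` is `NULL`: `"chromosome"`, `"subgenome"`,
#'   or `"genome"`.
#' @return A tibble with columns `scope`, `nA`, `nC`, `nG`, `nT`, `nN`,
#'   `total`.
#' @export
count_bases <- function(genome, regions = NULL,
                        by = c("chromosome", "subgenome", "genome")) {
  stopifnot(inherits(genome, "at_genome"))
  by <- match.arg(by)
  if (is.null(regions)) {
    per_chrom <- purrr::map_dfr(names(genome$seq), function(cn) {
      dplyr::mutate(count_bases_string(genome$seq[[cn]]), scope = cn)
    })
    out <- switch(by,
      chromosome = per_chrom,
      subgenome = per_chrom |>
        dplyr::mutate(scope = subgenome_of(.data$scope)) |>
        dplyr::group_by(.data$scope) |>
        dplyr::summarise(dplyr::across(dplyr::starts_with("n"), sum),
          .groups = "drop"
        ),
      genome = per_chrom |>
        dplyr::summarise(dplyr::across(dplyr::starts_with("n"), sum)) |>
        dplyr::mutate(scope = "genome")
    )
  } else {
    check_regions(regions, genome)
    out <- regions |>
      dplyr::mutate(
        .seq = substring(
          genome$seq[.data$chrom], .data$start, .data$end
        )
      ) |>
      dplyr::group_by(scope = .data$label) |>
      dplyr::summarise(
        count_bases_string(paste0(.data$.seq, collapse = "")),
        .groups = "drop"
      )
  }
  out |>
    dplyr::mutate(total = .data$nA + .data$nC + .data$nG + .data$nT + .data$nN) |>
    dplyr::select(
      "scope", "nA", "nC", "nG", "nT", "nN", "total"
    )
}

check_regions <- function(regions, genome) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(regions))) {
    stop("regions must have columns chrom, start, end", call. = FALSE)
  }
  unknown <- setdiff(unique(regions$chrom), names(genome$seq))
  if (length(unknown)) {
    stop("regions on unknown chromosome(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- regions$start < 1 | regions$end > genome$lengths[regions$chrom] |
    regions$start > regions$end
  if (any(bad)) {
    stop(sum(bad), " region(s) out of chromosome bounds", call. = FALSE)
  }
  invisible(regions)
}

#' [AT] fraction of base counts
#'
#' The [AT] value is the fraction of counted bases that are A or T; `N` is
#' excluded from the denominator. Scopes consisting entirely of `N` get `NA`.
#'
#' @param counts A tibble with columns `nA`, `nC`, `nG`, `nT` (e.g. from
#'   [count_bases()]).
#' @return `counts` with an added `at` column.
#' @export
#' @examples
#' at_fraction(tibble::tibble(nA = 1, nC = 1, nG = 1, nT = 1, nN = 0))$at
at_fraction <- function(counts) {
  tot <- counts$nA + counts$nC + counts$nG + counts$nT
  dplyr::mutate(
    tibble::as_tibble(counts),
    at = ifelse(tot > 0, (counts$nA + counts$nT) / tot, NA_real_)
  )
}

#' Parity-rule-2 deviations
#'
#' Under the second parity rule a single strand has \[A\] close to \[T\] and
#' \[C\] close to \[G\]. This returns the signed deviations
#' `dAT = [A] - [T]` and `dCG = [C] - [G]`, with fractions taken over the four
#' unambiguous bases.
#'
#' @inheritParams at_fraction
#' @return `counts` with added `dAT` and `dCG` columns.
#' @export
pr2_deviation <- function(counts) {
  tot <- counts$nA + counts$nC + counts$nG + counts$nT
  dplyr::mutate(
    tibble::as_tibble(counts),
    dAT = ifelse(tot > 0, (counts$nA - counts$nT) / tot, NA_real_),
    dCG = ifelse(tot > 0, (counts$nC - counts$nG) / tot, NA_real_)
  )
}

sum_counts <- function(counts) {
  c(
    nA = sum(counts$nA), nC = sum(counts$nC),
    nG = sum(counts$nG), nT = sum(counts$nT)
  )
}

#' Shuffling test for an [AT] difference between two base pools
#'
#' Draws `n_iter` multinomial bootstrap replicates of `sample_size` bases from
#' the base-composition pool implied by each side's counts, computes the [AT]
#' value of every replicate, and compares the two replicate sets with a
#' two-sample t-test (equal-variance by default, matching an
#' independent-sample t-test; Welch via `var_equal = FALSE`).
#'
#' @param counts_x,counts_y Base-count tibbles (rows are summed per side).
#' @param n_iter Number of bootstrap replicates per side (at least 2).
#' @param sample_size Number of bases drawn per replicate.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param var_equal Use the pooled-variance t-test (default `TRUE`).
#' @return One-row tibble with `at_x`, `at_y` (bootstrap means), `statistic`,
#'   `p_value`, `n_iter`, `sample_size`.
#' @export
shuffle_at_test <- function(counts_x, counts_y, n_iter = 100, sample_size,
                            seed = 1L, var_equal = TRUE) {
  stopifnot(n_iter >= 2, sample_size >= 1)
  cx <- sum_counts(counts_x)
  cy <- sum_counts(counts_y)
  if (sum(cx) == 0 || sum(cy) == 0) {
    stop("each side needs a positive number of A/C/G/T bases", call. = FALSE)
  }
  reps <- with_seed(seed, {
    rx <- rmultinom(n_iter, sample_size, cx / sum(cx))
    ry <- rmultinom(n_iter, sample_size, cy / sum(cy))
    list(
      x = (rx["nA", ] + rx["nT", ]) / sample_size,
      y = (ry["nA", ] + ry["nT", ]) / sample_size
    )
  })
  if (var(reps$x) == 0 && var(reps$y) == 0) {
    # degenerate: no resampling variance on either side
    p <- if (isTRUE(all.equal(mean(reps$x), mean(reps$y)))) 1 else 0
    stat <- NA_real_
  } else {
    tt <- t.test(reps$x, reps$y, var.equal = var_equal)
    p <- tt$p.value
    stat <- unname(tt$statistic)
  }
  tibble::tibble(
    at_x = mean(reps$x), at_y = mean(reps$y),
    statistic = stat, p_value = p,
    n_iter = n_iter, sample_size = sample_size
  )
}
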