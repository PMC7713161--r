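#' Gene-model container
#'
#' A flat feature table describing gene models: one row per feature with
#' columns `chrom`, `type` (`gene`, `mRNA`, `exon`, `CDS`,
#' `five_prime_UTR`, `three_prime_UTR`), `start`, `end` (1-based inclusive),
#' `strand` (`+`/`-`), `phase` (CDS only, else `NA`), `gene_id`,
#' `transcript_id`.
#'
#' @param features Data frame of features as described above.
#' @return A tibble of class `at_gene_models`.
#' @export
at_gene_models <- function(features) {
  features <- tibble::as_tibble(features)
  need <- c(
    "chrom", "type", "start", "end", "strand", "phase",
    "gene_id", "transcript_id"
  )
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    stop("gene models missing column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(features$start > features$end)) {
    stop("feature start > end", call. = FALSE)
  }
  class(features) <- c("at_gene_models", class(features))
  features
}

#' Read gene models from a GFF3 file
#'
#' @param path Path to a GFF3 file.
#' @return An [at_gene_models] tibble.
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- tibble::as_tibble(as.data.frame(g))
  id <- as.character(g$ID)
  parent <- vapply(
    g$Parent,
    function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
    character(1)
  )
  type <- as.character(g$type)
  tx_parent <- setNames(parent, id)[!is.na(id)]
  transcript_id <- ifelse(type %in% c("mRNA", "transcript"), id, parent)
  gene_id <- dplyr::case_when(
    type == "gene" ~ id,
    type %in% c("mRNA", "transcript") ~ parent,
    TRUE ~ unname(tx_parent[parent])
  )
  at_gene_models(tibble::tibble(
    chrom = as.character(g$seqid),
    type = type,
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = as.character(g$strand),
    phase = suppressWarnings(as.integer(as.character(g$phase))),
    gene_id = gene_id,
    transcript_id = transcript_id
  ))
}

#' Write gene models to a GFF3 file
#'
#' @param models An [at_gene_models] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  if (nrow(models) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  attrs <- dplyr::case_when(
    models$type == "gene" ~ paste0("ID=", models$gene_id),
    models$type %in% c("mRNA", "transcript") ~ paste0(
      "ID=", models$transcript_id, ";Parent=", models$gene_id
    ),
    TRUE ~ paste0(
      "ID=", models$transcript_id, ":", tolower(models$type), ":",
      seq_len(nrow(models)), ";Parent=", models$transcript_id
    )
  )
  lines <- paste(
    models$chrom, "atshift", models$type, models$start, models$end, ".",
    models$strand, ifelse(is.na(models$phase), ".", models$phase), attrs,
    sep = "\t"
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

revcomp_string <- function(s) {
  rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", s))))
}

# assemble per-transcript CDS info: coding-strand sequence and the genomic
# intervals in coding order
transcript_cds <- function(models, genome) {
  cds <- dplyr::filter(tibble::as_tibble(models), .data$type == "CDS")
  split(cds, cds$transcript_id) |>
    purrr::imap(function(df, tx) {
      df <- df[order(df$start), , drop = FALSE]
      total <- sum(df$end - df$start + 1)
      pieces <- substring(genome$seq[[df$chrom[1]]], df$start, df$end)
      seq_fwd <- paste0(pieces, collapse = "")
      strand <- df$strand[1]
      first_phase <- if (strand == "+") df$phase[1] else df$phase[nrow(df)]
      list(
        chrom = df$chrom[1], strand = strand,
        starts = df$start, ends = df$end, total = total,
        phase = first_phase %||% 0L,
        seq = if (strand == "+") seq_fwd else revcomp_string(seq_fwd)
      )
    })
}

classify_cds_hit <- function(pos, alt, tx) {
  # offset of pos along the forward-strand concatenation of CDS pieces
  before <- tx$ends < pos
  piece <- which(tx$starts <= pos & tx$ends >= pos)
  off <- sum((tx$ends - tx$starts + 1)[before]) + (pos - tx$starts[piece])
  cds_index <- if (tx$strand == "+") off + 1 else tx$total - off
  codon_idx <- ceiling(cds_index / 3)
  pos_in_codon <- cds_index - 3 * (codon_idx - 1)
  codon <- substring(tx$seq, 3 * codon_idx - 2, 3 * codon_idx)
  alt_coding <- if (tx$strand == "+") alt else complement_base(alt)
  alt_codon <- codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_coding
  if (grepl("N", codon)) {
    return("other_genic")
  }
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (codon_idx == 1 && codon != alt_codon) {
    return("other_genic") # start-codon change
  }
  if (aa_ref == "*" || aa_alt == "*") {
    return("other_genic") # stop loss or gain
  }
  if (aa_ref == aa_alt) "synonymous" else "missense"
}

#' Classify SNPs into seven functional annotation sets
#'
#' Each site gets exactly one class: `synonymous`, `missense`,
#' `other_genic` (start/stop/splice-disrupting or frame-anomalous coding
#' changes), `utr`, `intronic`, `gene_proximal` (within `proximal_bp` of a
#' gene) or `intergenic`. When a site hits several transcripts the most
#' severe effect wins, with severity
#' `missense > synonymous > other_genic > utr > intronic`. Transcripts whose
#' CDS length is not a multiple of three are skipped with a warning.
#'
#' @param sites Site tibble (columns `chrom`, `pos`, `ref`, `alt`) or an
#'   [at_geno] object.
#' @param models An [at_gene_models] tibble.
#' @param genome An [at_genome] object supplying the coding sequence.
#' @param proximal_bp Distance in bp defining `gene_proximal`.
#' @param splice_bp Width of the intronic splice region (counted as
#'   `other_genic`).
#' @return The site tibble with an added `annot_class` column.
#' @export
classify_sites <- function(sites, models, genome, proximal_bp = 5000,
                           splice_bp = 2) {
  if (inherits(sites, "at_geno")) sites <- sites$sites
  sites <- tibble::as_tibble(sites)
  feats <- tibble::as_tibble(models)
  txs <- transcript_cds(models, genome)
  bad <- names(txs)[vapply(
    txs, function(t) t$total %% 3 != 0 || (t$phase %||% 0) != 0, logical(1)
  )]
  if (length(bad)) {
    warning(
      "skipping transcript(s) with frame-anomalous CDS: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
    txs <- txs[setdiff(names(txs), bad)]
  }
  severity <- c(
    missense = 1, synonymous = 2, other_genic = 3, utr = 4, intronic = 5
  )

  feature_hits <- function(kind) {
    idx <- which(feats$type %in% kind)
    hits <- hit_table(sites, feats[idx, , drop = FALSE])
    lapply(hits, function(h) idx[h])
  }
  cds_hits <- feature_hits("CDS")
  utr_hits <- feature_hits(c("five_prime_UTR", "three_prime_UTR"))
  exon_hits <- feature_hits("exon")
  tx_hits <- feature_hits(c("mRNA", "transcript"))
  genes <- dplyr::filter(feats, .data$type == "gene")
  prox <- genes
  prox$start <- pmax(1L, genes$start - as.integer(proximal_bp))
  prox$end <- genes$end + as.integer(proximal_bp)
  prox_hits <- hit_table(sites, prox)

  annot <- vapply(seq_len(nrow(sites)), function(i) {
    classes <- character(0)
    for (h in cds_hits[[i]]) {
      tx <- txs[[feats$transcript_id[h]]]
      if (is.null(tx)) next
      classes <- c(classes, classify_cds_hit(sites$pos[i], sites$alt[i], tx))
    }
    if (length(utr_hits[[i]])) classes <- c(classes, "utr")
    for (h in tx_hits[[i]]) {
      # intron: inside the transcript but in none of its exons
      tx_id <- feats$transcript_id[h]
      in_exon <- any(feats$transcript_id[exon_hits[[i]]] %in% tx_id) ||
        any(feats$transcript_id[cds_hits[[i]]] %in% tx_id) ||
        any(feats$transcript_id[utr_hits[[i]]] %in% tx_id)
      if (!in_exon) {
        exons <- feats[
          which(
            feats$transcript_id == tx_id &
              feats$type %in%
                c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
          ),
        ]
        near_boundary <- any(
          abs(sites$pos[i] - exons$start) <= splice_bp |
            abs(sites$pos[i] - exons$end) <= splice_bp
        )
        classes <- c(classes, if (near_boundary) "other_genic" else "intronic")
      }
    }
    if (length(classes)) {
      return(names(which.min(severity[unique(classes)])))
    }
    if (length(prox_hits[[i]])) {
      return("gene_proximal")
    }
    "intergenic"
  }, character(1))
  dplyr::mutate(sites, annot_class = annot)
}

# list of feature row indices hit by each site
hit_table <- function(sites, feats) {
  out <- vector("list", nrow(sites))
  if (nrow(feats) == 0) {
    return(out)
  }
  for (cn in unique(feats$chrom)) {
    fi <- which(feats$chrom == cn)
    si <- which(sites$chrom == cn)
    if (!length(si)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[si], sites$pos[si]),
      IRanges::IRanges(feats$start[fi], feats$end[fi])
    )
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    for (u in unique(q)) {
      out[[si[u]]] <- c(out[[si[u]]], fi[s[q == u]])
    }
  }
  out
}

#' Merge the seven annotation classes into genic / non-genic sets
#'
#' `intergenic` and `gene_proximal` become `non_genic`; the five remaining
#' classes (`utr`, `intronic`, `synonymous`, `missense`, `other_genic`)
#' become `genic`.
#'
#' @param classes Character vector of annotation classes, or a tibble with
#'   an `annot_class` column.
#' @return Character vector (or tibble with added `annot_set` column).
#' @export
merge_sets <- function(classes) {
  map <- function(cl) {
    ifelse(cl %in% c("intergenic", "gene_proximal"), "non_genic", "genic")
  }
  if (is.data.frame(classes)) {
    dplyr::mutate(classes, annot_set = map(.data$annot_class))
  } else {
    map(classes)
  }
}

#' Equal-size random subsamples of two SNP sets
#'
#' Uniform sampling without replacement down to the smaller set's size, so
#' [AT] comparisons between annotation sets are not confounded by set size.
#' Deterministic under `seed`.
#'
#' @param set_x,set_y Data frames (or vectors) to subsample.
#' @param seed Integer seed.
#' @return List with elements `x` and `y` of equal size.
#' @export
subsample_equal <- function(set_x, set_y, seed = 1L) {
  size_of <- function(s) if (is.data.frame(s)) nrow(s) else length(s)
  take <- function(s, idx) {
    if (is.data.frame(s)) s[idx, , drop = FALSE] else s[idx]
  }
  nx <- size_of(set_x)
  ny <- size_of(set_y)
  stopifnot(nx > 0, ny > 0)
  m <- min(nx, ny)
  with_seed(seed, {
    ix <- sort(sample.int(nx, m))
    iy <- sort(sample.int(ny, m))
    list(x = take(set_x, ix), y = take(set_y, iy))
  })
}
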