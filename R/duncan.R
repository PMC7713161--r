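#' Duncan's multiple range test
#'
#' One-way ANOVA followed by Duncan's protected multiple range procedure.
#' Groups are ranked by mean; the range between the means ranked `i` and `j`
#' (spanning `p = j - i + 1` means) is compared against the least significant
#' range built from the studentized-range quantile at the protection level
#' `alpha_p = 1 - (1 - alpha)^(p - 1)`. A span declared non-significant
#' protects all of its sub-spans. Groups that share a letter are not
#' significantly different.
#'
#' For unequal group sizes the standard error of a pair uses the harmonic
#' mean of the two group sizes, `sqrt(MSE / n_h)` with
#' `n_h = 2 / (1/n_i + 1/n_j)`.
#'
#' @param values_by_group Either a data frame with columns `group` and
#'   `value`, or a named list of numeric vectors. For data frames whose value
#'   column is named differently, pass `value_col`.
#' @param alpha Significance level (default 0.05).
#' @param value_col,group_col Column names when `values_by_group` is a data
#'   frame.
#' @return Tibble ordered by decreasing mean with columns `group`, `n`,
#'   `mean`, `letter`; attributes `mse` and `df` carry the ANOVA error mean
#'   square and its degrees of freedom.
#' @export
#' @examples
#' d <- data.frame(
#'   group = rep(c("a", "b"), each = 10),
#'   value = c(rnorm(10), rnorm(10, 5))
#' )
#' duncan_mrt(d)
duncan_mrt <- function(values_by_group, alpha = 0.05,
                       value_col = "value", group_col = "group") {
  if (is.list(values_by_group) && !is.data.frame(values_by_group)) {
    values_by_group <- purrr::imap_dfr(
      values_by_group,
      function(v, g) tibble::tibble(group = g, value = v)
    )
    value_col <- "value"
    group_col <- "group"
  }
  if (value_col == "at_value" || !value_col %in% names(values_by_group)) {
    # allow composition profiles straight from accession_composition()
    if ("at_value" %in% names(values_by_group)) value_col <- "at_value"
  }
  df0 <- tibble::tibble(
    group = as.character(values_by_group[[group_col]]),
    value = as.numeric(values_by_group[[value_col]])
  )
  df0 <- dplyr::filter(df0, !is.na(.data$value))
  sizes <- table(df0$group)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  stats <- df0 |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$value),
      ss = sum((.data$value - mean(.data$value))^2),
      .groups = "drop"
    )
  k <- nrow(stats)
  n_tot <- sum(stats$n)
  dfe <- n_tot - k
  mse <- sum(stats$ss) / dfe
  # rank by decreasing mean; group name breaks ties deterministically
  ord <- order(-stats$mean, stats$group)
  m <- stats$mean[ord]
  nn <- stats$n[ord]
  sig <- duncan_significance(m, nn, mse, dfe, alpha)
  letters <- range_letters(!sig)
  tibble::tibble(
    group = stats$group[ord], n = nn, mean = m, letter = letters
  ) |>
    structure(mse = mse, df = dfe)
}

# significance matrix of the protected range procedure for means `m` sorted
# in decreasing order; TRUE means the pair differs significantly
duncan_significance <- function(m, nn, mse, dfe, alpha) {
  k <- length(m)
  sig <- matrix(FALSE, k, k)
  nonsig <- matrix(FALSE, k, k)
  diag(nonsig) <- TRUE
  for (p in seq(k, 2)) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    for (i in seq_len(k - p + 1)) {
      j <- i + p - 1
      if (nonsig[i, j]) next
      rng <- m[i] - m[j]
      if (mse == 0) {
        is_sig <- rng > 0
      } else {
        n_h <- 2 / (1 / nn[i] + 1 / nn[j])
        crit <- qtukey(1 - alpha_p, p, dfe) * sqrt(mse / n_h)
        is_sig <- rng > crit
      }
      if (is_sig) {
        sig[i, j] <- sig[j, i] <- TRUE
      } else {
        # protection: a non-significant span covers all its sub-spans
        nonsig[i:j, i:j] <- TRUE
      }
    }
  }
  sig
}

# assign compact letters from a symmetric "shares a group" matrix whose rows
# are ordered by decreasing mean; for range procedures the TRUE entries of
# each row are contiguous, so letters are maximal non-significant runs
range_letters <- function(ns) {
  k <- nrow(ns)
  runs <- vapply(seq_len(k), function(i) max(which(ns[i, ])), integer(1))
  ends <- cummax(runs)
  intervals <- list()
  for (i in seq_len(k)) {
    iv <- c(i, ends[i])
    if (length(intervals) &&
      intervals[[length(intervals)]][2] >= iv[2]) {
      next # dominated by an earlier interval
    }
    intervals[[length(intervals) + 1]] <- iv
  }
  out <- character(k)
  for (s in seq_along(intervals)) {
    iv <- intervals[[s]]
    idx <- iv[1]:iv[2]
    out[idx] <- paste0(out[idx], letters[(s - 1) %% 26 + 1])
  }
  out
}
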