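## Inclusion-assay count tables: percentages with the display convention
## used for near-background values, aggregator calls against a cutoff, and
## the exact-test association between predicted consequence and
## aggregation.

#' One inclusion-count record
#'
#' @param variant variant label (e.g., "E40G", "WT").
#' @param timepoint hours post-transfection (24 or 48).
#' @param n_counted cells counted (> 0).
#' @param n_inclusions cells with inclusions (0..n_counted).
#' @param als_associated is the variant ALS-associated?
#' @return An \code{inclusion_counts} object.
#' @export
inclusion_counts <- function(variant, timepoint, n_counted, n_inclusions,
                             als_associated = FALSE) {
  n_counted <- as.integer(n_counted)
  n_inclusions <- as.integer(n_inclusions)
  if (is.na(n_counted) || n_counted <= 0) {
    stop("n_counted must be positive", call. = FALSE)
  }
  if (is.na(n_inclusions) || n_inclusions < 0 ||
      n_inclusions > n_counted) {
    stop("n_inclusions must be in [0, n_counted]", call. = FALSE)
  }
  structure(list(variant = variant, timepoint = as.numeric(timepoint),
                 n_counted = n_counted, n_inclusions = n_inclusions,
                 als_associated = isTRUE(als_associated)),
            class = "inclusion_counts")
}

## round half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Percentage of cells with inclusions
#'
#' Raw percentage 100 * n_inclusions / n_counted. \code{display = TRUE}
#' renders the integer percent under round-half-up, with fractions in
#' (0, 1)\% shown as "<= 1\%" (near-background counts are reported as a
#' bound, not a rounded value).
#'
#' @param counts an \code{inclusion_counts} (or anything with
#'   \code{n_counted} / \code{n_inclusions} fields).
#' @param display return the display string instead of the raw number.
#' @return Numeric percentage, or character when \code{display}.
#' @examples
#' inclusion_fraction(inclusion_counts("E40G", 48, 238, 186))  # 78.15...
#' @export
inclusion_fraction <- function(counts, display = FALSE) {
  if (counts$n_counted <= 0) stop("zero denominator", call. = FALSE)
  pct <- 100 * counts$n_inclusions / counts$n_counted
  if (!display) return(pct)
  if (pct > 0 && pct < 1) return("≤ 1%")
  sprintf("%d%%", round_half_up(pct))
}

#' Call a variant an aggregator
#'
#' TRUE when the raw inclusion percentage strictly exceeds \code{cutoff}
#' at either timepoint. The margin over the background (e.g. wild-type)
#' fraction is reported per timepoint.
#'
#' @param counts_24,counts_48 \code{inclusion_counts} for the same variant
#'   at 24 and 48 hours.
#' @param cutoff aggregation-call cutoff, percent (default 5).
#' @param background optional list of two \code{inclusion_counts} (24, 48
#'   hr) giving the background rates.
#' @return List of class \code{aggregator_call}: \code{variant},
#'   \code{aggregator} (logical), \code{fractions}, \code{cutoff},
#'   \code{margin} (percent over background, NA without background).
#' @export
call_aggregator <- function(counts_24, counts_48, cutoff = 5,
                            background = NULL) {
  if (!identical(counts_24$variant, counts_48$variant)) {
    stop("timepoints belong to different variants: ", counts_24$variant,
         " vs ", counts_48$variant, call. = FALSE)
  }
  f <- c(`24` = inclusion_fraction(counts_24),
         `48` = inclusion_fraction(counts_48))
  margin <- c(`24` = NA_real_, `48` = NA_real_)
  if (!is.null(background)) {
    margin <- f - c(inclusion_fraction(background[[1]]),
                    inclusion_fraction(background[[2]]))
  }
  structure(list(variant = counts_24$variant,
                 aggregator = any(f > cutoff),
                 fractions = f, cutoff = cutoff, margin = margin),
            class = "aggregator_call")
}

#' @export
print.aggregator_call <- function(x, ...) {
  cat(sprintf("<aggregator_call> %s: %s (%.1f%% / %.1f%%, cutoff %g%%)\n",
              x$variant, if (x$aggregator) "aggregator" else "non-aggregator",
              x$fractions[1], x$fractions[2], x$cutoff))
  invisible(x)
}

#' Read an inclusion-count table
#'
#' Delimited text with header columns \code{variant}, \code{timepoint},
#' \code{n_counted}, \code{n_inclusions} and optionally
#' \code{als_associated}; any printed percentage columns are ignored in
#' favor of the raw counts. Row-level invariant violations are collected
#' and reported together.
#'
#' @param path file path (CSV by default).
#' @param sep field separator.
#' @return List of \code{inclusion_counts}, one per row, with attribute
#'   \code{"variants"} (unique variant labels in order).
#' @export
read_counts_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("variant", "timepoint", "n_counted", "n_inclusions")
  if (nrow(df) == 0) stop("empty counts table", call. = FALSE)
  if (!all(need %in% names(df))) {
    stop("counts table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!("als_associated" %in% names(df))) df$als_associated <- FALSE
  errors <- character(0)
  out <- list()
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      inclusion_counts(df$variant[i], df$timepoint[i], df$n_counted[i],
                       df$n_inclusions[i], df$als_associated[i]),
      error = function(e) {
        errors <<- c(errors, sprintf("row %d (%s): %s", i, df$variant[i],
                                     conditionMessage(e)))
        NULL
      })
    if (!is.null(rec)) out[[length(out) + 1]] <- rec
  }
  if (length(errors)) {
    stop("invalid rows in counts table:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  attr(out, "variants") <- unique(df$variant)
  out
}

#' Path to the packaged inclusion-count table
#'
#' The 12-variant, two-timepoint cell-count table (wild type, G93A, four
#' substitutions at position 40, six variants at position 133) with the
#' expected consequence labels alongside.
#'
#' @return File path of the packaged CSV.
#' @export
packaged_counts_path <- function() {
  system.file("extdata", "inclusion_counts.csv", package = "steriscan",
              mustWork = TRUE)
}

#' Expected consequence labels shipped with the packaged counts
#'
#' @return Named character vector, variant -> consequence label ("N/A" for
#'   the wild-type background row).
#' @export
packaged_expected_consequences <- function() {
  df <- utils::read.csv(packaged_counts_path(), stringsAsFactors = FALSE)
  df <- df[!duplicated(df$variant), ]
  stats::setNames(df$expected_consequence, df$variant)
}

#' Exact-test association between predicted consequence and aggregation
#'
#' Assembles the 2x2 contingency table (consequence-predicted vs none) x
#' (aggregator vs not) and computes the two-sided Fisher exact p-value and
#' the sample odds ratio (with Haldane +0.5 correction when any cell of a
#' zero margin requires it). The statistic is this package's
#' formalization of the qualitative association; it is labeled as such in
#' reports.
#'
#' @param calls list of \code{consequence_call} objects, or a logical /
#'   character vector (TRUE / any label other than "None" means a
#'   predicted consequence).
#' @param aggregator_flags logical vector, same length.
#' @return An \code{association_result}: \code{contingency} (2x2 matrix),
#'   \code{p_value}, \code{odds_ratio}, \code{haldane} (was the correction
#'   applied), \code{n}.
#' @export
associate <- function(calls, aggregator_flags) {
  predicted <- if (is.logical(calls)) calls
  else if (is.character(calls)) !vapply(calls, function(x)
    identical(.parse_labels(x), "NONE"), logical(1))
  else vapply(calls, function(cl) !identical(cl$labels, "NONE"), logical(1))
  if (length(predicted) != length(aggregator_flags)) {
    stop("calls and aggregator flags differ in length", call. = FALSE)
  }
  if (length(predicted) < 2) stop("need at least 2 variants", call. = FALSE)

  tab <- table(factor(predicted, levels = c(TRUE, FALSE)),
               factor(aggregator_flags, levels = c(TRUE, FALSE)))
  dimnames(tab) <- list(consequence = c("predicted", "none"),
                        aggregation = c("aggregator", "non-aggregator"))
  p <- stats::fisher.test(tab)$p.value
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  haldane <- any(c(a, b, cc, d) == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * cc)
  structure(list(contingency = unclass(tab), p_value = p, odds_ratio = or,
                 haldane = haldane, n = length(predicted)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("Association between predicted consequence and aggregation\n")
  cat("(package formalization; an exact test on the 2x2 table)\n\n")
  print(x$contingency)
  cat(sprintf("\nFisher exact p = %.6g; odds ratio = %.4g%s (n = %d)\n",
              x$p_value, x$odds_ratio,
              if (x$haldane) " [Haldane-corrected]" else "", x$n))
  invisible(x)
}

#' Summarise a counts table: percentages, aggregator calls, association
#'
#' Convenience wrapper reproducing the published-table layout: per variant
#' and timepoint the counted cells, inclusion-bearing cells, raw and
#' display percentages; aggregator calls against the background variant;
#' and, when expected or computed consequence labels are available, the
#' association result.
#'
#' @param counts list of \code{inclusion_counts} from
#'   \code{\link{read_counts_table}}.
#' @param cutoff aggregator cutoff, percent.
#' @param background_variant label of the background row (default "WT");
#'   the background variant is excluded from the association.
#' @param consequences optional named character vector, variant ->
#'   consequence label, used for the association.
#' @return List of class \code{aggregation_summary}: \code{table} (data
#'   frame), \code{aggregators} (named logical), \code{association}
#'   (NULL without labels).
#' @export
summarise_counts <- function(counts, cutoff = 5, background_variant = "WT",
                             consequences = NULL) {
  df <- do.call(rbind, lapply(counts, function(cc) data.frame(
    variant = cc$variant, timepoint = cc$timepoint,
    n_counted = cc$n_counted, n_inclusions = cc$n_inclusions,
    pct = inclusion_fraction(cc),
    pct_display = inclusion_fraction(cc, display = TRUE),
    stringsAsFactors = FALSE)))
  variants <- unique(df$variant)
  bg <- NULL
  if (background_variant %in% variants) {
    bi <- which(df$variant == background_variant)
    bg <- counts[bi[order(df$timepoint[bi])]]
  }
  agg <- stats::setNames(logical(0), character(0))
  for (v in variants) {
    vi <- which(df$variant == v)
    vi <- vi[order(df$timepoint[vi])]
    if (length(vi) != 2) next
    agg[v] <- call_aggregator(counts[[vi[1]]], counts[[vi[2]]],
                              cutoff = cutoff,
                              background = bg)$aggregator
  }
  assoc <- NULL
  if (!is.null(consequences)) {
    use <- setdiff(intersect(names(agg), names(consequences)),
                   background_variant)
    if (length(use) >= 2) {
      assoc <- associate(unname(consequences[use]), unname(agg[use]))
    }
  }
  structure(list(table = df, aggregators = agg, association = assoc,
                 cutoff = cutoff, background_variant = background_variant),
            class = "aggregation_summary")
}

#' @export
print.aggregation_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("\naggregators (cutoff %g%% at either timepoint): %s\n",
              x$cutoff,
              paste(names(x$aggregators)[x$aggregators], collapse = ", ")))
  if (!is.null(x$association)) { cat("\n"); print(x$association) }
  invisible(x)
}
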