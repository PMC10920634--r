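#' Methylxanthine positivity calls
#'
#' An item is positive for an analyte when its measured amount strictly
#' exceeds the threshold (default 700 pg/sample). Sub-threshold values are
#' reported as 0 in the `reported` table, as in the survey convention.
#'
#' @param records `data.frame` with `item_id` and analyte columns
#'   (`theobromine`, `theophylline`, `caffeine`; pg/sample, `NA` allowed).
#' @param threshold Positivity threshold in pg/sample (> 0).
#' @param analytes Analyte column names to call.
#' @return A list with `flags` (`data.frame` of logicals per analyte) and
#'   `reported` (values with sub-threshold entries zeroed).
#' @export
#' @examples
#' call_positive(data.frame(item_id = "a", theobromine = 700,
#'                          theophylline = 701, caffeine = 0))$flags
call_positive <- function(records, threshold = 700,
                          analytes = c("theobromine", "theophylline",
                                       "caffeine")) {
  if (threshold <= 0) stop("threshold must be positive")
  analytes <- intersect(analytes, names(records))
  if (!length(analytes)) stop("no analyte columns found")
  flags <- data.frame(item_id = records$item_id, stringsAsFactors = FALSE)
  reported <- flags
  for (a in analytes) {
    v <- records[[a]]
    flags[[a]] <- !is.na(v) & v > threshold
    reported[[a]] <- ifelse(flags[[a]], v, 0)
  }
  list(flags = flags, reported = reported, threshold = threshold)
}

#' Estimate the background break point of a measurement distribution
#'
#' Looks for the largest gap between consecutive log10-transformed sorted
#' values below the given upper quantile; the break point is the geometric
#' midpoint of that gap. When no gap exceeds `min_gap` decades the break is
#' reported as undefined.
#'
#' @param values Positive measurements (pg/sample); non-positive values are
#'   dropped.
#' @param min_gap Noise floor: minimum gap size in log10 decades.
#' @param upper_quantile Values above this quantile are ignored so extreme
#'   positives do not masquerade as the break.
#' @return A list with `defined` (logical), `breakpoint` (pg/sample, `NA`
#'   when undefined), `gap` (decades), `lower`, `upper` (gap edges).
#' @export
estimate_background_break <- function(values, min_gap = 0.5,
                                      upper_quantile = 0.95) {
  v <- sort(values[!is.na(values) & values > 0])
  if (length(v) < 20) stop("at least 20 positive-valued measurements required")
  v <- v[v <= quantile(v, upper_quantile)]
  lv <- log10(v)
  gaps <- diff(lv)
  if (!length(gaps) || max(gaps) < min_gap) {
    return(list(defined = FALSE, breakpoint = NA_real_,
                gap = if (length(gaps)) max(gaps) else NA_real_,
                lower = NA_real_, upper = NA_real_))
  }
  i <- which.max(gaps)
  list(defined = TRUE,
       breakpoint = 10^((lv[i] + lv[i + 1]) / 2),
       gap = gaps[i], lower = v[i], upper = v[i + 1])
}

#' Concordance between methylxanthine and aDNA presence calls
#'
#' Builds per-analyte 2x2 tables (chemistry positive/negative against aDNA
#' positive/negative) over items analyzed by both methods, with
#' percentages in both directions sharing the same both-positive cell.
#' Percentages are integer-rounded half-up, with one decimal alongside.
#'
#' @param chem_flags `data.frame` from [call_positive()]`$flags` (`item_id`
#'   plus logical analyte columns).
#' @param adna_positive Named logical vector of aDNA presence per item id.
#' @param strict When `TRUE` (default), item ids present in only one of
#'   the two inputs raise an error listing the orphans; otherwise the
#'   intersection is used.
#' @return An object of class `concordance_table`: per-analyte list of 2x2
#'   counts and percentages, plus `n_items`.
#' @export
concordance <- function(chem_flags, adna_positive, strict = TRUE) {
  chem_ids <- chem_flags$item_id
  adna_ids <- names(adna_positive)
  orphans <- c(setdiff(chem_ids, adna_ids), setdiff(adna_ids, chem_ids))
  if (length(orphans) && strict) {
    stop("item ids not analyzed by both methods: ",
         paste(utils::head(orphans, 10), collapse = ", "))
  }
  ids <- intersect(chem_ids, adna_ids)
  if (!length(ids)) stop("no items analyzed by both methods")
  adna <- adna_positive[ids]
  analytes <- setdiff(names(chem_flags), "item_id")
  out <- list()
  for (a in analytes) {
    chem <- chem_flags[[a]][match(ids, chem_flags$item_id)]
    tab <- c(both = sum(chem & adna),
             chem_only = sum(chem & !adna),
             adna_only = sum(!chem & adna),
             neither = sum(!chem & !adna))
    n_chem <- tab[["both"]] + tab[["chem_only"]]
    n_adna <- tab[["both"]] + tab[["adna_only"]]
    pct <- function(num, den) {
      if (den == 0) return(c(NA_real_, NA_real_))
      c(round_half_up(100 * num / den), round_half_up(100 * num / den, 1))
    }
    p_ca <- pct(tab[["both"]], n_chem)
    p_ac <- pct(tab[["both"]], n_adna)
    out[[a]] <- list(
      counts = tab, n_chem_positive = n_chem, n_adna_positive = n_adna,
      pct_chem_to_adna = p_ca[1], pct_chem_to_adna_1dp = p_ca[2],
      pct_adna_to_chem = p_ac[1], pct_adna_to_chem_1dp = p_ac[2]
    )
  }
  structure(list(analytes = out, n_items = length(ids)),
            class = "concordance_table")
}

#' Concordance table from marginal counts
#'
#' Reconstructs consistent per-item flags from published marginal counts
#' (items analyzed by both methods, chemistry-positive count, both-positive
#' count per analyte, and the aDNA-positive count) and delegates to
#' [concordance()]. Useful for recomputing percentages from a published
#' survey table.
#'
#' @param n_items Items analyzed by both methods.
#' @param adna_positive Number of aDNA-positive items among them.
#' @param analyte_counts `data.frame` with columns `analyte`,
#'   `chem_positive`, `both_positive`.
#' @return A `concordance_table`.
#' @export
#' @examples
#' concordance_from_counts(120, 85,
#'   data.frame(analyte = "theobromine", chem_positive = 96,
#'              both_positive = 62))
concordance_from_counts <- function(n_items, adna_positive, analyte_counts) {
  stopifnot(adna_positive <= n_items)
  ids <- sprintf("I%04d", seq_len(n_items))
  adna <- stats::setNames(seq_len(n_items) <= adna_positive, ids)
  flags <- data.frame(item_id = ids, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(analyte_counts))) {
    a <- analyte_counts$analyte[i]
    n_chem <- analyte_counts$chem_positive[i]
    n_both <- analyte_counts$both_positive[i]
    if (n_both > min(n_chem, adna_positive) ||
        n_chem - n_both > n_items - adna_positive) {
      stop("counts for ", a, " are not consistent with the margins")
    }
    f <- logical(n_items)
    f[seq_len(n_both)] <- TRUE                              # both positive
    f[adna_positive + seq_len(n_chem - n_both)] <- TRUE     # chem only
    flags[[a]] <- f
  }
  concordance(flags, adna)
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Chemistry/aDNA concordance over", x$n_items, "items\n")
  for (a in names(x$analytes)) {
    e <- x$analytes[[a]]
    cat(sprintf(
      "  %-12s chem+ %3d -> aDNA+ %3d (%g%%); aDNA+ %3d -> chem+ (%g%%)\n",
      a, e$n_chem_positive, e$counts[["both"]], e$pct_chem_to_adna,
      e$n_adna_positive, e$pct_adna_to_chem))
  }
  invisible(x)
}
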