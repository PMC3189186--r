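# Are positively selected sites enriched among ionizable residues?
# Site charge classification, selected-site calling from an SLR-style
# table, and the exact contingency test.

#' Classify alignment sites as charged / neutral / gap
#'
#' A site is `charged` iff the reference species' residue at that column is
#' one of the seven ionizable residues R, K, Y, C, H, E, D (the residues
#' that carry the pI); `gap` if the reference shows `-` (such sites are
#' excluded from enrichment); otherwise `neutral`.
#'
#' @param aln a [read_alignment()] result.
#' @param ref_species species whose residues define the classification.
#' @param sites 1-based alignment columns; default all columns.
#' @param charged_residues the ionizable residue set.
#' @return named character vector site -> class (names are the column
#'   numbers).
#' @export
classify_site_charge <- function(aln, ref_species, sites = seq_len(aln$width),
                                 charged_residues = c("R", "K", "Y", "C",
                                                      "H", "E", "D")) {
  stopifnot(inherits(aln, "pi_alignment"))
  if (!ref_species %in% names(aln$rows)) {
    stop("species '", ref_species, "' not in alignment")
  }
  if (any(sites < 1 | sites > aln$width)) {
    stop("site outside alignment columns 1..", aln$width)
  }
  chars <- strsplit(aln$rows[[ref_species]], "")[[1]][sites]
  cls <- ifelse(chars == "-", "gap",
                ifelse(chars %in% charged_residues, "charged", "neutral"))
  stats::setNames(cls, sites)
}

#' Call positively selected sites from a selection table
#'
#' A site is called selected when its p-value is at most `alpha` AND its
#' omega (site-wise dN/dS) exceeds 1 — small p-values with omega < 1
#' indicate purifying, not positive, selection.
#'
#' @param records data frame from [read_selection_table()].
#' @param alpha significance level in (0, 1).
#' @return integer vector of selected site numbers (possibly empty).
#' @export
call_selected_sites <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records), alpha > 0, alpha < 1)
  if (nrow(records) == 0L) return(integer(0))
  sort(records$site[records$pvalue <= alpha & records$omega > 1])
}

#' Enrichment of selected sites among charged residues
#'
#' Builds the 2x2 table (charged/neutral x selected/not) after dropping
#' gap-class sites, and tests over-representation of selection among charged
#' residues with a one-sided Fisher exact test (hypergeometric tail). A
#' chi-squared variant is available for comparison. `expected_random` is the
#' overall selected fraction — the fraction expected at any site class if
#' selected sites were scattered at random.
#'
#' @param selected integer vector of selected site numbers.
#' @param charge_classes named character vector site -> class from
#'   [classify_site_charge()]; every selected site must appear in it.
#' @param test `"fisher"` (default, exact) or `"chisq"`.
#' @return an object of class `enrichment_result`: list with `table`
#'   (named counts a, b, c, d), `frac_charged_selected`,
#'   `frac_neutral_selected`, `expected_random`, `p_value`, `odds_ratio`
#'   (sample odds ratio ad/bc), `conf_int` (exact 95% CI for the odds
#'   ratio; `NULL` for chisq) and `test`.
#' @export
enrichment_test <- function(selected, charge_classes,
                            test = c("fisher", "chisq")) {
  test <- match.arg(test)
  selected <- as.integer(selected)
  sites <- as.integer(names(charge_classes))
  if (any(is.na(sites))) stop("charge_classes must be named by site number")
  unknown <- setdiff(selected, sites)
  if (length(unknown)) {
    stop("selected site(s) without a charge class: ",
         paste(unknown, collapse = ", "))
  }
  keep <- charge_classes != "gap"
  charge_classes <- charge_classes[keep]
  sites <- sites[keep]
  selected <- intersect(selected, sites) # selected sites at ref gaps drop out
  n <- length(sites)
  if (n == 0L) stop("no classified (non-gap) sites to tabulate")

  is_sel <- sites %in% selected
  is_chg <- charge_classes == "charged"
  a <- sum(is_sel & is_chg); b <- sum(!is_sel & is_chg)
  cc <- sum(is_sel & !is_chg); d <- sum(!is_sel & !is_chg)

  m <- matrix(c(a, cc, b, d), nrow = 2,
              dimnames = list(charge = c("charged", "neutral"),
                              selection = c("selected", "background")))
  if (test == "fisher") {
    ft <- stats::fisher.test(m, alternative = "greater")
    p <- ft$p.value
    ci <- as.numeric(stats::fisher.test(m)$conf.int)
  } else {
    p <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
    if (is.nan(p)) p <- 1
    ci <- NULL
  }
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)

  structure(list(
    table = c(a = a, b = b, c = cc, d = d),
    frac_charged_selected = if (a + b > 0) a / (a + b) else NA_real_,
    frac_neutral_selected = if (cc + d > 0) cc / (cc + d) else NA_real_,
    expected_random = (a + cc) / n,
    p_value = p,
    odds_ratio = or,
    conf_int = ci,
    test = test
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  tb <- x$table
  cat("<enrichment_result>  (", x$test, " test)\n", sep = "")
  cat(sprintf("  charged: %d/%d selected (%.1f%%)   neutral: %d/%d (%.1f%%)\n",
              tb["a"], tb["a"] + tb["b"], 100 * x$frac_charged_selected,
              tb["c"], tb["c"] + tb["d"], 100 * x$frac_neutral_selected))
  cat(sprintf("  expected at random: %.1f%%   odds ratio %.3g   p = %.3g\n",
              100 * x$expected_random, x$odds_ratio, x$p_value))
  invisible(x)
}
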