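# The pI engine: net charge at a given pH from the Henderson-Hasselbalch
# model, and a bisection solve for the pH of zero net charge.
#
# Each ionizable group contributes a fractional charge:
#   base:  +count / (1 + 10^(pH - pKa))
#   acid:  -count / (1 + 10^(pKa - pH))
# so the total is strictly decreasing in pH whenever any group is present.

#' Build the ionizable-group multiset for a sequence
#'
#' Scans a mature amino-acid sequence and counts the titratable groups: one
#' basic group per R/K/H, one acidic group per D/E/C/Y (pKa values from
#' `table`), plus one N-terminal base and one C-terminal acid for the free
#' termini. `X` and other non-ionizable residues contribute nothing.
#'
#' Post-translational modifications may add acidic groups. Each phospho site
#' contributes the two phosphate protons (`phospho_pkas`, default pKa 1.2 and
#' 6.5). Glyco sites contribute nothing unless `sialic_per_glyco > 0`, in
#' which case each adds that many sialic-acid carboxyl groups at
#' `sialic_pka`.
#'
#' @param sequence mature amino-acid sequence (uppercase string; the 20
#'   standard letters plus `X`).
#' @param table a [pka_table][default_pka_table].
#' @param ptms `NULL`, or a data frame with columns `position` (1-based index
#'   into `sequence`), `kind` (`"phospho"` or `"glyco"`) and `evidence`.
#' @param phospho_pkas numeric vector of acidic pKa values added per phospho
#'   site.
#' @param sialic_per_glyco number of sialic-acid groups per glyco site
#'   (default 0: glycosylation has no charge effect).
#' @param sialic_pka pKa of a sialic-acid carboxyl group.
#' @return an `ionizable_groups` data frame with columns `group`, `pka`,
#'   `polarity`, `count`.
#' @examples
#' build_groups("KDKD", default_pka_table())
#' @export
build_groups <- function(sequence, table = default_pka_table(), ptms = NULL,
                         phospho_pkas = c(1.2, 6.5),
                         sialic_per_glyco = 0, sialic_pka = 2.6) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), .PISHIFT_RESIDUES)
  if (length(bad)) {
    stop("sequence contains non-amino-acid character(s): ",
         paste(bad, collapse = ", "))
  }
  res <- table$residues
  counts <- vapply(res$residue, function(r) sum(chars == r), integer(1))
  grp <- data.frame(
    group = c(res$residue, "nterm", "cterm"),
    pka = c(res$pka, table$nterm_pka, table$cterm_pka),
    polarity = c(res$polarity, "base", "acid"),
    count = c(counts, 1L, 1L),
    stringsAsFactors = FALSE
  )
  if (!is.null(ptms) && nrow(ptms)) {
    validate_ptms(ptms)
    if (any(ptms$position > length(chars))) {
      stop("PTM position beyond sequence end (length ", length(chars), ")")
    }
    n_phos <- sum(ptms$kind == "phospho")
    n_glyc <- sum(ptms$kind == "glyco")
    if (n_phos > 0) {
      grp <- rbind(grp, data.frame(
        group = paste0("phospho_pka", phospho_pkas), pka = phospho_pkas,
        polarity = "acid", count = n_phos, stringsAsFactors = FALSE))
    }
    if (n_glyc > 0 && sialic_per_glyco > 0) {
      grp <- rbind(grp, data.frame(
        group = "sialic", pka = sialic_pka, polarity = "acid",
        count = n_glyc * sialic_per_glyco, stringsAsFactors = FALSE))
    }
  }
  grp <- grp[grp$count > 0, , drop = FALSE]
  rownames(grp) <- NULL
  class(grp) <- c("ionizable_groups", "data.frame")
  grp
}

#' Net charge of a group set at a given pH
#'
#' Henderson-Hasselbalch fractional charges summed over all groups; strictly
#' decreasing in pH.
#'
#' @param groups an `ionizable_groups` data frame from [build_groups()].
#' @param pH numeric vector of pH values.
#' @return numeric vector of net charges, in elementary-charge units.
#' @examples
#' net_charge(build_groups("GG"), 7) # about -0.091
#' @export
net_charge <- function(groups, pH) {
  stopifnot(is.numeric(pH), all(is.finite(pH)))
  base <- groups$polarity == "base"
  vapply(pH, function(p) {
    pos <- sum(groups$count[base] / (1 + 10^(p - groups$pka[base])))
    neg <- sum(groups$count[!base] / (1 + 10^(groups$pka[!base] - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which [net_charge()] is zero. The charge curve is
#' strictly decreasing, so the root is unique when it exists; a peptide
#' whose groups are all of one polarity has no root and raises an error.
#' The default bracket 0..14 is widened automatically to -2..16 when the
#' charge has not changed sign within it.
#'
#' @param groups an `ionizable_groups` data frame.
#' @param precision bisection stops when the bracket is narrower than this
#'   (pH units; default 0.01, so the returned midpoint is within 0.005 of
#'   the true root).
#' @param bracket length-2 numeric, initial (low, high) pH bracket.
#' @param max_iter iteration cap.
#' @return the pI, in pH units (unrounded; see [protein_pi()] for the
#'   2-decimal reporting convention).
#' @examples
#' isoelectric_point(build_groups("GG")) # (8.0 + 3.1) / 2 = 5.55
#' @export
isoelectric_point <- function(groups, precision = 0.01, bracket = c(0, 14),
                              max_iter = 200L) {
  stopifnot(precision > 0, length(bracket) == 2L, bracket[1] < bracket[2])
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- net_charge(groups, lo); f_hi <- net_charge(groups, hi)
  if (!(f_lo > 0 && f_hi < 0)) {
    lo <- min(lo, -2); hi <- max(hi, 16)
    f_lo <- net_charge(groups, lo); f_hi <- net_charge(groups, hi)
    if (!(f_lo > 0 && f_hi < 0)) {
      stop("no isoelectric point in bracket [", lo, ", ", hi,
           "]: charge does not change sign",
           call. = FALSE)
    }
  }
  iter <- 0L
  while (hi - lo > precision && iter < max_iter) {
    mid <- (lo + hi) / 2
    f_mid <- net_charge(groups, mid)
    if (f_mid == 0) return(mid)
    if (f_mid > 0) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  (lo + hi) / 2
}

#' Mature-protein isoelectric point
#'
#' Convenience composition of [build_groups()] and [isoelectric_point()] for
#' a [protein_record()]. The record's sequence is taken to be the mature
#' (signal-cleaved) chain, whose new N-terminus receives the N-terminal pKa.
#' The result is rounded to 2 decimals, matching the solver's 1e-2
#' precision.
#'
#' @param record a `protein_record`.
#' @param table a [pka_table][default_pka_table].
#' @param use_ptms if `TRUE`, the record's PTM annotations contribute charge
#'   groups (see [build_groups()]); default `FALSE`, the sequence-only pI.
#' @param ... passed to [build_groups()] (phospho/sialic model parameters).
#' @return the pI in pH units, rounded to 2 decimals.
#' @export
protein_pi <- function(record, table = default_pka_table(), use_ptms = FALSE,
                       ...) {
  stopifnot(inherits(record, "protein_record"))
  ptms <- if (use_ptms) record$ptms else NULL
  groups <- build_groups(record$sequence, table, ptms = ptms, ...)
  round(isoelectric_point(groups), 2)
}

# pI of a bare sequence string (no record plumbing); used by the simulators.
sequence_pi <- function(sequence, table = default_pka_table(), ...) {
  isoelectric_point(build_groups(sequence, table, ...))
}
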