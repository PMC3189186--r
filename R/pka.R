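# The ionizable-group model: which residues titrate, at what pKa, and
# whether they lose (acid) or gain (base) a proton around that pKa.

.PISHIFT_RESIDUES <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]

#' Default pKa table
#'
#' The ionizable-group model used throughout the package: side-chain pKa
#' values for the seven titratable residues plus the free termini of the
#' mature chain. Basic groups (R, K, H, N-terminus) carry positive charge
#' below their pKa; acidic groups (D, E, C, Y, C-terminus) carry negative
#' charge above theirs.
#'
#' @return an object of class `pka_table`: a list with elements `residues`
#'   (data frame with columns `residue`, `pka`, `polarity`), `nterm_pka` and
#'   `cterm_pka`.
#' @examples
#' default_pka_table()
#' @export
default_pka_table <- function() {
  residues <- data.frame(
    residue  = c("R", "K", "Y", "C", "H", "E", "D"),
    pka      = c(12.48, 10.54, 10.46, 8.18, 6.04, 4.07, 3.90),
    polarity = c("base", "base", "acid", "acid", "base", "acid", "acid"),
    stringsAsFactors = FALSE
  )
  new_pka_table(residues, nterm_pka = 8.0, cterm_pka = 3.1)
}

new_pka_table <- function(residues, nterm_pka, cterm_pka) {
  stopifnot(
    is.data.frame(residues),
    all(c("residue", "pka", "polarity") %in% names(residues)),
    all(residues$polarity %in% c("acid", "base")),
    !anyDuplicated(residues$residue)
  )
  if (any(residues$pka <= 0 | residues$pka >= 14) ||
      nterm_pka <= 0 || nterm_pka >= 14 ||
      cterm_pka <= 0 || cterm_pka >= 14) {
    stop("all pKa values must lie strictly between 0 and 14")
  }
  structure(
    list(residues = residues, nterm_pka = nterm_pka, cterm_pka = cterm_pka),
    class = "pka_table"
  )
}

#' Read an alternative pKa table from TSV
#'
#' Lets published scales (EMBOSS-style or otherwise) be swapped in. The file
#' has three tab-separated columns `group`, `pka`, `polarity`; `group` is a
#' single residue letter, or `nterm` / `cterm` for the termini (both
#' required).
#'
#' @param path path to the TSV file.
#' @return a `pka_table`.
#' @export
read_pka_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group", "pka", "polarity")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("pKa table is missing required column(s): ", paste(miss, collapse = ", "))
  }
  tab$group <- as.character(tab$group)
  term <- tab$group %in% c("nterm", "cterm")
  if (!all(c("nterm", "cterm") %in% tab$group)) {
    stop("pKa table must contain 'nterm' and 'cterm' rows")
  }
  res <- tab[!term, , drop = FALSE]
  bad <- !res$group %in% setdiff(.PISHIFT_RESIDUES, "X")
  if (any(bad)) {
    stop("pKa table has invalid residue group(s): ",
         paste(res$group[bad], collapse = ", "))
  }
  new_pka_table(
    data.frame(residue = res$group, pka = as.numeric(res$pka),
               polarity = res$polarity, stringsAsFactors = FALSE),
    nterm_pka = as.numeric(tab$pka[tab$group == "nterm"][1]),
    cterm_pka = as.numeric(tab$pka[tab$group == "cterm"][1])
  )
}

#' @export
print.pka_table <- function(x, ...) {
  cat("pKa table (", nrow(x$residues), " side-chain groups)\n", sep = "")
  print(x$residues, row.names = FALSE)
  cat(sprintf("N-terminus %.2f (base), C-terminus %.2f (acid)\n",
              x$nterm_pka, x$cterm_pka))
  invisible(x)
}
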