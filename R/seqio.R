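# Sequence and table IO: FASTA records, signal-peptide cleavage, PTM and
# cleavage-position tables, alignments (FASTA / Clustal), and SLR-style
# per-site selection tables. All residue and column coordinates are 1-based
# inclusive.

.PTM_KINDS <- c("phospho", "glyco")
.PTM_EVIDENCE <- c("experimental", "by_similarity", "potential")

#' Construct a protein record
#'
#' One mature protein sequence with its species, ortholog-family label and
#' optional PTM annotations.
#'
#' @param id sequence identifier.
#' @param species species label.
#' @param family ortholog-family label.
#' @param sequence uppercase amino-acid string (20 standard letters plus X).
#' @param ptms `NULL` or a data frame with columns `position` (1-based into
#'   the mature sequence), `kind` (`phospho`/`glyco`) and `evidence`
#'   (`experimental`/`by_similarity`/`potential`).
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(id, species, family, sequence, ptms = NULL) {
  stopifnot(is.character(id), is.character(species), is.character(family),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("record '", id, "': empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), .PISHIFT_RESIDUES)
  if (length(bad)) {
    stop("record '", id, "': non-amino-acid character(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(ptms)) {
    ptms <- data.frame(position = integer(0), kind = character(0),
                       evidence = character(0), stringsAsFactors = FALSE)
  }
  validate_ptms(ptms)
  if (any(ptms$position > nchar(sequence))) {
    stop("record '", id, "': PTM position beyond sequence end")
  }
  structure(list(id = id, species = species, family = family,
                 sequence = sequence, ptms = ptms),
            class = "protein_record")
}

validate_ptms <- function(ptms) {
  stopifnot(is.data.frame(ptms),
            all(c("position", "kind", "evidence") %in% names(ptms)))
  if (nrow(ptms) == 0) return(invisible(ptms))
  if (any(ptms$position < 1) || any(ptms$position != floor(ptms$position))) {
    stop("PTM positions must be positive integers (1-based)")
  }
  if (!all(ptms$kind %in% .PTM_KINDS)) {
    stop("PTM kind must be one of: ", paste(.PTM_KINDS, collapse = ", "))
  }
  if (!all(ptms$evidence %in% .PTM_EVIDENCE)) {
    stop("PTM evidence must be one of: ", paste(.PTM_EVIDENCE, collapse = ", "))
  }
  invisible(ptms)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s [%s / %s], %d aa, %d PTM(s)\n",
              x$id, x$family, x$species, nchar(x$sequence), nrow(x$ptms)))
  invisible(x)
}

parse_fasta_header <- function(header, delim) {
  token <- strsplit(trimws(header), "[[:space:]]+")[[1]][1]
  fields <- strsplit(token, delim, fixed = TRUE)[[1]]
  if (length(fields) < 3L) {
    stop("FASTA header '", token, "' does not follow the ",
         "'family", delim, "species", delim, "id' convention")
  }
  list(family = fields[1], species = fields[2],
       id = paste(fields[-(1:2)], collapse = delim))
}

#' Read protein records from FASTA
#'
#' Headers follow the `family|species|id` convention (delimiter
#' configurable). Sequences are uppercased; trailing/internal `*` stop
#' symbols are stripped with a warning; any character outside the 20
#' standard residues plus `X` is an error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @param delim field delimiter inside headers (default `"|"`).
#' @return a list of [protein_record()] objects.
#' @export
read_fasta <- function(path, delim = "|") {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    h <- parse_fasta_header(headers[i], delim)
    s <- seqs[[i]]
    if (grepl("*", s, fixed = TRUE)) {
      warning("record '", h$id, "': stripping '*' stop symbol(s)",
              call. = FALSE)
      s <- gsub("*", "", s, fixed = TRUE)
    }
    out[[i]] <- protein_record(h$id, h$species, h$family, s)
  }
  out
}

#' Write protein records to FASTA
#'
#' Inverse of [read_fasta()]; headers are re-assembled as
#' `family<delim>species<delim>id`.
#'
#' @param records list of `protein_record`s.
#' @param path output path.
#' @param delim header field delimiter.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, delim = "|") {
  lines <- unlist(lapply(records, function(r) {
    c(paste0(">", r$family, delim, r$species, delim, r$id), r$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Remove a signal peptide from a record
#'
#' Drops residues `1..cleavage_pos` (the signal peptide; `cleavage_pos` is
#' the 1-based last residue of the signal) and renumbers PTM positions into
#' the mature chain. PTMs inside the removed prefix are dropped with a
#' warning. `cleavage_pos = 0` returns the record unchanged.
#'
#' @param record a `protein_record`.
#' @param cleavage_pos last residue of the signal peptide; `0 <=
#'   cleavage_pos < nchar(sequence)`.
#' @return the mature `protein_record`.
#' @export
apply_signal_cleavage <- function(record, cleavage_pos) {
  stopifnot(inherits(record, "protein_record"),
            is.numeric(cleavage_pos), length(cleavage_pos) == 1L,
            cleavage_pos == floor(cleavage_pos), cleavage_pos >= 0)
  n <- nchar(record$sequence)
  if (cleavage_pos >= n) {
    stop("record '", record$id, "': cleavage position ", cleavage_pos,
         " leaves no mature sequence (length ", n, ")")
  }
  if (cleavage_pos == 0) return(record)
  ptms <- record$ptms
  inside <- ptms$position <= cleavage_pos
  if (any(inside)) {
    warning("record '", record$id, "': dropping ", sum(inside),
            " PTM(s) inside the signal peptide", call. = FALSE)
    ptms <- ptms[!inside, , drop = FALSE]
  }
  ptms$position <- ptms$position - cleavage_pos
  protein_record(record$id, record$species, record$family,
                 substring(record$sequence, cleavage_pos + 1, n), ptms)
}

#' Read a signal-cleavage table
#'
#' Two tab-separated columns `id`, `cleavage_pos` (1-based last residue of
#' the signal peptide; 0 for none). Signal-peptide prediction itself is not
#' performed here — positions come from an external predictor.
#'
#' @param path TSV path.
#' @return data frame with columns `id`, `cleavage_pos`.
#' @export
read_cleavage_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "cleavage_pos"), names(tab))
  if (length(miss)) {
    stop("cleavage table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) stop("cleavage table has duplicate ids")
  tab$cleavage_pos <- as.integer(tab$cleavage_pos)
  if (any(is.na(tab$cleavage_pos)) || any(tab$cleavage_pos < 0)) {
    stop("cleavage_pos must be a nonnegative integer")
  }
  tab[, c("id", "cleavage_pos")]
}

#' Apply a cleavage table to a set of records
#'
#' Records whose id is absent from the table default to cleavage position 0
#' (no signal peptide) with a warning.
#'
#' @param records list of `protein_record`s.
#' @param cleavage data frame from [read_cleavage_table()].
#' @return list of mature `protein_record`s.
#' @export
apply_cleavage_table <- function(records, cleavage) {
  pos <- stats::setNames(cleavage$cleavage_pos, cleavage$id)
  lapply(records, function(r) {
    if (!r$id %in% names(pos)) {
      warning("record '", r$id, "' not in cleavage table; assuming no ",
              "signal peptide", call. = FALSE)
      return(r)
    }
    apply_signal_cleavage(r, pos[[r$id]])
  })
}

#' Read a PTM annotation table
#'
#' Tab-separated columns `id`, `position` (1-based, mature coordinates),
#' `kind` (`phospho`/`glyco`), `evidence`
#' (`experimental`/`by_similarity`/`potential`).
#'
#' @param path TSV path.
#' @return data frame with those four columns.
#' @export
read_ptm_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "position", "kind", "evidence"), names(tab))
  if (length(miss)) {
    stop("PTM table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  tab$position <- as.integer(tab$position)
  validate_ptms(tab)
  tab[, c("id", "position", "kind", "evidence")]
}

#' Attach PTM annotations to records
#'
#' @param records list of `protein_record`s.
#' @param ptm_table data frame from [read_ptm_table()].
#' @param evidence PTM evidence classes to keep (default: all three).
#' @return list of `protein_record`s with `ptms` filled in.
#' @export
attach_ptms <- function(records, ptm_table,
                        evidence = .PTM_EVIDENCE) {
  ptm_table <- ptm_table[ptm_table$evidence %in% evidence, , drop = FALSE]
  lapply(records, function(r) {
    mine <- ptm_table[ptm_table$id == r$id,
                      c("position", "kind", "evidence"), drop = FALSE]
    rownames(mine) <- NULL
    protein_record(r$id, r$species, r$family, r$sequence, mine)
  })
}

# ---- alignments -----------------------------------------------------------

species_from_header <- function(header, delim = "|") {
  token <- strsplit(trimws(header), "[[:space:]]+")[[1]][1]
  fields <- strsplit(token, delim, fixed = TRUE)[[1]]
  if (length(fields) >= 3L) fields[2] else token
}

new_alignment <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(sprintf("%s=%d", names(rows), widths), collapse = ", "))
  }
  if (anyDuplicated(names(rows))) stop("duplicate species in alignment")
  structure(list(rows = toupper(rows), width = widths[[1]]),
            class = "pi_alignment")
}

#' Read a protein multiple alignment
#'
#' Reads aligned FASTA or Clustal format into a species-keyed alignment.
#' Species keys are taken from the second `family|species|id` header field
#' when present, otherwise from the whole header token.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param delim FASTA header field delimiter.
#' @return an object of class `pi_alignment` with elements `rows` (named
#'   character vector of gapped sequences, gap `-`) and `width`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"), delim = "|") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("empty alignment file: ", path)
    rows <- as.character(set)
    names(rows) <- vapply(names(set), species_from_header, character(1),
                          delim = delim)
  } else {
    maln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    rows <- as.character(maln)
    names(rows) <- vapply(names(rows), species_from_header, character(1),
                          delim = delim)
  }
  new_alignment(rows)
}

#' @export
print.pi_alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d species x %d columns: %s\n",
              length(x$rows), x$width,
              paste(names(x$rows), collapse = ", ")))
  invisible(x)
}

#' Extract the region of one species alignable with another
#'
#' Concatenates the `ref_species` residues at alignment columns where BOTH
#' species are ungapped, preserving order. This is the operation behind
#' comparing the pI of the mutually alignable cores of two orthologs whose
#' lengths differ by indels.
#'
#' @param aln a `pi_alignment`.
#' @param ref_species species whose residues are returned.
#' @param other_species species whose gaps mask the reference.
#' @return an amino-acid string (possibly empty).
#' @export
extract_alignable_region <- function(aln, ref_species, other_species) {
  stopifnot(inherits(aln, "pi_alignment"))
  for (sp in c(ref_species, other_species)) {
    if (!sp %in% names(aln$rows)) stop("species '", sp, "' not in alignment")
  }
  a <- strsplit(aln$rows[[ref_species]], "")[[1]]
  b <- strsplit(aln$rows[[other_species]], "")[[1]]
  keep <- a != "-" & b != "-"
  paste(a[keep], collapse = "")
}

# ---- selection tables -----------------------------------------------------

#' Read an SLR-style per-site selection table
#'
#' Tab-separated with a header; required columns `site` (1-based alignment
#' column), `omega` (site-wise dN/dS-like statistic, nonnegative) and
#' `pvalue` (in [0, 1]); extra columns are kept. Rows are returned sorted by
#' site; duplicate sites are an error.
#'
#' @param path TSV path.
#' @return data frame sorted by `site`.
#' @export
read_selection_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("site", "omega", "pvalue"), names(tab))
  if (length(miss)) {
    stop("selection table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  tab$site <- as.integer(tab$site)
  tab$omega <- as.numeric(tab$omega)
  tab$pvalue <- as.numeric(tab$pvalue)
  if (any(is.na(tab$site)) || any(tab$site < 1)) {
    stop("site must be a positive integer alignment column")
  }
  if (anyDuplicated(tab$site)) {
    stop("duplicate site number(s): ",
         paste(unique(tab$site[duplicated(tab$site)]), collapse = ", "))
  }
  if (any(is.na(tab$omega)) || any(tab$omega < 0)) {
    stop("omega must be nonnegative")
  }
  if (any(is.na(tab$pvalue)) || any(tab$pvalue < 0 | tab$pvalue > 1)) {
    stop("pvalue must lie in [0, 1]")
  }
  tab[order(tab$site), , drop = FALSE]
}
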