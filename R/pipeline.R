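# End-to-end orchestration: pI table -> shift analysis -> enrichment ->
# parsimony, driven by a flat key=value config and an inputs manifest, with
# one reproducibility seed.

#' Default pipeline configuration
#'
#' Every tunable of the analysis in one flat list. Fields: `pka_table`
#' (`"builtin"` or a TSV path), `quantile_convention` (fixed tag
#' `"linear_order_statistics"`, R type 7), `bounds_low`/`bounds_high`
#' (pI discretization), `alpha` (selected-site calling), `n_perm`,
#' `perm_mode` (`"protein"`/`"threshold"`), `seed`, `phospho_pkas`,
#' `sialic_per_glyco`, `sialic_pka`, `use_ptms`.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    pka_table = "builtin",
    quantile_convention = "linear_order_statistics",
    bounds_low = 6.8,
    bounds_high = 7.2,
    alpha = 0.05,
    n_perm = 1000L,
    perm_mode = "protein",
    seed = 42L,
    phospho_pkas = c(1.2, 6.5),
    sialic_per_glyco = 0,
    sialic_pka = 2.6,
    use_ptms = FALSE
  )
}

#' Read a flat key=value config file
#'
#' Lines `key = value`; `#` starts a comment; numeric vectors are
#' comma-separated. Unknown keys are an error; unspecified keys keep their
#' [default_config()] values.
#'
#' @param path config file path.
#' @return config list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: '", key, "'")
    cfg[[key]] <- if (key %in% c("pka_table", "quantile_convention",
                                 "perm_mode")) {
      val
    } else if (key == "use_ptms") {
      as.logical(val)
    } else if (key %in% c("n_perm", "seed")) {
      as.integer(val)
    } else {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    }
  }
  cfg
}

#' Read an inputs manifest
#'
#' Flat `key = value` lines naming the inputs of [run_pipeline()]. Required:
#' `fasta`, `species_a`, `species_b`. Optional: `cleavage`, `ptm`,
#' `alignment`, `alignment_format` (default `fasta`), `slr`, `ref_species`,
#' `tree`, `family` (family of interest for parsimony/permutation focus).
#'
#' @param path manifest file path.
#' @return named list.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed manifest line: '", ln, "'")
    out[[trimws(kv[1])]] <- trimws(kv[2])
  }
  out
}

run_stage <- function(stage, expr) {
  pishift_log("INFO", "stage '", stage, "' ...")
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pI-shift analysis pipeline
#'
#' Stages, each optional after the first: (1) read sequences, cleave signal
#' peptides, attach PTMs, compute per-protein pI; (2) build the ortholog pI
#' set and run the shift analysis for the manifest's species pair,
#' including permutation p-values for flagged families; (3) selection
#' enrichment, when `alignment` + `slr` + `ref_species` are given; (4)
#' parsimony counts of discretized pI changes, when `tree` is given. A
#' run-metadata JSON echoing config and manifest makes reruns reproducible;
#' outputs are byte-identical for a fixed seed and config.
#'
#' @param manifest named list or path to a manifest file (see
#'   [read_manifest()]).
#' @param config config list or path (see [read_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`pi_table`,
#'   `shift`, `enrichment`, `parsimony`, `paths`).
#' @export
run_pipeline <- function(manifest, config = default_config(), out_dir) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(config)) config <- read_config(config)
  need <- setdiff(c("fasta", "species_a", "species_b"), names(manifest))
  if (length(need)) {
    stop("manifest is missing required key(s): ", paste(need, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- if (identical(config$pka_table, "builtin")) default_pka_table()
           else read_pka_table(config$pka_table)
  paths <- list()

  # -- stage 1: per-protein pI ---------------------------------------------
  pi_table <- run_stage("pi", {
    records <- read_fasta(manifest$fasta)
    if (!is.null(manifest$cleavage)) {
      records <- apply_cleavage_table(records,
                                      read_cleavage_table(manifest$cleavage))
    }
    if (!is.null(manifest$ptm)) {
      records <- attach_ptms(records, read_ptm_table(manifest$ptm))
    }
    do.call(rbind, lapply(records, function(r) {
      groups <- build_groups(
        r$sequence, table, ptms = if (isTRUE(config$use_ptms)) r$ptms,
        phospho_pkas = config$phospho_pkas,
        sialic_per_glyco = config$sialic_per_glyco,
        sialic_pka = config$sialic_pka)
      data.frame(id = r$id, species = r$species, family = r$family,
                 length = nchar(r$sequence),
                 pI = round(isoelectric_point(groups), 2),
                 net_charge_at_pH7 = round(net_charge(groups, 7), 3),
                 stringsAsFactors = FALSE)
    }))
  })
  paths$pi <- file.path(out_dir, "pi.tsv")
  utils::write.table(pi_table, paths$pi, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- stage 2: shift analysis ---------------------------------------------
  shift <- run_stage("shift", {
    piset <- ortholog_pi_set(data.frame(
      family = pi_table$family, species = pi_table$species,
      pi = pi_table$pI, stringsAsFactors = FALSE))
    diffs <- pairwise_diffs(piset, manifest$species_a, manifest$species_b)
    if (length(diffs) >= 4L) {
      res <- flag_shifters(diffs,
                           species_pair = c(manifest$species_a,
                                            manifest$species_b))
      pvals <- stats::setNames(rep(NA_real_, length(diffs)), names(diffs))
      for (f in res$flagged) {
        pvals[f] <- permutation_pvalue(
          piset, manifest$species_a, manifest$species_b, f,
          n_perm = config$n_perm, seed = config$seed,
          mode = config$perm_mode)
      }
      res$perm_pvalue <- pvals
      res
    } else {
      pishift_log("WARN", "fewer than 4 shared families; ",
                  "shift stage not run")
      NULL
    }
  })
  if (!is.null(shift)) {
    paths$shift <- file.path(out_dir, "shifts.tsv")
    utils::write.table(
      data.frame(family = names(shift$diffs),
                 abs_diff = round(unname(shift$diffs), 4),
                 flagged = names(shift$diffs) %in% shift$flagged,
                 perm_pvalue = unname(shift$perm_pvalue)),
      paths$shift, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # -- stage 3: selection enrichment ---------------------------------------
  enrichment <- NULL
  if (!is.null(manifest$alignment) && !is.null(manifest$slr) &&
      !is.null(manifest$ref_species)) {
    enrichment <- run_stage("enrichment", {
      aln <- read_alignment(manifest$alignment,
                            format = manifest$alignment_format %||% "fasta")
      slr <- read_selection_table(manifest$slr)
      selected <- call_selected_sites(slr, alpha = config$alpha)
      classes <- classify_site_charge(aln, manifest$ref_species,
                                      sites = slr$site)
      enrichment_test(selected, classes)
    })
    paths$enrichment <- file.path(out_dir, "enrichment.json")
    jsonlite::write_json(
      list(table = as.list(enrichment$table),
           frac_charged_selected = enrichment$frac_charged_selected,
           frac_neutral_selected = enrichment$frac_neutral_selected,
           expected_random = enrichment$expected_random,
           p_value = enrichment$p_value,
           odds_ratio = enrichment$odds_ratio,
           test = enrichment$test,
           alpha = config$alpha,
           ref_species = manifest$ref_species),
      paths$enrichment, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # -- stage 4: parsimony ---------------------------------------------------
  parsimony <- NULL
  if (!is.null(manifest$tree)) {
    parsimony <- run_stage("parsimony", {
      tree <- ape::read.tree(manifest$tree)
      piset <- ortholog_pi_set(data.frame(
        family = pi_table$family, species = pi_table$species,
        pi = pi_table$pI, stringsAsFactors = FALSE))
      mat <- piset$pi
      rows <- lapply(rownames(mat), function(f) {
        have <- colnames(mat)[!is.na(mat[f, ])]
        have <- intersect(have, tree$tip.label)
        if (length(have) < 2L) return(NULL)
        sub <- if (length(have) < length(tree$tip.label)) {
          ape::keep.tip(tree, have)
        } else tree
        states <- stats::setNames(
          discretize_pi(mat[f, have],
                        c(config$bounds_low, config$bounds_high)), have)
        data.frame(family = f, n_species = length(have),
                   n_changes = fitch_shift_count(sub, states),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    if (!is.null(parsimony)) {
      paths$parsimony <- file.path(out_dir, "parsimony.tsv")
      utils::write.table(parsimony, paths$parsimony, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  # -- run metadata ---------------------------------------------------------
  paths$metadata <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(
    list(package = "pishift",
         version = as.character(utils::packageVersion("pishift")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         config = config, manifest = manifest,
         stages_run = names(paths)[names(paths) != "metadata"]),
    paths$metadata, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(pi_table = pi_table, shift = shift,
                 enrichment = enrichment, parsimony = parsimony,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
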