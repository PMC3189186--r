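# Synthetic inputs with known ground truth: random proteins, targeted-pI
# mutagenesis, proteome-scale ortholog pI tables with planted outliers, and
# per-site selection tables with a planted charged/selected odds ratio.

.NEUTRAL_RESIDUES <- c("G", "A", "S", "T", "L", "V", "P", "N", "Q")
.BASIC_RESIDUES <- c("R", "K", "H")
.ACIDIC_RESIDUES <- c("D", "E", "C", "Y")

#' Random protein sequence
#'
#' Positions are drawn iid: with probability `charged_fraction` an ionizable
#' residue (basic from R/K/H with probability `basic_bias`, else acidic from
#' D/E/C/Y), otherwise a non-ionizable residue. About a quarter of residues
#' in real globular proteins are ionizable, hence the default.
#'
#' @param length number of residues (>= 2).
#' @param charged_fraction probability a position is ionizable.
#' @param basic_bias probability an ionizable position is basic.
#' @param seed RNG seed (`NULL`: use the current stream).
#' @return an amino-acid string.
#' @export
random_protein <- function(length, charged_fraction = 0.25, basic_bias = 0.5,
                           seed = NULL) {
  stopifnot(length >= 2, charged_fraction >= 0, charged_fraction <= 1,
            basic_bias >= 0, basic_bias <= 1)
  with_seed(seed, {
    charged <- stats::runif(length) < charged_fraction
    basic <- stats::runif(length) < basic_bias
    chars <- character(length)
    chars[!charged] <- sample(.NEUTRAL_RESIDUES, sum(!charged), replace = TRUE)
    chars[charged & basic] <- sample(.BASIC_RESIDUES, sum(charged & basic),
                                     replace = TRUE)
    chars[charged & !basic] <- sample(.ACIDIC_RESIDUES, sum(charged & !basic),
                                      replace = TRUE)
    paste(chars, collapse = "")
  })
}

#' Mutate a sequence toward a target pI
#'
#' Single-residue substitutions between the charged and neutral residue
#' classes only (length is preserved; no indels). The pI depends only on
#' the counts of the seven ionizable residue types, and it equals the
#' target exactly when the composition's net charge at the target pH is
#' zero (the charge curve is strictly decreasing). The climb therefore
#' greedily adds or removes one ionizable residue at a time, each move
#' shifting that charge by a known amount, until the zero-charge pH lies
#' within `tolerance` of the target; weak groups far from their pKa (Y, C,
#' H) supply arbitrarily fine steps. The winning composition is written
#' back onto the sequence by converting randomly chosen positions between
#' the neutral and charged classes.
#'
#' @param sequence starting amino-acid string.
#' @param target_pi target isoelectric point (pH units).
#' @param tolerance acceptable `|pI - target|`; must be at least 0.02
#'   (twice the solver precision).
#' @param max_steps maximum compositions examined by the search.
#' @param seed RNG seed.
#' @return the mutated sequence, whose pI is within `tolerance` of the
#'   target. If the target is unreachable a condition of class
#'   `pishift_target_unreachable` is signalled carrying the best pI reached
#'   (field `best_pi`).
#' @export
mutate_to_target_pi <- function(sequence, target_pi, tolerance = 0.05,
                                max_steps = 500L, seed = NULL) {
  stopifnot(tolerance >= 0.02, max_steps >= 1L)
  chars <- strsplit(toupper(sequence), "")[[1]]
  len <- length(chars)
  tab <- default_pka_table()
  types <- c(.BASIC_RESIDUES, .ACIDIC_RESIDUES)
  res <- tab$residues[match(types, tab$residues$residue), ]
  is_base <- res$polarity == "base"
  counts0 <- vapply(types, function(r) sum(chars == r), integer(1))

  # fractional charge of one group of each type at a pH; termini likewise
  unit_charge <- function(pH) {
    ifelse(is_base, 1 / (1 + 10^(pH - res$pka)),
           -1 / (1 + 10^(res$pka - pH)))
  }
  termini_charge <- function(pH) {
    1 / (1 + 10^(pH - tab$nterm_pka)) - 1 / (1 + 10^(tab$cterm_pka - pH))
  }
  pi_of_counts <- function(ct) {
    grp <- data.frame(
      group = c(types, "nterm", "cterm"),
      pka = c(res$pka, tab$nterm_pka, tab$cterm_pka),
      polarity = c(res$polarity, "base", "acid"),
      count = c(ct, 1L, 1L))
    isoelectric_point(grp[grp$count > 0, ])
  }
  # pI within [target - tol, target + tol] iff the (strictly decreasing)
  # charge curve is still >= 0 at target - tol and <= 0 at target + tol
  on_target <- function(ct) {
    sum(ct * unit_charge(target_pi - tolerance)) +
      termini_charge(target_pi - tolerance) >= 0 &&
    sum(ct * unit_charge(target_pi + tolerance)) +
      termini_charge(target_pi + tolerance) <= 0
  }

  if (on_target(counts0)) return(paste(chars, collapse = ""))

  # The residual is linear in the counts: q(ct) = q0 + sum(ct * u). A
  # two-type composition (one basic, one acidic) over a bounded count grid
  # already cancels q0 to within a fine step, so enumerate all such pairs,
  # rank by |q|, and polish the leaders with single-residue adjustments
  # until the sign-change window closes.
  u <- unit_charge(target_pi)
  q0 <- termini_charge(target_pi)
  cap <- min(len, 60L)
  grid_a <- rep(0:cap, each = cap + 1L)   # basic-residue count
  grid_b <- rep(0:cap, times = cap + 1L)  # acidic-residue count
  keep <- grid_a + grid_b <= len
  grid_a <- grid_a[keep]; grid_b <- grid_b[keep]
  combos <- do.call(rbind, lapply(which(is_base), function(bi) {
    do.call(rbind, lapply(which(!is_base), function(ai) {
      data.frame(bi = bi, ai = ai, a = grid_a, b = grid_b,
                 q = abs(q0 + grid_a * u[bi] + grid_b * u[ai]))
    }))
  }))
  combos <- combos[order(combos$q, combos$a + combos$b), ]
  combos <- combos[seq_len(min(200L, nrow(combos))), ]

  goal <- NULL
  best <- counts0; best_q <- abs(q0 + sum(counts0 * u))
  steps <- 0L
  for (r in seq_len(nrow(combos))) {
    if (steps >= max_steps || !is.null(goal)) break
    steps <- steps + 1L
    ct <- integer(length(types))
    ct[combos$bi[r]] <- combos$a[r]
    ct[combos$ai[r]] <- combos$b[r]
    # polish: single +/-1 moves that strictly shrink the residual |q|
    for (iter in 1:200) {
      if (on_target(ct)) { goal <- ct; break }
      q <- q0 + sum(ct * u)
      step_q <- c(if (sum(ct) < len) u else rep(NA_real_, length(u)),
                  ifelse(ct > 0L, -u, NA_real_))
      after <- abs(q + step_q)
      j <- which.min(after)
      if (!length(j) || is.na(after[j]) || after[j] >= abs(q) - 1e-12) break
      ct[(j - 1L) %% length(types) + 1L] <-
        ct[(j - 1L) %% length(types) + 1L] +
        (if (j <= length(types)) 1L else -1L)
    }
    if (is.null(goal) && abs(q0 + sum(ct * u)) < best_q) {
      best_q <- abs(q0 + sum(ct * u)); best <- ct
    }
  }
  if (is.null(goal)) {
    best_pi <- pi_of_counts(best)
    cond <- structure(
      class = c("pishift_target_unreachable", "error", "condition"),
      list(message = sprintf(
        "target pI %.2f unreachable within %d step(s); best achieved %.2f",
        target_pi, steps, best_pi),
        call = sys.call(-1), best_pi = best_pi))
    stop(cond)
  }
  best <- list(ct = goal)

  # materialize the winning composition: remove surplus ionizable residues
  # (-> random neutral), then add deficits at random neutral positions
  with_seed(seed, {
    delta <- best$ct - counts0
    for (t in seq_along(types)) {
      if (delta[t] < 0L) {
        pos <- which(chars == types[t])
        pos <- if (length(pos) > 1L) sample(pos, -delta[t]) else pos
        chars[pos] <- sample(.NEUTRAL_RESIDUES, -delta[t], replace = TRUE)
      }
    }
    for (t in seq_along(types)) {
      if (delta[t] > 0L) {
        pos <- which(chars %in% .NEUTRAL_RESIDUES)
        pos <- if (length(pos) > 1L) sample(pos, delta[t]) else pos
        chars[pos] <- types[t]
      }
    }
    paste(chars, collapse = "")
  })
}

#' Specification for a synthetic ortholog proteome
#'
#' The generated world emulates a proteome-scale background of ortholog pI
#' differences plus a handful of strongly shifted families. Family base pI
#' values follow the familiar bimodal proteome distribution (an acidic and a
#' basic mode). Between the first species (the reference) and each other
#' species a family drifts by a half-normal amount `|N(0, background_sigma)|`
#' with random sign; planted outlier families instead shift the second
#' species by exactly their target amount.
#'
#' @param n_families number of ortholog families (>= 4); default 1000.
#' @param species species labels; the first is the reference of every pair.
#' @param background_sigma half-normal drift scale, pH units.
#' @param outliers data frame with columns `family`, `shift` (target
#'   absolute pI shifts, > 0); families must exist and be unique.
#' @param length_range residue-length range for generated sequences (used by
#'   [simulate_family()]).
#' @param seed RNG seed.
#' @return a `synthetic_proteome_spec` list.
#' @export
synthetic_proteome_spec <- function(n_families = 1000L,
                                    species = c("human", "mouse"),
                                    background_sigma = 0.2,
                                    outliers = data.frame(
                                      family = sprintf("fam%04d", 1:3),
                                      shift = 2.0),
                                    length_range = c(80L, 400L),
                                    seed = 42L) {
  stopifnot(n_families >= 4L, length(species) >= 2L,
            background_sigma >= 0)
  if (nrow(outliers)) {
    stopifnot(all(c("family", "shift") %in% names(outliers)),
              all(outliers$shift > 0))
    if (anyDuplicated(outliers$family)) {
      stop("duplicate outlier family")
    }
  }
  structure(list(n_families = as.integer(n_families), species = species,
                 background_sigma = background_sigma, outliers = outliers,
                 length_range = length_range, seed = as.integer(seed)),
            class = "synthetic_proteome_spec")
}

#' Simulate a proteome-scale ortholog pI table with planted outliers
#'
#' See [synthetic_proteome_spec()] for the generative model. Outlier shifts
#' are applied to the second species, with the sign chosen to keep the
#' shifted value inside pH 3--12.
#'
#' @param spec a [synthetic_proteome_spec()].
#' @return list with `pi_set` (an [ortholog_pi_set()]), `outlier_families`
#'   (ground truth) and `spec`.
#' @export
simulate_proteome <- function(spec = synthetic_proteome_spec()) {
  stopifnot(inherits(spec, "synthetic_proteome_spec"))
  fams <- sprintf("fam%04d", seq_len(spec$n_families))
  if (nrow(spec$outliers) && !all(spec$outliers$family %in% fams)) {
    stop("outlier family not among the generated families")
  }
  with_seed(spec$seed, {
    # bimodal proteome pI background: acidic and basic modes
    acidic_mode <- stats::runif(spec$n_families) < 0.55
    base <- ifelse(acidic_mode,
                   stats::rnorm(spec$n_families, 5.5, 0.8),
                   stats::rnorm(spec$n_families, 8.6, 0.9))
    base <- pmin(pmax(base, 3.2), 12.3)
    mat <- matrix(NA_real_, spec$n_families, length(spec$species),
                  dimnames = list(fams, spec$species))
    mat[, 1] <- base
    for (j in seq_along(spec$species)[-1]) {
      drift <- abs(stats::rnorm(spec$n_families, 0, spec$background_sigma))
      sign <- sample(c(-1, 1), spec$n_families, replace = TRUE)
      mat[, j] <- base + sign * drift
    }
    if (nrow(spec$outliers)) {
      i <- match(spec$outliers$family, fams)
      up <- base[i] + spec$outliers$shift <= 12
      mat[i, 2] <- base[i] + ifelse(up, 1, -1) * spec$outliers$shift
    }
    list(pi_set = ortholog_pi_set(round(mat, 2)),
         outlier_families = as.character(spec$outliers$family),
         spec = spec)
  })
}

#' Specification for a synthetic selection-site table
#'
#' @param n_sites number of alignment sites.
#' @param charged_fraction probability a site is charged.
#' @param base_selected_rate P(selected | neutral site).
#' @param odds_ratio multiplicative odds of selection at charged sites
#'   relative to neutral sites (>= 0; 1 = no enrichment).
#' @param alpha significance level the generated p-values respect: selected
#'   sites get `p ~ U(0, alpha)`, others `p ~ U(alpha, 1)`.
#' @param seed RNG seed.
#' @return a `synthetic_selection_spec` list.
#' @export
synthetic_selection_spec <- function(n_sites = 500L, charged_fraction = 0.3,
                                     base_selected_rate = 0.05,
                                     odds_ratio = 1, alpha = 0.05,
                                     seed = 42L) {
  stopifnot(n_sites >= 1L, charged_fraction >= 0, charged_fraction <= 1,
            base_selected_rate >= 0, base_selected_rate <= 1,
            odds_ratio >= 0, alpha > 0, alpha < 1)
  structure(list(n_sites = as.integer(n_sites),
                 charged_fraction = charged_fraction,
                 base_selected_rate = base_selected_rate,
                 odds_ratio = odds_ratio, alpha = alpha,
                 seed = as.integer(seed)),
            class = "synthetic_selection_spec")
}

#' Plant selection sites with a controlled charged/selected odds ratio
#'
#' Site charge classes are Bernoulli(`charged_fraction`); selection flags
#' are Bernoulli with `P(selected | neutral) = base_selected_rate` and the
#' odds multiplied by `odds_ratio` at charged sites. The emitted p-values
#' and omegas are consistent with the binary call (p <= alpha and omega > 1
#' iff selected) — downstream only consumes the call, so no likelihood model
#' is simulated.
#'
#' @param spec a [synthetic_selection_spec()].
#' @return list with `charge_classes` (named vector site -> class), `sites`
#'   (a selection table data frame), `selected_sites` (ground truth) and
#'   `true_odds_ratio`.
#' @export
plant_selection_sites <- function(spec = synthetic_selection_spec()) {
  stopifnot(inherits(spec, "synthetic_selection_spec"))
  r <- spec$base_selected_rate
  p_charged <- if (r %in% c(0, 1)) r else {
    odds <- spec$odds_ratio * r / (1 - r)
    odds / (1 + odds)
  }
  if (p_charged < 0 || p_charged > 1) {
    stop("P(selected | charged) outside [0, 1] after odds adjustment")
  }
  with_seed(spec$seed, {
    n <- spec$n_sites
    charged <- stats::runif(n) < spec$charged_fraction
    sel <- stats::runif(n) < ifelse(charged, p_charged, r)
    pvals <- ifelse(sel, stats::runif(n) * spec$alpha,
                    spec$alpha + stats::runif(n) * (1 - spec$alpha))
    omega <- ifelse(sel, 1 + stats::rexp(n, 0.5), stats::runif(n))
    list(
      charge_classes = stats::setNames(
        ifelse(charged, "charged", "neutral"), seq_len(n)),
      sites = data.frame(site = seq_len(n), omega = omega, pvalue = pvals),
      selected_sites = which(sel),
      true_odds_ratio = spec$odds_ratio
    )
  })
}

#' Simulate one ortholog family as real sequences
#'
#' Builds an ancestral random protein and derives one ortholog per species;
#' species listed in `target_pi` are mutated ([mutate_to_target_pi()]) to
#' carry a prescribed isoelectric point, which is how planted pI shifts are
#' realised at the sequence level. Other species receive a few neutral
#' substitutions only.
#'
#' @param species species labels.
#' @param family family label.
#' @param length sequence length.
#' @param target_pi named numeric vector species -> target pI (optional).
#' @param seed RNG seed.
#' @return list of [protein_record()]s, one per species.
#' @export
simulate_family <- function(species, family = "fam0001", length = 180L,
                            target_pi = NULL, seed = 42L) {
  with_seed(seed, {
    anc <- random_protein(length)
    lapply(species, function(sp) {
      s <- anc
      if (!is.null(target_pi) && sp %in% names(target_pi)) {
        s <- mutate_to_target_pi(s, target_pi[[sp]], tolerance = 0.05,
                                 max_steps = 4L * length)
      } else {
        # sprinkle neutral-to-neutral substitutions: divergence w/o pI change
        chars <- strsplit(s, "")[[1]]
        idx <- which(chars %in% .NEUTRAL_RESIDUES)
        idx <- sample(idx, min(length(idx), max(3L, length %/% 20L)))
        chars[idx] <- sample(.NEUTRAL_RESIDUES, length(idx), replace = TRUE)
        s <- paste(chars, collapse = "")
      }
      protein_record(paste0(sp, "_", family), sp, family, s)
    })
  })
}
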