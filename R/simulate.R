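# Synthetic-data generator. Emulates the statistical structure the
# analyses assume: per-male courtship propensities on [0, 1] drawn from a
# Beta distribution whose mean is scaled down in trained males by a
# per-time-point suppression multiplier (multiplier m gives expected
# LI = 100 * (1 - m)); bouts laid down as an alternating on/off renewal
# process rescaled to hit the drawn fraction exactly; binomial T-maze
# choice counts; and DE tables with Wald-style p-values in which planted
# genes carry a concordant shifted logFC across designated replicate
# contrasts.

#' Construct a strain phenotype profile
#'
#' @param name Strain label.
#' @param naive_ci_mean Expected naive courtship index in percent.
#' @param naive_ci_concentration Beta concentration (precision) of the
#'   per-male courtship fraction; larger = less between-male variation.
#' @param suppression Named numeric vector mapping time-point labels to
#'   multipliers in `[0, 1]` applied to trained-male courtship propensity;
#'   multiplier 1 means no learning (expected LI 0), multiplier m gives
#'   expected LI `100 * (1 - m)`.
#' @return A list of class `strain_profile`.
#' @export
strain_profile <- function(name, naive_ci_mean = 50,
                           naive_ci_concentration = 10,
                           suppression = c("0" = 0.33, "2" = 0.33,
                                           "8" = 0.33)) {
  stopifnot(is.character(name), length(name) == 1L,
            naive_ci_mean > 0, naive_ci_mean < 100,
            naive_ci_concentration > 0)
  if (is.null(names(suppression)) || any(names(suppression) == "")) {
    stop("'suppression' must be named by time point", call. = FALSE)
  }
  if (any(suppression < 0 | suppression > 1)) {
    stop("suppression multipliers must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, naive_ci_mean = naive_ci_mean,
                 naive_ci_concentration = naive_ci_concentration,
                 suppression = suppression),
            class = "strain_profile")
}

#' Built-in strain phenotype profiles
#'
#' Three qualitative learning/memory phenotypes over a day 0 / day 2 /
#' day 8 retention design:
#' * `control`: learns and retains long-term memory (multiplier 0.33 at
#'   every time point, expected LI about 67);
#' * `cbs_like`: no learning at any time point (multiplier 1, expected LI
#'   about 0), the phenotype of CBS and double-deletion strains;
#' * `cse_like`: learns and retains at day 2 but loses retention by day 8
#'   (multiplier 0.33 at days 0 and 2, 1 at day 8), the CSE-deletion
#'   phenotype.
#'
#' @return A named list of [strain_profile()] objects.
#' @export
builtin_profiles <- function() {
  list(
    control = strain_profile("control",
                             suppression = c("0" = 0.33, "2" = 0.33,
                                             "8" = 0.33)),
    cbs_like = strain_profile("cbs_like",
                              suppression = c("0" = 1, "2" = 1, "8" = 1)),
    cse_like = strain_profile("cse_like",
                              suppression = c("0" = 0.33, "2" = 0.33,
                                              "8" = 1))
  )
}

#' Synthetic-experiment configuration
#'
#' @param profiles List of [strain_profile()] objects (default
#'   [builtin_profiles()]).
#' @param n_males_per_group Males per strain x condition x time point
#'   (default 20, the study design).
#' @param window Observation window in seconds (default 300).
#' @param timepoints Time-point labels; every profile must define a
#'   suppression multiplier for each.
#' @param timepoint_unit `"days"` or `"minutes"`.
#' @param mean_bout Mean courtship bout length in seconds for the renewal
#'   process (default 5).
#' @param seed Master seed recorded in all outputs.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(profiles = builtin_profiles(),
                         n_males_per_group = 20, window = 300,
                         timepoints = c("0", "2", "8"),
                         timepoint_unit = "days", mean_bout = 5,
                         seed = 1L) {
  if (n_males_per_group < 1L) {
    stop("n_males_per_group must be at least 1", call. = FALSE)
  }
  stopifnot(window > 0, mean_bout > 0, length(timepoints) >= 1L,
            timepoint_unit %in% c("minutes", "days"))
  timepoints <- as.character(timepoints)
  for (p in profiles) {
    if (!inherits(p, "strain_profile")) {
      stop("profiles must be strain_profile objects", call. = FALSE)
    }
    missing_tp <- setdiff(timepoints, names(p$suppression))
    if (length(missing_tp)) {
      stop(sprintf("profile '%s' lacks suppression multiplier(s) for time point(s) %s",
                   p$name, paste(missing_tp, collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(profiles = profiles,
                 n_males_per_group = as.integer(n_males_per_group),
                 window = window, timepoints = timepoints,
                 timepoint_unit = timepoint_unit, mean_bout = mean_bout,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Lay bouts as an alternating renewal process (exponential on/off with the
# configured mean bout length), rescaled so the union of bouts covers
# exactly frac * window seconds. The resulting CI is exactly 100 * frac.
.lay_bouts <- function(frac, window, mean_bout) {
  target <- frac * window
  if (target <= 0) return(matrix(numeric(0), ncol = 2,
                                 dimnames = list(NULL, c("start", "end"))))
  if (target >= window) {
    return(matrix(c(0, window), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  lens <- stats::rexp(max(2L, ceiling(target / mean_bout) + 4L),
                      rate = 1 / mean_bout)
  while (sum(lens) < target) {
    lens <- c(lens, stats::rexp(8L, rate = 1 / mean_bout))
  }
  k <- which(cumsum(lens) >= target)[1L]
  lens <- lens[seq_len(k)]
  lens <- lens * (target / sum(lens))
  gaps <- stats::rexp(k + 1L, rate = 1 / mean_bout)
  gaps <- gaps * ((window - target) / sum(gaps))
  starts <- cumsum(gaps)[seq_len(k)] + c(0, cumsum(lens))[seq_len(k)]
  cbind(start = starts, end = starts + lens)
}

#' Draw per-male courtship-index samples for one group
#'
#' The Beta layer of the generator: per-male courtship fractions drawn
#' from `Beta(mu * c, (1 - mu) * c)` with `mu` the profile's naive mean
#' (times the time point's suppression multiplier for trained males) and
#' `c` the concentration. Since bout placement reproduces the drawn
#' fraction exactly, these values are the CIs the ethogram analysis will
#' recover.
#'
#' @param profile A [strain_profile()].
#' @param timepoint Time-point label (must be in the profile's
#'   suppression map).
#' @param condition `"naive"` or `"trained"`.
#' @param n Number of males.
#' @param seed Optional seed.
#' @return Numeric vector of CI percentages.
#' @export
r_ci_sample <- function(profile, timepoint, condition, n, seed = NULL) {
  stopifnot(inherits(profile, "strain_profile"),
            condition %in% .CONDITIONS, n >= 1L)
  timepoint <- as.character(timepoint)
  if (!timepoint %in% names(profile$suppression)) {
    stop("no suppression multiplier for time point ", timepoint,
         call. = FALSE)
  }
  mult <- if (condition == "trained") profile$suppression[[timepoint]] else 1
  mu <- profile$naive_ci_mean / 100 * mult
  conc <- profile$naive_ci_concentration
  if (!is.null(seed)) set.seed(seed)
  if (mu <= 0) return(rep(0, n))
  if (mu >= 1) return(rep(100, n))
  100 * stats::rbeta(n, mu * conc, (1 - mu) * conc)
}

#' Generate a synthetic courtship ethogram dataset
#'
#' For every profile x time point x condition x male, draws a courtship
#' fraction from the Beta layer and lays bouts down as an alternating
#' renewal process covering exactly that fraction of the window. Identical
#' seeds give bit-identical output.
#'
#' @param config A [synth_config()].
#' @return A per-male observation tibble in the [read_ethograms()] schema
#'   (with `bouts` list column and `ci`).
#' @export
generate_ethograms <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  rows <- list()
  idx <- 0L
  for (p in config$profiles) {
    for (tp in config$timepoints) {
      for (cond in .CONDITIONS) {
        cis <- r_ci_sample(p, tp, cond, config$n_males_per_group)
        for (j in seq_len(config$n_males_per_group)) {
          idx <- idx + 1L
          b <- .lay_bouts(cis[j] / 100, config$window, config$mean_bout)
          rows[[idx]] <- tibble::tibble(
            male_id = sprintf("%s_t%s_%s_m%02d", p$name, tp, cond, j),
            strain = p$name, condition = cond, timepoint = tp,
            timepoint_unit = config$timepoint_unit,
            window = config$window, bouts = list(b),
            ci = compute_ci(b, config$window))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate binomial T-maze olfactory replicates
#'
#' Each replicate releases `n_flies_per_rep` males; the number choosing
#' the odorant arm is `Binomial(n_flies_per_rep, p_attract)`. Defaults
#' mirror the study design: 15 flies per run, 31 replicates.
#'
#' @param p_attract Per-fly probability of ending in the odorant arm.
#' @param n_flies_per_rep Flies per replicate (default 15).
#' @param n_reps Number of replicates (default 31).
#' @param genotype Genotype label for the output rows.
#' @param seed Optional seed.
#' @return A tibble with `replicate_id`, `genotype`, `n_odor`, `n_total`,
#'   `v`.
#' @export
generate_olfactory <- function(p_attract = 0.2, n_flies_per_rep = 15,
                               n_reps = 31, genotype = "control",
                               seed = NULL) {
  stopifnot(p_attract >= 0, p_attract <= 1, n_flies_per_rep >= 1,
            n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_odor <- stats::rbinom(n_reps, n_flies_per_rep, p_attract)
  tibble::tibble(replicate_id = sprintf("%s_r%02d", genotype,
                                        seq_len(n_reps)),
                 genotype = genotype, n_odor = n_odor,
                 n_total = as.integer(n_flies_per_rep),
                 v = preference_index(n_odor, n_flies_per_rep))
}

#' Write an olfactory replicate CSV
#' @param replicates Tibble with `replicate_id`, `genotype`, `n_odor`,
#'   `n_total`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_olfactory <- function(replicates, path) {
  utils::write.csv(as.data.frame(replicates)[c("replicate_id", "genotype",
                                               "n_odor", "n_total")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic DE tables with planted concordant signal
#'
#' Builds a gene universe, a flat term annotation, and one DE table per
#' contrast. Null genes draw `logFC ~ Normal(0, se)`; planted genes draw a
#' shifted logFC with a gene-level sign held concordant across all
#' contrasts (a fraction `frac_down` down-regulated, emulating the
#' predominance of down-regulation in the deletion strains). P-values are
#' Wald-style, `2 * pnorm(-|logFC| / se)`, so null p-values are uniform;
#' the FDR column is BH-adjusted within each table.
#'
#' Planted genes are drawn from the designated planted terms (each member
#' with probability `plant_prob`) plus `n_extra_planted` genes sampled
#' from the remaining universe.
#'
#' @param n_genes Universe size (default 8000).
#' @param contrasts Character vector of contrast labels (>= 1).
#' @param n_terms Number of annotation terms (default 40).
#' @param term_size_range Min/max genes per term (default 20-80).
#' @param planted_terms Term ids carrying planted signal (subset of the
#'   generated terms `T01..`); `NULL` for none.
#' @param plant_prob Probability a planted-term member is truly perturbed
#'   (default 0.8).
#' @param n_extra_planted Additional planted genes outside the planted
#'   terms (default 0).
#' @param effect_logfc Mean |log2 fold change| of planted genes (default
#'   2).
#' @param effect_sd SD of the planted logFC around the effect (default
#'   0.3).
#' @param se Per-gene logFC standard error driving the Wald p-values
#'   (default 0.25).
#' @param frac_down Fraction of planted genes down-regulated (default 1).
#' @param seed Seed (required for reproducibility; default 1).
#' @return A list with `tables` (named list of DE tibbles), `annotation`
#'   (tibble `gene_id`, `term_id`), and `planted` (tibble `gene_id`,
#'   `sign` — the ground truth).
#' @export
generate_de_tables <- function(n_genes = 8000,
                               contrasts = c("cbs_1", "cbs_2"),
                               n_terms = 40, term_size_range = c(20, 80),
                               planted_terms = "T01", plant_prob = 0.8,
                               n_extra_planted = 0, effect_logfc = 2,
                               effect_sd = 0.3, se = 0.25, frac_down = 1,
                               seed = 1L) {
  stopifnot(n_genes >= 10, length(contrasts) >= 1L, n_terms >= 1L,
            plant_prob >= 0, plant_prob <= 1, effect_logfc > 0, se > 0,
            frac_down >= 0, frac_down <= 1)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  term_ids <- sprintf("T%02d", seq_len(n_terms))
  sizes <- sample(term_size_range[1L]:term_size_range[2L], n_terms,
                  replace = TRUE)
  terms <- lapply(sizes, function(s) sample(genes, s))
  names(terms) <- term_ids
  if (!is.null(planted_terms)) {
    missing_t <- setdiff(planted_terms, term_ids)
    if (length(missing_t)) {
      stop("planted term(s) not in annotation: ",
           paste(missing_t, collapse = ", "), call. = FALSE)
    }
  }
  planted <- character()
  for (tid in planted_terms) {
    g <- terms[[tid]]
    planted <- union(planted, g[stats::runif(length(g)) < plant_prob])
  }
  if (n_extra_planted > 0L) {
    planted <- union(planted, sample(setdiff(genes, planted),
                                     n_extra_planted))
  }
  sgn <- stats::setNames(rep(1, length(planted)), planted)
  if (length(planted)) {
    sgn[stats::runif(length(planted)) < frac_down] <- -1
  }
  tables <- lapply(contrasts, function(ct) {
    lfc <- stats::rnorm(n_genes, 0, se)
    i <- match(planted, genes)
    lfc[i] <- sgn * abs(stats::rnorm(length(planted), effect_logfc,
                                     effect_sd))
    p <- 2 * stats::pnorm(-abs(lfc) / se)
    tibble::tibble(gene_id = genes, logFC = lfc, PValue = p,
                   FDR = stats::p.adjust(p, method = "BH"))
  })
  names(tables) <- contrasts
  annotation <- tibble::tibble(
    gene_id = unlist(terms, use.names = FALSE),
    term_id = rep(term_ids, times = sizes))
  list(tables = tables, annotation = annotation,
       planted = tibble::tibble(gene_id = planted, sign = unname(sgn)))
}

#' Write a flat annotation TSV
#' @param annotation Tibble with `gene_id`, `term_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(as.data.frame(annotation), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
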