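# Deterministic pipeline drivers over the analysis stages. Each driver
# takes a validated flat configuration, checks its inputs before writing
# anything, derives child seeds from the master seed, echoes the
# configuration used into the output directory, and writes fixed-schema
# TSV/CSV outputs. Rerunning a driver with an identical configuration and
# seed produces byte-identical files.

.RUN_DEFAULTS <- list(
  out_dir = ".",
  ethogram_csv = NULL,
  olfactory_csv = NULL,
  de_paths = NULL,          # named character vector: contrast -> TSV path
  annotation_tsv = NULL,
  de_groups = NULL,         # named list: group -> contrast labels
  control_strains = "control",
  control_genotype = "control",
  n_perm = 10000,
  alpha = 0.05,
  fdr_threshold = 0.05,
  concordance = "strict",
  n_males_per_group = 20,
  seed = 1L
)

#' Build and validate a pipeline run configuration
#'
#' Flat key-value configuration shared by the `run_*()` drivers. Unknown
#' keys are errors (fail fast); defaults follow the study's stated
#' analysis parameters: 10000 permutations, rejection at `alpha_R < 0.05`,
#' FDR threshold 0.05, strict concordance.
#'
#' @param ... Named settings overriding the defaults; see
#'   `courtsupp:::.RUN_DEFAULTS` for the full key list (`out_dir`,
#'   `ethogram_csv`, `olfactory_csv`, `de_paths`, `annotation_tsv`,
#'   `de_groups`, `control_strains`, `control_genotype`, `n_perm`,
#'   `alpha`, `fdr_threshold`, `concordance`, `n_males_per_group`,
#'   `seed`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) && (is.null(names(user)) || any(names(user) == ""))) {
    stop("all configuration settings must be named", call. = FALSE)
  }
  unknown <- setdiff(names(user), names(.RUN_DEFAULTS))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(.RUN_DEFAULTS, user, keep.null = TRUE)
  stopifnot(cfg$n_perm >= 1, cfg$alpha > 0, cfg$alpha < 1,
            cfg$fdr_threshold > 0, cfg$fdr_threshold < 1,
            cfg$concordance %in% c("strict", "lenient"))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# echo the configuration into the output directory as sorted key=value
# lines so every run is self-describing
.echo_config <- function(cfg, out_dir, stage) {
  flat <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.null(v)) {
      "NULL"
    } else if (is.list(v)) {
      paste(vapply(names(v), function(n) {
        paste0(n, ":", paste(v[[n]], collapse = "+"))
      }, character(1L)), collapse = ";")
    } else {
      paste(format(v, digits = 15), collapse = ",")
    }
  }, character(1L))
  lines <- paste0(sort(names(flat)), "=", flat[sort(names(flat))])
  writeLines(c(paste0("stage=", stage), lines),
             file.path(out_dir, paste0("config_", stage, ".txt")))
}

.child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

.ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

#' Simulate a full synthetic dataset to disk
#'
#' Writes a courtship ethogram CSV (built-in phenotype profiles at days
#' 0/2/8), an olfactory CSV (all genotypes sharing the control attraction
#' probability, as all strains retain normal repulsion), and one DE TSV
#' per contrast plus the annotation and planted-truth TSVs. All filenames
#' carry a `synthetic_` prefix.
#'
#' @param config A [run_config()]; uses `out_dir`, `seed`,
#'   `n_males_per_group`.
#' @return Invisibly, a named character vector of the written paths.
#' @export
run_simulate <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- .ensure_dir(config$out_dir)
  seeds <- .child_seeds(config$seed, 8L)

  eth <- generate_ethograms(synth_config(
    n_males_per_group = config$n_males_per_group, seed = seeds[1L]))
  paths <- c(ethograms = file.path(out, "synthetic_ethograms.csv"))
  write_ethograms(eth, paths[["ethograms"]])

  genotypes <- c("control", "cbs_like", "cse_like", "double_like")
  olf <- do.call(rbind, lapply(seq_along(genotypes), function(i) {
    generate_olfactory(genotype = genotypes[i], seed = seeds[1L + i])
  }))
  paths[["olfactory"]] <- file.path(out, "synthetic_olfactory.csv")
  write_olfactory(olf, paths[["olfactory"]])

  de <- generate_de_tables(contrasts = c("cbs_1", "cbs_2", "dd_1", "dd_2",
                                         "cse"),
                           planted_terms = c("T01", "T02"),
                           frac_down = 0.85, seed = seeds[6L])
  for (ct in names(de$tables)) {
    paths[[paste0("de_", ct)]] <-
      file.path(out, paste0("synthetic_de_", ct, ".tsv"))
    write_de_table(de$tables[[ct]], paths[[paste0("de_", ct)]])
  }
  paths[["annotation"]] <- file.path(out, "synthetic_annotation.tsv")
  write_annotation(de$annotation, paths[["annotation"]])
  paths[["planted"]] <- file.path(out, "synthetic_planted_truth.tsv")
  utils::write.table(as.data.frame(de$planted), paths[["planted"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  .echo_config(config, out, "simulate")
  invisible(paths)
}

#' Behavioral stage: ethogram CSV to learning-index time course
#'
#' Reads the ethogram CSV, aggregates per-male CIs into groups, runs
#' [li_timecourse()] with the configured controls, permutation count and
#' master seed, and writes `timecourse.tsv`.
#'
#' @param config A [run_config()]; uses `ethogram_csv`, `control_strains`,
#'   `n_perm`, `alpha`, `seed`, `out_dir`.
#' @return The time-course tibble, invisibly.
#' @export
run_behavior <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$ethogram_csv) || !file.exists(config$ethogram_csv)) {
    stop("ethogram_csv missing or not found: ",
         if (is.null(config$ethogram_csv)) "(unset)" else config$ethogram_csv,
         call. = FALSE)
  }
  obs <- read_ethograms(config$ethogram_csv)
  groups <- aggregate_groups(obs)
  tc <- li_timecourse(groups, control_strains = config$control_strains,
                      n_perm = config$n_perm, alpha = config$alpha,
                      seed = config$seed)
  out <- .ensure_dir(config$out_dir)
  write_timecourse(tc, file.path(out, "timecourse.tsv"))
  .echo_config(config, out, "behavior")
  invisible(tc)
}

#' Olfactory stage: replicate CSV to preference report
#'
#' @param config A [run_config()]; uses `olfactory_csv`,
#'   `control_genotype`, `out_dir`.
#' @return The report tibble, invisibly.
#' @export
run_olfactory <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$olfactory_csv) || !file.exists(config$olfactory_csv)) {
    stop("olfactory_csv missing or not found: ",
         if (is.null(config$olfactory_csv)) "(unset)" else config$olfactory_csv,
         call. = FALSE)
  }
  reps <- read_olfactory(config$olfactory_csv)
  rep_tab <- olfactory_report(reps, control = config$control_genotype)
  out <- .ensure_dir(config$out_dir)
  utils::write.table(as.data.frame(rep_tab), file.path(out, "olfactory_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  .echo_config(config, out, "olfactory")
  invisible(rep_tab)
}

#' DE set stage: contrast tables to concordance, partition and enrichment
#'
#' For each configured contrast group, selects direction-consistent genes
#' (singleton groups fall back to plain significance filtering), writes
#' per-group down/up counts (`de_counts.tsv`), the Venn partition of the
#' down- and up-regulated group sets (`venn_down.tsv`, `venn_up.tsv`),
#' and one Fisher enrichment TSV per group and direction against the
#' expressed-gene universe of that group's first table.
#'
#' @param config A [run_config()]; uses `de_paths`, `de_groups`,
#'   `annotation_tsv`, `fdr_threshold`, `concordance`, `out_dir`.
#' @return Invisibly, a list with `counts`, `venn_down`, `venn_up`,
#'   `enrichment` (named list of tibbles).
#' @export
run_degsets <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$de_paths) || !length(config$de_paths)) {
    stop("de_paths unset", call. = FALSE)
  }
  missing_f <- config$de_paths[!file.exists(config$de_paths)]
  if (length(missing_f)) {
    stop("DE table(s) not found: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$annotation_tsv) || !file.exists(config$annotation_tsv)) {
    stop("annotation_tsv missing or not found", call. = FALSE)
  }
  tables <- lapply(names(config$de_paths), function(ct) {
    read_de_table(config$de_paths[[ct]], contrast = ct)
  })
  names(tables) <- names(config$de_paths)
  annotation <- read_annotation(config$annotation_tsv)
  groups <- config$de_groups
  if (is.null(groups)) groups <- as.list(stats::setNames(names(tables),
                                                         names(tables)))

  group_sets <- list()
  count_rows <- list()
  for (g in names(groups)) {
    members <- groups[[g]]
    if (!all(members %in% names(tables))) {
      stop("de_groups refers to unknown contrast(s) in group ", g,
           call. = FALSE)
    }
    for (dir in c("down", "up")) {
      set <- if (length(members) >= 2L) {
        consistent_genes(tables[members], fdr_threshold = config$fdr_threshold,
                         direction = dir, mode = config$concordance)
      } else {
        significant_genes(tables[[members]],
                          fdr_threshold = config$fdr_threshold,
                          direction = dir)
      }
      group_sets[[paste(g, dir, sep = ".")]] <- set
      count_rows[[paste(g, dir, sep = ".")]] <-
        tibble::tibble(group = g, direction = dir, n_genes = length(set))
    }
  }
  counts <- do.call(rbind, count_rows)

  out <- .ensure_dir(config$out_dir)
  utils::write.table(as.data.frame(counts), file.path(out, "de_counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  venns <- list()
  for (dir in c("down", "up")) {
    sets <- group_sets[paste(names(groups), dir, sep = ".")]
    names(sets) <- names(groups)
    vp <- venn_partition(sets)
    venns[[dir]] <- vp
    utils::write.table(data.frame(region = vp$region, count = vp$count),
                       file.path(out, paste0("venn_", dir, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  enr <- list()
  for (g in names(groups)) {
    first_tab <- tables[[groups[[g]][1L]]]
    for (dir in c("down", "up")) {
      key <- paste(g, dir, sep = ".")
      e <- fisher_enrichment(group_sets[[key]], annotation,
                             fdr_threshold = config$fdr_threshold,
                             de_table = first_tab)
      enr[[key]] <- e
      utils::write.table(as.data.frame(e),
                         file.path(out, paste0("enrichment_", g, "_", dir,
                                               ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  .echo_config(config, out, "degsets")
  invisible(list(counts = counts, venn_down = venns$down,
                 venn_up = venns$up, enrichment = enr))
}
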