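# Learning/memory time course: one analysis row per strain x time point,
# with the three contrast families of the courtship-suppression figures:
# (i) trained vs naive within strain (did the strain learn?), (ii) LI vs
# each control strain at the same time point, (iii) delayed vs immediate
# retention within strain.

#' Learning-index time course with randomization inference
#'
#' For every strain x time point present in `groups`, computes the learning
#' index and three families of two-sided randomization tests: the
#' within-strain trained-vs-naive test, the LI contrast against each
#' control strain at the same time point, and the retention contrast
#' against the strain's earliest (baseline) time point. Flags mirror the
#' figure annotations: one symbol per control strain when the strain's LI
#' is significantly below that control's, and `#` when the delayed LI is
#' significantly below the baseline LI.
#'
#' @param groups Group tibble from [aggregate_groups()].
#' @param control_strains Character vector of control strain labels to
#'   contrast against (each at the same time point).
#' @param n_perm Permutations per test (default 10000).
#' @param alpha Rejection level for the flags (default 0.05).
#' @param seed Master seed; per-test child seeds are derived from it
#'   deterministically.
#' @param baseline_timepoint Optional label of the immediate test used for
#'   retention contrasts; default: the numerically smallest time point of
#'   each strain.
#' @return A tibble with one row per strain x time point: sample sizes,
#'   mean CIs, `li`, `alpha_within`, one `alpha_vs_<control>` column per
#'   control strain, `alpha_retention`, `flags` and `status`
#'   (`"ok"`/`"not_testable"`).
#' @export
li_timecourse <- function(groups, control_strains = character(),
                          n_perm = 10000, alpha = 0.05, seed = NULL,
                          baseline_timepoint = NULL) {
  vs_cols <- if (length(control_strains)) {
    paste0("alpha_vs_", control_strains)
  } else {
    character()
  }
  empty <- function() {
    base <- tibble::tibble(strain = character(), timepoint = character(),
                           timepoint_unit = character(), n_na = integer(),
                           n_tr = integer(), ci_na_mean = double(),
                           ci_tr_mean = double(), li = double(),
                           alpha_within = double())
    for (cc in vs_cols) base[[cc]] <- double()
    base$alpha_retention <- double()
    base$flags <- character()
    base$status <- character()
    base
  }
  if (nrow(groups) == 0L) return(empty())

  seed <- .draw_seed(seed)
  set.seed(seed)
  seed_pool <- sample.int(2147483646L, 16384L)
  used <- 0L
  next_seed <- function() {
    used <<- used + 1L
    seed_pool[[used]]
  }

  sample_of <- function(strain, timepoint, condition) {
    i <- which(groups$strain == strain & groups$timepoint == timepoint &
                 groups$condition == condition)
    if (length(i) == 0L) NULL else groups$cis[[i[1L]]]
  }

  keys <- unique(groups[c("strain", "timepoint", "timepoint_unit")])
  tp_num <- suppressWarnings(as.numeric(keys$timepoint))
  keys <- keys[order(keys$strain, tp_num, keys$timepoint), ]
  tp_num <- suppressWarnings(as.numeric(keys$timepoint))

  # a strain/timepoint is testable when both cohorts exist with n >= 2
  testable <- function(strain, timepoint) {
    na <- sample_of(strain, timepoint, "naive")
    tr <- sample_of(strain, timepoint, "trained")
    !is.null(na) && !is.null(tr) && length(na) >= 2L && length(tr) >= 2L &&
      mean(na) > 0
  }

  baseline_of <- function(strain) {
    if (!is.null(baseline_timepoint)) return(baseline_timepoint)
    i <- which(keys$strain == strain)
    i <- i[vapply(i, function(j) testable(strain, keys$timepoint[j]), logical(1L))]
    if (length(i) == 0L) return(NULL)
    keys$timepoint[i[order(tp_num[i])][1L]]
  }

  rows <- vector("list", nrow(keys))
  for (r in seq_len(nrow(keys))) {
    st <- keys$strain[r]
    tp <- keys$timepoint[r]
    na <- sample_of(st, tp, "naive")
    tr <- sample_of(st, tp, "trained")
    row <- tibble::tibble(strain = st, timepoint = tp,
                          timepoint_unit = keys$timepoint_unit[r],
                          n_na = length(na), n_tr = length(tr),
                          ci_na_mean = NA_real_, ci_tr_mean = NA_real_,
                          li = NA_real_, alpha_within = NA_real_)
    for (cc in vs_cols) row[[cc]] <- NA_real_
    row$alpha_retention <- NA_real_
    row$flags <- ""
    row$status <- "not_testable"

    if (!testable(st, tp)) {
      rows[[r]] <- row
      next
    }
    lr <- learning_index(na, tr)
    row$ci_na_mean <- lr$ci_na_mean
    row$ci_tr_mean <- lr$ci_tr_mean
    row$li <- lr$li
    row$status <- "ok"
    row$alpha_within <-
      randomization_two_sample(na, tr, n_perm = n_perm, seed = next_seed(),
                               exhaustive = "never")$alpha_R
    flags <- character()
    flag_symbols <- c("*", "&", "%", "@")[seq_along(control_strains)]
    for (ci in seq_along(control_strains)) {
      ctrl <- control_strains[ci]
      if (identical(ctrl, st) || !testable(ctrl, tp)) next
      ctrl_na <- sample_of(ctrl, tp, "naive")
      ctrl_tr <- sample_of(ctrl, tp, "trained")
      res <- randomization_li_contrast(list(ci_na = na, ci_tr = tr),
                                       list(ci_na = ctrl_na, ci_tr = ctrl_tr),
                                       n_perm = n_perm, seed = next_seed())
      row[[vs_cols[ci]]] <- res$alpha_R
      ctrl_li <- learning_index(ctrl_na, ctrl_tr)$li
      if (res$alpha_R < alpha && lr$li < ctrl_li) {
        flags <- c(flags, flag_symbols[ci])
      }
    }
    bl <- baseline_of(st)
    if (!is.null(bl) && !identical(bl, tp) && testable(st, bl)) {
      bl_na <- sample_of(st, bl, "naive")
      bl_tr <- sample_of(st, bl, "trained")
      res <- retention_contrast(list(ci_na = bl_na, ci_tr = bl_tr),
                                list(ci_na = na, ci_tr = tr),
                                n_perm = n_perm, seed = next_seed())
      row$alpha_retention <- res$alpha_R
      bl_li <- learning_index(bl_na, bl_tr)$li
      if (res$alpha_R < alpha && lr$li < bl_li) flags <- c(flags, "#")
    }
    row$flags <- paste(flags, collapse = "")
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}

#' Write a time-course results table as TSV
#'
#' @param timecourse Tibble from [li_timecourse()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(timecourse, path) {
  utils::write.table(as.data.frame(timecourse), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
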